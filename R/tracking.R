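## Linear-assignment tracking: optimal one-to-one frame-to-frame linking
## minimizing total squared displacement, with birth/death alternatives at
## cost max_link_um^2, then gap closing.  The assignment core is the
## shortest-augmenting-path Hungarian algorithm with potentials (O(n^3)).

#' Solve a square linear assignment problem
#'
#' Minimizes `sum(cost[i, p[i]])` over permutations `p`. Infeasible pairs
#' should be encoded as large finite costs.
#'
#' @param cost square numeric matrix.
#' @return Integer vector `p` with `p[i]` the column assigned to row `i`.
#' @examples
#' solveAssignment(rbind(c(1, 10), c(10, 1)))
#' @export
solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopIfNot(is.matrix(cost) && n == ncol(cost), "'cost' must be square")
  if (n == 0) return(integer(0))
  ## columns are offset by 1: index 1 is the virtual start column
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)         # p[j]: row currently assigned to column j-1
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  out <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) out[p[j]] <- j - 1L
  out
}

#' Linking configuration
#'
#' @param max_link_um maximum frame-to-frame displacement (um); larger
#'   moves break the track (birth/death cost is `max_link_um^2`).
#' @param max_gap maximum number of missed frames bridged by gap closing.
#' @return A validated list of class `LinkingConfig`.
#' @export
linkingConfig <- function(max_link_um = 10, max_gap = 2L) {
  stopIfNot(max_link_um > 0, "'max_link_um' must be > 0")
  stopIfNot(max_gap >= 0, "'max_gap' must be >= 0")
  structure(list(max_link_um = max_link_um, max_gap = as.integer(max_gap),
                 cost = "squared_euclidean"),
            class = "LinkingConfig")
}

## Optimal links between two detection sets; returns integer vector of
## length nrow(a): index into b, or NA (death).
linkPair <- function(a, b, max_link_um) {
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  bcost <- max_link_um^2
  BIG <- (max(d2[is.finite(d2)], bcost) + 1) * 1e6
  d2[d2 > bcost] <- BIG
  ## Jaqaman-style augmented square matrix:
  ## rows [real tracks, dummy births], cols [real detections, dummy deaths]
  C <- matrix(BIG, n + m, n + m)
  C[seq_len(n), seq_len(m)] <- d2
  C[cbind(seq_len(n), m + seq_len(n))] <- bcost   # deaths
  C[cbind(n + seq_len(m), seq_len(m))] <- bcost   # births
  C[n + seq_len(m), m + seq_len(n)] <- 0          # dummy-dummy complements
  ass <- solveAssignment(C)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- ass[i]
    if (j <= m && d2[i, j] < BIG) out[i] <- j
  }
  out
}

#' Link per-frame detections into tracks
#'
#' For each consecutive frame pair, detections are linked by an optimal
#' one-to-one assignment minimizing total squared Euclidean distance, with
#' per-detection birth/death alternatives at cost `max_link_um^2` (so no
#' link longer than `max_link_um` is ever made). Track ends are then
#' bridged to later track starts within `max_gap` missed frames by a
#' second assignment round.
#'
#' @param detections data.frame with columns `frame`, `x_um`, `y_um`
#'   (additional columns are carried along).
#' @param config a [linkingConfig()].
#' @param frame_interval_s seconds per frame, used to fill `t_s`.
#' @return data.frame (id, frame, t_s, x_um, y_um) ordered by id, frame.
#' @export
linkFrames <- function(detections, config = linkingConfig(),
                       frame_interval_s = NA_real_) {
  stopIfNot(all(c("frame", "x_um", "y_um") %in% names(detections)),
            "'detections' needs frame, x_um, y_um")
  if (!nrow(detections))
    return(data.frame(id = integer(0), frame = integer(0), t_s = numeric(0),
                      x_um = numeric(0), y_um = numeric(0)))
  frames <- sort(unique(detections$frame))
  bylist <- split(detections, detections$frame)
  ## active track bookkeeping
  det_id <- rep(NA_integer_, nrow(detections))
  rowids <- split(seq_len(nrow(detections)), detections$frame)
  next_id <- 1L
  prev_rows <- NULL
  for (fi in seq_along(frames)) {
    f <- as.character(frames[fi])
    cur <- bylist[[f]]
    cur_rows <- rowids[[f]]
    if (is.null(prev_rows)) {
      det_id[cur_rows] <- seq_len(nrow(cur))
      next_id <- nrow(cur) + 1L
    } else {
      prev <- detections[prev_rows, , drop = FALSE]
      contiguous <- frames[fi] == frames[fi - 1] + 1
      links <- if (contiguous)
        linkPair(cbind(prev$x_um, prev$y_um), cbind(cur$x_um, cur$y_um),
                 config$max_link_um)
      else rep(NA_integer_, nrow(prev))
      taken <- stats::na.omit(links)
      for (i in seq_along(links)) {
        if (!is.na(links[i]))
          det_id[cur_rows[links[i]]] <- det_id[prev_rows[i]]
      }
      born <- setdiff(seq_len(nrow(cur)), taken)
      if (length(born)) {
        det_id[cur_rows[born]] <- next_id + seq_along(born) - 1L
        next_id <- next_id + length(born)
      }
    }
    prev_rows <- cur_rows
  }
  out <- data.frame(id = det_id, frame = detections$frame,
                    t_s = if (is.na(frame_interval_s)) NA_real_
                          else (detections$frame - 1) * frame_interval_s,
                    x_um = detections$x_um, y_um = detections$y_um)

  ## gap closing: ends joined to starts within max_gap missed frames
  if (config$max_gap > 0) out <- closeGaps(out, config)
  out[order(out$id, out$frame), , drop = FALSE]
}

closeGaps <- function(tracks, config) {
  repeat {
    info <- do.call(rbind, lapply(split(tracks, tracks$id), function(g) {
      g <- g[order(g$frame), ]
      data.frame(id = g$id[1], f0 = g$frame[1], f1 = g$frame[nrow(g)],
                 x0 = g$x_um[1], y0 = g$y_um[1],
                 x1 = g$x_um[nrow(g)], y1 = g$y_um[nrow(g)])
    }))
    n <- nrow(info)
    if (n < 2) return(tracks)
    ## candidate joins: end of i -> start of j
    cost <- matrix(Inf, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      gap <- info$f0[j] - info$f1[i] - 1
      if (gap < 1 || gap > config$max_gap) next
      d2 <- (info$x1[i] - info$x0[j])^2 + (info$y1[i] - info$y0[j])^2
      if (sqrt(d2) > config$max_link_um * (gap + 1)) next
      cost[i, j] <- d2
    }
    if (!any(is.finite(cost))) return(tracks)
    ## greedy best-join first (iterated), deterministic
    k <- which(cost == min(cost), arr.ind = TRUE)[1, , drop = TRUE]
    from <- info$id[k[1]]; to <- info$id[k[2]]
    tracks$id[tracks$id == to] <- from
  }
}

#' Motility metrics of one track
#'
#' Total distance is the sum of step lengths, displacement the first-to-
#' last Euclidean distance, and the meandering index their ratio
#' (0 by convention for a zero-length path, flagged). Tracks displacing
#' less than `min_displacement_um` (default 10 um) are flagged as excluded
#' from condition comparisons.
#'
#' @param track data.frame with `x_um`, `y_um` ordered by frame (>= 2 rows).
#' @param min_displacement_um inclusion threshold (um).
#' @return `list(total_distance_um, displacement_um, meandering_index,
#'   included, degenerate)`.
#' @examples
#' trackMetrics(data.frame(x_um = c(0, 9, 9), y_um = c(0, 0, 12)))
#' @export
trackMetrics <- function(track, min_displacement_um = 10) {
  stopIfNot(nrow(track) >= 2, "track needs at least 2 points")
  p <- cbind(track$x_um, track$y_um)
  steps <- vecNorm(diff(p))
  total <- sum(steps)
  disp <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  mi <- if (total == 0) 0 else disp / total
  list(total_distance_um = total, displacement_um = disp,
       meandering_index = mi,
       included = disp >= min_displacement_um,
       degenerate = total == 0)
}

#' Per-step speeds and windowed path length of a track
#'
#' @param track data.frame with `t_s`, `x_um`, `y_um` ordered by time.
#' @param window_s optional trailing-window length (s); when supplied, the
#'   output includes, for each timepoint, the path length accumulated over
#'   `[t - window_s, t]`.
#' @return `list(speeds_um_min = <per-step data.frame>, windowed =
#'   <data.frame or NULL>)`. Step speed is step length / step duration,
#'   in um/min.
#' @export
speedSeries <- function(track, window_s = NULL) {
  stopIfNot(nrow(track) >= 2, "track needs at least 2 points")
  o <- order(track$t_s)
  t <- track$t_s[o]; x <- track$x_um[o]; y <- track$y_um[o]
  dtv <- diff(t)
  stopIfNot(all(dtv > 0), "zero or negative step interval")
  stepl <- sqrt(diff(x)^2 + diff(y)^2)
  sp <- data.frame(t_s = t[-1], step_um = stepl,
                   speed_um_min = stepl / dtv * 60)
  win <- NULL
  if (!is.null(window_s)) {
    stopIfNot(window_s <= t[length(t)] - t[1],
              "'window_s' exceeds the track duration")
    path <- vapply(seq_along(t), function(i) {
      inw <- which(sp$t_s <= t[i] & sp$t_s > t[i] - window_s)
      sum(sp$step_um[inw])
    }, numeric(1))
    win <- data.frame(t_s = t, path_um = path)
  }
  list(speeds_um_min = sp, windowed = win)
}

#' Histogram and Gaussian fit of a speed distribution
#'
#' Bins the speeds, then least-squares fits a Gaussian
#' \eqn{A exp(-(x-\mu)^2 / 2\sigma^2)} to the bin centres and counts. A
#' degenerate sample (all speeds equal) returns the sample mean with sd 0,
#' flagged; a poor fit (R^2 < 0.8, e.g. a bimodal sample) is flagged too.
#'
#' @param speeds numeric vector (um/min), length >= 10.
#' @param bin_width histogram bin width (um/min).
#' @return `list(histogram = data.frame(mid, count), mean, sd, r_squared,
#'   flagged)`.
#' @export
speedHistogramFit <- function(speeds, bin_width = 0.2) {
  stopIfNot(length(speeds) >= 10, "need at least 10 speeds")
  if (max(speeds) == min(speeds)) {
    return(list(histogram = data.frame(mid = speeds[1], count = length(speeds)),
                mean = speeds[1], sd = 0, r_squared = NA_real_, flagged = TRUE))
  }
  breaks <- seq(floor(min(speeds) / bin_width) * bin_width,
                ceiling(max(speeds) / bin_width) * bin_width, by = bin_width)
  h <- graphics::hist(speeds, breaks = breaks, plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts)
  start <- list(A = max(df$count), mu = mean(speeds), sig = stats::sd(speeds))
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(count ~ A * exp(-(mid - mu)^2 / (2 * sig^2)), data = df,
                 start = start,
                 control = stats::nls.control(warnOnly = TRUE, maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(histogram = df, mean = mean(speeds), sd = stats::sd(speeds),
                r_squared = NA_real_, flagged = TRUE))
  }
  pred <- stats::predict(fit)
  r2 <- 1 - sum((df$count - pred)^2) / sum((df$count - mean(df$count))^2)
  cf <- stats::coef(fit)
  list(histogram = df, mean = unname(cf["mu"]), sd = abs(unname(cf["sig"])),
       r_squared = r2, flagged = r2 < 0.8)
}

#' Relative distance of a track to a target over a trailing window
#'
#' Computes the per-frame Euclidean distance between the track and a target
#' (a fixed point, or a per-frame position series), normalized to the
#' distance at the window start (so the series starts at 1.0).
#'
#' @param track data.frame `frame`, `x_um`, `y_um` (ordered).
#' @param target length-2 numeric `c(x_um, y_um)`, or a data.frame with
#'   `frame`, `x_um`, `y_um` covering the track's frames.
#' @param eps_um floor for the normalizing distance (default 0.1 um); a
#'   floored normalization is flagged.
#' @return data.frame `frame`, `distance_um`, `relative`; attribute
#'   `flagged`.
#' @export
distanceToTarget <- function(track, target, eps_um = 0.1) {
  if (is.data.frame(target)) {
    m <- match(track$frame, target$frame)
    stopIfNot(!anyNA(m), "target must be defined on the track's frames")
    tx <- target$x_um[m]; ty <- target$y_um[m]
  } else {
    tx <- target[1]; ty <- target[2]
  }
  d <- sqrt((track$x_um - tx)^2 + (track$y_um - ty)^2)
  d0 <- d[1]
  flagged <- d0 < eps_um
  out <- data.frame(frame = track$frame, distance_um = d,
                    relative = d / max(d0, eps_um))
  attr(out, "flagged") <- flagged
  out
}
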