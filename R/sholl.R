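#' Sholl profile of a ramified cell across timepoints
#'
#' Counts crossings of the cell's skeleton with concentric circles in
#' increasing `step_um` intervals (default 10 um) centred on the soma
#' centroid, at each of the supplied timepoints (the classic protocol uses
#' five), and sums the per-radius crossings across timepoints.
#'
#' Crossings are counted analytically: each traced skeleton polyline
#' segment is intersected with each circle by solving the quadratic
#' \eqn{|p_0 + t v - c|^2 = r^2} for \eqn{t \in (0, 1]}; every transversal
#' intersection is one crossing.
#'
#' @param masks list of [CellMask-class], one per timepoint (default
#'   expectation: 5; override with `n_required`).
#' @param emtb_img,cytosol_img optional channel lists matching `masks`;
#'   only used to reuse [extractDendrites()] tracing (intensities do not
#'   affect crossings). When omitted, zero images are used.
#' @param step_um radius increment (um), > 0.
#' @param n_required number of timepoints the protocol expects (default 5).
#' @return data.frame with columns `radius_um`, `crossings` (integer sums
#'   across timepoints); attributes `cell`, `timepoints`.
#' @export
shollProfile <- function(masks, emtb_img = NULL, cytosol_img = NULL,
                         step_um = 10, n_required = 5L) {
  stopIfNot(step_um > 0, "'step_um' must be > 0")
  stopIfNot(length(masks) >= n_required,
            sprintf("Sholl profile needs %d timepoints, got %d",
                    n_required, length(masks)))
  px <- masks[[1]]@pixel_size_um
  zero <- function(m) matrix(0, m@dim[1], m@dim[2])
  total <- NULL
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    ei <- if (is.null(emtb_img)) zero(m) else emtb_img[[i]]
    ci <- if (is.null(cytosol_img)) zero(m) else cytosol_img[[i]]
    ds <- suppressWarnings(extractDendrites(m, ei, ci))
    cr <- shollCrossings(ds, step_um)
    if (is.null(total)) total <- cr
    else {
      n <- max(length(total), length(cr))
      total <- c(total, rep(0, n - length(total))) + c(cr, rep(0, n - length(cr)))
    }
  }
  out <- data.frame(radius_um = step_um * seq_along(total),
                    crossings = as.integer(total))
  attr(out, "cell") <- masks[[1]]@label
  attr(out, "timepoints") <- length(masks)
  out
}

## Crossing counts for one DendriteSet at radii step, 2*step, ...
shollCrossings <- function(ds, step_um) {
  if (!length(ds@paths)) return(integer(0))
  ctr <- ds@soma_center_um
  rmax <- max(vapply(ds@paths, function(p)
    max(sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)), numeric(1)))
  radii <- seq(step_um, by = step_um,
               length.out = max(1, floor(rmax / step_um) + 1))
  counts <- integer(length(radii))
  for (p in ds@paths) {
    for (ri in seq_along(radii)) {
      counts[ri] <- counts[ri] + segmentCircleCrossings(p, ctr, radii[ri])
    }
  }
  ## trim trailing all-zero radii beyond the arbor
  while (length(counts) > 1 && counts[length(counts)] == 0 &&
         radii[length(counts)] > rmax)
    counts <- counts[-length(counts)]
  counts
}

## Number of transversal intersections of a polyline with a circle.
segmentCircleCrossings <- function(poly, ctr, r) {
  n <- nrow(poly)
  if (n < 2) return(0L)
  total <- 0L
  for (i in seq_len(n - 1)) {
    a <- poly[i, ] - ctr
    v <- poly[i + 1, ] - poly[i, ]
    A <- sum(v^2)
    if (A < 1e-18) next
    B <- 2 * sum(a * v)
    C <- sum(a^2) - r^2
    disc <- B^2 - 4 * A * C
    if (disc <= 0) next                      # miss or tangent: no transversal
    sq <- sqrt(disc)
    for (t in c((-B - sq) / (2 * A), (-B + sq) / (2 * A))) {
      ## half-open (0, 1] so a crossing at a shared vertex counts once
      if (t > 1e-12 && t <= 1) total <- total + 1L
    }
  }
  total
}

#' Aggregate Sholl profiles across cells of a condition
#'
#' Converts each cell's summed crossings to percentages of its total, then
#' averages the percentage profiles over cells (radii aligned; missing
#' radii count as zero).
#'
#' @param profiles list of data.frames from [shollProfile()].
#' @return data.frame `radius_um`, `pct_crossings` (mean percentage per
#'   radius across cells), `n_cells`.
#' @export
shollSummary <- function(profiles) {
  stopIfNot(length(profiles) > 0, "no profiles supplied")
  rmax <- max(vapply(profiles, function(p) max(p$radius_um), numeric(1)))
  step <- profiles[[1]]$radius_um[1]
  radii <- seq(step, rmax, by = step)
  pct <- sapply(profiles, function(p) {
    v <- rep(0, length(radii))
    v[match(p$radius_um, radii)] <- p$crossings
    if (sum(v) > 0) 100 * v / sum(v) else v
  })
  if (is.null(dim(pct))) pct <- matrix(pct, ncol = length(profiles))
  data.frame(radius_um = radii, pct_crossings = rowMeans(pct),
             n_cells = length(profiles))
}
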