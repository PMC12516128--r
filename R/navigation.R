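#' Detect cell-obstacle encounters during directed migration
#'
#' An encounter opens at the first frame in which the MTOC is within
#' `encounter_dist_um` of an obstacle nucleus boundary and the obstacle
#' lies ahead of the MTOC along the approach axis (the unit vector from
#' the MTOC toward the nearest point of the wound outline, or a fixed
#' supplied axis). One event is opened per cell-obstacle pair.
#'
#' @param mtoc_track data.frame `frame`, `t_s`, `x_um`, `y_um` for the
#'   cell's MTOC (required).
#' @param nucleus_track same shape, for the nucleus.
#' @param obstacles data.frame `id`, `x_um`, `y_um`, `radius_um` (static).
#' @param approach one of: a length-2 unit vector (fixed axis), or an
#'   n x 2 matrix of wound-outline vertices (um) from which the axis is
#'   computed per frame.
#' @param encounter_dist_um encounter distance to the obstacle boundary
#'   (default 5).
#' @param cell id recorded in the events.
#' @return data.frame of open events: `cell`, `obstacle`,
#'   `encounter_frame`, `encounter_t_s`, `axis_x`, `axis_y`.
#' @export
detectEncounters <- function(mtoc_track, nucleus_track, obstacles, approach,
                             encounter_dist_um = 5, cell = 1L) {
  stopIfNot(!is.null(mtoc_track) && nrow(mtoc_track) > 0,
            "MTOC track required")
  fixed_axis <- is.numeric(approach) && is.null(dim(approach)) &&
    length(approach) == 2
  o <- order(mtoc_track$frame)
  mx <- mtoc_track$x_um[o]; my <- mtoc_track$y_um[o]
  nfr <- length(mx)
  if (fixed_axis) {
    a <- unitVec(approach)
    ax <- rep(a[1], nfr); ay <- rep(a[2], nfr)
  } else {
    axes <- t(vapply(seq_len(nfr), function(k) {
      unitVec(nearestPointOnPolygon(c(mx[k], my[k]), approach) - c(mx[k], my[k]))
    }, numeric(2)))
    ax <- axes[, 1]; ay <- axes[, 2]
  }
  events <- list()
  for (j in seq_len(nrow(obstacles))) {
    dx <- obstacles$x_um[j] - mx; dy <- obstacles$y_um[j] - my
    cond <- sqrt(dx^2 + dy^2) - obstacles$radius_um[j] <= encounter_dist_um &
      (dx * ax + dy * ay) > 0
    k <- which(cond)[1]
    if (is.na(k)) next
    events[[length(events) + 1]] <- data.frame(
      cell = cell, obstacle = obstacles$id[j],
      encounter_frame = mtoc_track$frame[o][k],
      encounter_t_s = mtoc_track$t_s[o][k],
      axis_x = ax[k], axis_y = ay[k])
  }
  if (!length(events))
    return(data.frame(cell = integer(0), obstacle = integer(0),
                      encounter_frame = integer(0), encounter_t_s = numeric(0),
                      axis_x = numeric(0), axis_y = numeric(0)))
  do.call(rbind, events)
}

#' Score an open navigation event
#'
#' A structure passes the obstacle when its projection onto the approach
#' axis exceeds the obstacle centroid's projection plus the obstacle
#' radius. The decision is whichever of MTOC and nucleus passes first
#' (a same-frame tie scores MTOC-first, documented); the outcome is
#' `success` when the MTOC passes within `window_s` of the encounter,
#' `failure` when at least `window_s` was observed without an MTOC pass,
#' and `censored` when the movie ends earlier. `navigation_time_s` is the
#' MTOC encounter-to-pass duration, set on success.
#'
#' @param event one row from [detectEncounters()].
#' @param mtoc_track,nucleus_track tracks (`frame`, `t_s`, `x_um`, `y_um`).
#' @param obstacles data.frame with the event's obstacle.
#' @param window_s observation window (default 3300 s = 55 min).
#' @return One-row data.frame: the event plus `mtoc_pass_t_s`,
#'   `nucleus_pass_t_s`, `decision`, `outcome`, `navigation_time_s`.
#' @export
scoreEvent <- function(event, mtoc_track, nucleus_track, obstacles,
                       window_s = 3300) {
  ob <- obstacles[obstacles$id == event$obstacle, , drop = FALSE]
  stopIfNot(nrow(ob) == 1, "event obstacle not found")
  a <- c(event$axis_x, event$axis_y)
  thresh <- (ob$x_um * a[1] + ob$y_um * a[2]) + ob$radius_um
  passT <- function(track) {
    sel <- track$frame >= event$encounter_frame
    pr <- track$x_um * a[1] + track$y_um * a[2]
    idx <- which(sel & pr > thresh)
    if (!length(idx)) NA_real_ else track$t_s[min(idx)]
  }
  mt <- passT(mtoc_track)
  nt <- if (!is.null(nucleus_track)) passT(nucleus_track) else NA_real_
  decision <- if (is.na(mt) && is.na(nt)) "none"
    else if (is.na(nt) || (!is.na(mt) && mt <= nt)) "mtoc_first"
    else "nucleus_first"
  observed_s <- max(mtoc_track$t_s) - event$encounter_t_s
  outcome <- if (!is.na(mt) && (mt - event$encounter_t_s) <= window_s) "success"
    else if (observed_s >= window_s) "failure"
    else "censored"
  nav_t <- if (outcome == "success") mt - event$encounter_t_s else NA_real_
  cbind(event,
        data.frame(mtoc_pass_t_s = mt, nucleus_pass_t_s = nt,
                   decision = decision, outcome = outcome,
                   navigation_time_s = nav_t))
}

#' Summarize navigation events
#'
#' @param events data.frame of closed events from [scoreEvent()].
#' @return `list(pct_mtoc_first, success_rate_pct, mean_navigation_time_s,
#'   n_decided, n_outcome, n_success)`: the MTOC-first percentage over
#'   decided events, the success percentage over success + failure
#'   (censored events excluded), and the mean navigation time over
#'   successes (NA when there is none).
#' @examples
#' ev <- data.frame(decision = rep(c("mtoc_first", "nucleus_first"), c(21, 4)),
#'                  outcome = "success", navigation_time_s = 600)
#' navigationSummary(ev)$pct_mtoc_first
#' @export
navigationSummary <- function(events) {
  stopIfNot(nrow(events) >= 1, "no events supplied")
  decided <- events[events$decision %in% c("mtoc_first", "nucleus_first"), ]
  concluded <- events[events$outcome %in% c("success", "failure"), ]
  succ <- events[events$outcome == "success", ]
  list(
    pct_mtoc_first = if (nrow(decided))
      100 * mean(decided$decision == "mtoc_first") else NA_real_,
    success_rate_pct = if (nrow(concluded))
      100 * mean(concluded$outcome == "success") else NA_real_,
    mean_navigation_time_s = if (nrow(succ))
      mean(succ$navigation_time_s) else NA_real_,
    n_decided = nrow(decided), n_outcome = nrow(concluded),
    n_success = nrow(succ))
}

#' Detect and score all navigation events of a synthetic scene
#'
#' Convenience wrapper running [detectEncounters()] and [scoreEvent()] on
#' the ground-truth tracks of a scratch-wound scene.
#'
#' @param truth a [GroundTruth-class] with a wound.
#' @param encounter_dist_um,window_s see the underlying functions.
#' @return data.frame of closed events (possibly 0 rows).
#' @export
navigateScene <- function(truth, encounter_dist_um = 5, window_s = 3300) {
  stopIfNot(nrow(truth@wound) > 0, "scene has no wound")
  poly <- woundPolygon(truth, 1L)
  obs <- truth@obstacles
  out <- list()
  for (i in unique(truth@tracks$id[truth@tracks$entity == "cell"])) {
    mt <- truth@tracks[truth@tracks$entity == "mtoc" & truth@tracks$id == i, ]
    nt <- truth@tracks[truth@tracks$entity == "nucleus" & truth@tracks$id == i, ]
    ev <- detectEncounters(mt, nt, obs, poly,
                           encounter_dist_um = encounter_dist_um, cell = i)
    for (k in seq_len(nrow(ev)))
      out[[length(out) + 1]] <- scoreEvent(ev[k, ], mt, nt, obs,
                                           window_s = window_s)
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Convert ground-truth passage records into scored navigation events
#'
#' Maps the passage bookkeeping of a [GroundTruth-class] (encounter and
#' pass frames realized by the simulation) onto the scored-event schema of
#' [scoreEvent()], applying the same decision, window and censoring rules.
#'
#' @param truth a [GroundTruth-class].
#' @param window_s observation window (default: the generating config's).
#' @return data.frame with `cell`, `obstacle`, `decision`, `outcome`,
#'   `navigation_time_s`.
#' @export
truthNavigationEvents <- function(truth, window_s = NULL) {
  p <- truth@passages
  stopIfNot(nrow(p) > 0, "no passage records in this scene")
  dt <- truth@config@frame_interval_s
  if (is.null(window_s)) window_s <- truth@config@navigation_window_s
  nf <- truth@config@n_frames
  nav_t <- (p$pass_frame - p$encounter_frame) * dt
  observed <- (nf - p$encounter_frame) * dt
  outcome <- ifelse(!is.na(nav_t) & nav_t <= window_s, "success",
                    ifelse(observed >= window_s, "failure", "censored"))
  decision <- ifelse(is.na(p$leader), "none",
                     ifelse(p$leader == "mtoc", "mtoc_first", "nucleus_first"))
  data.frame(cell = p$cell, obstacle = p$obstacle, decision = decision,
             outcome = outcome,
             navigation_time_s = ifelse(outcome == "success", nav_t, NA_real_))
}
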