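## Event-cohort generator: many independent cell-obstacle passages laid out
## in separate lanes, for calibration studies of the navigation scorer at
## event counts far beyond what a single rendered scene can hold.

#' Simulate a cohort of independent obstacle-passage events
#'
#' Each event is one cell approaching one static obstacle nucleus along a
#' fixed wound-directed axis (+x): the MTOC advances with per-frame step
#' lengths drawn at the configured cell speed, pauses at the obstacle, and
#' (for successful events) moves past it so that its encounter-to-pass
#' duration equals a draw from the configured pause distribution; the
#' nucleus trails or leads by a fixed offset according to the drawn
#' MTOC-first outcome. Failed events hold position for the full
#' observation window. Outcome draws respect forced-outcome vectors in the
#' config.
#'
#' @param config a [SceneConfig-class] (condition preset); the slots used
#'   are `frame_interval_s`, `cell_speed_um_min`, `navigation_pause_s`,
#'   `navigation_success_p`, `mtoc_first_p`, `navigation_window_s`,
#'   `obstacle_radius_um`, `rng_seed`.
#' @param n_events number of events.
#' @return list with `tracks` (per event: `mtoc`, `nucleus` data.frames and
#'   `obstacles`), `truth` (data.frame of drawn `success`, `leader`,
#'   `pause_s` per event), and `axis` (the fixed approach axis).
#' @export
simulateNavigationCohort <- function(config, n_events) {
  validObject(config)
  stopIfNot(n_events >= 1, "need at least one event")
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config@rng_seed)
  drawer <- makeOutcomeDrawer(config)
  dt <- config@frame_interval_s
  r_o <- config@obstacle_radius_um
  win <- config@navigation_window_s
  ox <- 30; oy <- 0
  pm <- config@navigation_pause_s
  delta <- 90

  success <- drawer$draw("navigation_success_p", n_events)
  leader <- ifelse(drawer$draw("mtoc_first_p", n_events), "mtoc", "nucleus")
  pause <- if (pm[2] == 0) rep(pm[1], n_events) else
    rnormPos(n_events, pm[1], pm[2])

  n_approach <- ceiling(12 / (config@cell_speed_um_min * dt / 60)) + 4
  nf <- n_approach + ceiling((win + max(pause) + 4 * dt) / dt)
  tracks <- vector("list", n_events)
  for (e in seq_len(n_events)) {
    steps <- rStepLength(nf, config@cell_speed_um_min * dt / 60)
    x <- pmin(15 + cumsum(steps), ox - r_o - 2)    # approach, then hold
    y <- rnorm(nf, 0, 0.15)
    ## encounter: same criterion the detector applies
    enc <- which(sqrt((ox - x)^2 + (oy - y)^2) - r_o <= 5 & x < ox)[1]
    t_enc <- (enc - 1) * dt
    tt <- (seq_len(nf) - 1) * dt
    mtoc_x <- x
    nuc_x <- x - 2.5
    if (success[e]) {
      cross <- tt >= t_enc + pause[e]
      adv <- (tt - (t_enc + pause[e])) / 60 * config@cell_speed_um_min
      mtoc_x[cross] <- ox + r_o + 0.8 + adv[cross]
      nuc_t <- if (leader[e] == "mtoc") pause[e] + delta
               else max(pause[e] - delta, dt)
      ncross <- tt >= t_enc + nuc_t
      nadv <- (tt - (t_enc + nuc_t)) / 60 * config@cell_speed_um_min
      nuc_x[ncross] <- ox + r_o + 0.8 + nadv[ncross]
    }
    tracks[[e]] <- list(
      mtoc = data.frame(frame = seq_len(nf), t_s = tt, x_um = mtoc_x, y_um = y),
      nucleus = data.frame(frame = seq_len(nf), t_s = tt, x_um = nuc_x,
                           y_um = y + rnorm(nf, 0, 0.1)),
      obstacles = data.frame(id = 1L, x_um = ox, y_um = oy, radius_um = r_o))
  }
  list(tracks = tracks,
       truth = data.frame(event = seq_len(n_events), success = success,
                          leader = leader, pause_s = pause),
       axis = c(1, 0))
}

#' Score a navigation cohort with the event detector and scorer
#'
#' Runs [detectEncounters()] and [scoreEvent()] over every event of a
#' [simulateNavigationCohort()] result.
#'
#' @param cohort output of [simulateNavigationCohort()].
#' @param encounter_dist_um,window_s scoring parameters.
#' @return data.frame of closed events, one row per detected event.
#' @export
scoreNavigationCohort <- function(cohort, encounter_dist_um = 5,
                                  window_s = 3300) {
  out <- vector("list", length(cohort$tracks))
  for (e in seq_along(cohort$tracks)) {
    tr <- cohort$tracks[[e]]
    ev <- detectEncounters(tr$mtoc, tr$nucleus, tr$obstacles, cohort$axis,
                           encounter_dist_um = encounter_dist_um, cell = e)
    if (!nrow(ev)) next
    out[[e]] <- scoreEvent(ev[1, ], tr$mtoc, tr$nucleus, tr$obstacles,
                           window_s = window_s)
  }
  do.call(rbind, out)
}

#' Render-detect-track pipeline for MTOC speed estimation
#'
#' Generates a synthetic scene, renders the microtubule-reporter channel
#' frame by frame (streaming, so long movies never hold a full stack in
#' memory), detects MTOC foci as bright spots with sub-pixel weighted
#' centroids, links them with the linear-assignment tracker, and returns
#' per-step speeds per track.
#'
#' @param config a [SceneConfig-class].
#' @param frames frames to process (default: all).
#' @param config_link a [linkingConfig()].
#' @return `list(tracks = <linked data.frame>, speeds = <data.frame id,
#'   t_s, speed_um_min>)`.
#' @export
mtocSpeedPipeline <- function(config, frames = NULL,
                              config_link = linkingConfig()) {
  sc <- generateScene(config, render = FALSE)
  if (is.null(frames)) frames <- seq_len(config@n_frames)
  set.seed(config@rng_seed + 1L)   # rendering noise stream
  dets <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    img <- renderSceneFrame(sc$truth, f, channels = "emtb",
                            noise = TRUE)$channels$emtb
    d <- detectMtocs(img, config@pixel_size_um, frame = f)
    dets[[k]] <- d
  }
  det <- do.call(rbind, dets)
  tracks <- linkFrames(det, config_link,
                       frame_interval_s = config@frame_interval_s)
  sp <- do.call(rbind, lapply(split(tracks, tracks$id), function(g) {
    if (nrow(g) < 2) return(NULL)
    s <- speedSeries(g)$speeds_um_min
    data.frame(id = g$id[1], t_s = s$t_s, speed_um_min = s$speed_um_min)
  }))
  list(tracks = tracks, speeds = sp)
}
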