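## Synthetic scene generator.
##
## The generator separates trajectory/event simulation (cheap, exact ground
## truth) from pixel rendering (optional).  All randomness flows from
## config@rng_seed.  Event probabilities may be replaced by logical vectors
## of forced outcomes, in which case the generator realizes exactly those
## outcomes, in order, by routing cells to deliberately placed obstacles or
## debris.

## Outcome source: scalar probability -> Bernoulli draws; logical vector ->
## forced outcomes consumed in order (recycled with a warning if exhausted).
makeOutcomeDrawer <- function(cfg) {
  counters <- new.env(parent = emptyenv())
  draw <- function(slotname, n = 1) {
    p <- slot(cfg, slotname)
    if (is.logical(p)) {
      i <- get0(slotname, counters, ifnotfound = 0L)
      idx <- ((i + seq_len(n) - 1L) %% length(p)) + 1L
      if (i + n > length(p))
        warning(sprintf("forced outcomes for '%s' exhausted; recycling", slotname))
      assign(slotname, i + n, counters)
      p[idx]
    } else {
      runif(n) < p
    }
  }
  n_forced <- function(slotname) {
    p <- slot(cfg, slotname)
    if (is.logical(p)) length(p) else NA_integer_
  }
  list(draw = draw, n_forced = n_forced)
}

## Nearest point on a polygon boundary to point p (both in um).
nearestPointOnPolygon <- function(p, poly) {
  n <- nrow(poly)
  best <- NULL; bestd <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    v <- b - a; len2 <- sum(v^2)
    t <- if (len2 < 1e-12) 0 else max(0, min(1, sum((p - a) * v) / len2))
    q <- a + t * v
    d <- sum((p - q)^2)
    if (d < bestd) { bestd <- d; best <- q }
  }
  best
}

distanceToPolygon <- function(p, poly) {
  q <- nearestPointOnPolygon(p, poly)
  sqrt(sum((p - q)^2))
}

## Reflect a proposed position into [0, w] x [0, h], preserving step length.
reflectIntoScene <- function(p, w, h) {
  x <- p[1]; y <- p[2]
  for (i in 1:4) {
    if (x < 0) x <- -x
    if (x > w) x <- 2 * w - x
    if (y < 0) y <- -y
    if (y > h) y <- 2 * h - y
  }
  c(min(max(x, 0), w), min(max(y, 0), h))
}

rotate90 <- function(v) c(-v[2], v[1])

randUnit <- function() {
  a <- runif(1, 0, 2 * pi)
  c(cos(a), sin(a))
}

#' Generate a synthetic epidermal time-lapse scene with ground truth
#'
#' Simulates ramified cells (soma disk plus tapering dendrites, one bright
#' perinuclear MTOC focus per cell) moving by a biased persistent random
#' walk among static obstacle nuclei, with optional scratch wound and
#' laser-ablation debris events, and optionally renders the scene into a
#' calibrated multi-channel [TimeLapse-class].
#'
#' Kinematics are speed-exact by construction: per-frame step lengths are
#' drawn from a gamma distribution whose mean equals the configured speed
#' times the frame interval, and contextual behavior (tethering of the MTOC
#' near the nucleus, wound-directed bias, obstacle avoidance, homing to
#' debris) only modulates the step *direction*, so realized mean per-step
#' speeds converge to the configured values. Obstacle passages, engulfment
#' events and end-of-movie phenotypes are recorded in the returned
#' [GroundTruth-class] exactly as realized; forced-outcome configurations
#' are realized exactly and in order.
#'
#' @param config a [SceneConfig-class].
#' @param render logical; render pixel data (otherwise only ground truth).
#' @param channels channels to render, subset of
#'   `c("cytosol", "emtb", "nuclei", "lifeact")`.
#' @param keep_masks logical; store per-frame ground-truth label masks in
#'   the returned truth (memory-heavy for long movies).
#' @return `list(timelapse = <TimeLapse or NULL>, truth = <GroundTruth>)`.
#' @examples
#' sc <- generateScene(sceneConfig(n_cells = 2L, n_frames = 5L,
#'                                 width_um = 80, height_um = 80),
#'                     render = FALSE)
#' sc$truth
#' @export
generateScene <- function(config, render = TRUE,
                          channels = c("cytosol", "emtb", "nuclei"),
                          keep_masks = FALSE) {
  validObject(config)
  stopIfNot(config@n_frames >= 1, "zero frames requested")
  channels <- match.arg(channels, c("cytosol", "emtb", "nuclei", "lifeact"),
                        several.ok = TRUE)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config@rng_seed)
  truth <- simulateTruth(config)
  tl <- NULL
  if (render) {
    d <- sceneDimPx(config)
    arr <- array(0, c(d[1], d[2], length(channels), config@n_frames))
    masks <- if (keep_masks) vector("list", config@n_frames) else NULL
    for (f in seq_len(config@n_frames)) {
      rf <- renderSceneFrame(truth, f, channels = channels, noise = TRUE,
                             label = keep_masks)
      for (k in seq_along(channels)) arr[, , k, f] <- rf$channels[[k]]
      if (keep_masks) masks[[f]] <- rf$label
    }
    if (keep_masks) truth@masks <- masks
    tl <- new("TimeLapse", data = arr, channels = channels,
              pixel_size_um = config@pixel_size_um,
              frame_interval_s = config@frame_interval_s)
  }
  list(timelapse = tl, truth = truth)
}

sceneDimPx <- function(cfg) {
  c(ceiling(cfg@height_um / cfg@pixel_size_um),
    ceiling(cfg@width_um / cfg@pixel_size_um))
}

## ---------------------------------------------------------------------------
## Trajectory / event simulation
## ---------------------------------------------------------------------------

simulateTruth <- function(cfg) {
  dt <- cfg@frame_interval_s
  nf <- cfg@n_frames
  nc <- cfg@n_cells
  w <- cfg@width_um; h <- cfg@height_um
  has_wound <- length(cfg@wound) > 0
  has_abl <- length(cfg@ablation) > 0
  drawer <- makeOutcomeDrawer(cfg)
  r_s <- cfg@soma_radius_um

  ## Wound polygon per frame: linear area closure at closure_rate_per_h.
  wound_polys <- vector("list", nf)
  if (has_wound) {
    poly0 <- cfg@wound$polygon
    ctr0 <- polygonCentroid(poly0)
    rate <- cfg@wound$closure_rate_per_h
    for (f in seq_len(nf)) {
      t_h <- (f - 1) * dt / 3600
      s <- sqrt(max(0.02, 1 - rate * t_h))
      wound_polys[[f]] <- sweep(sweep(poly0, 2, ctr0) * s, 2, ctr0, "+")
    }
  }

  ## Background obstacles (keratinocyte nuclei), outside the initial wound.
  n_obs <- round(cfg@obstacle_density_per_100um2 * w * h / 100)
  obs <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                    radius_um = numeric(0))
  if (n_obs > 0) {
    m <- 15
    ox <- runif(n_obs * 2, m, w - m); oy <- runif(n_obs * 2, m, h - m)
    keep <- rep(TRUE, n_obs * 2)
    if (has_wound) {
      ## no nuclei inside the scratch, none at its immediate margin
      keep <- !pointsInPolygon(cbind(ox, oy), wound_polys[[1]])
      dw <- vapply(seq_along(ox), function(k)
        distanceToPolygon(c(ox[k], oy[k]), wound_polys[[1]]), numeric(1))
      keep <- keep & dw > 20
    }
    ox <- ox[keep][seq_len(min(n_obs, sum(keep)))]
    oy <- oy[keep][seq_len(min(n_obs, sum(keep)))]
    obs <- data.frame(id = seq_along(ox), x_um = ox, y_um = oy,
                      radius_um = cfg@obstacle_radius_um)
  }

  ## Forced navigation events: cells are routed to deliberately placed
  ## obstacles so realized counts equal the forced outcome lists exactly.
  nfv <- c(drawer$n_forced("navigation_success_p"),
           drawer$n_forced("mtoc_first_p"))
  nfv <- nfv[!is.na(nfv)]
  n_forced_nav <- if (length(nfv)) max(nfv) else NA_integer_
  forced_nav <- has_wound && !is.na(n_forced_nav) && n_forced_nav > 0
  if (forced_nav) {
    stopIfNot(nc >= 1, "forced navigation outcomes need at least one cell")
  }

  ## Phenotype labels (wound scenes only); drawn before placement because
  ## wound-responding cells start near the wound.  Forced-outcome
  ## navigation configs route every cell to assigned obstacles, so no
  ## phenotype choreography is drawn for them.
  phen <- rep("neither", nc)
  if (has_wound && nc > 0 && !forced_nav) {
    u <- runif(nc)
    phen[u < cfg@wound$engulfing_p] <- "engulfing"
    phen[u >= cfg@wound$engulfing_p &
           u < cfg@wound$engulfing_p + cfg@wound$stretching_p] <- "stretching"
  }

  ## Initial cell placement: outside the wound, minimum separation; cells
  ## fated to respond at the wound start within reach of it.
  placeCells <- function() {
    pos <- matrix(NA_real_, nc, 2)
    ## keep whole arbors in view where the scene allows
    arbor <- r_s + cfg@dendrite_length_um[1] + 2 * cfg@dendrite_length_um[2] + 2
    margin <- min(arbor, min(w, h) / 3)
    margin <- max(margin, r_s + 2)
    for (i in seq_len(nc)) {
      dmax <- if (phen[i] == "neither") 120 else 40
      for (try in 1:200) {
        p <- c(runif(1, margin, w - margin), runif(1, margin, h - margin))
        ok <- TRUE
        if (has_wound) {
          dwound <- distanceToPolygon(p, wound_polys[[1]])
          inw <- pointsInPolygon(matrix(p, ncol = 2), wound_polys[[1]])
          if (inw || dwound < 15 || dwound > dmax) ok <- FALSE
        }
        if (ok && i > 1) {
          dd <- sqrt(rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE], 2, p)^2))
          if (any(dd < 2.2 * r_s)) ok <- FALSE
        }
        if (ok) break
      }
      pos[i, ] <- p
    }
    pos
  }
  pos0 <- placeCells()

  ## Per-cell morphology.
  ndend <- integer(nc)
  dend_angle <- vector("list", nc)
  dend_base <- vector("list", nc)
  dend_emtb <- vector("list", nc)
  for (i in seq_len(nc)) {
    mu <- cfg@dendrites_per_cell[1]; sd_ <- cfg@dendrites_per_cell[2]
    k <- if (sd_ == 0) round(mu) else round(rnorm(1, mu, sd_))
    k <- min(10L, max(3L, as.integer(k)))
    ndend[i] <- k
    base_a <- runif(1, 0, 2 * pi)
    dend_angle[[i]] <- (base_a + 2 * pi * (seq_len(k) - 1) / k +
                          rnorm(k, 0, 0.12)) %% (2 * pi)
    lm <- cfg@dendrite_length_um
    dend_base[[i]] <- if (lm[2] == 0) rep(lm[1], k) else rnormPos(k, lm[1], lm[2])
    dend_emtb[[i]] <- drawer$draw("emtb_positive_p", k)
  }

  ## Ablation / debris setup.
  debris <- NULL          # data.frame(cell, x_um, y_um)
  if (has_abl && nc > 0) {
    ab <- cfg@ablation
    k_forced <- drawer$n_forced("modality_dendritic_p")
    if (is.finite(k_forced) && k_forced > 1) {
      stopIfNot(nc >= k_forced,
                "forced engulfment outcomes need n_cells >= number of outcomes")
      dd <- lapply(seq_len(k_forced), function(i) {
        u <- randUnit()
        p <- reflectIntoScene(pos0[i, ] + u * runif(1, 10, 14), w, h)
        data.frame(cell = i, x_um = p[1], y_um = p[2])
      })
      debris <- do.call(rbind, dd)
    } else if (!is.null(ab$x_um) && !is.null(ab$y_um)) {
      d2 <- rowSums(sweep(pos0, 2, c(ab$x_um, ab$y_um))^2)
      debris <- data.frame(cell = which.min(d2), x_um = ab$x_um, y_um = ab$y_um)
    } else {
      ## site omitted: target a keratinocyte 10-14 um from a cell, as the
      ## ablation protocol selects targets near a Langerhans cell
      j <- sample.int(nc, 1)
      p <- reflectIntoScene(pos0[j, ] + randUnit() * runif(1, 10, 14), w, h)
      debris <- data.frame(cell = j, x_um = p[1], y_um = p[2])
    }
  }

  ## State.
  cell_xy <- array(NA_real_, c(nf, nc, 2))
  mtoc_xy <- array(NA_real_, c(nf, nc, 2))
  head_xy <- array(0, c(nf, nc, 2))
  dend_len <- lapply(seq_len(nc), function(i) matrix(NA_real_, nf, ndend[i]))
  dend_ang <- lapply(seq_len(nc), function(i) matrix(NA_real_, nf, ndend[i]))

  st <- lapply(seq_len(nc), function(i) {
    list(pos = pos0[i, ], mtoc = pos0[i, ] + randUnit() * 2.0,
         heading = randUnit(), mheading = randUnit(),
         state = "migrate", nav = NULL, eng = NULL,
         len = dend_base[[i]], ang = dend_angle[[i]],
         queue = integer(0),      # assigned forced-event indices
         activated = FALSE)
  })

  ## Forced navigation: round-robin assignment of events to cells.
  if (forced_nav) {
    for (e in seq_len(n_forced_nav)) {
      i <- ((e - 1) %% nc) + 1
      st[[i]]$queue <- c(st[[i]]$queue, e)
    }
  }

  ## Event bookkeeping.
  passages <- list()
  closed_pairs <- character(0)
  engulf_rec <- list()
  if (!is.null(debris)) {
    for (k in seq_len(nrow(debris))) {
      i <- debris$cell[k]
      st[[i]]$eng <- list(debris = c(debris$x_um[k], debris$y_um[k]),
                          phase = "waiting", modality = NA_character_,
                          success = NA, contact_frame = NA_integer_,
                          contact_structure = NA_character_,
                          engulf_frame = NA_integer_)
    }
  }

  mtoc_speed_mean <- rep(cfg@mtoc_speed_um_min, nc)
  encounter_dist <- 5

  obs$owner <- rep(NA_integer_, nrow(obs))
  nextForcedObstacle <- function(p, axis, owner) {
    ## Place an obstacle ahead of the cell on its way to the wound.
    q <- p + axis * 18
    q <- c(min(max(q[1], 12), w - 12), min(max(q[2], 12), h - 12))
    id <- nrow(obs) + 1L
    obs <<- rbind(obs, data.frame(id = id, x_um = q[1], y_um = q[2],
                                  radius_um = cfg@obstacle_radius_um,
                                  owner = owner))
    id
  }

  woundAxis <- function(p, f) {
    if (!has_wound) return(NULL)
    unitVec(nearestPointOnPolygon(p, wound_polys[[f]]) - p)
  }

  for (f in seq_len(nf)) {
    t_s <- (f - 1) * dt
    poly_f <- if (has_wound) wound_polys[[f]] else NULL

    ## Ablation trigger.
    if (has_abl && f == cfg@ablation$frame) {
      site <- if (!is.null(cfg@ablation$x_um))
        c(cfg@ablation$x_um, cfg@ablation$y_um)
      else c(debris$x_um[1], debris$y_um[1])
      for (i in seq_len(nc)) {
        pdist <- if (!is.null(st[[i]]$eng))
          sqrt(sum((st[[i]]$pos - st[[i]]$eng$debris)^2))
        else sqrt(sum((st[[i]]$pos - site)^2))
        if (pdist <= cfg@ablation$response_radius_um) {
          mtoc_speed_mean[i] <- cfg@mtoc_speed_post_um_min
          st[[i]]$activated <- TRUE
        }
        if (!is.null(st[[i]]$eng)) {
          e <- st[[i]]$eng
          e$phase <- "respond"
          e$modality <- if (drawer$draw("modality_dendritic_p")) "dendritic" else "motility"
          e$success <- drawer$draw("engulf_success_p")
          e$d0 <- sqrt(sum((st[[i]]$pos - e$debris)^2))
          ## dendrite aimed at the debris (dendritic modality)
          dir <- unitVec(e$debris - st[[i]]$pos)
          e$dend <- which.min(abs(((st[[i]]$ang - atan2(dir[2], dir[1]) + pi) %%
                                     (2 * pi)) - pi))
          e$ablation_frame <- f
          st[[i]]$eng <- e
          st[[i]]$state <- if (e$modality == "dendritic")
            "dendritic_engulf" else "motility_engulf"
        }
      }
    }

    for (i in seq_len(nc)) {
      s <- st[[i]]
      step_cell <- rStepLength(1, cfg@cell_speed_um_min * dt / 60)
      step_mtoc <- rStepLength(1, mtoc_speed_mean[i] * dt / 60)

      ## ----- cell-body update by state -----
      if (s$state == "migrate") {
        rnd <- randUnit()
        target_dir <- rnd
        if (has_wound) {
          a <- woundAxis(s$pos, f)
          ## cells fated to respond at the wound chemotax strongly
          b <- if (phen[i] == "neither") cfg@wound_bias
               else max(cfg@wound_bias, 0.85)
          target_dir <- unitVec(b * a + (1 - b) * rnd)
        }
        dir <- unitVec(cfg@persistence * s$heading +
                         (1 - cfg@persistence) * target_dir)
        ## neighbour repulsion (direction only)
        for (j in seq_len(nc)) {
          if (j != i) {
            dv <- s$pos - st[[j]]$pos
            if (sum(dv^2) < (2.0 * r_s)^2) dir <- unitVec(dir + 0.8 * unitVec(dv))
          }
        }
        ## keep non-engulfing cells out of the wound; cells not fated to
        ## respond also hold a standoff beyond their dendrite reach so
        ## their tips do not cross the outline
        if (has_wound && phen[i] != "engulfing") {
          p1 <- s$pos + dir * step_cell
          standoff <- if (phen[i] == "neither" && !forced_nav)
            r_s + max(dend_base[[i]]) * 1.1 + 1 else 0
          if (pointsInPolygon(matrix(p1, ncol = 2), poly_f) ||
              distanceToPolygon(p1, poly_f) < standoff)
            dir <- unitVec(-woundAxis(s$pos, f) + 0.5 * randUnit())
        }
        ## obstacle avoidance when not heading into a tracked encounter
        p1 <- s$pos + dir * step_cell
        if (nrow(obs) && !has_wound) {
          d2o <- (obs$x_um - p1[1])^2 + (obs$y_um - p1[2])^2
          if (any(d2o < (obs$radius_um + 1.5)^2)) {
            rot <- if (runif(1) < 0.5) 1 else -1
            dir <- unitVec(dir + rot * rotate90(dir))
            p1 <- s$pos + dir * step_cell
          }
        }
        s$pos <- reflectIntoScene(p1, w, h)
        s$heading <- dir

        ## phenotype choreography near the wound
        if (has_wound && phen[i] == "engulfing" &&
            pointsInPolygon(matrix(s$pos, ncol = 2), poly_f)) {
          s$state <- "at_wound_engulf"
        }
        if (has_wound && phen[i] == "stretching") {
          db <- distanceToPolygon(s$pos, poly_f)
          if (!pointsInPolygon(matrix(s$pos, ncol = 2), poly_f) && db < 6)
            s$state <- "at_wound_stretch"
        }
      } else if (s$state == "navigate") {
        nv <- s$nav
        o <- nv$obs_xy; r_o <- nv$obs_r
        a <- nv$axis; l <- rotate90(a) * nv$side
        el <- t_s - nv$t_enc
        drift <- min(1, el / max(nv$D, dt))
        mtoc_hold <- o - a * (r_o + 2.0) + l * (r_o + 1.5) * drift
        nuc_hold <- o - a * (r_o + 3.5) + l * (r_o + 1.2) * drift
        ## D is the MTOC encounter-to-pass duration; the nucleus trails or
        ## leads it by `delta` depending on the drawn decision
        mtoc_t <- nv$D
        nuc_t <- if (nv$leader == "mtoc") nv$D + nv$delta
                 else max(nv$D - nv$delta, dt)
        speed_out <- cfg@cell_speed_um_min * dt / 60
        posFor <- function(hold, t_cross) {
          if (!nv$success) return(hold + rnorm(2, 0, 0.15))
          if (el < t_cross) return(hold + rnorm(2, 0, 0.15))
          adv <- (el - t_cross) / dt * speed_out
          o + a * (r_o + 1.0 + adv) + l * (r_o + 1.0)
        }
        new_mtoc <- reflectIntoScene(posFor(mtoc_hold, mtoc_t), w, h)
        new_nuc <- reflectIntoScene(posFor(nuc_hold, nuc_t), w, h)
        s$mtoc <- new_mtoc
        s$heading <- a
        s$pos <- new_nuc
        done <- nv$success && el >= max(mtoc_t, nuc_t) + 2 * dt
        gave_up <- !nv$success && el >= cfg@navigation_window_s + 2 * dt
        if (done || gave_up) {
          s$state <- "migrate"
          if (gave_up) s$heading <- unitVec(rotate90(a) * nv$side + 0.3 * a)
          s$nav <- NULL
        }
      } else if (s$state == "motility_engulf") {
        e <- s$eng
        dvec <- e$debris - s$pos
        dd <- sqrt(sum(dvec^2))
        if (is.na(e$contact_frame)) {
          if (dd > 2.0) {
            stp <- rStepLength(1, cfg@cell_speed_um_min * 1.2 * dt / 60)
            s$pos <- reflectIntoScene(s$pos + unitVec(dvec) * min(stp, dd - 1.8), w, h)
            s$heading <- unitVec(dvec)
          }
          if (sqrt(sum((e$debris - s$pos)^2)) <= 2.05) {
            e$contact_frame <- f
            e$contact_structure <- "cell_body"
            if (e$success) e$engulf_frame <- f + 12L
          }
        } else {
          s$pos <- reflectIntoScene(s$pos + rnorm(2, 0, 0.1), w, h)
          if (!is.na(e$engulf_frame) && f >= e$engulf_frame) s$state <- "post_engulf"
        }
        s$eng <- e
      } else if (s$state == "dendritic_engulf") {
        e <- s$eng
        s$pos <- reflectIntoScene(s$pos + rnorm(2, 0, 0.08), w, h)
        dvec <- e$debris - s$pos
        e_ang <- atan2(dvec[2], dvec[1])
        s$ang[e$dend] <- e_ang
        need <- sqrt(sum(dvec^2)) - r_s
        if (is.na(e$contact_frame)) {
          s$len[e$dend] <- min(s$len[e$dend] + 0.35, need + 0.3)
          if (s$len[e$dend] >= need - 0.2) {
            e$contact_frame <- f
            e$contact_structure <- "dendrite"
            if (e$success) e$engulf_frame <- f + 12L
          }
        } else if (!is.na(e$engulf_frame) && f >= e$engulf_frame) {
          s$state <- "post_engulf"
        }
        s$eng <- e
      } else if (s$state %in% c("post_engulf", "at_wound_engulf", "at_wound_stretch")) {
        s$pos <- reflectIntoScene(s$pos + rnorm(2, 0, 0.08), w, h)
        if (s$state == "at_wound_engulf") {
          ## round up: retract dendrites
          s$len <- pmax(s$len * 0.8, 0.6)
          ## drift toward the wound centre, stay inside
          ctr <- polygonCentroid(poly_f)
          s$pos <- s$pos + unitVec(ctr - s$pos) * 0.15
        }
        if (s$state == "at_wound_stretch") {
          db <- nearestPointOnPolygon(s$pos, poly_f)
          dvec <- db - s$pos
          a1 <- atan2(dvec[2], dvec[1])
          s$ang[1] <- a1
          target_len <- sqrt(sum(dvec^2)) + 5
          s$len[1] <- min(s$len[1] + 0.6, target_len)
        }
      }

      ## ----- dendrite length dynamics (outside choreography) -----
      if (!s$state %in% c("dendritic_engulf", "at_wound_engulf", "at_wound_stretch") &&
          cfg@dendrite_length_um[2] > 0) {
        s$len <- pmax(0.6, s$len + 0.15 * (dend_base[[i]] - s$len) +
                        rnorm(ndend[i], 0, 0.04 * dend_base[[i]]))
      }

      ## ----- MTOC update -----
      if (s$state == "navigate") {
        ## choreographed above
      } else if (s$state %in% c("motility_engulf", "dendritic_engulf", "post_engulf") &&
                 !is.null(s$eng) && s$eng$phase == "respond") {
        dvec <- s$eng$debris - s$mtoc
        dd <- sqrt(sum(dvec^2))
        dir <- if (dd > 1.2) unitVec(unitVec(dvec) * 0.92 + 0.08 * randUnit())
               else unitVec(randUnit() + 2 * unitVec(dvec) * max(0, dd - 1.0))
        s$mtoc <- reflectIntoScene(s$mtoc + dir * step_mtoc, w, h)
      } else if (has_wound) {
        ## during directed migration the MTOC rides ahead of the nucleus
        s$mtoc <- reflectIntoScene(s$pos + s$heading * 2.5 + rnorm(2, 0, 0.3), w, h)
      } else {
        off <- s$mtoc - s$pos
        if (sqrt(sum(off^2)) > 3.5) {
          dir <- unitVec(s$pos + randUnit() * 1.0 - s$mtoc)
        } else {
          dir <- unitVec(0.5 * s$mheading + 0.5 * randUnit())
        }
        s$mheading <- dir
        s$mtoc <- reflectIntoScene(s$mtoc + dir * step_mtoc, w, h)
      }

      ## ----- navigation event opening (wound scenes) -----
      ## bookkeeping matches the encounter detector: one event per
      ## cell-obstacle pair at the first frame the MTOC is within the
      ## encounter distance of the boundary with the obstacle ahead.
      ## Outside the migrate state the event is recorded without
      ## choreography (incidental pass-by); its outcome is derived from
      ## the realized tracks like any other event.
      if (has_wound && !forced_nav && nrow(obs) &&
          (s$state != "migrate" || phen[i] != "neither")) {
        axis <- woundAxis(s$mtoc, f)
        dxo <- obs$x_um - s$mtoc[1]; dyo <- obs$y_um - s$mtoc[2]
        dcent <- sqrt(dxo^2 + dyo^2)
        near <- which(dcent - obs$radius_um <= encounter_dist &
                        (dxo * axis[1] + dyo * axis[2]) > 0)
        for (k in near) {
          key <- paste(i, obs$id[k], sep = "_")
          if (key %in% closed_pairs) next
          closed_pairs <- c(closed_pairs, key)
          passages[[length(passages) + 1]] <- list(
            cell = i,
            nav = list(obs_id = obs$id[k],
                       obs_xy = c(obs$x_um[k], obs$y_um[k]),
                       obs_r = obs$radius_um[k],
                       axis = axis, enc_frame = f))
        }
      }
      if (has_wound && s$state == "migrate" && phen[i] == "neither") {
        ## forced queue: route to the next assigned obstacle
        if (length(s$queue) && is.null(s$nav_target)) {
          axis0 <- woundAxis(s$pos, f)
          s$nav_target <- nextForcedObstacle(s$pos, axis0, i)
        }
        if (!is.null(s$nav_target)) {
          oo <- obs[obs$id == s$nav_target, ]
          s$heading <- unitVec(c(oo$x_um, oo$y_um) - s$pos)
        }
        if (nrow(obs)) {
          axis <- woundAxis(s$mtoc, f)
          dxo <- obs$x_um - s$mtoc[1]; dyo <- obs$y_um - s$mtoc[2]
          dcent <- sqrt(dxo^2 + dyo^2)
          near <- which(dcent - obs$radius_um <= encounter_dist &
                          (dxo * axis[1] + dyo * axis[2]) > 0)
          for (k in near) {
            key <- paste(i, obs$id[k], sep = "_")
            if (key %in% closed_pairs) next
            ## in forced mode, events happen only at a cell's own assigned
            ## obstacle so realized counts equal the forced lists exactly
            if (forced_nav &&
                (is.null(s$nav_target) || obs$id[k] != s$nav_target)) next
            closed_pairs <- c(closed_pairs, key)
            if (!is.null(s$nav_target) && obs$id[k] == s$nav_target) {
              s$nav_target <- NULL
              if (length(s$queue)) s$queue <- s$queue[-1]
            }
            ev <- list(success = drawer$draw("navigation_success_p"),
                       leader = if (drawer$draw("mtoc_first_p")) "mtoc" else "nucleus")
            pm <- cfg@navigation_pause_s
            D <- if (pm[2] == 0) pm[1] else rnormPos(1, pm[1], pm[2])
            s$nav <- list(obs_id = obs$id[k],
                          obs_xy = c(obs$x_um[k], obs$y_um[k]),
                          obs_r = obs$radius_um[k],
                          axis = axis, side = if (runif(1) < 0.5) 1 else -1,
                          t_enc = t_s, D = D, delta = 90,
                          success = ev$success, leader = ev$leader,
                          enc_frame = f)
            s$state <- "navigate"
            passages[[length(passages) + 1]] <- list(cell = i, nav = s$nav)
            break
          }
        }
      }

      ## record
      cell_xy[f, i, ] <- s$pos
      mtoc_xy[f, i, ] <- s$mtoc
      head_xy[f, i, ] <- s$heading
      dend_len[[i]][f, ] <- s$len
      dend_ang[[i]][f, ] <- s$ang
      st[[i]] <- s
    }
  }

  ## ----- assemble passage records from choreography + realized tracks -----
  pass_df <- data.frame(cell = integer(0), obstacle = integer(0),
                        encounter_frame = integer(0), pass_frame = integer(0),
                        nucleus_pass_frame = integer(0),
                        leader = character(0), success = logical(0))
  if (length(passages)) {
    rows <- lapply(passages, function(p) {
      nv <- p$nav
      i <- p$cell
      a <- nv$axis
      proj_o <- sum(nv$obs_xy * a)
      projs_m <- mtoc_xy[, i, 1] * a[1] + mtoc_xy[, i, 2] * a[2]
      projs_n <- cell_xy[, i, 1] * a[1] + cell_xy[, i, 2] * a[2]
      after <- seq_len(nf) >= nv$enc_frame
      mp <- which(after & projs_m > proj_o + nv$obs_r)[1]
      np <- which(after & projs_n > proj_o + nv$obs_r)[1]
      observed_s <- (nf - nv$enc_frame) * dt
      success <- if (!is.na(mp) &&
                     (mp - nv$enc_frame) * dt <= cfg@navigation_window_s) TRUE
        else if (observed_s >= cfg@navigation_window_s) FALSE
        else NA
      leader <- if (!is.na(mp) || !is.na(np)) {
        if (is.na(np) || (!is.na(mp) && mp <= np)) "mtoc" else "nucleus"
      } else NA_character_
      data.frame(cell = i, obstacle = nv$obs_id,
                 encounter_frame = nv$enc_frame,
                 pass_frame = if (is.na(mp)) NA_integer_ else as.integer(mp),
                 nucleus_pass_frame = if (is.na(np)) NA_integer_ else as.integer(np),
                 leader = leader, success = success)
    })
    pass_df <- do.call(rbind, rows)
  }

  ## ----- engulfment records -----
  eng_df <- data.frame(cell = integer(0), debris_x_um = numeric(0),
                       debris_y_um = numeric(0), ablation_frame = integer(0),
                       contact_frame = integer(0), contact_structure = character(0),
                       engulf_frame = integer(0), modality = character(0),
                       success = logical(0))
  if (!is.null(debris)) {
    rows <- lapply(seq_len(nrow(debris)), function(k) {
      i <- debris$cell[k]
      e <- st[[i]]$eng
      data.frame(cell = i, debris_x_um = e$debris[1], debris_y_um = e$debris[2],
                 ablation_frame = as.integer(e$ablation_frame %||% cfg@ablation$frame),
                 contact_frame = as.integer(e$contact_frame),
                 contact_structure = e$contact_structure,
                 engulf_frame = as.integer(e$engulf_frame),
                 modality = e$modality,
                 success = isTRUE(e$success) && !is.na(e$engulf_frame))
    })
    eng_df <- do.call(rbind, rows)
  }

  ## ----- tracks table -----
  mk <- function(entity, arr) {
    do.call(rbind, lapply(seq_len(nc), function(i) {
      data.frame(entity = entity, id = i, frame = seq_len(nf),
                 t_s = (seq_len(nf) - 1) * dt,
                 x_um = arr[, i, 1], y_um = arr[, i, 2])
    }))
  }
  tracks <- if (nc > 0) rbind(mk("cell", cell_xy), mk("nucleus", cell_xy),
                              mk("mtoc", mtoc_xy))
            else data.frame(entity = character(0), id = integer(0),
                            frame = integer(0), t_s = numeric(0),
                            x_um = numeric(0), y_um = numeric(0))

  ## ----- dendrite table -----
  dend_rows <- lapply(seq_len(nc), function(i) {
    k <- ndend[i]
    data.frame(cell = i,
               dendrite = rep(seq_len(k), each = nf),
               frame = rep(seq_len(nf), k),
               length_um = as.vector(dend_len[[i]]),
               angle_rad = as.vector(dend_ang[[i]]),
               emtb_positive = rep(dend_emtb[[i]], each = nf))
  })
  dend_df <- if (nc > 0) do.call(rbind, dend_rows) else
    data.frame(cell = integer(0), dendrite = integer(0), frame = integer(0),
               length_um = numeric(0), angle_rad = numeric(0),
               emtb_positive = logical(0))
  if (nrow(dend_df)) {
    px <- cell_xy[cbind(dend_df$frame, dend_df$cell, 1)]
    py <- cell_xy[cbind(dend_df$frame, dend_df$cell, 2)]
    dend_df$tip_x_um <- px + cos(dend_df$angle_rad) * (r_s + dend_df$length_um)
    dend_df$tip_y_um <- py + sin(dend_df$angle_rad) * (r_s + dend_df$length_um)
  } else {
    dend_df$tip_x_um <- numeric(0); dend_df$tip_y_um <- numeric(0)
  }

  wound_df <- data.frame(frame = integer(0), vertex = integer(0),
                         x_um = numeric(0), y_um = numeric(0))
  if (has_wound) {
    wound_df <- do.call(rbind, lapply(seq_len(nf), function(f) {
      p <- wound_polys[[f]]
      data.frame(frame = f, vertex = seq_len(nrow(p)),
                 x_um = p[, 1], y_um = p[, 2])
    }))
  }

  new("GroundTruth",
      tracks = tracks, dendrites = dend_df, passages = pass_df,
      engulfments = eng_df,
      phenotypes = data.frame(cell = seq_len(nc), label = phen,
                              stringsAsFactors = FALSE),
      wound = wound_df, obstacles = obs, masks = list(), config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Rendering
## ---------------------------------------------------------------------------

#' Render one frame of a synthetic scene
#'
#' Renders the requested channels of one frame from ground truth, applying
#' the configured noise model. Used internally by [generateScene()] and
#' directly when streaming long movies frame-by-frame without holding the
#' whole stack in memory.
#'
#' @param truth a [GroundTruth-class] from [generateScene()].
#' @param frame frame index.
#' @param channels channels to render.
#' @param noise apply the configured noise model.
#' @param label also return an integer ground-truth label matrix.
#' @return `list(channels = <named list of matrices>, label = <matrix or NULL>)`.
#' @export
renderSceneFrame <- function(truth, frame,
                             channels = c("cytosol", "emtb", "nuclei"),
                             noise = TRUE, label = FALSE) {
  cfg <- truth@config
  px <- cfg@pixel_size_um
  d <- sceneDimPx(cfg)
  lv <- .renderLevels
  r_s_px <- cfg@soma_radius_um / px

  tr <- truth@tracks
  cells <- tr[tr$entity == "cell" & tr$frame == frame, , drop = FALSE]
  mtocs <- tr[tr$entity == "mtoc" & tr$frame == frame, , drop = FALSE]
  dd <- truth@dendrites[truth@dendrites$frame == frame, , drop = FALSE]
  obs <- truth@obstacles
  has_wound <- nrow(truth@wound) > 0
  poly_f <- if (has_wound) woundPolygon(truth, frame) else NULL

  lab <- if (label) matrix(0L, d[1], d[2]) else NULL

  ## motion direction for the polarity (lifeact) channel
  want_lifeact <- "lifeact" %in% channels
  if (want_lifeact) {
    nf <- cfg@n_frames
    f2 <- min(frame + 1L, nf); f1 <- max(frame - 1L, 1L)
    trc <- tr[tr$entity == "cell", , drop = FALSE]
    nextpos <- trc[trc$frame == f2, c("id", "x_um", "y_um")]
    prevpos <- trc[trc$frame == f1, c("id", "x_um", "y_um")]
  }

  ## per-cell geometry, precomputed once
  geo <- lapply(seq_len(nrow(cells)), function(ci) {
    id <- cells$id[ci]
    c_rc <- c(umToRow(cells$y_um[ci], px), umToCol(cells$x_um[ci], px))
    ddc <- dd[dd$cell == id, , drop = FALSE]
    segs <- lapply(seq_len(nrow(ddc)), function(k)
      dendriteSegmentPx(c_rc, ddc[k, ], cfg))
    polar_dir <- NULL
    if (want_lifeact) {
      np <- nextpos[nextpos$id == id, ]; pp <- prevpos[prevpos$id == id, ]
      v <- c(np$x_um - pp$x_um, np$y_um - pp$y_um)
      if (vecNorm(v) > 1e-6) polar_dir <- unitVec(v)
    }
    list(id = id, c_rc = c_rc, ddc = ddc, segs = segs,
         mtoc = mtocs[mtocs$id == id, , drop = FALSE], polar_dir = polar_dir)
  })

  out <- vector("list", length(channels))
  names(out) <- channels
  for (ch in channels) {
    img <- matrix(0, d[1], d[2])
    for (g in geo) {
      c_rc <- g$c_rc
      if (ch == "cytosol") {
        .p <- patchDisk(d, c_rc[1], c_rc[2], r_s_px,
                                          lv$cyto_soma)
        if (!is.null(.p)) img[.p$rr, .p$cc] <- img[.p$rr, .p$cc] + .p$vals
        for (k in seq_along(g$segs)) {
          sg <- g$segs[[k]]
          .p <- patchTube(d, sg$p0, sg$p1, sg$w0, sg$w1,
                                            lv$cyto_dend, lv$cyto_dend_tip)
          if (!is.null(.p)) img[.p$rr, .p$cc] <- img[.p$rr, .p$cc] + .p$vals
        }
      } else if (ch == "emtb") {
        .p <- patchDisk(d, c_rc[1], c_rc[2], r_s_px,
                                          lv$cyto_soma * lv$emtb_soma_frac)
        if (!is.null(.p)) img[.p$rr, .p$cc] <- img[.p$rr, .p$cc] + .p$vals
        for (k in seq_along(g$segs)) {
          sg <- g$segs[[k]]
          fr <- if (g$ddc$emtb_positive[k]) lv$emtb_pos_frac else lv$emtb_neg_frac
          .p <- patchTube(d, sg$p0, sg$p1, sg$w0, sg$w1,
                                            lv$cyto_dend * fr,
                                            lv$cyto_dend_tip * fr)
          if (!is.null(.p)) img[.p$rr, .p$cc] <- img[.p$rr, .p$cc] + .p$vals
        }
        if (nrow(g$mtoc))
          .p <- patchSpot(d, umToRow(g$mtoc$y_um, px),
                                            umToCol(g$mtoc$x_um, px),
                                            lv$mtoc_sigma_um / px, lv$mtoc_amp)
          if (!is.null(.p)) img[.p$rr, .p$cc] <- img[.p$rr, .p$cc] + .p$vals
      } else if (ch == "nuclei") {
        .p <- patchDisk(d, c_rc[1], c_rc[2],
                                          cfg@nucleus_radius_um / px,
                                          lv$nucleus)
        if (!is.null(.p)) img[.p$rr, .p$cc] <- img[.p$rr, .p$cc] + .p$vals
      } else if (ch == "lifeact") {
        ## cell footprint at a base level; trailing half scaled up and
        ## leading half down so trailing/leading mean equals the target
        cell_img <- matrix(0, d[1], d[2])
        .p <- patchDisk(d, c_rc[1], c_rc[2],
                                                    r_s_px, lv$lifeact_base)
        if (!is.null(.p)) cell_img[.p$rr, .p$cc] <- cell_img[.p$rr, .p$cc] + .p$vals
        for (sg in g$segs)
          .p <- patchTube(d, sg$p0, sg$p1, sg$w0, sg$w1,
                                            lv$lifeact_base,
                                            lv$lifeact_base * 0.7)
          if (!is.null(.p)) cell_img[.p$rr, .p$cc] <- cell_img[.p$rr, .p$cc] + .p$vals
        ratio <- cfg@polarity_ratio
        if (!is.null(g$polar_dir) && abs(ratio - 1) > 1e-9) {
          idx <- which(cell_img > 0, arr.ind = TRUE)
          proj <- (idx[, 2] - c_rc[2]) * g$polar_dir[1] +
            (idx[, 1] - c_rc[1]) * g$polar_dir[2]
          scale <- ifelse(proj < 0, 2 * ratio / (ratio + 1), 2 / (ratio + 1))
          cell_img[idx] <- cell_img[idx] * scale
        }
        img <- img + cell_img
      }
    }
    if (ch == "nuclei") {
      ## static obstacle nuclei + debris
      for (k in seq_len(nrow(obs)))
        .p <- patchDisk(d, umToRow(obs$y_um[k], px),
                                          umToCol(obs$x_um[k], px),
                                          obs$radius_um[k] / px, lv$obstacle)
        if (!is.null(.p)) img[.p$rr, .p$cc] <- img[.p$rr, .p$cc] + .p$vals
      eng <- truth@engulfments
      if (nrow(eng)) {
        live <- eng[eng$ablation_frame <= frame &
                      (is.na(eng$engulf_frame) | eng$engulf_frame > frame), ,
                    drop = FALSE]
        for (k in seq_len(nrow(live)))
          .p <- patchSpot(d, umToRow(live$debris_y_um[k], px),
                                            umToCol(live$debris_x_um[k], px),
                                            1.5 / px, 250)
          if (!is.null(.p)) img[.p$rr, .p$cc] <- img[.p$rr, .p$cc] + .p$vals
      }
    }
    if (noise) img <- applyNoise(img, cfg@noise)
    out[[ch]] <- img
  }

  if (label) {
    for (g in geo) {
      pxs <- diskPixels(d, g$c_rc[1], g$c_rc[2], r_s_px)
      for (sg in g$segs)
        pxs <- rbind(pxs, tubePixels(d, sg$p0, sg$p1, sg$w0, sg$w1))
      lab[pxs] <- as.integer(g$id)
    }
  }
  list(channels = out, label = lab)
}

## Dendrite centreline in pixel coordinates: starts just inside the soma
## boundary, ends at the tip.
dendriteSegmentPx <- function(c_rc, drow, cfg) {
  px <- cfg@pixel_size_um
  u <- c(sin(drow$angle_rad), cos(drow$angle_rad))   # (row, col) direction
  r0 <- (cfg@soma_radius_um - 1) / px
  r1 <- (cfg@soma_radius_um + drow$length_um) / px
  hw <- .renderLevels$dend_halfwidth_um
  list(p0 = c_rc + u * r0, p1 = c_rc + u * r1,
       w0 = hw["base"] / px, w1 = hw["tip"] / px)
}


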