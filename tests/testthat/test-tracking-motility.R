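## Exhaustive-permutation oracle for small assignment problems.
permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
bruteAssignmentCost <- function(C) {
  P <- permutations(nrow(C))
  min(apply(P, 1, function(p) sum(C[cbind(seq_len(nrow(C)), p)])))
}

test_that("assignment solver equals the brute-force optimum up to n = 6", {
  set.seed(10)
  for (rep in 1:40) {
    n <- sample(1:6, 1)
    C <- matrix(runif(n * n) * 10, n)
    a <- solveAssignment(C)
    expect_equal(sort(a), seq_len(n))       # a permutation
    expect_equal(sum(C[cbind(seq_len(n), a)]), bruteAssignmentCost(C),
                 tolerance = 1e-10)
  }
})

test_that("frame-pair linking picks the globally optimal pairing", {
  ## two detections each: nearest-neighbour would pair A with (4,0) too,
  ## but the optimum pairs A->(4,0), B->(6,0) with total cost 16+16
  d <- data.frame(frame = c(1, 1, 2, 2), x_um = c(0, 10, 4, 6), y_um = 0)
  tr <- linkFrames(d, linkingConfig())
  tr <- tr[order(tr$frame, tr$x_um), ]
  a2 <- tr$x_um[tr$frame == 2][tr$id[tr$frame == 2] ==
                                 tr$id[tr$frame == 1 & tr$x_um == 0]]
  expect_equal(a2, 4)
  ## unambiguous nearest case
  d2 <- data.frame(frame = c(1, 1, 2, 2), x_um = c(0, 10, 1, 9), y_um = 0)
  t2 <- linkFrames(d2, linkingConfig())
  expect_equal(t2$id[t2$frame == 2 & t2$x_um == 1],
               t2$id[t2$frame == 1 & t2$x_um == 0])
  ## a jump of 2 x max_link terminates the track and births a new one
  d3 <- data.frame(frame = c(1, 2), x_um = c(0, 20), y_um = 0)
  t3 <- linkFrames(d3, linkingConfig(max_link_um = 10))
  expect_equal(length(unique(t3$id)), 2)
  ## linking equals brute force on random frame pairs with <= 6 detections
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    a <- cbind(runif(n, 0, 20), runif(n, 0, 20))
    b <- a + matrix(rnorm(2 * n, 0, 2), n)
    links <- epinav:::linkPair(a, b, max_link_um = 50)
    C <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    expect_equal(sum(C[cbind(seq_len(n), links)]), bruteAssignmentCost(C),
                 tolerance = 1e-10)
  }
})

test_that("gap closing bridges short detection dropouts", {
  d <- data.frame(frame = c(1, 3, 4), x_um = c(0, 1.2, 1.8), y_um = 0)
  expect_equal(length(unique(linkFrames(d, linkingConfig())$id)), 1)
  ## a gap longer than max_gap stays broken
  d2 <- data.frame(frame = c(1, 5), x_um = c(0, 1), y_um = 0)
  expect_equal(length(unique(linkFrames(d2, linkingConfig(max_gap = 2))$id)), 2)
})

test_that("track metrics follow the displacement / distance definitions", {
  m <- trackMetrics(data.frame(x_um = c(0, 3), y_um = c(0, 4)))
  expect_equal(m$total_distance_um, 5)
  expect_equal(m$displacement_um, 5)
  expect_equal(m$meandering_index, 1)
  expect_false(m$included)                      # below the 10 um rule
  m2 <- trackMetrics(data.frame(x_um = c(0, 1, 0), y_um = c(0, 0, 0)))
  expect_equal(m2$total_distance_um, 2)
  expect_equal(m2$meandering_index, 0)
  m3 <- trackMetrics(data.frame(x_um = c(0, 9, 9), y_um = c(0, 0, 12)))
  expect_equal(m3$total_distance_um, 21)
  expect_equal(m3$displacement_um, 15)
  expect_equal(m3$meandering_index, 15 / 21)
  expect_true(m3$included)
  expect_error(trackMetrics(data.frame(x_um = 0, y_um = 0)), "2 points")
})

test_that("meandering index lies in [0,1], 1 only for straight monotone paths", {
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(3:20, 1)
    tr <- data.frame(x_um = cumsum(rnorm(n)), y_um = cumsum(rnorm(n)))
    m <- trackMetrics(tr)
    expect_gte(m$meandering_index, 0)
    expect_lte(m$meandering_index, 1 + 1e-12)
  }
  ## collinear monotone path: MI exactly 1
  straight <- data.frame(x_um = c(0, 2, 5, 9), y_um = c(0, 4, 10, 18))
  expect_equal(trackMetrics(straight)$meandering_index, 1)
  ## collinear but non-monotone: MI < 1
  back <- data.frame(x_um = c(0, 5, 3), y_um = 0)
  expect_lt(trackMetrics(back)$meandering_index, 1)
})

test_that("speed series and windowed path length match direct summation", {
  tr <- data.frame(t_s = seq(0, 300, 30), x_um = seq(0, 7, 0.7), y_um = 0)
  s <- speedSeries(tr, window_s = 300)
  expect_true(all(abs(s$speeds_um_min$speed_um_min - 1.4) < 1e-12))
  expect_equal(s$windowed$path_um[11], 7)
  ## random-walk track vs brute-force window sums
  set.seed(13)
  tr2 <- data.frame(t_s = seq(0, 600, 30),
                    x_um = cumsum(rnorm(21, 0, 0.5)),
                    y_um = cumsum(rnorm(21, 0, 0.5)))
  s2 <- speedSeries(tr2, window_s = 150)
  steps <- sqrt(diff(tr2$x_um)^2 + diff(tr2$y_um)^2)
  for (i in seq_len(nrow(tr2))) {
    expected <- sum(steps[which(tr2$t_s[-1] <= tr2$t_s[i] &
                                  tr2$t_s[-1] > tr2$t_s[i] - 150)])
    expect_equal(s2$windowed$path_um[i], expected)
  }
  expect_error(speedSeries(data.frame(t_s = c(0, 0), x_um = 0:1, y_um = 0)),
               "interval")
})

test_that("Gaussian speed-histogram fits recover parameters and flag misfits", {
  degenerate <- speedHistogramFit(rep(2, 20))
  expect_equal(degenerate$mean, 2)
  expect_equal(degenerate$sd, 0)
  expect_true(degenerate$flagged)
  set.seed(14)
  f <- speedHistogramFit(rnorm(10000, 1.4, 0.4), bin_width = 0.1)
  expect_lt(abs(f$mean - 1.4), 0.05)
  expect_false(f$flagged)
  bimodal <- c(rnorm(3000, 1, 0.1), rnorm(3000, 4, 0.1))
  expect_true(speedHistogramFit(bimodal, bin_width = 0.1)$flagged)
})

test_that("relative distance to a target normalizes to the window start", {
  tr <- data.frame(frame = 1:11, x_um = seq(10, 0, -1), y_um = 0)
  d <- distanceToTarget(tr, c(0, 0))
  expect_equal(d$relative[1], 1)
  expect_equal(d$relative[11], 0)
  expect_true(all(diff(d$relative) < 0))
  ## stationary pair stays at 1.0
  st <- data.frame(frame = 1:5, x_um = 5, y_um = 0)
  expect_true(all(distanceToTarget(st, c(0, 0))$relative == 1))
  ## zero initial distance: floored normalization, flagged
  z <- data.frame(frame = 1:3, x_um = c(0, 1, 2), y_um = 0)
  dz <- distanceToTarget(z, c(0, 0))
  expect_true(attr(dz, "flagged"))
  expect_equal(dz$relative[2], 10)    # 1 um / 0.1 um floor
})

test_that("MTOC speed is recovered within 10% through render-detect-track", {
  cfg <- sceneConfig(n_cells = 10L, n_frames = 60L, width_um = 120,
                     height_um = 120, rng_seed = 21L,
                     obstacle_density_per_100um2 = 0)
  out <- mtocSpeedPipeline(cfg)
  expect_gte(length(unique(out$tracks$id)), 10)
  expect_lt(abs(mean(out$speeds$speed_um_min) - 1.4) / 1.4, 0.1)
})

test_that("MTOC approaches the debris during engulfment (relative distance)", {
  cfg <- sceneConfig(n_cells = 4L, n_frames = 40L, width_um = 150,
                     height_um = 150, rng_seed = 71L,
                     obstacle_density_per_100um2 = 0,
                     ablation = list(x_um = 75, y_um = 75, frame = 5L),
                     engulf_success_p = TRUE)
  sc <- generateScene(cfg, render = FALSE)
  eng <- engulfments(sc$truth)
  expect_equal(nrow(eng), 1)
  expect_true(eng$success[1])
  mt <- truthTracks(sc$truth, "mtoc")
  mt <- mt[mt$id == eng$cell[1], ]
  ## 5-minute window before engulfment
  w <- mt[mt$frame >= eng$engulf_frame[1] - 10 & mt$frame <= eng$engulf_frame[1], ]
  d <- distanceToTarget(w, c(eng$debris_x_um[1], eng$debris_y_um[1]))
  expect_lt(d$relative[nrow(d)], 0.3)
})
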