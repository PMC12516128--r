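## Hypergeometric enumeration oracle for a 2x2 Fisher's exact test
## (two-sided, by summing probabilities <= that of the observed table).
fisherOracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- sum(tab)
  prob <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }
  a_obs <- tab[1, 1]
  a_range <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(a_range, prob, numeric(1))
  sum(ps[ps <= prob(a_obs) * (1 + 1e-7)])
}

test_that("comparisons delegate to the standard tests and map stars", {
  ## identical samples: Mann-Whitney p = 1
  r <- compareGroups("mann_whitney", list(a = 1:10, b = 1:10))
  expect_equal(r$p_value, 1)
  expect_equal(r$stars, "ns")
  ## [[5,0],[0,5]] two-sided Fisher: p from the enumeration oracle
  tab <- rbind(c(5L, 0L), c(0L, 5L))
  rf <- compareGroups("fisher_exact", tab)
  expect_equal(rf$p_value, fisherOracle(tab), tolerance = 1e-9)
  expect_equal(round(rf$p_value, 4), 0.0079)
  ## chi-squared on two identical count vectors: statistic 0, p 1
  rc <- compareGroups("chi_squared", rbind(c(10L, 20L), c(10L, 20L)))
  expect_equal(unname(rc$statistic), 0)
  expect_equal(rc$p_value, 1)
  ## KS on clearly different samples is significant
  set.seed(30)
  rk <- compareGroups("ks", list(rnorm(200), rnorm(200, 3)))
  expect_lt(rk$p_value, 1e-4)
  expect_equal(rk$stars, "****")
  ## one-way ANOVA with Bonferroni pairwise table
  df <- data.frame(value = c(rnorm(20), rnorm(20, 2), rnorm(20, 2)),
                   group = rep(c("a", "b", "c"), each = 20))
  ra <- compareGroups("anova_bonferroni", df)
  expect_true(ra$significant)
  expect_equal(nrow(ra$pairwise), 3)
  expect_error(compareGroups("fisher_exact", rbind(c(0.5, 1), c(1, 2))),
               "integer")
})

test_that("random Fisher tables match the enumeration oracle", {
  set.seed(31)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(compareGroups("fisher_exact", tab)$p_value,
                 fisherOracle(tab), tolerance = 1e-7)
  }
})

test_that("star thresholds match the conventional legend mapping", {
  expect_equal(significanceStars(0.2), "ns")
  expect_equal(significanceStars(0.049), "*")
  expect_equal(significanceStars(0.009), "**")
  expect_equal(significanceStars(0.0009), "***")
  expect_equal(significanceStars(0.00009), "****")
})

test_that("the full pipeline runs, is deterministic, and contrasts conditions", {
  out1 <- file.path(tempdir(), "run1")
  out2 <- file.path(tempdir(), "run2")
  configs <- list(
    vehicle = conditionPreset("vehicle", n_cells = 8L, n_frames = 40L,
                              width_um = 250, height_um = 250, rng_seed = 91L,
                              obstacle_density_per_100um2 = 0.05,
                              wound = list(polygon = rightWoundPoly(250, 250))),
    nocodazole = conditionPreset("nocodazole", n_cells = 8L, n_frames = 40L,
                                 width_um = 250, height_um = 250,
                                 rng_seed = 92L,
                                 obstacle_density_per_100um2 = 0.05,
                                 wound = list(polygon = rightWoundPoly(250, 250))))
  res <- runPipeline(configs, out1)
  expect_true(file.exists(file.path(out1, "vehicle_tracks.csv")))
  expect_true(file.exists(file.path(out1, "comparisons.csv")))
  expect_true(file.exists(file.path(out1, "run_log.txt")))
  ## rerun with the same seeds: byte-identical tables
  runPipeline(configs, out2)
  expect_identical(readLines(file.path(out1, "vehicle_tracks.csv")),
                   readLines(file.path(out2, "vehicle_tracks.csv")))
  expect_identical(readLines(file.path(out1, "comparisons.csv")),
                   readLines(file.path(out2, "comparisons.csv")))
  ## empty scene config: clean stage-tagged rejection
  expect_error(runPipeline(list(vehicle = sceneConfig(n_cells = 0L)),
                           file.path(tempdir(), "run3")), "empty scene")
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("directed-migration metrics separate vehicle from nocodazole", {
  ## ground-truth-level cohort: nocodazole cells wander more (lower MI)
  mi <- function(cond, seed) {
    cfg <- conditionPreset(cond, n_cells = 12L, n_frames = 120L,
                           rng_seed = seed,
                           width_um = 300, height_um = 300,
                           obstacle_density_per_100um2 = 0,
                           wound = list(polygon = rightWoundPoly()))
    sc <- generateScene(cfg, render = FALSE)
    tr <- truthTracks(sc$truth, "cell")
    vapply(split(tr, tr$id), function(g)
      trackMetrics(g)$meandering_index, numeric(1))
  }
  mi_v <- mi("vehicle", 93L)
  mi_n <- mi("nocodazole", 94L)
  expect_gt(mean(mi_v), mean(mi_n))
  ## and fewer nocodazole cells accumulate at the wound margin
  endCount <- function(cond, seed) {
    cfg <- conditionPreset(cond, n_cells = 14L, n_frames = 150L,
                           rng_seed = seed, width_um = 300, height_um = 300,
                           obstacle_density_per_100um2 = 0,
                           wound = list(polygon = rightWoundPoly(),
                                        engulfing_p = 0, stretching_p = 0))
    sc <- generateScene(cfg, render = FALSE)
    roi <- buildMarginROI(woundPolygon(sc$truth, 1L))
    tr <- truthTracks(sc$truth, "cell")
    tr_f <- tr[tr$frame == 150, ]
    ## count cells whose centre lies in the margin at the end
    rel_x <- tr_f$x_um - roi@centroid[1]; rel_y <- tr_f$y_um - roi@centroid[2]
    u <- rel_x * roi@axis[1] + rel_y * roi@axis[2]
    v <- -rel_x * roi@axis[2] + rel_y * roi@axis[1]
    sum(abs(u) <= roi@margin_length_um / 2 & abs(v) <= roi@margin_width_um / 2)
  }
  n_v <- endCount("vehicle", 95L) + endCount("vehicle", 97L)
  n_n <- endCount("nocodazole", 96L) + endCount("nocodazole", 98L)
  expect_gt(n_v, n_n)
})
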