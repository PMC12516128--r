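polygonAreaTest <- function(poly) {
  n <- nrow(poly); x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

test_that("the margin rectangle follows the stated 150 x 1.2L formula", {
  ## wound of major-axis extent 100 um -> margin 150 x 120 um
  poly <- cbind(c(0, 100, 100, 0), c(0, 0, 20, 20))
  roi <- buildMarginROI(poly)
  expect_equal(roi@length_um, 100)
  expect_equal(roi@margin_width_um, 150)
  expect_equal(roi@margin_length_um, 120)
  ## margin area exact
  expect_equal(polygonAreaTest(roi@corners), 150 * 120)
  ## degenerate polygon rejected
  expect_error(buildMarginROI(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
})

test_that("a circular wound gets the deterministic tie-rule axis, flagged", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  circle <- cbind(50 + 30 * cos(th), 50 + 30 * sin(th))
  roi <- buildMarginROI(circle)
  expect_true(roi@axis_degenerate)
  expect_equal(roi@axis, c(1, 0))
  expect_equal(roi@length_um, 60, tolerance = 1e-3)
})

test_that("the margin axis aligns with a rotated ellipse's major axis", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  for (ang in c(0.3, 1.1, 2.0)) {
    R <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
    ell <- t(R %*% rbind(40 * cos(th), 15 * sin(th))) +
      matrix(rep(c(100, 100), each = length(th)), ncol = 2)
    roi <- buildMarginROI(ell)
    got <- atan2(roi@axis[2], roi@axis[1])
    diff <- abs(((got - ang + pi / 2) %% pi) - pi / 2)
    expect_lt(diff * 180 / pi, 2)
  }
})

test_that("margin counting applies the strict >50% rule and normalizes to t0", {
  poly <- cbind(c(100, 200, 200, 100), c(100, 100, 140, 140))
  roi <- buildMarginROI(poly)
  ## margin spans x in [90, 210], y in [45, 195]; build a square cell
  ## exactly half inside the x = 210 edge
  mk <- function(cx_um) {
    M <- matrix(FALSE, 600, 600)
    cols <- round((cx_um - 5) / 0.5 + 1):round((cx_um + 5) / 0.5)
    M[200:219, cols] <- TRUE
    maskFromMatrix(M)
  }
  exact_half <- mk(210)       # 50% inside: not counted
  just_in <- mk(209)          # > 50% inside: counted
  outside <- mk(260)
  cnt <- countCellsInMargin(list(list(exact_half, just_in, outside)), roi)
  expect_equal(cnt$count, 1)
  ## normalization to the first timepoint
  one <- list(list(just_in), list(just_in, mk(150)), list())
  cn <- countCellsInMargin(one, roi)
  expect_equal(cn$normalized, c(1, 2, 0))
  ## zero first-frame count: normalize by 1, flagged
  cz <- countCellsInMargin(list(list(outside), list(just_in)), roi)
  expect_true(attr(cz, "flagged"))
  expect_equal(cz$normalized, c(0, 1))
  ## monotone: enlarging the ROI never decreases the count (wider margin,
  ## and a larger wound whose margin is a superset)
  roi_wide <- buildMarginROI(poly, margin_width_um = 400)
  cnt_wide <- countCellsInMargin(list(list(exact_half, just_in, outside)),
                                 roi_wide)
  expect_gte(cnt_wide$count, cnt$count)
  grow <- sweep(sweep(poly, 2, c(150, 120)) * 1.6, 2, c(150, 120), "+")
  roi_grow <- buildMarginROI(grow, margin_width_um = 400)
  cnt_grow <- countCellsInMargin(list(list(exact_half, just_in, outside)),
                                 roi_grow)
  expect_gte(cnt_grow$count, cnt_wide$count)
})

test_that("wound areas normalize to time 0 and follow the closure rate", {
  sq <- function(s) cbind(c(0, s, s, 0), c(0, 0, s, s))
  ws <- woundAreaSeries(list(sq(sqrt(1000)), sq(sqrt(800)), sq(sqrt(500))))
  expect_equal(ws$normalized, c(1, 0.8, 0.5))
  expect_equal(woundAreaSeries(list(sq(10), sq(10)))$normalized, c(1, 1))
  expect_error(woundAreaSeries(list(cbind(c(0, 1, 2), c(0, 0, 0)))), "area")
  ## generator closure at rate r/hour gives a (1 - r t) normalized series
  cfg <- scratchConfig(n_cells = 0L, n_frames = 241L, seed = 8L,
                       wound = list(polygon = rightWoundPoly(),
                                    closure_rate_per_h = 0.3))
  sc <- generateScene(cfg, render = FALSE)
  polys <- lapply(c(1L, 121L, 241L), function(f) woundPolygon(sc$truth, f))
  ws2 <- woundAreaSeries(polys)
  expect_equal(ws2$normalized, c(1, 1 - 0.3 * 1, 1 - 0.3 * 2), tolerance = 0.05)
})

test_that("phenotype scoring applies the wound / circularity / tip rules", {
  poly <- cbind(c(100, 200, 200, 100), c(100, 100, 160, 160))
  roi <- buildMarginROI(poly)
  disk <- function(cx, cy, r_px) {
    M <- matrix(FALSE, 600, 600)
    d <- sqrt(outer((1:600 - cy / 0.5)^2, (1:600 - cx / 0.5)^2, "+"))
    M[d <= r_px] <- TRUE
    maskFromMatrix(M)
  }
  round_in <- disk(150, 130, 10)          # round cell centred in the wound
  out_cell <- disk(150, 190, 10)          # outside, below the wound
  stretch_path <- cbind(x_um = c(150, 150), y_um = c(185, 155))  # tip inside
  ds <- new("DendriteSet", cell = 2L, frame = 1L,
            table = data.frame(dendrite = 1L, length_um = 30, mean_emtb = 1,
                               mean_cyto = 1, ratio = 1, emtb_positive = TRUE),
            paths = list(stretch_path), soma_center_um = c(150, 190),
            soma_radius_um = 5)
  sc <- scorePhenotypes(list(round_in, out_cell), list(NULL, ds), poly, roi)
  expect_equal(sc$phenotype, c("engulfing", "stretching"))
  ## one mutually exclusive label per cell
  expect_equal(nrow(sc), 2)
  ## the same outside cell without a crossing dendrite is 'neither'
  sc2 <- scorePhenotypes(list(out_cell), list(NULL), poly, roi)
  expect_equal(sc2$phenotype, "neither")
  expect_error(scorePhenotypes(list(round_in), list(NULL), NULL, roi),
               "wound polygon")
})

test_that("configured phenotype fractions are recovered from scratch scenes", {
  got <- c(engulfing = 0, stretching = 0, neither = 0)
  truth_lab <- c(engulfing = 0, stretching = 0, neither = 0)
  for (seed in c(501L, 502L, 503L)) {
    cfg <- scratchConfig(n_cells = 12L, n_frames = 150L, seed = seed,
                         obstacle_density_per_100um2 = 0.05,
                         wound = list(polygon = rightWoundPoly(),
                                      engulfing_p = 0.3, stretching_p = 0.2))
    sc <- generateScene(cfg, render = FALSE)
    lab <- phenotypes(sc$truth)$label
    for (l in names(truth_lab)) truth_lab[l] <- truth_lab[l] + sum(lab == l)
    ## score from final-frame geometry: build masks and dendrite sets from
    ## ground truth
    f <- 150L
    tr <- truthTracks(sc$truth, "cell")
    tr_f <- tr[tr$frame == f, ]
    dd <- sc$truth@dendrites
    dd_f <- dd[dd$frame == f, ]
    poly <- woundPolygon(sc$truth, f)
    roi <- buildMarginROI(poly)
    for (i in tr_f$id) {
      ## synthetic round mask scaled by remaining dendrite length
      mean_len <- mean(dd_f$length_um[dd_f$cell == i])
      r_px <- 10
      cx <- tr_f$x_um[tr_f$id == i]; cy <- tr_f$y_um[tr_f$id == i]
      M <- matrix(FALSE, 600, 600)
      d <- sqrt(outer((1:600 - cy / 0.5)^2, (1:600 - cx / 0.5)^2, "+"))
      M[d <= r_px] <- TRUE
      mask <- maskFromMatrix(M)
      paths <- lapply(which(dd_f$cell == i), function(k) {
        cbind(x_um = c(cx, dd_f$tip_x_um[k]), y_um = c(cy, dd_f$tip_y_um[k]))
      })
      ds <- new("DendriteSet", cell = as.integer(i), frame = f,
                table = data.frame(dendrite = seq_along(paths),
                                   length_um = 1, mean_emtb = 1,
                                   mean_cyto = 1, ratio = 1,
                                   emtb_positive = TRUE),
                paths = paths, soma_center_um = c(cx, cy), soma_radius_um = 5)
      res <- scorePhenotypes(list(mask), list(ds), poly, roi)
      got[res$phenotype] <- got[res$phenotype] + 1
    }
  }
  n <- sum(got)
  expect_equal(n, sum(truth_lab))
  for (l in c("engulfing", "stretching"))
    expect_lt(abs(100 * got[[l]] / n - 100 * truth_lab[[l]] / n), 5 + 1e-9)
})
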