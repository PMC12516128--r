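test_that("bisection partitions the mask and matches the dot-product oracle", {
  set.seed(20)
  for (rep in 1:10) {
    ## irregular blob mask
    M <- matrix(FALSE, 40, 40)
    ctr <- c(20, 20)
    for (k in 1:6) {
      c2 <- ctr + round(rnorm(2, 0, 5))
      r <- sample(4:8, 1)
      d <- sqrt(outer((1:40 - c2[1])^2, (1:40 - c2[2])^2, "+"))
      M[d <= r] <- TRUE
    }
    mask <- maskFromMatrix(M)
    v <- unitVec(rnorm(2))
    halves <- bisectMask(mask, v)
    ## exact partition
    expect_equal(nrow(halves$trailing) + nrow(halves$leading),
                 nrow(mask@pixels))
    expect_equal(nrow(unique(rbind(halves$trailing, halves$leading))),
                 nrow(mask@pixels))
    ## per-pixel sign-of-dot-product oracle (x ~ col, y ~ row)
    cr <- mean(mask@pixels[, "row"]); cc <- mean(mask@pixels[, "col"])
    proj <- (mask@pixels[, "col"] - cc) * v[1] +
      (mask@pixels[, "row"] - cr) * v[2]
    expect_equal(nrow(halves$leading), sum(proj >= 0))
    expect_equal(nrow(halves$trailing), sum(proj < 0))
  }
})

test_that("a symmetric disk splits into equal halves for any direction", {
  mask <- diskMask(radius_px = 12)
  for (ang in c(0, 0.7, 2.1, 4.5)) {
    v <- c(cos(ang), sin(ang))
    halves <- bisectMask(mask, v)
    ## halves are equal up to the on-line pixels the tie rule sends leading
    cr <- mean(mask@pixels[, "row"]); cc <- mean(mask@pixels[, "col"])
    online <- sum(abs((mask@pixels[, "col"] - cc) * v[1] +
                        (mask@pixels[, "row"] - cr) * v[2]) < 1e-9)
    expect_lte(abs(nrow(halves$trailing) - nrow(halves$leading)),
               online + 0.02 * nrow(mask@pixels))
  }
  ## rightward motion on a rectangle: leading = right half
  M <- matrix(FALSE, 20, 30); M[5:15, 5:24] <- TRUE
  halves <- bisectMask(maskFromMatrix(M), c(1, 0))
  expect_true(all(halves$leading[, "col"] >= 14))
  expect_true(all(halves$trailing[, "col"] <= 14))
})

test_that("uniform and two-level cells give exact polarity ratios", {
  mask <- diskMask(radius_px = 12)
  img_u <- matrix(100, mask@dim[1], mask@dim[2])
  track <- data.frame(frame = 1:3, x_um = c(0, 1, 2), y_um = 0)
  masks <- lapply(1:3, function(f) { m <- mask; m@frame <- as.integer(f); m })
  pr <- polarityRatio(masks, list(img_u, img_u, img_u), track)
  expect_equal(pr$ratio, 1.0)
  ## trailing half at 200, leading at 100 under rightward motion
  ctr_col <- mean(mask@pixels[, "col"])
  img2 <- matrix(0, mask@dim[1], mask@dim[2])
  img2[, seq_len(ncol(img2)) < ctr_col] <- 200
  img2[, seq_len(ncol(img2)) >= ctr_col] <- 100
  pr2 <- polarityRatio(masks, list(img2, img2, img2), track)
  expect_equal(pr2$ratio, 2.0, tolerance = 0.02)
  ## motionless track: no polarity axis
  still <- data.frame(frame = 1:3, x_um = 0, y_um = 0)
  expect_error(polarityRatio(masks, list(img_u, img_u, img_u), still),
               "axis")
})

test_that("the ratio is rotation-invariant and inverts with direction", {
  ## analytic cell: disk with a two-level pattern along direction theta
  build <- function(theta, ratio) {
    n <- 41; ctr <- 21
    d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
    M <- d <= 15
    img <- matrix(0, n, n)
    proj <- outer(rep(1, n), 1:n - ctr) * cos(theta) +
      outer(1:n - ctr, rep(1, n)) * sin(theta)
    img[M & proj < 0] <- 100 * ratio
    img[M & proj >= 0] <- 100
    list(mask = maskFromMatrix(M), img = img)
  }
  ratios <- vapply(c(0, 0.6, 1.3, 2.5), function(th) {
    b <- build(th, 1.5)
    h <- bisectMask(b$mask, c(cos(th), sin(th)))
    mean(b$img[h$trailing]) / mean(b$img[h$leading])
  }, numeric(1))
  expect_true(all(abs(ratios - ratios[1]) / ratios[1] < 0.03))
  ## reversal: ratio(v) x ratio(-v) = 1
  b <- build(0.9, 1.5)
  h1 <- bisectMask(b$mask, c(cos(0.9), sin(0.9)))
  h2 <- bisectMask(b$mask, -c(cos(0.9), sin(0.9)))
  r1 <- mean(b$img[h1$trailing]) / mean(b$img[h1$leading])
  r2 <- mean(b$img[h2$trailing]) / mean(b$img[h2$leading])
  expect_lt(abs(r1 * r2 - 1), 0.03)
})

## Measure the mean polarity ratio of rendered migrating cells.
measuredSceneRatio <- function(condition, seeds, n_cells = 10L) {
  ratios <- c()
  for (seed in seeds) {
    cfg <- conditionPreset(condition,
                           n_cells = n_cells, n_frames = 10L,
                           width_um = 260, height_um = 260, rng_seed = seed,
                           obstacle_density_per_100um2 = 0,
                           wound = list(polygon = rightWoundPoly(260, 260)),
                           noise = noiseFree())
    sc <- generateScene(cfg, render = TRUE,
                        channels = c("cytosol", "lifeact"), keep_masks = TRUE)
    tr <- truthTracks(sc$truth, "cell")
    for (i in unique(tr$id)) {
      masks <- list(); imgs <- list()
      for (f in 1:10) {
        lab <- sc$truth@masks[[f]]
        if (!any(lab == i)) next
        p <- which(lab == i, arr.ind = TRUE)
        colnames(p) <- c("row", "col")
        masks[[length(masks) + 1]] <- new("CellMask", frame = as.integer(f),
                                          label = as.integer(i), pixels = p,
                                          dim = dim(lab), pixel_size_um = 0.5)
        imgs[[length(imgs) + 1]] <- frameMatrix(sc$timelapse, f, "lifeact")
      }
      if (length(masks) < 4) next
      r <- tryCatch(polarityRatio(masks, imgs, tr[tr$id == i, ])$ratio,
                    error = function(e) NA_real_)
      ratios <- c(ratios, r)
    }
  }
  ratios[!is.na(ratios)]
}

test_that("generated polarity targets are recovered and track the presets", {
  ## target 1.5 recovered within 10% over >= 20 cells
  r_noc <- measuredSceneRatio("nocodazole", c(301L, 302L))
  expect_gte(length(r_noc), 20)
  expect_lt(abs(mean(r_noc) - 1.5) / 1.5, 0.1)
  ## vehicle is unpolarized; ROCK co-inhibition restores vehicle level
  r_veh <- measuredSceneRatio("vehicle", c(303L, 305L))
  r_ri <- measuredSceneRatio("noc_rocki", c(304L, 306L))
  expect_gt(mean(r_noc), mean(r_veh))
  expect_lt(abs(mean(r_ri) - mean(r_veh)) / mean(r_veh), 0.1)
})
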