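test_that("segmentation finds disjoint bright objects and handles blanks", {
  img <- matrix(0, 60, 60)
  img[10:19, 10:19] <- 100
  img[40:49, 35:44] <- 100
  m <- segmentCells(img, pixel_size_um = 0.5, min_area_um2 = 5)
  expect_length(m, 2)
  expect_equal(vapply(m, function(x) nrow(x@pixels), numeric(1)), c(100, 100))
  ## deterministic labelling by bounding-box top, then left
  expect_equal(m[[1]]@label, 1L)
  expect_equal(min(m[[1]]@pixels[, "row"]), 10)
  ## blank image: empty list, not an error
  expect_length(segmentCells(matrix(0, 20, 20), 0.5), 0)
  ## uncalibrated image: rejection
  expect_error(segmentCells(img), "calibrated")
})

test_that("segmented masks overlap ground truth at IoU >= 0.8 at default noise", {
  cfg <- sceneConfig(n_cells = 4L, n_frames = 1L, width_um = 150,
                     height_um = 150, rng_seed = 31L,
                     obstacle_density_per_100um2 = 0)
  sc <- generateScene(cfg, render = TRUE, keep_masks = TRUE)
  masks <- segmentCells(frameMatrix(sc$timelapse, 1, "cytosol"), 0.5,
                        min_area_um2 = 30)
  truth_lab <- sc$truth@masks[[1]]
  expect_gte(length(masks), 4)
  for (id in 1:4) {
    tm <- truth_lab == id
    iou <- vapply(masks, function(m) {
      sm <- maskMatrix(m)
      sum(sm & tm) / sum(sm | tm)
    }, numeric(1))
    expect_gte(max(iou), 0.8)
  }
})

test_that("a star cell yields its five arms at the drawn length", {
  sc <- generateScene(starConfig(n_dend = 5, len_um = 12), keep_masks = TRUE)
  m <- segmentCells(frameMatrix(sc$timelapse, 1, "cytosol"), 0.5)
  expect_length(m, 1)
  ds <- extractDendrites(m[[1]],
                         frameMatrix(sc$timelapse, 1, "emtb"),
                         frameMatrix(sc$timelapse, 1, "cytosol"))
  expect_equal(nrow(ds@table), 5)
  expect_true(all(abs(ds@table$length_um - 12) <= 1))
  ## all paths start on the soma boundary
  starts <- t(vapply(ds@paths, function(p) p[1, ], numeric(2)))
  d0 <- sqrt(rowSums(sweep(starts, 2, ds@soma_center_um)^2))
  expect_true(all(abs(d0 - ds@soma_radius_um) < 1))
})

test_that("microtubule positivity uses a strict 0.5 ratio cut", {
  sc <- generateScene(starConfig(), keep_masks = TRUE)
  m <- segmentCells(frameMatrix(sc$timelapse, 1, "cytosol"), 0.5)[[1]]
  cyto <- frameMatrix(sc$timelapse, 1, "cytosol")
  ## synthetic EMTB channels with exactly controlled ratios
  ds06 <- extractDendrites(m, cyto * 0.6, cyto)
  expect_true(all(ds06@table$emtb_positive))
  ds05 <- extractDendrites(m, cyto * 0.5, cyto)
  expect_false(any(ds05@table$emtb_positive))
  ## monotonicity: raising EMTB intensity never flips positive -> negative
  ds08 <- extractDendrites(m, cyto * 0.8, cyto)
  expect_true(all(ds08@table$emtb_positive >= ds06@table$emtb_positive))
})

test_that("EMTB-positive dendrite fraction is recovered from rendered scenes", {
  got <- 0L; pos <- 0L; truth_pos <- 0L; truth_n <- 0L
  for (seed in c(101L, 102L, 103L)) {
    cfg <- sceneConfig(n_cells = 4L, n_frames = 1L, width_um = 160,
                       height_um = 160, rng_seed = seed,
                       obstacle_density_per_100um2 = 0,
                       emtb_positive_p = 0.8)
    sc <- generateScene(cfg, render = TRUE, keep_masks = TRUE)
    dd <- sc$truth@dendrites[sc$truth@dendrites$frame == 1, ]
    truth_pos <- truth_pos + sum(dd$emtb_positive)
    truth_n <- truth_n + nrow(dd)
    masks <- segmentCells(frameMatrix(sc$timelapse, 1, "cytosol"), 0.5,
                          min_area_um2 = 30)
    for (m in masks) {
      ds <- suppressWarnings(
        extractDendrites(m, frameMatrix(sc$timelapse, 1, "emtb"),
                         frameMatrix(sc$timelapse, 1, "cytosol")))
      got <- got + nrow(ds@table)
      pos <- pos + sum(ds@table$emtb_positive)
    }
  }
  expect_gte(got, 30)
  expect_lt(abs(100 * pos / got - 100 * truth_pos / truth_n), 5)
})

test_that("skeleton lengths track generator arm lengths within 10% without noise", {
  for (len in c(8, 15)) {
    sc <- generateScene(starConfig(n_dend = 4, len_um = len, seed = 17L),
                        keep_masks = TRUE)
    m <- segmentCells(frameMatrix(sc$timelapse, 1, "cytosol"), 0.5)[[1]]
    ds <- extractDendrites(m, frameMatrix(sc$timelapse, 1, "emtb"),
                           frameMatrix(sc$timelapse, 1, "cytosol"))
    expect_true(all(abs(ds@table$length_um - len) / len <= 0.1))
  }
})

test_that("dendrite metrics average over 10-minute samples", {
  mkds <- function(lens) {
    new("DendriteSet", cell = 1L, frame = 1L,
        table = data.frame(dendrite = seq_along(lens), length_um = lens,
                           mean_emtb = 1, mean_cyto = 1, ratio = 1,
                           emtb_positive = TRUE),
        paths = list(), soma_center_um = c(0, 0), soma_radius_um = 5)
  }
  ## constant 5 dendrites of 12 um at every sample
  series <- replicate(5, mkds(rep(12, 5)), simplify = FALSE)
  mm <- dendriteMetrics(series, times_s = seq(0, 2400, 600))
  expect_equal(mm$avg_count, 5)
  expect_equal(mm$avg_length_um, 12)
  expect_equal(mm$max_length_um, 12)
  ## counts 4 and 6 at two samples average to 5
  m2 <- dendriteMetrics(list(mkds(rep(10, 4)), mkds(rep(10, 6))),
                        times_s = c(0, 600))
  expect_equal(m2$avg_count, 5)
  expect_error(dendriteMetrics(list(), numeric(0)), "empty")
})

test_that("nocodazole scenes have longer, fewer dendrites than vehicle", {
  measure <- function(cond, seeds) {
    lens <- c(); counts <- c()
    for (seed in seeds) {
      cfg <- conditionPreset(cond, n_cells = 4L, n_frames = 1L,
                             width_um = 170, height_um = 170, rng_seed = seed,
                             obstacle_density_per_100um2 = 0)
      sc <- generateScene(cfg, render = TRUE)
      masks <- segmentCells(frameMatrix(sc$timelapse, 1, "cytosol"), 0.5,
                            min_area_um2 = 30)
      for (m in masks) {
        ds <- suppressWarnings(
          extractDendrites(m, frameMatrix(sc$timelapse, 1, "emtb"),
                           frameMatrix(sc$timelapse, 1, "cytosol")))
        if (nrow(ds@table)) {
          lens <- c(lens, mean(ds@table$length_um))
          counts <- c(counts, nrow(ds@table))
        }
      }
    }
    list(len = lens, count = counts)
  }
  veh <- measure("vehicle", c(201L, 202L))
  noc <- measure("nocodazole", c(203L, 204L))
  expect_gt(mean(noc$len), mean(veh$len))
  expect_gt(max(noc$len), max(veh$len))
  expect_lt(mean(noc$count), mean(veh$count))
})
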