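#' Segment cells from a single-channel frame
#'
#' Thresholds the image (Otsu by default, or a fixed value), labels
#' connected components and returns one [CellMask-class] per component with
#' area at least `min_area_um2`. Labels are assigned deterministically by
#' the (top, left) corner of each component's bounding box.
#'
#' @param img numeric matrix, one channel of one frame.
#' @param pixel_size_um calibration (um/pixel); must be supplied.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold (required when `threshold_method =
#'   "fixed"`).
#' @param min_area_um2 minimum object area (um^2).
#' @param frame frame index recorded in the masks.
#' @return List of [CellMask-class]; empty when nothing is above threshold.
#' @examples
#' img <- matrix(0, 40, 40); img[5:10, 5:10] <- 100
#' m <- segmentCells(img, pixel_size_um = 0.5)
#' length(m)
#' @export
segmentCells <- function(img, pixel_size_um,
                         threshold_method = c("otsu", "fixed"),
                         threshold = NULL, min_area_um2 = 20,
                         frame = 1L) {
  stopIfNot(is.matrix(img), "'img' must be a matrix")
  stopIfNot(!missing(pixel_size_um) && is.numeric(pixel_size_um) &&
              length(pixel_size_um) == 1 && pixel_size_um > 0,
            "image must be calibrated: supply a positive 'pixel_size_um'")
  stopIfNot(min_area_um2 >= 0, "'min_area_um2' must be >= 0")
  threshold_method <- match.arg(threshold_method)
  if (all(img <= 0) || max(img) == min(img)) return(list())
  thr <- if (threshold_method == "otsu") {
    rng <- range(img)
    norm <- (img - rng[1]) / (rng[2] - rng[1])
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) *
      (rng[2] - rng[1]) + rng[1]
  } else {
    stopIfNot(!is.null(threshold), "'threshold' required for fixed method")
    threshold
  }
  bin <- img > thr
  if (!any(bin)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labm <- EBImage::imageData(lab)
  ids <- setdiff(sort(unique(as.vector(labm))), 0)
  min_px <- min_area_um2 / pixel_size_um^2
  masks <- list()
  for (id in ids) {
    pix <- which(labm == id, arr.ind = TRUE)
    if (nrow(pix) < min_px) next
    masks[[length(masks) + 1]] <- pix
  }
  if (!length(masks)) return(list())
  ## deterministic labelling by bounding-box (top, left)
  key <- vapply(masks, function(p) min(p[, 1]) * (ncol(img) + 1) + min(p[, 2]),
                numeric(1))
  masks <- masks[order(key)]
  lapply(seq_along(masks), function(i) {
    p <- masks[[i]]
    colnames(p) <- c("row", "col")
    new("CellMask", frame = as.integer(frame), label = as.integer(i),
        pixels = p, dim = dim(img), pixel_size_um = pixel_size_um)
  })
}

#' Detect MTOC foci in a microtubule-reporter frame
#'
#' The MTOC is identified as the brightest microtubule-reporter (EMTB)
#' focus: the image is median-prefiltered (3 px), then either the global
#' maximum within each supplied cell mask is taken (one MTOC per cell), or,
#' without masks, bright foci are found by thresholding well above
#' background and labelling. Either way the returned position is the
#' intensity-weighted centroid of a small window around the peak, giving
#' sub-pixel localization.
#'
#' @param img EMTB-channel matrix.
#' @param pixel_size_um calibration.
#' @param cells optional list of [CellMask-class]; one detection per mask.
#' @param min_intensity minimum peak intensity for mask-free spot detection
#'   (default: background median plus 8 MADs).
#' @param frame frame index recorded in the output.
#' @return data.frame (frame, label, x_um, y_um, intensity).
#' @export
detectMtocs <- function(img, pixel_size_um, cells = NULL,
                        min_intensity = NULL, frame = 1L) {
  stopIfNot(is.matrix(img), "'img' must be a matrix")
  sm <- median3x3(img)
  peakRow <- function(pix) {
    vals <- sm[pix]
    top <- pix[which.max(vals), ]
    win <- 3L
    rr <- max(1, top[1] - win):min(nrow(img), top[1] + win)
    cc <- max(1, top[2] - win):min(ncol(img), top[2] + win)
    w <- sm[rr, cc, drop = FALSE]
    w <- pmax(w - min(w), 0)
    if (sum(w) == 0) w[] <- 1
    r0 <- sum(rr * rowSums(w)) / sum(w)
    c0 <- sum(cc * colSums(w)) / sum(w)
    c(r0, c0, max(vals))
  }
  out <- list()
  if (!is.null(cells)) {
    for (m in cells) {
      pk <- peakRow(m@pixels)
      out[[length(out) + 1]] <- data.frame(
        frame = as.integer(frame), label = m@label,
        x_um = colToUm(pk[2], pixel_size_um),
        y_um = rowToUm(pk[1], pixel_size_um), intensity = pk[3])
    }
  } else {
    if (is.null(min_intensity)) {
      ## MTOC foci are by far the brightest structures; half the image
      ## maximum separates them from dendritic microtubule signal while
      ## a robust noise floor guards near-empty frames
      med <- stats::median(sm)
      min_intensity <- max(0.5 * max(sm), med + 8 * stats::mad(sm))
    }
    bin <- sm > min_intensity
    if (any(bin)) {
      labm <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
      ids <- setdiff(sort(unique(as.vector(labm))), 0)
      k <- 0
      for (id in ids) {
        pix <- which(labm == id, arr.ind = TRUE)
        if (nrow(pix) < 3) next     # reject single-pixel noise excursions
        k <- k + 1
        pk <- peakRow(pix)
        out[[length(out) + 1]] <- data.frame(
          frame = as.integer(frame), label = k,
          x_um = colToUm(pk[2], pixel_size_um),
          y_um = rowToUm(pk[1], pixel_size_um), intensity = pk[3])
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), label = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  do.call(rbind, out)
}

#' Build cell masks from a ground-truth label matrix
#'
#' Converts an integer label matrix (e.g. from the synthetic generator's
#' `masks` slot) into [CellMask-class] objects, bypassing thresholding.
#' Useful for exercising downstream logic on noise-free geometry.
#'
#' @param labm integer label matrix (0 = background).
#' @param pixel_size_um calibration.
#' @param frame frame index recorded in the masks.
#' @return List of [CellMask-class].
#' @export
masksFromLabels <- function(labm, pixel_size_um, frame = 1L) {
  ids <- setdiff(sort(unique(as.vector(labm))), 0)
  lapply(ids, function(id) {
    p <- which(labm == id, arr.ind = TRUE)
    colnames(p) <- c("row", "col")
    new("CellMask", frame = as.integer(frame), label = as.integer(id),
        pixels = p, dim = dim(labm), pixel_size_um = pixel_size_um)
  })
}
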