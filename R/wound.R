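#' Build the wound-margin rectangle from a wound outline
#'
#' The margin is the standard counting region: a rectangle 150 um wide and
#' (wound length x 1.2) um long, centred on the wound centroid with its
#' long axis along the wound's major axis. The major axis is the principal
#' axis of the outline vertices; for outlines without a unique axis (e.g. a
#' circle) the principal vector with the smallest angle to the x-axis is
#' used and the result is flagged.
#'
#' @param wound_polygon n x 2 matrix of outline vertices (um), n >= 3.
#' @param frame frame index recorded in the ROI.
#' @param margin_width_um margin width (default 150).
#' @return A [WoundROI-class].
#' @examples
#' roi <- buildMarginROI(cbind(c(0, 100, 100, 0), c(0, 0, 20, 20)))
#' roi
#' @export
buildMarginROI <- function(wound_polygon, frame = 1L,
                           margin_width_um = 150) {
  stopIfNot(is.matrix(wound_polygon) && ncol(wound_polygon) == 2 &&
              nrow(wound_polygon) >= 3, "polygon must be an n x 2 matrix")
  stopIfNot(polygonArea(wound_polygon) > 0, "degenerate polygon (area 0)")
  ctr <- polygonCentroid(wound_polygon)
  X <- sweep(wound_polygon, 2, colMeans(wound_polygon))
  cv <- crossprod(X) / nrow(X)
  eg <- eigen(cv, symmetric = TRUE)
  degenerate <- abs(eg$values[1] - eg$values[2]) <
    1e-6 * max(eg$values[1], 1e-12)
  if (degenerate) {
    ## tie rule: principal vector with the smallest angle to the x-axis
    axis <- c(1, 0)
  } else {
    axis <- eg$vectors[, 1]
    if (axis[1] < 0 || (axis[1] == 0 && axis[2] < 0)) axis <- -axis
  }
  ## wound length: extent of the outline along the major axis
  proj <- X %*% axis
  len <- max(proj) - min(proj)
  ml <- 1.2 * len
  perp <- rotate90(axis)
  hw <- margin_width_um / 2; hl <- ml / 2
  corners <- rbind(ctr + axis * hl + perp * hw,
                   ctr + axis * hl - perp * hw,
                   ctr - axis * hl - perp * hw,
                   ctr - axis * hl + perp * hw)
  new("WoundROI", polygon = wound_polygon, frame = as.integer(frame),
      length_um = len, centroid = ctr, axis = as.numeric(axis),
      margin_width_um = margin_width_um, margin_length_um = ml,
      corners = corners, axis_degenerate = degenerate)
}

#' Count cells in the wound margin, normalized to the first timepoint
#'
#' A cell is counted in a frame when strictly more than 50% of its mask
#' area lies inside the margin rectangle. The count series is divided by
#' the count at the first frame; a zero first-frame count normalizes by 1
#' and flags the result.
#'
#' @param masks_per_frame list (one element per timepoint) of lists of
#'   [CellMask-class].
#' @param roi a [WoundROI-class].
#' @return data.frame `timepoint`, `count`, `normalized`; attribute
#'   `flagged`.
#' @export
countCellsInMargin <- function(masks_per_frame, roi) {
  counts <- vapply(masks_per_frame, function(masks) {
    sum(vapply(masks, function(m) maskFractionInRect(m, roi) > 0.5, logical(1)))
  }, numeric(1))
  denom <- if (length(counts) && counts[1] > 0) counts[1] else 1
  out <- data.frame(timepoint = seq_along(counts), count = counts,
                    normalized = counts / denom)
  attr(out, "flagged") <- length(counts) > 0 && counts[1] == 0
  out
}

## Fraction of a mask's area inside the (possibly rotated) margin rectangle.
maskFractionInRect <- function(mask, roi) {
  px <- mask@pixel_size_um
  x <- colToUm(mask@pixels[, "col"], px)
  y <- rowToUm(mask@pixels[, "row"], px)
  rel_x <- x - roi@centroid[1]; rel_y <- y - roi@centroid[2]
  a <- roi@axis; p <- rotate90(a)
  u <- rel_x * a[1] + rel_y * a[2]
  v <- rel_x * p[1] + rel_y * p[2]
  inside <- abs(u) <= roi@margin_length_um / 2 &
    abs(v) <= roi@margin_width_um / 2
  mean(inside)
}

#' Wound area closure series
#'
#' Polygon areas (shoelace formula) normalized to the area at time 0.
#'
#' @param polygons list of n x 2 matrices (um), first element = time 0.
#' @return data.frame `timepoint`, `area_um2`, `normalized`.
#' @export
woundAreaSeries <- function(polygons) {
  stopIfNot(length(polygons) >= 1, "need at least the time-0 polygon")
  areas <- vapply(polygons, polygonArea, numeric(1))
  stopIfNot(areas[1] > 0, "time-0 wound area is 0")
  data.frame(timepoint = seq_along(areas), area_um2 = areas,
             normalized = areas / areas[1])
}

#' Score engulfing / stretching phenotypes at the wound
#'
#' A cell is `engulfing` when its centroid lies inside the wound polygon
#' and its mask is rounded (circularity 4*pi*A/P^2 above
#' `round_threshold`); `stretching` when its centroid is outside the wound
#' but at least one dendrite tip lies inside; otherwise `neither`.
#' Denominators for rate summaries are the cells within the margin ROI.
#'
#' @param masks list of [CellMask-class] at the evaluation time.
#' @param dendrite_sets list of [DendriteSet-class] matching `masks` (can
#'   contain NULL for cells without traced dendrites).
#' @param wound_polygon n x 2 matrix (um).
#' @param roi a [WoundROI-class] (margin counting region).
#' @param round_threshold circularity cut for the rounded phagocytic
#'   phenotype (default 0.6).
#' @return data.frame `label` (cell), `phenotype`, `in_margin`,
#'   `circularity`.
#' @export
scorePhenotypes <- function(masks, dendrite_sets, wound_polygon, roi,
                            round_threshold = 0.6) {
  stopIfNot(!is.null(wound_polygon), "wound polygon required")
  rows <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    ctr <- maskCentroid(m)
    inside <- pointsInPolygon(matrix(ctr, ncol = 2), wound_polygon)
    circ <- maskCircularity(m)
    phen <- "neither"
    if (inside && circ > round_threshold) {
      phen <- "engulfing"
    } else if (!inside) {
      ds <- dendrite_sets[[i]]
      if (!is.null(ds) && length(ds@paths)) {
        tips <- do.call(rbind, lapply(ds@paths, function(p) p[nrow(p), ]))
        if (any(pointsInPolygon(tips, wound_polygon))) phen <- "stretching"
      }
    }
    data.frame(label = m@label, phenotype = phen,
               in_margin = maskFractionInRect(m, roi) > 0.5,
               circularity = circ)
  })
  do.call(rbind, rows)
}

## Circularity 4*pi*A/P^2 with perimeter estimated from the pixel boundary
## (edge-count perimeter with diagonal correction via EBImage features).
maskCircularity <- function(mask) {
  M <- maskMatrix(mask)
  fs <- EBImage::computeFeatures.shape(matrix(as.integer(M), nrow(M)))
  A <- fs[1, "s.area"]; P <- fs[1, "s.perimeter"]
  if (P <= 0) return(0)
  min(1, 4 * pi * A / P^2)
}
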