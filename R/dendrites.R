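#' Set of dendrites extracted from one cell mask
#'
#' @slot cell cell label.
#' @slot frame frame index.
#' @slot table data.frame with one row per dendrite: `dendrite`,
#'   `length_um`, `mean_emtb`, `mean_cyto`, `ratio`, `emtb_positive`.
#' @slot paths list of polylines (n x 2 matrices, columns x_um, y_um) from
#'   the soma boundary to each tip.
#' @slot soma_center_um,soma_radius_um maximal inscribed disk of the mask.
#' @seealso [extractDendrites()]
#' @export
setClass("DendriteSet", representation(
  cell = "integer", frame = "integer", table = "data.frame",
  paths = "list", soma_center_um = "numeric", soma_radius_um = "numeric"
))

setMethod("show", "DendriteSet", function(object) {
  cat(sprintf("DendriteSet: cell %d frame %d, %d dendrites, mean length %.1f um\n",
              object@cell, object@frame, nrow(object@table),
              if (nrow(object@table)) mean(object@table$length_um) else NA))
  invisible(NULL)
})

#' Extract dendrites from a cell mask by skeleton-branch tracing
#'
#' The soma is taken as the maximal inscribed disk of the mask (dilated by
#' 1 px); the mask skeleton is computed by thinning, skeleton pixels inside
#' the soma are removed, and each remaining connected piece attached to the
#' soma is traced from its soma-proximal root to its endpoints. Per root,
#' the longest root-to-tip geodesic is the primary dendrite; additional
#' endpoints count as separate dendrites only when their private branch
#' exceeds `min_branch_um`. Path length is the arc length of the traced
#' polyline (decimated to suppress pixel-staircase inflation), extended at
#' the tip by the local mask half-width, and measured from the soma
#' boundary. The microtubule status of each dendrite is the mean
#' EMTB / mean cytosol intensity ratio over the 1-px-dilated path
#' neighbourhood; a dendrite is EMTB-positive when the ratio strictly
#' exceeds 0.5.
#'
#' @param mask a [CellMask-class].
#' @param emtb_img,cytosol_img channel matrices, calibrated like the mask.
#' @param min_branch_um minimum side-branch length to count as a separate
#'   dendrite (default 2).
#' @return A [DendriteSet-class]; zero rows (with a warning) when the mask
#'   is no larger than its soma disk.
#' @export
extractDendrites <- function(mask, emtb_img, cytosol_img, min_branch_um = 2) {
  px <- mask@pixel_size_um
  M <- maskMatrix(mask)
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(M * 1)))
  soma_r_px <- max(dm)
  ctr_idx <- which(dm == soma_r_px, arr.ind = TRUE)[1, ]
  soma_center <- c(colToUm(ctr_idx[2], px), rowToUm(ctr_idx[1], px))

  empty <- new("DendriteSet", cell = mask@label, frame = mask@frame,
               table = data.frame(dendrite = integer(0), length_um = numeric(0),
                                  mean_emtb = numeric(0), mean_cyto = numeric(0),
                                  ratio = numeric(0), emtb_positive = logical(0)),
               paths = list(), soma_center_um = soma_center,
               soma_radius_um = soma_r_px * px)

  skel <- skeletonize(M)
  ## drop skeleton pixels inside the (1 px dilated) soma disk
  sk_idx <- which(skel, arr.ind = TRUE)
  if (!nrow(sk_idx)) { warning("mask has no skeleton outside the soma"); return(empty) }
  d_ctr <- sqrt((sk_idx[, 1] - ctr_idx[1])^2 + (sk_idx[, 2] - ctr_idx[2])^2)
  keep <- d_ctr > soma_r_px + 1
  if (!any(keep)) { warning("mask no larger than its soma disk; zero dendrites"); return(empty) }
  skel2 <- matrix(FALSE, nrow(M), ncol(M))
  skel2[sk_idx[keep, , drop = FALSE]] <- TRUE

  g <- skeletonGraph(skel2)
  comp <- igraph::components(g)
  paths <- list(); lens <- numeric(0)
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    vr <- igraph::V(g)$row[vids]; vc <- igraph::V(g)$col[vids]
    dc <- sqrt((vr - ctr_idx[1])^2 + (vc - ctr_idx[2])^2)
    if (min(dc) > soma_r_px + 2.5) next   # not attached to the soma
    root <- vids[which.min(dc)]
    deg <- igraph::degree(g, vids)
    tips <- vids[deg <= 1]
    tips <- setdiff(tips, root)
    if (!length(tips)) tips <- root
    dists <- igraph::distances(g, v = root, to = tips)[1, ]
    ord <- order(dists, decreasing = TRUE)
    claimed <- integer(0)
    for (ti in ord) {
      tip <- tips[ti]
      sp <- igraph::shortest_paths(g, from = root, to = tip)$vpath[[1]]
      spv <- as.integer(sp)
      if (length(claimed)) {
        new_part <- !(spv %in% claimed)
        if (!any(new_part)) next
        first_new <- which(new_part)[1]
        branch_start <- max(first_new - 1, 1)
        branch_px <- cbind(igraph::V(g)$row[spv[branch_start:length(spv)]],
                           igraph::V(g)$col[spv[branch_start:length(spv)]])
        if (polylineLength(branch_px) * px < min_branch_um) next
      }
      claimed <- union(claimed, spv)
      paths[[length(paths) + 1]] <- spv
    }
  }
  if (!length(paths)) { warning("no dendrites traced"); return(empty) }

  rows <- list(); polys <- list()
  for (k in seq_along(paths)) {
    spv <- paths[[k]]
    pr <- igraph::V(g)$row[spv]; pc <- igraph::V(g)$col[spv]
    ## decimate to suppress staircase length inflation
    n <- length(pr)
    sel <- unique(c(seq(1, n, by = 3), n))
    pts <- cbind(pr[sel], pc[sel])
    ## prepend the soma-boundary point; recover the thinning-eroded tip by
    ## marching from the skeleton endpoint along the tip direction to the
    ## mask boundary
    u0 <- unitVec(pts[1, ] - ctr_idx)
    start <- ctr_idx + u0 * soma_r_px
    if (nrow(pts) >= 3) {
      ut <- unitVec(pts[nrow(pts), ] - pts[nrow(pts) - 2, ])
    } else if (nrow(pts) == 2) {
      ut <- unitVec(pts[2, ] - pts[1, ])
    } else ut <- c(0, 0)
    tip <- pts[nrow(pts), ]
    if (any(ut != 0)) {
      ## thinning can leave a small hook at the endpoint, so probe a fan of
      ## directions around the tip heading and keep the longest extension
      a0 <- atan2(ut[1], ut[2])
      best <- 0
      for (da in seq(-0.5, 0.5, by = 0.125)) {
        uu <- c(sin(a0 + da), cos(a0 + da))
        ext <- 0
        for (step in seq(0.25, 12, by = 0.25)) {
          q <- round(pts[nrow(pts), ] + uu * step)
          if (q[1] < 1 || q[1] > nrow(M) || q[2] < 1 || q[2] > ncol(M) ||
              !M[q[1], q[2]]) break
          ext <- step
        }
        if (ext > best) { best <- ext; tip <- pts[nrow(pts), ] + uu * ext }
      }
      ## the mask ends in a rounded cap one half-width beyond the true tip;
      ## pull back by the local half-width (distance transform)
      q <- round(tip)
      if (q[1] >= 1 && q[1] <= nrow(M) && q[2] >= 1 && q[2] <= ncol(M)) {
        cap <- min(dm[q[1], q[2]], best)
        tip <- tip - unitVec(tip - pts[nrow(pts), ]) * cap
      }
    }
    pts <- rbind(start, pts, tip)
    len_um <- polylineLength(pts) * px
    ## 1-px dilated path neighbourhood for channel means
    nb <- do.call(rbind, lapply(c(-1, 0, 1), function(dr)
      do.call(rbind, lapply(c(-1, 0, 1), function(dc)
        cbind(pr + dr, pc + dc)))))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(M) &
               nb[, 2] >= 1 & nb[, 2] <= ncol(M), , drop = FALSE]
    nb <- unique(nb)
    me <- mean(emtb_img[nb]); mc <- mean(cytosol_img[nb])
    ratio <- if (mc > 0) me / mc else Inf
    rows[[k]] <- data.frame(dendrite = k, length_um = len_um,
                            mean_emtb = me, mean_cyto = mc, ratio = ratio,
                            emtb_positive = ratio > 0.5)
    polys[[k]] <- cbind(x_um = colToUm(pts[, 2], px),
                        y_um = rowToUm(pts[, 1], px))
  }
  new("DendriteSet", cell = mask@label, frame = mask@frame,
      table = do.call(rbind, rows), paths = polys,
      soma_center_um = soma_center, soma_radius_um = soma_r_px * px)
}

#' Time-averaged dendrite metrics
#'
#' Samples a time series of [DendriteSet-class] objects every
#' `sample_interval_s` seconds (default 600 s, i.e. every 10 min), counts
#' and measures dendrites at each sampled timepoint, and returns the
#' averages across the time course together with the overall maximum
#' length.
#'
#' @param dsets list of [DendriteSet-class].
#' @param times_s numeric vector of acquisition times (s), same length.
#' @param sample_interval_s sampling interval (s).
#' @return `list(avg_count, avg_length_um, max_length_um, n_samples)`.
#' @export
dendriteMetrics <- function(dsets, times_s, sample_interval_s = 600) {
  stopIfNot(length(dsets) > 0, "empty dendrite series")
  stopIfNot(length(dsets) == length(times_s),
            "'times_s' must match the series length")
  t_samples <- seq(min(times_s), max(times_s), by = sample_interval_s)
  pick <- vapply(t_samples, function(t) which.min(abs(times_s - t)), integer(1))
  pick <- unique(pick)
  counts <- vapply(dsets[pick], function(d) nrow(d@table), numeric(1))
  lens <- lapply(dsets[pick], function(d) d@table$length_um)
  all_lens <- unlist(lens)
  list(avg_count = mean(counts),
       avg_length_um = if (length(all_lens)) mean(vapply(lens, function(l)
         if (length(l)) mean(l) else NA_real_, numeric(1)), na.rm = TRUE) else NA_real_,
       max_length_um = if (length(all_lens)) max(all_lens) else NA_real_,
       n_samples = length(pick))
}
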