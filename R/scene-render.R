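## Rasterization helpers for the synthetic renderer.  All drawing happens in
## pixel units on plain matrices; callers convert physical coordinates with
## umToRow/umToCol.  Profiles are near-flat-topped with a ~1 px soft edge so
## that thresholding recovers the drawn footprint closely.
##
## To avoid repeated full-image copies, the helpers return additive patches
## (row range, column range, values) that the caller applies to a local
## matrix, which R can then modify in place.

patchDisk <- function(dim, row0, col0, radius_px, I, edge_px = 1.5) {
  r1 <- max(1L, floor(row0 - radius_px - edge_px))
  r2 <- min(dim[1], ceiling(row0 + radius_px + edge_px))
  c1 <- max(1L, floor(col0 - radius_px - edge_px))
  c2 <- min(dim[2], ceiling(col0 + radius_px + edge_px))
  if (r1 > r2 || c1 > c2) return(NULL)
  rr <- r1:r2; cc <- c1:c2
  d <- sqrt(outer((rr - row0)^2, (cc - col0)^2, "+"))
  f <- pmin(1, pmax(0, (radius_px + edge_px / 2 - d) / edge_px))
  list(rr = rr, cc = cc, vals = I * f)
}

patchSpot <- function(dim, row0, col0, sigma_px, A) {
  ext <- ceiling(4 * sigma_px)
  r1 <- max(1L, floor(row0 - ext)); r2 <- min(dim[1], ceiling(row0 + ext))
  c1 <- max(1L, floor(col0 - ext)); c2 <- min(dim[2], ceiling(col0 + ext))
  if (r1 > r2 || c1 > c2) return(NULL)
  rr <- r1:r2; cc <- c1:c2
  d2 <- outer((rr - row0)^2, (cc - col0)^2, "+")
  list(rr = rr, cc = cc, vals = A * exp(-d2 / (2 * sigma_px^2)))
}

## Tapering tube along p0 -> p1 (px coords c(row, col)), half-widths
## w0 -> w1 (px), intensities I0 -> I1 along its length.
patchTube <- function(dim, p0, p1, w0, w1, I0, I1, edge_px = 1.0) {
  wmax <- max(w0, w1) + edge_px
  r1 <- max(1L, floor(min(p0[1], p1[1]) - wmax))
  r2 <- min(dim[1], ceiling(max(p0[1], p1[1]) + wmax))
  c1 <- max(1L, floor(min(p0[2], p1[2]) - wmax))
  c2 <- min(dim[2], ceiling(max(p0[2], p1[2]) + wmax))
  if (r1 > r2 || c1 > c2) return(NULL)
  rr <- r1:r2; cc <- c1:c2
  v <- p1 - p0
  len2 <- sum(v^2)
  R <- matrix(rep(rr, length(cc)), ncol = length(cc))
  C <- matrix(rep(cc, each = length(rr)), ncol = length(cc))
  t <- if (len2 < 1e-12) matrix(0, nrow(R), ncol(R)) else
    pmin(1, pmax(0, ((R - p0[1]) * v[1] + (C - p0[2]) * v[2]) / len2))
  d <- sqrt((R - (p0[1] + t * v[1]))^2 + (C - (p0[2] + t * v[2]))^2)
  w <- w0 + t * (w1 - w0)
  I <- I0 + t * (I1 - I0)
  f <- pmin(1, pmax(0, (w + edge_px / 2 - d) / edge_px))
  list(rr = rr, cc = cc, vals = I * f)
}

## Binary footprints for ground-truth label masks.
diskPixels <- function(dim, row0, col0, radius_px) {
  r1 <- max(1L, floor(row0 - radius_px)); r2 <- min(dim[1], ceiling(row0 + radius_px))
  c1 <- max(1L, floor(col0 - radius_px)); c2 <- min(dim[2], ceiling(col0 + radius_px))
  if (r1 > r2 || c1 > c2) return(matrix(integer(0), 0, 2))
  rr <- r1:r2; cc <- c1:c2
  d <- sqrt(outer((rr - row0)^2, (cc - col0)^2, "+"))
  idx <- which(d <= radius_px, arr.ind = TRUE)
  cbind(row = rr[idx[, 1]], col = cc[idx[, 2]])
}

tubePixels <- function(dim, p0, p1, w0, w1) {
  wmax <- max(w0, w1)
  r1 <- max(1L, floor(min(p0[1], p1[1]) - wmax))
  r2 <- min(dim[1], ceiling(max(p0[1], p1[1]) + wmax))
  c1 <- max(1L, floor(min(p0[2], p1[2]) - wmax))
  c2 <- min(dim[2], ceiling(max(p0[2], p1[2]) + wmax))
  if (r1 > r2 || c1 > c2) return(matrix(integer(0), 0, 2))
  rr <- r1:r2; cc <- c1:c2
  v <- p1 - p0; len2 <- sum(v^2)
  R <- matrix(rep(rr, length(cc)), ncol = length(cc))
  C <- matrix(rep(cc, each = length(rr)), ncol = length(cc))
  t <- if (len2 < 1e-12) matrix(0, nrow(R), ncol(R)) else
    pmin(1, pmax(0, ((R - p0[1]) * v[1] + (C - p0[2]) * v[2]) / len2))
  d <- sqrt((R - (p0[1] + t * v[1]))^2 + (C - (p0[2] + t * v[2]))^2)
  w <- w0 + t * (w1 - w0)
  idx <- which(d <= w, arr.ind = TRUE)
  cbind(row = rr[idx[, 1]], col = cc[idx[, 2]])
}

## Intensity constants of the renderer (arbitrary camera units).
.renderLevels <- list(
  cyto_soma = 150, cyto_dend = 150, cyto_dend_tip = 120,
  emtb_soma_frac = 0.25, emtb_pos_frac = 0.9, emtb_neg_frac = 0.12,
  mtoc_amp = 500, mtoc_sigma_um = 0.8,
  nucleus = 200, obstacle = 180, lifeact_base = 120,
  dend_halfwidth_um = c(base = 1.0, tip = 0.45)
)

## Apply the noise model: Poisson shot noise on (signal + background) at
## `poisson_scale` photons per camera unit, plus additive Gaussian read
## noise.  poisson_scale = 0 disables shot noise (noise-free rendering).
applyNoise <- function(img, noise) {
  d <- dim(img)
  img <- img + noise$background
  if (noise$poisson_scale > 0) {
    img <- rpois(length(img), lambda = pmax(img, 0) * noise$poisson_scale) /
      noise$poisson_scale
    dim(img) <- d
  }
  if (noise$gaussian_sd > 0)
    img <- img + rnorm(length(img), 0, noise$gaussian_sd)
  pmax(img, 0)
}
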