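## Shared fixture builders.  Everything is generated in code; seeds are
## fixed so the suite is deterministic.

noiseFree <- function() list(background = 0, poisson_scale = 0, gaussian_sd = 0)

## One centred star-shaped cell with fixed dendrite geometry.
starConfig <- function(n_dend = 5, len_um = 12, seed = 5L, ...) {
  sceneConfig(n_cells = 1L, n_frames = 1L, width_um = 80, height_um = 80,
              rng_seed = seed, obstacle_density_per_100um2 = 0,
              dendrites_per_cell = c(n_dend, 0),
              dendrite_length_um = c(len_um, 0),
              noise = noiseFree(), ...)
}

## Rectangular scratch wound along the right-hand edge of the scene.
rightWoundPoly <- function(width_um = 300, height_um = 300) {
  cbind(c(width_um - 50, width_um - 10, width_um - 10, width_um - 50),
        c(40, 40, height_um - 40, height_um - 40))
}

scratchConfig <- function(n_cells = 10L, n_frames = 60L, seed = 1L,
                          wound = list(polygon = rightWoundPoly()), ...) {
  sceneConfig(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
              width_um = 300, height_um = 300, rng_seed = seed,
              wound = wound, ...)
}

## A CellMask built directly from a logical matrix.
maskFromMatrix <- function(M, pixel_size_um = 0.5, frame = 1L, label = 1L) {
  p <- which(M, arr.ind = TRUE)
  colnames(p) <- c("row", "col")
  new("CellMask", frame = as.integer(frame), label = as.integer(label),
      pixels = p, dim = dim(M), pixel_size_um = pixel_size_um)
}

diskMask <- function(radius_px = 10, pad = 3, pixel_size_um = 0.5) {
  n <- 2 * (radius_px + pad) + 1
  ctr <- radius_px + pad + 1
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  maskFromMatrix(d <= radius_px, pixel_size_um)
}

## Ground-truth per-step speeds (um/min) for one entity of a scene.
truthSpeeds <- function(truth, entity = "mtoc") {
  tr <- truthTracks(truth, entity)
  unlist(lapply(split(tr, tr$id), function(g) {
    g <- g[order(g$frame), ]
    sqrt(diff(g$x_um)^2 + diff(g$y_um)^2) / diff(g$t_s) * 60
  }))
}
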