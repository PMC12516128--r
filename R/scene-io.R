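#' Write a time-lapse stack and ground truth to disk
#'
#' The stack is written as a multi-page 32-bit float TIFF, frame-major with
#' channels interleaved (page order: frame 1 channel 1, frame 1 channel 2,
#' ..., frame 2 channel 1, ...). Calibration and channel names go to a YAML
#' sidecar `<stem>.yaml` next to the TIFF; ground-truth tables are written
#' as one CSV per record type, and the generating configuration as YAML.
#'
#' @param timelapse a [TimeLapse-class].
#' @param truth optional [GroundTruth-class].
#' @param dir output directory (created if needed).
#' @param stem file-name stem (default `"scene"`).
#' @return Invisibly, the paths written.
#' @export
writeTimeLapse <- function(timelapse, truth = NULL, dir, stem = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(timelapse@data)
  pages <- vector("list", d[4] * d[3])
  k <- 1
  for (f in seq_len(d[4])) for (ch in seq_len(d[3])) {
    pages[[k]] <- timelapse@data[, , ch, f]
    k <- k + 1
  }
  tif_path <- file.path(dir, paste0(stem, ".tif"))
  ## 32-bit float pages; intensities are stored as-is (camera units)
  tiff::writeTIFF(lapply(pages, function(m) m / 65535), tif_path,
                  bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_um = timelapse@pixel_size_um,
               frame_interval_s = timelapse@frame_interval_s,
               channels = as.list(timelapse@channels),
               n_frames = d[4], intensity_scale = 65535)
  yaml_path <- file.path(dir, paste0(stem, ".yaml"))
  yaml::write_yaml(meta, yaml_path)
  paths <- c(tif_path, yaml_path)
  if (!is.null(truth)) paths <- c(paths, writeGroundTruth(truth, dir, stem))
  invisible(paths)
}

writeGroundTruth <- function(truth, dir, stem = "scene") {
  tabs <- list(tracks = truth@tracks, dendrites = truth@dendrites,
               passages = truth@passages, engulfments = truth@engulfments,
               phenotypes = truth@phenotypes, wound = truth@wound,
               obstacles = truth@obstacles)
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(dir, sprintf("%s_%s.csv", stem, nm))
    write.csv(tabs[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  cfg_path <- file.path(dir, paste0(stem, "_config.yaml"))
  yaml::write_yaml(configToList(truth@config), cfg_path)
  c(paths, cfg_path)
}

configToList <- function(cfg) {
  sl <- slotNames(cfg)
  out <- lapply(sl, function(s) {
    v <- slot(cfg, s)
    if (s == "wound" && length(v)) v$polygon <- apply(v$polygon, 1, as.list)
    v
  })
  setNames(out, sl)
}

#' Read a time-lapse stack written by [writeTimeLapse()]
#'
#' @param path path to the TIFF (the YAML sidecar is found by replacing the
#'   extension), or a directory containing a single `<stem>.tif`.
#' @return A [TimeLapse-class].
#' @export
readTimeLapse <- function(path) {
  if (dir.exists(path)) {
    tifs <- list.files(path, pattern = "\\.tiff?$", full.names = TRUE)
    stopIfNot(length(tifs) == 1, "directory must contain exactly one TIFF")
    path <- tifs[1]
  }
  yaml_path <- sub("\\.tiff?$", ".yaml", path)
  stopIfNot(file.exists(yaml_path),
            "calibration sidecar (.yaml) not found next to the TIFF")
  meta <- yaml::read_yaml(yaml_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  ch <- unlist(meta$channels)
  n_ch <- length(ch)
  n_f <- length(pages) / n_ch
  stopIfNot(n_f == round(n_f), "page count is not a multiple of channel count")
  d1 <- dim(pages[[1]])
  arr <- array(0, c(d1[1], d1[2], n_ch, n_f))
  k <- 1
  for (f in seq_len(n_f)) for (c in seq_len(n_ch)) {
    arr[, , c, f] <- pages[[k]] * (meta$intensity_scale %||% 1)
    k <- k + 1
  }
  new("TimeLapse", data = arr, channels = ch,
      pixel_size_um = meta$pixel_size_um,
      frame_interval_s = meta$frame_interval_s)
}
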