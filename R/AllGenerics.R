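#' @name epinav-accessors
#' @title Accessors for epinav classes
#'
#' @description Small accessor generics: `nFrames`, `channelNames`,
#' `pixelSize`, `frameInterval`, `frameMatrix` (one channel of one frame as a
#' plain matrix), `truthTracks` (tracks of one entity kind as a data.frame),
#' `passages`, `engulfments`, `phenotypes`, `woundPolygon`, `obstacles`,
#' `maskCentroid` (um), `maskArea` (um^2) and `maskMatrix` (logical matrix).
#'
#' @param x an epinav object.
#' @param frame frame index.
#' @param channel channel name or index.
#' @param entity one of `"cell"`, `"mtoc"`, `"nucleus"`.
#' @return The extracted component; see each method.
NULL

#' @rdname epinav-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname epinav-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname epinav-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname epinav-accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname epinav-accessors
#' @export
setGeneric("frameMatrix", function(x, frame, channel) standardGeneric("frameMatrix"))
#' @rdname epinav-accessors
#' @export
setGeneric("truthTracks", function(x, entity = "cell") standardGeneric("truthTracks"))
#' @rdname epinav-accessors
#' @export
setGeneric("passages", function(x) standardGeneric("passages"))
#' @rdname epinav-accessors
#' @export
setGeneric("engulfments", function(x) standardGeneric("engulfments"))
#' @rdname epinav-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname epinav-accessors
#' @export
setGeneric("woundPolygon", function(x, frame = 1L) standardGeneric("woundPolygon"))
#' @rdname epinav-accessors
#' @export
setGeneric("obstacles", function(x) standardGeneric("obstacles"))
#' @rdname epinav-accessors
#' @export
setGeneric("maskCentroid", function(x) standardGeneric("maskCentroid"))
#' @rdname epinav-accessors
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))
#' @rdname epinav-accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname epinav-accessors
setMethod("nFrames", "TimeLapse", function(x) dim(x@data)[4])
#' @rdname epinav-accessors
setMethod("channelNames", "TimeLapse", function(x) x@channels)
#' @rdname epinav-accessors
setMethod("pixelSize", "TimeLapse", function(x) x@pixel_size_um)
#' @rdname epinav-accessors
setMethod("frameInterval", "TimeLapse", function(x) x@frame_interval_s)
#' @rdname epinav-accessors
setMethod("frameMatrix", "TimeLapse", function(x, frame, channel) {
  if (is.character(channel)) {
    channel <- match(channel, x@channels)
    stopIfNot(!is.na(channel), "unknown channel name")
  }
  x@data[, , channel, frame]
})

#' @rdname epinav-accessors
setMethod("truthTracks", "GroundTruth", function(x, entity = "cell") {
  x@tracks[x@tracks$entity == entity, , drop = FALSE]
})
#' @rdname epinav-accessors
setMethod("passages", "GroundTruth", function(x) x@passages)
#' @rdname epinav-accessors
setMethod("engulfments", "GroundTruth", function(x) x@engulfments)
#' @rdname epinav-accessors
setMethod("phenotypes", "GroundTruth", function(x) x@phenotypes)
#' @rdname epinav-accessors
setMethod("woundPolygon", "GroundTruth", function(x, frame = 1L) {
  w <- x@wound[x@wound$frame == frame, , drop = FALSE]
  if (!nrow(w)) return(NULL)
  cbind(x_um = w$x_um, y_um = w$y_um)
})
#' @rdname epinav-accessors
setMethod("obstacles", "GroundTruth", function(x) x@obstacles)

#' @rdname epinav-accessors
setMethod("maskCentroid", "CellMask", function(x) {
  c(x_um = colToUm(mean(x@pixels[, "col"]), x@pixel_size_um),
    y_um = rowToUm(mean(x@pixels[, "row"]), x@pixel_size_um))
})
#' @rdname epinav-accessors
setMethod("maskArea", "CellMask", function(x) nrow(x@pixels) * x@pixel_size_um^2)
#' @rdname epinav-accessors
setMethod("maskMatrix", "CellMask", function(x) {
  m <- matrix(FALSE, x@dim[1], x@dim[2])
  m[x@pixels] <- TRUE
  m
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %s, %g x %g um, %d frames @ %gs, %d cells\n",
              object@condition, object@width_um, object@height_um,
              object@n_frames, object@frame_interval_s, object@n_cells))
  cat(sprintf("  calibration %g um/px; wound: %s; ablation: %s\n",
              object@pixel_size_um,
              if (length(object@wound)) "yes" else "no",
              if (length(object@ablation)) "yes" else "no"))
  invisible(NULL)
})

setMethod("show", "TimeLapse", function(object) {
  d <- dim(object@data)
  cat(sprintf("TimeLapse: %d frames, %d x %d px, channels [%s]\n",
              d[4], d[1], d[2], paste(object@channels, collapse = ", ")))
  cat(sprintf("  %g um/px, %g s/frame\n",
              object@pixel_size_um, object@frame_interval_s))
  invisible(NULL)
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(paste0("GroundTruth: %d track points, %d passage records, ",
                     "%d engulfment records\n"),
              nrow(object@tracks), nrow(object@passages),
              nrow(object@engulfments)))
  invisible(NULL)
})

setMethod("show", "CellMask", function(object) {
  ctr <- maskCentroid(object)
  cat(sprintf("CellMask: frame %d label %d, %d px (%.1f um^2), centroid (%.1f, %.1f) um\n",
              object@frame, object@label, nrow(object@pixels),
              maskArea(object), ctr[1], ctr[2]))
  invisible(NULL)
})

setMethod("show", "WoundROI", function(object) {
  cat(sprintf("WoundROI: wound length %.1f um, margin %.0f x %.1f um%s\n",
              object@length_um, object@margin_width_um,
              object@margin_length_um,
              if (object@axis_degenerate) " (degenerate axis)" else ""))
  invisible(NULL)
})
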