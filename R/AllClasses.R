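#' @import methods
#' @importFrom stats rnorm rpois rgamma runif rbinom setNames complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

setClassUnion("probabilityOrOutcomes", c("numeric", "logical"))

#' Scene configuration for the synthetic time-lapse generator
#'
#' A `SceneConfig` holds every parameter of a synthetic epidermal scene:
#' physical calibration, cell morphology and kinematics, obstacle and wound
#' descriptors, event probabilities, and the noise model. Probability-valued
#' slots accept either a scalar probability in \[0, 1\] or a logical vector of
#' forced outcomes; in the latter case the generator realizes exactly those
#' outcomes in order, which removes sampling noise from worked examples.
#'
#' Distribution-valued slots (`dendrites_per_cell`, `dendrite_length_um`,
#' `navigation_pause_s`) are length-2 numeric vectors `c(mean, sd)`; an `sd`
#' of 0 forces the mean exactly.
#'
#' @slot rng_seed integer seed; identical (config, seed) pairs give
#'   bit-identical stacks and ground truth.
#' @slot width_um,height_um physical scene size (micrometres).
#' @slot pixel_size_um micrometres per pixel (default 0.5).
#' @slot frame_interval_s seconds between frames (default 30).
#' @slot n_frames,n_cells counts.
#' @slot soma_radius_um,nucleus_radius_um cell-body and nucleus radii.
#' @slot dendrites_per_cell,dendrite_length_um `c(mean, sd)` of the dendrite
#'   count (clamped to 3..10 when drawn) and dendrite length.
#' @slot cell_speed_um_min,mtoc_speed_um_min mean steady-state centroid and
#'   MTOC speeds (micrometres/minute).
#' @slot mtoc_speed_post_um_min mean MTOC speed after an ablation stimulus,
#'   applied to cells within the ablation response radius.
#' @slot persistence directional persistence of the random walk in \[0, 1)
#'   (weight of the previous direction in the new heading).
#' @slot wound_bias weight in \[0, 1\] of the wound-directed component of the
#'   heading when a wound is present.
#' @slot condition one of `"vehicle"`, `"nocodazole"`, `"paclitaxel"`,
#'   `"noc_rocki"` (nocodazole plus ROCK inhibitor).
#' @slot wound empty list, or `list(polygon = <n x 2 um matrix>,
#'   closure_rate_per_h =, engulfing_p =, stretching_p =)`.
#' @slot ablation empty list, or `list(x_um =, y_um =, frame =,
#'   response_radius_um =)`.
#' @slot obstacle_density_per_100um2 obstacle (keratinocyte) nuclei per
#'   100 square micrometres.
#' @slot obstacle_radius_um obstacle nucleus radius.
#' @slot navigation_success_p probability an obstacle passage succeeds
#'   (or forced outcomes).
#' @slot navigation_pause_s `c(mean, sd)` of the encounter-to-pass duration
#'   for successful passages (seconds).
#' @slot navigation_window_s observation window for scoring failure (55 min).
#' @slot mtoc_first_p probability the MTOC leads the nucleus past an obstacle.
#' @slot modality_dendritic_p probability an engulfment is dendrite-mediated.
#' @slot engulf_success_p probability an attempted engulfment succeeds.
#' @slot emtb_positive_p probability a dendrite carries microtubule signal.
#' @slot polarity_ratio target trailing/leading actin-reporter intensity
#'   ratio of migrating cells.
#' @slot noise `list(background =, poisson_scale =, gaussian_sd =)`.
#' @seealso [sceneConfig()], [conditionPreset()], [generateScene()]
#' @export
setClass("SceneConfig", representation(
  rng_seed = "integer",
  width_um = "numeric", height_um = "numeric",
  pixel_size_um = "numeric", frame_interval_s = "numeric",
  n_frames = "integer", n_cells = "integer",
  soma_radius_um = "numeric", nucleus_radius_um = "numeric",
  dendrites_per_cell = "numeric", dendrite_length_um = "numeric",
  cell_speed_um_min = "numeric", mtoc_speed_um_min = "numeric",
  mtoc_speed_post_um_min = "numeric",
  persistence = "numeric", wound_bias = "numeric",
  condition = "character",
  wound = "list", ablation = "list",
  obstacle_density_per_100um2 = "numeric", obstacle_radius_um = "numeric",
  navigation_success_p = "probabilityOrOutcomes",
  navigation_pause_s = "numeric",
  navigation_window_s = "numeric",
  mtoc_first_p = "probabilityOrOutcomes",
  modality_dendritic_p = "probabilityOrOutcomes",
  engulf_success_p = "probabilityOrOutcomes",
  emtb_positive_p = "probabilityOrOutcomes",
  polarity_ratio = "numeric",
  noise = "list"
))

validProbability <- function(x, name) {
  if (is.logical(x)) {
    if (length(x) < 1 || anyNA(x))
      return(sprintf("'%s': forced outcomes must be non-missing logicals", name))
    return(NULL)
  }
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
    return(sprintf("'%s' must be a probability in [0, 1]", name))
  NULL
}

validDistribution <- function(x, name) {
  if (length(x) != 2 || anyNA(x) || x[1] <= 0 || x[2] < 0)
    return(sprintf("'%s' must be c(mean > 0, sd >= 0)", name))
  NULL
}

setValidity("SceneConfig", function(object) {
  errs <- character(0)
  pos <- c("width_um", "height_um", "pixel_size_um", "frame_interval_s",
           "soma_radius_um", "nucleus_radius_um", "cell_speed_um_min",
           "mtoc_speed_um_min", "mtoc_speed_post_um_min",
           "obstacle_radius_um", "navigation_window_s", "polarity_ratio")
  for (s in pos) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v <= 0)
      errs <- c(errs, sprintf("'%s' must be a single positive number", s))
  }
  if (object@n_frames < 1) errs <- c(errs, "'n_frames' must be >= 1")
  if (object@n_cells < 0) errs <- c(errs, "'n_cells' must be >= 0")
  if (object@obstacle_density_per_100um2 < 0)
    errs <- c(errs, "'obstacle_density_per_100um2' must be >= 0")
  if (object@persistence < 0 || object@persistence >= 1)
    errs <- c(errs, "'persistence' must be in [0, 1)")
  if (object@wound_bias < 0 || object@wound_bias > 1)
    errs <- c(errs, "'wound_bias' must be in [0, 1]")
  for (s in c("navigation_success_p", "mtoc_first_p", "modality_dendritic_p",
              "engulf_success_p", "emtb_positive_p")) {
    e <- validProbability(slot(object, s), s)
    if (!is.null(e)) errs <- c(errs, e)
  }
  for (s in c("dendrites_per_cell", "dendrite_length_um", "navigation_pause_s")) {
    e <- validDistribution(slot(object, s), s)
    if (!is.null(e)) errs <- c(errs, e)
  }
  if (!object@condition %in% c("vehicle", "nocodazole", "paclitaxel", "noc_rocki"))
    errs <- c(errs, "unknown 'condition'")
  if (length(object@wound)) {
    poly <- object@wound$polygon
    if (is.null(poly) || !is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3)
      errs <- c(errs, "'wound$polygon' must be an n x 2 matrix, n >= 3")
    else if (any(poly[, 1] < 0 | poly[, 1] > object@width_um |
                 poly[, 2] < 0 | poly[, 2] > object@height_um))
      errs <- c(errs, "wound polygon lies outside the scene")
  }
  if (length(object@ablation)) {
    ab <- object@ablation
    if (is.null(ab$frame))
      errs <- c(errs, "'ablation' needs a frame")
    else if (ab$frame < 1 || ab$frame > object@n_frames)
      errs <- c(errs, "ablation frame outside the movie")
    ## site may be omitted: the generator then targets a keratinocyte
    ## 10-14 um from a cell, as in the ablation protocol
    if (!is.null(ab$x_um) && !is.null(ab$y_um) &&
        (ab$x_um < 0 || ab$x_um > object@width_um ||
         ab$y_um < 0 || ab$y_um > object@height_um))
      errs <- c(errs, "ablation site lies outside the scene")
  }
  nz <- object@noise
  if (!all(c("background", "poisson_scale", "gaussian_sd") %in% names(nz)) ||
      nz$background < 0 || nz$poisson_scale < 0 || nz$gaussian_sd < 0)
    errs <- c(errs, "'noise' must list non-negative background, poisson_scale, gaussian_sd")
  if (length(errs)) errs else TRUE
})

#' Calibrated multi-channel time-lapse stack
#'
#' Pixel data are stored as a 4-d array indexed `[row, col, channel, frame]`,
#' row 1 at the top, with the centre of pixel `(r, c)` at physical
#' coordinates `((c - 0.5) * pixel_size_um, (r - 0.5) * pixel_size_um)`.
#'
#' @slot data numeric array `[row, col, channel, frame]`, non-negative.
#' @slot channels channel names, e.g. `c("cytosol", "emtb", "nuclei")`.
#' @slot pixel_size_um,frame_interval_s physical calibration (> 0).
#' @seealso [frameMatrix()], [readTimeLapse()], [writeTimeLapse()]
#' @export
setClass("TimeLapse", representation(
  data = "array", channels = "character",
  pixel_size_um = "numeric", frame_interval_s = "numeric"
))

setValidity("TimeLapse", function(object) {
  errs <- character(0)
  d <- dim(object@data)
  if (length(d) != 4)
    errs <- c(errs, "'data' must be a 4-d array [row, col, channel, frame]")
  else if (d[3] != length(object@channels))
    errs <- c(errs, "third dimension must match length(channels)")
  if (any(object@data < 0)) errs <- c(errs, "intensities must be non-negative")
  if (length(object@pixel_size_um) != 1 || object@pixel_size_um <= 0)
    errs <- c(errs, "'pixel_size_um' must be a single positive number")
  if (length(object@frame_interval_s) != 1 || object@frame_interval_s <= 0)
    errs <- c(errs, "'frame_interval_s' must be a single positive number")
  if (length(errs)) errs else TRUE
})

#' Ground truth accompanying a synthetic scene
#'
#' Tabular truth records written by [generateScene()]: entity tracks
#' (cell centroid, MTOC, nucleus), per-frame dendrite geometry, obstacle
#' passage records, engulfment records, end-of-movie phenotype labels, the
#' wound polygon per frame, obstacle positions, and (optionally) per-frame
#' label masks.
#'
#' @slot tracks data.frame (entity, id, frame, t_s, x_um, y_um).
#' @slot dendrites data.frame (cell, dendrite, frame, length_um,
#'   angle_rad, emtb_positive, tip_x_um, tip_y_um).
#' @slot passages data.frame (cell, obstacle, encounter_frame, pass_frame,
#'   nucleus_pass_frame, leader, success).
#' @slot engulfments data.frame (cell, debris_x_um, debris_y_um,
#'   ablation_frame, contact_frame, contact_structure, engulf_frame,
#'   modality, success).
#' @slot phenotypes data.frame (cell, label) with label in
#'   engulfing/stretching/neither.
#' @slot wound data.frame (frame, vertex, x_um, y_um) - empty if no wound.
#' @slot obstacles data.frame (id, x_um, y_um, radius_um).
#' @slot masks list of integer label matrices (one per frame), possibly empty.
#' @slot config the generating [SceneConfig-class].
#' @export
setClass("GroundTruth", representation(
  tracks = "data.frame", dendrites = "data.frame", passages = "data.frame",
  engulfments = "data.frame", phenotypes = "data.frame", wound = "data.frame",
  obstacles = "data.frame", masks = "list", config = "SceneConfig"
))

setValidity("GroundTruth", function(object) {
  errs <- character(0)
  cfg <- object@config
  tr <- object@tracks
  if (nrow(tr)) {
    if (any(tr$x_um < 0 | tr$x_um > cfg@width_um |
            tr$y_um < 0 | tr$y_um > cfg@height_um))
      errs <- c(errs, "track coordinates outside the scene")
    if (any(tr$frame < 1 | tr$frame > cfg@n_frames))
      errs <- c(errs, "track frames outside the movie")
  }
  if (nrow(object@passages) &&
      !all(object@passages$cell %in% tr$id[tr$entity == "cell"]))
    errs <- c(errs, "passage records refer to unknown cells")
  if (length(errs)) errs else TRUE
})

#' Segmented cell mask for one frame
#'
#' @slot frame frame index.
#' @slot label integer label (deterministic: ordered by bounding-box top,
#'   then left).
#' @slot pixels integer matrix with columns `row`, `col`.
#' @slot dim dimensions (rows, cols) of the source image.
#' @slot pixel_size_um calibration.
#' @seealso [segmentCells()], [maskCentroid()], [maskArea()]
#' @export
setClass("CellMask", representation(
  frame = "integer", label = "integer", pixels = "matrix",
  dim = "integer", pixel_size_um = "numeric"
))

setValidity("CellMask", function(object) {
  errs <- character(0)
  if (nrow(object@pixels) < 1) errs <- c(errs, "mask is empty")
  if (ncol(object@pixels) != 2) errs <- c(errs, "'pixels' must have 2 columns")
  if (object@pixel_size_um <= 0) errs <- c(errs, "'pixel_size_um' must be > 0")
  if (length(errs)) errs else TRUE
})

#' Wound region of interest with derived margin rectangle
#'
#' The margin rectangle is 150 um wide and (wound length x 1.2) um long,
#' centred on the wound centroid with its long axis along the wound's major
#' axis, following the standard wound-margin counting convention.
#'
#' @slot polygon wound outline, n x 2 matrix (um).
#' @slot frame frame index.
#' @slot length_um major-axis extent of the wound.
#' @slot centroid polygon centroid (um).
#' @slot axis unit vector of the major axis.
#' @slot margin_width_um,margin_length_um margin rectangle dimensions.
#' @slot corners 4 x 2 matrix of margin rectangle corners (um).
#' @slot axis_degenerate TRUE when the outline has no unique major axis
#'   (e.g. a circle) and the axis was chosen by the documented tie rule.
#' @seealso [buildMarginROI()]
#' @export
setClass("WoundROI", representation(
  polygon = "matrix", frame = "integer", length_um = "numeric",
  centroid = "numeric", axis = "numeric",
  margin_width_um = "numeric", margin_length_um = "numeric",
  corners = "matrix", axis_degenerate = "logical"
))

setValidity("WoundROI", function(object) {
  errs <- character(0)
  if (abs(object@margin_length_um - 1.2 * object@length_um) > 1e-9)
    errs <- c(errs, "margin length must equal 1.2 x wound length")
  if (!pointsInPolygonRect(matrix(object@centroid, ncol = 2), object@corners))
    errs <- c(errs, "margin must contain the wound centroid")
  if (length(errs)) errs else TRUE
})

## Point-in-rectangle test for (possibly rotated) corner matrices.
pointsInPolygonRect <- function(pts, corners) {
  all(pointsInPolygon(pts, corners))
}
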