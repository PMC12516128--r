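#' Construct a synthetic-scene configuration
#'
#' Builds a validated [SceneConfig-class]. All arguments have vehicle-control
#' defaults; [conditionPreset()] derives the drug-treatment presets from
#' them. Physical defaults: 0.5 um/pixel, 30 s/frame, 5 um soma radius,
#' dendrite count 5 +/- 1 (clamped to 3..10), dendrite length 12 +/- 3 um,
#' steady-state MTOC speed 1.4 um/min rising to 1.8 um/min after a nearby
#' ablation, obstacle-passage success probability 0.76 with mean
#' encounter-to-pass time 675 s, MTOC-first probability 0.84, and
#' dendrite-mediated engulfment probability 0.825.
#'
#' @param rng_seed integer seed controlling every random draw.
#' @param width_um,height_um scene size in micrometres.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param n_frames,n_cells movie length and cell count.
#' @param soma_radius_um,nucleus_radius_um cell-body and nucleus radii (um).
#' @param dendrites_per_cell,dendrite_length_um `c(mean, sd)`.
#' @param cell_speed_um_min,mtoc_speed_um_min,mtoc_speed_post_um_min mean
#'   speeds (um/min).
#' @param persistence,wound_bias random-walk heading weights, see
#'   [SceneConfig-class].
#' @param condition condition label.
#' @param wound,ablation optional descriptors, see [SceneConfig-class].
#' @param obstacle_density_per_100um2,obstacle_radius_um obstacle nuclei.
#' @param navigation_success_p,mtoc_first_p,modality_dendritic_p,engulf_success_p,emtb_positive_p
#'   probabilities, or logical vectors of forced outcomes.
#' @param navigation_pause_s `c(mean, sd)` encounter-to-pass duration (s).
#' @param navigation_window_s failure-scoring observation window (s).
#' @param polarity_ratio target trailing/leading reporter ratio.
#' @param noise `list(background, poisson_scale, gaussian_sd)`.
#' @return A validated [SceneConfig-class] object.
#' @examples
#' cfg <- sceneConfig(n_cells = 3L, n_frames = 10L)
#' cfg
#' @export
sceneConfig <- function(rng_seed = 1L,
                        width_um = 300, height_um = 300,
                        pixel_size_um = 0.5, frame_interval_s = 30,
                        n_frames = 60L, n_cells = 8L,
                        soma_radius_um = 5, nucleus_radius_um = 3,
                        dendrites_per_cell = c(5, 1),
                        dendrite_length_um = c(12, 3),
                        cell_speed_um_min = 1.0,
                        mtoc_speed_um_min = 1.4,
                        mtoc_speed_post_um_min = 1.8,
                        persistence = 0.8, wound_bias = 0.6,
                        condition = "vehicle",
                        wound = list(), ablation = list(),
                        obstacle_density_per_100um2 = 0.2,
                        obstacle_radius_um = 4,
                        navigation_success_p = 0.76,
                        navigation_pause_s = c(675, 135),
                        navigation_window_s = 3300,
                        mtoc_first_p = 0.84,
                        modality_dendritic_p = 0.825,
                        engulf_success_p = 0.9,
                        emtb_positive_p = 0.7,
                        polarity_ratio = 1.0,
                        noise = list(background = 20, poisson_scale = 1,
                                     gaussian_sd = 4)) {
  if (length(ablation) && is.null(ablation$response_radius_um))
    ablation$response_radius_um <- 50
  if (length(wound)) {
    if (is.null(wound$closure_rate_per_h)) wound$closure_rate_per_h <- 0.15
    if (is.null(wound$engulfing_p)) wound$engulfing_p <- 0.20
    if (is.null(wound$stretching_p)) wound$stretching_p <- 0.047
  }
  new("SceneConfig",
      rng_seed = as.integer(rng_seed),
      width_um = width_um, height_um = height_um,
      pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
      n_frames = as.integer(n_frames), n_cells = as.integer(n_cells),
      soma_radius_um = soma_radius_um, nucleus_radius_um = nucleus_radius_um,
      dendrites_per_cell = dendrites_per_cell,
      dendrite_length_um = dendrite_length_um,
      cell_speed_um_min = cell_speed_um_min,
      mtoc_speed_um_min = mtoc_speed_um_min,
      mtoc_speed_post_um_min = mtoc_speed_post_um_min,
      persistence = persistence, wound_bias = wound_bias,
      condition = condition, wound = wound, ablation = ablation,
      obstacle_density_per_100um2 = obstacle_density_per_100um2,
      obstacle_radius_um = obstacle_radius_um,
      navigation_success_p = navigation_success_p,
      navigation_pause_s = navigation_pause_s,
      navigation_window_s = navigation_window_s,
      mtoc_first_p = mtoc_first_p,
      modality_dendritic_p = modality_dendritic_p,
      engulf_success_p = engulf_success_p,
      emtb_positive_p = emtb_positive_p,
      polarity_ratio = polarity_ratio,
      noise = noise)
}

#' Condition presets for the synthetic generator
#'
#' Returns a baseline [SceneConfig-class] adjusted in the effect directions
#' observed for each microtubule drug: `nocodazole` (depolymerization) gives
#' fewer but longer dendrites, higher motility with lower directional
#' persistence, trailing-edge actin enrichment (higher polarity ratio),
#' reduced dendrite-mediated engulfment and reduced engulfment success;
#' `paclitaxel` (stabilization) leaves morphology unchanged but makes
#' obstacle navigation mostly fail and slows successful passages;
#' `noc_rocki` is nocodazole plus ROCK inhibition, which restores the actin
#' polarity ratio to the control level; `vehicle` is identical to
#' [sceneConfig()] defaults.
#'
#' @param name one of `"vehicle"`, `"nocodazole"`, `"paclitaxel"`,
#'   `"noc_rocki"`.
#' @param ... overrides passed on to [sceneConfig()] (applied after the
#'   preset adjustments).
#' @return A [SceneConfig-class].
#' @examples
#' conditionPreset("nocodazole")@dendrite_length_um
#' @export
conditionPreset <- function(name, ...) {
  stopIfNot(is.character(name) && length(name) == 1 &&
              name %in% c("vehicle", "nocodazole", "paclitaxel", "noc_rocki"),
            "unknown condition preset")
  adj <- switch(name,
    vehicle = list(),
    nocodazole = list(
      dendrites_per_cell = c(3, 0.8),
      dendrite_length_um = c(18, 4),
      cell_speed_um_min = 1.5,
      persistence = 0.5, wound_bias = 0.25,
      polarity_ratio = 1.5,
      modality_dendritic_p = 0.45,
      engulf_success_p = 0.6),
    paclitaxel = list(
      navigation_success_p = 0.23,
      navigation_pause_s = c(2175, 435)),
    noc_rocki = list(
      dendrites_per_cell = c(3, 0.8),
      dendrite_length_um = c(18, 4),
      cell_speed_um_min = 1.5,
      persistence = 0.5, wound_bias = 0.25,
      polarity_ratio = 1.0,
      modality_dendritic_p = 0.45,
      engulf_success_p = 0.6))
  args <- utils::modifyList(c(adj, list(condition = name)), list(...))
  do.call(sceneConfig, args)
}
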