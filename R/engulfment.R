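#' Classify the modality of a debris-engulfment event
#'
#' Distinguishes the two engulfment strategies seen after laser ablation:
#' `motility`, in which the whole cell migrates and repositions next to
#' the debris before engulfing at the cell body, and `dendritic`, in which
#' a single dendrite reaches the debris while the soma stays distal. The
#' quantitative surrogate: the event is `motility` when the cell-body
#' centroid closes more than `closure_threshold` (default 50%) of its
#' initial centroid-debris distance between ablation and engulfment;
#' otherwise `dendritic`.
#'
#' @param cell_track data.frame `frame`, `t_s`, `x_um`, `y_um`.
#' @param debris length-2 numeric `c(x_um, y_um)`.
#' @param ablation_frame frame of the ablation.
#' @param engulf_frame frame of engulfment, or NA when none occurred.
#' @param contact_frame,contact_structure optional first-contact
#'   annotations carried into the output.
#' @param closure_threshold fraction of the initial distance (default 0.5).
#' @return One-row data.frame: `modality` (`"dendritic"`, `"motility"`, or
#'   NA when no engulfment/contact occurred), `success`, `closure`,
#'   `initial_distance_um` plus the supplied annotations.
#' @export
classifyModality <- function(cell_track, debris, ablation_frame,
                             engulf_frame = NA, contact_frame = NA,
                             contact_structure = NA_character_,
                             closure_threshold = 0.5) {
  o <- order(cell_track$frame)
  tf <- cell_track$frame[o]
  d <- sqrt((cell_track$x_um[o] - debris[1])^2 +
              (cell_track$y_um[o] - debris[2])^2)
  k0 <- which(tf >= ablation_frame)[1]
  stopIfNot(!is.na(k0), "track does not cover the ablation frame")
  d0 <- d[k0]
  success <- !is.na(engulf_frame)
  k1 <- if (success) which(tf >= engulf_frame)[1] else length(tf)
  if (is.na(k1)) k1 <- length(tf)
  closure <- if (d0 > 0) (d0 - d[k1]) / d0 else 0
  modality <- if (!success && is.na(contact_frame)) NA_character_
    else if (closure > closure_threshold) "motility" else "dendritic"
  data.frame(modality = modality, success = success, closure = closure,
             initial_distance_um = d0,
             contact_frame = contact_frame,
             contact_structure = contact_structure)
}

#' Classify every engulfment event of a synthetic ablation scene
#'
#' @param truth a [GroundTruth-class] with engulfment records.
#' @param closure_threshold see [classifyModality()].
#' @return data.frame, one row per event.
#' @export
classifyEngulfments <- function(truth, closure_threshold = 0.5) {
  eng <- truth@engulfments
  stopIfNot(nrow(eng) > 0, "scene has no engulfment events")
  rows <- lapply(seq_len(nrow(eng)), function(k) {
    tr <- truth@tracks[truth@tracks$entity == "cell" &
                         truth@tracks$id == eng$cell[k], ]
    cbind(data.frame(cell = eng$cell[k]),
          classifyModality(tr, c(eng$debris_x_um[k], eng$debris_y_um[k]),
                           eng$ablation_frame[k], eng$engulf_frame[k],
                           eng$contact_frame[k], eng$contact_structure[k],
                           closure_threshold = closure_threshold))
  })
  do.call(rbind, rows)
}

#' Summarize engulfment events
#'
#' @param events data.frame with `modality` and `success` columns.
#' @return `list(pct_dendritic, pct_success, counts)`; `counts` is the raw
#'   2 x 2 table (modality x success) suitable for Fisher's exact test.
#' @examples
#' ev <- data.frame(modality = rep(c("dendritic", "motility"), c(33, 7)),
#'                  success = TRUE)
#' engulfmentSummary(ev)$pct_dendritic
#' @export
engulfmentSummary <- function(events) {
  stopIfNot(nrow(events) >= 1, "no events supplied")
  cls <- events[!is.na(events$modality), , drop = FALSE]
  list(
    pct_dendritic = if (nrow(cls)) 100 * mean(cls$modality == "dendritic")
      else NA_real_,
    pct_success = 100 * mean(events$success),
    counts = table(factor(cls$modality, c("dendritic", "motility")),
                   factor(cls$success, c(FALSE, TRUE))))
}
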