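#' Group comparison with the tests used for imaging endpoints
#'
#' Thin dispatcher over the standard test implementations:
#' `mann_whitney` ([stats::wilcox.test()]), `fisher_exact`
#' ([stats::fisher.test()] on raw counts), `chi_squared`
#' ([stats::chisq.test()]), `ks` ([stats::ks.test()]),
#' `anova_bonferroni` (one-way [stats::aov()] with Bonferroni-adjusted
#' pairwise t-tests) and `two_way_anova_bonferroni`. Significance stars
#' follow the usual thresholds (0.05, 0.01, 0.001, 0.0001) and are
#' cosmetic output only.
#'
#' @param test test name (see above).
#' @param data for rank/KS tests: a list of >= 2 numeric vectors; for
#'   categorical tests: a contingency matrix of non-negative integer raw
#'   counts; for ANOVA: a data.frame with `value`, `group` (and `factor2`
#'   for the two-way case).
#' @param alpha significance level used only for the `significant` flag.
#' @return `list(test, statistic, p_value, stars, significant,
#'   pairwise = <data.frame or NULL>)`.
#' @examples
#' compareGroups("mann_whitney", list(a = 1:10, b = 1:10))$p_value
#' @export
compareGroups <- function(test = c("mann_whitney", "fisher_exact",
                                   "chi_squared", "ks", "anova_bonferroni",
                                   "two_way_anova_bonferroni"),
                          data, alpha = 0.05) {
  test <- match.arg(test)
  pairwise <- NULL
  if (test %in% c("mann_whitney", "ks")) {
    stopIfNot(is.list(data) && length(data) == 2,
              "rank/KS tests need a list of exactly 2 numeric vectors")
    res <- if (test == "mann_whitney")
      suppressWarnings(stats::wilcox.test(data[[1]], data[[2]], exact = FALSE))
    else suppressWarnings(stats::ks.test(data[[1]], data[[2]]))
    stat <- unname(res$statistic); p <- res$p.value
  } else if (test %in% c("fisher_exact", "chi_squared")) {
    stopIfNot(is.matrix(data) && all(data >= 0) && all(data == round(data)),
              "categorical tests need a matrix of non-negative integer counts")
    if (test == "fisher_exact") {
      res <- stats::fisher.test(data)
      stat <- NA_real_; p <- res$p.value
    } else {
      res <- suppressWarnings(stats::chisq.test(data))
      stat <- unname(res$statistic); p <- res$p.value
    }
  } else {
    stopIfNot(is.data.frame(data) && all(c("value", "group") %in% names(data)),
              "ANOVA needs a data.frame with 'value' and 'group'")
    data$group <- factor(data$group)
    stopIfNot(nlevels(data$group) >= 2, "need >= 2 groups")
    if (test == "anova_bonferroni") {
      fit <- stats::aov(value ~ group, data = data)
      an <- summary(fit)[[1]]
      stat <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
      pw <- stats::pairwise.t.test(data$value, data$group,
                                   p.adjust.method = "bonferroni")
      pairwise <- as.data.frame(as.table(pw$p.value))
      names(pairwise) <- c("group1", "group2", "p_adj")
      pairwise <- pairwise[stats::complete.cases(pairwise), , drop = FALSE]
    } else {
      stopIfNot("factor2" %in% names(data),
                "two-way ANOVA needs a 'factor2' column")
      data$factor2 <- factor(data$factor2)
      fit <- stats::aov(value ~ group * factor2, data = data)
      an <- summary(fit)[[1]]
      stat <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
      pw <- stats::pairwise.t.test(data$value,
                                   interaction(data$group, data$factor2),
                                   p.adjust.method = "bonferroni")
      pairwise <- as.data.frame(as.table(pw$p.value))
      names(pairwise) <- c("group1", "group2", "p_adj")
      pairwise <- pairwise[stats::complete.cases(pairwise), , drop = FALSE]
    }
  }
  list(test = test, statistic = stat, p_value = p,
       stars = significanceStars(p), significant = p < alpha,
       pairwise = pairwise)
}

#' Map a p-value to significance stars
#'
#' `****` below 0.0001, `***` below 0.001, `**` below 0.01, `*` below
#' 0.05, `ns` otherwise.
#'
#' @param p p-value.
#' @return Character.
#' @export
significanceStars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Run the full synthetic-experiment pipeline
#'
#' For each named condition config: generates the scene, runs segmentation
#' on a subsample of frames, links cell tracks from ground-truth-free
#' detections, computes motility metrics, margin counts (wound scenes) and
#' navigation/engulfment summaries where applicable; then compares
#' conditions pairwise (Mann-Whitney on motility metrics). All tables are
#' written as CSV under `out_dir` together with a run log recording every
#' parameter and seed.
#'
#' @param configs named list of [SceneConfig-class] (first name is the
#'   reference condition).
#' @param out_dir output directory.
#' @param segment_frames how many evenly spaced frames to segment
#'   (default 5).
#' @return Invisibly, a list with per-condition results and the
#'   comparison table.
#' @export
runPipeline <- function(configs, out_dir, segment_frames = 5L) {
  stopIfNot(is.list(configs) && length(configs) >= 1 &&
              !is.null(names(configs)), "named list of configs required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("epinav run: %d condition(s)", length(configs)))
  res <- list()
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    stopIfNot(cfg@n_cells > 0, sprintf("condition '%s': empty scene", nm))
    log_lines <- c(log_lines, sprintf("condition %s: seed %d, %d cells, %d frames",
                                      nm, cfg@rng_seed, cfg@n_cells, cfg@n_frames))
    sc <- generateScene(cfg, render = TRUE, keep_masks = FALSE)
    tl <- sc$timelapse
    frames <- unique(round(seq(1, cfg@n_frames, length.out = segment_frames)))
    dets <- list(); masks_per_frame <- list()
    for (f in frames) {
      masks <- segmentCells(frameMatrix(tl, f, "cytosol"), pixelSize(tl),
                            frame = f)
      stopIfNot(length(masks) > 0 || f != frames[1],
                sprintf("condition '%s': segmentation found no cells", nm))
      masks_per_frame[[as.character(f)]] <- masks
      if (length(masks))
        dets[[as.character(f)]] <- data.frame(
          ## consecutive timepoint index so the linker treats sampled
          ## frames as adjacent; source_frame keeps the original index
          frame = match(f, frames), source_frame = f,
          x_um = vapply(masks, function(m) maskCentroid(m)[1], numeric(1)),
          y_um = vapply(masks, function(m) maskCentroid(m)[2], numeric(1)))
    }
    stride_s <- frameInterval(tl) *
      (if (length(frames) > 1) diff(frames)[1] else 1)
    tracks <- linkFrames(do.call(rbind, dets),
                         linkingConfig(max_link_um = 60, max_gap = 1L),
                         frame_interval_s = stride_s)
    mets <- do.call(rbind, lapply(split(tracks, tracks$id), function(g) {
      if (nrow(g) < 2) return(NULL)
      m <- trackMetrics(g)
      data.frame(id = g$id[1], total_um = m$total_distance_um,
                 displacement_um = m$displacement_um,
                 meandering_index = m$meandering_index, included = m$included)
    }))
    margin <- NULL
    if (nrow(sc$truth@wound)) {
      roi <- buildMarginROI(woundPolygon(sc$truth, 1L))
      margin <- countCellsInMargin(unname(masks_per_frame), roi)
    }
    res[[nm]] <- list(truth = sc$truth, tracks = tracks, metrics = mets,
                      margin = margin)
    write.csv(tracks, file.path(out_dir, sprintf("%s_tracks.csv", nm)),
              row.names = FALSE)
    write.csv(mets, file.path(out_dir, sprintf("%s_motility.csv", nm)),
              row.names = FALSE)
    if (!is.null(margin))
      write.csv(margin, file.path(out_dir, sprintf("%s_margin.csv", nm)),
                row.names = FALSE)
  }
  comparisons <- NULL
  if (length(configs) >= 2) {
    nms <- names(configs)
    rows <- list()
    for (i in seq_along(nms)[-1]) {
      for (metric in c("total_um", "displacement_um", "meandering_index")) {
        a <- res[[nms[1]]]$metrics[[metric]]
        b <- res[[nms[i]]]$metrics[[metric]]
        if (length(a) >= 2 && length(b) >= 2) {
          cp <- compareGroups("mann_whitney", list(a, b))
          rows[[length(rows) + 1]] <- data.frame(
            reference = nms[1], condition = nms[i], metric = metric,
            n_ref = length(a), n_cond = length(b),
            mean_ref = mean(a), mean_cond = mean(b),
            p_value = cp$p_value, stars = cp$stars)
        }
      }
    }
    comparisons <- do.call(rbind, rows)
    if (!is.null(comparisons))
      write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                row.names = FALSE)
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(conditions = res, comparisons = comparisons))
}
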