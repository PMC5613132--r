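#' Adaptive laterality threshold
#'
#' Computes the per-subject threshold used for voxel counting: the mean
#' of the top 5% of Z values in the ROI pair is taken first, and the
#' threshold is 50% of that mean maximum activation.  "Top 5%" is the
#' largest `ceiling(0.05 * n)` values in a side's ROI (never fewer than
#' one voxel).  Because the text leaves "in one of the paired ROIs" open,
#' the side whose top-5% mean is computed is configurable; the default
#' `"max"` evaluates both sides and uses the larger mean, so the
#' dominant side sets the threshold and the rule is mirror-symmetric.
#'
#' @param map A 3-D [stat_map].
#' @param rois A [roi_pair] on the map's grid.
#' @param top_frac Fraction of ROI voxels defining "maximum activation"
#'   (default 0.05).
#' @param thr_frac Fraction of the top mean used as threshold (default 0.5).
#' @param source One of `"max"`, `"left"`, `"right"`, `"union"`: which ROI
#'   supplies the top-5% mean.
#' @return An object of class `adaptive_threshold` with fields
#'   `mean_top5`, `value` (= `thr_frac * mean_top5`), `source_side`.
#' @export
adaptive_threshold <- function(map, rois, top_frac = 0.05, thr_frac = 0.5,
                               source = c("max", "left", "right", "union")) {
  source <- match.arg(source)
  stopifnot(is_stat_map(map), inherits(rois, "roi_pair"))
  check_same_grid(map, rois$left)
  if (top_frac <= 0 || top_frac >= 1) stop("'top_frac' must be in (0, 1)")
  if (thr_frac <= 0 || thr_frac >= 1) stop("'thr_frac' must be in (0, 1)")

  top_mean <- function(vals) {
    k <- max(1L, ceiling(top_frac * length(vals)))
    mean(sort(vals, decreasing = TRUE)[seq_len(k)])
  }
  vl <- map$data[rois$left$data]
  vr <- map$data[rois$right$data]
  m <- switch(source,
    max = {
      ml <- top_mean(vl); mr <- top_mean(vr)
      if (ml >= mr) c(ml, 1) else c(mr, 2)
    },
    left = c(top_mean(vl), 1),
    right = c(top_mean(vr), 2),
    union = c(top_mean(c(vl, vr)), 0))
  mean_top5 <- m[1]
  if (!is.finite(mean_top5) || mean_top5 <= 0)
    stop("no positive activation in ROI pair: top-fraction mean is <= 0")
  structure(list(mean_top5 = mean_top5,
                 value = thr_frac * mean_top5,
                 source_side = c("union", "left", "right")[m[2] + 1]),
            class = "adaptive_threshold")
}

#' @export
print.adaptive_threshold <- function(x, ...) {
  cat(sprintf("<adaptive_threshold> %.4g (= %.4g top-fraction mean, %s side)\n",
              x$value, x$mean_top5, x$source_side))
  invisible(x)
}

#' Count strictly suprathreshold voxels in a mask
#'
#' @param map A 3-D [stat_map].
#' @param mask A [roi_mask] on the map's grid.
#' @param thr Threshold in Z units; voxels with value strictly greater
#'   than `thr` are counted.
#' @return Integer count.
#' @export
count_suprathreshold <- function(map, mask, thr) {
  stopifnot(is_stat_map(map), inherits(mask, "roi_mask"))
  check_same_grid(map, mask)
  if (inherits(thr, "adaptive_threshold")) thr <- thr$value
  sum(map$data[mask$data] > thr)
}

#' Laterality index from suprathreshold counts
#'
#' LI = 100 (L - R) / (L + R), where L and R are the numbers of voxels
#' surviving thresholding in the left and right ROI.  +100 indicates
#' complete left-hemispheric dominance, -100 complete right-hemispheric
#' dominance.
#'
#' @param n_left,n_right Non-negative voxel counts; their sum must be
#'   positive (an all-subthreshold map is an error, never a silent NaN).
#' @return LI in `[-100, 100]`.
#' @export
laterality_index <- function(n_left, n_right) {
  if (n_left < 0 || n_right < 0) stop("counts must be non-negative")
  if (n_left + n_right <= 0)
    stop("no suprathreshold voxels in either ROI")
  100 * (n_left - n_right) / (n_left + n_right)
}

#' Classify a laterality index
#'
#' LI above +33 is typical (left-dominant), below -33 is atypical
#' right-hemispheric, and the closed band `[-33, 33]` is bilateral.
#'
#' @param li Laterality index in `[-100, 100]`.
#' @param band Half-width of the bilateral band (default 33).
#' @return `"left_typical"`, `"bilateral"`, or `"right_atypical"`.
#' @export
classify_laterality <- function(li, band = 33) {
  if (any(!is.finite(li)) || any(li < -100) || any(li > 100))
    stop("'li' must lie in [-100, 100]")
  ifelse(li > band, "left_typical",
         ifelse(li < -band, "right_atypical", "bilateral"))
}

#' Full laterality measurement for one subject
#'
#' Runs the whole adaptive-threshold pipeline on one map: threshold from
#' the ROI pair, strict suprathreshold counts per side, LI, and class
#' label.
#'
#' @inheritParams adaptive_threshold
#' @param band Bilateral band half-width passed to [classify_laterality()].
#' @return A list of class `laterality_result`: `n_left`, `n_right`,
#'   `threshold` ([adaptive_threshold]), `li`, `label`, `subject_id`.
#' @export
measure_laterality <- function(map, rois, top_frac = 0.05, thr_frac = 0.5,
                               source = "max", band = 33) {
  thr <- adaptive_threshold(map, rois, top_frac = top_frac,
                            thr_frac = thr_frac, source = source)
  n_left <- count_suprathreshold(map, rois$left, thr)
  n_right <- count_suprathreshold(map, rois$right, thr)
  li <- laterality_index(n_left, n_right)
  structure(list(n_left = n_left, n_right = n_right, threshold = thr,
                 li = li, label = classify_laterality(li, band = band),
                 subject_id = map$subject_id),
            class = "laterality_result")
}

#' @export
print.laterality_result <- function(x, ...) {
  cat(sprintf("<laterality_result> %s L=%d R=%d thr=%.3g LI=%.1f (%s)\n",
              if (is.na(x$subject_id)) "" else x$subject_id,
              x$n_left, x$n_right, x$threshold$value, x$li, x$label))
  invisible(x)
}

#' Hemispheric extent of suprathreshold activity
#'
#' Recomputes the adaptive threshold on a whole-hemisphere ROI pair (in
#' the same manner as the Broca-area LI) and counts surviving voxels per
#' hemisphere: a diffuseness measure of how much tissue a subject
#' recruits, used to relate bilaterality to extent.
#'
#' @param map A 3-D [stat_map].
#' @param hemispheres A [roi_pair] of hemisphere masks.
#' @inheritParams adaptive_threshold
#' @return A list of class `extent_result`: `n_left`, `n_right`, `total`,
#'   `threshold`.
#' @export
hemispheric_extent <- function(map, hemispheres, top_frac = 0.05,
                               thr_frac = 0.5, source = "max") {
  thr <- adaptive_threshold(map, hemispheres, top_frac = top_frac,
                            thr_frac = thr_frac, source = source)
  nl <- count_suprathreshold(map, hemispheres$left, thr)
  nr <- count_suprathreshold(map, hemispheres$right, thr)
  structure(list(n_left = nl, n_right = nr, total = nl + nr,
                 threshold = thr),
            class = "extent_result")
}

#' Edinburgh handedness classification
#'
#' Scores of +40 and above indicate right-handedness, -40 and below
#' left-handedness, and scores in between ambidexterity.
#'
#' @param ehi_score Edinburgh laterality quotient(s) in `[-100, 100]`.
#' @return `"right"`, `"ambidextrous"`, or `"left"` (vectorized).
#' @export
classify_handedness <- function(ehi_score) {
  if (any(!is.finite(ehi_score)) || any(abs(ehi_score) > 100))
    stop("'ehi_score' must lie in [-100, 100]")
  ifelse(ehi_score >= 40, "right",
         ifelse(ehi_score <= -40, "left", "ambidextrous"))
}

#' Laterality table for a cohort
#'
#' Applies [measure_laterality()] to each map and joins subject metadata.
#'
#' @param maps List of [stat_map]s.
#' @param rois A [roi_pair].
#' @param meta Optional data frame with a `subject_id` column (and
#'   typically `ehi_score`, `sex`, `age`); `handedness` is derived from
#'   `ehi_score` when present.
#' @inheritParams measure_laterality
#' @return Data frame with one row per subject: `subject_id`, `n_left`,
#'   `n_right`, `threshold`, `li`, `label`, plus any metadata columns.
#' @export
cohort_laterality <- function(maps, rois, meta = NULL, top_frac = 0.05,
                              thr_frac = 0.5, source = "max", band = 33) {
  res <- lapply(maps, measure_laterality, rois = rois, top_frac = top_frac,
                thr_frac = thr_frac, source = source, band = band)
  tab <- data.frame(
    subject_id = vapply(res, function(r) as.character(r$subject_id), ""),
    n_left = vapply(res, function(r) r$n_left, 0L),
    n_right = vapply(res, function(r) r$n_right, 0L),
    threshold = vapply(res, function(r) r$threshold$value, 0),
    li = vapply(res, function(r) r$li, 0),
    label = vapply(res, function(r) r$label, ""),
    stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    if (!"subject_id" %in% names(meta))
      stop("'meta' must have a subject_id column")
    if ("ehi_score" %in% names(meta) && !"handedness" %in% names(meta))
      meta$handedness <- classify_handedness(meta$ehi_score)
    tab <- merge(tab, meta, by = "subject_id", sort = FALSE)
  }
  tab
}

#' Write / read a laterality table as TSV
#'
#' @param tab Data frame from [cohort_laterality()].
#' @param path Output path.
#' @return `path` (write) or the table (read).
#' @export
write_laterality_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_laterality_table
#' @export
read_laterality_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
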