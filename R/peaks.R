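#' Locate the peak of activity within an ROI
#'
#' The ROI voxel with the highest Z score.  Ties are broken by the
#' smallest linear (column-major) index, so the result is deterministic.
#'
#' @param map A 3-D [stat_map].
#' @param mask A non-empty [roi_mask] on the map's grid.
#' @return A `peak_result`: `voxel` (0-based `(i, j, k)`), `mm`
#'   (`(x, y, z)` world coordinates), `z_value`, `roi_label`,
#'   `subject_id`, `hemisphere`.
#' @export
find_peak <- function(map, mask) {
  stopifnot(is_stat_map(map), inherits(mask, "roi_mask"))
  check_same_grid(map, mask)
  idx <- which(mask$data)
  if (length(idx) == 0L) stop("mask is empty")
  vals <- map$data[idx]
  lin <- idx[which.max(vals)]  # which.max takes the first (smallest index) tie
  vox <- arrayInd(lin, dim(map$data))[1, ] - 1L
  mm <- voxel_to_mm(vox, map$affine, dim = dim(map$data))
  res <- structure(list(voxel = vox, mm = mm,
                        z_value = map$data[lin],
                        roi_label = mask$label,
                        subject_id = map$subject_id),
                   class = "peak_result")
  res$hemisphere <- hemisphere_of_peak(res)
  res
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("<peak_result> %s Z=%.3f at (%g, %g, %g) mm [%s], roi '%s'\n",
              if (is.na(x$subject_id)) "" else x$subject_id, x$z_value,
              x$mm[1], x$mm[2], x$mm[3], x$hemisphere, x$roi_label))
  invisible(x)
}

#' Hemisphere of a peak
#'
#' Sign of the world x coordinate: negative is left, positive is right,
#' exactly zero is midline.
#'
#' @param peak A `peak_result`, or a numeric `(x, y, z)` mm vector.
#' @return `"left"`, `"right"` or `"midline"`.
#' @export
hemisphere_of_peak <- function(peak) {
  x <- if (inherits(peak, "peak_result")) peak$mm[1] else peak[1]
  if (x < 0) "left" else if (x > 0) "right" else "midline"
}

#' Table of peak locations for a cohort
#'
#' @param maps List of [stat_map]s.
#' @param mask A [roi_mask] (commonly one side's ROI).
#' @return Data frame: `subject_id`, `i`, `j`, `k` (0-based), `x_mm`,
#'   `y_mm`, `z_mm`, `z_value`, `hemisphere`.
#' @export
peak_table <- function(maps, mask) {
  res <- lapply(maps, find_peak, mask = mask)
  data.frame(
    subject_id = vapply(res, function(r) as.character(r$subject_id), ""),
    i = vapply(res, function(r) r$voxel[1], 0L),
    j = vapply(res, function(r) r$voxel[2], 0L),
    k = vapply(res, function(r) r$voxel[3], 0L),
    x_mm = vapply(res, function(r) r$mm[1], 0),
    y_mm = vapply(res, function(r) r$mm[2], 0),
    z_mm = vapply(res, function(r) r$mm[3], 0),
    z_value = vapply(res, function(r) r$z_value, 0),
    hemisphere = vapply(res, function(r) r$hemisphere, ""),
    stringsAsFactors = FALSE)
}

#' Compare peak coordinates between groups along one axis
#'
#' Welch two-sample t test (equal variances not assumed) on the world-mm
#' peak coordinate of two groups along the chosen axis — e.g. testing
#' whether one group's peaks sit more anterior/posterior (y) or
#' superior/inferior (z).  The statistic follows the second-minus-first
#' group order convention of [welch_t_from_samples()].
#'
#' @param group_a,group_b Lists of `peak_result`s, or data frames from
#'   [peak_table()]; each group needs at least 2 peaks.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return A `welch_result` (see [welch_t_from_samples()]), with the two
#'   group means attached as `mean_a`, `mean_b`.
#' @export
compare_peak_axis <- function(group_a, group_b, axis = c("y", "z", "x")) {
  axis <- match.arg(axis)
  coord <- function(g) {
    if (is.data.frame(g)) return(g[[paste0(axis, "_mm")]])
    vapply(g, function(p) {
      stopifnot(inherits(p, "peak_result"))
      p$mm[match(axis, c("x", "y", "z"))]
    }, 0)
  }
  xa <- coord(group_a); xb <- coord(group_b)
  if (length(xa) < 2L || length(xb) < 2L)
    stop("each group needs at least 2 peaks")
  res <- welch_t_from_samples(xa, xb)
  res$mean_a <- mean(xa); res$mean_b <- mean(xb)
  res
}

#' Flag subjects whose peak hemisphere contradicts a group side
#'
#' Mirrors the exclusion of subjects whose individual peak falls in the
#' unexpected hemisphere before a group coordinate comparison.
#'
#' @param peaks Data frame from [peak_table()].
#' @param expected `"left"` or `"right"`.
#' @return Logical vector, `TRUE` where the peak is on the expected side.
#' @export
peak_side_consistent <- function(peaks, expected = c("left", "right")) {
  expected <- match.arg(expected)
  peaks$hemisphere == expected
}
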