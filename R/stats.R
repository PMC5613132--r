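#' Welch two-sample t test from printed summary statistics
#'
#' Welch's unequal-variance t test computed from group means, standard
#' deviations and sizes — the form needed to reproduce tests reported
#' only as summary statistics.  The statistic is `(m2 - m1) / se`
#' (second group minus first), so calling with (typical, atypical) in
#' that order reproduces reported signs; degrees of freedom follow
#' Welch-Satterthwaite and the p value is two-tailed.
#'
#' @param m1,sd1,n1 First group mean, SD (ddof = 1) and size.
#' @param m2,sd2,n2 Second group.
#' @return A `welch_result`: `t`, `df`, `p`, `n1`, `n2`.
#' @export
welch_t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    if (m1 == m2) {
      return(structure(list(t = 0, df = n1 + n2 - 2, p = 1,
                            n1 = n1, n2 = n2), class = "welch_result"))
    }
    stop("both standard deviations are 0 with unequal means")
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (m2 - m1) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, n1 = n1, n2 = n2),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t(%.1f) = %.2f, p = %.3f (two-tailed; n = %d, %d; second minus first)\n",
              x$df, x$t, x$p, x$n1, x$n2))
  invisible(x)
}

#' Welch two-sample t test from samples
#'
#' Identical to [welch_t_from_summary()] applied to the sample moments
#' (SD with ddof = 1).  Two identical constant samples return t = 0,
#' p = 1 by convention.
#'
#' @param xs,ys Numeric samples, each of length >= 2.
#' @return A `welch_result`.
#' @export
welch_t_from_samples <- function(xs, ys) {
  if (length(xs) < 2L || length(ys) < 2L) stop("each sample needs n >= 2")
  welch_t_from_summary(mean(xs), stats::sd(xs), length(xs),
                       mean(ys), stats::sd(ys), length(ys))
}

#' Pearson correlation with degrees of freedom
#'
#' Pearson r with its df = n - 2 and the two-tailed p value from
#' `t = r sqrt(df / (1 - r^2))`, as reported in subscripted form (e.g.
#' r with 61 df for n = 63).
#'
#' @param xs,ys Numeric vectors of equal length n >= 3, neither constant.
#' @return A `corr_result`: `r`, `df`, `p`, `n`.
#' @export
pearson_with_df <- function(xs, ys) {
  n <- length(xs)
  if (n != length(ys)) stop("vectors differ in length")
  if (n < 3L) stop("need n >= 3")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(xs, ys, method = "pearson")
  structure(list(r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value, n = n),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("Pearson r(%d) = %.3f, p = %.4g\n", x$df, x$r, x$p))
  invisible(x)
}

#' Voxelwise two-sample Welch t map
#'
#' Computes the Welch t statistic at every voxel between two groups of
#' maps on a shared grid.  As everywhere in this module the statistic is
#' second group minus first (`mean(B) - mean(A)` over its standard
#' error), so call with (reference, comparison) to get
#' comparison-positive contrasts.  Voxels with zero variance in both
#' groups are set to 0; their count is attached as attribute
#' `"n_zero_variance"`.
#'
#' @param maps_a,maps_b Lists of >= 2 [stat_map]s each.
#' @return A [stat_map] of t values with attributes `"df"` (voxelwise
#'   Welch df array) and `"n_zero_variance"`.
#' @export
two_sample_t_map <- function(maps_a, maps_b) {
  if (length(maps_a) < 2L || length(maps_b) < 2L)
    stop("each group needs at least 2 maps")
  ref <- maps_a[[1]]
  for (m in c(maps_a, maps_b)) check_same_grid(ref, m)
  dims <- dim(ref$data)
  nv <- prod(dims)
  ya <- vapply(maps_a, function(m) as.vector(m$data), numeric(nv))
  yb <- vapply(maps_b, function(m) as.vector(m$data), numeric(nv))
  n1 <- ncol(ya); n2 <- ncol(yb)
  m1 <- rowMeans(ya); m2 <- rowMeans(yb)
  v1 <- rowSums((ya - m1)^2) / (n1 - 1) / n1
  v2 <- rowSums((yb - m2)^2) / (n2 - 1) / n2
  se2 <- v1 + v2
  zero <- se2 <= 0
  t <- numeric(nv)
  df <- rep(n1 + n2 - 2, nv)
  ok <- !zero
  t[ok] <- (m2[ok] - m1[ok]) / sqrt(se2[ok])
  df[ok] <- se2[ok]^2 / (v1[ok]^2 / (n1 - 1) + v2[ok]^2 / (n2 - 1))
  out <- stat_map(array(t, dim = dims), ref$affine, map_kind = "contrast")
  attr(out, "df") <- array(df, dim = dims)
  attr(out, "n_zero_variance") <- sum(zero)
  out
}
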