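#' Temporal band-pass filter
#'
#' Hard discrete-Fourier window: frequency bins with
#' `f_lo < |f| < f_hi` are retained, all others — including the DC
#' component — are zeroed, so filtered series have (numerically) zero
#' mean.  There is no tapering; the window edges are exact, which makes
#' the pass/stop behavior directly testable against DFT bin arithmetic.
#'
#' @param x Numeric vector (one series), a T x V matrix (series in
#'   columns), or a [resting_run] whose voxel series are all filtered.
#' @param tr_s Sampling interval, seconds (taken from the run when `x`
#'   is a [resting_run]).
#' @param f_lo,f_hi Passband edges in Hz; `f_hi` must be below the
#'   Nyquist frequency `1 / (2 tr_s)`.
#' @return Filtered object of the same shape/class.
#' @export
bandpass <- function(x, tr_s = NULL, f_lo = 0.01, f_hi = 0.1) {
  if (inherits(x, "resting_run")) {
    d <- dim(x$data)
    mat <- t(matrix(x$data, prod(d[1:3]), d[4]))
    mat <- bandpass_series(mat, x$tr_s, f_lo, f_hi)
    x$data <- array(t(mat), dim = d)
    return(x)
  }
  if (is.null(tr_s)) stop("'tr_s' is required for vector/matrix input")
  bandpass_series(x, tr_s, f_lo, f_hi)
}

bandpass_series <- function(x, tr_s, f_lo = 0.01, f_hi = 0.1) {
  vec <- !is.matrix(x)
  m <- if (vec) matrix(x, ncol = 1) else x
  t_len <- nrow(m)
  if (t_len < 20L) stop("need at least 20 time points")
  nyq <- 1 / (2 * tr_s)
  if (f_hi >= nyq)
    stop(sprintf("f_hi (%g Hz) must be below Nyquist (%g Hz)", f_hi, nyq))
  if (f_lo >= f_hi) stop("f_lo must be below f_hi")
  freqs <- seq_len(t_len) - 1
  freqs <- pmin(freqs, t_len - freqs) / (t_len * tr_s)
  keep <- freqs > f_lo & freqs < f_hi
  ft <- stats::mvfft(m)
  ft[!keep, ] <- 0
  out <- Re(stats::mvfft(ft, inverse = TRUE)) / t_len
  if (vec) drop(out) else out
}

#' Friston-style 24-column motion expansion
#'
#' Expands 6 rigid-body motion parameters into 24 motion-related
#' waveforms: for each parameter, the parameter itself, its square, its
#' one-volume backward lag, and the squared lag, in that column order.
#' Lagged rows are padded with 0 at the first volume.
#'
#' @param motion T x 6 matrix.
#' @return T x 24 matrix with descriptive column names.
#' @export
expand_motion_regressors <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("'motion' must have 6 columns")
  if (nrow(motion) < 2L) stop("need at least 2 time points")
  t_len <- nrow(motion)
  out <- matrix(0, t_len, 24)
  nm <- character(24)
  for (p in 1:6) {
    m <- motion[, p]
    lag <- c(0, m[-t_len])
    cols <- (p - 1) * 4 + 1:4
    out[, cols] <- cbind(m, m^2, lag, lag^2)
    nm[cols] <- paste0("mot", p, c("", "_sq", "_lag", "_lag_sq"))
  }
  colnames(out) <- nm
  out
}

#' Backward difference of a series
#'
#' `d[t] = s[t] - s[t-1]`, with `d[1] = 0`; the cumulative sum of the
#' output plus the first sample recovers the input.
#'
#' @param x Numeric vector (or matrix, columnwise).
#' @return Object of the same shape.
#' @export
backward_difference <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, backward_difference))
  if (length(x) < 2L) stop("need at least 2 time points")
  c(0, diff(x))
}

#' Nuisance design matrix for a resting run
#'
#' Assembles the 28-column confound design: the Friston-style 24-column
#' motion expansion, the mean CSF series with its backward difference,
#' and the mean white-matter series with its backward difference.
#' Whole-brain global signal is deliberately not included; hemispheric
#' global signals are treated as signals of interest downstream.
#'
#' @param run A [resting_run] (its current data supply the tissue
#'   series — filter first if the design should be band-limited).
#' @param motion Optional motion matrix overriding `run$motion` (e.g. a
#'   band-passed copy).
#' @return A list of class `nuisance_design`: `matrix` (T x 28),
#'   `names`.
#' @export
build_nuisance_design <- function(run, motion = NULL) {
  stopifnot(inherits(run, "resting_run"))
  motion <- motion %||% run$motion
  mot24 <- expand_motion_regressors(motion)
  d <- dim(run$data)
  mat <- t(matrix(run$data, prod(d[1:3]), d[4]))
  csf <- rowMeans(mat[, as.vector(run$masks$csf), drop = FALSE])
  wm <- rowMeans(mat[, as.vector(run$masks$white), drop = FALSE])
  x <- cbind(mot24, csf = csf, csf_backdiff = backward_difference(csf),
             wm = wm, wm_backdiff = backward_difference(wm))
  structure(list(matrix = x, names = colnames(x)),
            class = "nuisance_design")
}

#' Remove nuisance variance by voxelwise OLS
#'
#' Regresses every voxel series on `[intercept | design]` by ordinary
#' least squares and returns the residual run.  All-zero design columns
#' are dropped (with a message); genuine rank deficiency among the
#' remaining columns is an error naming the collinear columns.
#' Residuals are orthogonal to every retained design column.
#'
#' @param run A [resting_run].
#' @param design A `nuisance_design` or a plain T x K matrix.
#' @return The residual [resting_run].
#' @export
nuisance_regress <- function(run, design) {
  stopifnot(inherits(run, "resting_run"))
  x <- if (inherits(design, "nuisance_design")) design$matrix
       else as.matrix(design)
  if (nrow(x) != dim(run$data)[4])
    stop("design rows must equal the number of volumes")
  nm <- colnames(x) %||% paste0("c", seq_len(ncol(x)))
  zero <- apply(x, 2, function(cc) all(cc == 0))
  if (any(zero)) {
    message(sprintf("dropping %d all-zero design column(s): %s",
                    sum(zero), paste(nm[zero], collapse = ", ")))
    x <- x[, !zero, drop = FALSE]
    nm <- nm[!zero]
  }
  xx <- cbind(intercept = 1, x)
  qr_x <- qr(xx)
  if (qr_x$rank < ncol(xx)) {
    bad <- setdiff(seq_len(ncol(xx)), qr_x$pivot[seq_len(qr_x$rank)])
    stop(sprintf("rank-deficient nuisance design; collinear column(s): %s",
                 paste(c("intercept", nm)[bad], collapse = ", ")))
  }
  d <- dim(run$data)
  mat <- t(matrix(run$data, prod(d[1:3]), d[4]))
  res <- qr.resid(qr_x, mat)
  run$data <- array(t(res), dim = d)
  run
}

#' Mean time series of a spherical seed
#'
#' Averages, per volume, the voxels whose centers lie within
#' `radius_mm` (Euclidean, inclusive) of the seed center; a 5 mm sphere
#' on a 2 mm grid covers 81 voxels.
#'
#' @param run A [resting_run].
#' @param seed A [seed_spec()].
#' @return Numeric vector of length T.
#' @export
extract_seed <- function(run, seed) {
  stopifnot(inherits(run, "resting_run"), inherits(seed, "seed_spec"))
  gs <- dim(run$data)[1:3]
  cg <- voxel_center_grid(gs, run$affine)
  d2x <- (cg$x - seed$center_mm[1])^2
  d2y <- (cg$y - seed$center_mm[2])^2
  d2z <- (cg$z - seed$center_mm[3])^2
  inside <- outer(outer(d2x, d2y, "+"), d2z, "+") <= seed$radius_mm^2
  n_in <- sum(inside)
  if (n_in == 0L)
    stop(sprintf("seed '%s' contains no voxel centers", seed$name))
  d <- dim(run$data)
  mat <- t(matrix(run$data, prod(d[1:3]), d[4]))
  rowMeans(mat[, as.vector(inside), drop = FALSE])
}

#' Hemispheric global signals
#'
#' Per-volume mean over the gray-matter voxels of each hemisphere
#' (world x < 0 left, x > 0 right; x = 0 voxels belong to neither).
#' These are signals of interest here, used as predictors, not removed.
#'
#' @param run A [resting_run] with hemisphere masks.
#' @return List with numeric `left` and `right` series of length T.
#' @export
hemispheric_global_signal <- function(run) {
  stopifnot(inherits(run, "resting_run"))
  hemi <- run$masks$hemispheres
  d <- dim(run$data)
  mat <- t(matrix(run$data, prod(d[1:3]), d[4]))
  list(left = rowMeans(mat[, as.vector(hemi$left$data), drop = FALSE]),
       right = rowMeans(mat[, as.vector(hemi$right$data), drop = FALSE]))
}

#' Seed + hemispheric-global-signal connectivity model
#'
#' Voxelwise multiple regression of the (preprocessed) run on
#' `[intercept | seed_1 .. seed_k | global_left | global_right]`.
#' Returns beta and t maps per predictor, plus the left-minus-right and
#' right-minus-left hemispheric global-signal contrast maps (exact
#' negations of each other).  Predictor pairs correlated above 0.99 in
#' absolute value are rejected by name.
#'
#' @param run A [resting_run], already nuisance-regressed and
#'   band-passed.
#' @param seeds List of [seed_spec()]s.
#' @param predictors Optional named list of precomputed predictor
#'   series overriding seed extraction (mostly for testing).
#' @return A `connectivity_result`: `beta` and `t` (named lists of 3-D
#'   arrays), `contrast_lr` and `contrast_rl` (3-D arrays), `predictor
#'   names`, `affine`, `subject_id`.
#' @export
seed_connectivity <- function(run, seeds, predictors = NULL) {
  stopifnot(inherits(run, "resting_run"))
  if (is.null(predictors)) {
    predictors <- lapply(seeds, function(s) extract_seed(run, s))
    names(predictors) <- vapply(seeds, function(s) s$name, "")
    gl <- hemispheric_global_signal(run)
    predictors$global_left <- gl$left
    predictors$global_right <- gl$right
  }
  p_mat <- do.call(cbind, predictors)
  pn <- colnames(p_mat)
  cc <- suppressWarnings(stats::cor(p_mat))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  if (any(abs(cc) > 0.99)) {
    ij <- which(abs(cc) > 0.99, arr.ind = TRUE)[1, ]
    stop(sprintf("collinear predictors: %s and %s (|r| > 0.99)",
                 pn[ij[1]], pn[ij[2]]))
  }
  x <- cbind(intercept = 1, p_mat)
  d <- dim(run$data)
  y <- t(matrix(run$data, prod(d[1:3]), d[4]))
  qr_x <- qr(x)
  beta <- qr.coef(qr_x, y)
  res <- qr.resid(qr_x, y)
  df <- nrow(x) - ncol(x)
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- diag(solve(crossprod(x)))
  gs <- d[1:3]
  as_arr <- function(v) array(v, dim = gs)
  betas <- lapply(seq_along(pn), function(i) as_arr(beta[i + 1, ]))
  names(betas) <- pn
  tmaps <- lapply(seq_along(pn), function(i) {
    se <- sqrt(sigma2 * xtx_inv_diag[i + 1])
    as_arr(ifelse(se > 0, beta[i + 1, ] / se, 0))
  })
  names(tmaps) <- pn
  con_lr <- betas$global_left - betas$global_right
  structure(list(beta = betas, t = tmaps,
                 contrast_lr = con_lr, contrast_rl = -con_lr,
                 predictors = pn, df = df, affine = run$affine,
                 subject_id = run$subject_id),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result> %s predictors: %s (df = %d)\n",
              if (is.na(x$subject_id)) "" else x$subject_id,
              paste(x$predictors, collapse = ", "), x$df))
  invisible(x)
}

#' Standard resting-state preprocessing chain
#'
#' Band-passes the voxel series and the motion parameters with the same
#' hard DFT window, builds the 28-column nuisance design from the
#' filtered data, and removes it by voxelwise OLS.  Because regressors
#' and data are filtered identically, the residuals stay orthogonal to
#' the confounds (no reintroduction of removed variance).
#'
#' @param run A raw [resting_run].
#' @param f_lo,f_hi Passband in Hz (defaults 0.01 and 0.1).
#' @param smooth_fwhm_mm Optional Gaussian FWHM applied volumewise after
#'   regression (default `NULL`, no smoothing).
#' @return The preprocessed [resting_run].
#' @export
preprocess_resting <- function(run, f_lo = 0.01, f_hi = 0.1,
                               smooth_fwhm_mm = NULL) {
  stopifnot(inherits(run, "resting_run"))
  filt <- bandpass(run, f_lo = f_lo, f_hi = f_hi)
  mot_f <- bandpass_series(run$motion, run$tr_s, f_lo, f_hi)
  design <- build_nuisance_design(filt, motion = mot_f)
  out <- nuisance_regress(filt, design)
  if (!is.null(smooth_fwhm_mm)) {
    d <- dim(out$data)
    for (tt in seq_len(d[4])) {
      vol <- stat_map(array(out$data[, , , tt], dim = d[1:3]), out$affine)
      out$data[, , , tt] <- gaussian_smooth(vol, smooth_fwhm_mm)$data
    }
  }
  out
}

#' Group contrast of subject-level connectivity maps
#'
#' Voxelwise Welch t map ([two_sample_t_map()]) over a chosen
#' subject-level map from each group's connectivity results.  The
#' statistic is group B minus group A.
#'
#' @param results_a,results_b Lists of `connectivity_result`s (>= 2
#'   each).
#' @param which `"contrast_lr"`, `"contrast_rl"`, or the name of a
#'   predictor whose beta map is compared.
#' @return A t-statistic [stat_map].
#' @export
group_connectivity_contrast <- function(results_a, results_b,
                                        which = "contrast_lr") {
  pick <- function(r) {
    arr <- if (which %in% c("contrast_lr", "contrast_rl")) r[[which]]
           else r$beta[[which]]
    if (is.null(arr)) stop(sprintf("unknown map '%s'", which))
    stat_map(arr, r$affine, map_kind = "beta")
  }
  two_sample_t_map(lapply(results_a, pick), lapply(results_b, pick))
}
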