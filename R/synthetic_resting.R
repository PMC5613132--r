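#' Resting-state run specification
#'
#' Describes a synthetic 4-D resting run: seed-coupled signals,
#' hemisphere-wide global components whose left/right amplitudes depend
#' on the group, Friston-style motion-correlated nuisance, CSF/WM-like
#' tissue signals, and white noise.  All temporal components of interest
#' are band-limited to the analysis passband so filtering does not
#' remove the planted structure.
#'
#' @param grid_shape 3-vector, first dimension even (default
#'   `c(20, 20, 12)`).
#' @param voxel_mm Isotropic voxel size (default 4).
#' @param t_len Number of volumes (default 180, i.e. 6 min at TR 2 s).
#' @param tr_s Repetition time in seconds (default 2).
#' @param seeds List of [seed_spec()]s with planted coupling: each may
#'   carry `target_mm` (center of the coupled remote region), `beta`
#'   (planted regression coefficient at the target peak) and
#'   `target_sigma_mm`.
#' @param seed_signal_amp Amplitude of the seed signal inside its
#'   sphere (default 2); the remote coupling scales with it, so the
#'   planted beta is amplitude-free.
#' @param global_amp Length-2 vector `(dominant, nondominant)` of
#'   hemispheric global-component amplitudes; the group flag decides
#'   which hemisphere is dominant (default `c(1, 0.5)`).
#' @param crossover_amp Amplitude with which the dominant hemisphere's
#'   global signal additionally couples into a Gaussian patch of the
#'   opposite hemisphere (default 0.5).  A uniform hemispheric
#'   component is absorbed exactly by its own hemisphere's mean
#'   predictor whatever its amplitude, so this contralateral coupling
#'   is what makes the group asymmetry detectable in the
#'   left-minus-right global contrast maps.
#' @param crossover_sigma_mm Spatial sigma of the crossover patch
#'   (default 8).
#' @param motion_amp Amplitude of motion-correlated spatial nuisance
#'   (default 0.5).
#' @param tissue_amp Amplitude of the CSF and WM tissue signals
#'   (default 1).
#' @param noise_sd White-noise SD (default 1).
#' @param seed Integer RNG seed.
#' @return A list of class `resting_spec`.
#' @export
resting_spec <- function(grid_shape = c(20L, 20L, 12L), voxel_mm = 4,
                         t_len = 180L, tr_s = 2,
                         seeds = default_resting_seeds(),
                         seed_signal_amp = 2,
                         global_amp = c(1, 0.5),
                         crossover_amp = 0.5, crossover_sigma_mm = 8,
                         motion_amp = 0.5, tissue_amp = 1,
                         noise_sd = 1, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (grid_shape[1] %% 2L != 0L)
    stop("first grid dimension must be even so the midline bisects it")
  if (t_len < 20L) stop("'t_len' must be at least 20 volumes")
  if (tr_s <= 0) stop("'tr_s' must be positive")
  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1:3, 4] <- -(grid_shape - 1) * voxel_mm / 2
  structure(list(grid_shape = grid_shape, voxel_mm = voxel_mm,
                 affine = aff, t_len = as.integer(t_len), tr_s = tr_s,
                 seeds = seeds, seed_signal_amp = seed_signal_amp,
                 global_amp = global_amp,
                 crossover_amp = crossover_amp,
                 crossover_sigma_mm = crossover_sigma_mm,
                 motion_amp = motion_amp, tissue_amp = tissue_amp,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "resting_spec")
}

#' Spherical seed specification
#'
#' @param center_mm World coordinates of the sphere center.
#' @param radius_mm Sphere radius, mm (default 5).
#' @param name Seed name.
#' @param target_mm,beta,target_sigma_mm Planted coupling (generator
#'   only): center, peak regression coefficient and spatial sigma
#'   (default 6 mm) of the remote region driven by this seed's signal.
#' @return A list of class `seed_spec`.
#' @export
seed_spec <- function(center_mm, radius_mm = 5, name = "seed",
                      target_mm = NULL, beta = 0, target_sigma_mm = 6) {
  if (radius_mm <= 0) stop("'radius_mm' must be positive")
  structure(list(center_mm = center_mm, radius_mm = radius_mm,
                 name = name, target_mm = target_mm, beta = beta,
                 target_sigma_mm = target_sigma_mm),
            class = "seed_spec")
}

default_resting_seeds <- function() {
  list(seed_spec(c(-22, 2, 2), name = "seed_left",
                 target_mm = c(-22, -26, 2), beta = 0.8),
       seed_spec(c(22, 2, 2), name = "seed_right",
                 target_mm = c(22, -26, 2), beta = 0.5))
}

#' Resting-state run container
#'
#' @param data 4-D array (x, y, z, t), all finite.
#' @param affine 4x4 voxel-to-mm transform.
#' @param tr_s Repetition time, seconds.
#' @param motion T x 6 motion parameters (3 translations mm, 3 rotations
#'   rad); rows must equal the number of volumes.
#' @param masks List with logical arrays `gray`, `white`, `csf` and a
#'   [roi_pair] `hemispheres`, all on the run's grid.
#' @param subject_id Subject identifier.
#' @return A list of class `resting_run`.
#' @export
resting_run <- function(data, affine, tr_s, motion, masks,
                        subject_id = NA_character_) {
  if (length(dim(data)) != 4L) stop("'data' must be a 4-D array")
  t_len <- dim(data)[4]
  if (t_len < 20L) stop("run must have at least 20 volumes")
  if (!all(is.finite(data))) stop("run contains non-finite values")
  motion <- as.matrix(motion)
  if (nrow(motion) != t_len || ncol(motion) != 6L)
    stop("'motion' must be a T x 6 matrix matching the number of volumes")
  for (nm in c("gray", "white", "csf"))
    if (!identical(dim(masks[[nm]]), dim(data)[1:3]))
      stop(sprintf("mask '%s' is not on the run's grid", nm))
  structure(list(data = data, affine = check_affine(affine), tr_s = tr_s,
                 motion = motion, masks = masks, subject_id = subject_id),
            class = "resting_run")
}

#' @export
print.resting_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<resting_run> %s, %d volumes at TR %.1f s %s\n",
              paste(d[1:3], collapse = "x"), d[4], x$tr_s,
              if (is.na(x$subject_id)) "" else x$subject_id))
  invisible(x)
}

resting_masks <- function(grid_shape, affine) {
  cg <- voxel_center_grid(grid_shape, affine)
  inb <- function(v, lim) abs(v) <= lim
  box <- function(ix, iy, iz) outer(outer(ix, iy, "&"), iz, "&")
  csf <- box(inb(cg$x, 6), inb(cg$y, 6), inb(cg$z, 6))
  wm <- box(inb(cg$x, 14), inb(cg$y, 14), inb(cg$z, 10)) & !csf
  gray <- !(csf | wm)
  full <- function(v) rep(TRUE, length(v))
  hemi <- roi_pair(
    roi_mask(box(cg$x < 0, full(cg$y), full(cg$z)) & gray,
             side = "left", label = "hemi_gray_left"),
    roi_mask(box(cg$x > 0, full(cg$y), full(cg$z)) & gray,
             side = "right", label = "hemi_gray_right"))
  list(gray = gray, white = wm, csf = csf, hemispheres = hemi)
}

# unit-variance band-limited signal (white noise restricted to the
# analysis passband)
band_signal <- function(t_len, tr_s, f_lo = 0.01, f_hi = 0.1) {
  x <- bandpass_series(stats::rnorm(t_len), tr_s, f_lo, f_hi)
  x / stats::sd(x)
}

#' Simulate a synthetic resting-state run
#'
#' Generates a 4-D run as the sum of (i) each seed's band-limited signal
#' placed in its spherical mask and coupled, with the planted beta, to a
#' Gaussian-profiled remote target region, (ii) hemisphere-wide
#' band-limited global components over gray matter, with the larger
#' amplitude on the left for the typical group and on the right for the
#' atypical group, (iii) motion-correlated spatial nuisance plus
#' CSF/WM-like tissue signals, and (iv) white noise.  A T x 6 motion
#' random walk is generated alongside.  The same spec, flag and seed
#' always produce a bit-identical run.
#'
#' @param spec A [resting_spec].
#' @param group_flag `"typical"` (left-dominant global component) or
#'   `"atypical"` (right-dominant).
#' @param seed Integer RNG seed.
#' @param subject_id Subject identifier.
#' @return A [resting_run] with attribute `"truth"` (planted seed
#'   signals, betas, global series and amplitudes).
#' @export
simulate_resting <- function(spec, group_flag = c("typical", "atypical"),
                             seed = 1L, subject_id = NA_character_) {
  stopifnot(inherits(spec, "resting_spec"))
  group_flag <- match.arg(group_flag)
  set.seed(as.integer(seed))
  gs <- spec$grid_shape; t_len <- spec$t_len
  nv <- prod(gs)
  masks <- resting_masks(gs, spec$affine)
  cg <- voxel_center_grid(gs, spec$affine)
  coords <- cbind(rep(cg$x, times = gs[2] * gs[3]),
                  rep(rep(cg$y, each = gs[1]), times = gs[3]),
                  rep(cg$z, each = gs[1] * gs[2]))

  dat <- matrix(0, t_len, nv)
  seed_signals <- list()
  for (sd_spec in spec$seeds) {
    s <- spec$seed_signal_amp * band_signal(t_len, spec$tr_s)
    seed_signals[[sd_spec$name]] <- s
    d2 <- colSums((t(coords) - sd_spec$center_mm)^2)
    sphere <- d2 <= sd_spec$radius_mm^2
    w <- as.numeric(sphere)
    if (!is.null(sd_spec$target_mm) && sd_spec$beta != 0) {
      d2t <- colSums((t(coords) - sd_spec$target_mm)^2)
      w <- w + sd_spec$beta * exp(-d2t / (2 * sd_spec$target_sigma_mm^2))
    }
    dat <- dat + s %o% w
  }

  amps <- if (group_flag == "typical") spec$global_amp
          else rev(spec$global_amp)
  g_l <- band_signal(t_len, spec$tr_s)
  g_r <- band_signal(t_len, spec$tr_s)
  dat <- dat + (amps[1] * g_l) %o% as.numeric(masks$hemispheres$left$data)
  dat <- dat + (amps[2] * g_r) %o% as.numeric(masks$hemispheres$right$data)
  # contralateral coupling of the dominant hemisphere's global signal
  patch_mm <- c(18, 10, 6)  # gray-matter patch, mirrored per group
  if (spec$crossover_amp > 0) {
    dom_is_left <- group_flag == "typical"
    g_dom <- if (dom_is_left) g_l else g_r
    ctr <- if (dom_is_left) patch_mm else patch_mm * c(-1, 1, 1)
    d2p <- colSums((t(coords) - ctr)^2)
    patch <- exp(-d2p / (2 * spec$crossover_sigma_mm^2)) *
      as.numeric(masks$gray)
    dat <- dat + (spec$crossover_amp * g_dom) %o% patch
  }

  motion <- apply(matrix(stats::rnorm(t_len * 6, sd = 0.02), t_len, 6),
                  2, cumsum)
  if (spec$motion_amp > 0) {
    w_mot <- matrix(stats::rnorm(nv * 6, sd = spec$motion_amp), nv, 6)
    dat <- dat + scale(motion, scale = FALSE) %*% t(w_mot)
  }
  if (spec$tissue_amp > 0) {
    dat <- dat + (spec$tissue_amp * band_signal(t_len, spec$tr_s)) %o%
      as.numeric(masks$csf)
    dat <- dat + (spec$tissue_amp * band_signal(t_len, spec$tr_s)) %o%
      as.numeric(masks$white)
  }
  if (spec$noise_sd > 0)
    dat <- dat + matrix(stats::rnorm(t_len * nv, sd = spec$noise_sd),
                        t_len, nv)

  run <- resting_run(array(t(dat), dim = c(gs, t_len)), spec$affine,
                     spec$tr_s, motion, masks, subject_id = subject_id)
  attr(run, "truth") <- list(group_flag = group_flag,
                             seed_signals = seed_signals,
                             betas = vapply(spec$seeds,
                                            function(s) s$beta, 0),
                             global_left = g_l, global_right = g_r,
                             global_amp = stats::setNames(
                               amps, c("left", "right")),
                             crossover_center =
                               if (group_flag == "typical") patch_mm
                               else patch_mm * c(-1, 1, 1),
                             seed = seed)
  run
}

#' Write / read FSL-style motion parameters
#'
#' Whitespace-delimited T x 6 text files (3 translations, 3 rotations).
#'
#' @param motion T x 6 numeric matrix.
#' @param path File path.
#' @export
write_motion_params <- function(motion, path) {
  utils::write.table(format(motion, digits = 10), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_params
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L) stop("motion file must have 6 columns")
  dimnames(m) <- NULL
  m
}
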