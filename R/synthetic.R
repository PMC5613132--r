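#' Cohort specification for synthetic activation maps
#'
#' Describes a cohort of per-subject verbal-fluency-like Z maps with
#' planted ground truth.  Each subject carries Gaussian activation blobs
#' centered in toy left/right inferior-frontal ("Broca" BA 44/45
#' analogue) ROIs whose amplitude ratio realizes a planted laterality
#' index, plus a broad "diffuse recruitment" component in the dominant
#' hemisphere whose spatial extent grows with bilaterality, plus white
#' Gaussian background noise in Z units.
#'
#' Group structure is planted in three coupled ways:
#' \itemize{
#'   \item the planted LI sampler differs by group (typical, bilateral,
#'     right-dominant);
#'   \item typical and atypical subjects activate *different locations*
#'     inside the ROI (atypical blob centers sit inferior to typical
#'     ones), so unthresholded spatial patterns separate the two groups
#'     and peak z coordinates differ by group;
#'   \item the suprathreshold extent is multiplied by
#'     `1 + kappa * (1 - |LI|/100)`, so more bilateral subjects recruit
#'     more tissue.
#' }
#'
#' @param n_subjects Number of subjects (default 63).
#' @param grid_shape 3-vector of grid dimensions; the first must be even
#'   so that the x = 0 plane bisects the grid (default `c(64, 64, 35)`).
#' @param voxel_mm Isotropic voxel size in mm (default 2).
#' @param proportions Named proportions of the three laterality classes,
#'   summing to 1 (default `c(typical = .83, bilateral = .09, right = .08)`).
#' @param li_samplers Named list of functions `n -> n planted LIs`, one
#'   per class; defaults draw truncated normals matching a strongly
#'   left-dominant typical class, a near-zero bilateral class and a
#'   strongly right-dominant class.
#' @param blob_amplitude Peak Z of the dominant-side blob (default 8).
#' @param blob_sigma_mm Gaussian sigma of the ROI blobs, mm (default 5).
#' @param diffuse_amplitude Peak Z of the diffuse hemispheric component
#'   (default 6; set 0 to disable).
#' @param diffuse_sigma_mm Sigma of the diffuse component, mm (default 20).
#' @param diffuse_sigma_jitter SD of the log-normal between-subject
#'   variability multiplying the diffuse component's sigma (default
#'   0.04), modelling individual differences in overall recruitment
#'   that are independent of laterality.
#' @param extent_base Baseline extent multiplier (default 1).
#' @param extent_kappa Coupling strength `kappa >= 0` between
#'   bilaterality and extent (default 1.5).
#' @param noise_sd Background noise standard deviation in Z units
#'   (default 1; set 0 for noiseless maps).
#' @param seed Integer RNG seed; all randomness in the generated cohort
#'   derives from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 63L,
                        grid_shape = c(64L, 64L, 35L),
                        voxel_mm = 2,
                        proportions = c(typical = 0.83, bilateral = 0.09,
                                        right = 0.08),
                        li_samplers = default_li_samplers(),
                        blob_amplitude = 8,
                        blob_sigma_mm = 5,
                        diffuse_amplitude = 6,
                        diffuse_sigma_mm = 20,
                        diffuse_sigma_jitter = 0.04,
                        extent_base = 1,
                        extent_kappa = 1.5,
                        noise_sd = 1,
                        seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("'grid_shape' must be 3 dimensions of at least 4 voxels")
  if (grid_shape[1] %% 2L != 0L)
    stop("first grid dimension must be even so the midline bisects it")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (!all(names(proportions) %in% c("typical", "bilateral", "right")))
    stop("proportions must be named typical/bilateral/right")
  if (blob_amplitude <= 0 || noise_sd < 0 || extent_kappa < 0)
    stop("invalid amplitude/noise/kappa")
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_shape = grid_shape, voxel_mm = voxel_mm,
                 affine = default_affine(grid_shape, voxel_mm),
                 proportions = proportions, li_samplers = li_samplers,
                 blob_amplitude = blob_amplitude,
                 blob_sigma_mm = blob_sigma_mm,
                 diffuse_amplitude = diffuse_amplitude,
                 diffuse_sigma_mm = diffuse_sigma_mm,
                 diffuse_sigma_jitter = diffuse_sigma_jitter,
                 extent_base = extent_base, extent_kappa = extent_kappa,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# planted-LI samplers per laterality class: strongly left-dominant
# typical subjects, near-zero bilateral subjects, strongly right-dominant
# atypical subjects, kept clear of the +/-33 class boundaries
default_li_samplers <- function() {
  list(typical = function(n) rtrunc_norm(n, 92, 13, 45, 100),
       bilateral = function(n) rtrunc_norm(n, 0, 12, -24, 24),
       right = function(n) rtrunc_norm(n, -88, 8, -100, -45))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# RAS affine with x and y centered on 0 and the z range shifted so its
# center sits at z = +10 mm (keeps superior blob/ROI coordinates inside
# the grid, as on a group EPI grid)
default_affine <- function(grid_shape, voxel_mm) {
  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1, 4] <- -(grid_shape[1] - 1) * voxel_mm / 2
  aff[2, 4] <- -(grid_shape[2] - 1) * voxel_mm / 2
  aff[3, 4] <- 10 - (grid_shape[3] - 1) * voxel_mm / 2
  aff
}

# mm-space geometry of the toy cohort, shared by generator and tests:
# mirror-symmetric inferior-frontal ROI boxes, group-specific blob
# centers inside them, and posterior diffuse-component centers
cohort_geometry <- function() {
  list(roi_box = list(x = c(-58, -38), y = c(8, 32), z = c(4, 36)),
       blob_center = list(typical = c(-48, 20, 26),
                          atypical = c(-48, 20, 12)),
       diffuse_center = c(-40, -40, 10))
}

voxel_center_grid <- function(grid_shape, affine) {
  xs <- affine[1, 1] * (seq_len(grid_shape[1]) - 1) + affine[1, 4]
  ys <- affine[2, 2] * (seq_len(grid_shape[2]) - 1) + affine[2, 4]
  zs <- affine[3, 3] * (seq_len(grid_shape[3]) - 1) + affine[3, 4]
  list(x = xs, y = ys, z = zs)
}

#' Toy left/right ROI pair and hemisphere masks
#'
#' `make_roi_pair()` builds mirror-symmetric box ROIs standing in for
#' left/right Broca's-area (BA 44/45) masks; at the default 2 mm grid
#' the boxes hold 2040 voxels per side, close to a probabilistic
#' cytoarchitectonic BA 44/45 mask.  `make_hemisphere_masks()` returns
#' the left (world x < 0) and right (x > 0) hemispheres, which partition
#' all voxels because the even first dimension leaves no voxel centered
#' on x = 0.
#'
#' @param spec A [cohort_spec] (its grid and affine are used).
#' @return A [roi_pair].
#' @export
make_roi_pair <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- cohort_geometry()$roi_box
  cg <- voxel_center_grid(spec$grid_shape, spec$affine)
  inx_l <- cg$x >= g$x[1] & cg$x <= g$x[2]
  inx_r <- cg$x >= -g$x[2] & cg$x <= -g$x[1]
  iny <- cg$y >= g$y[1] & cg$y <= g$y[2]
  inz <- cg$z >= g$z[1] & cg$z <= g$z[2]
  box <- function(ix) outer(outer(ix, iny, "&"), inz, "&")
  roi_pair(roi_mask(box(inx_l), side = "left", label = "broca_left"),
           roi_mask(box(inx_r), side = "right", label = "broca_right"))
}

#' @rdname make_roi_pair
#' @export
make_hemisphere_masks <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cg <- voxel_center_grid(spec$grid_shape, spec$affine)
  full_y <- rep(TRUE, spec$grid_shape[2])
  full_z <- rep(TRUE, spec$grid_shape[3])
  box <- function(ix) outer(outer(ix, full_y, "&"), full_z, "&")
  roi_pair(roi_mask(box(cg$x < 0), side = "left", label = "hemi_left"),
           roi_mask(box(cg$x > 0), side = "right", label = "hemi_right"))
}

# separable Gaussian blob evaluated on the full grid
blob_field <- function(grid_shape, affine, center_mm, sigma_mm, amplitude) {
  cg <- voxel_center_grid(grid_shape, affine)
  ex <- exp(-(cg$x - center_mm[1])^2 / (2 * sigma_mm^2))
  ey <- exp(-(cg$y - center_mm[2])^2 / (2 * sigma_mm^2))
  ez <- exp(-(cg$z - center_mm[3])^2 / (2 * sigma_mm^2))
  amplitude * outer(outer(ex, ey), ez)
}

# blob values at a fixed set of voxel centers (n x 3 mm matrix)
blob_at <- function(pts, center_mm, sigma_mm, amplitude) {
  d2 <- (pts[, 1] - center_mm[1])^2 + (pts[, 2] - center_mm[2])^2 +
        (pts[, 3] - center_mm[3])^2
  amplitude * exp(-d2 / (2 * sigma_mm^2))
}

extent_multiplier <- function(spec, li) {
  spec$extent_base * (1 + spec$extent_kappa * (1 - abs(li) / 100))
}

# Solve the non-dominant blob amplitude so that the EXPECTED
# suprathreshold count ratio under the cohort's noise level realizes the planted
# LI.  For a noiseless spec the expectation degenerates to indicator
# counts on the noiseless blob map.  With noise, the expected adaptive
# threshold is estimated once by Monte Carlo (the dominant blob sets it)
# and expected counts are the Gaussian exceedance probabilities summed
# over ROI voxels, a smooth function of the amplitude, so bisection
# converges without lattice quantization.  Planted |LI| beyond the
# noise-limited maximum (the expected count on the silent side never
# reaches zero) saturates at the boundary; residuals beyond `tol`
# off the boundary, or 10 LI units at it, raise an error rather than
# silently clipping.
solve_amplitudes <- function(spec, li, sigma_mm, centers, rois,
                             diffuse = NULL, tol = 2.5) {
  a_dom <- spec$blob_amplitude
  dom_left <- li >= 0
  pts_l <- which(rois$left$data, arr.ind = TRUE) - 1
  pts_r <- which(rois$right$data, arr.ind = TRUE) - 1
  mm_l <- voxel_to_mm(pts_l, spec$affine, dim = spec$grid_shape)
  mm_r <- voxel_to_mm(pts_r, spec$affine, dim = spec$grid_shape)
  c_l <- centers$left; c_r <- centers$right
  k <- max(1L, ceiling(0.05 * nrow(mm_l)))
  top_mean <- function(v) mean(sort(v, decreasing = TRUE)[seq_len(k)])

  # sub-threshold baseline contributed inside the ROIs by the diffuse
  # component; part of the signal model the amplitudes must compensate
  base_l <- 0; base_r <- 0
  if (!is.null(diffuse)) {
    base_l <- blob_at(mm_l, diffuse$center, diffuse$sigma, diffuse$amplitude)
    base_r <- blob_at(mm_r, diffuse$center, diffuse$sigma, diffuse$amplitude)
  }

  side_values <- function(a_other) {
    a_l <- if (dom_left) a_dom else a_other
    a_r <- if (dom_left) a_other else a_dom
    list(l = base_l + blob_at(mm_l, c_l, sigma_mm, a_l) +
           blob_at(mm_l, c_r, sigma_mm, a_r),
         r = base_r + blob_at(mm_r, c_l, sigma_mm, a_l) +
           blob_at(mm_r, c_r, sigma_mm, a_r))
  }

  noiseless <- spec$noise_sd == 0
  if (noiseless) {
    thr_of <- function(v) 0.5 * max(top_mean(v$l), top_mean(v$r))
    counts <- function(v, thr) c(sum(v$l > thr), sum(v$r > thr))
  } else {
    # expected adaptive threshold under noise, estimated once; it is set
    # by the dominant side and depends only weakly on the other blob
    v0 <- side_values(a_dom * (1 - abs(li) / 100))
    reps <- vapply(seq_len(40), function(i) {
      eps_l <- stats::rnorm(length(v0$l), sd = spec$noise_sd)
      eps_r <- stats::rnorm(length(v0$r), sd = spec$noise_sd)
      max(top_mean(v0$l + eps_l), top_mean(v0$r + eps_r))
    }, 0)
    thr_star <- 0.5 * mean(reps)
    thr_of <- function(v) thr_star
    counts <- function(v, thr)
      c(sum(stats::pnorm((v$l - thr) / spec$noise_sd)),
        sum(stats::pnorm((v$r - thr) / spec$noise_sd)))
  }
  eval_li <- function(a_other) {
    v <- side_values(a_other)
    n <- counts(v, thr_of(v))
    if (sum(n) <= 0) return(c(NA_real_, 0))
    c(100 * (n[1] - n[2]) / (n[1] + n[2]), n[1] + n[2])
  }

  at_boundary <- FALSE
  if (abs(li) >= 100 - 1e-9) {
    a_other <- 0; at_boundary <- TRUE
  } else if (abs(li) < 1e-9 && is.null(diffuse)) {
    # exactly symmetric blob pair; only valid without a diffuse baseline
    a_other <- a_dom
  } else if (!is.na(eval_li(0)[1]) && abs(eval_li(0)[1]) <= abs(li)) {
    # requested LI is more extreme than a silent non-dominant side yields
    a_other <- 0; at_boundary <- TRUE
  } else {
    # the diffuse baseline favors the dominant side, so the balancing
    # amplitude may exceed the dominant one; leave headroom
    lo <- 0; hi <- 2 * a_dom
    for (it in 1:48) {
      mid <- (lo + hi) / 2
      got <- eval_li(mid)[1]
      # achieved LI moves monotonically toward the non-dominant side as
      # that side's amplitude grows
      overshoot_low <- if (dom_left) got > li else got < li
      if (is.na(got) || overshoot_low) lo <- mid else hi <- mid
    }
    if (noiseless) {
      cand <- seq(lo, hi, length.out = 9)
      errs <- vapply(cand, function(a) abs(eval_li(a)[1] - li), 0)
      a_other <- cand[which.min(errs)]
    } else a_other <- (lo + hi) / 2
  }
  res <- eval_li(a_other)
  achieved <- res[1]
  tol_eff <- if (at_boundary) max(tol, 10)
             else if (noiseless && res[2] > 0) max(tol, 250 / res[2])
             else tol
  if (is.na(achieved) || abs(achieved - li) > tol_eff)
    stop(sprintf(
      "planted LI %.1f is not realizable with these amplitudes (closest %.1f)",
      li, if (is.na(achieved)) NA_real_ else achieved))
  list(a_left = if (dom_left) a_dom else a_other,
       a_right = if (dom_left) a_other else a_dom,
       achieved_li = achieved)
}

#' Simulate a single synthetic Z map
#'
#' Builds one subject's map: paired Gaussian blobs in the left/right toy
#' ROIs whose amplitudes are solved (by bisection on the noiseless map)
#' so the adaptive-threshold pipeline recovers the planted LI, a broad
#' diffuse component in the dominant hemisphere scaled by the
#' extent-bilaterality coupling, and white Gaussian noise.  The same
#' spec, LI and seed always produce a bit-identical map.
#'
#' @param spec A [cohort_spec].
#' @param planted_li Target laterality index in `[-100, 100]`.
#' @param group `"typical"`, `"bilateral"` or `"right"`; controls the
#'   (group-specific) blob location.  Defaults to the class of
#'   `planted_li` under the +/-33 rule.
#' @param seed Integer RNG seed for this map's noise.
#' @return A [stat_map] with attribute `"truth"` (planted parameters).
#' @export
simulate_zmap <- function(spec, planted_li, group = NULL, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.finite(planted_li) || abs(planted_li) > 100)
    stop("'planted_li' must lie in [-100, 100]")
  if (is.null(group)) {
    group <- switch(classify_laterality(planted_li),
                    left_typical = "typical", bilateral = "bilateral",
                    right_atypical = "right")
  }
  group <- match.arg(group, c("typical", "bilateral", "right"))
  geom <- cohort_geometry()
  ctr <- if (group == "typical") geom$blob_center$typical
         else geom$blob_center$atypical
  # sub-voxel anatomical jitter: breaks degenerate lattice shells so the
  # achievable LI grid is fine; the right blob mirrors the jittered
  # center, keeping each subject's blob pair symmetric
  set.seed(as.integer(seed))
  ctr <- ctr + stats::runif(3, -1, 1)
  centers <- list(left = ctr, right = ctr * c(-1, 1, 1))
  sigma_jit <- exp(stats::rnorm(1, 0, spec$diffuse_sigma_jitter))
  mult <- extent_multiplier(spec, planted_li)
  sc <- mult^(1 / 3)
  sigma_b <- spec$blob_sigma_mm * sc
  rois <- make_roi_pair(spec)
  diffuse <- NULL
  if (spec$diffuse_amplitude > 0) {
    dc <- geom$diffuse_center
    if (planted_li < 0) dc <- dc * c(-1, 1, 1)
    diffuse <- list(center = dc,
                    sigma = spec$diffuse_sigma_mm * sc * sigma_jit,
                    amplitude = spec$diffuse_amplitude)
  }
  amp <- solve_amplitudes(spec, planted_li, sigma_b, centers, rois,
                          diffuse = diffuse)

  dat <- blob_field(spec$grid_shape, spec$affine, centers$left,
                    sigma_b, amp$a_left) +
         blob_field(spec$grid_shape, spec$affine, centers$right,
                    sigma_b, amp$a_right)
  if (!is.null(diffuse))
    dat <- dat + blob_field(spec$grid_shape, spec$affine, diffuse$center,
                            diffuse$sigma, diffuse$amplitude)
  if (spec$noise_sd > 0) {
    dat <- dat + array(stats::rnorm(prod(spec$grid_shape),
                                    sd = spec$noise_sd),
                       dim = spec$grid_shape)
  }
  out <- stat_map(dat, spec$affine, map_kind = "zstat")
  attr(out, "truth") <- list(planted_li = planted_li,
                             achieved_noiseless_li = amp$achieved_li,
                             group = group, a_left = amp$a_left,
                             a_right = amp$a_right,
                             blob_sigma_mm = sigma_b,
                             diffuse_sigma_jitter = sigma_jit,
                             extent_multiplier = mult, seed = seed)
  out
}

#' Simulate a full synthetic cohort
#'
#' Draws each subject's laterality class from `spec$proportions`, a
#' planted LI from the class sampler, and metadata (Edinburgh handedness
#' score, sex, age) with left/ambidextrous handedness enriched in the
#' atypical classes, then generates one Z map per subject with
#' [simulate_zmap()].  A truth table records every planted quantity; no
#' analysis stage reads it.
#'
#' @param spec A [cohort_spec].
#' @return A list of class `cohort`: `maps` (list of [stat_map]),
#'   `meta` (data frame: subject_id, ehi_score, handedness, sex, age),
#'   `truth` (data frame of planted values), `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  cls <- sample(names(spec$proportions), n, replace = TRUE,
                prob = spec$proportions)
  lis <- numeric(n)
  for (g in unique(cls)) {
    idx <- which(cls == g)
    lis[idx] <- spec$li_samplers[[g]](length(idx))
  }
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)

  # handedness composition differs by laterality class: atypical classes
  # are enriched in left-handers and ambidextrous subjects
  hand_prob <- list(typical = c(right = 0.55, left = 0.30, ambidextrous = 0.15),
                    bilateral = c(right = 0.10, left = 0.55, ambidextrous = 0.35),
                    right = c(right = 0.10, left = 0.60, ambidextrous = 0.30))
  hand <- vapply(cls, function(g)
    sample(names(hand_prob[[g]]), 1, prob = hand_prob[[g]]), "")
  ehi <- vapply(hand, function(h) switch(h,
    right = stats::runif(1, 40, 100),
    left = stats::runif(1, -100, -40),
    ambidextrous = stats::runif(1, -39, 39)), 0)
  meta <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    ehi_score = round(ehi, 1),
    handedness = unname(hand),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = round(rtrunc_norm(n, 22.5, 3.4, 19, 39)),
    stringsAsFactors = FALSE)

  maps <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    grp <- if (cls[i] == "typical") "typical"
           else if (cls[i] == "bilateral") "bilateral" else "right"
    m <- simulate_zmap(spec, lis[i], group = grp, seed = sub_seeds[i])
    m$subject_id <- meta$subject_id[i]
    tr <- attr(m, "truth")
    truth[[i]] <- data.frame(subject_id = meta$subject_id[i],
                             class = cls[i], planted_li = lis[i],
                             achieved_noiseless_li = tr$achieved_noiseless_li,
                             extent_multiplier = tr$extent_multiplier,
                             a_left = tr$a_left, a_right = tr$a_right,
                             seed = sub_seeds[i],
                             stringsAsFactors = FALSE)
    maps[[i]] <- m
  }
  structure(list(maps = maps, meta = meta,
                 truth = do.call(rbind, truth), spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects on %s grid (%g mm)\n",
              length(x$maps), paste(x$spec$grid_shape, collapse = "x"),
              x$spec$voxel_mm))
  print(table(x$truth$class))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one NIfTI per subject plus `meta.tsv` and `truth.tsv`.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in cohort$maps)
    write_volume(m, file.path(dir, paste0(m$subject_id, "_zstat.nii.gz")))
  utils::write.table(cohort$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
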