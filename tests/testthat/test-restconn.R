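test_that("the hard DFT band-pass keeps the passband and kills the rest", {
  tr <- 2; t_len <- 180
  tt <- (seq_len(t_len) - 1) * tr
  pass <- sin(2 * pi * 0.05 * tt)
  stopb <- sin(2 * pi * 0.2 * tt)
  fp <- bandpass(pass, tr)
  fs <- bandpass(stopb, tr)
  expect_gte(var(fp) / var(pass), 0.99)
  expect_lte(var(fs) / var(stopb), 0.01)

  const <- rep(3.2, t_len)
  expect_equal(bandpass(const, tr), rep(0, t_len), tolerance = 1e-12)
  expect_lt(abs(mean(bandpass(rnorm(t_len), tr))), 1e-10)

  expect_error(bandpass(pass, tr, f_hi = 0.3), "Nyquist")
  expect_error(bandpass(pass, tr, f_lo = 0.2, f_hi = 0.1), "below")
  expect_error(bandpass(rnorm(10), tr), "20 time points")
})

test_that("band-pass matches independent DFT bin arithmetic", {
  tr <- 2; t_len <- 64
  set.seed(17)
  x <- rnorm(t_len)
  got <- bandpass(x, tr)
  # oracle: explicit projection onto the retained Fourier bins
  freqs <- (seq_len(t_len) - 1)
  freqs <- pmin(freqs, t_len - freqs) / (t_len * tr)
  keep <- freqs > 0.01 & freqs < 0.1
  base <- exp(2i * pi * outer(seq_len(t_len) - 1,
                              seq_len(t_len) - 1) / t_len)
  coef <- Conj(t(base)) %*% x / t_len
  oracle <- Re(base[, keep, drop = FALSE] %*% coef[keep])
  expect_equal(got, as.vector(oracle), tolerance = 1e-10)
})

test_that("motion expansion produces the 24 standard waveforms", {
  mot0 <- matrix(0, 30, 6)
  expect_true(all(expand_motion_regressors(mot0) == 0))
  set.seed(18)
  mot <- matrix(rnorm(30 * 6), 30, 6)
  ex <- expand_motion_regressors(mot)
  expect_equal(ncol(ex), 24)
  m1 <- c(1, 2); motx <- cbind(m1, matrix(0, 2, 5))
  ex2 <- expand_motion_regressors(motx)
  expect_equal(unname(ex2[, 1]), c(1, 2))
  expect_equal(unname(ex2[, 2]), c(1, 4))
  expect_equal(unname(ex2[, 3]), c(0, 1))
  expect_equal(unname(ex2[, 4]), c(0, 1))
  expect_error(expand_motion_regressors(mot[, 1:5]), "6 columns")
})

test_that("backward differences telescope back to the input", {
  expect_equal(backward_difference(rep(4, 10)), rep(0, 10))
  expect_equal(backward_difference(c(1, 3, 6)), c(0, 2, 3))
  set.seed(19)
  x <- rnorm(40)
  expect_equal(cumsum(backward_difference(x)) + x[1], x)
})

test_that("nuisance regression leaves residuals orthogonal to the design", {
  spec <- resting_spec(t_len = 80L)
  run <- simulate_resting(spec, "typical", seed = 21)
  des <- build_nuisance_design(run)
  expect_equal(ncol(des$matrix), 28)
  expect_equal(des$names[25:28],
               c("csf", "csf_backdiff", "wm", "wm_backdiff"))
  res <- nuisance_regress(run, des)
  d <- dim(res$data)
  mat <- t(matrix(res$data, prod(d[1:3]), d[4]))
  cc <- suppressWarnings(cor(des$matrix, mat))
  expect_lt(max(abs(cc), na.rm = TRUE), 1e-8)

  # a voxel equal to a design column is annihilated
  run2 <- run
  run2$data[1, 1, 1, ] <- des$matrix[, "csf"]
  res2 <- nuisance_regress(run2, des)
  expect_lt(max(abs(res2$data[1, 1, 1, ])), 1e-9)
})

test_that("zero columns are dropped and collinearity is reported by name", {
  spec <- resting_spec(t_len = 60L)
  run <- simulate_resting(spec, "typical", seed = 22)
  zero_design <- matrix(0, 60, 3,
                        dimnames = list(NULL, c("a", "b", "c")))
  expect_message(res <- nuisance_regress(run, zero_design), "all-zero")
  d <- dim(run$data)
  mat <- t(matrix(run$data, prod(d[1:3]), d[4]))
  demeaned <- sweep(mat, 2, colMeans(mat))
  expect_equal(as.vector(res$data),
               as.vector(array(t(demeaned), dim = d)), tolerance = 1e-10)

  x <- cbind(a = rnorm(60), b = rnorm(60))
  bad <- cbind(x, dup = x[, "a"] * 2)
  expect_error(nuisance_regress(run, bad), "dup")
})

test_that("seed extraction averages voxel centers inside the sphere", {
  # brute-force lattice oracle: 5 mm sphere on a 2 mm grid = 81 voxels
  offs <- expand.grid(i = -3:3, j = -3:3, k = -3:3)
  n_expected <- sum(4 * (offs$i^2 + offs$j^2 + offs$k^2) <= 25)
  expect_equal(n_expected, 81)

  gs <- c(12L, 12L, 12L)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -11
  dat <- array(rnorm(prod(gs) * 25), dim = c(gs, 25))
  masks <- list(gray = array(TRUE, gs), white = array(FALSE, gs),
                csf = array(FALSE, gs),
                hemispheres = mirror_rois(gs))
  run <- resting_run(dat, aff, 2, matrix(0, 25, 6), masks)
  ctr <- c(-1, -1, -1)   # a voxel center
  s <- extract_seed(run, seed_spec(ctr, radius_mm = 5))
  cg <- list(x = aff[1, 1] * (0:11) - 11, y = aff[2, 2] * (0:11) - 11,
             z = aff[3, 3] * (0:11) - 11)
  inside <- outer(outer((cg$x - ctr[1])^2, (cg$y - ctr[2])^2, "+"),
                  (cg$z - ctr[3])^2, "+") <= 25
  expect_equal(sum(inside), 81)
  oracle <- apply(dat, 4, function(v) mean(v[inside]))
  expect_equal(s, oracle, tolerance = 1e-12)

  tiny <- extract_seed(run, seed_spec(ctr, radius_mm = 0.5))
  vox <- round(mm_to_voxel(ctr, aff)) + 1
  expect_equal(tiny, dat[vox[1], vox[2], vox[3], ], tolerance = 1e-12)

  const <- run; const$data[] <- 7
  expect_equal(extract_seed(const, seed_spec(ctr, radius_mm = 5)),
               rep(7, 25))
  expect_error(extract_seed(run, seed_spec(c(500, 0, 0), radius_mm = 1)),
               "no voxel centers")
})

test_that("hemispheric global signals mirror when hemispheres swap", {
  spec <- resting_spec(t_len = 60L)
  run <- simulate_resting(spec, "typical", seed = 23)
  gs <- hemispheric_global_signal(run)

  const <- run; const$data[] <- 2.5
  gc <- hemispheric_global_signal(const)
  expect_equal(gc$left, rep(2.5, 60))
  expect_equal(gc$right, rep(2.5, 60))

  doubled <- run
  lm3 <- run$masks$hemispheres$left$data
  rm3 <- run$masks$hemispheres$right$data
  base <- array(rnorm(prod(dim(run$data)[1:3])), dim(run$data)[1:3])
  for (tt in seq_len(60)) {
    vol <- base
    vol[rm3] <- vol[rm3] / 2
    doubled$data[, , , tt] <- vol * (tt / 10)
  }
  gd <- hemispheric_global_signal(doubled)
  lmean <- mean(base[lm3]); rmean <- mean(base[rm3]) / 2
  expect_equal(gd$left / lmean, gd$right / rmean, tolerance = 1e-10)

  swapped <- run
  swapped$masks$hemispheres <- roi_pair(
    roi_mask(rm3, side = "left", label = "L"),
    roi_mask(lm3, side = "right", label = "R"))
  gsw <- hemispheric_global_signal(swapped)
  expect_equal(gsw$left, gs$right)
  expect_equal(gsw$right, gs$left)
})

test_that("connectivity results are exact and antisymmetric in contrasts", {
  spec <- resting_spec(t_len = 100L)
  run <- simulate_resting(spec, "typical", seed = 24)
  pre <- preprocess_resting(run)
  res <- seed_connectivity(pre, spec$seeds)
  expect_equal(res$contrast_lr, -res$contrast_rl)
  expect_named(res$beta, c("seed_left", "seed_right", "global_left",
                           "global_right"))

  # swapping the hemisphere masks swaps the global predictors and
  # negates the L-R contrast exactly
  pre_sw <- pre
  hemi <- pre$masks$hemispheres
  pre_sw$masks$hemispheres <- roi_pair(
    roi_mask(hemi$right$data, side = "left", label = "L"),
    roi_mask(hemi$left$data, side = "right", label = "R"))
  res_sw <- seed_connectivity(pre_sw, spec$seeds)
  expect_equal(res_sw$contrast_lr, res$contrast_rl, tolerance = 1e-10)

  dup <- seed_spec(c(-22, 2, 2), name = "dup")
  expect_error(seed_connectivity(pre, c(spec$seeds, list(dup))),
               "collinear")
})

test_that("planted seed couplings are recovered within tolerance", {
  spec <- resting_spec()
  est <- vapply(1:20, function(s) {
    run <- simulate_resting(spec, "typical", seed = 100 + s)
    pre <- preprocess_resting(run)
    res <- seed_connectivity(pre, spec$seeds)
    vox <- round(mm_to_voxel(spec$seeds[[1]]$target_mm, run$affine)) + 1
    res$beta$seed_left[vox[1], vox[2], vox[3]]
  }, 0)
  expect_lt(abs(mean(est) - 0.8), 0.05)
})

test_that("group contrasts vanish for identical groups and localize the planted asymmetry", {
  spec <- resting_spec(t_len = 150L)
  fit <- function(flag, s)
    seed_connectivity(preprocess_resting(
      simulate_resting(spec, flag, seed = s)), spec$seeds)
  ra <- lapply(1:4, function(s) fit("typical", s))
  rb <- lapply(5:8, function(s) fit("atypical", s))

  same <- group_connectivity_contrast(ra, ra, "contrast_lr")
  expect_true(all(same$data == 0))

  t_ab <- group_connectivity_contrast(ra, rb, "contrast_lr")
  t_ba <- group_connectivity_contrast(rb, ra, "contrast_lr")
  expect_equal(t_ab$data, -t_ba$data, tolerance = 1e-10)

  # the strongest gray-matter |t| voxel sits near a planted crossover
  # patch
  gray <- simulate_resting(spec, "typical", seed = 1)$masks$gray
  tg <- abs(t_ab$data); tg[!gray] <- 0
  peak_abs <- which.max(tg)
  vox <- arrayInd(peak_abs, dim(t_ab$data))[1, ] - 1
  mm <- voxel_to_mm(vox, t_ab$affine)
  d_typ <- sqrt(sum((mm - c(18, 10, 6))^2))
  d_aty <- sqrt(sum((mm - c(-18, 10, 6))^2))
  expect_lte(min(d_typ, d_aty), 12)
})
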