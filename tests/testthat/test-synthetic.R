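test_that("toy ROI pair and hemisphere masks have the planted geometry", {
  spec <- cohort_spec()
  rois <- make_roi_pair(spec)
  expect_identical(flip_x(rois$left)$data, rois$right$data)
  expect_false(any(rois$left$data & rois$right$data))
  expect_equal(sum(rois$left$data), sum(rois$right$data))

  hemis <- make_hemisphere_masks(spec)
  # hemisphere masks partition every voxel (no center sits at x = 0)
  expect_true(all(xor(hemis$left$data, hemis$right$data)))
  expect_identical(flip_x(hemis$left)$data, hemis$right$data)

  expect_error(cohort_spec(grid_shape = c(63, 64, 35)), "even")
})

test_that("noiseless planted maps recover their LI exactly at the endpoints", {
  spec <- cohort_spec(noise_sd = 0, diffuse_amplitude = 0)
  rois <- make_roi_pair(spec)
  left_only <- simulate_zmap(spec, 100, seed = 1)
  r <- measure_laterality(left_only, rois)
  expect_equal(r$li, 100)
  expect_equal(r$n_right, 0L)

  right_only <- simulate_zmap(spec, -100, seed = 1)
  expect_equal(measure_laterality(right_only, rois)$li, -100)

  balanced <- simulate_zmap(spec, 0, seed = 2, group = "bilateral")
  expect_equal(measure_laterality(balanced, rois)$li, 0)
})

test_that("map simulation is bit-reproducible and seed-sensitive", {
  spec <- cohort_spec()
  a <- simulate_zmap(spec, 60, seed = 11)
  b <- simulate_zmap(spec, 60, seed = 11)
  expect_identical(a$data, b$data)
  c <- simulate_zmap(spec, 60, seed = 12)
  expect_false(identical(a$data, c$data))
})

test_that("unrealizable planted LIs are refused, not clipped", {
  # tiny blobs against heavy noise cannot put the expected count ratio
  # anywhere near a strongly lateralized value
  spec <- cohort_spec(blob_amplitude = 1.5, noise_sd = 3,
                      diffuse_amplitude = 0)
  expect_error(simulate_zmap(spec, 95, seed = 1), "not realizable")
})

test_that("cohorts carry truth tables and honor class proportions", {
  spec <- small_cohort_spec(seed = 5)
  co <- simulate_cohort(spec)
  expect_length(co$maps, 63)
  expect_equal(nrow(co$truth), 63)
  expect_equal(nrow(co$meta), 63)
  expect_identical(co$truth$subject_id, co$meta$subject_id)

  counts <- table(factor(co$truth$class,
                         c("typical", "bilateral", "right")))
  # multinomial draw around (52.3, 5.7, 5.0)
  expect_lt(max(abs(counts - 63 * c(0.83, 0.09, 0.08))), 3 * 3)
  expect_true(all(abs(co$truth$planted_li) <= 100))
  # planted LIs respect their class bands
  expect_true(all(co$truth$planted_li[co$truth$class == "typical"] > 33))
  expect_true(all(abs(co$truth$planted_li[co$truth$class == "bilateral"]) <= 33))
  expect_true(all(co$truth$planted_li[co$truth$class == "right"] < -33))

  co2 <- simulate_cohort(spec)
  expect_identical(co2$truth, co$truth)
  expect_identical(co2$maps[[10]]$data, co$maps[[10]]$data)
})

test_that("extent multiplier couples to bilaterality only through kappa", {
  spec <- cohort_spec(extent_kappa = 1.5)
  expect_equal(lateralize:::extent_multiplier(spec, 100), 1)
  expect_equal(lateralize:::extent_multiplier(spec, 0), 2.5)
  expect_equal(lateralize:::extent_multiplier(spec, -100), 1)
  spec0 <- cohort_spec(extent_kappa = 0)
  lis <- seq(-100, 100, by = 25)
  expect_true(all(vapply(lis, function(l)
    lateralize:::extent_multiplier(spec0, l), 0) == 1))
})

test_that("cohorts can be written to disk as NIfTI + TSV", {
  spec <- cohort_spec(n_subjects = 2, grid_shape = c(16, 16, 8),
                      voxel_mm = 8, diffuse_amplitude = 0, seed = 2)
  co <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  m <- read_volume(file.path(dir, paste0(co$meta$subject_id[1],
                                         "_zstat.nii.gz")))
  expect_equal(m$data, co$maps[[1]]$data, tolerance = 1e-12)
  expect_equal(m$affine, spec$affine, tolerance = 1e-6)
})

test_that("resting runs are reproducible with planted structure", {
  spec <- resting_spec(t_len = 60L)
  r1 <- simulate_resting(spec, "typical", seed = 4)
  r2 <- simulate_resting(spec, "typical", seed = 4)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$motion, r2$motion)
  expect_equal(dim(r1$data)[4], 60L)
  tr <- attr(r1, "truth")
  expect_equal(unname(tr$global_amp), c(1, 0.5))
  ra <- simulate_resting(spec, "atypical", seed = 4)
  expect_equal(unname(attr(ra, "truth")$global_amp), c(0.5, 1))
})

test_that("a noiseless single-seed run yields exact regression recovery", {
  sd1 <- seed_spec(c(-22, 2, 2), name = "s1",
                   target_mm = c(-22, -26, 2), beta = 0.8,
                   target_sigma_mm = 4)
  spec <- resting_spec(seeds = list(sd1), noise_sd = 0, motion_amp = 0,
                       tissue_amp = 0, global_amp = c(0, 0),
                       crossover_amp = 0)
  run <- simulate_resting(spec, "typical", seed = 9)
  preds <- list(s1 = extract_seed(run, sd1))
  res <- seed_connectivity(run, list(sd1), predictors = preds)
  vox <- round(mm_to_voxel(sd1$target_mm, run$affine)) + 1
  expect_equal(res$beta$s1[vox[1], vox[2], vox[3]], 0.8,
               tolerance = 1e-8)
})

test_that("without a global component hemispheric means are noise averages", {
  spec <- resting_spec(seeds = list(), global_amp = c(0, 0),
                       crossover_amp = 0, motion_amp = 0, tissue_amp = 0,
                       noise_sd = 1, t_len = 150L)
  vars <- unlist(lapply(1:6, function(s) {
    run <- simulate_resting(spec, "typical", seed = s)
    gs <- hemispheric_global_signal(run)
    c(var(gs$left), var(gs$right))
  }))
  n_vox <- sum(simulate_resting(spec, "typical", seed = 1)
               $masks$hemispheres$left$data)
  expect_equal(mean(vars), 1 / n_vox, tolerance = 0.2)
})

test_that("motion parameter files round-trip in FSL layout", {
  set.seed(8)
  mot <- matrix(rnorm(120 * 6, sd = 0.05), 120, 6)
  f <- withr::local_tempfile(fileext = ".par")
  write_motion_params(mot, f)
  back <- read_motion_params(f)
  expect_equal(back, mot, tolerance = 1e-8)
})
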