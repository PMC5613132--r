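# small in-code fixtures shared across test files

tiny_map <- function(data, affine = diag(4), ...) {
  stat_map(data, affine, ...)
}

# 8x8x4 grid with a 40-voxel left ROI whose two largest values are 10
# and 8 (rest 1), and a mirrored right ROI of constant 1 -- the
# hand-checkable adaptive-threshold example
toy_threshold_fixture <- function() {
  dat <- array(0, dim = c(8, 8, 4))
  left <- array(FALSE, dim = c(8, 8, 4))
  left[1:2, 1:5, 1:4] <- TRUE   # 40 voxels
  right <- array(FALSE, dim = c(8, 8, 4))
  right[7:8, 1:5, 1:4] <- TRUE
  dat[left] <- 1
  dat[1, 1, 1] <- 10
  dat[2, 1, 1] <- 8
  dat[right] <- 1
  list(map = tiny_map(dat),
       rois = roi_pair(roi_mask(left, side = "left", label = "L"),
                       roi_mask(right, side = "right", label = "R")))
}

# mirror-symmetric ROI pair on an even-x grid, for antisymmetry checks
mirror_rois <- function(dims = c(10, 8, 6)) {
  stopifnot(dims[1] %% 2 == 0)
  left <- array(FALSE, dim = dims)
  left[2:4, 3:6, 2:5] <- TRUE
  right <- array(FALSE, dim = dims)
  right[dims[1] + 1 - (2:4), 3:6, 2:5] <- TRUE
  roi_pair(roi_mask(left, side = "left", label = "L"),
           roi_mask(right, side = "right", label = "R"))
}

# memoised expensive cohorts so several test files can share them
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_cohort_fixture <- function() {
  cached("default_cohort", {
    spec <- cohort_spec(seed = 20260901L)
    cohort <- simulate_cohort(spec)
    rois <- make_roi_pair(spec)
    hemis <- make_hemisphere_masks(spec)
    tab <- cohort_laterality(cohort$maps, rois, meta = cohort$meta)
    list(spec = spec, cohort = cohort, rois = rois, hemis = hemis,
         tab = tab)
  })
}

# reduced-resolution cohort spec used for replicated runs
small_cohort_spec <- function(seed, ...) {
  cohort_spec(seed = seed, grid_shape = c(44L, 44L, 24L), voxel_mm = 3,
              ...)
}
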