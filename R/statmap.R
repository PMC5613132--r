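#' Volumetric statistical map
#'
#' A `stat_map` bundles a 3-D (or, for resting-state runs, 4-D) array of
#' voxel values with the 4x4 affine that maps 0-based voxel indices to
#' world (RAS, mm) coordinates.  By convention the left hemisphere lies at
#' world x < 0, matching how MNI coordinates are reported.
#'
#' @param data Numeric array, 3-D or 4-D.  All values must be finite.
#' @param affine 4x4 numeric matrix, invertible, last row `(0,0,0,1)`.
#' @param subject_id Optional subject identifier.
#' @param map_kind One of `"zstat"`, `"beta"`, `"contrast"`.
#'
#' @return An object of class `stat_map` with elements `data`, `affine`,
#'   `subject_id`, `map_kind`.
#' @export
stat_map <- function(data, affine = diag(4), subject_id = NA_character_,
                     map_kind = c("zstat", "beta", "contrast")) {
  map_kind <- match.arg(map_kind)
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("'data' must be a 3-D or 4-D array")
  if (any(dim(data) <= 0L)) stop("grid dimensions must be positive")
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop(sprintf("map contains %d non-finite voxel(s)", n_bad))
  affine <- check_affine(affine)
  structure(list(data = data, affine = affine, subject_id = subject_id,
                 map_kind = map_kind),
            class = "stat_map")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be a 4x4 matrix")
  if (!all(is.finite(affine))) stop("'affine' must be finite")
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("'affine' must be invertible")
  affine
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<stat_map> %s [%s] %s\n",
              paste(d, collapse = "x"), x$map_kind,
              if (is.na(x$subject_id)) "" else x$subject_id))
  cat(sprintf("  values in [%.3g, %.3g]; voxel size %s mm\n",
              min(x$data), max(x$data),
              paste(signif(voxel_sizes(x$affine), 3), collapse = "x")))
  invisible(x)
}

#' @rdname stat_map
#' @param x Object to test.
#' @export
is_stat_map <- function(x) inherits(x, "stat_map")

voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Binary region-of-interest mask
#'
#' @param data Logical 3-D array on the same grid as the maps it will be
#'   applied to.  Must contain at least one `TRUE` voxel.
#' @param side `"left"`, `"right"` or `"none"`.
#' @param label Free-text label.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, side = c("none", "left", "right"), label = "roi") {
  side <- match.arg(side)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  data <- array(as.logical(data), dim = dim(data))
  if (anyNA(data)) stop("mask contains NA")
  if (!any(data)) stop("mask is empty")
  structure(list(data = data, side = side, label = label),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s' (%s): %d voxels on %s grid\n",
              x$label, x$side, sum(x$data),
              paste(dim(x$data), collapse = "x")))
  invisible(x)
}

#' Paired left/right masks
#'
#' A disjoint pair of left and right ROI masks on a common grid, e.g. the
#' left and right Broca's-area (BA 44/45) masks used for laterality
#' measurement, or whole-hemisphere masks.
#'
#' @param left,right `roi_mask` objects with sides `"left"`/`"right"`.
#' @return An object of class `roi_pair`.
#' @export
roi_pair <- function(left, right) {
  stopifnot(inherits(left, "roi_mask"), inherits(right, "roi_mask"))
  if (left$side != "left" || right$side != "right")
    stop("'left' and 'right' must have matching sides")
  if (!identical(dim(left$data), dim(right$data)))
    stop("mask grids differ")
  if (any(left$data & right$data))
    stop("left and right masks overlap")
  structure(list(left = left, right = right), class = "roi_pair")
}

check_same_grid <- function(a, b) {
  da <- dim(if (is_stat_map(a)) a$data else a$data)
  db <- dim(if (is_stat_map(b)) b$data else b$data)
  if (!identical(da[1:3], db[1:3]))
    stop(sprintf("grid mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}

#' Read / write NIfTI-1 volumes
#'
#' `read_volume()` reads a `.nii`/`.nii.gz` file into a [stat_map];
#' `write_volume()` writes one back.  The round trip preserves voxel data
#' bit-exactly and the affine to floating-point precision.  Files
#' containing non-finite voxels are rejected with a count of the offending
#' voxels.
#'
#' @param path File path.
#' @param subject_id,map_kind Passed to [stat_map()].
#' @return `read_volume()` returns a [stat_map]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, subject_id = NA_character_,
                        map_kind = "zstat") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))
  nd <- length(dim(dat))
  if (!nd %in% c(3L, 4L))
    stop(sprintf("expected a 3-D or 4-D image, got %d-D", nd))
  n_bad <- sum(!is.finite(dat))
  if (n_bad > 0L)
    stop(sprintf("'%s' contains %d non-finite voxel(s)", path, n_bad))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  stat_map(dat, aff, subject_id = subject_id, map_kind = map_kind)
}

#' @rdname read_volume
#' @param map A [stat_map].
#' @export
write_volume <- function(map, path) {
  stopifnot(is_stat_map(map))
  img <- RNifti::asNifti(map$data)
  img <- RNifti::`sform<-`(img, structure(map$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Voxel-index / world-coordinate conversion
#'
#' Converts 0-based voxel indices `(i, j, k)` to world mm coordinates via
#' the map affine, and back.  Indices must lie inside the grid.
#'
#' @param index Integer vector `(i, j, k)` (0-based) or an n x 3 matrix.
#' @param affine 4x4 affine, or a [stat_map] whose affine is used.
#' @param dim Optional grid dimensions for the bounds check (taken from
#'   the map when `affine` is a [stat_map]).
#' @return Numeric vector `(x, y, z)` in mm, or an n x 3 matrix.
#' @export
voxel_to_mm <- function(index, affine, dim = NULL) {
  if (is_stat_map(affine)) {
    dim <- dim %||% dim(affine$data)[1:3]
    affine <- affine$affine
  }
  affine <- check_affine(affine)
  idx <- if (is.matrix(index)) index else matrix(index, nrow = 1)
  if (ncol(idx) != 3L) stop("'index' must have 3 columns")
  if (!is.null(dim)) {
    if (any(idx < 0) || any(sweep(idx, 2, dim[1:3]) >= 0))
      stop("voxel index out of bounds")
  }
  xyz <- cbind(idx, 1) %*% t(affine)
  out <- xyz[, 1:3, drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  if (is.matrix(index)) out else drop(out)
}

#' @rdname voxel_to_mm
#' @param mm World coordinates `(x, y, z)` or an n x 3 matrix.
#' @export
mm_to_voxel <- function(mm, affine) {
  if (is_stat_map(affine)) affine <- affine$affine
  affine <- check_affine(affine)
  m <- if (is.matrix(mm)) mm else matrix(mm, nrow = 1)
  ijk <- cbind(m, 1) %*% t(solve(affine))
  out <- ijk[, 1:3, drop = FALSE]
  colnames(out) <- c("i", "j", "k")
  if (is.matrix(mm)) out else drop(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mirror a map across the first (x) grid axis
#'
#' Reverses the first array axis and leaves the affine untouched.  On a
#' grid whose x = 0 plane bisects the voxel lattice (as the synthetic
#' grids here are built to do) this equals a world-space left/right
#' mirror, without any resampling.  Applying it twice is the identity.
#'
#' @param x A [stat_map] or [roi_mask].
#' @return An object of the same class with the first axis reversed.
#' @export
flip_x <- function(x) {
  if (is_stat_map(x)) {
    nd <- length(dim(x$data))
    x$data <- if (nd == 3L) x$data[rev(seq_len(dim(x$data)[1])), , , drop = FALSE]
              else x$data[rev(seq_len(dim(x$data)[1])), , , , drop = FALSE]
    x
  } else if (inherits(x, "roi_mask")) {
    x$data <- x$data[rev(seq_len(dim(x$data)[1])), , , drop = FALSE]
    x$side <- switch(x$side, left = "right", right = "left", none = "none")
    x
  } else stop("flip_x() expects a stat_map or roi_mask")
}

#' Conjunction of two maps by the minimum statistic
#'
#' Voxelwise minimum of two Z maps on the same grid: a voxel is strongly
#' positive only where both effects are present, the standard minimum-
#' statistic conjunction test.
#'
#' @param map_a,map_b [stat_map]s on the same grid.
#' @return A [stat_map] of voxelwise minima.
#' @export
conjunction_min <- function(map_a, map_b) {
  stopifnot(is_stat_map(map_a), is_stat_map(map_b))
  if (!identical(dim(map_a$data), dim(map_b$data)))
    stop("grid mismatch between conjunction inputs")
  out <- map_a
  out$data <- pmin(map_a$data, map_b$data)
  out$subject_id <- NA_character_
  out
}

#' Gaussian smoothing of a volumetric map
#'
#' Separable Gaussian convolution with sigma = FWHM / (2 sqrt(2 ln 2))
#' per axis, expressed in mm and converted to voxels via the affine.
#' Normalized convolution is used (the kernel response is divided by the
#' smoothed all-ones field), so constant maps are exactly preserved and
#' the global sum of an interior-supported blob is preserved to well
#' within 1%.
#'
#' @param map A 3-D [stat_map].
#' @param fwhm_mm Full width at half maximum, mm, > 0.
#' @return The smoothed [stat_map].
#' @export
gaussian_smooth <- function(map, fwhm_mm) {
  stopifnot(is_stat_map(map), length(dim(map$data)) == 3L)
  if (!is.numeric(fwhm_mm) || fwhm_mm <= 0) stop("'fwhm_mm' must be > 0")
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vs <- voxel_sizes(map$affine)
  sm <- map$data
  ones <- array(1, dim = dim(map$data))
  for (ax in 1:3) {
    sig_v <- sigma_mm / vs[ax]
    r <- max(1L, ceiling(4 * sig_v))
    k <- exp(-((-r:r)^2) / (2 * sig_v^2))
    k <- k / sum(k)
    sm <- convolve_axis(sm, k, ax)
    ones <- convolve_axis(ones, k, ax)
  }
  map$data <- sm / ones
  map
}

# zero-padded 1-D convolution along one axis of a 3-D array,
# implemented as a sum of shifted copies (kernel radii here are small)
convolve_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- dim(arr)[axis]
  out <- array(0, dim = dim(arr))
  for (off in -r:r) {
    w <- kernel[off + r + 1L]
    if (w == 0) next
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    dst <- seq_len(n)[keep]
    src <- src[keep]
    idx_dst <- slice_index(dim(arr), axis, dst)
    idx_src <- slice_index(dim(arr), axis, src)
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      w * arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}

slice_index <- function(dims, axis, idx) {
  out <- lapply(dims, seq_len)
  out[[axis]] <- idx
  out
}

#' Connected-component cluster labeling
#'
#' Labels the 26-connected components of the strictly suprathreshold set
#' `{Z > z_thr}`, drops components smaller than `min_extent`, and
#' relabels survivors 1..K by descending size (ties by smaller original
#' component id).  This is plumbing for cluster bookkeeping; it does not
#' attempt random-field-theory clusterwise correction.
#'
#' @param map A 3-D [stat_map].
#' @param z_thr Threshold; voxels with value strictly greater survive.
#' @param min_extent Minimum cluster size in voxels (>= 1).
#' @return An object of class `cluster_set`: `labels` (integer array, 0 =
#'   background), `sizes`, `peak_z`, `peak_voxel` (0-based, K x 3),
#'   `peak_mm` (K x 3), `z_thr`, `min_extent`.
#' @export
label_clusters <- function(map, z_thr, min_extent = 1L) {
  stopifnot(is_stat_map(map), length(dim(map$data)) == 3L)
  min_extent <- as.integer(min_extent)
  if (min_extent < 1L) stop("'min_extent' must be >= 1")
  dims <- dim(map$data)
  supra <- which(map$data > z_thr)
  labels <- array(0L, dim = dims)
  empty <- function() {
    structure(list(labels = labels, sizes = integer(0),
                   peak_z = numeric(0),
                   peak_voxel = matrix(integer(0), 0, 3),
                   peak_mm = matrix(numeric(0), 0, 3),
                   z_thr = z_thr, min_extent = min_extent),
              class = "cluster_set")
  }
  if (length(supra) == 0L) return(empty())

  coord <- arrayInd(supra, dims)
  row_of <- integer(prod(dims))
  row_of[supra] <- seq_along(supra)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coord, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
           (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    tgt <- row_of[lin]
    src <- which(ok)[tgt > 0L]
    tgt <- tgt[tgt > 0L]
    if (length(src)) edges[[o]] <- cbind(src, tgt)
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    rbind(em, cbind(seq_along(supra), seq_along(supra))), directed = FALSE)
  comp <- igraph::components(g)$membership

  sizes <- tabulate(comp)
  keep <- which(sizes >= min_extent)
  if (length(keep) == 0L) return(empty())
  ord <- keep[order(-sizes[keep], keep)]
  new_id <- integer(length(sizes))
  new_id[ord] <- seq_along(ord)
  lab_vec <- new_id[comp]
  inside <- lab_vec > 0L
  labels[supra[inside]] <- lab_vec[inside]

  k <- length(ord)
  peak_z <- numeric(k); peak_voxel <- matrix(0L, k, 3)
  vals <- map$data[supra]
  for (c in seq_len(k)) {
    rows <- which(lab_vec == c)
    best <- rows[which.max(vals[rows])]
    peak_z[c] <- vals[best]
    peak_voxel[c, ] <- coord[best, ] - 1L  # 0-based
  }
  peak_mm <- voxel_to_mm(peak_voxel, map$affine, dim = dims)
  structure(list(labels = labels, sizes = sizes[ord], peak_z = peak_z,
                 peak_voxel = peak_voxel, peak_mm = peak_mm,
                 z_thr = z_thr, min_extent = min_extent),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), Z > %.3g, min extent %d\n",
              length(x$sizes), x$z_thr, x$min_extent))
  if (length(x$sizes)) print(utils::head(cluster_table(x), 10))
  invisible(x)
}

#' Cluster table
#'
#' @param clusters A `cluster_set` from [label_clusters()].
#' @return Data frame with columns `cluster_id`, `n_voxels`, `peak_z`,
#'   `peak_x_mm`, `peak_y_mm`, `peak_z_mm`.
#' @export
cluster_table <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  data.frame(cluster_id = seq_along(clusters$sizes),
             n_voxels = clusters$sizes,
             peak_z = clusters$peak_z,
             peak_x_mm = clusters$peak_mm[, 1],
             peak_y_mm = clusters$peak_mm[, 2],
             peak_z_mm = clusters$peak_mm[, 3])
}
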