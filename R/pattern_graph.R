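#' Spatial correlation between two maps inside a mask
#'
#' Pearson correlation of the two unthresholded voxel vectors restricted
#' to a mask — the similarity measure underlying the threshold-free
#' classification of activation patterns.
#'
#' @param map_a,map_b [stat_map]s on the same grid.
#' @param mask A [roi_mask] with at least 3 voxels.
#' @return Pearson r in `[-1, 1]`.
#' @export
spatial_correlation <- function(map_a, map_b, mask) {
  stopifnot(is_stat_map(map_a), is_stat_map(map_b),
            inherits(mask, "roi_mask"))
  check_same_grid(map_a, map_b); check_same_grid(map_a, mask)
  if (sum(mask$data) < 3L) stop("mask must contain at least 3 voxels")
  va <- map_a$data[mask$data]
  vb <- map_b$data[mask$data]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance in a masked map: correlation undefined")
  stats::cor(va, vb)
}

#' Subject-by-subject similarity matrix
#'
#' All pairwise masked spatial correlations between a cohort's
#' unthresholded Z maps (e.g. a 63 x 63 matrix for 63 subjects), the
#' input to graph construction.
#'
#' @param maps List of at least two [stat_map]s on a shared grid.
#' @param mask A [roi_mask] restricting the comparison (e.g. the Broca
#'   ROI pair union).
#' @param subject_ids Optional ids; defaults to the maps' own.
#' @return A `similarity_matrix`: `values` (n x n, symmetric, unit
#'   diagonal), `subject_ids`, `mask_label`.
#' @export
similarity_matrix <- function(maps, mask, subject_ids = NULL) {
  if (length(maps) < 2L) stop("need at least 2 maps")
  stopifnot(inherits(mask, "roi_mask"))
  for (m in maps) check_same_grid(m, mask)
  ids <- subject_ids %||%
    vapply(seq_along(maps), function(i) {
      id <- maps[[i]]$subject_id
      if (is.na(id)) sprintf("sub-%03d", i) else id
    }, "")
  vecs <- vapply(maps, function(m) m$data[mask$data],
                 numeric(sum(mask$data)))
  sds <- apply(vecs, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("zero variance in masked map(s): %s",
                 paste(ids[sds == 0], collapse = ", ")))
  vals <- stats::cor(vecs)
  diag(vals) <- 1
  dimnames(vals) <- list(ids, ids)
  structure(list(values = vals, subject_ids = ids,
                 mask_label = mask$label),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  n <- length(x$subject_ids)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<similarity_matrix> %d x %d on mask '%s'; off-diagonal r in [%.3f, %.3f]\n",
              n, n, x$mask_label, min(off), max(off)))
  invisible(x)
}

#' Write / read a similarity matrix as CSV
#'
#' CSV with a header row of subject ids and the ids repeated in the
#' first column.
#'
#' @param sim A `similarity_matrix`.
#' @param path File path.
#' @export
write_similarity_matrix <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  utils::write.csv(as.data.frame(sim$values), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  vals <- as.matrix(df)
  structure(list(values = vals, subject_ids = rownames(vals),
                 mask_label = "file"),
            class = "similarity_matrix")
}

#' Build a weighted subject graph from a similarity matrix
#'
#' Subjects become nodes of a complete weighted undirected graph with
#' edge weight equal to the pairwise correlation.  The modularity used
#' downstream is defined for nonnegative weights, so by default negative
#' correlations are truncated to zero and those edges dropped
#' (`negative = "truncate"`); `negative = "shift"` instead maps weights
#' to `(r + 1) / 2`.
#'
#' @param sim A `similarity_matrix`.
#' @param negative How to treat negative correlations.
#' @return An [igraph::igraph] weighted undirected graph.
#' @export
build_graph <- function(sim, negative = c("truncate", "shift")) {
  stopifnot(inherits(sim, "similarity_matrix"))
  negative <- match.arg(negative)
  w <- sim$values
  w <- switch(negative, truncate = pmax(w, 0), shift = (w + 1) / 2)
  diag(w) <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Detect communities of activation patterns
#'
#' Greedy two-phase modularity maximization (the Blondel/Louvain method)
#' on the weighted subject graph, yielding the groups of neural patterns.
#' The seed fixes the (randomized) node processing order, making the
#' result deterministic.
#'
#' @param graph Weighted undirected [igraph::igraph] with at least one
#'   vertex.
#' @param resolution Modularity resolution (default 1.0).
#' @param seed Integer RNG seed.
#' @return A `community_partition`: `labels` (named integer vector,
#'   communities numbered from 0 by decreasing size), `modularity`,
#'   `resolution`, `seed`.
#' @export
detect_communities <- function(graph, resolution = 1.0, seed = 1L) {
  if (!inherits(graph, "igraph")) stop("'graph' must be an igraph graph")
  if (igraph::vcount(graph) == 0L) stop("graph has no vertices")
  set.seed(as.integer(seed))
  if (igraph::ecount(graph) == 0L) {
    memb <- seq_len(igraph::vcount(graph))
    q <- 0
  } else {
    cl <- igraph::cluster_louvain(graph, resolution = resolution)
    memb <- igraph::membership(cl)
    q <- igraph::modularity(graph, memb,
                            weights = igraph::E(graph)$weight,
                            resolution = resolution)
  }
  sizes <- table(memb)
  relabel <- stats::setNames(seq_along(sizes) - 1L,
                             names(sort(sizes, decreasing = TRUE)))
  labels <- unname(relabel[as.character(memb)])
  names(labels) <- igraph::V(graph)$name %||% as.character(seq_along(labels))
  structure(list(labels = labels, modularity = q,
                 resolution = resolution, seed = as.integer(seed)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.4f (resolution %g)\n",
              length(unique(x$labels)), x$modularity, x$resolution))
  print(table(x$labels))
  invisible(x)
}

#' Agreement between a partition and reference labels
#'
#' Best-matching accuracy under label permutation: community labels are
#' matched one-to-one to reference classes so as to maximize the number
#' of agreeing subjects (optimal assignment on the confusion matrix),
#' and the agreement is that maximum divided by n.  Identical labelings
#' — up to any renaming — score 1.
#'
#' @param partition A `community_partition`, or a vector of labels named
#'   by subject.
#' @param reference Reference labels, named by subject (or in the same
#'   order if unnamed).
#' @return Agreement in `[0, 1]`.
#' @export
partition_agreement <- function(partition, reference) {
  lab <- if (inherits(partition, "community_partition")) partition$labels
         else partition
  if (!is.null(names(lab)) && !is.null(names(reference))) {
    if (!setequal(names(lab), names(reference)))
      stop("partition and reference cover different subject sets")
    reference <- reference[names(lab)]
  } else if (length(lab) != length(reference)) {
    stop("partition and reference have different lengths")
  }
  conf <- table(factor(lab), factor(reference))
  best_assignment_total(unclass(conf)) / length(lab)
}

# maximum-total one-to-one assignment on a (small) count matrix; exact
# permutation search up to 8 classes, greedy beyond
best_assignment_total <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  k <- max(nr, nc)
  sq <- matrix(0, k, k)
  sq[seq_len(nr), seq_len(nc)] <- m
  if (k <= 8L) {
    perms <- permutations_of(k)
    best <- 0
    for (p in perms)
      best <- max(best, sum(sq[cbind(seq_len(k), p)]))
    best
  } else {
    tot <- 0
    repeat {
      if (all(!is.finite(sq)) || max(sq, na.rm = TRUE) < 0) break
      ij <- which(sq == max(sq), arr.ind = TRUE)[1, ]
      tot <- tot + sq[ij[1], ij[2]]
      sq[ij[1], ] <- -Inf; sq[, ij[2]] <- -Inf
      if (all(!is.finite(sq))) break
    }
    tot
  }
}

permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in permutations_of(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Write a partition as JSON
#'
#' @param partition A `community_partition`.
#' @param path File path.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "community_partition"))
  jsonlite::write_json(as.list(partition$labels), path, auto_unbox = TRUE)
  invisible(path)
}

#' Threshold-free pattern classification of a cohort
#'
#' Convenience wrapper: similarity matrix inside the mask, weighted
#' graph, and Louvain communities.
#'
#' @inheritParams similarity_matrix
#' @inheritParams detect_communities
#' @inheritParams build_graph
#' @return List with `similarity`, `graph`, `partition`.
#' @export
classify_patterns <- function(maps, mask, resolution = 1.0, seed = 1L,
                              negative = "truncate") {
  sim <- similarity_matrix(maps, mask)
  g <- build_graph(sim, negative = negative)
  part <- detect_communities(g, resolution = resolution, seed = seed)
  list(similarity = sim, graph = g, partition = part)
}
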