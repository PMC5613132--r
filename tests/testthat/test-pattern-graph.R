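mask_all <- function(dims) roi_mask(array(TRUE, dims), label = "all")

test_that("spatial correlation is masked Pearson r", {
  set.seed(2)
  dims <- c(4, 4, 3)
  a <- tiny_map(array(rnorm(prod(dims)), dims))
  mask <- mask_all(dims)
  expect_equal(spatial_correlation(a, a, mask), 1)
  neg <- a; neg$data <- -a$data
  expect_equal(spatial_correlation(a, neg, mask), -1)

  m3 <- roi_mask(array(c(TRUE, TRUE, TRUE, rep(FALSE, 45)), c(4, 4, 3)),
                 label = "m3")
  b <- a; b$data[1:3] <- c(1, 2, 4); a$data[1:3] <- c(1, 2, 3)
  expect_equal(round(spatial_correlation(a, b, m3), 3), 0.982)

  const <- a; const$data[1:3] <- 5
  expect_error(spatial_correlation(const, b, m3), "zero variance")
  tiny <- roi_mask(array(c(TRUE, TRUE, rep(FALSE, 46)), c(4, 4, 3)))
  expect_error(spatial_correlation(a, b, tiny), "at least 3")
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(4)
  dims <- c(5, 5, 4)
  maps <- lapply(1:7, function(i) {
    m <- tiny_map(array(rnorm(prod(dims)), dims))
    m$subject_id <- sprintf("s%02d", i); m
  })
  sim <- similarity_matrix(maps, mask_all(dims))
  expect_equal(dim(sim$values), c(7, 7))
  expect_identical(sim$values, t(sim$values))
  expect_equal(unname(diag(sim$values)), rep(1, 7))
  expect_true(all(sim$values >= -1 & sim$values <= 1))

  dup <- similarity_matrix(list(maps[[1]], maps[[1]]), mask_all(dims),
                           subject_ids = c("a", "b"))
  expect_equal(unname(dup$values["a", "b"]), 1)

  # Pearson is invariant under a common voxelwise affine rescaling
  resc <- lapply(maps, function(m) { m$data <- 3.7 * m$data - 11; m })
  sim2 <- similarity_matrix(resc, mask_all(dims))
  expect_equal(sim2$values, sim$values, tolerance = 1e-12)

  f <- withr::local_tempfile(fileext = ".csv")
  write_similarity_matrix(sim, f)
  expect_equal(read_similarity_matrix(f)$values, sim$values,
               tolerance = 1e-12)
})

test_that("graph construction drops non-positive correlations by default", {
  vals <- matrix(0.5, 4, 4); diag(vals) <- 1
  vals[1, 2] <- vals[2, 1] <- -0.2
  sim <- structure(list(values = vals,
                        subject_ids = paste0("s", 1:4),
                        mask_label = "m"),
                   class = "similarity_matrix")
  dimnames(sim$values) <- list(sim$subject_ids, sim$subject_ids)
  g <- build_graph(sim)
  expect_equal(igraph::ecount(g), 5)          # 6 pairs minus the negative
  expect_true(all(igraph::E(g)$weight == 0.5))
  g2 <- build_graph(sim, negative = "shift")
  expect_equal(igraph::ecount(g2), 6)
  expect_equal(sort(unique(igraph::E(g2)$weight)), c(0.4, 0.75))
})

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(lab, k) {
    if (length(lab) == n) { out[[length(out) + 1L]] <<- lab; return() }
    for (v in seq_len(k + 1)) grow(c(lab, v), max(k, v))
  }
  grow(integer(0), 0L)
  out
}

test_that("uniform complete graphs form a single community (exhaustive check)", {
  g <- igraph::make_full_graph(6)
  igraph::E(g)$weight <- 0.5
  part <- detect_communities(g, seed = 1)
  expect_equal(length(unique(part$labels)), 1)
  expect_equal(part$modularity, 0)
  # no partition of a uniform complete graph has positive modularity
  qs <- vapply(all_partitions(6), function(p)
    igraph::modularity(g, p, weights = igraph::E(g)$weight), 0)
  expect_lte(max(qs), 0 + 1e-12)
})

test_that("planted two-block similarity recovers the blocks", {
  blocks <- rep(c(1, 2), c(7, 3))
  vals <- outer(blocks, blocks, function(a, b)
    ifelse(a == b, 0.6, 0.1))
  diag(vals) <- 1
  ids <- sprintf("s%02d", 1:10)
  dimnames(vals) <- list(ids, ids)
  sim <- structure(list(values = vals, subject_ids = ids,
                        mask_label = "m"), class = "similarity_matrix")
  g <- build_graph(sim)
  part <- detect_communities(g, seed = 3)
  expect_equal(length(unique(part$labels)), 2)
  expect_equal(partition_agreement(part,
                                   stats::setNames(blocks, ids)), 1)

  # brute-force over all 2-colorings: the planted split maximizes Q
  best_q <- -Inf; best_split <- NULL
  for (code in 0:(2^9 - 1)) {
    memb <- c(1, as.integer(intToBits(code))[1:9] + 1)
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
    if (q > best_q) { best_q <- q; best_split <- memb }
  }
  expect_equal(best_split, blocks)
  expect_gte(part$modularity, best_q - 1e-12)
})

test_that("degenerate graphs are handled", {
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  p1 <- detect_communities(g1, seed = 1)
  expect_equal(length(p1$labels), 1)
  expect_equal(p1$modularity, 0)
  expect_error(detect_communities(igraph::make_empty_graph(0), seed = 1),
               "no vertices")
})

test_that("returned modularity is never below the trivial partition", {
  set.seed(10)
  for (i in 1:6) {
    n <- sample(5:12, 1)
    vals <- matrix(runif(n * n), n, n)
    vals <- (vals + t(vals)) / 2
    diag(vals) <- 1
    ids <- paste0("s", seq_len(n))
    dimnames(vals) <- list(ids, ids)
    sim <- structure(list(values = vals, subject_ids = ids,
                          mask_label = "m"), class = "similarity_matrix")
    g <- build_graph(sim)
    if (igraph::ecount(g) == 0) next
    part <- detect_communities(g, seed = i)
    expect_gte(part$modularity, 0 - 1e-12)
  }
})

test_that("partition agreement is permutation-invariant matching accuracy", {
  ids <- paste0("s", 1:10)
  a <- stats::setNames(rep(c(0, 1), each = 5), ids)
  expect_equal(partition_agreement(a, a), 1)
  swapped <- stats::setNames(rep(c("x", "y"), each = 5), ids)
  expect_equal(partition_agreement(a, swapped[ids]), 1)
  two_off <- a; two_off[c(1, 6)] <- 1 - two_off[c(1, 6)]
  expect_equal(partition_agreement(a, two_off), 0.8)
  expect_error(partition_agreement(a, stats::setNames(rep(1, 3),
                                                      c("a", "b", "c"))),
               "different subject sets")
})
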