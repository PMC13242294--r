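test_that("build_knn_graph finds exact Euclidean neighbors", {
  # 4 collinear equally spaced points, k = 1: ends pick their adjacent
  # point; ties (interior) resolve to the lower index deterministically
  g <- build_knn_graph(cbind(0:3, 0), 1)
  expect_equal(g$neighbor_indices[1, ], 2L)
  expect_equal(g$neighbor_indices[4, ], 3L)
  expect_true(all(g$distances == 1))
  # hexagonal lattice interior spot has its 6 ring neighbors at distance 1
  ds <- simulate_tissue(sim_config(n_rows = 5, n_cols = 5, n_domains = 1,
                                   n_genes = 10, n_markers_per_domain = 1,
                                   n_housekeeping = 1))
  gh <- build_knn_graph(ds$coords, 6)
  center <- 13L  # row 3, col 3 of the 5x5 lattice
  expect_equal(unname(gh$distances[center, ]), rep(1, 6), tolerance = 1e-12)
  expect_error(build_knn_graph(cbind(0:3, 0), 4), "more spots")
  # no self neighbors, distances non-decreasing
  expect_false(any(gh$neighbor_indices == seq_len(25)))
  expect_true(all(diff(t(gh$distances)) >= -1e-12))
})

test_that("scatter_filtration follows the removal contract", {
  ds <- small_sim()
  # r = floor(knob / 10)
  f <- scatter_filtration(ds$counts,
                          filtration_config(knob = 100, n_iterations = 2),
                          seed = 1)
  expect_true(all(lengths(f$removed_per_iteration) == 10L))
  expect_equal(f$r, 10L)
  # removed sets pairwise disjoint, partition property
  all_removed <- unlist(f$removed_per_iteration)
  expect_false(anyDuplicated(all_removed) > 0)
  expect_setequal(c(f$retained_genes, all_removed), seq_len(ncol(ds$counts)))
  # T = 0 is a no-op
  f0 <- scatter_filtration(ds$counts, filtration_config(n_iterations = 0))
  expect_identical(f0$retained_genes, seq_len(ncol(ds$counts)))
  # determinism under seed
  f2 <- scatter_filtration(ds$counts,
                           filtration_config(knob = 100, n_iterations = 2),
                           seed = 1)
  expect_identical(f$removed_per_iteration, f2$removed_per_iteration)
  # exhausting the gene set errors before any work
  expect_error(
    scatter_filtration(ds$counts, filtration_config(knob = 500,
                                                    n_iterations = 10)),
    "exhaust")
})

test_that("scatter_filtration removes the dominant gene in the toy case", {
  # 5 spots x 6 genes, gene 3 maximal in every spot; m = 5, L = 1,
  # knob = 10 (r = 1), T = 1 -> gene 3 is the single removed gene.
  # Oracle: brute-force occurrence count over all spots.
  x <- matrix(1, 5, 6)
  x[, 3] <- 10
  oracle_counts <- vapply(seq_len(6), function(g)
    sum(apply(x, 1, which.max) == g), integer(1))
  expect_equal(which.max(oracle_counts), 3L)
  f <- scatter_filtration(x, filtration_config(knob = 10, n_iterations = 1,
                                               sample_size = 5, top_l = 1))
  expect_identical(f$removed_per_iteration[[1]], 3L)
  expect_identical(f$retained_genes, c(1L, 2L, 4L, 5L, 6L))
})

test_that("select_hvg ranks dispersed genes first, constants last", {
  set.seed(11)
  n <- 200
  # baseline genes with means spread over orders of magnitude so the
  # mean-variance trend is well determined
  lambdas <- 2^runif(30, 0, 5)
  base <- sapply(lambdas, function(l) rpois(n, l))
  x <- cbind(base,
             dispersed = rnbinom(n, size = 0.05, mu = 8),  # 10x+ dispersion
             flat = rep(3, n))                             # zero variance
  top <- select_hvg(x, 5)
  expect_equal(top[1], 31L)
  expect_false(32L %in% select_hvg(x, 31))
  expect_setequal(select_hvg(x, ncol(x)), seq_len(ncol(x)))
  expect_error(select_hvg(matrix(0, 5, 4), 2), "all-zero")
})

test_that("normalize_expression applies the four steps in order", {
  # library-size step: spot [2, 2] with s = 10 -> [5, 5]
  x <- matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE)
  lib <- x / rowSums(x) * 10
  expect_equal(unname(lib[1, ]), c(5, 5))
  # column z-scores: |mean| ~ 0 and unit variance absent clipping
  set.seed(3)
  big <- matrix(rpois(600, 10) + 1, 60, 10)
  out <- normalize_expression(big)
  expect_true(all(abs(colMeans(out)) < 1e-6))
  expect_true(all(abs(apply(out, 2, var) - 1) < 1e-4))
  # clip saturation hits the bound exactly
  spike <- matrix(c(rep(1, 99), 1e6), 50, 2)
  outc <- normalize_expression(spike, normalization_config(clip_high = 2,
                                                           clip_low = -2))
  expect_equal(max(outc), 2)
  # zero-total spot is named in the error
  zero <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE,
                 dimnames = list(c("good", "bad"), NULL))
  expect_error(normalize_expression(zero), "bad")
  # log1p(0) = 0 keeps all-zero genes centered at zero
  withz <- matrix(c(1, 2, 0, 3, 4, 0), 2, 3, byrow = TRUE)
  expect_equal(normalize_expression(withz)[, 3], c(0, 0))
})

test_that("neighborhood_features concatenates self and neighbor means", {
  g <- build_knn_graph(cbind(0:2, 0), 1)
  x <- matrix(c(0, 6, 0), 3, 1)
  nf <- neighborhood_features(x, g)
  expect_equal(dim(nf), c(3L, 2L))
  expect_equal(unname(nf[2, ]), c(6, 0))  # middle spot's neighbor is an end
  expect_equal(unname(nf[1, ]), c(0, 6))
  # identical expression everywhere -> [v || v]
  xc <- matrix(5, 3, 4)
  expect_true(all(neighborhood_features(xc, g) == 5))
  expect_equal(ncol(neighborhood_features(matrix(0, 3, 100), g)), 200L)
  expect_error(neighborhood_features(matrix(0, 4, 2), g), "different spot")
})

test_that("neighborhood_features commutes with spot permutation", {
  set.seed(5)
  coords <- matrix(runif(40), 20, 2)
  x <- matrix(rnorm(60), 20, 3)
  perm <- sample(20)
  a <- neighborhood_features(x, build_knn_graph(coords, 3))[perm, ]
  b <- neighborhood_features(x[perm, ], build_knn_graph(coords[perm, ], 3))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("fuse_features concatenates blocks in order", {
  b <- list(matrix(1, 4, 4), matrix(2, 4, 2), matrix(3, 4, 3))
  out <- fuse_features(b)
  expect_equal(dim(out), c(4L, 9L))
  expect_equal(unname(out[1, ]), c(rep(1, 4), rep(2, 2), rep(3, 3)))
  expect_equal(fuse_features(b[1]), b[[1]])
  expect_error(fuse_features(list(matrix(0, 3, 1), matrix(0, 4, 1))),
               "mismatched")
})

test_that("select_locations keeps the highest-total spots", {
  counts <- matrix(0, 10, 2)
  counts[, 1] <- 1:10
  ds <- spatial_dataset(counts, cbind(1:10, 0), truth_labels = 1:10)
  kept <- select_locations(ds, 0.4)
  expect_setequal(rowSums(kept$counts), 7:10)
  expect_setequal(kept$truth_labels, 7:10)
  expect_equal(nrow(select_locations(ds, 1)$counts), 10L)
  ds40 <- spatial_dataset(matrix(1:80, 40, 2), cbind(1:40, 0))
  expect_equal(nrow(select_locations(ds40, 0.05)$counts), 2L)
  expect_error(select_locations(ds, 0), "keep_fraction")
  expect_error(select_locations(ds, 1.2), "keep_fraction")
})

test_that("filtration is stable across seeds on the simulator", {
  ds <- small_sim()
  cfg <- filtration_config(knob = 50, n_iterations = 6)
  a <- unlist(scatter_filtration(ds$counts, cfg, seed = 1)$removed_per_iteration)
  b <- unlist(scatter_filtration(ds$counts, cfg, seed = 2)$removed_per_iteration)
  jaccard <- length(intersect(a, b)) / length(union(a, b))
  expect_gt(jaccard, 0.5)
})
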