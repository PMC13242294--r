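test_that("contingency counts co-occurrences exactly", {
  ct <- contingency(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_true(all(ct$counts == 1))
  expect_equal(ct$total, 4)
  ct2 <- contingency(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sum(diag(ct2$counts)), 3)
  expect_error(contingency(1:3, 1:4), "lengths")
})

test_that("ari matches identities and the hand-derived case", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)  # permutation invariant
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_error(ari(1, 1), "fewer than 2")
})

test_that("ari equals the brute-force pair-counting oracle", {
  # exhaustive over all two-label assignments of 5 spots
  labelings <- as.matrix(expand.grid(rep(list(1:2), 5)))
  for (i in seq(1, nrow(labelings), by = 7)) {
    for (j in seq(2, nrow(labelings), by = 9)) {
      a <- labelings[i, ]; b <- labelings[j, ]
      if (length(unique(a)) < 1 || length(unique(b)) < 1) next
      expect_equal(ari(a, b), ari_oracle(a, b), tolerance = 1e-12)
    }
  }
  # random labelings up to n = 8, up to 4 clusters
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(ari(a, b), ari_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("ari and nmi are symmetric and permutation invariant", {
  set.seed(31)
  for (rep in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:3, 12, replace = TRUE)
    expect_equal(ari(a, b), ari(b, a))
    expect_equal(nmi(a, b), nmi(b, a))
    perm <- sample(3)
    expect_equal(ari(perm[a], b), ari(a, b))
    expect_equal(nmi(perm[a], b), nmi(a, b), tolerance = 1e-12)
  }
})

test_that("nmi matches closed forms and the entropy oracle", {
  expect_equal(nmi(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3)), 1)
  expect_equal(nmi(c(1, 1, 1, 1), c(1, 1, 1, 1)), 1)  # zero-entropy case
  # independent balanced 2x2 table -> zero mutual information
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # independent hand computation from joint entropies
  a <- c(0, 0, 1, 1); b <- c(0, 0, 0, 1)
  p_joint <- c(2, 1, 1) / 4          # cells (0,0), (1,0), (1,1)
  h <- function(p) -sum(p * log(p))
  mi <- h(c(0.5, 0.5)) + h(c(0.75, 0.25)) - h(p_joint)
  expect_equal(nmi(a, b), 2 * mi / (h(c(0.5, 0.5)) + h(c(0.75, 0.25))))
  expect_equal(nmi(a, b), 0.3437, tolerance = 1e-3)
})

test_that("homogeneity and completeness move in the documented directions", {
  truth <- rep(1:2, each = 4)
  expect_equal(unname(homogeneity_completeness(truth, truth)), c(1, 1))
  split <- c(1, 1, 2, 2, 3, 3, 4, 4)   # refines truth
  hc <- homogeneity_completeness(truth, split)
  expect_equal(unname(hc["homogeneity"]), 1)
  expect_lt(hc["completeness"], 1)
  merged <- rep(1, 8)                   # coarsens truth
  hc2 <- homogeneity_completeness(truth, merged)
  expect_equal(unname(hc2["completeness"]), 1)
  expect_lt(hc2["homogeneity"], 1)
})

test_that("asw matches a manual silhouette and its limits", {
  # 4 points, two tight pairs far apart: hand computation
  x <- rbind(c(0, 0), c(0, 1), c(100, 0), c(100, 1))
  labs <- c(1, 1, 2, 2)
  a_i <- 1
  b_i <- mean(c(100, sqrt(100^2 + 1)))
  expect_equal(asw(x, labs), (b_i - a_i) / b_i, tolerance = 1e-9)
  expect_gt(asw(x, labs), 0.98)  # separation limit
  # shuffling labels on one blob lowers the silhouette
  set.seed(12)
  blobs <- make_blobs(n_per = 20, centers = rbind(c(0, 0), c(6, 6)),
                      sd = 0.5, seed = 3)
  shuffled <- blobs$labels
  shuffled[1:20] <- sample(1:2, 20, replace = TRUE)
  expect_lt(asw(blobs$x, shuffled), asw(blobs$x, blobs$labels))
  expect_error(asw(x, rep(1, 4)), "single cluster")
})

test_that("pas counts locally discordant spots", {
  grid <- as.matrix(expand.grid(x = 1:12, y = 1:12))
  # uniform labeling: nothing is abnormal
  expect_equal(pas(rep(1, 144), grid), 0)
  # contiguous half/half split: only boundary spots can be abnormal
  half <- ifelse(grid[, "x"] <= 6, 1, 2)
  expect_lt(pas(half, grid), 0.1)
  # single-row stripes: every interior spot disagrees with >= 6 of its 10
  # nearest neighbors (2 axial + 4 diagonal neighbors carry the other
  # stripe), so the interior is entirely abnormal
  stripes <- 1 + grid[, "y"] %% 2
  interior <- grid[, "x"] %in% 3:10 & grid[, "y"] %in% 3:10
  g <- build_knn_graph(grid, 10)
  nb <- matrix(stripes[g$neighbor_indices], nrow = 144)
  expect_true(all(rowSums(nb != stripes)[interior] >= 6))
  expect_gte(pas(stripes, grid), mean(interior))
  expect_error(pas(rep(1, 5), grid[1:5, ]), "more than")
})

test_that("chaos orders spatial disorder and is scale invariant", {
  set.seed(8)
  coords <- as.matrix(expand.grid(1:10, 1:10))
  compact <- ifelse(coords[, 1] <= 5, 1, 2)
  random <- sample(1:2, 100, replace = TRUE)
  expect_gte(chaos(random, coords), chaos(compact, coords))
  expect_equal(chaos(compact, coords), chaos(compact, coords * 10),
               tolerance = 1e-12)
  expect_warning(chaos(c(rep(1, 99), 2), coords), "singleton")
})

test_that("spatial autocorrelation matches a direct weight-matrix oracle", {
  oracle <- function(labels, graph) {
    n <- length(labels)
    w <- matrix(0, n, n)
    for (i in seq_len(n)) w[i, graph$neighbor_indices[i, ]] <- 1 / graph$k
    sizes <- table(labels)
    mi <- gc <- 0
    for (c in names(sizes)) {
      x <- as.numeric(labels == c)
      xc <- x - mean(x)
      num_i <- sum(w * outer(xc, xc))
      num_c <- sum(w * outer(x, x, function(a, b) (a - b)^2))
      mi <- mi + sizes[[c]] * (n / sum(w)) * num_i / sum(xc^2)
      gc <- gc + sizes[[c]] * ((n - 1) / (2 * sum(w))) * num_c / sum(xc^2)
    }
    c(mi / n, gc / n)
  }
  set.seed(14)
  coords <- matrix(runif(60), 30, 2)
  g <- build_knn_graph(coords, 4)
  for (rep in 1:5) {
    labs <- sample(1:3, 30, replace = TRUE)
    got <- spatial_autocorrelation(labs, g)
    want <- oracle(labs, g)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("spatial autocorrelation hits its classical limits", {
  line <- cbind(1:6, 0)
  g1 <- build_knn_graph(line, 1)
  # two contiguous blocks: strong positive autocorrelation
  blocks <- c(1, 1, 1, 2, 2, 2)
  sa <- spatial_autocorrelation(blocks, g1)
  expect_gt(sa["moran_i"], 0.5)
  expect_lt(sa["geary_c"], 0.5)
  # perfect alternation with k = 1: Moran's I = -1
  alt <- rep(c(1, 2), 3)
  expect_equal(unname(spatial_autocorrelation(alt, g1)["moran_i"]), -1)
  # coin-flip labels on a lattice: near zero
  set.seed(4)
  grid <- as.matrix(expand.grid(1:15, 1:15))
  coin <- sample(1:2, 225, replace = TRUE)
  expect_lt(abs(spatial_autocorrelation(coin, build_knn_graph(grid, 6))["moran_i"]),
            0.12)
  expect_error(spatial_autocorrelation(rep(1, 6), g1), "constant")
})

test_that("metric_report assembles supervised and unsupervised metrics", {
  ds <- small_sim()
  rep_ <- metric_report(ds$truth_labels, ds$coords,
                        shared_feature_space(ds, 10),
                        truth = ds$truth_labels)
  expect_equal(unname(rep_["ARI"]), 1)
  expect_equal(unname(rep_["NMI"]), 1)
  expect_true(all(c("ASW", "PAS", "CHAOS", "MoranI", "GearyC") %in%
                    names(rep_)))
  expect_gt(rep_["MoranI"], 0.5)  # planted laminar domains are coherent
  expect_lt(rep_["PAS"], 0.1)
})
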