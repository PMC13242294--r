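test_that("init_model is seeded and defaults to latent dimension 32", {
  m1 <- init_model(10, k = 3, seed = 5)
  m2 <- init_model(10, k = 3, seed = 5)
  expect_identical(m1$W1, m2$W1)
  expect_false(identical(init_model(10, k = 3, seed = 6)$W1, m1$W1))
  expect_equal(m1$d_latent, 32L)
  expect_equal(dim(m1$W1), c(10L, 32L))
  expect_equal(dim(m1$W3), c(32L, 3L))
})

test_that("encode and reconstruct are the written linear maps", {
  m <- init_model(4, 2, 2, seed = 1)
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(encode(x, m), x %*% m$W1)
  expect_equal(reconstruct(encode(x, m), m), x %*% m$W1 %*% m$W2)
  expect_equal(encode(matrix(0, 3, 4), m), matrix(0, 3, 2))
  # identity encoder
  mi <- init_model(3, 3, 2, seed = 1)
  mi$W1 <- diag(3)
  expect_equal(encode(x[, 1:3], mi), x[, 1:3])
  expect_error(encode(x, mi), "does not match")
})

test_that("reconstruction_loss is the mean squared row distance", {
  expect_equal(reconstruction_loss(matrix(0, 1, 2), matrix(c(3, 4), 1, 2)),
               25)
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(reconstruction_loss(x, x), 0)
  xhat <- x + 1
  expect_equal(reconstruction_loss(x, x + 2), 4 * reconstruction_loss(x, xhat))
})

test_that("soft_assign is a stabilized row-softmax", {
  m <- init_model(2, 2, 4, seed = 1)
  m$W3 <- matrix(0, 2, 4)
  sa <- soft_assign(matrix(rnorm(10), 5, 2), m)
  expect_true(all(abs(sa$Q - 0.25) < 1e-12))
  # closed form: scores (ln 2, 0) -> (2/3, 1/3)
  m2 <- init_model(2, 2, 2, seed = 1)
  m2$W3 <- rbind(c(log(2), 0), c(0, 0))
  sa2 <- soft_assign(matrix(c(1, 0), 1, 2), m2)
  expect_equal(unname(sa2$Q[1, ]), c(2 / 3, 1 / 3))
  # rows sum to one for random inputs, huge scores included
  sa3 <- soft_assign(matrix(rnorm(20, sd = 500), 10, 2), m)
  expect_equal(unname(rowSums(sa3$Q)), rep(1, 10), tolerance = 1e-6)
})

test_that("kl_divergence matches hand-computed values", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(kl_divergence(c(1, 0), c(0.9, 0.1)), log(1 / 0.9))
  expect_error(kl_divergence(c(-0.1, 1.1), c(0.5, 0.5)), "non-negative")
  # row averaging: stacking the same row leaves the value unchanged
  p <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  q <- rbind(c(0.25, 0.75), c(0.25, 0.75))
  expect_equal(kl_divergence(p, q), kl_divergence(p[1, ], q[1, ]))
})

test_that("stage 1 reaches the compressible optimum and is reproducible", {
  set.seed(9)
  # exactly rank-4 input with d_latent = 4: optimum is zero loss
  x <- matrix(rnorm(50 * 4), 50, 4) %*% matrix(rnorm(4 * 12), 4, 12)
  m <- init_model(12, 4, 2, seed = 3)
  init_loss <- reconstruction_loss(x, reconstruct(encode(x, m), m))
  m <- train_stage1_reconstruction(m, x, training_config(epochs = c(2000, 0, 0)))
  final <- tail(m$loss_history$l_rec, 1)
  expect_lt(final, 0.01 * init_loss)
  # 0 epochs: unchanged
  m0 <- init_model(12, 4, 2, seed = 3)
  expect_identical(train_stage1_reconstruction(m0, x, epochs = 0), m0)
  # determinism
  ma <- train_stage1_reconstruction(init_model(12, 4, 2, seed = 3), x,
                                    epochs = 50)
  mb <- train_stage1_reconstruction(init_model(12, 4, 2, seed = 3), x,
                                    epochs = 50)
  expect_identical(ma$loss_history, mb$loss_history)
  expect_lt(tail(ma$loss_history$l_rec, 1), ma$loss_history$l_rec[1])
})

test_that("stage 2 trains only the clustering layer", {
  # non-collinear centers: a bias-free linear layer can only separate
  # classes whose score difference changes sign along some direction
  blobs <- make_blobs(n_per = 40, centers = rbind(c(6, 0, 0), c(0, 6, 0)),
                      sd = 0.5, seed = 2)
  m <- init_model(3, 3, 2, seed = 4)
  m$W1 <- diag(3)  # latent = input: linearly separable clusters
  y <- one_hot_targets(blobs$labels, 2)
  m2 <- train_stage2_cluster_alignment(m, blobs$x, y,
                                       training_config(epochs = c(0, 400, 0)))
  expect_identical(m2$W1, m$W1)  # byte-identical freeze
  expect_identical(m2$W2, m$W2)
  q <- soft_assign(encode(blobs$x, m2), m2)$Q
  expect_gte(mean(max.col(q) == blobs$labels), 0.95)
  h <- subset(m2$loss_history, stage == "alignment")$l_clust
  expect_lte(tail(h, 1), h[1] * 1.05)
  expect_error(train_stage2_cluster_alignment(m, blobs$x,
                                              one_hot_targets(blobs$labels, 2)[, c(1, 2, 2)],
                                              fast_training()),
               "does not match")
})

test_that("stage 3 respects the loss weighting", {
  blobs <- make_blobs(n_per = 25, centers = rbind(c(0, 0), c(6, 6)),
                      sd = 0.6, seed = 8)
  y <- one_hot_targets(blobs$labels, 2)
  m <- init_model(2, 2, 2, seed = 1)
  # lambda_clust = 0 leaves the clustering layer untouched
  m_rec <- train_stage3_joint(m, blobs$x, y,
                              training_config(lambda_clust = 0,
                                              epochs = c(0, 0, 30)))
  expect_identical(m_rec$W3, m$W3)
  # lambda_rec = 0 descends the clustering loss
  m_cl <- train_stage3_joint(m, blobs$x, y,
                             training_config(lambda_rec = 0,
                                             epochs = c(0, 0, 200)))
  h <- subset(m_cl$loss_history, stage == "joint")$l_clust
  expect_lte(tail(h, 1), h[1])
})

test_that("hill climbing only accepts fitness improvements", {
  blobs <- make_blobs(n_per = 25, centers = rbind(c(0, 0), c(12, 12)),
                      sd = 0.4, seed = 3)
  m <- init_model(2, 2, 2, seed = 2)
  out0 <- hill_climb_train(m, blobs$x, iterations = 0, eps = 1.5,
                           min_points = 4, seed = 1)
  expect_identical(out0$model, m)
  out <- hill_climb_train(m, blobs$x, iterations = 30, eps = 1.5,
                          min_points = 4, seed = 1)
  expect_true(all(diff(out$fitness_trace) >= 0))
  expect_gte(tail(out$fitness_trace, 1), out$fitness_trace[1])
})

test_that("model checkpoints round-trip through JSON", {
  m <- init_model(5, 3, 2, seed = 1)
  m <- train_stage1_reconstruction(m, matrix(rnorm(40), 8, 5), epochs = 3)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  back <- load_model(f)
  expect_equal(back$W1, m$W1, tolerance = 1e-12)
  expect_equal(back$K, m$K)
  expect_equal(back$loss_history$l_rec, m$loss_history$l_rec,
               tolerance = 1e-12)
})
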