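# Linear autoencoder with an attached softmax clustering layer.
#
# The encoder/decoder are single bias-free linear maps, Z = X W1 and
# Xhat = Z W2, trained full-batch with Adam. The clustering layer
# S = Z W3 produces soft assignments via a row-wise softmax; during
# training it is aligned (KL divergence) with one-hot targets derived from
# spatially refined Gaussian-mixture labels. Training proceeds in stages:
# reconstruction only, clustering-layer alignment with frozen autoencoder,
# then joint fine-tuning of all weights.

#' Training configuration for the autoencoder stages
#'
#' @param lambda_rec Weight of the reconstruction loss. Default 1.
#' @param lambda_clust Weight of the clustering (KL) loss. Default 0.1.
#' @param epochs Integer vector of length 3: epochs for the
#'   reconstruction, alignment, and joint stages. Default c(200, 100, 200).
#' @param learning_rate Adam learning rate. Default 1e-3.
#' @param seed Integer seed; `NULL` defers to the caller.
#' @return A list of class `training_config`.
#' @export
training_config <- function(lambda_rec = 1, lambda_clust = 0.1,
                            epochs = c(200L, 100L, 200L),
                            learning_rate = 1e-3, seed = NULL) {
  if (lambda_rec < 0 || lambda_clust < 0)
    stop("loss weights must be non-negative")
  if (lambda_rec + lambda_clust <= 0)
    stop("at least one loss weight must be positive")
  if (length(epochs) != 3L) stop("epochs must have length 3")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(lambda_rec = lambda_rec, lambda_clust = lambda_clust,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = seed),
            class = "training_config")
}

#' Initialize a latent model
#'
#' Draws W1 (encoder), W2 (decoder) and W3 (clustering layer) from
#' scaled symmetric uniform distributions (Glorot-style); the clustering
#' layer is randomly initialized, never pretrained on labels.
#'
#' @param d_in Input feature dimension.
#' @param d_latent Latent dimension; default 32.
#' @param k Number of clusters K.
#' @param seed Integer seed; same seed gives bit-identical weights.
#' @return A list of class `latent_model` with weight matrices and an
#'   empty loss history.
#' @export
init_model <- function(d_in, d_latent = 32L, k, seed = 0L) {
  stopifnot(d_in >= 1, d_latent >= 1, k >= 1)
  set.seed(as.integer(seed))
  glorot <- function(a, b) {
    s <- sqrt(6 / (a + b))
    matrix(stats::runif(a * b, -s, s), a, b)
  }
  structure(list(W1 = glorot(d_in, d_latent), W2 = glorot(d_latent, d_in),
                 W3 = glorot(d_latent, k), d_in = as.integer(d_in),
                 d_latent = as.integer(d_latent), K = as.integer(k),
                 loss_history = empty_loss_history()),
            class = "latent_model")
}

empty_loss_history <- function() {
  data.frame(stage = character(0), epoch = integer(0), l_rec = numeric(0),
              l_clust = numeric(0), l_total = numeric(0))
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("latent_model: %d -> %d latent, K = %d (%d epochs trained)\n",
              x$d_in, x$d_latent, x$K, nrow(x$loss_history)))
  invisible(x)
}

#' Encode features into the latent space
#'
#' Z = X W1; a pure bias-free linear map.
#'
#' @param x Feature matrix, width `d_in`.
#' @param model A `latent_model`.
#' @return The n x d_latent latent matrix.
#' @export
encode <- function(x, model) {
  x <- as.matrix(x)
  if (ncol(x) != model$d_in)
    stop("input width ", ncol(x), " does not match model d_in ", model$d_in)
  x %*% model$W1
}

#' Reconstruct features from the latent space
#'
#' Xhat = Z W2.
#'
#' @param z Latent matrix, width `d_latent`.
#' @param model A `latent_model`.
#' @return The reconstructed n x d_in matrix.
#' @export
reconstruct <- function(z, model) {
  z <- as.matrix(z)
  if (ncol(z) != model$d_latent)
    stop("latent width ", ncol(z), " does not match model d_latent ",
         model$d_latent)
  z %*% model$W2
}

#' Mean squared reconstruction loss
#'
#' Mean over spots of the squared Euclidean distance between a row and its
#' reconstruction.
#'
#' @param x Original matrix.
#' @param xhat Reconstruction, same shape.
#' @return A single non-negative number.
#' @export
reconstruction_loss <- function(x, xhat) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!all(dim(x) == dim(xhat))) stop("shape mismatch")
  mean(rowSums((x - xhat)^2))
}

#' Soft cluster assignments from the clustering layer
#'
#' Computes S = Z W3 and converts each row to probabilities with a
#' numerically stabilized softmax (row max subtracted before
#' exponentiation).
#'
#' @param z Latent matrix.
#' @param model A `latent_model`.
#' @return A list of class `soft_assignment` with `Q` (n x K rows summing
#'   to 1) and `raw_scores`.
#' @export
soft_assign <- function(z, model) {
  z <- as.matrix(z)
  s <- z %*% model$W3
  q <- softmax_rows(s)
  structure(list(Q = q, raw_scores = s), class = "soft_assignment")
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

#' Row-averaged Kullback-Leibler divergence
#'
#' Treats each row of `p` and `q` as a probability vector, computes the
#' per-row divergence sum(p * log(p / q)) with zero `p` entries
#' contributing 0 and `q` floored at 1e-10, and averages over rows. The
#' row average (rather than the grand total) keeps the clustering-loss
#' weight independent of the number of spots.
#'
#' @param p,q Matrices (or vectors) of row-wise distributions.
#' @return A single non-negative number.
#' @export
kl_divergence <- function(p, q) {
  p <- rbind(p); q <- rbind(q)
  if (!all(dim(p) == dim(q))) stop("shape mismatch")
  if (any(p < 0) || any(q < 0)) stop("distributions must be non-negative")
  q <- pmax(q, 1e-10)
  terms <- ifelse(p > 0, p * log(p / q), 0)
  mean(rowSums(terms))
}

# --- full-batch Adam ---------------------------------------------------

adam_new <- function(shapes, lr) {
  list(lr = lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8, t = 0L,
       m = lapply(shapes, function(s) array(0, dim = s)),
       v = lapply(shapes, function(s) array(0, dim = s)))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * grads[[i]]
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * grads[[i]]^2
    mhat <- opt$m[[i]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[i]] / (1 - opt$beta2^opt$t)
    params[[i]] <- params[[i]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}

#' Stage 1: reconstruction-only training
#'
#' Full-batch Adam on the reconstruction loss; W3 untouched. The first
#' stage deliberately ignores the clustering objective so the latent space
#' settles on an information-preserving embedding before any cluster
#' signal is introduced.
#'
#' @param model A `latent_model`.
#' @param x Input matrix, width `d_in`.
#' @param cfg A [training_config()]; `cfg$epochs[1]` epochs are run unless
#'   `epochs` is given.
#' @param epochs Optional explicit epoch count.
#' @return The trained model with loss history appended.
#' @export
train_stage1_reconstruction <- function(model, x, cfg = training_config(),
                                        epochs = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(epochs)) epochs <- cfg$epochs[1L]
  if (epochs == 0L) return(model)
  opt <- adam_new(list(dim(model$W1), dim(model$W2)), cfg$learning_rate)
  params <- list(model$W1, model$W2)
  for (e in seq_len(epochs)) {
    z <- x %*% params[[1L]]
    xhat <- z %*% params[[2L]]
    err <- xhat - x
    l_rec <- mean(rowSums(err^2))
    if (!is.finite(l_rec))
      stop("non-finite reconstruction loss at epoch ", e)
    g_w2 <- (2 / n) * crossprod(z, err)
    g_w1 <- (2 / n) * crossprod(x, err %*% t(params[[2L]]))
    st <- adam_step(opt, params, list(g_w1, g_w2))
    opt <- st$opt; params <- st$params
    model$loss_history <- rbind(model$loss_history,
      data.frame(stage = "reconstruction", epoch = e, l_rec = l_rec,
                 l_clust = NA_real_, l_total = l_rec))
  }
  model$W1 <- params[[1L]]
  model$W2 <- params[[2L]]
  model
}

#' Stage 2: clustering-layer alignment (autoencoder frozen)
#'
#' Updates only W3 by descending the KL divergence between the one-hot
#' targets and the layer's soft assignments; W1 and W2 are byte-identical
#' before and after.
#'
#' @param model A `latent_model` (stage 1 trained).
#' @param x Input matrix.
#' @param y_targets One-hot n x K target matrix (refined mixture labels).
#' @param cfg A [training_config()].
#' @param epochs Optional explicit epoch count (default `cfg$epochs[2]`).
#' @return The model with W3 updated.
#' @export
train_stage2_cluster_alignment <- function(model, x, y_targets,
                                           cfg = training_config(),
                                           epochs = NULL) {
  x <- as.matrix(x); y <- as.matrix(y_targets)
  if (ncol(y) != model$K)
    stop("target width ", ncol(y), " does not match model K ", model$K)
  n <- nrow(x)
  if (is.null(epochs)) epochs <- cfg$epochs[2L]
  if (epochs == 0L) return(model)
  z <- encode(x, model)  # fixed: autoencoder frozen
  opt <- adam_new(list(dim(model$W3)), cfg$learning_rate)
  w3 <- model$W3
  for (e in seq_len(epochs)) {
    q <- softmax_rows(z %*% w3)
    l_clust <- kl_divergence(y, q)
    if (!is.finite(l_clust)) stop("non-finite clustering loss at epoch ", e)
    g_s <- (q - y) / n
    g_w3 <- crossprod(z, g_s)
    st <- adam_step(opt, list(w3), list(g_w3))
    opt <- st$opt; w3 <- st$params[[1L]]
    model$loss_history <- rbind(model$loss_history,
      data.frame(stage = "alignment", epoch = e, l_rec = NA_real_,
                 l_clust = l_clust, l_total = l_clust))
  }
  model$W3 <- w3
  model
}

#' Stage 3: joint fine-tuning
#'
#' Unfreezes all weights and minimizes
#' `lambda_rec * L_rec + lambda_clust * L_clust`. Retaining the
#' reconstruction term guards against embeddings that are separable but no
#' longer faithful to the data.
#'
#' @inheritParams train_stage2_cluster_alignment
#' @param epochs Optional explicit epoch count (default `cfg$epochs[3]`).
#' @return The model with all weights updated and both loss components
#'   recorded per epoch.
#' @export
train_stage3_joint <- function(model, x, y_targets, cfg = training_config(),
                               epochs = NULL) {
  x <- as.matrix(x); y <- as.matrix(y_targets)
  if (ncol(y) != model$K)
    stop("target width ", ncol(y), " does not match model K ", model$K)
  n <- nrow(x)
  if (is.null(epochs)) epochs <- cfg$epochs[3L]
  if (epochs == 0L) return(model)
  opt <- adam_new(list(dim(model$W1), dim(model$W2), dim(model$W3)),
                  cfg$learning_rate)
  params <- list(model$W1, model$W2, model$W3)
  lr_w <- cfg$lambda_rec; lc_w <- cfg$lambda_clust
  for (e in seq_len(epochs)) {
    z <- x %*% params[[1L]]
    xhat <- z %*% params[[2L]]
    err <- xhat - x
    q <- softmax_rows(z %*% params[[3L]])
    l_rec <- mean(rowSums(err^2))
    l_clust <- kl_divergence(y, q)
    l_total <- lr_w * l_rec + lc_w * l_clust
    if (!is.finite(l_total)) stop("non-finite loss at epoch ", e)
    g_s <- lc_w * (q - y) / n
    g_w3 <- crossprod(z, g_s)
    g_w2 <- lr_w * (2 / n) * crossprod(z, err)
    g_z <- lr_w * (2 / n) * err %*% t(params[[2L]]) +
      g_s %*% t(params[[3L]])
    g_w1 <- crossprod(x, g_z)
    st <- adam_step(opt, params, list(g_w1, g_w2, g_w3))
    opt <- st$opt; params <- st$params
    model$loss_history <- rbind(model$loss_history,
      data.frame(stage = "joint", epoch = e, l_rec = l_rec,
                 l_clust = l_clust, l_total = l_total))
  }
  model$W1 <- params[[1L]]
  model$W2 <- params[[2L]]
  model$W3 <- params[[3L]]
  model
}

#' Hill-climbing trainer (ablation only)
#'
#' Perturbs one weight tensor per step (round-robin over W1, W2, W3) with
#' additive Gaussian noise and accepts the perturbation iff the average
#' silhouette width of a density-based clustering of the latent embedding
#' strictly improves. Degenerate clusterings (fewer than two clusters)
#' score -1 and are never preferred over a valid split. Retained only to
#' reproduce the metaheuristic ablation; it is not part of the final
#' pipeline.
#'
#' @param model A `latent_model`.
#' @param x Input matrix.
#' @param iterations Number of perturbation steps.
#' @param eps,min_points Density-clustering radius and core-point
#'   threshold.
#' @param step_sd Perturbation scale; default 0.01.
#' @param seed Integer seed.
#' @return A list with the best-found `model` and the non-decreasing
#'   `fitness_trace`.
#' @export
hill_climb_train <- function(model, x, iterations = 50L, eps = 0.5,
                             min_points = 5L, step_sd = 0.01, seed = 0L) {
  x <- as.matrix(x)
  set.seed(as.integer(seed))
  fitness <- function(m) {
    z <- encode(x, m)
    lab <- dbscan_labels(z, eps, min_points)
    ok <- lab > 0L
    if (length(unique(lab[ok])) < 2L) return(-1)
    asw(z[ok, , drop = FALSE], lab[ok])
  }
  best <- fitness(model)
  trace <- best
  tensors <- c("W1", "W2", "W3")
  for (it in seq_len(iterations)) {
    cand <- model
    nm <- tensors[((it - 1L) %% 3L) + 1L]
    cand[[nm]] <- cand[[nm]] +
      matrix(stats::rnorm(length(cand[[nm]]), 0, step_sd),
             nrow(cand[[nm]]), ncol(cand[[nm]]))
    f <- fitness(cand)
    if (f > best) {
      best <- f
      model <- cand
    }
    trace <- c(trace, best)
  }
  list(model = model, fitness_trace = trace)
}

# Minimal density-based clustering (DBSCAN); 0 marks noise. Brute-force
# neighborhoods -- adequate at the spot counts this package targets.
dbscan_labels <- function(z, eps, min_points) {
  n <- nrow(z)
  d <- as.matrix(stats::dist(z))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_points
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      for (q in nbrs[[j]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Save / load a latent model as JSON
#'
#' Plain-text checkpoint of the three weight matrices, dimensions and loss
#' history.
#'
#' @param model A `latent_model`.
#' @param path Output path.
#' @return `path` (save) or the restored `latent_model` (load).
#' @export
save_model <- function(model, path) {
  obj <- list(W1 = model$W1, W2 = model$W2, W3 = model$W3,
              d_in = model$d_in, d_latent = model$d_latent, K = model$K,
              loss_history = model$loss_history)
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W1 = obj$W1, W2 = obj$W2, W3 = obj$W3,
                 d_in = as.integer(obj$d_in),
                 d_latent = as.integer(obj$d_latent), K = as.integer(obj$K),
                 loss_history = as.data.frame(obj$loss_history)),
            class = "latent_model")
}
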