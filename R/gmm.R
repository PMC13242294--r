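# Gaussian-mixture labeling of latent embeddings via EM.
#
# The final domain labels always come from a finite normal mixture fitted
# to the latent representation, not from the clustering layer. The default
# covariance family is a single full covariance shared by all components
# (the closest simple analogue of the equal-covariance mixture families),
# with per-component full or diagonal families available.

#' Gaussian mixture (EM) configuration
#'
#' @param covariance_model `"shared_full"` (default; one pooled full
#'   covariance), `"full"` (per component) or `"diagonal"`.
#' @param max_iter Maximum EM iterations. Default 300.
#' @param tol Convergence threshold on the log-likelihood change.
#'   Default 1e-6.
#' @param reg Ridge added to covariance diagonals. Default 1e-6.
#' @param n_init Number of k-means-seeded EM restarts; best log-likelihood
#'   wins. Default 5.
#' @param seed Integer seed; `NULL` defers to the caller.
#' @return A list of class `gmm_config`.
#' @export
gmm_config <- function(covariance_model = c("shared_full", "full", "diagonal"),
                       max_iter = 300L, tol = 1e-6, reg = 1e-6,
                       n_init = 5L, seed = NULL) {
  if (tol <= 0) stop("tol must be positive")
  if (reg < 0) stop("reg must be non-negative")
  structure(list(covariance_model = match.arg(covariance_model),
                 max_iter = as.integer(max_iter), tol = tol, reg = reg,
                 n_init = as.integer(n_init), seed = seed),
            class = "gmm_config")
}

#' Fit a Gaussian mixture to latent embeddings
#'
#' Runs EM to convergence from `n_init` k-means-seeded starts and keeps
#' the fit with the best log-likelihood. Hard labels are the argmax
#' responsibilities. Empty components are reported through
#' `n_effective_clusters`, never silently re-fitted.
#'
#' @param z Numeric n x d matrix of embeddings.
#' @param k Number of mixture components.
#' @param cfg A [gmm_config()].
#' @param seed Seed used when `cfg$seed` is `NULL`; default 0.
#' @return A list of class `cluster_result` with integer `labels` in
#'   1..K, `responsibilities` (rows sum to 1), `refined_labels`
#'   (initially equal to `labels`), `n_effective_clusters`, `loglik` and
#'   the per-iteration `loglik_trace` of the winning start.
#' @export
gmm_fit <- function(z, k, cfg = gmm_config(), seed = 0L) {
  z <- as.matrix(z)
  n <- nrow(z); d <- ncol(z)
  k <- as.integer(k)
  if (n <= k) stop("need more observations (", n, ") than components ", k)
  if (!is.null(cfg$seed)) seed <- cfg$seed
  if (k == 1L) {
    resp <- matrix(1, n, 1L)
    return(new_cluster_result(rep(1L, n), resp, loglik = NA_real_,
                              loglik_trace = numeric(0),
                              spot_ids = rownames(z)))
  }
  best <- NULL
  for (init in seq_len(cfg$n_init)) {
    set.seed(substream_seed(seed, paste0("gmm", init)))
    km <- suppressWarnings(stats::kmeans(z, centers = k, nstart = 1L,
                                         iter.max = 50L))
    fit <- tryCatch(gmm_em(z, k, km$cluster, cfg),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("EM failed for every start; a singular covariance despite ",
         "regularization -- try a larger reg or fewer components")
  labels <- max.col(best$resp, ties.method = "first")
  new_cluster_result(labels, best$resp, loglik = best$loglik,
                     loglik_trace = best$trace, spot_ids = rownames(z))
}

gmm_em <- function(z, k, hard_init, cfg) {
  n <- nrow(z); d <- ncol(z)
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), hard_init)] <- 1
  loglik <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(cfg$max_iter)) {
    # M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    pi_k <- nk / n
    mu <- crossprod(resp, z) / nk            # k x d
    covs <- m_step_cov(z, resp, mu, nk, cfg)
    # E step: per-component log densities
    logd <- matrix(0, n, k)
    for (j in seq_len(k)) {
      sig <- if (cfg$covariance_model == "shared_full") covs$shared else
        covs$per[[j]]
      logd[, j] <- log(pi_k[j]) + mvn_logpdf(z, mu[j, ], sig,
                                             diagonal = covs$diagonal)
    }
    mx <- apply(logd, 1L, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    new_ll <- sum(lse)
    resp <- exp(logd - lse)
    trace <- c(trace, new_ll)
    if (is.finite(loglik) && abs(new_ll - loglik) < cfg$tol) {
      loglik <- new_ll
      break
    }
    loglik <- new_ll
  }
  list(resp = resp, loglik = loglik, trace = trace)
}

m_step_cov <- function(z, resp, mu, nk, cfg) {
  d <- ncol(z); k <- ncol(resp)
  model <- cfg$covariance_model
  if (model == "shared_full") {
    s <- matrix(0, d, d)
    for (j in seq_len(k)) {
      c_j <- sweep(z, 2L, mu[j, ], "-")
      s <- s + crossprod(c_j * resp[, j], c_j)
    }
    s <- s / sum(nk) + diag(cfg$reg, d)
    list(shared = s, per = NULL, diagonal = FALSE)
  } else if (model == "full") {
    per <- lapply(seq_len(k), function(j) {
      c_j <- sweep(z, 2L, mu[j, ], "-")
      crossprod(c_j * resp[, j], c_j) / nk[j] + diag(cfg$reg, d)
    })
    list(shared = NULL, per = per, diagonal = FALSE)
  } else {
    per <- lapply(seq_len(k), function(j) {
      c_j <- sweep(z, 2L, mu[j, ], "-")
      colSums(c_j^2 * resp[, j]) / nk[j] + cfg$reg
    })
    list(shared = NULL, per = per, diagonal = TRUE)
  }
}

mvn_logpdf <- function(z, mu, sigma, diagonal = FALSE) {
  d <- ncol(z)
  c_z <- sweep(z, 2L, mu, "-")
  if (diagonal) {
    -0.5 * (d * log(2 * pi) + sum(log(sigma)) +
              rowSums(sweep(c_z^2, 2L, sigma, "/")))
  } else {
    ch <- tryCatch(chol(sigma),
                   error = function(e)
                     stop("singular covariance despite regularization; ",
                          "increase reg"))
    logdet <- 2 * sum(log(diag(ch)))
    w <- backsolve(ch, t(c_z), transpose = TRUE)
    -0.5 * (d * log(2 * pi) + logdet + colSums(w^2))
  }
}

new_cluster_result <- function(labels, resp, refined = NULL,
                               loglik = NA_real_, loglik_trace = numeric(0),
                               variant = NA_character_, provenance = NULL,
                               spot_ids = NULL) {
  structure(list(labels = as.integer(labels),
                 refined_labels = as.integer(if (is.null(refined)) labels
                                             else refined),
                 responsibilities = resp,
                 n_effective_clusters = length(unique(labels)),
                 loglik = loglik, loglik_trace = loglik_trace,
                 variant = variant, provenance = provenance,
                 spot_ids = spot_ids),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "cluster_result (%s): %d spots, %d effective cluster(s)\n",
    ifelse(is.na(x$variant), "gmm", x$variant), length(x$labels),
    x$n_effective_clusters))
  invisible(x)
}
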