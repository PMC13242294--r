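# Clustering quality metrics.
#
# Supervised agreement: ARI, NMI, homogeneity, completeness (all computed
# from the label contingency table; natural log throughout). Unsupervised
# spatial/cluster quality: average silhouette width, PAS (fraction of
# spots disagreeing with most of their spatial neighbors), CHAOS
# (within-cluster 1-NN spatial edge length), and Moran's I / Geary's C on
# the per-cluster one-hot indicators with row-normalized kNN weights.

#' Label contingency table
#'
#' @param labels_a,labels_b Two labelings of the same spots.
#' @return A list of class `contingency_table` with `counts`, `row_sums`,
#'   `col_sums` and `total`.
#' @export
contingency <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings have different lengths")
  tab <- table(factor(labels_a), factor(labels_b))
  counts <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  structure(list(counts = counts, row_sums = rowSums(counts),
                 col_sums = colSums(counts), total = sum(counts)),
            class = "contingency_table")
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, adjusted for chance:
#' 0 in expectation for random labelings, exactly 1 for identical
#' partitions; invariant to label permutations.
#'
#' @param labels_a,labels_b Two labelings of the same n >= 2 spots.
#' @return A number <= 1.
#' @export
ari <- function(labels_a, labels_b) {
  ct <- contingency(labels_a, labels_b)
  n <- ct$total
  if (n < 2) stop("ARI is undefined for fewer than 2 spots")
  sum_ij <- sum(choose(ct$counts, 2))
  sum_a <- sum(choose(ct$row_sums, 2))
  sum_b <- sum(choose(ct$col_sums, 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' `2 I(U; V) / (H(U) + H(V))` with natural logarithms; defined as 1 when
#' both labelings are single-cluster (zero entropy).
#'
#' @param labels_a,labels_b Two labelings of the same spots.
#' @return A number in \[0, 1\].
#' @export
nmi <- function(labels_a, labels_b) {
  ct <- contingency(labels_a, labels_b)
  n <- ct$total
  if (n < 2) stop("NMI is undefined for fewer than 2 spots")
  p_ab <- ct$counts / n
  p_a <- ct$row_sums / n
  p_b <- ct$col_sums / n
  h_a <- -sum(ifelse(p_a > 0, p_a * log(p_a), 0))
  h_b <- -sum(ifelse(p_b > 0, p_b * log(p_b), 0))
  if (h_a + h_b == 0) return(1)
  outer_p <- outer(p_a, p_b)
  mi <- sum(ifelse(p_ab > 0, p_ab * log(p_ab / outer_p), 0))
  2 * mi / (h_a + h_b)
}

#' Homogeneity and completeness
#'
#' Homogeneity = 1 - H(truth | pred) / H(truth): each predicted cluster
#' holds members of a single true class. Completeness = 1 - H(pred |
#' truth) / H(pred): each true class lands in a single predicted cluster.
#' Degenerate zero-entropy cases yield 1.
#'
#' @param truth,pred Two labelings of the same spots.
#' @return Named numeric vector `c(homogeneity = , completeness = )`.
#' @export
homogeneity_completeness <- function(truth, pred) {
  ct <- contingency(truth, pred)
  n <- ct$total
  p_ab <- ct$counts / n
  p_t <- ct$row_sums / n
  p_p <- ct$col_sums / n
  h_t <- -sum(ifelse(p_t > 0, p_t * log(p_t), 0))
  h_p <- -sum(ifelse(p_p > 0, p_p * log(p_p), 0))
  # H(truth | pred) = H(joint) - H(pred)
  h_joint <- -sum(ifelse(p_ab > 0, p_ab * log(p_ab), 0))
  hom <- if (h_t == 0) 1 else 1 - (h_joint - h_p) / h_t
  com <- if (h_p == 0) 1 else 1 - (h_joint - h_t) / h_p
  c(homogeneity = hom, completeness = com)
}

#' Average silhouette width
#'
#' Mean over spots of `(b - a) / max(a, b)` with Euclidean distances,
#' where a is the mean within-cluster distance and b the smallest mean
#' distance to another cluster. Spots in singleton clusters contribute 0.
#'
#' @param features Numeric n x d feature matrix.
#' @param labels Cluster labels; at least two non-empty clusters.
#' @return A number in \[-1, 1\].
#' @export
asw <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(features))
    stop("labels and features cover different spot sets")
  k <- max(labels)
  if (k < 2L) stop("silhouette is undefined for a single cluster")
  d <- as.matrix(stats::dist(features))
  sizes <- tabulate(labels, k)
  # mean distance from every spot to every cluster
  md <- vapply(seq_len(k), function(c)
    rowSums(d[, labels == c, drop = FALSE]) / sizes[c], numeric(nrow(d)))
  s <- numeric(length(labels))
  for (i in seq_along(labels)) {
    ci <- labels[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- md[i, ci] * sizes[ci] / (sizes[ci] - 1L)  # exclude self
    b <- min(md[i, -ci])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Percentage of abnormal spots (PAS)
#'
#' Fraction of spots whose label differs from at least `threshold` of
#' their `n_neighbors` nearest spatial neighbors; lower means spatially
#' smoother domains.
#'
#' @param labels Cluster labels.
#' @param coords n x 2 coordinate matrix; n must exceed `n_neighbors`.
#' @param n_neighbors Spatial neighborhood size. Default 10.
#' @param threshold Disagreement count defining "abnormal". Default 6.
#' @return A number in \[0, 1\].
#' @export
pas <- function(labels, coords, n_neighbors = 10L, threshold = 6L) {
  coords <- as.matrix(coords)
  if (nrow(coords) <= n_neighbors)
    stop("PAS needs more than ", n_neighbors, " spots")
  g <- build_knn_graph(coords, n_neighbors)
  labels <- as.integer(factor(labels))
  nb <- matrix(labels[g$neighbor_indices], nrow = length(labels))
  diff_count <- rowSums(nb != labels)
  mean(diff_count >= threshold)
}

#' CHAOS spatial disorder statistic
#'
#' On z-scored coordinates, computes for each cluster the mean edge
#' length of its within-cluster 1-nearest-neighbor graph, then returns
#' the spot-count-weighted mean across clusters. Lower values indicate
#' spatially smoother, more contiguous domains. Singleton clusters are
#' excluded with a warning.
#'
#' @param labels Cluster labels.
#' @param coords n x 2 coordinate matrix.
#' @return A non-negative number.
#' @export
chaos <- function(labels, coords) {
  coords <- as.matrix(coords)
  sds <- apply(coords, 2L, stats::sd)
  sds[sds == 0] <- 1
  z <- sweep(sweep(coords, 2L, colMeans(coords), "-"), 2L, sds, "/")
  labels <- as.integer(factor(labels))
  total <- 0
  weight <- 0
  for (c in unique(labels)) {
    idx <- which(labels == c)
    if (length(idx) < 2L) {
      warning("singleton cluster ", c, " excluded from CHAOS")
      next
    }
    d <- as.matrix(stats::dist(z[idx, , drop = FALSE]))
    diag(d) <- Inf
    nn1 <- apply(d, 1L, min)
    total <- total + sum(nn1)
    weight <- weight + length(idx)
  }
  if (weight == 0) stop("CHAOS needs at least one cluster with >= 2 spots")
  total / weight
}

#' Moran's I and Geary's C for a labeling
#'
#' Scores each cluster's one-hot indicator with row-normalized kNN
#' weights: Moran's I = (n / W) * sum(w_ij (x_i - xbar)(x_j - xbar)) /
#' sum((x_i - xbar)^2), Geary's C = ((n - 1) / (2 W)) *
#' sum(w_ij (x_i - x_j)^2) / sum((x_i - xbar)^2); cluster-size-weighted
#' means over clusters are returned. I near 1 / C near 0 indicate
#' spatially coherent domains.
#'
#' @param labels Cluster labels; at least two clusters.
#' @param graph A [build_knn_graph()] result over the same spots.
#' @return Named numeric vector `c(moran_i = , geary_c = )`.
#' @export
spatial_autocorrelation <- function(labels, graph) {
  labels <- as.integer(factor(labels))
  n <- length(labels)
  if (n != nrow(graph$neighbor_indices))
    stop("labels and neighbor graph cover different spot sets")
  k_cl <- max(labels)
  if (k_cl < 2L)
    stop("spatial autocorrelation of a constant labeling is undefined")
  k <- graph$k
  w <- 1 / k              # row-normalized weights; sum(W) = n
  sw <- n
  sizes <- tabulate(labels, k_cl)
  morans <- gearys <- numeric(k_cl)
  for (c in seq_len(k_cl)) {
    x <- as.numeric(labels == c)
    xc <- x - mean(x)
    ss <- sum(xc^2)
    nb <- matrix(x[graph$neighbor_indices], nrow = n)
    cross <- sum(xc * w * rowSums(matrix(xc[graph$neighbor_indices],
                                         nrow = n)))
    sqdiff <- sum(w * rowSums((nb - x)^2))
    morans[c] <- (n / sw) * cross / ss
    gearys[c] <- ((n - 1) / (2 * sw)) * sqdiff / ss
  }
  c(moran_i = sum(morans * sizes) / n, geary_c = sum(gearys * sizes) / n)
}

#' Full metric report for one labeling
#'
#' Computes the five unsupervised metrics (ASW on the supplied feature
#' space, PAS and CHAOS on the coordinates, Moran's I and Geary's C on the
#' kNN graph) and, when truth labels are given, the supervised agreement
#' metrics.
#'
#' @param labels Predicted labels.
#' @param coords n x 2 spatial coordinates.
#' @param features Feature matrix for the silhouette (e.g. a latent
#'   embedding or shared PCA space).
#' @param truth Optional ground-truth labels.
#' @param k_neighbors Spatial graph size for Moran/Geary. Default 6.
#' @return Named numeric vector of metric values.
#' @export
metric_report <- function(labels, coords, features, truth = NULL,
                          k_neighbors = 6L) {
  graph <- build_knn_graph(coords, k_neighbors)
  sa <- spatial_autocorrelation(labels, graph)
  out <- c(ASW = asw(features, labels),
           PAS = pas(labels, coords),
           CHAOS = chaos(labels, coords),
           MoranI = unname(sa["moran_i"]),
           GearyC = unname(sa["geary_c"]))
  if (!is.null(truth)) {
    hc <- homogeneity_completeness(truth, labels)
    out <- c(ARI = ari(truth, labels), NMI = nmi(truth, labels),
             homogeneity = unname(hc["homogeneity"]),
             completeness = unname(hc["completeness"]), out)
  }
  out
}

#' Shared PCA feature space for cross-method comparison
#'
#' Projects the normalized expression matrix onto its leading principal
#' components so external candidate labelings are scored on identical
#' features.
#'
#' @param dataset A `spatial_dataset`.
#' @param n_components Number of components. Default 20.
#' @param normalization A [normalization_config()].
#' @return An n x `n_components` score matrix.
#' @export
shared_feature_space <- function(dataset, n_components = 20L,
                                 normalization = normalization_config()) {
  x <- normalize_expression(dataset$counts, normalization)
  n_components <- min(n_components, dim(x) - 1L)
  pc <- stats::prcomp(x, rank. = n_components, center = TRUE, scale. = FALSE)
  pc$x
}
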