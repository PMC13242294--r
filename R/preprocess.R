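# Preprocessing: scatter gene filtration, variance-stabilized HVG
# selection, the four-step normalization (library size -> log1p -> z-score
# -> clip), spatial kNN graphs, neighborhood features, feature fusion, and
# informative-location selection.

#' Scatter filtration configuration
#'
#' Controls the iterative removal of broadly expressed "background" genes.
#' Per iteration, `sample_size` spots are sampled without replacement, each
#' sampled spot contributes its top-`top_l` expressed genes, and the
#' `r = floor(knob / 10)` genes occurring most often across the sample are
#' removed.
#'
#' @param knob Removal-intensity knob; `floor(knob / 10)` genes are removed
#'   per iteration. Default 100 (10 genes per iteration).
#' @param n_iterations Number of removal iterations T. Default 10.
#' @param sample_size Spots sampled per iteration; `NULL` (default) means
#'   `max(50, ceiling(0.1 * n_spots))`, resolved at run time.
#' @param top_l Number of top-expressed genes counted per sampled spot.
#'   Default 50.
#' @param seed Integer seed for the spot sampling; `NULL` defers to the
#'   caller's substream.
#' @return A list of class `filtration_config`.
#' @export
filtration_config <- function(knob = 100L, n_iterations = 10L,
                              sample_size = NULL, top_l = 50L, seed = NULL) {
  if (knob < 10) stop("knob must be >= 10 so that at least one gene is removed")
  if (n_iterations < 0) stop("n_iterations must be >= 0")
  if (top_l < 1) stop("top_l must be >= 1")
  structure(list(knob = as.integer(knob),
                 n_iterations = as.integer(n_iterations),
                 sample_size = sample_size, top_l = as.integer(top_l),
                 seed = seed),
            class = "filtration_config")
}

#' Normalization configuration
#'
#' @param target_sum Per-spot library-size scaling target s. Default 1e4.
#' @param clip_low,clip_high Clipping interval \[a, b\] applied after
#'   z-scoring. Defaults -10 and 10.
#' @param mean_mode `"per_gene"` (default) centers each gene on its own
#'   mean; `"global"` uses one scalar mean/sd for the whole matrix.
#' @return A list of class `normalization_config`.
#' @export
normalization_config <- function(target_sum = 1e4, clip_low = -10,
                                 clip_high = 10,
                                 mean_mode = c("per_gene", "global")) {
  if (target_sum <= 0) stop("target_sum must be positive")
  if (clip_low >= clip_high) stop("clip_low must be below clip_high")
  structure(list(target_sum = target_sum, clip_low = clip_low,
                 clip_high = clip_high, mean_mode = match.arg(mean_mode)),
            class = "normalization_config")
}

#' Build an exact Euclidean k-nearest-neighbor graph
#'
#' Self-neighbors are excluded; ties in distance are broken by spot index
#' so the graph is a deterministic function of the coordinates.
#'
#' @param coords Numeric matrix, one row per spot, two (or more) columns.
#' @param k Number of neighbors; must be below the number of spots.
#' @return A list of class `neighbor_graph` with `k`, `neighbor_indices`
#'   (n x k integer matrix) and `distances` (n x k, row-wise
#'   non-decreasing).
#' @export
build_knn_graph <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- as.integer(k)
  if (n <= k) stop("need more spots (", n, ") than neighbors k = ", k)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    o <- order(d[i, ], seq_len(n))[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- d[i, o]
  }
  structure(list(k = k, neighbor_indices = idx, distances = dst),
            class = "neighbor_graph")
}

#' Scatter filtration of broadly expressed genes
#'
#' Iteratively removes genes that recur among the top-L expressed genes of
#' randomly sampled spots. Such ubiquitously top-ranked genes are typically
#' housekeeping/background programs that dilute the spatial signal. Each
#' iteration samples `sample_size` spots without replacement, scores every
#' currently retained gene by its occurrence count among the sampled spots'
#' top-`top_l` sets, and removes the `floor(knob / 10)` highest-scoring
#' genes. Occurrence-score ties at the removal boundary are broken by
#' higher total expression, then by gene index, so the result is
#' deterministic under the seed.
#'
#' @param dataset A `spatial_dataset` or a spots-by-genes numeric matrix.
#' @param config A [filtration_config()].
#' @param seed Seed used when `config$seed` is `NULL`; default 0.
#' @return A list of class `filtration_result` with `retained_genes`
#'   (column indices into the input, ascending), `removed_per_iteration`
#'   (list of index vectors, each of length r), `occurrence_scores` (list
#'   of named per-iteration score vectors) and `sampled_spots`.
#' @export
scatter_filtration <- function(dataset, config = filtration_config(),
                               seed = 0L) {
  x <- if (inherits(dataset, "spatial_dataset")) dataset$counts else
    as.matrix(dataset)
  n <- nrow(x)
  p <- ncol(x)
  r <- config$knob %/% 10L
  t_iter <- config$n_iterations
  if (t_iter * r >= p - 1L)
    stop("configuration would exhaust the gene set: T * r = ", t_iter * r,
         " but only ", p, " genes are present")
  m <- config$sample_size
  if (is.null(m)) m <- max(50L, ceiling(0.1 * n))
  m <- min(as.integer(m), n)
  top_l <- config$top_l
  if (!is.null(config$seed)) seed <- config$seed

  totals <- colSums(x)
  current <- seq_len(p)
  removed <- vector("list", t_iter)
  scores <- vector("list", t_iter)
  sampled <- vector("list", t_iter)
  for (t in seq_len(t_iter)) {
    if (length(current) <= top_l)
      stop("top_l exceeds the number of retained genes at iteration ", t)
    set.seed(substream_seed(seed, paste0("scatter", t)))
    s_t <- sort(sample.int(n, m))
    counts <- integer(length(current))
    for (i in s_t) {
      xi <- x[i, current]
      top <- order(xi, -seq_along(xi), decreasing = TRUE)[seq_len(top_l)]
      counts[top] <- counts[top] + 1L
    }
    # remove the r highest-occurrence genes; ties by total expression,
    # then by gene index
    o <- order(-counts, -totals[current], current)[seq_len(r)]
    rem <- sort(current[o])
    removed[[t]] <- rem
    sc <- counts
    names(sc) <- as.character(current)
    scores[[t]] <- sc
    sampled[[t]] <- s_t
    current <- setdiff(current, rem)
  }
  structure(list(retained_genes = current, removed_per_iteration = removed,
                 occurrence_scores = scores, sampled_spots = sampled,
                 r = r, config = config),
            class = "filtration_result")
}

#' Select highly variable genes (variance-stabilizing ranking)
#'
#' Ranks genes by their standardized variance after fitting a
#' mean-variance trend in log10 space (loess, degree 2, span 0.3) on the
#' raw counts and clipping standardized counts at sqrt(n) — the usual
#' variance-stabilizing HVG recipe for UMI data. Zero-variance genes are
#' ranked last.
#'
#' @param counts Spots-by-genes numeric matrix of raw counts.
#' @param n_top Number of genes to return.
#' @return Integer vector of column indices, most variable first.
#' @export
select_hvg <- function(counts, n_top) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  p <- ncol(counts)
  if (n_top > p) stop("n_top exceeds the gene count")
  if (all(counts == 0)) stop("all-zero count matrix")
  mu <- colMeans(counts)
  v <- apply(counts, 2L, stats::var)
  usable <- mu > 0 & v > 0
  std_var <- numeric(p)
  if (sum(usable) >= 4L) {
    fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]),
                        span = 0.3, degree = 2,
                        control = stats::loess.control(surface = "direct"))
    exp_sd <- sqrt(10^stats::predict(fit, log10(mu[usable])))
    exp_sd[!is.finite(exp_sd) | exp_sd <= 0] <- sqrt(v[usable])[
      !is.finite(exp_sd) | exp_sd <= 0]
    clip <- sqrt(n)
    sub <- counts[, usable, drop = FALSE]
    z <- sweep(sub, 2L, mu[usable], "-")
    z <- sweep(z, 2L, exp_sd, "/")
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    std_var[usable] <- colSums(z^2) / (n - 1)
  } else {
    std_var[usable] <- v[usable]  # too few genes to fit a trend
  }
  order(-std_var, seq_len(p))[seq_len(n_top)]
}

#' Four-step expression normalization
#'
#' Applies, in order: per-spot library-size scaling to `target_sum`,
#' log1p, per-gene z-scoring (zero-variance genes map to 0), and clipping
#' to \[clip_low, clip_high\].
#'
#' @param counts Spots-by-genes numeric matrix; every spot must have a
#'   positive total count.
#' @param config A [normalization_config()].
#' @return Numeric matrix of the same shape.
#' @export
normalize_expression <- function(counts, config = normalization_config()) {
  x <- as.matrix(counts)
  totals <- rowSums(x)
  if (any(totals <= 0)) {
    bad <- which(totals <= 0)[1L]
    nm <- rownames(x)[bad]
    stop("spot ", if (!is.null(nm)) nm else bad, " has zero total count")
  }
  x <- x / totals * config$target_sum
  x <- log1p(x)
  if (config$mean_mode == "per_gene") {
    mu <- colMeans(x)
    sd <- apply(x, 2L, stats::sd)
    sd[sd == 0] <- 1  # zero-variance genes -> centered to exactly 0
    x <- sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
  } else {
    x <- (x - mean(x)) / stats::sd(x)
  }
  pmin(pmax(x, config$clip_low), config$clip_high)
}

#' Neighborhood mean expression features
#'
#' For each spot, concatenates its own expression vector with the mean
#' expression over its spatial neighbors, producing an n x 2p matrix.
#'
#' @param x Spots-by-genes numeric matrix.
#' @param graph A [build_knn_graph()] result over the same spots.
#' @return Numeric matrix with `2 * ncol(x)` columns.
#' @export
neighborhood_features <- function(x, graph) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(graph$neighbor_indices))
    stop("feature matrix and neighbor graph cover different spot sets")
  acc <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(graph$k))
    acc <- acc + x[graph$neighbor_indices[, j], , drop = FALSE]
  nb <- acc / graph$k
  colnames(nb) <- if (!is.null(colnames(x))) paste0(colnames(x), "_nbr")
  cbind(x, nb)
}

#' Fuse feature blocks by column-wise concatenation
#'
#' @param blocks List of numeric matrices sharing the row count.
#' @param scale If `TRUE`, z-score every column of every block first
#'   (zero-variance columns map to 0).
#' @return The concatenated matrix, columns in block order.
#' @export
fuse_features <- function(blocks, scale = FALSE) {
  if (!length(blocks)) stop("no feature blocks given")
  n <- vapply(blocks, nrow, integer(1))
  if (length(unique(n)) != 1L)
    stop("feature blocks have mismatched spot counts: ",
         paste(n, collapse = ", "))
  if (scale) {
    blocks <- lapply(blocks, function(b) {
      b <- as.matrix(b)
      sd <- apply(b, 2L, stats::sd)
      sd[sd == 0] <- 1
      sweep(sweep(b, 2L, colMeans(b), "-"), 2L, sd, "/")
    })
  }
  do.call(cbind, lapply(blocks, as.matrix))
}

#' Select informative locations
#'
#' Ranks spots by total count (a simple informativeness proxy; bead-based
#' assays in particular carry many low-signal background locations) and
#' keeps the top `ceiling(keep_fraction * n)`. Coordinates, identifiers,
#' truth labels and extra feature blocks are subset consistently.
#'
#' @param dataset A `spatial_dataset`.
#' @param keep_fraction Fraction of spots to keep, in (0, 1].
#' @param rank_fun Optional alternative ranking: a function mapping the
#'   dataset to one numeric score per spot (higher = kept first).
#' @return A `spatial_dataset` restricted to the selected spots, in their
#'   original order.
#' @export
select_locations <- function(dataset, keep_fraction, rank_fun = NULL) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  n <- nrow(dataset$counts)
  score <- if (is.null(rank_fun)) rowSums(dataset$counts) else
    rank_fun(dataset)
  n_keep <- ceiling(keep_fraction * n)
  keep <- sort(order(-score, seq_len(n))[seq_len(n_keep)])
  subset_spots(dataset, keep)
}
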