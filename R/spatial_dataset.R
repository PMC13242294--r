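# Core data container: a spot-by-gene expression matrix with planar
# coordinates, identifiers, optional ground-truth labels (evaluation only)
# and optional extra feature blocks (e.g. precomputed image embeddings).

#' Construct a spatial transcriptomics dataset
#'
#' Bundles a spot-by-gene count matrix with spot coordinates, identifiers
#' and optional ground-truth domain labels into a validated container used
#' by every other function in the package.
#'
#' @param counts Numeric matrix (or Matrix sparse matrix, coerced to dense),
#'   spots in rows and genes in columns. Entries must be non-negative.
#' @param coords Numeric matrix or data frame with one row per spot and two
#'   columns (x, y); lattice or pixel units.
#' @param spot_ids Character vector of unique spot identifiers. Defaults to
#'   the row names of `counts`.
#' @param gene_ids Character vector of unique gene identifiers. Defaults to
#'   the column names of `counts`.
#' @param truth_labels Optional vector of ground-truth domain labels, one
#'   per spot. Used only for evaluation, never for fitting.
#' @param extra_features Optional named list of numeric matrices, each with
#'   one row per spot (e.g. image embeddings).
#' @return An object of class `spatial_dataset`.
#' @examples
#' x <- matrix(rpois(12, 5), 4, 3)
#' ds <- spatial_dataset(x, cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)))
#' dim(ds$counts)
#' @export
spatial_dataset <- function(counts, coords, spot_ids = NULL, gene_ids = NULL,
                            truth_labels = NULL, extra_features = NULL) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(spot_ids)) {
    spot_ids <- rownames(counts)
    if (is.null(spot_ids)) spot_ids <- sprintf("spot_%04d", seq_len(nrow(counts)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(counts)
    if (is.null(gene_ids)) gene_ids <- sprintf("gene_%04d", seq_len(ncol(counts)))
  }
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(coords) != nrow(counts)) stop("coords must have one row per spot")
  if (length(spot_ids) != nrow(counts))
    stop("spot_ids length must equal nrow(counts)")
  if (length(gene_ids) != ncol(counts))
    stop("gene_ids length must equal ncol(counts)")
  rownames(counts) <- spot_ids
  colnames(counts) <- gene_ids
  rownames(coords) <- spot_ids
  x <- structure(
    list(counts = counts, coords = coords, spot_ids = spot_ids,
         gene_ids = gene_ids, truth_labels = truth_labels,
         extra_features = extra_features),
    class = "spatial_dataset")
  validate_spatial_dataset(x)
  x
}

#' Validate a spatial_dataset
#'
#' Checks the container invariants: non-negative counts, consistent
#' dimensions, unique identifiers, and truth-label length.
#'
#' @param x A `spatial_dataset`.
#' @return `x`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_spatial_dataset <- function(x) {
  stopifnot(inherits(x, "spatial_dataset"))
  if (any(x$counts < 0)) stop("counts must be non-negative")
  n <- nrow(x$counts)
  if (length(x$spot_ids) != n) stop("spot_ids length must equal nrow(counts)")
  if (nrow(x$coords) != n) stop("coords must have one row per spot")
  if (ncol(x$coords) != 2L) stop("coords must have exactly two columns (x, y)")
  if (length(x$gene_ids) != ncol(x$counts))
    stop("gene_ids length must equal ncol(counts)")
  if (anyDuplicated(x$spot_ids)) stop("duplicate spot_ids")
  if (anyDuplicated(x$gene_ids)) stop("duplicate gene_ids")
  if (!is.null(x$truth_labels) && length(x$truth_labels) != n)
    stop("truth_labels must have one entry per spot")
  if (!is.null(x$extra_features)) {
    for (nm in names(x$extra_features)) {
      if (nrow(x$extra_features[[nm]]) != n)
        stop("extra feature block '", nm, "' must have one row per spot")
    }
  }
  invisible(x)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d spots x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$truth_labels))
    cat(sprintf("  truth labels: %d domains\n",
                length(unique(x$truth_labels))))
  if (!is.null(x$extra_features))
    cat(sprintf("  extra feature blocks: %s\n",
                paste(names(x$extra_features), collapse = ", ")))
  invisible(x)
}

#' Subset a dataset by spots
#'
#' Keeps the given spots (by index), subsetting counts, coordinates,
#' identifiers, truth labels and extra feature blocks consistently.
#'
#' @param dataset A `spatial_dataset`.
#' @param idx Integer vector of spot indices to keep.
#' @return A `spatial_dataset` restricted to the selected spots.
#' @export
subset_spots <- function(dataset, idx) {
  spatial_dataset(
    dataset$counts[idx, , drop = FALSE],
    dataset$coords[idx, , drop = FALSE],
    spot_ids = dataset$spot_ids[idx],
    gene_ids = dataset$gene_ids,
    truth_labels = if (!is.null(dataset$truth_labels)) dataset$truth_labels[idx],
    extra_features = if (!is.null(dataset$extra_features))
      lapply(dataset$extra_features, function(b) b[idx, , drop = FALSE]))
}

#' Subset a dataset by genes
#'
#' @param dataset A `spatial_dataset`.
#' @param idx Integer vector of gene (column) indices to keep.
#' @return A `spatial_dataset` restricted to the selected genes.
#' @export
subset_genes <- function(dataset, idx) {
  spatial_dataset(
    dataset$counts[, idx, drop = FALSE],
    dataset$coords,
    spot_ids = dataset$spot_ids,
    gene_ids = dataset$gene_ids[idx],
    truth_labels = dataset$truth_labels,
    extra_features = dataset$extra_features)
}

# --- configuration -----------------------------------------------------

#' Top-level run configuration
#'
#' Collects the choices shared by the pipeline variants: which variant to
#' run, the number of clusters K, the latent dimension, the spatial
#' neighbor count, the master seed, and the nested per-stage
#' configurations. All package randomness flows from `seed`, expanded into
#' deterministic per-stage substreams, so a run is reproducible given
#' (inputs, config).
#'
#' @param variant One of `"G"`, `"GS"`, `"GN"`, `"Scatter"`, `"ACT"`,
#'   `"FACT"`.
#' @param n_clusters Number of spatial domains K (>= 2).
#' @param latent_dim Latent dimension of the autoencoder; default 32.
#' @param k_neighbors Spatial kNN neighborhood size; default 6, matching
#'   the hexagonal Visium layout.
#' @param n_hvg Number of highly variable genes retained; default 2000
#'   (capped at the gene count at run time).
#' @param seed Master integer seed.
#' @param filtration,normalization,training,gmm Nested stage
#'   configurations; see [filtration_config()], [normalization_config()],
#'   [training_config()], [gmm_config()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(variant = "ACT", n_clusters = 7, latent_dim = 32,
                       k_neighbors = 6, n_hvg = 2000, seed = 0L,
                       filtration = filtration_config(),
                       normalization = normalization_config(),
                       training = training_config(),
                       gmm = gmm_config()) {
  variant <- match.arg(variant, c("G", "GS", "GN", "Scatter", "ACT", "FACT"))
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (latent_dim < 1) stop("latent_dim must be >= 1")
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  structure(list(variant = variant, n_clusters = as.integer(n_clusters),
                 latent_dim = as.integer(latent_dim),
                 k_neighbors = as.integer(k_neighbors),
                 n_hvg = as.integer(n_hvg), seed = as.integer(seed),
                 filtration = filtration, normalization = normalization,
                 training = training, gmm = gmm),
            class = "run_config")
}

# Deterministic substream seed for a named pipeline stage. Keeps the
# derived seed strictly below 2^31 so it remains a valid R integer.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}
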