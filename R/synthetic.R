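# Synthetic spatial transcriptomics generator.
#
# Emulates the structure of spot-based cortex-like tissue: a hexagonal
# offset lattice (odd rows shifted by half a spot, row spacing sqrt(3)/2,
# so Euclidean 6-NN reproduces Visium adjacency), laminar domains
# stacked along y with optional sine-warped boundaries, domain-specific
# marker gene programs, ubiquitous high-expression housekeeping genes,
# and negative-binomial counts with log-normal library-size variation.

#' Simulation configuration
#'
#' Defaults describe a modest cortex-like section: a 30 x 30 lattice with
#' four laminar bands, 200 genes of which 10 per domain are markers with a
#' log2 fold change of 2 and 20 are housekeeping genes at ten times the
#' baseline mean everywhere, negative-binomial counts (dispersion size 2,
#' i.e. clearly overdispersed, as in spot-level UMI data) and a 0.3
#' log-normal sigma of per-spot depth.
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @param n_domains Number of laminar bands K_true.
#' @param curvature Sine amplitude (in row-spacing units) warping the
#'   band boundaries; 0 gives straight laminae.
#' @param n_genes Total gene count.
#' @param n_markers_per_domain Markers per domain.
#' @param n_housekeeping Ubiquitous high-expression genes.
#' @param marker_log2_fc Marker effect size (log2 fold change in-domain).
#' @param baseline_mean Baseline negative-binomial mean per gene.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param libsize_sigma Log-normal sigma of the per-spot depth factor.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_rows = 30L, n_cols = 30L, n_domains = 4L,
                       curvature = 0, n_genes = 200L,
                       n_markers_per_domain = 10L, n_housekeeping = 20L,
                       marker_log2_fc = 2, baseline_mean = 5,
                       dispersion = 2, libsize_sigma = 0.3, seed = 0L) {
  if (n_markers_per_domain * n_domains + n_housekeeping > n_genes)
    stop("marker and housekeeping genes exceed n_genes")
  if (marker_log2_fc < 0) stop("marker_log2_fc must be >= 0")
  if (baseline_mean <= 0 || dispersion <= 0)
    stop("baseline_mean and dispersion must be positive")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_domains = as.integer(n_domains), curvature = curvature,
                 n_genes = as.integer(n_genes),
                 n_markers_per_domain = as.integer(n_markers_per_domain),
                 n_housekeeping = as.integer(n_housekeeping),
                 marker_log2_fc = marker_log2_fc,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 libsize_sigma = libsize_sigma, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a tissue section
#'
#' Generates a hexagonal-lattice [spatial_dataset()] with planted laminar
#' domains (set as `truth_labels`). Counts are negative binomial with
#' mean `baseline * 2^(log2_fc)` for a marker inside its domain,
#' `10 * baseline` for housekeeping genes everywhere, and `baseline`
#' otherwise, all multiplied by a log-normal per-spot depth factor.
#' Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A `spatial_dataset` with truth labels; gene ids are prefixed
#'   `marker<d>_`, `hk_` or `noise_` so tests can address the programs.
#' @export
simulate_tissue <- function(config = sim_config()) {
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols
  n <- nr * nc
  k <- config$n_domains
  row_i <- rep(seq_len(nr) - 1L, each = nc)
  col_j <- rep(seq_len(nc) - 1L, times = nr)
  x <- col_j + 0.5 * (row_i %% 2L)
  y <- row_i * sqrt(3) / 2
  # laminar bands along y, optionally sine-warped along x
  height <- max(y) + 1e-9
  warp <- config$curvature * sin(2 * pi * x / max(x + 1e-9)) * sqrt(3) / 2
  band <- floor((y + warp) / height * k)
  band <- pmin(pmax(band, 0), k - 1L) + 1L
  # gene programs; per-gene baseline means are log-normally spread around
  # baseline_mean (real transcriptomes span orders of magnitude -- a flat
  # baseline would let the HVG mean-variance trend absorb the markers)
  ng <- config$n_genes
  nm <- config$n_markers_per_domain
  nh <- config$n_housekeeping
  gene_ids <- character(ng)
  base_g <- config$baseline_mean * 2^stats::rnorm(ng, 0, 1)
  mu_gene <- matrix(base_g, n, ng, byrow = TRUE)  # spot x gene means
  g <- 0L
  for (d in seq_len(k)) {
    for (j in seq_len(nm)) {
      g <- g + 1L
      gene_ids[g] <- sprintf("marker%d_%02d", d, j)
      mu_gene[band == d, g] <- base_g[g] * 2^config$marker_log2_fc
    }
  }
  for (j in seq_len(nh)) {
    g <- g + 1L
    gene_ids[g] <- sprintf("hk_%02d", j)
    mu_gene[, g] <- 10 * config$baseline_mean
  }
  if (g < ng) gene_ids[(g + 1L):ng] <- sprintf("noise_%03d", seq_len(ng - g))
  depth <- exp(stats::rnorm(n, 0, config$libsize_sigma))
  mu <- mu_gene * depth
  counts <- matrix(stats::rnbinom(n * ng, size = config$dispersion,
                                  mu = mu), n, ng)
  colnames(counts) <- gene_ids
  spatial_dataset(counts, cbind(x = x, y = y),
                  spot_ids = sprintf("s%04d", seq_len(n)),
                  gene_ids = gene_ids, truth_labels = band)
}

#' Corrupted candidate labelings for ensemble tests
#'
#' For each corruption rate rho, copies the truth labels and relabels a
#' fraction rho of spots uniformly at random over 1..K_true.
#'
#' @param dataset A `spatial_dataset` with truth labels.
#' @param qualities Numeric vector of corruption rates in \[0, 1\].
#' @param seed Integer seed.
#' @return Named list of label vectors (`rho_<rate>`).
#' @export
make_candidate_labelings <- function(dataset, qualities, seed = 0L) {
  if (is.null(dataset$truth_labels)) stop("dataset has no truth labels")
  if (any(qualities < 0 | qualities > 1))
    stop("corruption rates must lie in [0, 1]")
  truth <- as.integer(factor(dataset$truth_labels))
  k <- max(truth)
  n <- length(truth)
  out <- list()
  for (j in seq_along(qualities)) {
    rho <- qualities[j]
    set.seed(substream_seed(seed, paste0("candidate", j)))
    lab <- truth
    n_flip <- round(rho * n)
    if (n_flip > 0L) {
      idx <- sample.int(n, n_flip)
      lab[idx] <- sample.int(k, n_flip, replace = TRUE)
    }
    out[[sprintf("rho_%g", rho)]] <- lab
  }
  out
}
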