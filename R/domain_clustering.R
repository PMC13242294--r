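# Spatial label refinement, one-hot target construction, and the
# per-variant pipeline orchestrator.

#' Majority-vote spatial label refinement
#'
#' A spot's label flips to label L iff L differs from its current label
#' and strictly more than half of its spatial neighbors carry L. Ties and
#' non-strict majorities leave the spot unchanged. The default is a
#' single synchronous pass (all spots judged against the pre-pass labels);
#' `mode = "iterate"` repeats synchronous passes until a fixed point or
#' `max_passes`.
#'
#' @param labels Integer (or factor) labels, one per spot.
#' @param graph A [build_knn_graph()] result over the same spots.
#' @param mode `"single"` (default) or `"iterate"`.
#' @param max_passes Pass cap for `mode = "iterate"`. Default 10.
#' @return Integer labels of the same length; never introduces a label
#'   absent from the input.
#' @export
refine_labels <- function(labels, graph, mode = c("single", "iterate"),
                          max_passes = 10L) {
  mode <- match.arg(mode)
  labels <- as.integer(labels)
  if (length(labels) != nrow(graph$neighbor_indices))
    stop("labels and neighbor graph cover different spot sets")
  passes <- if (mode == "single") 1L else max_passes
  k <- graph$k
  for (p in seq_len(passes)) {
    nb_labels <- matrix(labels[graph$neighbor_indices],
                        nrow = length(labels), ncol = k)
    new_labels <- labels
    for (i in seq_along(labels)) {
      tab <- tabulate(nb_labels[i, ], nbins = max(labels))
      top <- max(tab)
      if (top * 2L > k) {            # strict majority of the neighborhood
        winners <- which(tab == top)
        if (length(winners) == 1L && winners != labels[i])
          new_labels[i] <- winners
      }
    }
    if (all(new_labels == labels)) {
      labels <- new_labels
      break
    }
    labels <- new_labels
  }
  labels
}

#' One-hot encode labels
#'
#' @param labels Integer labels in 1..K.
#' @param k Number of classes K.
#' @return An n x K binary matrix with exactly one 1 per row.
#' @export
one_hot_targets <- function(labels, k) {
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > k)) stop("labels out of range 1..", k)
  y <- matrix(0, length(labels), k)
  y[cbind(seq_along(labels), labels)] <- 1
  y
}

#' Run one pipeline variant end to end
#'
#' Executes the stage sequence of the requested variant and returns the
#' final, spatially refined clustering:
#'
#' * `G`: HVG -> normalize -> reconstruction training -> mixture fit
#' * `GS`: as `G` with z-scored coordinates fused into the input
#' * `GN`: as `G` with neighborhood mean expression concatenated
#' * `Scatter`: scatter filtration first, then as `G`
#' * `ACT`: as `G`, then refined mixture targets drive clustering-layer
#'   alignment and joint fine-tuning before the final mixture fit
#' * `FACT`: `ACT` preceded by scatter filtration
#'
#' Every variant ends with a majority-vote spatial refinement pass; the
#' unrefined labels are kept alongside.
#'
#' @param dataset A `spatial_dataset`.
#' @param config A [run_config()].
#' @return A `cluster_result` with `labels`, `refined_labels`,
#'   `responsibilities`, `variant` and a `provenance` snapshot (config,
#'   seed, retained gene count, input width).
#' @export
run_variant <- function(dataset, config = run_config()) {
  validate_spatial_dataset(dataset)
  variant <- config$variant
  seed <- config$seed
  counts <- dataset$counts
  retained <- seq_len(ncol(counts))

  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (variant %in% c("Scatter", "FACT")) {
    filt <- step("scatter_filtration",
                 scatter_filtration(counts, config$filtration,
                                    seed = substream_seed(seed, "filtration")))
    retained <- filt$retained_genes
    counts <- counts[, retained, drop = FALSE]
  }

  n_hvg <- min(config$n_hvg, ncol(counts))
  hvg <- step("select_hvg", select_hvg(counts, n_hvg))
  counts <- counts[, hvg, drop = FALSE]
  retained <- retained[hvg]

  x <- step("normalize_expression",
            normalize_expression(counts, config$normalization))

  graph <- step("build_knn_graph",
                build_knn_graph(dataset$coords, config$k_neighbors))

  if (variant == "GS") {
    x <- fuse_features(list(x, dataset$coords), scale = TRUE)
  } else if (variant == "GN") {
    x <- neighborhood_features(x, graph)
  }

  k <- config$n_clusters
  model <- init_model(ncol(x), config$latent_dim, k,
                      seed = substream_seed(seed, "init"))
  model <- step("stage1", train_stage1_reconstruction(model, x,
                                                      config$training))
  z <- encode(x, model)

  if (variant %in% c("ACT", "FACT")) {
    fit1 <- step("gmm_targets",
                 gmm_fit(z, k, config$gmm,
                         seed = substream_seed(seed, "gmm_stage2")))
    y2 <- one_hot_targets(refine_labels(fit1$labels, graph), k)
    model <- step("stage2",
                  train_stage2_cluster_alignment(model, x, y2,
                                                 config$training))
    fit2 <- step("gmm_targets2",
                 gmm_fit(encode(x, model), k, config$gmm,
                         seed = substream_seed(seed, "gmm_stage3")))
    y3 <- one_hot_targets(refine_labels(fit2$labels, graph), k)
    model <- step("stage3",
                  train_stage3_joint(model, x, y3, config$training))
    z <- encode(x, model)
  }

  fit <- step("gmm_final",
              gmm_fit(z, k, config$gmm,
                      seed = substream_seed(seed, "gmm_final")))
  refined <- refine_labels(fit$labels, graph)

  new_cluster_result(
    fit$labels, fit$responsibilities, refined = refined,
    loglik = fit$loglik, loglik_trace = fit$loglik_trace,
    variant = variant,
    provenance = list(config = unclass_config(config), seed = seed,
                      n_genes_retained = length(retained),
                      retained_genes = retained, input_width = ncol(x)),
    spot_ids = dataset$spot_ids)
}

unclass_config <- function(cfg) {
  rapply(unclass(cfg), unclass, how = "replace")
}
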