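# Unsupervised per-slide ensemble selection over candidate labelings.
#
# The five quality metrics (ASW, PAS, CHAOS, Moran's I, Geary's C) are
# min-max normalized across candidates, minimized metrics are flipped to
# benefit form, and the balanced rule picks the candidate whose normalized
# vector is Euclidean-closest to a reference profile built from max(ASW),
# max(Moran's I) and the medians of PAS, CHAOS, Geary's C. Ground-truth
# labels are never consulted.

ENSEMBLE_METRICS <- c("ASW", "PAS", "CHAOS", "MoranI", "GearyC")
MINIMIZED_METRICS <- c("PAS", "CHAOS", "GearyC")

#' Normalize a raw metric matrix to benefit form
#'
#' Min-max normalizes each metric column across candidate methods (with a
#' small epsilon in the denominator so constant columns are safe) and
#' flips the minimized metrics (PAS, CHAOS, Geary's C) so that larger
#' normalized values always mean better quality.
#'
#' @param raw Numeric matrix, methods in rows (named), the five metrics in
#'   columns (named `ASW`, `PAS`, `CHAOS`, `MoranI`, `GearyC`).
#' @param epsilon Denominator guard. Default 1e-8.
#' @return A list of class `metric_matrix` with `raw`, `normalized`,
#'   `methods`, `metrics`, `epsilon`.
#' @export
normalize_metric_matrix <- function(raw, epsilon = 1e-8) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 1L) stop("at least one method is required")
  if (is.null(rownames(raw)))
    rownames(raw) <- sprintf("method_%d", seq_len(nrow(raw)))
  missing_cols <- setdiff(ENSEMBLE_METRICS, colnames(raw))
  if (length(missing_cols))
    stop("missing metric columns: ", paste(missing_cols, collapse = ", "))
  raw <- raw[, ENSEMBLE_METRICS, drop = FALSE]
  bad <- which(!is.finite(raw), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite metric value for method '", rownames(raw)[bad[1, 1]],
         "', metric ", colnames(raw)[bad[1, 2]])
  z <- apply(raw, 2L, function(col)
    (col - min(col)) / (max(col) - min(col) + epsilon))
  z <- matrix(z, nrow = nrow(raw), dimnames = dimnames(raw))
  z[, MINIMIZED_METRICS] <- 1 - z[, MINIMIZED_METRICS]
  structure(list(raw = raw, normalized = z, methods = rownames(raw),
                 metrics = ENSEMBLE_METRICS, epsilon = epsilon),
            class = "metric_matrix")
}

#' Balanced reference profile
#'
#' Max of the normalized column for ASW and Moran's I (reward the
#' strongest separation and spatial coherence on offer); median for PAS,
#' CHAOS and Geary's C (avoid degenerate over-smoothed or over-fragmented
#' extremes). Even method counts use the midpoint of the central pair.
#'
#' @param matrix A `metric_matrix`.
#' @return Named numeric 5-vector.
#' @export
reference_profile <- function(matrix) {
  z <- matrix$normalized
  c(ASW = max(z[, "ASW"]),
    PAS = stats::median(z[, "PAS"]),
    CHAOS = stats::median(z[, "CHAOS"]),
    MoranI = max(z[, "MoranI"]),
    GearyC = stats::median(z[, "GearyC"]))
}

#' Balanced reference-point selection
#'
#' Selects the candidate whose normalized metric vector minimizes the
#' squared Euclidean distance to the reference profile. Distance ties are
#' broken by method-name order with a warning.
#'
#' @param matrix A `metric_matrix`.
#' @return A list of class `selection_result` with `reference`,
#'   `distances`, `selected` and `rule = "balanced"`.
#' @export
select_balanced <- function(matrix) {
  ref <- reference_profile(matrix)
  z <- matrix$normalized
  d <- rowSums(sweep(z, 2L, ref[colnames(z)], "-")^2)
  winners <- names(d)[d == min(d)]
  if (length(winners) > 1L)
    warning("distance tie between ", paste(winners, collapse = ", "),
            "; selecting by name order")
  sel <- sort(winners)[1L]
  structure(list(reference = ref, distances = d, selected = sel,
                 rule = "balanced"),
            class = "selection_result")
}

#' Single-metric selection
#'
#' Picks the candidate with the extremal raw value of one metric in its
#' own direction: maximal ASW, minimal PAS or CHAOS. Ties are broken by
#' method-name order with a warning.
#'
#' @param matrix A `metric_matrix`.
#' @param metric One of `"ASW"`, `"PAS"`, `"CHAOS"`.
#' @return A `selection_result` (its `rule` names the metric).
#' @export
select_single_metric <- function(matrix, metric = c("ASW", "PAS", "CHAOS")) {
  metric <- match.arg(metric)
  col <- stats::setNames(matrix$raw[, metric], rownames(matrix$raw))
  score <- if (metric == "ASW") -col else col  # order: smaller = better
  winners <- names(score)[score == min(score)]
  if (length(winners) > 1L)
    warning("tie in ", metric, " between ", paste(winners, collapse = ", "),
            "; selecting by name order")
  sel <- sort(winners)[1L]
  structure(list(reference = NULL, distances = score, selected = sel,
                 rule = tolower(metric)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s rule): selected '%s'\n", x$rule,
              x$selected))
  invisible(x)
}

#' Run the ensemble selector over candidate labelings
#'
#' Computes the five unsupervised metrics for every candidate on a shared
#' feature space (by default the leading principal components of the
#' normalized expression matrix, so external candidates are scored on
#' identical features), applies the selection rule, and returns the
#' winning labels. Truth labels are deliberately not a parameter: the
#' selection never consults them.
#'
#' @param dataset A `spatial_dataset`.
#' @param candidates Named list; each element labels every spot, either an
#'   unnamed vector in dataset order or a vector named by spot id.
#' @param rule `"balanced"` (default), `"asw"`, `"pas"`, or `"chaos"`.
#' @param features Optional shared feature matrix for the silhouette;
#'   default [shared_feature_space()] of the dataset.
#' @param k_neighbors Spatial graph size for Moran/Geary. Default 6.
#' @return A list with `selection` (a `selection_result`), `labels` (the
#'   winning labeling), and `metric_matrix`.
#' @export
run_ensemble <- function(dataset, candidates,
                         rule = c("balanced", "asw", "pas", "chaos"),
                         features = NULL, k_neighbors = 6L) {
  rule <- match.arg(rule)
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    stop("candidates must be a named list")
  n <- nrow(dataset$counts)
  candidates <- lapply(candidates, function(lab) {
    if (!is.null(names(lab))) {
      miss <- setdiff(dataset$spot_ids, names(lab))
      if (length(miss))
        stop("candidate labeling missing ", length(miss), " spot(s), e.g. ",
             miss[1L])
      lab <- lab[dataset$spot_ids]
    }
    if (length(lab) != n)
      stop("candidate labeling must cover every spot")
    lab
  })
  if (is.null(features)) features <- shared_feature_space(dataset)
  graph <- build_knn_graph(dataset$coords, k_neighbors)
  raw <- t(vapply(candidates, function(lab) {
    sa <- spatial_autocorrelation(lab, graph)
    c(ASW = asw(features, lab), PAS = pas(lab, dataset$coords),
      CHAOS = chaos(lab, dataset$coords),
      MoranI = unname(sa["moran_i"]), GearyC = unname(sa["geary_c"]))
  }, numeric(5L)))
  mm <- normalize_metric_matrix(raw)
  sel <- if (rule == "balanced") select_balanced(mm) else
    select_single_metric(mm, toupper(rule))
  list(selection = sel, labels = candidates[[sel$selected]],
       metric_matrix = mm)
}
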