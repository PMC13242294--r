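# Nonparametric benchmark comparison across slides: Friedman test with
# tie correction, exact one-sided paired Wilcoxon signed-rank tests (full
# null enumeration, required to reproduce p-values like 9.77e-4 at n = 12
# exactly), Holm's step-down correction, and the rank-biserial effect
# size.

#' Build a score table
#'
#' @param scores Numeric matrix or data frame, methods in rows (named) and
#'   slides in columns (named); no missing cells, at least 2 slides.
#' @return A list of class `score_table`.
#' @export
score_table <- function(scores) {
  m <- as.matrix(scores)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("score table has missing cells")
  if (ncol(m) < 2L) stop("need at least 2 slides")
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("method_%d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("slide_%d", seq_len(ncol(m)))
  structure(list(methods = rownames(m), slides = colnames(m), scores = m),
            class = "score_table")
}

#' Friedman test across methods
#'
#' Ranks methods within each slide (average ranks on ties) and computes
#' the chi-squared statistic with the usual tie correction (switchable),
#' with the asymptotic chi-squared p-value on k - 1 degrees of freedom.
#'
#' @param table A [score_table()] (or coercible matrix) with >= 3 methods
#'   and >= 2 slides.
#' @param tie_correction Apply the tie correction factor. Default TRUE.
#' @return Named list with `chi2`, `p`, `df`.
#' @export
friedman_test <- function(table, tie_correction = TRUE) {
  if (!inherits(table, "score_table")) table <- score_table(table)
  m <- table$scores
  k <- nrow(m)
  n <- ncol(m)
  if (k < 3L) stop("Friedman test needs at least 3 methods")
  ranks <- apply(m, 2L, rank)              # rank methods within each slide
  rj <- rowSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  if (tie_correction) {
    ties <- sum(apply(m, 2L, function(col) {
      cnt <- tabulate(match(col, unique(col)))
      sum(cnt^3 - cnt)
    }))
    corr <- 1 - ties / (n * k * (k^2 - 1))
    if (corr > 0) chi2 <- chi2 / corr
  }
  df <- k - 1L
  list(chi2 = chi2, p = stats::pchisq(chi2, df, lower.tail = FALSE), df = df)
}

#' Exact one-sided paired Wilcoxon signed-rank test
#'
#' Tests the alternative that `a` tends to exceed `b` over paired slides.
#' Zero differences are dropped; tied absolute differences receive
#' average ranks. The p-value is exact: the null distribution of W+ is
#' built over all 2^n sign patterns (via a generating-function
#' convolution, equivalent to full enumeration), so that e.g. 12/12
#' concordant slides give p = 1/4096.
#'
#' @param a,b Paired score vectors of equal length (n <= 25 after
#'   dropping zeros).
#' @return Named list with `p_raw`, `wins` (count of `a > b`),
#'   `delta_mean` (`mean(a) - mean(b)`), `w_plus` and `n_used`.
#' @export
wilcoxon_one_sided <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors differ in length")
  wins <- sum(a > b)
  delta_mean <- mean(a) - mean(b)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero; the test is undefined")
  if (n > 25L) stop("exact enumeration supports at most 25 nonzero pairs")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  # exact null distribution of W+ over all 2^n sign patterns; doubled
  # ranks make average ranks integral for the convolution
  r2 <- round(2 * r)
  dist <- numeric(sum(r2) + 1L)           # index i -> weight of 2*W+ = i-1
  dist[1L] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), dist[seq_len(length(dist) - ri)])
    dist <- dist + shifted
  }
  total <- 2^n
  obs <- round(2 * w_plus)
  p_raw <- sum(dist[(obs + 1L):length(dist)]) / total
  list(p_raw = p_raw, wins = wins, delta_mean = delta_mean,
       w_plus = w_plus, n_used = n)
}

#' Holm step-down adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th by (m - i + 1),
#' enforces monotone non-decrease, caps at 1, and returns the adjusted
#' values in the input order.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order.
#' @export
holm_adjust <- function(p_values) {
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values)
  adj <- p_values[o] * (m - seq_len(m) + 1L)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Rank-biserial correlation for paired scores
#'
#' `(W+ - W-) / (W+ + W-)` from the signed ranks of the nonzero
#' differences: 1 when every difference favors `a`, -1 when every one
#' favors `b`.
#'
#' @param a,b Paired score vectors.
#' @return A number in \[-1, 1\].
#' @export
rank_biserial <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) stop("all differences are zero; effect size undefined")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  (w_plus - w_minus) / (w_plus + w_minus)
}

#' Compare proposed methods against baselines across slides
#'
#' Runs a Friedman test over the chosen method set (skipped with a
#' warning below 3 methods) and, for each proposed method, one-sided
#' paired Wilcoxon tests against every baseline with Holm correction
#' applied within that method's baseline family, plus the rank-biserial
#' effect size.
#'
#' @param table A [score_table()] (or coercible matrix).
#' @param proposed Character vector of proposed method names.
#' @param baselines Character vector of baseline method names.
#' @param friedman_methods Optional method subset for the Friedman test;
#'   default all rows of the table.
#' @return A list of class `comparison_report` with `friedman` and a
#'   `pairwise` data frame (proposed, baseline, wins, n_slides,
#'   delta_mean, p_raw, p_holm, rank_biserial).
#' @export
compare_methods <- function(table, proposed, baselines,
                            friedman_methods = NULL) {
  if (!inherits(table, "score_table")) table <- score_table(table)
  unknown <- setdiff(c(proposed, baselines, friedman_methods),
                     table$methods)
  if (length(unknown))
    stop("unknown method(s): ", paste(unknown, collapse = ", "))
  fr_rows <- if (is.null(friedman_methods)) table$methods else
    friedman_methods
  friedman <- if (length(fr_rows) >= 3L) {
    friedman_test(score_table(table$scores[fr_rows, , drop = FALSE]))
  } else {
    warning("fewer than 3 methods; Friedman test skipped")
    NULL
  }
  pairwise <- NULL
  for (pm in proposed) {
    rows <- lapply(baselines, function(bm) {
      w <- wilcoxon_one_sided(table$scores[pm, ], table$scores[bm, ])
      data.frame(proposed = pm, baseline = bm, wins = w$wins,
                 n_slides = ncol(table$scores), delta_mean = w$delta_mean,
                 p_raw = w$p_raw,
                 rank_biserial = rank_biserial(table$scores[pm, ],
                                               table$scores[bm, ]),
                 stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, rows)
    fam$p_holm <- holm_adjust(fam$p_raw)
    pairwise <- rbind(pairwise, fam)
  }
  if (!is.null(pairwise))
    pairwise <- pairwise[, c("proposed", "baseline", "wins", "n_slides",
                             "delta_mean", "p_raw", "p_holm",
                             "rank_biserial")]
  structure(list(friedman = friedman, pairwise = pairwise),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  if (!is.null(x$friedman))
    cat(sprintf("Friedman chi2 = %.2f (df = %d), p = %.3g\n",
                x$friedman$chi2, x$friedman$df, x$friedman$p))
  if (!is.null(x$pairwise)) {
    cat("Pairwise one-sided Wilcoxon (Holm within each proposed family):\n")
    print(format(x$pairwise, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Published 12-slide benchmark ARI fixture
#'
#' Loads the packaged per-slide adjusted Rand index table for 13 methods
#' on the 12-section human cortex benchmark, shipped as plain CSV. Used by
#' the statistics module's tests and the acceptance report.
#'
#' @return A [score_table()] with 13 methods and 12 slides.
#' @export
benchmark_ari_fixture <- function() {
  path <- system.file("extdata", "dlpfc_benchmark_ari.csv",
                      package = "spadec", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df[[1L]]
  score_table(m)
}
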