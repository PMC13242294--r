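# Readers and writers for the standard on-disk formats: 10x-style
# MatrixMarket triplets with features/barcodes TSVs, dense CSV matrices,
# tissue_positions CSV dialects, and two-column label CSVs.

#' Load a spatial dataset from disk
#'
#' Reads a spot-by-gene count matrix and a spot position table, intersects
#' their barcodes, and returns a [spatial_dataset()]. Spots present in only
#' one of the two sources are dropped with a message; zero overlap is an
#' error. The spot order of the result follows the barcode order of the
#' counts file.
#'
#' @param counts_path For `format = "mtx10x"`, the `matrix.mtx` file (or the
#'   directory containing it); `features.tsv` and `barcodes.tsv` (optionally
#'   gzipped) must sit next to it. For `format = "dense_csv"`, a CSV with
#'   spots in rows (first column = spot id) and genes in columns.
#' @param positions_path Positions CSV: either a generic `spot_id,x,y` table
#'   or a 10x `tissue_positions` file (5- or 6-column dialect, with or
#'   without header).
#' @param format One of `"mtx10x"`, `"dense_csv"`, `"h5ad"`. The `"h5ad"`
#'   route is not available in this build (no HDF5 binding) and raises an
#'   informative error.
#' @param keep_out_of_tissue For 10x positions files, keep rows with
#'   `in_tissue == 0` (default drops them, matching Visium convention).
#' @return A `spatial_dataset`.
#' @export
load_dataset <- function(counts_path, positions_path,
                         format = c("mtx10x", "dense_csv", "h5ad"),
                         keep_out_of_tissue = FALSE) {
  format <- match.arg(format)
  if (format == "h5ad")
    stop("format 'h5ad' is not supported in this build: no HDF5 reader ",
         "is available; export the matrix as mtx10x or dense_csv instead")
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
  if (!file.exists(positions_path))
    stop("positions file not found: ", positions_path)

  mat <- switch(format,
    mtx10x = read_mtx10x(counts_path),
    dense_csv = read_dense_csv(counts_path))
  pos <- read_positions(positions_path, keep_out_of_tissue = keep_out_of_tissue)

  shared <- intersect(rownames(mat), pos$spot_id)
  if (length(shared) == 0L)
    stop("no overlapping spot barcodes between counts and positions")
  dropped <- (nrow(mat) - length(shared)) + (nrow(pos) - length(shared))
  if (dropped > 0L)
    message(dropped, " spot(s) present in only one input were dropped")
  keep <- rownames(mat)[rownames(mat) %in% shared]  # counts-file order
  mat <- mat[keep, , drop = FALSE]
  pos <- pos[match(keep, pos$spot_id), , drop = FALSE]

  spatial_dataset(mat, cbind(x = pos$x, y = pos$y), spot_ids = keep)
}

# 10x triplet reader: matrix.mtx is genes x barcodes; transposed on load.
read_mtx10x <- function(path) {
  if (dir.exists(path)) {
    mtx <- first_existing(file.path(path, c("matrix.mtx", "matrix.mtx.gz")))
    base <- path
  } else {
    mtx <- path
    base <- dirname(path)
  }
  if (is.na(mtx)) stop("matrix.mtx not found under ", path)
  feat <- first_existing(file.path(base, c("features.tsv", "features.tsv.gz",
                                           "genes.tsv", "genes.tsv.gz")))
  bc <- first_existing(file.path(base, c("barcodes.tsv", "barcodes.tsv.gz")))
  if (is.na(feat) || is.na(bc))
    stop("companion features.tsv/barcodes.tsv not found next to ", mtx)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("unreadable MatrixMarket file ", mtx,
                                         ": ", conditionMessage(e)))
  features <- utils::read.delim(feat, header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  gene_ids <- if (ncol(features) >= 2L) features[[2L]] else features[[1L]]
  if (nrow(features) != nrow(m) || length(barcodes) != ncol(m))
    stop("features/barcodes dimensions do not match the matrix")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers in ", feat)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in ", bc)
  out <- as.matrix(Matrix::t(m))
  dimnames(out) <- list(barcodes, gene_ids)
  out
}

read_dense_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("unreadable CSV ", path, ": ",
                             conditionMessage(e)))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(colnames(df)[-1L]))  # before [.data.frame deduplicates
    stop("duplicate gene column names in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(ids)) stop("duplicate spot ids in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

first_existing <- function(paths) {
  hit <- paths[file.exists(paths)]
  if (length(hit)) hit[[1L]] else NA_character_
}

#' Read a spot positions table
#'
#' Accepts a generic `spot_id,x,y` CSV or either 10x `tissue_positions`
#' dialect (5 or 6 columns: barcode, in_tissue, array_row, array_col,
#' \[pxl_row,\] pxl_col; header optional). For 10x dialects the pixel
#' columns provide the planar coordinates (x = last column, y = second to
#' last) and `in_tissue == 0` rows are dropped unless requested otherwise.
#'
#' @param path CSV path.
#' @param keep_out_of_tissue Keep `in_tissue == 0` rows (10x dialects only).
#' @return Data frame with columns `spot_id`, `x`, `y`.
#' @export
read_positions <- function(path, keep_out_of_tissue = FALSE) {
  head1 <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  has_header <- !suppressWarnings(all(!is.na(as.numeric(head1[-1L]))))
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) == 3L) {
    out <- data.frame(spot_id = as.character(df[[1L]]),
                      x = as.numeric(df[[2L]]), y = as.numeric(df[[3L]]),
                      stringsAsFactors = FALSE)
  } else if (ncol(df) %in% c(5L, 6L)) {
    nc <- ncol(df)
    out <- data.frame(spot_id = as.character(df[[1L]]),
                      in_tissue = as.integer(df[[2L]]),
                      x = as.numeric(df[[nc]]),
                      y = as.numeric(df[[nc - 1L]]),
                      stringsAsFactors = FALSE)
    if (!keep_out_of_tissue) out <- out[out$in_tissue != 0L, , drop = FALSE]
    out$in_tissue <- NULL
  } else {
    stop("unrecognized positions dialect (", ncol(df), " columns) in ", path)
  }
  if (anyDuplicated(out$spot_id)) stop("duplicate barcodes in ", path)
  out
}

#' Read a two-column label CSV
#'
#' Parses a `spot_id,label` table, auto-detecting an optional header row
#' (recognized when the first field is one of the usual id column names).
#' Labels are kept as opaque character categories.
#'
#' @param path CSV path.
#' @return Named character vector mapping spot id to label, in file order.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) return(stats::setNames(character(0), character(0)))
  if (ncol(df) < 2L) stop("labels file must have two columns: ", path)
  header_words <- c("spot", "spot_id", "barcode", "id", "spotid")
  if (tolower(df[1L, 1L]) %in% header_words) df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate spot_id in ", path)
  stats::setNames(df[[2L]], ids)
}

#' Write labels to CSV
#'
#' Writes a `spot_id,label` CSV (quoted where needed) that round-trips
#' through [read_labels()] to an identical mapping.
#'
#' @param labels A `cluster_result` (its refined labels are written), or a
#'   vector of labels named by spot id, or an unnamed vector combined with
#'   `spot_ids`.
#' @param path Output CSV path.
#' @param spot_ids Spot identifiers, required when `labels` is unnamed.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, spot_ids = NULL) {
  if (inherits(labels, "cluster_result")) {
    spot_ids <- labels$spot_ids
    labels <- labels$refined_labels
  }
  if (is.null(spot_ids)) spot_ids <- names(labels)
  if (is.null(spot_ids) && length(labels) > 0L)
    stop("spot_ids required when labels are unnamed")
  if (length(spot_ids) != length(labels))
    stop("labels and spot_ids lengths differ")
  df <- data.frame(spot_id = as.character(spot_ids),
                   label = as.character(labels), stringsAsFactors = FALSE)
  tryCatch(utils::write.csv(df, path, row.names = FALSE),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Write a dataset in 10x-style layout
#'
#' Emits `matrix.mtx` (genes x barcodes), `features.tsv`, `barcodes.tsv`,
#' a generic `positions.csv` and, when truth labels are present,
#' `truth.csv` under the given prefix directory.
#'
#' @param dataset A `spatial_dataset`.
#' @param out_prefix Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, out_prefix) {
  dir.create(out_prefix, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(dataset$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(out_prefix, "matrix.mtx"))
  utils::write.table(
    data.frame(dataset$gene_ids, dataset$gene_ids, "Gene Expression"),
    file.path(out_prefix, "features.tsv"), sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  writeLines(dataset$spot_ids, file.path(out_prefix, "barcodes.tsv"))
  utils::write.csv(
    data.frame(spot_id = dataset$spot_ids, x = dataset$coords[, 1L],
               y = dataset$coords[, 2L]),
    file.path(out_prefix, "positions.csv"), row.names = FALSE)
  if (!is.null(dataset$truth_labels))
    write_labels(stats::setNames(dataset$truth_labels, dataset$spot_ids),
                 file.path(out_prefix, "truth.csv"))
  invisible(out_prefix)
}
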