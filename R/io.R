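# Count matrix IO, per-cell QC and log-normalization.

#' Read a 10x-style sparse count matrix
#'
#' Loads a Matrix Market coordinate file together with its feature and barcode
#' tables into a sparse genes x cells count matrix. Gene identifiers are taken
#' from the feature table's symbol column (second column when present,
#' otherwise the first) and made unique with a deterministic `.1`, `.2`, ...
#' suffix scheme; the original feature table, including the undisambiguated
#' symbols, is retained in the `"features"` attribute. Gzipped inputs are
#' handled transparently.
#'
#' @param matrix_path Path to the Matrix Market (`.mtx` or `.mtx.gz`) file,
#'   1-based coordinate format with integer entries.
#' @param features_path Path to the feature table (`features.tsv(.gz)` or
#'   `genes.tsv(.gz)`): tab-delimited, no header, one row per gene.
#' @param barcodes_path Path to the barcode table, one barcode per row.
#' @return A `dgCMatrix` of non-negative integer counts, genes in rows and
#'   cells in columns, with unique dimnames and the feature table attached as
#'   attribute `"features"`.
#' @examples
#' sim <- simulate_counts(simulation_config(n_genes = 50,
#'   classes = c(EP = 10, DS = 10)))
#' d <- tempfile(); write_counts(sim$counts, d)
#' cm <- read_counts(file.path(d, "matrix.mtx"),
#'                   file.path(d, "features.tsv"),
#'                   file.path(d, "barcodes.tsv"))
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path) {
  mat <- .with_text(matrix_path, Matrix::readMM)
  features <- .with_text(features_path, function(con)
    utils::read.delim(con, header = FALSE, stringsAsFactors = FALSE))
  barcodes <- .with_text(barcodes_path, function(con)
    utils::read.delim(con, header = FALSE, stringsAsFactors = FALSE))[[1L]]
  if (nrow(features) != nrow(mat)) {
    stop("feature table has ", nrow(features), " records but matrix header declares ",
         nrow(mat), " rows", call. = FALSE)
  }
  if (length(barcodes) != ncol(mat)) {
    stop("barcode table has ", length(barcodes), " records but matrix header declares ",
         ncol(mat), " columns", call. = FALSE)
  }
  x <- if (methods::is(mat, "sparseMatrix")) mat@x else as.vector(mat)
  if (any(x < 0)) stop("count matrix contains negative entries", call. = FALSE)
  if (any(x != round(x))) stop("count matrix contains non-integer entries", call. = FALSE)
  mat <- methods::as(methods::as(mat, "CsparseMatrix"), "dMatrix")
  symbols <- if (ncol(features) >= 2L) features[[2L]] else features[[1L]]
  rownames(mat) <- make.unique(symbols, sep = ".")
  if (anyDuplicated(barcodes)) stop("cell barcodes are not unique", call. = FALSE)
  colnames(mat) <- barcodes
  attr(mat, "features") <- features
  mat
}

#' Write a count matrix as 10x-style triplet files
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` (uncompressed) into
#' `dir`, so that [read_counts()] round-trips the matrix exactly.
#'
#' @param cm Sparse genes x cells count matrix with dimnames.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(cm, dir) {
  stopifnot(!is.null(rownames(cm)), !is.null(colnames(cm)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(cm, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  feats <- attr(cm, "features")
  if (is.null(feats)) {
    feats <- data.frame(V1 = rownames(cm), V2 = rownames(cm),
                        V3 = "Gene Expression")
  }
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(colnames(cm)), file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}

# Run `fn` on a (gz-transparent) text connection, closing it afterwards.
.with_text <- function(path, fn) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  fn(con)
}

#' Per-cell quality-control metrics
#'
#' Computes, for every cell: total counts (`n_counts`), number of detected
#' genes (`n_genes`), percentage of counts in mitochondrial genes
#' (`pct_mito`), and `log10_genes_per_umi = log10(n_genes) / log10(n_counts)`.
#' Mitochondrial genes are recognized by a case-sensitive identifier prefix,
#' `"MT-"` by default (human nomenclature). Cells with zero total counts get
#' `pct_mito = 0` and are flagged in the `zero_total` column; QC must be
#' computable before any filtering.
#'
#' @param cm Sparse genes x cells count matrix.
#' @param mito_prefix Gene-identifier prefix marking mitochondrial genes.
#' @return A data.frame with one row per cell: `cell_id`, `n_counts`,
#'   `n_genes`, `pct_mito`, `log10_genes_per_umi`, `zero_total`.
#' @export
compute_qc <- function(cm, mito_prefix = "MT-") {
  cm <- methods::as(cm, "CsparseMatrix")
  n_counts <- Matrix::colSums(cm)
  n_genes <- Matrix::colSums(cm > 0)
  mito <- startsWith(rownames(cm), mito_prefix)
  mito_counts <- if (any(mito)) Matrix::colSums(cm[mito, , drop = FALSE]) else
    rep(0, ncol(cm))
  zero_total <- n_counts == 0
  pct_mito <- ifelse(zero_total, 0, 100 * mito_counts / pmax(n_counts, 1))
  lgpu <- ifelse(n_counts > 1, log10(pmax(n_genes, 1)) / log10(n_counts), NA_real_)
  data.frame(cell_id = colnames(cm), n_counts = as.integer(round(n_counts)),
             n_genes = as.integer(n_genes), pct_mito = pct_mito,
             log10_genes_per_umi = lgpu, zero_total = zero_total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' QC threshold presets
#'
#' Two named presets are shipped. `"default"`: total counts > 1000, detected
#' genes > 400, mitochondrial percentage <= 12. `"integration"` (used for
#' whole-tissue donor datasets that are merged before analysis): total counts
#' > 500, detected genes > 250 and < 7500, mitochondrial percentage <= 5,
#' log10 genes-per-UMI < 0.8. Lower bounds and upper gene/complexity bounds
#' are strict; the mitochondrial bound is inclusive.
#'
#' @param preset `"default"` or `"integration"`, or ignored when all bounds are
#'   given explicitly.
#' @param min_counts,min_genes Strict lower bounds.
#' @param max_genes Strict upper bound on detected genes, or `NA` for none.
#' @param max_pct_mito Inclusive upper bound on mitochondrial percentage.
#' @param max_log10_genes_per_umi Strict upper bound, or `NA` for none.
#' @return A list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(preset = c("default", "integration"),
                          min_counts = NULL, min_genes = NULL, max_genes = NULL,
                          max_pct_mito = NULL, max_log10_genes_per_umi = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    default = list(min_counts = 1000L, min_genes = 400L, max_genes = NA_integer_,
                   max_pct_mito = 12, max_log10_genes_per_umi = NA_real_),
    integration = list(min_counts = 500L, min_genes = 250L, max_genes = 7500L,
                       max_pct_mito = 5, max_log10_genes_per_umi = 0.8))
  for (f in names(base)) {
    v <- get(f)
    if (!is.null(v)) base[[f]] <- v
  }
  stopifnot(base$min_counts >= 0, base$max_pct_mito >= 0, base$max_pct_mito <= 100)
  if (!is.na(base$max_genes) && base$min_genes >= base$max_genes)
    stop("min_genes must be below max_genes", call. = FALSE)
  base$preset <- preset
  structure(base, class = "qc_thresholds")
}

#' Filter cells on QC metrics
#'
#' Retains exactly the cells satisfying all configured bounds: strict `>` on
#' counts and genes lower bounds, strict `<` on the gene and complexity upper
#' bounds, inclusive `<=` on the mitochondrial percentage. The gene set is
#' unchanged. Cell counts before and after are reported via `message()`.
#'
#' @param cm Sparse genes x cells count matrix.
#' @param qc QC table from [compute_qc()], aligned to the cells of `cm`.
#' @param thresholds A [qc_thresholds()] object (default preset if missing).
#' @return The column-subsetted count matrix; empty (0 cells) with a warning
#'   if no cell passes.
#' @export
filter_cells <- function(cm, qc, thresholds = qc_thresholds("default")) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (!identical(qc$cell_id, colnames(cm)))
    stop("QC table is not aligned to the columns of the count matrix", call. = FALSE)
  keep <- qc$n_counts > thresholds$min_counts &
    qc$n_genes > thresholds$min_genes &
    qc$pct_mito <= thresholds$max_pct_mito
  if (!is.na(thresholds$max_genes))
    keep <- keep & qc$n_genes < thresholds$max_genes
  if (!is.na(thresholds$max_log10_genes_per_umi))
    keep <- keep & !is.na(qc$log10_genes_per_umi) &
      qc$log10_genes_per_umi < thresholds$max_log10_genes_per_umi
  message("filter_cells: ", sum(keep), " of ", ncol(cm), " cells retained (preset: ",
          thresholds$preset, ")")
  if (!any(keep)) warning("all cells removed by QC filtering", call. = FALSE)
  out <- cm[, keep, drop = FALSE]
  attr(out, "features") <- attr(cm, "features")
  out
}

#' Log-normalize a count matrix
#'
#' Scales each cell to a common library size and log-transforms:
#' `value = ln(1 + scale_factor * count / cell_total)` with the conventional
#' scale factor of 10,000 (counts per 10K). Zeros stay zero, so sparsity is
#' preserved, and within a cell the transform is strictly increasing in the
#' count. Natural log is used; the base is recorded in the result so
#' downstream fold changes can stay base-consistent.
#'
#' @param cm Sparse genes x cells count matrix; every cell must have total
#'   count > 0 (filter first).
#' @param scale_factor Library-size target, default 10,000.
#' @return A `dgCMatrix` of normalized values with attributes `scale_factor`
#'   and `log_base` (`"natural"`).
#' @export
log_normalize <- function(cm, scale_factor = 1e4) {
  cm <- methods::as(methods::as(cm, "CsparseMatrix"), "dMatrix")
  totals <- Matrix::colSums(cm)
  if (any(totals == 0))
    stop("cells with zero total counts present; run filter_cells() before log_normalize()",
         call. = FALSE)
  per_entry_total <- rep.int(totals, diff(cm@p))
  cm@x <- log1p(scale_factor * cm@x / per_entry_total)
  attr(cm, "scale_factor") <- scale_factor
  attr(cm, "log_base") <- "natural"
  cm
}

#' Read a per-cell metadata table
#'
#' Delimited text with a header row; must contain a `cell_id` column. Standard
#' optional columns are `sample`, `donor_id`, `donor_age` (years) and
#' `cell_type`.
#'
#' @param path Path to the table (tab- or comma-delimited, gz allowed).
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  first <- .with_text(path, function(con) readLines(con, n = 1L))
  sep <- if (grepl("\t", first)) "\t" else ","
  meta <- .with_text(path, function(con)
    utils::read.table(con, header = TRUE, sep = sep, stringsAsFactors = FALSE))
  if (!"cell_id" %in% names(meta))
    stop("metadata table must contain a 'cell_id' column", call. = FALSE)
  if ("donor_age" %in% names(meta)) {
    bad <- !is.na(meta$donor_age) & (meta$donor_age <= 0 | !is.finite(meta$donor_age))
    if (any(bad)) stop("donor_age must be positive and finite where present",
                       call. = FALSE)
  }
  meta
}
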