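# Cohort-level downstream analyses: per-donor senescent burden, age
# correlation, senescence-marker correlation, matrisome median profiles.

#' Default senescence marker panel
#'
#' Canonical senescence-associated genes used for pairwise marker correlation:
#' CDKN1A, CDKN2A, IGFBP3, SERPINE1, IGF1, CXCL12, IL6, MMP3, TP53.
#'
#' @return Character vector of gene symbols.
#' @export
senescence_markers <- function() {
  c("CDKN1A", "CDKN2A", "IGFBP3", "SERPINE1", "IGF1", "CXCL12", "IL6", "MMP3",
    "TP53")
}

#' Per-donor senescent-cell burden
#'
#' Joins per-cell predictions to cell metadata (validated one-to-one on
#' `cell_id`), restricts to cells annotated with the requested cell type (or a
#' caller-supplied boolean mask), and tabulates per-donor percentages of each
#' predicted label over that donor's fibroblasts, `"unassigned"` included in
#' the denominator. Donors with fewer than `min_fibroblasts` fibroblasts are
#' dropped (reported via `message()`). Percentages over assigned cells only
#' are reported alongside.
#'
#' @param pred Prediction table from [classify_cells()] (needs `cell_id` and
#'   `assigned_label`).
#' @param meta Cell metadata with columns `cell_id`, `donor_id`, and
#'   optionally `donor_age` and `cell_type`.
#' @param cell_type Annotation value selecting the cells of interest; `NULL`
#'   uses all cells.
#' @param cells Optional boolean mask over rows of `meta`, an alternative to
#'   `cell_type` for datasets where fibroblast identity comes from marker
#'   inspection rather than a metadata column.
#' @param min_fibroblasts Minimum fibroblast count for a donor to be retained.
#' @return data.frame of class `"senpred_cohort"`: `donor_id`, `age`,
#'   `n_cells`, `n_fibroblasts`, one `pct_<label>` column per class plus
#'   `pct_unassigned`, and matching `pct_<label>_of_assigned` columns.
#' @export
burden_by_donor <- function(pred, meta, cell_type = "fibroblast", cells = NULL,
                            min_fibroblasts = 100) {
  stopifnot(all(c("cell_id", "assigned_label") %in% names(pred)),
            all(c("cell_id", "donor_id") %in% names(meta)))
  if (anyDuplicated(pred$cell_id)) stop("duplicate cell_id in predictions", call. = FALSE)
  if (anyDuplicated(meta$cell_id)) stop("duplicate cell_id in metadata", call. = FALSE)
  m <- merge(pred[, c("cell_id", "assigned_label")], meta, by = "cell_id")
  if (nrow(m) == 0) stop("predictions and metadata share no cell_id", call. = FALSE)
  if (!is.null(cells)) {
    stopifnot(is.logical(cells), length(cells) == nrow(meta))
    m <- m[m$cell_id %in% meta$cell_id[cells], , drop = FALSE]
  } else if (!is.null(cell_type)) {
    if (!"cell_type" %in% names(m))
      stop("metadata has no 'cell_type' column; pass cells= instead", call. = FALSE)
    m <- m[!is.na(m$cell_type) & m$cell_type == cell_type, , drop = FALSE]
  }
  classes <- setdiff(unique(pred$assigned_label), "unassigned")
  std <- c("EP", "ES", "DS")
  classes <- if (all(classes %in% std)) std else
    c(intersect(std, classes), setdiff(sort(classes), std))
  lev <- c(classes, "unassigned")
  total_cells <- table(meta$donor_id)
  donors <- unique(m$donor_id)
  rows <- lapply(donors, function(d) {
    sub <- m[m$donor_id == d, , drop = FALSE]
    nf <- nrow(sub)
    tab <- table(factor(sub$assigned_label, levels = lev))
    pct <- 100 * as.numeric(tab) / nf
    assigned <- sub$assigned_label != "unassigned"
    pct_a <- if (any(assigned))
      100 * as.numeric(table(factor(sub$assigned_label[assigned], levels = classes))) /
        sum(assigned)
    else rep(NA_real_, length(classes))
    age <- if ("donor_age" %in% names(sub)) sub$donor_age[1] else NA_real_
    out <- data.frame(donor_id = d, age = age,
                      n_cells = as.integer(total_cells[[as.character(d)]]),
                      n_fibroblasts = nf, stringsAsFactors = FALSE)
    out[paste0("pct_", lev)] <- as.list(pct)
    out[paste0("pct_", classes, "_of_assigned")] <- as.list(pct_a)
    out
  })
  cs <- do.call(rbind, rows)
  drop <- cs$n_fibroblasts < min_fibroblasts
  if (any(drop))
    message("burden_by_donor: ", sum(drop), " donor(s) dropped with < ",
            min_fibroblasts, " fibroblasts: ",
            paste(cs$donor_id[drop], collapse = ", "))
  cs <- cs[!drop, , drop = FALSE]
  if (nrow(cs) == 0) stop("no donors with at least ", min_fibroblasts,
                          " fibroblasts", call. = FALSE)
  rownames(cs) <- NULL
  class(cs) <- c("senpred_cohort", "data.frame")
  cs
}

#' Correlate senescent burden with donor age
#'
#' Pearson correlation across donors between age and a chosen burden column,
#' with the two-sided p-value from the t transform on n - 2 degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param cs Cohort summary from [burden_by_donor()].
#' @param field Burden column to correlate, default `"pct_DS"`.
#' @return List of class `"senpred_age_cor"`: `r`, `p_value`, `n_donors`,
#'   `field`.
#' @export
correlate_with_age <- function(cs, field = "pct_DS") {
  stopifnot(field %in% names(cs))
  ok <- !is.na(cs$age) & !is.na(cs[[field]])
  x <- cs$age[ok]; y <- cs[[field]][ok]
  if (length(x) < 3) stop("at least 3 donors with ages are required", call. = FALSE)
  if (stats::var(x) == 0) stop("donor ages have zero variance", call. = FALSE)
  if (stats::var(y) == 0) stop("burden values have zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n_donors = length(x), field = field),
            class = "senpred_age_cor")
}

#' @export
print.senpred_age_cor <- function(x, ...) {
  cat(sprintf("%s vs age over %d donors: Pearson r = %.3f, p = %.4g\n",
              x$field, x$n_donors, x$r, x$p_value))
  invisible(x)
}

#' Pairwise senescence-marker correlation with Ward clustering
#'
#' Pearson correlation between all pairs of panel genes over the chosen
#' cells' normalized expression, with Ward ("ward.D2") hierarchical
#' clustering of the correlation matrix rows providing the dendrogram order.
#' Panel genes absent from the matrix are dropped with a warning; genes with
#' constant expression are kept in the matrix but masked as `NA` (undefined)
#' and excluded from clustering.
#'
#' @param nm Normalized genes x cells matrix.
#' @param cells Optional cell subset (indices, names or logical mask).
#' @param panel Gene panel, default [senescence_markers()].
#' @return List of class `"senpred_marker_cor"`: `cor` (genes x genes, `NA`
#'   where undefined), `order` (gene names in dendrogram order), `hclust`,
#'   `constant` (masked genes).
#' @export
marker_correlation <- function(nm, cells = NULL, panel = senescence_markers()) {
  stopifnot(length(panel) > 0, !anyDuplicated(panel))
  if (!is.null(cells)) nm <- nm[, cells, drop = FALSE]
  if (ncol(nm) < 3) stop("at least 3 cells are required", call. = FALSE)
  missing <- setdiff(panel, rownames(nm))
  if (length(missing)) {
    warning("panel genes absent and dropped: ", paste(missing, collapse = ", "),
            call. = FALSE)
    panel <- setdiff(panel, missing)
  }
  if (!length(panel)) stop("no panel genes present in the matrix", call. = FALSE)
  X <- as.matrix(Matrix::t(nm[panel, , drop = FALSE]))
  sds <- apply(X, 2L, stats::sd)
  constant <- colnames(X)[sds == 0]
  R <- matrix(NA_real_, length(panel), length(panel), dimnames = list(panel, panel))
  ok <- setdiff(panel, constant)
  if (length(ok) >= 1) R[ok, ok] <- stats::cor(X[, ok, drop = FALSE])
  hc <- NULL
  ord <- ok
  if (length(ok) >= 2) {
    hc <- stats::hclust(stats::dist(R[ok, ok, drop = FALSE]), method = "ward.D2")
    ord <- ok[hc$order]
  }
  structure(list(cor = R, order = ord, hclust = hc, constant = constant),
            class = "senpred_marker_cor")
}

#' Median matrisome expression profiles by condition
#'
#' For each condition, computes the per-gene median of normalized expression
#' over that condition's cells, drops genes whose median is zero in every
#' condition, and applies Ward ("ward.D2") hierarchical clustering over both
#' conditions and genes.
#'
#' @param nm_by_condition Named list (>= 2 entries) of normalized
#'   genes x cells matrices, one per condition.
#' @param gene_set Genes to profile (e.g. a matrisome list); genes must be
#'   present in every condition's matrix to be used.
#' @return List of class `"senpred_matrisome"`: `medians` (genes x
#'   conditions), `n_genes` retained, `gene_order`, `condition_order`,
#'   `gene_hclust`, `condition_hclust`.
#' @export
matrisome_profile <- function(nm_by_condition, gene_set) {
  stopifnot(is.list(nm_by_condition), length(nm_by_condition) >= 2,
            !is.null(names(nm_by_condition)))
  genes <- Reduce(intersect, lapply(nm_by_condition, rownames))
  genes <- intersect(gene_set, genes)
  if (!length(genes)) stop("no genes of the set present in all conditions", call. = FALSE)
  med <- vapply(nm_by_condition, function(nm) {
    apply(as.matrix(nm[genes, , drop = FALSE]), 1L, stats::median)
  }, numeric(length(genes)))
  med <- matrix(med, nrow = length(genes),
                dimnames = list(genes, names(nm_by_condition)))
  keep <- rowSums(med != 0) > 0
  med <- med[keep, , drop = FALSE]
  if (nrow(med) == 0) stop("all genes have zero median in every condition", call. = FALSE)
  gene_hc <- if (nrow(med) >= 2)
    stats::hclust(stats::dist(med), method = "ward.D2") else NULL
  cond_hc <- stats::hclust(stats::dist(t(med)), method = "ward.D2")
  structure(list(medians = med, n_genes = nrow(med),
                 gene_order = if (is.null(gene_hc)) rownames(med) else
                   rownames(med)[gene_hc$order],
                 condition_order = colnames(med)[cond_hc$order],
                 gene_hclust = gene_hc, condition_hclust = cond_hc),
            class = "senpred_matrisome")
}
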