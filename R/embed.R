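# Feature selection, scaling, PCA, SNN-Louvain clustering, marker testing.

#' Select highly variable genes by standardized variance
#'
#' Ranks genes by their variance after variance stabilization: a loess curve
#' (span 0.3, degree 2) of log10(variance) on log10(mean) is fit over genes
#' with positive variance, each gene's values are standardized with its fitted
#' expected standard deviation, standardized values are clipped at
#' sqrt(n_cells), and the variance of the clipped values ranks the genes.
#' Constant genes rank last. When fewer than 50 variable genes are available
#' the loess span falls back to 1 so the trend remains estimable.
#'
#' @param nm Normalized (or raw) genes x cells matrix, sparse.
#' @param n Number of genes to return (all genes, ranked, if fewer exist).
#' @param span Loess span for the mean-variance trend.
#' @return Character vector of gene identifiers in decreasing rank order.
#' @export
select_hvg <- function(nm, n = 2000, span = 0.3) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  nm <- methods::as(nm, "CsparseMatrix")
  nc <- ncol(nm)
  if (nc < 2) stop("at least 2 cells are required", call. = FALSE)
  mu <- Matrix::rowMeans(nm)
  v <- (Matrix::rowSums(nm^2) - nc * mu^2) / (nc - 1)
  v <- pmax(v, 0)
  var_genes <- v > 0
  std_var <- numeric(nrow(nm))
  if (sum(var_genes) >= 2) {
    df <- data.frame(lm = log10(mu[var_genes]), lv = log10(v[var_genes]))
    use_span <- if (sum(var_genes) < 50) 1 else span
    fit <- suppressWarnings(stats::loess(lv ~ lm, data = df, span = use_span,
                                         degree = 2))
    sd_exp <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(nc)
    tm <- Matrix::t(nm[var_genes, , drop = FALSE])  # cells x genes: column slices
    g_idx <- rep.int(seq_len(ncol(tm)), diff(tm@p))
    z <- pmin((tm@x - mu[var_genes][g_idx]) / sd_exp[g_idx], clip)
    nnz <- diff(tm@p)
    z0 <- pmin(-mu[var_genes] / sd_exp, clip)   # value shared by all zero entries
    s1 <- rowsum_vec(z, g_idx, ncol(tm)) + (nc - nnz) * z0
    s2 <- rowsum_vec(z^2, g_idx, ncol(tm)) + (nc - nnz) * z0^2
    std_var[var_genes] <- (s2 - s1^2 / nc) / (nc - 1)
  }
  ord <- order(-std_var, -mu, rownames(nm))
  rownames(nm)[ord][seq_len(min(n, nrow(nm)))]
}

# rowsum() over a numeric vector grouped by integer index, with fixed length
rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Scale genes to zero mean and unit variance
#'
#' Computes per-gene z-scores across cells for the chosen genes, then caps
#' values at `clip` (upper side; default 10). The per-gene mean and standard
#' deviation are retained so that query data can later be projected with the
#' training parameters. Zero-variance genes are dropped with a warning.
#'
#' @param nm Normalized genes x cells matrix.
#' @param genes Genes to scale (e.g. from [select_hvg()]).
#' @param clip Cap applied to scaled values.
#' @return List of class `"senpred_scaling"`: `scaled` (cells x genes dense
#'   matrix), `genes`, `gene_mean`, `gene_sd`, `clip`.
#' @export
scale_genes <- function(nm, genes, clip = 10) {
  missing <- setdiff(genes, rownames(nm))
  if (length(missing))
    stop("genes absent from the matrix: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  X <- as.matrix(Matrix::t(nm[genes, , drop = FALSE]))  # cells x genes
  mu <- colMeans(X)
  n <- nrow(X)
  sdv <- sqrt(colSums(sweep(X, 2L, mu)^2) / (n - 1))
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) dropped from scaling", call. = FALSE)
    X <- X[, !zero, drop = FALSE]
    mu <- mu[!zero]; sdv <- sdv[!zero]; genes <- genes[!zero]
  }
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  Z[Z > clip] <- clip
  structure(list(scaled = Z, genes = genes, gene_mean = mu, gene_sd = sdv,
                 clip = clip), class = "senpred_scaling")
}

#' Fit PCA on scaled expression
#'
#' Singular value decomposition of the (re-)centered scaled matrix. The sign
#' of each component is fixed deterministically: the largest-magnitude loading
#' of every PC is made positive. The returned embedding bundles the HVG list,
#' scaling parameters, centering vector, loadings, training scores and
#' explained variances — everything needed to project query cells.
#'
#' @param scaling A `"senpred_scaling"` object from [scale_genes()].
#' @param n_pcs Number of components; default (and `"all"`)
#'   `min(50, n_cells - 1, n_genes)`.
#' @return List of class `"senpred_embedding"` with elements `hvg`,
#'   `gene_mean`, `gene_sd`, `clip`, `center`, `loadings` (genes x PCs),
#'   `scores` (cells x PCs), `explained_variance`.
#' @export
fit_pca <- function(scaling, n_pcs = NULL) {
  stopifnot(inherits(scaling, "senpred_scaling"))
  X <- scaling$scaled
  max_pcs <- min(nrow(X) - 1L, ncol(X))
  if (is.null(n_pcs) || identical(n_pcs, "all")) n_pcs <- min(50L, max_pcs)
  if (n_pcs > max_pcs)
    stop("n_pcs must be at most min(n_cells - 1, n_genes) = ", max_pcs, call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  sv <- svd(Xc, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(k) {
    j <- which.max(abs(sv$v[, k]))
    sv$v[j, k] < 0
  }, logical(1))
  sv$v[, flip] <- -sv$v[, flip]
  sv$u[, flip] <- -sv$u[, flip]
  loadings <- sv$v
  rownames(loadings) <- scaling$genes
  colnames(loadings) <- paste0("PC", seq_len(n_pcs))
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  dimnames(scores) <- list(rownames(X), colnames(loadings))
  structure(list(hvg = scaling$genes, gene_mean = scaling$gene_mean,
                 gene_sd = scaling$gene_sd, clip = scaling$clip,
                 center = center, loadings = loadings, scores = scores,
                 explained_variance = sv$d[seq_len(n_pcs)]^2 / (nrow(X) - 1)),
            class = "senpred_embedding")
}

#' @export
print.senpred_embedding <- function(x, ...) {
  cat("senpred embedding:", length(x$hvg), "genes,", ncol(x$loadings),
      "PCs,", nrow(x$scores), "training cells\n")
  invisible(x)
}

#' SNN-graph Louvain clustering in PC space
#'
#' Builds a k-nearest-neighbor graph on the PC scores (Euclidean distance,
#' each cell's neighbor set includes itself), converts it to a shared
#' nearest-neighbor graph with Jaccard edge weights, prunes edges below
#' `prune`, and partitions it with the Louvain algorithm at the given
#' resolution. The seed fixes tie-breaking, so labels are reproducible.
#' Cluster ids are contiguous from 0, ordered by decreasing size.
#'
#' @param em A `"senpred_embedding"` or a cells x PCs score matrix.
#' @param k Neighborhood size (including self).
#' @param resolution Louvain resolution parameter.
#' @param prune Jaccard cutoff below which SNN edges are dropped.
#' @param seed Random seed for Louvain tie-breaking.
#' @return List of class `"senpred_clusters"`: integer `labels` (0-based,
#'   named by cell), `resolution`, `modularity`, `k`, `prune`.
#' @export
cluster_cells <- function(em, k = 20, resolution = 0.8, prune = 1/15, seed = 42) {
  scores <- if (inherits(em, "senpred_embedding")) em$scores else as.matrix(em)
  n <- nrow(scores)
  if (k >= n) stop("k must be below the number of cells (", n, ")", call. = FALSE)
  d <- as.matrix(stats::dist(scores))
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))  # self is 1st (dist 0)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(nn)),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  snn <- shared / (2 * k - shared)
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  raw <- igraph::membership(cl)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(raw)])
  names(labels) <- rownames(scores)
  structure(list(labels = labels, resolution = resolution,
                 modularity = igraph::modularity(cl), k = k, prune = prune,
                 seed = seed),
            class = "senpred_clusters")
}

#' Cluster-count sweep over Louvain resolutions
#'
#' Reports the number of clusters and modularity across a resolution grid, a
#' programmatic aid for choosing a resolution.
#'
#' @inheritParams cluster_cells
#' @param resolutions Numeric grid of resolutions.
#' @return data.frame with columns `resolution`, `n_clusters`, `modularity`.
#' @export
sweep_resolution <- function(em, resolutions = seq(0.2, 1.2, by = 0.2),
                             k = 20, prune = 1/15, seed = 42) {
  rows <- lapply(resolutions, function(r) {
    cl <- cluster_cells(em, k = k, resolution = r, prune = prune, seed = seed)
    data.frame(resolution = r, n_clusters = length(unique(cl$labels)),
               modularity = cl$modularity)
  })
  do.call(rbind, rows)
}

#' Wilcoxon marker genes per cluster
#'
#' For each cluster versus all other cells, genes are screened on detection
#' fraction (must exceed `min_pct` in the cluster or in the rest) and on
#' absolute log2 fold change of de-logged means with pseudocount 1,
#' `log2((mean(expm1(x))_in + 1) / (mean(expm1(x))_out + 1))`, which must
#' exceed `min_log2fc`. Surviving genes are tested with the Wilcoxon rank-sum
#' test on normalized values; p-values are Bonferroni-adjusted over the genes
#' tested for that cluster. Clusters with fewer than 3 cells are skipped with
#' a warning.
#'
#' @param nm Normalized genes x cells matrix.
#' @param clusters A `"senpred_clusters"` object or per-cell label vector
#'   aligned to the columns of `nm`.
#' @param min_pct Detection-fraction screen.
#' @param min_log2fc Fold-change screen (absolute log2).
#' @return data.frame with columns `gene`, `cluster`, `log2_fc`, `pct_in`,
#'   `pct_out`, `p_value`, `p_adjusted`, ordered by cluster then p-value.
#' @export
find_markers <- function(nm, clusters, min_pct = 0.25, min_log2fc = 0.25) {
  labels <- if (inherits(clusters, "senpred_clusters")) clusters$labels else clusters
  if (length(labels) != ncol(nm))
    stop("cluster labels are not aligned to the matrix columns", call. = FALSE)
  ids <- sort(unique(labels))
  if (length(ids) < 2) stop("at least 2 clusters are required", call. = FALSE)
  out <- list()
  for (cl in ids) {
    in_cells <- labels == cl
    if (sum(in_cells) < 3) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped", call. = FALSE)
      next
    }
    pct_in <- Matrix::rowMeans(nm[, in_cells, drop = FALSE] > 0)
    pct_out <- Matrix::rowMeans(nm[, !in_cells, drop = FALSE] > 0)
    m_in <- Matrix::rowMeans(expm1(nm[, in_cells, drop = FALSE]))
    m_out <- Matrix::rowMeans(expm1(nm[, !in_cells, drop = FALSE]))
    l2fc <- log2((m_in + 1) / (m_out + 1))
    cand <- which((pct_in > min_pct | pct_out > min_pct) & abs(l2fc) > min_log2fc)
    if (!length(cand)) next
    sub <- as.matrix(nm[cand, , drop = FALSE])
    p <- vapply(seq_along(cand), function(i) {
      suppressWarnings(stats::wilcox.test(sub[i, in_cells], sub[i, !in_cells])$p.value)
    }, numeric(1))
    res <- data.frame(gene = rownames(nm)[cand], cluster = cl,
                      log2_fc = l2fc[cand], pct_in = pct_in[cand],
                      pct_out = pct_out[cand], p_value = p,
                      p_adjusted = pmin(1, p * length(cand)),
                      row.names = NULL, stringsAsFactors = FALSE)
    out[[as.character(cl)]] <- res[order(res$p_value), ]
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(gene = character(), cluster = integer(),
                                      log2_fc = numeric(), pct_in = numeric(),
                                      pct_out = numeric(), p_value = numeric(),
                                      p_adjusted = numeric())
  rownames(res) <- NULL
  attr(res, "fold_change") <- "log2, pseudocount 1 on de-logged means"
  attr(res, "adjustment") <- "bonferroni over genes tested per cluster"
  res
}
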