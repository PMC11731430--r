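# Independent oracles and small fixture builders shared across tests.

# Closed-form linear discriminant analysis posterior: class means, pooled
# (maximum-likelihood) covariance plus the same relative ridge used by the EM
# fit, empirical class priors. Coded directly from the Gaussian density with
# solve() rather than Cholesky; shares no code path with fit_mda().
lda_posterior_oracle <- function(X, labels, ridge = 1e-6) {
  X <- as.matrix(X)
  classes <- unique(as.character(labels))
  n <- nrow(X); d <- ncol(X)
  means <- lapply(classes, function(cl) colMeans(X[labels == cl, , drop = FALSE]))
  S <- matrix(0, d, d)
  for (i in seq_along(classes)) {
    ctr <- sweep(X[labels == classes[i], , drop = FALSE], 2, means[[i]])
    S <- S + crossprod(ctr)
  }
  S <- S / n
  S <- S + diag(ridge * mean(diag(S)), d)
  Sinv <- solve(S)
  logdet <- determinant(S, logarithm = TRUE)$modulus
  priors <- table(factor(labels, levels = classes)) / n
  logd <- sapply(seq_along(classes), function(i) {
    ctr <- sweep(X, 2, means[[i]])
    -0.5 * (rowSums((ctr %*% Sinv) * ctr) + as.numeric(logdet) + d * log(2 * pi)) +
      log(as.numeric(priors[i]))
  })
  m <- apply(logd, 1, max)
  p <- exp(logd - m)
  p <- p / rowSums(p)
  colnames(p) <- classes
  p
}

# Gaussian class mixture scores in d dimensions: two labeled classes whose
# means are `sep` apart on the first axis, unit spherical covariance.
make_gaussian_scores <- function(n_per_class = 150, d = 10, sep = 6, seed = 1,
                                 classes = c("EP", "DS")) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_along(classes), function(i) {
    mu <- rep(0, d); mu[1] <- (i - 1) * sep
    matrix(rnorm(n_per_class * d), n_per_class, d) +
      matrix(mu, n_per_class, d, byrow = TRUE)
  }))
  list(X = X, labels = rep(classes, each = n_per_class))
}

# Tiny sparse count matrix from a dense definition, genes x cells.
make_counts <- function(mat, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- sprintf("C%03d", seq_len(ncol(mat)))
  m <- Matrix::Matrix(mat, sparse = TRUE)
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  m
}

# Small default-program simulation reused by several files (cheap: 300 cells).
small_sim <- function(seed = 3, classes = c(EP = 150, DS = 150), n_genes = 300) {
  simulate_counts(simulation_config(n_genes = n_genes, n_de_genes = 60,
                                    classes = classes, seed = seed))
}
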