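# HVG selection, scaling, PCA, SNN-Louvain clustering, marker testing.

sim <- small_sim()
nm <- log_normalize(sim$counts)

test_that("select_hvg returns all genes ranked when fewer exist than requested", {
  hvg <- select_hvg(nm, n = 2000)
  expect_equal(sort(hvg), sort(rownames(nm)))
  expect_equal(length(hvg), nrow(nm))
})

test_that("constant genes never outrank varying genes", {
  m <- as.matrix(sim$counts)
  m <- rbind(m, CONST = 5)           # constant across cells
  cm <- make_counts(m, genes = rownames(m))
  hvg <- select_hvg(log_normalize(cm), n = nrow(m))
  expect_equal(hvg[length(hvg)], "CONST")
})

test_that("genes with planted excess dispersion rank at the top", {
  set.seed(42)
  n_cells <- 400; n_genes <- 300
  mu <- exp(rnorm(n_genes, 1, 0.2))          # matched means
  phi <- rep(0.05, n_genes)
  hot <- sample(n_genes, 20)
  phi[hot] <- 0.5                            # 10x inflated dispersion
  m <- matrix(rnbinom(n_genes * n_cells, mu = rep(mu, n_cells),
                      size = rep(1 / phi, n_cells)), n_genes, n_cells)
  cm <- make_counts(m)
  top <- select_hvg(cm, n = 20)
  expect_setequal(top, rownames(cm)[hot])
})

test_that("scale_genes yields zero mean, unit sd, clipping and parameter identity", {
  hvg <- select_hvg(nm, n = 100)
  sc <- scale_genes(nm, hvg)
  expect_equal(max(abs(colMeans(sc$scaled))), 0, tolerance = 1e-10)
  sds <- apply(sc$scaled, 2, sd)
  expect_equal(unname(sds), rep(1, length(sds)), tolerance = 1e-10)
  # a value far above the mean (~14 sds here) is stored as the clip value
  cm1 <- make_counts(matrix(c(rep(1, 100), 30, rep(1, 100)), 1, 201))
  sc1 <- scale_genes(cm1, rownames(cm1), clip = 2)
  expect_equal(max(sc1$scaled), 2)
  # re-scaling the training data with stored parameters reproduces the input
  Z <- sweep(sweep(as.matrix(Matrix::t(nm[sc$genes, ])), 2, sc$gene_mean),
             2, sc$gene_sd, "/")
  Z[Z > sc$clip] <- sc$clip
  expect_equal(Z, sc$scaled)
})

test_that("scale_genes drops zero-variance genes with a warning", {
  m <- rbind(as.matrix(nm[1:5, ]), CONST = 1)
  expect_warning(sc <- scale_genes(make_counts(m, genes = rownames(m)), rownames(m)),
                 "zero-variance")
  expect_false("CONST" %in% sc$genes)
})

test_that("fit_pca produces an orthonormal, variance-ordered decomposition", {
  sc <- scale_genes(nm, select_hvg(nm, 150))
  em <- fit_pca(sc, n_pcs = 10)
  expect_equal(crossprod(em$loadings), diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(em$explained_variance) <= 1e-10))
  # scores are the centered scaled data times the loadings
  Xc <- sweep(sc$scaled, 2, em$center)
  expect_equal(Xc %*% em$loadings, em$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  # deterministic sign: largest-magnitude loading per PC is positive
  for (k in 1:10) expect_gt(em$loadings[which.max(abs(em$loadings[, k])), k], 0)
})

test_that("PCA recovers exact low rank and reconstructs at full rank", {
  set.seed(5)
  B <- matrix(rnorm(40), 20, 2) %*% matrix(rnorm(2 * 30), 2, 30)  # rank 2
  sc <- structure(list(scaled = B, genes = sprintf("g%d", 1:30),
                       gene_mean = rep(0, 30), gene_sd = rep(1, 30), clip = 10),
                  class = "senpred_scaling")
  em <- fit_pca(sc, n_pcs = 10)
  ev <- em$explained_variance
  expect_lt(sum(ev[3:10]) / sum(ev), 1e-10)
  recon <- em$scores %*% t(em$loadings)
  expect_equal(recon, sweep(B, 2, em$center), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(fit_pca(sc, n_pcs = 25), "n_pcs")
})

test_that("two well-separated blobs cluster into exactly 2 reproducible groups", {
  g <- make_gaussian_scores(n_per_class = 100, d = 5, sep = 25, seed = 9)
  cl <- cluster_cells(g$X)
  expect_equal(length(unique(cl$labels)), 2L)
  expect_equal(sort(unique(cl$labels)), c(0L, 1L))
  expect_length(cl$labels, 200L)
  # same seed, bit-identical labels
  cl2 <- cluster_cells(g$X)
  expect_identical(cl$labels, cl2$labels)
  # each blob is one cluster
  expect_equal(length(unique(cl$labels[1:100])), 1L)
  expect_equal(length(unique(cl$labels[101:200])), 1L)
  # modularity beats the all-singletons partition (modularity < 0 there)
  expect_gt(cl$modularity, 0)
  expect_error(cluster_cells(g$X[1:10, ], k = 20), "k must be below")
})

test_that("resolution sweep reports cluster counts over the grid", {
  g <- make_gaussian_scores(n_per_class = 60, d = 4, sep = 15, seed = 2)
  sw <- sweep_resolution(g$X, resolutions = c(0.4, 0.8))
  expect_equal(nrow(sw), 2L)
  expect_true(all(sw$n_clusters >= 1))
})

test_that("find_markers recovers a planted marker and applies both screens", {
  set.seed(31)
  n <- 120
  cl <- rep(c(0L, 1L), each = n / 2)
  m <- matrix(rnbinom(80 * n, mu = 3, size = 10), 80, n)
  m[1, cl == 0] <- rnbinom(n / 2, mu = 15, size = 10)   # 5x planted marker
  m[2, ] <- rbinom(n, 1, 0.08) * 3                      # detected in <10% everywhere
  m[3, cl == 0] <- rnbinom(n / 2, mu = 3.2, size = 50)  # tiny true fold change
  cm <- make_counts(m)
  nm2 <- log_normalize(cm)
  mk <- find_markers(nm2, cl)
  row <- mk[mk$gene == "G001" & mk$cluster == 0, ]
  expect_equal(nrow(row), 1L)
  expect_gt(row$log2_fc, 0.25)
  expect_lt(row$p_adjusted, 0.05)
  expect_false("G002" %in% mk$gene)
  expect_false("G003" %in% mk$gene)
  expect_true(all(mk$p_adjusted >= mk$p_value))
  expect_true(all(mk$pct_in >= 0 & mk$pct_in <= 1))
})

test_that("find_markers skips tiny clusters and requires 2 clusters", {
  cm <- make_counts(matrix(rpois(40 * 20, 3), 40, 20))
  nm2 <- log_normalize(cm)
  expect_error(find_markers(nm2, rep(0L, 20)), "2 clusters")
  labs <- c(rep(0L, 18), 1L, 1L)
  expect_warning(find_markers(nm2, labs), "fewer than 3")
})

test_that("marker Wilcoxon p-values agree with a permutation oracle", {
  set.seed(77)
  n <- 10
  x <- c(rnorm(n, 0), rnorm(n, 1.1))
  cl <- rep(c(0L, 1L), each = n)
  m <- matrix(1, 2, 2 * n)             # filler gene keeps >=2 genes
  m <- rbind(m, round(exp(x)))
  cm <- make_counts(m)
  nm2 <- log_normalize(cm)
  mk <- suppressWarnings(find_markers(nm2, cl, min_pct = 0, min_log2fc = 0))
  p_pkg <- mk$p_value[mk$gene == "G003" & mk$cluster == 0]
  # rank-sum permutation distribution, 10,000 draws
  v <- as.matrix(nm2)["G003", ]
  obs <- sum(rank(v)[cl == 0])
  stat <- replicate(10000, sum(rank(v)[sample(2 * n, n)]))
  mu <- mean(stat)
  p_perm <- mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
  expect_equal(p_pkg, p_perm, tolerance = 0.05)
})
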