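# Training/evaluation harness: splitting, CV, projection, thresholded
# assignment, metrics, serialization.

sim <- small_sim(seed = 13)
nm <- log_normalize(sim$counts)
labs <- sim$labels
tc <- suppressMessages(train_classifier(nm, labs, method = "mda", n_hvg = 150,
                                        n_pcs = 15, cv_folds = 3, seed = 13))

test_that("stratified_split preserves class proportions, is disjoint and seeded", {
  labels <- rep(c("EP", "DS"), c(60, 40))
  sp <- stratified_split(labels, test_fraction = 0.2, seed = 5)
  expect_equal(sum(labels[sp$test] == "EP"), 12L)
  expect_equal(sum(labels[sp$test] == "DS"), 8L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_identical(sp, stratified_split(labels, 0.2, seed = 5))
  expect_error(stratified_split(rep("EP", 10)), "2 classes")
  expect_error(stratified_split(c(rep("EP", 10), "DS")), "2 cells")
})

test_that("cross-validation reports one entry per fold and training needs 2 classes", {
  tc5 <- suppressMessages(train_classifier(nm, labs, method = "mda", n_hvg = 100,
                                           n_pcs = 10, cv_folds = 5, seed = 1))
  expect_equal(nrow(tc5$cv_metrics), 5L)
  expect_equal(tc5$cv_metrics$fold, 1:5)
  expect_true(all(c("roc_auc", "sensitivity", "specificity") %in%
                    names(tc5$cv_metrics)))
  expect_true(all(tc5$cv_metrics$roc_auc >= 0 & tc5$cv_metrics$roc_auc <= 1))
  expect_error(suppressMessages(train_classifier(nm, rep("EP", ncol(nm)))),
               "2 classes")
})

test_that("evaluate_classifier matches the hand-counted confusion example", {
  # truth EP,EP,DS,DS / predicted EP,DS,DS,DS with DS as positive class:
  # TP=2 FN=0 TN=1 FP=1 -> sensitivity 1, specificity 0.5
  conf <- table(truth = factor(c("EP", "EP", "DS", "DS"), levels = c("EP", "DS")),
                pred = factor(c("EP", "DS", "DS", "DS"), levels = c("EP", "DS")))
  cm <- confusion_metrics(conf)
  expect_equal(unname(cm$sensitivity[2]), 1)
  expect_equal(unname(cm$specificity[2]), 0.5)
  expect_equal(cm$accuracy, 0.75)
})

test_that("sensitivity/specificity agree with brute-force counting on random tables", {
  set.seed(99)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    n <- 60
    truth <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:k], n, replace = TRUE)
    conf <- table(factor(truth, levels = letters[1:k]),
                  factor(pred, levels = letters[1:k]))
    cm <- confusion_metrics(conf)
    for (j in 1:k) {
      cl <- letters[j]
      tp <- sum(truth == cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      tn <- sum(truth != cl & pred != cl)
      fp <- sum(truth != cl & pred == cl)
      expect_identical(unname(cm$sensitivity[j]), tp / (tp + fn))
      expect_identical(unname(cm$specificity[j]), tn / (tn + fp))
    }
    expect_identical(cm$accuracy, mean(truth == pred))
  }
})

test_that("rank-formula ROC-AUC matches pROC and is 0.5 under label permutation", {
  skip_if_not_installed("pROC")
  set.seed(123)
  score <- rnorm(200)
  pos <- rbinom(200, 1, plogis(score)) == 1
  expect_equal(roc_auc(score, pos),
               as.numeric(pROC::auc(pROC::roc(pos, score, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  perm <- sample(pos)
  expect_equal(roc_auc(score, perm),
               as.numeric(pROC::auc(pROC::roc(perm, score, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("perfect predictions give a diagonal confusion, accuracy 1, AUC 1", {
  sp <- stratified_split(labs, 0.25, seed = 3)
  ev <- evaluate_classifier(tc, nm[, sp$test], labs[sp$test])
  # the synthetic classes are fully separated, so the model is exact here
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(ev$roc_auc), rep(1, 2))
  expect_equal(sum(diag(ev$confusion)), ev$n_cells)
  expect_equal(unname(rowSums(ev$confusion_pct)), rep(100, 2))
  expect_error(evaluate_classifier(tc, nm[, sp$test],
                                   rep("XX", length(sp$test))), "outside")
})

test_that("projection of the training matrix reproduces training scores", {
  scores <- suppressMessages(project_query(tc, nm))
  expect_equal(unname(scores), unname(tc$embedding$scores), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(attr(scores, "missing_fraction"), 0)
})

test_that("projection is invariant to gene order and imputes missing HVGs at zero", {
  perm <- sample(nrow(nm))
  s1 <- project_query(tc, nm)
  s2 <- project_query(tc, nm[perm, ])
  expect_equal(s1, s2)
  # deleting one HVG acts exactly as a scaled value of 0 for that gene
  drop <- tc$embedding$hvg[1]
  s3 <- suppressMessages(project_query(tc, nm[setdiff(rownames(nm), drop), ]))
  Z <- sweep(sweep(as.matrix(Matrix::t(nm[tc$embedding$hvg, ])), 2,
                   tc$embedding$gene_mean), 2, tc$embedding$gene_sd, "/")
  Z[Z > tc$embedding$clip] <- tc$embedding$clip
  Z[, drop] <- 0
  manual <- sweep(Z, 2, tc$embedding$center) %*% tc$embedding$loadings
  expect_equal(unname(s3), unname(manual), tolerance = 1e-10, ignore_attr = TRUE)
  # too many missing genes is an error
  expect_error(project_query(tc, nm[tc$embedding$hvg[1:10], ]), "missing")
})

test_that("assignment respects the rejection threshold boundary", {
  pred <- classify_cells(tc, nm)
  expect_s3_class(pred, "senpred_prediction")
  expect_equal(rowSums(as.matrix(pred[, tc$classes])), rep(1, nrow(pred)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # the threshold rule itself, at and just below the boundary
  assign_rule <- function(max_post, arg, thr) if (max_post >= thr) arg else "unassigned"
  expect_equal(assign_rule(0.54, "EP", 0.55), "unassigned")
  expect_equal(assign_rule(0.55, "EP", 0.55), "EP")
  pred_strict <- classify_cells(tc, nm, prob_threshold = 0.999999999)
  expect_true(all(pred_strict$assigned_label %in% c(tc$classes, "unassigned")))
  # the stored summary reports percentages over all and over assigned cells
  s <- attr(pred, "summary")
  expect_equal(sum(s$pct_of_all), 100, tolerance = 1e-9)
})

test_that("argmax posterior picks the labeled class", {
  post <- c(EP = 0.90, ES = 0.05, DS = 0.05)
  expect_equal(names(post)[which.max(post)], "EP")
})

test_that("save/load round-trip classifies identically and validates archives", {
  f <- tempfile(fileext = ".rds")
  save_classifier(tc, f)
  tc2 <- load_classifier(f)
  p1 <- classify_cells(tc, nm[, 1:100])
  p2 <- classify_cells(tc2, nm[, 1:100])
  expect_identical(p1$assigned_label, p2$assigned_label)
  expect_equal(as.matrix(p1[, tc$classes]), as.matrix(p2[, tc$classes]),
               tolerance = 1e-12)
  # truncated archive: error, not a crash
  raw <- readBin(f, "raw", file.info(f)$size)
  trunc <- tempfile(fileext = ".rds")
  writeBin(raw[1:50], trunc)
  expect_error(load_classifier(trunc), "truncated|corrupt")
  # unknown method tag is refused by name
  bad <- tc; bad$method <- "random_forest"
  f2 <- tempfile(fileext = ".rds"); saveRDS(unclass(bad), f2)
  expect_error(load_classifier(f2), "random_forest")
  # format version mismatch is refused
  old <- tc; old$version <- "senpred-classifier-0"
  f3 <- tempfile(fileext = ".rds"); saveRDS(unclass(old), f3)
  expect_error(load_classifier(f3), "format")
})

test_that("CV ROC-AUC does not decrease with synthetic class separation", {
  aucs <- vapply(c(0.2, 0.8, 2), function(fc) {
    s <- simulate_counts(simulation_config(n_genes = 300, n_de_genes = 60,
                                           classes = c(EP = 120, DS = 120),
                                           log2_fc = fc, seed = 17))
    m <- log_normalize(s$counts)
    t <- suppressMessages(train_classifier(m, s$labels, method = "mda",
                                           n_hvg = 100, n_pcs = 10,
                                           cv_folds = 3, seed = 17))
    mean(t$cv_metrics$roc_auc)
  }, numeric(1))
  expect_true(all(diff(aucs) >= -1e-9))
})
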