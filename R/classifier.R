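# Training/evaluation/prediction harness: stratified splitting, CV over PC
# scores, query projection, thresholded assignment, serialization.

CLASSIFIER_FORMAT_VERSION <- "senpred-classifier-1"
KNOWN_METHODS <- c("mda", "svm_rbf", "knn", "glm")

#' Stratified train/test split
#'
#' Splits cells into training and test sets preserving per-class proportions
#' to within one cell, reproducibly under the seed.
#'
#' @param labels Class label per cell.
#' @param test_fraction Fraction held out for testing.
#' @param seed Random seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 42) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("at least 2 classes are required", call. = FALSE)
  if (any(tab < 2)) stop("every class needs at least 2 cells", call. = FALSE)
  set.seed(seed)
  test <- integer(0)
  for (cl in names(tab)) {
    ids <- which(labels == cl)
    n_test <- round(length(ids) * test_fraction)
    test <- c(test, sample(ids, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

# stratified fold assignment, 1..k per cell
.make_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    ids <- sample(which(labels == cl))
    folds[ids] <- rep_len(seq_len(k), length(ids))
  }
  folds
}

#' Area under the ROC curve (rank formula)
#'
#' Mann-Whitney form of the AUC: ties receive average ranks.
#'
#' @param score Numeric classifier score, higher meaning more positive.
#' @param positive Logical (or coercible) positive-class indicator.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-class sensitivity/specificity from a confusion matrix
#'
#' Rows are truth, columns predictions. Sensitivity is TP/(TP+FN) and
#' specificity TN/(TN+FP), one-vs-rest per class.
#'
#' @param confusion Square counts matrix with identical row/column class order.
#' @return List with numeric vectors `sensitivity`, `specificity` and scalar
#'   `accuracy`.
#' @export
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  total <- sum(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- total - tp - fn - fp
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = sum(tp) / total)
}

# ---- method backends ------------------------------------------------------
# Each backend fits on PC scores and returns a model with a posterior matrix
# predictor. Non-MDA methods fit one binary one-vs-rest model per class and
# renormalize the per-class probabilities to sum to 1.

.median_gamma <- function(X, max_n = 500) {
  if (nrow(X) > max_n) X <- X[sample(nrow(X), max_n), , drop = FALSE]
  med <- stats::median(stats::dist(X))
  if (!is.finite(med) || med <= 0) med <- 1
  1 / (2 * med^2)
}

.fit_backend <- function(method, X, y, classes, hyper, seed, subclasses = 3) {
  set.seed(seed)
  if (method == "mda") {
    return(list(kind = "mda",
                fit = fit_mda(X, factor(y, levels = classes),
                              subclasses_per_class = subclasses, seed = seed)))
  }
  if (method == "svm_rbf") {
    gamma <- .median_gamma(X)
    fits <- lapply(classes, function(cl) {
      yy <- factor(y == cl, levels = c(FALSE, TRUE))
      e1071::svm(X, yy, kernel = "radial", cost = hyper$cost, gamma = gamma,
                 probability = TRUE)
    })
    return(list(kind = "svm_rbf", fits = fits, classes = classes, gamma = gamma))
  }
  if (method == "knn") {
    return(list(kind = "knn", X = X, y = y, k = hyper$k, classes = classes))
  }
  if (method == "glm") {
    fits <- lapply(classes, function(cl) {
      df <- data.frame(.y = as.numeric(y == cl), X)
      suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = df))
    })
    return(list(kind = "glm", fits = fits, classes = classes))
  }
  stop("unknown method: ", method, call. = FALSE)
}

.backend_posteriors <- function(model, X, classes, seed = 1) {
  X <- as.matrix(X)
  if (model$kind == "mda") return(mda_posteriors(model$fit, X))
  p <- switch(model$kind,
    svm_rbf = vapply(seq_along(classes), function(i) {
      pr <- stats::predict(model$fits[[i]], X, probability = TRUE)
      attr(pr, "probabilities")[, "TRUE"]
    }, numeric(nrow(X))),
    knn = {
      set.seed(seed)  # class::knn breaks distance ties randomly
      vapply(seq_along(classes), function(i) {
        yy <- factor(model$y == classes[i], levels = c(FALSE, TRUE))
        pr <- class::knn(model$X, X, cl = yy, k = model$k, prob = TRUE)
        win <- attr(pr, "prob")
        ifelse(pr == "TRUE", win, 1 - win)
      }, numeric(nrow(X)))
    },
    glm = vapply(seq_along(classes), function(i) {
      stats::predict(model$fits[[i]], newdata = data.frame(X), type = "response")
    }, numeric(nrow(X))),
    stop("unknown backend kind: ", model$kind, call. = FALSE))
  p <- matrix(p, nrow = nrow(X), dimnames = list(rownames(X), classes))
  p <- pmax(p, 1e-12)
  p / rowSums(p)
}

.hyper_grid <- function(method) {
  switch(method,
    mda = list(list()),
    svm_rbf = lapply(c(0.25, 0.5, 1), function(cost) list(cost = cost)),
    knn = lapply(c(5L, 7L, 9L), function(k) list(k = k)),
    glm = list(list()))
}

# macro metrics for one fitted backend on held-out scores
.fold_metrics <- function(post, truth, classes) {
  pred <- classes[max.col(post, ties.method = "first")]
  conf <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  cm <- confusion_metrics(conf)
  auc <- mean(vapply(classes, function(cl) roc_auc(post[, cl], truth == cl),
                     numeric(1)), na.rm = TRUE)
  c(roc_auc = auc, sensitivity = mean(cm$sensitivity, na.rm = TRUE),
    specificity = mean(cm$specificity, na.rm = TRUE), accuracy = cm$accuracy)
}

#' Train a senescence classifier
#'
#' Full training pipeline on a normalized reference matrix: highly variable
#' gene selection, z-scaling with clipping, PCA, then the chosen classifier on
#' the PC scores. Model selection and reporting use stratified, seeded k-fold
#' cross-validation on the scores; for `svm_rbf` and `knn` a small
#' hyperparameter grid (SVM cost 0.25/0.5/1 with median-heuristic kernel
#' width; k = 5/7/9) is chosen by mean CV ROC-AUC. `mda` fits one joint
#' multiclass model; the other methods fit one binary one-vs-rest model per
#' class with renormalized probabilities.
#'
#' @param nm Normalized genes x cells training matrix (see [log_normalize()]).
#' @param labels Class label per cell (2 or more classes).
#' @param method One of `"mda"`, `"svm_rbf"`, `"knn"`, `"glm"`.
#' @param n_hvg Number of highly variable genes.
#' @param n_pcs `"all"` (default: `min(50, n_cells - 1, n_hvg)`) or an integer.
#' @param cv_folds Number of stratified CV folds.
#' @param prob_threshold Posterior rejection threshold used by
#'   [classify_cells()]; cells below it are labeled `"unassigned"`.
#' @param subclasses_per_class Subclass count for the MDA backend.
#' @param seed Seed controlling splits, initialization and tie-breaking.
#' @return Object of class `"senpred_classifier"`: `method`, `classes`,
#'   `embedding`, `model`, `hyper`, `cv_metrics` (per-fold data.frame),
#'   `cv_summary`, `config`, `version`.
#' @export
train_classifier <- function(nm, labels, method = c("mda", "svm_rbf", "knn", "glm"),
                             n_hvg = 2000, n_pcs = "all", cv_folds = 5,
                             prob_threshold = 0.55, subclasses_per_class = 3,
                             seed = 42) {
  method <- match.arg(method)
  stopifnot(cv_folds >= 2, prob_threshold >= 0.5, prob_threshold < 1)
  labels <- as.character(labels)
  if (length(labels) != ncol(nm))
    stop("labels are not aligned to the matrix columns", call. = FALSE)
  classes <- unique(labels)
  if (length(classes) < 2) stop("training requires at least 2 classes", call. = FALSE)

  hvg <- select_hvg(nm, n = n_hvg)
  scaling <- scale_genes(nm, hvg)
  em <- fit_pca(scaling, n_pcs = n_pcs)
  X <- em$scores

  folds <- .make_folds(labels, cv_folds, seed)
  grid <- .hyper_grid(method)
  grid_metrics <- lapply(grid, function(hyper) {
    per_fold <- t(vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      fit <- .fit_backend(method, X[tr, , drop = FALSE], labels[tr], classes,
                          hyper, seed = seed + f, subclasses = subclasses_per_class)
      post <- .backend_posteriors(fit, X[!tr, , drop = FALSE], classes,
                                  seed = seed + f)
      .fold_metrics(post, labels[!tr], classes)
    }, numeric(4)))
    per_fold
  })
  mean_auc <- vapply(grid_metrics, function(m) mean(m[, "roc_auc"]), numeric(1))
  best <- which.max(mean_auc)
  hyper <- grid[[best]]
  cv <- data.frame(fold = seq_len(cv_folds), grid_metrics[[best]])
  if (length(grid) > 1)
    message("train_classifier: selected ", method, " hyperparameters ",
            paste(names(hyper), unlist(hyper), sep = "=", collapse = ", "),
            " (mean CV ROC-AUC ", signif(mean_auc[best], 4), ")")

  final <- .fit_backend(method, X, labels, classes, hyper, seed = seed,
                        subclasses = subclasses_per_class)
  structure(list(method = method, classes = classes, embedding = em,
                 model = final, hyper = hyper, cv_metrics = cv,
                 cv_summary = colMeans(cv[, -1, drop = FALSE]),
                 config = list(n_hvg = n_hvg, n_pcs = ncol(em$loadings),
                               cv_folds = cv_folds,
                               prob_threshold = prob_threshold,
                               subclasses_per_class = subclasses_per_class,
                               seed = seed, folds = folds),
                 version = CLASSIFIER_FORMAT_VERSION),
            class = "senpred_classifier")
}

#' @export
print.senpred_classifier <- function(x, ...) {
  cat("senpred classifier (", x$method, "): classes ",
      paste(x$classes, collapse = "/"), ", ", length(x$embedding$hvg),
      " genes, ", x$config$n_pcs, " PCs\n", sep = "")
  cat("  mean CV: ", paste(names(x$cv_summary),
                           signif(x$cv_summary, 4), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Project query cells into a trained feature space
#'
#' Restricts the query to the training HVGs, scales with the *training*
#' per-gene mean/sd and clip, imputes genes absent from the query at the
#' training mean (scaled value 0), re-centers with the training centering
#' vector and multiplies by the training loadings. The fraction of missing
#' HVGs is reported via `message()` and attached as attribute
#' `"missing_fraction"`.
#'
#' @param tc A `"senpred_classifier"` or `"senpred_embedding"`.
#' @param nm_query Normalized genes x cells query matrix (same normalization
#'   contract as training).
#' @param max_missing Error if more than this fraction of training HVGs is
#'   absent from the query.
#' @param align Optional hook: a `function(scores, embedding)` returning
#'   adjusted scores, applied after projection. Plain projection is the
#'   default; the hook is the insertion point for a batch-harmonization step
#'   between reference and query when one is wanted.
#' @return Cells x PCs score matrix.
#' @export
project_query <- function(tc, nm_query, max_missing = 0.5, align = NULL) {
  em <- if (inherits(tc, "senpred_classifier")) tc$embedding else tc
  stopifnot(inherits(em, "senpred_embedding"))
  present <- em$hvg[em$hvg %in% rownames(nm_query)]
  missing_fraction <- 1 - length(present) / length(em$hvg)
  if (missing_fraction > max_missing)
    stop(sprintf("%.1f%% of training HVGs are missing from the query (cutoff %.0f%%)",
                 100 * missing_fraction, 100 * max_missing), call. = FALSE)
  if (missing_fraction > 0)
    message(sprintf("project_query: %.2f%% of training HVGs missing; imputed at training mean",
                    100 * missing_fraction))
  n <- ncol(nm_query)
  Z <- matrix(0, n, length(em$hvg), dimnames = list(colnames(nm_query), em$hvg))
  Xp <- as.matrix(Matrix::t(nm_query[present, , drop = FALSE]))
  Zp <- sweep(sweep(Xp, 2L, em$gene_mean[present]), 2L, em$gene_sd[present], "/")
  Zp[Zp > em$clip] <- em$clip
  Z[, present] <- Zp
  Zc <- sweep(Z, 2L, em$center)
  scores <- Zc %*% em$loadings
  if (!is.null(align)) scores <- align(scores, em)
  attr(scores, "missing_fraction") <- missing_fraction
  scores
}

#' Classify query cells with a rejection threshold
#'
#' Projects the query into the training feature space, computes class
#' posteriors with the fitted model, and assigns each cell the argmax class
#' when its maximum posterior is at least `prob_threshold`, `"unassigned"`
#' otherwise. Ties are broken by class order.
#'
#' @inheritParams project_query
#' @param prob_threshold Rejection threshold; defaults to the value stored at
#'   training time (0.55 by default).
#' @return data.frame (class `"senpred_prediction"`): `cell_id`, one posterior
#'   column per class, `max_posterior`, `assigned_label`. Attribute
#'   `"summary"` holds label percentages over all cells and over assigned
#'   cells.
#' @export
classify_cells <- function(tc, nm_query, prob_threshold = NULL, max_missing = 0.5) {
  stopifnot(inherits(tc, "senpred_classifier"))
  if (is.null(prob_threshold)) prob_threshold <- tc$config$prob_threshold
  scores <- project_query(tc, nm_query, max_missing = max_missing)
  post <- .backend_posteriors(tc$model, scores, tc$classes, seed = tc$config$seed)
  max_post <- apply(post, 1L, max)
  arg <- tc$classes[max.col(post, ties.method = "first")]
  label <- ifelse(max_post >= prob_threshold, arg, "unassigned")
  out <- data.frame(cell_id = colnames(nm_query), post, max_posterior = max_post,
                    assigned_label = label, row.names = NULL,
                    stringsAsFactors = FALSE, check.names = FALSE)
  lev <- c(tc$classes, "unassigned")
  pct_all <- 100 * table(factor(label, levels = lev)) / length(label)
  assigned <- label != "unassigned"
  pct_assigned <- if (any(assigned))
    100 * table(factor(label[assigned], levels = tc$classes)) / sum(assigned)
  else table(factor(character(), levels = tc$classes))
  attr(out, "summary") <- list(pct_of_all = pct_all, pct_of_assigned = pct_assigned,
                               prob_threshold = prob_threshold)
  class(out) <- c("senpred_prediction", "data.frame")
  out
}

#' Evaluate a classifier on held-out cells
#'
#' Projects the test cells, classifies by plain argmax (no rejection
#' threshold, so the confusion matrix is complete), and reports the confusion
#' matrix (rows = truth), row-normalized percentages, per-class one-vs-rest
#' sensitivity, specificity and ROC-AUC (macro-averaged across classes), and
#' overall accuracy.
#'
#' @inheritParams project_query
#' @param labels_test Truth label per test cell; must be a subset of the
#'   training classes.
#' @return List of class `"senpred_evaluation"`: `confusion`,
#'   `confusion_pct`, `sensitivity`, `specificity`, `roc_auc`,
#'   `mean_roc_auc`, `accuracy`, `n_cells`.
#' @export
evaluate_classifier <- function(tc, nm_test, labels_test, max_missing = 0.5) {
  stopifnot(inherits(tc, "senpred_classifier"))
  labels_test <- as.character(labels_test)
  unknown <- setdiff(unique(labels_test), tc$classes)
  if (length(unknown))
    stop("test labels outside training classes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  scores <- project_query(tc, nm_test, max_missing = max_missing)
  post <- .backend_posteriors(tc$model, scores, tc$classes, seed = tc$config$seed)
  pred <- tc$classes[max.col(post, ties.method = "first")]
  conf <- table(truth = factor(labels_test, levels = tc$classes),
                predicted = factor(pred, levels = tc$classes))
  cm <- confusion_metrics(conf)
  auc <- vapply(tc$classes, function(cl) roc_auc(post[, cl], labels_test == cl),
                numeric(1))
  pct <- sweep(conf, 1L, pmax(rowSums(conf), 1), "/") * 100
  structure(list(confusion = conf, confusion_pct = pct,
                 sensitivity = stats::setNames(cm$sensitivity, tc$classes),
                 specificity = stats::setNames(cm$specificity, tc$classes),
                 roc_auc = auc, mean_roc_auc = mean(auc, na.rm = TRUE),
                 accuracy = cm$accuracy, n_cells = length(labels_test)),
            class = "senpred_evaluation")
}

#' @export
print.senpred_evaluation <- function(x, ...) {
  cat("senpred evaluation on", x$n_cells, "cells: accuracy",
      signif(x$accuracy, 4), ", macro ROC-AUC", signif(x$mean_roc_auc, 4), "\n")
  print(x$confusion)
  invisible(x)
}

#' Save / load a trained classifier
#'
#' The archive is a single RDS file holding a format-versioned manifest
#' (method tag, class order, configuration, gene list) plus the numeric model
#' arrays. `load_classifier()` refuses archives with a mismatched format
#' version or an unknown method tag, and reports truncated/corrupt files as
#' errors rather than crashing. A loaded classifier reproduces the saved
#' model's posteriors bit-for-bit.
#'
#' @param tc A `"senpred_classifier"`.
#' @param path File path for the archive.
#' @return `save_classifier()` returns `path` invisibly; `load_classifier()`
#'   the restored classifier.
#' @export
save_classifier <- function(tc, path) {
  stopifnot(inherits(tc, "senpred_classifier"))
  saveRDS(tc, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read classifier archive (truncated or corrupt): ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || is.null(obj$version))
    stop("not a senpred classifier archive", call. = FALSE)
  if (!identical(obj$version, CLASSIFIER_FORMAT_VERSION))
    stop("classifier archive format '", obj$version,
         "' does not match supported format '", CLASSIFIER_FORMAT_VERSION, "'",
         call. = FALSE)
  if (!obj$method %in% KNOWN_METHODS)
    stop("unknown method tag in archive: '", obj$method, "'", call. = FALSE)
  class(obj) <- "senpred_classifier"
  obj
}
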