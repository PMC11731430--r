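# Mixture discriminant analysis: per-class Gaussian subclass mixtures with a
# shared covariance, fit by EM on labeled data.

#' Fit a mixture discriminant analysis model
#'
#' Each class j is modeled as a mixture of `subclasses_per_class` Gaussian
#' subclasses sharing a single pooled covariance matrix across all subclasses
#' of all classes: `f_j(x) = sum_r pi_jr N(x; mu_jr, Sigma)`. Because labels
#' are observed, EM runs over the latent subclass memberships only: the E-step
#' computes within-class subclass responsibilities, the M-step updates the
#' subclass weights, subclass means and the responsibility-weighted pooled
#' covariance. The covariance is regularized with a ridge of
#' `ridge * mean(diag(Sigma))` on the diagonal. Subclass means are initialized
#' by per-class k-means under the given seed; the observed-data log-likelihood
#' is tracked and is non-decreasing. Class priors are the empirical class
#' frequencies.
#'
#' A class with fewer cells than the requested subclass count has its subclass
#' count reduced to its cell count, with a warning.
#'
#' @param scores Numeric cells x d matrix (typically PC scores).
#' @param labels Class label per cell; class order follows first appearance
#'   (or factor levels).
#' @param subclasses_per_class Number of Gaussian subclasses per class.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param ridge Relative diagonal regularization of the pooled covariance.
#' @param seed Seed for the k-means initialization.
#' @return Object of class `"senpred_mda"`: `classes`, `class_priors`,
#'   `subclass_weights` (list), `subclass_means` (list of R_j x d matrices),
#'   `shared_cov`, `ridge`, `lambda`, `log_likelihood_trace`, `converged`, `d`.
#' @export
fit_mda <- function(scores, labels, subclasses_per_class = 3, max_iter = 100,
                    tol = 1e-6, ridge = 1e-6, seed = 1) {
  X <- as.matrix(scores)
  d <- ncol(X)
  stopifnot(d >= 1, nrow(X) == length(labels))
  classes <- if (is.factor(labels)) levels(droplevels(labels)) else
    as.character(unique(labels))
  labels <- as.character(labels)
  n <- nrow(X)
  idx <- lapply(classes, function(cl) which(labels == cl))
  names(idx) <- classes
  R <- vapply(classes, function(cl) {
    nj <- length(idx[[cl]])
    if (nj < subclasses_per_class) {
      warning("class '", cl, "' has ", nj, " cells; subclass count reduced to ", nj,
              call. = FALSE)
      as.integer(nj)
    } else as.integer(subclasses_per_class)
  }, integer(1))
  if (any(R < 1)) stop("every class needs at least one cell", call. = FALSE)

  set.seed(seed)
  means <- list(); weights <- list()
  for (cl in classes) {
    Xj <- X[idx[[cl]], , drop = FALSE]
    if (R[[cl]] == 1L) {
      means[[cl]] <- matrix(colMeans(Xj), 1L, d)
      weights[[cl]] <- 1
    } else if (R[[cl]] == nrow(Xj)) {
      means[[cl]] <- unname(Xj)           # one subclass per cell
      weights[[cl]] <- rep(1 / nrow(Xj), nrow(Xj))
    } else {
      km <- suppressWarnings(stats::kmeans(Xj, centers = R[[cl]], nstart = 5,
                                           iter.max = 50))
      means[[cl]] <- unname(km$centers)
      weights[[cl]] <- as.numeric(table(factor(km$cluster, levels = seq_len(R[[cl]])))) /
        nrow(Xj)
      weights[[cl]] <- pmax(weights[[cl]], 1e-8)
      weights[[cl]] <- weights[[cl]] / sum(weights[[cl]])
    }
  }
  priors <- vapply(idx, length, integer(1)) / n

  pool_cov <- function(resp_list) {
    # resp_list[[cl]]: n_j x R_j responsibilities
    S <- matrix(0, d, d)
    for (cl in classes) {
      Xj <- X[idx[[cl]], , drop = FALSE]
      for (r in seq_len(R[[cl]])) {
        w <- resp_list[[cl]][, r]
        ctr <- sweep(Xj, 2L, means[[cl]][r, ])
        S <- S + crossprod(ctr * sqrt(w))
      }
    }
    S / n
  }

  # initial responsibilities: hard assignment to nearest initial center
  resp <- lapply(classes, function(cl) {
    Xj <- X[idx[[cl]], , drop = FALSE]
    D <- outer(rowSums(Xj^2), rep(1, R[[cl]])) -
      2 * Xj %*% t(means[[cl]]) +
      outer(rep(1, nrow(Xj)), rowSums(means[[cl]]^2))
    hard <- max.col(-D, ties.method = "first")
    diag(R[[cl]])[hard, , drop = FALSE]
  })
  names(resp) <- classes

  Sig_raw <- pool_cov(resp)
  lambda <- ridge * mean(diag(Sig_raw))
  if (lambda <= 0) lambda <- ridge
  Sigma <- Sig_raw + diag(lambda, d)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ch <- tryCatch(chol(Sigma), error = function(e)
      stop("shared covariance is singular despite ridge regularization", call. = FALSE))
    # E-step + log-likelihood
    ll <- 0
    for (cl in classes) {
      Xj <- X[idx[[cl]], , drop = FALSE]
      lg <- .log_gauss(Xj, means[[cl]], ch)                       # n_j x R_j
      lg <- sweep(lg, 2L, log(weights[[cl]]), "+")
      m <- apply(lg, 1L, max)
      lse <- m + log(rowSums(exp(lg - m)))
      resp[[cl]] <- exp(lg - lse)
      ll <- ll + sum(lse) + nrow(Xj) * log(priors[[cl]])
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    for (cl in classes) {
      Xj <- X[idx[[cl]], , drop = FALSE]
      Nr <- colSums(resp[[cl]])
      weights[[cl]] <- pmax(Nr, 1e-12) / nrow(Xj)
      weights[[cl]] <- weights[[cl]] / sum(weights[[cl]])
      means[[cl]] <- sweep(t(resp[[cl]]) %*% Xj, 1L, pmax(Nr, 1e-12), "/")
    }
    Sig_raw <- pool_cov(resp)
    lambda <- ridge * mean(diag(Sig_raw))
    if (lambda <= 0) lambda <- ridge
    Sigma <- Sig_raw + diag(lambda, d)
  }

  structure(list(classes = classes, class_priors = priors,
                 subclass_weights = weights, subclass_means = means,
                 shared_cov = Sigma, ridge = ridge, lambda = lambda,
                 log_likelihood_trace = trace, converged = converged, d = d),
            class = "senpred_mda")
}

# log N(x; mu_r, Sigma) for each row of X and each row of M, given chol(Sigma)
.log_gauss <- function(X, M, ch) {
  d <- ncol(X)
  logdet <- 2 * sum(log(diag(ch)))
  # Mahalanobis via triangular solve
  out <- matrix(0, nrow(X), nrow(M))
  for (r in seq_len(nrow(M))) {
    z <- backsolve(ch, t(sweep(X, 2L, M[r, ])), transpose = TRUE)
    out[, r] <- -0.5 * (colSums(z^2) + logdet + d * log(2 * pi))
  }
  out
}

#' Class posteriors from a fitted MDA model
#'
#' Computes `P(class j | x) = prior_j f_j(x) / sum_k prior_k f_k(x)` in log
#' space with per-row max subtraction for numerical stability. Rows sum to 1.
#'
#' @param model A `"senpred_mda"` object.
#' @param scores Numeric cells x d matrix; d must match the model.
#' @return Matrix of posteriors, one row per cell, one column per class (in
#'   model class order).
#' @export
mda_posteriors <- function(model, scores) {
  stopifnot(inherits(model, "senpred_mda"))
  X <- as.matrix(scores)
  if (ncol(X) != model$d)
    stop("score dimension ", ncol(X), " does not match model dimension ", model$d,
         call. = FALSE)
  ch <- chol(model$shared_cov)
  lp <- vapply(model$classes, function(cl) {
    lg <- .log_gauss(X, model$subclass_means[[cl]], ch)
    lg <- sweep(lg, 2L, log(model$subclass_weights[[cl]]), "+")
    m <- apply(lg, 1L, max)
    m + log(rowSums(exp(lg - m))) + log(model$class_priors[[cl]])
  }, numeric(nrow(X)))
  lp <- matrix(lp, nrow = nrow(X), dimnames = list(rownames(X), model$classes))
  mx <- apply(lp, 1L, max)
  post <- exp(lp - mx)
  post / rowSums(post)
}

#' @export
predict.senpred_mda <- function(object, newdata, type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  post <- mda_posteriors(object, newdata)
  if (type == "posterior") return(post)
  object$classes[max.col(post, ties.method = "first")]
}

#' @export
print.senpred_mda <- function(x, ...) {
  cat("senpred MDA model:", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), "),",
      sum(vapply(x$subclass_weights, length, integer(1))), "subclasses, d =", x$d, "\n")
  cat("  converged:", x$converged, "after", length(x$log_likelihood_trace),
      "EM iterations\n")
  invisible(x)
}
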