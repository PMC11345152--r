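#' Cross-validated selection of the CP rank
#'
#' K-fold cross-validation over subjects. For each fold and candidate rank:
#' (1) CP factors are fit on the training subjects only; (2) the basis-space
#' regression coefficient `gamma*` is estimated on the training scores (the
#' closed-form posterior mean, which makes CV deterministic); (3) held-out
#' scores are predicted as `G_test = Z_test gamma*`; (4) held-out maps are
#' reconstructed as `[[ lambda; A1, A2, A3, G_test ]]` with the training
#' weights; (5) the Frobenius norm of `Y_test - Yhat_test` is averaged over
#' folds. The selected rank minimizes the averaged error, ties broken toward
#' the smaller rank.
#'
#' @param y a [contrast_tensor()] (or 4D array).
#' @param Z design matrix (`N x p`, intercept first) or a one-sided formula
#'   used with `data`.
#' @param ranks integer vector of candidate ranks.
#' @param folds number of folds (default 10).
#' @param seed integer seed controlling the (random, seeded) fold assignment
#'   and ALS restarts.
#' @param data data frame of covariates when `Z` is a formula.
#' @param prior optional [fosr_prior()] used for every rank (default weakly
#'   informative).
#' @param aggregate `"mean_norm"` (default) averages per-fold Frobenius norms;
#'   `"norm_of_mean"` takes the Frobenius norm of the fold-averaged residual.
#' @param tol,max_iter,n_restarts ALS settings (lighter defaults than
#'   [cp_decompose()] since CV refits many times).
#' @return an object of class `cpfosr_cv`: `ranks`, `cv_error`,
#'   `selected_rank`, `folds`, `fold_assignment`, `seed`.
#' @export
cv_rank <- function(y, Z, ranks, folds = 10L, seed = 1L, data = NULL,
                    prior = NULL, aggregate = c("mean_norm", "norm_of_mean"),
                    tol = 1e-6, max_iter = 200L, n_restarts = 1L) {
  aggregate <- match.arg(aggregate)
  if (!inherits(y, "contrast_tensor")) y <- contrast_tensor(y)
  if (inherits(Z, "formula")) {
    mf <- stats::model.frame(Z, data)
    Z <- stats::model.matrix(attr(mf, "terms"), mf)
  }
  Z <- as.matrix(Z)
  N <- dim(y$data)[4L]
  if (nrow(Z) != N) stop("`Z` must have one row per subject")
  if (folds < 2L) stop("`folds` must be >= 2")
  ranks <- sort(unique(as.integer(ranks)))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fold_assignment <- sample(rep(seq_len(folds), length.out = N))
  if (min(tabulate(fold_assignment, folds)) < 1L)
    stop("more folds than subjects")
  if (N - max(tabulate(fold_assignment, folds)) < ncol(Z))
    stop("every fold must leave at least p training subjects")

  # per-fold residual sum of squares; both aggregations derive from it
  rss <- matrix(NA_real_, nrow = folds, ncol = length(ranks),
                dimnames = list(NULL, ranks))
  skipped <- logical(length(ranks))
  for (k in seq_len(folds)) {
    tr <- fold_assignment != k
    y_tr <- contrast_tensor(y$data[, , , tr, drop = FALSE], mask = y$mask)
    ytest_mat <- subject_matrix(
      contrast_tensor(y$data[, , , !tr, drop = FALSE], mask = y$mask))
    for (j in seq_along(ranks)) {
      R <- ranks[j]
      if (R >= sum(tr)) {
        skipped[j] <- TRUE
        next
      }
      cp <- cp_decompose(y_tr, R = R, tol = tol, max_iter = max_iter,
                         n_restarts = n_restarts, seed = seed + k)
      G_tr <- project(y_tr, cp)
      post <- posterior_params(G_tr, Z[tr, , drop = FALSE],
                               prior = if (is.null(prior))
                                 fosr_prior(ncol(Z), R) else prior)
      g_test <- Z[!tr, , drop = FALSE] %*% post$gn
      rss[k, j] <- sum((ytest_mat - g_test %*% cp$L)^2)
    }
  }
  if (any(skipped))
    warning("ranks skipped (>= training subjects): ",
            paste(ranks[skipped], collapse = ", "))
  cv_error <- if (aggregate == "mean_norm") {
    colMeans(sqrt(rss))              # average of per-fold Frobenius norms
  } else {
    sqrt(colSums(rss)) / folds       # norm of the stacked residual, averaged
  }
  ok <- is.finite(cv_error)
  if (!any(ok)) stop("no candidate rank could be evaluated")
  selected <- ranks[ok][which.min(cv_error[ok])]  # ascending -> smallest wins ties
  structure(list(ranks = ranks, cv_error = cv_error, folds = folds,
                 fold_assignment = fold_assignment, selected_rank = selected,
                 aggregate = aggregate, seed = seed),
            class = "cpfosr_cv")
}

#' @export
print.cpfosr_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV for CP rank selection\n", x$folds))
  print(data.frame(rank = x$ranks, cv_error = x$cv_error), row.names = FALSE)
  cat(sprintf("selected rank: %d\n", x$selected_rank))
  invisible(x)
}

#' @export
plot.cpfosr_cv <- function(x, ...) {
  graphics::plot(x$ranks, x$cv_error, type = "b", xlab = "CP rank",
                 ylab = "CV Frobenius error", ...)
  graphics::abline(v = x$selected_rank, lty = 2)
  invisible(x)
}
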