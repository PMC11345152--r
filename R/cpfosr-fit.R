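#' Fit the CP tensor-basis function-on-scalar regression model
#'
#' Two-step fit of population-level activation maps from a stack of subject
#' contrast volumes. (1) A rank-`R` CP decomposition of the 4D tensor yields a
#' spatial basis `L` and projector `P`; each subject's map is reduced to `R`
#' basis scores `G = Y_(4)' P`. (2) The scores are regressed on subject
#' covariates, `G = Z gamma* + E*`, with rows of `E*` i.i.d.
#' `N_R(0, Sigma_eps)` and a conjugate Matrix-Normal/Inverse-Wishart prior,
#' so the posterior is available in closed form and sampled exactly
#' (no burn-in needed). Voxel-space coefficient maps are `gamma = gamma* L`.
#'
#' @param formula one-sided formula for the subject covariates, e.g. `~ sex`;
#'   an intercept (the population-average activation map) is always included.
#' @param data data frame of subject covariates, rows in the order of the
#'   tensor's subject dimension.
#' @param tensor a [contrast_tensor()] (or plain 4D array) of subject maps.
#' @param rank CP rank `R`; select it with [cv_rank()].
#' @param M number of posterior draws (default 2000; draws are i.i.d.).
#' @param prior a [fosr_prior()]; default weakly informative prior when `NULL`.
#' @param tol,max_iter,n_restarts ALS settings passed to [cp_decompose()].
#' @param seed integer seed for the ALS restarts and posterior sampling.
#' @return an object of class `cpfosr` with components `cp` (the
#'   [cp_decompose()] basis), `scores` (`N x R`), `Z`, `posterior`, `draws`,
#'   `terms` and `call`. Methods: [coef.cpfosr()], [fitted.cpfosr()],
#'   [residuals.cpfosr()], [predict.cpfosr()], [simulate.cpfosr()],
#'   `summary`, `plot`, and [simbas()] for voxelwise inference.
#' @examples
#' sim <- gen_multisubject(dims = c(8, 8, 8), N = 24, R_true = 2, seed = 5)
#' fit <- cpfosr(~ sex, data = sim$covariates, tensor = sim$tensor,
#'               rank = 2, M = 200, seed = 5)
#' fit
#' dim(coef(fit, space = "voxel"))
#' @export
cpfosr <- function(formula, data, tensor, rank, M = 2000L, prior = NULL,
                   tol = 1e-8, max_iter = 500L, n_restarts = 3L, seed = 1L) {
  if (!inherits(tensor, "contrast_tensor")) tensor <- contrast_tensor(tensor)
  mf <- stats::model.frame(formula, data)
  Z <- stats::model.matrix(attr(mf, "terms"), mf)
  if (nrow(Z) != dim(tensor$data)[4L])
    stop("`data` has ", nrow(Z), " rows but the tensor has ",
         dim(tensor$data)[4L], " subjects")
  cp <- cp_decompose(tensor, R = rank, tol = tol, max_iter = max_iter,
                     n_restarts = n_restarts, seed = seed, build = TRUE)
  G <- project(tensor, cp)
  post <- posterior_params(G, Z, prior = prior)
  draws <- draw_posterior(post, M = M, seed = seed)
  structure(
    list(cp = cp, scores = G, Z = Z, posterior = post, draws = draws,
         terms = attr(mf, "terms"), subject_ids = tensor$subject_ids,
         spatial_dim = dim(tensor$data)[1:3], mask = tensor$mask,
         grid_meta = tensor$grid_meta, seed = seed, call = match.call()),
    class = "cpfosr")
}

#' @export
print.cpfosr <- function(x, ...) {
  cat("CP tensor-basis function-on-scalar regression\n")
  cat("Call: "); print(x$call)
  cat(sprintf("  subjects: %d;  grid: %s (%d voxels);  CP rank: %d\n",
              nrow(x$Z), paste(x$spatial_dim, collapse = " x "),
              ncol(x$cp$L), x$cp$R))
  cat(sprintf("  CP relative fit error: %.4f\n", x$cp$fit_rel_error))
  cat(sprintf("  covariates: %s\n", paste(colnames(x$Z), collapse = ", ")))
  cat(sprintf("  posterior draws: %d (i.i.d.)\n", x$draws$M))
  invisible(x)
}

#' Extract coefficient maps
#'
#' @param object a [cpfosr()] fit.
#' @param space `"basis"` for the `p x R` posterior mean `gn` of `gamma*`,
#'   `"voxel"` for the `p x Nv` posterior mean of `gamma = gamma* L`.
#' @param ... unused.
#' @export
coef.cpfosr <- function(object, space = c("basis", "voxel"), ...) {
  space <- match.arg(space)
  gn <- object$posterior$gn
  rownames(gn) <- colnames(object$Z)
  if (space == "basis") gn else gn %*% object$cp$L
}

#' @export
fitted.cpfosr <- function(object, space = c("basis", "voxel"), ...) {
  space <- match.arg(space)
  object$Z %*% coef(object, space = space)
}

#' Residuals of the basis-space regression
#'
#' @param object a [cpfosr()] fit.
#' @param space `"basis"` for `G - Z gn` (`N x R`), `"voxel"` for the
#'   subject-by-voxel residual of the reconstructed maps.
#' @param ... unused.
#' @export
residuals.cpfosr <- function(object, space = c("basis", "voxel"), ...) {
  space <- match.arg(space)
  if (space == "basis") {
    object$scores - object$Z %*% object$posterior$gn
  } else {
    ymat <- object$scores %*% object$cp$L   # basis-space reconstruction
    ymat - fitted(object, space = "voxel")
  }
}

#' Predict population-level maps for new covariate values
#'
#' @param object a [cpfosr()] fit.
#' @param newdata data frame of covariates; the fit's design is reused when
#'   omitted.
#' @param space `"voxel"` (default) for predicted mean maps (`nrow x Nv`),
#'   `"basis"` for predicted basis scores.
#' @param ... unused.
#' @export
predict.cpfosr <- function(object, newdata = NULL,
                           space = c("voxel", "basis"), ...) {
  space <- match.arg(space)
  Z <- if (is.null(newdata)) object$Z else
    stats::model.matrix(stats::delete.response(object$terms), newdata)
  Z %*% coef(object, space = space)
}

#' Simulate subject maps from the posterior predictive
#'
#' Draws `gamma*`, `Sigma_eps` from the posterior, then new subject scores
#' `G = Z gamma* + E*` with `E*` rows `N_R(0, Sigma_eps)`, and reconstructs
#' voxel-space maps `G L`.
#'
#' @param object a [cpfosr()] fit.
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` matrices (`N x Nv`).
#' @export
simulate.cpfosr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  d <- draw_posterior(object$posterior, M = nsim,
                      seed = if (is.null(seed)) stats::runif(1, 0, 2^30) else seed)
  lapply(seq_len(nsim), function(m) {
    est <- object$Z %*% d$gamma_star[, , m]
    estar <- matrix(stats::rnorm(nrow(object$Z) * object$cp$R), nrow(object$Z)) %*%
      chol_jitter(d$sigma_eps[, , m])
    (est + estar) %*% object$cp$L
  })
}

#' @export
summary.cpfosr <- function(object, ...) {
  gs <- object$draws$gamma_star
  qs <- apply(gs, c(1, 2), stats::quantile, probs = c(0.025, 0.5, 0.975))
  tab <- data.frame(
    coefficient = rep(colnames(object$Z), times = object$cp$R),
    component = rep(seq_len(object$cp$R), each = ncol(object$Z)),
    mean = as.vector(object$posterior$gn),
    sd = as.vector(apply(gs, c(1, 2), stats::sd)),
    q2.5 = as.vector(qs[1, , ]), median = as.vector(qs[2, , ]),
    q97.5 = as.vector(qs[3, , ]))
  out <- list(fit = object, basis_coef = tab)
  class(out) <- "summary.cpfosr"
  out
}

#' @export
print.summary.cpfosr <- function(x, ...) {
  print(x$fit)
  cat("\nBasis-space coefficients (posterior):\n")
  print(utils::head(x$basis_coef, 20), row.names = FALSE, digits = 3)
  if (nrow(x$basis_coef) > 20)
    cat("  ... (", nrow(x$basis_coef) - 20, " more rows)\n", sep = "")
  invisible(x)
}

#' Plot a mid-axial slice of a coefficient map
#'
#' @param x a [cpfosr()] fit.
#' @param coefficient name or index of the covariate map to show.
#' @param slice index along the third spatial dimension (middle by default).
#' @param ... passed to [graphics::image()].
#' @export
plot.cpfosr <- function(x, coefficient = 1L, slice = NULL, ...) {
  maps <- coef(x, space = "voxel")
  if (is.character(coefficient)) coefficient <- match(coefficient, colnames(x$Z))
  vol <- grid_vector(maps[coefficient, ], x$spatial_dim, x$mask, fill = 0)
  if (is.null(slice)) slice <- ceiling(x$spatial_dim[3] / 2)
  graphics::image(vol[, , slice], main = paste0(colnames(x$Z)[coefficient],
                                                " (slice ", slice, ")"),
                  useRaster = TRUE, ...)
  invisible(x)
}
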