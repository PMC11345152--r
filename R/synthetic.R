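#' Generate a multi-subject contrast tensor with known low-rank truth
#'
#' Simulates the model the package fits: smooth unimodal ("blob") spatial
#' components of exact CP rank `R_true`, subject scores driven by covariates
#' (`G = Z gamma*_true + subject noise`), and i.i.d. Gaussian voxel noise:
#' `Y = fold(G L_true, 4) + noise`. The design has an intercept, a binary
#' covariate `sex` (when `p >= 2`), and standardized continuous covariates for
#' any further columns. Regenerating with the same seed reproduces the tensor
#' bit-identically.
#'
#' Spatial components are outer products of 1D Gaussian bumps with distinct
#' peak locations, which mimics focal activation topology while guaranteeing
#' exact CP rank; the weights `lambda` decrease linearly. The signal-to-noise
#' ratio is defined as `||Z gamma* L||_F / ||voxel noise||_F`; passing `snr`
#' overrides `sigma_voxel` to hit that ratio in expectation.
#'
#' @param dims integer 3-vector of spatial dimensions (each >= 4).
#' @param N number of subjects (must exceed `p`).
#' @param R_true generating CP rank (must not exceed any spatial dimension).
#' @param p number of design columns including the intercept.
#' @param effect_scales length-p vector scaling each covariate's basis-space
#'   effect; a zero entry makes that covariate's true map identically zero.
#' @param sigma_subject sd of the subject-score noise `E*`.
#' @param sigma_voxel sd of the i.i.d. voxel noise (ignored when `snr` given).
#' @param snr optional target `||signal||_F / ||noise||_F`.
#' @param seed integer seed.
#' @return list with `tensor` (a [contrast_tensor()]), `covariates` (data
#'   frame), `Z` (design matrix) and `truth` (class `synthetic_truth`:
#'   `lam_true`, `factors_true`, `L_true`, `gamma_true` (`p x R`),
#'   `gamma_vox_true` (`p x Nv`), `G_true`, `sigma_subject`, `sigma_voxel`,
#'   `snr`, `seed`).
#' @export
gen_multisubject <- function(dims = c(30, 30, 30), N = 50, R_true = 4, p = 2,
                             effect_scales = c(1, rep(0.5, p - 1)),
                             sigma_subject = 0.2, sigma_voxel = 0.05,
                             snr = NULL, seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 4L)) stop("`dims` must be 3 values >= 4")
  if (R_true > min(dims))
    stop("`R_true` must not exceed the smallest spatial dimension")
  if (N <= p) stop("`N` must exceed p")
  if (length(effect_scales) != p) stop("`effect_scales` must have length p")
  set.seed(as.integer(seed) %% .Machine$integer.max)

  # unit-norm smooth spatial factors: distinct bump peaks per component/mode
  bump <- function(len, r) {
    centers <- seq(0.2, 0.8, length.out = R_true)[r]
    x <- seq(0, 1, length.out = len)
    prof <- exp(-(x - centers)^2 / (2 * 0.12^2))
    prof / sqrt(sum(prof^2))
  }
  factors_true <- lapply(1:3, function(k)
    sapply(seq_len(R_true), function(r) bump(dims[k], r)))
  lam_true <- seq(1, 0.5, length.out = R_true) * prod(dims)^(1 / 4)
  L_true <- lam_true * t(khatri_rao(rev(factors_true)))   # R x Nv

  # design: intercept, binary sex, then standardized continuous covariates
  covariates <- data.frame(row.names = seq_len(N))
  if (p >= 2) covariates$sex <- rep_len(c(0L, 1L), N)[sample(N)]
  if (p >= 3) for (j in 3:p)
    covariates[[paste0("x", j - 1L)]] <- as.numeric(scale(stats::rnorm(N)))
  Z <- cbind("(Intercept)" = 1, as.matrix(covariates))

  gamma_true <- matrix(stats::rnorm(p * R_true), p, R_true) * effect_scales
  G_true <- Z %*% gamma_true +
    matrix(stats::rnorm(N * R_true, sd = sigma_subject), N, R_true)

  signal_mat <- G_true %*% L_true                          # N x Nv
  Nv <- prod(dims)
  if (!is.null(snr)) {
    mean_norm <- sqrt(sum((Z %*% gamma_true %*% L_true)^2))
    sigma_voxel <- mean_norm / (snr * sqrt(N * Nv))
  }
  noise <- matrix(stats::rnorm(N * Nv, sd = sigma_voxel), N, Nv)
  tensor <- contrast_tensor(fold(t(signal_mat + noise), 4L, c(dims, N)))

  truth <- structure(
    list(lam_true = lam_true, factors_true = factors_true, L_true = L_true,
         gamma_true = gamma_true, gamma_vox_true = gamma_true %*% L_true,
         G_true = G_true, sigma_subject = sigma_subject,
         sigma_voxel = sigma_voxel,
         snr = sqrt(sum((Z %*% gamma_true %*% L_true)^2)) /
           max(sqrt(sum(noise^2)), .Machine$double.xmin),
         seed = seed),
    class = "synthetic_truth")
  list(tensor = tensor, covariates = covariates, Z = Z, truth = truth)
}

#' Null simulation: intercept effect only
#'
#' Same generator as [gen_multisubject()] with every covariate effect zeroed
#' except the intercept, for error-rate and coverage simulations (the true
#' map of each non-intercept covariate is identically zero).
#'
#' @inheritParams gen_multisubject
#' @param intercept_scale effect scale of the intercept.
#' @param ... further arguments passed to [gen_multisubject()].
#' @export
gen_null <- function(dims = c(30, 30, 30), N = 50, R_true = 4, seed = 1L,
                     p = 2, intercept_scale = 1, ...) {
  gen_multisubject(dims = dims, N = N, R_true = R_true, p = p,
                   effect_scales = c(intercept_scale, rep(0, p - 1)),
                   seed = seed, ...)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic truth: R_true = %d, p = %d, snr = %.3g\n",
              length(x$lam_true), nrow(x$gamma_true), x$snr))
  cat(sprintf("  sigma_subject = %g, sigma_voxel = %g, seed = %d\n",
              x$sigma_subject, x$sigma_voxel, x$seed))
  invisible(x)
}
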