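#' Matrix-Normal / Inverse-Wishart prior for the basis-space regression
#'
#' Prior for the basis-space model `G = Z gamma* + E*` with rows of `E*`
#' i.i.d. `N_R(0, Sigma_eps)`:
#' `gamma* ~ MN(g0, L0^-1, Sigma_eps)` and `Sigma_eps ~ InvWishart(V0, nu0)`.
#' Defaults are weakly informative: `g0 = 0`, `L0 = l0_scale * I_p` (near
#' flat), `V0 = v0_scale * I_R`, `nu0 = R + 2` (the smallest integer degrees
#' of freedom giving a finite prior mean for `Sigma_eps`).
#'
#' @param p number of covariate columns (including the intercept).
#' @param R basis rank.
#' @param g0 `p x R` prior mean matrix (scalar is recycled).
#' @param L0 `p x p` symmetric positive semidefinite row-precision, or a
#'   scalar multiplying the identity.
#' @param V0 `R x R` symmetric positive definite scale, or a scalar
#'   multiplying the identity.
#' @param nu0 degrees of freedom, must exceed `R - 1`.
#' @return an object of class `fosr_prior`.
#' @export
fosr_prior <- function(p, R, g0 = 0, L0 = 1e-6, V0 = 1, nu0 = R + 2) {
  if (length(g0) == 1L) g0 <- matrix(g0, p, R)
  g0 <- as.matrix(g0)
  if (!all(dim(g0) == c(p, R))) stop("`g0` must be a ", p, " x ", R, " matrix")
  if (length(L0) == 1L) L0 <- diag(L0, p)
  if (length(V0) == 1L) V0 <- diag(V0, R)
  L0 <- as.matrix(L0); V0 <- as.matrix(V0)
  check_sym_psd(L0, "L0", strict = FALSE)
  check_sym_psd(V0, "V0", strict = TRUE)
  if (nu0 <= R - 1) stop("`nu0` must exceed R - 1 = ", R - 1)
  structure(list(p = p, R = R, g0 = g0, L0 = L0, V0 = V0, nu0 = nu0),
            class = "fosr_prior")
}

check_sym_psd <- function(m, name, strict) {
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("`", name, "` must be a symmetric square matrix")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  lo <- if (strict) .Machine$double.eps * max(abs(ev), 1) else -1e-10 * max(abs(ev), 1)
  if (min(ev) < lo)
    stop("`", name, "` must be positive ", if (strict) "definite" else "semidefinite")
  invisible(TRUE)
}

#' Conjugate posterior of the basis-space regression
#'
#' Closed-form Matrix-Normal/Inverse-Wishart update for `G = Z gamma* + E*`:
#' `Ln = Z'Z + L0`, `gn = Ln^-1 (Z'G + L0 g0)`, `nun = nu0 + N`, and
#' `Vn = V0 + (G - Z gn)'(G - Z gn) + (gn - g0)' L0 (gn - g0)`.
#'
#' @param G `N x R` matrix of subject basis scores (see [project()]).
#' @param Z `N x p` design matrix (first column the intercept).
#' @param prior a [fosr_prior()]; defaults are used when `NULL`.
#' @return an object of class `fosr_posterior` with `gn`, `Ln`, `Vn`, `nun`.
#' @export
posterior_params <- function(G, Z, prior = NULL) {
  G <- as.matrix(G); Z <- as.matrix(Z)
  if (nrow(G) != nrow(Z)) stop("`G` and `Z` must have the same number of rows")
  N <- nrow(Z); p <- ncol(Z); R <- ncol(G)
  if (N <= p) warning("N <= p: the design has as many covariates as subjects")
  if (is.null(prior)) prior <- fosr_prior(p, R)
  stopifnot(inherits(prior, "fosr_prior"))
  if (prior$p != p || prior$R != R)
    stop("prior dimensions (p = ", prior$p, ", R = ", prior$R,
         ") do not match the data (p = ", p, ", R = ", R, ")")
  Ln <- crossprod(Z) + prior$L0
  gn <- tryCatch(solve(Ln, crossprod(Z, G) + prior$L0 %*% prior$g0),
                 error = function(e)
                   stop("posterior precision Ln is singular ",
                        "(rank-deficient Z with a flat prior): ",
                        conditionMessage(e)))
  resid <- G - Z %*% gn
  dg <- gn - prior$g0
  Vn <- prior$V0 + crossprod(resid) + t(dg) %*% prior$L0 %*% dg
  Vn <- (Vn + t(Vn)) / 2
  structure(list(gn = gn, Ln = Ln, Vn = Vn, nun = prior$nu0 + N,
                 N = N, p = p, R = R, prior = prior),
            class = "fosr_posterior")
}

#' @export
print.fosr_posterior <- function(x, ...) {
  cat(sprintf("Matrix-Normal/Inverse-Wishart posterior (p = %d, R = %d, N = %d)\n",
              x$p, x$R, x$N))
  cat(sprintf("  nun = %g\n", x$nun))
  invisible(x)
}

#' Sample from the conjugate posterior
#'
#' Exact two-block composition sampling from the closed-form posterior: each
#' draw takes `Sigma_eps ~ InvWishart(Vn, nun)` then
#' `gamma* | Sigma_eps ~ MN(gn, Ln^-1, Sigma_eps)`. Because both blocks are
#' the exact marginal/conditional, the draws are i.i.d.; `burn` and `thin`
#' are accepted for interface compatibility with MCMC-style workflows but
#' default to 0 and 1.
#'
#' @param post a [posterior_params()] result.
#' @param M number of retained draws.
#' @param seed integer seed; identical seeds reproduce the draws exactly.
#' @param burn,thin discarded initial draws and thinning stride.
#' @return an object of class `fosr_draws`: `gamma_star` (`p x R x M` array),
#'   `sigma_eps` (`R x R x M` array), `M`, `seed`.
#' @export
draw_posterior <- function(post, M, seed = 1L, burn = 0L, thin = 1L) {
  stopifnot(inherits(post, "fosr_posterior"))
  if (M < 1L) stop("`M` must be >= 1")
  R <- post$R; p <- post$p
  if (post$nun <= R - 1) stop("improper posterior: nun <= R - 1")
  M_total <- burn + M * thin
  set.seed(as.integer(seed) %% .Machine$integer.max)

  Vn_inv <- chol2inv(chol_jitter(post$Vn))
  Vn_inv <- (Vn_inv + t(Vn_inv)) / 2
  # Wishart draws W ~ W(Vn^-1, nun); Sigma_eps = W^-1 ~ InvWishart(Vn, nun)
  W <- stats::rWishart(M_total, df = post$nun, Sigma = Vn_inv)
  Ln_chol <- chol_jitter(post$Ln)              # upper U, U'U = Ln
  A <- backsolve(Ln_chol, diag(p))             # A A' = Ln^-1

  keep <- logical(M_total)
  keep[burn + seq.int(thin, M * thin, by = thin)] <- TRUE
  gamma_star <- array(NA_real_, dim = c(p, R, M))
  sigma_eps <- array(NA_real_, dim = c(R, R, M))
  j <- 0L
  for (m in seq_len(M_total)) {
    sig <- chol2inv(chol_jitter(W[, , m]))
    sig <- (sig + t(sig)) / 2
    x <- matrix(stats::rnorm(p * R), p, R)
    g <- post$gn + A %*% x %*% chol_jitter(sig)
    if (keep[m]) {
      j <- j + 1L
      gamma_star[, , j] <- g
      sigma_eps[, , j] <- sig
    }
  }
  structure(list(gamma_star = gamma_star, sigma_eps = sigma_eps,
                 M = M, seed = seed, burn = burn, thin = thin),
            class = "fosr_draws")
}

# Cholesky with a tiny diagonal jitter retry on near-singular input
chol_jitter <- function(m, jitter = 1e-10) {
  tryCatch(chol(m), error = function(e) {
    tryCatch(chol(m + diag(jitter * max(diag(m), 1), nrow(m))),
             error = function(e2)
               stop("Cholesky factorization failed even with jitter: ",
                    conditionMessage(e2)))
  })
}

#' @export
print.fosr_draws <- function(x, ...) {
  d <- dim(x$gamma_star)
  cat(sprintf("%d posterior draws of gamma* (%d x %d) and Sigma_eps (%d x %d)\n",
              x$M, d[1], d[2], dim(x$sigma_eps)[1], dim(x$sigma_eps)[2]))
  invisible(x)
}
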