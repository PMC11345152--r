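#' CP decomposition of a multi-subject contrast tensor
#'
#' Fits a rank-`R` canonical polyadic (CP) decomposition
#' `Y ~ [[ lambda; A1, A2, A3, G ]]` by alternating least squares (ALS),
#' minimizing the Frobenius norm of the residual. All factor columns are
#' normalized to unit Euclidean norm with the magnitudes absorbed into the
#' nonnegative weight vector `lambda`; components are ordered by decreasing
#' weight. The first restart is initialized from truncated SVDs of the mode
#' unfoldings, further restarts from seeded random factors, and the best fit
#' over restarts is kept, so the result is deterministic given `seed`.
#'
#' @param y a [contrast_tensor()] or a plain 4D (or K-D) numeric array.
#' @param R CP rank (number of rank-one components), a positive integer.
#' @param tol convergence tolerance on the relative change of the fit
#'   (relative Frobenius error) between ALS sweeps.
#' @param max_iter maximum ALS sweeps per restart.
#' @param n_restarts number of initializations (1 SVD-based + the rest random).
#' @param seed integer seed controlling the random restarts.
#' @param build if `TRUE` (default) also fill the spatial basis `L` and
#'   projector `P` via [build_basis()] (4D input only).
#' @return an object of class `cp_basis` with elements `lam` (weights),
#'   `A1`, `A2`, `A3` (unit-column spatial factors), `G` (unit-column subject
#'   factor), `fit_rel_error`, `converged`, `n_iter`, and -- after
#'   [build_basis()] -- the `R x Nv` basis `L` and `Nv x R` projector `P`.
#' @references Kolda, T. G. and Bader, B. W. (2009) Tensor decompositions and
#'   applications. SIAM Review 51(3), 455-500.
#' @export
cp_decompose <- function(y, R, tol = 1e-8, max_iter = 500L, n_restarts = 3L,
                         seed = 1L, build = TRUE) {
  is_ct <- inherits(y, "contrast_tensor")
  x <- if (is_ct) y$data else y
  if (is.null(dim(x)) || length(dim(x)) < 2L)
    stop("`y` must be an array of order >= 2")
  if (!all(is.finite(x)))
    stop("tensor contains non-finite values; clean or mask them before fitting")
  if (R < 1L || R != round(R)) stop("`R` must be a positive integer")
  R <- as.integer(R)
  d <- dim(x)
  K <- length(d)

  # voxels that are exactly zero for every subject yield zero basis columns;
  # they are kept in the fit but counted for reporting
  n_zero_vox <- if (K == 4L) {
    sum(rowSums(abs(unfold(x, 4L))) == 0)
  } else 0L

  set.seed(as.integer(seed) %% .Machine$integer.max)
  xt <- lapply(seq_len(K), function(n) t(unfold(x, n)))  # p_n x prod(others)
  norm_x <- sqrt(sum(x^2))

  best <- NULL
  for (rs in seq_len(max(1L, as.integer(n_restarts)))) {
    init <- cp_init(xt, d, R, svd_init = (rs == 1L))
    fit <- cp_als_core(xt, d, R, init, norm_x, tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$fit_rel_error < best$fit_rel_error) best <- fit
  }

  # normalize every mode, absorb magnitudes into lambda, order by weight
  lam <- best$lam
  factors <- best$factors
  for (n in seq_len(K)) {
    nrm <- sqrt(colSums(factors[[n]]^2))
    nrm[nrm == 0] <- 1
    factors[[n]] <- sweep(factors[[n]], 2L, nrm, "/")
    lam <- lam * nrm
  }
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]
  factors <- lapply(factors, function(a) a[, ord, drop = FALSE])

  out <- structure(
    list(R = R, lam = lam, factors = factors,
         fit_rel_error = best$fit_rel_error,
         converged = best$converged, n_iter = best$n_iter,
         dims = d, n_zero_voxels = n_zero_vox,
         mask = if (is_ct) y$mask else NULL,
         grid_meta = if (is_ct) y$grid_meta else NULL,
         L = NULL, P = NULL),
    class = "cp_basis")
  if (K == 4L) {
    names(out$factors) <- c("A1", "A2", "A3", "G")
    out$A1 <- out$factors[[1L]]; out$A2 <- out$factors[[2L]]
    out$A3 <- out$factors[[3L]]; out$G <- out$factors[[4L]]
    if (build) out <- build_basis(out)
  }
  out
}

# SVD or random initialization for modes 2..K (mode 1 is updated first)
cp_init <- function(xt, d, R, svd_init) {
  K <- length(d)
  lapply(seq_len(K), function(n) {
    if (n == 1L) return(matrix(0, d[n], R))
    a <- matrix(stats::rnorm(d[n] * R), d[n], R)
    if (svd_init) {
      r_svd <- min(R, d[n], ncol(xt[[n]]))
      sv <- svd(xt[[n]], nu = r_svd, nv = 0L)
      a[, seq_len(r_svd)] <- sv$u
    }
    sweep(a, 2L, pmax(sqrt(colSums(a^2)), .Machine$double.eps), "/")
  })
}

# one ALS run; factors kept unit-column with weights in lam
cp_als_core <- function(xt, d, R, factors, norm_x, tol, max_iter) {
  K <- length(d)
  gram <- lapply(factors, crossprod)
  lam <- rep(1, R)
  rel_err <- Inf
  converged <- FALSE
  it <- 0L
  if (norm_x == 0) {
    return(list(factors = factors, lam = rep(0, R), fit_rel_error = 0,
                converged = TRUE, n_iter = 0L))
  }
  for (it in seq_len(max_iter)) {
    for (n in seq_len(K)) {
      others <- rev(setdiff(seq_len(K), n))       # descending mode order
      kr <- khatri_rao(factors[others])
      u <- xt[[n]] %*% kr                         # p_n x R (MTTKRP)
      w <- Reduce("*", gram[others])              # Hadamard of Gramians
      a_tilde <- tryCatch(t(solve(w, t(u))), error = function(e) {
        t(solve(w + diag(1e-12 * mean(diag(w)) + 1e-300, R), t(u)))
      })
      if (n == K) {
        # cheap exact fit: ||X - Xhat||^2 from the last-mode update
        err2 <- norm_x^2 - 2 * sum(u * a_tilde) + sum(crossprod(a_tilde) * w)
        new_rel <- sqrt(max(err2, 0)) / norm_x
      }
      lam <- sqrt(colSums(a_tilde^2))
      lam[lam == 0] <- .Machine$double.eps
      factors[[n]] <- sweep(a_tilde, 2L, lam, "/")
      gram[[n]] <- crossprod(factors[[n]])
    }
    if (is.finite(rel_err) && abs(rel_err - new_rel) < tol * max(rel_err, .Machine$double.eps)) {
      rel_err <- new_rel
      converged <- TRUE
      break
    }
    rel_err <- new_rel
  }
  list(factors = factors, lam = lam, fit_rel_error = rel_err,
       converged = converged, n_iter = it)
}

#' Build the spatial basis L and projector P from CP factors
#'
#' Forms `L = Lambda (A3 (x) A2 (x) A1)^T` (Khatri-Rao product, first spatial
#' index varying fastest, matching [unfold()]'s mode-4 row ordering) of shape
#' `R x Nv`, and the Moore-Penrose pseudoinverse `P = L^+` of shape `Nv x R`
#' used to project subject maps down to `R` basis scores. When the source
#' tensor carries a mask, only mask voxels enter the linearization.
#'
#' @param cp a `cp_basis` from [cp_decompose()].
#' @return `cp` with `L`, `P` and `effective_rank` filled; a warning is issued
#'   when `L` is row-rank deficient.
#' @export
build_basis <- function(cp) {
  stopifnot(inherits(cp, "cp_basis"))
  if (is.null(cp$A1)) stop("spatial factors are missing; fit a 4D tensor first")
  L <- cp$lam * t(khatri_rao(list(cp$A3, cp$A2, cp$A1)))  # R x Nv (full grid)
  if (!is.null(cp$mask)) L <- L[, as.vector(cp$mask), drop = FALSE]
  sv <- svd(L, nu = 0L, nv = 0L)$d
  eff_rank <- sum(sv > max(dim(L)) * .Machine$double.eps * max(sv, 0))
  if (eff_rank < cp$R)
    warning("basis L is rank deficient: effective rank ", eff_rank,
            " < R = ", cp$R)
  cp$L <- L
  cp$P <- MASS::ginv(L)
  cp$effective_rank <- eff_rank
  cp
}

#' Project subject maps onto the CP basis
#'
#' Returns the `N x R` score matrix `Y_(4)^T P`, the least-squares coordinates
#' of each subject's map in the spatial basis. For a tensor reconstructed
#' exactly from the basis this recovers the subject factor `G`.
#'
#' @param y a [contrast_tensor()] (or 4D array) on the same grid/mask as `cp`.
#' @param cp a `cp_basis` with `L`, `P` built.
#' @return `N x R` numeric matrix of subject scores.
#' @export
project <- function(y, cp) {
  stopifnot(inherits(cp, "cp_basis"))
  if (is.null(cp$P)) stop("basis not built; call build_basis() first")
  if (!inherits(y, "contrast_tensor"))
    y <- contrast_tensor(y, mask = cp$mask)
  if (!all(dim(y$data)[1:3] == cp$dims[1:3]))
    stop("spatial dimensions of `y` do not match the basis")
  if (n_voxels(y) != nrow(cp$P))
    stop("voxel count of `y` (", n_voxels(y),
         ") does not match the basis projector (", nrow(cp$P), ")")
  subject_matrix(y) %*% cp$P
}

#' @export
print.cp_basis <- function(x, ...) {
  cat(sprintf("CP tensor basis (rank %d)\n", x$R))
  cat(sprintf("  dims: %s\n", paste(x$dims, collapse = " x ")))
  cat(sprintf("  relative Frobenius fit error: %.6g\n", x$fit_rel_error))
  cat(sprintf("  converged: %s (%d sweeps)\n", x$converged, x$n_iter))
  if (!is.null(x$L))
    cat(sprintf("  basis L: %d x %d;  projector P: %d x %d\n",
                nrow(x$L), ncol(x$L), nrow(x$P), ncol(x$P)))
  if (x$n_zero_voxels > 0)
    cat(sprintf("  note: %d all-zero voxels retained (zero basis columns)\n",
                x$n_zero_voxels))
  invisible(x)
}
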