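#' Mode-n matricization (unfolding) of a tensor
#'
#' Rearranges a K-order tensor into a matrix with the `mode` index along the
#' *columns*: column `k` of the result holds the slice of `x` with the mode
#' index fixed at `k`, linearized over the remaining modes with the first
#' remaining mode varying fastest. For a 2x3x4 tensor unfolded along mode 3,
#' column `k` is `(x[1,1,k], x[2,1,k], x[1,2,k], x[2,2,k], x[1,3,k], x[2,3,k])`.
#'
#' Note this is the transpose of the more common convention that puts the mode
#' index along the rows; [fold()] inverts it exactly.
#'
#' @param x array (any order >= 1).
#' @param mode integer in `1..length(dim(x))`; the mode mapped to columns.
#' @return a `prod(dim(x)[-mode]) x dim(x)[mode]` matrix.
#' @seealso [fold()], [khatri_rao()]
#' @export
#' @examples
#' x <- array(1:24, dim = c(2, 3, 4))
#' unfold(x, 3)[, 2]  # the vectorized slice x[, , 2]
unfold <- function(x, mode) {
  if (is.null(dim(x))) dim(x) <- length(x)
  d <- dim(x)
  K <- length(d)
  if (!is.numeric(mode) || length(mode) != 1L || mode < 1L || mode > K || mode != round(mode))
    stop("`mode` must be a single integer in 1..", K)
  mode <- as.integer(mode)
  perm <- c(setdiff(seq_len(K), mode), mode)
  xp <- aperm(x, perm)
  dim(xp) <- c(prod(d[-mode]), d[mode])
  xp
}

#' Fold a matricized tensor back into array form
#'
#' Exact inverse of [unfold()]: `fold(unfold(x, m), m, dim(x))` returns `x`.
#'
#' @param xmat matrix produced by (or shaped like the output of) [unfold()].
#' @param mode the mode that lies along the columns of `xmat`.
#' @param shape integer vector of target tensor dimensions.
#' @return array with `dim(shape)`.
#' @export
fold <- function(xmat, mode, shape) {
  shape <- as.integer(shape)
  K <- length(shape)
  if (mode < 1L || mode > K || mode != round(mode))
    stop("`mode` must be a single integer in 1..", K)
  mode <- as.integer(mode)
  xmat <- as.matrix(xmat)
  if (nrow(xmat) != prod(shape[-mode]) || ncol(xmat) != shape[mode])
    stop("dimensions of `xmat` (", nrow(xmat), "x", ncol(xmat),
         ") are inconsistent with `shape` and `mode`")
  perm <- c(setdiff(seq_len(K), mode), mode)
  x <- array(xmat, dim = shape[perm])
  aperm(x, match(seq_len(K), perm))
}

#' Khatri-Rao (columnwise Kronecker) product
#'
#' Column `r` of the result is the Kronecker product of the r-th columns of the
#' input matrices, taken in the order given; the row count is the product of
#' the input row counts, with the index of the *last* matrix in the list
#' varying fastest (the usual Kronecker layout). `khatri_rao(list(A3, A2, A1))`
#' therefore linearizes a (p1, p2, p3) grid with the first spatial index
#' fastest, matching [unfold()]'s row ordering for a mode-4 unfolding.
#'
#' @param factors list of numeric matrices sharing one column count R.
#' @return matrix with `prod(rows)` rows and R columns.
#' @export
khatri_rao <- function(factors) {
  if (!is.list(factors) || length(factors) < 1L)
    stop("`factors` must be a non-empty list of matrices")
  factors <- lapply(factors, as.matrix)
  R <- ncol(factors[[1L]])
  if (any(vapply(factors, ncol, 1L) != R))
    stop("all factor matrices must share the same number of columns")
  Reduce(function(a, b) {
    I <- nrow(a); J <- nrow(b)
    a[rep(seq_len(I), each = J), , drop = FALSE] *
      b[rep(seq_len(J), times = I), , drop = FALSE]
  }, factors)
}
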