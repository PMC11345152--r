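#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = dgamma(t, a1, b1) - ratio * dgamma(t, a2, b2)`, the standard
#' peak-plus-undershoot shape (peak near 5 s, undershoot near 15 s).
#'
#' @param t time in seconds (nonnegative).
#' @param peak_shape,peak_rate gamma parameters of the positive lobe.
#' @param under_shape,under_rate gamma parameters of the undershoot.
#' @param ratio undershoot amplitude relative to the peak.
#' @return numeric vector `h(t)`.
#' @export
hrf_double_gamma <- function(t, peak_shape = 6, peak_rate = 1,
                             under_shape = 16, under_rate = 1, ratio = 1 / 6) {
  stats::dgamma(t, shape = peak_shape, rate = peak_rate) -
    ratio * stats::dgamma(t, shape = under_shape, rate = under_rate)
}

#' Build a task design matrix by HRF convolution
#'
#' Each stimulus is represented as a boxcar (onset/duration, in seconds) on a
#' fine time grid, convolved with the canonical double-gamma hemodynamic
#' response, and sampled every `TR` seconds for `T` frames.
#'
#' @param onsets named list, one element per stimulus; each element a data
#'   frame (or list) with `onset` and `duration` in seconds. A stimulus with
#'   zero rows yields an all-zero column.
#' @param T number of time frames.
#' @param TR repetition time in seconds.
#' @param dt internal convolution grid step (seconds).
#' @param hrf function of time in seconds; default [hrf_double_gamma()].
#' @return an object of class `task_design`: `X` (`T x J`),
#'   `regressor_names`, `TR`.
#' @export
build_design <- function(onsets, T, TR, dt = 0.1, hrf = hrf_double_gamma) {
  if (!is.list(onsets) || length(onsets) == 0L)
    stop("`onsets` must be a non-empty list of stimulus onset tables")
  if (is.null(names(onsets)) || any(names(onsets) == ""))
    names(onsets) <- paste0("stim", seq_along(onsets))
  total <- T * TR
  tgrid <- seq(0, total - dt, by = dt)
  h <- hrf(tgrid)
  X <- sapply(onsets, function(ev) {
    ev <- as.data.frame(ev)
    box <- numeric(length(tgrid))
    if (nrow(ev) > 0) {
      if (any(ev$onset < 0 | ev$onset >= total))
        stop("stimulus onsets must lie within [0, T*TR)")
      for (i in seq_len(nrow(ev))) {
        dur <- if (is.null(ev$duration)) 0 else ev$duration[i]
        on_i <- ev$onset[i]
        sel <- tgrid >= on_i & tgrid <= on_i + max(dur, dt / 2)
        box[sel] <- 1
      }
    }
    conv <- stats::convolve(box, rev(h), type = "open")[seq_along(tgrid)] * dt
    conv[findInterval(seq(0, by = TR, length.out = T), tgrid)]
  })
  structure(list(X = matrix(X, nrow = T), regressor_names = names(onsets),
                 TR = TR),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("task design: %d frames (TR = %gs), %d regressors: %s\n",
              nrow(x$X), x$TR, ncol(x$X),
              paste(x$regressor_names, collapse = ", ")))
  invisible(x)
}

#' Per-voxel GLM contrast map for one subject
#'
#' Ordinary least squares fit of the voxelwise time-series model
#' `y_t(v) = sum_j b_j(v) x_j(t) + e_t(v)`, returning the coefficient matrix
#' `B` and the map of a stimulus contrast `c'B`. This is the minimal
#' subject-level engine producing the 3D contrast volumes consumed by the
#' multi-subject stage; errors are treated as i.i.d.
#'
#' @param y time-by-space data: a `T x Nv` matrix or a 4D array with time
#'   first (`T x p1 x p2 x p3`).
#' @param design a [build_design()] result (or a plain `T x J` matrix).
#' @param contrast length-J contrast vector.
#' @return an object of class `subject_maps`: `B` (`J x Nv`), `contrast_map`
#'   (length Nv), `spatial_dim` (when the input was 4D).
#' @export
fit_glm_contrast <- function(y, design, contrast) {
  X <- if (inherits(design, "task_design")) design$X else as.matrix(design)
  spatial_dim <- NULL
  if (is.array(y) && length(dim(y)) == 4L) {
    spatial_dim <- dim(y)[2:4]
    y <- matrix(y, nrow = dim(y)[1L])
  }
  y <- as.matrix(y)
  if (nrow(y) != nrow(X))
    stop("time dimension of `y` (", nrow(y), ") does not match the design (",
         nrow(X), ")")
  J <- ncol(X)
  if (length(contrast) != J) stop("`contrast` must have length ", J)
  qx <- qr(X)
  if (qx$rank < J) {
    bad <- colnames(X, do.NULL = FALSE)[qx$pivot[(qx$rank + 1):J]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qx, y)                      # J x Nv
  structure(list(B = B, contrast_map = drop(crossprod(contrast, B)),
                 spatial_dim = spatial_dim),
            class = "subject_maps")
}

#' @export
print.subject_maps <- function(x, ...) {
  cat(sprintf("subject-level GLM maps: %d regressors x %d voxels\n",
              nrow(x$B), ncol(x$B)))
  invisible(x)
}
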