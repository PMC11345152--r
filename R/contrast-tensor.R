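#' Multi-subject contrast tensor
#'
#' Bundles a 4D array of per-subject 3D contrast values (spatial dims
#' `p1 x p2 x p3`, subject dim `N` last) with an optional brain mask, the grid
#' metadata of the source volumes, and the ordered subject identifiers.
#'
#' @param data 4D numeric array indexed `(j1, j2, j3, n)`.
#' @param mask optional 3D logical array matching the spatial dims; when
#'   present, only `TRUE` voxels enter the basis linearization.
#' @param grid_meta opaque metadata (e.g. a NIfTI header/template) carried
#'   through to any volume written back to disk.
#' @param subject_ids character vector of length `N`, in the order of the
#'   fourth array dimension. Defaults to `"sub-001"`, ...
#' @return an object of class `contrast_tensor`.
#' @export
contrast_tensor <- function(data, mask = NULL, grid_meta = NULL, subject_ids = NULL) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (p1 x p2 x p3 x N)")
  storage.mode(data) <- "double"
  d <- dim(data)
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim = dim(mask))
    if (!identical(dim(mask), d[1:3]))
      stop("`mask` dimensions must match the spatial dimensions of `data`")
  }
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("sub-%03d", seq_len(d[4L]))
  } else if (length(subject_ids) != d[4L]) {
    stop("`subject_ids` must have length N = ", d[4L])
  }
  structure(
    list(data = data, mask = mask, grid_meta = grid_meta,
         subject_ids = as.character(subject_ids)),
    class = "contrast_tensor")
}

#' @export
print.contrast_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat("Multi-subject contrast tensor\n")
  cat(sprintf("  grid: %d x %d x %d  (%d voxels%s)\n", d[1], d[2], d[3],
              n_voxels(x), if (is.null(x$mask)) "" else " in mask"))
  cat(sprintf("  subjects: %d\n", d[4]))
  invisible(x)
}

#' @export
dim.contrast_tensor <- function(x) dim(x$data)

# number of voxels entering the linearization (mask-aware)
n_voxels <- function(y) {
  if (is.null(y$mask)) prod(dim(y$data)[1:3]) else sum(y$mask)
}

# N x Nv subject-by-voxel matrix (transpose of unfold(., 4)), mask applied
subject_matrix <- function(y) {
  d <- dim(y$data)
  m <- t(unfold(y$data, 4L))
  if (!is.null(y$mask)) m <- m[, as.vector(y$mask), drop = FALSE]
  m
}

# place an Nv vector back on the 3D grid (NA outside the mask)
grid_vector <- function(v, spatial_dim, mask = NULL, fill = NA_real_) {
  if (is.null(mask)) {
    array(v, dim = spatial_dim)
  } else {
    out <- array(fill, dim = spatial_dim)
    out[as.vector(mask)] <- v
    out
  }
}
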