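#' Assemble a contrast tensor from per-subject NIfTI volumes
#'
#' Reads one 3D volume per subject, checks that all share a grid, matches
#' volumes to covariate rows by subject ID, and stacks them (in covariate
#' table order) into a [contrast_tensor()] together with the design matrix.
#' Non-finite voxels are masked out (their count is reported via `message`).
#'
#' @param volume_paths character vector of NIfTI paths, named by subject ID
#'   (unnamed paths are matched to the table rows positionally).
#' @param covariates data frame whose first column is `subject_id`, or the
#'   path of a delimited text file (TSV/CSV) with that layout. Remaining
#'   columns are covariates; an intercept is added automatically.
#' @param mask optional path of a 3D NIfTI mask (nonzero = in brain).
#' @return list with `tensor` (a [contrast_tensor()]), `Z` (design matrix)
#'   and `covariates` (the table, in subject order).
#' @export
assemble_tensor <- function(volume_paths, covariates, mask = NULL) {
  if (is.character(covariates) && length(covariates) == 1L)
    covariates <- read_covariates(covariates)
  covariates <- as.data.frame(covariates)
  if (!"subject_id" %in% names(covariates))
    stop("the covariate table must contain a `subject_id` column (first)")
  ids <- as.character(covariates$subject_id)
  if (is.null(names(volume_paths))) {
    if (length(volume_paths) != length(ids))
      stop("unnamed `volume_paths` must match the covariate table length")
    names(volume_paths) <- ids
  }
  missing_vol <- setdiff(ids, names(volume_paths))
  if (length(missing_vol) > 0)
    stop("no volume for subject ID(s): ", paste(missing_vol, collapse = ", "))
  extra <- setdiff(names(volume_paths), ids)
  if (length(extra) > 0)
    stop("volume(s) without a covariate row: ", paste(extra, collapse = ", "))

  vols <- lapply(ids, function(id) RNifti::readNifti(volume_paths[[id]]))
  d0 <- dim(vols[[1L]])
  if (length(d0) != 3L) stop("subject volumes must be 3D")
  for (i in seq_along(vols)) {
    if (!identical(dim(vols[[i]]), d0))
      stop("grid mismatch in ", volume_paths[[ids[i]]], ": ",
           paste(dim(vols[[i]]), collapse = "x"), " vs ",
           paste(d0, collapse = "x"))
  }
  data <- array(NA_real_, dim = c(d0, length(ids)))
  for (i in seq_along(vols)) data[, , , i] <- as.array(vols[[i]])

  mask_arr <- if (!is.null(mask)) {
    m <- as.array(RNifti::readNifti(mask))
    if (!identical(dim(m), d0)) stop("mask grid does not match the volumes")
    m != 0
  } else NULL
  bad <- apply(data, 1:3, function(v) any(!is.finite(v)))
  if (any(bad)) {
    message(sum(bad), " voxel(s) with non-finite values masked out")
    mask_arr <- if (is.null(mask_arr)) !bad else mask_arr & !bad
    data[!is.finite(data)] <- 0
  }
  tensor <- contrast_tensor(data, mask = mask_arr,
                            grid_meta = RNifti::niftiHeader(vols[[1L]]),
                            subject_ids = ids)
  Z <- design_matrix(covariates)
  list(tensor = tensor, Z = Z, covariates = covariates)
}

#' Read a delimited covariate table
#'
#' First column must be `subject_id`; the delimiter is sniffed (tab or comma).
#'
#' @param path text file path.
#' @return data frame.
#' @export
read_covariates <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Design matrix from a covariate table
#'
#' Expands all columns except `subject_id` with [stats::model.matrix()]
#' (factors become indicator columns) and prepends an intercept, which is the
#' population-average activation map.
#'
#' @param covariates data frame with a `subject_id` column.
#' @return `N x p` design matrix.
#' @export
design_matrix <- function(covariates) {
  covariates <- as.data.frame(covariates)
  vars <- setdiff(names(covariates), "subject_id")
  if (length(vars) == 0L)
    return(matrix(1, nrow(covariates), 1,
                  dimnames = list(NULL, "(Intercept)")))
  f <- stats::as.formula(paste("~", paste(sprintf("`%s`", vars), collapse = "+")))
  stats::model.matrix(f, covariates)
}

#' Write an Nv map (or 3D array) as a NIfTI volume
#'
#' Values are re-folded onto the grid with the package-wide column-major
#' (first index fastest) linearization; voxels outside the mask are written
#' as 0. Grid metadata from the source volumes is carried over when present.
#'
#' @param values numeric vector of length Nv, or a 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spatial_dim integer 3-vector (unused when `values` is 3D).
#' @param mask optional 3D logical mask matching the linearization.
#' @param grid_meta optional NIfTI header/template to copy geometry from.
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, path, spatial_dim = NULL, mask = NULL,
                         grid_meta = NULL) {
  vol <- if (is.array(values) && length(dim(values)) == 3L) values
  else grid_vector(as.numeric(values), spatial_dim, mask, fill = 0)
  img <- if (!is.null(grid_meta)) RNifti::asNifti(vol, reference = grid_meta)
  else RNifti::asNifti(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D NIfTI volume as an array
#' @param path NIfTI file path.
#' @return numeric array with the header attached as attribute `grid_meta`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "grid_meta") <- RNifti::niftiHeader(img)
  out
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path config file path.
#' @param known character vector of accepted keys (defaults to the pipeline
#'   keys used by the command-line interface).
#' @return named list of character values.
#' @export
read_config <- function(path, known = cpfosr_config_keys()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lines[vapply(kv, length, 1L) != 2L]
  if (length(bad) > 0) stop("malformed config line(s): ",
                            paste(bad, collapse = "; "))
  keys <- vapply(kv, `[`, "", 1L)
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  stats::setNames(lapply(kv, `[`, 2L), keys)
}

#' Accepted configuration keys for the pipeline
#' @return character vector.
#' @export
cpfosr_config_keys <- function() {
  c("ranks", "folds", "rank", "M", "alpha", "min_size", "connectivity",
    "prior.l0_scale", "prior.v0_scale", "prior.nu0", "seed",
    "tol", "max_iter", "n_restarts", "out_dir")
}

#' Persist / restore a fitted model
#'
#' The fitted model (CP factors, weights, basis, posterior parameters and
#' draws) is stored as a single RDS container so inference can run in a
#' separate process from fitting.
#'
#' @param fit a [cpfosr()] object.
#' @param path container path (`.rds`).
#' @return `path` (write) or the restored `cpfosr` object (read).
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "cpfosr"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "cpfosr"))
    stop("`", path, "` does not contain a cpfosr model container")
  fit
}
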