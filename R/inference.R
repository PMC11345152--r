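#' Back-project posterior draws to voxel space and form max statistics
#'
#' For a covariate contrast `c` (length p), each posterior draw `m` gives a
#' voxel map `C^(m)(v) = c' gamma*^(m) L[, v]`. This computes the posterior
#' mean map `c_hat`, the voxelwise posterior standard deviation `c_sd`
#' (sample sd across draws, denominator M-1) and the max standardized
#' deviation statistics `z^(m) = max_v |C^(m)(v) - c_hat(v)| / c_sd(v)`,
#' streaming over voxel chunks so no M x Nv matrix is ever materialized.
#'
#' Voxels with zero posterior sd cannot be standardized: they are marked
#' ineligible, excluded from the max, and later assigned `P_SimBaS = 1`.
#'
#' @param draws a [draw_posterior()] result.
#' @param cp a `cp_basis` with `L` built.
#' @param contrast numeric vector of length p defining `C = c' gamma`.
#' @param chunk_size voxels per streaming chunk.
#' @return list with `c_hat`, `c_sd` (length Nv), `z_stats` (length M),
#'   `eligible` (logical Nv), `n_ineligible`, and `degenerate` (`TRUE` when no
#'   voxel could be standardized).
#' @export
backproject_stats <- function(draws, cp, contrast, chunk_size = 4096L) {
  stopifnot(inherits(cp, "cp_basis"))
  if (is.null(cp$L)) stop("basis not built; call build_basis() first")
  gs <- draws$gamma_star
  p <- dim(gs)[1L]; R <- dim(gs)[2L]; M <- dim(gs)[3L]
  if (length(contrast) != p)
    stop("`contrast` must have length p = ", p)
  if (R != cp$R) stop("draw rank does not match the basis rank")
  # basis-space contrast draws: D[m, ] = c' gamma*^(m)  (M x R)
  D <- t(apply(gs, 3L, function(g) drop(crossprod(contrast, g))))
  if (R == 1L) D <- matrix(D, ncol = 1L)
  Nv <- ncol(cp$L)

  c_hat <- numeric(Nv); c_sd <- numeric(Nv)
  z <- numeric(M)
  starts <- seq.int(1L, Nv, by = chunk_size)
  # pass 1: voxelwise mean and sd
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, Nv)
    cm <- D %*% cp$L[, idx, drop = FALSE]            # M x |idx|
    mu <- colMeans(cm)
    c_hat[idx] <- mu
    c_sd[idx] <- sqrt(colSums(cm^2) / (M - 1) - colSums(cm) * mu / (M - 1))
  }
  c_sd[c_sd < 0 | !is.finite(c_sd)] <- 0
  eligible <- c_sd > 0
  # pass 2: per-draw max standardized deviation over eligible voxels
  if (any(eligible)) {
    for (s in starts) {
      idx <- s:min(s + chunk_size - 1L, Nv)
      el <- eligible[idx]
      if (!any(el)) next
      idx <- idx[el]
      cm <- D %*% cp$L[, idx, drop = FALSE]
      dev <- abs(cm - rep(c_hat[idx], each = M)) / rep(c_sd[idx], each = M)
      z <- pmax(z, apply(dev, 1L, max))
    }
  } else {
    z <- rep(NA_real_, M)
    warning("degenerate inference: all voxels have zero posterior sd")
  }
  list(c_hat = c_hat, c_sd = c_sd, z_stats = z, eligible = eligible,
       n_ineligible = sum(!eligible), degenerate = !any(eligible), M = M)
}

#' Simultaneous band scores (SimBaS)
#'
#' `P_SimBaS(v) = (1/M) #\{m : |c_hat(v)| / c_sd(v) <= z^(m)\}`, the minimum
#' significance level at which the joint credible band at `v` excludes zero.
#' Ineligible (zero-sd) voxels get `P_SimBaS = 1` and are never flagged.
#'
#' @param stats a [backproject_stats()] result.
#' @return numeric vector of length Nv with values in `\{0, 1/M, ..., 1\}`.
#' @export
simbas_map <- function(stats) {
  M <- stats$M
  if (stats$degenerate) return(rep(1, length(stats$c_hat)))
  zs <- sort(stats$z_stats)
  p <- rep(1, length(stats$c_hat))
  t_v <- abs(stats$c_hat[stats$eligible]) / stats$c_sd[stats$eligible]
  # count of z >= t  =  M - count(z < t)
  p[stats$eligible] <- (M - findInterval(t_v, zs, left.open = TRUE)) / M
  p
}

#' Joint credible bands
#'
#' Simultaneous 100(1-alpha)% credible band
#' `I_alpha(v) = c_hat(v) +/- q_(1-alpha) c_sd(v)` where the critical value is
#' the order statistic `q_(1-alpha) = z_(ceil((1-alpha) M))` of the max
#' statistics, so that the band excludes zero at `v` exactly when
#' `P_SimBaS(v) <= alpha` on the 1/M grid.
#'
#' @param stats a [backproject_stats()] result.
#' @param alpha simultaneous level in (0, 1) with `M (1 - alpha) >= 1`.
#' @return list with `band_lo`, `band_hi` (length Nv) and `q`.
#' @export
joint_bands <- function(stats, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single value in (0, 1)")
  M <- stats$M
  if (M * (1 - alpha) < 1)
    stop("alpha = ", alpha, " is too extreme for M = ", M,
         " draws; increase M")
  if (stats$degenerate) stop("degenerate inference: no eligible voxels")
  # guard the order-statistic index against floating-point creep in (1-a)*M
  k <- (1 - alpha) * M
  idx <- if (abs(k - round(k)) < 1e-8) round(k) else ceiling(k)
  q <- sort(stats$z_stats)[idx]
  list(band_lo = stats$c_hat - q * stats$c_sd,
       band_hi = stats$c_hat + q * stats$c_sd, q = q, alpha = alpha)
}

#' Extract significant clusters from a SimBaS map
#'
#' Thresholds `P_SimBaS < alpha`, labels 3D connected components under the
#' chosen neighborhood connectivity, drops components smaller than `min_size`
#' voxels, and tabulates the survivors sorted by size.
#'
#' @param p_simbas numeric vector (length Nv) of SimBaS scores.
#' @param spatial_dim integer 3-vector of grid dimensions.
#' @param alpha voxelwise flagging level (default 0.01).
#' @param min_size minimum cluster extent in voxels (default 125).
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners; default).
#' @param mask optional 3D logical mask mapping the Nv vector onto the grid.
#' @param c_hat,c_sd optional maps used to report each cluster's peak.
#' @return list with `labels` (3D integer array, 0 = background) and `table`
#'   (data frame: label, size, peak voxel indices, peak |c_hat|/c_sd).
#' @export
flag_clusters <- function(p_simbas, spatial_dim, alpha = 0.01, min_size = 125L,
                          connectivity = 26L, mask = NULL,
                          c_hat = NULL, c_sd = NULL) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  flag_grid <- grid_vector(p_simbas < alpha, spatial_dim, mask, fill = FALSE)
  flag_grid[is.na(flag_grid)] <- FALSE
  lab <- label_components(flag_grid, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  relab <- integer(length(sizes))
  empty <- data.frame(label = integer(), size = integer(),
                      peak_i = integer(), peak_j = integer(),
                      peak_k = integer(), peak_stat = numeric())
  if (length(keep) == 0L) {
    return(list(labels = array(0L, dim = spatial_dim), table = empty,
                alpha = alpha, min_size = min_size,
                connectivity = connectivity))
  }
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  relab[keep] <- seq_along(keep)
  out_lab <- array(0L, dim = spatial_dim)
  pos <- lab > 0
  out_lab[pos] <- relab[lab[pos]]

  stat_grid <- if (!is.null(c_hat) && !is.null(c_sd)) {
    g <- grid_vector(abs(c_hat) / ifelse(c_sd > 0, c_sd, NA), spatial_dim, mask)
    g
  } else NULL
  tab <- do.call(rbind, lapply(seq_along(keep), function(i) {
    vox <- which(out_lab == i, arr.ind = TRUE)
    if (!is.null(stat_grid)) {
      st <- stat_grid[cbind(vox)]
      pk <- which.max(ifelse(is.na(st), -Inf, st))
      peak_stat <- st[pk]
    } else {
      pk <- 1L; peak_stat <- NA_real_
    }
    data.frame(label = i, size = nrow(vox), peak_i = vox[pk, 1],
               peak_j = vox[pk, 2], peak_k = vox[pk, 3],
               peak_stat = peak_stat)
  }))
  list(labels = out_lab, table = tab, alpha = alpha, min_size = min_size,
       connectivity = connectivity)
}

# 3D connected-component labeling: vectorized neighbor-offset edge lists fed
# to igraph; labels are arbitrary positive integers, 0 is background
label_components <- function(flag, connectivity) {
  d <- dim(flag)
  stopifnot(length(d) == 3L)
  idx <- which(flag)
  lab <- array(0L, dim = d)
  if (length(idx) == 0L) return(lab)
  offs <- connectivity_offsets(connectivity)
  coord <- arrayInd(idx, d)
  id_of <- integer(prod(d))
  id_of[idx] <- seq_along(idx)
  edges <- list()
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coord, 2L, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    hit <- flag[nb_lin]
    if (!any(hit)) next
    edges[[length(edges) + 1L]] <-
      cbind(id_of[idx[ok][hit]], id_of[nb_lin[hit]])
  }
  if (length(edges) == 0L) {
    comp <- seq_along(idx)                      # all isolated voxels
  } else {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  lab[idx] <- as.integer(comp)
  lab
}

# half-space is not enough here: use the full symmetric offset set so each
# flagged voxel sees all neighbors (edges are deduplicated by igraph)
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6" = g[ord == 1, , drop = FALSE],
         "18" = g[ord <= 2, , drop = FALSE],
         "26" = g)
}

#' Voxelwise inference for a fitted model: SimBaS, bands and clusters
#'
#' Convenience wrapper running [backproject_stats()], [simbas_map()],
#' [joint_bands()] and [flag_clusters()] for one covariate contrast of a
#' [cpfosr()] fit.
#'
#' @param fit a [cpfosr()] object.
#' @param contrast covariate name, index, or a full length-p contrast vector.
#' @param alpha flagging level (default 0.01).
#' @param band_alpha level for the reported joint band (defaults to `alpha`).
#' @param min_size minimum cluster extent in voxels (default 125).
#' @param connectivity 6, 18 or 26 (default).
#' @param chunk_size voxels per streaming chunk in [backproject_stats()].
#' @return an object of class `cpfosr_simbas`: `c_hat`, `c_sd`, `p_simbas`,
#'   `z_stats`, `band_lo`, `band_hi`, `flagged`, `clusters` (see
#'   [flag_clusters()]), plus the contrast and settings.
#' @export
simbas <- function(fit, contrast = 1L, alpha = 0.01, band_alpha = alpha,
                   min_size = 125L, connectivity = 26L, chunk_size = 4096L) {
  stopifnot(inherits(fit, "cpfosr"))
  p <- ncol(fit$Z)
  cvec <- contrast_vector(contrast, colnames(fit$Z))
  st <- backproject_stats(fit$draws, fit$cp, cvec, chunk_size = chunk_size)
  ps <- simbas_map(st)
  bands <- if (!st$degenerate) joint_bands(st, band_alpha) else
    list(band_lo = rep(NA_real_, length(ps)),
         band_hi = rep(NA_real_, length(ps)), q = NA_real_)
  flagged <- ps < alpha
  cl <- flag_clusters(ps, fit$spatial_dim, alpha = alpha, min_size = min_size,
                      connectivity = connectivity, mask = fit$mask,
                      c_hat = st$c_hat, c_sd = st$c_sd)
  structure(
    list(contrast = cvec, contrast_label = contrast_label(contrast, colnames(fit$Z)),
         c_hat = st$c_hat, c_sd = st$c_sd, p_simbas = ps,
         z_stats = st$z_stats, eligible = st$eligible,
         n_ineligible = st$n_ineligible, degenerate = st$degenerate,
         band_lo = bands$band_lo, band_hi = bands$band_hi, q = bands$q,
         flagged = flagged, clusters = cl, alpha = alpha,
         band_alpha = band_alpha, min_size = min_size,
         connectivity = connectivity, spatial_dim = fit$spatial_dim,
         mask = fit$mask, grid_meta = fit$grid_meta, M = st$M),
    class = "cpfosr_simbas")
}

contrast_vector <- function(contrast, coef_names) {
  p <- length(coef_names)
  if (is.character(contrast)) {
    i <- match(contrast, coef_names)
    if (is.na(i)) stop("unknown coefficient '", contrast, "'")
    cvec <- numeric(p); cvec[i] <- 1
  } else if (length(contrast) == 1L) {
    cvec <- numeric(p); cvec[as.integer(contrast)] <- 1
  } else if (length(contrast) == p) {
    cvec <- as.numeric(contrast)
  } else {
    stop("`contrast` must be a name, an index, or a length-", p, " vector")
  }
  cvec
}

contrast_label <- function(contrast, coef_names) {
  if (is.character(contrast)) contrast
  else if (length(contrast) == 1L) coef_names[as.integer(contrast)]
  else "custom contrast"
}

#' @export
print.cpfosr_simbas <- function(x, ...) {
  cat(sprintf("SimBaS inference for '%s'\n", x$contrast_label))
  cat(sprintf("  %d draws; alpha = %g; min cluster size = %d (%d-connectivity)\n",
              x$M, x$alpha, x$min_size, x$connectivity))
  cat(sprintf("  flagged voxels (P_SimBaS < alpha): %d of %d\n",
              sum(x$flagged), length(x$flagged)))
  if (x$n_ineligible > 0)
    cat(sprintf("  zero-variance voxels (never flagged): %d\n", x$n_ineligible))
  if (nrow(x$clusters$table) == 0) {
    cat("  no clusters at the extent threshold\n")
  } else {
    cat("  clusters:\n")
    print(x$clusters$table, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
plot.cpfosr_simbas <- function(x, slice = NULL, ...) {
  if (is.null(slice)) slice <- ceiling(x$spatial_dim[3] / 2)
  vol <- grid_vector(x$c_hat, x$spatial_dim, x$mask, fill = 0)
  sig <- grid_vector(x$flagged, x$spatial_dim, x$mask, fill = FALSE)
  graphics::image(vol[, , slice], useRaster = TRUE,
                  main = sprintf("%s (slice %d); flagged outlined",
                                 x$contrast_label, slice), ...)
  if (any(sig[, , slice], na.rm = TRUE)) {
    d <- x$spatial_dim
    pts <- which(sig[, , slice], arr.ind = TRUE)
    graphics::points((pts[, 1] - 1) / (d[1] - 1), (pts[, 2] - 1) / (d[2] - 1),
                     pch = ".", cex = 2)
  }
  invisible(x)
}
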