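# Independent oracles used across the suite. These deliberately use naive
# loops / enumeration so they share no code path with the implementation.

# element-by-element mode-n unfolding: row index enumerated directly from the
# remaining subscripts (first remaining subscript varying fastest)
unfold_oracle <- function(x, mode) {
  d <- dim(x)
  K <- length(d)
  rest <- setdiff(seq_len(K), mode)
  out <- matrix(NA_real_, prod(d[rest]), d[mode])
  idx_grid <- as.matrix(expand.grid(lapply(d[rest], seq_len)))
  for (row in seq_len(nrow(idx_grid))) {
    for (k in seq_len(d[mode])) {
      sub <- integer(K)
      sub[rest] <- idx_grid[row, ]
      sub[mode] <- k
      out[row, k] <- x[matrix(sub, 1)]
    }
  }
  out
}

# triple-loop columnwise Kronecker product of a list of matrices
khatri_rao_oracle <- function(mats) {
  R <- ncol(mats[[1]])
  cols <- lapply(seq_len(R), function(r) {
    v <- 1
    for (m in mats) v <- kronecker(v, m[, r])
    v
  })
  do.call(cbind, cols)
}

# naive CP reconstruction from weights + factor list
cp_reconstruct <- function(lam, factors) {
  factors <- unname(factors)
  d <- vapply(factors, nrow, 1L)
  x <- array(0, dim = d)
  for (r in seq_along(lam)) {
    comp <- Reduce(function(a, b) outer(a, b), lapply(factors, function(f) f[, r]))
    x <- x + lam[r] * comp
  }
  x
}

# recursive flood fill for 3D connected components (slow, obviously correct)
flood_fill_oracle <- function(flag, connectivity) {
  d <- dim(flag)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- switch(as.character(connectivity),
                 "6" = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
                 "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
                 "26" = offs)
  lab <- array(0L, dim = d)
  cur <- 0L
  for (v in which(flag)) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    stack <- v
    lab[v] <- cur
    while (length(stack) > 0) {
      at <- stack[length(stack)]
      stack <- stack[-length(stack)]
      sub <- arrayInd(at, d)
      for (o in seq_len(nrow(offs))) {
        nb <- sub + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- (nb[3] - 1) * d[1] * d[2] + (nb[2] - 1) * d[1] + nb[1]
        if (flag[lin] && lab[lin] == 0L) {
          lab[lin] <- cur
          stack <- c(stack, lin)
        }
      }
    }
  }
  lab
}

# do two labelings induce the same partition of the flagged voxels?
same_partition <- function(a, b) {
  ia <- a[a > 0]; ib <- b[b > 0]
  if (length(ia) != length(ib)) return(FALSE)
  all(tapply(ib, ia, function(v) length(unique(v))) == 1) &&
    all(tapply(ia, ib, function(v) length(unique(v))) == 1)
}

# well-separated unit-norm factor matrix for exact-rank fixtures
random_factor <- function(nrow, R, seed_shift = 0) {
  a <- matrix(stats::rnorm(nrow * R), nrow, R)
  q <- qr.Q(qr(a))[, seq_len(R), drop = FALSE]  # orthonormal => well conditioned
  q
}

# a small deterministic basis-space fixture for posterior tests
fosr_fixture <- function(N = 40, p = 2, R = 5, seed = 42) {
  set.seed(seed)
  Z <- cbind(1, stats::rnorm(N))
  gamma <- matrix(stats::rnorm(p * R), p, R)
  G <- Z %*% gamma + matrix(stats::rnorm(N * R, sd = 0.5), N, R)
  list(Z = Z, G = G, gamma = gamma)
}
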