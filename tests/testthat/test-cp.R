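test_that("an all-ones tensor is an exact rank-1 fit with lambda = sqrt(prod(dims))", {
  x <- array(1, dim = c(2, 3, 4, 2))
  cp <- cp_decompose(x, R = 1, seed = 1)
  expect_equal(cp$lam, sqrt(48), tolerance = 1e-8)
  expect_lt(cp$fit_rel_error, 1e-8)
  for (k in 1:4)
    expect_equal(abs(cp$factors[[k]][, 1]),
                 rep(1 / sqrt(dim(x)[k]), dim(x)[k]), tolerance = 1e-7)
})

test_that("an exactly rank-3 tensor is recovered to numerical precision at R = 3", {
  set.seed(21)
  d <- c(6, 7, 5, 10)
  factors <- lapply(d, random_factor, R = 3)
  lam <- c(5, 3, 2)
  x <- cp_reconstruct(lam, factors)
  cp <- cp_decompose(x, R = 3, seed = 2)
  expect_lt(cp$fit_rel_error, 1e-6)
  expect_equal(cp_reconstruct(cp$lam, cp$factors), x, tolerance = 1e-5)
  # weights sorted decreasing, factors unit norm
  expect_equal(cp$lam, sort(cp$lam, decreasing = TRUE))
  expect_equal(sort(cp$lam), sort(lam), tolerance = 1e-6)
  for (k in 1:4)
    expect_equal(colSums(cp$factors[[k]]^2), rep(1, 3), tolerance = 1e-10)
})

test_that("restart-protected fit error is monotone in the rank", {
  set.seed(22)
  d <- c(5, 6, 4, 8)
  x <- cp_reconstruct(c(4, 2, 1), lapply(d, random_factor, R = 3))
  e2 <- cp_decompose(x, R = 2, n_restarts = 5, seed = 7)$fit_rel_error
  e3 <- cp_decompose(x, R = 3, n_restarts = 5, seed = 7)$fit_rel_error
  expect_gte(e2, e3)
})

test_that("reconstruction error is invariant to component permutation and sign flips", {
  set.seed(23)
  d <- c(5, 4, 6, 7)
  factors <- lapply(d, random_factor, R = 2)
  lam <- c(3, 1.5)
  x <- cp_reconstruct(lam, factors)
  # flip the sign of one column in two modes (product of flips is +1)
  f2 <- factors
  f2[[1]][, 2] <- -f2[[1]][, 2]
  f2[[3]][, 2] <- -f2[[3]][, 2]
  expect_equal(cp_reconstruct(lam, f2), x, tolerance = 1e-12)
  # permute components
  f3 <- lapply(factors, function(f) f[, 2:1])
  expect_equal(cp_reconstruct(lam[2:1], f3), x, tolerance = 1e-12)
})

test_that("cp_decompose is deterministic given a seed and rejects non-finite input", {
  set.seed(24)
  x <- array(rnorm(2 * 3 * 4 * 5), dim = c(2, 3, 4, 5))
  a <- cp_decompose(x, R = 2, seed = 9)
  b <- cp_decompose(x, R = 2, seed = 9)
  expect_identical(a$lam, b$lam)
  expect_identical(a$factors, b$factors)
  x[1, 1, 1, 1] <- NA
  expect_error(cp_decompose(x, R = 2), "non-finite")
})

test_that("build_basis places a single-entry basis for standard-basis factors", {
  cp <- structure(list(
    R = 1L, lam = 2,
    A1 = matrix(c(1, 0, 0), 3, 1), A2 = matrix(c(1, 0, 0, 0), 4, 1),
    A3 = matrix(c(1, 0), 2, 1), G = matrix(1, 5, 1),
    dims = c(3L, 4L, 2L, 5L), mask = NULL, n_zero_voxels = 0L),
    class = "cp_basis")
  cp <- build_basis(cp)
  expect_equal(dim(cp$L), c(1L, 24L))
  expect_equal(cp$L[1, 1], 2)
  expect_equal(sum(cp$L != 0), 1L)
  expect_equal(cp$P[1, 1], 0.5)
  expect_equal(sum(cp$P != 0), 1L)
})

test_that("L P = I_R for full-row-rank bases and L matches the factor formula", {
  set.seed(25)
  d <- c(4, 5, 6)
  A1 <- random_factor(4, 3); A2 <- random_factor(5, 3); A3 <- random_factor(6, 3)
  lam <- c(2, 1.3, 0.7)
  cp <- structure(list(R = 3L, lam = lam, A1 = A1, A2 = A2, A3 = A3,
                       G = matrix(rnorm(21), 7, 3), dims = c(d, 7L),
                       mask = NULL, n_zero_voxels = 0L),
                  class = "cp_basis")
  cp <- build_basis(cp)
  expect_equal(dim(cp$L), c(3L, 120L))
  # reproduce L entrywise from the factors via the Kronecker oracle
  L_oracle <- diag(lam) %*% t(khatri_rao_oracle(list(A3, A2, A1)))
  expect_equal(cp$L, L_oracle, tolerance = 1e-12)
  expect_lt(max(abs(cp$L %*% cp$P - diag(3))), 1e-8)
})

test_that("projection recovers subject scores of basis-generated data", {
  set.seed(26)
  d <- c(4, 5, 6)
  N <- 9
  A1 <- random_factor(4, 3); A2 <- random_factor(5, 3); A3 <- random_factor(6, 3)
  G <- matrix(rnorm(N * 3), N, 3)
  lam <- c(3, 2, 1)
  cp <- structure(list(R = 3L, lam = lam, A1 = A1, A2 = A2, A3 = A3, G = G,
                       dims = c(d, N), mask = NULL, n_zero_voxels = 0L),
                  class = "cp_basis")
  cp <- build_basis(cp)
  y <- contrast_tensor(fold(t(G %*% cp$L), 4, c(d, N)))
  expect_equal(project(y, cp), G, tolerance = 1e-8, ignore_attr = TRUE)
  # mode-4 unfolding times P recovers G (projection oracle)
  expect_equal(t(unfold(y$data, 4)) %*% cp$P, G, tolerance = 1e-8)
  expect_equal(project(contrast_tensor(array(0, c(d, N))), cp),
               matrix(0, N, 3), ignore_attr = TRUE)

  # scores converge to G as the voxel noise vanishes
  errs <- sapply(c(1e-1, 1e-3, 1e-6), function(s) {
    yn <- y$data + array(rnorm(prod(d) * N, sd = s), c(d, N))
    max(abs(project(contrast_tensor(yn), cp) - G))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("masked projection uses only mask voxels, consistently with build_basis", {
  set.seed(27)
  d <- c(4, 4, 4); N <- 8
  sim <- gen_multisubject(dims = d, N = N, R_true = 2, seed = 27,
                          sigma_subject = 0, sigma_voxel = 0)
  mask <- array(runif(prod(d)) > 0.3, dim = d)
  ym <- contrast_tensor(sim$tensor$data, mask = mask)
  cp <- cp_decompose(ym, R = 2, seed = 27)
  expect_equal(ncol(cp$L), sum(mask))
  expect_equal(nrow(cp$P), sum(mask))
  sc <- project(ym, cp)
  expect_equal(dim(sc), c(N, 2L))
})

test_that("a rank-deficient basis triggers an effective-rank warning", {
  cp <- structure(list(
    R = 2L, lam = c(1, 1),
    A1 = matrix(c(1, 0), 2, 2), A2 = matrix(c(1, 0), 2, 2),
    A3 = matrix(c(1, 0), 2, 2), G = matrix(1, 3, 2),
    dims = c(2L, 2L, 2L, 3L), mask = NULL, n_zero_voxels = 0L),
    class = "cp_basis")  # duplicated columns => rank(L) = 1
  expect_warning(build_basis(cp), "rank deficient")
})
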