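# build a minimal cp_basis with a given L (for driving inference directly)
basis_stub <- function(L, dims = NULL) {
  R <- nrow(L)
  structure(list(R = R, lam = rep(1, R), L = L, P = MASS::ginv(L),
                 dims = dims, mask = NULL, n_zero_voxels = 0L),
            class = "cp_basis")
}

draws_stub <- function(gamma_star) {  # p x R x M array
  structure(list(gamma_star = gamma_star, sigma_eps = NULL,
                 M = dim(gamma_star)[3]), class = "fosr_draws")
}

test_that("posterior mean, sd and max statistics match hand enumeration", {
  # p = 1, R = 1, L = (1, 2); draws of gamma*: 1, 2, 3
  L <- matrix(c(1, 2), 1, 2)
  d <- draws_stub(array(c(1, 2, 3), dim = c(1, 1, 3)))
  st <- backproject_stats(d, basis_stub(L), contrast = 1)
  # C draws: voxel1 (1,2,3), voxel2 (2,4,6); means (2,4); sds (1,2)
  expect_equal(st$c_hat, c(2, 4))
  expect_equal(st$c_sd, c(1, 2))
  expect_equal(st$z_stats, c(1, 0, 1))   # standardized deviations identical
  ps <- simbas_map(st)                    # t = (2, 2): no z >= 2
  expect_equal(ps, c(0, 0))
})

test_that("chunked and unchunked streaming agree to numerical precision", {
  set.seed(51)
  p <- 3; R <- 4; M <- 60; Nv <- 500
  L <- matrix(rnorm(R * Nv), R, Nv)
  gs <- array(rnorm(p * R * M), dim = c(p, R, M))
  cvec <- c(1, -0.5, 2)
  a <- backproject_stats(draws_stub(gs), basis_stub(L), cvec, chunk_size = 7L)
  b <- backproject_stats(draws_stub(gs), basis_stub(L), cvec, chunk_size = 10000L)
  expect_equal(a$c_hat, b$c_hat, tolerance = 1e-12)
  expect_equal(a$c_sd, b$c_sd, tolerance = 1e-12)
  expect_equal(a$z_stats, b$z_stats, tolerance = 1e-12)
})

test_that("identical draws yield a degenerate-inference flag, never a crash", {
  gs <- array(rep(c(1, 2), each = 1, times = 5), dim = c(1, 2, 5))
  gs[] <- rep(c(1, 2), times = 5)        # same gamma* in all 5 draws
  L <- matrix(rnorm(8), 2, 4)
  expect_warning(st <- backproject_stats(draws_stub(gs), basis_stub(L), 1),
                 "degenerate")
  expect_true(st$degenerate)
  expect_equal(st$c_sd, rep(0, 4))
  expect_equal(simbas_map(st), rep(1, 4))
  expect_error(joint_bands(st, 0.05), "degenerate")
})

test_that("SimBaS scores follow the direct counting definition", {
  st <- list(c_hat = c(2.5, 0, 10), c_sd = c(1, 1, 1), z_stats = c(1, 2, 3, 4),
             eligible = rep(TRUE, 3), degenerate = FALSE, M = 4)
  ps <- simbas_map(st)
  expect_equal(ps[1], 0.5)    # z >= 2.5 for 2 of 4 draws
  expect_equal(ps[2], 1)      # c_hat = 0 can never be excluded
  expect_equal(ps[3], 0)      # above every max statistic
  expect_true(all(ps %in% ((0:4) / 4)))
})

test_that("the band critical value is the ascending order statistic", {
  st <- list(c_hat = c(1, -2), c_sd = c(0.5, 1), z_stats = c(3, 1, 4, 2),
             eligible = c(TRUE, TRUE), degenerate = FALSE, M = 4)
  b <- joint_bands(st, alpha = 0.25)
  expect_equal(b$q, 3)                       # z_(ceil(0.75 * 4)) = z_(3)
  expect_equal(b$band_lo, c(1, -2) - 3 * c(0.5, 1))
  expect_equal(b$band_hi, c(1, -2) + 3 * c(0.5, 1))
  # nested bands: smaller alpha gives a wider band
  b2 <- joint_bands(st, alpha = 0.5)
  expect_gte(b$q, b2$q)
  expect_true(all(b$band_lo <= b2$band_lo) && all(b$band_hi >= b2$band_hi))
  expect_error(joint_bands(st, alpha = 0.9), "increase M")
  expect_error(joint_bands(st, alpha = 1.2), "alpha")
})

test_that("SimBaS and band inversion agree exactly on the 1/M alpha grid", {
  set.seed(52)
  M <- 200; Nv <- 120
  z <- abs(rnorm(M)) * 2
  st <- list(c_hat = rnorm(Nv), c_sd = runif(Nv, 0.5, 2), z_stats = z,
             eligible = rep(TRUE, Nv), degenerate = FALSE, M = M)
  ps <- simbas_map(st)
  for (alpha in (1:(M - 1)) / M) {
    b <- joint_bands(st, alpha)
    excluded <- b$band_lo > 0 | b$band_hi < 0
    expect_identical(ps <= alpha, excluded)
  }
  # flagged set shrinks monotonically as alpha decreases
  n_flag <- sapply(c(0.2, 0.1, 0.05, 0.01), function(a) sum(ps < a))
  expect_true(all(diff(n_flag) <= 0))
})

test_that("clusters below the extent threshold are dropped", {
  d <- c(20, 20, 20)
  ps <- array(1, dim = d)
  ps[1:5, 1:13, 1:2] <- 0      # 130 voxels
  ps[10:12, 10:13, 10:14] <- 0 # 60 voxels
  cl <- flag_clusters(as.vector(ps), d, alpha = 0.5, min_size = 125)
  expect_equal(nrow(cl$table), 1L)
  expect_equal(cl$table$size, 130L)
  expect_equal(sum(cl$labels > 0), 130L)

  cl_all <- flag_clusters(as.vector(ps), d, alpha = 0.5, min_size = 1)
  expect_equal(sort(cl_all$table$size), c(60L, 130L))
  expect_equal(cl_all$table$size, c(130L, 60L))  # sorted by size descending

  none <- flag_clusters(rep(1, prod(d)), d, alpha = 0.5, min_size = 1)
  expect_equal(nrow(none$table), 0L)
  expect_true(all(none$labels == 0L))
})

test_that("component labels match a brute-force flood fill for all connectivities", {
  set.seed(53)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:3) {
      flag <- array(runif(12^3) < 0.2, dim = c(12, 12, 12))
      ours <- cpfosr:::label_components(flag, conn)
      oracle <- flood_fill_oracle(flag, conn)
      expect_true(same_partition(ours, oracle))
      expect_identical(ours > 0, oracle > 0)
    }
  }
  expect_error(flag_clusters(rep(0, 8), c(2, 2, 2), connectivity = 10), "connectivity")
})

test_that("simbas() wraps the pipeline and reports cluster peaks", {
  sim <- gen_multisubject(dims = c(10, 10, 10), N = 30, R_true = 2, seed = 54,
                          snr = 5)
  fit <- cpfosr(~ sex, data = sim$covariates, tensor = sim$tensor, rank = 2,
                M = 400, seed = 54)
  s <- simbas(fit, "(Intercept)", alpha = 0.05, min_size = 10)
  expect_s3_class(s, "cpfosr_simbas")
  expect_equal(length(s$p_simbas), 1000L)
  expect_true(all(s$p_simbas >= 0 & s$p_simbas <= 1))
  expect_true(all(s$p_simbas[s$flagged] < 0.05))
  expect_true(all(s$clusters$table$size >= 10))
  # peak statistic is the max standardized mean within each cluster
  if (nrow(s$clusters$table) > 0) {
    lab <- s$clusters$labels
    stat <- array(abs(s$c_hat) / ifelse(s$c_sd > 0, s$c_sd, NA), dim = dim(lab))
    for (i in s$clusters$table$label)
      expect_equal(s$clusters$table$peak_stat[s$clusters$table$label == i],
                   max(stat[lab == i], na.rm = TRUE))
  }
  expect_output(print(s), "SimBaS")
})
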