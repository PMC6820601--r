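test_that("kappa/range conversion follows sqrt(8 nu)/rho and round-trips", {
  expect_equal(kappa_from_range(2, nu = 0.5), 1.0)
  expect_equal(kappa_from_range(10, nu = 1), sqrt(8) / 10, tolerance = 1e-12)
  expect_equal(kappa_from_range(10, nu = 1), 0.282843, tolerance = 1e-5)
  for (rho in c(0.5, 2, 10, 37)) {
    for (nu in c(0.5, 1, 2.5)) {
      expect_equal(range_from_kappa(kappa_from_range(rho, nu), nu), rho)
    }
  }
  expect_error(kappa_from_range(-1), "positive")
  expect_error(range_from_kappa(0), "positive")
})

test_that("SPDE variance link evaluates the closed form and inverts", {
  expect_equal(sigma2_from_spde(1, 1, nu = 1, d = 2), 1 / (4 * pi),
    tolerance = 1e-12
  )
  # tau enters squared in the denominator
  expect_equal(
    sigma2_from_spde(1, 2, nu = 1) / sigma2_from_spde(1, 1, nu = 1), 1 / 4
  )
  for (kappa in c(0.3, 1, 4)) {
    for (tau in c(0.1, 1, 7)) {
      expect_equal(
        tau_from_sigma2(sigma2_from_spde(kappa, tau), kappa), tau,
        tolerance = 1e-12
      )
    }
  }
  expect_error(sigma2_from_spde(-1, 1), "positive")
})

test_that("Matern covariance: marginal variance at distance zero, range convention, exponential special case", {
  coords <- cbind(c(0, 10, 3), c(0, 0, 4))
  C <- matern_cov(coords, sigma2 = 2.5, range = 10, nu = 1)
  expect_equal(diag(C), rep(2.5, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(C))
  # range parameter = distance of correlation near 0.1 (0.139 at nu = 1)
  kd <- kappa_from_range(10, 1) * 10
  expect_equal(C[1, 2] / 2.5, kd * besselK(kd, 1), tolerance = 1e-12)
  expect_equal(C[1, 2] / 2.5, 0.1397, tolerance = 1e-3)
  # nu = 1/2 reduces to the exponential covariance exp(-kappa d), kappa = 2/rho
  set.seed(4)
  pts <- cbind(runif(12, 0, 20), runif(12, 0, 20))
  C12 <- matern_cov(pts, sigma2 = 1.7, range = 6, nu = 0.5)
  D <- as.matrix(dist(pts))
  expect_equal(C12, 1.7 * exp(-(2 / 6) * D), tolerance = 1e-10)
  expect_error(matern_cov(cbind(NA, 1)), "finite")
})

test_that("AR1 precision is the inverse of the dense AR1 covariance", {
  # stationary variance: sigma2_x / (1 - rho^2)
  Q3 <- ar1_precision(3, 0.8, sigma2_innov = 0.36)
  expect_equal(solve(as.matrix(Q3))[1, 1], 1.0, tolerance = 1e-12)
  # rho = 0: independence at scale 1/sigma2
  expect_equal(
    as.matrix(ar1_precision(4, 0, sigma2_innov = 2)), diag(0.5, 4)
  )
  # dense inversion oracle
  for (rho in c(-0.6, 0.5, 0.9)) {
    S <- ar1_cov(5, rho)
    expect_equal(
      as.matrix(ar1_precision(5, rho)) %*% S, diag(5),
      tolerance = 1e-8, ignore_attr = TRUE
    )
  }
  expect_error(ar1_precision(3, 1), "rho")
})

test_that("AR1xAR1 Kronecker structure: separable correlations and exact inverse pair", {
  x <- ar1xar1_cov(4, 3, rho_r = 0.8, rho_c = 0.8, sigma2 = 1)
  expect_equal(
    as.matrix(x$prec %*% x$cov), diag(12),
    tolerance = 1e-10, ignore_attr = TRUE
  )
  # correlation at row lag a, col lag b = rho_r^a rho_c^b; lag (1,1) -> 0.64
  idx <- function(r, c) (r - 1) * 3 + c
  expect_equal(x$cov[idx(1, 1), idx(2, 2)], 0.8 * 0.8)
  expect_equal(x$cov[idx(1, 1), idx(3, 2)], 0.8^2 * 0.8)
  expect_equal(diag(x$cov), rep(1, 12)) # sigma2 is the marginal variance
  x0 <- ar1xar1_cov(3, 3, 0, 0, 2)
  expect_equal(x0$cov, diag(2, 9), ignore_attr = TRUE)
  # inverse-pair oracle on grids up to 6x6
  for (dims in list(c(2, 5), c(6, 6))) {
    xx <- ar1xar1_cov(dims[1], dims[2], 0.7, -0.3, 0.5)
    expect_equal(
      as.matrix(xx$prec %*% xx$cov), diag(prod(dims)),
      tolerance = 1e-8, ignore_attr = TRUE
    )
  }
  expect_error(ar1xar1_cov(0, 3, 0.5, 0.5), "grid")
  expect_error(ar1xar1_cov(3, 3, 1.2, 0.5), "rho")
})

test_that("AR1 effective range: lag where correlation reaches 0.1", {
  expect_equal(ar1_range(0.1), 1.0)
  expect_equal(ar1_range(0.8), log(0.1) / log(0.8))
  expect_equal(round(ar1_range(0.8)), 10)
  # monotone in rho
  rhos <- seq(0.1, 0.95, by = 0.05)
  expect_true(all(diff(ar1_range(rhos)) > 0))
  expect_error(ar1_range(1), "rho")
  expect_error(ar1_range(-0.2), "rho")
})

test_that("field sampling: determinism, near-zero variance limit, MC marginal variance", {
  S <- matern_cov(expand.grid(x = 0:6, y = 0:6), sigma2 = 2, range = 3)
  a <- sample_field(S, 3, seed = 11)
  b <- sample_field(S, 3, seed = 11)
  expect_identical(a, b)
  tiny <- sample_field(matern_cov(cbind(0:3, 0), sigma2 = 1e-12, range = 3),
    2,
    seed = 1
  )
  expect_lt(max(abs(tiny)), 1e-4)
  # mean over coordinates of empirical/target variance within 3 MC se
  draws <- sample_field(S, 1000, seed = 5)
  ratio <- mean(apply(draws, 1, var) / 2)
  expect_lt(abs(ratio - 1), 3 * sqrt(2 / 999))
  # sparse-precision route agrees in distribution
  pr <- ar1xar1_cov(6, 5, 0.6, 0.6, 1.5)
  dr2 <- sample_field(pr$prec, 1000, seed = 6)
  expect_lt(abs(mean(apply(dr2, 1, var) / 1.5) - 1), 3 * sqrt(2 / 999))
  # non-positive-definite input reports a diagnostic
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(sample_field(bad), "eigenvalue")
})

test_that("Nelder wheel layout: geometry, growing areas and densities", {
  nl <- nelder_layout()
  expect_equal(nrow(nl), 300)
  expect_equal(length(unique(round(nl$density, 10))), 10)
  expect_true(all(table(round(nl$density, 10)) == 30))
  theta <- 2 * pi / 30
  expect_equal(nl$area[nl$ring == 1][1],
    theta * 10^2 * (1.15 - 1 / 1.15) / 2,
    tolerance = 1e-12
  )
  expect_equal(nl$area[nl$ring == 1][1], 2.937, tolerance = 1e-3)
  expect_equal(nl$density[nl$ring == 1][1], 0.3405, tolerance = 1e-4)
  expect_equal(max(nl$radius), 10 * 1.15^9, tolerance = 1e-12)
  expect_equal(max(nl$radius), 35.18, tolerance = 1e-3)
  expect_equal(nl$density, 1 / nl$area)
  expect_error(nelder_layout(k = 1), "expand")
})

test_that("lattice layout uses twice the row spacing between columns", {
  lay <- lattice_layout(3, 4)
  expect_equal(nrow(lay), 12)
  expect_equal(sort(unique(lay$x_coord)), c(0, 2, 4, 6))
  expect_equal(sort(unique(lay$y_coord)), c(0, 1, 2))
  expect_false(anyDuplicated(lay[, c("row", "col")]) > 0)
})
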