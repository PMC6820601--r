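#' Matern scale parameter from the spatial range
#'
#' The range \eqn{\rho} is the distance at which the Matern correlation has
#' dropped to approximately 0.1; the scale parameter is
#' \eqn{\kappa = \sqrt{8\nu}/\rho}.
#'
#' @param range Spatial range \eqn{\rho > 0}.
#' @param nu Smoothness \eqn{\nu > 0}; the default 1 gives, with \eqn{d = 2},
#'   the SPDE setting \eqn{\alpha = \nu + d/2 = 2}.
#' @return The scale parameter \eqn{\kappa}.
#' @export
#' @examples
#' kappa_from_range(10, nu = 1)
kappa_from_range <- function(range, nu = 1) {
  stopifnot(is.numeric(range), is.numeric(nu))
  if (any(range <= 0) || any(nu <= 0)) {
    stop("`range` and `nu` must be positive", call. = FALSE)
  }
  sqrt(8 * nu) / range
}

#' @rdname kappa_from_range
#' @param kappa Scale parameter \eqn{\kappa > 0}.
#' @export
range_from_kappa <- function(kappa, nu = 1) {
  if (any(kappa <= 0) || any(nu <= 0)) {
    stop("`kappa` and `nu` must be positive", call. = FALSE)
  }
  sqrt(8 * nu) / kappa
}

#' Marginal variance of the SPDE representation of a Matern field
#'
#' For the Matern field defined through the stochastic partial differential
#' equation \eqn{(\kappa^2 - \Delta)^{\alpha/2} x(s) = W(s)} with
#' \eqn{\alpha = \nu + d/2}, the marginal variance is
#' \deqn{\sigma_s^2 = \Gamma(\nu) / (\Gamma(\alpha) (4\pi)^{d/2} \kappa^{2\nu} \tau^2).}
#'
#' @param kappa,tau Positive SPDE parameters controlling range and variance.
#' @param nu Smoothness (default 1).
#' @param d Spatial dimension (default 2).
#' @return Marginal variance \eqn{\sigma_s^2}.
#' @export
sigma2_from_spde <- function(kappa, tau, nu = 1, d = 2) {
  if (any(kappa <= 0) || any(tau <= 0) || any(nu <= 0)) {
    stop("`kappa`, `tau` and `nu` must be positive", call. = FALSE)
  }
  alpha <- nu + d / 2
  gamma(nu) / (gamma(alpha) * (4 * pi)^(d / 2) * kappa^(2 * nu) * tau^2)
}

#' @rdname sigma2_from_spde
#' @param sigma2 Target marginal variance.
#' @export
tau_from_sigma2 <- function(sigma2, kappa, nu = 1, d = 2) {
  if (any(sigma2 <= 0) || any(kappa <= 0) || any(nu <= 0)) {
    stop("`sigma2` and `kappa` must be positive", call. = FALSE)
  }
  alpha <- nu + d / 2
  sqrt(gamma(nu) / (gamma(alpha) * (4 * pi)^(d / 2) * kappa^(2 * nu) * sigma2))
}

#' Matern covariance matrix over a set of plot coordinates
#'
#' \deqn{C(s_i, s_j) = \frac{\sigma_s^2}{2^{\nu-1}\Gamma(\nu)}
#'   (\kappa \|s_j - s_i\|)^\nu K_\nu(\kappa \|s_j - s_i\|)}
#' with \eqn{K_\nu} the modified Bessel function of the second kind and
#' \eqn{\kappa = \sqrt{8\nu}/\rho}. At distance zero the covariance equals the
#' marginal variance \eqn{\sigma_s^2}.
#'
#' @param coords Two-column matrix or data frame of coordinates.
#' @param sigma2 Marginal variance \eqn{\sigma_s^2 > 0}.
#' @param range Range \eqn{\rho > 0} (distance of correlation ~0.1).
#' @param nu Smoothness (default 1).
#' @return A dense symmetric positive semi-definite covariance matrix.
#' @export
matern_cov <- function(coords, sigma2 = 1, range = 10, nu = 1) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    stop("coordinates must be finite numeric values", call. = FALSE)
  }
  if (sigma2 <= 0 || range <= 0 || nu <= 0) {
    stop("`sigma2`, `range` and `nu` must be positive", call. = FALSE)
  }
  D <- as.matrix(stats::dist(coords))
  sigma2 * matern_corr(D, range = range, nu = nu)
}

# Matern correlation for a matrix/vector of distances (1 at d = 0).
matern_corr <- function(D, range, nu = 1) {
  kappa <- kappa_from_range(range, nu)
  R <- D
  pos <- D > 0
  kd <- kappa * D[pos]
  R[pos] <- 2^(1 - nu) / gamma(nu) * kd^nu * besselK(kd, nu)
  R[!pos] <- 1
  R
}

#' Precision matrix of a stationary first-order autoregressive process
#'
#' The AR1 process is \eqn{x_1 \sim N(0, \sigma_x^2/(1-\rho^2))},
#' \eqn{x_i | x_{i-1} \sim N(\rho x_{i-1}, \sigma_x^2)}; its precision matrix
#' is tridiagonal.
#'
#' @param n Length of the process (>= 1).
#' @param rho Autocorrelation, |rho| < 1.
#' @param sigma2_innov Innovation variance \eqn{\sigma_x^2}; the stationary
#'   marginal variance is \eqn{\sigma_x^2/(1-\rho^2)}.
#' @return Sparse symmetric tridiagonal precision matrix (class `dsCMatrix`).
#' @export
ar1_precision <- function(n, rho, sigma2_innov = 1) {
  stopifnot(n >= 1)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (sigma2_innov <= 0) stop("`sigma2_innov` must be positive", call. = FALSE)
  if (n == 1) {
    return(Matrix::Matrix((1 - rho^2) / sigma2_innov, 1, 1, sparse = TRUE))
  }
  main <- c(1, rep(1 + rho^2, n - 2), 1)
  Q <- Matrix::bandSparse(n, n,
    k = c(0, 1),
    diagonals = list(main, rep(-rho, n - 1)), symmetric = TRUE
  )
  Q / sigma2_innov
}

#' Covariance matrix of a stationary AR1 process
#'
#' @inheritParams ar1_precision
#' @return Dense covariance matrix with entries
#'   \eqn{\sigma_x^2 \rho^{|i-j|} / (1-\rho^2)}.
#' @export
ar1_cov <- function(n, rho, sigma2_innov = 1) {
  stopifnot(n >= 1)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  idx <- seq_len(n)
  sigma2_innov / (1 - rho^2) * rho^abs(outer(idx, idx, "-"))
}

#' Separable AR1 x AR1 covariance and precision over a lattice
#'
#' Plots on an `n_rows` x `n_cols` lattice are modelled with the separable
#' covariance \eqn{\sigma_x^2 (R_r \otimes R_c)} where \eqn{R_r, R_c} are AR1
#' *correlation* matrices in the row and column direction, so `sigma2` is the
#' marginal variance of every plot and the correlation at row lag a and column
#' lag b is \eqn{\rho_r^a \rho_c^b}. Plots are ordered row-major (row index
#' varies slowest), matching `lattice_layout()`.
#'
#' @param n_rows,n_cols Lattice dimensions (>= 1).
#' @param rho_r,rho_c Autocorrelations in the row and column directions.
#' @param sigma2 Marginal variance of each plot effect.
#' @return List with dense `cov` and sparse `prec` (exact inverses of each
#'   other), ordered row-major.
#' @export
ar1xar1_cov <- function(n_rows, n_cols, rho_r = 0.8, rho_c = 0.8, sigma2 = 1) {
  if (n_rows < 1 || n_cols < 1) stop("grid size must be >= 1", call. = FALSE)
  if (abs(rho_r) >= 1 || abs(rho_c) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (sigma2 <= 0) stop("`sigma2` must be positive", call. = FALSE)
  # correlation-scale AR1: innovation variance 1 - rho^2 gives unit marginals
  Rr <- ar1_cov(n_rows, rho_r, sigma2_innov = 1 - rho_r^2)
  Rc <- ar1_cov(n_cols, rho_c, sigma2_innov = 1 - rho_c^2)
  Qr <- ar1_precision(n_rows, rho_r, sigma2_innov = 1 - rho_r^2)
  Qc <- ar1_precision(n_cols, rho_c, sigma2_innov = 1 - rho_c^2)
  list(
    cov = sigma2 * kronecker(Rr, Rc),
    prec = Matrix::forceSymmetric(kronecker(Qr, Qc) / sigma2)
  )
}

#' @rdname ar1xar1_cov
#' @export
ar1xar1_precision <- function(n_rows, n_cols, rho_r = 0.8, rho_c = 0.8,
                              sigma2 = 1) {
  ar1xar1_cov(n_rows, n_cols, rho_r, rho_c, sigma2)$prec
}

#' Effective range of an AR1 process
#'
#' Distance (in lag units) at which the AR1 correlation \eqn{\rho^d} drops to
#' 0.1: \eqn{\log(0.1)/\log(\rho)}. An autocorrelation of 0.8 corresponds to a
#' range of about 10 units.
#'
#' @param rho Autocorrelation in (0, 1).
#' @return Lag distance at correlation 0.1.
#' @export
ar1_range <- function(rho) {
  if (any(rho <= 0) || any(rho >= 1)) stop("rho must be in (0, 1)", call. = FALSE)
  log(0.1) / log(rho)
}

#' Sample zero-mean Gaussian fields from a covariance or precision structure
#'
#' @param structure A dense covariance matrix, or a sparse precision matrix
#'   (anything inheriting from `Matrix::sparseMatrix`), or a list with a
#'   `cov` or `prec` element as returned by [ar1xar1_cov()].
#' @param n_samples Number of independent draws.
#' @param seed Optional integer seed for reproducible draws.
#' @return Matrix with one column per draw (`n_plots` x `n_samples`).
#' @export
sample_field <- function(structure, n_samples = 1, seed = NULL) {
  draw <- function() {
    if (is.list(structure) && !is.null(structure$prec)) {
      structure <- structure$prec
    } else if (is.list(structure) && !is.null(structure$cov)) {
      structure <- structure$cov
    }
    if (methods::is(structure, "sparseMatrix")) {
      Q <- structure
      n <- nrow(Q)
      ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Q), LDL = FALSE, perm = TRUE),
        error = function(e) {
          stop("precision matrix is not positive definite: ", conditionMessage(e),
            call. = FALSE
          )
        }
      )
      z <- matrix(stats::rnorm(n * n_samples), n, n_samples)
      # x = P' L^-T z  gives Var(x) = Q^-1
      ex <- Matrix::expand(ch)
      as.matrix(Matrix::crossprod(ex$P, Matrix::solve(Matrix::t(ex$L), z)))
    } else {
      S <- as.matrix(structure)
      n <- nrow(S)
      L <- tryCatch(chol(S), error = function(e) {
        ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
        stop(sprintf(
          "covariance matrix is not positive definite (smallest eigenvalue %.3e)", ev
        ), call. = FALSE)
      })
      crossprod(L, matrix(stats::rnorm(n * n_samples), n, n_samples))
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Rectangular field-trial lattice layout
#'
#' Builds a tibble of plot positions for an `n_rows` x `n_cols` lattice.
#' Defaults mirror long narrow cereal plots: unit row spacing and column
#' spacing twice as large.
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @param row_spacing,col_spacing Physical distances between plot centres.
#' @param trial_id Identifier copied into the `trial_id` column.
#' @return Tibble with columns `trial_id`, `plot`, `row`, `col`, `x_coord`
#'   (column direction), `y_coord` (row direction), ordered row-major.
#' @export
lattice_layout <- function(n_rows, n_cols, row_spacing = 1, col_spacing = 2,
                           trial_id = "trial1") {
  stopifnot(n_rows >= 1, n_cols >= 1)
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  tibble::tibble(
    trial_id = trial_id,
    plot = seq_len(nrow(g)),
    row = g$row,
    col = g$col,
    x_coord = (g$col - 1) * col_spacing,
    y_coord = (g$row - 1) * row_spacing
  )
}

#' Nelder wheel spacing-trial layout
#'
#' Trees sit at intersections of `n_spokes` spokes and `n_rings` concentric
#' rings, ring radii growing geometrically: \eqn{r_i = r_1 k^{i-1}}. The
#' growing area of a tree in ring i is \eqn{\theta r_i^2 (k - k^{-1})/2} with
#' \eqn{\theta = 2\pi/n_{spokes}}, and planting density is its inverse, so a
#' single wheel tests one density per ring.
#'
#' @param n_rings Number of rings (default 10).
#' @param n_spokes Number of spokes (default 30).
#' @param r1 Radius of the innermost ring (default 10).
#' @param k Ring expansion factor (> 1; default 1.15).
#' @return Tibble with `tree`, `ring`, `spoke`, `radius`, `angle`, `x_coord`,
#'   `y_coord`, `area`, `density`.
#' @export
#' @examples
#' nelder_layout()
nelder_layout <- function(n_rings = 10, n_spokes = 30, r1 = 10, k = 1.15) {
  stopifnot(n_rings >= 1, n_spokes >= 3, r1 > 0)
  if (k <= 1) stop("ring factor `k` must exceed 1 (rings must expand)", call. = FALSE)
  theta <- 2 * pi / n_spokes
  g <- expand.grid(spoke = seq_len(n_spokes), ring = seq_len(n_rings))
  radius <- r1 * k^(g$ring - 1)
  angle <- (g$spoke - 1) * theta
  area <- theta * radius^2 * (k - 1 / k) / 2
  tibble::tibble(
    tree = seq_len(nrow(g)),
    ring = g$ring,
    spoke = g$spoke,
    radius = radius,
    angle = angle,
    x_coord = radius * cos(angle),
    y_coord = radius * sin(angle),
    area = area,
    density = 1 / area
  )
}
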