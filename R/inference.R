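#' Fisher-type transform of an autocorrelation
#'
#' \eqn{z = \log((1+\rho)/(1-\rho))}, a monotone bijection from (-1, 1) to
#' the real line with inverse \eqn{\rho = \tanh(z/2)}. A Gaussian prior with
#' mean 0 and standard deviation 0.15 on z puts the 95% limits of \eqn{\rho}
#' at approximately -0.15 and 0.15.
#'
#' @param rho Autocorrelation in (-1, 1).
#' @return Transformed value z.
#' @export
rho_to_z <- function(rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  log((1 + rho) / (1 - rho))
}

#' @rdname rho_to_z
#' @param z Real-valued transformed autocorrelation.
#' @export
z_to_rho <- function(z) tanh(z / 2)

#' Quantile of the autocorrelation under its transformed Gaussian prior
#'
#' @param p Probability.
#' @param prior_sd Standard deviation of the Gaussian prior on z.
#' @return The rho-scale quantile \eqn{\tanh(\Phi^{-1}(p) \cdot sd / 2)}.
#' @export
rho_prior_quantile <- function(p, prior_sd = 0.15) {
  z_to_rho(stats::qnorm(p, 0, prior_sd))
}

#' Inverse-gamma density
#'
#' Density of the inverse-gamma distribution with shape \eqn{\alpha} and
#' (inverse) scale \eqn{\beta}: \eqn{f(x) = \beta^\alpha / \Gamma(\alpha)
#' x^{-\alpha-1} e^{-\beta/x}}. The default hyperprior on variance parameters
#' uses shape 1 and scale 5e-5.
#'
#' @param x Positive evaluation points.
#' @param shape,scale Positive parameters.
#' @param log Return the log density.
#' @return Density values.
#' @export
dinvgamma <- function(x, shape = 1, scale = 5e-5, log = FALSE) {
  ld <- shape * base::log(scale) - lgamma(shape) -
    (shape + 1) * base::log(x) - scale / x
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

# theta handling ------------------------------------------------------------

theta_init <- function(model) {
  vapply(model$hypers, function(h) h$init, numeric(1))
}

theta_natural <- function(model, tvec) {
  stats::setNames(
    lapply(seq_along(model$hypers), function(i) {
      unname(model$hypers[[i]]$to_natural(tvec[i]))
    }),
    names(model$hypers)
  )
}

theta_unconstrained <- function(model, natural) {
  out <- theta_init(model)
  for (nm in names(natural)) {
    h <- model$hypers[[nm]]
    if (is.null(h)) stop("unknown hyperparameter: ", nm, call. = FALSE)
    out[match(nm, names(model$hypers))] <- switch(h$type,
      logvar = log(natural[[nm]]),
      rho = rho_to_z(natural[[nm]]),
      gauss = log(natural[[nm]])
    )
  }
  out
}

log_prior_theta <- function(model, tvec) {
  sum(vapply(
    seq_along(model$hypers),
    function(i) model$hypers[[i]]$log_prior(tvec[i]), numeric(1)
  ))
}

#' Joint prior precision of the latent field
#'
#' Assembles the block-diagonal prior precision of all latent effects (fixed
#' effects, genetic effects, spatial fields) at the given hyperparameter
#' values.
#'
#' @param model An [assemble_model()] object.
#' @param theta Named list/vector of hyperparameters on the natural scale
#'   (missing entries keep their initialization values).
#' @return List with sparse `Q` (block-diagonal prior precision), its
#'   `logdet`, and the per-block precisions.
#' @export
joint_precision <- function(model, theta) {
  tvec <- theta_unconstrained(model, as.list(theta))
  th <- theta_natural(model, tvec)
  parts <- lapply(model$blocks, function(b) b$Qfun(th))
  list(
    Q = Matrix::bdiag(lapply(parts, function(p) p$Q)),
    logdet = sum(vapply(parts, function(p) p$logdet, numeric(1))),
    blocks = parts
  )
}

# Dense Gaussian core: everything the Gaussian-likelihood model needs at one
# hyperparameter value. The exact latent conditional posterior is
# N(mu, Qpost^-1) with Qpost = Qprior + A'A/s2e and mu = Qpost^-1 A'y/s2e.
lgm_core <- function(model, tvec, want_cov = FALSE) {
  th <- theta_natural(model, tvec)
  s2e <- th$sigma2_e
  N <- model$n_latent
  Qp <- matrix(0, N, N)
  logdet_prior <- 0
  for (i in seq_along(model$blocks)) {
    b <- model$blocks[[i]]
    part <- b$Qfun(th)
    idx <- model$block_start[i]:model$block_end[i]
    Qp[idx, idx] <- as.matrix(part$Q)
    logdet_prior <- logdet_prior + part$logdet
  }
  Qpost <- Qp + model$AtA / s2e
  ch <- safe_chol(Qpost)
  b <- model$Aty / s2e
  mu <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  logdet_post <- 2 * sum(log(diag(ch)))
  loglik <- 0.5 * logdet_prior - 0.5 * logdet_post -
    model$n_obs / 2 * log(2 * pi * s2e) -
    0.5 * (model$yty / s2e - sum(b * mu))
  out <- list(
    mu = mu, loglik = loglik, chol = ch,
    logdet_prior = logdet_prior, logdet_post = logdet_post, s2e = s2e
  )
  if (want_cov) {
    out$cov <- chol2inv(ch)
    out$sd <- sqrt(diag(out$cov))
  }
  out
}

#' Exact latent posterior at fixed hyperparameters
#'
#' For the Gaussian likelihood the conditional posterior of the latent field
#' is exactly Gaussian; this returns its mean and marginal standard
#' deviations, equal to generalized-least-squares Bayesian linear-model
#' algebra.
#'
#' @inheritParams joint_precision
#' @return Tibble with `block`, `label`, `mean`, `sd` for every latent
#'   effect; the posterior covariance is attached as attribute `"cov"`.
#' @export
latent_posterior <- function(model, theta) {
  tvec <- theta_unconstrained(model, as.list(theta))
  core <- lgm_core(model, tvec, want_cov = TRUE)
  out <- latent_tibble(model, core$mu, core$sd)
  attr(out, "cov") <- core$cov
  out
}

latent_tibble <- function(model, mu, sd) {
  blocks <- rep(
    names(model$blocks),
    times = vapply(model$blocks, function(b) b$size, numeric(1))
  )
  labels <- unlist(lapply(model$blocks, function(b) {
    if (is.null(b$labels)) as.character(seq_len(b$size)) else as.character(b$labels)
  }), use.names = FALSE)
  tibble::tibble(block = blocks, label = labels, mean = mu, sd = sd)
}

#' Log posterior of the hyperparameters (up to a constant)
#'
#' Gaussian-likelihood closed form: the latent field is integrated out
#' exactly (log-determinants plus a quadratic form), then the log prior and
#' transformation Jacobians are added.
#'
#' @inheritParams joint_precision
#' @return Scalar log posterior density (unnormalized).
#' @export
log_marginal_post <- function(model, theta) {
  tvec <- theta_unconstrained(model, as.list(theta))
  log_marginal_post_t(model, tvec)
}

log_marginal_post_t <- function(model, tvec) {
  val <- unname(lgm_core(model, tvec)$loglik + log_prior_theta(model, tvec))
  if (!is.finite(val)) {
    stop(
      "non-finite hyperparameter log posterior at theta = (",
      paste(signif(tvec, 4), collapse = ", "), ")",
      call. = FALSE
    )
  }
  val
}

# integration points around the mode ---------------------------------------

integration_points <- function(strategy, mode, sds, n_hyper) {
  if (strategy == "eb" || n_hyper == 0) {
    return(matrix(mode, nrow = 1))
  }
  if (strategy == "grid" && n_hyper <= 4) {
    offs <- expand.grid(rep(list(c(-1, 0, 1)), n_hyper))
    pts <- t(apply(offs, 1, function(o) mode + o * sds))
    return(pts)
  }
  # CCD-style: mode plus two scaled axis points per dimension
  pts <- matrix(mode, nrow = 1)
  for (i in seq_len(n_hyper)) {
    for (s in c(-1.2, 1.2)) {
      p <- mode
      p[i] <- p[i] + s * sds[i]
      pts <- rbind(pts, p)
    }
  }
  pts
}

#' Fit a latent Gaussian field-trial model
#'
#' Finds the hyperparameter posterior mode by quasi-Newton optimization on
#' the unconstrained scale, optionally explores the posterior with a tensor
#' grid (3 points per dimension, up to 4 dimensions) or a CCD-style design
#' (mode plus scaled axis points), and returns latent posterior summaries as
#' mixtures over the integration points weighted by the normalized posterior.
#'
#' @param model An [assemble_model()] object.
#' @param strategy `"eb"` (mode plug-in), `"grid"`, or `"ccd"`.
#' @param control List: `maxit` (default 200), `reltol` (1e-8), `init`
#'   (named natural-scale warm start), `hyper_sd` (compute the Laplace
#'   Hessian even under `"eb"`; default TRUE).
#' @return Object of class `lgm_fit` with latent summaries (`$latent`),
#'   hyperparameter summaries (`$hyper`), mode, Hessian-based standard
#'   deviations, integration points/weights and the log posterior at the
#'   mode.
#' @export
fit_lgm <- function(model, strategy = c("eb", "grid", "ccd"),
                    control = list()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(model, "lgm_model"))
  maxit <- control$maxit %||% 200
  reltol <- control$reltol %||% 1e-8
  hyper_sd <- control$hyper_sd %||% TRUE
  t0 <- theta_init(model)
  if (!is.null(control$init)) {
    t0 <- theta_unconstrained(model, as.list(control$init))
  }
  nh <- length(t0)
  # line-search excursions to absurd hyperparameter values are repelled with
  # a large finite penalty rather than an error
  negfn <- function(t) {
    val <- tryCatch(
      lgm_core(model, t)$loglik + log_prior_theta(model, t),
      error = function(e) -Inf
    )
    if (!is.finite(val)) 1e10 + sum(t^2) else -val
  }
  opt <- stats::optim(t0, negfn,
    method = if (nh > 1) "BFGS" else "BFGS",
    control = list(maxit = maxit, reltol = reltol)
  )
  if (opt$convergence != 0) {
    stop(sprintf(
      "hyperparameter optimization did not converge (code %d, %d evaluations): %s",
      opt$convergence, opt$counts[1], opt$message %||% ""
    ), call. = FALSE)
  }
  mode <- opt$par
  H <- NULL
  sds <- rep(0.5, nh)
  if (hyper_sd || strategy != "eb") {
    H <- stats::optimHess(mode, negfn)
    covH <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(covH) && all(diag(covH) > 0)) {
      sds <- sqrt(diag(covH))
    }
  }
  pts <- integration_points(strategy, mode, sds, nh)
  lp <- apply(pts, 1, function(t) log_marginal_post_t(model, t))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  # mixture over integration points for the latent posterior
  N <- model$n_latent
  mu_mix <- numeric(N)
  m2_mix <- numeric(N)
  cov_u <- NULL
  mu_u <- NULL
  ui <- which(names(model$blocks) == "markers")
  uidx <- if (length(ui)) model$block_start[ui]:model$block_end[ui] else NULL
  for (k in seq_len(nrow(pts))) {
    core <- lgm_core(model, pts[k, ], want_cov = TRUE)
    mu_mix <- mu_mix + w[k] * core$mu
    m2_mix <- m2_mix + w[k] * (core$sd^2 + core$mu^2)
    if (!is.null(uidx)) {
      Cu <- core$cov[uidx, uidx, drop = FALSE] +
        tcrossprod(core$mu[uidx])
      cov_u <- if (is.null(cov_u)) w[k] * Cu else cov_u + w[k] * Cu
      mu_u <- if (is.null(mu_u)) {
        w[k] * core$mu[uidx]
      } else {
        mu_u + w[k] * core$mu[uidx]
      }
    }
  }
  sd_mix <- sqrt(pmax(m2_mix - mu_mix^2, 0))
  if (!is.null(uidx)) cov_u <- cov_u - tcrossprod(mu_u)

  nat_mode <- theta_natural(model, mode)
  # delta method through the monotone transform for natural-scale sds;
  # interval endpoints transform exactly
  jac <- abs(vapply(seq_len(nh), function(i) {
    eps <- 1e-4
    (model$hypers[[i]]$to_natural(mode[i] + eps) -
      model$hypers[[i]]$to_natural(mode[i] - eps)) / (2 * eps)
  }, numeric(1)))
  lo <- vapply(seq_len(nh), function(i) {
    model$hypers[[i]]$to_natural(mode[i] - 1.96 * sds[i])
  }, numeric(1))
  hi <- vapply(seq_len(nh), function(i) {
    model$hypers[[i]]$to_natural(mode[i] + 1.96 * sds[i])
  }, numeric(1))
  hyper_tbl <- tibble::tibble(
    name = names(model$hypers),
    mode = vapply(nat_mode, function(v) v, numeric(1)),
    mode_t = mode,
    sd_t = sds,
    sd = jac * sds,
    lower = lo,
    upper = hi
  )

  structure(
    list(
      model = model, strategy = strategy,
      theta_mode = stats::setNames(mode, names(model$hypers)),
      theta_natural = nat_mode,
      hyper = hyper_tbl, hessian = H, theta_sd = sds,
      points = pts, weights = w,
      latent = latent_tibble(model, mu_mix, sd_mix),
      mu_u = mu_u, cov_u = cov_u,
      logpost_mode = -opt$value, opt_counts = opt$counts
    ),
    class = "lgm_fit"
  )
}

#' @export
print.lgm_fit <- function(x, ...) {
  cat(sprintf(
    "<lgm_fit> %s spatial, %s genetic (%s strategy)\n",
    x$model$spec$spatial, x$model$spec$genetic, x$strategy
  ))
  cat("hyperparameter posterior modes:\n")
  print(as.data.frame(x$hyper[, c("name", "mode", "sd")]), row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior genetic effects (estimated breeding values) per line
#'
#' For marker models the line effect is \eqn{z_j^* u^*} with mean and
#' standard deviation from the posterior of the component effects; for iid
#' or relationship-matrix models it is the line's latent effect itself.
#'
#' @param fit An [fit_lgm()] object.
#' @return Tibble with `line_id`, `mean`, `sd`.
#' @export
line_effects <- function(fit) {
  spec <- fit$model$spec
  if (spec$genetic %in% c("markers", "markers_iid")) {
    Zs <- fit$model$Zstar_lines
    pm <- as.numeric(Zs %*% fit$mu_u)
    pv <- rowSums((Zs %*% fit$cov_u) * Zs)
    tibble::tibble(
      line_id = fit$model$lines, mean = pm, sd = sqrt(pmax(pv, 0))
    )
  } else if (spec$genetic %in% c("iid", "grm")) {
    bl <- if (spec$genetic == "iid") "line_iid" else "line_grm"
    lt <- fit$latent[fit$latent$block == bl, ]
    tibble::tibble(line_id = lt$label, mean = lt$mean, sd = lt$sd)
  } else {
    stop("model has no genetic effects", call. = FALSE)
  }
}

#' Predict breeding values for genotyped, unphenotyped lines
#'
#' Uses the posterior of the marker-component effects: mean
#' \eqn{Z^*_{new} E(u^*)} and variance from the quadratic form with the
#' posterior covariance of \eqn{u^*}.
#'
#' @param fit A marker-model [fit_lgm()].
#' @param Zstar_new Compressed marker matrix of the new lines (same
#'   components as the training fit).
#' @return Tibble with `line_id` (rownames or index), `mean`, `sd`.
#' @export
predict_lines <- function(fit, Zstar_new) {
  if (is.null(fit$mu_u)) {
    stop("fit has no marker-effect block; predictions need a marker model",
      call. = FALSE
    )
  }
  Zstar_new <- as.matrix(Zstar_new)
  if (ncol(Zstar_new) != length(fit$mu_u)) {
    stop(sprintf(
      "Zstar_new has %d columns but the fit used %d components",
      ncol(Zstar_new), length(fit$mu_u)
    ), call. = FALSE)
  }
  pm <- as.numeric(Zstar_new %*% fit$mu_u)
  pv <- rowSums((Zstar_new %*% fit$cov_u) * Zstar_new)
  ids <- rownames(Zstar_new) %||% as.character(seq_len(nrow(Zstar_new)))
  tibble::tibble(line_id = ids, mean = pm, sd = sqrt(pmax(pv, 0)))
}
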