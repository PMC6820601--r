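#' Genomic data container for model building
#'
#' Centres (optionally scales) a dosage matrix, computes the VanRaden
#' relationship matrix if requested, and compresses the centred matrix with
#' principal components for marker-effect models.
#'
#' @param Z_raw Dosage matrix (lines x markers); rownames or `line_ids` give
#'   the line identifiers.
#' @param line_ids Line identifiers (defaults to rownames).
#' @param p_star,var_explained Compression rule passed to [pc_compress()];
#'   defaults to the 95% variance-explained rule.
#' @param scale_markers Scale centred columns to unit variance.
#' @param grm Also compute the relationship matrix `A` (needed for
#'   `genetic = "grm"` models).
#' @return Object of class `genomic_data`.
#' @export
genomic_data <- function(Z_raw, line_ids = rownames(Z_raw), p_star = NULL,
                         var_explained = NULL, scale_markers = FALSE,
                         grm = FALSE) {
  Z_raw <- as.matrix(Z_raw)
  if (is.null(line_ids)) stop("line identifiers required", call. = FALSE)
  stopifnot(length(line_ids) == nrow(Z_raw))
  vr <- vanraden_grm(Z_raw, scale_markers = scale_markers)
  pc <- pc_compress(vr$Z, p_star = p_star, var_explained = var_explained)
  rownames(pc$Zstar) <- line_ids
  structure(
    list(
      Z = vr$Z, Zstar = pc$Zstar, V = pc$V, d = pc$d, p_star = pc$p_star,
      var_explained = pc$var_explained, k = vr$k, q = vr$q,
      A = if (grm) vr$A else NULL, line_ids = as.character(line_ids)
    ),
    class = "genomic_data"
  )
}

#' @export
print.genomic_data <- function(x, ...) {
  cat(sprintf(
    "<genomic_data> %d lines, %d markers -> %d components (%.1f%% var), k = %.3f\n",
    length(x$line_ids), ncol(x$Z), x$p_star, 100 * x$var_explained, x$k
  ))
  invisible(x)
}

#' Model specification
#'
#' Chooses the spatial component, the genetic component and the fixed-effect
#' structure of the latent Gaussian field-trial model
#' \eqn{y(s_i) | \eta(s_i) \sim N(\eta(s_i), \sigma_e^2)},
#' \eqn{\eta(s_i) = \beta_0 + w_i \beta + g_j + x(s_i)}.
#'
#' @param spatial One of `"nospatial"`, `"rowcol"` (independent row and
#'   column effects), `"ar1xar1"` (separable autoregressive), `"matern"`
#'   (Gaussian random field, exact dense covariance) or `"matern_spde"`
#'   (finite-element Markov approximation).
#' @param genetic One of `"none"`, `"iid"` (independent line effects
#'   \eqn{n_j}), `"grm"` (relationship-matrix effects \eqn{a_j}),
#'   `"markers"` (principal-component marker effects \eqn{u^*}), or
#'   `"markers_iid"` (marker effects plus independent line effects).
#' @param covariates Names of phenotype-table columns entering as fixed
#'   effects (Gaussian prior, variance 1000).
#' @param per_trial_intercept Trial-specific intercepts \eqn{\beta_k} instead
#'   of a single \eqn{\beta_0}.
#' @param spatial_groups Named list mapping group names to trial ids; trials
#'   in a group share spatial hyperparameters (fields stay independent across
#'   trials). Default: one group containing every trial.
#' @param nu Matern smoothness (fixed at 1 so that \eqn{\alpha = 2}).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(spatial = c("nospatial", "rowcol", "ar1xar1", "matern",
                         "matern_spde"),
                       genetic = c("iid", "none", "grm", "markers",
                         "markers_iid"),
                       covariates = character(),
                       per_trial_intercept = FALSE,
                       spatial_groups = NULL, nu = 1) {
  structure(
    list(
      spatial = match.arg(spatial), genetic = match.arg(genetic),
      covariates = covariates, per_trial_intercept = per_trial_intercept,
      spatial_groups = spatial_groups, nu = nu
    ),
    class = "model_spec"
  )
}

# hyperparameter descriptors ------------------------------------------------

hyper_logvar <- function(name, init, beta = 5e-5) {
  list(
    name = name, type = "logvar", init = init,
    to_natural = function(t) exp(t),
    log_prior = function(t) log(beta) - beta * exp(-t) - t
  )
}

# Default prior follows the software default the study setting corresponds
# to: Gaussian with mean 0 and *precision* 0.15 (sd ~ 2.58) on the
# transformed autocorrelation. A literal sd of 0.15 would confine rho to
# about (-0.15, 0.15) a priori and rule out the autocorrelations (~0.8)
# that separable field-trial models routinely estimate.
hyper_rho <- function(name, prior_sd = 1 / sqrt(0.15)) {
  list(
    name = name, type = "rho", init = 0,
    # clamp away from +/-1 so extreme optimizer excursions stay valid
    to_natural = function(t) max(min(tanh(t / 2), 1 - 1e-8), -1 + 1e-8),
    log_prior = function(t) stats::dnorm(t, 0, prior_sd, log = TRUE)
  )
}

hyper_gauss <- function(name, mean, sd = 1, init = mean) {
  force(mean)
  force(sd)
  list(
    name = name, type = "gauss", init = init,
    to_natural = function(t) exp(t),
    log_prior = function(t) stats::dnorm(t, mean, sd, log = TRUE)
  )
}

# Cholesky with escalating diagonal jitter (documented fallback for nearly
# singular covariances, e.g. Matern ranges far beyond the field diameter).
safe_chol <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) {
    return(ch)
  }
  scale <- mean(diag(M))
  for (j in c(1e-10, 1e-8, 1e-6, 1e-4)) {
    ch <- tryCatch(chol(M + diag(j * scale, nrow(M))), error = function(e) NULL)
    if (!is.null(ch)) {
      return(ch)
    }
  }
  stop("matrix not positive definite even after jitter", call. = FALSE)
}

# latent block constructors -------------------------------------------------
# A block is: name, size, A (sparse n_obs x size), labels, and
# Qfun(th) -> list(Q, logdet) with th the block's natural hyperparameters.

block_iid <- function(name, A, hyper_name, labels = NULL) {
  size <- ncol(A)
  list(
    name = name, size = size, A = A, hypers = hyper_name, labels = labels,
    Qfun = function(th) {
      v <- th[[hyper_name]]
      list(Q = Matrix::Diagonal(size, 1 / v), logdet = -size * log(v))
    }
  )
}

block_fixed <- function(name, A, prior_var = 1000, labels = NULL) {
  size <- ncol(A)
  list(
    name = name, size = size, A = A, hypers = character(), labels = labels,
    Qfun = function(th) {
      list(
        Q = Matrix::Diagonal(size, 1 / prior_var),
        logdet = -size * log(prior_var)
      )
    }
  )
}

block_grm <- function(name, A, Arel, hyper_name, labels = NULL) {
  size <- ncol(A)
  ch <- safe_chol(Arel)
  Ainv <- chol2inv(ch)
  logdetA <- 2 * sum(log(diag(ch)))
  list(
    name = name, size = size, A = A, hypers = hyper_name, labels = labels,
    Qfun = function(th) {
      v <- th[[hyper_name]]
      list(Q = Ainv / v, logdet = -logdetA - size * log(v))
    }
  )
}

block_ar1xar1 <- function(name, A, n_rows, n_cols, hyper_names) {
  size <- n_rows * n_cols
  list(
    name = name, size = size, A = A, hypers = hyper_names, labels = NULL,
    Qfun = function(th) {
      rr <- th[[hyper_names[1]]]
      rc <- th[[hyper_names[2]]]
      v <- th[[hyper_names[3]]]
      Qr <- ar1_precision(n_rows, rr, sigma2_innov = 1 - rr^2)
      Qc <- ar1_precision(n_cols, rc, sigma2_innov = 1 - rc^2)
      list(
        Q = kronecker(Qr, Qc) / v,
        logdet = -n_cols * (n_rows - 1) * log(1 - rr^2) -
          n_rows * (n_cols - 1) * log(1 - rc^2) - size * log(v)
      )
    }
  )
}

block_matern <- function(name, A, coords, hyper_names, nu = 1, cache = NULL) {
  size <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  # trials with identical plot geometry share the computed precision
  dhash <- rlang::hash(round(D, 10))
  list(
    name = name, size = size, A = A, hypers = hyper_names, labels = NULL,
    Qfun = function(th) {
      kappa <- th[[hyper_names[1]]]
      tau <- th[[hyper_names[2]]]
      key <- paste(dhash, kappa, tau)
      if (!is.null(cache) && identical(cache$key, key)) {
        return(cache$val)
      }
      s2 <- sigma2_from_spde(kappa, tau, nu = nu)
      C <- s2 * matern_corr(D, range = range_from_kappa(kappa, nu), nu = nu)
      ch <- safe_chol(C)
      val <- list(Q = chol2inv(ch), logdet = -2 * sum(log(diag(ch))))
      if (!is.null(cache)) {
        cache$key <- key
        cache$val <- val
      }
      val
    }
  )
}

block_matern_spde <- function(name, A, mesh, hyper_names) {
  fem <- fem_matrices(mesh)
  Cinv <- Matrix::Diagonal(x = 1 / Matrix::diag(fem$C))
  size <- nrow(mesh$loc)
  list(
    name = name, size = size, A = A, hypers = hyper_names, labels = NULL,
    Qfun = function(th) {
      kappa <- th[[hyper_names[1]]]
      tau <- th[[hyper_names[2]]]
      Q <- tau^2 * (kappa^4 * fem$C + 2 * kappa^2 * fem$G +
        fem$G %*% Cinv %*% fem$G)
      Q <- Matrix::forceSymmetric(Q)
      ld <- 2 * Matrix::determinant(
        Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE),
        logarithm = TRUE, sqrt = TRUE
      )$modulus
      list(Q = Q, logdet = as.numeric(ld))
    }
  )
}

obs_indicator <- function(idx, n_levels) {
  Matrix::sparseMatrix(
    i = seq_along(idx), j = idx, x = 1,
    dims = c(length(idx), n_levels)
  )
}

#' Assemble a latent Gaussian model from a specification and data
#'
#' Builds the observation map, latent effect blocks and hyperparameter list
#' for the chosen model. Spatial fields are independent across trials and
#' share hyperparameters within each spatial group. The hyperparameter count
#' is guarded: more than 10 warns and more than 20 is an error, since the
#' hyperparameter posterior is explored by numerical integration.
#'
#' @param spec A [model_spec()].
#' @param phenotypes Tibble with `trial_id`, `phenotype`, plot positions
#'   (`row`, `col`, `x_coord`, `y_coord`), `line_id` (unless
#'   `genetic = "none"`) and any covariate columns named in the spec.
#' @param genomics A [genomic_data()] (required for marker and grm models).
#' @param mesh_args Optional list(extension, spacing) for the SPDE backend.
#' @return Object of class `lgm_model`.
#' @export
assemble_model <- function(spec, phenotypes, genomics = NULL,
                           mesh_args = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  ph <- tibble::as_tibble(phenotypes)
  n_obs <- nrow(ph)
  y <- ph$phenotype
  trials <- unique(as.character(ph$trial_id))
  blocks <- list()
  hypers <- list()

  # fixed effects
  if (spec$per_trial_intercept) {
    ti <- match(as.character(ph$trial_id), trials)
    X <- obs_indicator(ti, length(trials))
    xlab <- paste0("intercept_", trials)
  } else {
    X <- Matrix::Matrix(1, n_obs, 1, sparse = TRUE)
    xlab <- "intercept"
  }
  for (cv in spec$covariates) {
    if (!cv %in% names(ph)) stop("covariate column not found: ", cv, call. = FALSE)
    val <- ph[[cv]]
    if (is.character(val) || is.factor(val)) {
      f <- factor(val)
      if (nlevels(f) < 2) stop("covariate has a single level: ", cv, call. = FALSE)
      Xc <- obs_indicator(as.integer(f), nlevels(f))[, -1, drop = FALSE]
      X <- cbind(X, Xc)
      xlab <- c(xlab, paste0(cv, "_", levels(f)[-1]))
    } else {
      X <- cbind(X, Matrix::Matrix(val, n_obs, 1, sparse = TRUE))
      xlab <- c(xlab, cv)
    }
  }
  blocks$fixed <- block_fixed("fixed", X, labels = xlab)

  # genetic blocks
  var_y <- stats::var(y)
  lines <- NULL
  if (spec$genetic != "none") {
    if (!"line_id" %in% names(ph)) stop("phenotypes lack `line_id`", call. = FALSE)
    lines <- sort(unique(as.character(ph$line_id)))
    li <- match(as.character(ph$line_id), lines)
    if (spec$genetic %in% c("grm", "markers", "markers_iid")) {
      if (is.null(genomics)) stop("genomic data required for this model", call. = FALSE)
      missing_lines <- setdiff(lines, genomics$line_ids)
      if (length(missing_lines) > 0) {
        stop(
          "lines absent from genomic data: ",
          paste(utils::head(missing_lines, 5), collapse = ", "),
          call. = FALSE
        )
      }
    }
    if (spec$genetic %in% c("iid", "markers_iid")) {
      blocks$line_iid <- block_iid(
        "line_iid", obs_indicator(li, length(lines)), "sigma2_n",
        labels = lines
      )
      hypers$sigma2_n <- hyper_logvar("sigma2_n", init = 0)
    }
    if (spec$genetic == "grm") {
      Arel <- genomics$A
      if (is.null(Arel)) stop("genomic data built without `grm = TRUE`", call. = FALSE)
      Arel <- Arel[
        match(lines, genomics$line_ids),
        match(lines, genomics$line_ids),
        drop = FALSE
      ]
      blocks$line_grm <- block_grm(
        "line_grm", obs_indicator(li, length(lines)), Arel, "sigma2_a",
        labels = lines
      )
      hypers$sigma2_a <- hyper_logvar("sigma2_a", init = 0)
    }
    if (spec$genetic %in% c("markers", "markers_iid")) {
      Zs <- genomics$Zstar[match(lines, genomics$line_ids), , drop = FALSE]
      Amark <- methods::as(
        methods::as(Matrix::Matrix(Zs[li, , drop = FALSE]), "generalMatrix"),
        "CsparseMatrix"
      )
      blocks$markers <- block_iid(
        "markers", Amark, "sigma2_u",
        labels = paste0("pc", seq_len(ncol(Zs)))
      )
      hypers$sigma2_u <- hyper_logvar("sigma2_u", init = log(var_y / ncol(Zs)))
    }
  }

  # spatial blocks, grouped hyperparameters
  if (spec$spatial != "nospatial") {
    groups <- spec$spatial_groups
    if (is.null(groups)) groups <- list(g1 = trials)
    claimed <- unlist(groups)
    if (!setequal(claimed, trials) || anyDuplicated(claimed)) {
      stop("spatial_groups must partition the trial set", call. = FALSE)
    }
    matern_cache <- new.env(parent = emptyenv())
    for (gname in names(groups)) {
      gtr <- intersect(trials, groups[[gname]])
      sub_all <- ph[as.character(ph$trial_id) %in% gtr, , drop = FALSE]
      if (spec$spatial == "rowcol") {
        hr <- paste0("sigma2_r_", gname)
        hc <- paste0("sigma2_c_", gname)
        hypers[[hr]] <- hyper_logvar(hr, init = 0)
        hypers[[hc]] <- hyper_logvar(hc, init = 0)
      } else if (spec$spatial == "ar1xar1") {
        hn <- paste0(c("rho_r_", "rho_c_", "sigma2_x_"), gname)
        hypers[[hn[1]]] <- hyper_rho(hn[1])
        hypers[[hn[2]]] <- hyper_rho(hn[2])
        hypers[[hn[3]]] <- hyper_logvar(hn[3], init = 0)
      } else {
        # Matern priors scale with the field: prior mean at range =
        # diameter/5 and unit marginal variance; optimizer starts at
        # range = diameter/4.
        crd <- as.matrix(sub_all[, c("x_coord", "y_coord")])
        diam <- sqrt(sum((apply(crd, 2, max) - apply(crd, 2, min))^2))
        k0 <- kappa_from_range(diam / 5, spec$nu)
        t0 <- tau_from_sigma2(1, k0, spec$nu)
        ki <- kappa_from_range(diam / 4, spec$nu)
        hk <- paste0("kappa_", gname)
        ht <- paste0("tau_", gname)
        hypers[[hk]] <- hyper_gauss(hk, mean = log(k0), init = log(ki))
        hypers[[ht]] <- hyper_gauss(ht,
          mean = log(t0),
          init = log(tau_from_sigma2(max(var_y / 2, 1e-3), ki, spec$nu))
        )
      }
      for (tr in gtr) {
        sub <- ph[as.character(ph$trial_id) == tr, , drop = FALSE]
        rows_obs <- which(as.character(ph$trial_id) == tr)
        bname <- paste0("spatial_", tr)
        if (spec$spatial == "rowcol") {
          rlev <- sort(unique(sub$row))
          clev <- sort(unique(sub$col))
          Ar <- Matrix::sparseMatrix(
            i = rows_obs, j = match(sub$row, rlev), x = 1,
            dims = c(n_obs, length(rlev))
          )
          Ac <- Matrix::sparseMatrix(
            i = rows_obs, j = match(sub$col, clev), x = 1,
            dims = c(n_obs, length(clev))
          )
          blocks[[paste0("row_", tr)]] <- block_iid(
            paste0("row_", tr), Ar, paste0("sigma2_r_", gname)
          )
          blocks[[paste0("col_", tr)]] <- block_iid(
            paste0("col_", tr), Ac, paste0("sigma2_c_", gname)
          )
        } else if (spec$spatial == "ar1xar1") {
          nr <- max(sub$row)
          nc <- max(sub$col)
          cell <- (sub$row - 1L) * nc + sub$col # row-major
          As <- Matrix::sparseMatrix(
            i = rows_obs, j = cell, x = 1, dims = c(n_obs, nr * nc)
          )
          blocks[[bname]] <- block_ar1xar1(
            bname, As, nr, nc, paste0(c("rho_r_", "rho_c_", "sigma2_x_"), gname)
          )
        } else if (spec$spatial == "matern") {
          crd <- as.matrix(sub[, c("x_coord", "y_coord")])
          ucrd <- unique(crd)
          key <- match(
            paste(crd[, 1], crd[, 2]),
            paste(ucrd[, 1], ucrd[, 2])
          )
          As <- Matrix::sparseMatrix(
            i = rows_obs, j = key, x = 1, dims = c(n_obs, nrow(ucrd))
          )
          blocks[[bname]] <- block_matern(
            bname, As, ucrd,
            paste0(c("kappa_", "tau_"), gname),
            nu = spec$nu, cache = matern_cache
          )
        } else { # matern_spde
          crd <- as.matrix(sub[, c("x_coord", "y_coord")])
          diam <- sqrt(sum((apply(crd, 2, max) - apply(crd, 2, min))^2))
          ext <- if (!is.null(mesh_args$extension)) mesh_args$extension else diam / 5
          spc <- if (!is.null(mesh_args$spacing)) mesh_args$spacing else diam / 25
          mesh <- make_mesh(crd, extension = ext, spacing = spc)
          Amesh <- mesh_project(mesh, crd)
          ii <- Matrix::summary(Amesh)
          As <- Matrix::sparseMatrix(
            i = rows_obs[ii$i], j = ii$j, x = ii$x,
            dims = c(n_obs, nrow(mesh$loc))
          )
          blocks[[bname]] <- block_matern_spde(
            bname, As, mesh, paste0(c("kappa_", "tau_"), gname)
          )
        }
      }
    }
  }

  hypers <- c(list(sigma2_e = hyper_logvar("sigma2_e", init = 0)), hypers)
  # scale-aware default starts for the variance components
  nvar <- sum(vapply(hypers, function(h) h$type == "logvar", logical(1)))
  for (nm in names(hypers)) {
    if (hypers[[nm]]$type == "logvar" && nm != "sigma2_u") {
      hypers[[nm]]$init <- log(var_y / nvar)
    }
  }
  n_hyper <- length(hypers)
  if (n_hyper > 20) {
    stop(sprintf(
      "model has %d hyperparameters; the integration scheme supports at most 20",
      n_hyper
    ), call. = FALSE)
  }
  if (n_hyper > 10) {
    warning(sprintf(
      "model has %d hyperparameters; inference degrades above 10", n_hyper
    ), call. = FALSE)
  }

  A <- do.call(cbind, lapply(blocks, function(b) b$A))
  sizes <- vapply(blocks, function(b) b$size, numeric(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  out <- structure(
    list(
      spec = spec, y = y, n_obs = n_obs, blocks = blocks, hypers = hypers,
      A = A, AtA = as.matrix(Matrix::crossprod(A)),
      Aty = as.numeric(Matrix::crossprod(A, y)), yty = sum(y^2),
      block_start = starts, block_end = ends, n_latent = sum(sizes),
      trials = trials, lines = lines,
      Zstar_lines = if (spec$genetic %in% c("markers", "markers_iid")) {
        genomics$Zstar[match(lines, genomics$line_ids), , drop = FALSE]
      } else {
        NULL
      }
    ),
    class = "lgm_model"
  )
  attr(out, "obs_trial") <- as.character(ph$trial_id)
  if ("x_coord" %in% names(ph)) attr(out, "obs_x") <- ph$x_coord
  if ("y_coord" %in% names(ph)) attr(out, "obs_y") <- ph$y_coord
  out
}

#' @export
print.lgm_model <- function(x, ...) {
  cat(sprintf(
    "<lgm_model> %s spatial, %s genetic: %d obs, %d latent, %d hyperparameters\n",
    x$spec$spatial, x$spec$genetic, x$n_obs, x$n_latent, length(x$hypers)
  ))
  invisible(x)
}

#' Hyperparameter names of an assembled model
#' @param model An `lgm_model`.
#' @return Character vector of hyperparameter names.
#' @export
hyper_names <- function(model) names(model$hypers)
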