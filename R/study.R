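#' Simulation-study configuration
#'
#' Describes the full grid of the breeding-programme simulation study:
#' proportions of spatially structured environmental variance, spatial-field
#' generator, marker usage, and the analysis models compared. Defaults mirror
#' the headline study (two 50 x 20-plot locations, 1000 PYT lines, 500
#' marker components, 1000 prediction lines); `desk_study_config()` is a
#' proportionally scaled-down version for interactive use and testing.
#'
#' @param n_reps Number of independent programme realizations.
#' @param prop_spatial Proportions of environmental variance that are
#'   spatially structured.
#' @param generator `"matern"` or `"ar1xar1"` spatial-field generator.
#' @param markers Logical vector: fit without and/or with genome-wide
#'   markers.
#' @param models Spatial analysis models to compare.
#' @param programme A [programme_config()].
#' @param n_rows,n_cols Plot lattice dimensions per location.
#' @param p_star Marker components kept for the marker models.
#' @param n_pred Genotyped, unphenotyped doubled haploids scored for
#'   out-of-sample prediction.
#' @param n_top,n_rank Top-capture parameters (true best `n_top` found in
#'   estimated best `n_rank`).
#' @param strategy,fit_control Passed to [fit_lgm()].
#' @return List of class `study_config`.
#' @export
study_config <- function(n_reps = 10,
                         prop_spatial = c(0, 0.5, 0.75),
                         generator = c("matern", "ar1xar1"),
                         markers = c(FALSE, TRUE),
                         models = c("nospatial", "rowcol", "ar1xar1", "matern"),
                         programme = programme_config(),
                         n_rows = 50, n_cols = 20,
                         p_star = 500, n_pred = 1000,
                         n_top = 10, n_rank = 100,
                         strategy = "eb",
                         fit_control = list(reltol = 1e-6, hyper_sd = FALSE)) {
  generator <- match.arg(generator)
  stopifnot(n_rows * n_cols == programme$n_pyt)
  structure(
    list(
      n_reps = n_reps, prop_spatial = prop_spatial, generator = generator,
      markers = markers, models = models, programme = programme,
      n_rows = n_rows, n_cols = n_cols, p_star = p_star, n_pred = n_pred,
      n_top = n_top, n_rank = n_rank, strategy = strategy,
      fit_control = fit_control
    ),
    class = "study_config"
  )
}

#' @rdname study_config
#' @param ... Overrides passed on to [study_config()].
#' @export
desk_study_config <- function(...) {
  defaults <- list(
    programme = programme_config(
      n_founders = 50, n_crosses = 20, n_dh_per_cross = 25,
      n_pyt = 200, n_advanced = 50, n_parents = 25, burnin_years = 10
    ),
    n_rows = 20, n_cols = 10, p_star = 100, n_pred = 200,
    n_top = 10, n_rank = 20
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(study_config, args)
}

#' Run the breeding-programme simulation study
#'
#' For each replicate: run the breeding programme, simulate preliminary-
#' yield-trial phenotypes at two locations for each spatial proportion, fit
#' every model x marker combination jointly over the two locations (fixed
#' location effect, spatial hyperparameters shared across locations), and
#' score correlation, CRPS and top-capture against true breeding values for
#' the phenotyped PYT lines and - with markers - for a held-out set of
#' genotyped, unphenotyped doubled haploids.
#'
#' @param config A [study_config()].
#' @param seed Integer study seed; every replicate and stage is seeded
#'   deterministically from it.
#' @param verbose Print per-replicate progress.
#' @return Object of class `sim_study`: `results` (long per-replicate
#'   tibble), `summary` (mean/SE per cell), `realized_h2` and the manifest.
#' @export
run_simulation_study <- function(config = desk_study_config(), seed = 1,
                                 verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  seed <- as.integer(seed)
  if (any(config$markers) && config$p_star < 1) {
    stop("marker models requested with no components", call. = FALSE)
  }
  layouts <- list(
    lattice_layout(config$n_rows, config$n_cols, trial_id = "loc1"),
    lattice_layout(config$n_rows, config$n_cols, trial_id = "loc2")
  )
  warm <- new.env(parent = emptyenv())
  rows <- list()
  h2s <- numeric(config$n_reps)
  for (r in seq_len(config$n_reps)) {
    prog <- run_programme(config$programme, seed = seed + 7919L * r)
    h2s[r] <- prog$h2_realized
    gen <- NULL
    pool_idx <- NULL
    if (any(config$markers)) {
      pool_idx <- withr::with_seed(
        seed + 7919L * r + 1L,
        sample.int(n_ind(prog$dh_pool), min(config$n_pred, n_ind(prog$dh_pool)))
      )
      Z_all <- rbind(
        dosage(prog$pyt, "snp"),
        dosage(subset_population(prog$dh_pool, pool_idx), "snp")
      )
      rownames(Z_all) <- c(prog$pyt$ids, prog$dh_pool$ids[pool_idx])
      poly <- colMeans(Z_all) / 2
      keep <- poly > 0 & poly < 1
      gen <- genomic_data(Z_all[, keep, drop = FALSE],
        p_star = min(config$p_star, sum(keep), nrow(Z_all) - 1)
      )
    }
    for (prop in config$prop_spatial) {
      vc <- variance_config(prop_spatial = prop, generator = config$generator)
      ph <- simulate_trial_phenotypes(
        prog, layouts, vc, prog$sigma2_e_pyt,
        seed = seed + 7919L * r + round(1000 * prop) + 3L
      )
      ph <- standardize_phenotypes(ph, "year")
      s <- ph$std_scale[1]
      bv_pyt <- tibble::tibble(line_id = prog$pyt$ids, bv = prog$pyt_bv)
      for (use_markers in config$markers) {
        for (mod in config$models) {
          spec <- model_spec(
            spatial = mod,
            genetic = if (use_markers) "markers" else "iid",
            covariates = "trial_id"
          )
          model <- assemble_model(spec, ph, genomics = gen)
          key <- paste(mod, use_markers, prop, sep = "|")
          ctrl <- config$fit_control
          if (!is.null(warm[[key]])) ctrl$init <- warm[[key]]
          fit <- fit_lgm(model, strategy = config$strategy, control = ctrl)
          warm[[key]] <- fit$theta_natural
          eff <- line_effects(fit)
          eff <- eff[match(bv_pyt$line_id, eff$line_id), ]
          if (use_markers) {
            ctr <- mean(c(prog$pyt_bv, prog$dh_pool_bv[pool_idx]))
          } else {
            ctr <- mean(prog$pyt_bv)
          }
          t_pyt <- (bv_pyt$bv - ctr) / s
          res <- tibble::tibble(
            rep = r, prop_spatial = prop, generator = config$generator,
            markers = use_markers, model = mod,
            cor_pyt = bv_correlation(t_pyt, eff$mean),
            crps_pyt = mean(crps_gaussian(eff$mean, eff$sd, t_pyt)),
            top_pyt = top_capture(t_pyt, eff$mean, config$n_top, config$n_rank),
            cor_pred = NA_real_, crps_pred = NA_real_, top_pred = NA_real_,
            sigma2_e_hat = fit$theta_natural$sigma2_e,
            logpost = fit$logpost_mode
          )
          if (use_markers) {
            Zs_new <- gen$Zstar[
              match(prog$dh_pool$ids[pool_idx], gen$line_ids), ,
              drop = FALSE
            ]
            pr <- predict_lines(fit, Zs_new)
            t_pool <- (prog$dh_pool_bv[pool_idx] - ctr) / s
            res$cor_pred <- bv_correlation(t_pool, pr$mean)
            res$crps_pred <- mean(crps_gaussian(pr$mean, pr$sd, t_pool))
            res$top_pred <- top_capture(
              t_pool, pr$mean, config$n_top, config$n_rank
            )
          }
          rows[[length(rows) + 1]] <- res
        }
      }
    }
    if (verbose) message(sprintf("replicate %d/%d done", r, config$n_reps))
  }
  results <- dplyr::bind_rows(rows)
  structure(
    list(
      results = results,
      summary = if (config$n_reps >= 2) {
        summarize_study(results,
          metrics = c(
            "cor_pyt", "crps_pyt", "top_pyt",
            "cor_pred", "crps_pred", "top_pred"
          ),
          groups = c("prop_spatial", "generator", "markers", "model")
        )
      },
      realized_h2 = h2s,
      manifest = run_manifest(seed, config)
    ),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study> %d replicates, generator %s (realized plot h2 %.3f)\n",
    max(x$results$rep), x$results$generator[1], mean(x$realized_h2)
  ))
  if (!is.null(x$summary)) print(x$summary, n = Inf)
  invisible(x)
}

#' Run the Nelder wheel spacing-trial experiment
#'
#' Simulates tree phenotypes on a Nelder wheel (intercept + density effect +
#' Matern spatial field + residual) and fits the Matern model and the
#' NoSpatial model. Posterior summaries of the five parameters (intercept,
#' density effect, spatial variance, range, residual variance) are returned
#' with 95% intervals.
#'
#' @param seed Integer seed.
#' @param truth Named list of true values: `intercept`, `beta_density`,
#'   `sigma2_s`, `range`, `sigma2_e`.
#' @param design Arguments for [nelder_layout()].
#' @param strategy Integration strategy for the Matern fit.
#' @return List of class `nelder_run`: `params` tibble (parameter, truth,
#'   posterior mean/mode, 95% interval, model), the two fits, the layout and
#'   the simulated field.
#' @export
run_nelder <- function(seed = 1,
                       truth = list(
                         intercept = 10, beta_density = 10,
                         sigma2_s = 0.5, range = 10, sigma2_e = 0.5
                       ),
                       design = list(), strategy = "grid") {
  lay <- do.call(nelder_layout, design)
  coords <- as.matrix(lay[, c("x_coord", "y_coord")])
  sim <- withr::with_seed(as.integer(seed), {
    x <- as.numeric(sample_field(
      matern_cov(coords, sigma2 = truth$sigma2_s, range = truth$range), 1
    ))
    e <- stats::rnorm(nrow(lay), 0, sqrt(truth$sigma2_e))
    list(x = x, e = e)
  })
  ph <- tibble::tibble(
    trial_id = "wheel",
    row = lay$ring, col = lay$spoke,
    x_coord = lay$x_coord, y_coord = lay$y_coord,
    density = lay$density,
    phenotype = truth$intercept + truth$beta_density * lay$density +
      sim$x + sim$e
  )
  fits <- list(
    matern = fit_lgm(
      assemble_model(
        model_spec(spatial = "matern", genetic = "none", covariates = "density"),
        ph
      ),
      strategy = strategy
    ),
    nospatial = fit_lgm(
      assemble_model(
        model_spec(spatial = "nospatial", genetic = "none", covariates = "density"),
        ph
      ),
      strategy = "eb"
    )
  )
  params <- dplyr::bind_rows(lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    fx <- fit$latent[fit$latent$block == "fixed", ]
    out <- tibble::tibble(
      model = nm,
      parameter = c("intercept", "beta_density"),
      truth = c(truth$intercept, truth$beta_density),
      estimate = fx$mean,
      lower = fx$mean - 1.96 * fx$sd,
      upper = fx$mean + 1.96 * fx$sd
    )
    hy <- fit$hyper
    se <- hy[hy$name == "sigma2_e", ]
    out <- dplyr::bind_rows(out, tibble::tibble(
      model = nm, parameter = "sigma2_e", truth = truth$sigma2_e,
      estimate = se$mode, lower = se$lower, upper = se$upper
    ))
    if (nm == "matern") {
      ik <- match("kappa_g1", hy$name)
      it <- match("tau_g1", hy$name)
      covt <- tryCatch(solve(fit$hessian), error = function(e) NULL)
      lk <- fit$theta_mode[["kappa_g1"]]
      lt <- fit$theta_mode[["tau_g1"]]
      sd_lk <- hy$sd_t[ik]
      # log sigma2_s = log Gamma-terms - 2 nu log kappa - 2 log tau
      g <- c(-2, -2) # nu = 1
      sd_ls <- if (!is.null(covt)) {
        sqrt(max(t(g) %*% covt[c(ik, it), c(ik, it)] %*% g, 0))
      } else {
        NA_real_
      }
      ls_mode <- log(sigma2_from_spde(exp(lk), exp(lt)))
      lr_mode <- log(range_from_kappa(exp(lk)))
      out <- dplyr::bind_rows(out, tibble::tibble(
        model = nm,
        parameter = c("sigma2_s", "range"),
        truth = c(truth$sigma2_s, truth$range),
        estimate = exp(c(ls_mode, lr_mode)),
        lower = exp(c(ls_mode - 1.96 * sd_ls, lr_mode - 1.96 * sd_lk)),
        upper = exp(c(ls_mode + 1.96 * sd_ls, lr_mode + 1.96 * sd_lk))
      ))
    }
    out
  }))
  structure(
    list(
      params = params, fits = fits, layout = lay,
      true_field = sim$x, phenotypes = ph,
      manifest = run_manifest(seed, list(truth = truth, design = design))
    ),
    class = "nelder_run"
  )
}

#' Posterior spatial-field surface for a Nelder wheel fit
#'
#' Conditions the Matern field on the fitted latent posterior to produce the
#' posterior mean and standard deviation of the spatial effect on a regular
#' prediction grid (kriging through the fitted covariance at the
#' hyperparameter mode).
#'
#' @param run A [run_nelder()] result.
#' @param n_grid Grid resolution per axis.
#' @return Tibble with `x_coord`, `y_coord`, `mean`, `sd`.
#' @export
nelder_field_surface <- function(run, n_grid = 25) {
  fit <- run$fits$matern
  model <- fit$model
  th <- fit$theta_natural
  kappa <- th$kappa_g1
  tau <- th$tau_g1
  s2 <- sigma2_from_spde(kappa, tau)
  rng <- range_from_kappa(kappa)
  obs <- as.matrix(unique(run$layout[, c("x_coord", "y_coord")]))
  ext <- max(abs(obs)) * 1.05
  gx <- seq(-ext, ext, length.out = n_grid)
  grid <- as.matrix(expand.grid(x_coord = gx, y_coord = gx))
  lp <- latent_posterior(model, fit$theta_natural)
  sp <- lp$block == paste0("spatial_", model$trials[1])
  mu_x <- lp$mean[sp]
  cov_all <- attr(lp, "cov")
  cov_x <- cov_all[sp, sp, drop = FALSE]
  Coo <- matern_cov(obs, sigma2 = s2, range = rng)
  D_go <- sqrt(outer(grid[, 1], obs[, 1], "-")^2 +
    outer(grid[, 2], obs[, 2], "-")^2)
  Cgo <- s2 * matern_corr(D_go, range = rng)
  W <- Cgo %*% chol2inv(chol(Coo + diag(1e-10, nrow(Coo))))
  mean_g <- as.numeric(W %*% mu_x)
  # prior conditional variance + propagated posterior uncertainty of x_obs
  var_g <- s2 - rowSums(W * Cgo) + rowSums((W %*% cov_x) * W)
  tibble::tibble(
    x_coord = grid[, 1], y_coord = grid[, 2],
    mean = mean_g, sd = sqrt(pmax(var_g, 0))
  )
}

#' Run the multi-trial analysis on synthetic shared-variance data
#'
#' Generates four field trials (two replicates of each line per trial) whose
#' spatial fields come in two groups with distinct Matern hyperparameters,
#' then fits single-trial models (per-trial standardization) and the joint
#' multi-trial model with trial-specific intercepts and two grouped spatial
#' hyperparameter sets. With `markers = TRUE`, principal-component marker
#' effects are added alongside the iid line effects.
#'
#' @param seed Integer seed.
#' @param n_rows,n_cols Plot lattice per trial (each trial holds
#'   `n_rows * n_cols / 2` lines twice).
#' @param markers Include marker effects (adds the `sigma2_u`
#'   hyperparameter and records `p_star`).
#' @param sigma2_g,sigma2_e Genetic and residual variances.
#' @param spatial_groups List of two groups of trial ids with `sigma2_s` and
#'   `range` elements for the generating fields.
#' @return List of class `multitrial_run`: `joint` fit, `single` fits,
#'   `n_spatial_sets`, `genetic_sd` comparison tibble, manifest.
#' @export
run_multitrial <- function(seed = 1, n_rows = 20, n_cols = 10,
                           markers = FALSE,
                           sigma2_g = 0.3, sigma2_e = 0.3,
                           spatial_groups = list(
                             y2011 = list(
                               trials = c("t1", "t2"), sigma2_s = 0.4, range = 10
                             ),
                             y2012 = list(
                               trials = c("t3", "t4"), sigma2_s = 0.15, range = 4
                             )
                           )) {
  n_plots <- n_rows * n_cols
  if (n_plots %% 2 != 0) stop("plot count per trial must be even", call. = FALSE)
  m <- n_plots / 2
  dat <- withr::with_seed(as.integer(seed), {
    genome <- sim_genome(n_chr = 10, n_snp = 50, n_qtl = 20)
    founders <- make_founders(genome, 20)
    pop <- cross_and_dh(founders, n_crosses = 20, n_dh_per_cross = ceiling(m / 20))
    pop <- subset_population(pop, seq_len(m))
    arch <- trait_architecture(genome, pop, target_var = sigma2_g)
    bv <- true_breeding_values(pop, arch)
    phs <- list()
    for (g in spatial_groups) {
      for (tr in g$trials) {
        lay <- lattice_layout(n_rows, n_cols, trial_id = tr)
        x <- as.numeric(sample_field(
          matern_cov(lay[, c("x_coord", "y_coord")],
            sigma2 = g$sigma2_s, range = g$range
          ), 1
        ))
        # alpha-lattice-like replicate structure: each line once per half
        assign1 <- sample.int(m)
        assign2 <- m + sample.int(m)
        line_of_plot <- integer(n_plots)
        first_half <- lay$row <= n_rows / 2
        line_of_plot[first_half] <- assign1[seq_len(sum(first_half))]
        line_of_plot[!first_half] <- assign2[seq_len(sum(!first_half))] - m
        phs[[tr]] <- tibble::tibble(
          trial_id = tr, year = 1L,
          row = lay$row, col = lay$col,
          x_coord = lay$x_coord, y_coord = lay$y_coord,
          line_id = pop$ids[line_of_plot], bv = bv[line_of_plot],
          spatial = x, noise = stats::rnorm(n_plots, 0, sqrt(sigma2_e)),
          phenotype = 0
        )
        phs[[tr]]$phenotype <- stats::rnorm(1, 0, 0.5) + phs[[tr]]$bv +
          phs[[tr]]$spatial + phs[[tr]]$noise
      }
    }
    list(ph = dplyr::bind_rows(phs), pop = pop, bv = bv)
  })
  gen <- NULL
  p_star <- NA_integer_
  if (markers) {
    Z <- dosage(dat$pop, "snp")
    rownames(Z) <- dat$pop$ids
    poly <- colMeans(Z) / 2
    gen <- genomic_data(Z[, poly > 0 & poly < 1, drop = FALSE],
      var_explained = 0.95
    )
    p_star <- gen$p_star
  }
  genetic <- if (markers) "markers_iid" else "iid"
  groups <- lapply(spatial_groups, function(g) g$trials)
  joint <- fit_lgm(
    assemble_model(
      model_spec(
        spatial = "matern", genetic = genetic,
        per_trial_intercept = TRUE, spatial_groups = groups
      ),
      standardize_phenotypes(dat$ph, "all"),
      genomics = gen
    ),
    strategy = "eb"
  )
  single <- lapply(split(dat$ph, dat$ph$trial_id), function(sub) {
    fit_lgm(
      assemble_model(
        model_spec(spatial = "matern", genetic = genetic),
        standardize_phenotypes(sub, "trial"),
        genomics = gen
      ),
      strategy = "eb"
    )
  })
  gsd <- dplyr::bind_rows(
    tibble::tibble(
      fit = "joint", trial = "all",
      sd_sigma2_n = joint$hyper$sd[joint$hyper$name == "sigma2_n"]
    ),
    dplyr::bind_rows(lapply(names(single), function(tr) {
      tibble::tibble(
        fit = "single", trial = tr,
        sd_sigma2_n = single[[tr]]$hyper$sd[single[[tr]]$hyper$name == "sigma2_n"]
      )
    }))
  )
  structure(
    list(
      joint = joint, single = single,
      n_spatial_sets = sum(grepl("^kappa_", joint$hyper$name)),
      genetic_sd = gsd, p_star = p_star, data = dat$ph,
      manifest = run_manifest(seed, list(
        n_rows = n_rows, n_cols = n_cols,
        markers = markers, groups = groups
      ))
    ),
    class = "multitrial_run"
  )
}

#' Compact run manifest
#'
#' @param seed The seed used.
#' @param config The configuration object (hashed).
#' @return Tibble with seed, configuration hash and package version.
#' @export
run_manifest <- function(seed, config) {
  tibble::tibble(
    seed = as.integer(seed),
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("spatfield"))
  )
}
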