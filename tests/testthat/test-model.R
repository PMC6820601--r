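test_that("hyperparameter sets enumerate as the model structure dictates", {
  ph <- toy_phenotypes()
  m1 <- assemble_model(model_spec("nospatial", "iid"), ph)
  expect_setequal(hyper_names(m1), c("sigma2_e", "sigma2_n"))
  m2 <- assemble_model(model_spec("rowcol", "iid"), ph)
  expect_setequal(
    hyper_names(m2),
    c("sigma2_e", "sigma2_n", "sigma2_r_g1", "sigma2_c_g1")
  )
  m3 <- assemble_model(model_spec("matern", "none"), ph)
  expect_setequal(hyper_names(m3), c("sigma2_e", "kappa_g1", "tau_g1"))
})

test_that("multi-trial grouping: 4 trials in 2 groups with markers + iid gives 9 hyperparameters", {
  ph <- dplyr::bind_rows(lapply(sprintf("t%d", 1:4), function(tr) {
    toy_phenotypes(trial_id = tr, seed = match(tr, sprintf("t%d", 1:4)))
  }))
  gen <- toy_genomics(m = 15)
  spec <- model_spec("ar1xar1", "markers_iid",
    per_trial_intercept = TRUE,
    spatial_groups = list(a = c("t1", "t2"), b = c("t3", "t4"))
  )
  m <- assemble_model(spec, ph, gen)
  expect_equal(length(hyper_names(m)), 9)
  expect_setequal(
    hyper_names(m),
    c(
      "sigma2_e", "sigma2_n", "sigma2_u",
      "rho_r_a", "rho_c_a", "sigma2_x_a",
      "rho_r_b", "rho_c_b", "sigma2_x_b"
    )
  )
  # one latent spatial block per trial even when hyperparameters are shared
  expect_equal(sum(grepl("^spatial_", names(m$blocks))), 4)
  # trial-specific intercepts present
  expect_equal(sum(grepl("^intercept_", m$blocks$fixed$labels)), 4)
  expect_error(
    assemble_model(
      model_spec("matern", "iid", spatial_groups = list(a = c("t1", "nope"))),
      ph
    ),
    "partition"
  )
})

test_that("two locations share one spatial hyperparameter set by default", {
  ph <- dplyr::bind_rows(
    toy_phenotypes(trial_id = "loc1", seed = 1),
    toy_phenotypes(trial_id = "loc2", seed = 2)
  )
  m <- assemble_model(
    model_spec("matern", "iid", covariates = "trial_id"), ph
  )
  expect_setequal(
    hyper_names(m),
    c("sigma2_e", "sigma2_n", "kappa_g1", "tau_g1")
  )
  expect_equal(sum(grepl("^spatial_", names(m$blocks))), 2)
  # fixed location effect included via the covariate dummy
  expect_true("trial_id_loc2" %in% m$blocks$fixed$labels)
})

test_that("marker models refuse lines that are absent from the genomic data", {
  ph <- toy_phenotypes()
  gen <- toy_genomics(m = 10) # fewer lines than phenotyped
  expect_error(
    assemble_model(model_spec("nospatial", "markers"), ph, gen),
    "absent"
  )
  expect_error(
    assemble_model(model_spec("nospatial", "markers"), ph, NULL),
    "genomic data required"
  )
})

test_that("hyperparameter count guard refuses more than 20", {
  ph <- dplyr::bind_rows(lapply(1:7, function(i) {
    toy_phenotypes(trial_id = sprintf("t%d", i), seed = i)
  }))
  groups <- as.list(sprintf("t%d", 1:7))
  names(groups) <- sprintf("g%d", 1:7)
  expect_error(
    assemble_model(
      model_spec("ar1xar1", "iid", spatial_groups = groups), ph
    ),
    "at most 20"
  )
  groups5 <- as.list(sprintf("t%d", 1:5))
  names(groups5) <- sprintf("g%d", 1:5)
  ph5 <- ph[ph$trial_id %in% sprintf("t%d", 1:5), ]
  expect_warning(
    assemble_model(
      model_spec("ar1xar1", "iid", spatial_groups = groups5), ph5
    ),
    "degrades above 10"
  )
})

test_that("relationship-matrix and marker-effect models are equivalent reparameterizations", {
  gen <- toy_genomics(m = 30, seed = 5, p_star = 29)
  ph <- toy_phenotypes(n_rows = 6, n_cols = 10, m = 30, seed = 6)
  mg <- assemble_model(model_spec("nospatial", "grm"), ph, gen)
  mm <- assemble_model(model_spec("nospatial", "markers"), ph, gen)
  s2a <- 0.7
  lg <- latent_posterior(mg, list(sigma2_e = 0.4, sigma2_a = s2a))
  lm_ <- latent_posterior(mm, list(sigma2_e = 0.4, sigma2_u = s2a / gen$k))
  a_grm <- lg$mean[lg$block == "line_grm"]
  a_mark <- as.numeric(
    mm$Zstar_lines %*% lm_$mean[lm_$block == "markers"]
  )
  expect_equal(a_grm, a_mark, tolerance = 1e-6)
})

test_that("assembly is pure: identical inputs give identical structure and posteriors", {
  ph <- toy_phenotypes()
  m1 <- assemble_model(model_spec("ar1xar1", "iid"), ph)
  m2 <- assemble_model(model_spec("ar1xar1", "iid"), ph)
  expect_identical(hyper_names(m1), hyper_names(m2))
  expect_identical(names(m1$blocks), names(m2$blocks))
  th <- list(
    sigma2_e = 0.3, sigma2_n = 0.8, rho_r_g1 = 0.5, rho_c_g1 = 0.4,
    sigma2_x_g1 = 0.2
  )
  expect_identical(latent_posterior(m1, th)$mean, latent_posterior(m2, th)$mean)
})

test_that("ar1xar1 and matern spatial blocks reproduce the standalone builders", {
  ph <- toy_phenotypes(n_rows = 4, n_cols = 3, m = 6, reps = 2)
  m <- assemble_model(model_spec("ar1xar1", "iid"), ph)
  th <- theta_defaults <- list(
    sigma2_e = 1, sigma2_n = 1, rho_r_g1 = 0.6, rho_c_g1 = 0.3,
    sigma2_x_g1 = 0.9
  )
  jp <- joint_precision(m, th)
  Qs <- jp$blocks$spatial_t1$Q
  expect_equal(
    as.matrix(Qs),
    as.matrix(ar1xar1_precision(4, 3, 0.6, 0.3, 0.9)),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  # matern spatial block is the inverse of the dense covariance
  mmat <- assemble_model(model_spec("matern", "iid"), ph)
  kappa <- 0.5
  tau <- 1.2
  thm <- list(
    sigma2_e = 1, sigma2_n = 1, kappa_g1 = kappa, tau_g1 = tau
  )
  jpm <- joint_precision(mmat, thm)
  lay <- unique(ph[, c("x_coord", "y_coord")])
  Cex <- matern_cov(lay,
    sigma2 = sigma2_from_spde(kappa, tau),
    range = range_from_kappa(kappa)
  )
  expect_equal(
    as.matrix(jpm$blocks$spatial_t1$Q %*% Cex), diag(nrow(lay)),
    tolerance = 1e-8, ignore_attr = TRUE
  )
})

test_that("the finite-element Matern backend fits and mirrors the dense model", {
  ph <- toy_phenotypes(n_rows = 8, n_cols = 5, m = 20, reps = 2, seed = 50)
  m_spde <- assemble_model(
    model_spec("matern_spde", "iid"), ph,
    mesh_args = list(extension = 6, spacing = 1.5)
  )
  expect_setequal(
    hyper_names(m_spde), c("sigma2_e", "sigma2_n", "kappa_g1", "tau_g1")
  )
  f_spde <- fit_lgm(m_spde, control = list(hyper_sd = FALSE))
  m_dense <- assemble_model(model_spec("matern", "iid"), ph)
  f_dense <- fit_lgm(m_dense, control = list(hyper_sd = FALSE))
  # the two backends agree on the line-effect posterior to field-trial
  # accuracy (the mesh discretization keeps them from exact equality)
  e1 <- line_effects(f_spde)
  e2 <- line_effects(f_dense)
  expect_gt(cor(e1$mean, e2$mean[match(e1$line_id, e2$line_id)]), 0.95)
})
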