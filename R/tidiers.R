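#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted latent Gaussian model
#'
#' @param x An [fit_lgm()] object.
#' @param effects `"hyper"` (default) for hyperparameter posterior summaries
#'   or `"latent"` for latent-effect summaries.
#' @param ... Unused.
#' @return A tibble: hyperparameters with `term`, `estimate` (posterior
#'   mode), `std.error`, `conf.low`, `conf.high`; or latent effects with
#'   `block`, `term`, `estimate`, `std.error`.
#' @method tidy lgm_fit
#' @export
tidy.lgm_fit <- function(x, effects = c("hyper", "latent"), ...) {
  effects <- match.arg(effects)
  if (effects == "hyper") {
    tibble::tibble(
      term = x$hyper$name, estimate = x$hyper$mode,
      std.error = x$hyper$sd,
      conf.low = x$hyper$lower, conf.high = x$hyper$upper
    )
  } else {
    tibble::tibble(
      block = x$latent$block, term = x$latent$label,
      estimate = x$latent$mean, std.error = x$latent$sd
    )
  }
}

#' Glance at a fitted latent Gaussian model
#'
#' @param x An [fit_lgm()] object.
#' @param ... Unused.
#' @return One-row tibble with observation and latent counts, hyperparameter
#'   count, log posterior at the mode, strategy and optimizer evaluations.
#' @method glance lgm_fit
#' @export
glance.lgm_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$model$n_obs, n_latent = x$model$n_latent,
    n_hyper = length(x$model$hypers),
    logpost = x$logpost_mode, strategy = x$strategy,
    fn_evals = as.integer(x$opt_counts[1])
  )
}

#' Plot the fitted spatial surface of a latent Gaussian model
#'
#' Tile map of the posterior mean spatial effect per trial (lattice models),
#' a diagnostic of where the model places spatially structured variation.
#'
#' @param object An [fit_lgm()] object with a spatial component.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lgm_fit
#' @export
autoplot.lgm_fit <- function(object, ...) {
  model <- object$model
  if (model$spec$spatial == "nospatial") {
    stop("fit has no spatial component to plot", call. = FALSE)
  }
  ph_idx <- seq_len(model$n_obs)
  # posterior mean spatial contribution per plot: sum over spatial blocks
  sp_blocks <- grep("^(spatial_|row_|col_)", names(model$blocks), value = TRUE)
  contrib <- rep(0, model$n_obs)
  for (bn in sp_blocks) {
    i <- match(bn, names(model$blocks))
    idx <- model$block_start[i]:model$block_end[i]
    mu <- object$latent$mean[idx]
    contrib <- contrib + as.numeric(model$blocks[[bn]]$A %*% mu)
  }
  df <- tibble::tibble(obs = ph_idx, spatial = contrib)
  df$trial_id <- model_trial_ids(model)
  df$x <- model_obs_coord(model, "x")
  df$y <- model_obs_coord(model, "y")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$spatial)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~trial_id) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(
      x = "column direction", y = "row direction",
      fill = "posterior mean\nspatial effect"
    ) +
    ggplot2::theme_minimal()
}

# observation metadata stored on assembly (kept small; reconstructed from A)
model_trial_ids <- function(model) {
  attr(model, "obs_trial") %||% rep(model$trials[1], model$n_obs)
}

model_obs_coord <- function(model, which) {
  attr(model, paste0("obs_", which)) %||% rep(NA_real_, model$n_obs)
}

#' Plot a simulation-study summary
#'
#' Dot-and-errorbar chart of mean scores (with +/- 1 SE) by spatial model,
#' spatial proportion and marker usage.
#'
#' @param object A `sim_study` from [run_simulation_study()].
#' @param metric Which metric to display (default `"cor_pyt"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_study
#' @export
autoplot.sim_study <- function(object, metric = "cor_pyt", ...) {
  s <- object$summary
  mcol <- paste0(metric, "_mean")
  ecol <- paste0(metric, "_se")
  if (!mcol %in% names(s)) stop("unknown metric: ", metric, call. = FALSE)
  s <- s[!is.na(s[[mcol]]), ]
  ggplot2::ggplot(s, ggplot2::aes(
    x = factor(.data$prop_spatial), y = .data[[mcol]],
    colour = .data$model, group = .data$model
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data[[mcol]] - .data[[ecol]],
        ymax = .data[[mcol]] + .data[[ecol]]
      ),
      width = 0.2, position = ggplot2::position_dodge(0.3)
    ) +
    ggplot2::facet_wrap(~markers, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "proportion of spatial variance", y = metric,
      colour = "spatial model"
    ) +
    ggplot2::theme_minimal()
}

#' Plot Nelder wheel posterior parameter intervals
#'
#' @param object A `nelder_run` from [run_nelder()].
#' @param ... Unused.
#' @return A ggplot object showing posterior estimates, 95% intervals and
#'   the true values.
#' @method autoplot nelder_run
#' @export
autoplot.nelder_run <- function(object, ...) {
  ggplot2::ggplot(object$params, ggplot2::aes(
    x = .data$model, y = .data$estimate, colour = .data$model
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.2
    ) +
    ggplot2::geom_hline(
      ggplot2::aes(yintercept = .data$truth),
      linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "posterior estimate (95% interval)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom rlang .data
NULL
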