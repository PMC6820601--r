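#' Breeding-programme configuration
#'
#' Defaults mirror a wheat programme: 100 crosses of 50 inbred parents with
#' 100 doubled haploids per cross (10,000 headrows a year), the best 1000
#' entering a preliminary yield trial (PYT) grown once in each of two
#' locations, the best 100 advancing and the best 50 used as parents of the
#' next cycle. Plot heritability is 0.25 in the PYT and 0.1 in headrows.
#'
#' `h2_anchor` fixes when the residual variance is derived from the genetic
#' variance: `"initial"` sets it once from the first doubled-haploid cohort
#' (so selection erodes the effective heritability over cycles, as in
#' programme simulators that set the error variance at burn-in start);
#' `"current"` re-derives it each year from the realized variance of the PYT
#' entrants.
#'
#' @param n_founders,n_crosses,n_dh_per_cross Programme sizes.
#' @param n_pyt Lines selected from headrows into the PYT.
#' @param n_advanced,n_parents Lines advanced from the PYT; parents of the
#'   next cycle.
#' @param burnin_years Phenotypic-selection years before the recorded year.
#' @param h2_headrow,h2_pyt Plot-level heritabilities at each stage.
#' @param h2_anchor `"initial"` or `"current"` (see Details).
#' @param genome A [sim_genome()]; default is the reduced 21 x (100 SNP +
#'   100 QTL) genome.
#' @return A list of class `programme_config`.
#' @export
programme_config <- function(n_founders = 50, n_crosses = 100,
                             n_dh_per_cross = 100, n_pyt = 1000,
                             n_advanced = 100, n_parents = 50,
                             burnin_years = 19, h2_headrow = 0.1,
                             h2_pyt = 0.25, h2_anchor = c("initial", "current"),
                             genome = sim_genome()) {
  h2_anchor <- match.arg(h2_anchor)
  stopifnot(
    h2_pyt > 0, h2_pyt < 1, h2_headrow > 0, h2_headrow < 1,
    n_pyt <= n_crosses * n_dh_per_cross, n_advanced <= n_pyt,
    n_parents <= n_advanced || n_parents <= n_pyt
  )
  structure(
    list(
      n_founders = n_founders, n_crosses = n_crosses,
      n_dh_per_cross = n_dh_per_cross, n_pyt = n_pyt,
      n_advanced = n_advanced, n_parents = n_parents,
      burnin_years = burnin_years, h2_headrow = h2_headrow,
      h2_pyt = h2_pyt, h2_anchor = h2_anchor, genome = genome
    ),
    class = "programme_config"
  )
}

#' Run the breeding programme to the recorded year
#'
#' Simulates `burnin_years` cycles of phenotypic selection (headrows ->
#' PYT -> advanced -> parents) and one further cycle whose PYT entrants and
#' non-selected doubled haploids are returned for analysis. Selection sizes
#' exceeding candidate counts raise an error.
#'
#' @param config A [programme_config()].
#' @param seed Integer seed; the run is fully reproducible.
#' @return A list of class `programme_state`: `pyt` (PYT `population`),
#'   `pyt_bv` (true breeding values), `dh_pool` (the year's non-PYT doubled
#'   haploids with `dh_pool_bv`), the trait `arch`, realized variances
#'   (`sigma2_g0` initial, `sigma2_g_pyt` current PYT, `sigma2_e_pyt`
#'   residual), effective plot heritability `h2_realized`, and the per-cycle
#'   mean true breeding value of PYT entrants (`bv_trajectory`).
#' @export
run_programme <- function(config, seed = 1L) {
  stopifnot(inherits(config, "programme_config"))
  withr::with_seed(as.integer(seed), run_programme_impl(config))
}

run_programme_impl <- function(config) {
  g <- config$genome
  founders <- make_founders(g, config$n_founders)
  parents <- founders
  arch <- NULL
  sigma2_e_head <- sigma2_e_pyt <- NULL
  sigma2_g0 <- NA_real_
  traj <- numeric(0)
  n_dh <- config$n_crosses * config$n_dh_per_cross
  if (config$n_pyt > n_dh) stop("selection size exceeds candidate count", call. = FALSE)

  for (year in seq_len(config$burnin_years + 1L)) {
    dh <- cross_and_dh(parents, config$n_crosses, config$n_dh_per_cross)
    if (is.null(arch)) {
      # anchor the trait scale on the very first doubled-haploid cohort
      arch <- trait_architecture(g, dh, target_var = 1)
      sigma2_g0 <- 1
      sigma2_e_head <- sigma2_g0 * (1 - config$h2_headrow) / config$h2_headrow
      sigma2_e_pyt <- sigma2_g0 * (1 - config$h2_pyt) / config$h2_pyt
    }
    bv <- true_breeding_values(dh, arch)
    if (config$h2_anchor == "current") {
      v <- stats::var(bv)
      sigma2_e_head <- v * (1 - config$h2_headrow) / config$h2_headrow
      sigma2_e_pyt <- v * (1 - config$h2_pyt) / config$h2_pyt
    }
    # headrow stage: single unreplicated plot per line
    y_head <- bv + stats::rnorm(n_dh, 0, sqrt(sigma2_e_head))
    sel <- order(y_head, decreasing = TRUE)[seq_len(config$n_pyt)]
    pyt <- subset_population(dh, sel)
    pyt_bv <- bv[sel]
    traj <- c(traj, mean(pyt_bv))
    # PYT: one plot in each of two locations; selection on the line mean
    y_pyt <- pyt_bv + stats::rnorm(config$n_pyt, 0, sqrt(sigma2_e_pyt / 2))
    adv <- order(y_pyt, decreasing = TRUE)[seq_len(config$n_advanced)]
    par_idx <- adv[seq_len(min(config$n_parents, length(adv)))]
    if (year <= config$burnin_years) {
      parents <- subset_population(pyt, par_idx)
    } else {
      pool_idx <- setdiff(seq_len(n_dh), sel)
      out <- list(
        pyt = pyt, pyt_bv = pyt_bv,
        dh_pool = subset_population(dh, pool_idx),
        dh_pool_bv = bv[pool_idx],
        arch = arch, sigma2_g0 = sigma2_g0,
        sigma2_g_pyt = stats::var(pyt_bv),
        sigma2_e_pyt = sigma2_e_pyt,
        h2_realized = stats::var(pyt_bv) / (stats::var(pyt_bv) + sigma2_e_pyt),
        bv_trajectory = traj, year = year
      )
      class(out) <- "programme_state"
      return(out)
    }
  }
}

#' @export
print.programme_state <- function(x, ...) {
  cat(sprintf(
    "<programme_state> year %d: %d PYT lines (realized plot h2 %.3f), %d pool DH\n",
    x$year, n_ind(x$pyt), x$h2_realized, n_ind(x$dh_pool)
  ))
  invisible(x)
}

#' Trial variance configuration
#'
#' Governs the phenotype simulation of the preliminary yield trial. The total
#' environmental (plot) variance `sigma2_e` is split into a spatially
#' structured share `prop_spatial` and independent plot noise; year and
#' location effects each have variance equal to `sigma2_e`.
#'
#' @param prop_spatial Proportion of environmental variance that is spatially
#'   structured (0, 0.5 or 0.75 in the study grid); must be in [0, 1).
#' @param generator `"matern"` (range `range`) or `"ar1xar1"`
#'   (autocorrelation `rho` in both directions).
#' @param range Matern range in row-spacing units.
#' @param rho AR1 autocorrelation (row and column).
#' @return A list of class `variance_config`.
#' @export
variance_config <- function(prop_spatial = 0,
                            generator = c("matern", "ar1xar1"),
                            range = 10, rho = 0.8) {
  generator <- match.arg(generator)
  stopifnot(prop_spatial >= 0, prop_spatial < 1, range > 0, rho > -1, rho < 1)
  structure(
    list(
      prop_spatial = prop_spatial, generator = generator,
      range = range, rho = rho
    ),
    class = "variance_config"
  )
}

#' Simulate preliminary-yield-trial phenotypes on field layouts
#'
#' Each line is planted once per location, plots randomly assigned. The
#' phenotype is the sum of year, location, genetic, spatially dependent plot
#' and independent plot residual effects:
#' \eqn{y = year + loc_k + BV_j + x(s_i) + e_i}. Spatial fields are drawn
#' independently per location from the configured generator with marginal
#' variance `prop_spatial * sigma2_e`; the independent residual has variance
#' `(1 - prop_spatial) * sigma2_e`.
#'
#' @param lines Tibble with `line_id` and `bv` (true breeding values), or a
#'   `programme_state` (its PYT is used).
#' @param layouts Layout tibble(s) as from [lattice_layout()]; a list gets
#'   row-bound. Total plots per trial must equal the number of lines.
#' @param var_config A [variance_config()].
#' @param sigma2_e Total environmental plot variance.
#' @param seed Optional integer seed.
#' @return Tibble with one row per plot: `trial_id`, `year`, `row`, `col`,
#'   `x_coord`, `y_coord`, `line_id`, `bv`, `spatial`, `noise`, `phenotype`.
#' @export
simulate_trial_phenotypes <- function(lines, layouts, var_config, sigma2_e,
                                      seed = NULL) {
  stopifnot(inherits(var_config, "variance_config"), sigma2_e > 0)
  if (inherits(lines, "programme_state")) {
    lines <- tibble::tibble(line_id = lines$pyt$ids, bv = lines$pyt_bv)
  }
  if (is.list(layouts) && !is.data.frame(layouts)) {
    layouts <- dplyr::bind_rows(layouts)
  }
  build <- function() {
    trials <- split(layouts, layouts$trial_id)
    m <- nrow(lines)
    for (tr in trials) {
      if (nrow(tr) != m) {
        stop(sprintf(
          "layout '%s' has %d plots but there are %d lines",
          tr$trial_id[1], nrow(tr), m
        ), call. = FALSE)
      }
    }
    s2x <- var_config$prop_spatial * sigma2_e
    s2n <- (1 - var_config$prop_spatial) * sigma2_e
    year_eff <- stats::rnorm(1, 0, sqrt(sigma2_e))
    out <- purrr::map(trials, function(tr) {
      loc_eff <- stats::rnorm(1, 0, sqrt(sigma2_e))
      perm <- sample.int(m)
      if (s2x > 0) {
        x <- if (var_config$generator == "matern") {
          S <- matern_cov(tr[, c("x_coord", "y_coord")],
            sigma2 = s2x, range = var_config$range
          )
          as.numeric(sample_field(S, 1))
        } else {
          tr2 <- tr[order(tr$row, tr$col), ]
          xr <- ar1xar1_cov(max(tr$row), max(tr$col),
            rho_r = var_config$rho, rho_c = var_config$rho, sigma2 = s2x
          )
          xx <- as.numeric(sample_field(xr$prec, 1))
          xx[order(order(tr$row, tr$col))] # back to layout order
        }
      } else {
        x <- rep(0, m)
      }
      e <- stats::rnorm(m, 0, sqrt(s2n))
      tibble::tibble(
        trial_id = tr$trial_id, year = 1L,
        row = tr$row, col = tr$col,
        x_coord = tr$x_coord, y_coord = tr$y_coord,
        line_id = lines$line_id[perm], bv = lines$bv[perm],
        spatial = x, noise = e,
        phenotype = year_eff + loc_eff + lines$bv[perm] + x + e
      )
    })
    dplyr::bind_rows(out)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Standardize phenotypes within groups
#'
#' Centres and scales the `phenotype` column to zero mean and unit standard
#' deviation within each group: `"year"` pools locations within the same year
#' (the convention for the simulated trials), `"trial"` standardizes each
#' trial separately (single-trial analyses), `"all"` uses one global
#' mean/scale (multi-trial analyses).
#'
#' @param tbl Phenotype tibble with `phenotype` (and `year`/`trial_id`).
#' @param grouping `"year"`, `"trial"` or `"all"`.
#' @return The tibble with standardized `phenotype` plus the centring
#'   (`std_center`) and scaling (`std_scale`) used for each row.
#' @export
standardize_phenotypes <- function(tbl, grouping = c("year", "trial", "all")) {
  grouping <- match.arg(grouping)
  key <- switch(grouping,
    year = tbl$year,
    trial = tbl$trial_id,
    all = rep(1L, nrow(tbl))
  )
  groups <- split(seq_len(nrow(tbl)), key)
  ctr <- scl <- numeric(nrow(tbl))
  for (idx in groups) {
    if (length(idx) < 2) stop("standardization group with < 2 records", call. = FALSE)
    m <- mean(tbl$phenotype[idx])
    s <- stats::sd(tbl$phenotype[idx])
    if (s == 0) stop("constant phenotype in a standardization group", call. = FALSE)
    ctr[idx] <- m
    scl[idx] <- s
  }
  tbl$std_center <- ctr
  tbl$std_scale <- scl
  tbl$phenotype <- (tbl$phenotype - ctr) / scl
  tbl
}
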