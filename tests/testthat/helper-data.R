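# Small fixtures built in code.

# lattice phenotype table with m lines planted reps times each
toy_phenotypes <- function(n_rows = 6, n_cols = 5, m = 15, reps = 2,
                           trial_id = "t1", seed = 1, sd_g = 1, sd_e = 0.5) {
  withr::with_seed(seed, {
    lay <- lattice_layout(n_rows, n_cols, trial_id = trial_id)
    stopifnot(nrow(lay) == m * reps)
    ids <- sprintf("L%03d", seq_len(m))
    g <- stats::rnorm(m, 0, sd_g)
    assign <- as.vector(replicate(reps, sample.int(m)))
    tibble::tibble(
      trial_id = trial_id, year = 1L,
      row = lay$row, col = lay$col,
      x_coord = lay$x_coord, y_coord = lay$y_coord,
      line_id = ids[assign], g_true = g[assign],
      phenotype = 1.5 + g[assign] + stats::rnorm(m * reps, 0, sd_e)
    )
  })
}

# tiny genotyped population and its genomic data
toy_genomics <- function(m = 20, seed = 2, p_star = NULL, grm = TRUE) {
  withr::with_seed(seed, {
    g <- sim_genome(n_chr = 3, n_snp = 20, n_qtl = 10)
    pop <- cross_and_dh(make_founders(g, 8), n_crosses = m, n_dh_per_cross = 1)
    Z <- dosage(pop, "snp")
    rownames(Z) <- sprintf("L%03d", seq_len(m))
    q <- colMeans(Z) / 2
    Z <- Z[, q > 0 & q < 1, drop = FALSE]
    genomic_data(Z, p_star = p_star %||% (m - 1), grm = grm)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
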