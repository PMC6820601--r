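test_that("genome map: disjoint QTL/marker indices, increasing positions", {
  g <- sim_genome(n_chr = 3, n_snp = 10, n_qtl = 5)
  expect_equal(sum(g$loci$is_qtl), 15)
  expect_equal(nrow(g$loci), 45)
  for (ch in 1:3) {
    expect_true(all(diff(g$loci$pos[g$loci$chr == ch]) > 0))
  }
})

test_that("founders are fully inbred with the requested allele-frequency law", {
  g <- sim_genome(n_chr = 1, n_snp = 5, n_qtl = 5)
  f <- make_founders(g, 2, seed = 3)
  expect_equal(dim(f$hap1), c(2, 10))
  expect_identical(f$hap1, f$hap2)
  expect_true(all(dosage(f) %in% c(0L, 2L)))
  expect_equal(heterozygosity(f), c(0, 0))
  # point mass at q = 0.5: empirical frequency within 3 MC standard errors
  gbig <- sim_genome(n_chr = 1, n_snp = 10000, n_qtl = 0)
  fb <- make_founders(gbig, 10, maf = 0.5, seed = 7)
  qhat <- mean(dosage(fb)) / 2
  expect_lt(abs(qhat - 0.5), 3 * sqrt(0.25 / (10 * 10000)))
  expect_error(make_founders(g, 1), "2 founders")
})

test_that("founder/progeny dimensions match the programme description", {
  g <- sim_genome(n_chr = 21, n_snp = 4, n_qtl = 4) # scaled loci, full chr count
  f <- make_founders(g, 50, seed = 1)
  expect_equal(dim(dosage(f)), c(50, 21 * 8))
  d <- cross_and_dh(f, 4, 5, seed = 2)
  expect_equal(n_ind(d), 20)
})

test_that("doubled haploids have zero heterozygosity; identical parents give clones", {
  g <- sim_genome(n_chr = 2, n_snp = 20, n_qtl = 10)
  f <- make_founders(g, 6, seed = 5)
  d <- cross_and_dh(f, 10, 8, seed = 6)
  expect_equal(max(heterozygosity(d)), 0)
  expect_true(all(dosage(d) %in% c(0L, 2L)))
  # two identical parents: no segregating loci, progeny are clones of the parent
  twin <- subset_population(f, c(1, 1))
  dd <- cross_and_dh(twin, 1, 5, seed = 7)
  for (i in 1:5) expect_equal(dd$hap1[i, ], f$hap1[1, ])
})

test_that("breeding values are the dosage-effect cross product", {
  g <- sim_genome(n_chr = 1, n_snp = 2, n_qtl = 1)
  f <- make_founders(g, 4, seed = 9)
  arch <- trait_architecture(g, f, target_var = 1, seed = 1)
  zero <- arch
  zero$effects <- 0 * zero$effects
  expect_equal(true_breeding_values(f, zero), rep(0, 4))
  # 1 QTL, unit effect: BV equals QTL dosage
  unit <- arch
  unit$effects <- 1
  expect_equal(true_breeding_values(f, unit), as.numeric(dosage(f, "qtl")))
  # var(BV) equals the quadratic form with the dosage covariance (oracle)
  g2 <- sim_genome(n_chr = 2, n_snp = 5, n_qtl = 10)
  p2 <- cross_and_dh(make_founders(g2, 8, seed = 2), 6, 10, seed = 3)
  a2 <- trait_architecture(g2, p2, target_var = 2.3, seed = 4)
  bv <- true_breeding_values(p2, a2)
  Sg <- stats::cov(dosage(p2, "qtl"))
  expect_equal(stats::var(bv), as.numeric(t(a2$effects) %*% Sg %*% a2$effects),
    tolerance = 1e-10
  )
  expect_equal(stats::var(bv), 2.3, tolerance = 1e-10)
  # genome mismatch is an error
  expect_error(true_breeding_values(f, a2), "genome")
})

test_that("programme run: counts, heritability anchoring, selection response", {
  cfg <- programme_config(
    n_founders = 8, n_crosses = 6, n_dh_per_cross = 10,
    n_pyt = 20, n_advanced = 8, n_parents = 4, burnin_years = 4,
    genome = sim_genome(n_chr = 4, n_snp = 20, n_qtl = 20),
    h2_anchor = "current"
  )
  st <- run_programme(cfg, seed = 2)
  expect_equal(n_ind(st$pyt), 20)
  expect_equal(n_ind(st$dh_pool), 40)
  expect_equal(length(st$bv_trajectory), 5)
  # "current" anchor: cohort-level h2 equals the configured value exactly
  cohort_var <- stats::var(c(st$pyt_bv, st$dh_pool_bv))
  expect_equal(cohort_var / (cohort_var + st$sigma2_e_pyt), 0.25,
    tolerance = 1e-10
  )
  expect_error(
    run_programme(programme_config(
      n_crosses = 2, n_dh_per_cross = 2, n_pyt = 5,
      n_advanced = 2, n_parents = 2,
      genome = sim_genome(1, 5, 5)
    ), seed = 1),
    "selection size|n_pyt"
  )
})

test_that("selection on phenotype raises mean breeding value over cycles", {
  cfg <- programme_config(
    n_founders = 10, n_crosses = 8, n_dh_per_cross = 15,
    n_pyt = 30, n_advanced = 10, n_parents = 5, burnin_years = 5,
    genome = sim_genome(n_chr = 5, n_snp = 10, n_qtl = 20)
  )
  for (s in 1:5) {
    traj <- run_programme(cfg, seed = 100 + s)$bv_trajectory
    steps <- diff(traj)
    expect_lte(sum(steps <= 0), 1) # allow one non-monotone step
    expect_gt(traj[length(traj)], traj[1])
  }
})

test_that("selected sets have higher mean breeding value than candidates", {
  g <- sim_genome(2, 10, 10)
  p <- cross_and_dh(make_founders(g, 6, seed = 1), 10, 20, seed = 2)
  a <- trait_architecture(g, p, 1, seed = 3)
  bv <- true_breeding_values(p, a)
  sel <- order(bv, decreasing = TRUE)[1:40] # truncation on true BV
  expect_gt(mean(bv[sel]), mean(bv))
})
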