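#' Wheat-like genome map
#'
#' Defines a genome of `n_chr` chromosomes, each carrying `n_snp` neutral
#' marker loci and `n_qtl` trait loci, equally spaced on a genetic map of
#' `chr_length` Morgans per chromosome. QTL are interleaved evenly among the
#' markers so that marker and QTL indices are disjoint.
#'
#' @param n_chr Number of chromosomes.
#' @param n_snp,n_qtl Marker and QTL loci per chromosome.
#' @param chr_length Genetic length of each chromosome in Morgans.
#' @return Object of class `genome`: a locus table plus totals.
#' @export
#' @examples
#' sim_genome(n_chr = 2, n_snp = 10, n_qtl = 10)
sim_genome <- function(n_chr = 21, n_snp = 100, n_qtl = 100, chr_length = 1) {
  stopifnot(n_chr >= 1, n_snp >= 1, n_qtl >= 0, chr_length > 0)
  L <- n_snp + n_qtl
  l <- seq_len(L)
  # exactly n_qtl TRUE, spread evenly along the chromosome
  is_qtl <- (floor(l * n_qtl / L) - floor((l - 1) * n_qtl / L)) == 1
  loci <- tidyr::expand_grid(chr = seq_len(n_chr), within = l)
  loci$pos <- chr_length * (loci$within - 0.5) / L
  loci$is_qtl <- rep(is_qtl, n_chr)
  loci$locus <- seq_len(nrow(loci))
  structure(
    list(
      loci = tibble::as_tibble(loci), n_chr = n_chr, n_snp = n_snp,
      n_qtl = n_qtl, chr_length = chr_length, n_loci = nrow(loci)
    ),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf(
    "<genome> %d chromosomes x (%d SNP + %d QTL), %.2g Morgan each\n",
    x$n_chr, x$n_snp, x$n_qtl, x$chr_length
  ))
  invisible(x)
}

new_population <- function(hap1, hap2, genome, ids, generation = 0L) {
  structure(
    list(
      hap1 = hap1, hap2 = hap2, genome = genome,
      ids = ids, generation = generation
    ),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf(
    "<population> %d individuals, %d loci, generation %d\n",
    nrow(x$hap1), ncol(x$hap1), x$generation
  ))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `population`.
#' @return Integer count.
#' @export
n_ind <- function(pop) nrow(pop$hap1)

#' Allele dosage matrix of a population
#'
#' @param pop A `population`.
#' @param loci Optional locus subset (indices or `"qtl"` / `"snp"`).
#' @return Integer matrix (individuals x loci) with entries in 0/1/2.
#' @export
dosage <- function(pop, loci = NULL) {
  if (identical(loci, "qtl")) loci <- which(pop$genome$loci$is_qtl)
  if (identical(loci, "snp")) loci <- which(!pop$genome$loci$is_qtl)
  if (is.null(loci)) {
    pop$hap1 + pop$hap2
  } else {
    pop$hap1[, loci, drop = FALSE] + pop$hap2[, loci, drop = FALSE]
  }
}

#' Per-individual heterozygosity
#' @param pop A `population`.
#' @return Numeric vector: fraction of heterozygous loci per individual
#'   (exactly 0 for doubled haploids and inbred founders).
#' @export
heterozygosity <- function(pop) {
  rowMeans(pop$hap1 != pop$hap2)
}

#' Simulate fully inbred founder lines
#'
#' Each founder is homozygous at every locus; the alternative allele is
#' carried with a per-locus frequency drawn from Uniform(`maf[1]`, `maf[2]`)
#' (a degenerate interval gives a point mass). Keeping frequencies away from
#' 0 and 1 avoids monomorphic loci that would break genomic-relationship
#' scaling.
#'
#' @param genome A [sim_genome()] object.
#' @param n_founders Number of founder lines (>= 2).
#' @param maf Length-2 allele-frequency range (or a single value).
#' @param seed Optional integer seed.
#' @return A `population` of inbred founders.
#' @export
make_founders <- function(genome, n_founders, maf = c(0.1, 0.9), seed = NULL) {
  stopifnot(inherits(genome, "genome"))
  if (n_founders < 2) stop("need at least 2 founders to make crosses", call. = FALSE)
  if (length(maf) == 1) maf <- c(maf, maf)
  stopifnot(maf[1] >= 0, maf[2] <= 1, maf[1] <= maf[2])
  build <- function() {
    L <- genome$n_loci
    q <- stats::runif(L, maf[1], maf[2])
    hap <- matrix(
      stats::rbinom(n_founders * L, 1L, rep(q, each = n_founders)),
      nrow = n_founders, ncol = L
    )
    pop <- new_population(hap, hap, genome,
      ids = paste0("F", seq_len(n_founders)), generation = 0L
    )
    pop$founder_freq <- q
    pop
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Meiosis: one recombinant gamete per individual listed in `idx` (with
# repetition allowed). Haldane model: Poisson(chr_length) crossovers per
# chromosome, uniform positions, random start phase.
meiosis <- function(pop, idx) {
  genome <- pop$genome
  n_g <- length(idx)
  gam <- matrix(0L, n_g, genome$n_loci)
  loci <- genome$loci
  for (ch in seq_len(genome$n_chr)) {
    cols <- which(loci$chr == ch)
    pos <- loci$pos[cols]
    h1 <- pop$hap1[idx, cols, drop = FALSE]
    h2 <- pop$hap2[idx, cols, drop = FALSE]
    phase <- stats::rbinom(n_g, 1L, 0.5)
    k <- stats::rpois(n_g, genome$chr_length)
    # origin(l) = (phase + number of crossovers before pos_l) mod 2
    origin <- matrix(phase, n_g, length(cols))
    for (g in which(k > 0)) {
      xo <- sort(stats::runif(k[g], 0, genome$chr_length))
      origin[g, ] <- (phase[g] + findInterval(pos, xo)) %% 2L
    }
    gam[, cols] <- ifelse(origin == 0L, h1, h2)
  }
  gam
}

#' Cross parents and produce doubled-haploid progeny
#'
#' Each cross pairs two distinct parents; every doubled-haploid progeny is a
#' single recombinant gamete from the F1, duplicated into both haplotypes, so
#' progeny heterozygosity is exactly zero. Recombination follows a Haldane
#' model with on average one crossover per Morgan.
#'
#' @param parents A `population` of (inbred or outbred) parents.
#' @param n_crosses Number of crosses; parent pairs are drawn at random.
#' @param n_dh_per_cross Doubled-haploid progeny per cross.
#' @param seed Optional integer seed.
#' @return A `population` of `n_crosses * n_dh_per_cross` doubled haploids,
#'   with a `cross` attribute recording the parent pair of each progeny.
#' @export
cross_and_dh <- function(parents, n_crosses, n_dh_per_cross, seed = NULL) {
  stopifnot(inherits(parents, "population"))
  if (n_ind(parents) < 1) stop("empty parent set", call. = FALSE)
  stopifnot(n_crosses >= 1, n_dh_per_cross >= 1)
  build <- function() {
    np <- n_ind(parents)
    if (np >= 2) {
      pairs <- t(replicate(n_crosses, sample.int(np, 2)))
    } else {
      pairs <- cbind(rep(1L, n_crosses), rep(1L, n_crosses))
    }
    # gametes from each parent of the cross; for inbred parents these are
    # simply the parental haplotypes
    p1 <- rep(pairs[, 1], each = n_dh_per_cross)
    p2 <- rep(pairs[, 2], each = n_dh_per_cross)
    inbred <- identical(parents$hap1, parents$hap2) ||
      all(parents$hap1 == parents$hap2)
    if (inbred) {
      # a gamete from a fully inbred parent is its haplotype
      f1_h1 <- parents$hap1[p1, , drop = FALSE]
      f1_h2 <- parents$hap1[p2, , drop = FALSE]
    } else {
      f1_h1 <- meiosis(parents, p1)
      f1_h2 <- meiosis(parents, p2)
    }
    f1 <- new_population(f1_h1, f1_h2, parents$genome,
      ids = sprintf("tmp%d", seq_along(p1)),
      generation = parents$generation + 1L
    )
    gam <- meiosis(f1, seq_len(n_ind(f1)))
    dh <- new_population(gam, gam, parents$genome,
      ids = sprintf(
        "G%d_C%d_D%d", parents$generation + 1L,
        rep(seq_len(n_crosses), each = n_dh_per_cross),
        rep(seq_len(n_dh_per_cross), n_crosses)
      ),
      generation = parents$generation + 1L
    )
    dh$cross <- rep(seq_len(n_crosses), each = n_dh_per_cross)
    dh
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Subset a population
#' @param pop A `population`.
#' @param idx Individual indices to keep.
#' @return The subsetted `population`.
#' @export
subset_population <- function(pop, idx) {
  out <- pop
  out$hap1 <- pop$hap1[idx, , drop = FALSE]
  out$hap2 <- pop$hap2[idx, , drop = FALSE]
  out$ids <- pop$ids[idx]
  if (!is.null(pop$cross)) out$cross <- pop$cross[idx]
  out
}

#' Additive trait architecture
#'
#' Draws standard Gaussian allele-substitution effects for every QTL and
#' rescales them so that the realized breeding-value variance in `pop` equals
#' `target_var`. Only the variance scale matters for the Gaussian analysis
#' models, so the effect-size law is the simplest adequate choice.
#'
#' @param genome A [sim_genome()] object.
#' @param pop Reference `population` in which the variance is anchored.
#' @param target_var Realized genetic variance after rescaling.
#' @param seed Optional integer seed.
#' @return Object of class `trait_arch` with `effects` (one per QTL) and the
#'   realized `sigma2_g` in `pop`.
#' @export
trait_architecture <- function(genome, pop, target_var = 1, seed = NULL) {
  stopifnot(inherits(genome, "genome"), inherits(pop, "population"))
  if (genome$n_qtl * genome$n_chr == 0) stop("genome has no QTL", call. = FALSE)
  build <- function() {
    eff <- stats::rnorm(sum(genome$loci$is_qtl))
    bv <- as.numeric(dosage(pop, "qtl") %*% eff)
    v <- stats::var(bv)
    if (v <= 0) stop("no genetic variance segregating in reference population", call. = FALSE)
    eff <- eff * sqrt(target_var / v)
    structure(
      list(effects = eff, genome = genome, sigma2_g = target_var),
      class = "trait_arch"
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' True breeding values
#'
#' \eqn{BV_j = \sum_l d_{jl} \alpha_l} over QTL dosages and allele
#' substitution effects; deterministic given population and architecture.
#'
#' @param pop A `population`.
#' @param arch A [trait_architecture()] object on the same genome.
#' @return Numeric vector of breeding values, one per individual.
#' @export
true_breeding_values <- function(pop, arch) {
  stopifnot(inherits(pop, "population"), inherits(arch, "trait_arch"))
  if (!identical(
    dim(arch$genome$loci)[1], dim(pop$genome$loci)[1]
  ) || arch$genome$n_chr != pop$genome$n_chr) {
    stop("architecture and population use different genomes", call. = FALSE)
  }
  as.numeric(dosage(pop, "qtl") %*% arch$effects)
}
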