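#' Write and read phenotype/layout tables as delimited text
#'
#' Plain tab-separated text with a header row; the standard interchange
#' format for trial records (one row per plot).
#'
#' @param tbl A phenotype or layout tibble.
#' @param path File path.
#' @return `write_table_tsv()` returns `path` invisibly; `read_table_tsv()`
#'   returns a tibble.
#' @export
write_table_tsv <- function(tbl, path) {
  utils::write.table(tbl, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
}

#' Write a population's genotypes as delimited text
#'
#' Dosage matrix (lines x loci, values 0/1/2) with a sidecar locus table
#' (`<path>.loci.tsv`: chromosome, index, QTL flag, allele frequency).
#'
#' @param pop A `population`.
#' @param path Base file path for the dosage matrix.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(pop, path) {
  Z <- dosage(pop)
  rownames(Z) <- pop$ids
  utils::write.table(Z, path,
    sep = "\t", quote = FALSE,
    row.names = TRUE, col.names = FALSE
  )
  loci <- pop$genome$loci
  loci$allele_freq <- colMeans(Z) / 2
  utils::write.table(
    loci[, c("chr", "within", "is_qtl", "allele_freq")],
    paste0(path, ".loci.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Serialize a fit's posterior summaries to delimited text
#'
#' Writes one row per latent effect (block, label, mean, sd), a
#' hyperparameter summary table (`<path>.hyper.tsv`) and a scalar metadata
#' block (`<path>.meta.tsv`).
#'
#' @param fit An [fit_lgm()] object.
#' @param path Base file path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  write_table_tsv(fit$latent, path)
  write_table_tsv(
    fit$hyper[, c("name", "mode", "sd", "lower", "upper")],
    paste0(path, ".hyper.tsv")
  )
  write_table_tsv(glance(fit), paste0(path, ".meta.tsv"))
  invisible(path)
}
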