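#' Impute missing marker dosages with the column mean
#'
#' @param Z_raw Dosage matrix (lines x markers) with `NA` for missing calls.
#' @return The matrix with every missing entry replaced by its column mean.
#' @export
impute_marker_missing <- function(Z_raw) {
  Z_raw <- as.matrix(Z_raw)
  nas <- is.na(Z_raw)
  if (!any(nas)) {
    return(Z_raw)
  }
  full_na <- colSums(!nas) == 0
  if (any(full_na)) {
    stop(
      "fully missing marker column(s): ",
      paste(utils::head(which(full_na), 5), collapse = ", "),
      call. = FALSE
    )
  }
  mu <- colMeans(Z_raw, na.rm = TRUE)
  idx <- which(nas, arr.ind = TRUE)
  Z_raw[idx] <- mu[idx[, 2]]
  Z_raw
}

#' VanRaden genomic relationship matrix
#'
#' \eqn{A = Z Z^T / k} with column-centred dosages \eqn{Z} and
#' \eqn{k = 2 \sum_l q_l (1 - q_l)} for allele frequencies \eqn{q_l}.
#'
#' @param Z_raw Dosage matrix (lines x markers), entries 0/1/2 (missing
#'   values must be imputed first).
#' @param q Allele frequencies per marker; by default estimated from the data
#'   as column means / 2.
#' @param scale_markers Also divide each centred column by its standard
#'   deviation before forming relationships (centre-only is the default).
#' @return List with `A` (m x m relationship matrix), `Z` (centred, possibly
#'   scaled), `k`, and `q`.
#' @export
vanraden_grm <- function(Z_raw, q = NULL, scale_markers = FALSE) {
  Z_raw <- as.matrix(Z_raw)
  if (anyNA(Z_raw)) stop("missing dosages: impute first", call. = FALSE)
  if (is.null(q)) q <- colMeans(Z_raw) / 2
  mono <- q <= 0 | q >= 1
  if (any(mono)) {
    stop(
      "monomorphic marker column(s): ",
      paste(utils::head(which(mono), 5), collapse = ", "),
      call. = FALSE
    )
  }
  Z <- sweep(Z_raw, 2, 2 * q)
  if (scale_markers) {
    sds <- apply(Z, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant marker column(s) cannot be scaled", call. = FALSE)
    }
    Z <- sweep(Z, 2, sds, "/")
  }
  k <- 2 * sum(q * (1 - q))
  if (k <= 0) stop("zero heterozygosity scaling k", call. = FALSE)
  list(A = tcrossprod(Z) / k, Z = Z, k = k, q = q)
}

#' Compress a centred marker matrix with principal components
#'
#' Singular value decomposition \eqn{Z = U S V^T}; the compressed matrix
#' keeps the leading principal components \eqn{Z^* = Z V[, 1..p^*]}. The rule
#' is either an explicit component count or the proportion of variation in Z
#' (cumulative squared singular values) to retain.
#'
#' @param Z Column-centred dosage matrix (lines x markers).
#' @param p_star Number of components to keep (capped at `rank(Z)` is an
#'   error).
#' @param var_explained Alternative rule: smallest `p_star` whose components
#'   explain at least this proportion (e.g. 0.95) of the variation in Z.
#' @return List with `Zstar` (m x p_star), `V` (rotation), `d` (singular
#'   values), `p_star`, and `var_explained` actually achieved.
#' @export
pc_compress <- function(Z, p_star = NULL, var_explained = NULL) {
  Z <- as.matrix(Z)
  if (is.null(p_star) && is.null(var_explained)) {
    var_explained <- 0.95
  }
  sv <- svd(Z)
  tol <- max(dim(Z)) * max(sv$d) * .Machine$double.eps
  rk <- sum(sv$d > tol)
  if (is.null(p_star)) {
    cum <- cumsum(sv$d^2) / sum(sv$d^2)
    p_star <- which(cum >= var_explained)[1]
  }
  if (p_star > rk) {
    stop(sprintf("p_star = %d exceeds rank(Z) = %d", p_star, rk), call. = FALSE)
  }
  V <- sv$v[, seq_len(p_star), drop = FALSE]
  list(
    Zstar = Z %*% V, V = V, d = sv$d, p_star = p_star,
    var_explained = sum(sv$d[seq_len(p_star)]^2) / sum(sv$d^2)
  )
}

#' Extend a genomic relationship matrix with non-genotyped lines
#'
#' Non-genotyped lines are appended as an identity block with zero
#' relationship to the genotyped lines (and to each other), preserving
#' positive semi-definiteness.
#'
#' @param A Relationship matrix of the genotyped lines.
#' @param m_extra Number of non-genotyped lines to append.
#' @return The block-extended relationship matrix.
#' @export
extend_grm <- function(A, m_extra) {
  stopifnot(m_extra >= 0)
  if (m_extra == 0) {
    return(A)
  }
  m <- nrow(A)
  out <- diag(m + m_extra)
  out[seq_len(m), seq_len(m)] <- A
  rn <- rownames(A)
  if (!is.null(rn)) {
    nm <- c(rn, paste0("ng", seq_len(m_extra)))
    dimnames(out) <- list(nm, nm)
  }
  out
}
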