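#' Continuous ranked probability score for a Gaussian predictive
#'
#' \eqn{CRPS(F, y) = \int (F(u) - 1\{y \le u\})^2 du}, evaluated in closed
#' form for \eqn{F = N(\mu, \sigma^2)}:
#' \deqn{\sigma [ z(2\Phi(z) - 1) + 2\phi(z) - 1/\sqrt{\pi} ]}
#' with \eqn{z = (y-\mu)/\sigma}. Negatively oriented: smaller is better. A
#' zero-variance forecast reduces to the absolute error.
#'
#' @param mu,sigma Predictive mean and standard deviation (sigma >= 0).
#' @param y Realized value(s).
#' @return CRPS value(s).
#' @export
#' @examples
#' crps_gaussian(0, 1, 0) # 0.2337
crps_gaussian <- function(mu, sigma, y) {
  if (any(sigma < 0)) stop("`sigma` must be non-negative", call. = FALSE)
  z <- ifelse(sigma > 0, (y - mu) / sigma, 0)
  out <- sigma * (z * (2 * stats::pnorm(z) - 1) + 2 * stats::dnorm(z) -
    1 / sqrt(pi))
  ifelse(sigma > 0, out, abs(y - mu))
}

#' Correlation between true and estimated values
#'
#' Plain Pearson correlation with defensive checks on degenerate input.
#'
#' @param true_val,est_val Equal-length numeric vectors (n >= 3).
#' @return Pearson correlation coefficient.
#' @export
bv_correlation <- function(true_val, est_val) {
  if (length(true_val) != length(est_val) || length(true_val) < 3) {
    stop("need equal-length vectors with at least 3 values", call. = FALSE)
  }
  if (stats::sd(true_val) == 0 || stats::sd(est_val) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  stats::cor(true_val, est_val)
}

#' Capture of the true top individuals in the estimated ranking
#'
#' Counts how many of the `n_top` individuals with the largest true values
#' appear among the `n_rank` individuals with the largest estimated values
#' (larger is better, as for yield). Ties are broken by the stable original
#' order.
#'
#' @param true_val,est_val Equal-length numeric vectors.
#' @param n_top Number of true best individuals to look for (default 10).
#' @param n_rank Size of the estimated top set (default 100).
#' @return Integer in `[0, n_top]`.
#' @export
top_capture <- function(true_val, est_val, n_top = 10, n_rank = 100) {
  n <- length(true_val)
  if (length(est_val) != n) stop("length mismatch", call. = FALSE)
  if (n_top > n_rank || n_rank > n) {
    stop("need n_top <= n_rank <= length", call. = FALSE)
  }
  true_top <- order(true_val, decreasing = TRUE)[seq_len(n_top)]
  est_top <- order(est_val, decreasing = TRUE)[seq_len(n_rank)]
  sum(true_top %in% est_top)
}

#' Aggregate replicate study results into mean/SE tables
#'
#' @param results Long tibble of per-replicate scores with a `rep` column,
#'   grouping columns (e.g. `prop_spatial`, `markers`, `model`) and one or
#'   more metric columns.
#' @param metrics Names of the metric columns to aggregate (default: every
#'   numeric column except `rep` and the grouping columns).
#' @param groups Character vector of grouping columns (default: all
#'   non-metric, non-`rep` columns).
#' @return Tibble keyed by the grouping columns with `<metric>_mean`,
#'   `<metric>_se` (sd divided by the square root of the replicate count)
#'   and `n_rep` columns. Cells with fewer than 2 replicates are an error.
#' @export
summarize_study <- function(results, metrics = NULL, groups = NULL) {
  results <- tibble::as_tibble(results)
  if (!"rep" %in% names(results)) stop("`results` needs a `rep` column", call. = FALSE)
  if (is.null(groups)) {
    groups <- setdiff(
      names(results)[!vapply(results, is.numeric, logical(1)) |
        names(results) %in% c("prop_spatial")],
      c("rep", metrics)
    )
  }
  if (is.null(metrics)) {
    metrics <- setdiff(
      names(results)[vapply(results, is.numeric, logical(1))],
      c("rep", groups)
    )
  }
  out <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      dplyr::across(
        dplyr::all_of(metrics),
        list(
          mean = ~ mean(.x),
          se = ~ stats::sd(.x) / sqrt(dplyr::n())
        ),
        .names = "{.col}_{.fn}"
      ),
      n_rep = dplyr::n(), .groups = "drop"
    )
  if (any(out$n_rep < 2)) {
    bad <- out[out$n_rep < 2, groups, drop = FALSE]
    stop(
      "cells with fewer than 2 replicates: ",
      paste(utils::capture.output(print(as.data.frame(bad))), collapse = "; "),
      call. = FALSE
    )
  }
  out
}
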