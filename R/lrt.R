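# The core statistic: a one-sided likelihood-ratio test of the binomial
# difference rates in an exon (x_e successes in n_e unmasked bp) versus its
# intronic reference (x_i in n_i), H0: p_e <= p_i vs H1: p_e > p_i.
#
# The unconstrained MLEs are x_e/n_e and x_i/n_i; when the exonic estimate
# does not exceed the intronic one the null region contains the unconstrained
# maximum and the statistic is 0. Otherwise the null maximum sits on the
# boundary p_e = p_i at the pooled rate (x_e + x_i)/(n_e + n_i), and
# -2 ln(lambda) is referred to chi-squared with 1 df.

# x * log(p) with the 0 * log(0) := 0 convention.
xlogy <- function(x, p) {
  len <- max(length(x), length(p))
  out <- numeric(len)
  x <- rep_len(x, len); p <- rep_len(p, len)
  nz <- x != 0
  out[nz] <- x[nz] * log(p[nz])
  out
}

binom_loglik <- function(x, n, p) xlogy(x, p) + xlogy(n - x, 1 - p)

#' One-sided exon/intron likelihood-ratio test
#'
#' Vectorized over the rows of a pair tibble (or over bare count vectors via
#' [lrt_test()]). Adds the maximum-likelihood estimates, the likelihood ratio
#' `lambda`, the statistic `-2 ln(lambda)` and the chi-squared(1) upper-tail
#' p-value.
#'
#' @param pairs tibble with integer columns `x_e`, `n_e`, `x_i`, `n_i`
#'   (e.g. from [exon_pairs()]). Rows with `n_e` or `n_i` of 0 are left `NA`.
#' @return `pairs` with columns `p_hat_e`, `p_hat_i`, `p_hat_0`, `lambda`,
#'   `statistic`, `p_value` appended.
#' @export
lrt_exon <- function(pairs) {
  with(pairs, {
    if (any(x_e > n_e | x_i > n_i | x_e < 0 | x_i < 0)) {
      stop("counts must satisfy 0 <= x <= n", call. = FALSE)
    }
  })
  testable <- pairs$n_e > 0 & pairs$n_i > 0
  p_e <- ifelse(testable, pairs$x_e / pairs$n_e, NA_real_)
  p_i <- ifelse(testable, pairs$x_i / pairs$n_i, NA_real_)
  p_0 <- ifelse(testable,
                (pairs$x_e + pairs$x_i) / (pairs$n_e + pairs$n_i), NA_real_)
  ll_alt <- binom_loglik(pairs$x_e, pairs$n_e, p_e) +
    binom_loglik(pairs$x_i, pairs$n_i, p_i)
  ll_null <- binom_loglik(pairs$x_e, pairs$n_e, p_0) +
    binom_loglik(pairs$x_i, pairs$n_i, p_0)
  stat <- ifelse(!testable, NA_real_,
                 ifelse(p_e <= p_i, 0, pmax(0, 2 * (ll_alt - ll_null))))
  dplyr::mutate(
    pairs,
    p_hat_e = p_e, p_hat_i = p_i, p_hat_0 = p_0,
    lambda = exp(-stat / 2),
    statistic = stat,
    p_value = chi2_pvalue(stat)
  )
}

#' @rdname lrt_exon
#' @param x_e,n_e,x_i,n_i bare count vectors.
#' @export
lrt_test <- function(x_e, n_e, x_i, n_i) {
  lrt_exon(tibble::tibble(x_e = x_e, n_e = n_e, x_i = x_i, n_i = n_i))
}

#' Chi-squared(1) upper-tail p-value of the LRT statistic
#'
#' @param statistic `-2 ln(lambda)`, non-negative.
#' @return Upper-tail probability; 1 at statistic 0.
#' @export
chi2_pvalue <- function(statistic) {
  if (any(statistic < 0, na.rm = TRUE)) {
    stop("statistic must be non-negative", call. = FALSE)
  }
  stats::pchisq(statistic, df = 1, lower.tail = FALSE)
}

#' Storey q-values
#'
#' Computes q-values with the proportion of true nulls estimated by Storey's
#' smoother method: pi0(lambda) = mean(p > lambda) / (1 - lambda) over the
#' grid lambda = 0.05, 0.10, ..., 0.95, smoothed with a cubic smoothing
#' spline and evaluated at the largest lambda, bounded to (0, 1]. For fewer
#' than 100 p-values the smoother is unstable and pi0 falls back to
#' min(1, 2 * mean(p)). With `pi0 = 1` the result equals Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param pi0 optional fixed proportion of true nulls.
#' @param lambda tuning grid for the smoother estimate.
#' @return q-values in input order.
#' @export
storey_qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) < 1) stop("need at least one p-value", call. = FALSE)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- min(1, 2 * mean(p))
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(1, max(pi0, 0))
    }
    if (pi0 <= 0) pi0 <- .Machine$double.eps
  }
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]", call. = FALSE)
  o <- order(p)
  # grouped so that pi0 = 1 reproduces Benjamini-Hochberg bit for bit
  q_sorted <- pi0 * (m / seq_len(m) * p[o])
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Collapse redundant exons shared by overlapping transcripts
#'
#' Overlapping transcripts are analyzed independently; for scan-level counts
#' an exon is identified by its genomic key (chrom, start, end, strand) and
#' kept once (first occurrence).
#'
#' @param results tibble with `chrom`, `gstart`, `gend`, `strand` columns.
#' @return The non-redundant subset.
#' @export
nonredundant_exons <- function(results) {
  dplyr::distinct(results, .data$chrom, .data$gstart, .data$gend,
                  .data$strand, .keep_all = TRUE)
}

#' Significant exon set and cascade counts
#'
#' Filters LRT results to the exons called accelerated: q-value at or below
#' the cutoff and exonic rate strictly above the intronic rate. The returned
#' tibble keeps the input order and carries the scan cascade counts (tested,
#' D_e > D_i, significant) as the `"cascade"` attribute.
#'
#' @param results tibble with `q_value`, `D_e`, `D_i` columns.
#' @param q_cut q-value cutoff (default 0.05).
#' @return The significant subset, with attribute `cascade`.
#' @export
significant_set <- function(results, q_cut = 0.05) {
  stopifnot(all(c("q_value", "D_e", "D_i") %in% names(results)))
  de_gt_di <- !is.na(results$D_e) & !is.na(results$D_i) & results$D_e > results$D_i
  sig <- de_gt_di & !is.na(results$q_value) & results$q_value <= q_cut
  out <- results[sig, , drop = FALSE]
  attr(out, "cascade") <- tibble::tibble(
    tested = sum(!is.na(results$q_value)),
    de_gt_di = sum(de_gt_di),
    significant = sum(sig)
  )
  out
}
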