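#' Excess of significant tests under the cumulative binomial
#'
#' Given `k` significant results out of `n` tests at level `alpha`,
#' computes the probability of observing at least `k` significant tests by
#' chance, `P(X >= k)` with `X ~ Binomial(n, alpha)`, plus the critical
#' count of significant tests compatible with chance.
#'
#' Two conventions for the "expected by chance" count are reported, since
#' the strictness of the inequality is a matter of taste:
#' `critical_count` is the largest `k0` such that `P(X >= k0 + 1) > alpha`
#' (observing up to `k0` significant tests is unremarkable), and
#' `critical_count_lower` is `critical_count - 1`.
#'
#' @param k number of significant tests observed.
#' @param n number of tests performed.
#' @param alpha nominal level of the individual tests (default 0.05).
#' @return list with `p_exceed`, `critical_count`, `critical_count_lower`.
#' @export
binomial_excess <- function(k, n, alpha = 0.05) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  p_exceed <- stats::pbinom(k - 1, n, alpha, lower.tail = FALSE)
  # largest k0 with P(X >= k0+1) > alpha
  kk <- 0:n
  tail_next <- stats::pbinom(kk, n, alpha, lower.tail = FALSE)  # P(X >= k0+1)
  crit <- max(kk[tail_next > alpha])
  list(p_exceed = p_exceed, critical_count = crit,
       critical_count_lower = crit - 1L)
}

#' Benjamini-Yekutieli FDR adjustment within groups
#'
#' Applies the B-Y step-up adjustment (valid under arbitrary dependence;
#' correction factor `c(m) = sum(1/1..m)`) separately within each group of
#' tests, as recommended when batteries mix tests of different kinds
#' (e.g. Hardy-Weinberg tests grouped by population, linkage tests grouped
#' by locus pair).
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param groups grouping factor/vector, same length as `p`; `NA` p-values
#'   are passed through as `NA`.
#' @return numeric vector of adjusted p-values, original order.
#' @export
by_fdr <- function(p, groups = rep(1L, length(p))) {
  if (length(groups) != length(p)) stop("groups length mismatch")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  adj <- rep(NA_real_, length(p))
  for (g in unique(groups)) {
    i <- which(groups == g & !is.na(p))
    if (length(i) == 0L) {
      message("by_fdr: group '", g, "' has no defined tests; skipped")
      next
    }
    adj[i] <- stats::p.adjust(p[i], method = "BY")
  }
  adj
}
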