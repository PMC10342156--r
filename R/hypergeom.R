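#' Upper-tail hypergeometric probability, computed in log space
#'
#' Shared tail kernel for the two enrichment tests in the pipeline: the
#' shared-miRNA ceRNA test and the cluster/subpathway gene-overlap test.
#' Computes P(X >= r) for X hypergeometric with population size `m`, `t`
#' successes and `n` draws, by summing the probability mass from `i = r`
#' upward with log-space binomial coefficients (equivalent to
#' 1 - sum_{i=0}^{r-1} of the mass, without the cancellation of the
#' complement form).
#'
#' @param m Population size (total miRNA universe / gene universe).
#' @param t Number of successes in the population.
#' @param n Number of draws.
#' @param r Observed overlap; the tail starts here.
#' @return P(X >= r) in (0, 1]; exactly 1 when `r = 0`.
#' @keywords internal
hyper_upper_tail <- function(m, t, n, r) {
  if (length(m) != 1L || length(t) != 1L || length(n) != 1L || length(r) != 1L)
    stop("hyper_upper_tail takes scalar arguments")
  if (anyNA(c(m, t, n, r)) || any(c(m, t, n, r) != floor(c(m, t, n, r))))
    stop("m, t, n, r must be non-negative integers")
  if (t > m || n > m) stop("t and n must not exceed m")
  if (r < 0 || r > min(t, n)) stop("r must satisfy 0 <= r <= min(t, n)")
  if (r == 0) return(1)
  i <- r:min(t, n)
  logterms <- lchoose(t, i) + lchoose(m - t, n - i) - lchoose(m, n)
  mx <- max(logterms)
  min(1, exp(mx + log(sum(exp(logterms - mx)))))
}
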