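# Mann-Whitney U / Wilcoxon rank-sum machinery shared by the compositional
# tests and the differential-expression module.
#
# Two evaluation paths:
#   * exact: the full permutation null of the rank-sum statistic, computed
#     by dynamic programming over doubled mid-ranks. Doubling turns
#     half-integer mid-ranks (ties) into integers so the distribution of
#     subset rank sums can be tabulated exactly; subset counts stay below
#     2^53 for the sample sizes where this path is used, so doubles are
#     exact.
#   * approximate: normal approximation with the usual tie correction and
#     a 0.5 continuity correction.

# Exact two-sided p-value for the observed U given combined mid-ranks.
mw_exact_p <- function(r, n1, U_obs) {
  N <- length(r)
  n2 <- N - n1
  d <- as.integer(round(2 * r))
  maxs <- sum(sort(d, decreasing = TRUE)[seq_len(n1)])
  # f[k+1, s+1] = number of size-k subsets of the ranks with doubled sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = maxs + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(N)) {
    di <- d[i]
    kmax <- min(n1, i)
    for (k in kmax:1) {
      src <- f[k, seq_len(maxs + 1L - di)]
      idx <- (di + 1L):(maxs + 1L)
      f[k + 1L, idx] <- f[k + 1L, idx] + src
    }
  }
  counts <- f[n1 + 1L, ]
  s2 <- which(counts > 0) - 1L           # doubled rank sums with support
  counts <- counts[s2 + 1L]
  U <- s2 / 2 - n1 * (n1 + 1) / 2
  center <- n1 * n2 / 2
  dev <- abs(U - center)
  keep <- dev >= abs(U_obs - center) - 1e-9
  sum(counts[keep]) / choose(N, n1)
}

# Normal approximation with tie correction and continuity correction.
mw_approx_p <- function(r, n1, U_obs) {
  N <- length(r)
  n2 <- N - n1
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  mu <- n1 * n2 / 2
  z <- (U_obs - mu - sign(U_obs - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Mann-Whitney U test with exact tie-aware null for small samples
#'
#' Two-sided rank-sum test using mid-ranks. For small samples (combined
#' n at most \code{exact_max_n}) the p-value is computed from the exact
#' permutation distribution of the statistic, which remains valid under
#' ties; larger samples use the normal approximation with tie correction
#' and continuity correction.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) the exact
#'   path; default \code{NULL} decides by sample size.
#' @param exact_max_n combined-size cutoff for the automatic exact path.
#' @return list with \code{statistic} (U for \code{x}), \code{p.value},
#'   and \code{method}.
#' @export
mann_whitney_u <- function(x, y, exact = NULL, exact_max_n = 40L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) .stopf("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- if (is.null(exact)) (n1 + n2) <= exact_max_n else isTRUE(exact)
  p <- if (use_exact) mw_exact_p(r, n1, U) else mw_approx_p(r, n1, U)
  list(statistic = U, p.value = p,
       method = if (use_exact) "exact" else "normal approximation")
}
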