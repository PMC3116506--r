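#' Probability that the majority of reads at a position is erroneous
#'
#' With per-position error probability `p` and an odd read depth `N`, the
#' consensus base is wrong when more than half the reads are erroneous:
#' `P(X >= (N+1)/2)` for `X ~ Binomial(N, p)`, computed by direct
#' summation. Even depths are rejected (a majority is undefined at a tie).
#'
#' @param N odd read depth (>= 1).
#' @param p per-position error probability in `[0, 1]`.
#' @return The majority-error probability.
#' @export
majority_error_prob <- function(N, p) {
  if (length(N) != 1L || N < 1L || N %% 2L == 0L)
    stop("N must be a single odd integer >= 1 (majority undefined for even N)")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  k <- ((N + 1) / 2):N
  sum(dbinom(k, N, p))
}

#' Minimum read depth for consensus correction
#'
#' The smallest odd `N` for which the majority-error probability does not
#' exceed `alpha`. Requires `p < 0.5`; otherwise no finite depth works.
#' The tolerated probabilities used in practice are 0.001, 0.01 and 0.05.
#'
#' @param p per-position error probability (< 0.5).
#' @param alpha tolerated probability of an erroneous majority, in (0, 1).
#' @param n_max search cap (internal safety net).
#' @return The smallest adequate odd depth.
#' @export
min_coverage <- function(p, alpha, n_max = 100001L) {
  if (p >= 0.5) stop("no finite depth can fix p >= 0.5")
  if (p < 0) stop("p must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  N <- 1L
  while (N <= n_max) {
    if (majority_error_prob(N, p) <= alpha) return(N)
    N <- N + 2L
  }
  stop("no solution found below N = ", n_max)
}

#' Cumulative probability envelope of the erroneous fraction in a sample
#'
#' `P(X <= k)` for `k = 0..k_max`, `X ~ Binomial(N, p)`: the probability
#' that at most `k` of `N` sampled reads are erroneous at a position with
#' error rate `p`. Suitable for mapping to banded probability envelopes
#' (>= 0.95, 0.8-0.95, 0.6-0.8, 0.5-0.6, 0.4-0.5, 0.2-0.4, < 0.2).
#'
#' @param N sample size (>= 1).
#' @param p per-position error probability.
#' @param k_max largest count evaluated (0 <= k_max <= N).
#' @return A numeric vector of length `k_max + 1`, named by `k`.
#' @export
error_envelope <- function(N, p, k_max = N) {
  if (N < 1L) stop("N must be >= 1")
  if (k_max < 0L || k_max > N) stop("k_max must be in 0..N")
  k <- 0:k_max
  setNames(pbinom(k, N, p), k)
}

#' Coverage-requirement grid
#'
#' Minimum consensus depth over a grid of error rates and tolerated
#' majority-error probabilities.
#'
#' @param p_grid error rates (< 0.5).
#' @param alpha_grid tolerated probabilities.
#' @return A long-format `data.frame` (`p`, `alpha`, `min_coverage`).
#' @export
coverage_grid <- function(p_grid = seq(0.01, 0.45, by = 0.01),
                          alpha_grid = c(0.001, 0.01, 0.05)) {
  out <- expand.grid(p = p_grid, alpha = alpha_grid)
  out$min_coverage <- mapply(min_coverage, out$p, out$alpha)
  out
}
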