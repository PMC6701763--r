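# Ewens sampling formula machinery for Fu's Fs. The distribution of the
# number of distinct alleles K in a sample of n under the neutral
# infinite-alleles model is P(K = k) = |s(n,k)| theta^k / theta^(n), with
# |s(n,k)| unsigned Stirling numbers of the first kind and theta^(n) the
# rising factorial. Two independent numerical routes are provided:
#   * "stirling": log-space Stirling recurrence |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)|
#   * "crp":      forward probability recurrence of the Chinese restaurant
#                 process, p_{i+1}(k) = p_i(k) i/(theta+i) + p_i(k-1) theta/(theta+i)
# Both are exact in exact arithmetic; they must agree to ~1e-12 in doubles and
# that agreement is a tested contract. (A big-integer route is not available
# in this environment; tests additionally check both against exact-in-double
# Stirling numbers for n <= 12.)

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Log unsigned Stirling numbers of the first kind for fixed n
#'
#' Computes `log |s(n, k)|` for `k = 1..n` by the standard recurrence carried
#' in log space, so it is usable far beyond the double-precision overflow
#' point of the raw integers.
#'
#' @param n Row index (sample size), `n >= 1`.
#' @return Numeric vector of length `n`: `log |s(n, k)|`.
#' @export
log_stirling1 <- function(n) {
  stopifnot(n >= 1)
  row <- 0 # log|s(1,1)|
  if (n == 1) return(row)
  for (i in seq_len(n - 1)) {
    # row holds k = 1..i; |s(i+1,k)| = i|s(i,k)| + |s(i,k-1)|
    row <- logaddexp(c(-Inf, row), log(i) + c(row, -Inf))
  }
  row
}

#' Distribution of the number of alleles under the Ewens sampling formula
#'
#' @param theta Scaled mutation rate, `theta > 0`.
#' @param n Sample size, `n >= 1`.
#' @param method `"stirling"` (log-space Stirling numbers) or `"crp"`
#'   (forward Chinese-restaurant-process recurrence). The two agree to
#'   ~1e-12 and serve as mutual cross-checks.
#' @return Numeric probability vector over `K = 1..n`, summing to 1.
#' @export
ewens_k_distribution <- function(theta, n, method = c("crp", "stirling")) {
  method <- match.arg(method)
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta) || theta <= 0) {
    abort("theta must be a single positive number", class = "mothwaves_input_error")
  }
  stopifnot(n >= 1)
  if (method == "crp") {
    p <- c(1, rep(0, n - 1))
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        p <- p * i / (theta + i) + c(0, p[-n]) * theta / (theta + i)
      }
    }
    return(p)
  }
  ls <- log_stirling1(n)
  k <- seq_len(n)
  log_rising <- sum(log(theta + 0:(n - 1)))
  exp(ls + k * log(theta) - log_rising)
}

#' Fu's Fs neutrality statistic
#'
#' `Fs = ln(S' / (1 - S'))` where `S' = P(K >= h_obs)` under the Ewens
#' sampling formula with `theta` set to the mean pairwise differences `k`
#' (the diversity-based estimate of the population mutation rate). Large
#' negative values indicate an excess of haplotypes relative to neutral
#' equilibrium — the signature of population expansion.
#'
#' @param k Mean pairwise nucleotide differences (used as theta), `k > 0`.
#' @param n Sample size, `n >= 2`.
#' @param h_obs Observed number of haplotypes, `1 <= h_obs <= n`.
#' @param method Passed to [ewens_k_distribution()].
#' @return Fu's Fs; `+/-Inf` with attribute `boundary = TRUE` when the tail
#'   probability is numerically 0 or 1.
#' @export
fus_fs <- function(k, n, h_obs, method = "crp") {
  if (!is.finite(k) || k <= 0) {
    warn("Fu's Fs is undefined when k <= 0", class = "mothwaves_undefined_stat")
    return(NA_real_)
  }
  stopifnot(n >= 2, h_obs >= 1, h_obs <= n)
  p <- ewens_k_distribution(k, n, method)
  s_prime <- sum(p[h_obs:n])
  if (s_prime <= 0 || s_prime >= 1) {
    out <- if (s_prime <= 0) -Inf else Inf
    attr(out, "boundary") <- TRUE
    return(out)
  }
  log(s_prime / (1 - s_prime))
}
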