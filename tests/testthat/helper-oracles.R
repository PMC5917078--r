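# Independent oracles used only by the tests.

# Two-sided Fisher exact p for a 2x2 table by exhaustive enumeration of the
# hypergeometric support with fixed margins: sum the probabilities of all
# tables no more probable than the observed one.
fisher_p_enum <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force consecutive-sedentary prompt count over a fully sedentary
# worn span of T minutes: floor(T / interval).
expected_prompts_full_span <- function(T_min, interval) floor(T_min / interval)

# Exact central 99% band for a binomial count: the estimate recovers the
# configured rate when the observed count falls inside it.
binom99_band <- function(n, p) {
  c(stats::qbinom(0.005, n, p), stats::qbinom(0.995, n, p))
}
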