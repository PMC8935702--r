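# Independent oracles, kept deliberately separate from the package's own
# computation paths: direct enumeration / closed forms at tiny n.

# HWE exact test by direct log-factorial enumeration of the conditional
# distribution of the heterozygote count given the allele margin.
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n_aa + n_Aa
  rare <- min(nA, nB)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  logw <- vapply(hs, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2)
  }, numeric(1))
  probs <- exp(logw - max(logw))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Pearson chi-square on a 2x2 table by the closed form
# N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)), df = 1
chisq_2x2_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (with the same margins) no more
# likely than the observed one.
fisher_2x2_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  k <- a + c          # column 1 total
  n <- c + d
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Beta quantile by brute-force numeric integration of the density
# (adaptive quadrature for the CDF, bisection for the quantile)
beta_quantile_numint <- function(p, a, b) {
  cdf <- function(x) {
    stats::integrate(stats::dbeta, 0, x, shape1 = a, shape2 = b,
                     rel.tol = 1e-10)$value
  }
  stats::uniroot(function(x) cdf(x) - p, c(1e-12, 1 - 1e-12),
                 tol = 1e-10)$root
}
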