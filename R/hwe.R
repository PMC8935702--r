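#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test for Hardy-Weinberg proportions from a single
#' SNP's genotype counts. Conditional on the observed allele margin, the
#' heterozygote count follows a known distribution; the p-value is the
#' probability-sum form: the total probability of all heterozygote counts
#' whose conditional probability does not exceed that of the observed
#' count. The distribution is built by the standard recurrence over
#' heterozygote counts (two apart, fixed parity), so the test is exact for
#' any sample size without factorial overflow.
#'
#' A monomorphic site (no copies of one allele) is trivially in
#' equilibrium and returns `p = 1`.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (homozygous ref, heterozygous,
#'   homozygous alt); nonnegative, not all zero.
#' @return The exact p-value.
#' @references Wigginton JE, Cutler DJ, Abecasis GR (2005) A note on exact
#'   tests of Hardy-Weinberg equilibrium. Am J Hum Genet 76:887-893.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be nonnegative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)

  rare <- 2 * min(n_AA, n_aa) + n_Aa     # copies of the rarer allele
  if (rare == 0) return(1)

  # heterozygote counts share the parity of the rare-allele total
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1

  probs <- numeric(rare + 1)             # index h+1 holds P(h hets), unnormalised
  probs[mid + 1] <- 1
  homr <- (rare - mid) / 2
  homc <- n - mid - homr
  h <- mid
  while (h >= 2) {
    probs[h - 1] <- probs[h + 1] * h * (h - 1) /
      (4 * (homr + 1) * (homc + 1))
    h <- h - 2
    homr <- homr + 1
    homc <- homc + 1
  }
  homr <- (rare - mid) / 2
  homc <- n - mid - homr
  h <- mid
  while (h <= rare - 2) {
    probs[h + 3] <- probs[h + 1] * 4 * homr * homc / ((h + 2) * (h + 1))
    h <- h + 2
    homr <- homr - 1
    homc <- homc - 1
  }

  probs <- probs / sum(probs)
  p_obs <- probs[n_Aa + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
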