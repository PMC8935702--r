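#' Beta prior on the pathogenic allele frequency
#'
#' Pseudo-counts of a Beta prior on the pooled pathogenic allele frequency
#' `q`. The default is the Jeffreys prior Beta(0.5, 0.5): with `x`
#' pathogenic alleles among `n`, the posterior is
#' Beta(`x` + 0.5, `n` - `x` + 0.5).
#'
#' @param alpha0 Pseudo-count for the pathogenic allele, `> 0`.
#' @param beta0 Pseudo-count for the non-pathogenic allele, `> 0`.
#' @return An object of class `"bayes_prior"`.
#' @export
bayes_prior <- function(alpha0 = 0.5, beta0 = 0.5) {
  if (!is.numeric(alpha0) || !is.numeric(beta0) || alpha0 <= 0 || beta0 <= 0) {
    stop("prior pseudo-counts must be positive", call. = FALSE)
  }
  structure(list(alpha0 = alpha0, beta0 = beta0), class = "bayes_prior")
}

new_prevalence_estimate <- function(method, phi, ci_low = NA_real_,
                                    ci_high = NA_real_, x = NA_real_,
                                    n = NA_real_) {
  stopifnot(phi >= 0, phi <= 1)
  if (!is.na(ci_low) && !(ci_low <= phi && phi <= ci_high)) {
    stop("interval must bracket the point estimate", call. = FALSE)
  }
  structure(list(method = method, phi = phi, ci_low = ci_low,
                 ci_high = ci_high, x = x, n = n),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat("Affected-frequency estimate [", x$method, "]: phi = ",
      signif(x$phi, 5), " (", reciprocal_render(x$phi), ")", sep = "")
  if (!is.na(x$ci_low)) {
    cat(" 95% interval ", reciprocal_render(x$ci_low), "-",
        reciprocal_render(x$ci_high), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Carrier frequency of a cohort
#'
#' Fraction of individuals heterozygous for at least one pathogenic/
#' likely-pathogenic variant, `C/N`.
#'
#' @param counts A [cohort_counts()] object.
#' @return Carrier frequency in `[0, 1]`.
#' @export
carrier_frequency <- function(counts) {
  stopifnot(inherits(counts, "cohort_counts"))
  if (counts$N == 0) stop("invalid cohort: N must be positive", call. = FALSE)
  counts$C / counts$N
}

#' Couple's carrier risk
#'
#' Probability that both members of a random couple are carriers: the
#' product of the two carrier frequencies. Under autosomal recessive
#' inheritance a quarter of such couples' offspring are expected affected.
#'
#' @param f1,f2 Carrier frequencies in `[0, 1]`.
#' @return `f1 * f2`.
#' @export
couple_carrier_risk <- function(f1, f2) {
  stopifnot(f1 >= 0, f1 <= 1, f2 >= 0, f2 <= 1)
  f1 * f2
}

#' Affected frequency from the carrier frequency (method 1)
#'
#' The simplest estimator: the couple's carrier risk `(C/N)^2` divided by 4
#' for the autosomal recessive inheritance model, so
#' `phi = (C/N)^2 / 4 = q_hat^2` with `q_hat = C/(2N)`.
#'
#' @param counts A [cohort_counts()] object.
#' @return A `prevalence_estimate` with method `"carrier_frequency"` and no
#'   interval.
#' @export
estimate_method1 <- function(counts) {
  f <- carrier_frequency(counts)
  new_prevalence_estimate("carrier_frequency", couple_carrier_risk(f, f) / 4,
                          x = counts$C, n = 2 * counts$N)
}

#' Gender-stratified affected frequency (method 2)
#'
#' The permutation-and-combination estimator: a random couple pairs one
#' male and one female, so the couple's risk uses the gender-specific
#' carrier frequencies, `phi = (C_m/N_m) * (C_f/N_f) / 4`. A zero-sized
#' gender stratum is an error (no silent fallback to method 1).
#'
#' @param counts A [cohort_counts()] object with both strata populated.
#' @return A `prevalence_estimate` with method `"permutation_combination"`.
#' @export
estimate_method2 <- function(counts) {
  stopifnot(inherits(counts, "cohort_counts"))
  if (counts$N_male == 0 || counts$N_female == 0) {
    stop("gender stratum of size zero: method 2 is undefined", call. = FALSE)
  }
  fm <- counts$C_male / counts$N_male
  ff <- counts$C_female / counts$N_female
  new_prevalence_estimate("permutation_combination",
                          couple_carrier_risk(fm, ff) / 4,
                          x = counts$C, n = 2 * counts$N)
}

#' Bayesian affected frequency with credible interval (method 3)
#'
#' Beta-binomial model on the pooled pathogenic allele frequency `q`: with
#' `x` pathogenic alleles observed among `n` and a Beta(`alpha0`, `beta0`)
#' prior, the posterior is Beta(`x + alpha0`, `n - x + beta0`). The affected
#' frequency is `phi = q^2` (homozygous or compound-heterozygous genotypes
#' under Hardy-Weinberg). The default point estimate squares the posterior
#' mean of `q`; the equal-tailed credible interval on `q` is squared
#' end-point-wise, which is valid because `q -> q^2` is monotone on `[0, 1]`.
#'
#' For carrier-count cohorts use `x = C` (each carrier contributes one
#' pathogenic allele — the standard assumption for a disease-free cohort
#' where no individual carries two pathogenic variants) and `n = 2N`.
#'
#' @param x Pathogenic allele count, `0 <= x <= n`.
#' @param n Total allele count, `> 0`.
#' @param prior A [bayes_prior()]; Jeffreys Beta(0.5, 0.5) by default.
#' @param level Interval coverage probability in `(0, 1)`; default 0.95.
#' @param point Point summary of the posterior on `q` to square:
#'   `"mean"` (default), `"median"` or `"mode"`.
#' @return A `prevalence_estimate` with method `"bayesian"` and interval.
#' @examples
#' # 110 carriers among 20,905 individuals -> x = 110, n = 41,810
#' estimate_method3(110, 41810)
#' @export
estimate_method3 <- function(x, n, prior = bayes_prior(), level = 0.95,
                             point = c("mean", "median", "mode")) {
  stopifnot(inherits(prior, "bayes_prior"))
  point <- match.arg(point)
  if (!is.numeric(x) || !is.numeric(n) || n <= 0 || x < 0 || x > n) {
    stop("invalid counts: need 0 <= x <= n and n > 0", call. = FALSE)
  }
  if (level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)", call. = FALSE)
  }
  a <- x + prior$alpha0
  b <- n - x + prior$beta0
  q_hat <- switch(point,
    mean = a / (a + b),
    median = stats::qbeta(0.5, a, b),
    mode = if (a > 1 && b > 1) (a - 1) / (a + b - 2) else a / (a + b))
  tail <- (1 - level) / 2
  q_lo <- stats::qbeta(tail, a, b)
  q_hi <- stats::qbeta(1 - tail, a, b)
  new_prevalence_estimate("bayesian", q_hat^2,
                          ci_low = q_lo^2, ci_high = q_hi^2, x = x, n = n)
}

#' Average of several affected-frequency estimates
#'
#' Arithmetic mean on the frequency scale (never of the reciprocals).
#'
#' @param estimates Numeric vector of frequencies in `[0, 1]`, or a list of
#'   `prevalence_estimate` objects.
#' @return The mean frequency.
#' @export
average_prevalence <- function(estimates) {
  if (is.list(estimates) && all(vapply(estimates, inherits, TRUE,
                                       "prevalence_estimate"))) {
    estimates <- vapply(estimates, function(e) e$phi, numeric(1))
  }
  estimates <- as.numeric(estimates)
  if (length(estimates) == 0L) stop("no estimates to average", call. = FALSE)
  if (any(estimates < 0 | estimates > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  mean(estimates)
}

#' Render a frequency as "1/R"
#'
#' The conventional display of a rare-disease frequency: the reciprocal,
#' rounded half away from zero, with thousands separators (e.g.
#' `"1/144,469"`). A zero frequency renders as `"0"`.
#'
#' @param phi Frequency in `[0, 1]`.
#' @return A display string.
#' @export
reciprocal_render <- function(phi) {
  stopifnot(length(phi) == 1L, phi >= 0, phi <= 1)
  if (phi == 0) return("0")
  paste0("1/", format(floor(1 / phi + 0.5), big.mark = ",", scientific = FALSE))
}

#' Rounded reciprocal of a frequency
#'
#' @param phi Frequency, `> 0`.
#' @return `round(1/phi)` (half away from zero) as a plain number.
#' @export
reciprocal_of <- function(phi) {
  stopifnot(phi > 0)
  floor(1 / phi + 0.5)
}

#' All three affected-frequency estimates for one cohort
#'
#' Convenience wrapper running methods 1-3 on the same cohort; method 3
#' takes `x = C`, `n = 2N`.
#'
#' @inheritParams estimate_method1
#' @inheritParams estimate_method3
#' @return A named list of three `prevalence_estimate` objects.
#' @export
estimate_all <- function(counts, prior = bayes_prior(), level = 0.95) {
  list(carrier_frequency = estimate_method1(counts),
       permutation_combination = estimate_method2(counts),
       bayesian = estimate_method3(counts$C, 2 * counts$N, prior, level))
}
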