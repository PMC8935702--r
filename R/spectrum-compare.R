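#' Build a 2x2 allele-count contingency table
#'
#' Rows are cohorts, columns are alternate/reference allele counts:
#' `(a, b, c, d) = (AC1, AN1 - AC1, AC2, AN2 - AC2)`. Both entries must
#' describe the same variant.
#'
#' @param e1,e2 Single-row [allele_counts()] entries for the same variant.
#' @return An object of class `"allele_table"` with fields `a, b, c, d`.
#' @export
build_allele_table <- function(e1, e2) {
  if (nrow(e1) != 1L || nrow(e2) != 1L) {
    stop("build_allele_table expects single-row entries", call. = FALSE)
  }
  if (e1$key != e2$key) {
    stop("mismatched variant keys: ", e1$key, " vs ", e2$key, call. = FALSE)
  }
  allele_table(e1$AC, e1$AN - e1$AC, e2$AC, e2$AN - e2$AC)
}

#' @rdname build_allele_table
#' @param a,b,c,d Nonnegative allele counts (cohort-1 alt, cohort-1 ref,
#'   cohort-2 alt, cohort-2 ref).
#' @export
allele_table <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(v < 0)) stop("allele counts must be nonnegative", call. = FALSE)
  if (sum(v) == 0) stop("all-zero table", call. = FALSE)
  structure(as.list(v), class = "allele_table")
}

#' Compare allele frequencies between two cohorts
#'
#' Odds ratio and association p-value for a 2x2 allele-count table. The
#' odds ratio is the sample `(a*d)/(b*c)`, reported as `Inf` when the
#' comparison cohort has zero alternate alleles (`c = 0`, `a > 0`) and `0`
#' in the mirrored case; an optional Haldane-Anscombe +0.5 correction
#' yields finite values. The p-value comes from a Pearson chi-square test
#' without continuity correction; with `test = "auto"` Fisher's exact test
#' is selected instead whenever any expected cell is below 5 (the choice is
#' logged via `message()`).
#'
#' @param t An [allele_table()].
#' @param test `"chisq"`, `"fisher"`, or `"auto"` (default; chi-square
#'   unless an expected cell < 5).
#' @param haldane Add 0.5 to every cell before forming the odds ratio.
#' @return A list of class `"af_comparison"`: `odds_ratio`, `p_raw`,
#'   `p_adj` (NA until [adjust_pvalues()]), `test`, `statistic`.
#' @export
compare_af <- function(t, test = c("auto", "chisq", "fisher"),
                       haldane = FALSE) {
  stopifnot(inherits(t, "allele_table"))
  test <- match.arg(test)
  m <- matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE)
  if (test == "auto") {
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    test <- if (any(expected < 5)) "fisher" else "chisq"
    if (test == "fisher") {
      message("expected cell < 5: using Fisher's exact test")
    }
  }
  or <- odds_ratio_2x2(t$a, t$b, t$c, t$d, haldane = haldane)
  if (test == "chisq") {
    ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    p <- ht$p.value
    stat <- unname(ht$statistic)
  } else {
    p <- stats::fisher.test(m)$p.value
    stat <- NA_real_
  }
  structure(list(odds_ratio = or, p_raw = p, p_adj = NA_real_,
                 test = test, statistic = stat),
            class = "af_comparison")
}

#' Sample odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)` with the zero-cell conventions used throughout: `Inf` when
#' the second cohort has no alternate alleles but the first does, `0` in
#' the mirrored case, `NaN` when both alt cells are empty.
#'
#' @param a,b,c,d Cell counts.
#' @param haldane Add 0.5 to every cell first (Haldane-Anscombe).
#' @return The odds ratio.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, haldane = FALSE) {
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  if (c == 0 && a > 0) return(Inf)
  if (a == 0 && c > 0) return(0)
  if (a == 0 && c == 0) return(NaN)
  (a * d) / (b * c)
}

#' Bonferroni adjustment of p-values
#'
#' Each p-value multiplied by the family size, capped at 1; order
#' preserved. Delegates to [stats::p.adjust()].
#'
#' @param ps Numeric vector of p-values in `[0, 1]`.
#' @param method Adjustment strategy (only `"bonferroni"` is offered).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(ps, method = "bonferroni") {
  method <- match.arg(method)
  if (any(ps < 0 | ps > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(ps, method = method)
}

#' Total allele frequency of a protein domain
#'
#' Sums the allele frequencies of every variant annotated to the given
#' protein domain — the per-domain pathogenic burden used to compare where
#' in the protein a population's pathogenic alleles concentrate.
#'
#' @param entries An [allele_counts()] table.
#' @param variants A [variant_table()] carrying the `domain` annotation for
#'   every entry.
#' @param domain Domain label (`"TMD1"`, `"NBD1"`, `"R"`, `"TMD2"`,
#'   `"NBD2"`, or `"none"`).
#' @return The summed allele frequency (0 when no variant is in the domain).
#' @export
domain_af_total <- function(entries, variants, domain) {
  stopifnot(inherits(variants, "variant_table"))
  missing_keys <- setdiff(entries$key, variants$key)
  if (length(missing_keys) > 0L) {
    stop("unknown variant key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  dom <- variants$domain[match(entries$key, variants$key)]
  sum(af_of(entries)[dom == domain])
}

#' Compare prevalence estimates under two screening panels
#'
#' Panel B is a restriction of panel A (it captures a subset of the
#' detected pathogenic alleles: `x_b <= x_a`). Both affected frequencies
#' are estimated by the Bayesian framework ([estimate_method3()]) on the
#' same allele denominator, summarised by their ratio, with significance
#' from a two-proportion Pearson chi-square on `x_a` vs `x_b` out of `n`
#' (a documented default; see the methods vignette).
#'
#' @param x_a,x_b Pathogenic allele counts captured by each panel,
#'   `0 <= x_b <= x_a <= n`.
#' @param n Total allele count.
#' @param prior A [bayes_prior()].
#' @param level Interval coverage for the per-panel estimates.
#' @return A list of class `"panel_comparison"`: `estimate_a`,
#'   `estimate_b`, `odds_ratio` (`phi_a / phi_b`), `p_value`.
#' @export
compare_panel_estimates <- function(x_a, x_b, n, prior = bayes_prior(),
                                    level = 0.95) {
  if (!(0 <= x_b && x_b <= x_a && x_a <= n)) {
    stop("need 0 <= x_b <= x_a <= n (panel B restricts panel A)",
         call. = FALSE)
  }
  est_a <- estimate_method3(x_a, n, prior, level)
  est_b <- estimate_method3(x_b, n, prior, level)
  if (x_b == 0) {
    warning("panel B captures no pathogenic alleles; odds ratio is infinite")
    or <- Inf
  } else {
    or <- est_a$phi / est_b$phi
  }
  m <- matrix(c(x_a, n - x_a, x_b, n - x_b), nrow = 2, byrow = TRUE)
  p <- if (x_a == x_b) 1 else
    suppressWarnings(stats::chisq.test(m, correct = FALSE))$p.value
  structure(list(estimate_a = est_a, estimate_b = est_b,
                 odds_ratio = or, p_value = p),
            class = "panel_comparison")
}

#' @export
print.panel_comparison <- function(x, ...) {
  cat("Panel comparison: ", reciprocal_render(x$estimate_a$phi), " vs ",
      reciprocal_render(x$estimate_b$phi), ", OR = ",
      signif(x$odds_ratio, 3), ", P = ", signif(x$p_value, 2), "\n", sep = "")
  invisible(x)
}
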