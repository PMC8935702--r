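---
title: "Estimating recessive-disease prevalence and comparing CFTR genetic spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating recessive-disease prevalence and comparing CFTR genetic spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cftrspectrum)
```

# The problem

Cystic fibrosis (CF) is an autosomal recessive disease caused by pathogenic
variants in the *CFTR* gene. In populations without newborn CF screening,
prevalence must be estimated indirectly: large diagnostic exome-sequencing
cohorts reveal how many individuals are *carriers* — heterozygous for a
pathogenic or likely-pathogenic (P/LP) variant — and from the carrier
frequency one can project how often two carrier parents will produce an
affected child. This package implements that projection three ways, compares
carrier-screening panels by how much of a population's pathogenic-allele
spectrum they capture, tests cross-population allele-frequency differences,
and summarises phased haplotype structure around the gene, including the
joint two-SNP genotype backgrounds on which founder mutations ride.

All computations run from summary counts (cohort totals and carrier
tallies), flat allele-count tables, and phased VCFs — no raw sequencing data
is required — and a seeded generator produces synthetic cohorts with the
statistical structure the estimators assume, so the entire pipeline is
testable at desk scale.

# The three prevalence estimators

Let $N$ be the number of screened individuals, $C$ the heterozygous P/LP
carriers among them, and $q$ the pooled pathogenic allele frequency. Under
Hardy–Weinberg equilibrium (HWE) the affected frequency (prevalence at
birth) is $\varphi = q^2$.

**Method 1 — carrier frequency.** A random couple is carrier × carrier with
probability $(C/N)^2$, and a quarter of their children are affected:
$$\varphi_1 = \frac{1}{4}\left(\frac{C}{N}\right)^2 .$$

**Method 2 — gender-stratified (permutation-and-combination).** A couple
pairs one male and one female, so the couple risk uses the gender-specific
carrier frequencies:
$$\varphi_2 = \frac{1}{4}\,\frac{C_m}{N_m}\,\frac{C_f}{N_f}.$$
The two methods coincide exactly when carriers split proportionally between
the strata; method 2 refuses to run on an empty stratum rather than
silently falling back.

**Method 3 — Bayesian framework.** Treat the pathogenic allele count $x$
among $n$ total alleles as binomial in $q$ with a conjugate
$\mathrm{Beta}(\alpha_0, \beta_0)$ prior, giving the posterior
$q \mid x \sim \mathrm{Beta}(x+\alpha_0,\; n-x+\beta_0)$. The point
estimate squares the posterior mean,
$$\varphi_3 = \left(\frac{x+\alpha_0}{n+\alpha_0+\beta_0}\right)^2 ,$$
and the 95% interval squares the equal-tailed posterior quantiles of $q$ —
valid because $q \mapsto q^2$ is monotone on $[0,1]$. For carrier-count
cohorts, $x = C$ and $n = 2N$: each carrier contributes exactly one
pathogenic allele, the standard assumption for a disease-free cohort in
which no individual carries two pathogenic variants (individual-level input
can override it).

## Parameter choices

* **Prior** — default Jeffreys, $\alpha_0=\beta_0=0.5$. It is the standard
  objective prior for a binomial proportion, adds half a pseudo-count to
  each allele class, and at these cohort sizes ($n \approx 2\times10^4$ to
  $4\times10^4$) moves the estimate by well under 0.5%. Both pseudo-counts
  are exposed in `bayes_prior()`.
* **Point summary** — the posterior *mean* of $q$, squared. The posterior
  median and mode are available behind `point =` in `estimate_method3()`;
  at these counts all three agree to three significant digits.
* **Interval** — equal-tailed quantiles, not highest-posterior-density: the
  equal-tailed form is what screening reports conventionally print and is
  invariant under the monotone $q^2$ transform.
* **Coverage level** — 0.95 by default, configurable via `level`.

Frequencies are displayed as rounded reciprocals ("1/144,469"); rounding is
half away from zero. Averages of several estimates are taken on the
frequency scale, never on reciprocals.

## What the estimators assume

All three assume random mating, HWE, complete detection of the panel's
variants, and no more than one pathogenic variant per screened individual.
Diagnostic (patient-ascertained) cohorts can violate HWE; the estimators do
not correct for that, which is precisely why the synthetic generator draws
under HWE — it tests the estimators under their own assumptions, with an
explicit knob to break them.

# Screening-panel comparison

A screening panel is a named set of variant keys (`chrom:pos:ref:alt`).
Restricting a cohort's per-variant carrier tally to a panel
(`carriers_in_panel()`) yields the pathogenic allele count that panel would
have detected; `compare_panel_estimates()` re-estimates $\varphi$ under two
nested panels on the same allele denominator and summarises the distortion
as the ratio $\varphi_A/\varphi_B$. Panels that miss population-specific
alleles can understate prevalence several-fold.

The significance test for the difference between two panel-restricted
estimates is a genuine design choice — there is no canonical test for the
difference of two squared posterior means. We use a two-proportion Pearson
chi-square on the captured allele counts ($x_A$ vs $x_B$ out of $n$),
document it as such, and make no claim that it reproduces any particular
published panel-comparison p-value.

# Allele-frequency comparison

Per-variant cross-cohort comparison builds the 2×2 allele-count table
(alt/ref × cohort) and reports the sample odds ratio with a Pearson
chi-square p-value (no continuity correction). With `test = "auto"` (the
default) Fisher's exact test is selected whenever any expected cell is
below 5, and the switch is logged — rare pathogenic alleles against a large
reference population routinely produce such cells. Zero-cell odds ratios
are reported as `Inf`/`0` by convention; a Haldane–Anscombe +0.5 correction
is available for users needing finite values. Multiple testing is adjusted
by Bonferroni (`adjust_pvalues()`, delegating to `stats::p.adjust`);
the significance threshold used for reporting is the caller's, not
hard-coded. Protein-domain burden (`domain_af_total()`) sums per-variant
AFs within a domain annotation (TMD1, NBD1, R, TMD2, NBD2, none), and the
per-domain totals partition the overall AF sum.

# Haplotype structure and founder backgrounds

The haplotype module consumes phasing, it never computes it: input VCFs
must use the phased `|` genotype separator, and any `/` aborts with the
offending sample and position. Haplotype-block boundaries are likewise
inputs (plink `.blocks.det` files), since block detection belongs to
upstream tooling.

* **SNP filter** — MAF ≥ 0.01 and HWE exact-test p ≥ 0.001, both
  inclusive; these are the conventional pre-phasing filters for block
  analysis. The HWE test is the exact conditional test (probability-sum
  form) computed by the standard recurrence over heterozygote counts, so it
  is stable at any cohort size; the test suite checks it against full
  enumeration for every genotype table of size ≤ 30.
* **Block spectra** — per-block haplotype counts over all $2N$
  chromosomes; the top-5 classes are kept and the rest merged into
  "other", with rank-5 ties broken lexicographically on the haplotype
  string so results are deterministic. Spectra are compared across cohorts
  by Pearson chi-square over the union of categories.
* **Combined share** — concatenating the per-block strings gives the
  modal cross-block haplotype share, a diversity summary bounded above by
  each block's own top share.
* **Founder association** — at the two exonic tag SNPs rs213950
  (c.1408G>A, alleles G/A) and rs1042077 (c.2562T>G, alleles T/G), each
  haplotype carries a joint label such as `A-G` or `A-T`. For each label,
  a 2×2 table of P/LP-carrying vs non-carrying haplotypes with vs without
  the label is tested by two-sided Fisher's exact test; the chi-square /
  Fisher split (spectra by chi-square, the 2×2 carrier association by
  Fisher) follows the convention of keeping the exact test for the sparse
  carrier margin.

# The synthetic-cohort generator

`simulate_cohort()` draws gender as Bernoulli(`male_fraction`) and, per
variant, genotypes under HWE at the configured allele frequency —
conditioned on *not* homozygous-affected by default, mirroring the
exclusion of diagnosed patients from screening cohorts
(`exclude_affected = FALSE` restores plain HWE draws).
`simulate_phased_cohort()` gives each individual two independent draws from
an explicit haplotype pool; when a pathogenic background is configured,
per-haplotype P/LP flags are planted so that the odds of carrying a flag on
the named background versus any other equal the configured odds ratio while
the marginal flag rate is preserved exactly (the off-background rate is
solved by root finding). One config seed drives a private RNG stream, so
every fixture is bit-identical across runs and the ambient RNG state is
never touched.

The default two-SNP pool sets the `A-G` background frequency to 0.425 and
`A-T` to 0.010 — the reported East-Asian-cohort values for those
backgrounds — while the split of the remaining mass between `G-T` (0.400)
and `G-G` (0.165) is not published anywhere and is a stylised choice made
once; it affects only the background-composition of simulations, not any
estimator.

What the generator deliberately does **not** emulate: linkage beyond the
explicit pool (no recombination or LD decay), demographic structure or
relatedness, genotyping error, ascertainment bias, or departure from HWE
unless `exclude_affected` (or a user-supplied pool) introduces it. Passing
tests on synthetic cohorts therefore demonstrate correctness of the
estimators under their stated assumptions — not robustness to the
ascertainment quirks of real diagnostic cohorts.

# Numerical and degenerate-input policy

* Validation is loud: inconsistent cohort counts, duplicate variant keys,
  unknown pathogenicity classes, `AC > AN`, unphased genotypes and empty
  gender strata are all construction- or read-time errors, never silent
  repairs.
* An empty panel intersection is a valid, flagged result; a panel-restricted
  allele count of zero yields an infinite ratio with a warning.
* Beta quantiles come from `stats::qbeta`; the chi-square and Fisher tests
  are `stats::chisq.test(correct = FALSE)` and `stats::fisher.test`.
* Reciprocal rendering rounds half away from zero; comparisons should be
  made on frequencies, with reciprocals treated as display.

# Scale of the bundled verification

The test suite exercises the pipeline at sizes chosen to make sampling
error negligible relative to the tolerances while keeping a desk-scale
footprint: interval coverage is measured over 500 simulated cohorts of
50,000 individuals at $q = 0.00263$ (the package's own check that the 95%
interval covers $q^2$ 93–97% of the time; the analytic coverage at this
design is 95.2%); pool recovery uses 5,000 individuals; the founder
association is recovered at a 20,905-individual exome scale with a planted
odds ratio of 2.25. The HWE exact test is verified against enumeration for
all $\binom{n+2}{2}$ genotype tables up to $n = 30$.

# Known limitations

* Carrier-based allele counting assumes at most one P/LP allele per
  individual; cohorts with appreciable compound heterozygosity need
  individual-level genotypes.
* No penetrance modelling, de-novo rate, or consanguinity adjustment.
* Coordinates are taken as given (hg19 conventions for the bundled tag
  SNPs); there is no liftover.
* The haplotype module analyses the blocks it is given; it performs no LD
  computation or block inference.
* Patient-ascertained cohorts can depart from HWE, biasing all three
  estimators in ways the package measures (via the generator's knobs) but
  does not correct.
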