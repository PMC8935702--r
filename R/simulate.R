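# evaluate expr under a private RNG stream, restoring ambient state after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' The CFTR exonic tag-SNP pair
#'
#' The two exonic SNPs used for the joint-genotype analysis: rs213950
#' (c.1408G>A, V470M; alleles G/A) and rs1042077 (c.2562T>G; alleles T/G).
#' Joint labels are written `"<rs213950 allele>-<rs1042077 allele>"`:
#' `"A-T"` marks the F508del founder background, `"A-G"` the G970D
#' background. Positions are hg19 and serve as coordinates for synthetic
#' fixtures.
#'
#' @return A data.frame usable as the `snps` slot of a [phased_cohort()].
#' @export
cftr_tag_snps <- function() {
  data.frame(id = c("rs213950", "rs1042077"),
             chrom = c("7", "7"),
             pos = c(117199644L, 117227792L),
             ref = c("G", "T"),
             alt = c("A", "G"),
             stringsAsFactors = FALSE)
}

#' Default joint-genotype haplotype pool
#'
#' A stylised East-Asian-like pool over the two tag SNPs of
#' [cftr_tag_snps()]: the `"A-G"` and `"A-T"` frequencies (0.425, 0.010)
#' follow the reported cohort allele frequencies of those backgrounds; the
#' split of the remainder between `"G-T"` and `"G-G"` is a modelling
#' choice (see the methods vignette).
#'
#' @return Named numeric vector of haplotype frequencies summing to 1.
#' @export
cftr_default_pool <- function() {
  c("A-G" = 0.425, "A-T" = 0.010, "G-T" = 0.400, "G-G" = 0.165)
}

#' Simulation configuration
#'
#' Parameters of the synthetic-cohort generator. Genotypes are drawn under
#' Hardy-Weinberg equilibrium at the configured allele frequencies — the
#' assumption the prevalence estimators make — with homozygous-affected
#' individuals excluded by default (mirroring the exclusion of diagnosed
#' patients from a screening cohort). Haplotypes are drawn independently
#' from an explicit pool; an optional enrichment knob plants
#' pathogenic-allele flags preferentially on one haplotype background with
#' a configured odds ratio.
#'
#' @param n_individuals Cohort size.
#' @param male_fraction Probability an individual is male (default 0.5).
#' @param variant_afs Named numeric vector, variant key -> pathogenic
#'   allele frequency; all in `[0, 0.5]`.
#' @param haplotype_pool Named numeric vector, haplotype label (alleles
#'   joined by `"-"`) -> frequency; must sum to 1 within 1e-9.
#' @param snps SNP definition table (as in [phased_cohort()]) for the
#'   pool's positions; defaults to [cftr_tag_snps()] when the pool has
#'   two-allele labels.
#' @param plp_background Optional `list(label =, or =)`: the haplotype
#'   label pathogenic flags are enriched on and the enrichment odds ratio
#'   (`> 0`; `or = 1` plants flags independently of background).
#' @param plp_rate Marginal fraction of haplotypes flagged as carrying a
#'   pathogenic variant (default 0: no flags).
#' @param exclude_affected Drop homozygous-affected genotypes from cohort
#'   draws (default `TRUE`).
#' @param seed Integer seed; every generator call is deterministic given
#'   the config.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_individuals,
                              male_fraction = 0.5,
                              variant_afs = NULL,
                              haplotype_pool = NULL,
                              snps = NULL,
                              plp_background = NULL,
                              plp_rate = 0,
                              exclude_affected = TRUE,
                              seed = 1L) {
  stopifnot(n_individuals >= 1, male_fraction >= 0, male_fraction <= 1,
            plp_rate >= 0, plp_rate < 1)
  if (!is.null(variant_afs)) {
    if (is.null(names(variant_afs))) {
      stop("variant_afs must be named by variant key", call. = FALSE)
    }
    if (any(variant_afs < 0 | variant_afs > 0.5)) {
      stop("pathogenic allele frequencies must lie in [0, 0.5]", call. = FALSE)
    }
  }
  if (!is.null(haplotype_pool)) {
    if (is.null(names(haplotype_pool)) || length(haplotype_pool) == 0L) {
      stop("haplotype_pool must be a named frequency vector", call. = FALSE)
    }
    if (abs(sum(haplotype_pool) - 1) > 1e-9) {
      stop("haplotype pool frequencies must sum to 1", call. = FALSE)
    }
    if (is.null(snps)) snps <- cftr_tag_snps()
    n_sites <- lengths(strsplit(names(haplotype_pool), "-", fixed = TRUE))
    if (any(n_sites != nrow(snps))) {
      stop("pool labels must have one allele per SNP (joined by '-')",
           call. = FALSE)
    }
  }
  if (!is.null(plp_background)) {
    stopifnot(is.list(plp_background),
              all(c("label", "or") %in% names(plp_background)),
              plp_background$or > 0)
    if (!is.null(haplotype_pool) &&
        !plp_background$label %in% names(haplotype_pool)) {
      stop("plp_background label '", plp_background$label,
           "' is not in the haplotype pool", call. = FALSE)
    }
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 male_fraction = male_fraction,
                 variant_afs = variant_afs,
                 haplotype_pool = haplotype_pool,
                 snps = snps,
                 plp_background = plp_background,
                 plp_rate = plp_rate,
                 exclude_affected = exclude_affected,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a carrier-count cohort
#'
#' Draws gender and per-variant genotypes for `n_individuals` under
#' Hardy-Weinberg equilibrium at the configured allele frequencies
#' (conditioned on not homozygous-affected when `exclude_affected`), and
#' tallies heterozygous carriers by gender. An individual heterozygous for
#' at least one configured variant counts as one carrier.
#'
#' @param cfg A [simulation_config()] with `variant_afs` set.
#' @return A list: `counts` (a [cohort_counts()]) and `carriers` (named
#'   vector, variant key -> heterozygous-carrier count).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(cfg$variant_afs)) {
    stop("config has no variant_afs to simulate", call. = FALSE)
  }
  with_seed(cfg$seed, {
    n <- cfg$n_individuals
    male <- stats::runif(n) < cfg$male_fraction
    is_carrier <- logical(n)
    per_variant <- vapply(cfg$variant_afs, function(q) {
      probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
      if (cfg$exclude_affected) {
        probs[3] <- 0
        probs <- probs / sum(probs)
      }
      gt <- sample.int(3L, n, replace = TRUE, prob = probs) - 1L
      het <- gt == 1L
      is_carrier <<- is_carrier | het
      sum(het)
    }, numeric(1))
    counts <- cohort_counts(N = n,
                            N_male = sum(male), N_female = sum(!male),
                            C = sum(is_carrier),
                            C_male = sum(is_carrier & male),
                            C_female = sum(is_carrier & !male))
    list(counts = counts, carriers = per_variant)
  })
}

# marginal flag rate r = f*p1 + (1-f)*p0 with odds(p1) = or * odds(p0);
# solve for the off-background rate p0
solve_background_rates <- function(rate, f_background, or) {
  p1_of <- function(p0) or * p0 / (1 - p0 + or * p0)
  if (or == 1 || f_background %in% c(0, 1)) {
    p0 <- rate
  } else {
    p0 <- stats::uniroot(function(p0) {
      f_background * p1_of(p0) + (1 - f_background) * p0 - rate
    }, c(0, 1 - 1e-12), tol = 1e-14)$root
  }
  c(p_background = p1_of(p0), p_other = p0)
}

#' Simulate a phased cohort from an explicit haplotype pool
#'
#' Each individual receives two independent draws from the configured pool
#' (no linkage beyond the pool structure itself). When `plp_rate > 0`,
#' pathogenic-allele flags are planted per haplotype; with a
#' `plp_background`, the flag probability on the named background is set
#' so that its odds relative to other backgrounds equal the configured
#' odds ratio while preserving the marginal rate.
#'
#' @param cfg A [simulation_config()] with `haplotype_pool` set.
#' @return A [phased_cohort()].
#' @export
simulate_phased_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  pool <- cfg$haplotype_pool
  if (is.null(pool)) {
    stop("config has no haplotype_pool to simulate", call. = FALSE)
  }
  snps <- cfg$snps
  pool_alleles <- do.call(rbind, strsplit(names(pool), "-", fixed = TRUE))
  for (j in seq_len(nrow(snps))) {
    bad <- !pool_alleles[, j] %in% c(snps$ref[j], snps$alt[j])
    if (any(bad)) {
      stop("pool allele(s) ", paste(unique(pool_alleles[bad, j]), collapse = ","),
           " not in {ref, alt} of SNP ", snps$id[j], call. = FALSE)
    }
  }
  with_seed(cfg$seed, {
    n_hap <- 2L * cfg$n_individuals
    draw <- sample.int(length(pool), n_hap, replace = TRUE, prob = pool)
    alleles <- matrix(0L, nrow = n_hap, ncol = nrow(snps))
    for (j in seq_len(nrow(snps))) {
      alleles[, j] <- as.integer(pool_alleles[draw, j] == snps$alt[j])
    }
    flags <- NULL
    if (cfg$plp_rate > 0) {
      if (is.null(cfg$plp_background)) {
        flags <- stats::runif(n_hap) < cfg$plp_rate
      } else {
        bg <- names(pool)[draw] == cfg$plp_background$label
        rates <- solve_background_rates(cfg$plp_rate,
                                        unname(pool[cfg$plp_background$label]),
                                        cfg$plp_background$or)
        p <- ifelse(bg, rates["p_background"], rates["p_other"])
        flags <- stats::runif(n_hap) < p
      }
    }
    phased_cohort(snps, alleles, plp_flags = flags)
  })
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits, for the configured simulation, every flat-file format the
#' pipeline consumes — cohort-counts TSV, allele-count TSV, panel TSV and
#' (when a haplotype pool is configured) a phased VCF — such that reading
#' them back through the io functions reproduces the in-memory objects.
#' Output is plain text and byte-identical across runs at a fixed seed.
#'
#' @param cfg A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture_bundle <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(cfg$variant_afs)) {
    sim <- simulate_cohort(cfg)
    p <- file.path(outdir, "cohort_counts.tsv")
    write_cohort_counts_tsv(list(simulated = sim$counts), p)
    paths["cohort_counts"] <- p

    keys <- names(cfg$variant_afs)
    ac <- allele_counts(keys, AC = unname(sim$carriers),
                        AN = 2 * cfg$n_individuals, population = "simulated")
    p <- file.path(outdir, "allele_counts.tsv")
    write_allele_counts_tsv(ac, p)
    paths["allele_counts"] <- p

    kd <- parse_variant_key(keys)
    vt <- variant_table(kd$chrom, kd$pos, kd$ref, kd$alt,
                        hgvs_c = keys, legacy = keys,
                        pclass = "P", domain = "none")
    p <- file.path(outdir, "panel.tsv")
    write_panel_tsv(vt, p)
    paths["panel"] <- p
  }
  if (!is.null(cfg$haplotype_pool)) {
    phased <- simulate_phased_cohort(cfg)
    p <- file.path(outdir, "phased.vcf")
    write_phased_vcf(phased, p)
    paths["phased_vcf"] <- p
  }
  invisible(paths)
}
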