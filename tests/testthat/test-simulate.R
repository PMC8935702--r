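test_that("config invariants are enforced", {
  expect_error(simulation_config(100, variant_afs = c(v1 = 0.6)),
               "\\[0, 0.5\\]")
  expect_error(simulation_config(100, variant_afs = 0.1), "named")
  expect_error(simulation_config(100, haplotype_pool = c("A-G" = 0.5,
                                                         "G-T" = 0.4)),
               "sum to 1")
  expect_error(simulation_config(100, haplotype_pool = c("A-G" = 0.5,
                                                         "G-T" = 0.5),
                                 plp_background = list(label = "A-T", or = 2)),
               "not in the haplotype pool")
  expect_error(simulation_config(100, male_fraction = 1.2))
})

test_that("cohort draws respect degenerate parameter settings", {
  cfg0 <- simulation_config(500, variant_afs = c("1:1:A:G" = 0), seed = 3)
  expect_equal(simulate_cohort(cfg0)$counts$C, 0)

  cfg_m <- simulation_config(500, male_fraction = 1,
                             variant_afs = c("1:1:A:G" = 0.05), seed = 3)
  res <- simulate_cohort(cfg_m)
  expect_equal(res$counts$C_female, 0)
  expect_equal(res$counts$N_female, 0)
})

test_that("observed carrier frequency matches the binomial expectation", {
  q <- 0.00263
  n <- 50000
  set.seed(202)
  obs <- vapply(1:200, function(i) {
    cfg <- simulation_config(n, variant_afs = c("1:1:A:G" = q),
                             exclude_affected = FALSE, seed = 1000 + i)
    simulate_cohort(cfg)$counts$C / n
  }, numeric(1))
  p_het <- 2 * q * (1 - q)
  se_mean <- sqrt(p_het * (1 - p_het) / n) / sqrt(200)
  expect_lt(abs(mean(obs) - p_het), 3 * se_mean)
})

test_that("prevalence estimators recover q^2 on large simulated cohorts", {
  q <- 0.005
  n <- 5e5
  phis <- vapply(1:50, function(i) {
    cfg <- simulation_config(n, variant_afs = c("1:1:A:G" = q),
                             exclude_affected = FALSE, seed = 7000 + i)
    sim <- simulate_cohort(cfg)
    c(estimate_method1(sim$counts)$phi,
      estimate_method2(sim$counts)$phi,
      estimate_method3(sim$counts$C, 2 * n)$phi)
  }, numeric(3))
  # carriers are heterozygotes, so q is estimated via C/(2N) ~ q(1-q);
  # at q = 0.005 that bias is ~1%, well inside the 10% recovery band
  for (m in 1:3) {
    expect_lt(abs(mean(phis[m, ]) - q^2) / q^2, 0.10)
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- simulation_config(300, variant_afs = c("1:1:A:G" = 0.01,
                                                "1:2:C:T" = 0.02),
                           haplotype_pool = cftr_default_pool(),
                           plp_rate = 0.01, seed = 99)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a, b)
  pa <- simulate_phased_cohort(cfg); pb <- simulate_phased_cohort(cfg)
  expect_identical(pa, pb)
  # and the generator never disturbs the ambient RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_cohort(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("phased draws recover the configured pool frequencies", {
  pool <- c("G-T" = 0.5, "A-G" = 0.3, "A-T" = 0.2)
  cfg <- simulation_config(5000, haplotype_pool = pool, seed = 17)
  pc <- simulate_phased_cohort(cfg)
  d <- haplotype_frequencies(pc, c("rs213950", "rs1042077"))
  got <- hap_freqs(d)[c("GT", "AG", "AT")]
  for (i in 1:3) {
    se <- sqrt(pool[i] * (1 - pool[i]) / 10000)
    expect_lt(abs(got[i] - pool[i]), 3 * se)
  }
  # single-haplotype pool: every chromosome identical
  mono <- simulation_config(100, haplotype_pool = c("A-G" = 1), seed = 1)
  expect_equal(combined_top_share(simulate_phased_cohort(mono),
                                  list(c("rs213950", "rs1042077"))), 1)
})

test_that("background enrichment hits the requested marginal rate and odds", {
  rate <- 0.02
  cfg <- simulation_config(50000, haplotype_pool = cftr_default_pool(),
                           plp_background = list(label = "A-G", or = 3),
                           plp_rate = rate, seed = 23)
  pc <- simulate_phased_cohort(cfg)
  expect_lt(abs(mean(pc$plp_flags) - rate),
            3 * sqrt(rate * (1 - rate) / 1e5))
  res <- joint_genotype_association(pc, "rs213950", "rs1042077")
  or_ag <- res$odds_ratio[res$label == "A-G"]
  expect_gt(or_ag, 2)
  expect_lt(or_ag, 4.5)
})

test_that("fixture bundles round-trip through the io module byte-identically", {
  cfg <- simulation_config(150, variant_afs = c("7:117199644:G:A" = 0.02,
                                                "7:117230454:G:A" = 0.05),
                           haplotype_pool = cftr_default_pool(),
                           plp_rate = 0.01, seed = 41)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  p1 <- write_fixture_bundle(cfg, d1)
  p2 <- write_fixture_bundle(cfg, d2)
  for (nm in names(p1)) {                         # determinism
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
  # counts TSV round-trips to the same object
  sim <- simulate_cohort(cfg)
  back <- read_cohort_counts_tsv(p1[["cohort_counts"]])$simulated
  expect_equal(back, sim$counts)
  # allele counts round-trip
  ac <- read_allele_counts_tsv(p1[["allele_counts"]], "simulated")
  expect_equal(unname(stats::setNames(ac$AC, ac$key)[names(cfg$variant_afs)]),
               unname(sim$carriers))
  # panel round-trips
  vt <- read_panel_tsv(p1[["panel"]])
  expect_setequal(vt$key, names(cfg$variant_afs))
  # phased VCF round-trips to the same cohort (modulo the flags,
  # which a VCF does not carry)
  pc <- simulate_phased_cohort(cfg)
  pc_back <- read_phased_vcf(p1[["phased_vcf"]])
  expect_equal(pc_back$alleles, pc$alleles, ignore_attr = TRUE)
  expect_equal(pc_back$snps$id, pc$snps$id)
})
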