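test_that("HWE exact test handles monomorphic and extreme-heterozygote inputs", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 100), 1)
  expect_lt(hwe_exact_test(0, 100, 0), 1e-20)   # total heterozygote excess
  expect_gt(hwe_exact_test(57, 14, 50), 0)      # deficit, but a valid p
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), "nonnegative")
})

test_that("HWE exact test matches enumeration on a sample of small tables", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:30, 1)
    split <- rmultinom(1, n, c(1, 1, 1))
    expect_equal(hwe_exact_test(split[1], split[2], split[3]),
                 hwe_enum_oracle(split[1], split[2], split[3]),
                 tolerance = 1e-12)
  }
})

test_that("SNP filtering applies inclusive MAF and HWE thresholds", {
  # 100 individuals; build SNPs with planted properties
  set.seed(5)
  n <- 100
  geno_to_hap <- function(gt) {
    # deterministic phase: alt allele on the first haplotype of hets
    h1 <- as.integer(gt >= 1)
    h2 <- as.integer(gt == 2)
    as.vector(rbind(h1, h2))
  }
  gt_common <- rbinom(n, 2, 0.3)                  # passes both filters
  gt_rare <- c(1, rep(0, n - 1))                  # MAF 0.005 < 0.01
  gt_boundary <- c(1, 1, rep(0, n - 2))           # MAF exactly 0.01
  gt_hwe_fail <- rep(1, n)                        # all-het, HWE p ~ 0
  alleles <- cbind(geno_to_hap(gt_common), geno_to_hap(gt_rare),
                   geno_to_hap(gt_boundary), geno_to_hap(gt_hwe_fail))
  snps <- data.frame(id = c("ok", "rare", "boundary", "hwe_fail"),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  cohort <- phased_cohort(snps, alleles)
  kept <- filter_snps(cohort)
  expect_setequal(kept$snps$id, c("ok", "boundary"))

  # survivor set matches a brute-force per-SNP check
  brute <- sapply(1:4, function(j) {
    af <- mean(alleles[, j]); maf <- min(af, 1 - af)
    gt <- alleles[seq(1, 2 * n, 2), j] + alleles[seq(2, 2 * n, 2), j]
    maf >= 0.01 && hwe_enum_oracle(sum(gt == 0), sum(gt == 1), sum(gt == 2)) >= 0.001
  })
  expect_equal(kept$snps$id, snps$id[brute])

  expect_warning(filter_snps(cohort, maf_min = 0.9), "all SNPs removed")
})

test_that("haplotype frequencies count allele strings over the block", {
  all_ref <- phased_cohort(data.frame(id = c("s1", "s2"), ref = c("A", "C"),
                                      alt = c("G", "T")),
                           matrix(0L, nrow = 4, ncol = 2))
  d <- haplotype_frequencies(all_ref, c("s1", "s2"))
  expect_equal(unname(hap_freqs(d)), 1)
  expect_equal(names(d$counts), "AC")
  expect_equal(d$total, 4)

  d2 <- haplotype_frequencies(toy_phased(), c("s1", "s2"))
  expect_equal(sum(hap_freqs(d2)), 1)
  expect_equal(d2$total, 6)
  expect_error(haplotype_frequencies(toy_phased(), c("s1", "zz")), "unknown SNP")
})

test_that("top-k collapse conserves counts and breaks ties lexicographically", {
  d <- haplotype_distribution("b", c(AA = 10, AB = 5, BA = 3))
  expect_identical(collapse_top_k(d, 5), d)       # <= k classes: unchanged

  counts <- c(H1 = 40, H2 = 25, H3 = 12, H4 = 8, H5 = 6, H6 = 5, H7 = 4)
  cd <- collapse_top_k(haplotype_distribution("b", counts), 5)
  expect_length(cd$counts, 6)
  expect_equal(cd$total, sum(counts))             # conservation
  expect_equal(unname(cd$counts["other"]), 5 + 4)

  # tie at rank k: the lexicographically smaller string wins
  tied <- haplotype_distribution("b", c(ZZ = 5, AA = 5, MM = 9))
  kept <- collapse_top_k(tied, 2)
  expect_setequal(setdiff(names(kept$counts), "other"), c("MM", "AA"))
})

test_that("block-spectrum comparison is a symmetric chi-square over shared categories", {
  d1 <- haplotype_distribution("b1", c(AA = 50, AB = 30, BB = 20))
  expect_equal(compare_block_distributions(d1, d1), 1)

  d2 <- haplotype_distribution("b1", c(AA = 20, AB = 30, BB = 50))
  p12 <- compare_block_distributions(d1, d2)
  expect_equal(p12, compare_block_distributions(d2, d1))  # symmetry

  # disjoint supports at large counts: p ~ 0
  da <- haplotype_distribution("b1", c(AA = 500, AB = 500))
  db <- haplotype_distribution("b1", c(BA = 500, BB = 500))
  expect_lt(compare_block_distributions(da, db), 1e-100)

  # closed-form 2x2 check via the chi-square oracle
  dx <- haplotype_distribution("b1", c(H1 = 3, H2 = 7))
  dy <- haplotype_distribution("b1", c(H1 = 5, H2 = 5))
  expect_equal(compare_block_distributions(dx, dy),
               chisq_2x2_oracle(3, 7, 5, 5), tolerance = 1e-12)

  expect_error(compare_block_distributions(d1, haplotype_distribution("b2", c(AA = 1))),
               "different blocks")
  expect_error(compare_block_distributions(
    haplotype_distribution("b1", c(AA = 5)),
    haplotype_distribution("b1", c(AA = 9))), "one shared haplotype")
})

test_that("combined top share equals enumeration and is bounded by block tops", {
  tp <- toy_phased()
  blocks <- list(c("s1", "s2"), c("s3", "s4"))
  # hand enumeration over the six haplotypes: 0000 x3, 0011 x2, 1100 x1
  expect_equal(combined_top_share(tp, blocks), 3 / 6)
  # degenerate single block equals that block's top frequency
  d <- haplotype_frequencies(tp, c("s1", "s2"))
  expect_equal(combined_top_share(tp, list(c("s1", "s2"))),
               max(hap_freqs(d)))
  # bounded by the minimum per-block top share
  tops <- sapply(blocks, function(b) max(hap_freqs(haplotype_frequencies(tp, b))))
  expect_lte(combined_top_share(tp, blocks), min(tops))
  # all-identical haplotypes give share 1
  mono <- phased_cohort(data.frame(id = "s1", ref = "A", alt = "G"),
                        matrix(0L, 4, 1))
  expect_equal(combined_top_share(mono, list("s1")), 1)
  expect_error(combined_top_share(tp, list()), "no blocks")
  expect_error(combined_top_share(tp, list("s1", "s1")), "non-overlapping")
})

test_that("joint genotype association is Fisher-exact per label", {
  # flags planted exactly on the two 0011 haplotypes of the toy cohort
  tp <- toy_phased(plp_flags = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
  res <- joint_genotype_association(tp, "s3", "s4")
  expect_setequal(res$label, c("G-T", "A-T", "G-C", "A-C"))
  # the A-C background (alt-alt at s3,s4) holds both flagged haplotypes
  row <- res[res$label == "A-C", ]
  expect_equal(row$n_plp, 2)
  expect_equal(row$n_other, 0)
  expect_identical(row$odds_ratio, Inf)
  # every Fisher p matches the hypergeometric oracle
  for (i in seq_len(nrow(res))) {
    a <- res$n_plp[i]; c <- res$n_other[i]
    expect_equal(res$p_value[i], fisher_2x2_oracle(a, 2 - a, c, 4 - c),
                 tolerance = 1e-12)
  }
  expect_error(joint_genotype_association(toy_phased(), "s3", "s4"),
               "no P/LP")
  expect_error(joint_genotype_association(tp, "zz", "s4"), "not present")
})
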