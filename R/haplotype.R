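#' Phased cohort container
#'
#' Holds the output of statistical phasing: for each individual, two
#' haplotypes (allele sequences) over an ordered set of biallelic SNPs.
#' Alleles are stored as a 0/1 integer matrix (0 = ref, 1 = alt) with two
#' consecutive rows per individual, so a cohort of N individuals has 2N
#' haplotype rows. Optionally each haplotype carries a pathogenic-allele
#' flag (`plp_flags`): whether that chromosome also bears a pathogenic/
#' likely-pathogenic variant, the basis of the founder-background
#' association test.
#'
#' @param snps A data.frame with columns `id`, `ref`, `alt` (optionally
#'   `chrom`, `pos`), one row per SNP in matrix column order.
#' @param alleles Integer matrix of 0/1 values, `2N x nrow(snps)`.
#' @param plp_flags Optional logical vector of length `2N`.
#' @return An object of class `"phased_cohort"`.
#' @export
phased_cohort <- function(snps, alleles, plp_flags = NULL) {
  stopifnot(is.data.frame(snps), all(c("id", "ref", "alt") %in% names(snps)))
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != nrow(snps)) {
    stop("alleles matrix must have one column per SNP", call. = FALSE)
  }
  if (nrow(alleles) %% 2 != 0) {
    stop("haplotypes come in pairs: the row count must be even", call. = FALSE)
  }
  if (length(alleles) > 0 && !all(alleles %in% c(0L, 1L))) {
    stop("alleles must be coded 0 (ref) or 1 (alt)", call. = FALSE)
  }
  if (!is.null(plp_flags) && length(plp_flags) != nrow(alleles)) {
    stop("plp_flags must have one entry per haplotype", call. = FALSE)
  }
  storage.mode(alleles) <- "integer"
  structure(list(snps = snps, alleles = alleles, plp_flags = plp_flags),
            class = "phased_cohort")
}

#' @export
print.phased_cohort <- function(x, ...) {
  cat("Phased cohort:", nrow(x$alleles) / 2, "individuals,",
      nrow(x$snps), "SNPs")
  if (!is.null(x$plp_flags)) {
    cat(",", sum(x$plp_flags), "P/LP-carrying haplotypes")
  }
  cat("\n")
  invisible(x)
}

#' Number of individuals in a phased cohort
#' @param cohort A [phased_cohort()].
#' @return Integer count.
#' @export
n_individuals <- function(cohort) {
  stopifnot(inherits(cohort, "phased_cohort"))
  nrow(cohort$alleles) %/% 2L
}

# allele strings (base letters, concatenated) for a set of SNP columns
hap_strings <- function(cohort, snp_idx = seq_len(nrow(cohort$snps))) {
  if (length(snp_idx) == 0L) stop("no SNPs selected", call. = FALSE)
  bases <- vapply(snp_idx, function(j) {
    ifelse(cohort$alleles[, j] == 0L, cohort$snps$ref[j], cohort$snps$alt[j])
  }, character(nrow(cohort$alleles)))
  if (is.null(dim(bases))) bases <- matrix(bases, nrow = 1)
  apply(bases, 1, paste0, collapse = "")
}

#' Filter SNPs on minor allele frequency and Hardy-Weinberg equilibrium
#'
#' Retains exactly the SNPs with `MAF >= maf_min` (inclusive) whose
#' genotype counts pass the Hardy-Weinberg exact test at
#' `p >= hwe_min` — the standard pre-filter before haplotype-block
#' analysis. Haplotypes are re-projected onto the retained SNPs.
#'
#' @param cohort A [phased_cohort()].
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param hwe_min Minimum Hardy-Weinberg exact-test p-value (default 0.001).
#' @return The filtered `phased_cohort` (a warning is raised if every SNP
#'   is removed).
#' @export
filter_snps <- function(cohort, maf_min = 0.01, hwe_min = 0.001) {
  stopifnot(inherits(cohort, "phased_cohort"))
  n2 <- nrow(cohort$alleles)
  keep <- vapply(seq_len(nrow(cohort$snps)), function(j) {
    col <- cohort$alleles[, j]
    af <- sum(col) / n2
    maf <- min(af, 1 - af)
    if (maf < maf_min) return(FALSE)
    gt <- col[seq(1, n2, by = 2)] + col[seq(2, n2, by = 2)]
    hwe_exact_test(sum(gt == 0L), sum(gt == 1L), sum(gt == 2L)) >= hwe_min
  }, logical(1))
  if (!any(keep)) warning("all SNPs removed by the MAF/HWE filter")
  phased_cohort(cohort$snps[keep, , drop = FALSE],
                cohort$alleles[, keep, drop = FALSE],
                cohort$plp_flags)
}

#' Haplotype frequency distribution of a block
#'
#' Counts each distinct allele string over the block's SNPs across all 2N
#' haplotypes of the cohort.
#'
#' @param cohort A [phased_cohort()].
#' @param block_snps Ordered character vector of SNP ids forming the block;
#'   must all be present in the cohort.
#' @param block_id Label for the block (defaults to the SNP ids joined).
#' @return An object of class `"haplotype_distribution"` with fields
#'   `block_id`, `counts` (named, haplotype string -> allele count) and
#'   `total` (`= 2N`).
#' @export
haplotype_frequencies <- function(cohort, block_snps,
                                  block_id = paste(block_snps, collapse = "|")) {
  stopifnot(inherits(cohort, "phased_cohort"))
  idx <- match(block_snps, cohort$snps$id)
  if (anyNA(idx)) {
    stop("unknown SNP(s) in block: ",
         paste(block_snps[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  tab <- table(hap_strings(cohort, idx))
  haplotype_distribution(block_id,
                         stats::setNames(as.integer(tab), names(tab)))
}

#' @rdname haplotype_frequencies
#' @param counts Named integer vector, haplotype string -> allele count.
#' @export
haplotype_distribution <- function(block_id, counts) {
  if (length(counts) == 0L || is.null(names(counts))) {
    stop("counts must be a non-empty named vector", call. = FALSE)
  }
  if (any(counts < 0)) stop("haplotype counts must be nonnegative", call. = FALSE)
  structure(list(block_id = block_id, counts = counts, total = sum(counts)),
            class = "haplotype_distribution")
}

#' Haplotype frequencies of a distribution
#' @param d A `haplotype_distribution`.
#' @return Named numeric vector summing to 1.
#' @export
hap_freqs <- function(d) {
  stopifnot(inherits(d, "haplotype_distribution"))
  d$counts / d$total
}

#' @export
print.haplotype_distribution <- function(x, ...) {
  cat("Haplotype block '", x$block_id, "': ", length(x$counts),
      " haplotype(s), ", x$total, " alleles\n", sep = "")
  f <- sort(hap_freqs(x), decreasing = TRUE)
  print(round(utils::head(f, 10), 4))
  invisible(x)
}

#' Collapse a haplotype distribution to its top k classes
#'
#' Keeps the `k` most frequent haplotypes and merges the remainder into an
#' `"other"` category (the usual rendering of a block's frequency
#' spectrum). Ties at rank `k` are broken lexicographically on the
#' haplotype string, so the result is deterministic. Total counts are
#' conserved; a distribution with at most `k` classes is returned
#' unchanged.
#'
#' @param d A `haplotype_distribution`.
#' @param k Number of classes to keep (default 5).
#' @return A `haplotype_distribution` with at most `k + 1` classes.
#' @export
collapse_top_k <- function(d, k = 5) {
  stopifnot(inherits(d, "haplotype_distribution"), k >= 1)
  if (length(d$counts) <= k) return(d)
  ord <- order(-d$counts, names(d$counts))
  top <- ord[seq_len(k)]
  counts <- c(d$counts[top], other = sum(d$counts[ord[-seq_len(k)]]))
  haplotype_distribution(d$block_id, counts)
}

#' Compare two haplotype frequency spectra
#'
#' Pearson chi-square test (no continuity correction) on the 2 x K table
#' of haplotype counts over the union of both distributions' categories;
#' categories absent from both are dropped. Apply [collapse_top_k()]
#' consistently to both inputs beforehand if a collapsed comparison is
#' wanted.
#'
#' @param d1,d2 `haplotype_distribution` objects for the same block.
#' @return The chi-square p-value.
#' @export
compare_block_distributions <- function(d1, d2) {
  stopifnot(inherits(d1, "haplotype_distribution"),
            inherits(d2, "haplotype_distribution"))
  if (!identical(d1$block_id, d2$block_id)) {
    stop("distributions describe different blocks: '", d1$block_id,
         "' vs '", d2$block_id, "'", call. = FALSE)
  }
  cats <- union(names(d1$counts), names(d2$counts))
  m <- rbind(ifelse(is.na(match(cats, names(d1$counts))), 0,
                    d1$counts[match(cats, names(d1$counts))]),
             ifelse(is.na(match(cats, names(d2$counts))), 0,
                    d2$counts[match(cats, names(d2$counts))]))
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2L) {
    stop("only one shared haplotype category: test undefined", call. = FALSE)
  }
  suppressWarnings(stats::chisq.test(m, correct = FALSE))$p.value
}

#' Share of the modal cross-block haplotype
#'
#' Concatenates each haplotype's allele strings across several
#' (non-overlapping) blocks and returns the frequency of the most common
#' combined haplotype among all 2N chromosomes — a summary of overall
#' haplotype diversity (lower share = more diversity).
#'
#' @param cohort A [phased_cohort()].
#' @param blocks Non-empty list of SNP-id vectors, pairwise disjoint
#'   subsets of the cohort's SNPs.
#' @return Frequency of the modal combined haplotype.
#' @export
combined_top_share <- function(cohort, blocks) {
  stopifnot(inherits(cohort, "phased_cohort"))
  if (length(blocks) == 0L) stop("no blocks given", call. = FALSE)
  all_ids <- unlist(blocks)
  if (anyDuplicated(all_ids)) {
    stop("blocks must be non-overlapping", call. = FALSE)
  }
  idx <- match(all_ids, cohort$snps$id)
  if (anyNA(idx)) {
    stop("unknown SNP(s): ", paste(all_ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  tab <- table(hap_strings(cohort, idx))
  max(tab) / sum(tab)
}

#' Joint two-SNP genotype association with pathogenic backgrounds
#'
#' For two SNPs (e.g. the CFTR exonic tag SNPs rs213950 and rs1042077),
#' each haplotype carries one of four joint labels, written
#' `"<allele1>-<allele2>"` (e.g. `"A-G"`). For every label this tests
#' whether pathogenic/likely-pathogenic-carrying haplotypes are enriched
#' for that background: a 2x2 table of (P/LP-carrying alleles with /
#' without the label) vs (non-carrying alleles with / without it), with a
#' two-sided Fisher's exact p-value and the sample odds ratio. A label
#' enriched among carrier haplotypes marks a candidate founder background.
#'
#' @param cohort A [phased_cohort()] with `plp_flags` populated.
#' @param snp1,snp2 SNP ids present in the cohort.
#' @return A data.frame with one row per joint label: `label`, `n_plp`,
#'   `n_other` (haplotypes with the label in each group), `af_plp`,
#'   `af_other`, `odds_ratio`, `p_value`.
#' @export
joint_genotype_association <- function(cohort, snp1, snp2) {
  stopifnot(inherits(cohort, "phased_cohort"))
  flags <- cohort$plp_flags
  if (is.null(flags) || !any(flags)) {
    stop("no P/LP-carrying haplotypes: association is undefined", call. = FALSE)
  }
  i1 <- match(snp1, cohort$snps$id)
  i2 <- match(snp2, cohort$snps$id)
  if (is.na(i1) || is.na(i2)) {
    stop("SNP(s) not present: ",
         paste(c(snp1, snp2)[is.na(c(i1, i2))], collapse = ", "),
         call. = FALSE)
  }
  base1 <- ifelse(cohort$alleles[, i1] == 0L, cohort$snps$ref[i1],
                  cohort$snps$alt[i1])
  base2 <- ifelse(cohort$alleles[, i2] == 0L, cohort$snps$ref[i2],
                  cohort$snps$alt[i2])
  labels <- paste(base1, base2, sep = "-")
  all_labels <- as.vector(outer(c(cohort$snps$ref[i1], cohort$snps$alt[i1]),
                                c(cohort$snps$ref[i2], cohort$snps$alt[i2]),
                                paste, sep = "-"))
  res <- lapply(all_labels, function(lab) {
    a <- sum(flags & labels == lab)
    b <- sum(flags & labels != lab)
    c <- sum(!flags & labels == lab)
    d <- sum(!flags & labels != lab)
    p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
    data.frame(label = lab, n_plp = a, n_other = c,
               af_plp = a / sum(flags), af_other = c / sum(!flags),
               odds_ratio = odds_ratio_2x2(a, b, c, d), p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
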