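# strict TSV reader: tab-separated, UTF-8, '#' comment lines ignored,
# header mandatory, required columns checked
read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

to_num <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0L) {
    stop(path, ": non-numeric ", what, " at data row ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a screening-panel variant TSV
#'
#' Schema: tab-separated with header columns `chrom`, `pos`, `ref`, `alt`,
#' `hgvs_c`, `legacy`, `pclass`, `domain`; lines starting with `#` are
#' ignored. Rows are validated (positions, allele strings, the five
#' pathogenicity classes, domain labels) with the offending data row
#' reported, and duplicate variant keys are rejected.
#'
#' @param path Path to the TSV file.
#' @return A [variant_table()].
#' @export
read_panel_tsv <- function(path) {
  df <- read_tsv_strict(path, c("chrom", "pos", "ref", "alt",
                                "hgvs_c", "legacy", "pclass", "domain"))
  if (nrow(df) == 0L) {
    return(variant_table(character(0), integer(0), character(0), character(0)))
  }
  pos <- to_num(df$pos, "pos", path)
  bad <- which(is.na(pos) | pos < 1 | pos != round(pos))
  if (length(bad) > 0L) {
    stop(path, ": invalid position at data row ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$pclass %in% .pclass_levels)
  if (length(bad) > 0L) {
    stop(path, ": unknown pathogenicity class '", df$pclass[bad[1]],
         "' at data row ", bad[1], call. = FALSE)
  }
  bad <- which(!df$domain %in% .domain_levels)
  if (length(bad) > 0L) {
    stop(path, ": unknown domain label '", df$domain[bad[1]],
         "' at data row ", bad[1], call. = FALSE)
  }
  variant_table(df$chrom, as.integer(pos), df$ref, df$alt,
                hgvs_c = df$hgvs_c, legacy = df$legacy,
                pclass = df$pclass, domain = df$domain)
}

#' Build a screening panel from a variant table
#'
#' @param variants A [variant_table()].
#' @param name Panel name.
#' @param pclasses Pathogenicity classes to include (default P and LP).
#' @return A [screening_panel()].
#' @export
panel_from_variants <- function(variants, name, pclasses = c("P", "LP")) {
  stopifnot(inherits(variants, "variant_table"))
  screening_panel(name, variants$key[variants$pclass %in% pclasses])
}

#' Write a variant table as a panel TSV
#' @param variants A [variant_table()].
#' @param path Output path.
#' @export
write_panel_tsv <- function(variants, path) {
  stopifnot(inherits(variants, "variant_table"))
  cols <- c("chrom", "pos", "ref", "alt", "hgvs_c", "legacy", "pclass", "domain")
  utils::write.table(as.data.frame(variants)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read cohort carrier counts from TSV
#'
#' Schema: columns `cohort`, `N`, `N_male`, `N_female`, `C`, `C_male`,
#' `C_female`. Each row is validated through [cohort_counts()].
#'
#' @param path Path to the TSV file.
#' @return Named list of [cohort_counts()], one per row.
#' @export
read_cohort_counts_tsv <- function(path) {
  df <- read_tsv_strict(path, c("cohort", "N", "N_male", "N_female",
                                "C", "C_male", "C_female"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    cohort_counts(N = to_num(df$N[i], "N", path),
                  N_male = to_num(df$N_male[i], "N_male", path),
                  N_female = to_num(df$N_female[i], "N_female", path),
                  C = to_num(df$C[i], "C", path),
                  C_male = to_num(df$C_male[i], "C_male", path),
                  C_female = to_num(df$C_female[i], "C_female", path))
  })
  stats::setNames(out, df$cohort)
}

#' Write cohort counts to TSV
#' @param counts_list Named list of [cohort_counts()].
#' @param path Output path.
#' @export
write_cohort_counts_tsv <- function(counts_list, path) {
  rows <- lapply(names(counts_list), function(nm) {
    cc <- counts_list[[nm]]
    data.frame(cohort = nm, N = cc$N, N_male = cc$N_male,
               N_female = cc$N_female, C = cc$C, C_male = cc$C_male,
               C_female = cc$C_female, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gnomAD-style allele-count TSV
#'
#' Schema: columns `chrom`, `pos`, `ref`, `alt`, `population`, `AC`, `AN`.
#' Allele frequencies are always recomputed as `AC/AN`, never trusted from
#' the file; `AC > AN` is an error, `AC = AN` (a fixed non-SNP-like site)
#' is accepted with a warning.
#'
#' @param path Path to the TSV file.
#' @param population Population label to extract (e.g. `"nfe"`); a
#'   population absent from the file yields an empty table with a warning.
#' @return An [allele_counts()] table for the requested population.
#' @export
read_allele_counts_tsv <- function(path, population) {
  df <- read_tsv_strict(path, c("chrom", "pos", "ref", "alt",
                                "population", "AC", "AN"))
  df <- df[df$population == population, , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("population '", population, "' not found in ", path)
    return(allele_counts(character(0), numeric(0), numeric(0)))
  }
  AC <- to_num(df$AC, "AC", path)
  AN <- to_num(df$AN, "AN", path)
  if (any(AC > AN)) {
    stop(path, ": AC exceeds AN at data row ",
         paste(which(AC > AN), collapse = ", "), call. = FALSE)
  }
  if (any(AC == AN)) {
    warning(path, ": AC equals AN for ", sum(AC == AN),
            " variant(s) (fixed site; check input)")
  }
  allele_counts(variant_key(df$chrom, df$pos, df$ref, df$alt),
                AC, AN, population = population)
}

#' Write an allele-count table to TSV
#' @param ac An [allele_counts()] table.
#' @param path Output path.
#' @export
write_allele_counts_tsv <- function(ac, path) {
  kd <- parse_variant_key(ac$key)
  out <- data.frame(chrom = kd$chrom, pos = kd$pos, ref = kd$ref,
                    alt = kd$alt, population = ac$population,
                    AC = ac$AC, AN = ac$AN, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a phased VCF into a phased cohort
#'
#' Consumes phasing output: a VCF 4.x file whose GT fields all use the
#' phased `"|"` separator. Only biallelic SNPs are retained; multi-allelic
#' and indel records are skipped with a logged count. Any unphased (`"/"`)
#' genotype is an error naming the first offending sample and position —
#' phasing is consumed here, never computed.
#'
#' @param path Path to the VCF (plain or bgzipped).
#' @param plp_keys Optional character vector of variant keys
#'   (`"chrom:pos:ref:alt"`) of pathogenic/likely-pathogenic variants
#'   present in the VCF; each haplotype carrying an alternate allele at
#'   any of them has its `plp_flags` entry set.
#' @return A [phased_cohort()].
#' @export
read_phased_vcf <- function(path, plp_keys = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {          # single-record files drop to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))

  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(unphased)) {
    hit <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype for sample '", colnames(gt)[hit[2]],
         "' at ", fix$CHROM[hit[1]], ":", fix$POS[hit[1]],
         " — input must be fully phased", call. = FALSE)
  }

  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0L) {
    message("skipped ", n_skipped, " non-biallelic-SNP record(s)")
  }

  split_hap <- function(rows) {
    g <- gt[rows, , drop = FALSE]
    a1 <- suppressWarnings(apply(g, 2, function(x)
      as.integer(sub("\\|.*$", "", x))))
    a2 <- suppressWarnings(apply(g, 2, function(x)
      as.integer(sub("^.*\\|", "", x))))
    if (length(rows) == 1L) {
      a1 <- matrix(a1, nrow = 1); a2 <- matrix(a2, nrow = 1)
    }
    if (anyNA(a1) || anyNA(a2)) {
      stop("missing or malformed GT field(s) in ", path, call. = FALSE)
    }
    # interleave: rows 2s-1, 2s are the two haplotypes of sample s
    n_s <- ncol(g)
    out <- matrix(0L, nrow = 2L * n_s, ncol = length(rows))
    out[seq(1L, 2L * n_s, by = 2L), ] <- t(a1)
    out[seq(2L, 2L * n_s, by = 2L), ] <- t(a2)
    out
  }

  snp_rows <- which(is_snp)
  if (length(snp_rows) == 0L) stop("no biallelic SNPs in ", path, call. = FALSE)
  alleles <- split_hap(snp_rows)
  if (!all(alleles %in% c(0L, 1L))) {
    stop("multi-allelic genotype index among biallelic records in ", path,
         call. = FALSE)
  }
  ids <- fix$ID[snp_rows]
  keys <- variant_key(fix$CHROM[snp_rows], as.integer(fix$POS[snp_rows]),
                      fix$REF[snp_rows], fix$ALT[snp_rows])
  ids[is.na(ids) | ids == "."] <- keys[is.na(ids) | ids == "."]
  snps <- data.frame(id = ids, chrom = fix$CHROM[snp_rows],
                     pos = as.integer(fix$POS[snp_rows]),
                     ref = fix$REF[snp_rows], alt = fix$ALT[snp_rows],
                     stringsAsFactors = FALSE)

  flags <- NULL
  if (!is.null(plp_keys)) {
    all_keys <- variant_key(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT)
    plp_rows <- which(all_keys %in% plp_keys)
    if (length(plp_rows) > 0L) {
      plp_alleles <- split_hap(plp_rows)
      flags <- rowSums(plp_alleles > 0L) > 0L
    } else {
      flags <- rep(FALSE, nrow(alleles))
    }
  }
  phased_cohort(snps, alleles, plp_flags = flags)
}

#' Write a phased cohort as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 file with phased GT fields (`"|"` separator),
#' one sample column per individual. The inverse of [read_phased_vcf()]
#' for cohorts whose SNP table carries `chrom` and `pos`.
#'
#' @param cohort A [phased_cohort()].
#' @param path Output path.
#' @param sample_prefix Sample-name prefix (default `"S"`).
#' @export
write_phased_vcf <- function(cohort, path, sample_prefix = "S") {
  stopifnot(inherits(cohort, "phased_cohort"))
  snps <- cohort$snps
  if (!all(c("chrom", "pos") %in% names(snps))) {
    stop("cohort SNP table must carry chrom and pos to write a VCF",
         call. = FALSE)
  }
  n <- n_individuals(cohort)
  samples <- paste0(sample_prefix, seq_len(n))
  header <- c("##fileformat=VCFv4.2",
              "##source=cftrspectrum",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  odd <- seq(1L, 2L * n, by = 2L)
  rows <- vapply(seq_len(nrow(snps)), function(j) {
    gts <- paste(cohort$alleles[odd, j], cohort$alleles[odd + 1L, j],
                 sep = "|")
    paste(c(snps$chrom[j], snps$pos[j], snps$id[j], snps$ref[j],
            snps$alt[j], ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read plink haplotype-block definitions (.blocks.det)
#'
#' Parses the whitespace-delimited `.blocks.det` table produced by plink's
#' block detection (`--blocks`), returning the SNP-id list of each block.
#' Block detection itself is out of scope: blocks are inputs here.
#'
#' @param path Path to the `.blocks.det` file.
#' @return Named list of character vectors (SNP ids per block), named
#'   `block1`, `block2`, ... in file order.
#' @export
read_blocks_det <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"SNPS" %in% names(df)) {
    stop(path, ": no SNPS column — not a .blocks.det file?", call. = FALSE)
  }
  blocks <- strsplit(df$SNPS, "|", fixed = TRUE)
  stats::setNames(blocks, paste0("block", seq_along(blocks)))
}
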