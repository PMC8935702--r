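# Shared fixtures, all built in code at test time.

children_cohort <- function() {
  cohort_counts(N = 20905, N_male = 12773, N_female = 8132,
                C = 110, C_male = 73, C_female = 37)
}

parents_cohort <- function() {
  cohort_counts(N = 10038, N_male = 5012, N_female = 5026,
                C = 60, C_male = 38, C_female = 22)
}

# tiny hand-built phased cohort: 3 individuals, 4 SNPs, rows are
# haplotypes coded 0/1 over s1..s4
toy_phased <- function(plp_flags = NULL) {
  snps <- data.frame(id = paste0("s", 1:4),
                     chrom = "7", pos = 101:104,
                     ref = c("A", "C", "G", "T"),
                     alt = c("G", "T", "A", "C"),
                     stringsAsFactors = FALSE)
  alleles <- rbind(c(0, 0, 0, 0),
                   c(0, 0, 0, 0),
                   c(0, 0, 1, 1),
                   c(0, 0, 0, 0),
                   c(0, 0, 1, 1),
                   c(1, 1, 0, 0))
  phased_cohort(snps, alleles, plp_flags = plp_flags)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a small panel TSV with a mix of pathogenicity classes
toy_panel_lines <- function() {
  c("chrom\tpos\tref\talt\thgvs_c\tlegacy\tpclass\tdomain",
    "7\t117199644\tG\tA\tc.1408G>A\tV470M\tB\tnone",
    "7\t117230454\tG\tA\tc.2909G>A\tG970D\tP\tTMD2",
    "7\t117199645\tA\tC\tc.2936A>C\tD979A\tP\tTMD2",
    "7\t117180330\tT\tG\tc.263T>G\tL88X\tLP\tnone")
}
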