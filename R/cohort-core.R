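#' Variant identity key
#'
#' Variants are identified throughout the package by the VCF-style tuple
#' `(chrom, pos, ref, alt)` with 1-based positions, rendered as the string
#' `"chrom:pos:ref:alt"`. Legacy names (e.g. `"G970D"`) and HGVS cDNA names
#' are display-only aliases and never take part in identity.
#'
#' @param chrom Chromosome label (e.g. `"7"` or `"chr7"`).
#' @param pos 1-based position, `>= 1`.
#' @param ref,alt Reference and alternate allele strings; must differ.
#' @return Character vector of keys.
#' @examples
#' variant_key("7", 117559590, "G", "A")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("variant positions must be integers >= 1", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Split variant keys back into their components
#'
#' @param key Character vector of `"chrom:pos:ref:alt"` keys.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed variant key(s): ", paste(key[bad], collapse = ", "),
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
             ref = m[, 3], alt = m[, 4], stringsAsFactors = FALSE)
}

.pclass_levels <- c("P", "LP", "VUS", "LB", "B")
.domain_levels <- c("TMD1", "NBD1", "R", "TMD2", "NBD2", "none")

#' Construct a validated variant table
#'
#' A variant table is a plain data.frame with one row per variant and columns
#' `chrom`, `pos`, `ref`, `alt`, `hgvs_c`, `legacy`, `pclass`, `domain`, plus
#' the derived `key`. Pathogenicity classes follow the five ACMG-style
#' levels P, LP, VUS, LB, B; protein-domain labels are those of the CFTR
#' domain architecture (TMD1, NBD1, R, TMD2, NBD2) or `"none"` for variants
#' outside any annotated domain. Classes are taken as given: there is no
#' curation logic here.
#'
#' @param chrom,pos,ref,alt Variant coordinates, recycled to equal length.
#' @param hgvs_c,legacy Display names (cDNA HGVS and legacy nomenclature).
#' @param pclass Pathogenicity class, one of `"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`.
#' @param domain Protein-domain label or `"none"`.
#' @return A `data.frame` of class `"variant_table"` keyed by
#'   `(chrom, pos, ref, alt)`.
#' @export
variant_table <- function(chrom, pos, ref, alt,
                          hgvs_c = NA_character_, legacy = NA_character_,
                          pclass = "P", domain = "none") {
  key <- variant_key(chrom, pos, ref, alt)
  if (anyDuplicated(key)) {
    stop("duplicate variant key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  n <- length(key)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   hgvs_c = rep_len(as.character(hgvs_c), n),
                   legacy = rep_len(as.character(legacy), n),
                   pclass = rep_len(as.character(pclass), n),
                   domain = rep_len(as.character(domain), n),
                   key = key, stringsAsFactors = FALSE)
  bad <- !df$pclass %in% .pclass_levels
  if (any(bad)) {
    stop("unknown pathogenicity class: ",
         paste(unique(df$pclass[bad]), collapse = ", "),
         " (expected one of ", paste(.pclass_levels, collapse = "/"), ")",
         call. = FALSE)
  }
  bad <- !df$domain %in% .domain_levels
  if (any(bad)) {
    stop("unknown protein-domain label: ",
         paste(unique(df$domain[bad]), collapse = ", "), call. = FALSE)
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Construct a screening panel
#'
#' A screening panel is a named set of variant keys: the fixed list of
#' variants a carrier-screening assay genotypes. Panel sensitivity in a
#' population depends on how much of that population's pathogenic-allele
#' spectrum the set covers, which is why restricting a cohort's detected
#' carriers to a panel (see [carriers_in_panel()]) can change a prevalence
#' estimate dramatically.
#'
#' @param name Panel name (free text).
#' @param variants Character vector of variant keys; duplicates are rejected.
#' @param allow_empty Permit an empty variant set (used for intersection
#'   results); an empty panel is flagged with attribute `empty = TRUE`.
#' @return An object of class `"screening_panel"`.
#' @seealso [intersect_panels()]
#' @export
screening_panel <- function(name, variants, allow_empty = FALSE) {
  variants <- as.character(variants)
  if (anyDuplicated(variants)) {
    stop("panel '", name, "' contains duplicate variant keys", call. = FALSE)
  }
  if (length(variants) == 0L && !allow_empty) {
    stop("panel '", name, "' has no variants", call. = FALSE)
  }
  structure(list(name = name, variants = variants),
            empty = length(variants) == 0L,
            class = "screening_panel")
}

#' @export
print.screening_panel <- function(x, ...) {
  cat("Screening panel '", x$name, "': ", length(x$variants), " variant(s)\n",
      sep = "")
  invisible(x)
}

#' Intersect two screening panels
#'
#' Returns the panel whose variant set is the exact set intersection of the
#' two inputs, named `"a∩b"`. An empty intersection is a valid result and
#' is flagged via the `empty` attribute.
#'
#' @param a,b `screening_panel` objects.
#' @return A `screening_panel` (possibly empty).
#' @export
intersect_panels <- function(a, b) {
  stopifnot(inherits(a, "screening_panel"), inherits(b, "screening_panel"))
  screening_panel(paste0(a$name, "∩", b$name),
                  intersect(a$variants, b$variants), allow_empty = TRUE)
}

#' Sum carrier counts over a panel
#'
#' Restricts a per-variant carrier tally to the variants a screening panel
#' would detect. Variants absent from the tally contribute zero.
#'
#' @param per_variant_carriers Named nonnegative integer vector,
#'   variant key -> carrier count.
#' @param panel A `screening_panel`.
#' @return Total carriers detectable by the panel (integer-valued numeric).
#' @export
carriers_in_panel <- function(per_variant_carriers, panel) {
  stopifnot(inherits(panel, "screening_panel"))
  if (length(per_variant_carriers) == 0L) return(0)
  if (is.null(names(per_variant_carriers))) {
    stop("per_variant_carriers must be named by variant key", call. = FALSE)
  }
  if (any(per_variant_carriers < 0)) {
    stop("carrier counts must be nonnegative", call. = FALSE)
  }
  sum(per_variant_carriers[names(per_variant_carriers) %in% panel$variants])
}

#' Gender-stratified cohort carrier counts
#'
#' The raw material of every prevalence estimator: total individuals and
#' heterozygous pathogenic/likely-pathogenic (P/LP) carriers, each split by
#' gender. All consistency constraints (`N = N_male + N_female`,
#' `C = C_male + C_female`, carriers bounded by their stratum size) are
#' checked at construction and violations are rejected.
#'
#' @param N Total individuals.
#' @param N_male,N_female Individuals per gender stratum.
#' @param C Heterozygous P/LP carriers.
#' @param C_male,C_female Carriers per gender stratum.
#' @return An object of class `"cohort_counts"`.
#' @examples
#' # the pediatric cohort of the worked example
#' cohort_counts(N = 20905, N_male = 12773, N_female = 8132,
#'               C = 110, C_male = 73, C_female = 37)
#' @export
cohort_counts <- function(N, N_male, N_female, C, C_male, C_female) {
  vals <- c(N = N, N_male = N_male, N_female = N_female,
            C = C, C_male = C_male, C_female = C_female)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("cohort counts must be nonnegative integers", call. = FALSE)
  }
  if (N != N_male + N_female) {
    stop("N must equal N_male + N_female (", N, " != ",
         N_male + N_female, ")", call. = FALSE)
  }
  if (C != C_male + C_female) {
    stop("C must equal C_male + C_female (", C, " != ",
         C_male + C_female, ")", call. = FALSE)
  }
  if (C > N || C_male > N_male || C_female > N_female) {
    stop("carrier counts cannot exceed the individuals in their stratum",
         call. = FALSE)
  }
  structure(as.list(vals), class = "cohort_counts")
}

#' @export
print.cohort_counts <- function(x, ...) {
  cat("Cohort: N =", x$N, paste0("(", x$N_male, "M/", x$N_female, "F),"),
      "carriers C =", x$C, paste0("(", x$C_male, "M/", x$C_female, "F)\n"))
  invisible(x)
}

#' Construct a validated allele-count table
#'
#' One row per variant (and optionally per population): alternate-allele
#' count `AC`, total allele count `AN`, with allele frequency `AF = AC/AN`
#' and minor allele frequency `MAF = min(AF, 1 - AF)` always recomputed,
#' never trusted from input.
#'
#' @param key Variant keys (`"chrom:pos:ref:alt"`).
#' @param AC,AN Alternate and total allele counts; `0 <= AC <= AN`, `AN > 0`.
#' @param population Optional population label, recycled.
#' @return A `data.frame` of class `"allele_counts"` with columns `key`,
#'   `population`, `AC`, `AN`, `AF`, `MAF`.
#' @export
allele_counts <- function(key, AC, AN, population = NA_character_) {
  AC <- as.numeric(AC); AN <- as.numeric(AN)
  if (any(AN <= 0)) stop("AN must be positive", call. = FALSE)
  if (any(AC < 0) || any(AC > AN)) {
    stop("AC must satisfy 0 <= AC <= AN", call. = FALSE)
  }
  df <- data.frame(key = as.character(key),
                   population = rep_len(as.character(population), length(key)),
                   AC = AC, AN = AN,
                   AF = if (length(AC)) AC / AN else numeric(0),
                   stringsAsFactors = FALSE)
  df$MAF <- pmin(df$AF, 1 - df$AF)
  class(df) <- c("allele_counts", "data.frame")
  df
}

#' Allele frequency of allele-count entries
#'
#' @param entry An `allele_counts` row (or several).
#' @return Numeric vector `AC/AN`.
#' @export
af_of <- function(entry) {
  if (!all(c("AC", "AN") %in% names(entry))) {
    stop("entry must carry AC and AN columns", call. = FALSE)
  }
  if (any(entry$AN <= 0)) stop("invalid entry: AN must be positive", call. = FALSE)
  entry$AC / entry$AN
}
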