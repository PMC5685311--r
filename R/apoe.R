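#' APOE diplotype calling and cohort frequencies
#'
#' The three common APOE isoforms are haplotypes of two coding SNPs,
#' rs429358 (codon 112) and rs7412 (codon 158), both C/T: E2 = (T, T),
#' E3 = (T, C), E4 = (C, C). The fourth combination (C, T) is the very
#' rare E1 haplotype, outside the six-genotype universe this module
#' resolves into. Unphased two-SNP genotypes resolve uniquely except the
#' double heterozygote, which admits E2/E4 or E1/E3; it is called E2/E4
#' (the only resolution without E1) with `ambiguous = TRUE`.
#'
#' @name apoe
NULL

#' Haplotype-to-isoform map for the two APOE SNPs
#'
#' Shipped as an explicit table for auditability; alleles are on the
#' GRCh37 forward strand as conventionally reported for these rsIDs.
#' @export
APOE_HAPLOTYPE_MAP <- tibble::tibble(
  rs429358 = c("T", "T", "C", "C"),
  rs7412   = c("T", "C", "C", "T"),
  allele   = c("E2", "E3", "E4", "E1"))

APOE_GENOTYPES <- c("E2/E2", "E2/E3", "E2/E4", "E3/E3", "E3/E4", "E4/E4")

parse_gt_pair <- function(gt, rsid) {
  if (is.na(gt) || !grepl("^[ACGT][/|][ACGT]$", gt)) {
    stop_input(sprintf("missing or invalid %s genotype: '%s'", rsid, gt),
               "neuropanel_bad_genotype")
  }
  strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)[[1]]
}

#' Call an APOE diplotype from the two SNP genotypes
#'
#' @param gt_rs429358,gt_rs7412 Unphased genotypes over \{C, T\}, e.g.
#'   `"T/C"`.
#' @param strand_flip If TRUE, complement incoming alleles (for call sets
#'   reported on the opposite strand) before applying the haplotype map.
#' @return A one-row tibble: `allele1`, `allele2` (sorted, E2 < E3 < E4),
#'   `genotype` (e.g. `"E3/E4"`), `ambiguous`, `gt_rs429358`, `gt_rs7412`.
#'   Genotype pairs resolvable only through the E1 haplotype raise an
#'   `UNRESOLVABLE_HAPLOTYPE` error.
#' @examples
#' call_apoe_diplotype("T/T", "C/C")  # E3/E3
#' call_apoe_diplotype("C/T", "C/T")  # E2/E4, ambiguous
#' @export
call_apoe_diplotype <- function(gt_rs429358, gt_rs7412,
                                strand_flip = FALSE) {
  a112 <- parse_gt_pair(gt_rs429358, "rs429358")
  a158 <- parse_gt_pair(gt_rs7412, "rs7412")
  if (strand_flip) {
    comp <- c(C = "G", G = "C", A = "T", T = "A")
    a112 <- unname(comp[a112])
    a158 <- unname(comp[a158])
  }
  if (!all(c(a112, a158) %in% c("C", "T"))) {
    stop_input(
      sprintf("alleles must be C/T after any strand flip: %s + %s",
              gt_rs429358, gt_rs7412),
      "neuropanel_bad_genotype")
  }
  map <- APOE_HAPLOTYPE_MAP
  hap_of <- function(x112, x158) {
    map$allele[map$rs429358 == x112 & map$rs7412 == x158]
  }
  # two phasings of the unphased pair
  phasings <- list(
    sort(c(hap_of(a112[1], a158[1]), hap_of(a112[2], a158[2]))),
    sort(c(hap_of(a112[1], a158[2]), hap_of(a112[2], a158[1]))))
  phasings <- unique(phasings)
  valid <- Filter(function(p) !"E1" %in% p, phasings)
  if (length(valid) == 0) {
    stop_input(
      sprintf("UNRESOLVABLE_HAPLOTYPE: genotypes %s + %s imply the rare E1 haplotype",
              gt_rs429358, gt_rs7412),
      "neuropanel_unresolvable_haplotype")
  }
  dip <- valid[[1]]
  tibble(allele1 = dip[1], allele2 = dip[2],
         genotype = paste(dip, collapse = "/"),
         ambiguous = length(phasings) > 1,
         gt_rs429358 = gt_rs429358, gt_rs7412 = gt_rs7412)
}

#' Vectorised diplotype calling
#'
#' @inheritParams call_apoe_diplotype
#' @return Tibble with one row per input pair.
#' @export
call_apoe_diplotypes <- function(gt_rs429358, gt_rs7412,
                                 strand_flip = FALSE) {
  stopifnot(length(gt_rs429358) == length(gt_rs7412))
  bind_rows(purrr::map2(gt_rs429358, gt_rs7412, call_apoe_diplotype,
                        strand_flip = strand_flip))
}

#' Cohort APOE genotype table
#'
#' Counts the six genotypes per diagnosis stratum and overall, with
#' percentages of each stratum's n to one decimal.
#'
#' @param genotypes Character vector of called genotypes (`"E3/E3"` ...).
#' @param diagnoses Parallel vector of diagnosis codes (optional; when
#'   omitted only the Total row is produced).
#' @return Tibble: `diagnosis`, `n`, then count and `pct_` columns per
#'   genotype.
#' @export
apoe_cohort_table <- function(genotypes, diagnoses = NULL) {
  stopifnot(all(genotypes %in% APOE_GENOTYPES))
  diagnoses <- diagnoses %||% rep("Total", length(genotypes))
  strata <- c("Total", setdiff(unique(diagnoses), "Total"))
  rows <- lapply(strata, function(s) {
    g <- if (s == "Total") genotypes else genotypes[diagnoses == s]
    cnt <- table(factor(g, levels = APOE_GENOTYPES))
    row <- tibble(diagnosis = s, n = length(g))
    for (gt in APOE_GENOTYPES) {
      key <- gsub("/", "", tolower(gt))
      row[[paste0("n_", key)]] <- as.integer(cnt[[gt]])
      row[[paste0("pct_", key)]] <- pct_of(cnt[[gt]], length(g), 1)
    }
    row
  })
  out <- bind_rows(rows)
  stopifnot(all(rowSums(out[paste0("n_", gsub("/", "", tolower(APOE_GENOTYPES)))]) == out$n))
  out
}

#' APOE allele frequencies from genotype counts
#'
#' freq(a) = (2 x hom(a) + het carrying a) / (2 x n); reported to three
#' decimals.
#'
#' @param counts Named integer vector or list over the six genotypes
#'   (`E2/E2` ... `E4/E4`); missing names count as zero.
#' @return Named numeric vector `c(E2 =, E3 =, E4 =)`.
#' @examples
#' apoe_allele_frequencies(c(`E2/E3` = 26, `E2/E4` = 1, `E3/E3` = 131,
#'                           `E3/E4` = 45, `E4/E4` = 13))
#' @export
apoe_allele_frequencies <- function(counts) {
  cnt <- setNames(rep(0L, length(APOE_GENOTYPES)), APOE_GENOTYPES)
  counts <- unlist(counts)
  bad <- setdiff(names(counts), APOE_GENOTYPES)
  if (length(bad) > 0) {
    stop_input(sprintf("unknown APOE genotype(s): %s",
                       paste(bad, collapse = ", ")),
               "neuropanel_bad_genotype")
  }
  cnt[names(counts)] <- counts
  n <- sum(cnt)
  if (n == 0) {
    stop_input("cannot compute allele frequencies for an empty cohort",
               "neuropanel_empty_cohort")
  }
  tally <- c(E2 = 0, E3 = 0, E4 = 0)
  for (gt in APOE_GENOTYPES) {
    alleles <- strsplit(gt, "/", fixed = TRUE)[[1]]
    for (a in alleles) tally[a] <- tally[a] + cnt[[gt]]
  }
  round_half_up(tally / (2 * n), 3)
}
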