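#' Cross-platform genotype concordance
#'
#' Compares diploid genotype calls between a test platform (sequencing)
#' and a reference platform (array, allelic-discrimination assay or
#' Sanger) at the intersection of their typed sites. Genotypes are
#' compared as unordered allele sets (both platforms are unphased).
#' Sites typed on only one platform never enter the rate; they are
#' returned in a coverage-difference list. Missing genotypes at a shared
#' site are excluded from the denominator and tallied.
#'
#' @name concordance
NULL

site_key <- function(x) paste(x$chrom, x$pos, sep = ":")

gt_sorted <- function(gt) {
  vapply(strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE),
         function(a) paste(sort(a), collapse = "/"), character(1))
}

gt_is_carrier <- function(gt, ref) {
  mapply(function(g, r) {
    if (is.na(g)) return(NA)
    any(strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)[[1]] != r)
  }, gt, ref)
}

#' Genotype concordance between two call sets
#'
#' @param test,reference Tibbles with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `genotype` (unphased allele pair, e.g. `"G/A"`; `NA` for a
#'   missing call at a typed site).
#' @param sites Optional restriction: tibble with `chrom`, `pos` columns.
#' @return List of class `concordance_result`: `n_sites_compared`
#'   (sample-site comparisons), `n_concordant`, `rate` (percent, one
#'   decimal), `false_positives` and `false_negatives` (tibbles),
#'   `n_missing`, `test_only_sites` and `reference_only_sites` (character
#'   keys).
#' @export
genotype_concordance <- function(test, reference, sites = NULL) {
  tk <- unique(site_key(test))
  rk <- unique(site_key(reference))
  shared <- intersect(tk, rk)
  if (!is.null(sites)) shared <- intersect(shared, site_key(sites))
  if (length(shared) == 0) {
    stop_input("NO_OVERLAP: no comparable sites between call sets",
               "neuropanel_no_overlap")
  }
  t2 <- test |> mutate(key = site_key(test)) |> filter(.data$key %in% shared)
  r2 <- reference |> mutate(key = site_key(reference)) |>
    filter(.data$key %in% shared)
  merged <- full_join(
    t2 |> select("sample_id", "key", "ref", gt_test = "genotype"),
    r2 |> select("sample_id", "key", ref_ref = "ref",
                 gt_ref = "genotype"),
    by = c("sample_id", "key"))
  merged$ref <- ifelse(is.na(merged$ref), merged$ref_ref, merged$ref)
  missing <- is.na(merged$gt_test) | is.na(merged$gt_ref)
  cmp <- merged[!missing, ]
  if (nrow(cmp) == 0) {
    stop_input("NO_OVERLAP: all shared sites have a missing genotype",
               "neuropanel_no_overlap")
  }
  concordant <- gt_sorted(cmp$gt_test) == gt_sorted(cmp$gt_ref)
  test_car <- gt_is_carrier(cmp$gt_test, cmp$ref)
  ref_car <- gt_is_carrier(cmp$gt_ref, cmp$ref)
  fp <- cmp[!concordant & test_car & !ref_car, ]
  fn <- cmp[!concordant & ref_car, ]
  structure(list(
    n_sites_compared = nrow(cmp),
    n_concordant = sum(concordant),
    rate = round_half_up(100 * sum(concordant) / nrow(cmp), 1),
    false_positives = fp[, c("sample_id", "key", "gt_test", "gt_ref")],
    false_negatives = fn[, c("sample_id", "key", "gt_test", "gt_ref")],
    n_missing = sum(missing),
    test_only_sites = setdiff(tk, rk),
    reference_only_sites = setdiff(rk, tk)),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> %d/%d concordant (%.1f%%), %d FP, %d FN, %d missing\n",
              x$n_concordant, x$n_sites_compared, x$rate,
              nrow(x$false_positives), nrow(x$false_negatives), x$n_missing))
  invisible(x)
}

#' Array-marker filtering cascade
#'
#' Reduces a set of array markers to those relevant for sequencing
#' validation, applying in order: (1) drop noncoding and synonymous
#' markers; (2) drop markers with MAF > `maf_threshold` in **any** of the
#' 1000 Genomes / ESP / ExAC databases (note: any-database here, unlike
#' the every-database rarity rule used for clinical prioritisation);
#' (3) drop markers overlapping segmental duplications; (4) keep only
#' markers predicted damaging by PolyPhen-2 or deleterious by SIFT.
#'
#' @param markers Tibble with columns `consequence`, `maf_1000g`,
#'   `maf_esp`, `maf_exac`, `in_segdup`, `polyphen`, `sift` (plus any key
#'   columns, carried through).
#' @inheritParams is_rare
#' @return List: `survivors` (tibble) and `tally` (tibble of per-step
#'   removals plus the surviving count; removals and survivors sum to the
#'   input count).
#' @export
array_marker_filter <- function(markers, config = prioritisation_config()) {
  n0 <- nrow(markers)
  noncoding <- markers$consequence %in% c("noncoding", "synonymous")
  m1 <- markers[!noncoding, ]
  thr <- config$maf_threshold
  common <- (m1$maf_1000g %missing% 0) > thr |
    (m1$maf_esp %missing% 0) > thr |
    (m1$maf_exac %missing% 0) > thr
  m2 <- m1[!common, ]
  segdup <- m2$in_segdup %missing% FALSE
  m3 <- m2[!segdup, ]
  damaging <- (m3$polyphen %in% c("possibly_damaging", "probably_damaging")) |
    (m3$sift %in% "deleterious")
  m4 <- m3[damaging, ]
  tally <- tibble(
    step = c("noncoding_or_synonymous", "common_any_database",
             "segmental_duplication", "not_predicted_damaging", "kept"),
    n = c(sum(noncoding), sum(common), sum(segdup), sum(!damaging),
          nrow(m4)))
  stopifnot(sum(tally$n) == n0)
  list(survivors = m4, tally = tally)
}
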