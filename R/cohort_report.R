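#' Cohort-level report tables
#'
#' Builders for the study-style summary tables: demographics, other risk
#' variants (C9orf72 expansion carriers and the six APOE genotypes),
#' diagnostic yield (0/1/2/3+ qualifying variants per sample) and variant
#' origin (gene-diagnosis concordance and disease-database membership).
#' Percentage denominators follow the printed conventions: yield bins for
#' 1/2/3+ variants are percentages of the with-variant count, the
#' without-variant bin of the stratum n; variant-origin columns are
#' percentages of the stratum's variant count. Percentages are rounded
#' half-away-from-zero and always recomputed from the stored counts.
#'
#' @name cohort_report
NULL

DIAGNOSIS_ORDER <- c("Total", "AD_MCI", "ALS", "FTD", "PD", "VCI")

strata_of <- function(diagnoses) {
  c("Total", intersect(DIAGNOSIS_ORDER, unique(diagnoses)))
}

check_samples <- function(samples) {
  stopifnot(all(c("sample_id", "diagnosis") %in% names(samples)))
  diagnosis_category(unique(samples$diagnosis))
  invisible(samples)
}

#' Demographics summary table
#'
#' @param samples Sample-metadata tibble with columns `sample_id`,
#'   `diagnosis`, `age`, `sex` (`"M"`/`"F"`), `ethnicity`.
#' @return Tibble with Total and per-diagnosis rows: n, mean/sd/min/max
#'   age (one decimal), male:female ratio in `x.y:1.0` form (`"all male"`
#'   / `"all female"` sentinels for single-sex strata) and percent
#'   Caucasian.
#' @export
demographics_table <- function(samples) {
  check_samples(samples)
  if (nrow(samples) == 0) {
    stop_input("empty cohort", "neuropanel_empty_cohort")
  }
  rows <- lapply(strata_of(samples$diagnosis), function(s) {
    d <- if (s == "Total") samples else samples[samples$diagnosis == s, ]
    n_m <- sum(d$sex == "M")
    n_f <- sum(d$sex == "F")
    ratio <- if (n_f == 0 && n_m == 0) NA_character_
    else if (n_f == 0) "all male"
    else if (n_m == 0) "all female"
    else sprintf("%.1f:1.0", round_half_up(n_m / n_f, 1))
    tibble(diagnosis = s, n = nrow(d),
           mean_age = round_half_up(mean(d$age), 1),
           sd_age = round_half_up(stats::sd(d$age), 1),
           min_age = min(d$age), max_age = max(d$age),
           male_female = ratio,
           pct_caucasian = pct_of(sum(d$ethnicity == "Caucasian"), nrow(d), 1))
  })
  bind_rows(rows)
}

#' Diagnostic-yield table
#'
#' Bins each sample by its qualifying-variant count (0 / 1 / 2 / 3+).
#'
#' @param counts Tibble `sample_id`, `n_variants` (from
#'   [count_variants_per_sample()]), one row per cohort sample.
#' @param samples Sample-metadata tibble (`sample_id`, `diagnosis`).
#' @return Tibble with Total and per-diagnosis rows: `n`,
#'   `n_without`/`pct_without` (of n), `n_with`/`pct_with` (of n),
#'   `n_with_1`, `n_with_2`, `n_with_ge3` with percentages of `n_with`.
#' @export
yield_table <- function(counts, samples) {
  check_samples(samples)
  x <- left_join(samples, counts, by = "sample_id")
  if (anyNA(x$n_variants)) {
    stop_input("every sample needs a variant count", "neuropanel_bad_input")
  }
  rows <- lapply(strata_of(samples$diagnosis), function(s) {
    d <- if (s == "Total") x else x[x$diagnosis == s, ]
    n <- nrow(d)
    n_without <- sum(d$n_variants == 0)
    n_with <- n - n_without
    n1 <- sum(d$n_variants == 1)
    n2 <- sum(d$n_variants == 2)
    n3 <- sum(d$n_variants >= 3)
    tibble(diagnosis = s, n = n,
           n_without = n_without, pct_without = pct_of(n_without, n),
           n_with = n_with, pct_with = pct_of(n_with, n),
           n_with_1 = n1, pct_with_1 = pct_of(n1, n_with),
           n_with_2 = n2, pct_with_2 = pct_of(n2, n_with),
           n_with_ge3 = n3, pct_with_ge3 = pct_of(n3, n_with))
  })
  out <- bind_rows(rows)
  stopifnot(all(out$n_without + out$n_with == out$n),
            all(out$n_with_1 + out$n_with_2 + out$n_with_ge3 == out$n_with))
  out
}

#' Variant-origin table
#'
#' Counts non-excluded, non-artifact variants per stratum and splits them
#' by gene-diagnosis concordance and by disease-database membership.
#'
#' @param classified Cohort-wide classified tibble.
#' @param samples Sample-metadata tibble (`sample_id`, `diagnosis`).
#' @return Tibble with Total and per-diagnosis rows; the concordant /
#'   other split and the in-database / not-in-database split each conserve
#'   `n_variants`.
#' @export
variant_origin_table <- function(classified, samples) {
  check_samples(samples)
  keep <- classified$category != "excluded" &
    !(classified$recurrent_artifact %missing% FALSE)
  v <- classified[keep, ]
  v <- left_join(v[, setdiff(names(v), "diagnosis")],
                 samples[, c("sample_id", "diagnosis")], by = "sample_id")
  rows <- lapply(strata_of(samples$diagnosis), function(s) {
    d <- if (s == "Total") v else v[v$diagnosis == s, ]
    nsamp <- if (s == "Total") nrow(samples)
    else sum(samples$diagnosis == s)
    nv <- nrow(d)
    in_diag <- sum(d$concordant_gene)
    in_db <- sum((d$in_hgmd %missing% FALSE) | (d$in_clinvar %missing% FALSE))
    tibble(diagnosis = s, n = nsamp,
           n_with_variants = n_distinct(d$sample_id),
           pct_with_variants = pct_of(n_distinct(d$sample_id), nsamp),
           n_variants = nv,
           n_in_diagnosed_gene = in_diag,
           pct_in_diagnosed_gene = pct_of(in_diag, nv),
           n_in_other_panel_gene = nv - in_diag,
           pct_in_other_panel_gene = pct_of(nv - in_diag, nv),
           n_in_disease_db = in_db,
           pct_in_disease_db = pct_of(in_db, nv),
           n_not_in_disease_db = nv - in_db,
           pct_not_in_disease_db = pct_of(nv - in_db, nv))
  })
  out <- bind_rows(rows)
  stopifnot(all(out$n_in_diagnosed_gene + out$n_in_other_panel_gene ==
                  out$n_variants),
            all(out$n_in_disease_db + out$n_not_in_disease_db ==
                  out$n_variants))
  out
}

#' Other-risk table: C9orf72 expansion carriers and APOE genotypes
#'
#' @param samples Sample-metadata tibble with `sample_id`, `diagnosis` and
#'   logical `c9orf72_expansion`.
#' @param apoe_genotypes Character vector of called APOE genotypes
#'   parallel to `samples` rows.
#' @return Tibble with Total and per-diagnosis rows: `n`, C9orf72 carrier
#'   count and percentage, then count and percentage per APOE genotype.
#'   Percentages of each stratum's n, printed-table precision (two
#'   decimals below 10 percent, one above).
#' @export
other_risk_table <- function(samples, apoe_genotypes) {
  check_samples(samples)
  stopifnot(length(apoe_genotypes) == nrow(samples),
            all(apoe_genotypes %in% APOE_GENOTYPES))
  rows <- lapply(strata_of(samples$diagnosis), function(s) {
    sel <- if (s == "Total") rep(TRUE, nrow(samples))
    else samples$diagnosis == s
    d <- samples[sel, ]
    g <- apoe_genotypes[sel]
    n <- nrow(d)
    row <- tibble(diagnosis = s, n = n,
                  n_c9orf72 = sum(d$c9orf72_expansion),
                  pct_c9orf72 = fmt_pct_mixed(sum(d$c9orf72_expansion), n))
    cnt <- table(factor(g, levels = APOE_GENOTYPES))
    for (gt in APOE_GENOTYPES) {
      key <- gsub("/", "", tolower(gt))
      row[[paste0("n_", key)]] <- as.integer(cnt[[gt]])
      row[[paste0("pct_", key)]] <- fmt_pct_mixed(cnt[[gt]], n)
    }
    row
  })
  bind_rows(rows)
}

#' Sanger amplicon-count estimate
#'
#' How many PCR reactions would Sanger-sequencing the whole target need,
#' at a given amplicon capacity? For the 971,388 bp panel at 500 bp per
#' reaction this is 1,943 reactions.
#'
#' @param target_bp Total target size in base pairs.
#' @param bp_per_reaction Bases covered per reaction (default 500).
#' @return Integer reaction count (ceiling of the quotient).
#' @export
estimate_sanger_amplicons <- function(target_bp, bp_per_reaction = 500) {
  if (target_bp <= 0 || bp_per_reaction <= 0) {
    stop_input("target_bp and bp_per_reaction must be positive",
               "neuropanel_bad_input")
  }
  as.integer(ceiling(target_bp / bp_per_reaction))
}
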