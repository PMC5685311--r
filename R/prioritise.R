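#' Variant prioritisation and clinical dichotomisation
#'
#' Variants are first filtered on rarity (MAF < 1% in the population
#' databases) and consequence (missense, nonsense, frameshift, in-frame
#' indel, splicing). Survivors are dichotomised: *clinically relevant* if
#' previously reported in a disease database (HGMD or ClinVar) **and**
#' supported by in-silico predictions (PolyPhen-2/SIFT, with CADD as a
#' veto); otherwise *uncertain significance*. Each classified variant also
#' carries a gene-diagnosis concordance flag (is the gene's panel category
#' the one matching the carrier's diagnosis?).
#'
#' @name prioritise
NULL

QUALIFYING_CONSEQUENCES <- c("missense", "nonsense", "frameshift",
                             "inframe_indel", "splicing")

#' Prioritisation configuration
#'
#' @param maf_threshold Rarity cutoff as a fraction (default 0.01, i.e.
#'   MAF < 1%).
#' @param rarity_rule `"all_dbs"` (default): rare iff **every** database
#'   where the variant is present reports MAF below threshold; absence from
#'   all databases counts as rare. `"exac_only"`: only the ExAC MAF is
#'   consulted.
#' @param cadd_scale `"phred"` (default) or `"raw"`; determines the default
#'   `cadd_cutoff` (20 on the phred scale, 0 on the raw scale).
#' @param cadd_cutoff CADD score below which the damaging-prediction call
#'   is vetoed; a missing CADD never vetoes.
#' @param artifact_cohort_fraction Carrier fraction across the whole cohort
#'   above which a variant is flagged as a likely sequencing/alignment
#'   artifact (default 0.10). Flagged variants are reported, not dropped.
#' @return A list of class `prioritisation_config`.
#' @export
prioritisation_config <- function(maf_threshold = 0.01,
                                  rarity_rule = c("all_dbs", "exac_only"),
                                  cadd_scale = c("phred", "raw"),
                                  cadd_cutoff = NULL,
                                  artifact_cohort_fraction = 0.10) {
  rarity_rule <- match.arg(rarity_rule)
  cadd_scale <- match.arg(cadd_scale)
  cadd_cutoff <- cadd_cutoff %||% if (cadd_scale == "phred") 20 else 0
  if (!is.numeric(maf_threshold) || maf_threshold <= 0 || maf_threshold >= 1) {
    stop_input("maf_threshold must lie in (0, 1)", "neuropanel_bad_config")
  }
  if (!is.numeric(artifact_cohort_fraction) ||
      artifact_cohort_fraction <= 0 || artifact_cohort_fraction > 1) {
    stop_input("artifact_cohort_fraction must lie in (0, 1]",
               "neuropanel_bad_config")
  }
  structure(list(maf_threshold = maf_threshold, rarity_rule = rarity_rule,
                 cadd_scale = cadd_scale, cadd_cutoff = cadd_cutoff,
                 artifact_cohort_fraction = artifact_cohort_fraction),
            class = "prioritisation_config")
}

#' Read a prioritisation config from YAML or JSON
#'
#' The file may set any subset of the [prioritisation_config()] fields;
#' unset fields take their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `prioritisation_config`.
#' @export
read_prioritisation_config <- function(path) {
  if (!file.exists(path)) {
    stop_input(sprintf("config file not found: %s", path),
               "neuropanel_missing_file")
  }
  fields <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("maf_threshold", "rarity_rule", "cadd_scale", "cadd_cutoff",
             "artifact_cohort_fraction")
  bad <- setdiff(names(fields), known)
  if (length(bad) > 0) {
    stop_input(sprintf("unknown config field(s): %s",
                       paste(bad, collapse = ", ")),
               "neuropanel_bad_config")
  }
  do.call(prioritisation_config, fields)
}

#' Is a variant rare?
#'
#' Under the `all_dbs` rule, a variant is rare iff every database MAF that
#' is present falls below the threshold; a missing MAF ("not observed in
#' that database") never disqualifies, and a variant absent from all
#' databases is rare. Under `exac_only`, only `maf_exac` is consulted.
#'
#' @param maf_1000g,maf_esp,maf_exac Numeric MAF vectors (NA = absent).
#' @param config A [prioritisation_config()].
#' @return Logical vector.
#' @export
is_rare <- function(maf_1000g, maf_esp, maf_exac,
                    config = prioritisation_config()) {
  thr <- config$maf_threshold
  if (config$rarity_rule == "exac_only") {
    return(is.na(maf_exac) | maf_exac < thr)
  }
  (is.na(maf_1000g) | maf_1000g < thr) &
    (is.na(maf_esp) | maf_esp < thr) &
    (is.na(maf_exac) | maf_exac < thr)
}

#' Does a consequence qualify as potentially deleterious?
#'
#' TRUE for missense, nonsense, frameshift, in-frame indel and splicing;
#' FALSE for synonymous and noncoding; unknown tokens are an error.
#'
#' @param consequence Character vector of consequence tokens.
#' @return Logical vector.
#' @export
qualifying_consequence <- function(consequence) {
  bad <- setdiff(unique(consequence[!is.na(consequence)]),
                 KNOWN_CONSEQUENCES)
  if (length(bad) > 0) {
    stop_input(sprintf("unknown consequence token(s): %s",
                       paste(bad, collapse = ", ")),
               "neuropanel_bad_consequence")
  }
  consequence %in% QUALIFYING_CONSEQUENCES
}

#' Aggregate in-silico damaging predictions
#'
#' Support requires PolyPhen-2 in \{possibly_damaging, probably_damaging\}
#' OR SIFT = deleterious; a present CADD score below `cadd_cutoff` vetoes
#' the call. Returns `"true"`, `"false"` or `"unknown"` (the latter when
#' all three predictors are missing).
#'
#' @param polyphen,sift Character vectors (`NA` = missing).
#' @param cadd Numeric vector (`NA` = missing).
#' @inheritParams is_rare
#' @return Character vector over `c("true", "false", "unknown")`.
#' @export
predicted_damaging <- function(polyphen, sift, cadd,
                               config = prioritisation_config()) {
  support <- (polyphen %in% c("possibly_damaging", "probably_damaging")) |
    (sift %in% "deleterious")
  veto <- !is.na(cadd) & cadd < config$cadd_cutoff
  out <- ifelse(support & !veto, "true", "false")
  out[is.na(polyphen) & is.na(sift) & is.na(cadd)] <- "unknown"
  out
}

#' Classify annotated variants
#'
#' Applies the full rule set per row: off-panel genes and unannotated calls
#' are excluded (`OFF_PANEL`), then rarity (`NOT_RARE`) and consequence
#' (`NOT_QUALIFYING_CONSEQUENCE`) filters; survivors are
#' `clinically_relevant` iff in HGMD or ClinVar **and**
#' `predicted_damaging` is `"true"`, otherwise `uncertain_significance`.
#' `reason_codes` records, in rule order, the failed filter (excluded
#' variants) or the evidence trail (survivors).
#'
#' @param annotated Annotated-variant tibble from [join_annotations()].
#' @param samples Sample-metadata tibble with `sample_id` and `diagnosis`
#'   columns (diagnoses in `AD_MCI`, `ALS`, `FTD`, `PD`, `VCI`).
#' @param panel A [load_panel()] definition.
#' @inheritParams is_rare
#' @return The input tibble with `diagnosis`, `category`, `reason_codes`,
#'   `concordant_gene` and `recurrent_artifact` columns added.
#' @export
classify_variants <- function(annotated, samples, panel,
                              config = prioritisation_config()) {
  stopifnot(inherits(panel, "panel_definition"))
  diagnosis_category(unique(samples$diagnosis))  # validates
  av <- left_join(annotated,
                  samples[, c("sample_id", "diagnosis")],
                  by = "sample_id")
  if (anyNA(av$diagnosis)) {
    stop_input(sprintf("sample(s) missing from metadata: %s",
                       paste(unique(av$sample_id[is.na(av$diagnosis)]),
                             collapse = ", ")),
               "neuropanel_unknown_sample")
  }
  n <- nrow(av)
  if (n == 0) {
    av$category <- character()
    av$reason_codes <- character()
    av$concordant_gene <- logical()
    av$recurrent_artifact <- logical()
    return(av)
  }
  primary <- resolve_gene(panel, av$gene)
  on_panel <- !is.na(primary)
  rare <- is_rare(av$maf_1000g, av$maf_esp, av$maf_exac, config)
  qual <- rep(FALSE, n)
  qual[!is.na(av$consequence)] <-
    qualifying_consequence(av$consequence[!is.na(av$consequence)])
  damaging <- predicted_damaging(av$polyphen, av$sift, av$cadd, config)
  in_db <- (av$in_hgmd %missing% FALSE) | (av$in_clinvar %missing% FALSE)

  gene_cat <- panel$genes$disease_category[match(primary, panel$genes$symbol)]
  concord <- unname(!is.na(gene_cat) &
                      gene_cat == diagnosis_category(av$diagnosis))

  category <- character(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    r <- character()
    if (!on_panel[i]) r <- c(r, "OFF_PANEL")
    if (on_panel[i] && !rare[i]) r <- c(r, "NOT_RARE")
    if (on_panel[i] && !qual[i]) r <- c(r, "NOT_QUALIFYING_CONSEQUENCE")
    if (length(r) > 0) {
      category[i] <- "excluded"
    } else if (in_db[i] && damaging[i] == "true") {
      category[i] <- "clinically_relevant"
      r <- c("RARE", "QUALIFYING_CONSEQUENCE", "IN_DISEASE_DB",
             "PREDICTED_DAMAGING")
    } else {
      category[i] <- "uncertain_significance"
      r <- c("RARE", "QUALIFYING_CONSEQUENCE",
             if (!in_db[i]) "NOT_IN_DISEASE_DB",
             if (damaging[i] == "false") "PREDICTION_NOT_SUPPORTIVE",
             if (damaging[i] == "unknown") "PREDICTION_UNKNOWN")
    }
    reasons[i] <- paste(r, collapse = ",")
  }
  av$category <- category
  av$reason_codes <- reasons
  av$concordant_gene <- concord
  av$recurrent_artifact <- FALSE
  av
}

#' Classify a single variant
#'
#' Convenience scalar wrapper around [classify_variants()].
#'
#' @param variant One-row annotated-variant tibble (or list coercible to
#'   one) carrying the call and annotation fields.
#' @param diagnosis The carrier's diagnosis code.
#' @inheritParams classify_variants
#' @return One-row classified tibble.
#' @export
classify_variant <- function(variant, diagnosis, panel,
                             config = prioritisation_config()) {
  av <- as_tibble(variant)
  stopifnot(nrow(av) == 1)
  if (!"sample_id" %in% names(av)) av$sample_id <- "sample"
  samples <- tibble(sample_id = av$sample_id, diagnosis = diagnosis)
  classify_variants(av, samples, panel, config)
}

#' Flag recurrent artifacts across the cohort
#'
#' A variant key carried by more than `artifact_cohort_fraction` of the
#' cohort's samples is flagged as a likely sequencing or alignment
#' artifact; the flag is annotated, never silently dropped. Also annotates
#' `shared_in_diagnosis`, the number of samples with the same diagnosis
#' carrying the same variant.
#'
#' @param classified Cohort-wide classified tibble.
#' @param n_samples Total cohort size (denominator for carrier fraction).
#' @inheritParams is_rare
#' @return `classified` with `recurrent_artifact` and `shared_in_diagnosis`
#'   updated.
#' @export
flag_recurrent_artifacts <- function(classified, n_samples,
                                     config = prioritisation_config()) {
  stopifnot(n_samples >= 1)
  if (nrow(classified) == 0) {
    classified$shared_in_diagnosis <- integer()
    return(classified)
  }
  key <- paste(classified$chrom, classified$pos, classified$ref,
               classified$alt)
  carriers <- tapply(classified$sample_id, key,
                     function(s) length(unique(s)))
  frac <- as.numeric(carriers[key]) / n_samples
  classified$recurrent_artifact <- frac > config$artifact_cohort_fraction
  dkey <- paste(key, classified$diagnosis)
  dcar <- tapply(classified$sample_id, dkey, function(s) length(unique(s)))
  classified$shared_in_diagnosis <- as.integer(dcar[dkey])
  classified
}

#' Per-sample variant counts and the 0/1/2/3+ distribution
#'
#' Counts only non-excluded, non-artifact-flagged variants. Samples in
#' `sample_ids` with no qualifying variant count as zero, so the
#' distribution bins partition the cohort.
#'
#' @param classified Cohort-wide classified tibble (after
#'   [flag_recurrent_artifacts()]).
#' @param sample_ids Character vector of all cohort sample ids.
#' @return List with `counts` (tibble sample_id, n_variants) and
#'   `distribution` (tibble bin in `0`,`1`,`2`,`3+` and n).
#' @export
count_variants_per_sample <- function(classified, sample_ids) {
  keep <- classified$category != "excluded" & !classified$recurrent_artifact
  kept <- classified[keep, ]
  n_var <- table(factor(kept$sample_id, levels = sample_ids))
  counts <- tibble(sample_id = sample_ids, n_variants = as.integer(n_var))
  bins <- cut(counts$n_variants, breaks = c(-1, 0, 1, 2, Inf),
              labels = c("0", "1", "2", "3+"))
  distribution <- tibble(bin = c("0", "1", "2", "3+"),
                         n = as.integer(table(bins)))
  stopifnot(sum(distribution$n) == length(sample_ids))
  list(counts = counts, distribution = distribution)
}
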