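#' End-to-end cohort pipeline
#'
#' Wires the stages together over a bundle on disk: read sample metadata
#' and per-sample VCFs, join the annotation resource, classify and flag
#' artifacts, call APOE diplotypes, tabulate, and write the report files.
#'
#' @param metadata Path to the sample-metadata TSV (columns `sample_id`,
#'   `diagnosis`, `age`, `sex`, `ethnicity`, `family_history`,
#'   `c9orf72_expansion`, `gt_rs429358`, `gt_rs7412`).
#' @param vcf_dir Directory of per-sample VCFs named `<sample_id>.vcf`.
#' @param annotations Path to the annotation resource TSV.
#' @param out_dir Output directory (created if needed). Writes
#'   `classified_report.tsv`, `other_risk_table.tsv`, `yield_table.tsv`,
#'   `variant_origin_table.tsv` and `summary.json`.
#' @param panel Panel definition (default: the packaged 80-gene panel).
#' @param config A [prioritisation_config()].
#' @param quiet Suppress per-step progress messages.
#' @return Invisibly, a list with all intermediate and final tables.
#' @export
run_pipeline <- function(metadata, vcf_dir, annotations, out_dir,
                         panel = load_panel(),
                         config = prioritisation_config(),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  for (p in c(metadata, vcf_dir, annotations)) {
    if (!file.exists(p)) {
      stop_input(sprintf("pipeline input not found: %s", p),
                 "neuropanel_missing_file")
    }
  }
  samples <- readr::read_tsv(metadata, show_col_types = FALSE, na = ".",
                             progress = FALSE)
  check_samples(samples)
  say("step metadata: %d samples", nrow(samples))

  ann <- read_annotations(annotations)
  say("step annotations: %d records", nrow(ann))

  vcfs <- file.path(vcf_dir, paste0(samples$sample_id, ".vcf"))
  missing_vcfs <- vcfs[!file.exists(vcfs)]
  if (length(missing_vcfs) > 0) {
    stop_input(sprintf("missing VCF(s): %s",
                       paste(utils::head(missing_vcfs, 3), collapse = ", ")),
               "neuropanel_missing_file")
  }
  calls <- bind_rows(purrr::map2(vcfs, samples$sample_id, read_vcf))
  say("step vcf: %d calls", nrow(calls))

  annotated <- join_annotations(calls, ann)
  classified <- classify_variants(annotated, samples, panel, config)
  classified <- flag_recurrent_artifacts(classified, nrow(samples), config)
  say("step classify: %d clinically relevant, %d uncertain, %d excluded, %d artifact-flagged",
      sum(classified$category == "clinically_relevant"),
      sum(classified$category == "uncertain_significance"),
      sum(classified$category == "excluded"),
      sum(classified$recurrent_artifact))

  counted <- count_variants_per_sample(classified, samples$sample_id)

  dips <- call_apoe_diplotypes(samples$gt_rs429358, samples$gt_rs7412)
  say("step apoe: %d diplotypes (%d ambiguous)", nrow(dips),
      sum(dips$ambiguous))

  demo <- demographics_table(samples)
  yield <- yield_table(counted$counts, samples)
  origin <- variant_origin_table(classified, samples)
  risk <- other_risk_table(samples, dips$genotype)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report(classified, file.path(out_dir, "classified_report.tsv"))
  readr::write_tsv(risk, file.path(out_dir, "other_risk_table.tsv"),
                   na = ".", progress = FALSE)
  readr::write_tsv(yield, file.path(out_dir, "yield_table.tsv"),
                   na = ".", progress = FALSE)
  readr::write_tsv(origin, file.path(out_dir, "variant_origin_table.tsv"),
                   na = ".", progress = FALSE)

  apoe_counts <- table(factor(dips$genotype, levels = APOE_GENOTYPES))
  summary <- list(
    n_samples = nrow(samples),
    n_calls = nrow(calls),
    n_clinically_relevant = sum(classified$category == "clinically_relevant"),
    n_uncertain_significance =
      sum(classified$category == "uncertain_significance"),
    n_excluded = sum(classified$category == "excluded"),
    n_artifact_flagged = sum(classified$recurrent_artifact),
    yield_distribution = stats::setNames(as.list(counted$distribution$n),
                                         counted$distribution$bin),
    apoe_allele_frequencies =
      as.list(apoe_allele_frequencies(as.list(apoe_counts))),
    total_target_bp = panel$total_target_bp)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("step report: wrote 5 files to %s", out_dir)

  invisible(list(samples = samples, calls = calls, classified = classified,
                 counts = counted, diplotypes = dips, demographics = demo,
                 yield = yield, origin = origin, other_risk = risk,
                 summary = summary))
}
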