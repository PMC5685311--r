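#' Variant I/O: VCF reading, annotation joining, report writing
#'
#' Calls are held as one tibble row per sample-allele with columns
#' `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt`, `genotype`
#' (unphased allele pair such as `"G/A"`), `depth`. The annotation resource
#' is a TSV keyed by (`chrom`, `pos`, `ref`, `alt`) carrying gene,
#' consequence, per-database minor allele frequencies, PolyPhen-2/SIFT
#' categories, CADD score and HGMD/ClinVar membership. `"."` denotes
#' missing throughout.
#'
#' @name variant_io
NULL

KNOWN_CONSEQUENCES <- c("missense", "nonsense", "frameshift",
                        "inframe_indel", "splicing", "synonymous",
                        "noncoding")

ANNOTATION_COLS <- c("gene", "consequence", "maf_1000g", "maf_esp",
                     "maf_exac", "polyphen", "sift", "cadd",
                     "in_hgmd", "in_clinvar", "hgvs_c", "hgvs_p")

# Parsimony-trim a ref/alt pair: drop shared suffix, then shared prefix
# (always keeping at least one base of each), shifting pos right for each
# prefix base removed. Left-alignment against the reference genome is out
# of scope; keys are assumed already left-aligned by the caller.
normalise_variant <- function(pos, ref, alt) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Read a per-sample VCF into a call tibble
#'
#' Multi-allelic records are decomposed into biallelic calls (one row per
#' non-reference allele carried by the sample); genotypes are reported as
#' unphased allele pairs. Half-call genotypes (e.g. `./1`) are dropped with
#' a warning; hom-reference and fully missing genotypes yield no call.
#'
#' @param path Path to a VCF 4.x file (uncompressed or bgzipped).
#' @param sample_id Sample identifier to assign; defaults to the VCF sample
#'   column name.
#' @return Tibble of calls (possibly zero rows).
#' @export
read_vcf <- function(path, sample_id = NULL) {
  if (!file.exists(path)) {
    stop_input(sprintf("VCF not found: %s", path), "neuropanel_missing_file")
  }
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) {
      stop_input(sprintf("malformed VCF %s: %s", path, conditionMessage(e)),
                 "neuropanel_bad_vcf")
    })
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(sample_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  genotype = character(), depth = integer()))
  }
  if (ncol(v@gt) < 2) {
    stop_input(sprintf("VCF %s has no sample column", path),
               "neuropanel_bad_vcf")
  }
  vcf_sample <- colnames(v@gt)[2]
  sample_id <- sample_id %||% vcf_sample
  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- which(is.na(pos) | pos < 1)
  if (length(bad) > 0) {
    stop_input(sprintf("VCF %s record %d: invalid POS '%s' (1-based positions required)",
                       path, bad[1], fix$POS[bad[1]]),
               "neuropanel_bad_vcf")
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")[, vcf_sample]
  dp_raw <- suppressWarnings(
    as.integer(vcfR::extract.gt(v, element = "DP")[, vcf_sample]))

  rows <- vector("list", nrow(fix))
  n_half <- 0L
  for (i in seq_len(nrow(fix))) {
    gt <- gt_raw[i]
    if (is.na(gt)) next
    alleles_idx <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)[[1]]
    if (length(alleles_idx) != 2) {
      stop_input(sprintf("VCF %s record %d: non-diploid genotype '%s'",
                         path, i, gt), "neuropanel_bad_vcf")
    }
    if (any(alleles_idx == ".")) {
      if (!all(alleles_idx == ".")) n_half <- n_half + 1L
      next
    }
    idx <- as.integer(alleles_idx)
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    allele_str <- c(fix$REF[i], alts)[idx + 1]
    carried <- sort(unique(idx[idx > 0]))
    if (length(carried) == 0) next
    sub <- lapply(carried, function(a) {
      nv <- normalise_variant(pos[i], fix$REF[i], alts[a])
      tibble(sample_id = sample_id, chrom = fix$CHROM[i], pos = nv$pos,
             ref = nv$ref, alt = nv$alt,
             genotype = paste(allele_str, collapse = "/"),
             depth = dp_raw[i])
    })
    rows[[i]] <- bind_rows(sub)
  }
  if (n_half > 0) {
    warn(sprintf("%s: dropped %d half-call genotype(s)", path, n_half))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(sample_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  genotype = character(), depth = integer()))
  }
  out
}

#' Read an annotation resource TSV
#'
#' @param path TSV with header columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`, `maf_1000g`, `maf_esp`, `maf_exac`, `polyphen`,
#'   `sift`, `cadd`, `in_hgmd`, `in_clinvar`, `hgvs_c`, `hgvs_p`;
#'   `"."` for missing.
#' @return Tibble keyed uniquely by (chrom, pos, ref, alt).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop_input(sprintf("annotation resource not found: %s", path),
               "neuropanel_missing_file")
  }
  ann <- readr::read_tsv(
    path, show_col_types = FALSE, na = ".", progress = FALSE,
    col_types = readr::cols(
      chrom = "c", pos = "i", ref = "c", alt = "c", gene = "c",
      consequence = "c", maf_1000g = "d", maf_esp = "d", maf_exac = "d",
      polyphen = "c", sift = "c", cadd = "d", in_hgmd = "l",
      in_clinvar = "l", hgvs_c = "c", hgvs_p = "c"))
  check_annotation_table(ann)
  ann
}

check_annotation_table <- function(ann) {
  key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(key)) {
    stop_input(sprintf("duplicate annotation key(s): %s",
                       paste(unique(key[duplicated(key)])[1], collapse = ", ")),
               "neuropanel_duplicate_key")
  }
  mafs <- c(ann$maf_1000g, ann$maf_esp, ann$maf_exac)
  if (any(!is.na(mafs) & (mafs < 0 | mafs > 1))) {
    stop_input("MAF outside [0, 1] in annotation resource",
               "neuropanel_bad_annotation")
  }
  invisible(ann)
}

#' Join calls to the annotation resource
#'
#' Exact-match join on (chrom, pos, ref, alt). Unmatched calls are retained
#' with all annotation fields missing and `annotated = FALSE`; output row
#' count always equals input call count.
#'
#' @param calls Call tibble from [read_vcf()].
#' @param annotations Annotation tibble from [read_annotations()].
#' @return Annotated-variant tibble.
#' @export
join_annotations <- function(calls, annotations) {
  check_annotation_table(annotations)
  ann <- annotations[, c("chrom", "pos", "ref", "alt", ANNOTATION_COLS)]
  out <- left_join(calls, ann, by = c("chrom", "pos", "ref", "alt"))
  key_call <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
  key_ann <- paste(ann$chrom, ann$pos, ann$ref, ann$alt)
  out$annotated <- key_call %in% key_ann
  stopifnot(nrow(out) == nrow(calls))
  out
}

REPORT_COLS <- c("sample_id", "diagnosis", "chrom", "pos", "ref", "alt",
                 "genotype", "depth", ANNOTATION_COLS, "annotated",
                 "category", "reason_codes", "concordant_gene",
                 "recurrent_artifact")

#' Write / read a classified-variant report
#'
#' TSV with one row per sample-variant, deterministically ordered by
#' (sample_id, chrom, pos, alt); `"."` for missing. `read_report()` inverts
#' `write_report()` losslessly.
#'
#' @param classified Classified-variant tibble from [classify_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(classified, path) {
  if (!dir.exists(dirname(path))) {
    stop_input(sprintf("unwritable path: %s", path), "neuropanel_bad_path")
  }
  out <- classified
  for (col in setdiff(REPORT_COLS, names(out))) out[[col]] <- NA
  out <- out[, REPORT_COLS]
  out <- arrange(out, .data$sample_id, .data$chrom, .data$pos, .data$alt)
  readr::write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_tsv(
    path, show_col_types = FALSE, na = ".", progress = FALSE,
    col_types = readr::cols(
      sample_id = "c", diagnosis = "c", chrom = "c", pos = "i", ref = "c",
      alt = "c", genotype = "c", depth = "i", gene = "c", consequence = "c",
      maf_1000g = "d", maf_esp = "d", maf_exac = "d", polyphen = "c",
      sift = "c", cadd = "d", in_hgmd = "l", in_clinvar = "l", hgvs_c = "c",
      hgvs_p = "c", annotated = "l", category = "c", reason_codes = "c",
      concordant_gene = "l", recurrent_artifact = "l"))
}

# Write an annotation resource TSV (used by the simulator and tests).
#' @rdname read_annotations
#' @param annotations Annotation tibble to write.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, na = ".", progress = FALSE)
  invisible(path)
}
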