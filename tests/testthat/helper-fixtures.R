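# Shared fixture builders; everything is generated in code.

the_panel <- neuropanel::load_panel()

make_annotation <- function(chrom = "21", pos = 1000L, ref = "G", alt = "A",
                            gene = "APP", consequence = "missense",
                            maf_1000g = NA_real_, maf_esp = NA_real_,
                            maf_exac = NA_real_, polyphen = NA_character_,
                            sift = NA_character_, cadd = NA_real_,
                            in_hgmd = FALSE, in_clinvar = FALSE,
                            hgvs_c = NA_character_, hgvs_p = NA_character_) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 gene = gene, consequence = consequence,
                 maf_1000g = maf_1000g, maf_esp = maf_esp,
                 maf_exac = maf_exac, polyphen = polyphen, sift = sift,
                 cadd = cadd, in_hgmd = in_hgmd, in_clinvar = in_clinvar,
                 hgvs_c = hgvs_c, hgvs_p = hgvs_p)
}

make_call <- function(sample_id = "S1", chrom = "21", pos = 1000L,
                      ref = "G", alt = "A", genotype = "G/A",
                      depth = 50L) {
  tibble::tibble(sample_id = sample_id, chrom = chrom,
                 pos = as.integer(pos), ref = ref, alt = alt,
                 genotype = genotype, depth = as.integer(depth))
}

make_av <- function(sample_id = "S1", ...) {
  ann <- make_annotation(...)
  dplyr::bind_cols(
    make_call(sample_id = sample_id, chrom = ann$chrom, pos = ann$pos,
              ref = ann$ref, alt = ann$alt),
    ann[, setdiff(names(ann), c("chrom", "pos", "ref", "alt"))])
}

write_vcf_text <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"))
  writeLines(c(header, lines), path)
  path
}

# Per-stratum fixture matching the published diagnostic-yield counts.
yield_fixture <- function() {
  spec <- tibble::tibble(
    diagnosis = c("AD_MCI", "ALS", "FTD", "PD", "VCI"),
    n0 = c(7, 6, 4, 16, 27), n1 = c(18, 6, 9, 22, 21),
    n2 = c(10, 8, 7, 13, 19), n3 = c(5, 2, 1, 5, 10))
  rows <- purrr::pmap(spec, function(diagnosis, n0, n1, n2, n3) {
    tibble::tibble(diagnosis = diagnosis,
                   n_variants = rep(c(0L, 1L, 2L, 3L), c(n0, n1, n2, n3)))
  })
  x <- dplyr::bind_rows(rows)
  x$sample_id <- sprintf("S%03d", seq_len(nrow(x)))
  x
}

# Per-stratum fixture matching the published variant-origin counts.
origin_fixture <- function() {
  spec <- tibble::tibble(
    diagnosis = c("AD_MCI", "ALS", "FTD", "PD", "VCI"),
    n_diag = c(40, 22, 21, 56, 77),
    n_with = c(33, 16, 17, 40, 50),
    nv = c(55, 28, 27, 63, 93),
    in_diag = c(19, 17, 12, 31, 28),
    in_db = c(12, 10, 3, 11, 26))
  samples <- dplyr::bind_rows(purrr::pmap(
    spec[, c("diagnosis", "n_diag")],
    function(diagnosis, n_diag) {
      tibble::tibble(diagnosis = diagnosis,
                     sample_id = sprintf("%s_%03d", diagnosis,
                                         seq_len(n_diag)))
    }))
  classified <- dplyr::bind_rows(purrr::pmap(
    spec, function(diagnosis, n_diag, n_with, nv, in_diag, in_db) {
      tibble::tibble(
        diagnosis = diagnosis,
        sample_id = sprintf("%s_%03d", diagnosis,
                            ((seq_len(nv) - 1) %% n_with) + 1),
        category = "uncertain_significance",
        concordant_gene = seq_len(nv) <= in_diag,
        in_hgmd = seq_len(nv) <= in_db,
        in_clinvar = FALSE,
        recurrent_artifact = FALSE)
    }))
  list(samples = samples, classified = classified)
}

# Independent brute-force oracle for the classification rules: plain
# nested conditionals over precomputed predicates, written without
# reference to classify_variants().
oracle_classify <- function(on_panel, rare, qualifying, in_db, damaging) {
  if (!on_panel) return("excluded")
  if (!rare) return("excluded")
  if (!qualifying) return("excluded")
  if (in_db && identical(damaging, "true")) return("clinically_relevant")
  "uncertain_significance"
}

# Independent APOE oracle: enumerate both phasings of the unphased pair
# under the codon-112/158 haplotype code and drop any involving E1.
oracle_apoe <- function(gt1, gt2) {
  a <- strsplit(gt1, "/")[[1]]
  b <- strsplit(gt2, "/")[[1]]
  hap <- function(x, y) {
    if (x == "T" && y == "T") "E2"
    else if (x == "T" && y == "C") "E3"
    else if (x == "C" && y == "C") "E4"
    else "E1"
  }
  phasings <- unique(list(sort(c(hap(a[1], b[1]), hap(a[2], b[2]))),
                          sort(c(hap(a[1], b[2]), hap(a[2], b[1])))))
  valid <- Filter(function(p) !"E1" %in% p, phasings)
  if (length(valid) == 0) return(NULL)
  list(genotype = paste(valid[[1]], collapse = "/"),
       ambiguous = length(phasings) > 1)
}
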