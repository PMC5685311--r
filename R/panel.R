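#' Panel model: the 80-gene neurodegeneration panel
#'
#' The panel assigns each of its 80 genes to one of four disease categories:
#' `ALS_FTD` (amyotrophic lateral sclerosis / frontotemporal dementia, a
#' joint category), `AD_MCI` (Alzheimer's disease / mild cognitive
#' impairment), `PD` (Parkinson's disease) and `VCI` (vascular cognitive
#' impairment). Clinical diagnoses are coded `AD_MCI`, `ALS`, `FTD`, `PD`,
#' `VCI`; the two joint categories cover two diagnoses each.
#'
#' @name panel_model
NULL

PANEL_CATEGORIES <- c("ALS_FTD", "AD_MCI", "PD", "VCI")
DIAGNOSES <- c("AD_MCI", "ALS", "FTD", "PD", "VCI")

# diagnosis -> panel category
diagnosis_category <- function(diagnosis) {
  if (!is.character(diagnosis) || anyNA(diagnosis) ||
      !all(diagnosis %in% DIAGNOSES)) {
    bad <- setdiff(unique(as.character(diagnosis)), DIAGNOSES)
    stop_input(
      sprintf("unknown diagnosis: %s (expected one of %s)",
              paste(bad, collapse = ", "), paste(DIAGNOSES, collapse = ", ")),
      "neuropanel_unknown_diagnosis")
  }
  c(AD_MCI = "AD_MCI", ALS = "ALS_FTD", FTD = "ALS_FTD",
    PD = "PD", VCI = "VCI")[diagnosis]
}

#' Load a panel definition
#'
#' Reads the gene table (TSV with columns `symbol`, `alias`,
#' `chromosomal_location`, `disease_category`, `associated_phenotype`,
#' `inheritance_note`) and the target intervals (BED3+, 0-based half-open)
#' and returns a `panel_definition` object. The packaged resource describes
#' an 80-gene panel with a total target size of 971,388 bp; its BED is a
#' synthetic stand-in (one interval per gene) because only the total target
#' size, not probe coordinates, is published.
#'
#' @param genes_tsv Path to the gene table TSV.
#' @param targets_bed Path to the target BED file.
#' @return A list of class `panel_definition` with elements `genes`
#'   (tibble), `targets` (tibble: chrom, start, end, symbol) and
#'   `total_target_bp`.
#' @examples
#' panel <- load_panel()
#' nrow(panel$genes)       # 80
#' panel$total_target_bp   # 971388
#' @export
load_panel <- function(genes_tsv = panel_resource("panel_genes.tsv"),
                       targets_bed = panel_resource("panel_targets_synthetic.bed")) {
  if (!file.exists(genes_tsv)) {
    stop_input(sprintf("panel gene table not found: %s", genes_tsv),
               "neuropanel_missing_file")
  }
  if (!file.exists(targets_bed)) {
    stop_input(sprintf("panel target BED not found: %s", targets_bed),
               "neuropanel_missing_file")
  }
  genes <- readr::read_tsv(genes_tsv, show_col_types = FALSE,
                           na = ".", progress = FALSE)
  required <- c("symbol", "chromosomal_location", "disease_category")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop_input(sprintf("panel gene table lacks columns: %s",
                       paste(missing_cols, collapse = ", ")),
               "neuropanel_bad_panel")
  }
  if (nrow(genes) == 0) {
    stop_input("panel gene table is empty", "neuropanel_bad_panel")
  }
  if (anyDuplicated(genes$symbol)) {
    stop_input(sprintf("duplicate gene symbol(s): %s",
                       paste(unique(genes$symbol[duplicated(genes$symbol)]),
                             collapse = ", ")),
               "neuropanel_bad_panel")
  }
  bad_cat <- setdiff(unique(genes$disease_category), PANEL_CATEGORIES)
  if (length(bad_cat) > 0) {
    stop_input(sprintf("unknown disease_category token(s): %s",
                       paste(bad_cat, collapse = ", ")),
               "neuropanel_bad_panel")
  }
  if (!"alias" %in% names(genes)) genes$alias <- NA_character_
  targets <- readr::read_tsv(
    targets_bed, show_col_types = FALSE, progress = FALSE,
    col_names = c("chrom", "start", "end", "symbol"),
    col_types = readr::cols(chrom = "c", start = "i", end = "i", symbol = "c"))
  if (any(targets$end < targets$start)) {
    stop_input("target interval with negative length", "neuropanel_bad_panel")
  }
  structure(
    list(genes = genes,
         targets = targets,
         total_target_bp = sum(targets$end - targets$start)),
    class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("<panel_definition> %d genes, %d target intervals, %s bp\n",
              nrow(x$genes), nrow(x$targets),
              format(x$total_target_bp, big.mark = ",")))
  print(table(x$genes$disease_category))
  invisible(x)
}

panel_resource <- function(file) {
  system.file("extdata", file, package = "neuropanel", mustWork = TRUE)
}

# Resolve a possibly-aliased symbol (e.g. PRKN -> PARK2, DJ1 -> PARK7,
# STH -> MAPT) to the panel's primary symbol; NA if not on panel.
resolve_gene <- function(panel, gene) {
  idx <- match(gene, panel$genes$symbol)
  alias_idx <- match(gene, panel$genes$alias)
  out <- panel$genes$symbol[ifelse(is.na(idx), alias_idx, idx)]
  out
}

#' Genes assigned to a clinical diagnosis
#'
#' ALS and FTD both map to the joint `ALS_FTD` category; AD and MCI share
#' `AD_MCI`.
#'
#' @param panel A `panel_definition`.
#' @param diagnosis One of `"AD_MCI"`, `"ALS"`, `"FTD"`, `"PD"`, `"VCI"`.
#' @return Character vector of gene symbols.
#' @export
genes_for_disease <- function(panel, diagnosis) {
  stopifnot(inherits(panel, "panel_definition"), length(diagnosis) == 1)
  cat_ <- diagnosis_category(diagnosis)
  panel$genes$symbol[panel$genes$disease_category == cat_]
}

#' Is a gene concordant with a diagnosis?
#'
#' TRUE iff the gene's panel category covers the diagnosis (variants in such
#' genes are "in the disease gene as diagnosed"). Aliases resolve to their
#' primary symbol.
#'
#' @inheritParams genes_for_disease
#' @param gene Gene symbol (alias accepted).
#' @return Logical scalar.
#' @export
is_concordant_gene <- function(panel, gene, diagnosis) {
  stopifnot(inherits(panel, "panel_definition"), length(gene) == 1)
  primary <- resolve_gene(panel, gene)
  if (is.na(primary)) {
    stop_input(sprintf("gene not on panel: %s", gene),
               "neuropanel_off_panel")
  }
  cat_ <- diagnosis_category(diagnosis)
  unname(panel$genes$disease_category[match(primary, panel$genes$symbol)] ==
           cat_)
}
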