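#' Sequencing-run quality control
#'
#' Per-run metrics mirror the standard amplicon-panel QC sheet: reads
#' passing filter (integer percent of total reads), mapped reads, the
#' fraction of mapped reads at or above Q30, the fraction of target bases
#' covered by at least 30 reads (one decimal), and mean/min/max target
#' coverage.
#'
#' @name run_qc
NULL

#' Build a run-QC input object
#'
#' @param total_reads,reads_pf,mapped_reads,reads_ge_q30 Read counts;
#'   must satisfy reads_ge_q30 <= mapped_reads <= reads_pf <= total_reads.
#'   `reads_ge_q30` counts mapped reads whose mean base quality is >= Q30.
#' @param per_base_depths Integer vector of aligned depth at every target
#'   base.
#' @param cluster_density Optional, thousands of clusters per mm^2.
#' @return A list of class `run_qc_input`.
#' @export
run_qc_input <- function(total_reads, reads_pf, mapped_reads,
                         reads_ge_q30, per_base_depths,
                         cluster_density = NA_real_) {
  if (total_reads <= 0) {
    stop_input("total_reads must be positive", "neuropanel_bad_qc_input")
  }
  if (length(per_base_depths) == 0) {
    stop_input("per_base_depths is empty", "neuropanel_bad_qc_input")
  }
  if (reads_pf > total_reads || mapped_reads > reads_pf ||
      reads_ge_q30 > mapped_reads || any(per_base_depths < 0)) {
    stop_input("run QC read-count invariants violated (require q30 <= mapped <= PF <= total, depths >= 0)",
               "neuropanel_bad_qc_input")
  }
  structure(list(total_reads = total_reads, reads_pf = reads_pf,
                 mapped_reads = mapped_reads, reads_ge_q30 = reads_ge_q30,
                 per_base_depths = as.numeric(per_base_depths),
                 cluster_density = cluster_density),
            class = "run_qc_input")
}

#' Compute run-level QC metrics
#'
#' @param input A [run_qc_input()].
#' @return One-row tibble: `pct_reads_pf` (integer percent), `pct_mapped`
#'   and `pct_q30` (one decimal), `pct_target_ge_30x` (one decimal),
#'   `mean_cov` (one decimal), `min_cov`, `max_cov`.
#' @examples
#' d <- rep(30, 100)
#' compute_run_metrics(run_qc_input(29.1e6, 24.1e6, 22e6, 20e6, d))
#' @export
compute_run_metrics <- function(input) {
  stopifnot(inherits(input, "run_qc_input"))
  d <- input$per_base_depths
  tibble(
    pct_reads_pf = round_half_up(100 * input$reads_pf / input$total_reads, 0),
    pct_mapped = round_half_up(100 * input$mapped_reads / input$reads_pf, 1),
    pct_q30 = round_half_up(100 * input$reads_ge_q30 / input$mapped_reads, 1),
    pct_target_ge_30x = round_half_up(100 * sum(d >= 30) / length(d), 1),
    mean_cov = round_half_up(mean(d), 1),
    min_cov = min(d),
    max_cov = max(d))
}

#' Evaluate pass/fail thresholds on run metrics
#'
#' @param metrics One-row tibble from [compute_run_metrics()].
#' @param thresholds Named list of lower bounds on metric columns, e.g.
#'   `list(pct_target_ge_30x = 80, pct_q30 = 85)`. An empty list passes.
#' @return List: `pass` (logical) and `failing` (character vector of
#'   metric names below their bound).
#' @export
run_passes <- function(metrics, thresholds = list()) {
  bad <- setdiff(names(thresholds), names(metrics))
  if (length(bad) > 0) {
    stop_input(sprintf("unknown metric(s) in thresholds: %s",
                       paste(bad, collapse = ", ")),
               "neuropanel_bad_config")
  }
  failing <- names(thresholds)[vapply(
    names(thresholds),
    function(m) metrics[[m]] < thresholds[[m]], logical(1))]
  list(pass = length(failing) == 0, failing = failing)
}
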