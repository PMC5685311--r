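#' @importFrom rlang abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join full_join bind_rows n_distinct across row_number rename
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rbinom rnbinom rnorm rpois runif setNames
NULL

# Round half away from zero (printed tables use commercial rounding, not
# banker's rounding as in base round()).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage of num/den at `digits` decimals; NA when den == 0.
pct_of <- function(num, den, digits = 1) {
  ifelse(den == 0, NA_real_, round_half_up(100 * num / den, digits))
}

# Printed-table percentage style: two decimals below 10%, one decimal above,
# matching the precision used for small risk-genotype percentages.
fmt_pct_mixed <- function(num, den) {
  raw <- ifelse(den == 0, 0, 100 * num / den)
  ifelse(raw < 10, round_half_up(raw, 2), round_half_up(raw, 1))
}

stop_input <- function(msg, class) {
  abort(msg, class = c(class, "neuropanel_error"))
}

`%missing%` <- function(x, default) ifelse(is.na(x), default, x)
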