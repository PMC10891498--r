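# Published summary statistics from a relative-validity study of a
# smartphone food record against same-day 24-hour dietary recalls
# (n = 211 adults with plausible energy intakes). The study's raw survey
# data are not deposited; these printed per-variable summaries are shipped
# as fixed inputs so that downstream rules (relevance flagging, medians of
# correlations, tallies) can be exercised and checked against the
# published counts, and so that the synthetic-data generator can default
# to realistic, study-shaped conditions.

#' Parse a p-value as printed in a results table
#'
#' Published tables print truncated p-values such as `".005"` or
#' `"<.001"`. A `"<x"` entry is mapped to the bound `x` itself, which is
#' sufficient for every rule of the form p below a threshold not tighter
#' than the bound.
#'
#' @param p Character vector of printed p-values (`NA` allowed).
#' @return Numeric vector.
#' @export
#' @examples
#' parse_printed_p(c(".005", "<.001", ".05"))
parse_printed_p <- function(p) {
  p <- trimws(as.character(p))
  p <- stringr::str_remove(p, "^<")
  suppressWarnings(as.numeric(p))
}

read_reference <- function(file) {
  readr::read_tsv(dv_extdata(file), show_col_types = FALSE, progress = FALSE)
}

#' Published reference summaries
#'
#' Accessors for the shipped per-variable summaries of the validation
#' study (test method "a" = smartphone food record, reference method "b" =
#' 24-hour dietary recall, same day, n = 211):
#'
#' * `reference_food_group_table()` — the 16 food groups whose 75th
#'   percentile was positive under at least one method: mean (SD), median
#'   (IQR) per method, signed rank p-value as printed (`p_printed`, with a
#'   parsed numeric `p_value`), and the Spearman correlation.
#' * `reference_nutrient_table()` — the same layout for 29 nutrients,
#'   with a `unit` column.
#' * `reference_consumer_table()` — all 19 food groups: consumer counts,
#'   consumers-only medians, McNemar and consumers-only signed rank
#'   p-values as printed.
#' * `reference_recording_modes()` — entry counts per food-identification
#'   mode (894 recorded items).
#'
#' @return A tibble (see above).
#' @export
reference_food_group_table <- function() {
  tab <- read_reference("reference_food_group_summary.tsv")
  tab$p_value <- parse_printed_p(tab$p_printed)
  tab
}

#' @rdname reference_food_group_table
#' @export
reference_nutrient_table <- function() {
  tab <- read_reference("reference_nutrient_summary.tsv")
  tab$p_value <- parse_printed_p(tab$p_printed)
  tab
}

#' @rdname reference_food_group_table
#' @export
reference_consumer_table <- function() {
  tab <- read_reference("reference_consumer_summary.tsv")
  tab$mcnemar_p <- parse_printed_p(tab$mcnemar_p_printed)
  tab$wilcoxon_p <- parse_printed_p(tab$wilcoxon_p_printed)
  tab
}

#' @rdname reference_food_group_table
#' @export
reference_recording_modes <- function() {
  read_reference("reference_recording_modes.tsv")
}
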