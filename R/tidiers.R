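# broom-style accessors for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn bland_altman One-row tibble of agreement statistics.
#' @param x A `dv_bland_altman` object.
#' @param ... Unused.
#' @export
tidy.dv_bland_altman <- function(x, ...) {
  tibble(
    n = x$n,
    mean_difference = x$mean_difference,
    sd_difference = x$sd_difference,
    loa_low = x$loa_low,
    loa_high = x$loa_high
  )
}

#' @describeIn compare_tables The per-variable paired comparison tibble.
#' @param x A `dv_comparison` object.
#' @param ... Unused.
#' @export
tidy.dv_comparison <- function(x, ...) x$paired

#' @describeIn compare_tables One-row summary: variables compared, relevant
#'   differences, median correlation.
#' @export
glance.dv_comparison <- function(x, ...) {
  tibble(
    n_variables = nrow(x$paired),
    n_pairs = if (nrow(x$paired)) x$paired$n[1] else 0L,
    n_relevant = sum(x$paired$relevant_difference, na.rm = TRUE),
    median_spearman = median_of_correlations(x$paired$spearman_rho)
  )
}

#' @describeIn run_study The paired comparison table of a study run.
#' @param x A `dv_study` object.
#' @param ... Unused.
#' @export
tidy.dv_study <- function(x, ...) x$comparison$paired

#' @describeIn run_study One-row study summary.
#' @export
glance.dv_study <- function(x, ...) {
  ba <- tidy(x$bland_altman_energy)
  tibble(
    n_analysed = x$n_analysed,
    n_variables = nrow(x$comparison$paired),
    n_relevant = sum(x$comparison$paired$relevant_difference, na.rm = TRUE),
    median_spearman = median_of_correlations(x$comparison$paired$spearman_rho),
    energy_mean_difference = ba$mean_difference,
    energy_loa_low = ba$loa_low,
    energy_loa_high = ba$loa_high,
    mean_underreporting_pct = x$misreporting$mean_underreporting_pct
  )
}
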