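# Building the study's result tables: paired comparisons per variable,
# consumer comparisons per food group, stratified variants, recording-mode
# tallies, and usability-questionnaire scoring.

#' BMI class (3 classes)
#'
#' @param bmi_kg_m2 Numeric BMI values.
#' @param cuts Lower bounds of the upper two classes, default 25 and 30.
#' @return Character vector: `"under_25"`, `"25_to_30"`, `"30_plus"`.
#' @export
bmi_class <- function(bmi_kg_m2, cuts = c(25, 30)) {
  case_when(
    bmi_kg_m2 < cuts[1] ~ "under_25",
    bmi_kg_m2 < cuts[2] ~ "25_to_30",
    TRUE ~ "30_plus"
  )
}

paired_comparison_rows <- function(joined, variables) {
  purrr::map_dfr(variables, function(v) {
    a <- joined[[paste0(v, "_a")]]
    b <- joined[[paste0(v, "_b")]]
    w <- wilcoxon_signed_rank(a - b)
    rho <- if (length(a) >= 3) suppressWarnings(spearman_rho(a, b)) else NA_real_
    flag <- relevance_flag(median(a), median(b), w$p_value)
    tibble(
      variable = v, n = length(a),
      mean_a = mean(a), sd_a = sd(a),
      median_a = median(a),
      q25_a = unname(quantile(a, 0.25)), q75_a = unname(quantile(a, 0.75)),
      mean_b = mean(b), sd_b = sd(b),
      median_b = median(b),
      q25_b = unname(quantile(b, 0.25)), q75_b = unname(quantile(b, 0.75)),
      wilcoxon_p = w$p_value,
      spearman_rho = rho,
      relevant_difference = flag$relevant,
      direction = flag$direction
    )
  })
}

consumer_comparison_rows <- function(joined, variables) {
  purrr::map_dfr(variables, function(v) {
    a <- joined[[paste0(v, "_a")]]
    b <- joined[[paste0(v, "_b")]]
    ca <- a > 0
    cb <- b > 0
    mc <- suppressWarnings(mcnemar(ca, cb))
    both <- ca & cb
    w_cons <- if (sum(both) >= 1 && any(a[both] - b[both] != 0)) {
      wilcoxon_signed_rank(a[both] - b[both])$p_value
    } else {
      NA_real_
    }
    tibble(
      variable = v, n = length(a),
      consumers_a = sum(ca), consumers_b = sum(cb),
      median_consumers_a = if (any(ca)) median(a[ca]) else NA_real_,
      median_consumers_b = if (any(cb)) median(b[cb]) else NA_real_,
      mcnemar_p = mc$p_value,
      consumers_wilcoxon_p = w_cons
    )
  })
}

#' Paired-method comparison tables
#'
#' The full comparison battery for two daily-intake tables covering the
#' same participants on the same day: per variable, location and spread
#' under each method, the Wilcoxon signed rank p-value on paired
#' differences, the Spearman rank correlation, and the >10% relevance
#' flag against the reference method (method B). Food groups whose 75th
#' percentile is zero under both methods are excluded from the main table
#' (they remain in the consumer table). A consumer table reports consumer
#' counts, the McNemar test on being a consumer, and consumers-only
#' medians with a signed rank test over pairs consuming under both
#' methods. Optional stratified variants repeat the main table within
#' strata of education and/or BMI class.
#'
#' @param daily_a Daily totals under the test method (e.g. an app food
#'   record), from [daily_totals()].
#' @param daily_b Daily totals under the reference method (e.g. 24-hour
#'   dietary recalls), same participants and day.
#' @param variables Columns to compare; defaults to the food-group
#'   columns. Consumer rows are built for variables that are food groups.
#' @param roster Participant roster; required when `strata` is given.
#' @param strata Character subset of `c("education", "bmi")`.
#' @param p75_filter Apply the 75th-percentile-positive reporting filter
#'   to the main table, default `TRUE`.
#' @return An object of class `dv_comparison`: list with tibbles `paired`
#'   and `consumers`, and (when requested) `strata`, a named list of
#'   per-stratum paired tibbles. Supports `tidy()` and `glance()`.
#' @export
compare_tables <- function(daily_a, daily_b, variables = NULL, roster = NULL,
                           strata = NULL, p75_filter = TRUE) {
  daily_a <- as_tibble(daily_a)
  daily_b <- as_tibble(daily_b)
  groups <- intersect(wheel_of_five_groups(), names(daily_a))
  variables <- variables %||% groups
  missing_v <- setdiff(variables, intersect(names(daily_a), names(daily_b)))
  if (length(missing_v)) {
    abort(paste0(
      "variable(s) absent from both methods: ",
      paste(missing_v, collapse = ", ")
    ))
  }
  keys <- intersect(c("participant_id", "day_index"), names(daily_a))
  joined <- dplyr::inner_join(
    daily_a[c(keys, variables)], daily_b[c(keys, variables)],
    by = keys, suffix = c("_a", "_b")
  ) %>%
    arrange(.data$participant_id)
  if (nrow(joined) == 0) abort("no paired participant-days between methods")

  paired <- paired_comparison_rows(joined, variables)
  group_vars <- intersect(variables, groups)
  consumers <- consumer_comparison_rows(joined, group_vars)

  if (p75_filter) {
    drop <- paired$variable %in% group_vars &
      paired$q75_a == 0 & paired$q75_b == 0
    paired <- paired[!drop, ]
  }

  out <- list(paired = paired, consumers = consumers)
  if (!is.null(strata)) {
    if (is.null(roster)) abort("stratified comparison needs a roster")
    strata <- match.arg(strata, c("education", "bmi"), several.ok = TRUE)
    roster <- as_tibble(roster)
    if (!"bmi_kg_m2" %in% names(roster)) {
      roster$bmi_kg_m2 <- roster$weight_kg / roster$height_m^2
    }
    roster$bmi <- bmi_class(roster$bmi_kg_m2)
    out$strata <- list()
    for (s in strata) {
      for (lev in sort(unique(roster[[s]]))) {
        ids <- roster$participant_id[roster[[s]] == lev]
        sub <- joined[joined$participant_id %in% ids, ]
        label <- paste0(s, ":", lev)
        if (nrow(sub) < 2) {
          warn(paste0("stratum ", label, " has n < 2; suppressed"))
          next
        }
        sp <- paired_comparison_rows(sub, variables)
        if (p75_filter) {
          dropped <- sp$variable %in% group_vars & sp$q75_a == 0 & sp$q75_b == 0
          sp <- sp[!dropped, ]
        }
        out$strata[[label]] <- sp
      }
    }
  }
  class(out) <- "dv_comparison"
  out
}

#' @export
print.dv_comparison <- function(x, ...) {
  flagged <- sum(x$paired$relevant_difference, na.rm = TRUE)
  cat(
    "Paired-method comparison: ", nrow(x$paired), " variable(s), ",
    flagged, " with a relevant difference\n",
    sep = ""
  )
  print(x$paired, ...)
  invisible(x)
}

#' Recording-mode tally
#'
#' Counts and shares of entries by food-identification mode, plus the
#' share of branded identifications (brand-level text search plus barcode
#' scanning) among entries that were not re-selected from previously
#' recorded items.
#'
#' @param entries A record-entry tibble with an `identification_mode`
#'   column, or a named integer vector / tibble (`identification_mode`,
#'   `n`) of pre-tallied counts.
#' @return A list: `tally` (tibble `identification_mode`, `n`,
#'   `share_pct`), `n_entries`, `scan_share_pct`, and
#'   `branded_excl_previous_pct`.
#' @export
recording_mode_tally <- function(entries) {
  if (is.data.frame(entries) && "n" %in% names(entries)) {
    counts <- setNames(entries$n, entries$identification_mode)
  } else if (is.numeric(entries) && !is.null(names(entries))) {
    counts <- entries
  } else {
    counts <- table(as_tibble(entries)$identification_mode)
    counts <- setNames(as.integer(counts), names(counts))
  }
  bad <- setdiff(names(counts), identification_modes())
  if (length(bad)) {
    abort(paste0("unknown identification mode(s): ", paste(bad, collapse = ", ")))
  }
  full <- setNames(rep(0L, length(identification_modes())), identification_modes())
  full[names(counts)] <- counts
  total <- sum(full)
  if (total == 0) abort("no entries to tally")
  branded <- full[["branded_search"]] + full[["barcode_scan"]]
  denom_excl <- total - full[["previously_selected"]]
  list(
    tally = tibble(
      identification_mode = names(full),
      n = as.integer(full),
      share_pct = 100 * as.numeric(full) / total
    ),
    n_entries = total,
    scan_share_pct = 100 * full[["barcode_scan"]] / total,
    branded_excl_previous_pct = if (denom_excl > 0) 100 * branded / denom_excl else NA_real_
  )
}

#' System Usability Scale scoring
#'
#' Standard SUS scoring of the 10-item usability questionnaire: odd
#' (positively worded) items contribute response minus 1, even (negatively
#' worded) items contribute 5 minus response, and the sum is scaled by 2.5
#' to a 0-100 score. Participants missing any item are excluded from the
#' total score but still contribute to the per-item means.
#'
#' @param responses Long tibble with columns `participant_id`, `item`
#'   (1-10), `response` (1-5).
#' @return A list: `by_person` (tibble `participant_id`, `sus_score`),
#'   `item_means` (tibble `item`, `mean_response`, `sd_response`),
#'   `mean_score`, `sd_score`, `n_scored`.
#' @export
#' @examples
#' r <- tidyr::crossing(participant_id = "p1", item = 1:10) |>
#'   dplyr::mutate(response = 3)
#' sus_score(r)$mean_score # 50
sus_score <- function(responses) {
  responses <- as_tibble(responses)
  if (any(!responses$item %in% 1:10)) abort("items must be numbered 1-10")
  if (any(!responses$response %in% 1:5, na.rm = TRUE)) {
    abort("responses must be on the 1-5 scale")
  }
  item_means <- responses %>%
    filter(!is.na(.data$response)) %>%
    group_by(.data$item) %>%
    summarise(
      mean_response = mean(.data$response),
      sd_response = sd(.data$response),
      .groups = "drop"
    )
  by_person <- responses %>%
    filter(!is.na(.data$response)) %>%
    group_by(.data$participant_id) %>%
    summarise(
      n_items = dplyr::n_distinct(.data$item),
      sus_score = 2.5 * sum(if_else(
        .data$item %% 2 == 1, .data$response - 1, 5 - .data$response
      )),
      .groups = "drop"
    ) %>%
    filter(.data$n_items == 10) %>%
    select("participant_id", "sus_score")
  list(
    by_person = by_person,
    item_means = item_means,
    mean_score = if (nrow(by_person)) mean(by_person$sus_score) else NA_real_,
    sd_score = if (nrow(by_person) > 1) sd(by_person$sus_score) else NA_real_,
    n_scored = nrow(by_person)
  )
}
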