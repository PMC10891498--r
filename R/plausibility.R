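# Estimated basal metabolic rate, Goldberg-type screening of
# participant-days for implausible energy reporting, and cohort-level
# misreporting summaries.

#' Henry BMR coefficient table
#'
#' The linear weight-and-height equations for estimated basal metabolic
#' rate, in MJ/day, as a versioned data asset: one row per gender and age
#' band, with an intercept and coefficients on weight (kg) and height (m).
#' The age bands partition 18-79 without overlap. Ships with the package
#' but can be replaced by any table of the same shape (e.g. to swap in
#' Schofield-type equations).
#'
#' @param path Path to a TSV coefficient table; defaults to the shipped
#'   asset.
#' @return A tibble with columns `gender`, `age_min`, `age_max`,
#'   `intercept_mj`, `coef_weight_mj_per_kg`, `coef_height_mj_per_m`.
#' @export
#' @examples
#' henry_coefficients()
henry_coefficients <- function(path = NULL) {
  path <- path %||% dv_extdata("henry_bmr_weight_height.tsv")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  # Bands must partition the survey age range per gender.
  for (g in unique(tab$gender)) {
    b <- tab[tab$gender == g, ]
    b <- b[order(b$age_min), ]
    if (b$age_min[1] > 18 || any(diff(b$age_min) != (b$age_max[-nrow(b)] - b$age_min[-nrow(b)] + 1))) {
      abort("BMR coefficient age bands do not partition the age range")
    }
  }
  tab
}

#' Estimated basal metabolic rate (Henry equations)
#'
#' Evaluates the linear weight-and-height BMR equation for each
#' participant: intercept + a * weight + b * height, in MJ/day, converted
#' to kcal/day (1 MJ = 239.006 kcal).
#'
#' @param gender `"man"` or `"woman"` (vectorized).
#' @param age_years Age in whole years; must fall in a covered band.
#' @param weight_kg Body weight in kg.
#' @param height_m Body height in meters.
#' @param coefficients Coefficient table from [henry_coefficients()].
#' @return Numeric vector of BMR in kcal/day.
#' @export
#' @examples
#' henry_bmr("man", 30, 80, 1.80)
henry_bmr <- function(gender, age_years, weight_kg, height_m,
                      coefficients = henry_coefficients()) {
  n <- max(length(gender), length(age_years), length(weight_kg), length(height_m))
  gender <- rep_len(gender, n)
  age_years <- rep_len(age_years, n)
  weight_kg <- rep_len(weight_kg, n)
  height_m <- rep_len(height_m, n)
  if (any(!gender %in% coefficients$gender)) abort("unknown gender")
  if (any(weight_kg <= 0) || any(height_m <= 0)) {
    abort("weight and height must be positive")
  }
  row <- mapply(function(g, a) {
    hit <- which(
      coefficients$gender == g & coefficients$age_min <= a &
        coefficients$age_max >= a
    )
    if (length(hit) != 1) NA_integer_ else hit
  }, gender, age_years)
  if (anyNA(row)) {
    abort(paste0(
      "age outside covered BMR bands: ",
      paste(unique(age_years[is.na(row)]), collapse = ", ")
    ))
  }
  mj <- coefficients$intercept_mj[row] +
    coefficients$coef_weight_mj_per_kg[row] * weight_kg +
    coefficients$coef_height_mj_per_m[row] * height_m
  unname(mj * KCAL_PER_MJ)
}

#' Screen participant-days for implausible energy intake
#'
#' Goldberg-type screening: a recorded day is plausible when the ratio of
#' reported energy intake to estimated BMR lies in `[ratio_low,
#' ratio_high]` (both bounds inclusive, since the exclusion rule is a ratio
#' below 0.6 or above 3.0). Days outside the band are removed from all
#' downstream comparisons.
#'
#' @param daily A daily-totals tibble with an `energy_kcal` column.
#' @param roster A participant roster (for gender, age, weight, height).
#' @param ratio_low,ratio_high Plausibility bounds on EI/BMR, defaults 0.6
#'   and 3.0.
#' @param coefficients BMR coefficient table.
#' @return A tibble, one row per screened participant-day: `participant_id`,
#'   `day_index`, `energy_kcal`, `bmr_kcal`, `ei_bmr_ratio`, `plausible`,
#'   and `reporter_class` (`under` / `plausible` / `over`).
#' @export
screen_days <- function(daily, roster, ratio_low = 0.6, ratio_high = 3.0,
                        coefficients = henry_coefficients()) {
  daily <- as_tibble(daily)
  roster <- as_tibble(roster)
  missing <- setdiff(unique(daily$participant_id), roster$participant_id)
  if (length(missing)) {
    abort(paste0(
      "participant(s) absent from roster: ", paste(missing, collapse = ", ")
    ))
  }
  idx <- match(daily$participant_id, roster$participant_id)
  bmr <- henry_bmr(
    roster$gender[idx], roster$age_years[idx], roster$weight_kg[idx],
    roster$height_m[idx], coefficients
  )
  ratio <- daily$energy_kcal / bmr
  # relative tolerance so that days engineered to sit exactly on a bound
  # are not reclassified by floating-point jitter
  tol <- 1e-9 * pmax(1, abs(ratio))
  in_band <- ratio >= ratio_low - tol & ratio <= ratio_high + tol
  tibble(
    participant_id = daily$participant_id,
    day_index = daily$day_index,
    energy_kcal = daily$energy_kcal,
    bmr_kcal = bmr,
    ei_bmr_ratio = ratio,
    plausible = in_band,
    reporter_class = case_when(
      !in_band & ratio < ratio_low ~ "under",
      !in_band & ratio > ratio_high ~ "over",
      TRUE ~ "plausible"
    )
  )
}

#' Drop implausible days from a daily-totals table
#'
#' @param daily A daily-totals tibble.
#' @param screens The result of [screen_days()] on the same table.
#' @return `daily` restricted to plausible participant-days.
#' @export
keep_plausible_days <- function(daily, screens) {
  keep <- screens[screens$plausible, c("participant_id", "day_index")]
  out <- semi_join(as_tibble(daily), keep, by = c("participant_id", "day_index"))
  attr(out, "group_columns") <- attr(daily, "group_columns")
  attr(out, "nutrient_columns") <- attr(daily, "nutrient_columns")
  out
}

#' Cohort energy-misreporting summary
#'
#' Each participant's measured physical activity level (PAL) is energy
#' intake over BMR. Relative misreporting is (measured - expected) /
#' expected; the cohort mean is reported as a percentage (negative =
#' underreporting; the `mean_underreporting_pct` field carries the positive
#' underreporting magnitude). Individuals are additionally classified as
#' under- or over-reporters against configurable measured-PAL cutoffs; the
#' cutoffs producing any particular published count are not standardized,
#' so these defaults are a documented choice, not a reproduction target.
#'
#' @param screens A tibble from [screen_days()] (one row per
#'   participant-day; multiple days per participant are averaged first).
#' @param expected_pal Expected physical activity level, default 1.59.
#' @param under_cutoff,over_cutoff Measured-PAL cutoffs for per-person
#'   classification, defaults 1.10 and 2.0.
#' @return A list with `mean_measured_pal`, `mean_relative_misreporting_pct`
#'   (signed), `mean_underreporting_pct` (positive magnitude), and
#'   `by_person` (tibble with per-person PAL and class).
#' @export
underreporting_summary <- function(screens, expected_pal = 1.59,
                                   under_cutoff = 1.10, over_cutoff = 2.0) {
  screens <- as_tibble(screens)
  if (nrow(screens) == 0) abort("no screened participant-days")
  by_person <- screens %>%
    group_by(.data$participant_id) %>%
    summarise(measured_pal = mean(.data$ei_bmr_ratio), .groups = "drop") %>%
    mutate(
      relative_misreporting = (.data$measured_pal - expected_pal) / expected_pal,
      class = case_when(
        .data$measured_pal < under_cutoff ~ "under",
        .data$measured_pal > over_cutoff ~ "over",
        TRUE ~ "plausible"
      )
    )
  mean_pal <- mean(by_person$measured_pal)
  rel <- (mean_pal - expected_pal) / expected_pal
  list(
    mean_measured_pal = mean_pal,
    mean_relative_misreporting_pct = 100 * rel,
    mean_underreporting_pct = -100 * rel,
    by_person = by_person
  )
}

#' Mean misreporting percentage from a PAL deficit
#'
#' The arithmetic behind a published misreporting figure: a cohort whose
#' measured PAL falls short of the expected PAL by `deficit` underreports
#' by `deficit / expected_pal`, as a percentage.
#'
#' @param deficit Expected minus measured mean PAL.
#' @param expected_pal Expected physical activity level, default 1.59.
#' @return Underreporting percentage.
#' @export
#' @examples
#' pal_deficit_pct(0.316) # about 19.9
pal_deficit_pct <- function(deficit, expected_pal = 1.59) {
  100 * deficit / expected_pal
}
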