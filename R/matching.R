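# Selection of one matched comparator per case participant from an
# external pool, on characteristics associated with dietary intake, with
# stepwise relaxation of the matching criteria.

#' Build matching keys from a roster
#'
#' Matching characteristics: gender, age class (5-year bands), weight class
#' (10-kg bands), and educational level (3 classes). Bands are half-open
#' and lower-inclusive, anchored at multiples of the band width: age 23
#' falls in [20, 25), weight 67 kg in [60, 70).
#'
#' @param roster A participant roster tibble.
#' @param age_width Width of age classes in years, default 5.
#' @param weight_width Width of weight classes in kg, default 10.
#' @return `roster` with added `age_class` and `weight_class` columns (the
#'   lower band edge, as integers).
#' @export
#' @examples
#' r <- tibble::tibble(
#'   participant_id = "p1", gender = "woman", age_years = 23,
#'   height_m = 1.7, weight_kg = 67, education = "high"
#' )
#' build_match_key(r)[, c("age_class", "weight_class")]
build_match_key <- function(roster, age_width = 5, weight_width = 10) {
  roster <- as_tibble(roster)
  roster %>%
    mutate(
      age_class = age_width * floor(.data$age_years / age_width),
      weight_class = weight_width * floor(.data$weight_kg / weight_width)
    )
}

match_eligible <- function(case, pool_keys, level) {
  ok <- pool_keys$gender == case$gender &
    pool_keys$weight_class == case$weight_class
  if (level %in% c("full", "education_relaxed")) {
    ok <- ok & pool_keys$age_class == case$age_class
  }
  if (level == "full") {
    ok <- ok & pool_keys$education == case$education
  }
  ok
}

#' Match each case to one comparator from a pool
#'
#' Greedy 1:1 matching without replacement, cases processed in roster
#' order. For each case the full key (gender, age class, weight class,
#' education) is tried first; failing that, education is dropped, then the
#' age class (gender and weight class always match). Among eligible
#' comparators the one with the same or closest height is chosen, ties
#' broken by smallest comparator id. Cases with no eligible comparator are
#' recorded as unmatched, never fabricated.
#'
#' @param cases,pool Roster tibbles; the pool must be disjoint from the
#'   cases.
#' @param age_width,weight_width Band widths for [build_match_key()].
#' @return A tibble with one row per case: `case_id`, `control_id`,
#'   `relaxation_level` (`full`, `education_relaxed`, `age_relaxed`,
#'   `unmatched`), and `height_gap_m`.
#' @export
match_cohort <- function(cases, pool, age_width = 5, weight_width = 10) {
  cases <- build_match_key(cases, age_width, weight_width)
  pool <- build_match_key(pool, age_width, weight_width)
  if (length(intersect(cases$participant_id, pool$participant_id))) {
    abort("pool must be disjoint from cases")
  }
  if (nrow(pool) == 0) {
    warn("empty comparator pool; all cases unmatched")
  }
  available <- rep(TRUE, nrow(pool))
  results <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    case <- cases[i, ]
    chosen <- NA_integer_
    level_used <- "unmatched"
    for (level in c("full", "education_relaxed", "age_relaxed")) {
      elig <- which(available & match_eligible(case, pool, level))
      if (length(elig)) {
        gap <- abs(pool$height_m[elig] - case$height_m)
        best <- elig[order(gap, pool$participant_id[elig])][1]
        chosen <- best
        level_used <- level
        break
      }
    }
    if (!is.na(chosen)) available[chosen] <- FALSE
    results[[i]] <- tibble(
      case_id = case$participant_id,
      control_id = if (is.na(chosen)) NA_character_ else pool$participant_id[chosen],
      relaxation_level = level_used,
      height_gap_m = if (is.na(chosen)) {
        NA_real_
      } else {
        abs(pool$height_m[chosen] - case$height_m)
      }
    )
  }
  bind_rows(results)
}
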