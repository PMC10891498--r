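# Synthetic paired validation studies with known ground truth. The
# generator emulates the study conditions: a cohort with the published
# gender / age / education / BMI mix, zero-inflated log-normal food-group
# consumption with the published consumer probabilities and consumers-only
# medians under the reference method, per-group method bias and
# rank-correlation targets taken from the published comparison tables,
# group-level omission (forgotten condiments and sauces), and energy tied
# to Henry BMR through a physical-activity-level distribution with median
# 1.59 and a configurable fraction of extreme reporters.

largest_remainder <- function(n, proportions) {
  raw <- n * proportions / sum(proportions)
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_frac <- order(raw - counts, decreasing = TRUE)
    counts[order_frac[seq_len(short)]] <- counts[order_frac[seq_len(short)]] + 1
  }
  as.integer(counts)
}

# Pearson correlation needed on the log scale to hit a target Spearman
# for a bivariate normal (and the log-noise sd that produces it).
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)
pearson_to_spearman <- function(rho_p) (6 / pi) * asin(rho_p / 2)

default_group_spec <- function() {
  cons <- reference_consumer_table()
  fg <- reference_food_group_table()
  rho <- setNames(fg$spearman_rho, fg$variable)
  n_ref <- 211
  tibble(
    food_group = cons$variable,
    p_consume = cons$consumers_b / n_ref,
    median_g = cons$median_consumers_b,
    sdlog = 0.6,
    bias = cons$median_consumers_a / cons$median_consumers_b,
    omission = pmax(0, 1 - cons$consumers_a / cons$consumers_b),
    rho_target = unname(ifelse(
      is.na(rho[cons$variable]), 0.70, rho[cons$variable]
    ))
  )
}

#' Configuration of a synthetic paired study
#'
#' All defaults are the published study conditions: n = 211 participants
#' with the published gender (104/107), age-band (76/77/58 across 18-39 /
#' 40-59 / 60-79), education (37/81/93) and BMI-category (1/81/73/56)
#' mixes; per-food-group consumer probabilities and consumers-only medians
#' of the reference method; per-group bias ratios (ratio of consumers-only
#' medians), omission probabilities (relative consumer-count deficits,
#' clamped at zero), and target Spearman correlations from the published
#' tables; PAL log-normal with median 1.59; and an extreme-reporter
#' fraction of 16/227.
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed; all generator output is a pure function of
#'   the configuration including this seed.
#' @param groups Per-group tibble with columns `food_group`, `p_consume`,
#'   `median_g` (consumers-only median, g/day, reference method), `sdlog`
#'   (log-sd of the positive part), `bias` (method-A over method-B ratio),
#'   `omission` (probability a consumed group is absent from method A),
#'   `rho_target` (target Spearman between methods among co-consumers).
#' @param pal_median,pal_sdlog Log-normal PAL distribution of plausible
#'   reporters.
#' @param extreme_fraction Fraction of participants generated as extreme
#'   energy reporters.
#' @param extreme_low_share Of the extremes, the share with implausibly
#'   low EI/BMR (the rest are implausibly high).
#' @param pal_method_sdlog Log-sd of the between-method PAL perturbation.
#' @param closure_kcal_per_g Energy density of the caloric beverage used
#'   to close each day's energy balance (booked under `drinks`).
#' @param gender_mix,age_band_mix,education_mix,bmi_mix Named numeric
#'   vectors of class proportions (normalized internally).
#' @param supplement_prob Probability a participant logs a dietary
#'   supplement entry (excluded from intake totals by construction).
#' @param guarantee_matches If `TRUE`, the comparator pool contains a
#'   full-key match for every case.
#' @param pool_size Comparator-pool size, default `n_participants`.
#' @return A `dv_synthetic_config` list.
#' @export
synthetic_config <- function(n_participants = 211, seed = 1,
                             groups = default_group_spec(),
                             pal_median = 1.59, pal_sdlog = 0.13,
                             extreme_fraction = 16 / 227,
                             extreme_low_share = 0.9,
                             pal_method_sdlog = 0.03,
                             closure_kcal_per_g = 0.45,
                             gender_mix = c(man = 104, woman = 107),
                             age_band_mix = c(`18` = 76, `40` = 77, `60` = 58),
                             education_mix = c(low = 37, middle = 81, high = 93),
                             bmi_mix = c(
                               under = 1, normal = 81, over = 73, obese = 56
                             ),
                             supplement_prob = 0.3,
                             guarantee_matches = TRUE,
                             pool_size = NULL) {
  groups <- as_tibble(groups)
  stopifnot(
    all(groups$p_consume >= 0 & groups$p_consume <= 1),
    all(groups$omission >= 0 & groups$omission <= 1),
    all(groups$bias > 0), all(groups$sdlog > 0),
    extreme_fraction >= 0, extreme_fraction < 1
  )
  rho_p <- spearman_to_pearson(groups$rho_target)
  groups$noise_sdlog <- if_else(
    rho_p >= 1 - 1e-12, 0, groups$sdlog * sqrt(pmax(0, 1 / rho_p^2 - 1))
  )
  cfg <- list(
    n_participants = n_participants, seed = seed, groups = groups,
    pal_median = pal_median, pal_sdlog = pal_sdlog,
    extreme_fraction = extreme_fraction,
    extreme_low_share = extreme_low_share,
    pal_method_sdlog = pal_method_sdlog,
    closure_kcal_per_g = closure_kcal_per_g,
    gender_mix = gender_mix, age_band_mix = age_band_mix,
    education_mix = education_mix, bmi_mix = bmi_mix,
    supplement_prob = supplement_prob,
    guarantee_matches = guarantee_matches,
    pool_size = pool_size %||% n_participants
  )
  class(cfg) <- "dv_synthetic_config"
  cfg
}

#' Ground truth of a synthetic configuration
#'
#' Closed-form target values recoverable by the pipeline: per group, the
#' true method bias (ratio of consumers-only medians), the true Spearman
#' correlation among co-consumers (log-scale bivariate normal:
#' `(6/pi) asin(rho_P / 2)` with `rho_P = sdlog / sqrt(sdlog^2 +
#' noise_sdlog^2)`), consumer probabilities under both methods, and the
#' configured extreme-reporter fraction. With `mc_n` set, a large-sample
#' Monte-Carlo estimate of the Spearman correlation is added as a check on
#' the closed form.
#'
#' @param config A [synthetic_config()].
#' @param mc_n Optional Monte-Carlo sample size (e.g. `1e5`).
#' @return A list with `groups` (tibble) and `extreme_fraction`.
#' @export
ground_truth <- function(config, mc_n = NULL) {
  g <- config$groups
  rho_p <- g$sdlog / sqrt(g$sdlog^2 + g$noise_sdlog^2)
  out <- tibble(
    food_group = g$food_group,
    bias = g$bias,
    median_b = g$median_g,
    median_a = g$bias * g$median_g,
    rho_spearman = pearson_to_spearman(rho_p),
    p_consume_b = g$p_consume,
    p_consume_a = g$p_consume * (1 - g$omission)
  )
  if (!is.null(mc_n)) {
    out$rho_spearman_mc <- vapply(seq_len(nrow(g)), function(i) {
      lb <- rnorm(mc_n, log(g$median_g[i]), g$sdlog[i])
      la <- log(g$bias[i]) + lb + rnorm(mc_n, 0, g$noise_sdlog[i])
      cor(rank(la), rank(lb))
    }, numeric(1))
  }
  list(groups = out, extreme_fraction = config$extreme_fraction)
}

#' Generate a synthetic cohort and comparator pool
#'
#' Class counts follow the configured proportions by largest remainder
#' (so the default mix reproduces the published 104 men / 107 women at
#' n = 211 exactly). Heights are drawn per gender, BMI per published
#' category, and weight derived from the two. With `guarantee_matches`
#' the pool is built by jittering each case within its matching bands, so
#' a full-key match exists for every case.
#'
#' @param config A [synthetic_config()].
#' @return A list with tibbles `cases` and `pool` (roster layout plus
#'   derived `bmi_kg_m2`).
#' @export
generate_cohort <- function(config) {
  set.seed(config$seed)
  n <- config$n_participants
  draw_roster <- function(n, prefix) {
    gender <- rep(names(config$gender_mix), largest_remainder(n, config$gender_mix))
    edu <- rep(names(config$education_mix), largest_remainder(n, config$education_mix))
    band <- rep(
      as.numeric(names(config$age_band_mix)),
      largest_remainder(n, config$age_band_mix)
    )
    bmi_cat <- rep(names(config$bmi_mix), largest_remainder(n, config$bmi_mix))
    # independent shuffles: class margins exact, joints random
    gender <- sample(gender)
    edu <- sample(edu)
    band <- sample(band)
    bmi_cat <- sample(bmi_cat)
    age <- as.integer(band + floor(runif(n, 0, ifelse(band == 18, 22, 20))))
    age <- pmin(age, 79L)
    height <- if_else(
      gender == "man", rnorm(n, 1.81, 0.07), rnorm(n, 1.67, 0.06)
    )
    bmi <- dplyr::case_match(
      bmi_cat,
      "under" ~ runif(n, 17.0, 18.4),
      "normal" ~ runif(n, 18.5, 24.9),
      "over" ~ runif(n, 25.0, 29.9),
      "obese" ~ runif(n, 30.0, 39.0)
    )
    tibble(
      participant_id = sprintf("%s%04d", prefix, seq_len(n)),
      gender = gender,
      age_years = age,
      height_m = round(height, 2),
      weight_kg = round(bmi * height^2, 1),
      education = edu
    ) %>%
      mutate(bmi_kg_m2 = .data$weight_kg / .data$height_m^2)
  }
  cases <- draw_roster(n, "P")
  if (config$guarantee_matches) {
    np <- config$pool_size
    base <- cases[rep_len(seq_len(n), np), ]
    keyed <- build_match_key(base)
    age <- as.integer(
      keyed$age_class + floor(runif(np, 0, 5))
    )
    weight <- round(keyed$weight_class + runif(np, 0, 10), 1)
    pool <- tibble(
      participant_id = sprintf("C%04d", seq_len(np)),
      gender = base$gender,
      age_years = pmin(pmax(age, 18L), 79L),
      height_m = round(base$height_m + rnorm(np, 0, 0.02), 2),
      weight_kg = weight,
      education = base$education
    ) %>%
      mutate(bmi_kg_m2 = .data$weight_kg / .data$height_m^2)
  } else {
    pool <- draw_roster(config$pool_size, "C")
  }
  list(cases = cases, pool = pool)
}

#' Synthetic food database
#'
#' One generic food per Wheel of Five group with a realistic energy
#' density and coarse macronutrient split, a zero-energy water item and a
#' caloric beverage (both `drinks`), and a supplement item. Synthetic
#' stand-ins, not sourced from any licensed composition database.
#'
#' @param config A [synthetic_config()].
#' @return A list with `foods` (composition tibble) and `group_map`.
#' @export
generate_food_database <- function(config) {
  groups <- wheel_of_five_groups()
  energy_per_100g <- c(
    vegetables = 30, fruit = 55, added_fats = 720, fish = 150, legumes = 100,
    meat = 200, eggs = 150, nuts = 600, milk_and_milk_products = 60,
    cheese = 350, bread = 260, cereal_products = 130, potatoes = 90,
    drinks = 0, sandwich_spreads = 300, soups = 40, snacks = 300,
    sauces = 150, other = 200
  )
  fat_share <- c(
    vegetables = 0.1, fruit = 0.02, added_fats = 0.98, fish = 0.45,
    legumes = 0.05, meat = 0.55, eggs = 0.6, nuts = 0.75,
    milk_and_milk_products = 0.45, cheese = 0.72, bread = 0.08,
    cereal_products = 0.08, potatoes = 0.02, drinks = 0,
    sandwich_spreads = 0.4, soups = 0.35, snacks = 0.45, sauces = 0.6,
    other = 0.3
  )
  protein_share <- c(
    vegetables = 0.25, fruit = 0.04, added_fats = 0.01, fish = 0.5,
    legumes = 0.25, meat = 0.4, eggs = 0.35, nuts = 0.15,
    milk_and_milk_products = 0.25, cheese = 0.27, bread = 0.14,
    cereal_products = 0.12, potatoes = 0.08, drinks = 0,
    sandwich_spreads = 0.1, soups = 0.2, snacks = 0.08, sauces = 0.05,
    other = 0.1
  )
  codes <- paste0("SYN_", toupper(groups))
  foods <- tibble(
    food_code = codes,
    is_branded = FALSE,
    generic_parent = NA_character_,
    density_g_per_ml = if_else(groups %in% c("drinks", "milk_and_milk_products", "soups"), 1.0, NA_real_),
    edible_fraction = 1,
    fat_absorption_fraction = 0,
    edible_units = NA_character_,
    energy_kcal = unname(energy_per_100g[groups]),
    fat_g = round(unname(energy_per_100g[groups] * fat_share[groups]) / 9, 2),
    protein_g = round(unname(energy_per_100g[groups] * protein_share[groups]) / 4, 2),
    carbohydrate_g = round(pmax(
      0,
      unname(energy_per_100g[groups] *
        (1 - fat_share[groups] - protein_share[groups])) / 4
    ), 2)
  )
  closure <- tibble(
    food_code = "SYN_CALORIC_BEVERAGE", is_branded = FALSE,
    generic_parent = NA_character_, density_g_per_ml = 1.0,
    edible_fraction = 1, fat_absorption_fraction = 0,
    edible_units = NA_character_,
    energy_kcal = 100 * config$closure_kcal_per_g,
    fat_g = 0, protein_g = 0,
    carbohydrate_g = round(100 * config$closure_kcal_per_g / 4, 2)
  )
  supp <- tibble(
    food_code = "SYN_SUPPLEMENT", is_branded = FALSE,
    generic_parent = NA_character_, density_g_per_ml = NA_real_,
    edible_fraction = 1, fat_absorption_fraction = 0,
    edible_units = NA_character_,
    energy_kcal = 0, fat_g = 0, protein_g = 0, carbohydrate_g = 0
  )
  foods <- bind_rows(foods, closure, supp)
  group_map <- tibble(
    food_code = c(codes, "SYN_CALORIC_BEVERAGE", "SYN_SUPPLEMENT"),
    food_group = c(groups, "drinks", "other")
  )
  list(foods = validate_composition(foods), group_map = group_map)
}

group_occasion <- function(group) {
  breakfast <- c("bread", "sandwich_spreads", "milk_and_milk_products", "cereal_products")
  midday <- c("cheese", "fruit", "eggs", "soups")
  evening <- c(
    "vegetables", "meat", "fish", "potatoes", "legumes", "sauces",
    "added_fats", "other"
  )
  case_when(
    group %in% breakfast ~ "breakfast",
    group %in% midday ~ "midday_meal",
    group %in% evening ~ "evening_meal",
    TRUE ~ "in_between"
  )
}

occasion_time <- function(occasion) {
  c(
    breakfast = "08:00", midday_meal = "12:30", evening_meal = "18:00",
    in_between = "15:00", supplement = "09:00"
  )[occasion]
}

#' Generate a complete paired synthetic study
#'
#' Draws, per participant and one shared analysis day, reference-method
#' (B) food-group amounts from the zero-inflated log-normal model, then
#' derives test-method (A) amounts as B times the group bias times
#' multiplicative log-normal noise, with independent per-group omission.
#' Each day's energy is closed to PAL times Henry BMR with a caloric
#' beverage (participants generated as extreme reporters get PAL outside
#' the 0.6-3.0 plausibility band; their amounts are scaled down when the
#' food energy alone already exceeds the low target). Record entries are
#' emitted in exactly the export layout that [read_food_records()] reads.
#'
#' @param config A [synthetic_config()].
#' @return A list: `records_a`, `records_b` (record-entry tibbles),
#'   `roster`, `pool`, `foods`, `group_map`, `truth` (from
#'   [ground_truth()]), and `participants` (per-participant PAL and
#'   extreme status).
#' @export
generate_paired_study <- function(config) {
  cohort <- generate_cohort(config) # seeds the RNG with config$seed
  db <- generate_food_database(config)
  g <- config$groups
  n <- config$n_participants
  roster <- cohort$cases

  bmr <- henry_bmr(
    roster$gender, roster$age_years, roster$weight_kg, roster$height_m
  )
  n_extreme <- round(config$extreme_fraction * n)
  extreme_ids <- sample(seq_len(n), n_extreme)
  extreme_low <- rep(FALSE, n)
  extreme_high <- rep(FALSE, n)
  if (n_extreme > 0) {
    low <- runif(n_extreme) < config$extreme_low_share
    extreme_low[extreme_ids[low]] <- TRUE
    extreme_high[extreme_ids[!low]] <- TRUE
  }
  pal_base <- rlnorm(n, log(config$pal_median), config$pal_sdlog)
  pal_base <- pmin(pmax(pal_base, 0.65), 2.9)
  pal_base[extreme_low] <- runif(sum(extreme_low), 0.30, 0.55)
  pal_base[extreme_high] <- runif(sum(extreme_high), 3.2, 4.0)
  pal_b <- pal_base
  pal_a <- pal_base * exp(rnorm(n, 0, config$pal_method_sdlog))
  pal_a[!extreme_low & !extreme_high] <-
    pmin(pmax(pal_a[!extreme_low & !extreme_high], 0.65), 2.9)
  pal_a[extreme_low] <- pmin(pal_a[extreme_low], 0.55)
  pal_a[extreme_high] <- pmax(pal_a[extreme_high], 3.2)

  day <- sample(1:3, n, replace = TRUE)
  ng <- nrow(g)

  consumes_b <- matrix(runif(n * ng) < rep(g$p_consume, each = n), n, ng)
  amounts_b <- matrix(
    rlnorm(n * ng, rep(log(g$median_g), each = n), rep(g$sdlog, each = n)),
    n, ng
  ) * consumes_b
  noise <- matrix(rnorm(n * ng, 0, rep(g$noise_sdlog, each = n)), n, ng)
  omitted <- matrix(runif(n * ng) < rep(g$omission, each = n), n, ng)
  amounts_a <- amounts_b * rep(g$bias, each = n) * exp(noise) * !omitted

  energy_density <- db$foods$energy_kcal[
    match(paste0("SYN_", toupper(g$food_group)), db$foods$food_code)
  ] / 100

  build_method <- function(amounts, pal) {
    target <- pal * bmr
    implied <- as.numeric(amounts %*% energy_density)
    scale <- if_else(
      (extreme_low | extreme_high) & implied > target, target / implied, 1
    )
    amounts <- amounts * scale
    implied <- implied * scale
    closure_g <- pmax(0, (target - implied) / config$closure_kcal_per_g)
    list(amounts = amounts, closure_g = closure_g)
  }
  ma <- build_method(amounts_a, pal_a)
  mb <- build_method(amounts_b, pal_b)

  supplement <- runif(n) < config$supplement_prob
  mode_pool <- reference_recording_modes()
  mode_pool <- mode_pool[mode_pool$identification_mode != "supplement_entry", ]
  # one identification mode per participant-group cell, shared by both
  # methods, so that a bias-free configuration yields identical files
  mode_cells <- matrix(
    sample(
      mode_pool$identification_mode, n * ng,
      replace = TRUE, prob = mode_pool$n
    ),
    n, ng
  )

  build_records <- function(m) {
    rows <- which(m$amounts > 0, arr.ind = TRUE)
    entries <- tibble(
      participant_id = roster$participant_id[rows[, 1]],
      day_index = day[rows[, 1]],
      occasion = group_occasion(g$food_group[rows[, 2]]),
      food_code = paste0("SYN_", toupper(g$food_group[rows[, 2]])),
      identification_mode = mode_cells[rows],
      amount_value = round(m$amounts[rows], 2),
      amount_unit = "gram",
      unit_count = 1
    )
    closure_sel <- which(m$closure_g > 0.5)
    closure <- tibble(
      participant_id = roster$participant_id[closure_sel],
      day_index = day[closure_sel],
      occasion = "in_between",
      food_code = "SYN_CALORIC_BEVERAGE",
      identification_mode = "barcode_scan",
      amount_value = round(m$closure_g[closure_sel], 2),
      amount_unit = "gram",
      unit_count = 1
    )
    supp <- tibble(
      participant_id = roster$participant_id[supplement],
      day_index = day[supplement],
      occasion = "supplement",
      food_code = "SYN_SUPPLEMENT",
      identification_mode = "supplement_entry",
      amount_value = 1,
      amount_unit = "gram",
      unit_count = 1
    )
    bind_rows(entries, closure, supp) %>%
      mutate(
        clock_time = unname(occasion_time(.data$occasion)),
        place = "home",
        preparation_method = NA_character_,
        fat_used_code = NA_character_,
        reported_state = "as_consumed"
      ) %>%
      arrange(.data$participant_id, .data$day_index, .data$occasion, .data$food_code)
  }

  list(
    records_a = build_records(ma),
    records_b = build_records(mb),
    roster = roster,
    pool = cohort$pool,
    foods = db$foods,
    group_map = db$group_map,
    truth = ground_truth(config),
    participants = tibble(
      participant_id = roster$participant_id,
      day_index = day,
      pal_a = pal_a, pal_b = pal_b, bmr_kcal = bmr,
      extreme = extreme_low | extreme_high
    )
  )
}

#' Write a synthetic study to disk
#'
#' Emits exactly the file formats the readers consume: `records_a.csv`,
#' `records_b.csv`, `roster.csv`, `pool.csv`, `composition.tsv`,
#' `group_map.tsv`, plus `ground_truth.csv`.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return The study list from [generate_paired_study()], invisibly, with
#'   a `paths` element.
#' @export
simulate_study <- function(config, dir) {
  study <- generate_paired_study(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    records_a = file.path(dir, "records_a.csv"),
    records_b = file.path(dir, "records_b.csv"),
    roster = file.path(dir, "roster.csv"),
    pool = file.path(dir, "pool.csv"),
    composition = file.path(dir, "composition.tsv"),
    group_map = file.path(dir, "group_map.tsv"),
    ground_truth = file.path(dir, "ground_truth.csv")
  )
  readr::write_csv(study$records_a, paths$records_a, progress = FALSE)
  readr::write_csv(study$records_b, paths$records_b, progress = FALSE)
  roster_cols <- c(
    "participant_id", "gender", "age_years", "height_m", "weight_kg",
    "education"
  )
  readr::write_csv(study$roster[roster_cols], paths$roster, progress = FALSE)
  readr::write_csv(study$pool[roster_cols], paths$pool, progress = FALSE)
  readr::write_tsv(study$foods, paths$composition, progress = FALSE)
  readr::write_tsv(study$group_map, paths$group_map, progress = FALSE)
  readr::write_csv(study$truth$groups, paths$ground_truth, progress = FALSE)
  study$paths <- paths
  invisible(study)
}
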