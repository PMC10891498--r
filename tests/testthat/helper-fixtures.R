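# Fixtures built in code: a small composition table exercising every
# conversion factor, entry builders, and an exact-enumeration oracle for
# the signed rank test.

test_foods <- function() {
  tibble::tibble(
    food_code = c(
      "apple", "milk_drink", "rice", "fries", "oil", "banana_brand",
      "bread", "cheese", "tomato", "chicken", "cola", "spread"
    ),
    is_branded = c(
      FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE
    ),
    generic_parent = c(
      NA, NA, NA, NA, NA, "apple", NA, NA, NA, NA, NA, NA
    ),
    density_g_per_ml = c(NA, 1.03, NA, NA, 0.92, NA, NA, NA, NA, NA, 1.0, NA),
    edible_fraction = c(0.65, 1, 1, 1, 1, 0.65, 1, 1, 0.95, 1, 1, 1),
    fat_absorption_fraction = c(0, 0, 0, 0.05, 0, 0, 0, 0, 0, 0.08, 0, 0),
    edible_units = c(
      "gram;natural_unit", NA, NA, NA, NA, "natural_unit",
      NA, NA, "natural_unit", NA, NA, NA
    ),
    `unit_g.natural_unit` = c(120, NA, NA, NA, NA, 130, 35, 20, 80, NA, NA, 15),
    `unit_g.household_measure` = c(NA, 150, 60, NA, 10, NA, NA, NA, NA, NA, 250, NA),
    `yield.boiled` = c(NA, NA, 2.5, NA, NA, NA, NA, NA, NA, 0.8, NA, NA),
    `yield.fried` = c(NA, NA, NA, 0.9, NA, NA, NA, NA, NA, 0.75, NA, NA),
    energy_kcal = c(55, 60, 130, 300, 880, 55, 260, 350, 20, 160, 45, 300),
    protein_g = c(0.3, 3.4, 2.7, 3.5, 0, 0.3, 9, 25, 1, 27, 0, 1),
    fat_g = c(0.2, 3.5, 0.3, 15, 98, 0.2, 2, 28, 0.2, 5, 0, 30)
  )
}

test_group_map <- function() {
  tibble::tibble(
    food_code = c(
      "apple", "milk_drink", "rice", "fries", "oil", "banana_brand",
      "bread", "cheese", "tomato", "chicken", "cola", "spread"
    ),
    food_group = c(
      "fruit", "milk_and_milk_products", "cereal_products", "potatoes",
      "added_fats", "fruit", "bread", "cheese", "vegetables", "meat",
      "drinks", "sandwich_spreads"
    )
  )
}

make_entry <- function(participant_id = "p1", day_index = 1L,
                       occasion = "breakfast", food_code = "apple",
                       identification_mode = "generic_search",
                       amount_value = 100, amount_unit = "gram",
                       unit_count = 1, clock_time = "08:00",
                       place = "home", preparation_method = NA_character_,
                       fat_used_code = NA_character_,
                       reported_state = "as_consumed") {
  tibble::tibble(
    participant_id = participant_id, day_index = day_index,
    occasion = occasion, clock_time = clock_time, place = place,
    food_code = food_code, identification_mode = identification_mode,
    amount_value = amount_value, amount_unit = amount_unit,
    unit_count = unit_count, preparation_method = preparation_method,
    fat_used_code = fat_used_code, reported_state = reported_state
  )
}

write_records_csv <- function(entries, path = tempfile(fileext = ".csv")) {
  readr::write_csv(entries, path, progress = FALSE)
  path
}

test_roster <- function(n = 4) {
  tibble::tibble(
    participant_id = paste0("p", seq_len(n)),
    gender = rep_len(c("man", "woman"), n),
    age_years = rep_len(c(30L, 25L, 45L, 68L), n),
    height_m = rep_len(c(1.80, 1.65, 1.75, 1.60), n),
    weight_kg = rep_len(c(80, 60, 90, 70), n),
    education = rep_len(c("low", "middle", "high", "middle"), n)
  )
}

# Exact two-sided signed rank p-value by enumerating all 2^n sign
# assignments of the absolute differences (the independent oracle for the
# normal approximation).
exact_signed_rank_p <- function(differences) {
  d <- differences[differences != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  e_w <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-12)
}
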