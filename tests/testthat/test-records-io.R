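test_that("record exports parse to canonical order and round-trip", {
  entries <- dplyr::bind_rows(
    make_entry(occasion = "evening_meal", clock_time = "18:30"),
    make_entry(occasion = "breakfast", clock_time = "07:45"),
    make_entry(occasion = "midday_meal", clock_time = "12:15", food_code = "bread")
  )
  path <- write_records_csv(entries)
  parsed <- read_food_records(path)
  expect_equal(nrow(parsed), 3)
  expect_equal(
    parsed$occasion, c("breakfast", "midday_meal", "evening_meal")
  )
  expect_equal(nrow(record_diagnostics(parsed)), 0)

  # identity round-trip through the writer
  out <- tempfile(fileext = ".csv")
  write_report(parsed, out)
  reread <- read_food_records(out)
  expect_equal(as.data.frame(reread), as.data.frame(parsed))
})

test_that("invalid rows are rejected with diagnostics, counts conserved", {
  entries <- dplyr::bind_rows(
    make_entry(),
    make_entry(amount_value = -5),
    make_entry(unit_count = 0),
    make_entry(occasion = "brunch"),
    make_entry(amount_value = 0.5, amount_unit = "recipe_fraction",
               identification_mode = "recipe"),
    make_entry(amount_value = 1.5, amount_unit = "recipe_fraction",
               identification_mode = "recipe"),
    make_entry(identification_mode = "supplement_entry", occasion = "breakfast")
  )
  path <- write_records_csv(entries)
  parsed <- suppressMessages(read_food_records(path))
  diags <- record_diagnostics(parsed)
  expect_equal(nrow(parsed) + nrow(diags), nrow(entries))
  expect_true("negative amount" %in% diags$message)
  expect_true("non-positive unit count" %in% diags$message)
  expect_true("unknown eating occasion" %in% diags$message)
  expect_true("recipe fraction outside (0, 1]" %in% diags$message)
  expect_true(
    "supplement entry outside supplement occasion" %in% diags$message
  )
  # the valid recipe-fraction row survived
  expect_true(any(parsed$amount_unit == "recipe_fraction"))
})

test_that("missing mandatory columns are fatal; dialects remap and reparse", {
  entries <- make_entry()
  path <- write_records_csv(dplyr::select(entries, -"food_code"))
  expect_error(read_food_records(path), "mandatory column")

  # renamed columns and decimal commas through a dialect
  renamed <- entries
  renamed$amount_value <- "150,5"
  names(renamed)[names(renamed) == "participant_id"] <- "pid"
  names(renamed)[names(renamed) == "amount_value"] <- "hoeveelheid"
  path2 <- tempfile(fileext = ".csv")
  readr::write_csv(renamed, path2, progress = FALSE)
  d <- record_dialect(
    columns = c(participant_id = "pid", amount_value = "hoeveelheid"),
    decimal_comma = TRUE
  )
  parsed <- read_food_records(path2, d)
  expect_equal(parsed$amount_value, 150.5)
  expect_equal(parsed$participant_id, "p1")
})

test_that("identification-mode tallies reproduce the published shares", {
  counts <- c(
    generic_search = 211, previously_selected = 175, branded_search = 169,
    barcode_scan = 114, recipe = 16, associated_item = 147,
    supplement_entry = 62
  )
  # as a full 894-row entry table read back from disk
  entries <- tibble::tibble(
    participant_id = "p1", day_index = 1L, occasion = "in_between",
    clock_time = "10:00", place = "home", food_code = "apple",
    identification_mode = rep(names(counts), counts),
    amount_value = 10, amount_unit = "gram", unit_count = 1,
    preparation_method = NA_character_, fat_used_code = NA_character_,
    reported_state = "as_consumed"
  )
  entries$occasion[entries$identification_mode == "supplement_entry"] <-
    "supplement"
  parsed <- read_food_records(write_records_csv(entries))
  tally <- recording_mode_tally(parsed)
  expect_equal(
    tally$tally$n[match(names(counts), tally$tally$identification_mode)],
    unname(as.integer(counts))
  )
  expect_equal(tally$n_entries, 894)
  expect_equal(tally$scan_share_pct, 100 * 114 / 894)
  expect_equal(tally$branded_excl_previous_pct, 100 * 283 / 719)
})

test_that("composition tables validate structure and invariants", {
  foods <- test_foods()
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(foods, path, progress = FALSE)
  parsed <- read_composition_table(path)
  expect_equal(nrow(parsed), 12)
  expect_true("energy_kcal" %in% nutrient_columns(parsed))
  expect_equal(parsed$edible_fraction[parsed$food_code == "apple"], 0.65)

  expect_error(
    validate_composition(dplyr::select(foods, -"energy_kcal")),
    "energy_kcal"
  )
  expect_error(
    validate_composition(dplyr::bind_rows(foods, foods[1, ])),
    "duplicate"
  )
  bad_edible <- foods
  bad_edible$edible_fraction[1] <- 1.2
  expect_error(validate_composition(bad_edible), "edible_fraction")
  orphan <- foods
  orphan$generic_parent[orphan$food_code == "banana_brand"] <- NA
  expect_error(validate_composition(orphan), "generic_parent")
})

test_that("group map and roster readers validate their domains", {
  gm_path <- tempfile(fileext = ".tsv")
  readr::write_tsv(test_group_map(), gm_path, progress = FALSE)
  gm <- read_group_map(gm_path)
  expect_equal(nrow(gm), 12)
  bad <- test_group_map()
  bad$food_group[1] <- "candy"
  readr::write_tsv(bad, gm_path, progress = FALSE)
  expect_error(read_group_map(gm_path), "unknown food group")

  r_path <- tempfile(fileext = ".csv")
  roster <- test_roster()
  roster$age_years[2] <- 17L
  readr::write_csv(roster, r_path, progress = FALSE)
  parsed <- suppressMessages(read_roster(r_path))
  expect_equal(nrow(parsed), 3)
  expect_equal(record_diagnostics(parsed)$message, "age outside 18-79")
  expect_equal(parsed$bmi_kg_m2, parsed$weight_kg / parsed$height_m^2)
})

test_that("reports render deterministically and round-trip", {
  res <- tibble::tibble(
    variable = c("fruit", "sauces"), median_a = c(83.4, 2.1),
    median_b = c(130.2, 22.3), wilcoxon_p = c(0.005, 0.0004)
  )
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_report(res, p1, digits = c(median_a = 0, median_b = 0))
  write_report(res, p2, digits = c(median_a = 0, median_b = 0))
  expect_identical(readLines(p1), readLines(p2))
  reread <- read_report(p1)
  expect_equal(reread$median_a, c(83, 2))

  empty <- tempfile(fileext = ".csv")
  write_report(res[0, ], empty)
  expect_equal(length(readLines(empty)), 1) # header only

  md <- tempfile(fileext = ".md")
  write_report(res, md, format = "markdown")
  lines <- readLines(md)
  expect_match(lines[1], "^\\| variable")
  expect_equal(length(lines), 2 + nrow(res))
})
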