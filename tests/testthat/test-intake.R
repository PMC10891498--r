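test_that("portion-to-gram conversion applies each factor as specified", {
  foods <- test_foods()
  # 1 x 100 g, no factors (bread has no gram-edible flag)
  e <- make_entry(food_code = "bread", amount_value = 100)
  expect_equal(grams_consumed(e, foods)$grams, 100)

  # 250 mL of a drink with density 1.03 g/mL
  e <- make_entry(
    food_code = "milk_drink", amount_value = 250, amount_unit = "milliliter"
  )
  expect_equal(grams_consumed(e, foods)$grams, 257.5)

  # 120 g of an unpeeled item, edible fraction 0.65, reported raw by weight
  e <- make_entry(food_code = "apple", amount_value = 120)
  expect_equal(grams_consumed(e, foods)$grams, 78)

  # 100 g unprepared rice, boiling yield 2.5
  e <- make_entry(
    food_code = "rice", amount_value = 100,
    preparation_method = "boiled", reported_state = "unprepared"
  )
  expect_equal(grams_consumed(e, foods)$grams, 250)

  # natural units: 2 x 35 g slices of bread
  e <- make_entry(
    food_code = "bread", amount_value = 1, amount_unit = "natural_unit",
    unit_count = 2
  )
  expect_equal(grams_consumed(e, foods)$grams, 70)

  # edible fraction per unit: tomato flagged for natural_unit only
  by_unit <- make_entry(
    food_code = "tomato", amount_value = 1, amount_unit = "natural_unit"
  )
  expect_equal(grams_consumed(by_unit, foods)$grams, 80 * 0.95)
  by_gram <- make_entry(food_code = "tomato", amount_value = 80)
  expect_equal(grams_consumed(by_gram, foods)$grams, 80)
})

test_that("unquantifiable portions and unknown preparations error", {
  foods <- test_foods()
  e <- make_entry(
    food_code = "fries", amount_value = 1, amount_unit = "natural_unit"
  )
  expect_error(grams_consumed(e, foods), "unquantifiable portion")
  e <- make_entry(
    food_code = "rice", amount_value = 100,
    preparation_method = "microwaved", reported_state = "unprepared"
  )
  expect_error(grams_consumed(e, foods), "preparation")
  e <- make_entry(food_code = "dragonfruit")
  expect_error(grams_consumed(e, foods), "not in composition table")
})

test_that("fat absorption creates attributed extra entries only when due", {
  foods <- test_foods()
  # 200 g fried item with absorption 0.05 -> 10 g of the specified oil
  e <- grams_consumed(
    make_entry(
      food_code = "fries", amount_value = 200,
      preparation_method = "fried", fat_used_code = "oil"
    ),
    foods
  )
  extra <- apply_fat_absorption(e, foods)
  expect_equal(nrow(extra), 1)
  expect_equal(extra$grams, 10)
  expect_equal(extra$food_code, "oil")
  expect_equal(extra$identification_mode, "associated_item")

  # absorption zero -> nothing
  e0 <- grams_consumed(
    make_entry(
      food_code = "rice", amount_value = 100,
      preparation_method = "fried", fat_used_code = "oil"
    ),
    foods
  )
  expect_equal(nrow(apply_fat_absorption(e0, foods)), 0)

  # raw preparation gates the absorption even when the food absorbs fat
  raw <- grams_consumed(
    make_entry(
      food_code = "fries", amount_value = 200, preparation_method = "raw",
      fat_used_code = "oil"
    ),
    foods
  )
  expect_equal(nrow(apply_fat_absorption(raw, foods)), 0)

  # unresolvable fat code errors with context
  bad <- grams_consumed(
    make_entry(
      food_code = "fries", amount_value = 200,
      preparation_method = "fried", fat_used_code = "lard"
    ),
    foods
  )
  expect_error(apply_fat_absorption(bad, foods), "lard")
})

test_that("recipe disaggregation scales ingredients by the eaten fraction", {
  recipes <- tibble::tibble(
    recipe_id = "stew",
    food_code = c("rice", "chicken"),
    grams = c(400, 200)
  )
  base <- make_entry(
    food_code = "stew", amount_value = 0.25, amount_unit = "recipe_fraction",
    identification_mode = "recipe"
  )
  out <- disaggregate_recipe(base, recipes)
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$amount_value), c(50, 100))
  expect_equal(sum(out$amount_value), 0.25 * 600)
  expect_true(all(out$amount_unit == "gram"))

  whole <- base
  whole$amount_value <- 1
  out1 <- disaggregate_recipe(whole, recipes)
  expect_equal(sort(out1$amount_value), c(200, 400))

  zero <- base
  zero$amount_value <- 0
  expect_error(disaggregate_recipe(zero, recipes), "fraction")
})

test_that("daily totals aggregate by group and nutrient, per gram", {
  foods <- test_foods()
  gm <- test_group_map()
  # 150 g of cheese at 350 kcal/100 g
  e <- make_entry(food_code = "cheese", amount_value = 150)
  d <- daily_totals(e, foods, gm)
  expect_equal(d$cheese, 150)
  expect_equal(d$energy_kcal, 150 * 3.5)
  expect_equal(d$protein_g, 150 * 0.25)

  # empty day produces all-zero totals
  d0 <- daily_totals(
    e[0, ], foods, gm,
    complete_days = tibble::tibble(participant_id = "p9", day_index = 1L)
  )
  expect_equal(nrow(d0), 1)
  expect_equal(d0$energy_kcal, 0)
  expect_true(all(d0[wheel_of_five_groups()] == 0))

  # supplements excluded from totals
  supp <- make_entry(
    food_code = "cheese", occasion = "supplement",
    identification_mode = "supplement_entry", amount_value = 500
  )
  expect_equal(daily_totals(dplyr::bind_rows(e, supp), foods, gm)$cheese, 150)

  # unresolvable codes listed
  expect_error(
    daily_totals(make_entry(food_code = "durian"), foods, gm), "durian"
  )
})

test_that("daily totals are additive, scale linearly, and conserve mass", {
  foods <- test_foods()
  gm <- test_group_map()
  groups <- wheel_of_five_groups()
  set.seed(11)
  for (rep in 1:5) {
    pick <- sample(c("apple", "bread", "cheese", "tomato", "milk_drink"), 3)
    a <- purrr::map_dfr(pick, function(f) {
      make_entry(food_code = f, amount_value = runif(1, 10, 300))
    })
    b <- make_entry(
      food_code = "fries", amount_value = runif(1, 50, 200),
      occasion = "evening_meal", preparation_method = "fried",
      fat_used_code = "oil"
    )
    ta <- daily_totals(a, foods, gm)
    tb <- daily_totals(b, foods, gm)
    tab <- daily_totals(dplyr::bind_rows(a, b), foods, gm)
    # additivity over entry sets
    expect_equal(
      as.numeric(tab[c(groups, "energy_kcal")]),
      as.numeric(ta[c(groups, "energy_kcal")]) +
        as.numeric(tb[c(groups, "energy_kcal")])
    )
    # doubling amounts doubles totals
    a2 <- dplyr::mutate(a, amount_value = amount_value * 2)
    expect_equal(
      as.numeric(daily_totals(a2, foods, gm)[c(groups, "energy_kcal")]),
      2 * as.numeric(ta[c(groups, "energy_kcal")])
    )
    # conservation: group grams equal item grams incl. absorbed fat
    items <- grams_consumed(dplyr::bind_rows(a, b), foods)
    fat <- apply_fat_absorption(items, foods)
    expect_equal(
      sum(tab[groups]), sum(items$grams) + sum(fat$grams)
    )
    expect_true(all(as.matrix(tab[c(groups, "energy_kcal")]) >= 0))
  }
})
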