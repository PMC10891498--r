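# Conversion of validated record entries into grams-as-consumed per item
# and then into daily food-group and nutrient totals per participant-day.

default_fat_preparations <- function() {
  c("fried", "deep_fried", "stir_fried", "baked", "roasted")
}

#' Grams as consumed for each record entry
#'
#' Converts every entry's reported portion into grams in its consumed
#' state: portion weight times number of portions, times the food's density
#' for volumes reported in milliliters, times the edible fraction when the
#' reported form includes an inedible part (per-unit applicability is
#' carried by the descriptor's `edible_units` field), and times the
#' preparation yield factor when the amount was estimated as unprepared
#' food.
#'
#' @param entries A tibble of record entries from [read_food_records()].
#'   Entries with `amount_unit == "recipe_fraction"` must be resolved first
#'   with [disaggregate_recipe()].
#' @param foods A composition table from [read_composition_table()].
#' @return `entries` with an added `grams` column.
#' @export
grams_consumed <- function(entries, foods) {
  entries <- as_tibble(entries)
  if (any(entries$amount_unit == "recipe_fraction")) {
    abort("recipe_fraction entries must be disaggregated before conversion")
  }
  unresolved <- setdiff(unique(entries$food_code), foods$food_code)
  if (length(unresolved)) {
    abort(paste0(
      "food code(s) not in composition table: ",
      paste(unresolved, collapse = ", ")
    ))
  }
  idx <- match(entries$food_code, foods$food_code)
  unit_weight <- rep(1, nrow(entries))

  measured_units <- c("household_measure", "natural_unit", "commercial_unit")
  for (u in measured_units) {
    sel <- entries$amount_unit == u
    if (!any(sel)) next
    col <- paste0("unit_g.", u)
    w <- if (col %in% names(foods)) foods[[col]][idx] else rep(NA_real_, nrow(entries))
    if (any(sel & (is.na(w) | w <= 0))) {
      offenders <- unique(entries$food_code[sel & (is.na(w) | w <= 0)])
      abort(paste0(
        "unquantifiable portion: no ", u, " weight for ",
        paste(offenders, collapse = ", ")
      ))
    }
    unit_weight[sel] <- w[sel]
  }
  ml <- entries$amount_unit == "milliliter"
  if (any(ml)) {
    dens <- foods$density_g_per_ml[idx]
    dens[is.na(dens)] <- 1
    unit_weight[ml] <- dens[ml]
  }

  grams <- entries$amount_value * entries$unit_count * unit_weight

  # Edible fraction only where the reported form includes the inedible part.
  edible_units <- strsplit(
    ifelse(is.na(foods$edible_units[idx]), "", foods$edible_units[idx]), ";"
  )
  applies <- unname(mapply(
    function(u, lst) u %in% trimws(lst),
    entries$amount_unit, edible_units
  ))
  grams <- grams * ifelse(applies, foods$edible_fraction[idx], 1)

  # Yield factor for amounts estimated as unprepared food.
  unprep <- entries$reported_state == "unprepared"
  if (any(unprep)) {
    prep <- entries$preparation_method
    if (any(unprep & (is.na(prep) | prep == ""))) {
      abort("unprepared amount without a preparation method")
    }
    yf <- rep(NA_real_, nrow(entries))
    for (p in unique(prep[unprep])) {
      col <- paste0("yield.", p)
      sel <- unprep & prep == p
      if (!col %in% names(foods)) {
        abort(paste0("unknown preparation method: ", p))
      }
      yf[sel] <- foods[[col]][match(entries$food_code[sel], foods$food_code)]
    }
    if (any(unprep & (is.na(yf) | yf <= 0))) {
      abort("missing yield factor for an unprepared amount")
    }
    grams[unprep] <- grams[unprep] * yf[unprep]
  }

  entries$grams <- grams
  entries
}

#' Absorbed preparation fat as additional entries
#'
#' Frying and similar preparations add fat to the food. For every entry
#' whose preparation method involves added fat and whose descriptor carries
#' a positive fat-absorption fraction, an extra entry is produced for the
#' specified fat, with grams equal to the item's consumed grams times the
#' absorption fraction. The extra entries flow into all downstream totals
#' under the fat's own food code (and hence its food group).
#'
#' @param entries A tibble with a `grams` column, from [grams_consumed()].
#' @param foods A composition table.
#' @param fat_preparations Preparation methods that involve added fat.
#' @return A tibble of extra entries (possibly zero rows), same columns as
#'   `entries`, with `identification_mode = "associated_item"`.
#' @export
apply_fat_absorption <- function(entries, foods,
                                 fat_preparations = default_fat_preparations()) {
  entries <- as_tibble(entries)
  if (!"grams" %in% names(entries)) {
    abort("entries need a grams column; run grams_consumed() first")
  }
  idx <- match(entries$food_code, foods$food_code)
  frac <- foods$fat_absorption_fraction[idx]
  sel <- !is.na(entries$preparation_method) &
    entries$preparation_method %in% fat_preparations &
    frac > 0
  if (!any(sel)) {
    return(entries[0, ])
  }
  fat_codes <- entries$fat_used_code[sel]
  if (any(is.na(fat_codes) | fat_codes == "")) {
    abort("fat-involving preparation without a fat_used_code")
  }
  bad <- setdiff(unique(fat_codes), foods$food_code)
  if (length(bad)) {
    abort(paste0(
      "fat_used_code(s) not in composition table: ",
      paste(bad, collapse = ", ")
    ))
  }
  extra <- entries[sel, ]
  extra$grams <- entries$grams[sel] * frac[sel]
  extra$food_code <- fat_codes
  extra$identification_mode <- "associated_item"
  extra$amount_value <- extra$grams
  extra$amount_unit <- "gram"
  extra$unit_count <- 1
  extra$preparation_method <- NA_character_
  extra$fat_used_code <- NA_character_
  extra$reported_state <- "as_consumed"
  extra
}

#' Disaggregate recipe entries into ingredient entries
#'
#' A recipe entry records the consumed fraction of a user-defined mixed
#' dish. Each such entry is replaced by one gram-denominated entry per
#' ingredient, contributing fraction times the ingredient's grams in the
#' full recipe.
#'
#' @param entries A tibble of record entries; rows with
#'   `amount_unit == "recipe_fraction"` reference a `recipe_id` via their
#'   `food_code`.
#' @param recipes A tibble with columns `recipe_id`, `food_code`, `grams`
#'   (grams of each ingredient in the full recipe).
#' @return `entries` with recipe rows replaced by ingredient rows.
#' @export
disaggregate_recipe <- function(entries, recipes) {
  entries <- as_tibble(entries)
  is_recipe <- entries$amount_unit == "recipe_fraction"
  if (!any(is_recipe)) {
    return(entries)
  }
  recipes <- as_tibble(recipes)
  if (any(recipes$grams <= 0)) abort("recipe ingredient grams must be positive")
  rec_rows <- entries[is_recipe, ]
  frac <- rec_rows$amount_value * rec_rows$unit_count
  if (any(frac <= 0 | frac > 1)) {
    abort("recipe fraction outside (0, 1]")
  }
  unknown <- setdiff(unique(rec_rows$food_code), recipes$recipe_id)
  if (length(unknown)) {
    abort(paste0("unknown recipe id(s): ", paste(unknown, collapse = ", ")))
  }
  expanded <- purrr::map_dfr(seq_len(nrow(rec_rows)), function(i) {
    ing <- recipes[recipes$recipe_id == rec_rows$food_code[i], ]
    out <- rec_rows[rep(i, nrow(ing)), ]
    out$food_code <- ing$food_code
    out$amount_value <- frac[i] * ing$grams
    out$amount_unit <- "gram"
    out$unit_count <- 1
    out
  })
  bind_rows(entries[!is_recipe, ], expanded)
}

#' Daily food-group and nutrient totals
#'
#' The core aggregation: recipe entries are disaggregated, portions are
#' converted to grams as consumed, absorbed preparation fat is added, every
#' item is mapped to exactly one Wheel of Five group, and grams and
#' nutrients are summed per participant-day. Nutrient totals are grams
#' times the per-gram composition (per-100 g values divided by 100).
#' Supplement entries are excluded from both group and nutrient totals
#' (they remain visible to [recording_mode_tally()]).
#'
#' @param entries Validated record entries.
#' @param foods Composition table.
#' @param group_map Tibble `food_code`, `food_group`.
#' @param recipes Optional recipe table for [disaggregate_recipe()].
#' @param fat_preparations Preparation methods that involve added fat.
#' @param complete_days Optional tibble (`participant_id`, `day_index`) of
#'   participant-days that must appear in the output even when no food was
#'   recorded (all-zero totals).
#' @return A wide tibble, one row per participant-day: `participant_id`,
#'   `day_index`, one grams/day column per food group (attribute
#'   `group_columns`), and one column per nutrient including `energy_kcal`
#'   (attribute `nutrient_columns`).
#' @export
daily_totals <- function(entries, foods, group_map, recipes = NULL,
                         fat_preparations = default_fat_preparations(),
                         complete_days = NULL) {
  entries <- as_tibble(entries)
  foods <- validate_composition(foods)
  nutrients <- nutrient_columns(foods)
  groups <- wheel_of_five_groups()

  entries <- entries[entries$identification_mode != "supplement_entry", ]
  if (!is.null(recipes)) entries <- disaggregate_recipe(entries, recipes)

  if (nrow(entries) > 0) {
    unresolved <- setdiff(
      unique(entries$food_code),
      intersect(foods$food_code, group_map$food_code)
    )
    if (length(unresolved)) {
      abort(paste0(
        "unresolvable food code(s): ", paste(unresolved, collapse = ", ")
      ))
    }
    entries <- grams_consumed(entries, foods)
    extra <- apply_fat_absorption(entries, foods, fat_preparations)
    if (nrow(extra) > 0) {
      bad <- setdiff(unique(extra$food_code), group_map$food_code)
      if (length(bad)) {
        abort(paste0(
          "fat code(s) missing from group map: ", paste(bad, collapse = ", ")
        ))
      }
    }
    items <- bind_rows(entries, extra) %>%
      left_join(group_map, by = "food_code")

    comp_idx <- match(items$food_code, foods$food_code)
    group_tot <- items %>%
      group_by(.data$participant_id, .data$day_index, .data$food_group) %>%
      summarise(grams = sum(.data$grams), .groups = "drop") %>%
      tidyr::pivot_wider(
        names_from = "food_group", values_from = "grams", values_fill = 0
      )

    per_gram <- as.matrix(foods[comp_idx, nutrients, drop = FALSE]) / 100
    per_gram[is.na(per_gram)] <- 0
    nut <- as_tibble(per_gram * items$grams)
    nut$participant_id <- items$participant_id
    nut$day_index <- items$day_index
    nut_tot <- nut %>%
      group_by(.data$participant_id, .data$day_index) %>%
      summarise(across(all_of(nutrients), sum), .groups = "drop")

    out <- left_join(group_tot, nut_tot, by = c("participant_id", "day_index"))
  } else {
    out <- tibble(participant_id = character(), day_index = integer())
  }

  for (g in setdiff(groups, names(out))) out[[g]] <- numeric(nrow(out))
  for (nu in setdiff(nutrients, names(out))) out[[nu]] <- numeric(nrow(out))

  if (!is.null(complete_days)) {
    missing_days <- anti_join(
      as_tibble(complete_days), out,
      by = c("participant_id", "day_index")
    )
    if (nrow(missing_days) > 0) {
      zeros <- missing_days
      for (col in c(groups, nutrients)) zeros[[col]] <- 0
      out <- bind_rows(out, zeros)
    }
  }

  out <- out %>%
    select(all_of(c("participant_id", "day_index", groups, nutrients))) %>%
    arrange(.data$participant_id, .data$day_index)
  attr(out, "group_columns") <- groups
  attr(out, "nutrient_columns") <- nutrients
  out
}

#' Food-group columns of a daily-totals table
#' @param daily A tibble from [daily_totals()].
#' @return Character vector of group column names.
#' @export
group_columns <- function(daily) {
  attr(daily, "group_columns") %||%
    intersect(wheel_of_five_groups(), names(daily))
}
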