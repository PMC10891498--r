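# Reading and writing the tabular artifacts of a validation study:
# food-record exports, the food-composition table, the food-group map,
# the participant roster, and result reports.

#' Default dialect for food-record export files
#'
#' Export schemas differ between recording apps, so column names and number
#' formatting are configurable through a dialect: a list with a `columns`
#' mapping (canonical field -> column name in the file), a `delimiter`, and
#' a `decimal_comma` flag for locales that export `1,5` for one-and-a-half.
#'
#' @param columns Named character vector overriding individual column names.
#' @param delimiter Field delimiter, default `","`.
#' @param decimal_comma If `TRUE`, numbers in the file use a decimal comma.
#' @return A dialect list usable with [read_food_records()].
#' @export
#' @examples
#' d <- record_dialect(columns = c(participant_id = "pid"))
#' d$columns[["participant_id"]]
record_dialect <- function(columns = character(), delimiter = ",",
                           decimal_comma = FALSE) {
  canonical <- c(
    "participant_id", "day_index", "occasion", "clock_time", "place",
    "food_code", "identification_mode", "amount_value", "amount_unit",
    "unit_count", "preparation_method", "fat_used_code", "reported_state"
  )
  map <- setNames(canonical, canonical)
  if (length(columns)) {
    bad <- setdiff(names(columns), canonical)
    if (length(bad)) {
      abort(paste0("unknown dialect fields: ", paste(bad, collapse = ", ")))
    }
    map[names(columns)] <- columns
  }
  list(columns = map, delimiter = delimiter, decimal_comma = decimal_comma)
}

#' Read a dialect configuration from a YAML file
#'
#' @param path Path to a YAML file with optional keys `columns` (a mapping),
#'   `delimiter`, and `decimal_comma`.
#' @return A dialect list, as from [record_dialect()].
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  record_dialect(
    columns = unlist(cfg$columns %||% character()),
    delimiter = cfg$delimiter %||% ",",
    decimal_comma = isTRUE(cfg$decimal_comma)
  )
}

dv_parse_number <- function(x, decimal_comma = FALSE) {
  x <- trimws(as.character(x))
  if (decimal_comma) x <- gsub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

# Mandatory canonical fields for a record export; the rest are optional.
record_mandatory <- function() {
  c(
    "participant_id", "day_index", "occasion", "food_code",
    "identification_mode", "amount_value", "amount_unit", "unit_count"
  )
}

#' Read a food-record export file
#'
#' Parses one-row-per-consumed-item export files. Rows failing validation
#' (negative amounts, unknown occasion or unit, zero unit counts, recipe
#' fractions outside (0, 1], supplement-mode rows outside the supplement
#' occasion) are skipped and reported as row-numbered diagnostics rather
#' than silently dropped; missing mandatory columns are fatal. Surviving
#' entries are returned in canonical order: participant, day, eating
#' occasion, clock time.
#'
#' @param path Path to a delimited export file.
#' @param dialect Column-name / number-format mapping from [record_dialect()].
#' @return A tibble of validated food-record entries with a `diagnostics`
#'   attribute (see [record_diagnostics()]).
#' @export
read_food_records <- function(path, dialect = record_dialect()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_delim(
    path,
    delim = dialect$delimiter, col_types = readr::cols(.default = "c"),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(
    unname(dialect$columns[record_mandatory()]), names(raw)
  )
  if (length(missing)) {
    abort(paste0(
      "missing mandatory column(s): ", paste(missing, collapse = ", ")
    ))
  }
  # Map file columns back to canonical names; absent optional columns -> NA.
  canon <- tibble(.rows = nrow(raw))
  for (field in names(dialect$columns)) {
    col <- dialect$columns[[field]]
    canon[[field]] <- if (col %in% names(raw)) raw[[col]] else NA_character_
  }
  canon$.row <- seq_len(nrow(canon))

  canon <- canon %>%
    mutate(
      day_index = dv_parse_number(.data$day_index, dialect$decimal_comma),
      amount_value = dv_parse_number(.data$amount_value, dialect$decimal_comma),
      unit_count = dv_parse_number(.data$unit_count, dialect$decimal_comma),
      reported_state = if_else(
        is.na(.data$reported_state) | .data$reported_state == "",
        "as_consumed", .data$reported_state
      )
    )

  problem <- case_when(
    is.na(canon$participant_id) | canon$participant_id == "" ~ "missing participant id",
    is.na(canon$day_index) | canon$day_index < 1 |
      canon$day_index != round(canon$day_index) ~ "invalid day index",
    !canon$occasion %in% eating_occasions() ~ "unknown eating occasion",
    is.na(canon$food_code) | canon$food_code == "" ~ "missing food code",
    !canon$identification_mode %in% identification_modes() ~
      "unknown identification mode",
    is.na(canon$amount_value) ~ "unparseable amount",
    canon$amount_value < 0 ~ "negative amount",
    !canon$amount_unit %in% amount_units() ~ "unknown amount unit",
    is.na(canon$unit_count) | canon$unit_count <= 0 ~ "non-positive unit count",
    canon$amount_unit == "recipe_fraction" &
      (canon$amount_value <= 0 | canon$amount_value > 1) ~
      "recipe fraction outside (0, 1]",
    canon$identification_mode == "supplement_entry" &
      canon$occasion != "supplement" ~
      "supplement entry outside supplement occasion",
    !canon$reported_state %in% c("as_consumed", "unprepared") ~
      "unknown reported state",
    TRUE ~ NA_character_
  )

  diagnostics <- tibble(
    row = canon$.row[!is.na(problem)],
    message = problem[!is.na(problem)]
  )
  if (nrow(diagnostics) > 0) {
    inform(paste0(
      nrow(diagnostics), " of ", nrow(canon),
      " record row(s) rejected during parsing"
    ))
  }

  out <- canon[is.na(problem), ] %>%
    mutate(
      day_index = as.integer(.data$day_index),
      occasion = factor(.data$occasion, levels = eating_occasions())
    ) %>%
    arrange(
      .data$participant_id, .data$day_index, .data$occasion,
      .data$clock_time
    ) %>%
    mutate(occasion = as.character(.data$occasion)) %>%
    select(-".row")
  attr(out, "diagnostics") <- diagnostics
  attr(out, "n_input_rows") <- nrow(canon)
  out
}

#' Row-level diagnostics from a read operation
#'
#' @param x A tibble returned by [read_food_records()] or [read_roster()].
#' @return A tibble with columns `row` and `message`, one row per rejected
#'   input row.
#' @export
record_diagnostics <- function(x) {
  attr(x, "diagnostics") %||% tibble(row = integer(), message = character())
}

#' Read a food-composition table
#'
#' One row per food, keyed by `food_code`, with per-100 g nutrient values.
#' Structural columns are `food_code`, `is_branded`, `generic_parent`,
#' `density_g_per_ml`, `edible_fraction`, `fat_absorption_fraction`, and
#' `edible_units` (semicolon-separated list of amount units whose reported
#' form includes the inedible part). Portion weights are `unit_g.<unit>`
#' columns (grams per one household/natural/commercial unit) and
#' preparation yield factors are `yield.<method>` columns (prepared weight
#' over unprepared weight). Every remaining numeric column is treated as a
#' nutrient, per 100 g; unknown nutrients pass through untouched. An
#' `energy_kcal` nutrient column is required.
#'
#' @param path Path to a delimited file.
#' @param delim Field delimiter, default tab.
#' @return A tibble of food descriptors with a `nutrients` attribute naming
#'   the nutrient columns.
#' @export
read_composition_table <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  foods <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE
  )
  validate_composition(foods)
}

#' @rdname read_composition_table
#' @param foods A data frame already holding the composition columns.
#' @export
validate_composition <- function(foods) {
  foods <- as_tibble(foods)
  structural <- c(
    "food_code", "is_branded", "generic_parent", "density_g_per_ml",
    "edible_fraction", "fat_absorption_fraction", "edible_units"
  )
  if (!"food_code" %in% names(foods)) abort("composition table lacks food_code")
  if (anyDuplicated(foods$food_code)) {
    abort(paste0(
      "duplicate food_code in composition table: ",
      paste(unique(foods$food_code[duplicated(foods$food_code)]),
        collapse = ", "
      )
    ))
  }
  for (col in setdiff(structural, names(foods))) {
    foods[[col]] <- switch(col,
      is_branded = FALSE,
      generic_parent = NA_character_,
      density_g_per_ml = NA_real_,
      edible_fraction = 1,
      fat_absorption_fraction = 0,
      edible_units = NA_character_
    )
  }
  foods$is_branded <- as.logical(foods$is_branded)
  foods$edible_fraction[is.na(foods$edible_fraction)] <- 1
  foods$fat_absorption_fraction[is.na(foods$fat_absorption_fraction)] <- 0
  if (any(foods$edible_fraction <= 0 | foods$edible_fraction > 1)) {
    abort("edible_fraction outside (0, 1]")
  }
  if (any(foods$fat_absorption_fraction < 0 | foods$fat_absorption_fraction >= 1)) {
    abort("fat_absorption_fraction outside [0, 1)")
  }
  branded_orphan <- foods$is_branded &
    (is.na(foods$generic_parent) | foods$generic_parent == "")
  if (any(branded_orphan)) {
    abort(paste0(
      "branded food(s) without generic_parent: ",
      paste(foods$food_code[branded_orphan], collapse = ", ")
    ))
  }
  nutrients <- setdiff(
    names(foods)[vapply(foods, is.numeric, logical(1))],
    c(structural, grep("^(unit_g|yield)\\.", names(foods), value = TRUE))
  )
  if (!"energy_kcal" %in% nutrients) {
    abort("composition table lacks an energy_kcal nutrient column")
  }
  if (any(foods[nutrients] < 0, na.rm = TRUE)) {
    abort("negative nutrient values in composition table")
  }
  attr(foods, "nutrients") <- nutrients
  foods
}

#' Nutrient columns of a composition table
#' @param foods A tibble from [read_composition_table()].
#' @return Character vector of nutrient column names.
#' @export
nutrient_columns <- function(foods) {
  attr(foods, "nutrients") %||%
    attr(validate_composition(foods), "nutrients")
}

#' Read a food-group map
#'
#' Two columns: `food_code` and `food_group`, assigning each food to one
#' Wheel of Five group (see [wheel_of_five_groups()]).
#'
#' @param path Path to a delimited file.
#' @param delim Field delimiter, default tab.
#' @return A tibble with columns `food_code`, `food_group`.
#' @export
read_group_map <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  gm <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE
  )
  if (!all(c("food_code", "food_group") %in% names(gm))) {
    abort("group map needs columns food_code, food_group")
  }
  bad <- setdiff(unique(gm$food_group), wheel_of_five_groups())
  if (length(bad)) {
    abort(paste0("unknown food group(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(gm$food_code)) {
    abort("a food maps to more than one group")
  }
  as_tibble(gm[c("food_code", "food_group")])
}

#' Read a participant roster
#'
#' Columns `participant_id`, `gender` (`man`/`woman`), `age_years`,
#' `height_m`, `weight_kg`, `education` (`low`/`middle`/`high`). BMI is
#' derived as weight / height squared, never read from the file. Rows with
#' out-of-range values (age outside 18-79, non-positive height or weight)
#' are rejected with diagnostics.
#'
#' @param path Path to a delimited file.
#' @param delim Field delimiter, default `","`.
#' @return A tibble with a derived `bmi_kg_m2` column and a `diagnostics`
#'   attribute.
#' @export
read_roster <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  r <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE
  )
  need <- c(
    "participant_id", "gender", "age_years", "height_m", "weight_kg",
    "education"
  )
  missing <- setdiff(need, names(r))
  if (length(missing)) {
    abort(paste0("roster lacks column(s): ", paste(missing, collapse = ", ")))
  }
  validate_roster(as_tibble(r[need]))
}

#' @rdname read_roster
#' @param roster A data frame already holding the roster columns.
#' @export
validate_roster <- function(roster) {
  roster <- as_tibble(roster)
  problem <- case_when(
    !roster$gender %in% genders() ~ "unknown gender",
    is.na(roster$age_years) | roster$age_years < 18 | roster$age_years > 79 ~
      "age outside 18-79",
    is.na(roster$height_m) | roster$height_m <= 0 ~ "non-positive height",
    is.na(roster$weight_kg) | roster$weight_kg <= 0 ~ "non-positive weight",
    !roster$education %in% education_levels() ~ "unknown education level",
    TRUE ~ NA_character_
  )
  diagnostics <- tibble(
    row = which(!is.na(problem)), message = problem[!is.na(problem)]
  )
  if (nrow(diagnostics) > 0) {
    inform(paste0(nrow(diagnostics), " roster row(s) rejected"))
  }
  out <- roster[is.na(problem), ] %>%
    mutate(
      age_years = as.integer(.data$age_years),
      bmi_kg_m2 = .data$weight_kg / .data$height_m^2
    )
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Write a results report
#'
#' Writes a comparison-result tibble with a deterministic column order and
#' fixed numeric rendering, so that the same results always produce a
#' byte-identical file.
#'
#' @param results A tibble (e.g. from [compare_tables()]).
#' @param path Output path.
#' @param format `"csv"` or `"markdown"`.
#' @param digits Named integer vector: decimals to render for specific
#'   columns (unnamed columns keep full precision in CSV, 3 decimals in
#'   markdown).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "markdown"),
                         digits = NULL) {
  format <- match.arg(format)
  results <- as_tibble(results)
  if (!is.null(digits)) {
    for (col in intersect(names(digits), names(results))) {
      results[[col]] <- round(results[[col]], digits[[col]])
    }
  }
  if (format == "csv") {
    readr::write_csv(results, path, progress = FALSE)
  } else {
    fmt_cell <- function(x) {
      if (is.numeric(x)) {
        ifelse(is.na(x), "", formatC(x, format = "fg", digits = 3))
      } else {
        ifelse(is.na(x), "", as.character(x))
      }
    }
    cells <- vapply(results, fmt_cell, character(nrow(results)))
    if (nrow(results) == 1L) cells <- matrix(cells, nrow = 1)
    lines <- c(
      paste0("| ", paste(names(results), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(results)), collapse = "|"), "|"),
      if (nrow(results)) {
        apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
      }
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a CSV report written by [write_report()]
#' @param path Path to the report.
#' @return A tibble.
#' @export
read_report <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
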