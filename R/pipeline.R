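# End-to-end orchestration: ingest -> intake -> screen -> (match) ->
# compare -> report, with a manifest for re-runnable, auditable analyses.

#' Run configuration
#'
#' Collects every input path and analysis setting of a study run. Can be
#' built in code or loaded from YAML with [read_run_config()].
#'
#' @param records_a,records_b Paths to the two methods' record exports
#'   (method A = test method, method B = reference method).
#' @param composition,group_map,roster Paths to the composition table,
#'   group map, and participant roster.
#' @param pool Optional path to an external comparator roster; when given,
#'   matched comparators are selected and written.
#' @param output_dir Directory for the result bundle.
#' @param dialect Optional path to a dialect YAML for the record files.
#' @param ei_bmr_low,ei_bmr_high Plausibility bounds on EI/BMR.
#' @param expected_pal Expected physical activity level.
#' @param strata Stratification variables, subset of
#'   `c("education", "bmi")`.
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed matters when the inputs were simulated).
#' @return A `dv_run_config` list.
#' @export
run_config <- function(records_a, records_b, composition, group_map, roster,
                       output_dir, pool = NULL, dialect = NULL,
                       ei_bmr_low = 0.6, ei_bmr_high = 3.0,
                       expected_pal = 1.59, strata = NULL, seed = 1L) {
  cfg <- list(
    records_a = records_a, records_b = records_b, composition = composition,
    group_map = group_map, roster = roster, pool = pool,
    output_dir = output_dir, dialect = dialect,
    ei_bmr_low = ei_bmr_low, ei_bmr_high = ei_bmr_high,
    expected_pal = expected_pal, strata = strata, seed = as.integer(seed)
  )
  class(cfg) <- "dv_run_config"
  cfg
}

#' @rdname run_config
#' @param path Path to a YAML file whose keys mirror the [run_config()]
#'   arguments.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run a complete relative-validity study
#'
#' Fixed stage order: read and validate all inputs; compute daily totals
#' per method; pair each participant's test-method day with the
#' reference-method record for the same day (unpaired days are dropped and
#' logged); screen test-method days for implausible EI/BMR and drop
#' excluded days from both methods; optionally select matched comparators
#' from an external pool; run the comparison battery (overall, consumers,
#' strata) and Bland-Altman for energy; and write the result bundle with a
#' manifest. Re-running with identical inputs produces byte-identical
#' tables.
#'
#' @param config A [run_config()] or a path to a YAML run configuration.
#' @return An object of class `dv_study`: list with `comparison`
#'   (`dv_comparison`), `bland_altman_energy`, `screens`, `misreporting`,
#'   `matches` (or `NULL`), `flow`, `n_analysed`, `dropped_unpaired`, and
#'   `paths` of everything written.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "dv_run_config"))
  for (f in c("records_a", "records_b", "composition", "group_map", "roster")) {
    if (!file.exists(config[[f]])) {
      abort(paste0("input file missing (", f, "): ", config[[f]]))
    }
  }
  dialect <- if (is.null(config$dialect)) {
    record_dialect()
  } else {
    read_dialect(config$dialect)
  }

  entries_a <- read_food_records(config$records_a, dialect)
  entries_b <- read_food_records(config$records_b, dialect)
  foods <- read_composition_table(config$composition)
  group_map <- read_group_map(config$group_map)
  roster <- read_roster(config$roster)

  daily_a <- daily_totals(entries_a, foods, group_map)
  daily_b <- daily_totals(entries_b, foods, group_map)

  pairs_b <- daily_b[c("participant_id", "day_index")]
  paired_a <- semi_join(daily_a, pairs_b, by = c("participant_id", "day_index"))
  dropped <- anti_join(
    daily_a[c("participant_id", "day_index")], pairs_b,
    by = c("participant_id", "day_index")
  )
  dropped <- bind_rows(
    dropped,
    anti_join(
      pairs_b, daily_a[c("participant_id", "day_index")],
      by = c("participant_id", "day_index")
    )
  )
  if (nrow(dropped) > 0) {
    inform(paste0(nrow(dropped), " unpaired participant-day(s) dropped"))
  }
  if (nrow(paired_a) == 0) {
    abort("zero valid same-day pairs between the two methods")
  }

  screens <- screen_days(
    paired_a, roster,
    ratio_low = config$ei_bmr_low, ratio_high = config$ei_bmr_high
  )
  keep_a <- keep_plausible_days(paired_a, screens)
  keep_b <- semi_join(
    daily_b, keep_a[c("participant_id", "day_index")],
    by = c("participant_id", "day_index")
  )
  if (nrow(keep_a) == 0) abort("no plausible paired days after screening")

  misreporting <- underreporting_summary(
    screens[screens$plausible, ],
    expected_pal = config$expected_pal
  )

  matches <- NULL
  if (!is.null(config$pool)) {
    pool <- read_roster(config$pool)
    analysed_roster <- roster[
      roster$participant_id %in% keep_a$participant_id,
    ]
    matches <- match_cohort(analysed_roster, pool)
  }

  nutrients <- attr(daily_totals(
    entries_a[0, ], foods, group_map
  ), "nutrient_columns")
  comparison <- compare_tables(
    keep_a, keep_b,
    variables = c(intersect(wheel_of_five_groups(), names(keep_a)), nutrients),
    roster = roster, strata = config$strata
  )
  energy <- dplyr::inner_join(
    keep_a[c("participant_id", "day_index", "energy_kcal")],
    keep_b[c("participant_id", "day_index", "energy_kcal")],
    by = c("participant_id", "day_index"), suffix = c("_a", "_b")
  ) %>%
    arrange(.data$participant_id)
  ba <- bland_altman(energy$energy_kcal_a, energy$energy_kcal_b)

  flow <- flow_summary(c(
    completed = dplyr::n_distinct(paired_a$participant_id),
    excluded = dplyr::n_distinct(paired_a$participant_id) -
      dplyr::n_distinct(keep_a$participant_id)
  ))

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$output_dir, f)
  paths <- list(
    paired = p("paired_comparison.csv"),
    consumers = p("consumer_comparison.csv"),
    bland_altman = p("bland_altman_energy.csv"),
    screening = p("screening_log.csv"),
    flow = p("participant_flow.csv"),
    manifest = p("manifest.json")
  )
  write_report(comparison$paired, paths$paired)
  write_report(comparison$consumers, paths$consumers)
  write_report(tidy(ba), paths$bland_altman)
  write_report(screens, paths$screening)
  write_report(flow, paths$flow)
  if (!is.null(comparison$strata)) {
    for (s in names(comparison$strata)) {
      f <- p(paste0("paired_", gsub(":", "_", s), ".csv"))
      write_report(comparison$strata[[s]], f)
      paths[[paste0("stratum_", s)]] <- f
    }
  }
  if (!is.null(matches)) {
    paths$matches <- p("matches.csv")
    write_report(matches, paths$matches)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dietvalid")),
    seed = config$seed,
    inputs = config[c(
      "records_a", "records_b", "composition", "group_map", "roster", "pool"
    )],
    settings = config[c(
      "ei_bmr_low", "ei_bmr_high", "expected_pal", "strata"
    )],
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    n_analysed = dplyr::n_distinct(keep_a$participant_id)
  )
  jsonlite::write_json(
    manifest, paths$manifest,
    auto_unbox = TRUE, pretty = TRUE, null = "null"
  )

  out <- list(
    comparison = comparison, bland_altman_energy = ba, screens = screens,
    misreporting = misreporting, matches = matches, flow = flow,
    n_analysed = manifest$n_analysed, dropped_unpaired = dropped,
    manifest = manifest, paths = paths
  )
  class(out) <- "dv_study"
  out
}

#' @export
print.dv_study <- function(x, ...) {
  cat("Relative-validity study run\n")
  cat("  participants analysed:", x$n_analysed, "\n")
  cat(
    "  relevant differences:",
    sum(x$comparison$paired$relevant_difference, na.rm = TRUE), "of",
    nrow(x$comparison$paired), "variables\n"
  )
  cat(
    "  energy limits of agreement: [",
    format(x$bland_altman_energy$loa_low, digits = 4), ", ",
    format(x$bland_altman_energy$loa_high, digits = 4), "] kcal\n",
    sep = ""
  )
  invisible(x)
}

#' Participant-flow summary
#'
#' Condenses stage counts into the recruitment-and-selection flow. The
#' number analysed is completed minus excluded-by-screening; counts must
#' be non-negative and non-increasing along the flow.
#'
#' @param counts Named numeric vector with `completed` and `excluded`,
#'   optionally preceded by `contacted` and `invited`.
#' @return A tibble with columns `stage` and `n`.
#' @export
#' @examples
#' flow_summary(c(completed = 227, excluded = 16)) # analysed: 211
flow_summary <- function(counts) {
  need <- c("completed", "excluded")
  if (!all(need %in% names(counts))) {
    abort("counts must include 'completed' and 'excluded'")
  }
  if (any(counts < 0)) abort("flow counts must be non-negative")
  if (counts[["excluded"]] > counts[["completed"]]) {
    abort("excluded cannot exceed completed")
  }
  stages <- intersect(
    c("contacted", "invited", "completed"), names(counts)
  )
  ordered <- counts[stages]
  if (any(diff(unname(ordered)) > 0)) {
    abort("flow counts must be non-increasing along the flow")
  }
  tibble(
    stage = c(stages, "excluded", "analysed"),
    n = as.integer(c(
      unname(ordered), counts[["excluded"]],
      counts[["completed"]] - counts[["excluded"]]
    ))
  )
}
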