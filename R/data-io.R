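#' Read and validate monitoring tables
#'
#' Readers for the five CSV dialects the pipeline consumes. Each reader parses
#' with [readr::read_csv()], coerces types, and runs the corresponding
#' `validate_*()` check so that downstream estimators can assume the
#' invariants hold. All files are UTF-8, comma-delimited, with a header row.
#'
#' Column schemas:
#' \describe{
#'   \item{encounters.csv}{`bear_id, population, birth_year, year,
#'     interval (1-8), status (alive|dead|censored), cause
#'     (human|natural|unknown|NA)`. One row per monitored interval.}
#'   \item{litters.csv}{`mother_id, population, year, cubs_emergence,
#'     cubs_survived, monitored_to_autumn (0/1)`.}
#'   \item{states.csv}{`bear_id, population, year, state (A|C|Y|T), age`.}
#'   \item{primiparity.csv}{`bear_id, population, age, first_litter (0/1)`.
#'     One row per age at which a female was monitored while nulliparous,
#'     plus (if observed) one row with `first_litter = 1` at the age of her
#'     first litter.}
#'   \item{interbirth.csv}{`bear_id, population, birth_year, offset,
#'     next_litter (0/1)`. One row per year offset (1, 2, ...) after an
#'     observed birth during which the female was still monitored without a
#'     subsequent litter, plus one row with `next_litter = 1` at the offset
#'     of the next litter if observed.}
#' }
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @name read_monitoring
NULL

csv_cols <- function(path, spec) {
  missing <- setdiff(names(spec$cols), names(readr::spec_csv(path)$cols))
  if (length(missing) > 0) {
    abort(sprintf(
      "file '%s' is missing mandatory column(s): %s",
      path, paste(missing, collapse = ", ")
    ), class = "bearvitals_schema_error")
  }
  readr::read_csv(path, col_types = spec, progress = FALSE)
}

#' @rdname read_monitoring
#' @export
read_encounters <- function(path) {
  spec <- readr::cols(
    bear_id = readr::col_character(),
    population = readr::col_character(),
    birth_year = readr::col_integer(),
    year = readr::col_integer(),
    interval = readr::col_integer(),
    status = readr::col_character(),
    cause = readr::col_character()
  )
  validate_encounters(csv_cols(path, spec))
}

#' @rdname read_monitoring
#' @export
read_litters <- function(path) {
  spec <- readr::cols(
    mother_id = readr::col_character(),
    population = readr::col_character(),
    year = readr::col_integer(),
    cubs_emergence = readr::col_integer(),
    cubs_survived = readr::col_integer(),
    monitored_to_autumn = readr::col_logical()
  )
  validate_litters(csv_cols(path, spec))
}

#' @rdname read_monitoring
#' @export
read_states <- function(path) {
  spec <- readr::cols(
    bear_id = readr::col_character(),
    population = readr::col_character(),
    year = readr::col_integer(),
    state = readr::col_character(),
    age = readr::col_integer()
  )
  validate_states(csv_cols(path, spec))
}

#' @rdname read_monitoring
#' @export
read_primiparity <- function(path) {
  spec <- readr::cols(
    bear_id = readr::col_character(),
    population = readr::col_character(),
    age = readr::col_integer(),
    first_litter = readr::col_integer()
  )
  validate_primiparity(csv_cols(path, spec))
}

#' @rdname read_monitoring
#' @export
read_interbirth <- function(path) {
  spec <- readr::cols(
    bear_id = readr::col_character(),
    population = readr::col_character(),
    birth_year = readr::col_integer(),
    offset = readr::col_integer(),
    next_litter = readr::col_integer()
  )
  validate_interbirth(csv_cols(path, spec))
}

validation_error <- function(msg, bear = NULL, rows = NULL) {
  where <- c(
    if (!is.null(bear)) sprintf("bear_id %s", paste(bear, collapse = ", ")),
    if (!is.null(rows)) sprintf("row(s) %s", paste(rows, collapse = ", "))
  )
  if (length(where) > 0) msg <- paste0(msg, " [", paste(where, collapse = "; "), "]")
  abort(msg, class = "bearvitals_validation_error")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing mandatory column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "bearvitals_schema_error")
  }
}

#' Validate monitoring tables
#'
#' Checks the invariants of each table: an encounter history has at most one
#' `dead` record and it (or a `censored` record) terminates the monitored
#' span; intervals are strictly increasing within a bear; litter survivors
#' never exceed cubs at emergence; state sequences use only the four
#' reproductive states; a first litter postdates all nulliparous ages; a
#' completed interbirth interval falls inside the monitored offsets.
#' Violations raise a classed error naming the bear and row.
#'
#' @param df A tibble as returned by the corresponding reader.
#' @return `df`, invisibly coerced to a tibble, if all checks pass.
#' @name validate_monitoring
NULL

#' @rdname validate_monitoring
#' @export
validate_encounters <- function(df) {
  require_columns(df, c("bear_id", "population", "birth_year", "year",
                        "interval", "status"), "encounter table")
  df <- tibble::as_tibble(df)
  if (!"cause" %in% names(df)) df$cause <- NA_character_
  bad <- which(!df$status %in% c("alive", "dead", "censored"))
  if (length(bad) > 0) {
    validation_error("status must be alive, dead or censored",
                     bear = unique(df$bear_id[bad]), rows = bad)
  }
  bad <- which(df$interval < 1L | df$interval > INTERVALS_PER_YEAR)
  if (length(bad) > 0) {
    validation_error("interval must be in 1..8",
                     bear = unique(df$bear_id[bad]), rows = bad)
  }
  # per-bear ordering and termination; a re-collared bear carries a segment
  # suffix in bear_id, so each bear_id is one uninterrupted monitored span
  for (id in unique(df$bear_id)) {
    idx <- which(df$bear_id == id)
    h <- df[idx, ]
    key <- h$year * INTERVALS_PER_YEAR + h$interval
    o <- order(key)
    if (any(duplicated(key)) || any(diff(key[o]) < 1)) {
      validation_error("intervals must be strictly increasing", bear = id)
    }
    term <- which(h$status[o] %in% c("dead", "censored"))
    if (sum(h$status == "dead") > 1) {
      validation_error("more than one dead record", bear = id)
    }
    if (length(term) > 0 && min(term) < length(idx)) {
      validation_error("dead/censored must terminate the history", bear = id)
    }
  }
  invisible(df)
}

#' @rdname validate_monitoring
#' @export
validate_litters <- function(df) {
  require_columns(df, c("mother_id", "population", "year", "cubs_emergence",
                        "cubs_survived", "monitored_to_autumn"), "litter table")
  df <- tibble::as_tibble(df)
  df$monitored_to_autumn <- as.logical(df$monitored_to_autumn)
  bad <- which(df$cubs_emergence < 1L)
  if (length(bad) > 0) {
    validation_error("cubs_emergence must be at least 1",
                     bear = unique(df$mother_id[bad]), rows = bad)
  }
  bad <- which(df$monitored_to_autumn &
                 (df$cubs_survived < 0L | df$cubs_survived > df$cubs_emergence))
  if (length(bad) > 0) {
    validation_error("cubs_survived must lie in [0, cubs_emergence]",
                     bear = unique(df$mother_id[bad]), rows = bad)
  }
  invisible(df)
}

#' @rdname validate_monitoring
#' @export
validate_states <- function(df) {
  require_columns(df, c("bear_id", "population", "year", "state", "age"),
                  "state table")
  df <- tibble::as_tibble(df)
  bad <- which(!df$state %in% REPRO_STATES)
  if (length(bad) > 0) {
    validation_error("state must be one of A, C, Y, T",
                     bear = unique(df$bear_id[bad]), rows = bad)
  }
  dup <- df |>
    dplyr::count(.data$bear_id, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    validation_error("duplicate bear-year state records",
                     bear = unique(dup$bear_id))
  }
  invisible(df)
}

#' @rdname validate_monitoring
#' @export
validate_primiparity <- function(df) {
  require_columns(df, c("bear_id", "population", "age", "first_litter"),
                  "primiparity table")
  df <- tibble::as_tibble(df)
  chk <- df |>
    dplyr::group_by(.data$bear_id) |>
    dplyr::summarise(
      n_event = sum(.data$first_litter),
      ok = sum(.data$first_litter) == 0 ||
        (sum(.data$first_litter) == 1 &&
           .data$age[.data$first_litter == 1][1] >
             max(c(-Inf, .data$age[.data$first_litter == 0]))),
      .groups = "drop"
    )
  bad <- chk$bear_id[chk$n_event > 1 | !chk$ok]
  if (length(bad) > 0) {
    validation_error(
      "first litter must be unique and exceed all nulliparous monitored ages",
      bear = bad
    )
  }
  invisible(df)
}

#' @rdname validate_monitoring
#' @export
validate_interbirth <- function(df) {
  require_columns(df, c("bear_id", "population", "birth_year", "offset",
                        "next_litter"), "interbirth table")
  df <- tibble::as_tibble(df)
  chk <- df |>
    dplyr::group_by(.data$bear_id, .data$birth_year) |>
    dplyr::summarise(
      ok = sum(.data$next_litter) <= 1 &&
        (sum(.data$next_litter) == 0 ||
           .data$offset[.data$next_litter == 1][1] == max(.data$offset)),
      .groups = "drop"
    )
  bad <- unique(chk$bear_id[!chk$ok])
  if (length(bad) > 0) {
    validation_error(
      "a completed interval must be unique and be the last monitored offset",
      bear = bad
    )
  }
  invisible(df)
}

filter_population <- function(df, population, col = "population") {
  if (is.null(population)) return(df)
  known <- unique(df[[col]])
  if (!all(population %in% known)) {
    abort(sprintf(
      "unknown population label(s): %s (data has: %s)",
      paste(setdiff(population, known), collapse = ", "),
      paste(known, collapse = ", ")
    ))
  }
  df[df[[col]] %in% population, , drop = FALSE]
}

#' Cumulative monitoring effort in bear-years
#'
#' Sums monitored intervals over all encounter histories and converts to
#' bear-years at eight intervals per year (monthly April-October plus one
#' pooled denning interval). Every row of the encounter table - including a
#' terminal `dead` or `censored` row - counts as one monitored interval.
#'
#' @param encounters A validated encounter table.
#' @param population Optional population label(s) to restrict to.
#' @return Bear-years of monitoring (a single number).
#' @examples
#' enc <- tibble::tibble(
#'   bear_id = "F01", population = "MM", birth_year = 2000L,
#'   year = 2006L, interval = 1:8, status = "alive", cause = NA_character_
#' )
#' bear_years(enc) # 1
#' @export
bear_years <- function(encounters, population = NULL) {
  encounters <- filter_population(encounters, population)
  nrow(encounters) / INTERVALS_PER_YEAR
}

#' Mortality rate per bear-year of monitoring
#'
#' Deaths (optionally restricted by recorded cause) divided by bear-years of
#' monitoring. This is the crude exposure-standardised death rate, not a
#' survival probability.
#'
#' @inheritParams bear_years
#' @param causes Optional subset of `c("human", "natural", "unknown")`;
#'   `NULL` counts all deaths.
#' @return Deaths per bear-year (a single number).
#' @export
mortality_rate <- function(encounters, population = NULL, causes = NULL) {
  encounters <- filter_population(encounters, population)
  by <- nrow(encounters) / INTERVALS_PER_YEAR
  if (by == 0) {
    abort("mortality rate is undefined: zero bear-years of monitoring")
  }
  deaths <- encounters$status == "dead"
  if (!is.null(causes)) deaths <- deaths & encounters$cause %in% causes
  sum(deaths) / by
}

#' Write monitoring tables
#'
#' Writes a named list of monitoring tables (any of `encounters`, `litters`,
#' `states`, `primiparity`, `interbirth`, `yearlings`) to `<name>.csv` under
#' `dir`. Inverse of the `read_*()` family for the five standard tables.
#'
#' @param tables Named list of tibbles.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_monitoring_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p, progress = FALSE)
    p
  }, character(1))
  invisible(paths)
}
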