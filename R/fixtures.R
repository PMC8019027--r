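#' Reconstructed monitoring data for two small brown bear populations
#'
#' Synthetic-but-faithful example tables for a 2005-2018 telemetry study of
#' two small brown bear populations in southwestern British Columbia: the
#' McGillvary Mountains (MM, ~45 bears, connected) and the North
#' Stein-Nahatlatch (NSN, <25 bears, isolated). They are reconstructed in
#' code from the study's published summary totals; fields the summaries pin
#' down exactly (litter counts and fates, transition-rate numerators and
#' denominators, bear-years and death tallies) are exact, while fields the
#' summaries leave free (individual intact-litter sizes, the year-by-year
#' arrangement of state sequences, ages outside events) are filled with any
#' consistent choice. They drive the examples and give every estimator a
#' realistic small-sample input.
#'
#' \describe{
#'   \item{`bc_bear_litters()`}{13 mother-years: 21 cubs in 9 MM litters
#'     (one not monitored to autumn; 17 of the 20 monitored cubs survived)
#'     and 9 cubs in 4 NSN litters (3 survived).}
#'   \item{`bc_bear_yearlings()`}{26 yearlings (20 MM, 6 NSN), no deaths.}
#'   \item{`bc_bear_states()`}{Annual reproductive states for 13 MM adult
#'     females (38 transitions) and 6 NSN females (30 transitions), arranged
#'     to reproduce the published transition rates.}
#'   \item{`bc_bear_encounters()`}{Monthly encounter histories giving 43.1
#'     (MM) and 26.0 (NSN) bear-years with 0 and 5 deaths (2 human, 3
#'     natural).}
#'   \item{`bc_bear_interbirth()`}{Four completed NSN interbirth intervals
#'     (4, 4, 5, 5 years) under complete monitoring.}
#' }
#'
#' @return A validated tibble (see [read_monitoring] for schemas).
#' @name bc_bear_data
NULL

#' @rdname bc_bear_data
#' @export
bc_bear_litters <- function() {
  validate_litters(tibble::tibble(
    mother_id = c(sprintf("MM-F%02d", 1:9), sprintf("NSN-F%02d", 1:4)),
    population = rep(c("MM", "NSN"), c(9, 4)),
    year = c(2007:2015, 2007:2010),
    cubs_emergence = c(3L, 2L, 3L, 3L, 3L, 2L, 2L, 2L, 1L, 3L, 2L, 2L, 2L),
    cubs_survived  = c(1L, 1L, 3L, 3L, 3L, 2L, 2L, 2L, NA, 0L, 1L, 1L, 1L),
    monitored_to_autumn = c(rep(TRUE, 8), FALSE, rep(TRUE, 4))
  ))
}

#' @rdname bc_bear_data
#' @export
bc_bear_yearlings <- function() {
  tibble::tibble(
    mother_id = c(sprintf("MM-F%02d", 1:8), sprintf("NSN-F%02d", 1:3)),
    population = rep(c("MM", "NSN"), c(8, 3)),
    year = c(2008:2015, 2008:2010),
    n_yearlings = c(3L, 3L, 3L, 2L, 2L, 2L, 3L, 2L, 2L, 2L, 2L),
    n_survived  = c(3L, 3L, 3L, 2L, 2L, 2L, 3L, 2L, 2L, 2L, 2L)
  )
}

#' @rdname bc_bear_data
#' @export
bc_bear_states <- function() {
  seqs <- list(
    # MM: 13 females, 38 transitions
    # (AA 10, AC 6, CY 9, YT 9, TA 3, TC 1)
    MM = list(
      c("C", "Y", "T", "A"), c("C", "Y", "T", "A"), c("C", "Y", "T", "A"),
      c("C", "Y", "T", "C"),
      c("A", "C", "Y", "T"), c("A", "C", "Y", "T"), c("A", "C", "Y", "T"),
      c("A", "C", "Y", "T"), c("A", "C", "Y", "T"),
      c("A", "A", "A", "A", "C"),
      c("A", "A", "A", "A"), c("A", "A", "A", "A"),
      c("A", "A")
    ),
    # NSN: 6 females, 30 transitions
    # (AA 8, AC 4, CA 1, CY 5, YT 6, TA 6)
    NSN = list(
      c("Y", "T", "A", "A", "C", "Y", "T", "A"),
      c("A", "C", "Y", "T", "A", "C", "Y", "T", "A"),
      c("C", "A", "A", "C", "Y", "T", "A"),
      c("C", "Y", "T", "A"),
      c("A", "A", "A", "A"), c("A", "A", "A", "A")
    )
  )
  rows <- purrr::imap(seqs, function(bears, pop) {
    purrr::imap(bears, function(s, i) {
      tibble::tibble(
        bear_id = sprintf("%s-S%02d", pop, i), population = pop,
        year = 2005L + ((i - 1L) %% 5L) + seq_along(s) - 1L,
        state = s, age = 6L + (i %% 4L) + seq_along(s) - 1L
      )
    })
  })
  validate_states(dplyr::bind_rows(purrr::flatten(rows)))
}

#' @rdname bc_bear_data
#' @export
bc_bear_encounters <- function() {
  span <- function(id, pop, birth_year, start_year, n_intervals,
                   final = "censored", cause = NA_character_) {
    g <- seq_len(n_intervals)
    status <- rep("alive", n_intervals)
    status[n_intervals] <- final
    causes <- rep(NA_character_, n_intervals)
    causes[n_intervals] <- if (final == "dead") cause else NA_character_
    tibble::tibble(
      bear_id = id, population = pop, birth_year = birth_year,
      year = start_year + (g - 1L) %/% INTERVALS_PER_YEAR,
      interval = ((g - 1L) %% INTERVALS_PER_YEAR) + 1L,
      status = status, cause = causes
    )
  }
  # MM: 16 females, 345 monitored intervals = 43.1 bear-years, no deaths
  mm <- purrr::map(1:16, function(i) {
    span(sprintf("MM-E%02d", i), "MM", 1998L + (i %% 8L),
         2005L + (i - 1L) %% 9L, if (i < 16) 22L else 15L)
  })
  # NSN: 9 females, 208 monitored intervals = 26.0 bear-years, 5 deaths
  # (two nulliparous females killed by humans at ages 7 and 8; natural
  # deaths at ages 18, 4 and 20)
  nsn_cfg <- list(
    list(n = 24L, final = "dead", cause = "human", age_end = 7L),
    list(n = 24L, final = "dead", cause = "human", age_end = 8L),
    list(n = 24L, final = "dead", cause = "natural", age_end = 18L),
    list(n = 24L, final = "dead", cause = "natural", age_end = 4L),
    list(n = 24L, final = "dead", cause = "natural", age_end = 20L),
    list(n = 24L, final = "censored", cause = NA_character_, age_end = 10L),
    list(n = 24L, final = "censored", cause = NA_character_, age_end = 12L),
    list(n = 24L, final = "censored", cause = NA_character_, age_end = 9L),
    list(n = 16L, final = "censored", cause = NA_character_, age_end = 11L)
  )
  nsn <- purrr::imap(nsn_cfg, function(cf, i) {
    start <- 2005L + (i - 1L) %% 6L
    yrs <- (cf$n - 1L) %/% INTERVALS_PER_YEAR
    span(sprintf("NSN-E%02d", i), "NSN", start + yrs - cf$age_end,
         start, cf$n, cf$final, cf$cause)
  })
  validate_encounters(dplyr::bind_rows(c(mm, nsn)))
}

#' @rdname bc_bear_data
#' @export
bc_bear_interbirth <- function() {
  completed <- c(4L, 4L, 5L, 5L)
  ids <- c("NSN-I01", "NSN-I01", "NSN-I02", "NSN-I03")
  births <- c(2006L, 2010L, 2007L, 2008L)
  validate_interbirth(dplyr::bind_rows(purrr::pmap(
    list(ids, births, completed),
    function(id, by, t) {
      tibble::tibble(bear_id = id, population = "NSN", birth_year = by,
                     offset = seq_len(t),
                     next_litter = as.integer(seq_len(t) == t))
    }
  )))
}

#' Published transition matrices and point vital rates
#'
#' `bc_bear_transition_matrix()` returns the published reproductive-state
#' transition rates for a population as a [transition_matrix()] (rows are
#' renormalised, absorbing 2-decimal rounding). `bc_bear_vital_rates()`
#' returns the published point estimates of the survival schedule and
#' reproductive rate as a [vital_rates()] set (MM: cub 0.85, yearling 1.00,
#' independent female 1.00, m 0.23; NSN: 0.33, 1.00, 0.81, m 0.19).
#'
#' @param population `"MM"` or `"NSN"`.
#' @param m Optionally override the reproductive rate.
#' @return A [transition_matrix()] or [vital_rates()] object.
#' @export
bc_bear_transition_matrix <- function(population = c("MM", "NSN")) {
  population <- match.arg(population)
  P <- if (population == "MM") {
    rbind(
      c(0.63, 0.38, 0.00, 0.00),
      c(0.00, 0.00, 1.00, 0.00),
      c(0.00, 0.00, 0.00, 1.00),
      c(0.75, 0.25, 0.00, 0.00)
    )
  } else {
    rbind(
      c(0.67, 0.33, 0.00, 0.00),
      c(0.17, 0.00, 0.83, 0.00),
      c(0.00, 0.00, 0.00, 1.00),
      c(1.00, 0.00, 0.00, 0.00)
    )
  }
  transition_matrix(P)
}

#' @rdname bc_bear_transition_matrix
#' @export
bc_bear_vital_rates <- function(population = c("MM", "NSN"), m = NULL) {
  population <- match.arg(population)
  if (population == "MM") {
    vital_rates(0.85, 1.00, 1.00, 1.00, m = m %||% 0.23)
  } else {
    vital_rates(0.33, 1.00, 0.81, 0.81, m = m %||% 0.19)
  }
}
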