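#' Define a simulated population's true vital rates
#'
#' A `population_truth` bundles the generating parameters of one simulated
#' population: age-class survival, the litter-size distribution, the per-age
#' hazard of a first litter, the annual probability that an available parous
#' female produces cubs, and the weaning age. These are the quantities the
#' estimators are later asked to recover.
#'
#' @param label Population label (e.g. `"MM"`).
#' @param n_initial_females Independent (age 2+) females alive at study start.
#' @param s_cub,s_yearling,s_subadult,s_adult Annual survival probabilities by
#'   age class (cub = first year, yearling = second, subadult = ages 2-5,
#'   adult = 6+).
#' @param litter_size_pmf Named probability vector on litter sizes
#'   `c("1", "2", "3")`; must sum to 1.
#' @param first_litter_hazard Named per-age probability that a nulliparous
#'   female has her first litter at that age; ages beyond the last named age
#'   continue at the last value, ages below the first are 0.
#' @param breed_prob Annual probability that a parous female who is available
#'   (alone, or litter lost) produces cubs the following spring.
#' @param weaning_age Age (2 or 3) at which surviving offspring leave their
#'   mother.
#' @param capture_schedule Optional integer vector of new collars per study
#'   year; recycled/truncated to the scenario length.
#' @return A `population_truth` list.
#' @export
population_truth <- function(label,
                             n_initial_females = 12,
                             s_cub = 0.80,
                             s_yearling = 0.90,
                             s_subadult = 0.90,
                             s_adult = 0.95,
                             litter_size_pmf = c("1" = 0.10, "2" = 0.47, "3" = 0.43),
                             first_litter_hazard = c("6" = 0.10, "7" = 0.25, "8" = 0.30),
                             breed_prob = 0.35,
                             weaning_age = 3,
                             capture_schedule = NULL) {
  probs <- c(s_cub, s_yearling, s_subadult, s_adult, breed_prob,
             litter_size_pmf, first_litter_hazard)
  if (any(probs < 0 | probs > 1)) {
    abort("all survival, hazard and breeding probabilities must be in [0, 1]")
  }
  if (abs(sum(litter_size_pmf) - 1) > 1e-8) {
    abort("litter_size_pmf must sum to 1")
  }
  if (!weaning_age %in% c(2, 3)) abort("weaning_age must be 2 or 3")
  structure(
    list(
      label = label, n_initial_females = as.integer(n_initial_females),
      s_cub = s_cub, s_yearling = s_yearling,
      s_subadult = s_subadult, s_adult = s_adult,
      litter_size_pmf = litter_size_pmf,
      first_litter_hazard = first_litter_hazard,
      breed_prob = breed_prob, weaning_age = weaning_age,
      capture_schedule = capture_schedule
    ),
    class = "population_truth"
  )
}

#' Define a telemetry-study simulation scenario
#'
#' A scenario couples one or more [population_truth()] objects with the
#' monitoring design: study length, collaring effort, collar longevity,
#' relocation frequency and per-relocation detection. Monitoring is laid over
#' a freely running demographic simulation, so estimator inputs inherit
#' staggered entry, collar loss and censoring exactly as a field study would
#' produce them.
#'
#' @param populations List of [population_truth()] objects.
#' @param n_years Study duration in years (at least 2).
#' @param start_year Calendar year of the first den emergence.
#' @param collar_life_mean Mean collar retention (exponential), years.
#' @param detection_prob Probability a relocation flight finds the bear.
#' @param relocations_per_year Relocation flights per active season.
#' @param censor_rule_weeks Gap of unknown status that triggers censoring;
#'   with the monthly interval structure this is two consecutive missed
#'   relocations (8 weeks).
#' @param rng_seed Optional integer seed; identical seeds give identical
#'   simulations.
#' @return A `simulation_scenario` list.
#' @export
scenario <- function(populations,
                     n_years = 14,
                     start_year = 2005L,
                     collar_life_mean = 3,
                     detection_prob = 0.95,
                     relocations_per_year = 3,
                     censor_rule_weeks = 8,
                     rng_seed = NULL) {
  if (inherits(populations, "population_truth")) populations <- list(populations)
  if (n_years < 2) abort("n_years must be at least 2")
  if (detection_prob < 0 || detection_prob > 1) {
    abort("detection_prob must be in [0, 1]")
  }
  structure(
    list(
      populations = populations, n_years = as.integer(n_years),
      start_year = as.integer(start_year),
      collar_life_mean = collar_life_mean,
      detection_prob = detection_prob,
      relocations_per_year = as.integer(relocations_per_year),
      censor_rule_weeks = censor_rule_weeks,
      rng_seed = rng_seed
    ),
    class = "simulation_scenario"
  )
}

#' Study-conditions scenario for the two monitored populations
#'
#' Returns the default two-population scenario: true vital rates set to the
#' study's point estimates (MM: cub survival 0.85, yearling 1.00, independent
#' female 1.00, mean litter size 2.33; NSN: 0.33, 1.00, 0.81, 2.25), with
#' roughly 16 (MM) and 9 (NSN) females collared over a 14-year study and NSN
#' captures ceasing after year 7.
#'
#' @param n_years Study duration in years.
#' @param rng_seed Optional seed passed to [scenario()].
#' @return A `simulation_scenario`.
#' @export
scenario_study <- function(n_years = 14, rng_seed = NULL) {
  mm <- population_truth(
    label = "MM", n_initial_females = 14,
    s_cub = 0.85, s_yearling = 1.00, s_subadult = 1.00, s_adult = 1.00,
    litter_size_pmf = c("1" = 0.10, "2" = 0.47, "3" = 0.43), # mean 2.33
    capture_schedule = c(3, 2, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0)
  )
  nsn <- population_truth(
    label = "NSN", n_initial_females = 9,
    s_cub = 0.33, s_yearling = 1.00, s_subadult = 0.81, s_adult = 0.81,
    litter_size_pmf = c("1" = 0.15, "2" = 0.45, "3" = 0.40), # mean 2.25
    capture_schedule = c(2, 2, 2, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0)
  )
  scenario(list(mm, nsn), n_years = n_years, rng_seed = rng_seed)
}

first_litter_prob <- function(hazard, age) {
  ages <- as.integer(names(hazard))
  if (age < min(ages)) return(0)
  if (age > max(ages)) return(unname(hazard[length(hazard)]))
  unname(hazard[as.character(age)])
}

draw_litter_size <- function(pmf) {
  as.integer(sample(as.integer(names(pmf)), 1, prob = pmf))
}

#' Simulate a telemetry-monitored bear population
#'
#' Runs an individual-based annual simulation of each population in the
#' scenario and overlays the monitoring process, returning the five estimator
#' input tables (plus yearling fate records) together with the generating
#' truth. Females follow the reproductive cycle A -> C -> Y -> (T) -> A with
#' per-cub independent first-year survival; independent-female mortality is
#' applied annually by age class with the death assigned to a uniformly drawn
#' monitoring interval; surviving weaned offspring are recruited as new
#' (initially uncollared) females with probability 1/2 of being female.
#' Monitoring applies staggered capture, exponential collar life,
#' per-relocation detection, and censors a history at the last known status
#' once two consecutive relocations fail (a gap of more than 8 weeks).
#'
#' @param scn A [scenario()].
#' @return A `bear_simulation` list with elements `encounters`, `litters`,
#'   `yearlings`, `states`, `primiparity`, `interbirth` (tibbles) and `truth`.
#' @examples
#' sim <- simulate_population(scenario_study(rng_seed = 42))
#' dplyr::count(sim$encounters, population, status)
#' @export
simulate_population <- function(scn) {
  stopifnot(inherits(scn, "simulation_scenario"))
  if (!is.null(scn$rng_seed)) set.seed(scn$rng_seed)
  out <- lapply(scn$populations, function(tr) simulate_one(tr, scn))
  tables <- lapply(
    c("encounters", "litters", "yearlings", "states", "primiparity", "interbirth"),
    function(nm) dplyr::bind_rows(lapply(out, `[[`, nm))
  )
  names(tables) <- c("encounters", "litters", "yearlings", "states",
                     "primiparity", "interbirth")
  structure(
    c(tables, list(truth = list(scenario = scn,
                                populations = scn$populations))),
    class = "bear_simulation"
  )
}

# Demography: one population, all females tracked whether collared or not.
# States are recorded at den emergence of each study year; transitions happen
# over the following year. Returns the monitoring tables for this population.
simulate_one <- function(tr, scn) {
  ny <- scn$n_years
  # female registry; fixed-size columns grown as recruits appear
  new_female <- function(id, age0, entry_year, parous) {
    list(id = id, entry = entry_year, age0 = age0, parous_at = if (parous) 0L else NA_integer_,
         state = rep(NA_character_, ny + 1), ndep = rep(0L, ny + 1),
         litter = rep(NA_integer_, ny + 1),
         yrl_surv = rep(NA_integer_, ny + 1),
         death_year = NA_integer_, death_interval = NA_integer_)
  }
  females <- list()
  for (i in seq_len(tr$n_initial_females)) {
    age0 <- sample(2:12, 1)
    f <- new_female(sprintf("%s-F%02d", tr$label, i), age0, 1L, parous = age0 >= 9)
    f$state[1] <- "A"
    females[[length(females) + 1]] <- f
  }
  n_named <- tr$n_initial_females

  age_of <- function(f, y) f$age0 + (y - f$entry)

  for (y in seq_len(ny)) {
    recruits <- list()
    for (k in seq_along(females)) {
      f <- females[[k]]
      if (!is.na(f$death_year) || f$entry > y || is.na(f$state[y])) next
      age <- age_of(f, y)
      # independent-female survival over year y
      s_ind <- if (age <= 5) tr$s_subadult else tr$s_adult
      dies <- runif(1) > s_ind
      st <- f$state[y]
      if (dies) {
        f$death_year <- y
        f$death_interval <- sample.int(INTERVALS_PER_YEAR, 1)
        # dependents of a dead mother are lost and never recruited
        females[[k]] <- f
        next
      }
      # offspring survival and next-spring state
      breeds <- function() {
        p <- if (is.na(f$parous_at)) first_litter_prob(tr$first_litter_hazard, age + 1)
             else tr$breed_prob
        runif(1) < p
      }
      nxt <- switch(st,
        A = if (breeds()) "C" else "A",
        C = {
          sc <- rbinom(1, f$ndep[y], tr$s_cub)
          if (sc > 0) { f$ndep[y + 1] <- sc; "Y" } else if (breeds()) "C" else "A"
        },
        Y = {
          sy <- rbinom(1, f$ndep[y], tr$s_yearling)
          f$yrl_surv[y] <- sy
          if (tr$weaning_age == 2) {
            if (sy > 0) recruits <- c(recruits, list(c(n = sy, age = 2L, year = y + 1L)))
            if (breeds()) "C" else "A"
          } else if (sy > 0) { f$ndep[y + 1] <- sy; "T" } else if (breeds()) "C" else "A"
        },
        T = {
          st2 <- rbinom(1, f$ndep[y], tr$s_subadult)
          if (st2 > 0) recruits <- c(recruits, list(c(n = st2, age = 3L, year = y + 1L)))
          if (breeds()) "C" else "A"
        }
      )
      if (nxt == "C") {
        f$litter[y + 1] <- draw_litter_size(tr$litter_size_pmf)
        f$ndep[y + 1] <- f$litter[y + 1]
        if (is.na(f$parous_at)) f$parous_at <- y + 1L
      }
      f$state[y + 1] <- nxt
      females[[k]] <- f
    }
    # weaned offspring recruit as independent females with prob 1/2 each
    for (r in recruits) {
      n_fem <- rbinom(1, r[["n"]], 0.5)
      for (j in seq_len(n_fem)) {
        n_named <- n_named + 1
        f <- new_female(sprintf("%s-F%02d", tr$label, n_named),
                        r[["age"]], as.integer(r[["year"]]), parous = FALSE)
        if (r[["year"]] <= ny + 1) f$state[r[["year"]]] <- "A"
        females[[length(females) + 1]] <- f
      }
    }
  }

  monitor_one(tr, scn, females, age_of)
}

# Monitoring layer: staggered captures, collar life, detection, censoring.
monitor_one <- function(tr, scn, females, age_of) {
  ny <- scn$n_years
  sched <- tr$capture_schedule %||% rep(1L, ny)
  sched <- rep_len(as.integer(sched), ny)
  reloc_iv <- unique(pmin(7L, pmax(1L, round(seq(1, 7, length.out = scn$relocations_per_year)))))

  collared_now <- rep(FALSE, length(females))
  ever_collared <- rep(FALSE, length(females))
  spans <- list() # one span per collar deployment

  for (y in seq_len(ny)) {
    alive_y <- vapply(females, function(f) {
      f$entry <= y && !is.na(f$state[y]) &&
        (is.na(f$death_year) || f$death_year >= y)
    }, logical(1))
    candidates <- which(alive_y & !collared_now &
                          vapply(females, function(f) age_of(f, y) >= 2, logical(1)))
    # prefer never-collared bears, as a field crew would
    candidates <- candidates[order(ever_collared[candidates])]
    n_new <- sched[y]
    if (n_new > length(candidates)) {
      warn(sprintf(
        "population %s, year %d: %d captures scheduled but only %d candidate females; truncating",
        tr$label, y, n_new, length(candidates)
      ))
      n_new <- length(candidates)
    }
    if (n_new > 0) {
      take <- candidates[seq_len(n_new)]
      for (k in take) {
        f <- females[[k]]
        seg <- sum(vapply(spans, function(s) s$idx == k, logical(1)))
        id <- if (seg == 0) f$id else sprintf("%s.%d", f$id, seg + 1)
        life_iv <- max(1L, ceiling(rexp(1, rate = 1 / scn$collar_life_mean) * INTERVALS_PER_YEAR))
        spans[[length(spans) + 1]] <- list(idx = k, id = id, start_year = y,
                                           g0 = (y - 1L) * INTERVALS_PER_YEAR + 1L,
                                           gdrop = (y - 1L) * INTERVALS_PER_YEAR + life_iv)
        collared_now[k] <- TRUE
        ever_collared[k] <- TRUE
      }
    }
    # collars dropping during year y free the bear for future recapture
    for (s in spans) {
      if (s$gdrop <= y * INTERVALS_PER_YEAR) collared_now[s$idx] <- FALSE
    }
    for (k in which(vapply(females, function(f) !is.na(f$death_year) && f$death_year == y, logical(1)))) {
      collared_now[k] <- FALSE
    }
  }

  enc <- list(); lit <- list(); yrl <- list(); sta <- list(); pri <- list(); ibi <- list()
  g_end_study <- ny * INTERVALS_PER_YEAR

  for (s in spans) {
    f <- females[[s$idx]]
    g_death <- if (is.na(f$death_year)) Inf
               else (f$death_year - 1L) * INTERVALS_PER_YEAR + f$death_interval
    # detection-driven censoring: two consecutive missed relocations censor
    # the history at the last interval of known status
    g_censor <- Inf
    if (scn$detection_prob < 1) {
      g_last_known <- s$g0
      misses <- 0L
      g_att_max <- min(s$gdrop, g_death, g_end_study)
      for (g in s$g0:g_att_max) {
        iv <- ((g - 1L) %% INTERVALS_PER_YEAR) + 1L
        if (!iv %in% reloc_iv) next
        if (g >= g_death) break # mortality signal: death always detected
        if (runif(1) < scn$detection_prob) {
          g_last_known <- g
          misses <- 0L
        } else {
          misses <- misses + 1L
          if (misses >= 2L) { g_censor <- g_last_known; break }
        }
      }
    }
    ends <- c(death = g_death, drop = s$gdrop, lost = g_censor, study = g_end_study)
    g_end <- min(ends)
    fate <- names(ends)[which.min(ends)]
    final <- switch(fate, death = "dead", drop = "censored",
                    lost = "censored", study = "alive")
    gg <- s$g0:g_end
    yy <- ((gg - 1L) %/% INTERVALS_PER_YEAR) + 1L
    status <- rep("alive", length(gg))
    status[length(status)] <- final
    cause <- rep(NA_character_, length(gg))
    if (final == "dead") cause[length(cause)] <- sample(c("human", "natural"), 1)
    enc[[length(enc) + 1]] <- tibble::tibble(
      bear_id = s$id, population = tr$label,
      birth_year = scn$start_year - f$age0 + (f$entry - 1L),
      year = scn$start_year + yy - 1L,
      interval = ((gg - 1L) %% INTERVALS_PER_YEAR) + 1L,
      status = status, cause = cause
    )

    # reproductive observations require the collar active at den emergence
    obs_years <- unique(yy[((gg - 1L) %% INTERVALS_PER_YEAR) + 1L == 1L])
    open_births <- integer(0) # observed births awaiting a subsequent litter
    for (y in obs_years) {
      st <- f$state[y]
      if (is.na(st)) next
      age <- age_of(f, y)
      sta[[length(sta) + 1]] <- tibble::tibble(
        bear_id = s$id, population = tr$label,
        year = scn$start_year + y - 1L, state = st, age = age
      )
      # primiparity exposure: nulliparous years and the first-litter event
      if (is.na(f$parous_at) || f$parous_at > y) {
        pri[[length(pri) + 1]] <- tibble::tibble(
          bear_id = f$id, population = tr$label, age = age, first_litter = 0L
        )
      } else if (f$parous_at == y) {
        pri[[length(pri) + 1]] <- tibble::tibble(
          bear_id = f$id, population = tr$label, age = age, first_litter = 1L
        )
      }
      g_autumn <- (y - 1L) * INTERVALS_PER_YEAR + 7L
      mon_autumn <- g_autumn <= g_end &&
        (is.na(f$death_year) || f$death_year > y)
      if (st == "C") {
        n_surv <- if (y < length(f$state) && identical(f$state[y + 1], "Y")) {
          f$ndep[y + 1]
        } else 0L
        lit[[length(lit) + 1]] <- tibble::tibble(
          mother_id = f$id, population = tr$label,
          year = scn$start_year + y - 1L,
          cubs_emergence = f$ndep[y],
          cubs_survived = if (mon_autumn) n_surv else NA_integer_,
          monitored_to_autumn = mon_autumn
        )
      }
      if (st == "Y" && mon_autumn && !is.na(f$yrl_surv[y])) {
        yrl[[length(yrl) + 1]] <- tibble::tibble(
          mother_id = f$id, population = tr$label,
          year = scn$start_year + y - 1L,
          n_yearlings = f$ndep[y], n_survived = f$yrl_surv[y]
        )
      }
      # interbirth exposure: offsets from each observed birth, closed by the
      # next observed litter
      for (b in open_births) {
        ibi[[length(ibi) + 1]] <- tibble::tibble(
          bear_id = f$id, population = tr$label,
          birth_year = scn$start_year + b - 1L,
          offset = y - b, next_litter = as.integer(st == "C")
        )
      }
      if (st == "C") {
        open_births <- c(y)
      }
    }
  }

  empty <- function(...) tibble::tibble(...)
  list(
    encounters = if (length(enc)) dplyr::bind_rows(enc) else
      empty(bear_id = character(), population = character(),
            birth_year = integer(), year = integer(), interval = integer(),
            status = character(), cause = character()),
    litters = if (length(lit)) dplyr::bind_rows(lit) else
      empty(mother_id = character(), population = character(), year = integer(),
            cubs_emergence = integer(), cubs_survived = integer(),
            monitored_to_autumn = logical()),
    yearlings = if (length(yrl)) dplyr::bind_rows(yrl) else
      empty(mother_id = character(), population = character(), year = integer(),
            n_yearlings = integer(), n_survived = integer()),
    states = if (length(sta)) dplyr::bind_rows(sta) else
      empty(bear_id = character(), population = character(), year = integer(),
            state = character(), age = integer()),
    primiparity = if (length(pri)) dplyr::bind_rows(pri) else
      empty(bear_id = character(), population = character(), age = integer(),
            first_litter = integer()),
    interbirth = if (length(ibi)) dplyr::bind_rows(ibi) else
      empty(bear_id = character(), population = character(),
            birth_year = integer(), offset = integer(), next_litter = integer())
  )
}
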