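test_that("identical seeds give identical simulations and CSV output", {
  s1 <- simulate_population(scenario_study(rng_seed = 99))
  s2 <- simulate_population(scenario_study(rng_seed = 99))
  for (nm in c("encounters", "litters", "yearlings", "states",
               "primiparity", "interbirth")) {
    expect_identical(s1[[nm]], s2[[nm]])
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_monitoring_tables(s1["encounters"], d1)
  write_monitoring_tables(s2["encounters"], d2)
  expect_identical(readLines(file.path(d1, "encounters.csv")),
                   readLines(file.path(d2, "encounters.csv")))
})

test_that("immortal never-breeding population yields no deaths and all-A states", {
  tr <- population_truth("P1", n_initial_females = 10,
                         s_cub = 1, s_yearling = 1, s_subadult = 1, s_adult = 1,
                         first_litter_hazard = c("6" = 0), breed_prob = 0)
  sim <- simulate_population(scenario(tr, n_years = 8, rng_seed = 3))
  expect_false(any(sim$encounters$status == "dead"))
  expect_true(all(sim$states$state == "A"))
  expect_equal(nrow(sim$litters), 0)
})

test_that("perfect monitoring of an immortal cohort records every bear-year", {
  tr <- population_truth("P1", n_initial_females = 6,
                         s_cub = 1, s_yearling = 1, s_subadult = 1, s_adult = 1,
                         first_litter_hazard = c("6" = 0), breed_prob = 0,
                         capture_schedule = c(6, rep(0, 7)))
  scn <- scenario(tr, n_years = 8, collar_life_mean = 1e6,
                  detection_prob = 1, rng_seed = 5)
  sim <- simulate_population(scn)
  expect_equal(bear_years(sim$encounters), 6 * 8)
})

test_that("impossible capture schedules warn and truncate", {
  tr <- population_truth("P1", n_initial_females = 2,
                         s_cub = 1, s_yearling = 1, s_subadult = 1, s_adult = 1,
                         first_litter_hazard = c("6" = 0), breed_prob = 0,
                         capture_schedule = c(5, rep(0, 4)))
  expect_warning(simulate_population(scenario(tr, n_years = 5, rng_seed = 1)),
                 "truncating")
})

test_that("every monitored cub is resolved by its second spring", {
  sim <- simulate_population(scenario_study(rng_seed = 123))
  lit <- sim$litters[sim$litters$monitored_to_autumn, ]
  expect_true(all(lit$cubs_survived >= 0 & lit$cubs_survived <= lit$cubs_emergence))
  # survivors observed as a yearling family the following spring (when the
  # mother's state is itself observed)
  nxt <- dplyr::inner_join(
    dplyr::mutate(lit, year = year + 1L),
    sim$states, by = c("mother_id" = "bear_id", "population", "year")
  )
  expect_true(all(nxt$state[nxt$cubs_survived > 0] == "Y"))
  expect_true(all(nxt$state[nxt$cubs_survived == 0] %in% c("A", "C")))
})

test_that("the study scenario reproduces the monitoring design it emulates", {
  scn <- scenario_study()
  expect_equal(vapply(scn$populations, `[[`, character(1), "label"),
               c("MM", "NSN"))
  expect_equal(scn$populations[[1]]$s_cub, 0.85)
  expect_equal(scn$populations[[2]]$s_adult, 0.81)
  expect_equal(sum(scn$populations[[1]]$litter_size_pmf *
                     as.integer(names(scn$populations[[1]]$litter_size_pmf))),
               2.33)
  expect_equal(sum(scn$populations[[2]]$litter_size_pmf *
                     as.integer(names(scn$populations[[2]]$litter_size_pmf))),
               2.25)
  sim <- simulate_population(scenario_study(rng_seed = 17))
  # staggered entry: first monitored year varies across bears
  first_year <- tapply(sim$encounters$year, sim$encounters$bear_id, min)
  expect_gt(length(unique(first_year)), 3)
})

test_that("known-fate estimation recovers the generating adult survival", {
  # replicate studies at the design's own scale, truth 0.81 everywhere
  set.seed(2024)
  est <- vapply(1:60, function(i) {
    scn <- scenario_study(rng_seed = 5000 + i)
    scn$populations <- lapply(scn$populations, function(tr) {
      tr$s_subadult <- 0.81
      tr$s_adult <- 0.81
      tr
    })
    sim <- suppressWarnings(simulate_population(scn))
    fit_known_fate(sim$encounters, "null")$cells$s_annual[1]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.81), 0.02)
})
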