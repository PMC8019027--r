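test_that("risk table matches a hand tally under staggered exit", {
  enc <- dplyr::bind_rows(
    encounter_rows("b1", 3, final = "dead", cause = "natural"),
    encounter_rows("b2", 5, final = "censored")
  )
  rt <- build_risk_table(enc)
  expect_equal(rt$n_at_risk, c(2, 2, 2, 1, 1))
  expect_equal(rt$n_deaths, c(0, 0, 1, 0, 0))
  expect_equal(rt$n_censored, c(0, 0, 0, 0, 1))

  expect_equal(nrow(build_risk_table(enc[0, ])), 0)

  sim <- simulate_population(scenario_study(rng_seed = 31))
  rt <- build_risk_table(sim$encounters, "population")
  expect_equal(sum(rt$n_at_risk), nrow(sim$encounters))
})

test_that("Kaplan-Meier equals the hand-computed product limit", {
  rt <- tibble::tibble(
    group = "all", interval = 1:4,
    n_at_risk = c(10L, 9L, 8L, 8L),
    n_deaths = c(1L, 1L, 0L, 2L),
    n_censored = c(0L, 1L, 0L, 0L)
  )
  km <- kaplan_meier(rt)
  expect_equal(km$annual$annual_s, (9 / 10) * (8 / 9) * 1 * (6 / 8))
  # Greenwood variance of log S, assembled by hand
  expect_equal(
    km$annual$annual_s * exp(qnorm(0.975) *
      sqrt(1 / (10 * 9) + 1 / (9 * 8) + 2 / (8 * 6))),
    km$annual$ci_high, tolerance = 1e-10
  )
})

test_that("KM without censoring is the empirical survivor function", {
  set.seed(41)
  n <- 40
  dies <- runif(n) < 0.3
  enc <- purrr::map_dfr(seq_len(n), function(i) {
    encounter_rows(sprintf("b%02d", i), 8,
                   final = if (dies[i]) "dead" else "alive",
                   cause = if (dies[i]) "natural" else NA_character_)
  })
  km <- kaplan_meier(build_risk_table(enc))
  expect_equal(km$annual$annual_s, mean(!dies), tolerance = 1e-12)
})

test_that("zero-death data gives S = 1 with an asymmetric (lower, 1) interval; total loss gives 0", {
  enc <- purrr::map_dfr(1:12, function(i) encounter_rows(sprintf("b%02d", i), 16))
  km <- kaplan_meier(build_risk_table(enc))
  expect_equal(km$annual$annual_s, 1)
  expect_equal(km$annual$ci_high, 1)
  expect_lt(km$annual$ci_low, 1)
  expect_gt(km$annual$ci_low, 0.8)

  dead <- purrr::map_dfr(1:5, function(i) {
    encounter_rows(sprintf("d%d", i), 1, final = "dead", cause = "natural")
  })
  expect_equal(kaplan_meier(build_risk_table(dead))$annual$annual_s, 0)
})

test_that("known-fate MLE equals the closed-form binomial proportion and a grid oracle", {
  enc <- dplyr::bind_rows(
    purrr::map_dfr(1:5, function(i) {
      encounter_rows(sprintf("d%d", i), 4, final = "dead", cause = "natural")
    }),
    encounter_rows("a1", 6)
  ) # 26 intervals, 5 deaths
  m <- fit_known_fate(enc, "null")
  expect_equal(m$cells$s_interval, 21 / 26)
  expect_equal(m$ess, 26)

  # independent grid-search oracle on a 30-interval fixture
  enc30 <- dplyr::bind_rows(
    purrr::map_dfr(1:3, function(i) {
      encounter_rows(sprintf("g%d", i), 6, final = "dead", cause = "natural")
    }),
    encounter_rows("g9", 12)
  )
  grid <- seq(0.5, 1 - 1e-4, by = 1e-4)
  ll <- 27 * log(grid) + 3 * log(1 - grid)
  s_grid <- grid[which.max(ll)]
  expect_equal(fit_known_fate(enc30, "null")$cells$s_interval, s_grid,
               tolerance = 1e-3)
})

test_that("saturated grouping equals per-cell binomial proportions", {
  sim <- simulate_population(scenario_study(rng_seed = 77))
  m <- fit_known_fate(sim$encounters, "population")
  kf <- sim$encounters[sim$encounters$status %in% c("alive", "dead"), ]
  for (pop in unique(kf$population)) {
    expect_equal(
      m$cells$s_interval[m$cells$cell == pop],
      mean(kf$status[kf$population == pop] == "alive")
    )
  }
})

test_that("AICc table ranks, differences and weights follow the closed form", {
  enc <- dplyr::bind_rows(
    purrr::map_dfr(1:4, function(i) {
      encounter_rows(sprintf("d%d", i), 8, final = "dead", cause = "natural",
                     population = c("P1", "P2")[1 + i %% 2],
                     birth_year = 2000L - i)
    }),
    encounter_rows("a1", 16), encounter_rows("a2", 16, population = "P2")
  )
  models <- lapply(c("null", "population", "age"),
                   function(m) fit_known_fate(enc, m))
  tab <- aicc_table(models)
  expect_equal(tab$delta, tab$AICc - min(tab$AICc))
  expect_equal(tab$weight, exp(-tab$delta / 2) / sum(exp(-tab$delta / 2)))
  expect_equal(sum(tab$weight), 1)

  two <- aicc_table(models[c(1, 1)])
  expect_equal(two$delta, c(0, 0))
  expect_equal(two$weight, c(0.5, 0.5))

  other <- fit_known_fate(encounter_rows("z", 10), "null")
  expect_error(aicc_table(list(models[[1]], other)), "differing data")
})

test_that("model averaging weights real-scale survival over qualifying models", {
  enc <- dplyr::bind_rows(
    purrr::map_dfr(1:4, function(i) {
      encounter_rows(sprintf("d%d", i), 8, final = "dead", cause = "natural",
                     population = c("P1", "P2")[1 + i %% 2])
    }),
    encounter_rows("a1", 24), encounter_rows("a2", 24, population = "P2")
  )
  models <- lapply(c("null", "population"), function(m) fit_known_fate(enc, m))
  tab <- aicc_table(models)

  single <- model_average(models, enc, threshold = 1e-9)
  top <- models[[which(vapply(models, `[[`, character(1), "name") == tab$model[1])]]
  for (i in seq_len(nrow(single))) {
    key <- if (top$model == "null") "all" else single$population[i]
    expect_equal(single$annual_s[i], top$cells$s_annual[top$cells$cell == key])
  }

  # both models qualify: hand-computed weighted mean
  avg <- model_average(models, enc, threshold = Inf)
  w <- tab$weight / sum(tab$weight)
  m_by_name <- setNames(models, vapply(models, `[[`, character(1), "name"))
  for (i in seq_len(nrow(avg))) {
    pred <- vapply(tab$model, function(nm) {
      m <- m_by_name[[nm]]
      key <- if (m$model == "null") "all" else avg$population[i]
      m$cells$s_annual[m$cells$cell == key]
    }, numeric(1))
    expect_equal(avg$annual_s[i], sum(w * pred))
  }
})

test_that("annual survival decreases as deaths are added", {
  base <- purrr::map_dfr(1:10, function(i) encounter_rows(sprintf("b%d", i), 8))
  s_of <- function(enc) fit_known_fate(enc, "null")$cells$s_annual
  more <- function(k) {
    dplyr::bind_rows(base, purrr::map_dfr(seq_len(k), function(i) {
      encounter_rows(sprintf("x%d", i), 4, final = "dead", cause = "natural")
    }))
  }
  s <- vapply(0:3, function(k) s_of(more(k)), numeric(1))
  expect_true(all(diff(s) < 0))
})
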