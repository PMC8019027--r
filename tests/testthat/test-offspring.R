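test_that("cub survival reproduces the study's worked fractions", {
  set.seed(1)
  lit <- bc_bear_litters()
  mm <- cub_survival(lit, "MM")
  expect_equal(mm$point, 17 / 20)
  expect_equal(round(mm$point, 2), 0.85)
  expect_equal(mm$n, 20)
  nsn <- cub_survival(lit, "NSN")
  expect_equal(nsn$point, 3 / 9)
  expect_equal(round(nsn$point, 2), 0.33)
  # the litter not monitored to autumn is censored out of survival
  expect_equal(sum(lit$cubs_emergence[lit$population == "MM"]), 21)
})

test_that("degenerate samples: all survive, and undefined inputs error", {
  set.seed(2)
  lit <- tibble::tibble(
    mother_id = c("a", "b"), population = "P1", year = 2006L,
    cubs_emergence = c(2L, 3L), cubs_survived = c(2L, 3L),
    monitored_to_autumn = TRUE
  )
  cs <- cub_survival(lit)
  expect_equal(cs$point, 1)
  expect_equal(c(cs$ci_low, cs$ci_high), c(1, 1))
  expect_true("variance-undefined" %in% cs$flags)
  expect_error(cub_survival(lit[0, ]), "undefined")
})

test_that("bootstrap mean converges to the plug-in point at large B", {
  set.seed(3)
  cs <- cub_survival(bc_bear_litters(), "MM", B = 10000)
  expect_lt(abs(mean(cs$replicates) - cs$point), 0.01)
})

test_that("cub-level and litter-level resampling share the point estimate", {
  set.seed(4)
  a <- cub_survival(bc_bear_litters(), "NSN", unit = "cub")
  b <- cub_survival(bc_bear_litters(), "NSN", unit = "litter")
  expect_equal(a$point, b$point)
})

test_that("interval width shrinks with sample size at fixed survival", {
  set.seed(5)
  make <- function(k) {
    tibble::tibble(
      mother_id = sprintf("m%d", 1:k), population = "P1", year = 2006L,
      cubs_emergence = 4L, cubs_survived = 3L, monitored_to_autumn = TRUE
    )
  }
  small <- cub_survival(make(5))
  large <- cub_survival(make(50))
  expect_lte(large$ci_high - large$ci_low, small$ci_high - small$ci_low)
})

test_that("yearling survival handles the zero-mortality boundary", {
  set.seed(6)
  ys <- yearling_survival(bc_bear_yearlings(), "MM")
  expect_equal(ys$point, 1)
  expect_true("variance-undefined" %in% ys$flags)
  expect_equal(ys$n, 20)

  half <- tibble::tibble(mother_id = "a", population = "P1", year = 2006L,
                         n_yearlings = 2L, n_survived = 1L)
  expect_equal(yearling_survival(half)$point, 0.5)
})

test_that("yearling survival recovers a known generating rate", {
  set.seed(7)
  n <- 500
  surv <- rbinom(n, 2, 0.9)
  big <- tibble::tibble(mother_id = sprintf("m%d", 1:n), population = "P1",
                        year = 2006L, n_yearlings = 2L, n_survived = surv)
  expect_lt(abs(yearling_survival(big, B = 500)$point - 0.9), 0.02)
})

test_that("litter-independence ANOVA separates clustered from independent fates", {
  # identical survival proportion in every litter: no litter effect at all
  even <- tibble::tibble(
    mother_id = sprintf("m%d", 1:4), population = "P1", year = 2006L,
    cubs_emergence = 2L, cubs_survived = 1L, monitored_to_autumn = TRUE
  )
  res <- litter_independence_test(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # whole litters live or die together: strong clustering, hand-computed F
  clustered <- tibble::tibble(
    mother_id = sprintf("m%d", 1:4), population = "P1", year = 2006L,
    cubs_emergence = 3L, cubs_survived = c(3L, 3L, 0L, 0L),
    monitored_to_autumn = TRUE
  )
  res <- litter_independence_test(clustered)
  # between-litter SS = 3, within = 0 -> F is infinite in exact arithmetic
  expect_gt(res$statistic, 1e10)
  expect_lt(res$p_value, 1e-10)

  mixed <- tibble::tibble(
    mother_id = sprintf("m%d", 1:4), population = "P1", year = 2006L,
    cubs_emergence = c(3L, 3L, 2L, 2L), cubs_survived = c(3L, 2L, 1L, 2L),
    monitored_to_autumn = TRUE
  )
  res <- litter_independence_test(mixed)
  # hand ANOVA: group means 1, 2/3, 1/2, 1; grand mean 0.8
  fates <- c(1, 1, 1, 1, 1, 0, 1, 0, 1, 1)
  groups <- rep(1:4, c(3, 3, 2, 2))
  ssb <- sum(tapply(fates, groups, function(x) length(x) * (mean(x) - 0.8)^2))
  ssw <- sum(tapply(fates, groups, function(x) sum((x - mean(x))^2)))
  f_hand <- (ssb / 3) / (ssw / 6)
  expect_equal(res$statistic, f_hand, tolerance = 1e-10)

  # study-reconstruction fixture: fates independent of litter membership
  expect_gt(litter_independence_test(bc_bear_litters())$p_value, 0.05)

  singletons <- tibble::tibble(
    mother_id = c("a", "b"), population = "P1", year = 2006L,
    cubs_emergence = 1L, cubs_survived = 1L, monitored_to_autumn = TRUE
  )
  expect_error(litter_independence_test(singletons), "two or more cubs")
})
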