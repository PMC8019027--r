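test_that("Leslie assembly places survival and fecundity where the model says", {
  v <- bc_bear_vital_rates("MM")
  L <- build_leslie(v)
  expect_equal(dim(L), c(25, 25))
  sub <- L[cbind(2:25, 1:24)]
  expect_equal(length(sub), 24)
  expect_true(all(sub %in% c(0.85, 1)))
  expect_equal(sum(L[1, ] > 0), 19)
  expect_true(all(L[1, 7:25] == 0.23))
  expect_true(all(L[1, 1:6] == 0))

  # round trip: rates -> matrix -> rates -> identical matrix
  v2 <- vital_rates(sub[1], sub[2], sub[3], sub[7], m = L[1, 25])
  expect_identical(build_leslie(v2), L)

  # fecundity discount flag
  expect_equal(build_leslie(v, fecundity_discount = TRUE)[1, 25], 0.23 * 0.85)
})

test_that("survivorship is a non-increasing product starting at 1", {
  v <- bc_bear_vital_rates("NSN")
  l <- survivorship(v)
  expect_equal(unname(l[1]), 1)
  expect_true(all(diff(l) <= 0))
  expect_equal(unname(l[3]), 0.33 * 1.00)
  expect_equal(unname(l[4]), 0.33 * 0.81)
})

test_that("eigenvalue growth rate agrees with the Euler-Lotka bisection root", {
  set.seed(30)
  for (i in 1:40) {
    v <- random_vital_rates()
    expect_equal(growth_rate(build_leslie(v)), euler_lotka_lambda(v),
                 tolerance = 1e-6)
  }
})

test_that("R0 and generation time follow their defining sums and limits", {
  # 3-class hand example: l = (1, 0.5, 0.25), F = (0, 1, 1)
  L3 <- rbind(c(0, 1, 1), c(0.5, 0, 0), c(0, 0.5, 0))
  expect_equal(net_reproductive_rate(L3), 0.5 + 0.25)

  v0 <- vital_rates(0.9, 0.9, 0.9, 0.9, m = 0)
  expect_equal(net_reproductive_rate(build_leslie(v0)), 0)

  # calibrate m so that R0 = 1; then lambda = 1 and the limit branch engages
  v <- vital_rates(0.8, 0.9, 0.92, 0.95, m = 1)
  l <- survivorship(v)
  m_star <- 1 / sum(l[7:25])
  v1 <- vital_rates(0.8, 0.9, 0.92, 0.95, m = m_star)
  L1 <- build_leslie(v1)
  expect_equal(net_reproductive_rate(L1), 1)
  expect_equal(growth_rate(L1), 1, tolerance = 1e-9)
  x <- 0:24
  fec <- c(rep(0, 6), rep(m_star, 19))
  expect_equal(generation_time(L1), sum(x * l * fec) / sum(l * fec))
})

test_that("the sign of lambda - 1 matches the sign of R0 - 1", {
  set.seed(31)
  for (i in 1:30) {
    L <- build_leslie(random_vital_rates())
    expect_equal(sign(growth_rate(L) - 1),
                 sign(net_reproductive_rate(L) - 1))
  }
})

test_that("stage transition rates collapse correctly in closed-form cases", {
  v <- bc_bear_vital_rates("MM")
  l <- survivorship(v)
  # single-age stage: leaves with certainty
  expect_equal(stage_transition_rate(1, 2, l, 1.07), 1)
  # lambda = 1 and constant survivorship on a stage of width w: P = 1/w
  l_flat <- rep(1, 25)
  expect_equal(stage_transition_rate(2, 6, l_flat, 1), 1 / 4)
  expect_error(stage_transition_rate(5, 3, l, 1), "x_i < x_j")
  expect_error(stage_transition_rate(2, 6, rep(0, 25), 1), "zero survivorship")
})

test_that("stage-model and aggregated stable distributions coincide", {
  set.seed(32)
  for (i in 1:30) {
    v <- random_vital_rates()
    a <- stable_stage_distribution(v, method = "stage_model")
    b <- stable_stage_distribution(v, method = "aggregate")
    expect_equal(a, b, tolerance = 1e-6)
    expect_equal(sum(a), 1)
    expect_true(all(a >= 0))
  }
})

test_that("stable age structure is uniform at lambda = 1 with perfect survival", {
  v <- vital_rates(1, 1, 1, 1, m = 1 / 19)
  L <- build_leslie(v)
  expect_equal(growth_rate(L), 1, tolerance = 1e-9)
  w <- stable_age_distribution(L)
  expect_equal(unname(w), rep(1 / 25, 25), tolerance = 1e-6)
})

test_that("the faster-growing population is younger at the stable structure", {
  w_mm <- stable_age_distribution(build_leslie(bc_bear_vital_rates("MM")))
  w_nsn <- stable_age_distribution(build_leslie(bc_bear_vital_rates("NSN")))
  expect_gt(sum(w_mm[2:6]), sum(w_nsn[2:6])) # yearling + subadult share
})

test_that("lambda increases with every vital rate", {
  v <- vital_rates(0.7, 0.85, 0.9, 0.93, m = 0.25)
  lam0 <- growth_rate(build_leslie(v))
  bump <- function(field) {
    v2 <- v
    v2[[field]] <- v2[[field]] + 0.02
    growth_rate(build_leslie(vital_rates(v2$s_cub, v2$s_yearling,
                                         v2$s_subadult, v2$s_adult, v2$m)))
  }
  for (f in c("s_cub", "s_yearling", "s_subadult", "s_adult", "m")) {
    expect_gt(bump(f), lam0)
  }
})

test_that("Monte Carlo projection is exact for degenerate inputs and shows the Jensen effect", {
  set.seed(33)
  pt <- list(s_cub = 0.85, s_yearling = 1, s_subadult = 1, s_adult = 1, m = 0.23)
  pr <- monte_carlo_projection(pt, n_iter = 25)
  lam <- growth_rate(build_leslie(bc_bear_vital_rates("MM")))
  expect_equal(pr$summary$mean[1], lam, tolerance = 1e-12)
  expect_equal(pr$summary$ci_low[1], pr$summary$ci_high[1])
  expect_equal(pr$rejected, 0)

  # strongly skewed cub-survival replicates: E[lambda] < lambda(E[rates])
  set.seed(34)
  cub_reps <- c(rep(0.05, 500), rep(0.61, 500)) # mean 0.33
  sk <- monte_carlo_projection(
    list(s_cub = cub_reps, s_yearling = 1, s_subadult = 0.81,
         s_adult = 0.81, m = 0.19),
    n_iter = 400
  )
  lam_mean_rates <- growth_rate(build_leslie(vital_rates(0.33, 1, 0.81, 0.81, 0.19)))
  expect_lt(sk$summary$mean[1], lam_mean_rates)
})

test_that("out-of-range vital-rate draws are rejected and tallied", {
  set.seed(35)
  pr <- monte_carlo_projection(
    list(s_cub = c(0.8, 1.4), s_yearling = 1, s_subadult = 1, s_adult = 1,
         m = 0.2),
    n_iter = 50
  )
  expect_gt(pr$rejected, 0)
  expect_true(all(pr$iterations$lambda > 0))
})
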