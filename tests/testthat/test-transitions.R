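seq_states <- function(id, states, start_age = 6L, pop = "P1") {
  tibble::tibble(bear_id = id, population = pop,
                 year = 2006L + seq_along(states) - 1L,
                 state = states, age = start_age + seq_along(states) - 1L)
}

test_that("transition counts follow consecutive adult state pairs", {
  tm <- estimate_transitions(seq_states("f1", c("A", "C", "Y", "T", "A")))
  for (tr in c("AC", "CY", "YT", "TA")) {
    expect_equal(tm$counts[substr(tr, 1, 1), substr(tr, 2, 2)], 1L)
  }
  expect_equal(sum(tm$counts), 4L)

  # subadult origin years are excluded from transition estimation
  young <- seq_states("f2", c("A", "A", "A"), start_age = 5L)
  tm2 <- estimate_transitions(dplyr::bind_rows(
    seq_states("f1", c("A", "C", "Y", "T", "A")), young
  ))
  expect_equal(sum(tm2$counts), 5L) # f2 contributes only her adult-origin pair

  # non-consecutive years contribute nothing
  gap <- seq_states("f3", c("A", "C"))
  gap$year <- c(2006L, 2009L)
  expect_error(estimate_transitions(gap), "no consecutive")
})

test_that("impossible transitions are rejected with the bear named", {
  bad <- seq_states("f9", c("A", "Y"))
  expect_error(estimate_transitions(bad), "AY")
  expect_error(estimate_transitions(bad), "f9")
})

test_that("reconstructed study sequences reproduce the published matrices", {
  st <- bc_bear_states()
  mm <- estimate_transitions(st, "MM")
  expect_equal(sum(mm$counts), 38L)
  expect_equal(mm$P["T", "A"], 0.75)
  expect_equal(mm$P["T", "C"], 0.25)
  expect_equal(mm$counts["T", "A"], 3L)
  expect_equal(unname(abs(mm$P - bc_bear_transition_matrix("MM")$P)) < 0.011,
               matrix(TRUE, 4, 4), ignore_attr = TRUE)
  nsn <- estimate_transitions(st, "NSN")
  expect_equal(sum(nsn$counts), 30L)
  expect_equal(unname(abs(nsn$P - bc_bear_transition_matrix("NSN")$P)) < 0.011,
               matrix(TRUE, 4, 4), ignore_attr = TRUE)
})

test_that("multinomial estimation recovers a known generating matrix", {
  set.seed(20)
  P <- rbind(c(0.6, 0.4, 0, 0), c(0.1, 0.1, 0.8, 0),
             c(0.1, 0.1, 0, 0.8), c(0.7, 0.3, 0, 0))
  dimnames(P) <- list(REPRO_STATES_T(), REPRO_STATES_T())
  seqs <- simulate_sequences(P, n_females = 600, len = 14)
  est <- estimate_transitions(seqs)
  expect_gte(sum(est$counts), 500)
  expect_true(all(abs(est$P - P) < 0.05))
  # and the permitted-zero structure is preserved exactly
  expect_true(all(est$P[P == 0] == 0))
})

test_that("stationary distribution is a fixed point matching the left eigenvector", {
  for (pop in c("MM", "NSN")) {
    tm <- bc_bear_transition_matrix(pop)
    ss <- stable_state(tm)
    expect_lt(sum(abs(as.numeric(ss$pi %*% tm$P) - ss$pi)), 1e-10)
    e <- eigen(t(tm$P))
    v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
    expect_equal(unname(ss$pi), v / sum(v), tolerance = 1e-9)
    expect_equal(sum(ss$pi), 1)
  }
})

test_that("a deterministic cycle has the uniform fixed point but no limit from a corner", {
  P <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1), c(1, 0, 0, 0))
  tm <- transition_matrix(P)
  expect_equal(unname(stable_state(tm, start = c(1, 1, 1, 1))$pi),
               rep(0.25, 4))
  expect_error(stable_state(tm, max_iter = 1000), "periodic")
})

test_that("reproductive rate composes litter size, cub-state proportion and sex ratio", {
  expect_equal(round(reproductive_rate(2.33, 0.20), 2), 0.23)
  expect_equal(round(reproductive_rate(2.25, 0.17), 2), 0.19)
  expect_equal(reproductive_rate(0, 0.2), 0)
  # linear in every argument
  expect_equal(reproductive_rate(2 * 2.33, 0.2), 2 * reproductive_rate(2.33, 0.2))
  expect_equal(reproductive_rate(2.33, 0.1), reproductive_rate(2.33, 0.2) / 2)
  expect_equal(reproductive_rate(2.33, 0.2, female_fraction = 1),
               2 * reproductive_rate(2.33, 0.2))
})

test_that("bootstrapping the stable state is degenerate for one female and stabilises in B", {
  set.seed(21)
  one <- seq_states("only", c("A", "A", "C", "Y", "T", "A", "A", "C", "Y", "T", "A"))
  bs <- bootstrap_stable_state(one, B = 50)
  for (s in REPRO_STATES_T()) {
    expect_equal(bs[[s]]$ci_low, bs[[s]]$ci_high)
  }

  seqs <- simulate_sequences(bc_bear_transition_matrix("MM")$P, 25, 8)
  set.seed(22)
  b1 <- bootstrap_stable_state(seqs, B = 1000)
  set.seed(23)
  b2 <- bootstrap_stable_state(seqs, B = 10000)
  expect_lt(abs(b1$C$ci_low - b2$C$ci_low), 0.01)
  expect_lt(abs(b1$C$ci_high - b2$C$ci_high), 0.01)
})

test_that("study-scale bootstrap interval for the cub-state proportion has the published magnitude", {
  set.seed(24)
  bs <- bootstrap_stable_state(bc_bear_states(), "MM", B = 1000)
  expect_equal(bs$C$point, 0.2, tolerance = 0.01)
  # published interval is 0.13-0.30; assert order of magnitude, not exactness
  expect_gt(bs$C$ci_low, 0.05)
  expect_lt(bs$C$ci_high, 0.45)
  expect_gt(bs$C$ci_high - bs$C$ci_low, 0.05)
})
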