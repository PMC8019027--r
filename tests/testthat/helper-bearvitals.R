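# small constructors shared across tests

encounter_rows <- function(bear_id, n, final = "alive", cause = NA_character_,
                           population = "P1", birth_year = 2000L,
                           start_year = 2006L) {
  g <- seq_len(n)
  status <- rep("alive", n)
  status[n] <- final
  causes <- rep(NA_character_, n)
  if (final == "dead") causes[n] <- cause
  tibble::tibble(
    bear_id = bear_id, population = population, birth_year = birth_year,
    year = start_year + (g - 1L) %/% 8L, interval = ((g - 1L) %% 8L) + 1L,
    status = status, cause = causes
  )
}

# simulate state sequences from a known transition matrix (independent oracle
# input for the multinomial estimator)
simulate_sequences <- function(P, n_females, len, start_year = 2006L) {
  purrr::map_dfr(seq_len(n_females), function(i) {
    s <- character(len)
    s[1] <- sample(REPRO_STATES_T(), 1)
    for (t in 2:len) {
      s[t] <- sample(REPRO_STATES_T(), 1, prob = P[s[t - 1], ])
    }
    tibble::tibble(bear_id = sprintf("S%03d", i), population = "P1",
                   year = start_year + seq_len(len) - 1L, state = s,
                   age = 6L + seq_len(len) - 1L)
  })
}

REPRO_STATES_T <- function() c("A", "C", "Y", "T")

random_vital_rates <- function() {
  vital_rates(
    s_cub = runif(1, 0.2, 0.95), s_yearling = runif(1, 0.5, 1),
    s_subadult = runif(1, 0.5, 1), s_adult = runif(1, 0.7, 0.99),
    m = runif(1, 0.05, 0.5)
  )
}

# interbirth histories with true interval 4 + Geometric(p) and monitoring
# window W years after each birth (heavy right-censoring when W is short)
censored_interbirth <- function(n_females, p_breed = 0.5, max_window = 6) {
  purrr::map_dfr(seq_len(n_females), function(i) {
    t_true <- 4L + rgeom(1, p_breed)
    w <- sample.int(max_window, 1)
    t_obs <- min(t_true, w)
    if (t_obs < 1) return(NULL)
    tibble::tibble(
      bear_id = sprintf("IB%03d", i), population = "P1", birth_year = 2006L,
      offset = seq_len(t_obs),
      next_litter = as.integer(seq_len(t_obs) == t_true)
    )
  })
}
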