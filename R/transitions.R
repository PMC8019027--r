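permitted_mask <- function() {
  m <- matrix(FALSE, 4, 4, dimnames = list(REPRO_STATES, REPRO_STATES))
  for (tr in PERMITTED_TRANSITIONS) {
    m[substr(tr, 1, 1), substr(tr, 2, 2)] <- TRUE
  }
  m
}

#' Construct a reproductive-state transition matrix
#'
#' Builds a `transition_matrix` over the states A (alone), C (with cubs),
#' Y (with yearlings), T (with two-year-or-older dependents) from a 4x4
#' probability matrix. Only the ten biologically possible transitions may
#' carry mass; rows are renormalised to sum to 1 (printed estimates are often
#' rounded to 2 decimals, so small excesses are tolerated and scaled away).
#'
#' @param probs 4x4 numeric matrix, rows = origin state in A, C, Y, T order.
#' @param counts Optional 4x4 matrix of the transition tallies behind the
#'   probabilities.
#' @return An object of class `transition_matrix`.
#' @export
transition_matrix <- function(probs, counts = NULL) {
  probs <- as.matrix(probs)
  stopifnot(all(dim(probs) == c(4, 4)))
  dimnames(probs) <- list(REPRO_STATES, REPRO_STATES)
  if (any(probs[!permitted_mask()] != 0)) {
    abort("transition matrix has mass on a biologically impossible transition")
  }
  if (any(probs < 0)) abort("transition probabilities must be non-negative")
  rs <- rowSums(probs)
  estimable <- rs > 0
  if (any(abs(rs[estimable] - 1) > 0.05)) {
    abort("rows must sum to 1 (within rounding tolerance)")
  }
  probs[estimable, ] <- probs[estimable, , drop = FALSE] / rs[estimable]
  structure(
    list(P = probs, counts = counts, estimable = estimable,
         n = if (is.null(counts)) NA_integer_ else sum(counts)),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Reproductive-state transition matrix",
      if (!is.na(x$n)) sprintf("(%d observed transitions)", x$n), "\n")
  print(round(x$P, 3))
  if (any(!x$estimable)) {
    cat("inestimable row(s):",
        paste(REPRO_STATES[!x$estimable], collapse = ", "), "\n")
  }
  invisible(x)
}

state_pairs <- function(states, adult_min) {
  states |>
    dplyr::arrange(.data$bear_id, .data$year) |>
    dplyr::group_by(.data$bear_id) |>
    dplyr::mutate(to = dplyr::lead(.data$state),
                  to_year = dplyr::lead(.data$year)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$to), .data$to_year == .data$year + 1,
                  .data$age >= adult_min)
}

#' Estimate reproductive-state transition probabilities
#'
#' Multinomial maximum likelihood per originating state from consecutive-year
#' state observations of adult females: entry (s -> s') is the count of
#' observed s -> s' transitions over all transitions out of s. Because a
#' female must survive and be re-observed for a transition to be recorded,
#' survival and detection are implicitly 1 and need no parameters. Observed
#' transitions outside the permitted set raise a validation error; an origin
#' state never observed leaves its row flagged inestimable.
#'
#' @param states A validated state table.
#' @param population Optional population label(s).
#' @param adult_min Minimum (origin-year) age for a pair to count.
#' @return A [transition_matrix()] with counts attached.
#' @examples
#' estimate_transitions(bc_bear_states(), population = "MM")
#' @export
estimate_transitions <- function(states, population = NULL, adult_min = 6L) {
  states <- filter_population(states, population)
  pairs <- state_pairs(states, adult_min)
  if (nrow(pairs) == 0) abort("no consecutive-year adult state pairs")
  key <- paste0(pairs$state, pairs$to)
  bad <- !key %in% PERMITTED_TRANSITIONS
  if (any(bad)) {
    validation_error(
      sprintf("impossible transition(s) observed: %s",
              paste(unique(key[bad]), collapse = ", ")),
      bear = unique(pairs$bear_id[bad])
    )
  }
  counts <- matrix(0L, 4, 4, dimnames = list(REPRO_STATES, REPRO_STATES))
  tab <- table(factor(pairs$state, REPRO_STATES), factor(pairs$to, REPRO_STATES))
  counts[] <- as.integer(tab)
  probs <- counts
  rs <- rowSums(counts)
  probs[rs > 0, ] <- counts[rs > 0, , drop = FALSE] / rs[rs > 0]
  transition_matrix(probs, counts = counts)
}

#' Stationary reproductive-state distribution
#'
#' Iterates the Markov chain \eqn{\pi \leftarrow \pi T} from a starting
#' distribution (by default every female alone) until the L1 change falls
#' below `tol`, returning the asymptotic stable reproductive-state
#' distribution. The fixed point equals the leading left eigenvector of the
#' transition matrix.
#'
#' @param tm A [transition_matrix()]. An inestimable (never-observed) origin
#'   row is tolerated when the chain assigns it no stationary mass; if the
#'   stationary distribution would need such a row, an error names it.
#' @param start Starting distribution over (A, C, Y, T).
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; a periodic chain that cycles without
#'   converging raises an error naming the cycle states.
#' @return An object of class `stable_state`: list with `pi` (named
#'   proportions), `iterations`, and the matrix used.
#' @examples
#' stable_state(bc_bear_transition_matrix("MM"))$pi
#' @export
stable_state <- function(tm, start = c(1, 0, 0, 0), tol = 1e-12,
                         max_iter = 1e5) {
  stopifnot(inherits(tm, "transition_matrix"))
  P <- tm$P
  if (any(!tm$estimable)) {
    # a state never observed as an origin is tolerable only if the chain
    # never reaches it: give it a self-loop so any reachable mass is trapped
    # and detected after convergence
    for (j in which(!tm$estimable)) P[j, j] <- 1
  }
  p <- as.numeric(start) / sum(start)
  for (i in seq_len(max_iter)) {
    q <- as.numeric(p %*% P)
    q <- q / sum(q)
    if (sum(abs(q - p)) < tol) {
      if (any(!tm$estimable) && sum(q[!tm$estimable]) > 1e-8) {
        abort(sprintf(
          "stationary distribution needs inestimable row(s): %s",
          paste(REPRO_STATES[!tm$estimable], collapse = ", ")
        ))
      }
      return(structure(
        list(pi = setNames(q, REPRO_STATES), iterations = i, matrix = tm),
        class = "stable_state"
      ))
    }
    p <- q
  }
  abort(sprintf(
    "no convergence in %d iterations (periodic chain?); last distribution: %s",
    max_iter, paste(sprintf("%s=%.3f", REPRO_STATES, p), collapse = ", ")
  ))
}

#' @export
print.stable_state <- function(x, ...) {
  cat(sprintf("Stable reproductive-state distribution (%d iterations):\n",
              x$iterations))
  print(round(x$pi, 4))
  invisible(x)
}

#' Mean reproductive rate
#'
#' Female cubs per adult female per year: the female fraction of the mean
#' litter (cub sex is unobserved, so half the cubs are taken to be female)
#' times the stationary proportion of adult females with cubs.
#'
#' @param litter_size Mean cubs per litter (a number or a [boot_dist]).
#' @param pi_c Stationary proportion of females in state C (a number, a
#'   [stable_state], or a [boot_dist]).
#' @param female_fraction Fraction of cubs that are female.
#' @return m, in female cubs per year per adult female.
#' @export
reproductive_rate <- function(litter_size, pi_c, female_fraction = 0.5) {
  if (inherits(litter_size, "boot_dist")) litter_size <- litter_size$point
  if (inherits(pi_c, "stable_state")) pi_c <- unname(pi_c$pi["C"])
  if (inherits(pi_c, "boot_dist")) pi_c <- pi_c$point
  stopifnot(litter_size >= 0, pi_c >= 0, pi_c <= 1,
            female_fraction >= 0, female_fraction <= 1)
  female_fraction * litter_size * pi_c
}

#' Bootstrap the stable reproductive-state distribution
#'
#' Resamples females (each with her full set of observed transitions) with
#' replacement, re-estimates the transition matrix and recomputes the
#' stationary distribution per replicate. Replicates in which some origin
#' state was never observed are redrawn and tallied.
#'
#' @inheritParams estimate_transitions
#' @param B Bootstrap replicates.
#' @return A list of four [boot_dist] objects (one per state) with the
#'   redraw tally in each `$extra`, plus attributes `point` (the full-data
#'   stationary distribution).
#' @export
bootstrap_stable_state <- function(states, population = NULL, B = 1000,
                                   adult_min = 6L) {
  states <- filter_population(states, population)
  point_tm <- estimate_transitions(states, adult_min = adult_min)
  point_pi <- stable_state(point_tm)$pi
  pairs <- state_pairs(states, adult_min)
  by_female <- split(pairs, pairs$bear_id)
  reps <- matrix(NA_real_, B, 4)
  b <- 1L
  redraws <- 0L
  while (b <= B) {
    if (redraws > 100 * B) abort("too many inestimable bootstrap replicates")
    samp <- dplyr::bind_rows(
      by_female[sample(names(by_female), length(by_female), replace = TRUE)]
    )
    counts <- matrix(0L, 4, 4, dimnames = list(REPRO_STATES, REPRO_STATES))
    counts[] <- as.integer(table(factor(samp$state, REPRO_STATES),
                                 factor(samp$to, REPRO_STATES)))
    rs <- pmax(rowSums(counts), 1L)
    tm <- transition_matrix(counts / rs, counts = counts)
    # a resampled chain can be periodic (a pure C->Y->T->C cycle) or need a
    # row no resample can estimate; such replicates have no stationary
    # limit and are redrawn and tallied
    pi_b <- tryCatch(stable_state(tm, max_iter = 5000)$pi,
                     error = function(e) NULL)
    if (is.null(pi_b)) { redraws <- redraws + 1L; next }
    reps[b, ] <- pi_b
    b <- b + 1L
  }
  out <- lapply(1:4, function(j) {
    new_boot_dist(paste0("pi_", REPRO_STATES[j]), point = unname(point_pi[j]),
                  replicates = reps[, j], n = length(by_female),
                  extra = list(redraws = redraws))
  })
  names(out) <- REPRO_STATES
  attr(out, "point") <- point_pi
  out
}
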