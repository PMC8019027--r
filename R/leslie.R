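#' Assemble a vital-rate set
#'
#' Bundles the age-class survival schedule and the flat adult fecundity that
#' parameterise the Leslie matrix: cub (first year), yearling (second year),
#' subadult (ages 2-5) and adult (6+) annual survival, and m = female cubs
#' per female per year applied to ages `adult_min` through `max_age` (the age
#' of last reproduction).
#'
#' @param s_cub,s_yearling,s_subadult,s_adult Annual survival probabilities.
#' @param m Female cubs per female per year for reproductive ages.
#' @param adult_min First reproductive (adult) age.
#' @param max_age Age of last reproduction; the matrix has classes
#'   `0..max_age`.
#' @return An object of class `vital_rates`.
#' @examples
#' v <- vital_rates(0.85, 1, 1, 1, m = 0.23)
#' growth_rate(build_leslie(v))
#' @export
vital_rates <- function(s_cub, s_yearling, s_subadult, s_adult, m,
                        adult_min = 6L, max_age = 24L) {
  s <- c(s_cub, s_yearling, s_subadult, s_adult)
  if (any(s < 0 | s > 1)) abort("survival probabilities must be in [0, 1]")
  if (m < 0) abort("m must be non-negative")
  if (!(2 < adult_min && adult_min <= max_age)) {
    abort("need 2 < adult_min <= max_age")
  }
  structure(
    list(s_cub = s_cub, s_yearling = s_yearling, s_subadult = s_subadult,
         s_adult = s_adult, m = m, adult_min = as.integer(adult_min),
         max_age = as.integer(max_age)),
    class = "vital_rates"
  )
}

# per-age survival vector P_0..P_{max_age-1} (subdiagonal of the Leslie matrix)
age_survival <- function(v) {
  c(v$s_cub, v$s_yearling,
    rep(v$s_subadult, v$adult_min - 2L),
    rep(v$s_adult, v$max_age - v$adult_min))
}

#' Survivorship schedule l(x)
#'
#' Probability of surviving from birth to age x, for x = 0..max_age:
#' \eqn{l(0) = 1}, \eqn{l(x) = \prod_{a<x} P_a} with the age-class survival
#' on the subdiagonal of the Leslie matrix.
#'
#' @param v A [vital_rates()] set.
#' @return Named numeric vector of length `max_age + 1`.
#' @export
survivorship <- function(v) {
  l <- cumprod(c(1, age_survival(v)))
  setNames(l, 0:v$max_age)
}

#' Build the Leslie matrix
#'
#' A `(max_age+1)` square age-structured projection matrix: survival on the
#' subdiagonal, fecundities `m` in the first row for ages `adult_min` through
#' `max_age`. By default the fecundity row carries `m` undiscounted (the
#' convention under which the dominant eigenvalue solves
#' \eqn{\sum_x \lambda^{-(x+1)} l(x) m_x = 1}); a pre-breeding census that
#' discounts fecundity by first-year survival (`F = s_cub * m`) is available
#' via `fecundity_discount = TRUE` for sensitivity analysis.
#'
#' @param v A [vital_rates()] set.
#' @param fecundity_discount Multiply fecundities by cub survival?
#' @return A `(max_age+1) x (max_age+1)` matrix with dimnames `0..max_age`.
#' @export
build_leslie <- function(v, fecundity_discount = FALSE) {
  n <- v$max_age + 1L
  L <- matrix(0, n, n, dimnames = list(0:v$max_age, 0:v$max_age))
  surv <- age_survival(v)
  L[cbind(2:n, 1:(n - 1))] <- surv
  fec <- v$m * (if (fecundity_discount) v$s_cub else 1)
  L[1, (v$adult_min + 1L):n] <- fec
  L
}

# extract the vital-rate ingredients back out of a Leslie matrix
leslie_parts <- function(L) {
  n <- nrow(L)
  surv <- L[cbind(2:n, 1:(n - 1))]
  list(surv = surv, fec = L[1, ], l = cumprod(c(1, surv)))
}

#' Population growth rate
#'
#' The dominant eigenvalue of the Leslie matrix (finite annual growth rate
#' lambda), from the dense eigendecomposition. A matrix with no fecundity is
#' reducible on its support; its spectral radius is still returned, with a
#' warning.
#'
#' @param L A Leslie matrix.
#' @return lambda (a single number).
#' @export
growth_rate <- function(L) {
  if (any(L < 0)) abort("Leslie matrix must be non-negative")
  ev <- eigen(L, only.values = TRUE)$values
  lam <- Re(ev[which.max(Mod(ev))])
  if (all(L[1, ] == 0)) {
    warn("matrix has zero fecundity (reducible); lambda is its spectral radius")
  }
  lam
}

#' Euler-Lotka growth rate
#'
#' Solves \eqn{\sum_x \lambda^{-(x+1)} l(x) F_x = 1} for lambda by bisection
#' (stats::uniroot). Under the package's assembly convention this renewal
#' equation characterises the same lambda as the dominant eigenvalue of
#' [build_leslie()], so the two serve as mutual cross-checks through
#' independent algorithms.
#'
#' @param v A [vital_rates()] set.
#' @param fecundity_discount As in [build_leslie()].
#' @param tol Root tolerance.
#' @return lambda (a single number).
#' @export
euler_lotka_lambda <- function(v, fecundity_discount = FALSE, tol = 1e-9) {
  l <- survivorship(v)
  x <- 0:v$max_age
  fec <- ifelse(x >= v$adult_min, v$m * (if (fecundity_discount) v$s_cub else 1), 0)
  if (all(fec * l == 0)) abort("no reproduction: Euler-Lotka equation has no root")
  f <- function(lam) sum(lam^(-(x + 1)) * l * fec) - 1
  uniroot(f, interval = c(1e-6, 10), tol = tol)$root
}

#' Net reproductive rate and generation time
#'
#' `net_reproductive_rate()` returns \eqn{R_0 = \sum_x l(x) F_x}, the
#' expected lifetime production of female cubs per female. `generation_time()`
#' returns \eqn{\ln R_0 / \ln \lambda} (the time for the population to grow
#' by a factor of its lifetime reproduction); at \eqn{\lambda = 1} the limit
#' \eqn{\sum_x x\, l(x) F_x / \sum_x l(x) F_x} (the mean age of offspring
#' production) is used.
#'
#' @param L A Leslie matrix.
#' @return A single number.
#' @export
net_reproductive_rate <- function(L) {
  p <- leslie_parts(L)
  sum(p$l * p$fec)
}

#' @rdname net_reproductive_rate
#' @export
generation_time <- function(L) {
  r0 <- net_reproductive_rate(L)
  if (r0 == 0) return(NA_real_)
  lam <- suppressWarnings(growth_rate(L))
  if (abs(lam - 1) < 1e-9) {
    p <- leslie_parts(L)
    x <- as.numeric(rownames(L)) %||% (seq_len(nrow(L)) - 1)
    sum(x * p$l * p$fec) / sum(p$l * p$fec)
  } else {
    log(r0) / log(lam)
  }
}

#' Conditional stage-transition rate
#'
#' The probability that an individual in the age-group stage starting at age
#' `x_i` moves to the next stage (starting at `x_j`), conditional on survival
#' and on the population growing at rate lambda:
#' \deqn{P_{j,i} = \frac{\lambda^{-(x_j - x_i - 1)}\, l(x_j - 1)}
#'   {\sum_{x = x_i}^{x_j - 1} \lambda^{-(x - x_i)}\, l(x)}}
#' This collapses an age-structured model into a stage-structured one while
#' preserving its stable structure.
#'
#' @param x_i First age of the current stage.
#' @param x_j First age of the next stage (`x_i < x_j`).
#' @param l Survivorship vector `l(0..max_age)` (see [survivorship()]).
#' @param lambda Population growth rate.
#' @return The transition probability (a single number).
#' @export
stage_transition_rate <- function(x_i, x_j, l, lambda) {
  if (!(x_i < x_j && x_j <= length(l))) abort("need x_i < x_j <= max_age + 1")
  if (lambda <= 0) abort("lambda must be positive")
  ages <- x_i:(x_j - 1)
  lx <- l[ages + 1]
  if (any(lx <= 0)) abort("zero survivorship within the stage")
  unname(lambda^(-(x_j - x_i - 1)) * l[x_j] / sum(lambda^(-(ages - x_i)) * lx))
}

#' Stable age distribution
#'
#' The dominant right eigenvector of the Leslie matrix, normalised to sum
#' to 1: the asymptotic proportion of females in each age class.
#'
#' @param L A Leslie matrix.
#' @return Named numeric vector over ages.
#' @export
stable_age_distribution <- function(L) {
  e <- eigen(L)
  i <- which.max(Mod(e$values))
  w <- abs(Re(e$vectors[, i]))
  setNames(w / sum(w), rownames(L))
}

#' Stable stage distribution
#'
#' The asymptotic proportions in the four life stages (cub, yearling,
#' subadult, adult), computed two ways: `"stage_model"` builds the
#' 4-stage matrix using the conditional transition rates of
#' [stage_transition_rate()] and takes its dominant right eigenvector;
#' `"aggregate"` sums the Leslie matrix's stable age distribution over the
#' stage bins. The two agree to numerical precision, which the package's
#' tests use as a cross-check.
#'
#' @param v A [vital_rates()] set.
#' @param lambda Population growth rate; computed from the Leslie matrix if
#'   omitted.
#' @param method `"stage_model"` or `"aggregate"`.
#' @param fecundity_discount As in [build_leslie()].
#' @return Named numeric 4-vector (cub, yearling, subadult, adult).
#' @export
stable_stage_distribution <- function(v, lambda = NULL,
                                      method = c("stage_model", "aggregate"),
                                      fecundity_discount = FALSE) {
  method <- match.arg(method)
  L <- build_leslie(v, fecundity_discount)
  if (is.null(lambda)) lambda <- growth_rate(L)
  stages <- c("cub", "yearling", "subadult", "adult")
  if (method == "aggregate") {
    w <- stable_age_distribution(L)
    out <- c(w[1], w[2], sum(w[3:(v$adult_min)]),
             sum(w[(v$adult_min + 1):(v$max_age + 1)]))
    return(setNames(out, stages))
  }
  l <- survivorship(v)
  p_sub <- stage_transition_rate(2, v$adult_min, l, lambda)
  p_ad <- stage_transition_rate(v$adult_min, v$max_age + 1, l, lambda)
  fec <- v$m * (if (fecundity_discount) v$s_cub else 1)
  A <- matrix(0, 4, 4, dimnames = list(stages, stages))
  A["yearling", "cub"] <- v$s_cub
  A["subadult", "yearling"] <- v$s_yearling
  A["subadult", "subadult"] <- v$s_subadult * (1 - p_sub)
  A["adult", "subadult"] <- v$s_subadult * p_sub
  A["adult", "adult"] <- v$s_adult * (1 - p_ad)
  A["cub", "adult"] <- fec
  e <- eigen(A)
  i <- which.max(Mod(e$values))
  w <- abs(Re(e$vectors[, i]))
  setNames(w / sum(w), stages)
}
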