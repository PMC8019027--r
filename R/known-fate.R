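age_class_of <- function(age, adult_min = 6L) {
  dplyr::if_else(age >= adult_min, "adult", "subadult")
}

#' Build a staggered-entry risk table
#'
#' Tallies, for each group and monitoring interval of the 8-interval annual
#' cycle, the number of bears at risk, dying, and censored. A bear
#' contributes to the risk set of every interval it was monitored (staggered
#' entry); deaths and censoring events are placed in their recorded interval,
#' with deaths counted before censors.
#'
#' @param encounters A validated encounter table.
#' @param grouping One of `"none"`, `"population"`, `"age"` (subadult 2-5 vs
#'   adult 6+, age incrementing at den emergence).
#' @param adult_min First adult age.
#' @return A tibble with columns `group`, `interval`, `n_at_risk`,
#'   `n_deaths`, `n_censored`.
#' @export
build_risk_table <- function(encounters,
                             grouping = c("none", "population", "age"),
                             adult_min = 6L) {
  grouping <- match.arg(grouping)
  if (nrow(encounters) == 0) {
    return(tibble::tibble(group = character(), interval = integer(),
                          n_at_risk = integer(), n_deaths = integer(),
                          n_censored = integer()))
  }
  df <- dplyr::mutate(
    encounters,
    group = switch(grouping,
      none = "all",
      population = .data$population,
      age = age_class_of(.data$year - .data$birth_year, adult_min)
    )
  )
  out <- df |>
    dplyr::group_by(.data$group, .data$interval) |>
    dplyr::summarise(
      n_at_risk = dplyr::n(),
      n_deaths = sum(.data$status == "dead"),
      n_censored = sum(.data$status == "censored"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group, .data$interval)
  attr(out, "grouping") <- grouping
  out
}

#' Staggered-entry Kaplan-Meier survival
#'
#' Product-limit estimation on a risk table: interval survival
#' \eqn{\hat s_t = 1 - d_t / n_t}, annual survival the product over the
#' 8-interval April-to-March cycle, variance by Greenwood's formula with the
#' confidence interval constructed on the log-survival scale. Groups with no
#' deaths return annual survival 1.00 with an asymmetric profile-likelihood
#' interval of the form (lower, 1.00). Intervals with an empty risk set are
#' skipped with a warning.
#'
#' @param risk A risk table from [build_risk_table()].
#' @param conf_level Confidence level.
#' @return An object of class `km_fit`: a list with `interval` (per-interval
#'   estimates) and `annual` (per-group annual survival with CI) tibbles.
#' @export
kaplan_meier <- function(risk, conf_level = 0.95) {
  if (nrow(risk) == 0) abort("empty risk table")
  z <- qnorm(1 - (1 - conf_level) / 2)
  iv <- risk |>
    dplyr::filter({
      empty <- .data$n_at_risk == 0
      if (any(empty)) warn("intervals with an empty risk set were skipped")
      !empty
    }) |>
    dplyr::mutate(s_hat = 1 - .data$n_deaths / .data$n_at_risk)
  annual <- iv |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      annual_s = prod(.data$s_hat),
      # Greenwood variance of log S
      se_log = sqrt(sum(.data$n_deaths /
                          (.data$n_at_risk * (.data$n_at_risk - .data$n_deaths)))),
      n_intervals = sum(.data$n_at_risk),
      n_deaths = sum(.data$n_deaths),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_low = dplyr::if_else(
        .data$n_deaths == 0,
        exp(-qchisq(conf_level, 1) / 2 / .data$n_intervals)^INTERVALS_PER_YEAR,
        pmin(1, .data$annual_s * exp(-z * .data$se_log))
      ),
      ci_high = dplyr::if_else(
        .data$n_deaths == 0, 1,
        pmin(1, .data$annual_s * exp(z * .data$se_log))
      ),
      method = dplyr::if_else(.data$n_deaths == 0, "KM/profile", "KM")
    ) |>
    dplyr::select("group", "annual_s", "ci_low", "ci_high", "method",
                  "n_intervals", "n_deaths")
  structure(list(interval = iv, annual = annual, conf_level = conf_level),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Staggered-entry Kaplan-Meier fit\n")
  print(x$annual, ...)
  invisible(x)
}

# bear-interval data for the known-fate likelihood: alive rows survived the
# interval, dead rows did not; censored rows have unknown fate and drop out
known_fate_data <- function(encounters, adult_min = 6L) {
  encounters |>
    dplyr::filter(.data$status %in% c("alive", "dead")) |>
    dplyr::mutate(
      survived = as.integer(.data$status == "alive"),
      age_class = age_class_of(.data$year - .data$birth_year, adult_min)
    )
}

#' Fit a known-fate survival model
#'
#' Maximises the product-Bernoulli known-fate likelihood over monitored
#' bear-intervals: an interval survived contributes \eqn{s_{cell}}, a death
#' contributes \eqn{1 - s_{cell}}; censored intervals contribute nothing.
#' The three candidate structures are a common survival `S(~1)`, a
#' population effect `S(~Pop)`, and an age-class effect `S(~Age)`. With a
#' purely categorical design the MLE is the per-cell binomial proportion,
#' reported on the logit scale and converted to annual survival as the
#' interval estimate to the 8th power (equal hazard across the monitored
#' cycle, with the pooled denning interval treated as a single interval
#' exactly as the data are coded). AICc uses effective sample size equal to
#' the number of bear-intervals. Cells with no deaths are boundary estimates,
#' reported with profile-likelihood intervals of the form (lower, 1.00);
#' cells with no data are flagged inestimable.
#'
#' @param encounters A validated encounter table.
#' @param model One of `"null"`, `"population"`, `"age"`.
#' @param adult_min First adult age.
#' @param conf_level Confidence level.
#' @return An object of class `known_fate_model` with elements `name`,
#'   `model`, `cells` (per-cell estimates), `loglik`, `k`, `ess`, `AICc`.
#' @export
fit_known_fate <- function(encounters,
                           model = c("null", "population", "age"),
                           adult_min = 6L, conf_level = 0.95) {
  model <- match.arg(model)
  df <- known_fate_data(encounters, adult_min)
  if (nrow(df) == 0) abort("no monitored bear-intervals")
  df$cell <- switch(model,
    null = "all",
    population = df$population,
    age = df$age_class
  )
  z <- qnorm(1 - (1 - conf_level) / 2)
  chi <- qchisq(conf_level, 1)
  cells <- df |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(n = dplyr::n(), survived = sum(.data$survived),
                     .groups = "drop") |>
    dplyr::mutate(
      deaths = .data$n - .data$survived,
      s_interval = .data$survived / .data$n,
      logit = log(.data$s_interval / (1 - .data$s_interval)),
      s_annual = .data$s_interval^INTERVALS_PER_YEAR,
      estimable = .data$n > 0
    )
  ci <- purrr::map2(cells$s_interval, cells$n, function(s, n) {
    if (s >= 1) {
      # boundary: profile likelihood n*log(s) >= -chi/2
      c(exp(-chi / 2 / n)^INTERVALS_PER_YEAR, 1)
    } else if (s <= 0) {
      c(0, (1 - exp(-chi / 2 / n))^INTERVALS_PER_YEAR)
    } else {
      se <- 1 / sqrt(n * s * (1 - s)) # SE of logit
      lg <- log(s / (1 - s)) + c(-z, z) * se
      (1 / (1 + exp(-lg)))^INTERVALS_PER_YEAR
    }
  })
  cells$ci_low <- vapply(ci, `[`, numeric(1), 1)
  cells$ci_high <- vapply(ci, `[`, numeric(1), 2)
  xlx <- function(x, l) ifelse(x == 0, 0, x * log(l))
  ll <- sum(xlx(cells$survived, cells$s_interval) +
              xlx(cells$deaths, 1 - cells$s_interval))
  k <- nrow(cells)
  ess <- nrow(df)
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (ess - k - 1)
  structure(
    list(
      name = switch(model, null = "S(~1)", population = "S(~Pop)", age = "S(~Age)"),
      model = model, cells = cells, loglik = ll, k = k, ess = ess, AICc = aicc,
      adult_min = adult_min, conf_level = conf_level,
      n_deaths = sum(cells$deaths)
    ),
    class = "known_fate_model"
  )
}

#' @export
print.known_fate_model <- function(x, ...) {
  cat(sprintf("Known-fate model %s: logLik %.2f, k %d, AICc %.2f (ess %d)\n",
              x$name, x$loglik, x$k, x$AICc, x$ess))
  print(x$cells, ...)
  invisible(x)
}

#' AICc model-selection table
#'
#' Ranks known-fate models by AICc and attaches differences from the top
#' model and Akaike weights \eqn{\omega_i \propto \exp(-\Delta_i / 2)}.
#' Models must have been fitted to the same data.
#'
#' @param models List of [fit_known_fate()] objects.
#' @return A tibble with columns `model`, `k`, `loglik`, `AICc`, `delta`,
#'   `weight`, ranked best-first.
#' @export
aicc_table <- function(models) {
  if (length(models) < 2) abort("need at least two models to rank")
  ess <- vapply(models, `[[`, numeric(1), "ess")
  nd <- vapply(models, `[[`, numeric(1), "n_deaths")
  if (length(unique(ess)) > 1 || length(unique(nd)) > 1) {
    abort("models were fitted on differing data (bear-intervals or deaths differ)")
  }
  tab <- tibble::tibble(
    model = vapply(models, `[[`, character(1), "name"),
    k = vapply(models, `[[`, numeric(1), "k"),
    loglik = vapply(models, `[[`, numeric(1), "loglik"),
    AICc = vapply(models, `[[`, numeric(1), "AICc")
  ) |>
    dplyr::mutate(
      delta = .data$AICc - min(.data$AICc),
      weight = exp(-.data$delta / 2) / sum(exp(-.data$delta / 2))
    ) |>
    dplyr::arrange(.data$delta)
  tab
}

#' Model-averaged annual survival
#'
#' Averages annual survival on the real scale across models within
#' `threshold` AICc units of the best model, with Akaike weights
#' renormalised over the qualifying set. Estimates (and interval bounds) are
#' produced for every population-by-age-class cell present in the data; a
#' single qualifying model returns its own estimates.
#'
#' @param models List of [fit_known_fate()] objects fitted to the same data.
#' @param encounters The encounter table the models were fitted to.
#' @param threshold AICc difference below which a model enters the average.
#' @return A tibble with one row per (population, age_class) group:
#'   `annual_s`, `ci_low`, `ci_high`, `method`.
#' @export
model_average <- function(models, encounters, threshold = 2) {
  tab <- aicc_table(models)
  keep <- tab$model[tab$delta < threshold]
  w <- tab$weight[tab$delta < threshold]
  w <- w / sum(w)
  models <- models[match(keep, vapply(models, `[[`, character(1), "name"))]
  adult_min <- models[[1]]$adult_min
  groups <- known_fate_data(encounters, adult_min) |>
    dplyr::distinct(.data$population, .data$age_class)
  predict_cell <- function(m, pop, ac) {
    key <- switch(m$model, null = "all", population = pop, age = ac)
    row <- m$cells[m$cells$cell == key, ]
    c(row$s_annual, row$ci_low, row$ci_high)
  }
  est <- purrr::pmap(groups, function(population, age_class) {
    preds <- vapply(models, predict_cell, numeric(3), population, age_class)
    drop(preds %*% w)
  })
  groups |>
    dplyr::mutate(
      annual_s = vapply(est, `[`, numeric(1), 1),
      ci_low = vapply(est, `[`, numeric(1), 2),
      ci_high = vapply(est, `[`, numeric(1), 3),
      method = if (length(models) == 1) "top-model" else "model-averaged"
    )
}

#' Nonparametric bootstrap of known-fate annual survival
#'
#' Resamples bears (whole encounter histories) with replacement and refits
#' the per-group binomial known-fate MLE, yielding replicate distributions of
#' annual survival suitable for Monte Carlo projection. Replicates in which a
#' group has no monitored intervals are redrawn.
#'
#' @param encounters A validated encounter table.
#' @param B Number of bootstrap replicates.
#' @param grouping `"population"`, `"age"` or `"none"`.
#' @param adult_min First adult age.
#' @return A named list of [boot_dist] objects, one per group.
#' @export
bootstrap_known_fate <- function(encounters, B = 1000,
                                 grouping = c("population", "age", "none"),
                                 adult_min = 6L) {
  grouping <- match.arg(grouping)
  df <- known_fate_data(encounters, adult_min)
  df$grp <- switch(grouping, none = "all", population = df$population,
                   age = df$age_class)
  groups <- sort(unique(df$grp))
  ids <- unique(df$bear_id)
  by_bear <- split(df[c("grp", "survived")], df$bear_id)
  est <- function(d) {
    vapply(groups, function(g) {
      x <- d$survived[d$grp == g]
      if (length(x) == 0) return(NA_real_)
      mean(x)^INTERVALS_PER_YEAR
    }, numeric(1))
  }
  point <- est(df)
  reps <- matrix(NA_real_, B, length(groups))
  b <- 1L
  attempts <- 0L
  while (b <= B) {
    attempts <- attempts + 1L
    if (attempts > 50 * B) abort("too many inestimable bootstrap replicates")
    d <- dplyr::bind_rows(by_bear[sample(ids, length(ids), replace = TRUE)])
    r <- est(d)
    if (any(is.na(r))) next
    reps[b, ] <- r
    b <- b + 1L
  }
  out <- lapply(seq_along(groups), function(j) {
    new_boot_dist(paste0("annual_survival[", groups[j], "]"),
                  point = point[j], replicates = reps[, j],
                  n = sum(df$grp == groups[j]))
  })
  names(out) <- groups
  out
}
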