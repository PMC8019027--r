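#' Discrete hazard schedule
#'
#' Tabulates, per age (or interval offset), the number of females at risk
#' and the number of first-litter (or next-litter) events, with the discrete
#' hazard \eqn{h_t = events_t / at\_risk_t}. This is the availability
#' weighting that removes the bias toward early-maturing females (or short
#' interbirth intervals): each female contributes to the risk set only at
#' ages/offsets she was actually monitored and still event-free.
#'
#' @param df Long-format table with one row per (female, time-at-risk).
#' @param time_col Name of the time column (`"age"` or `"offset"`).
#' @param event_col Name of the 0/1 event column.
#' @return A tibble with columns `time`, `n_at_risk`, `n_events`, `h`.
#' @export
hazard_schedule <- function(df, time_col, event_col) {
  tibble::tibble(time = df[[time_col]], event = df[[event_col]]) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(n_at_risk = dplyr::n(), n_events = sum(.data$event),
                     .groups = "drop") |>
    dplyr::mutate(h = .data$n_events / .data$n_at_risk) |>
    dplyr::arrange(.data$time)
}

# mean event time from a hazard schedule:
# P(t) = h_t * prod_{t' < t} (1 - h_{t'}), truncated at the last observed
# event and renormalised over the observed range
hazard_mean <- function(sched) {
  if (sum(sched$n_events) == 0) return(NA_real_)
  last_event <- max(sched$time[sched$n_events > 0])
  sched <- sched[sched$time <= last_event, , drop = FALSE]
  p <- sched$h * cumprod(c(1, head(1 - sched$h, -1)))
  sum(sched$time * p) / sum(p)
}

hazard_boot <- function(df, id_col, time_col, event_col, B, statistic) {
  sched <- hazard_schedule(df, time_col, event_col)
  point <- hazard_mean(sched)
  if (is.na(point)) abort(sprintf("no events observed: %s is undefined", statistic))
  by_female <- split(df, df[[id_col]])
  res <- boot_resample(by_female, function(samp) {
    hazard_mean(hazard_schedule(dplyr::bind_rows(samp), time_col, event_col))
  }, B)
  p_total <- {
    last_event <- max(sched$time[sched$n_events > 0])
    s <- sched[sched$time <= last_event, , drop = FALSE]
    sum(s$h * cumprod(c(1, head(1 - s$h, -1))))
  }
  new_boot_dist(statistic, point = point, replicates = res$replicates,
                n = length(by_female),
                extra = list(schedule = sched, p_total = p_total,
                             redraws = res$redraws))
}

#' Weighted mean age of primiparity
#'
#' Estimates the mean age at first litter from all monitored nulliparous
#' females, including those never monitored to parturition. The age-specific
#' first-litter probability is the discrete hazard \eqn{h_a} (events over
#' females monitored nulliparous at age \eqn{a}); the age distribution is
#' \eqn{P(a) = h_a \prod_{a'<a}(1-h_{a'})}, truncated at the last age with an
#' observed event and renormalised, and the estimate is \eqn{\sum a P(a) /
#' \sum P(a)}. Bootstrap resamples whole females. The renormalisation mass
#' `p_total` is retained in `$extra` so truncation is visible.
#'
#' Whether the event is "first litter" or "first surviving litter" is decided
#' by how the input table was coded; the estimator is agnostic.
#'
#' @param primiparity A validated primiparity table.
#' @param population Optional population label(s).
#' @param B Bootstrap replicates.
#' @return A [boot_dist] (mean age, years).
#' @export
primiparity <- function(primiparity, population = NULL, B = 1000) {
  df <- filter_population(primiparity, population)
  hazard_boot(df, "bear_id", "age", "first_litter", B, "age_of_primiparity")
}

#' Weighted mean interbirth interval
#'
#' The same availability-weighted hazard estimator as [primiparity()],
#' applied to year offsets `t = 1, 2, ...` from an observed birth: the risk
#' set at offset `t` is the set of birth events whose female was still
#' monitored and had no subsequent litter, so partial (censored) intervals
#' inform the estimate and completed short intervals do not dominate.
#'
#' @param interbirth A validated interbirth table.
#' @inheritParams primiparity
#' @return A [boot_dist] (mean interval, years).
#' @export
interbirth_interval <- function(interbirth, population = NULL, B = 1000) {
  df <- filter_population(interbirth, population)
  hazard_boot(df, "bear_id", "offset", "next_litter", B, "interbirth_interval")
}

#' Bootstrap mean litter size
#'
#' Cubs at den emergence per litter: total cubs over total litters, with
#' litter-level resampling for the confidence interval. All litters with an
#' emergence count contribute (monitoring to autumn is not required).
#'
#' @param litters A validated litter table.
#' @inheritParams primiparity
#' @return A [boot_dist] (cubs per litter).
#' @examples
#' set.seed(1)
#' litter_size(bc_bear_litters(), population = "MM") # 21 cubs / 9 litters
#' @export
litter_size <- function(litters, population = NULL, B = 1000) {
  litters <- filter_population(litters, population)
  if (nrow(litters) == 0) abort("no litters with an emergence count")
  sizes <- litters$cubs_emergence
  res <- boot_resample(sizes, mean, B)
  new_boot_dist("litter_size", point = mean(sizes), replicates = res$replicates,
                n = length(sizes), extra = list(redraws = res$redraws))
}
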