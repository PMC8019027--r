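offspring_boot <- function(n, survived, unit, B, statistic, n_label) {
  point <- sum(survived) / sum(n)
  if (unit == "cub") {
    fates <- rep(rep(c(1L, 0L), length(n)),
                 times = as.vector(rbind(survived, n - survived)))
    res <- boot_resample(fates, mean, B)
  } else {
    idx <- seq_along(n)
    res <- boot_resample(idx, function(i) sum(survived[i]) / sum(n[i]), B)
  }
  flags <- character()
  if (all(survived == n)) flags <- "variance-undefined"
  new_boot_dist(statistic, point = point, replicates = res$replicates,
                n = sum(n), flags = flags,
                extra = list(unit = unit, redraws = res$redraws,
                             n_groups = length(n)))
}

#' Bootstrap cub survival
#'
#' First-year cub survival from litter records: the point estimate is total
#' surviving cubs over total monitored cubs; uncertainty comes from
#' resampling with replacement (B replicates, percentile intervals). Litters
#' not monitored to autumn are excluded (censored). The default resampling
#' unit is the individual cub - justified when
#' [litter_independence_test()] finds no litter effect - with whole-litter
#' resampling available for sensitivity analysis.
#'
#' @param litters A validated litter table.
#' @param population Optional population label(s).
#' @param B Bootstrap replicates.
#' @param unit Resampling unit, `"cub"` or `"litter"`.
#' @return A [boot_dist].
#' @examples
#' set.seed(1)
#' cub_survival(bc_bear_litters(), population = "MM")
#' @export
cub_survival <- function(litters, population = NULL, B = 1000,
                         unit = c("cub", "litter")) {
  unit <- match.arg(unit)
  litters <- filter_population(litters, population)
  litters <- litters[litters$monitored_to_autumn, , drop = FALSE]
  if (nrow(litters) == 0 || sum(litters$cubs_emergence) == 0) {
    abort("no monitored cubs: cub survival is undefined")
  }
  offspring_boot(litters$cubs_emergence, litters$cubs_survived, unit, B,
                 "cub_survival", "cubs")
}

#' Bootstrap yearling survival
#'
#' As [cub_survival()], on yearling fate records (`mother_id`, `population`,
#' `year`, `n_yearlings`, `n_survived`). Samples with no mortalities return
#' a point estimate of 1.0 flagged `"variance-undefined"`.
#'
#' @param yearlings Yearling fate table.
#' @inheritParams cub_survival
#' @return A [boot_dist].
#' @export
yearling_survival <- function(yearlings, population = NULL, B = 1000,
                              unit = c("cub", "litter")) {
  unit <- match.arg(unit)
  yearlings <- filter_population(yearlings, population)
  if (nrow(yearlings) == 0 || sum(yearlings$n_yearlings) == 0) {
    abort("no monitored yearlings: yearling survival is undefined")
  }
  offspring_boot(yearlings$n_yearlings, yearlings$n_survived, unit, B,
                 "yearling_survival", "yearlings")
}

#' Test independence of cub fates within litters
#'
#' One-way ANOVA of per-cub binary fate (survived/died) grouped by litter.
#' A large p-value supports resampling at the cub level in
#' [cub_survival()]; strong within-litter clustering of fates (whole litters
#' living or dying together) yields a small p-value.
#'
#' @param litters A validated litter table (monitored litters only are used).
#' @param population Optional population label(s).
#' @return A one-row tibble: `statistic` (F), `df_litter`, `df_resid`,
#'   `p_value`, `n_litters`, `n_cubs`.
#' @export
litter_independence_test <- function(litters, population = NULL) {
  litters <- filter_population(litters, population)
  litters <- litters[litters$monitored_to_autumn, , drop = FALSE]
  if (nrow(litters) < 2 || sum(litters$cubs_emergence >= 2) < 2) {
    abort("need at least two monitored litters with two or more cubs")
  }
  df <- tibble::tibble(
    litter = rep(paste(litters$mother_id, litters$year, sep = ":"),
                 litters$cubs_emergence),
    fate = unlist(purrr::map2(litters$cubs_survived, litters$cubs_emergence,
                              function(s, n) c(rep(1L, s), rep(0L, n - s))))
  )
  fit <- anova(lm(fate ~ litter, data = df))
  f <- fit$`F value`[1]
  p <- fit$`Pr(>F)`[1]
  if (is.nan(f)) { # zero variance everywhere: no evidence of a litter effect
    f <- 0
    p <- 1
  }
  tibble::tibble(
    statistic = f, df_litter = fit$Df[1], df_resid = fit$Df[2],
    p_value = p, n_litters = nrow(litters), n_cubs = nrow(df)
  )
}
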