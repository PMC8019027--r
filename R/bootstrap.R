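#' Bootstrap distribution of a statistic
#'
#' Container for a bootstrapped vital-rate estimate: the plug-in point
#' estimate on the original sample, the replicate values, and percentile
#' (2.5/97.5) confidence limits. Created by the estimator functions; rarely
#' constructed directly.
#'
#' @param statistic Name of the statistic.
#' @param point Plug-in estimate on the original sample.
#' @param replicates Numeric vector of bootstrap replicate values.
#' @param n Size of the original sample (resampling units).
#' @param flags Optional character vector of caveats (e.g.
#'   `"variance-undefined"` when no events were observed).
#' @param extra Optional named list of method-specific extras.
#' @return An object of class `boot_dist`.
#' @name boot_dist
#' @export
new_boot_dist <- function(statistic, point, replicates, n,
                          flags = character(), extra = list()) {
  qs <- quantile(replicates, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  structure(
    list(statistic = statistic, point = point, replicates = replicates,
         ci_low = qs[1], ci_high = qs[2], B = length(replicates), n = n,
         flags = flags, extra = extra),
    class = "boot_dist"
  )
}

#' @export
print.boot_dist <- function(x, ...) {
  cat(sprintf("%s: %.3f (95%% CI %.3f-%.3f), B = %d, n = %d\n",
              x$statistic, x$point, x$ci_low, x$ci_high, x$B, x$n))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
mean.boot_dist <- function(x, ...) mean(x$replicates, ...)

# resample a statistic until it evaluates to a finite value, tallying redraws
boot_resample <- function(units, stat, B, max_factor = 50) {
  reps <- numeric(B)
  b <- 1L
  redraws <- 0L
  while (b <= B) {
    if (redraws > max_factor * B) {
      abort("bootstrap failed: too many degenerate replicates")
    }
    v <- stat(sample(units, length(units), replace = TRUE))
    if (!is.finite(v)) { redraws <- redraws + 1L; next }
    reps[b] <- v
    b <- b + 1L
  }
  list(replicates = reps, redraws = redraws)
}
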