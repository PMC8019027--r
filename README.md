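# bearvitals

Demographic analysis for small, telemetry-monitored brown bear populations —
the regime where a handful of collared females is most of the population, and
where standard capture–recapture machinery has nothing to work with.

Wildlife agencies monitoring threatened bear populations collar adult females,
relocate them by air through the active season, and record three kinds of
data: monthly known-fate encounter histories (each bear's status is known
whenever she is monitored), litter observations (cubs counted at den emergence
and again before denning), and annual reproductive states — alone (A), with
cubs (C), with yearlings (Y), or with 2-year-or-older dependents (T).
`bearvitals` turns those tables into population-level inference:

- **Known-fate survival** of independent females: the product-Bernoulli
  likelihood over monitored intervals, with candidate models S(~1), S(~Pop),
  S(~Age), AICc selection, Akaike-weight model averaging, and a
  staggered-entry Kaplan–Meier companion. Annual survival is the interval
  estimate over the 8-interval year (monthly April–October plus one pooled
  denning interval).
- **Offspring survival** by bootstrap (default B = 1000), with an ANOVA check
  that cub fates are independent of litter membership.
- **Reproductive timing** by availability-weighted discrete hazards: mean age
  of primiparity and mean interbirth interval, estimated without the bias
  toward early maturers and short intervals that raw means suffer under
  collar loss. P(event at t) = h_t ∏<sub>t'&lt;t</sub>(1 − h<sub>t'</sub>).
- **A 4-state reproductive Markov chain**: multinomial transition estimates
  over the ten biologically possible transitions, iterated from (1,0,0,0) to
  the stationary state distribution π; the mean reproductive rate is
  m = 0.5 × litter size × π<sub>C</sub>.
- **Leslie-matrix projection**: a 25-age-class matrix (survival subdiagonal,
  fecundities m for ages 6–24) whose dominant eigenvalue λ is cross-checked
  against the Euler–Lotka root ∑ λ^−(x+1) l(x) m<sub>x</sub> = 1; R0,
  generation time, stable age and stable stage structure (via Caswell's
  conditional stage-transition rates), and Monte Carlo propagation of
  bootstrap uncertainty into λ.
- **An individual-based simulator** of the whole observation process
  (staggered captures, collar drop, per-relocation detection, 8-week
  censoring) with known true rates, so every estimator is testable by
  parameter recovery.

Everything takes a data frame and returns a tibble; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

The package ships reconstructed monitoring tables for two adjacent study
populations in southwestern British Columbia — the McGillvary Mountains (MM,
~45 bears, connected) and the North Stein-Nahatlatch (NSN, <25 bears,
isolated) — rebuilt in code from published summary totals (see
`?bc_bear_data` for what is exact and what is filled consistently).

```r
library(bearvitals)
set.seed(42)

lit <- bc_bear_litters()
litter_size(lit, "MM")
#> litter_size: 2.333 (95% CI 1.889-2.778), B = 1000, n = 9
cub_survival(lit, "NSN")
#> cub_survival: 0.333 (95% CI 0.000-0.667), B = 1000, n = 9
litter_independence_test(lit)$p_value
#> [1] 0.0887  # no evidence cub fates cluster by litter: resample cubs

stable_state(bc_bear_transition_matrix("MM"))
#> Stable reproductive-state distribution (57 iterations):
#>      A      C      Y      T
#> 0.3992 0.2003 0.2003 0.2003
reproductive_rate(2.333, 0.2003)
#> [1] 0.2336  # female cubs per adult female per year

growth_rate(build_leslie(bc_bear_vital_rates("MM")))
#> [1] 1.093  # growing ~9%/yr
growth_rate(build_leslie(bc_bear_vital_rates("NSN")))
#> [1] 0.854  # declining ~15%/yr
```

So 2.33 cubs per litter with a fifth of adult females holding cubs yields
0.23 female cubs per female-year; fed into the Leslie matrix with each
population's survival schedule, the connected population grows (λ ≈ 1.09)
while the small isolated one declines steeply (λ ≈ 0.85) — the survival gap,
not reproduction, separates them.

The same machinery runs on simulated data with known truth:

```r
sim <- simulate_population(scenario_study(rng_seed = 1))
models <- lapply(c("population", "null", "age"),
                 function(m) fit_known_fate(sim$encounters, m))
aicc_table(models)
#> # A tibble: 3 × 6
#>   model       k loglik  AICc delta  weight
#> 1 S(~Pop)     2  -22.0  48.0   0   0.993
#> 2 S(~1)       1  -28.3  58.7  10.7 0.00474
#> 3 S(~Age)     2  -27.9  59.8  11.8 0.00270
model_average(models, sim$encounters)
#> 1 MM  adult/subadult  1.000 (0.961-1.00)   # truth 1.00
#> 2 NSN adult/subadult  0.765 (0.529-0.895)  # truth 0.81
```

`run_pipeline(list(scenario = scenario_study(rng_seed = 1), seed = 1))` runs
every stage end to end and returns (optionally writes) a report of all
estimates with CIs and sample sizes.

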