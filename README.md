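# remdyn

Relational event models (REMs) for continuous-time social interaction data.

Many studies now record *who* interacted with *whom*, *when*, for *how
long*, and in *which setting* — smartphone experience sampling of student
cohorts, proximity sensors, communication logs. `remdyn` estimates
continuous-time models of such relational event histories: which factors
(actor traits, demographic similarity, interaction history, calendar
context, setting) drive the rate at which each pair of actors starts their
next interaction, how those drivers change over time, and how well the
fitted model predicts who interacts next. It is aimed at researchers in
social and personality psychology, network science and epidemiological
modelling who work with timestamped dyadic or group interaction records.

## The model

At any time *t*, the risk set R(t) holds every candidate event — all
N(N−1)/2 unordered actor pairs (s, r), optionally crossed with event types
*c*. Each candidate has a log-linear rate

```
log λ(s, r, c, t) = Σ_p β_p x_p(s, r, c, t)
```

where the statistics x_p are exogenous (baseline, gender/age similarity
indicators, pair minimum/maximum of standardized traits, weekend and
group-context indicators, setting dummies) or endogenous functions of the
past history:

* **inertia** — Σ over past events of the dyad of `ln(d_e) / (|A_e| − 1)`,
  weighting each past interaction by its log duration and down-weighting
  interactions that happened inside large groups;
* **shared partners** — the number of distinct third actors both members
  interacted with before *t*;
* setting-specific variants of both, restricted to past events of the
  entry's own type.

Endogenous statistics are standardized per time point over the risk set.
Under a piecewise-constant hazard, the waiting time to the next event is
exponential with rate Σ_{R(t)} λ, and the observed event is drawn with
probability proportional to its rate. `remdyn` maximizes either the full
likelihood (exact waiting times) or the ordinal likelihood (event order
only) by Newton–Raphson with analytic derivatives, and reports standard
errors, BIC and a top-5% predictive hit rate (with a best-ranked-dyad
refinement for group events). Group interactions are handled by splitting
them into their constituent dyads, evenly spaced inside the following
minute, with statistics evaluated at the pre-spacing minute; a group
indicator plus the log event-count expansion factor separates the
mechanical rate inflation from the real tendency to interact in groups. A
moving-window mode refits the model in overlapping time slices to trace
time-varying coefficients, and a generative simulator produces synthetic
histories from any configured model.

## Worked example

Simulate a small 12-actor cohort for one week from a known model, split
group interactions, build the design and refit:

```r
library(remdyn)

actors <- tibble::tibble(
  actor_id  = sprintf("s%02d", 1:12),
  gender    = rep(c("female", "male"), c(9, 3)),
  age       = c(rep(20, 10), 26, 27),
  age_group = ifelse(age <= 24, "young", "older"),
  extraversion = as.vector(scale(rnorm(12)))
)
specs <- effects(
  effect_baseline(),
  effect_trait_extreme("extraversion", "min"),
  effect_inertia()
)
sim <- simulate_rem(sim_config(
  actors, specs,
  beta = c(baseline = -6, extraversion.min = 0.25, inertia = 0.3),
  t_max = 7 * 1440, seed = 2024,
  group_size_probs = c("2" = 0.7, "3" = 0.3)
))
split <- split_group_events(sim$events, seed = 1)
split$report
#> # A tibble: 1 × 3
#>   n_raw_events n_dyadic_events expansion_log_factor
#>          <int>           <int>                <dbl>
#> 1         1503            2397                0.467

rs  <- build_risk_set(actors)
d   <- build_design(split$events, rs, actors, specs)
fit <- fit_rem(d, kind = "full")
tidy(fit)
#> # A tibble: 3 × 6
#>   term             estimate std.error statistic  p.value rate.multiplier
#>   <chr>               <dbl>     <dbl>     <dbl>    <dbl>           <dbl>
#> 1 baseline           -5.54     0.0270   -205.   0                0.00392
#> 2 extraversion.min    0.220    0.0340      6.46 1.03e-10         1.25
#> 3 inertia             0.188    0.0205      9.20 3.56e-20         1.21

glance(fit)
#> # A tibble: 1 × 7
#>    logLik    BIC  nobs  npar likelihood converged iterations
#>     <dbl>  <dbl> <int> <int> <chr>      <lgl>          <dbl>
#> 1 -15771. 31566.  2397     3 full       TRUE              11

top_share_hit_rate(fit$coefficients, d, share = 0.05, seed = 3)
#> <rem_gof> top-5% hit rate: 16.8% over 1503 original events
```

Reading the output: the 1503 raw interactions became 2397 dyadic events
after group splitting (log expansion factor 0.467). The recovered
coefficients sit near the generating values (−6, 0.25, 0.3; the baseline
absorbs the splitting inflation of about 0.47, −6 + 0.47 ≈ −5.5). The
rate multipliers say a pair whose *less* extraverted member is one
standard deviation more extraverted starts interactions at 1.25 times the
rate, and a pair one standard deviation more intense in past interaction
at 1.21 times. The fitted model places at least one dyad of the observed
interaction inside the top 5% of 66 predicted rates for 16.8% of events —
well above the ~6% a rate-constant model would achieve here (a top set of
ceiling(0.05 × 66) = 4 of 66 dyads, slightly more for group events).

`fit_moving_window()` + `autoplot()` trace coefficients over sliding
windows; `read_run_config()` with `cmd_fit()` / `cmd_fit_windows()` /
`cmd_simulate()` drive whole runs from a YAML file, and
`inst/cli/remdyn.R` exposes those as shell subcommands.

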