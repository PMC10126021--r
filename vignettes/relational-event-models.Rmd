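---
title: "Relational event models in remdyn: model, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relational event models in remdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remdyn)
```

## The model

A relational event history is a time-ordered sequence of interactions
among a fixed set of actors: each event records its onset (minutes since
the start of observation), the set of participants, optionally a setting
label (here: leisure versus study-related), and a duration. `remdyn`
models such histories with an undirected relational event model (REM):
at every instant each candidate event — each unordered pair of actors,
optionally crossed with an event type — carries a rate

$$\log \lambda(s, r, c, t) = \sum_p \beta_p\, x_p(s, r, c, t),$$

and under the piecewise-constant-hazard assumption (rates change only when
an event occurs) the waiting time to the next event is exponential with
rate $\sum_{\mathcal R(t)} \lambda$, while the identity of the next event
is multinomial with probabilities $\lambda / \sum \lambda$. The product of
these two factors over the observed sequence is the **full likelihood**;
dropping the waiting-time factor (using only the order of events) gives
the **ordinal likelihood**, a sequence of conditional multinomial choice
probabilities. Both are implemented in `loglik()` exactly as written
above; the full-likelihood form follows from the exponential density and
the piecewise-constant hazard, and a unit test verifies the ordinal form
against brute-force enumeration of the choice probabilities on small risk
sets. The ordinal likelihood cannot identify an intercept (the choice
probabilities are invariant to a constant shift), so baseline effects
belong only in full-likelihood fits.

Two assumptions deserve emphasis. First, conditioning on the history
renders events independent, so everything the past contributes must enter
through the endogenous statistics; mis-specified statistics are
confounding, not noise. Second, the risk set must contain every event
that *could* have occurred. By default every pair is always at risk;
interval-based availability per actor (`availability` list-column) trims
the active risk set when that is wrong.

## Statistics

Exogenous effects: a baseline (all ones; the intercept on the log-rate
scale), pair similarity indicators for categorical attributes (e.g.
`both.male` and `mixed.gender`, with the majority pair — both female,
both young — as reference), pair minimum and maximum of standardized
trait scores (`extraversion.min` tells how extraverted the *least*
extraverted member is), a weekend indicator (constant over the risk set,
driven by a configured start weekday; weekends are Saturday and Sunday),
a group-context indicator (1 when the observed event came from a group
interaction), and type dummies on typed risk sets.

Endogenous effects summarize the history strictly before the evaluation
time. Inertia weights every past event of the dyad by
$\ln(d_e)/(|A_e| - 1)$: long interactions predict repetition better than
short ones, and meeting inside a large group is a weaker tie than meeting
alone (an unweighted variant, weight 1 per event, is available via
`effect_inertia(weighted = FALSE)` for comparison). Shared partners
counts *distinct* third actors both members interacted with — distinct,
because the statistic is meant to capture the social circle, not its
volume, and the defining phrase "the number of students h" reads as a
count of actors. The setting-specific variants restrict the history to
past events of the entry's own type; by construction they sum (inertia)
or are bounded by (shared partners) their untyped counterparts, which the
tests exploit as partition identities.

Count-type endogenous statistics grow with the history and would make
coefficients incomparable across time, so they are standardized **per
time point** over the (active) risk set: $(x - \bar x)/\mathrm{SD}(x)$.
Two choices the formula leaves open: we use the sample SD (n − 1), and a
degenerate (constant) vector maps to all zeros rather than NaN so the
first events of a history remain usable. Exogenous indicators and traits
are never rescaled per event; traits arrive standardized across actors
(mean imputation of missing scores first, then z-scoring — in that
order).

Interactions are elementwise products of two previously defined columns;
endogenous components enter already scaled and the product is not
re-standardized, mirroring ordinary regression practice.

## Group events and spacing

Group interactions are decomposed into all constituent dyads. Because no
two events may share a timestamp, the $M = m(m-1)/2$ dyadic events of a
group observed at minute $t$ are placed at $t + k/(M+1)$, $k = 1..M$, in
seeded random order — evenly spaced and strictly inside $(t, t+1)$, so
they can never collide with the next integer minute. The spacing is an
estimation device only: every split event carries the pre-spacing onset
as its `stat_time`, all statistics are evaluated there, all members of a
group share one statistic block, and no constituent feeds back into its
own group's statistics. The induced extra events inflate the baseline
rate mechanically; the `group` indicator absorbs this, and
`net_group_effect()` subtracts the log expansion factor
$\ln(n_\text{dyadic}/n_\text{raw})$ to recover the substantive tendency
to interact in groups. Raw events that share an onset minute without
being one group keep their input-file order (a documented tie-break; the
history for each is everything strictly before its own minute).

Durations of 1 minute or less are rejected at ingest: the log-duration
weight would be non-positive, and the data model targets interactions of
5+ minutes.

## Estimation

Both likelihoods are globally concave in $\beta$ (sums of linear terms
and negated convex functions), so `fit_rem()` uses Newton–Raphson with
the analytic gradient and Hessian, step-halving on non-improving steps, a
deterministic start at zero, convergence at gradient max-norm below 1e-8,
and at most 200 iterations. The Hessian is needed for the observed-
information standard errors anyway, which makes full Newton both cheaper
and more deterministic than quasi-Newton alternatives; a finite-
difference check of gradient and Hessian is part of the test suite, and
the baseline-only model is verified against its closed form
$\hat\beta = \ln(M/(R\,T))$. Collinear design columns are rejected by
name before fitting. Wald p-values are two-sided with significance
conventionally read at 0.05; no multiplicity correction is applied. BIC
is $-2\ell + p\ln M$ with $M$ the number of *split* dyadic events — the
unit the likelihood runs over.

## Moving windows

To let coefficients vary over time, a window of fixed length slides over
the sequence in fixed steps; the same model is refitted on the events of
each window and the per-window estimates form a trajectory (three-day
windows stepping one day — two days of overlap — are a good default for
multi-week histories: smooth enough to read, local enough to show daily
structure). Two boundary decisions: endogenous statistics inside a window
see only the window's own history (`window_start`), consistent with the
idea that a window isolates the recent process; and the waiting time of a
window's first event is measured from the window start, which keeps the
within-window baseline interpretable. With a single window covering the
whole span both choices reduce to the global fit exactly — a property the
tests assert to 1e-10. A weekend effect is redundant in this mode (the
trajectory itself shows any weekly rhythm) and triggers a warning.
Windows below a minimum event count (default 100) are skipped: with fewer
events per window the per-window Hessian gets ill-conditioned and the
trajectory noise swamps any signal.

## Goodness of fit

`top_share_hit_rate()` asks: in what share of observed events was the
observed dyad among the top 5% of candidates by predicted rate? For an
event that came from a group interaction, the *best-ranked* constituent
dyad decides (predicting any member pair of the group counts). The top
set holds $k = \lceil \text{share} \cdot |\mathcal R|\rceil$ entries —
ceiling so the set is never empty — and rate ties are broken by a seeded
random permutation, which makes the metric well defined for rate-constant
models: on purely dyadic data a baseline-only model hits with probability
exactly $k/R$. Note the discreteness: at $R = 45$ and share 0.05,
$k/R = 3/45 \approx 6.7\%$, not 5%; calibration checks in the tests use
$R = 120$ where $k/R$ is exactly the nominal share. The metric depends
only on rate ranks, so it is invariant to any strictly increasing
transform of the rates, and it is monotone in the share — both are
property-tested.

## The simulator

`simulate_rem()` runs the generative counterpart of the model: competing
exponential clocks over the risk set, with rates recomputed after every
event from the *same* statistic code the estimator uses (one
implementation, no oracle drift). The REM governs the dyad (and type)
choice and the waiting time; everything else is drawn from configured
exogenous mechanisms — durations from a clamped log-normal, group sizes
from a configured distribution (extra members sampled uniformly around
the chosen dyad), untyped settings from a (possibly time-varying)
probability. Two deliberate approximations: time-varying exogenous
statistics (the weekend flag) are held at their value at the start of
each inter-event interval, consistent with the piecewise-constant hazard
but slightly blurring rates across midnight boundaries; and the `group`
context indicator cannot be a generative covariate (it describes the
observed event, which does not exist before it is drawn), so
`sim_config()` rejects it.

One instability is worth knowing about. A *per-event-standardized*
endogenous statistic is a fine estimation covariate but a dangerous
generative one on large risk sets: when only one of $R$ entries has
history, its z-score is roughly $\sqrt R$ (about 88 at $R = 7875$), so
even a modest positive coefficient multiplies that entry's rate
astronomically and the simulation collapses into a self-exciting cascade
on one dyad. At small $R$ (a few hundred entries) the bound $\sqrt{R-1}$
keeps moderate coefficients stable — the parameter-recovery experiments
run safely at $R = 190$ with an inertia coefficient of 0.3 — but the
synthetic cohort generator below deliberately uses a purely exogenous
truth.

`generate_connect_like()` produces a synthetic stand-in for a freshman
interaction cohort with the following fixed conditions: 126 actors (101
female / 25 male; 103 aged ≤ 24 / 23 older, ages drawn inside each band),
standardized extraversion and agreeableness generated from the reported
raw-score moments (means 5.1 / 5.0, SDs 1.1 / 0.8); 23 days of events;
durations log-normal with median 30 minutes and log-SD 1.06 (chosen so
~97.5% fall below 240 minutes), clamped to [5, 1805] and rounded to whole
minutes; group sizes 2–10 with P(2) = 0.64 and P(≤3) = 0.81 (and
P(≤8) = 0.975); two settings with study-related interaction more likely
on weekdays (0.55) than weekends (0.20); true model baseline −11.26
(calibrated so the 23-day volume lands near 2900 raw events) and weekend
−0.78. Onsets are rounded to whole minutes to match the shape of app-
reported data. What this generator does *not* emulate: real histories
have endogenous clustering (inertia, closure), circadian structure within
days, and actor-level activity heterogeneity. Tests passing on this
synthetic data therefore validate the *machinery* — combinatorics,
likelihoods, recovery, calibration — not any substantive claim about real
interaction dynamics.

## Problem sizes used in the test suite

The simulation-based checks run at deliberately modest sizes chosen to
make the statistical assertions sharp rather than to mimic a full study:
parameter recovery uses 50 replicate histories of ~470 events among 20
actors (and 50 more at a doubled horizon to verify the RMSE shrinks),
with truth (baseline −8, inertia 0.3, trait-minimum 0.2) and acceptance
bands of three Monte-Carlo standard errors; gof calibration uses ~450
dyadic events among 16 actors; the moving-window shift experiment
concatenates two 2-day segments (inertia 0 then 0.4) among 15 actors and
requires at least half the true shift to appear between the early and
late window means. Window unit tests run on a 6-day, ~270-event history
among 8 actors.

## Known limitations

* Undirected events only; sender/receiver statistics (reciprocity,
  degrees) are out of scope, though the risk-set entry structure does not
  preclude adding them.
* No memory decay: all in-window (or all, globally) past events weigh
  equally apart from the duration/group-size weight; the moving window is
  the package's instrument for recency.
* The group-splitting device assumes every group member treats every
  other member as a potential partner while the group lasts — reasonable
  for small groups (the targeted data are ~81% pairs and triads), not for
  large externally structured gatherings.
* In-sample gof: the hit rate is computed on the fitted sequence by
  default; pass a held-out design for out-of-sample evaluation.
* Hypothesis-free window trajectories invite overinterpretation;
  per-window confidence bands are Wald and ignore between-window
  dependence from overlapping data.
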