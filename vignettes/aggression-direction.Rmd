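---
title: "Modelling the direction of female aggression along dominance hierarchies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the direction of female aggression along dominance hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggdir)
```

`aggdir` implements a complete analysis of *aggression direction* in
female dominance hierarchies: not how often females aggress, but whether
aggression is aimed at more or less powerful rivals, and what shifts that
aim. This vignette is the package's own account of the method — the model
and its assumptions, the tunable parameters, the synthetic-data generator
and what it does and does not emulate, the numerical conventions, and the
known limitations.

## 1. From submission events to daily ranks

Power relationships are inferred from ritualized submission signals —
decided avoidance (one female walks away from an approaching groupmate)
and displacement (she yields her spot) — rather than from aggression,
because submission is the more reliable proxy of an established
relationship. The rating engine is a sequential Elo system:

* every female present at the study onset starts at 1000 points;
* a female entering the hierarchy later (maturing into adulthood or
  immigrating) starts at the *minimum* score held by the group's females
  on her entrance day, computed before any of that day's updates — the
  biologically sensible prior that newcomers start at the bottom, and the
  only reading of "the entrance day's minimum" that is not circular;
* after each event both scores move by `(1 − p) · k` points, where `p` is
  the winner's expected winning probability before the event. `k = 100`
  for every submission event (all carry equal weight). The default
  probability curve is the probit `pnorm((r_w − r_l) / (200 * sqrt(2)))`,
  the convention of the standard sequential-rating routine for animal
  dominance data; the chess-style logistic `1 / (1 + 10^(−Δ/400))` is
  selectable (`elo_config(win_prob = "logistic")`). Total points are
  conserved by construction.

Scores carry forward unchanged between interaction days, and each
group-day is standardized to `[0, 1]` by min–max over **all** adult
females present that day, interacted or not (a score must exist for every
aggression participant, so the standardization population cannot be
restricted to prior interactants; restricting it is not supported).
Degenerate group-days are explicit: a lone female has no within-group
standing (`NA`, and aggression on such days is excluded downstream with a
logged count); a day on which all present females hold the same raw score
maps everyone to 0.5.

Two conventions deserve emphasis because the data do not determine them:

* **Within-day order.** Field logs carry no timestamps, so same-day
  submission events are processed in file order. Sequence-dependent
  results therefore depend on the within-day row order of the input — a
  deliberate, documented sensitivity rather than a hidden one.
* **Which daily state an aggression event sees.** Aggression on day *d*
  is scored against the end-of-day ratings of *d* (after all of that
  day's submission updates); `elo_config(timing = "start_of_day")`
  records the alternative preference. Daily scores are the finest
  resolution the method defines; sub-daily timing is unknowable.

### Study-level standings and the jitter problem

A single day's Elo snapshot is jolted by up to `k` points per event, so
with `k = 100` the *ordering* of close neighbours flips back and forth
even when the underlying hierarchy is perfectly stable. Any question
about "the" hierarchy of a study period is therefore answered by
time-averaging: `elo_ranking()` orders females by their mean score over
the trailing half of the rated span (individuals who left earlier are
averaged over the trailing half of their own tenure), and
`score_events(reference = "rolling")` scores an event against each
participant's mean standardized score over ±180 days around the event.
The rolling reference is used for the submission-direction summary (what
fraction of submission events ran *against* the hierarchy), for two
reasons: a submission event moves the very rating that would otherwise
classify it (the same-day reference systematically under-counts
reversals), and a whole-study average can straddle group-composition
changes for females with partial tenure. In simulation the rolling
reference recovers the generator's true reversal rate to within about a
percentage point, while the same-day and previous-day references miss it
by several.

## 2. The interaction score

Each aggressive interaction between two adult females of a group gets

```
score = standardized Elo(recipient) − standardized Elo(aggressor)
```

so `score ∈ [−1, 1]`, +1 exactly when the group's lowest-ranking female
attacks the highest-ranking one, and positive values are aggression up
the hierarchy. Aggressive behaviours are classified by a three-level
ethogram — mild (vocal threats, pull vegetation), moderate (chest-beat,
strut displays, charges, push), severe (contact aggression: hit, bite,
chase, fight…) — carried by an overridable `ethogram()` object so
field-site naming variants can be absorbed in configuration. Exact ties
(`score == 0`, possible only when two females share a raw score) are
reported as their own category in `direction_summary()` rather than
folded into either direction; they are measure-zero once ratings have
separated. The across-group summary is the *unweighted* mean (± SD) of
group percentages, so small groups are not swamped by large ones.

Exclusions are never silent: events whose participants are not rated
adult females of the group that day, events on degenerate group-days,
and events whose aggressor's reproductive state is unknown are tallied
by reason in `attr(scored, "exclusions")` and reported in a message.

## 3. Daily reproductive state

States come from longitudinal demography with a strict precedence:

1. **Pregnant** on any day followed by a parturition in 1–255 days.
   Counting pregnancy day `p = 256 − (days until birth)`, the trimester
   bins are the closed, non-overlapping `[1, 85]`, `[86, 170]`,
   `[171, 255]` (printed trimester bounds are often ambiguous at the
   joints; 85-day bins with deterministic assignment resolve them). The
   day before birth is pregnancy day 255; the parturition day itself is
   the first lactation day.
2. Else **cycling** when a mating has been observed on or before the day
   and after her last parturition. For nulliparous females "since her
   last parturition" is undefined; the rule becomes "since reaching adult
   age" — an assumption, stated here.
3. Else **lactating** while she has a dependent infant: the day is not
   after the last nipple-contact record of her most recent offspring.
   Whether dependence should require additional survival or weaning
   criteria is not resolvable from nipple-contact records alone;
   last-nipple-contact is used as the operational rule.
4. Else **unknown** — there is no residual category in the biology, so
   unknown female-days are excluded from modelling with a logged count.

Adulthood is strict (`age > threshold`), with species-specific
thresholds: females > 10 y (western) / > 8 y (mountain), males > 14 y /
> 12 y. The same thresholds drive the daily group-composition counts
(`n_males`, `n_females`) used as model covariates.

## 4. The direction model

`direction_model()` fits the interaction score on intensity (reference
mild), number of adult males, number of adult females, reproductive state
(reference cycling), and species (reference mountain), with four
*crossed* random intercepts: aggressor identity, recipient identity,
unordered dyad, and group — the standard structure for directed dyadic
data with repeated measures ("identities of interacting females" are two
crossed terms, not one).

A bounded response with a "logit" mean structure admits several
formalizations, and the choice is surfaced as the `family` argument
rather than hidden:

* `beta_logit` (default): map the score to `(0, 1)` by `y' = (y + 1)/2`,
  squeeze off the boundaries with `y'' = (y'(n − 1) + 0.5)/n`
  (the standard compression for boundary-valued proportions), and fit a
  beta family with logit link. Estimates are reported on the logit scale
  and every output labels its scale.
* `linear_logit`: Gaussian mixed model on `qlogis(y'')`.
* `linear`: Gaussian mixed model on the raw score; estimates are directly
  in score units, convenient for simulation studies and effect-size
  reasoning.

Estimation is maximum likelihood (Laplace approximation, `glmmTMB`) and
deterministic given data and specification. Numerical conventions:

* Non-convergence is an explicit error carrying the optimizer
  diagnostics, never a silent partial result.
* A variance component that collapses onto the zero boundary can leave
  the Hessian uninvertible; the fit then pins that component at exactly
  zero by refitting without it, with a warning. Components estimated at
  (but not breaking) the boundary warn and stay.
* 95% intervals are the conventional Wald `estimate ± 1.96 · SE` on the
  reported scale; profile intervals are out of scope.
* Categorical fixed effects observed at a single level (e.g. species in a
  one-species dataset) are dropped with a warning.

**Inference machinery.** `type2_wald_tests()` computes, per fixed term,
the joint Wald chi-square of all its coefficients (with no interactions
in the model this *is* the Type-II test; it matches `car::Anova` to
numerical precision in the test suite). `tukey_contrasts()` computes all
pairwise differences among reproductive states with single-step adjusted
p-values `p_i = P(max_j |Z_j| ≥ |z_i|)` under the joint normal of the
contrast statistics, estimated by Monte Carlo (default 100,000 draws,
fixed seed, ~1e-3 resolution, bit-for-bit reproducible) and clamped into
the analytic envelope `[p_raw, min(1, m · p_raw)]`; a degenerate contrast
covariance falls back to Bonferroni with a warning. `vif_terms()` reports
Fox–Monette generalized variance-inflation factors with the
`GVIF^(1/(2 df))` normalization. `predict_effects()` gives
population-level predictions on the score scale along one covariate with
delta-style confidence bands transformed through the monotone inverse
link.

**Residual diagnostics.** `residual_diagnostics()` ranks each observation
among `n_sim` responses simulated from the fitted model (ties
randomized), giving PIT residuals that are marginally uniform when the
model is adequate; uniformity is tested by Kolmogorov–Smirnov and
dispersion by the ratio of observed to simulated residual variance with a
two-sided Monte Carlo p-value. Fewer than 50 simulations are refused as
unstable. One caveat is inherent to the method: the simulations redraw
the random effects, so residuals are correlated within identity clusters
and the KS uniformity test is anti-conservative under strong crossed
random effects — in the package's own null calibration the dispersion
test holds its nominal level while KS over-rejects. Read the uniformity
p-value jointly with the dispersion test and the residual plot, not as a
standalone gatekeeper.

## 5. The synthetic-data generator

`simulation_scenario()` + `simulate_study()` produce a complete study
bundle — interaction log, demography, and ground truth (daily states,
realized scores, the latent hierarchy) — whose tables pass the package's
own validators, so every pipeline stage is testable without field data.

**What the default scenario emulates.** Five groups (one western, four
mountain) of 6–9 females observed for three years; stable latent
hierarchies with newcomers entering at the bottom; submission events at
0.05 per dyad-day (~55 per dyad over the study — enough to resolve the
hierarchy, matching the observed stability) directed down the latent
hierarchy except with probability `epsilon = 0.16`, the observed
share of reversed submissions; aggression at ~6,900 events with the
published intensity mix; reproductive cycles (cycling 60–300 d, gestation
255 d, lactation 550–950 d) whose demography records reproduce the
intended state sequence *exactly* under `classify_state()` (a mating
opens every cycling phase; the last nipple contact falls on the final
lactation day — idealizations that make the classifier–generator closure
exact); male counts changing 2–5 times per study; and female churn (two
maturing entrants, two departures, one transient immigrant per group)
that reproduces the within-group variability of daily female counts seen
in multi-year field records.

**Score mechanism.** Each aggression event draws a target score from the
linear model `μ = β·x` (published effect sizes as the default truth) plus
Gaussian noise (`sigma = 0.30`), then attacks the present female whose
realized rank difference is nearest the target — guaranteeing attainable
scores in small groups. The intercept (−0.168) and `sigma` are generator
design constants calibrated once by simulation so that the pooled
up-hierarchy fraction of the default scenario sits at ~42%; with the
frozen defaults the across-seed means are ~42 ± 1% up-hierarchy
aggression and ~16 ± 0.7% up-hierarchy submissions at ~6,900 events.

**An identification limit worth knowing.** Under that selection
mechanism the realized score is a property of the *pair* (it equals the
chosen recipient's rank difference), so covariate effects live entirely
in *which dyads are used*, not in outcomes conditional on a dyad. A model
with crossed identity random intercepts absorbs exactly that between-dyad
variation: fixed effects estimated from selection-generated scores are
attenuated toward zero and can even flip sign — not an implementation
artefact but a structural consequence of rank-difference responses under
perfectly stable hierarchies (real data escape it to the degree that
standings drift over years). Estimator validation therefore uses
`simulate_scores()`: responses drawn from the direction model's *own*
generative process (linear predictor + independent random intercepts +
noise, clamped to `[−1, 1]`) on the realistic covariate structure of a
bundle — the canonical parameter-recovery design. With the published
effect sizes as truth at n ≈ 7,000, the test suite recovers all seven
focal coefficient signs in ≥ 18 of 20 seeded replicates and holds the
per-term Wald type-I error at 5 ± 3% under a null generator.

**What passing tests do and do not show.** Closure of the generator and
pipeline demonstrates internal consistency — the classifier inverts the
generator's demography, the scorer reproduces its scores exactly, the
direction statistics land on their targets — and the recovery study
demonstrates that the estimator works on data that satisfy its
assumptions. None of this certifies the model against real field data,
where hierarchies drift, observation effort varies, states are
misrecorded, and the selection-vs-outcome distinction above is a live
scientific question.

## 6. Problem sizes and reproducibility

All randomness flows from explicit seeds (`simulation_scenario(seed=)`,
`tukey_contrasts(seed=)`, `residual_diagnostics(seed=)`,
`pipeline_config(seed=)`); reruns with identical configuration produce
identical artifacts, and Monte Carlo p-values are reproducible
bit-for-bit given `(seed, mc_draws)`. The shipped validation suite runs
at deliberate desk scale: 1,000 random sequences for the Elo-engine
oracle, 100 seeded runs for hierarchy recovery, five bundles (~35,000
events) for the direction-statistic closure, 20 full-size replicates for
sign recovery, and 100 reduced replicates (~1,300 events each, two
groups) for type-I calibration — sizes chosen to give stable Monte Carlo
estimates of each property.

## 7. Known limitations

* Latent ranks are fixed for a study span; rank dynamics (real take-overs,
  rank reversals over years) are a non-goal of the generator.
* Aggression *rates* are out of scope by design: direction is independent
  of observation effort, rates are not, and no effort data are modelled.
* The submission-reversal summary depends on the reference standings
  (same-day, previous-day, rolling, study-level); the package defaults to
  the rolling reference and exposes the rest rather than pretending the
  choice does not matter.
* Only two species labels and their adult-age thresholds are built in;
  other taxa need explicit `age_thresholds()`.
* The beta family models a squeezed response; its coefficients are on the
  logit scale and not numerically identical to score-scale effects (the
  `linear` family is provided for that reading).
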