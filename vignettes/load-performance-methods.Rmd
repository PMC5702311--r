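---
title: "Training-load metrics and dose-response modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-load metrics and dose-response modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loadperf)
```

This vignette documents the statistical model behind `loadperf`, the
conventions and tunable parameters that matter, what the synthetic season
generator does and does not emulate, and the design decisions taken where
the problem was genuinely open.

## The monitoring problem

In-season Australian football weeks follow a fixed rhythm: two main
"on-legs" field sessions, two recovery sessions and one match, with a
12-item wellness diary (1–10 Likert items) collected post-match. External
load (GPS) and internal response (wellness) carry complementary
information, and a single combined score is easier to periodise against
than eight separate series. The weekly **global load** is the weighted sum
implemented in `global_load()`; the weights (see `load_weights()`) express
performance-staff judgement about how fatiguing each input is — e.g. a
metre of match high-velocity running (1/10) counts double a training one
(1/20), and each high deceleration (20) twice a high acceleration (10).
One point of note: the wellness total enters positively (×3), so feeling
*better* raises "load". The score is kept exactly as specified rather than
sign-corrected; users who want wellness as a penalty can pass a negative
weight.

## Derivative measures and their conventions

All derivative measures operate per player on a contiguous weekly grid
(missing weeks are explicit `NA` gaps).

**Smoothed load.** `S_w = λ·L_{w−1} + (1−λ)·S_{w−1}`. Two conventions need
fixing:

* *Time constant.* We use `1/λ` weeks — λ ∈ {0.67, 0.5, 0.33, 0.25} ↦
  {1.5, 2, 3, 4} weeks — rather than the `(2−λ)/λ` convention used
  elsewhere in the EWMA literature, because the smoothed load over `1/λ`
  weeks tracks the simple cumulative load of a similar period most
  closely. A common reading of this convention is that one time constant
  "contains about two-thirds of the total weighting". That is exact only
  in the small-λ limit (1 − e⁻¹ ≈ 0.63) and at λ = 0.25
  (`ewma_weight_fraction(0.25)` = 0.684); at λ = 0.67 the first
  ⌈1/λ⌉ = 2 kernel weights already carry 0.891 of the total. The package
  exposes the exact fraction rather than asserting the folklore value.
* *Alignment (predictor lag).* As a predictor of week-w performance the
  default smoothed value uses loads only through week w−1 (the literal
  recurrence above, `predictor_lag = 1`), so the predictor never contains
  the week being predicted. The differential load defaults to
  `predictor_lag = 0` because its defining quantity is "the change between
  the current and previous week". Both alignments are available on both
  measures via the `predictor_lag` argument.

**Initialization.** The recurrence is seeded with the first observed value
(`first_value`): at lag 1 the first defined smoothed value is `S_2 = L_1`.
This keeps early-season weeks usable; the alternative `burn_in` policy
discards the first ⌈1/λ⌉ weeks of each run for users who prefer
transient-free series. Differential load seeds with the first observed
change.

**Gaps.** A missing week (bye, injury) breaks the recurrence, which
restarts with re-initialization after the gap. We deliberately do not
impute load across gaps: fabricating load during an injury week would bias
exactly the weeks where monitoring matters most.

**Monotony and strain** use the trailing 3-week window of *weekly* loads
(not the traditional daily grain): monotony = mean/SD with the sample
(n−1) SD — with 3-point windows a population SD would inflate monotony by
√(3/2) — and strain = monotony × mean. Zero-SD windows are flagged `NA`
rather than infinite so downstream models skip them. **Acute:chronic**
uses the coupled convention: the 4-week chronic mean includes the current
week, so a constant series gives exactly 1.

**Within-player SD**, the unit of "1 SD" training changes, is the
df-weighted root-mean-square of the players' own SDs
(`within_player_sd()`), not the SD of the pooled player-weeks, which would
mix between- and within-player variation.

## The dose-response model

For one measure and one position group, performance is modelled as a
quadratic in the measure centered at the position-group mean, plus
%-match-time as a linear covariate, with random player intercept, linear
and quadratic terms (independent variance components) and a residual. The
`complex` variant adds substituted-on/off dummies and a match random
intercept. Estimation is REML via `lme4::lmer`; the model specification,
contrasts and inference layer are this package's own.

Design choices worth spelling out:

* **Independent variance components.** Position groups hold 3–13 players;
  a full random-effect covariance matrix is not estimable at that size, so
  the three player terms are entered as separate `(0 + term | player)`
  components.
* **Convergence fallback.** A non-convergent fit is retried without the
  player-quadratic term, then without the player-linear term; drops are
  recorded in `fit$dropped` and non-convergence in `fit$converged`.
  Boundary (singular) fits are legitimate small-variance estimates and are
  kept, flagged in `fit$singular`.
* **Single player.** With one player the mixed model degenerates; the fit
  reduces explicitly to OLS (verified against a matrix-algebra oracle in
  the tests).
* **Effect contrasts.** `Δ(k) = b1·k·s + b2·(2m·k·s + k²·s²)` at
  evaluation point `m` on the centered scale (default 0, the group mean),
  with `s` the within-player SD. The 90% CL uses the t quantile with
  `df = n_obs − n_fixed`; the model's residual df is a defensible default
  and is configurable via the `df` argument — variance-component
  uncertainty is not propagated, which makes the limits slightly liberal
  in small groups.
* **Match time** enters raw (uncentered); its coefficient is reported but
  not interpreted.
* **Reliability model.** The true between-player SD of a measure is the
  square root of the player variance component from a mixed model with
  seasonal trend (linear in week) and problem-week dummy as fixed effects
  and player, match and match×problem random intercepts. At realistic
  within:between variance ratios (e.g. 138:34 for weekly load) this
  component often lands on the boundary at 0 in a single season — itself
  an informative result (no substantial between-player differences).

## Magnitude-based inference

Effects are standardized against the observed between-player SD of the
performance score averaged over position groups (default 25), *not* the
measure's SD. The smallest important change is 0.2 × 25 = 5 raw units.
Given an effect Δ and its 90% limits, the probabilities that the true
effect is substantially positive/negative are t-tail probabilities beyond
±5; the qualifier scale is <0.5% most unlikely, 0.5–5% very unlikely,
5–25% unlikely, 25–75% possibly, 75–95% likely, 95–99.5% very likely,
>99.5% most likely, and an effect is *unclear* when both substantial
probabilities exceed 5%. For df > 100 the normal limit is used to
stabilize the tails. The three probabilities (substantially negative /
trivial / substantially positive) sum to 1 exactly.

The **training recommendation** maps the (−1 SD, +1 SD) effect pair to a
prescription ("Reduce by >1 SD", "Reduce by ~1 SD", "Reduce by 0 to
~1 SD", "Increase", "No change") — see `recommend_training()`. This
mapping is a reconstruction of how a practitioner reads the paired
effects, not a published generative rule, and is documented as such.

## The synthetic season generator

`simulate_squad()` emulates a 24-week season of a 35-player squad
(13 defenders, 13 forwards, 6 midfielders, 3 rucks) with position-specific
weekly-load means and within-player SDs (541±138, 576±144, 560±135,
475±98), performance levels (65±27, 68±28, 101±27, 80±21), player load
means spread with SD 34 and performance intercepts with SD 25. Weekly
loads are i.i.d. around player means by default; an AR(1) switch
(`ar_rho`, tests use 0.3) adds the temporal structure without which
smoothed/differential measures carry no signal. Each week's target load is
decomposed — wellness drawn first, match counts and work rate next,
distances scaled to fill, training distance absorbing the residual — so
that `global_load()` on the emitted session/wellness fields reproduces the
weekly load to machine precision (the conservation contract the tests
assert at 1e−6). Problem weeks (probability 0.08) halve the training
fields and feed the reliability model's dummy.

The planted dose-response defaults to b1 = −0.0333, b2 = −1.94e−4 on
centered weekly load: an inverted U peaking ≈0.6 within-player SD below
the mean, whose ±1 defender-SD effects are +0.9/−8.3 performance points —
a realistic magnitude for this setting.

What the generator does **not** emulate: opposition and fixture effects,
within-season periodisation trends (available but off by default), missing
matches and partial seasons, autocorrelated wellness, measurement error in
GPS variables, or any structure in the proprietary performance score
beyond "position mean + player offset + dose-response + noise". Passing
recovery tests therefore demonstrates that the estimator recovers what the
generator planted under the stated conditions — not that real data meet
those conditions.

## Simulation sizes and numerical tolerances

The recovery suites fit the defender group (13 players × 24 weeks) across
100 replicate seasons for bias (compared at 3 Monte-Carlo SEs) and 100 for
null CI coverage (≥85% per-interval); the inverted-U pattern check uses 50
replicates with a planted peak at −0.5 SD and counts fitted curve peaks in
[−1.5, 0.5] SD. The acceptance script uses 60/60/50 replicates. The
smoothing recurrence is checked against an explicit kernel-sum expansion
on 1000 random series (length ≤ 52) at 1e−9 relative tolerance; exact
hand-computed oracles cover every load metric. Sub-seeds for replicate r
are fixed offsets from the run seed.

## Known limitations

* Confidence limits ignore variance-component uncertainty (see above).
* The rucks group (3 players) is reported with deliberately wide limits
  rather than suppressed; recommendations there rest on few observations.
* Monotony/strain on the weekly grain are interpretable only relative to
  themselves; they are not comparable to daily-grain monotony values.
* The wellness-direction question (higher wellness raises load) is
  inherited from the scoring scheme, not resolved by the package.
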