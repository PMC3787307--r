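---
title: "Methods: the rEV model, its estimation, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the rEV model, its estimation, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igtEV)
```

## The task and the model

The Iowa Gambling Task presents four decks. Every card pays a fixed gain
($100 for decks A and B, $50 for C and D) and, on scheduled positions, a
loss; each deck loses a fixed total per 10 cards ($1250 for A/B, $250 for
C/D), so A/B net −$250 and C/D net +$250 per 10 cards. The published task
description constrains only these sums and the punishment frequencies (five
small punishments per 10 cards in A and C, one large in B and D), not the
within-cycle positions. `igt_decks()` therefore uses the canonical
within-block program (A: 150/300/200/250/350 at positions 3, 5, 7, 9, 10;
B: 1250 at position 9; C: 50 at positions 3, 5, 7, 9, 10; D: 250 at
position 10), which satisfies every printed constraint; any alternative
program meeting the same invariants can be loaded from JSON.

The revised Expectancy-Valence model has three subject-level parameters:

* **Attention weight to gains, `w` ∈ [0, 1]** (dimensionless). The valence
  of an outcome is `v = w·win − (1 − w)·loss`, with the loss entered as a
  positive magnitude. `w = 0` is a purely loss-driven evaluator.
* **Recency, `phi` ∈ [0, 1]** (dimensionless learning rate). Only the
  chosen deck's expectancy moves: `E ← E + phi·(v − E)`. `phi = 1` keeps
  only the last outcome; `phi = 0` never learns.
* **Consistency, `c` ∈ [0, c_max]**, mapped to the softmax sensitivity
  `theta`. The default mapping is the trial-independent `theta = 3^c − 1`;
  the trial-dependent `theta(t) = (t/10)^c` is selectable
  (`ev_control(theta_variant = "trial_pow")`). The published formula for
  this quantity is typographically corrupted (it reads as a constant power
  of `c` yet is written as a function of `t`, and its stated bound reuses
  the recency symbol), so both standard readings are implemented and the
  choice is an explicit, logged setting rather than an assertion about the
  original analysis. `c = 0` gives uniform random choice under the default
  variant. `c_max = 5` follows the common bound in the rEV literature and
  is configurable.

Expectancies start at zero for all decks — an explicit assumption (the
source text is silent) that makes the first choice uniform. The one-step-
ahead likelihood accumulates `log Pr[chosen deck | history]` before each
update. All money stays in task dollars; expectancies are therefore on the
scale of tens to hundreds, which matters for identifiability (below).

The baseline comparison model predicts every choice from the subject's own
overall choice proportions; its maximised log-likelihood is
`Σ_j n_j log(n_j/T)`. Both models carry three free parameters (the baseline
has four proportions and one constraint), so the BIC statistic
`2·ΔlogLik − Δk·log T` reduces to twice the log-likelihood difference;
positive values favour the cognitive model. The full formula is retained
for unequal parameter counts.

## Numerical choices

* **Softmax overflow**: probabilities use max-subtraction, so arbitrarily
  large `theta·E` is safe.
* **Probability floor**: `prob_floor = 1e-10` bounds each trial's
  probability away from zero before the log. Without it a single surprising
  switch under a saturated softmax sends the likelihood to −∞ and strands
  the optimiser. The log-likelihood is weakly decreasing in the floor and
  independent of it whenever no probability reaches it.
* **Optimisation**: the likelihood is maximised over
  `[0,1] × [0,1] × [0, c_max]` via Nelder–Mead on a logit-transformed
  unconstrained space, restarted from a 4×4×4 lattice of interior points
  (`ev_control(n_grid)`), relative tolerance `1e-6`. rEV likelihood
  surfaces are multi-modal and flat in places; multi-start is the standard
  remedy. Ties within tolerance are broken toward lexicographically
  smaller `(w, phi, c)`, which makes the fit deterministic — no random
  jitter is used, so results do not depend on any seed.
* **Degenerate inputs**: empty sessions, fewer than 10 trials, parameters
  outside their boxes, non-finite expectancies and malformed session files
  all raise immediate, named errors.

## Identifiability and the recovery design

With dollar-scale expectancies, `theta = 3^c − 1` saturates the softmax for
`c` above roughly 1: the model then predicts the argmax deck with
probability near 1 and the likelihood is *flat* over an interval of `w`
values that produce the same preference ordering. `w` is set-identified on
such sessions, and the deterministic tie-break returns the lower edge of
the plateau — a negative bias in recovered `w` (about −0.2 against uniform
box draws) that no amount of data removes. Rank correlation between true
and recovered `w` remains high (≈ 0.84 over 200 agents at 100 trials)
because the plateau moves with the true value.

`recovery_experiment()` quantifies this. For horizon comparisons it uses a
nested design: one 500-trial session is simulated per agent and the model
is refit on each leading prefix, so the 100- vs 500-trial comparison is
paired on common realisations. With independent sessions per horizon the
true RMSE improvement (~0.005) would drown in the Monte-Carlo noise of 200
independent draws; pairing removes that between-session noise while keeping
the stated sizes. Validation runs in this package use 200 agents at
horizons 100 and 500, and 100 agents for the model-adequacy check (mean BIC
statistic on data simulated with `c ≥ 1`), sizes at which all summaries are
stable to the second decimal.

## The synthetic cohort generator

No subject-level data are deposited, so every downstream stage is exercised
on a synthetic cohort whose *margins and contrasts* reproduce the published
tables. The generator (`cohort_config()` / `generate_cohort()`) draws, per
subject:

* age ~ N(16.2, 0.55) years; gender ~ Bernoulli(0.5);
  school type vocational with probability 82/181;
* T1 current smoking from a logistic model on gender and school type whose
  odds ratios (8.68 for males, 4.47 for vocational students) are the ones
  implied by the printed group compositions, with the intercept calibrated
  numerically (`uniroot`) so the marginal prevalence is 9.4%;
* working memory ~ N(61.8, 6.8) truncated to [0, 72]; academic performance
  on 1–5 with mean ≈ 3.56 (≈ 3.0 for T1 smokers, mirroring the printed
  group difference);
* true rEV parameters from truncated normals: overall w 0.40 ± 0.36,
  phi 0.23 ± 0.33, c 4.0 ± 4.0 on [0, 5]; T1 smokers use the printed
  smoker-column means. Truncation (not clipping) preserves the box while
  keeping means approximately at their targets — documented as
  approximate;
* T2 current smoking from `logit P = β0 + 3.075·smoker_t1 − 2.673·w`,
  using the *true* w (the published Model I coefficients injected as
  generative truth), the intercept again calibrated by numerical
  integration over each T1 group's w distribution so the T2 margin is
  12.2%. Conditioning on true rather than fitted w cleanly separates
  generator truth from estimation noise; the pipeline then shows the
  attenuation that refitting introduces. The lower mean w among future
  smokers (≈ 0.34 vs 0.47 at n = 10⁴) *emerges* from this model rather
  than being sampled directly;
* smoking levels (0–6, the seven questionnaire options coded by
  `code_smoking_level()`) conditionally on current-smoker status from the
  printed per-wave frequency columns. One printed T2 cell count is
  internally inconsistent with its percentage and column total; the
  percentages were trusted (counts 6, 3, 10, 1, 1, 1 of 22);
* a 100-trial IGT session simulated generatively from the subject's true
  parameters.

The whole cohort is a pure function of `(config, seed)`.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: recruitment attrition and exclusions,
school-level clustering, self-report measurement error, any covariate
dependence
beyond the stated gender/school/smoking contrasts (the source gives only
margins, so the joint distribution is a modelling choice), and any direct
dependence of IGT behavior on smoking beyond the shared parameters. Effect
*directions* and approximate magnitudes are recoverable; subject-level
realism is not claimed.

## The statistical stage

* **Chi-squares** are plain Pearson on 2×2 tables with no continuity
  correction — this exactly reproduces all five published composition
  statistics (48.53, 10.81, 7.35, 9.97, 5.29), which a Yates-corrected test
  does not; verified in the test suite.
* **t-tests** default to the pooled-variance Student form (the era's
  default); Welch is available by flag. Which form the original analysis
  used is unstated.
* **The block×group contrast** uses the two-block identity: with exactly
  two within-subject blocks, the group×block interaction of a split-plot
  ANCOVA equals the between-group effect on the difference score
  `block2 − block1` (and the group main effect is the between-group effect
  on the subject means), each tested with covariate adjustment. This avoids
  unspecified mixed-model machinery while remaining algebraically exact.
* **Model I** (logistic, follow-up current smoker) reports `exp(B)` with
  Wald intervals `exp(B ± 1.96·SE)`. Complete separation is detected and
  flagged, never silently returned.
* **Model II** (linear, follow-up smoking level) reports the raw
  coefficient, the standardized beta (all design columns and the outcome
  z-scored, dummies included, matching the conventions of the published
  table — whose "Exp(B)" column evidently holds standardized betas), and a
  Wald interval on the raw scale, which is how the published intervals
  behave.
* Focal predictors (net score, w, phi, c) are examined one at a time, each
  adjusted for age, gender, school type, working memory, academic
  performance and the baseline value of the outcome — eight models in all.
  No multiple-testing correction is applied, matching the source analysis.

## Pipeline and reproducibility

`run_pipeline()` chains generation → per-subject ML fitting → behavioral
metrics → the statistical stage, asserts record-count conservation after
every join, and writes all tables as UTF-8 CSV (floats at 6 significant
digits) plus a JSON test log. A single global seed fans out to
stage-specific seeds by stable string hashing (`stage_seed()`), so stages
rerun independently yet reproducibly and a full rerun is byte-identical.
The packaged default configuration (181 subjects, 100 trials, 4×4×4
starts) completes in well under a minute on one CPU; degenerate
configurations (tiny cohorts, empty smoking cells) complete with recorded
notes instead of failures.

## Known limitations

* Under the default sensitivity mapping, `w` and especially `c` are weakly
  identified for highly consistent subjects (likelihood plateaus); recovered
  `w` carries a negative bias for such agents. Interval or hierarchical
  estimation would sharpen this but is out of scope.
* The generator's covariate dependence structure beyond the stated
  contrasts is a modelling choice, not an empirical claim.
* No hierarchical/Bayesian estimation and no alternative model families
  (PVL, VPP); the baseline comparison is the only model-adequacy check.
```{r example}
fit <- ev_fit(simulate_igt(ev_params(0.3, 0.3, 1.5), n_trials = 80, seed = 3))
summary(fit)
```
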