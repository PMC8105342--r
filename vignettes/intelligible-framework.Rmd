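---
title: "Robust, knowledge-audited variable selection for clinical risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust, knowledge-audited variable selection for clinical risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intelligible)
```

## Scope and model

This package builds binary prognostic models on tabular clinical cohorts
— one row per patient, mixed continuous and binary admission-time
variables, a dichotomized functional outcome (1 = unfavorable; for an
ordinal 1–8 functional scale the split is at ≤ 4) — and subjects the
model's inputs to two vetting stages before the final fit. The classifier
is a gradient-boosted tree ensemble with a logistic link; its risk score
is `P(unfavorable)`. The vetting uses per-patient Shapley attributions
`φ`: the model output for a patient decomposes as the base value (mean
model output over a background population) plus the sum of per-variable
contributions, with positive `φ` raising predicted risk.

The pipeline (`run_framework()`) is: stratified 25% holdout → stage-1 fit
on all candidates → bootstrap robustness screen → stage-2 fit on robust
variables → knowledge audit with counterfactual bias quantification →
human-confirmed exclusions → stage-3 ("intelligible") fit. The test rows
are scored once per stage and are never consulted by any selection step;
this is asserted by tests that corrupt the test partition and verify the
selections are unchanged.

## Attribution backends

Two estimators stand behind `explain()`:

* **`tree_path`** — the cover-weighted tree recursion shipped with the
  booster. It is the fast path used inside the bootstrap screen, where
  thousands of models must be explained and only the *rank* relation
  between a variable and its attribution matters.
* **`interventional`** (default for reporting) — exact Shapley values of
  the interventional value function
  `v(S) = mean over background rows r of f(x_S, r_{-S})`, computed per
  tree by enumerating leaves. For one explicand, one background row and
  one leaf, the coalition predicate factorizes into features that must
  come from the explicand and features that must come from the background
  row, and the Shapley value of that AND-game has a closed form; summing
  over leaves, trees and background rows gives the ensemble value with no
  sampling error. The implementation collapses repeated path constraints
  per feature into one interval, compares in `float32` exactly as the
  booster does, and is verified against a brute-force `2^d`
  subset-enumeration oracle (`exact_shapley()`) to `1e-6` on randomized
  small ensembles.

Attributions are natively additive in log-odds. Probability-space
attributions are produced by rescaling each row's log-odds attributions by
`(p(x) − p_base) / (m(x) − m_base)` (with the derivative limit at the
degenerate point), which preserves signs and makes local accuracy — base
value plus row sum equals the model output — hold exactly in the declared
space. This rescaling is a reporting convention, not a second attribution
theory; the open question of which space a clinical report should quote is
resolved in favor of probability because per-patient narratives ("this
finding adds 1.8% risk") are read in probability points.

For local accuracy the interventional backend evaluates the ensemble's
margins in double precision from the parsed trees (the booster itself
stores `float32`); the booster's constant offset is recovered by
averaging. Attribution row sums therefore reproduce the reported fitted
values to machine precision, and those fitted values agree with the
booster's own predictions to `float32` resolution.

## The robustness screen

For each of `B` bootstrap replicates of the development set the model is
refit (mean imputation refit inside the replicate), the full development
set is re-attributed, and each variable's monotone association between
value and attribution is summarized by Kendall's `τ_b` with tie
corrections in both margins; the per-replicate p-value uses the
tie-corrected normal approximation of `C − D`. Both statistics are
computed in `O(n log n)` (merge-sort inversion counting), because the
pooled association concatenates all `B × n` (value, attribution) pairs.

The robustness *decision* is a bootstrap sign test. The per-replicate
`τ` values of a variable form its bootstrap direction distribution;
the screening p-value is the fraction of replicates that fail to support
the dominant direction, so at `α = 0.1` a variable passes only if its
sign holds in more than 90% of refits. Replicates in which the ensembles
never split on the variable (degenerate, constant attribution) count
against stability: a variable the model rarely uses has no robust
behavior to validate. Design rationale: the tie-corrected normal p of the
*pooled* `τ` is reported for reference but deliberately not used as the
gate — concatenating `B` dependent copies of the same evaluation rows
inflates the effective sample size until any nonzero association is
"significant", which simulation showed selects nearly every pure-noise
variable. The sign test expresses the question the screen actually asks —
is the direction of this variable's effect stable under resampling of the
training data? — and is the only construction we found under which planted
noise is rejected at the rates a useful screen needs. An alternative
consensus rule (median per-replicate p below `α` and ≥ 80% sign
agreement among assessable replicates) is exposed via
`select_robust(strategy = "consensus")`.

The screen's operating characteristics on the default synthetic cohort
(n = 831, 20 signals, 40 noise variables, `B = 50`, ten seeds) are a mean
planted-signal sensitivity of about 0.81 and mean noise specificity of
about 0.90; both are recomputed by the acceptance tests. Two caveats are
inherent rather than implementation artifacts. First, a noise variable
whose *realized* cohort correlation is large by chance is statistically
indistinguishable from a weak true signal — no resampling scheme can
separate them — so specificity cannot reach 1. Second, sign stability is
counted against total replicates, so weak signals that the regularized
ensembles use only sporadically are missed; that conservatism is the
intended trade.

## The knowledge audit

Expectations are declarative: per variable, `increases_risk`,
`decreases_risk`, or `unknown`, plus a free-text provenance note.
A robust variable is flagged counterintuitive when a known expectation
contradicts the sign of its pooled `τ`; unknown expectations never flag.
The observed direction reuses the stability evidence rather than a fresh
fit, keeping both selection stages on the same footing. For flagged
binary variables the audit quantifies the model-level bias with the
counterfactual risk difference `δp` on the held-out patients: set the
variable to 0 and to 1 with everything else fixed and subtract the
predicted risks. `δp` is a probe of *model behavior*; no causal claim is
made or needed — the point is precisely that the model's counterfactual
response contradicts known causal direction. Exclusion is never automatic:
`finalize_variables()` accepts only confirmations of flagged variables
(an explicit override exists for expert-driven exclusions the machine did
not flag), and `run_framework()`'s default of confirming every flag
mirrors a review board that upholds all flags; pass `confirm = "none"` or
an explicit list otherwise. Continuous variables are flagged by `τ` sign
only; `δp` for them requires user-chosen intervention values (for example
quartiles) because no canonical pair exists.

## The synthetic cohort generator

`sim_spec()` defaults define the study conditions and are deliberately
fixed: n = 831 patients, outcome prevalence ≈ 0.42, 20 signal variables
(14 standard-normal continuous with log-odds coefficients tapering from
0.8 to 0.35 in alternating signs, anchored by one strongly protective
covariate at −1.6; 6 Bernoulli(0.35) binary with coefficients 1.2 to 0.7,
scaled up so effective effect sizes match the continuous ones), 40 noise
variables (30 continuous, 10 binary), 5% missing cells completely at
random, and one confounded binary variable.

The confounder emulates the substance-misuse structure: its latent
propensity is a Gaussian score correlated at 0.85 with the measured
protective anchor and at 0.4 with an *unmeasured* protective factor `U`
(log-odds effect −1.2) that also enters the outcome; its own causal
effect is harmful (+0.2). Crude association: strongly protective
(log-OR ≈ −1.4). Adjusting for the full planted pathway (anchor and `U`)
recovers the harmful sign. The unmeasured component is essential: with a
purely measured link the fitted ensembles adjust the anchor well enough
that the confounder is used only sporadically and the counterintuitive
behavior is expressed unreliably; real confounded variables proxy several
pathways, some of them latent to the model, and the generator keeps `U`
in its ground-truth output so simulation studies can verify both the
marginal flip and the adjusted recovery. Missingness is MCAR only — the
mean-imputation rule the package implements makes no claim beyond that
mechanism.

What passing tests on these cohorts does and does not show: the simulator
plants clean monotone effects, independent Gaussian noise and a single
confounder, so recovery rates here are an upper bound on what the screen
achieves on real EHR data with correlated measurements, non-monotone
physiology and label noise; conversely the confounder-audit results show
the pipeline detects the targeted bias structure when it is present, not
that it finds every bias.

## Defaults and numerical choices

* Protocol constants: test fraction 0.25, `B = 1000`, `α = 0.1`, 5 CV
  folds, classification threshold 0.5 — the shipped study design
  (acceptance-tested). Simulation studies in the tests and the acceptance
  script scale the bootstrap to `B = 50`, a size at which the pooled `τ`
  of selected variables is stable to within 0.05 of its `2B` value.
* Boosting hyperparameters (`default_hyperparameters()`): 80 rounds,
  depth 3, learning rate 0.1, `min_child_weight` 8, `lambda` 1, no
  row/column subsampling (fits are deterministic given data and seed),
  single-threaded. Tuned once on synthetic cohorts to the regime where
  training AUC ≈ 0.99 and test AUC ≈ 0.78–0.84 at n = 831 with 61
  candidates — enough capacity to express the planted confounder, enough
  regularization that noise usage stays sporadic. No class reweighting by
  default (`scale_pos_weight` exposed).
* Holdout and CV are stratified by label; the holdout rounds half up;
  fold sizes differ by at most one.
* Mean imputation treats binary columns like continuous ones (the rule is
  "replace by the training average", applied uniformly); it errors on
  all-missing training columns and is idempotent.
* Per-replicate bootstrap seeds derive from the master seed, so any
  replicate is reproducible in isolation; single-class replicates are
  redrawn up to a retry cap.
* Degenerate inputs: constant value or attribution vectors raise a classed
  error at the `τ` level and mark the variable non-assessable (never
  robust) at the screen level; ties in `τ` use the standard `τ_b`
  corrections; the AUC uses midranks (ties count half).
* The brute-force Shapley oracle enumerates at most `2^12` coalitions and
  evaluates them in one batched prediction call.

## Problem sizes in the shipped studies

The packaged tests and `scripts/acceptance.R` use: oracle equivalence on
50 random ensembles with up to 8 features and 16 background rows; local
accuracy on a 1000-row cohort with a 512-row background; 500 randomized
tie-heavy vectors against an `O(n²)` pair-counting oracle plus exact
permutation nulls at n = 8; recovery and audit studies over 10–20 seeded
cohorts at n = 831 and `B = 50`; and a fully instrumented end-to-end run
at n = 320. These sizes were chosen to exercise every claim at study
scale on a single CPU.

## Known limitations

* The screening p-values are scores for ranking and gating, not
  calibrated error rates; no multiple-testing correction is applied
  across variables (the subsequent expert stage is the designed control).
* `τ_b` measures monotone association only; a variable with a strong
  U-shaped effect can be robust-in-behavior yet show `τ ≈ 0`. The screen
  will drop it — a conservative, documented bias shared with the
  underlying method.
* The probability-space attribution rescaling distributes the row's total
  probability change proportionally to the log-odds attributions; other
  allocations exist and differ in the tails.
* Bootstrap refits inherit the cohort's realized quirks; the screen
  protects against instability under resampling, not against biases
  shared by every resample of the same cohort — that is exactly the gap
  the knowledge audit exists to cover.
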