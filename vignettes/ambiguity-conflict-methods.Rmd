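---
title: "Modelling decisions under ambiguity and informational conflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling decisions under ambiguity and informational conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambicon)
```

## The problem

Most laboratory work on decision making under uncertainty manipulates
*ambiguity* — imprecise information about outcome probabilities, such as an
interval that is known to contain the true value. *Informational conflict* is
different in kind: two equally credible sources each give a precise
probability, but the two messages disagree. `ambicon` provides an end-to-end,
fully synthetic test bed for asking whether these two kinds of degraded
information are processed the same way, behaviourally (choice modelling) and
neurally (voxelwise GLMs with an out-of-sample region-of-interest
confirmation step).

Because no participant data are available for this paradigm, the package
treats the *generator* as a first-class module: every analysis component can
be exercised against data whose ground truth is known, so calibration and
recovery are testable claims rather than assumptions.

## The task

Each trial presents a lottery over a deck of 100 cards of three types. The
count of Type 1 cards is always known; the combined count of Type 2 and
Type 3 cards — the **level** `L`, an even number between 6 and 94 — is the
parametric uncertainty variable. The decision maker chooses among a $3 sure
gain or a $10 bet on one card type. Conditions differ only in what is known
about the Type 2 / Type 3 composition:

* **risk** — exactly `L/2` of each;
* **ambiguity** — only the total `L` is given;
* **conflict** — source A asserts `(round(L/3), L - round(L/3))` and source B
  the swapped pair, so the two messages average to the even split;
* **ignorance** — structurally generated like ambiguity here; its behavioural
  findings are out of scope and it exists so that the four-condition GLM is
  fully specified.

Under the information-neutral reading (interval midpoint under ambiguity,
message mean under conflict) a Type 2 bet wins with probability `L/200` in
every condition, so the conditions are matched on expected value at every
level, and the winning probability sweeps 0.03–0.47 over the default level
set. A risk-neutral agent bets on the uncertain types exactly when
`L > 200/3`, which the default level list makes true on exactly ten of the 32
risk trials.

The exact 30-level list used in the original deck table is not published;
`default_levels()` is the package's own construction satisfying every stated
constraint simultaneously (30 distinct even levels spanning 6–94, twenty at
or below 66 and ten above `200/3`, with the two per-condition repeats drawn
from the low subset so the risk-neutral bet count stays at ten).

A session is 4 runs of 200 volumes at TR 2.5 s, each run holding 8 trials of
each of the five trial types (the four conditions plus fixation-only); gamble
trials last 6.5 s with 1 s of fixation after, and the slack up to the run
length is distributed as seeded inter-trial baseline. Desk-scale geometries
(2 runs × 120 volumes, or 5 trials per type for very small fixtures) are
available through `build_session()` arguments; tests and examples state the
geometry they use.

## The choice model

Choice follows a subjective-expected-utility multinomial logit. The weight of
an option paying `x` with probability `pi` is

    W = x^theta * pi^gamma

and choice probabilities are the softmax of the four option weights. `theta`
is the monetary utility exponent; `gamma` is a condition-specific probability
weighting applied **only to options whose winning probability is uncertain**
(the Type 2 / Type 3 bets in ambiguity, conflict and ignorance trials). The
sure gain and the Type 1 bet have precisely known probabilities, so they
always carry `gamma = 1`; risk trials therefore reduce to the identifying
`gamma = 1` special case. `gamma > 1` means aversion (uncertain probabilities
are shrunk), `gamma < 1` seeking. We deliberately add no extra softmax
temperature: utilities equal weights, `theta` already scales them, and a
temperature would not be separately identifiable here.

Model-free attitude scores complement the model: with a "bet" meaning a
Type 2 or Type 3 choice, `RA = 10 - bets(risk)` (ten being the risk-neutral
benchmark), `AA = bets(risk) - bets(ambiguity)` and
`CA = bets(risk) - bets(conflict)`; positive values mean aversion.

`second_order_variance()` quantifies the variance-ordering feature of the
design: the variance of the Type 2 winning probability under the decision
maker's information is `0` under risk, `Var(k/100), k ~ U{0..L}` under
ambiguity and the two-point message variance under conflict. Ambiguity
strictly exceeds conflict at every admissible level while the mean winning
probability is identical. Single-draw *outcome* variance cannot be the
distinguishing quantity — it is identical across conditions whenever the
marginal means match — so the winning-probability variance is the reading
implemented.

## Estimation

`fit_subject()` maximises the trial-level likelihood over
`(ln theta, ln gamma_A, ln gamma_C, ln gamma_I)` with L-BFGS-B inside the
boxes `theta` in `[0.05, 5]`, `gamma` in `[0.05, 10]`, from five seeded
starts (the first at the neutral point). Missed responses are dropped;
an all-sure-gain subject is flagged unidentifiable and returned at the
neutral defaults with bound flags set. `grid_oracle()` is a brute-force
exhaustive grid argmin used as an independent check: on every tested dataset
the optimiser's negative log-likelihood must not exceed the oracle's.

Per-subject maximum likelihood was chosen over hierarchical or Bayesian
estimation: no priors or sampler details are available to reproduce, and
independent MLE keeps each subject's estimate an auditable function of their
own choices. At 32 trials per condition the conflict attitude is the hardest
parameter (strongly averse subjects rarely bet, so their likelihood is flat
upward and a few estimates censor at the upper bound); recovery correlations
at the study's trial counts are measured in the test suite rather than
asserted from theory.

## Group behavioural statistics

`attitude_summary()` applies the single-pass 3-SD outlier rule to AA and CA
(mean and SD computed over the full vector, no iteration — the simplest
reading of the stated rule), excludes flagged subjects from all analyses,
and reports one-sample t tests of RA/AA/CA against 0 and of the
probability-weighting attitudes against neutrality. Ambiguity attitudes are
log-normally distributed, so the ambiguity test runs on `ln gamma_A` vs 0
(this is also the only reading under which the published t statistic is
arithmetically consistent with the published mean and standard error);
the conflict test uses raw `gamma_C` vs 1. Effect sizes follow the
`d = t / sqrt(n)` reporting convention throughout, and correlations among
attitudes use `ln gamma_A` with raw `gamma_C`. The raw-scale `gamma_C` test
is slightly anticonservative under a neutral population because fitted
`gamma` estimates are right-skewed; the log-scale test is the calibrated one
and both are exercised in the tests.

## The synthetic cohort

`population_spec()` defaults encode the study conditions: 32 subjects (16
male, age 25.2 ± 5.6), `gamma_A` log-normal with arithmetic mean 0.85,
`gamma_C` log-normal with mean 1.69. Only standard errors of those means are
published, so the between-subject SDs are `SE × sqrt(30)` (1.10 and 0.88).
`theta` and the ignorance weight are unit-median log-normals with log-SD 0.3
— their population spread is unreported, and this is a free choice held
fixed. Response times are log-normal in milliseconds (baseline `log(1600)`,
trial scatter 0.25 on the log scale) with condition offsets
(+0.07 ambiguity, +0.10 conflict, +0.08 ignorance) and a 0.085
subject-by-condition jitter, chosen once so that the paired risk-vs-conflict
effect is large, risk-vs-ambiguity moderate, and ambiguity-vs-conflict small
and unreliable at n = 32 — the qualitative ordering of the reported response
time pattern.

## The BOLD simulator

`simulate_bold()` builds, per subject and run, the subject's own first-level
design matrix (including their response times) and multiplies the designated
regressor column by a per-subject region amplitude for every voxel of each
planted spherical region. The default pattern mirrors the headline findings:

| region    | loads on         | amplitude (PSC)      | coupling                 |
|-----------|------------------|----------------------|--------------------------|
| vmPFC     | ambiguity level  | −0.015 / card ± 0.003| —                        |
| left VS   | conflict level   | +0.002 / card ± 0.0005| —                       |
| mPFC      | ambiguity dummy  | 0.3 ± 0.15           | `ln gamma_A`, r = +0.61  |
| right VS  | conflict dummy   | 0.3 ± 0.15           | `gamma_C`, r = −0.67     |

Noise is AR(1) in time (coefficient 0.3, innovation SD 0.5 PSC) and
Gaussian-smoothed in space (sigma 1 voxel). Two deliberate design choices:

* **Only the noise field is smoothed.** The planted signal is added
  unsmoothed, so the planted per-unit amplitude is exactly the quantity a
  correct GLM should recover; recovery tests then measure estimator bias,
  not kernel-induced dilution.
* **Attitude couplings are planted exactly in-cohort.** The coupled
  amplitude is built by residualising a noise vector against the
  standardised attitude and mixing to the target correlation, so the
  *realised* cohort correlation equals the target (0.61 / −0.67) rather than
  fluctuating around it. Downstream correlation estimates then measure what
  the pipeline loses (attenuation, split noise), not what the cohort draw
  happened to be.

Output is raw intensity around a baseline of 100 so that
percent-signal-change conversion is part of the analysed path. What the
generator does **not** emulate: anatomy, physiological noise, motion, scanner
drift, spatial heterogeneity of the HRF. Passing tests therefore demonstrate
the estimators' correctness and calibration under the model's assumptions,
not robustness to real-data artefacts.

## First-level GLM

`double_gamma_hrf()` is the canonical two-gamma kernel (shapes 6 and 16,
unit scales, undershoot ratio 1/6, peak-normalised; peak at 5 s, undershoot
near 15 s); other conventions are reachable through its arguments. The main
model per run is 4 condition boxcar dummies, 4 level-modulated boxcars, and
a response-time impulse regressor (amplitude equal to the trial RT in
seconds), all convolved at 0.1 s resolution and sampled at the TR; "per
scan" mean-centering is read as per-run: modulators are centred within the
run before convolution and the sampled parametric/RT columns are re-centred
exactly, with a per-run intercept closing the model. The subjective-value
confound model replaces the level modulators and RT with per-condition
modulators carrying `subjective_value()` of the chosen option (8 task
regressors).

`fit_glm()` is ordinary least squares on all voxels at once. With
`ar1 = TRUE` it estimates the residual lag-1 autocorrelation per voxel,
pools the median across voxels, and applies one Cochrane–Orcutt
quasi-differencing pass within runs (first volume scaled by
`sqrt(1 - rho^2)`) before refitting. Pooling keeps the solve fully
vectorised; since OLS is unbiased under AR(1) noise, prewhitening here buys
efficiency and honest single-subject variances rather than bias correction.
AR(1) is handled at this stage because the synthetic data are deliberately
not "preprocessed"; an acquisition pipeline that already removed temporal
autocorrelation would set `ar1 = FALSE`. High-pass filtering is not applied:
the generator produces no drift, and the original filter's exact form is not
recoverable from its description.

Group inference is voxelwise and random-effects: one-sample t maps of
per-subject parameter estimates, Pearson brain–behaviour maps against
`ln gamma_A` / `gamma_C`, paired contrasts (conflict-level minus
ambiguity-level), and a minimum-statistic conjunction (both effects
individually significant with the same sign). `cluster_threshold()`
reimplements Monte-Carlo cluster-extent thresholding in simplified form:
smoothed Gaussian null maps, voxelwise two-sided threshold, 6-connected
cluster sizes, and the smallest extent whose family-wise false-positive rate
is at most 0.05.

## Out-of-sample ROI confirmation

`run_confirmation_pipeline()` implements the split-half procedure:

1. **Split** the cohort into halves matched on age, sex and the two
   model-based attitudes. The matching algorithm (greedy nearest-neighbour
   pairing on standardised variables within sex, random member assignment)
   is this package's construction; only the matching variables were
   specified.
2. **Explore** on half 1: group t maps for the ambiguity- and conflict-level
   regressors, correlation maps of the ambiguity/conflict main effects
   against `ln gamma_A` / `gamma_C`; local maxima above the two-sided
   alpha = 0.05 statistic threshold, pruned to a minimum 4-voxel separation.
3. **Confirm** on half 2: a sphere ROI at each candidate peak, the ROI-mean
   time course refit with the main model per held-out subject, and the
   target effect tested one-sided in the exploratory direction at
   alpha = 0.05. Cross-specificity statistics (the other condition's level
   effect; the other attitude against its condition's main effect) are
   recorded two-sided for every candidate — the analogue of the published
   cross-check table.

The sphere radius deserves a note: the source convention is a literal radius
of "10 voxels", which at 3.5 mm voxels would be a 35 mm sphere — implausibly
large, and half the width of the desk-scale grids used here. The pipeline
default is a 3-voxel radius matching the planted region scale;
`sphere_mask()` takes any radius if the literal convention (or a
millimetre-converted one) is wanted.

Calibration follows from the design: candidate selection uses only half 1,
confirmation only half 2, so under the null each candidate confirms with
probability at most the one-sided alpha regardless of how aggressively
exploration searches. The candidate cap (`max_peaks`, default 100) is a
compute guard, not an error control — capping too low can crowd true
moderate peaks below the null field's maxima, which matters for correlation
maps at n = 16 where null peaks reach |r| ≈ 0.8.

## Problem sizes and what the checks show

The package's own verification runs at desk scale, chosen as the smallest
geometries at which every claim is still a meaningful statistical test:
24³-voxel grids with 2 runs × 120 volumes for full-pipeline studies (the
acquisition-scale 4 × 200 geometry remains the session default for
behavioural work), 10³–12³ grids with shortened runs for replicate-heavy
recovery and calibration studies, 200 subjects × 128 trials for parameter
recovery with a 25-subject 10× trial arm for bias scaling, 50 replicate
datasets for amplitude recovery, 1000 replicate splits of a null dataset for
confirmation calibration, and 5 replicate full studies for the planted
confirmation pattern.

Two power facts are worth knowing when reading those results. The planted
level effects (−0.015 and +0.002 PSC/card) are strong at this noise level
and confirm essentially always. The attitude couplings are not: with 16
subjects per half, the half-sample correlation of an exactly-planted r = 0.61
fluctuates with an SD near 0.11, against exploratory/confirmatory criticals
of about 0.50/0.43 — per-study confirmation probability is roughly
two-thirds, an n-limited property of the split design itself, not of the
estimators. The replicate-based checks therefore require repeated
sign-correct confirmation of the attitude regions rather than certainty,
while the pooled 32-subject correlation at the planted region is required to
sit inside the target's 95% sampling CI.

## Known limitations

* The default level list and conflict-message rule are reconstructions from
  stated constraints, not the unpublished originals.
* Estimation is per-subject MLE; with 32 trials per condition, strongly
  averse subjects can censor at the `gamma` upper bound.
* The BOLD model is linear-time-invariant with stationary AR(1) noise; no
  drift, motion or physiological structure.
* The raw-scale `gamma_C` group test inherits skew from the estimator and
  is mildly anticonservative under the null; the log-scale test is the
  calibrated one.
* Ignorance-condition behaviour is generated as an ambiguity placeholder and
  never analysed.
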