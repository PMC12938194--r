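---
title: "Modelling decision performance under rule hierarchy and practice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling decision performance under rule hierarchy and practice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(driftlearn)
```

driftlearn implements a complete analysis pipeline for two-choice decision
experiments that cross an external difficulty factor — the number of nested
conditional rules a trial requires (*rule hierarchy*, three levels) — with an
intrinsic learning factor (*block*, five successive task segments). The
pipeline runs end-to-end on synthetic data, because raw data from studies of
this design are typically not shareable: a forward drift-diffusion simulator
generates trial-level reaction times and accuracies, and every downstream
stage (ANOVA, hierarchical Bayesian model comparison, random-forest
importance analysis) is exercised and tested against that generator.

## The drift-diffusion model

Each trial is modelled as noisy evidence accumulating from a starting point
toward one of two absorbing boundaries. Four parameters describe a cell of
the design:

* **drift rate** `v` (evidence/s): efficiency of evidence accumulation;
* **boundary separation** `a` (evidence units): response caution;
* **non-decision time** `t0` (seconds): encoding and motor time added to the
  first-passage time;
* **start proportion** `z` in (0, 1): the starting point as a fraction of
  `a`; the absolute bias is `Z0 = z * a`.

The diffusion coefficient is fixed at 1, so all parameters are expressed on
that scale. The upper boundary codes a *correct* response; accuracy coding
matches the binary correct/incorrect outcome analysed throughout. The
likelihood of a (choice, RT) pair is the Wiener first-passage-time (WFPT)
density, computed in compiled code with the standard small-time and
large-time series representations; the representation needing fewer terms at
truncation error `eps = 1e-7` is selected per evaluation, and the two
branches agree to better than one part in `1e6` everywhere (this is tested
against a long fixed-truncation reference series).

Trials with `rt <= t0` receive a floored log-density of −700 rather than
−Inf, so constraint-violating proposals during sampling are rejectable
rather than fatal.

The reference parameter values shipped with the generator
(`ddm_population()`) are hierarchy-level and block-level posterior means of
a published hierarchical fit of this design; non-decision times are stored
in seconds (the source table prints them on a millisecond scale, so they
are divided by 1000 on ingestion — self-consistency in one time unit is
what recovery tests require). Between-subject standard deviations are not
reported in that source; the package uses one fixed, task-typical set
(`v`: 0.10, `a`: 0.20, `t0`: 0.05 s, `z`: 0.03) chosen once at the scale of
individual differences commonly reported for hierarchical diffusion fits.

## The forward simulator

`simulate_trials()` integrates the diffusion by Euler–Maruyama with
`dt = 0.001` s. Two numerical choices matter:

* **Bridge correction.** A plain Euler scheme only detects a boundary hit
  at grid points, which biases choice fractions measurably (about 2.4
  binomial standard errors at n = 20,000 for typical parameters). After
  every step the probability that the unobserved continuous path crossed
  either boundary *within* the step is computed from the Brownian bridge
  and resolved by an extra uniform draw. With this correction the
  simulated choice fraction matches the closed-form absorption probability
  `(1 − e^{−2vaz})/(1 − e^{−2va})` to within Monte-Carlo error across the
  admissible region.
* **Cap at 60 s.** Trials not absorbed within the cap are resampled. The
  slowest admissible cells (boundary separation above 6 with drift below
  0.4) have mean decision times near 8 s; a short cap (say 10 s) truncates
  a substantial fraction of their mass and visibly distorts both choice
  fractions and the likelihood. At 60 s the truncated mass is negligible
  (order `e^{−11}`) for every cell in the reference table.

## Hierarchical estimation

`fit_ddm()` estimates one of four model structures by adaptive random-walk
Metropolis–Hastings with three chains of 3000 iterations (1500 burn-in) by
default. The hierarchy is centred: subject-level parameters are normal
around group-level means, truncated to the constraint region `a > 0.1`,
`z` in (0, 1), `t0` in (0, the cell's minimum observed RT). The minimum-RT
bound is applied to the group-level mean as well — without it the
hyper-mean of `t0` is unidentified above the subject-level truncation and
wanders upward. The group-mean bound is computed per *hierarchy* wherever
the model's cells carry one, so competing model structures share identical
mean supports: a per-cell bound would hand block-resolved structures a
likelihood gain (sitting against each cell's own faster minimum RT) that
grows with the trial count and has nothing to do with the hypotheses under
comparison.

Hyperpriors are uniform: `v` means on [−5, 5], `a` on [0.1, 10], `t0` on
[0.01, 3 s], `z` on [0.01, 0.99]; group scales uniform on (0, half the
mean range]. Proposals walk on unconstrained transforms (identity for `v`,
log for `a` and scales, logit for `z`, range-logit for `t0`) with the
Jacobian in the acceptance ratio. Every 200 iterations during burn-in each
component family's step size is multiplied by `exp(±0.1)` according to
whether its windowed acceptance sits above or below the 0.30 target; step
sizes are frozen after burn-in, so the post-burn-in chain is a
fixed-kernel Markov chain. Post-burn-in acceptance settles in the 0.25–0.35
band.

Three structural moves are interleaved with the component-wise updates,
all exact Metropolis–Hastings proposals: a **group translation** (a cell's
group mean and every subject value in the cell shift together, leaving the
prior deviations unchanged), a **group dilation** (a pooled scale and the
subject deviations it governs are multiplied by a common factor, with the
prior density and coordinate Jacobian cancelling except for the scale
coordinate), and a **scale jump** that proposes a pooled scale directly
from its inverse-gamma conditional given the subject deviations, with the
truncation normalizers supplying the acceptance ratio (in the additive
model, whose subject priors are plain normal, this reduces to an exact
Gibbs draw). The first two decouple the centred hierarchy's funnel
geometry; the third traverses the concentrated and diffuse regions of a
weakly identified scale — `sigma_t0` in slow cells is the canonical case —
in a single step. The scale jump carries no step size, so it is bookkept
outside the tuned random-walk acceptance statistics. With these moves,
desk-scale fits reach max R-hat below 1.05 within 3 × 1500 iterations.

One related prior detail: the scale hyperprior's "half the mean range" cap
is computed for `t0` from the *effective* mean range — the minimum
observed RT bounds the `t0` mean by construction — rather than the
nominal [0.01, 3 s] support. The nominal cap leaves a long, nearly flat
tail in `sigma_t0` (non-decision time is weakly identified by slow cells'
likelihood), which destabilizes its convergence diagnostic without adding
scientific content.

Chains are initialized from moment-based (EZ-style) estimates computed on
each pooled design cell, jittered per chain for over-dispersion, so the
Gelman–Rubin diagnostic is informative.

### The four model structures

The factor map applies to all four diffusion parameters at once, and —
deliberately — to the *subject* level as well as the group level:

| Model | Group-level locations | Subject level | free locations |
|---|---|---|---|
| 1 | one mean per hierarchy | 3 values/parameter | 12 |
| 2 | one mean per block | 5 values/parameter | 20 |
| 3 | hierarchy baselines + zero-sum block offsets | additive (3 + 4 free) | 28 |
| 4 | one mean per hierarchy × block cell | 15 values/parameter | 60 |

An additive model whose subjects carry free cell-wise parameters could
absorb an interaction at the subject level and become empirically
indistinguishable from the full model; constraining the subject level to
the same additive structure is what makes the model space a real
hypothesis ladder. For Model 3 the subject-level block offsets carry plain
normal priors on the four free coordinates with an admissibility indicator
on the implied cell values (the truncation mass is negligible away from
the bounds, and an exact normalizer for the jointly-constrained additive
decomposition has no closed form).

Group scales are pooled: one per parameter and hierarchy (Models 1, 3, 4)
or per parameter and block (Model 2), plus one offset scale per parameter
in Model 3. A free scale per design cell would be unidentifiable with six
trials per cell.

The published table this design comes from prints 60 degrees of freedom
for *both* the additive and the interaction model; no additive
parameterization can have the same free-location count as the cell-wise
model, so the additive structure here has `4 × (3 + 5 − 1) = 28` free
locations and the printed additive count is treated as a typographical
inconsistency of the source.

### Information criteria and LOO

`AIC = 2k − 2 logL̂` and `BIC = k log n − 2 logL̂` use a **group-level**
plug-in likelihood: the likelihood of the data as a function of the
group-level cell values only (`k` is the free group-location count),
maximized over the retained posterior draws. Two choices matter here.
First, group-level rather than subject-level: evaluating the plug-in at
subject-level posterior means would let every model's subject layer absorb
trial noise — the cell-wise model gains over a hundred log-likelihood
units of pure overfit on 900 null trials that `k` never penalizes, and
the comparison degenerates to "always pick the most flexible structure".
With the group-level plug-in the criteria compare exactly the parameters
they count. Second, the maximum over retained draws rather than the value
at the posterior means: AIC and BIC are maximum-likelihood criteria, and
the best visited draw is a stable constrained-ML proxy that does not
inherit the Monte-Carlo noise of posterior-mean estimates — at desk
scales that noise (several log-likelihood units) is comparable to the AIC
margins being decided.

`elpd_loo()` implements Pareto-smoothed importance-sampling LOO from the
retained draws' pointwise log-likelihood matrix (subject-level, so the
predictive is the fitted hierarchical model): per observation the largest
importance ratios are replaced by expected order statistics of a
generalized Pareto tail fitted by the Zhang–Stephens profile method;
shapes above 0.7 attach a reliability warning. The standard error of a
pairwise ELPD difference is computed from the pointwise differences, never
from the two standard errors in quadrature. Selection follows the lowest
AIC among converged fits (max R-hat < 1.05), with every pairwise ELPD
difference reported against the `2 × SE` rule.

### Interaction summary

The scalar "interaction posterior mean" reported for cell-wise fits is not
uniquely defined by a 3 × 5 cell table. `interaction_contrast()` computes,
per posterior draw, the difference-of-differences of group cell means
averaged over adjacent hierarchy pairs and adjacent block pairs, and any
alternative 3 × 5 contrast matrix can be supplied. No equivalence with any
particular published scalar is asserted.

## Behavioural statistics

`preprocess_trials()` applies participant screening first (learning-phase
accuracy below 80%, or a failed hierarchical-response protocol flag), then
trims RT outliers in one pass: below 0.2 s, or above the participant ×
hierarchy × block cell mean plus 3 SD. The source methods do not state
their outlier thresholds; these are conventional values, documented and
configurable. `rm_anova()` aggregates trials to participant × cell means
(mean accuracy, or mean correct RT) and delegates the 3 × 5
repeated-measures ANOVA to `car::Anova` (multivariate linear model with a
within-subject design), reporting Greenhouse–Geisser–corrected degrees of
freedom and p-values and partial eta squared
`SS_effect / (SS_effect + SS_error)`; the sums of squares are verified
against a brute-force decomposition in the tests. Pairwise comparisons are
paired t-tests with Bonferroni adjustment (the source is silent on the
correction).

## Features and forests

`build_features()` assembles the eleven trial-level features: block, rule
hierarchy and their product; the four diffusion parameters `v`, `a`, `t0`,
`Z0` mapped to each trial from the subject × cell posterior means of a
cell-wise fit, plus the cell's mean group-level R-hat as a convergence
index; and three dynamic features — cumulative moving averages (CMA) of
accuracy and of log RT over trials `1..t−1` of the same participant only,
and the rule-switch flag. The start proportion `z` is excluded because it
is `Z0/a`. The first trial has no history: the accuracy CMA starts at 0.5
and the RT CMA is left missing, to be imputed with the *training-fold*
median log-RT history at fit time — this preserves the guarantee, tested
by perturbation, that no feature value at trial `t` depends on trials at
or after `t`.

Forests are grown by `ranger` (trees limited to depth 10 and terminal
nodes of at least 5, bootstrap resampling with stored in-bag counts);
n_trees defaults to 300 (unstated in the source; configurable).
Classification trees split on Gini impurity and draw *all* features at
each split (pure bagging, the literal reading of the source's procedure);
regression trees on variance reduction with `ceiling(11/3) = 4` features.
The package implements the evaluation machinery itself: out-of-bag
aggregation from the stored in-bag counts, participant-grouped 5-fold
cross-validation (folds partition participants, sizes differing by at most
one; the methods-section grouped scheme is used where the source's results
section once says "stratified"), 50-repeat OOB permutation importance
(accuracy drop for classification, RMSE increase for regression, floored
at zero and normalized to sum to one; F1 uses the correct class as
positive), and the full-versus-Top-8 refit comparison.

## What the generator does and does not emulate

The generator reproduces the design's structure: 5 blocks × 3 hierarchies
× 6 trials per cell (90 trials per participant, hierarchy order randomized
within block), a screening fixture with 40 collected and exactly 6
excluded participants (5 learning-accuracy, 1 protocol; 15%), and
diffusion-generated RT/accuracy with cell-wise parameters at the reference
posterior means. It does not emulate fixation jitter, cue screens, the
multi-keypress response structure (one RT per trial), sequential
dependencies beyond the cell parameters, fatigue, or contaminant
responses. Passing tests therefore demonstrate internal consistency of the
estimation and analysis machinery under the model's own assumptions — not
robustness to the contaminants and non-stationarities of real data.

## Problem sizes used by the test-suite harnesses

The package's checks run at deliberately reduced scales, chosen as the
smallest sizes at which each property is statistically decidable:
parameter recovery and convergence on 10 subjects × 30 trials per
hierarchy with 3 chains × 1500 iterations; the planted-interaction
selection harness on 12 subjects × 12 trials per cell (the
difference-of-KL between the cell-wise truth and its best additive
approximation must clear the AIC penalty gap of 32 log-units, which fixes
the minimum trial count); the null selection harness on 10 subjects at the
study's own 6 trials per cell. Forest harnesses use a few hundred
synthetic trials with 60-tree forests.

## Known limitations

* The sampler is random-walk Metropolis–Hastings by design; gradient-based
  samplers would scale better to many more subjects.
* Inter-trial variability parameters (sv, st0, sz) are not modelled.
* The plug-in information criteria are not marginal-likelihood based;
  their absolute magnitudes are not comparable across packages, only
  differences within a run are meaningful.
* PSIS-LOO reliability degrades (flagged k̂ > 0.7) for observations with
  extreme importance ratios, as with any IS-based LOO.
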