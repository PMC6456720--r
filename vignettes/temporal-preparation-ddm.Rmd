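---
title: "Modelling temporal preparation with hierarchical drift-diffusion models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temporal preparation with hierarchical drift-diffusion models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In a variable-foreperiod task, a warning signal precedes an imperative
stimulus by a random delay (the foreperiod), and the subject makes a speeded
two-choice response (left/right key to a left/right stimulus).  When
foreperiods in a block are drawn from a distribution that is narrow and
short, stimulus onset is easy to anticipate; when the distribution is long
and wide, it is not.  The working hypothesis this package operationalises is
that *temporal uncertainty* — how poorly the subject can anticipate onset —
is expressed in the decision stage as a widening of the boundary separation
of a drift-diffusion process, and that dopamine depletion (as in Parkinson's
disease tested off medication) saturates that uncertainty so that the
boundary no longer tracks the manipulation.

`tpddm` provides the full loop needed to study this claim in simulation:

1. a synthetic-cohort generator reproducing the blocked 2×2 task design
   with known ground-truth parameters,
2. an exact Wiener first-passage-time (WFPT) likelihood and a trial
   simulator,
3. hierarchical Bayesian estimation of three competing model variants with
   DIC comparison, convergence diagnostics, posterior predictive checks and
   posterior-overlap group inference, and
4. the companion behavioural layer: outlier filtering, per-subject Poisson
   and linear regressions, and group-level frequentist tests.

## Task design and the synthetic cohort

The design crosses foreperiod *duration* (Short: mean 1500 ms; Long:
3000 ms) with foreperiod *variability* (Low: SD 100 ms; High: 600 ms).
Foreperiods are truncated-Gaussian: at 500–2500 ms for the Short cells and
2000–4000 ms for the Long cells, symmetric about the mean so that
truncation does not move it.  A session is 4 blocks × 120 trials, one
condition per block, with block order balanced by a cyclic Latin square.
Each cell carries a temporal-predictability rank `tp_rank` from 4 (most
predictable) to 1.

The ordering of the two middle cells is not forced by the design.  The
package ranks duration before variability (Short/Low = 4, Short/High = 3,
Long/Low = 2, Long/High = 1), because onset uncertainty grows with both the
length and the spread of the foreperiod distribution and the duration
manipulation is the larger of the two effects here; `make_condition_grid()`
accepts any permutation for sensitivity analyses.

Every regression in the package uses the recoded predictor `x = 4 -
tp_rank`, so `x = 0` at the highest predictability and an intercept is
literally "the value when onset is most predictable"; positive slopes mean
the quantity grows as predictability falls.

`generate_cohort()` draws, per subject, a boundary intercept/slope pair
over `x` (`b = b0 + b1 x`), one drift rate, and one non-decision time from
group-level normals, then simulates every trial with the diffusion
simulator.  The default group truths follow the published group-level
estimates for this task: boundary intercept/slope 0.869/0.040 (controls),
0.931/0.059 (patients on medication), 1.065/0.001 (patients off
medication), with between-subject SDs of roughly 0.10–0.16 and 0.05.
Drift (3.1–3.5 per second) and non-decision time (250–290 ms) are chosen so
simulated mean RTs fall in the empirical 300–450 ms band with accuracy near
95%.  An optional per-group drift slope `v1` generates drift-driven rather
than boundary-driven predictability effects, which the model-recovery
studies need; an optional `fp_effect` adds a hazard-style speeding of
responses at long foreperiods, and `lapse_rate` injects missed responses
for exercising validity filters.

What the generator does *not* emulate: sequential effects (block order,
learning, fatigue), across-trial parameter variability, contaminant RTs
other than lapses, and any correlation between behavioural and clinical
state.  Passing recovery tests therefore show that the estimator works when
its assumptions hold, not that real patient data satisfy them.

```{r}
library(tpddm)
spec <- cohort_spec(n_subjects_per_group = 16,
                    groups = default_group_truth(), seed = 1)
cohort <- generate_cohort(spec)
head(cohort$trials)
```

## The diffusion model and its likelihood

A two-boundary Wiener process with unit diffusion coefficient accumulates
evidence from start point `z` between boundaries 0 and `b`; absorption at a
boundary triggers the mapped response after a non-decision latency `t0`.
Under *stimulus coding* the lower/upper boundaries are the left/right
responses, and the drift is `+v` for right-side stimuli and `-v` for
left-side ones, so a single positive `v` expresses evidence quality toward
the correct response.  Because left/right stimuli are equiprobable and
counterbalanced, the start point is fixed at the unbiased midpoint
`z/b = 0.5` in all fitted models (configurable in `ddm_params()` for the
density and simulator).

The unit-diffusion, seconds-scale convention makes fitted boundaries land
in the 0.8–1.1 range of the published estimates; milliseconds are converted
at module boundaries and the trial tables store integer-rounded
milliseconds at I/O.

The defective first-passage density is evaluated by the standard dual
series representation: a small-time image expansion and a large-time
eigenfunction expansion.  The truncation depth of each series is computed
from the requested absolute error (default `1e-7`), and the cheaper series
is selected by the usual error-bound crossover; nothing is hard-coded.  The
upper-boundary density is obtained from the lower-boundary series by the
reflection `(v, w) -> (-v, 1 - w)`.  Densities are zero (log-likelihood
`-Inf`) for response times at or below `t0` — a contract, not an error, so
samplers can treat impossible proposals as rejections.

The simulator is an Euler–Maruyama walk (default step `1e-4` s, hard cap
20 s with explicit censoring flags).  Discrete monitoring of a continuous
barrier misses in-step crossings, inflating first-passage times by
`O(sqrt(dt))` — about +2.4% on the mean at `dt = 1e-4`.  The simulator
therefore pulls the absorption thresholds inward by `0.5826*sqrt(dt)` (the
continuity correction for discretely monitored barriers) by default, after
which simulated and analytic distributions agree at Kolmogorov–Smirnov test
precision with 10^5 draws.  `correct = FALSE` restores the plain walk.

## Hierarchical estimation

Three variants differ in which parameters may vary across the four
predictability conditions: `M1_boundary` frees boundary separation only,
`M2_drift` frees drift only, `M3_both` frees both.  Non-decision time never
varies by condition but is free across groups; each group (e.g. controls,
patients on, patients off) gets a fully independent hierarchy — no shared
hyperpriors — matching the design in which groups are estimated separately.

Priors are weakly informative and live in `default_priors()`: group-mean
boundary ~ Normal(1.5, 0.75) on positive support, drift ~ Normal(2, 3),
non-decision time ~ Normal(0.3, 0.25) on positive support, and half-Normal
(0.5) priors on the group SDs.  They cover the plausible human two-choice
regime without dominating subjects who contribute several hundred trials.
Positivity of subject-level boundaries and non-decision times is enforced
through the likelihood support itself (the WFPT density is zero for invalid
parameters), which keeps the hierarchy conjugate where it can be.

The sampler is Metropolis-within-Gibbs: subject-level parameters are
updated by vectorised random-walk Metropolis (subjects are conditionally
independent given the group level), group means by conjugate Gibbs draws
(inverse-CDF truncated normal where the support is positive), and group SDs
by log-scale random walks.  Proposal scales adapt toward ~35% acceptance
during burn-in only, so the post-burn-in chain is a valid fixed-kernel
chain.  Everything is deterministic given `seed`.

The reference run mirrors the production setting of 50,000 iterations with
5,000 discarded as burn-in.  All recovery studies, tests and the acceptance
script use a documented reduced profile — 4,000 iterations, 1,000 burn-in,
2 chains — which is sufficient for the group-level quantities examined
(R-hat < 1.1 throughout in the recovery runs); the scale-down is explicit,
never silent.  The test suite additionally uses a smaller "smoke" profile
(800/250) for structural end-to-end checks only.

```{r}
fit <- fit_hddm(cohort$trials, variant = "M1_boundary",
                n_samples = 4000, n_burn = 1000, n_chains = 2, seed = 2)
summary(fit)
dic(fit)
```

### Model comparison, checks and group inference

`dic()` computes the conditional DIC at the subject-level parameters — the
standard choice for hierarchical diffusion models — with
`p_D = mean deviance - deviance at the posterior mean` and
`DIC = mean deviance + p_D`; independent group hierarchies add.
`compare_models()` ranks fits on identical data (verified by fingerprint)
and reports pairwise DIC differences, flagging exact ties.

`posterior_predictive_check()` simulates full replicates of the fitted
trials from random posterior draws (500 in the reference analysis) and
compares observed RT quantiles (10/30/50/70/90%) and correct-choice
proportions per group × condition against the central 95% band of the
replicates.

Group inference on a shared parameter uses the posterior-overlap statistic
`q = 2 min{P(theta_a > theta_b), P(theta_a < theta_b)}`, estimated by
paired resampling of the two groups' draws with ties split evenly.  The
prose notion of "overlap proportion" is ambiguous; this two-sided
exceedance definition is a declared choice: it is symmetric, invariant to
common monotone shifts, 1 for identical posteriors and 0 for disjoint ones,
and reproduces the usual decision logic.  Significance is flagged at
`q < 0.05/3 ≈ 0.0167`, Bonferroni-corrected for the three pairwise group
contrasts.

## Behavioural layer

* `filter_rts()` marks a response invalid when its RT is below 100 ms or
  exceeds the subject's median by more than 3 *unscaled* median absolute
  deviations (no 1.4826 consistency factor), one-sided and inclusive at the
  boundary.  The rule is applied per subject.  Note it is not idempotent
  under heavy contamination: removing extreme values shrinks the survivors'
  MAD, so a second pass can remove more.  On realistic uncontaminated RT
  distributions a second pass removes nothing.
* `poisson_regression()` regresses integer-millisecond RTs on `x` with a
  log link and the Poisson variance function (quasi-likelihood;
  overdispersion does not move the point estimates, and only the point
  estimates feed the group tests).  It is run at trial level; whether to
  include error trials is a switch in `subject_regressions()` (included by
  default).
* `foreperiod_slope()` is the within-trial hazard check: ordinary least
  squares of RT on foreperiod, negative slopes meaning faster responses
  later in the trial.
* `boundary_regression()` fits the per-subject line through the four
  posterior-mean boundaries over `x`.
* `group_tests()` wraps the standard machinery (one-way ANOVA with
  eta-squared, Welch-corrected post-hocs with fractional df, paired and
  one-sample t-tests with Cohen's d_z), `spearman_boundary_rt()` the
  boundary–RT rank correlation, and `fisher_z()` the arctanh transform used
  before parametric tests on correlations.

## Pipeline

`run_pipeline()` sequences generate → filter → fit → compare → analyse →
report from a single config (R list, YAML or JSON), with one seed split
deterministically across stages, and persists every intermediate artifact
(trial CSV, ground-truth sidecar, posterior draws as long CSV plus JSON
metadata, regression tables, a single JSON report).  Identical config and
seed give an identical report body.

## Numerical and design choices, in one place

* Density series: truncation depths from the error bound; default absolute
  error `1e-7`; small/large-time crossover by comparing required terms.
* Simulator: Euler step `1e-4` s; continuity correction on by default;
  20 s cap with explicit censoring.
* Sampler: adaptation only during burn-in; Robbins–Monro step tied to the
  iteration number; at least 2 chains enforced for diagnostics.
* R-hat: classic between/within variance ratio; identical constant chains
  give exactly 1 by convention.
* Recovery problem sizes: 16 subjects × 480 trials for parameter recovery
  (3 seeds), 10 subjects × 480 trials per generating model for DIC model
  recovery (3 seeds), both at the reduced profile; these sizes give stable
  group-level estimates while keeping a full recovery study tractable on a
  single CPU.
* Ties and degenerate inputs: MAD 0 keeps everything at or below the
  median; flat regressions return slope 0 with R² defined as 1 for an
  exact fit; `compare_models()` reports exact DIC ties rather than breaking
  them.

## Known limitations

* No across-trial variability parameters (drift, start point, t0); the
  fitted model family does not include them, matching the three variants
  under study.
* No collapsing-boundary or urgency variants, and no WAIC/LOO.
* The Poisson regression treats rounded RTs as counts; this is a
  quasi-likelihood device for point estimation, not a generative claim.
* Synthetic cohorts are stationary within a session; none of the
  order/learning effects a real two-session patient study may contain are
  modelled, and empirical patient-level results are outside what simulation
  can reproduce.
* The generator draws boundary, drift and non-decision parameters
  independently across subjects.  Real cohorts show correlated individual
  differences (slow subjects tend to be slow in every parameter), which
  inflate pooled boundary-RT correlations; with independent nuisance
  variation at realistic levels the within-group Spearman correlation
  between fitted boundaries and mean RTs sits near 0.4–0.7 even when
  boundary recovery against ground truth exceeds r = 0.8.
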