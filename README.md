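# tpddm — hierarchical drift-diffusion modelling of temporal preparation

`tpddm` is an R package for studying how *temporal predictability* shapes
two-choice decisions in variable-foreperiod tasks, and how that coupling
degrades when dopamine is depleted (as in Parkinson's disease tested off
medication).  It is aimed at cognitive and clinical modellers who want a
fully simulated, ground-truth-controlled version of this analysis: generate
a synthetic cohort, fit competing hierarchical drift-diffusion models,
compare them, and run the accompanying behavioural statistics.

## The model

Each trial is a two-boundary Wiener diffusion: evidence `x` starts at
`z = b/2` between boundaries 0 and `b`, drifts at rate `±v` (sign set by
the stimulus side under *stimulus coding*: lower boundary = left response,
upper = right) with unit diffusion coefficient, and the response time is
the first-passage time plus a non-decision latency `t0`.  The trial
likelihood is the defective first-passage density

    f(t | b, v, z, t0)

evaluated by the standard dual (small-time / large-time) series expansion
with adaptive truncation.  Subjects are random draws from group-level
normals (a hierarchy per group), and three variants compete:

| variant | condition-varying | fixed across conditions |
|---|---|---|
| `M1_boundary` | boundary `b` per predictability level | `v`, `t0` |
| `M2_drift` | drift `v` per predictability level | `b`, `t0` |
| `M3_both` | `b` and `v` | `t0` |

Models are fitted by Metropolis-within-Gibbs MCMC and compared by DIC;
group differences are assessed by the posterior-overlap statistic
`q = 2 min{P(θ_a > θ_b), P(θ_a < θ_b)}` with a Bonferroni-corrected
threshold of 0.05/3 ≈ 0.0167.  The behavioural layer mirrors the RT
analyses: a per-subject Poisson regression of RT on the predictability
rank, a foreperiod-effect linear regression, an RT validity filter
(RT < 100 ms or above median + 3 MAD), and one-way ANOVA / Welch /
paired-t group tests with η² and Cohen's d_z effect sizes.

## Worked example

Generate a control-like cohort of 8 subjects (4 blocks × 120 trials each,
boundary intercept 0.869 and slope 0.040 over the predictability steps) and
fit the boundary-varying variant at the reduced MCMC profile:

```r
library(tpddm)
spec <- cohort_spec(n_subjects_per_group = 8,
                    groups = default_group_truth()["Control"], seed = 1)
cohort <- generate_cohort(spec)
fit <- fit_hddm(cohort$trials, variant = "M1_boundary",
                n_samples = 4000, n_burn = 1000, n_chains = 2, seed = 2)
summary(fit)
```

```
Group-level posterior summary (M1_boundary)

Group: Control 
 parameter   mean     sd   q2.5  q97.5 rhat
   mu_b[1] 0.8529 0.0481 0.7613 0.9513    1
   mu_b[2] 0.9171 0.0493 0.8209 1.0173    1
   mu_b[3] 0.9866 0.0494 0.8907 1.0878    1
   mu_b[4] 1.0402 0.0499 0.9450 1.1421    1
     sig_b 0.1280 0.0237 0.0905 0.1868    1
   mu_v[1] 3.4173 0.1340 3.1476 3.6794    1
     sig_v 0.3315 0.1208 0.1566 0.6276    1
     mu_t0 0.2606 0.0107 0.2390 0.2819    1
    sig_t0 0.0283 0.0103 0.0155 0.0562    1
```

`mu_b[1]`…`mu_b[4]` are the group-mean boundaries from the most to the
least predictable condition: the fitted profile rises from 0.85 to 1.04,
recovering this cohort's generating intercept/slope structure; `mu_v[1]`
and `mu_t0` recover the shared drift (truth 3.5 per second) and
non-decision time (truth 0.25 s), and all chains converge (R-hat = 1.00).
Continuing,

```r
d <- dic(fit)                       # DIC -8546.2 (p_D 43.2)
sb <- subject_boundaries(fit)       # posterior-mean boundary per condition
s1 <- sb[sb$subject_id == sb$subject_id[1], ]
boundary_regression(s1$boundary, s1$tp_rank)
#> intercept 0.82804  slope 0.040503  R^2 0.707
```

gives the conditional DIC and the per-subject boundary-vs-predictability
line whose intercept/slope are the quantities compared across groups.
`run_pipeline()` chains all stages (generate → filter → fit → compare →
analyse → report) from one seeded config.

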