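test_that("R-hat: identical chains give 1, split chains diverge", {
  set.seed(30)
  x <- rnorm(2000)
  # chains with identical draws
  expect_equal(rhat(cbind(x, x)), 1, tolerance = 1e-3)
  # constant identical chains: exactly 1 by convention
  expect_identical(rhat(cbind(rep(2, 50), rep(2, 50))), 1)
  # chains stuck at different constants: far above the 1.1 threshold
  expect_gt(rhat(cbind(rep(0, 50), rep(5, 50))), 1.1)
  # well-mixed independent chains stay near 1
  expect_lt(rhat(matrix(rnorm(4000), ncol = 4)), 1.05)
  expect_error(rhat(matrix(1:10, ncol = 1)), "2 chains")
  expect_error(rhat(matrix(1:8, ncol = 2)), "10 post-burn")
})

test_that("overlap q: limits, oracle, symmetry and shift invariance", {
  set.seed(31)
  a <- rnorm(20000)
  # same distribution: full overlap
  expect_equal(overlap_q(a, a), 1, tolerance = 0.02)
  # disjoint supports: zero overlap
  expect_identical(overlap_q(runif(1000, 0, 1), runif(1000, 2, 3)), 0)
  # oracle for two unit normals 3 SD apart: q = 2*Phi(-3/sqrt(2))
  b <- rnorm(20000, 3)
  q_true <- 2 * pnorm(-3 / sqrt(2))
  expect_lt(abs(overlap_q(a, b, n_resample = 2e5) - q_true), 0.006)
  # symmetry and invariance under a common shift
  q_ab <- overlap_q(a, b, n_resample = 1e5)
  expect_equal(overlap_q(b, a, n_resample = 1e5), q_ab, tolerance = 0.02)
  expect_equal(overlap_q(a + 7, b + 7, n_resample = 1e5), q_ab,
               tolerance = 0.02)
  expect_error(overlap_q(numeric(0), 1:3), "non-empty")
})

test_that("model layout per variant and input validation", {
  ch <- tiny_cohort()
  lay1 <- tpddm:::variant_layout("M1_boundary")
  lay2 <- tpddm:::variant_layout("M2_drift")
  lay3 <- tpddm:::variant_layout("M3_both")
  expect_equal(c(lay1$nb, lay1$nv), c(4, 1))
  expect_equal(c(lay2$nb, lay2$nv), c(1, 4))
  expect_equal(c(lay3$nb, lay3$nv), c(4, 4))
  expect_error(tpddm:::variant_layout("M4"), "unknown variant")
  m1 <- hddm_model(ch$trials, "M1_boundary")
  expect_s3_class(m1, "hddm_model")
  expect_error(hddm_model(ch$trials, "M4"), "'arg' should be one")
  expect_error(hddm_model(ch$trials[, -3], "M1_boundary"), NA)  # session not required
  expect_error(hddm_model(ch$trials[, setdiff(names(ch$trials), "rt_ms")]),
               "rt_ms")
  # an empty (group, condition) cell is rejected by name
  tr <- ch$trials[ch$trials$tp_rank != 2, ]
  expect_error(hddm_model(tr, "M1_boundary"), "empty \\(group, condition\\)")
})

test_that("fitted parameter sets match the variant definition", {
  f1 <- tiny_fit("M1_boundary")
  g <- f1$groups[[1]]
  expect_equal(sum(grepl("^mu_b", g$par_names)), 4)
  expect_equal(sum(grepl("^mu_v", g$par_names)), 1)
  expect_true("mu_t0" %in% g$par_names)
  f2 <- tiny_fit("M2_drift")
  g2 <- f2$groups[[1]]
  expect_equal(sum(grepl("^mu_b", g2$par_names)), 1)
  expect_equal(sum(grepl("^mu_v", g2$par_names)), 4)
})

test_that("sampling is deterministic given the seed", {
  ch <- tiny_cohort()
  tr <- ch$trials[ch$trials$subject_id %in%
                    unique(ch$trials$subject_id)[1:2], ]
  f1 <- fit_hddm(tr, "M1_boundary", n_samples = 150, n_burn = 50,
                 n_chains = 2, seed = 99)
  f2 <- fit_hddm(tr, "M1_boundary", n_samples = 150, n_burn = 50,
                 n_chains = 2, seed = 99)
  expect_identical(f1$groups[[1]]$chains, f2$groups[[1]]$chains)
  f3 <- fit_hddm(tr, "M1_boundary", n_samples = 150, n_burn = 50,
                 n_chains = 2, seed = 100)
  expect_false(identical(f1$groups[[1]]$chains, f3$groups[[1]]$chains))
})

test_that("null likelihood reproduces the priors (smoke)", {
  ch <- tiny_cohort()
  f <- fit_hddm(ch$trials, "M1_boundary", n_samples = 3000, n_burn = 500,
                n_chains = 2, seed = 33, likelihood = "null")
  mu_v <- posterior_param(f, "Control", "mu_v[1]")
  pr <- default_priors()
  # marginal of the group mean under a flat likelihood is its prior
  expect_lt(abs(mean(mu_v) - pr$mu_v[["mean"]]), 0.4)
  expect_lt(abs(sd(mu_v) - pr$mu_v[["sd"]]), 0.6)
  mu_t0 <- posterior_param(f, "Control", "mu_t0")
  expect_true(all(mu_t0 > 0))
})

test_that("single-subject input still yields a well-defined fit", {
  ch <- tiny_cohort()
  tr <- ch$trials[ch$trials$subject_id == unique(ch$trials$subject_id)[1], ]
  f <- fit_hddm(tr, "M1_boundary", n_samples = 200, n_burn = 50,
                n_chains = 2, seed = 44)
  expect_s3_class(f, "hddm_fit")
  d <- tpddm:::post_draws(f$groups[[1]], f$n_burn)
  expect_true(all(is.finite(d)))
})

test_that("DIC arithmetic: point-mass posterior has p_d = 0", {
  f <- tiny_fit("M1_boundary")
  # collapse every chain onto a single posterior draw
  fp <- f
  fp$groups <- lapply(f$groups, function(g) {
    row <- g$chains[[1]][nrow(g$chains[[1]]), , drop = FALSE]
    g$chains <- lapply(g$chains, function(m) row[rep(1, nrow(m)), , drop = FALSE])
    g
  })
  d <- dic(fp)
  expect_equal(d$p_d, 0, tolerance = 1e-3)
  expect_equal(d$dic, d$mean_deviance, tolerance = 1e-3)
})

test_that("compare_models ranks by DIC, reports ties, rejects foreign fits", {
  f1 <- tiny_fit("M1_boundary")
  f2 <- tiny_fit("M2_drift")
  cmp <- compare_models(list(M1_boundary = f1, M2_drift = f2))
  expect_equal(cmp$dic, sort(cmp$dic))
  expect_equal(cmp$delta_dic[1], 0)
  # duplicated fit: explicit tie
  cmp2 <- compare_models(list(a = f1, b = f1))
  expect_true(all(cmp2$tie_with_best))
  expect_equal(cmp2$delta_dic, c(0, 0))
  # different data rejected
  spec <- cohort_spec(n_subjects_per_group = 2,
                      groups = default_group_truth()["Control"],
                      n_trials_per_block = 20, seed = 55)
  other <- generate_cohort(spec)
  f3 <- fit_hddm(other$trials, "M1_boundary", n_samples = 150, n_burn = 50,
                 n_chains = 2, seed = 1)
  expect_error(compare_models(list(f1, f3)), "identical trial data")
  expect_error(compare_models(list(f1)), "at least 2")
})

test_that("posterior predictive checks cover self-generated data", {
  f <- tiny_fit("M1_boundary")
  # n_sims = 1: exactly one replicate per cell statistic
  p1 <- posterior_predictive_check(f, n_sims = 1, seed = 60)
  expect_equal(p1$n_sims, 1)
  expect_true(all(p1$summaries$sim_lo == p1$summaries$sim_hi))
  # fitted to its own data: most cells inside the 95% band
  p <- posterior_predictive_check(f, n_sims = 80, seed = 61)
  expect_gt(p$coverage, 0.85)
})

test_that("posterior predictive check flags a mis-specified fit", {
  # boundary-driven data with a steep predictability profile, fitted with the
  # drift-only variant: the replicate distribution cannot track all observed
  # cell statistics
  spec <- cohort_spec(
    n_subjects_per_group = 4,
    groups = list(Control = list(
      mean = c(b0 = 0.8, b1 = 0.2, v = 3.5, t0 = 0.25),
      sd = c(b0 = 0.05, b1 = 0.02, v = 0.2, t0 = 0.01))),
    n_trials_per_block = 80, seed = 66)
  ch <- generate_cohort(spec)
  f <- fit_hddm(ch$trials, "M2_drift", n_samples = 900, n_burn = 300,
                n_chains = 2, seed = 67)
  p <- posterior_predictive_check(f, n_sims = 60, seed = 68)
  expect_true(any(!p$summaries$covered))
})
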