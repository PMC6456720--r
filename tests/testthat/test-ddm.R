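test_that("absorption probability: symmetry, limits, closed form vs simulation", {
  expect_equal(upper_prob(ddm_params(b = 1, v = 0, w = 0.5)), 0.5)
  expect_equal(upper_prob(ddm_params(b = 2, v = 50, z = 0.4)), 1, tolerance = 1e-6)
  expect_equal(upper_prob(ddm_params(b = 2, v = -50, z = 1.6)), 0, tolerance = 1e-6)
  # continuity at v -> 0
  expect_equal(upper_prob(ddm_params(b = 2, v = 1e-10, z = 0.7)), 0.35,
               tolerance = 1e-6)
  # closed form agrees with an independently written oracle
  for (pars in list(c(2, 1, 1), c(1.5, -0.8, 0.9), c(0.8, 2.5, 0.3))) {
    p <- ddm_params(b = pars[1], v = pars[2], z = pars[3])
    expect_equal(upper_prob(p), oracle_upper_prob(pars[1], pars[2], pars[3]),
                 tolerance = 1e-10)
  }
  # Monte-Carlo check at (b=2, v=1, z=1)
  p <- ddm_params(b = 2, v = 1, z = 1)
  set.seed(10)
  n <- 40000
  s <- simulate_fpt(p, n = n)
  phat <- mean(s$boundary == "upper")
  se <- sqrt(phat * (1 - phat) / n)
  expect_lt(abs(phat - upper_prob(p)), 3 * se)
})

test_that("zero-drift mean decision time matches the closed form z(b-z)", {
  p <- ddm_params(b = 1, v = 0, z = 0.5)
  set.seed(11)
  s <- simulate_fpt(p, n = 30000)
  expect_false(any(s$censored))
  se <- sd(s$decision_time) / sqrt(nrow(s))
  # 3 MC standard errors plus a small discretisation allowance
  expect_lt(abs(mean(s$decision_time) - 0.25), 3 * se + 0.002)
  expect_true(all(s$rt > p$t0))
})

test_that("density normalises to the absorption split on a stress grid", {
  for (b in c(0.5, 1.5, 3)) for (v in c(-3, 0, 1, 3)) for (w in c(0.2, 0.5, 0.8)) {
    p <- ddm_params(b = b, v = v, w = w, t0 = 0.2)
    fl <- integrate(function(t) wfpt_density(t, "lower", p), p$t0, Inf,
                    rel.tol = 1e-9)$value
    fu <- integrate(function(t) wfpt_density(t, "upper", p), p$t0, Inf,
                    rel.tol = 1e-9)$value
    expect_lt(abs(fl + fu - 1), 1e-4)
    expect_lt(abs(fu - upper_prob(p)), 1e-4)
  }
})

test_that("density is zero at or below t0 and respects reflection symmetry", {
  p <- ddm_params(b = 1.5, v = 0.7, w = 0.4, t0 = 0.3)
  expect_equal(wfpt_density(c(0.1, 0.3), "upper", p), c(0, 0))
  expect_error(wfpt_density(1, "upper", p, err_tol = 0), "err_tol")
  tgrid <- seq(0.31, 3, length.out = 40)
  for (v in c(-1.2, 0, 0.7)) for (w in c(0.3, 0.5, 0.65)) {
    pu <- ddm_params(b = 1.5, v = v, w = w, t0 = 0.3)
    pl <- ddm_params(b = 1.5, v = -v, w = 1 - w, t0 = 0.3)
    expect_equal(wfpt_density(tgrid, "upper", pu),
                 wfpt_density(tgrid, "lower", pl), tolerance = 1e-12)
  }
})

test_that("series expansions agree through the crossover region", {
  # compare default-precision evaluation against a much stricter tolerance;
  # the switch between small- and large-time branches moves with err_tol, so
  # agreement across a dense time grid exercises both sides of the crossover
  for (b in c(0.7, 1.5, 2.5)) {
    p <- ddm_params(b = b, v = 0.8, w = 0.5, t0 = 0)
    tgrid <- seq(0.02, 6, length.out = 300)
    d1 <- wfpt_density(tgrid, "upper", p, err_tol = 1e-7)
    d0 <- wfpt_density(tgrid, "upper", p, err_tol = 1e-12)
    expect_lt(max(abs(d1 - d0)), 1e-6)
  }
})

test_that("simulated decision times match the analytic law (KS)", {
  p <- ddm_params(b = 1.5, v = 0.8, z = 0.75, t0 = 0.3)
  set.seed(12)
  s <- simulate_fpt(p, n = 30000)
  su <- s$decision_time[s$boundary == "upper" & !s$censored]
  pu <- upper_prob(p)
  cdf <- function(q) vapply(q, function(qq)
    integrate(function(t) wfpt_density(t + p$t0, "upper", p), 0, qq,
              rel.tol = 1e-9)$value / pu, 0)
  ks <- suppressWarnings(stats::ks.test(su, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("long walks are censored and flagged, never dropped", {
  p <- ddm_params(b = 3, v = 0, w = 0.5)
  set.seed(13)
  s <- simulate_fpt(p, n = 200, cap = 0.05)
  expect_equal(nrow(s), 200)
  expect_true(any(s$censored))
  expect_true(all(is.na(s$boundary[s$censored])))
  expect_true(all(s$decision_time[s$censored] >= 0.05 - 1e-9))
})

test_that("trial log-likelihood: support, stimulus coding, grid recovery", {
  p <- ddm_params(b = 1.2, v = 2, t0 = 0.25)
  # rt at or below t0 yields the -Inf sentinel, not an error
  expect_identical(loglik_trial(c(0.1, 0.25), "LEFT", "LEFT", p),
                   c(-Inf, -Inf))
  # v = 0 and central start: LEFT and RIGHT responses equally likely
  p0 <- ddm_params(b = 1.2, v = 0, t0 = 0.1)
  expect_equal(loglik_trial(0.6, "LEFT", "LEFT", p0),
               loglik_trial(0.6, "RIGHT", "LEFT", p0), tolerance = 1e-12)
  # drift sign follows the stimulus: correct responses more likely
  expect_gt(loglik_trial(0.5, "RIGHT", "RIGHT", p),
            loglik_trial(0.5, "LEFT", "RIGHT", p))
  expect_gt(loglik_trial(0.5, "LEFT", "LEFT", p),
            loglik_trial(0.5, "RIGHT", "LEFT", p))
  # grid search over b on simulated data recovers the generating value
  set.seed(14)
  truth <- ddm_params(b = 1.2, v = 2.5, t0 = 0.25)
  stim <- sample(c("LEFT", "RIGHT"), 2000, replace = TRUE)
  sim <- simulate_fpt(ddm_params(b = 1.2, v = 2.5, t0 = 0.25), n = 2000)
  # stimulus coding: simulate with +v then flip boundary labels for LEFT
  resp <- ifelse(stim == "RIGHT",
                 ifelse(sim$boundary == "upper", "RIGHT", "LEFT"),
                 ifelse(sim$boundary == "upper", "LEFT", "RIGHT"))
  grid_b <- seq(0.8, 1.6, by = 0.05)
  ll <- vapply(grid_b, function(bb)
    sum(loglik_trial(sim$rt, resp, stim,
                     ddm_params(b = bb, v = 2.5, t0 = 0.25))), 0)
  expect_lt(abs(grid_b[which.max(ll)] - 1.2), 0.1)
})
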