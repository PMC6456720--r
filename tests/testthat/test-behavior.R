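test_that("MAD filter implements the stated rule exactly", {
  # median 320, raw MAD 20, upper cut 380, lower cut 100
  mask <- filter_rts(c(90, 300, 310, 320, 330, 340, 5000))
  expect_identical(mask, c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(mask), 5)
  # degenerate spread: MAD 0, boundary inclusive, all retained
  expect_true(all(filter_rts(rep(250, 6))))
  # boundary value exactly at median + 3 MAD survives (median 320, MAD 20)
  expect_true(all(filter_rts(c(290, 300, 320, 320, 340, 380))))
  # absolute lower cut
  expect_false(any(filter_rts(c(50, 60, 99, 99))))
  expect_error(filter_rts(numeric(0)), "non-empty")
})

test_that("MAD filter is stable on uncontaminated data", {
  # on data without gross outliers a second pass removes nothing; note the
  # literal rule is not idempotent under heavy contamination, because
  # removing extreme values shrinks the MAD of the survivors
  rts <- round(350 + 30 * sin(1:200) + 20 * cos(7 * (1:200)))
  once <- rts[filter_rts(rts)]
  expect_true(all(filter_rts(once)))
  # and the filter only ever removes, never re-admits
  set.seed(20)
  for (i in 1:10) {
    x <- rlnorm(150, log(350), 0.4)
    x[1:3] <- c(20, 4000, 9000)
    m1 <- filter_rts(x)
    expect_true(all(x[m1] >= 100))
    expect_lte(sum(filter_rts(x[m1])), sum(m1))
  }
})

test_that("Poisson regression: coding, flat case, monotone case, recovery", {
  # constant RT: slope 0 and exp(intercept) equals the constant
  r <- poisson_regression(rep(350, 40), rep(1:4, 10))
  expect_equal(r$beta1, 0, tolerance = 1e-8)
  expect_equal(exp(r$beta0), 350, tolerance = 1e-8)
  # RTs increasing as predictability falls: positive slope
  tp <- rep(4:1, each = 25)
  r2 <- poisson_regression(300 + 10 * (4 - tp), tp)
  expect_gt(r2$beta1, 0)
  expect_true(r2$r_squared >= 0 && r2$r_squared <= 1)
  # generative recovery around published control values (334 ms, 0.015/step)
  set.seed(21)
  tpg <- rep(4:1, each = 120)
  x <- 4 - tpg
  mu <- exp(log(334) + 0.015 * x)
  y <- rpois(480, mu)
  rg <- poisson_regression(y, tpg)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::quasipoisson()))
  ci <- suppressMessages(stats::confint(fit))
  expect_gt(0.015, ci[2, 1]); expect_lt(0.015, ci[2, 2])
  expect_equal(rg$beta1, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_error(poisson_regression(c(300, 310), c(2, 2)), "distinct")
  expect_error(poisson_regression(c(-1, 300), c(1, 2)), "non-positive")
})

test_that("foreperiod regression: exact line and flat case", {
  fp <- seq(500, 2500, length.out = 60)
  r <- foreperiod_slope(400 - 0.02 * fp, fp)
  expect_equal(r$beta1, -0.02, tolerance = 1e-10)
  expect_equal(r$beta0, 400, tolerance = 1e-8)
  expect_equal(r$r_squared, 1)
  r0 <- foreperiod_slope(rep(350, 60), fp)
  expect_equal(r0$beta1, 0, tolerance = 1e-12)
  expect_error(foreperiod_slope(c(1, 2), c(700, 700)), "distinct")
})

test_that("boundary regression: exact line, flat profile, missing condition", {
  r <- boundary_regression(c(0.9, 0.95, 1.0, 1.05), 4:1)
  expect_equal(r$beta1, 0.05, tolerance = 1e-12)
  expect_equal(r$beta0, 0.9, tolerance = 1e-12)
  # flat profile emulating dopamine-depleted patients
  rf <- boundary_regression(rep(1.065, 4), 1:4)
  expect_equal(rf$beta1, 0, tolerance = 1e-12)
  expect_equal(rf$beta0, 1.065, tolerance = 1e-12)
  expect_error(boundary_regression(c(1, 1, 1), c(4, 3, 2)), "tp_rank 1")
})

test_that("regressions are equivariant under condition relabeling", {
  set.seed(22)
  tp <- rep(4:1, each = 30)
  rts <- round(rlnorm(120, log(350 + 5 * (4 - tp)), 0.1))
  perm <- sample(120)
  a <- poisson_regression(rts, tp)
  b <- poisson_regression(rts[perm], tp[perm])
  expect_equal(a$beta0, b$beta0, tolerance = 1e-10)
  expect_equal(a$beta1, b$beta1, tolerance = 1e-10)
})

test_that("group tests match textbook formulas on hand fixtures", {
  # identical groups: F = 0, p = 1
  g <- rep(c("a", "b", "c"), each = 4)
  v <- rep(c(1, 2, 3, 4), 3)
  an <- group_tests(v, g, "anova")
  expect_equal(an$statistic, 0, tolerance = 1e-12)
  expect_equal(an$p, 1, tolerance = 1e-12)
  expect_equal(an$effect_size, 0, tolerance = 1e-12)
  # paired fixture y = x + 1: d_z = mean(diff)/sd(diff) with zero spread in
  # differences is infinite, so use a 5-pair fixture with spread
  x <- c(10, 12, 9, 14, 11); y <- c(12, 13, 12, 15, 14)
  pt <- group_tests(y, x, "paired_t")
  d <- y - x
  expect_equal(pt$effect_size, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(pt$statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(pt$df, 4)
  # one-sample d_z
  os <- group_tests(d, design = "one_sample_t")
  expect_equal(os$effect_size, mean(d) / sd(d), tolerance = 1e-12)
  # Welch df below pooled df for heteroscedastic groups
  set.seed(23)
  a <- rnorm(16, 0, 1); b <- rnorm(16, 0, 10)
  wt <- group_tests(c(a, b), rep(c("a", "b"), each = 16), "welch_posthoc")
  s1 <- var(a); s2 <- var(b)
  df_oracle <- (s1 / 16 + s2 / 16)^2 /
    ((s1 / 16)^2 / 15 + (s2 / 16)^2 / 15)
  expect_equal(wt$df, df_oracle, tolerance = 1e-8)
  expect_lt(wt$df, 30)
  # student two-sample uses pooled df
  st <- group_tests(c(a, b), rep(c("a", "b"), each = 16), "two_sample_t")
  expect_equal(st$df, 30)
  # one-tailed option shifts the p-value
  ot <- group_tests(d, design = "one_sample_t", alternative = "greater")
  expect_equal(ot$p, os$p / 2, tolerance = 1e-10)
  expect_error(group_tests(1:5, c(1, 2), "paired_t"), "aligned")
})

test_that("Spearman correlation and Fisher transform behave as stated", {
  expect_equal(spearman_boundary_rt(1:8, (1:8)^3), 1)
  expect_equal(spearman_boundary_rt(1:8, -(1:8)^3), -1)
  expect_error(spearman_boundary_rt(1:2, 1:2), "3 matched")
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- c(-0.9, -0.3, 0.2, 0.8)
  expect_equal(fisher_z(r), -fisher_z(-r))
  expect_error(fisher_z(1), "< 1")
})
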