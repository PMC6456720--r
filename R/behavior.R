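#' Outlier filter for one subject's reaction times
#'
#' A response is invalid when its RT is below 100 ms, or exceeds the
#' subject's median RT by more than 3 median absolute deviations.  The MAD is
#' unscaled (no normal-consistency factor) and the rule is one-sided: only
#' the upper tail is trimmed, boundary values inclusive (an RT exactly at
#' median + 3 MAD survives).  Apply per subject and session, since the rule
#' is individual.
#'
#' @param rts numeric vector of RTs in ms for one subject-session.
#' @return logical validity mask in input order (TRUE = keep).
#' @examples
#' filter_rts(c(90, 300, 310, 320, 330, 340, 5000))  # keeps the middle five
#' @export
filter_rts <- function(rts) {
  if (!length(rts)) stop("'rts' must be non-empty")
  med <- stats::median(rts, na.rm = TRUE)
  mad_raw <- stats::median(abs(rts - med), na.rm = TRUE)
  ok <- !is.na(rts) & rts >= 100 & rts <= med + 3 * mad_raw
  ok
}

# shared builder for the three per-subject regression results
regression_result <- function(beta0, beta1, fitted, observed) {
  r2 <- if (stats::var(observed) == 0 || stats::var(fitted) == 0) {
    if (isTRUE(all.equal(fitted, observed))) 1 else 0
  } else stats::cor(fitted, observed)^2
  structure(list(beta0 = unname(beta0), beta1 = unname(beta1),
                 r_squared = min(max(r2, 0), 1)),
            class = "fp_regression")
}

#' @export
print.fp_regression <- function(x, ...) {
  cat(sprintf("intercept %.5g  slope %.5g  R^2 %.3f\n",
              x$beta0, x$beta1, x$r_squared))
  invisible(x)
}

#' Per-subject Poisson regression of RT on temporal predictability
#'
#' Log-link regression of integer-millisecond RTs on the recoded
#' predictability predictor \code{x = 4 - tp_rank} (x = 0 at highest
#' predictability), with the Poisson variance function
#' (quasi-likelihood; overdispersion leaves the point estimates unchanged).
#' Under this coding \code{exp(beta0)} is the expected RT when stimulus
#' onset is most predictable and \code{beta1 > 0} means RTs slow as
#' predictability falls.
#'
#' @param rts valid RTs in ms (positive), one subject.
#' @param tp tp_rank per trial (4 = most predictable .. 1).
#' @return a \code{\link{regression_result}} (beta0 on the log-ms scale).
#' @export
poisson_regression <- function(rts, tp) {
  if (length(unique(tp)) < 2) stop("need >= 2 distinct predictability levels")
  if (any(rts <= 0)) stop("non-positive RT encountered; filter trials first")
  x <- tp_to_x(tp)
  y <- round(rts)
  fit <- stats::glm(y ~ x, family = stats::quasipoisson(link = "log"))
  regression_result(stats::coef(fit)[1], stats::coef(fit)[2],
                    stats::fitted(fit), y)
}

#' Per-subject foreperiod-effect regression
#'
#' Ordinary least squares of RT on foreperiod length.  A negative slope is
#' the classical foreperiod effect: faster responses when the stimulus
#' arrives later in the trial.
#'
#' @param rts valid RTs in ms.
#' @param foreperiods matching foreperiods in ms.
#' @return a \code{regression_result}; beta1 in ms of RT per ms of
#'   foreperiod.
#' @export
foreperiod_slope <- function(rts, foreperiods) {
  if (length(unique(foreperiods)) < 2) stop("need >= 2 distinct foreperiods")
  fit <- stats::lm(rts ~ foreperiods)
  regression_result(stats::coef(fit)[1], stats::coef(fit)[2],
                    stats::fitted(fit), rts)
}

#' Per-subject linear regression of fitted boundary on predictability
#'
#' Least-squares line through the four posterior-mean boundary values over
#' the recoded predictor \code{x = 4 - tp_rank}; the intercept is the
#' boundary at highest predictability and the slope the widening per
#' predictability step.
#'
#' @param boundaries one fitted boundary per condition (posterior means).
#' @param tp_ranks matching tp_rank values; all four of 1..4 must appear
#'   exactly once.
#' @return a \code{regression_result} in boundary units.
#' @export
boundary_regression <- function(boundaries, tp_ranks) {
  miss <- setdiff(1:4, tp_ranks)
  if (length(miss))
    stop("missing condition(s): tp_rank ", paste(miss, collapse = ", "))
  if (length(boundaries) != length(tp_ranks) || length(boundaries) != 4)
    stop("exactly one boundary per condition is required")
  x <- tp_to_x(tp_ranks)
  fit <- stats::lm(boundaries ~ x)
  regression_result(stats::coef(fit)[1], stats::coef(fit)[2],
                    stats::fitted(fit), boundaries)
}

#' Group-level frequentist tests on per-subject statistics
#'
#' Standard designs used on per-subject regression coefficients: one-way
#' ANOVA with eta-squared, Welch-corrected two-group post-hocs (fractional
#' degrees of freedom, Cohen's d), paired and one-sample t-tests (Cohen's
#' d_z = mean difference / SD of differences).
#'
#' @param values numeric vector of per-subject statistics.
#' @param groups factor/character of group labels (anova, welch_posthoc,
#'   two_sample_t); for \code{paired_t} a second measurement vector aligned
#'   by subject; ignored for \code{one_sample_t}.
#' @param design one of \code{"anova"}, \code{"welch_posthoc"},
#'   \code{"paired_t"}, \code{"one_sample_t"}, \code{"two_sample_t"}.
#' @param mu null value for the one-sample design.
#' @param alternative test sidedness, as in \code{t.test} (one-tailed
#'   within-group medication contrasts use \code{"greater"}/\code{"less"}).
#' @return list of class \code{"fp_group_test"}: \code{statistic},
#'   \code{df}, \code{p}, \code{effect_size}, \code{effect_label}.
#' @export
group_tests <- function(values, groups = NULL,
                        design = c("anova", "welch_posthoc", "paired_t",
                                   "one_sample_t", "two_sample_t"),
                        mu = 0, alternative = "two.sided") {
  design <- match.arg(design)
  out <- switch(design,
    anova = {
      g <- factor(groups)
      if (nlevels(g) < 2 || any(table(g) < 2))
        stop("ANOVA needs >= 2 groups of >= 2 subjects")
      fit <- stats::aov(values ~ g)
      s <- summary(fit)[[1]]
      eta2 <- s[1, "Sum Sq"] / sum(s[, "Sum Sq"])
      list(statistic = s[1, "F value"], df = s[, "Df"], p = s[1, "Pr(>F)"],
           effect_size = eta2, effect_label = "eta_squared")
    },
    welch_posthoc = {
      g <- factor(groups)
      if (nlevels(g) != 2) stop("Welch post-hoc compares exactly 2 groups")
      a <- values[g == levels(g)[1]]; b <- values[g == levels(g)[2]]
      tt <- stats::t.test(a, b, var.equal = FALSE, alternative = alternative)
      sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                   (length(a) + length(b) - 2))
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, effect_size = (mean(a) - mean(b)) / sp,
           effect_label = "cohen_d")
    },
    paired_t = {
      if (length(values) != length(groups))
        stop("paired design needs two aligned measurement vectors")
      d <- values - groups
      tt <- stats::t.test(d, mu = 0, alternative = alternative)
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, effect_size = mean(d) / stats::sd(d),
           effect_label = "cohen_dz")
    },
    one_sample_t = {
      tt <- stats::t.test(values, mu = mu, alternative = alternative)
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, effect_size = (mean(values) - mu) / stats::sd(values),
           effect_label = "cohen_dz")
    },
    two_sample_t = {
      g <- factor(groups)
      if (nlevels(g) != 2) stop("two-sample design compares exactly 2 groups")
      a <- values[g == levels(g)[1]]; b <- values[g == levels(g)[2]]
      tt <- stats::t.test(a, b, var.equal = TRUE, alternative = alternative)
      sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                   (length(a) + length(b) - 2))
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, effect_size = (mean(a) - mean(b)) / sp,
           effect_label = "cohen_d")
    })
  structure(out, class = "fp_group_test")
}

#' @export
print.fp_group_test <- function(x, ...) {
  cat(sprintf("statistic %.4g, df %s, p %.4g, %s %.3g\n", x$statistic,
              paste(round(x$df, 2), collapse = "/"), x$p,
              x$effect_label, x$effect_size))
  invisible(x)
}

#' Spearman correlation between fitted boundaries and mean RTs
#'
#' Rank correlation (mid-rank ties) between per subject-condition fitted
#' boundary values and the matching empirical mean RTs, the model-fit check
#' that high boundaries go with slow responding.
#'
#' @param boundaries fitted boundary per subject-condition.
#' @param mean_rts matching mean RTs.
#' @return Spearman rho.
#' @export
spearman_boundary_rt <- function(boundaries, mean_rts) {
  if (length(boundaries) != length(mean_rts) || length(boundaries) < 3)
    stop("need >= 3 matched pairs")
  stats::cor(boundaries, mean_rts, method = "spearman")
}

#' Fisher z-transform of a correlation
#'
#' \code{atanh(r)}, mapping correlations to an approximately normal scale
#' for parametric group tests.
#'
#' @param r correlation(s), |r| < 1.
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  atanh(r)
}

#' Per-subject regression table for a trial set
#'
#' Convenience wrapper running the MAD filter and the Poisson and
#' foreperiod regressions per subject, returning a tidy table.
#'
#' @param trials trial table in the cohort schema.
#' @param error_trials keep error responses (response != stimulus) in the RT
#'   analyses (default TRUE; the exclusion rule is exposed as a switch).
#' @return data frame: subject_id, group, analysis, beta0, beta1, r2,
#'   n_trials.
#' @export
subject_regressions <- function(trials, error_trials = TRUE) {
  keep <- trials$response %in% c("LEFT", "RIGHT") & !is.na(trials$rt_ms)
  if (!error_trials) keep <- keep & trials$response == trials$stimulus
  trials <- trials[keep, , drop = FALSE]
  rows <- lapply(split(trials, trials$subject_id), function(tr) {
    ok <- filter_rts(tr$rt_ms)
    tr <- tr[ok, , drop = FALSE]
    pr <- poisson_regression(tr$rt_ms, tr$tp_rank)
    fr <- foreperiod_slope(tr$rt_ms, tr$foreperiod_ms)
    data.frame(subject_id = tr$subject_id[1], group = tr$group[1],
               analysis = c("poisson_tp", "foreperiod"),
               beta0 = c(pr$beta0, fr$beta0),
               beta1 = c(pr$beta1, fr$beta1),
               r2 = c(pr$r_squared, fr$r_squared),
               n_trials = nrow(tr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
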