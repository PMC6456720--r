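# Independent oracles used across tests.

# Moments of Normal(mu, sigma) truncated to [lo, hi], by numeric integration
# (independent of the package's sampler).
truncnorm_moments <- function(mu, sigma, lo, hi) {
  mass <- stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mu, sigma),
                         lo, hi, rel.tol = 1e-10)$value / mass
  m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mu, sigma),
                         lo, hi, rel.tol = 1e-10)$value / mass
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

# Closed-form absorption probability at the upper boundary (gambler's ruin
# with drift), written out independently of the package implementation.
oracle_upper_prob <- function(b, v, z) {
  if (abs(v) < 1e-12) return(z / b)
  (1 - exp(-2 * v * z)) / (1 - exp(-2 * v * b))
}

# Small single-group cohort + reduced fit, built once and reused by the
# inference and pipeline tests (kept deliberately small).
tiny_fit_cache <- new.env()
tiny_cohort <- function() {
  if (is.null(tiny_fit_cache$cohort)) {
    spec <- cohort_spec(
      n_subjects_per_group = 4,
      groups = list(Control = list(
        mean = c(b0 = 0.9, b1 = 0.05, v = 3.5, t0 = 0.25),
        sd = c(b0 = 0.12, b1 = 0.04, v = 0.4, t0 = 0.02))),
      n_trials_per_block = 60, seed = 101)
    tiny_fit_cache$cohort <- generate_cohort(spec)
  }
  tiny_fit_cache$cohort
}
tiny_fit <- function(variant = "M1_boundary") {
  key <- paste0("fit_", variant)
  if (is.null(tiny_fit_cache[[key]]))
    tiny_fit_cache[[key]] <- fit_hddm(tiny_cohort()$trials, variant,
                                      n_samples = 800, n_burn = 250,
                                      n_chains = 2, seed = 11)
  tiny_fit_cache[[key]]
}
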