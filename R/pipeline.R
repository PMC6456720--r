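trial_schema <- c("subject_id", "group", "session", "block", "duration_level",
                  "variability_level", "tp_rank", "foreperiod_ms", "stimulus",
                  "response", "rt_ms", "valid")

#' Read / write a trial table
#'
#' The on-disk format is UTF-8 CSV with exactly the schema columns
#' (subject_id, group, session, block, duration_level, variability_level,
#' tp_rank, foreperiod_ms, stimulus, response, rt_ms, valid); times are
#' written as integer-rounded milliseconds.  \code{read_trials(write_trials(x))}
#' reproduces the written table exactly.
#'
#' @param path CSV file path.
#' @return \code{read_trials}: the trial table (data frame).
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(trial_schema, names(raw))
  unknown_cols <- setdiff(names(raw), trial_schema)
  if (length(missing_cols) || length(unknown_cols))
    stop("trial CSV schema mismatch; missing: [",
         paste(missing_cols, collapse = ", "), "], unknown: [",
         paste(unknown_cols, collapse = ", "), "]")
  num_col <- function(col, integer = FALSE) {
    x <- raw[[col]]
    x[x == "" | x == "NA"] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop("non-numeric '", col, "' at row ", bad[1], ": \"", x[bad[1]], "\"")
    if (integer) as.integer(v) else v
  }
  out <- data.frame(
    subject_id = raw$subject_id, group = raw$group,
    session = num_col("session", TRUE), block = num_col("block", TRUE),
    duration_level = raw$duration_level,
    variability_level = raw$variability_level,
    tp_rank = num_col("tp_rank", TRUE),
    foreperiod_ms = num_col("foreperiod_ms"),
    stimulus = raw$stimulus, response = raw$response,
    rt_ms = num_col("rt_ms"),
    valid = raw$valid %in% c("TRUE", "true", "1"),
    stringsAsFactors = FALSE
  )
  out
}

#' @param trials trial table in the schema above.
#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(trial_schema, names(trials))
  if (length(miss)) stop("trial table lacks columns: ", paste(miss, collapse = ", "))
  out <- trials[, trial_schema]
  out$foreperiod_ms <- round(out$foreperiod_ms)
  out$rt_ms <- round(out$rt_ms)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write / read a ground-truth sidecar table
#'
#' @param truth ground-truth table (subject_id, group, parameter, value).
#' @param path CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

default_run_config <- function() {
  list(
    seed = 1L,
    cohort = list(n_subjects_per_group = 16L, n_blocks = 4L,
                  n_trials_per_block = 120L, lapse_rate = 0, fp_effect = 0),
    variants = c("M1_boundary", "M2_drift", "M3_both"),
    profile = "reduced",     # reduced: 4000/1000 x 2 chains; production: 50000/5000
    n_chains = 2L,
    out_dir = NULL,
    error_trials = TRUE,
    ppc_sims = 0L
  )
}

mcmc_profile <- function(profile) {
  switch(profile,
         smoke = list(n_samples = 800L, n_burn = 250L),
         reduced = list(n_samples = 4000L, n_burn = 1000L),
         production = list(n_samples = 50000L, n_burn = 5000L),
         stop("unknown MCMC profile: ", profile))
}

#' Run the full analysis pipeline
#'
#' Generate (or load) a cohort, apply the validity filter, fit the requested
#' model variants, compare them by DIC, run the behavioural and boundary
#' regressions with group tests and posterior-overlap inference, and emit a
#' single report.  Every random draw flows from the single config seed
#' through fixed per-stage offsets, so identical configs give identical
#' reports; intermediate artifacts are persisted to \code{out_dir} when one
#' is given.
#'
#' @param config a list (or path to a YAML/JSON file) with any of the fields
#'   of the default config: \code{seed}, \code{cohort} (arguments of
#'   \code{\link{cohort_spec}}, or a \code{trials_csv} path to load instead
#'   of generating), \code{variants}, \code{profile}
#'   (\code{"reduced"} = 4,000 iterations / 1,000 burn-in,
#'   \code{"production"} = 50,000 / 5,000), \code{n_chains}, \code{out_dir},
#'   \code{error_trials}, \code{ppc_sims}.
#' @return an object of class \code{"fp_report"}: list with the DIC table,
#'   winning variant, per-subject regression tables, group tests, overlap
#'   q-values for the winning fit, recovery metrics when ground truth is
#'   available, and the config in force.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (!length(cfg$variants)) stop("config lists no model variants to fit")
  cfg$variants <- match.arg(cfg$variants,
                            c("M1_boundary", "M2_drift", "M3_both"),
                            several.ok = TRUE)
  prof <- mcmc_profile(cfg$profile)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  # --- stage 1: obtain trials
  truth <- NULL
  if (!is.null(cfg$cohort$trials_csv)) {
    trials <- read_trials(cfg$cohort$trials_csv)
  } else {
    spec_args <- cfg$cohort
    spec_args$trials_csv <- NULL
    spec_args$seed <- cfg$seed
    cohort <- do.call(cohort_spec, spec_args)
    cohort <- generate_cohort(cohort)
    trials <- cohort$trials
    truth <- cohort$ground_truth
    if (!is.null(out_dir)) {
      write_trials(trials, file.path(out_dir, "trials.csv"))
      write_ground_truth(truth, file.path(out_dir, "ground_truth.csv"))
    }
  }

  # --- stage 2: validity filter (per subject)
  set.seed(cfg$seed + 1L)
  keep <- trials$response %in% c("LEFT", "RIGHT") & !is.na(trials$rt_ms)
  for (sid in unique(trials$subject_id)) {
    i <- which(trials$subject_id == sid & keep)
    if (length(i)) keep[i] <- filter_rts(trials$rt_ms[i])
  }
  filter_counts <- tapply(!keep, trials$subject_id, sum)
  ftrials <- trials[keep, , drop = FALSE]

  # --- stage 3: fit variants
  fits <- list()
  for (vi in seq_along(cfg$variants)) {
    v <- cfg$variants[vi]
    fits[[v]] <- fit_hddm(ftrials, variant = v,
                          n_samples = prof$n_samples, n_burn = prof$n_burn,
                          n_chains = cfg$n_chains,
                          seed = cfg$seed + 100L * vi)
  }

  # --- stage 4: model comparison
  comparison <- if (length(fits) >= 2) compare_models(fits) else NULL
  winner <- if (is.null(comparison)) names(fits)[1] else comparison$model[1]
  wfit <- fits[[winner]]

  # --- stage 5: behavioural + boundary analyses
  set.seed(cfg$seed + 2L)
  regs <- subject_regressions(ftrials, error_trials = cfg$error_trials)
  sb <- subject_boundaries(wfit)
  brows <- lapply(split(sb, sb$subject_id), function(d) {
    r <- boundary_regression(d$boundary, d$tp_rank)
    data.frame(subject_id = d$subject_id[1], group = d$group[1],
               analysis = "boundary", beta0 = r$beta0, beta1 = r$beta1,
               r2 = r$r_squared, n_trials = 4L, stringsAsFactors = FALSE)
  })
  regs <- rbind(regs, do.call(rbind, brows))
  rownames(regs) <- NULL

  group_level <- list()
  for (an in unique(regs$analysis)) {
    d <- regs[regs$analysis == an, ]
    group_level[[an]] <- list(
      slope_anova = if (length(unique(d$group)) >= 2)
        unclass(group_tests(d$beta1, d$group, "anova")) else NULL,
      slope_vs_zero = lapply(split(d, d$group), function(x)
        unclass(group_tests(x$beta1, design = "one_sample_t")))
    )
  }

  # Spearman boundary-RT correspondence per group
  mean_rt <- stats::aggregate(rt_ms ~ subject_id + tp_rank, ftrials, mean)
  sb$mean_rt <- mean_rt$rt_ms[match(paste(sb$subject_id, sb$tp_rank),
                                    paste(mean_rt$subject_id, mean_rt$tp_rank))]
  spearman <- vapply(split(sb, sb$group), function(d)
    spearman_boundary_rt(d$boundary, d$mean_rt), 0)

  # posterior-overlap inference on shared parameters of the winning fit
  set.seed(cfg$seed + 3L)
  overlap <- NULL
  if (length(wfit$groups) >= 2) {
    pars <- intersect(c("mu_v[1]", "mu_t0"), wfit$groups[[1]]$par_names)
    overlap <- do.call(rbind, lapply(pars, function(p) overlap_matrix(wfit, p)))
  }

  # recovery metrics against ground truth, when present
  recovery <- NULL
  if (!is.null(truth)) {
    bt <- regs[regs$analysis == "boundary", ]
    tw <- stats::reshape(truth[truth$parameter %in% c("b0", "b1"), ],
                         idvar = "subject_id", timevar = "parameter",
                         direction = "wide", v.names = "value",
                         drop = "group")
    m <- match(bt$subject_id, tw$subject_id)
    recovery <- list(
      boundary_intercept_r = stats::cor(bt$beta0, tw$value.b0[m]),
      boundary_slope_r = stats::cor(bt$beta1, tw$value.b1[m])
    )
  }

  ppc <- if (cfg$ppc_sims > 0)
    posterior_predictive_check(wfit, n_sims = cfg$ppc_sims) else NULL

  report <- structure(list(
    config = cfg,
    mcmc = c(prof, list(n_chains = cfg$n_chains)),
    filter_counts = as.list(filter_counts),
    comparison = if (is.null(comparison)) NULL else as.data.frame(comparison),
    winner = winner,
    regressions = regs,
    group_level = group_level,
    spearman_boundary_rt = as.list(spearman),
    overlap = overlap,
    recovery = recovery,
    ppc_coverage = if (is.null(ppc)) NULL else ppc$coverage,
    rhat_max = max(unlist(rhat(wfit)))
  ), class = "fp_report")

  if (!is.null(out_dir)) {
    utils::write.csv(regs, file.path(out_dir, "regressions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_body(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (v in names(fits)) write_posterior(fits[[v]], out_dir, v)
  }
  report
}

# serialisable body of a report (drops nothing but flattens classes)
report_body <- function(report) {
  x <- unclass(report)
  x$regressions <- as.data.frame(x$regressions)
  x
}

#' @export
print.fp_report <- function(x, ...) {
  cat("Variable-foreperiod pipeline report\n")
  if (!is.null(x$comparison)) {
    cat("\nModel comparison:\n")
    print.data.frame(x$comparison, row.names = FALSE, digits = 6)
  }
  cat("\nWinning variant:", x$winner, "\n")
  cat("Max R-hat (winning fit):", round(x$rhat_max, 4), "\n")
  cat("\nSpearman boundary-RT rho by group:\n")
  print(unlist(x$spearman_boundary_rt))
  if (!is.null(x$recovery)) {
    cat("\nRecovery vs ground truth: boundary intercept r =",
        round(x$recovery$boundary_intercept_r, 3), ", slope r =",
        round(x$recovery$boundary_slope_r, 3), "\n")
  }
  invisible(x)
}

# persist posterior draws as long CSV (chain, iter, parameter, value) + JSON
# metadata, one pair of files per group
write_posterior <- function(fit, out_dir, label) {
  for (g in names(fit$groups)) {
    gf <- fit$groups[[g]]
    keep <- grep("^(mu_|sig_)|^deviance$", gf$par_names, value = TRUE)
    long <- do.call(rbind, lapply(seq_along(gf$chains), function(ch) {
      m <- gf$chains[[ch]][, keep, drop = FALSE]
      data.frame(chain = ch, iter = seq_len(nrow(m)),
                 parameter = rep(keep, each = nrow(m)),
                 value = as.vector(m))
    }))
    base <- file.path(out_dir, paste0("posterior_", label, "_", gsub("[^A-Za-z0-9]", "", g)))
    utils::write.csv(long, paste0(base, ".csv"), row.names = FALSE)
    jsonlite::write_json(list(variant = fit$variant, group = g,
                              n_samples = fit$n_samples, n_burn = fit$n_burn,
                              n_chains = fit$n_chains, seed = fit$seed,
                              priors = fit$priors,
                              rhat_max = max(rhat_group(gf, fit$n_burn))),
                         paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}

#' Read a pipeline config from YAML or JSON
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return config list for \code{\link{run_pipeline}}.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be a .yaml/.yml or .json file")
}
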