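#' Default group-level generative truths
#'
#' Ground-truth parameter means and between-subject SDs for three cohorts
#' emulating healthy controls and Parkinson's patients on and off
#' dopaminergic medication.  Boundary separation is expressed as a linear
#' function of the predictability predictor \code{x = 4 - tp_rank}
#' (\code{b = b0 + b1 * x}), so \code{b0} is the boundary when stimulus onset
#' is most predictable and \code{b1} the widening per predictability step.
#' The boundary intercept/slope means and SDs follow the published
#' group-level estimates for this task (controls 0.869/0.040, patients on
#' medication 0.931/0.059, patients off medication 1.065/0.001 with an
#' essentially flat profile); drift rate and non-decision time are set so
#' simulated mean RTs land in the empirical 300-450 ms range with accuracy
#' around 95 percent.
#'
#' @return named list of per-group lists with elements \code{mean} and
#'   \code{sd}, each containing \code{b0}, \code{b1}, \code{v}, \code{t0}
#'   (boundary units; drift per second; seconds).
#' @export
default_group_truth <- function() {
  list(
    "Control" = list(mean = c(b0 = 0.869, b1 = 0.040, v = 3.5, t0 = 0.25),
                     sd   = c(b0 = 0.16,  b1 = 0.05,  v = 0.5, t0 = 0.03)),
    "PD-on"   = list(mean = c(b0 = 0.931, b1 = 0.059, v = 3.3, t0 = 0.27),
                     sd   = c(b0 = 0.10,  b1 = 0.05,  v = 0.5, t0 = 0.03)),
    "PD-off"  = list(mean = c(b0 = 1.065, b1 = 0.001, v = 3.1, t0 = 0.29),
                     sd   = c(b0 = 0.14,  b1 = 0.05,  v = 0.5, t0 = 0.03))
  )
}

#' Specify a synthetic cohort
#'
#' Collects everything needed to generate a multi-group trial table with
#' known ground truth: group-level parameter means and between-subject SDs,
#' the session geometry, and the seed.
#'
#' @param n_subjects_per_group subjects per group.
#' @param groups named list as returned by \code{\link{default_group_truth}};
#'   any subset of groups may be supplied.  A group's mean/sd vectors may
#'   additionally name \code{v1}, a drift change per predictability step
#'   (default 0), for generating drift-driven rather than boundary-driven
#'   predictability effects.
#' @param n_blocks,n_trials_per_block session geometry (4 x 120 by default).
#' @param seed integer seed; all randomness in \code{\link{generate_cohort}}
#'   flows from it.
#' @param lapse_rate probability that a trial is a miss (response NONE, no
#'   RT); 0 by default, available for exercising validity filters.
#' @param fp_effect foreperiod effect on non-decision time, in seconds of t0
#'   per second of foreperiod deviation from the block mean.  Negative values
#'   make responses faster at longer foreperiods (a classical hazard-driven
#'   foreperiod effect); 0 disables it.
#' @param dt Euler step for the trial simulator, seconds.
#' @param tp_ranks passed to \code{\link{make_condition_grid}}.
#' @return an object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_subjects_per_group = 16L,
                        groups = default_group_truth(),
                        n_blocks = 4L, n_trials_per_block = 120L,
                        seed = 1L, lapse_rate = 0, fp_effect = 0,
                        dt = 1e-4, tp_ranks = NULL) {
  stopifnot(n_subjects_per_group >= 1, n_blocks >= 1, n_trials_per_block >= 1,
            lapse_rate >= 0, lapse_rate < 1, dt > 0, length(seed) == 1)
  for (g in names(groups)) {
    m <- groups[[g]]$mean; s <- groups[[g]]$sd
    need <- c("b0", "b1", "v", "t0")
    if (!all(need %in% names(m)) || !all(need %in% names(s)))
      stop("group '", g, "' must define mean and sd for ",
           paste(need, collapse = ", "))
    # optional drift profile over predictability (v1 = change per step)
    if (!"v1" %in% names(m)) groups[[g]]$mean <- c(m, v1 = 0)
    if (!"v1" %in% names(s)) groups[[g]]$sd <- c(s, v1 = 0)
    m <- groups[[g]]$mean; s <- groups[[g]]$sd
    if (any(s < 0)) stop("group '", g, "': SDs must be >= 0")
    if (m[["t0"]] <= 0) stop("group '", g, "': t0 must be > 0")
    b_at_x <- m[["b0"]] + m[["b1"]] * 0:3
    if (any(b_at_x <= 0))
      stop("group '", g, "': implied boundary non-positive at predictability ",
           "step x = ", paste(which(b_at_x <= 0) - 1, collapse = ", "))
  }
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 groups = groups, n_blocks = as.integer(n_blocks),
                 n_trials_per_block = as.integer(n_trials_per_block),
                 seed = as.integer(seed), lapse_rate = lapse_rate,
                 fp_effect = fp_effect, dt = dt, tp_ranks = tp_ranks),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' For every subject, draws individual DDM parameters around the group means
#' (boundary per condition via the intercept/slope profile over
#' \code{x = 4 - tp_rank}; drift, non-decision time and the unbiased start
#' point shared across conditions), builds a blocked session schedule with
#' Latin-square condition ordering, and simulates each trial's response and
#' RT with the Euler-Maruyama diffusion simulator.  Subjects whose drawn
#' parameters would be invalid (non-positive boundary at some condition, or
#' non-positive t0) are redrawn.
#'
#' The generation is fully reproducible: the cohort seed is split into one
#' sub-seed per subject, so the same spec always yields the same table.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return an object of class \code{"fp_cohort"}: a list with \code{trials}
#'   (the trial table: subject_id, group, session, block, duration_level,
#'   variability_level, tp_rank, foreperiod_ms, stimulus, response, rt_ms,
#'   valid) and \code{ground_truth} (long table: subject_id, group,
#'   parameter, value; parameters b0, b1, v, t0 and the per-condition
#'   boundaries b_x0..b_x3).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- if (is.null(spec$tp_ranks)) make_condition_grid()
          else make_condition_grid(spec$tp_ranks)
  set.seed(spec$seed)
  n_g <- length(spec$groups)
  n_s <- spec$n_subjects_per_group
  subj_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_g * n_s),
                       nrow = n_s)
  trials <- vector("list", n_g * n_s)
  truth <- vector("list", n_g * n_s)
  k <- 0L
  for (gi in seq_len(n_g)) {
    gname <- names(spec$groups)[gi]
    gm <- spec$groups[[gi]]$mean; gs <- spec$groups[[gi]]$sd
    for (si in seq_len(n_s)) {
      k <- k + 1L
      set.seed(subj_seeds[si, gi])
      sid <- sprintf("%s_s%02d", gname, si)
      # draw subject parameters; redraw on invalid support
      repeat {
        b0 <- stats::rnorm(1, gm[["b0"]], gs[["b0"]])
        b1 <- stats::rnorm(1, gm[["b1"]], gs[["b1"]])
        v  <- stats::rnorm(1, gm[["v"]],  gs[["v"]])
        v1 <- stats::rnorm(1, gm[["v1"]], gs[["v1"]])
        t0 <- stats::rnorm(1, gm[["t0"]], gs[["t0"]])
        b_cond <- b0 + b1 * 0:3
        v_cond <- v + v1 * 0:3
        if (all(b_cond > 0.05) && t0 > 0.05 && all(v_cond > 0)) break
      }
      sched <- build_session_schedule(grid, spec$n_blocks,
                                      spec$n_trials_per_block,
                                      order_index = ((si - 1L) %% 4L) + 1L)
      x <- tp_to_x(sched$tp_rank)
      b_trial <- b0 + b1 * x
      v_trial <- v + v1 * x
      t0_trial <- t0 + spec$fp_effect *
        (sched$foreperiod_ms - grid$mu[match(sched$tp_rank, grid$tp_rank)]) / 1000
      t0_trial <- pmax(t0_trial, 0.05)
      sgn <- ifelse(sched$stimulus == "RIGHT", 1, -1)
      sim <- .ddm_simulate_cpp(nrow(sched), b_trial, sgn * v_trial,
                               b_trial / 2, spec$dt, 20)
      response <- ifelse(is.na(sim[, 2]), NA_character_,
                         c("LEFT", "RIGHT")[sim[, 2] + 1])
      rt_ms <- (sim[, 1] + t0_trial) * 1000
      lapse <- if (spec$lapse_rate > 0)
        stats::runif(nrow(sched)) < spec$lapse_rate else rep(FALSE, nrow(sched))
      miss <- lapse | is.na(response)
      response[miss] <- "NONE"
      rt_ms[miss] <- NA_real_
      trials[[k]] <- data.frame(
        subject_id = sid, group = gname, session = 1L,
        block = sched$block,
        duration_level = sched$duration_level,
        variability_level = sched$variability_level,
        tp_rank = sched$tp_rank,
        foreperiod_ms = sched$foreperiod_ms,
        stimulus = sched$stimulus, response = response,
        rt_ms = rt_ms, valid = !miss,
        stringsAsFactors = FALSE
      )
      truth[[k]] <- data.frame(
        subject_id = sid, group = gname,
        parameter = c("b0", "b1", "v", "v1", "t0", paste0("b_x", 0:3)),
        value = c(b0, b1, v, v1, t0, b_cond),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(trials = do.call(rbind, trials),
                 ground_truth = do.call(rbind, truth),
                 spec = spec),
            class = "fp_cohort")
}

#' @export
print.fp_cohort <- function(x, ...) {
  tr <- x$trials
  cat("Synthetic variable-foreperiod cohort\n")
  cat(sprintf("  %d trials, %d subjects, groups: %s\n",
              nrow(tr), length(unique(tr$subject_id)),
              paste(unique(tr$group), collapse = ", ")))
  cat(sprintf("  seed %d, lapse rate %.3g\n", x$spec$seed, x$spec$lapse_rate))
  invisible(x)
}
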