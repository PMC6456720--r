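#' @export
print.hddm_fit <- function(x, ...) {
  cat("Hierarchical drift-diffusion fit (", x$variant, ")\n", sep = "")
  cat(sprintf("  %d chains x %d iterations (%d burn-in), seed %d\n",
              x$n_chains, x$n_samples, x$n_burn, x$seed))
  cat(sprintf("  groups: %s\n", paste(names(x$groups), collapse = ", ")))
  cat(sprintf("  sampling time: %.1f s\n", x$elapsed))
  if (x$likelihood == "null")
    cat("  NOTE: null likelihood (prior-recovery run)\n")
  invisible(x)
}

#' Posterior summary of a hierarchical DDM fit
#'
#' Summarises the group-level parameters of each group: posterior mean, SD,
#' central 95\% credible interval and the Gelman-Rubin R-hat.
#'
#' @param object an \code{hddm_fit}.
#' @param ... unused.
#' @return an object of class \code{"summary.hddm_fit"}: a named list of
#'   per-group data frames.
#' @export
summary.hddm_fit <- function(object, ...) {
  out <- lapply(object$groups, function(g) {
    keep <- grep("^(mu_|sig_)", g$par_names, value = TRUE)
    d <- post_draws(g, object$n_burn)[, keep, drop = FALSE]
    rh <- rhat_group(g, object$n_burn)[keep]
    data.frame(parameter = keep,
               mean = colMeans(d),
               sd = apply(d, 2, stats::sd),
               q2.5 = apply(d, 2, stats::quantile, 0.025),
               q97.5 = apply(d, 2, stats::quantile, 0.975),
               rhat = rh, row.names = NULL)
  })
  structure(out, class = "summary.hddm_fit", variant = object$variant)
}

#' @export
print.summary.hddm_fit <- function(x, digits = 3, ...) {
  cat("Group-level posterior summary (", attr(x, "variant"), ")\n", sep = "")
  for (g in names(x)) {
    cat("\nGroup:", g, "\n")
    print(format(x[[g]], digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Posterior-mean parameter estimates
#'
#' @param object an \code{hddm_fit}.
#' @param level \code{"group"} for group-level means/SDs, \code{"subject"}
#'   for per-subject posterior means (one boundary per condition column the
#'   variant frees, one drift column likewise, one t0).
#' @param ... unused.
#' @return named list of per-group matrices (subject level) or named vectors
#'   (group level).
#' @export
coef.hddm_fit <- function(object, level = c("group", "subject"), ...) {
  level <- match.arg(level)
  lapply(object$groups, function(g) {
    d <- post_draws(g, object$n_burn)
    if (level == "group") {
      keep <- grep("^(mu_|sig_)", g$par_names, value = TRUE)
      colMeans(d[, keep, drop = FALSE])
    } else {
      keep <- grep("^(b|v|t0)\\[", g$par_names, value = TRUE)
      m <- colMeans(d[, keep, drop = FALSE])
      attr(m, "subjects") <- g$subj_levels
      m
    }
  })
}

#' Posterior-mean boundary per subject and condition
#'
#' Expands the fitted subject-level boundaries to the four predictability
#' conditions (constant across conditions for variants that do not free the
#' boundary), the quantity entering the per-subject boundary regression.
#'
#' @param fit an \code{hddm_fit}.
#' @return data frame with \code{subject_id}, \code{group}, \code{x}
#'   (predictability predictor 0..3, 0 = most predictable), \code{tp_rank}
#'   and \code{boundary}.
#' @export
subject_boundaries <- function(fit) {
  out <- lapply(fit$groups, function(g) {
    d <- post_draws(g, fit$n_burn)
    rows <- lapply(seq_len(g$S), function(s) {
      bcols <- sprintf("b[%d,%d]", s, g$bcol)   # length 4: column per condition
      data.frame(subject_id = g$subj_levels[s], group = g$group,
                 x = 0:3, tp_rank = 4:1,
                 boundary = colMeans(d[, bcols, drop = FALSE]),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate replicate datasets from the posterior
#'
#' Draws \code{nsim} parameter vectors from the post-burn-in posterior and
#' simulates, for each, a full replicate of the fitted trials (same subjects,
#' conditions and stimulus sides) with the Euler-Maruyama simulator.
#'
#' @param object an \code{hddm_fit}.
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param dt Euler step in seconds for the replicate simulation.
#' @param ... unused.
#' @return list of \code{nsim} data frames with \code{group},
#'   \code{subject_id}, \code{cond} (1 = most predictable), \code{stimulus},
#'   \code{response}, \code{rt} (seconds).
#' @export
simulate.hddm_fit <- function(object, nsim = 1, seed = NULL, dt = 1e-3, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) simulate_fit_once(object, dt = dt))
}

# one replicate dataset from a randomly chosen posterior draw
simulate_fit_once <- function(fit, dt = 1e-3) {
  reps <- lapply(fit$groups, function(g) {
    d <- post_draws(g, fit$n_burn)
    row <- d[sample.int(nrow(d), 1L), ]
    dat <- g$data
    bmat <- matrix(row[sprintf("b[%d,%d]", rep(seq_len(g$S), g$nb),
                               rep(seq_len(g$nb), each = g$S))], g$S, g$nb)
    vmat <- matrix(row[sprintf("v[%d,%d]", rep(seq_len(g$S), g$nv),
                               rep(seq_len(g$nv), each = g$S))], g$S, g$nv)
    t0s <- row[sprintf("t0[%d]", seq_len(g$S))]
    tb <- if (g$nb == 1L) bmat[, 1][dat$subj]
          else bmat[cbind(dat$subj, g$bcol[dat$cond])]
    tv0 <- if (g$nv == 1L) vmat[, 1][dat$subj]
           else vmat[cbind(dat$subj, g$vcol[dat$cond])]
    sim <- .ddm_simulate_cpp(length(dat$rt), tb, dat$sgn * tv0, tb / 2, dt, 20)
    data.frame(group = g$group,
               subject_id = g$subj_levels[dat$subj],
               cond = dat$cond,
               stimulus = ifelse(dat$sgn > 0, "RIGHT", "LEFT"),
               response = ifelse(is.na(sim[, 2]), NA_character_,
                                 c("LEFT", "RIGHT")[sim[, 2] + 1]),
               rt = sim[, 1] + t0s[dat$subj],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out
}

#' Trace plots of group-level parameters
#'
#' @param x an \code{hddm_fit}.
#' @param group group to plot (default: first).
#' @param pars parameter names; default all group-level means and SDs.
#' @param ... passed to \code{matplot}.
#' @export
plot.hddm_fit <- function(x, group = names(x$groups)[1], pars = NULL, ...) {
  g <- x$groups[[group]]
  if (is.null(pars)) pars <- grep("^(mu_|sig_)", g$par_names, value = TRUE)
  nper <- length(pars)
  old <- graphics::par(mfrow = c(ceiling(nper / 2), 2), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    tr <- sapply(g$chains, function(m) m[, p])
    graphics::matplot(tr, type = "l", lty = 1, ylab = p,
                      main = paste(group, p), ...)
    graphics::abline(v = x$n_burn, lty = 2)
  }
  invisible(x)
}
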