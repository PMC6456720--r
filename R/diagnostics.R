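#' Gelman-Rubin potential scale reduction
#'
#' The classic between/within-chain variance ratio: with m chains of n
#' post-burn-in draws, \eqn{W} the mean within-chain variance and \eqn{B/n}
#' the variance of chain means, \eqn{\hat R = \sqrt{((n-1)/n\,W + B/n)/W}}.
#' Chains that are identical (zero between- and within-chain variance) give
#' exactly 1.
#'
#' @param x draws: a numeric matrix with one column per chain, or an
#'   \code{hddm_fit} (per-parameter R-hat for every group).
#' @param ... unused.
#' @return a single value (matrix method) or a named list of named vectors
#'   (fit method).
#' @export
rhat <- function(x, ...) UseMethod("rhat")

#' @rdname rhat
#' @export
rhat.matrix <- function(x, ...) {
  m <- ncol(x); n <- nrow(x)
  if (m < 2) stop("R-hat needs at least 2 chains")
  if (n < 10) stop("R-hat needs at least 10 post-burn-in iterations")
  means <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B_over_n <- stats::var(means)            # = B/n
  if (W == 0 && B_over_n == 0) return(1)
  if (W == 0) return(Inf)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' @rdname rhat
#' @export
rhat.hddm_fit <- function(x, ...) {
  lapply(x$groups, rhat_group, n_burn = x$n_burn)
}

rhat_group <- function(g, n_burn) {
  keep <- setdiff(g$par_names, "deviance")
  vapply(keep, function(p) {
    rhat.matrix(sapply(g$chains, function(m)
      m[(n_burn + 1):nrow(m), p]))
  }, 0)
}

#' Deviance information criterion of a fit
#'
#' Conditional DIC computed at the subject-level parameters: the deviance is
#' \eqn{D(\theta) = -2 \sum \log L}, \eqn{\bar D} its posterior mean over
#' draws, \eqn{p_D = \bar D - D(\bar\theta)} the effective number of
#' parameters (deviance at the posterior mean of the subject-level
#' parameters), and \eqn{DIC = \bar D + p_D}.  Group hierarchies are
#' independent, so group DICs add.
#'
#' @param fit an \code{hddm_fit}.
#' @return list with \code{dic}, \code{p_d}, \code{mean_deviance} (totals)
#'   and \code{per_group} (data frame).
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "hddm_fit"))
  per <- lapply(fit$groups, function(g) {
    d <- post_draws(g, fit$n_burn)
    dbar <- mean(d[, "deviance"])
    dat <- g$data
    bmat <- matrix(colMeans(d[, sprintf("b[%d,%d]", rep(seq_len(g$S), g$nb),
                                        rep(seq_len(g$nb), each = g$S)),
                              drop = FALSE]), g$S, g$nb)
    vmat <- matrix(colMeans(d[, sprintf("v[%d,%d]", rep(seq_len(g$S), g$nv),
                                        rep(seq_len(g$nv), each = g$S)),
                              drop = FALSE]), g$S, g$nv)
    t0s <- colMeans(d[, sprintf("t0[%d]", seq_len(g$S)), drop = FALSE])
    tb <- if (g$nb == 1L) bmat[, 1][dat$subj]
          else bmat[cbind(dat$subj, g$bcol[dat$cond])]
    tv <- if (g$nv == 1L) vmat[, 1][dat$subj]
          else vmat[cbind(dat$subj, g$vcol[dat$cond])]
    ll <- .wfpt_loglik_grouped_cpp(dat$rt, dat$upper, tb, dat$sgn * tv, t0s[dat$subj],
                                   0.5, 1e-7, rep(1L, length(dat$rt)), 1L)
    dhat <- -2 * ll
    data.frame(group = g$group, mean_deviance = dbar, p_d = dbar - dhat,
               dic = 2 * dbar - dhat, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  list(dic = sum(per$dic), p_d = sum(per$p_d),
       mean_deviance = sum(per$mean_deviance), per_group = per)
}

#' Rank competing model variants by DIC
#'
#' @param fits named list of \code{hddm_fit} objects fitted to the same
#'   trials (checked via a data fingerprint).
#' @return an object of class \code{"hddm_comparison"}: a data frame with
#'   one row per model, ascending DIC, \code{delta_dic} relative to the best
#'   model, and a tie flag.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits to compare")
  if (is.null(names(fits))) names(fits) <- vapply(fits, `[[`, "", "variant")
  fps <- lapply(fits, `[[`, "fingerprint")
  if (!all(vapply(fps, identical, TRUE, fps[[1]])))
    stop("fits were not computed on identical trial data")
  d <- lapply(fits, dic)
  tab <- data.frame(model = names(fits),
                    dic = vapply(d, `[[`, 0, "dic"),
                    p_d = vapply(d, `[[`, 0, "p_d"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$dic), ]
  tab$delta_dic <- tab$dic - tab$dic[1]
  tab$tie_with_best <- tab$delta_dic == 0
  rownames(tab) <- NULL
  structure(tab, class = c("hddm_comparison", "data.frame"))
}

#' @export
print.hddm_comparison <- function(x, ...) {
  cat("Model comparison by DIC (lower is better)\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  if (sum(x$tie_with_best) > 1)
    cat("note: models tied with the best (delta DIC = 0): ",
        paste(x$model[x$tie_with_best], collapse = ", "), "\n")
  invisible(x)
}

#' Posterior overlap between two groups' parameter draws
#'
#' The two-sided exceedance statistic
#' \eqn{q = 2 \min\{\hat P(\theta_a > \theta_b), \hat P(\theta_a < \theta_b)\}},
#' estimated by paired resampling of the two draw sets (ties split evenly).
#' Identical distributions give q near 1; well-separated posteriors give q
#' near 0.  Group differences are flagged significant when q falls below the
#' Bonferroni-corrected threshold 0.05/3 (three pairwise group contrasts).
#'
#' @param samples_a,samples_b numeric vectors of posterior draws of the same
#'   parameter in two groups.
#' @param n_resample number of resampled pairs.
#' @return proportion q in [0, 1].
#' @export
overlap_q <- function(samples_a, samples_b, n_resample = NULL) {
  if (!length(samples_a) || !length(samples_b))
    stop("both sample sets must be non-empty")
  n <- if (is.null(n_resample)) max(length(samples_a), length(samples_b), 1e4)
       else n_resample
  a <- sample(samples_a, n, replace = TRUE)
  b <- sample(samples_b, n, replace = TRUE)
  gt <- mean(a > b) + 0.5 * mean(a == b)
  q <- 2 * min(gt, 1 - gt)
  min(q, 1)
}

#' Pairwise posterior-overlap matrix across groups
#'
#' @param fit an \code{hddm_fit} with >= 2 groups.
#' @param parameter group-level parameter name (e.g. \code{"mu_v[1]"},
#'   \code{"mu_t0"}).
#' @param alpha family-wise error level; the per-comparison threshold is
#'   \code{alpha} divided by the number of pairwise contrasts (Bonferroni).
#' @return data frame with one row per group pair: \code{q},
#'   \code{threshold}, \code{significant}.
#' @export
overlap_matrix <- function(fit, parameter, alpha = 0.05) {
  gs <- names(fit$groups)
  if (length(gs) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(gs, 2)
  thr <- alpha / ncol(pairs)
  rows <- apply(pairs, 2, function(pr) {
    q <- overlap_q(posterior_param(fit, pr[1], parameter),
                   posterior_param(fit, pr[2], parameter))
    data.frame(group_a = pr[1], group_b = pr[2], parameter = parameter,
               q = q, threshold = thr, significant = q < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior predictive check
#'
#' Simulates \code{n_sims} full replicates of the fitted trials from random
#' posterior draws and compares observed versus simulated RT quantiles
#' (10/30/50/70/90\%) and proportions of correct choices per group and
#' predictability condition.  A cell statistic is "covered" when the
#' observed value lies inside the central 95\% band of the simulated values.
#'
#' @param fit an \code{hddm_fit}.
#' @param n_sims number of posterior replicates (>= 1; 500 in the reference
#'   analysis).
#' @param dt Euler step for replicate simulation, seconds.
#' @param seed optional seed.
#' @return an object of class \code{"hddm_ppc"}: list with \code{summaries}
#'   (per group x condition x statistic: observed value, simulated band) and
#'   \code{coverage} (fraction of cells covered).
#' @export
posterior_predictive_check <- function(fit, n_sims = 500, dt = 1e-3,
                                       seed = NULL) {
  stopifnot(n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  stat_names <- c(paste0("rt_q", probs * 100), "p_correct")
  cell_stats <- function(rt, correct) c(stats::quantile(rt, probs, names = FALSE),
                                        mean(correct))
  # observed
  obs <- lapply(fit$groups, function(g) {
    dat <- g$data
    correct <- dat$upper == as.integer(dat$sgn > 0)
    do.call(rbind, lapply(1:4, function(cc) {
      i <- dat$cond == cc
      data.frame(group = g$group, cond = cc, stat = stat_names,
                 observed = cell_stats(dat$rt[i], correct[i]),
                 stringsAsFactors = FALSE)
    }))
  })
  obs <- do.call(rbind, obs); rownames(obs) <- NULL
  # simulated
  sims <- array(NA_real_, c(n_sims, nrow(obs)))
  for (s in seq_len(n_sims)) {
    rep_s <- simulate_fit_once(fit, dt = dt)
    rep_s <- rep_s[!is.na(rep_s$response), , drop = FALSE]
    correct <- rep_s$response == rep_s$stimulus
    key <- paste(rep_s$group, rep_s$cond)
    vals <- unlist(lapply(seq_len(nrow(obs) / length(stat_names)), function(k) {
      g <- obs$group[(k - 1) * length(stat_names) + 1]
      cc <- obs$cond[(k - 1) * length(stat_names) + 1]
      i <- key == paste(g, cc)
      cell_stats(rep_s$rt[i], correct[i])
    }))
    sims[s, ] <- vals
  }
  obs$sim_lo <- apply(sims, 2, stats::quantile, 0.025)
  obs$sim_hi <- apply(sims, 2, stats::quantile, 0.975)
  obs$sim_median <- apply(sims, 2, stats::median)
  obs$covered <- obs$observed >= obs$sim_lo & obs$observed <= obs$sim_hi
  structure(list(summaries = obs, coverage = mean(obs$covered),
                 n_sims = n_sims),
            class = "hddm_ppc")
}

#' @export
print.hddm_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive check (%d replicates)\n", x$n_sims))
  cat(sprintf("  %.1f%% of group x condition statistics inside the 95%% band\n",
              100 * x$coverage))
  invisible(x)
}
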