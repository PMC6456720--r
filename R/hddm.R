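#' Default weakly-informative priors for the hierarchical DDM
#'
#' Group-mean priors: boundary ~ Normal(1.5, 0.75) restricted to positive
#' values, drift ~ Normal(2, 3), non-decision time ~ Normal(0.3, 0.25)
#' restricted to positive values.  Group between-subject SDs carry
#' half-Normal(0.5) priors.  These cover the plausible human two-choice RT
#' regime without dominating subjects contributing several hundred trials.
#'
#' @return list with elements \code{mu_b}, \code{mu_v}, \code{mu_t0} (each
#'   \code{c(mean, sd)}) and \code{sd_scale} (half-normal scales for the
#'   group SDs of b, v, t0).
#' @export
default_priors <- function() {
  list(mu_b  = c(mean = 1.5, sd = 0.75),
       mu_v  = c(mean = 2,   sd = 3),
       mu_t0 = c(mean = 0.3, sd = 0.25),
       sd_scale = c(b = 0.5, v = 0.5, t0 = 0.5))
}

# Variant layout: which parameters vary over the 4 predictability conditions.
# Non-decision time never varies by condition; start point is fixed at w=0.5.
variant_layout <- function(variant) {
  switch(variant,
    M1_boundary = list(nb = 4L, nv = 1L),
    M2_drift    = list(nb = 1L, nv = 4L),
    M3_both     = list(nb = 4L, nv = 4L),
    stop("unknown variant: ", variant))
}

#' Build a hierarchical DDM model from a trial table
#'
#' Validates the trial table, keeps valid two-choice trials, and prepares one
#' independent hierarchy per group.  The three variants differ in which
#' parameters may vary across the four temporal-predictability conditions:
#' \code{M1_boundary} frees boundary separation only, \code{M2_drift} frees
#' drift rate only, \code{M3_both} frees both.  Non-decision time is constant
#' across conditions (but free across groups), and the start point is fixed
#' at the unbiased midpoint \code{z/b = 0.5}.
#'
#' @param trials trial table in the cohort schema (needs subject_id, group,
#'   tp_rank, stimulus, response, rt_ms, and optionally valid).
#' @param variant one of \code{"M1_boundary"}, \code{"M2_drift"},
#'   \code{"M3_both"}.
#' @param priors prior specification, see \code{\link{default_priors}}.
#' @return an object of class \code{"hddm_model"}.
#' @export
hddm_model <- function(trials, variant = c("M1_boundary", "M2_drift", "M3_both"),
                       priors = default_priors()) {
  variant <- match.arg(variant)
  need <- c("subject_id", "group", "tp_rank", "stimulus", "response", "rt_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table lacks columns: ", paste(miss, collapse = ", "))
  keep <- trials$response %in% c("LEFT", "RIGHT") & !is.na(trials$rt_ms)
  if ("valid" %in% names(trials)) keep <- keep & trials$valid
  trials <- trials[keep, , drop = FALSE]
  if (!nrow(trials)) stop("no valid trials")
  cells <- table(factor(trials$group),
                 factor(tp_to_x(trials$tp_rank), levels = 0:3))
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty (group, condition) cell: group '", rownames(cells)[bad[1]],
         "', predictability step x = ", colnames(cells)[bad[2]])
  }
  groups <- unique(trials$group)
  data <- lapply(groups, function(g) {
    tr <- trials[trials$group == g, , drop = FALSE]
    subj_levels <- sort(unique(tr$subject_id))
    subj <- match(tr$subject_id, subj_levels)
    cond <- tp_to_x(tr$tp_rank) + 1L        # 1 = most predictable
    list(group = g, subj_levels = subj_levels, S = length(subj_levels),
         subj = subj, cond = cond,
         rt = tr$rt_ms / 1000,
         upper = as.integer(tr$response == "RIGHT"),
         sgn = ifelse(tr$stimulus == "RIGHT", 1, -1))
  })
  names(data) <- groups
  structure(list(variant = variant, priors = priors, data = data,
                 trials = trials,
                 fingerprint = c(n = nrow(trials),
                                 rt_sum = round(sum(trials$rt_ms), 6),
                                 tp_sum = sum(trials$tp_rank))),
            class = "hddm_model")
}

#' @export
print.hddm_model <- function(x, ...) {
  cat("Hierarchical DDM model (", x$variant, ")\n", sep = "")
  for (d in x$data)
    cat(sprintf("  group %-10s %d subjects, %d trials\n",
                d$group, d$S, length(d$rt)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Metropolis-within-Gibbs sampler for one group hierarchy.
#
# Subject-level parameters are updated by vectorised random-walk Metropolis
# (subjects are conditionally independent given the group level); group means
# get conjugate Gibbs draws (truncated to positive support for b and t0);
# group SDs get random-walk Metropolis on the log scale.  Proposal scales
# adapt toward ~35% acceptance during burn-in only.  Positivity of b and t0
# is enforced through the likelihood support: the Wiener density is zero for
# invalid parameters, so such proposals are always rejected.
# ---------------------------------------------------------------------------
fit_group_mcmc <- function(dat, variant, priors, n_samples, n_burn, n_chains,
                           seed, err_tol, w = 0.5, likelihood = "wfpt") {
  lay <- variant_layout(variant)
  nb <- lay$nb; nv <- lay$nv
  S <- dat$S
  bcol <- if (nb == 4L) 1:4 else rep(1L, 4)   # condition -> parameter column
  vcol <- if (nv == 4L) 1:4 else rep(1L, 4)
  subj <- dat$subj; cond <- dat$cond
  rt <- dat$rt; upper <- dat$upper; sgn <- dat$sgn
  ntr <- length(rt)
  cellid <- subj + (cond - 1L) * S            # matrix(vec, S, 4) layout
  bcolt <- bcol[cond]; vcolt <- vcol[cond]
  idx_bcol <- lapply(seq_len(nb), function(j) which(bcolt == j))
  idx_vcol <- lapply(seq_len(nv), function(j) which(vcolt == j))
  null_lik <- identical(likelihood, "null")

  min_rt <- vapply(seq_len(S), function(s) min(rt[subj == s]), 0)

  cell_loglik <- function(idx, tb, tv, tt0) {
    if (null_lik) return(matrix(0, S, 4))
    matrix(.wfpt_loglik_grouped_cpp(rt[idx], upper[idx], tb, tv, tt0,
                                    w, err_tol, cellid[idx], S * 4L), S, 4)
  }
  trial_b <- function(idx, bmat) if (nb == 1L) bmat[, 1][subj[idx]]
                                 else bmat[cbind(subj[idx], bcolt[idx])]
  trial_v <- function(idx, vmat) {
    vv <- if (nv == 1L) vmat[, 1][subj[idx]]
          else vmat[cbind(subj[idx], vcolt[idx])]
    sgn[idx] * vv
  }

  # conjugate normal-mean draw, optionally truncated to (0, Inf)
  draw_mu <- function(values, sig, prior, positive) {
    n <- length(values)
    pv <- prior[["sd"]]^2
    s2 <- 1 / (n / sig^2 + 1 / pv)
    m <- s2 * (sum(values) / sig^2 + prior[["mean"]] / pv)
    s <- sqrt(s2)
    if (positive) {
      lo <- stats::pnorm(0, m, s)
      stats::qnorm(stats::runif(1, lo, 1), m, s)
    } else stats::rnorm(1, m, s)
  }

  par_names <- c(sprintf("mu_b[%d]", seq_len(nb)), "sig_b",
                 sprintf("mu_v[%d]", seq_len(nv)), "sig_v",
                 "mu_t0", "sig_t0",
                 sprintf("b[%d,%d]", rep(seq_len(S), nb), rep(seq_len(nb), each = S)),
                 sprintf("v[%d,%d]", rep(seq_len(S), nv), rep(seq_len(nv), each = S)),
                 sprintf("t0[%d]", seq_len(S)),
                 "deviance")
  npar <- length(par_names)

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    bmat <- matrix(stats::runif(S * nb, 0.8, 1.3), S, nb)
    vmat <- matrix(stats::rnorm(S * nv, 2.5, 0.7), S, nv)
    t0s <- pmin(0.6 * min_rt, 0.5) * stats::runif(S, 0.85, 1)
    mu_b <- colMeans(bmat); sig_b <- 0.3
    mu_v <- colMeans(vmat); sig_v <- 0.5
    mu_t0 <- mean(t0s); sig_t0 <- 0.1
    sc_b <- rep(0.08, nb); sc_v <- rep(0.25, nv); sc_t0 <- 0.02
    sc_sig <- c(b = 0.3, v = 0.3, t0 = 0.3)

    all_idx <- seq_len(ntr)
    L <- cell_loglik(all_idx, trial_b(all_idx, bmat), trial_v(all_idx, vmat),
                     t0s[subj])
    draws <- matrix(NA_real_, n_samples, npar, dimnames = list(NULL, par_names))

    for (iter in seq_len(n_samples)) {
      adapt <- iter <= n_burn
      gam <- if (adapt) min(0.05, 2 / sqrt(iter)) else 0

      # --- subject-level boundary columns
      for (j in seq_len(nb)) {
        prop <- bmat[, j] + sc_b[j] * stats::rnorm(S)
        Cj <- which(bcol == j)
        idx <- idx_bcol[[j]]
        bmp <- bmat; bmp[, j] <- prop
        newL <- cell_loglik(idx, trial_b(idx, bmp), trial_v(idx, vmat),
                            t0s[subj[idx]])
        dll <- rowSums(newL[, Cj, drop = FALSE]) -
               rowSums(L[, Cj, drop = FALSE])
        dpr <- stats::dnorm(prop, mu_b[j], sig_b, log = TRUE) -
               stats::dnorm(bmat[, j], mu_b[j], sig_b, log = TRUE)
        acc <- log(stats::runif(S)) < dll + dpr
        acc[is.na(acc)] <- FALSE
        bmat[acc, j] <- prop[acc]
        L[acc, Cj] <- newL[acc, Cj]
        if (adapt) sc_b[j] <- sc_b[j] * exp(gam * (mean(acc) - 0.35))
      }

      # --- subject-level drift columns
      for (j in seq_len(nv)) {
        prop <- vmat[, j] + sc_v[j] * stats::rnorm(S)
        Cj <- which(vcol == j)
        idx <- idx_vcol[[j]]
        vmp <- vmat; vmp[, j] <- prop
        newL <- cell_loglik(idx, trial_b(idx, bmat), trial_v(idx, vmp),
                            t0s[subj[idx]])
        dll <- rowSums(newL[, Cj, drop = FALSE]) -
               rowSums(L[, Cj, drop = FALSE])
        dpr <- stats::dnorm(prop, mu_v[j], sig_v, log = TRUE) -
               stats::dnorm(vmat[, j], mu_v[j], sig_v, log = TRUE)
        acc <- log(stats::runif(S)) < dll + dpr
        acc[is.na(acc)] <- FALSE
        vmat[acc, j] <- prop[acc]
        L[acc, Cj] <- newL[acc, Cj]
        if (adapt) sc_v[j] <- sc_v[j] * exp(gam * (mean(acc) - 0.35))
      }

      # --- subject-level non-decision time
      prop <- t0s + sc_t0 * stats::rnorm(S)
      newL <- cell_loglik(all_idx, trial_b(all_idx, bmat),
                          trial_v(all_idx, vmat), prop[subj])
      dll <- rowSums(newL) - rowSums(L)
      dpr <- stats::dnorm(prop, mu_t0, sig_t0, log = TRUE) -
             stats::dnorm(t0s, mu_t0, sig_t0, log = TRUE)
      acc <- log(stats::runif(S)) < dll + dpr
      acc[is.na(acc)] <- FALSE
      t0s[acc] <- prop[acc]
      L[acc, ] <- newL[acc, ]
      if (adapt) sc_t0 <- sc_t0 * exp(gam * (mean(acc) - 0.35))

      # --- group means (conjugate Gibbs)
      for (j in seq_len(nb))
        mu_b[j] <- draw_mu(bmat[, j], sig_b, priors$mu_b, positive = TRUE)
      for (j in seq_len(nv))
        mu_v[j] <- draw_mu(vmat[, j], sig_v, priors$mu_v, positive = FALSE)
      mu_t0 <- draw_mu(t0s, sig_t0, priors$mu_t0, positive = TRUE)

      # --- group SDs (log-scale Metropolis, half-normal priors)
      upd_sig <- function(sig, values, means, scale_prior, step) {
        lp <- function(s)
          sum(stats::dnorm(values, means, s, log = TRUE)) +
            stats::dnorm(s, 0, scale_prior, log = TRUE) + log(s)
        prop <- exp(log(sig) + step * stats::rnorm(1))
        if (log(stats::runif(1)) < lp(prop) - lp(sig)) c(prop, 1) else c(sig, 0)
      }
      r <- upd_sig(sig_b, as.vector(bmat), rep(mu_b, each = S),
                   priors$sd_scale[["b"]], sc_sig[["b"]])
      sig_b <- r[1]
      if (adapt) sc_sig[["b"]] <- sc_sig[["b"]] * exp(gam * (r[2] - 0.35))
      r <- upd_sig(sig_v, as.vector(vmat), rep(mu_v, each = S),
                   priors$sd_scale[["v"]], sc_sig[["v"]])
      sig_v <- r[1]
      if (adapt) sc_sig[["v"]] <- sc_sig[["v"]] * exp(gam * (r[2] - 0.35))
      r <- upd_sig(sig_t0, t0s, rep(mu_t0, S),
                   priors$sd_scale[["t0"]], sc_sig[["t0"]])
      sig_t0 <- r[1]
      if (adapt) sc_sig[["t0"]] <- sc_sig[["t0"]] * exp(gam * (r[2] - 0.35))

      draws[iter, ] <- c(mu_b, sig_b, mu_v, sig_v, mu_t0, sig_t0,
                         as.vector(bmat), as.vector(vmat), t0s,
                         -2 * sum(L))
    }
    chains[[ch]] <- draws
  }
  list(group = dat$group, chains = chains, par_names = par_names,
       subj_levels = dat$subj_levels, S = S, nb = nb, nv = nv,
       bcol = bcol, vcol = vcol, data = dat)
}

#' Fit a hierarchical drift-diffusion model
#'
#' Estimates the joint posterior of group- and subject-level DDM parameters
#' by Metropolis-within-Gibbs MCMC, with one fully independent hierarchy per
#' group.  The reference run mirrors the production setting of 50,000
#' iterations with the first 5,000 discarded as burn-in; a reduced profile
#' (4,000 / 1,000, 2 chains) is appropriate for recovery studies and tests.
#' Sampling is deterministic given \code{seed}.
#'
#' @param object an \code{\link{hddm_model}}, or a trial table to be passed
#'   to \code{hddm_model} together with \code{variant} and \code{priors}.
#' @param variant,priors used when \code{object} is a trial table.
#' @param n_samples total MCMC iterations per chain (including burn-in).
#' @param n_burn iterations discarded as burn-in; must be < \code{n_samples}.
#' @param n_chains number of chains (>= 2 required for convergence
#'   diagnostics).
#' @param seed integer seed governing all chains.
#' @param err_tol truncation error of the Wiener density series.
#' @param likelihood \code{"wfpt"} for the Wiener likelihood, or
#'   \code{"null"} to replace it with a constant (prior-recovery smoke runs).
#' @return an object of class \code{"hddm_fit"}; see
#'   \code{\link{summary.hddm_fit}}, \code{\link{dic}}, \code{\link{rhat}},
#'   \code{\link{posterior_predictive_check}}.
#' @export
fit_hddm <- function(object, variant = c("M1_boundary", "M2_drift", "M3_both"),
                     priors = default_priors(), n_samples = 50000L,
                     n_burn = 5000L, n_chains = 2L, seed = 1L,
                     err_tol = 1e-7, likelihood = c("wfpt", "null")) {
  likelihood <- match.arg(likelihood)
  if (!inherits(object, "hddm_model"))
    object <- hddm_model(object, variant = variant, priors = priors)
  if (n_samples <= n_burn) stop("'n_samples' must exceed 'n_burn'")
  if (n_chains < 2) stop("at least 2 chains are required for diagnostics")
  t_start <- proc.time()[["elapsed"]]
  groups <- lapply(seq_along(object$data), function(gi)
    fit_group_mcmc(object$data[[gi]], object$variant, object$priors,
                   as.integer(n_samples), as.integer(n_burn),
                   as.integer(n_chains),
                   seed = seed + 1000L * (gi - 1L),
                   err_tol = err_tol, likelihood = likelihood))
  names(groups) <- names(object$data)
  structure(list(variant = object$variant, priors = object$priors,
                 groups = groups, n_samples = as.integer(n_samples),
                 n_burn = as.integer(n_burn), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), err_tol = err_tol,
                 likelihood = likelihood,
                 fingerprint = object$fingerprint,
                 elapsed = proc.time()[["elapsed"]] - t_start),
            class = "hddm_fit")
}

# post-burn-in draws of one group, chains stacked (iterations x parameters)
post_draws <- function(gfit, n_burn) {
  do.call(rbind, lapply(gfit$chains, function(m)
    m[(n_burn + 1):nrow(m), , drop = FALSE]))
}

#' Extract posterior draws of one parameter
#'
#' @param fit an \code{hddm_fit}.
#' @param group group name.
#' @param parameter parameter name as in the fit (e.g. \code{"mu_b[1]"},
#'   \code{"mu_v[1]"}, \code{"mu_t0"}).
#' @return numeric vector of post-burn-in draws pooled over chains.
#' @export
posterior_param <- function(fit, group, parameter) {
  g <- fit$groups[[group]]
  if (is.null(g)) stop("unknown group: ", group)
  if (!parameter %in% g$par_names) stop("unknown parameter: ", parameter)
  post_draws(g, fit$n_burn)[, parameter]
}
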