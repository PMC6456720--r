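#' Drift-diffusion parameter set
#'
#' Bundles the four parameters of the two-boundary diffusion under the
#' convention: diffusion coefficient 1, time in seconds, boundaries at 0
#' (lower) and \code{b} (upper).  The start point may be given either as an
#' absolute position \code{z} in (0, b) or as the relative position
#' \code{w = z/b}; it defaults to the unbiased midpoint \code{w = 0.5}.
#'
#' @param b boundary separation, > 0 (dimensionless under unit diffusion).
#' @param v drift rate per second; sign points toward the upper boundary.
#' @param t0 non-decision time in seconds, >= 0.
#' @param z absolute start point in (0, b); overrides \code{w} if given.
#' @param w relative start point z/b in (0, 1).
#' @return an object of class \code{"ddm_params"}.
#' @examples
#' p <- ddm_params(b = 2, v = 1, z = 1, t0 = 0.3)
#' upper_prob(p)
#' @export
ddm_params <- function(b, v, t0 = 0, z = NULL, w = 0.5) {
  if (!is.null(z)) w <- z / b
  stopifnot(b > 0, is.finite(v), t0 >= 0, w > 0, w < 1)
  structure(list(b = b, v = v, t0 = t0, w = w), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Drift-diffusion parameters (unit diffusion, time in s):\n")
  cat(sprintf("  b = %.4g  v = %.4g  z/b = %.4g  t0 = %.4g\n",
              x$b, x$v, x$w, x$t0))
  invisible(x)
}

#' Probability of absorption at the upper boundary
#'
#' Exact closed form for a diffusion with drift \code{v}, unit variance,
#' boundaries at 0 and \code{b}, started at \code{z = w*b}:
#' \deqn{P(upper) = (1 - e^{-2 v z}) / (1 - e^{-2 v b}),}
#' continuous at \code{v = 0} where it equals \code{z/b}.
#'
#' @param params a \code{\link{ddm_params}} object.
#' @return probability in [0, 1].
#' @export
upper_prob <- function(params) {
  b <- params$b; v <- params$v; z <- params$w * b
  if (abs(v * b) < 1e-9) return(z / b)
  # expm1 keeps the ratio stable for small |v|
  p <- expm1(-2 * v * z) / expm1(-2 * v * b)
  min(max(p, 0), 1)
}

#' Simulate first-passage samples by Euler-Maruyama
#'
#' Walks \code{x <- x + v dt + sqrt(dt) N(0,1)} from the start point until a
#' boundary is crossed.  Walks that survive past \code{cap} seconds are
#' returned as censored samples (boundary \code{NA}), never dropped.
#' Randomness comes from R's global RNG.
#'
#' Discrete monitoring of a continuous barrier misses crossings between
#' steps, biasing first-passage times upward by O(sqrt(dt)).  With
#' \code{correct = TRUE} (default) the absorption thresholds are pulled
#' inward by \code{0.5826 * sqrt(dt)}, the standard continuity correction
#' for discretely monitored barriers, which removes this bias to first
#' order.
#'
#' @param params a \code{\link{ddm_params}} object.
#' @param n number of independent trials.
#' @param dt Euler step in seconds.
#' @param cap hard time cap in seconds.
#' @param correct apply the barrier continuity correction.
#' @return data frame with \code{decision_time} (s), \code{boundary}
#'   (\code{"lower"}/\code{"upper"}/\code{NA}), \code{rt} (=
#'   decision_time + t0) and \code{censored}.
#' @export
simulate_fpt <- function(params, n = 1L, dt = 1e-4, cap = 20, correct = TRUE) {
  stopifnot(dt > 0, cap > dt, n >= 1)
  m <- .ddm_simulate_cpp(as.integer(n), params$b, params$v,
                         params$w * params$b, dt, cap, as.integer(correct))
  boundary <- c("lower", "upper")[m[, 2] + 1]
  data.frame(
    decision_time = m[, 1],
    boundary = boundary,
    rt = m[, 1] + params$t0,
    censored = m[, 3] == 1,
    stringsAsFactors = FALSE
  )
}

#' First-passage-time density of the diffusion
#'
#' Defective density of the response time \code{t} (including non-decision
#' time) at the named boundary.  Computed from the dual series representation
#' of the Wiener first-passage density: a small-time image expansion and a
#' large-time eigenfunction expansion, switching by the standard error-bound
#' crossover so the truncation depth always meets \code{err_tol}.  The density
#' integrates over \code{t > t0} to that boundary's absorption probability,
#' and is 0 for \code{t <= t0} by contract.
#'
#' @param t response times in seconds (vectorised).
#' @param boundary \code{"lower"} or \code{"upper"}.
#' @param params a \code{\link{ddm_params}} object.
#' @param err_tol absolute truncation error, > 0.
#' @return density values, per second.
#' @export
wfpt_density <- function(t, boundary = c("lower", "upper"), params,
                         err_tol = 1e-7) {
  boundary <- match.arg(boundary)
  if (err_tol <= 0) stop("'err_tol' must be > 0")
  u <- t - params$t0
  out <- numeric(length(t))
  ok <- which(u > 0)
  if (length(ok))
    out[ok] <- .wfpt_density_cpp(u[ok], rep(as.integer(boundary == "upper"),
                                            length(ok)),
                                 params$b, params$v, params$w, err_tol)
  out
}

#' Trial log-likelihood under stimulus coding
#'
#' Maps responses to boundaries (LEFT to lower, RIGHT to upper) and sets the
#' drift sign by the stimulus side (+v when the stimulus is RIGHT, -v when
#' LEFT), so a single positive drift magnitude expresses evidence toward the
#' correct response.  Returns \code{-Inf} for response times at or below the
#' non-decision time (an impossible datum), not an error.
#'
#' @param rt response times in seconds (vectorised).
#' @param response,stimulus character vectors, \code{"LEFT"}/\code{"RIGHT"}.
#' @param params a \code{\link{ddm_params}} object.
#' @param err_tol series truncation error.
#' @return log densities; \code{-Inf} where \code{rt <= t0}.
#' @export
loglik_trial <- function(rt, response, stimulus, params, err_tol = 1e-7) {
  stopifnot(all(response %in% c("LEFT", "RIGHT")),
            all(stimulus %in% c("LEFT", "RIGHT")))
  n <- max(length(rt), length(response), length(stimulus))
  rt <- rep_len(rt, n)
  upper <- as.integer(rep_len(response, n) == "RIGHT")
  sgn <- ifelse(rep_len(stimulus, n) == "RIGHT", 1, -1)
  ll <- .wfpt_loglik_grouped_cpp(rt, upper, rep(params$b, n), sgn * params$v,
                                 rep(params$t0, n), params$w, err_tol,
                                 seq_len(n), n)
  ll
}

# Summed log-likelihood of a prepared trial set, grouped by an integer id.
# Internal workhorse for the samplers: all per-trial parameter vectors are
# already expanded to trial length and the drift sign already applied.
wfpt_loglik_grouped <- function(rt, upper, b, v, t0, w, err, gid, ngroups) {
  .wfpt_loglik_grouped_cpp(rt, upper, b, v, t0, w, err, gid, ngroups)
}
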