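#' The four foreperiod conditions of the 2x2 design
#'
#' The variable-foreperiod task crosses mean foreperiod duration (Short:
#' 1500 ms; Long: 3000 ms) with foreperiod variability (Low: SD 100 ms; High:
#' SD 600 ms).  Foreperiods are drawn from Gaussians truncated symmetrically
#' around the mean: at 500 and 2500 ms for the Short distributions, at 2000
#' and 4000 ms for the Long ones.  Each cell carries a temporal-predictability
#' rank \code{tp_rank} from 4 (most predictable) down to 1 (least).
#'
#' The ordering of the middle cells on the predictability scale is not
#' uniquely determined by the design; the default ranks duration before
#' variability (Short/Low = 4, Short/High = 3, Long/Low = 2, Long/High = 1),
#' consistent with onset uncertainty growing with both the length and the
#' variability of the foreperiod.  Any permutation can be supplied instead.
#'
#' @param tp_ranks named integer vector assigning ranks 1..4 to the cells
#'   \code{"Short/Low"}, \code{"Short/High"}, \code{"Long/Low"},
#'   \code{"Long/High"}; must be a permutation of 1:4.
#' @return A data frame with one row per condition and columns
#'   \code{duration_level}, \code{variability_level}, \code{mu}, \code{sigma},
#'   \code{lower}, \code{upper} (all times in ms) and \code{tp_rank}.
#' @examples
#' make_condition_grid()
#' @export
make_condition_grid <- function(tp_ranks = c("Short/Low" = 4L, "Short/High" = 3L,
                                             "Long/Low" = 2L, "Long/High" = 1L)) {
  grid <- data.frame(
    duration_level    = c("Short", "Short", "Long", "Long"),
    variability_level = c("Low", "High", "Low", "High"),
    mu    = c(1500, 1500, 3000, 3000),
    sigma = c(100, 600, 100, 600),
    lower = c(500, 500, 2000, 2000),
    upper = c(2500, 2500, 4000, 4000),
    stringsAsFactors = FALSE
  )
  cell <- paste(grid$duration_level, grid$variability_level, sep = "/")
  if (!setequal(names(tp_ranks), cell) || !setequal(tp_ranks, 1:4))
    stop("'tp_ranks' must assign a permutation of 1:4 to the cells ",
         paste(cell, collapse = ", "))
  grid$tp_rank <- as.integer(tp_ranks[cell])
  grid
}

#' Draw foreperiods from a truncated Gaussian condition
#'
#' Samples from Normal(mu, sigma) conditioned on the interval
#' \code{[lower, upper]}.  Rejection sampling from the untruncated normal is
#' used (the four design cells all have acceptance probability >= 0.90); if a
#' batch fails to fill within a generous number of rounds the exact
#' inverse-CDF construction takes over.  Randomness comes from R's global RNG,
#' so results are reproducible under \code{set.seed()}.
#'
#' @param condition one row of \code{\link{make_condition_grid}} (or any list
#'   with \code{mu}, \code{sigma}, \code{lower}, \code{upper} in ms).
#' @param n number of draws.
#' @return numeric vector of n foreperiods in ms, all within
#'   \code{[lower, upper]}.
#' @export
sample_foreperiod <- function(condition, n = 1L) {
  mu <- condition$mu; sigma <- condition$sigma
  lo <- condition$lower; hi <- condition$upper
  stopifnot(is.finite(mu), sigma > 0, lo < mu, mu < hi)
  out <- numeric(0)
  rounds <- 0L
  while (length(out) < n && rounds < 50L) {
    need <- n - length(out)
    x <- stats::rnorm(ceiling(need / 0.85), mu, sigma)
    out <- c(out, x[x >= lo & x <= hi])
    rounds <- rounds + 1L
  }
  if (length(out) < n) {  # inverse-CDF fallback, exact for any truncation
    need <- n - length(out)
    u <- stats::runif(need, stats::pnorm(lo, mu, sigma), stats::pnorm(hi, mu, sigma))
    out <- c(out, stats::qnorm(u, mu, sigma))
  }
  out[seq_len(n)]
}

#' Build one session's blocked trial schedule
#'
#' A session is \code{n_blocks} blocks of \code{n_trials} trials; every block
#' runs a single foreperiod condition throughout.  Block-to-condition
#' assignment follows a cyclic Latin square: \code{order_index} selects the
#' row, so running indices 1..4 across participants/sessions balances
#' condition order.  Stimulus side is drawn equiprobably LEFT/RIGHT and
#' independently per trial.
#'
#' @param conditions condition grid from \code{\link{make_condition_grid}}.
#' @param n_blocks number of blocks; must equal \code{nrow(conditions)}.
#' @param n_trials trials per block (120 in the reference design).
#' @param order_index Latin-square row, an integer in 1..\code{n_blocks}.
#' @return data frame with one row per trial: \code{block}, \code{trial},
#'   condition columns, \code{foreperiod_ms}, \code{stimulus}.
#' @export
build_session_schedule <- function(conditions, n_blocks = 4L, n_trials = 120L,
                                   order_index = 1L) {
  k <- nrow(conditions)
  if (n_blocks != k)
    stop("'n_blocks' (", n_blocks, ") must equal the number of conditions (", k, ")")
  if (!is.numeric(order_index) || length(order_index) != 1L ||
      order_index < 1L || order_index > k || order_index != round(order_index))
    stop("'order_index' must be an integer in 1..", k)
  # cyclic Latin square row: block j runs condition ((order_index + j - 2) mod k) + 1
  cond_of_block <- ((order_index + seq_len(k) - 2L) %% k) + 1L
  rows <- lapply(seq_len(n_blocks), function(blk) {
    ci <- cond_of_block[blk]
    cnd <- conditions[ci, , drop = FALSE]
    data.frame(
      block = blk,
      trial = seq_len(n_trials),
      duration_level = cnd$duration_level,
      variability_level = cnd$variability_level,
      tp_rank = cnd$tp_rank,
      foreperiod_ms = sample_foreperiod(cnd, n_trials),
      stimulus = sample(c("LEFT", "RIGHT"), n_trials, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Generate a training block with exponential foreperiods
#'
#' The training block uses a non-ageing (exponential) foreperiod distribution
#' with mean 1000 ms, so elapsed time carries no information about stimulus
#' onset.  Trials are flagged \code{training = TRUE}.
#'
#' @param n_trials number of trials (default 40).
#' @param mean_ms mean of the exponential foreperiod distribution, ms.
#' @return data frame with \code{trial}, \code{foreperiod_ms},
#'   \code{stimulus}, \code{training}.
#' @export
generate_training_block <- function(n_trials = 40L, mean_ms = 1000) {
  stopifnot(n_trials > 0, mean_ms > 0)
  data.frame(
    trial = seq_len(n_trials),
    foreperiod_ms = stats::rexp(n_trials, rate = 1 / mean_ms),
    stimulus = sample(c("LEFT", "RIGHT"), n_trials, replace = TRUE),
    training = TRUE,
    stringsAsFactors = FALSE
  )
}

# recode temporal predictability rank (4 = most predictable) to the regression
# predictor x = 4 - tp_rank, so x = 0 at highest predictability and the
# intercept of any regression over x is the value at highest predictability
tp_to_x <- function(tp_rank) 4L - as.integer(tp_rank)
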