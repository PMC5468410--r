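#' Exponential learning curve
#'
#' `P(s) = pmax - (pmax - p0) * exp(-s / tau)` for session index `s = 1, 2, ...`
#' in performance points (0-100).
#'
#' @param s Session index (vectorized).
#' @param p0,pmax Initial and asymptotic performance, `0 <= p0 <= pmax <= 100`.
#' @param tau Learning time constant in sessions; must be positive.
#' @return Numeric vector of expected performance values.
#' @export
learning_curve <- function(s, p0, pmax, tau) {
  if (tau <= 0) stop("`tau` must be positive.", call. = FALSE)
  if (p0 < 0 || p0 > pmax || pmax > 100) {
    stop("Need 0 <= p0 <= pmax <= 100.", call. = FALSE)
  }
  pmax - (pmax - p0) * exp(-s / tau)
}

#' Simulate behavioral task logs for a training course
#'
#' Produces, per session, raw event logs for the four concurrent subtasks of a
#' multi-attribute task battery -- tracking (TRCK: cursor distances),
#' communications (COMM: correct flags and reaction times), system monitoring
#' (SYSM: correct flags and reaction times) and resource management (RMAN:
#' main-tank fuel levels around the 2,500 lbs target) -- constructed so that
#' each subtask's performance index matches the session's learning-curve value
#' up to bounded (truncated Gaussian, +/- 2 SD) noise.
#'
#' @param config A [sim_course_config()].
#' @return A list with `performance`, a tibble of per-session target values,
#'   and `logs`, a list (one element per session) of subtask log tibbles
#'   (`trck`, `comm`, `sysm`, `rman`). Score the logs with
#'   [score_session_behavior()].
#' @export
simulate_behavior <- function(config) {
  stopifnot(inherits(config, "sim_course_config"))
  pc <- config$perf_curve
  s <- seq_len(config$n_sessions)
  target <- learning_curve(s, pc[["p0"]], pc[["pmax"]], pc[["tau"]])
  logs <- lapply(s, function(k) {
    withr::with_seed(session_seed(config$seed, 10000L + k), {
      p <- clip(target[k] + trunc_norm(1, config$behavior_sd), 0, 100)
      simulate_session_logs(p, config$behavior_sd)
    })
  })
  list(
    performance = tibble::tibble(session = s, target = target),
    logs = logs
  )
}

# one session's raw subtask logs at session-level performance p (0-100)
simulate_session_logs <- function(p, sdev) {
  miss <- 1 - p / 100
  sub_p <- clip(p + trunc_norm(4, sdev / 2), 0, 100)

  d_max <- 100
  trck <- tibble::tibble(
    distance = clip(d_max * (1 - sub_p[1] / 100) +
                      trunc_norm(200, 2), 0, d_max),
    max_distance = d_max
  )

  comm <- event_log(n = 7, p = sub_p[2], rt_max = 20)
  sysm <- event_log(n = 10, p = sub_p[3], rt_max = 5)

  dev_target <- 2500 * (1 - sub_p[4] / 100)
  n_rm <- 180
  rman <- tibble::tibble(
    tank = rep(c("A", "B"), each = n_rm / 2),
    level = clip(2500 + sample(c(-1, 1), n_rm, replace = TRUE) *
                   pmax(dev_target + trunc_norm(n_rm, 25), 0), 0, 5000)
  )
  list(trck = trck, comm = comm, sysm = sysm, rman = rman)
}

# COMM/SYSM event log whose index (accuracy and timeliness equally weighted)
# is close to p; the number of correct events is the rounded expectation so
# accuracy noise stays bounded by the event quantization
event_log <- function(n, p, rt_max) {
  n_true <- round(n * p / 100)
  correct <- sample(rep(c(TRUE, FALSE), c(n_true, n - n_true)))
  rt <- clip(rt_max * (1 - p / 100) + trunc_norm(n, rt_max / 50), 0, rt_max)
  tibble::tibble(correct = correct, reaction_time = rt, max_time = rt_max)
}

trunc_norm <- function(n, sdev) {
  if (sdev <= 0) return(numeric(n))
  clip(stats::rnorm(n, 0, sdev), -2 * sdev, 2 * sdev)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
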