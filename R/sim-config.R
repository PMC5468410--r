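#' Configuration for a simulated training course
#'
#' Defines a multi-session, two-condition (EASY/HARD) EEG training course with
#' known ground truth: condition-dependent frontal theta and parietal alpha
#' band power, a per-session drift of the discriminative spatial/spectral
#' signature, and an exponential behavioral learning curve.
#'
#' Each session consists of `blocks_per_session` condition blocks of
#' `condition_block_duration` seconds, alternating EASY and HARD, tiling the
#' session exactly. The EEG in every block is 1/f ("pink") background noise
#' plus band-limited theta (frontal) and alpha (parietal) rhythms. In HARD
#' blocks the per-channel oscillator power is scaled by
#' `1 + (effect - 1) * m`, where `m` in `[0, 1]` is the session's signature
#' pattern: the channel with `m = 1` realizes the configured HARD/EASY power
#' ratio exactly. Session `s` perturbs this signature relative to session 1
#' by `drift_schedule[s]` (radians): the pattern rotates between two
#' orthogonal patterns supported on complementary channel subsets (a drift
#' step of pi/2 relocates the discriminative channels entirely -- functional
#' reorganization), and the oscillator center frequencies shift by
#' `0.5 * drift_schedule[s]` Hz.
#'
#' @param n_sessions Number of training sessions.
#' @param channels Channel labels (10-10 names); must contain the full frontal
#'   and parietal feature sets (see [frontal_channels()], [parietal_channels()]).
#' @param fs Sampling frequency in Hz; must exceed 60 Hz so the 1-30 Hz
#'   analysis band is representable.
#' @param condition_block_duration Duration of one condition block, seconds.
#' @param blocks_per_session Number of alternating EASY/HARD blocks.
#' @param iaf_true Ground-truth individual alpha frequency in Hz.
#' @param theta_effect HARD/EASY theta band-power ratio on frontal channels.
#' @param alpha_effect HARD/EASY alpha band-power ratio on parietal channels
#'   (values below 1 emulate workload-related alpha desynchronization).
#' @param drift_schedule Non-negative numeric of length `n_sessions`; drift
#'   angle (radians) of each session's signature relative to session 1.
#'   Default: no drift in session 1, increasing drift that freezes from
#'   session 3 on (a course that stabilizes mid-way).
#' @param perf_curve Named numeric `c(p0=, pmax=, tau=)` of the learning curve
#'   `P(s) = pmax - (pmax - p0) * exp(-s / tau)` in performance points (0-100).
#' @param noise_sd Standard deviation of the pink background noise, microvolts.
#' @param theta_amplitude,alpha_amplitude EASY-condition oscillator RMS
#'   amplitude in microvolts on the strongest channel of the spatial pattern.
#' @param behavior_sd SD of truncated-Gaussian session-level performance noise,
#'   performance points.
#' @param seed Integer seed; all generated data are a deterministic function
#'   of the configuration.
#' @return An object of class `sim_course_config`.
#' @examples
#' cfg <- sim_course_config(n_sessions = 2, condition_block_duration = 10,
#'                          fs = 128, seed = 1)
#' @export
sim_course_config <- function(n_sessions = 6,
                              channels = default_montage(),
                              fs = 256,
                              condition_block_duration = 450,
                              blocks_per_session = 4,
                              iaf_true = 10,
                              theta_effect = 2,
                              alpha_effect = 0.5,
                              drift_schedule = NULL,
                              perf_curve = c(p0 = 60, pmax = 91, tau = 0.8),
                              noise_sd = 10,
                              theta_amplitude = 12,
                              alpha_amplitude = 12,
                              behavior_sd = 2,
                              seed = 1L) {
  if (n_sessions < 1) stop("Need at least one session.", call. = FALSE)
  if (fs <= 2 * 30) {
    stop("`fs` must exceed 60 Hz (2 x 30 Hz filter band).", call. = FALSE)
  }
  if (condition_block_duration <= 0 || blocks_per_session < 1) {
    stop("Block duration and count must be positive.", call. = FALSE)
  }
  if (anyDuplicated(channels)) stop("Channel labels must be unique.", call. = FALSE)
  missing_ch <- setdiff(c(frontal_channels(), parietal_channels()), channels)
  if (length(missing_ch)) {
    stop("Channels must include the frontal and parietal feature sets; missing: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  if (is.null(drift_schedule)) {
    drift_schedule <- pmin(0.4 * (seq_len(n_sessions) - 1), 0.8)
  }
  if (length(drift_schedule) != n_sessions || any(drift_schedule < 0)) {
    stop("`drift_schedule` must be non-negative, one value per session.",
         call. = FALSE)
  }
  pc <- as.list(perf_curve)
  if (!all(c("p0", "pmax", "tau") %in% names(pc))) {
    stop("`perf_curve` needs named elements p0, pmax, tau.", call. = FALSE)
  }
  if (pc$tau <= 0) stop("Learning-curve `tau` must be positive.", call. = FALSE)
  if (pc$p0 < 0 || pc$p0 > pc$pmax || pc$pmax > 100) {
    stop("Need 0 <= p0 <= pmax <= 100.", call. = FALSE)
  }
  if (theta_effect <= 0 || alpha_effect <= 0) {
    stop("Effect ratios must be positive.", call. = FALSE)
  }
  structure(
    list(n_sessions = as.integer(n_sessions), channels = as.character(channels),
         fs = fs, condition_block_duration = condition_block_duration,
         blocks_per_session = as.integer(blocks_per_session),
         iaf_true = iaf_true, theta_effect = theta_effect,
         alpha_effect = alpha_effect, drift_schedule = drift_schedule,
         perf_curve = c(p0 = pc$p0, pmax = pc$pmax, tau = pc$tau),
         noise_sd = noise_sd, theta_amplitude = theta_amplitude,
         alpha_amplitude = alpha_amplitude, behavior_sd = behavior_sd,
         seed = as.integer(seed)),
    class = "sim_course_config"
  )
}

#' @export
print.sim_course_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_course_config> %d sessions, %d x %gs blocks @ %g Hz, %d channels\n",
    "  IAF %g Hz; theta effect %g, alpha effect %g; drift: %s\n",
    "  perf curve p0=%g pmax=%g tau=%g; seed %d\n"),
    x$n_sessions, x$blocks_per_session, x$condition_block_duration, x$fs,
    length(x$channels), x$iaf_true, x$theta_effect, x$alpha_effect,
    paste(signif(x$drift_schedule, 2), collapse = " "),
    x$perf_curve[["p0"]], x$perf_curve[["pmax"]], x$perf_curve[["tau"]],
    x$seed))
  invisible(x)
}

# deterministic sub-seed; kept < 2^31 and exact in double arithmetic
session_seed <- function(seed, k) {
  as.integer(((seed %% 65536) * 65537 + k * 101159) %% 2147483647)
}
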