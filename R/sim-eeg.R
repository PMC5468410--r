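#' Simulate one EEG training session
#'
#' Generates a continuous multi-channel recording for one session of a
#' simulated course: per-channel 1/f background noise plus band-limited theta
#' and alpha oscillations whose condition-dependent amplitudes on frontal and
#' parietal channels realize the configured HARD/EASY power ratios. The
#' discriminative signature of session `s` is rotated in channel space and
#' shifted in frequency by the session's drift value relative to session 1.
#' Output is bit-identical for a given `(config, session)`.
#'
#' @param config A [sim_course_config()].
#' @param session Session index, `1..n_sessions`.
#' @return An [eeg_recording()] with alternating EASY/HARD block annotations.
#' @export
simulate_session <- function(config, session) {
  stopifnot(inherits(config, "sim_course_config"))
  if (session < 1 || session > config$n_sessions) {
    stop("`session` must lie in 1..n_sessions.", call. = FALSE)
  }
  fs <- config$fs
  n_block <- round(fs * config$condition_block_duration)
  n_ch <- length(config$channels)
  conds <- rep(c("EASY", "HARD"), length.out = config$blocks_per_session)
  delta <- config$drift_schedule[session]

  w <- signature_weights(config, delta)
  f_theta <- (config$iaf_true - 4) + 0.5 * delta
  f_alpha <- config$iaf_true + 0.5 * delta

  blocks <- withr::with_seed(session_seed(config$seed, session), {
    lapply(seq_along(conds), function(b) {
      hard <- conds[b] == "HARD"
      # per-channel HARD/EASY power ratio: the configured effect expressed
      # through the session's signature pattern m in [0, 1]
      gain <- function(effect, m) if (hard) sqrt(1 + (effect - 1) * m) else 1
      bg <- config$noise_sd *
        matrix(vapply(seq_len(n_ch), function(i) pink_noise(n_block),
                      numeric(n_block)), nrow = n_ch, byrow = TRUE)
      rest_alpha <- band_noise(n_block, fs, config$iaf_true)
      bg +
        config$theta_amplitude *
          spatial_oscillation(w$theta * gain(config$theta_effect, w$m_theta),
                              n_block, fs, f_theta) +
        config$alpha_amplitude *
          spatial_oscillation(w$alpha * gain(config$alpha_effect, w$m_alpha),
                              n_block, fs, f_alpha) +
        (config$alpha_amplitude / 2) * outer(w$posterior, rest_alpha)
    })
  })
  data <- do.call(cbind, blocks)
  ann <- tibble::tibble(
    onset = (seq_along(conds) - 1) * config$condition_block_duration,
    duration = config$condition_block_duration,
    condition = conds
  )
  eeg_recording(data, fs, config$channels, ann)
}

#' Simulate an eyes-closed rest recording
#'
#' One-minute (by default) eyes-closed rest with a prominent alpha rhythm at
#' the configured ground-truth IAF over parieto-occipital and parietal
#' channels, used to estimate the individual alpha frequency.
#'
#' @param config A [sim_course_config()].
#' @param duration Rest duration in seconds.
#' @return An [eeg_recording()] without annotations.
#' @export
simulate_rest <- function(config, duration = 60) {
  stopifnot(inherits(config, "sim_course_config"))
  if (duration <= 0) stop("`duration` must be positive.", call. = FALSE)
  fs <- config$fs
  n <- round(fs * duration)
  n_ch <- length(config$channels)
  post <- config$channels %in% c(posterior_channels(), parietal_channels())
  withr::with_seed(session_seed(config$seed, 0L), {
    bg <- config$noise_sd *
      matrix(vapply(seq_len(n_ch), function(i) pink_noise(n),
                    numeric(n)), nrow = n_ch, byrow = TRUE)
    alpha <- band_noise(n, fs, config$iaf_true, halfwidth = 0.75)
    gain <- ifelse(post, 2 * config$alpha_amplitude, 0.2 * config$alpha_amplitude)
    data <- bg + outer(gain, alpha)
    eeg_recording(data, fs, config$channels)
  })
}

# unit-RMS 1/f^(beta/2)-shaped noise
pink_noise <- function(n, beta = 1) {
  white <- stats::rnorm(n)
  idx <- c(0, seq_len(n - 1))
  f <- pmin(idx, n - idx)           # symmetric frequency index
  scale <- 1 / pmax(f, 1)^(beta / 2)
  x <- Re(stats::fft(stats::fft(white) * scale, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

# band-limited oscillation over a channel set: each active channel carries a
# mixture of a common rhythm and a channel-specific one (band power
# fluctuates semi-independently across sites, as in scalp EEG, so epochs are
# informative on many channels at once), scaled by the spatial weights
spatial_oscillation <- function(w, n, fs, center, rho = 0.3) {
  active <- which(w != 0)
  out <- matrix(0, length(w), n)
  if (!length(active)) return(out)
  common <- band_noise(n, fs, center)
  for (ch in active) {
    out[ch, ] <- w[ch] * (sqrt(rho) * common +
                            sqrt(1 - rho) * band_noise(n, fs, center))
  }
  out
}

# unit-RMS band-limited noise centered at `center` Hz (stochastic phase, so
# epoch-scale segments are incoherent with one another)
band_noise <- function(n, fs, center, halfwidth = 1) {
  pad <- round(2 * fs)
  bf <- signal::butter(2, c(center - halfwidth, center + halfwidth) / (fs / 2),
                       type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * pad))
  x <- x[(pad + 1):(pad + n)]
  x / stats::sd(x)
}

# The oscillators ride on every channel of their set with a fixed jittered
# amplitude pattern (unit maximum). What drifts across sessions is the
# discriminative signature: the per-channel pattern m in [0, 1] saying how
# strongly each channel expresses the HARD/EASY effect. The base pattern and
# a companion pattern live on near-disjoint channel subsets, and drift by
# delta radians rotates between them -- emulating the functional
# reorganization of practice, where the sites carrying the workload effect
# relocate while the rhythms themselves persist. The channel where m = 1
# realizes the configured effect ratio exactly.
signature_weights <- function(config, delta) {
  ch <- config$channels
  front <- ch %in% frontal_channels()
  pari <- ch %in% parietal_channels()
  base <- withr::with_seed(session_seed(config$seed, 999983L), {
    list(theta_dir = split_directions(sum(front)),
         alpha_dir = split_directions(sum(pari)),
         theta_amp = 1 + 0.2 * abs(stats::rnorm(sum(front))),
         alpha_amp = 1 + 0.2 * abs(stats::rnorm(sum(pari))))
  })
  expand <- function(vals, mask) {
    out <- numeric(length(ch))
    out[mask] <- vals
    out
  }
  rot_m <- function(dir) {
    m <- (cos(delta) * dir$u + sin(delta) * dir$v)^2
    m / max(m)
  }
  post <- numeric(length(ch))
  post[ch %in% posterior_channels()] <- 1
  list(theta = expand(base$theta_amp / max(base$theta_amp), front),
       alpha = expand(base$alpha_amp / max(base$alpha_amp), pari),
       m_theta = expand(rot_m(base$theta_dir), front),
       m_alpha = expand(rot_m(base$alpha_dir), pari),
       posterior = post)
}

# two unit directions supported on complementary halves of the channel set
# (orthogonal by construction), so a 90-degree drift relocates the signature
# to entirely different channels
split_directions <- function(k) {
  half <- sample(k, floor(k / 2))
  u <- numeric(k)
  v <- numeric(k)
  u[half] <- 0.5 + abs(stats::rnorm(length(half)))
  v[-half] <- 0.5 + abs(stats::rnorm(k - length(half)))
  list(u = u / sqrt(sum(u^2)), v = v / sqrt(sum(v^2)))
}
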