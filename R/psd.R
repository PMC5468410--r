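#' Hanning-windowed power spectral density of one epoch
#'
#' Single-taper periodogram: a Hanning window spanning the full epoch, one
#' FFT, one-sided density scaling. The bin spacing equals
#' `1 / epoch_length` Hz (0.5 Hz for a 2-s epoch).
#'
#' @param epoch Numeric vector (one channel) or channels x samples matrix.
#' @param fs Sampling frequency in Hz.
#' @return A list with `freq` (Hz) and `power` (channels x bins matrix,
#'   microvolts^2/Hz, all non-negative).
#' @export
compute_psd <- function(epoch, fs) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  n <- ncol(epoch)
  if (n < 2) stop("Epoch must have at least 2 samples.", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive.", call. = FALSE)
  w <- hanning_window(n)
  xw <- sweep(epoch, 2, w, `*`)
  ft <- t(stats::mvfft(t(xw)))
  nf <- floor(n / 2) + 1L
  p <- (Mod(ft[, seq_len(nf), drop = FALSE])^2) * (2 / (fs * sum(w^2)))
  p[, 1] <- p[, 1] / 2
  if (n %% 2 == 0) p[, nf] <- p[, nf] / 2
  list(freq = (seq_len(nf) - 1) * fs / n, power = p)
}

hanning_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# PSD for every epoch: returns freq and an [epoch, channel, bin] array
psd_epochs <- function(es) {
  d <- dim(es$data)
  n <- d[3]
  w <- hanning_window(n)
  nf <- floor(n / 2) + 1L
  m <- matrix(aperm(es$data, c(3, 1, 2)), nrow = n) * w
  ft <- stats::mvfft(m)
  p <- (Mod(ft[seq_len(nf), , drop = FALSE])^2) * (2 / (es$fs * sum(w^2)))
  p[1, ] <- p[1, ] / 2
  if (n %% 2 == 0) p[nf, ] <- p[nf, ] / 2
  list(freq = (seq_len(nf) - 1) * es$fs / n,
       power = aperm(array(p, dim = c(nf, d[1], d[2])), c(2, 3, 1)))
}

#' Estimate the individual alpha frequency from eyes-closed rest
#'
#' Averages Hanning periodograms of consecutive `epoch_length`-second windows
#' over parieto-occipital channels (labels starting `PO`/`O`; all channels if
#' none are present) and locates the dominant spectral peak inside
#' `search_range`. The theta band is anchored at `[IAF-6, IAF-2]` Hz and the
#' alpha band at `[IAF-2, IAF+2]` Hz.
#'
#' A peak must be a strict interior maximum of the searched range and exceed
#' `min_prominence` times the median in-range power; a flat or monotone
#' spectrum (e.g. white noise) raises an error asking for a manual IAF.
#'
#' @param rest An [eeg_recording()] of eyes-closed rest, >= 10 s.
#' @param search_range Numeric length-2, Hz (default 7-13, the standard
#'   alpha-peak convention).
#' @param channels Optional channel labels to average over.
#' @param epoch_length Analysis window in seconds.
#' @param min_prominence Peak power / median in-range power required.
#' @return An `iaf_profile`: `iaf`, `theta_band`, `alpha_band`,
#'   `search_range`, `channels_used`, `prominence`.
#' @export
estimate_iaf <- function(rest, search_range = c(7, 13), channels = NULL,
                         epoch_length = 2, min_prominence = 1.5) {
  stopifnot(inherits(rest, "eeg_recording"))
  if (rec_duration(rest) < 10) {
    stop("Rest recording must be at least 10 s long.", call. = FALSE)
  }
  if (is.null(channels)) {
    channels <- grep("^(PO|O)", rest$channels, value = TRUE)
    if (length(channels) == 0) channels <- rest$channels
  }
  sel <- match(channels, rest$channels)
  if (anyNA(sel)) stop("Unknown channels requested.", call. = FALSE)
  fs <- rest$fs
  spl <- round(epoch_length * fs)
  n_ep <- floor(ncol(rest$data) / spl)
  acc <- 0
  for (e in seq_len(n_ep)) {
    seg <- rest$data[sel, ((e - 1) * spl + 1):(e * spl), drop = FALSE]
    ps <- compute_psd(seg, fs)
    acc <- acc + colMeans(ps$power)
  }
  freq <- (seq_len(floor(spl / 2) + 1L) - 1) * fs / spl
  spectrum <- acc / n_ep
  in_range <- which(freq >= search_range[1] & freq <= search_range[2])
  if (length(in_range) < 3) stop("Search range too narrow.", call. = FALSE)
  pk <- in_range[which.max(spectrum[in_range])]
  prominence <- spectrum[pk] / stats::median(spectrum[in_range])
  interior <- pk != in_range[1] && pk != in_range[length(in_range)]
  if (!interior || prominence < min_prominence) {
    stop("No clear alpha peak in the rest spectrum; supply the IAF manually ",
         "via iaf_profile().", call. = FALSE)
  }
  iaf_profile(freq[pk], search_range = search_range,
              channels_used = channels, prominence = prominence)
}

#' Manually specify (or wrap) an individual alpha frequency
#'
#' @param iaf IAF in Hz.
#' @param search_range Range within which the IAF was sought.
#' @param channels_used Channels averaged for the estimate.
#' @param prominence Peak prominence (peak / median in-range power).
#' @return An `iaf_profile` with IAF-anchored theta `[IAF-6, IAF-2]` and
#'   alpha `[IAF-2, IAF+2]` bands.
#' @export
iaf_profile <- function(iaf, search_range = c(7, 13), channels_used = NULL,
                        prominence = NA_real_) {
  if (iaf < search_range[1] || iaf > search_range[2]) {
    stop("IAF must lie within the search range.", call. = FALSE)
  }
  structure(
    list(iaf = iaf, theta_band = c(iaf - 6, iaf - 2),
         alpha_band = c(iaf - 2, iaf + 2), search_range = search_range,
         channels_used = channels_used, prominence = prominence),
    class = "iaf_profile"
  )
}

#' @export
print.iaf_profile <- function(x, ...) {
  cat(sprintf("<iaf_profile> IAF = %g Hz; theta [%g, %g] Hz, alpha [%g, %g] Hz\n",
              x$iaf, x$theta_band[1], x$theta_band[2],
              x$alpha_band[1], x$alpha_band[2]))
  invisible(x)
}
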