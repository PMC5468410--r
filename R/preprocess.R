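#' Zero-phase Butterworth band-pass filter
#'
#' Applies a fifth-order (by default) Butterworth high-pass at `low` Hz and
#' low-pass at `high` Hz to every channel, each forward-backward
#' (zero-phase), so condition labels are not smeared across epochs by filter
#' delay. The effective magnitude response is the squared single-pass
#' response.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Filter order of each section.
#' @return A filtered [eeg_recording()] with the same shape and labels.
#' @export
bandpass_filter <- function(rec, low = 1, high = 30, order = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    stop("Need 0 < low < high < fs/2.", call. = FALSE)
  }
  lp <- signal::butter(order, high / (rec$fs / 2), type = "low")
  hp <- signal::butter(order, low / (rec$fs / 2), type = "high")
  filt <- t(apply(rec$data, 1, function(x) {
    signal::filtfilt(hp, signal::filtfilt(lp, x))
  }))
  eeg_recording(filt, rec$fs, rec$channels, rec$annotations)
}

#' Segment a recording into fixed-length overlapping epochs
#'
#' Within each annotated condition block of duration `T`, epochs of
#' `epoch_length` seconds start every `shift` seconds from the block onset, so
#' a block yields `floor((T - epoch_length) / shift) + 1` epochs. Epochs never
#' straddle block boundaries; a block shorter than `epoch_length` yields zero
#' epochs with a warning.
#'
#' @param rec An annotated [eeg_recording()].
#' @param epoch_length Epoch length in seconds.
#' @param shift Epoch step in seconds; must be positive.
#' @return An object of class `eeg_epochs`: a `n_epochs x channels x samples`
#'   array plus an `info` tibble (epoch, onset, condition).
#' @export
segment_epochs <- function(rec, epoch_length = 2, shift = 0.125) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$annotations) || nrow(rec$annotations) == 0) {
    stop("Recording has no condition annotations to epoch within.", call. = FALSE)
  }
  if (shift <= 0 || epoch_length <= 0) {
    stop("`epoch_length` and `shift` must be positive.", call. = FALSE)
  }
  fs <- rec$fs
  spl <- round(epoch_length * fs)
  onsets <- condition <- list()
  for (b in seq_len(nrow(rec$annotations))) {
    blk <- rec$annotations[b, ]
    n_ep <- n_epochs_in_block(blk$duration, epoch_length, shift)
    if (n_ep == 0) {
      warning(sprintf("Block %d (%s, %.3g s) shorter than the epoch length; no epochs.",
                      b, blk$condition, blk$duration), call. = FALSE)
      next
    }
    onsets[[b]] <- blk$onset + (seq_len(n_ep) - 1) * shift
    condition[[b]] <- rep(blk$condition, n_ep)
  }
  onsets <- unlist(onsets) %||% numeric(0)
  condition <- unlist(condition) %||% character(0)
  n_ep <- length(onsets)
  if (n_ep == 0) stop("No epochs could be formed.", call. = FALSE)
  data <- array(NA_real_, dim = c(n_ep, nrow(rec$data), spl))
  starts <- round(onsets * fs) + 1L
  for (e in seq_len(n_ep)) {
    data[e, , ] <- rec$data[, starts[e]:(starts[e] + spl - 1L)]
  }
  structure(
    list(data = data, fs = fs, channels = rec$channels,
         epoch_length = epoch_length, shift = shift,
         info = tibble::tibble(epoch = seq_len(n_ep), onset = onsets,
                               condition = condition)),
    class = "eeg_epochs"
  )
}

# epoch-count formula for one block
n_epochs_in_block <- function(duration, epoch_length, shift) {
  if (duration < epoch_length) return(0L)
  as.integer(floor((duration - epoch_length) / shift + 1e-9)) + 1L
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%gs / %gs shift)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$epoch_length, x$shift))
  print(table(x$info$condition))
  if ("artifact" %in% names(x$info)) {
    cat(sprintf("  %d epochs flagged as artifact\n", sum(x$info$artifact)))
  }
  invisible(x)
}

#' Flag artifact epochs by three criteria
#'
#' An epoch is flagged if ANY channel violates ANY criterion:
#' \describe{
#'   \item{threshold}{any sample exceeds `amp_limit` microvolts in magnitude;}
#'   \item{trend}{the least-squares linear slope over the epoch exceeds
#'     `slope_limit` microvolts/second in magnitude;}
#'   \item{step}{any sample-to-sample difference exceeds `step_limit`
#'     microvolts in magnitude.}
#' }
#' Flags and the criteria that fired are recorded in the epoch `info` tibble;
#' the operation is idempotent and per-epoch independent.
#'
#' @param es An `eeg_epochs` object.
#' @param amp_limit Amplitude limit, microvolts (default 100).
#' @param slope_limit Trend limit, microvolts/second (default 3).
#' @param step_limit Sample-to-sample limit, microvolts (default 25).
#' @return `es` with `info` columns `amp_exceeded`, `slope_exceeded`,
#'   `step_exceeded`, `artifact` and `criterion` added/updated.
#' @export
mark_artifacts <- function(es, amp_limit = 100, slope_limit = 3,
                           step_limit = 25) {
  stopifnot(inherits(es, "eeg_epochs"))
  if (amp_limit <= 0 || slope_limit <= 0 || step_limit <= 0) {
    stop("Artifact limits must be positive.", call. = FALSE)
  }
  d <- dim(es$data)
  if (d[1] == 0) stop("Empty epoch set.", call. = FALSE)
  # samples x (epoch, channel) matrix
  m <- matrix(aperm(es$data, c(3, 1, 2)), nrow = d[3])
  amp <- colSums(abs(m) > amp_limit) > 0
  step <- colSums(abs(m[-1, , drop = FALSE] - m[-d[3], , drop = FALSE]) >
                    step_limit) > 0
  tc <- ((seq_len(d[3]) - 1) / es$fs)
  tc <- tc - mean(tc)
  slope <- abs(as.vector(crossprod(tc, m)) / sum(tc^2)) > slope_limit
  per_epoch <- function(v) rowSums(matrix(v, nrow = d[1])) > 0
  info <- es$info
  info$amp_exceeded <- per_epoch(amp)
  info$slope_exceeded <- per_epoch(slope)
  info$step_exceeded <- per_epoch(step)
  info$artifact <- info$amp_exceeded | info$slope_exceeded | info$step_exceeded
  info$criterion <- vapply(seq_len(d[1]), function(e) {
    fired <- c("threshold", "trend", "step")[c(info$amp_exceeded[e],
                                               info$slope_exceeded[e],
                                               info$step_exceeded[e])]
    if (length(fired)) paste(fired, collapse = "+") else NA_character_
  }, character(1))
  es$info <- info
  es
}

#' Drop flagged artifact epochs
#'
#' @param es An `eeg_epochs` object that has been through [mark_artifacts()].
#' @return The epoch set restricted to artifact-free epochs.
#' @export
drop_artifacts <- function(es) {
  stopifnot(inherits(es, "eeg_epochs"))
  if (!"artifact" %in% names(es$info)) {
    stop("Run mark_artifacts() first.", call. = FALSE)
  }
  subset_epochs(es, which(!es$info$artifact))
}

subset_epochs <- function(es, idx) {
  es$data <- es$data[idx, , , drop = FALSE]
  es$info <- es$info[idx, , drop = FALSE]
  es$info$epoch <- seq_len(nrow(es$info))
  es
}
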