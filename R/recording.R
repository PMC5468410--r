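#' Continuous multi-channel EEG recording
#'
#' A light container for a continuous EEG recording: a channels x samples
#' matrix in microvolts, the sampling rate, ordered unique channel labels and
#' (optionally) condition annotations as a tibble with columns `onset`,
#' `duration` (seconds) and `condition`.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling frequency in Hz.
#' @param channels Character vector of unique channel labels, one per row.
#' @param annotations Optional tibble/data.frame with columns `onset`,
#'   `duration`, `condition`; intervals must lie inside the recording.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels, annotations = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix.", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number.", call. = FALSE)
  }
  if (length(channels) != nrow(data)) {
    stop("`channels` must have one label per data row.", call. = FALSE)
  }
  if (anyDuplicated(channels)) {
    stop("Channel labels must be unique.", call. = FALSE)
  }
  dur <- ncol(data) / fs
  if (!is.null(annotations)) {
    annotations <- tibble::as_tibble(annotations)
    need <- c("onset", "duration", "condition")
    if (!all(need %in% names(annotations))) {
      stop("Annotations need columns onset, duration, condition.", call. = FALSE)
    }
    if (any(annotations$onset < 0) ||
        any(annotations$onset + annotations$duration > dur + 1e-9)) {
      stop("Annotations fall outside the recording.", call. = FALSE)
    }
  }
  structure(
    list(data = data, fs = fs, channels = as.character(channels),
         annotations = annotations),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$annotations)) {
    cat(sprintf("  %d annotation blocks: %s\n", nrow(x$annotations),
                paste(unique(x$annotations$condition), collapse = ", ")))
  }
  invisible(x)
}

#' @export
as_tibble.eeg_recording <- function(x, ...) {
  out <- tibble::as_tibble(t(x$data), .name_repair = "minimal")
  names(out) <- x$channels
  out$time <- (seq_len(ncol(x$data)) - 1) / x$fs
  dplyr::relocate(out, "time")
}

rec_duration <- function(rec) ncol(rec$data) / rec$fs
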