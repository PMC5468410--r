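#' Assemble the IAF-anchored spectral feature matrix
#'
#' One row per artifact-free epoch; one column per (channel, frequency-bin)
#' pair, where channels are the frontal + parietal feature sets and bins span
#' the combined theta + alpha band `[IAF-6, IAF+2]` Hz inclusive -- 17 bins at
#' the 0.5 Hz resolution of a 2-s epoch (the IAF-2 edge bin shared by theta
#' and alpha is counted once). Features are identified by the channel and the
#' bin's offset from the IAF (e.g. `"Fz@IAF-2.5"`), so matrices from sessions
#' with the same resolution align across sessions by construction.
#'
#' @param es An `eeg_epochs` object. If artifact flags are present, flagged
#'   epochs are dropped; it is an error if none remain.
#' @param iaf An `iaf_profile` (see [estimate_iaf()]) or a numeric IAF in Hz.
#' @param channels Channels to use; defaults to the frontal + parietal sets.
#'   Missing channels are dropped with a warning.
#' @param log10_features If `TRUE`, log10-transform the band powers
#'   (off by default).
#' @return An `eeg_features` object: `x` (epochs x features power matrix),
#'   `features` (tibble: feature, channel, bin_hz, offset_hz), `condition`,
#'   `iaf`, `resolution`.
#' @export
build_feature_matrix <- function(es, iaf,
                                 channels = c(frontal_channels(),
                                              parietal_channels()),
                                 log10_features = FALSE) {
  stopifnot(inherits(es, "eeg_epochs"))
  if (inherits(iaf, "iaf_profile")) iaf <- iaf$iaf
  if ("artifact" %in% names(es$info) && any(es$info$artifact)) {
    es <- drop_artifacts(es)
  }
  if (dim(es$data)[1] == 0) {
    stop("No artifact-free epochs left to build features from.", call. = FALSE)
  }
  resolution <- 1 / es$epoch_length
  missing_ch <- setdiff(channels, es$channels)
  if (length(missing_ch)) {
    warning("Dropping channels absent from the recording: ",
            paste(missing_ch, collapse = ", "), call. = FALSE)
    channels <- setdiff(channels, missing_ch)
  }
  if (length(channels) == 0) stop("No feature channels available.", call. = FALSE)

  ps <- psd_epochs(es)
  bins <- seq(iaf - 6, iaf + 2, by = resolution)
  bin_idx <- vapply(bins, function(b) {
    i <- which(abs(ps$freq - b) < resolution / 4)
    if (length(i) != 1) NA_integer_ else i
  }, integer(1))
  if (anyNA(bin_idx)) {
    stop("Band bins do not lie on the spectral grid; check IAF and epoch length.",
         call. = FALSE)
  }
  ch_idx <- match(channels, es$channels)
  # channel-major ordering, fixed by the requested channel list (independent
  # of the order channels appear in the recording)
  feat <- tidyr::expand_grid(channel = channels, bin_hz = bins)
  x <- matrix(NA_real_, nrow = dim(es$data)[1], ncol = nrow(feat))
  for (i in seq_along(ch_idx)) {
    cols <- (i - 1) * length(bins) + seq_along(bins)
    x[, cols] <- ps$power[, ch_idx[i], bin_idx, drop = TRUE]
  }
  if (log10_features) x <- log10(pmax(x, .Machine$double.xmin))
  feat$offset_hz <- feat$bin_hz - iaf
  feat$feature <- sprintf("%s@IAF%+g", feat$channel, feat$offset_hz)
  colnames(x) <- feat$feature
  structure(
    list(x = x, features = feat[, c("feature", "channel", "bin_hz", "offset_hz")],
         condition = es$info$condition, iaf = iaf, resolution = resolution),
    class = "eeg_features"
  )
}

#' @export
print.eeg_features <- function(x, ...) {
  cat(sprintf("<eeg_features> %d epochs x %d features (%d channels x %d bins), IAF %g Hz\n",
              nrow(x$x), ncol(x$x), length(unique(x$features$channel)),
              length(unique(x$features$bin_hz)), x$iaf))
  print(table(x$condition))
  invisible(x)
}

#' @export
as_tibble.eeg_features <- function(x, ...) {
  out <- tibble::as_tibble(x$x)
  out$condition <- x$condition
  dplyr::relocate(out, "condition")
}

# check two feature objects describe the same (channel, IAF-offset) space
assert_aligned_features <- function(a, b) {
  ok <- identical(a$features$channel, b$features$channel) &&
    isTRUE(all.equal(a$features$offset_hz, b$features$offset_hz)) &&
    isTRUE(all.equal(a$resolution, b$resolution))
  if (!ok) {
    stop("Feature spaces are not aligned by (channel, IAF-offset); ",
         "sessions must share montage and spectral resolution.", call. = FALSE)
  }
  invisible(TRUE)
}
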