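# Small simulated-course configurations and hand-built objects shared by the
# tests. All fixtures are generated in code; nothing is read from disk.

tiny_config <- function(seed = 1L, n_sessions = 2, fs = 128,
                        block = 24, blocks = 2, ...) {
  sim_course_config(n_sessions = n_sessions, fs = fs,
                    condition_block_duration = block,
                    blocks_per_session = blocks, seed = seed, ...)
}

# a recording made from an explicit channels x samples matrix with one
# annotation block per condition
toy_recording <- function(data, fs, conditions = NULL,
                          channels = paste0("ch", seq_len(nrow(data)))) {
  ann <- NULL
  if (!is.null(conditions)) {
    dur <- ncol(data) / fs / length(conditions)
    ann <- tibble::tibble(onset = (seq_along(conditions) - 1) * dur,
                          duration = dur, condition = conditions)
  }
  eeg_recording(data, fs, channels, ann)
}

# sinusoid recording helper
sine_recording <- function(freq, fs = 256, dur = 8, amp = 1, n_ch = 1,
                           conditions = NULL) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * t)
  toy_recording(matrix(rep(x, each = n_ch), nrow = n_ch), fs, conditions)
}

# an eeg_epochs object built directly from a list of channels x samples
# epoch matrices (bypasses segment_epochs for artifact-criterion tests)
manual_epochs <- function(epochs, fs, epoch_length = NULL) {
  n_ch <- nrow(epochs[[1]])
  spl <- ncol(epochs[[1]])
  data <- array(NA_real_, dim = c(length(epochs), n_ch, spl))
  for (e in seq_along(epochs)) data[e, , ] <- epochs[[e]]
  structure(
    list(data = data, fs = fs, channels = paste0("ch", seq_len(n_ch)),
         epoch_length = epoch_length %||% (spl / fs), shift = 1,
         info = tibble::tibble(epoch = seq_along(epochs), onset = 0,
                               condition = "EASY")),
    class = "eeg_epochs")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent brute-force stepwise oracle: recompute every partial-F p-value
# from scratch with lm()/add1()/drop1() at every step and record the path
oracle_stepwise_path <- function(X, y, alpha_enter = 0.05, alpha_remove = 0.1,
                                 max_iter = NULL) {
  yv <- ifelse(y == sort(unique(as.character(y)))[2] | y == "HARD", 1, -1)
  if (is.null(max_iter)) max_iter <- min(ncol(X), floor(nrow(X) / 3))
  df <- data.frame(y = yv, X)
  vars <- colnames(X)
  included <- character(0)
  path <- list()
  iter <- 0
  repeat {
    if (iter >= max_iter) break
    if (nrow(df) - length(included) - 2 < 1) break
    cand <- setdiff(vars, included)
    if (!length(cand)) break
    fit <- stats::lm(stats::reformulate(c("1", included), "y"), data = df)
    a1 <- stats::add1(fit, scope = stats::reformulate(c(included, cand)),
                      test = "F")
    pv <- a1[["Pr(>F)"]][-1]
    best <- which.min(pv)                     # first = lowest column index
    if (!is.finite(pv[best]) || pv[best] >= alpha_enter) break
    included <- c(included, rownames(a1)[-1][best])
    iter <- iter + 1
    path[[length(path) + 1]] <- c("enter", rownames(a1)[-1][best])
    repeat {
      fit <- stats::lm(stats::reformulate(c("1", included), "y"), data = df)
      if (length(included) == 0) break
      d1 <- stats::drop1(fit, test = "F")
      pr <- d1[["Pr(>F)"]][-1]
      worst <- which.max(pr)
      if (!is.finite(pr[worst]) || pr[worst] <= alpha_remove) break
      path[[length(path) + 1]] <- c("remove", rownames(d1)[-1][worst])
      included <- setdiff(included, rownames(d1)[-1][worst])
    }
  }
  do.call(rbind, path)
}

# O(n^2) all-pairs concordance oracle for the AUC
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
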