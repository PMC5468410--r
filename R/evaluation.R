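#' Rank-based area under the ROC curve
#'
#' AUC computed as the normalized Mann-Whitney U statistic:
#' `(concordant pairs + 0.5 * ties) / (n_pos * n_neg)` -- the probability that
#' a randomly chosen positive epoch scores above a randomly chosen negative
#' one. Invariant under strictly increasing transforms of the scores.
#'
#' @param scores Real-valued discriminant score per epoch.
#' @param labels Binary labels; the positive class is `positive`, `"HARD"`
#'   when present, or the last factor level.
#' @param positive Optional positive-class label.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` differ in length.", call. = FALSE)
  }
  labels <- as.factor(labels)
  lev <- levels(droplevels(labels))
  if (length(lev) != 2) stop("Both classes must be present.", call. = FALSE)
  if (is.null(positive)) positive <- if ("HARD" %in% lev) "HARD" else lev[2]
  pos <- as.character(labels) == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)               # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired t statistic between two fold-paired AUC vectors
#'
#' Classical paired t with `n - 1` degrees of freedom; the sign is retained
#' (positive when `a` exceeds `b` on average). Zero-variance differences give
#' `t = 0` when the mean difference is zero and an error otherwise (the
#' statistic would be infinite).
#'
#' @param a,b Equal-length (>= 2) numeric vectors paired by fold.
#' @return The t statistic.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("Need equal-length paired vectors of length >= 2.", call. = FALSE)
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(0)
    stop("Zero variance with nonzero mean difference: t is infinite.",
         call. = FALSE)
  }
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}

# seeded, shuffled, stratified fold assignment
make_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

#' Within-session cross-validated AUC (Intra analysis)
#'
#' Seeded, shuffled, stratified 10-fold cross-validation inside one session:
#' for each fold, an asSWLDA is calibrated on the other nine folds and the
#' held-out fold's epochs are scored; the fold AUC is recorded.
#'
#' @param features An `eeg_features` object for the session.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed controlling the fold shuffle.
#' @param ... Passed to [asswlda()].
#' @return A tibble (`mode`, `fold`, `auc`) with one row per fold.
#' @export
intra_cv <- function(features, n_folds = 10, seed = 1L, ...) {
  stopifnot(inherits(features, "eeg_features"))
  check_class_counts(features$condition, n_folds)
  fold <- make_folds(features$condition, n_folds, seed)
  auc <- vapply(seq_len(n_folds), function(k) {
    tr <- fold != k
    fit <- asswlda(features$x[tr, , drop = FALSE], features$condition[tr], ...)
    s <- predict(fit, features$x[!tr, , drop = FALSE])
    auc_roc(s, features$condition[!tr])
  }, numeric(1))
  tibble::tibble(mode = "intra", fold = seq_len(n_folds), auc = auc)
}

#' Between-session cross-validated AUC (Inter analysis)
#'
#' For fold `k`, a classifier calibrated on session `n` minus its fold `k` is
#' tested on session `n+1`'s fold `k`, and vice versa; the fold AUC is the
#' mean of the two directions. Fold partitions are the same seeded partitions
#' used by [intra_cv()] (pass the same per-session seeds), so the 10 inter
#' AUCs are paired fold-by-fold with the intra AUCs for the paired t test.
#'
#' Feature spaces must align by (channel, IAF-offset); otherwise an error is
#' raised.
#'
#' @param features_a,features_b `eeg_features` of consecutive sessions.
#' @param n_folds Number of folds (default 10).
#' @param seed_a,seed_b Fold-shuffle seeds of the two sessions.
#' @param ... Passed to [asswlda()].
#' @return A tibble (`mode`, `fold`, `auc`).
#' @export
inter_cv <- function(features_a, features_b, n_folds = 10,
                     seed_a = 1L, seed_b = 2L, ...) {
  stopifnot(inherits(features_a, "eeg_features"),
            inherits(features_b, "eeg_features"))
  assert_aligned_features(features_a, features_b)
  check_class_counts(features_a$condition, n_folds)
  check_class_counts(features_b$condition, n_folds)
  fold_a <- make_folds(features_a$condition, n_folds, seed_a)
  fold_b <- make_folds(features_b$condition, n_folds, seed_b)
  one_way <- function(ftr, fte, fold_tr, fold_te, k) {
    fit <- asswlda(ftr$x[fold_tr != k, , drop = FALSE],
                   ftr$condition[fold_tr != k], ...)
    s <- predict(fit, fte$x[fold_te == k, , drop = FALSE])
    auc_roc(s, fte$condition[fold_te == k])
  }
  auc <- vapply(seq_len(n_folds), function(k) {
    mean(c(one_way(features_a, features_b, fold_a, fold_b, k),
           one_way(features_b, features_a, fold_b, fold_a, k)))
  }, numeric(1))
  tibble::tibble(mode = "inter", fold = seq_len(n_folds), auc = auc)
}

#' Intra/Inter comparison statistics for a pair of consecutive sessions
#'
#' Computes the two paired t statistics comparing each session's intra-session
#' fold AUCs against the shared inter-session fold AUCs, and their average,
#' the raw Cognitive Stability Index of the session pair. Values near zero
#' mean the discriminative brain-feature pattern transferred unchanged across
#' the two sessions.
#'
#' @param intra_n,intra_n1 Fold tibbles from [intra_cv()] for sessions `n`
#'   and `n+1`.
#' @param inter Fold tibble from [inter_cv()] for the pair.
#' @return One-row tibble: `t_n`, `t_n1`, `csi_raw`, mean AUC summaries.
#' @export
session_pair_stats <- function(intra_n, intra_n1, inter) {
  t_n <- paired_t(intra_n$auc, inter$auc)
  t_n1 <- paired_t(intra_n1$auc, inter$auc)
  tibble::tibble(
    t_n = t_n, t_n1 = t_n1,
    csi_raw = cognitive_stability_index(t_n, t_n1),
    mean_auc_intra_n = mean(intra_n$auc),
    mean_auc_intra_n1 = mean(intra_n1$auc),
    mean_auc_inter = mean(inter$auc)
  )
}

check_class_counts <- function(labels, n_folds) {
  counts <- table(labels)
  if (length(counts) != 2) {
    stop("Both conditions must be present.", call. = FALSE)
  }
  if (any(counts < n_folds)) {
    stop(sprintf("Each condition needs at least %d epochs for %d-fold CV.",
                 n_folds, n_folds), call. = FALSE)
  }
  invisible(TRUE)
}
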