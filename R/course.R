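#' Run the full training-assessment pipeline on a simulated course
#'
#' End-to-end orchestration: simulate the eyes-closed rest and every session,
#' band-pass filter, epoch, reject artifacts, build IAF-anchored feature
#' matrices, run the intra- and inter-session cross-validated asSWLDA
#' analyses, score the behavioral logs, and assemble the per-session-pair
#' Cognitive Stability Index and triangle-area training metric. The whole run
#' is a deterministic function of `config` and `seed`.
#'
#' @param config A [sim_course_config()].
#' @param epoch_length,shift Epoching parameters in seconds (defaults 2 and
#'   0.125).
#' @param n_folds Cross-validation folds (default 10).
#' @param alpha_enter,alpha_remove Stepwise thresholds (defaults 0.05, 0.1).
#' @param filter_band,filter_order Band-pass settings (defaults 1-30 Hz,
#'   order 5).
#' @param amp_limit,slope_limit,step_limit Artifact criteria (defaults 100
#'   microvolts, 3 microvolts/s, 25 microvolts).
#' @param iaf Optional `iaf_profile` to skip rest-based estimation.
#' @param performance_reference `"max"` (default) normalizes mean performance
#'   by the subject's best session; `"absolute"` normalizes by 100.
#' @param seed Master seed; defaults to the config seed.
#' @param verbose Emit progress messages.
#' @return A `training_course` object: `pairs` (one row per session pair with
#'   t statistics, raw/normalized cognitive stability, behavioral measures and
#'   triangle areas), `sessions`, `folds` (all fold-level AUCs), `iaf`,
#'   `config`. `tidy()` returns the pair tibble, `glance()` a one-row summary.
#' @examples
#' \donttest{
#' cfg <- sim_course_config(n_sessions = 3, fs = 128,
#'                          condition_block_duration = 24,
#'                          blocks_per_session = 2, seed = 7)
#' course <- run_course(cfg, shift = 0.5)
#' tidy(course)
#' }
#' @export
run_course <- function(config,
                       epoch_length = 2, shift = 0.125, n_folds = 10,
                       alpha_enter = 0.05, alpha_remove = 0.1,
                       filter_band = c(1, 30), filter_order = 5,
                       amp_limit = 100, slope_limit = 3, step_limit = 25,
                       iaf = NULL,
                       performance_reference = c("max", "absolute"),
                       seed = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sim_course_config"))
  performance_reference <- match.arg(performance_reference)
  seed <- as.integer(seed %||% config$seed)
  say <- function(...) if (verbose) message(sprintf(...))

  if (is.null(iaf)) {
    say("Estimating IAF from simulated rest ...")
    rest <- simulate_rest(config)
    rest <- bandpass_filter(rest, filter_band[1], filter_band[2], filter_order)
    iaf <- estimate_iaf(rest)
  }
  say("IAF = %g Hz", iaf$iaf)

  feats <- vector("list", config$n_sessions)
  sessions <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    say("Session %d: simulate + preprocess", s)
    rec <- simulate_session(config, s)
    rec <- bandpass_filter(rec, filter_band[1], filter_band[2], filter_order)
    es <- segment_epochs(rec, epoch_length, shift)
    es <- mark_artifacts(es, amp_limit, slope_limit, step_limit)
    n_art <- sum(es$info$artifact)
    es <- drop_artifacts(es)
    feats[[s]] <- build_feature_matrix(es, iaf)
    sessions[[s]] <- tibble::tibble(session = s,
                                    n_epochs = nrow(es$info),
                                    n_artifact = n_art)
  }

  say("Behavioral logs + scoring")
  beh <- simulate_behavior(config)
  perf <- dplyr::bind_rows(lapply(beh$logs, score_session_behavior))
  sessions <- dplyr::bind_cols(dplyr::bind_rows(sessions), perf)

  cv_seed <- function(s) session_seed(seed, 20000L + s)
  intra <- lapply(seq_len(config$n_sessions), function(s) {
    say("Intra analysis, session %d", s)
    dplyr::mutate(
      intra_cv(feats[[s]], n_folds, cv_seed(s),
               alpha_enter = alpha_enter, alpha_remove = alpha_remove),
      session = s, .before = 1)
  })
  pairs <- lapply(seq_len(config$n_sessions - 1), function(n) {
    say("Inter analysis, sessions %d-%d", n, n + 1)
    inter <- inter_cv(feats[[n]], feats[[n + 1]], n_folds,
                      seed_a = cv_seed(n), seed_b = cv_seed(n + 1),
                      alpha_enter = alpha_enter, alpha_remove = alpha_remove)
    stats <- session_pair_stats(intra[[n]], intra[[n + 1]], inter)
    dplyr::bind_cols(
      tibble::tibble(pair = n, session_n = n, session_n1 = n + 1),
      stats,
      tibble::tibble(inter_folds = list(inter))
    )
  })
  pairs <- dplyr::bind_rows(pairs)

  p <- sessions$performance
  ref <- if (performance_reference == "max") max(p) else 100
  pairs$p_n <- p[pairs$session_n]
  pairs$p_n1 <- p[pairs$session_n1]
  pairs$mean_performance <-
    mean_performance(pairs$p_n, pairs$p_n1, reference = ref)
  pairs$performance_stability <-
    performance_stability(pairs$p_n, pairs$p_n1)
  pairs$cognitive_stability <- normalize_cognitive_stability(pairs$csi_raw)
  tri <- triangle_area(pairs$mean_performance, pairs$performance_stability,
                       pairs$cognitive_stability)
  pairs$area <- tri$area
  pairs$area_normalized <- tri$area_normalized

  folds <- dplyr::bind_rows(
    dplyr::bind_rows(intra),
    dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
      dplyr::mutate(pairs$inter_folds[[i]], session = pairs$session_n[i],
                    .before = 1)
    }))
  )
  pairs$inter_folds <- NULL

  structure(
    list(pairs = pairs, sessions = sessions, folds = folds, iaf = iaf,
         config = config, seed = seed,
         performance_reference = performance_reference),
    class = "training_course"
  )
}

#' @export
print.training_course <- function(x, ...) {
  cat(sprintf("<training_course> %d sessions, %d session pairs (seed %d)\n",
              nrow(x$sessions), nrow(x$pairs), x$seed))
  print(x$pairs[, c("pair", "csi_raw", "mean_performance",
                    "performance_stability", "cognitive_stability",
                    "area_normalized")])
  invisible(x)
}

#' @export
tidy.training_course <- function(x, ...) x$pairs

#' @export
glance.training_course <- function(x, ...) {
  tibble::tibble(
    n_sessions = nrow(x$sessions),
    n_pairs = nrow(x$pairs),
    iaf = x$iaf$iaf,
    final_performance = x$sessions$performance[nrow(x$sessions)],
    final_area_normalized = x$pairs$area_normalized[nrow(x$pairs)],
    mean_intra_auc = mean(x$folds$auc[x$folds$mode == "intra"]),
    mean_inter_auc = mean(x$folds$auc[x$folds$mode == "inter"])
  )
}
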