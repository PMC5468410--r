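#' Performance indexes of the four MATB subtasks
#'
#' Each index is a percentage in `[0, 100]`:
#' \describe{
#'   \item{TRCK}{`100 * (1 - mean(distance) / max_distance)` -- complement of
#'     the mean cursor distance relative to its fixed maximum.}
#'   \item{COMM / SYSM}{`100 * (w1 * accuracy + w2 * mean(1 - rt / rt_max))` --
#'     equally weighted (by default) accuracy and timeliness.}
#'   \item{RMAN}{`100 * mean(pmax(0, 1 - |level - target| / target))` --
#'     mean closeness of the main-tank fuel levels to the 2,500 lbs target.}
#' }
#'
#' @param log Tibble of raw events: `distance`/`max_distance` for TRCK;
#'   `correct`/`reaction_time`/`max_time` for COMM and SYSM; `level` (and
#'   optionally `tank`) for RMAN.
#' @param weights Length-2 accuracy/timeliness weights for COMM and SYSM
#'   (default `c(0.5, 0.5)`).
#' @param target RMAN fuel target in lbs (default 2500).
#' @return The index as a single percentage; `NA` with a warning for an empty
#'   COMM/SYSM event log (index undefined).
#' @name subtask-indexes
NULL

#' @rdname subtask-indexes
#' @export
trck_index <- function(log) {
  d_max <- unique(log$max_distance)
  if (length(d_max) != 1 || d_max <= 0) {
    stop("TRCK log needs a single positive `max_distance`.", call. = FALSE)
  }
  if (any(log$distance < 0 | log$distance > d_max)) {
    stop("Distances must lie in [0, max_distance].", call. = FALSE)
  }
  clip(100 * (1 - mean(log$distance) / d_max), 0, 100)
}

#' @rdname subtask-indexes
#' @export
comm_index <- function(log, weights = c(0.5, 0.5)) {
  event_index(log, weights, "COMM")
}

#' @rdname subtask-indexes
#' @export
sysm_index <- function(log, weights = c(0.5, 0.5)) {
  event_index(log, weights, "SYSM")
}

event_index <- function(log, weights, what) {
  if (nrow(log) == 0) {
    warning(sprintf("%s log has no events; index undefined.", what),
            call. = FALSE)
    return(NA_real_)
  }
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("Accuracy/timeliness weights must be non-negative and sum to 1.",
         call. = FALSE)
  }
  rt_max <- unique(log$max_time)
  if (length(rt_max) != 1 || rt_max <= 0) {
    stop("Event log needs a single positive `max_time`.", call. = FALSE)
  }
  if (any(log$reaction_time < 0)) {
    stop("Reaction times must be non-negative.", call. = FALSE)
  }
  acc <- mean(log$correct)
  timeliness <- mean(1 - pmin(log$reaction_time, rt_max) / rt_max)
  clip(100 * (weights[1] * acc + weights[2] * timeliness), 0, 100)
}

#' @rdname subtask-indexes
#' @export
rman_index <- function(log, target = 2500) {
  if (nrow(log) == 0 || target <= 0) {
    stop("RMAN log must be non-empty with a positive target.", call. = FALSE)
  }
  closeness <- pmax(0, 1 - abs(log$level - target) / target)
  clip(100 * mean(closeness), 0, 100)
}

#' Global performance index
#'
#' Unweighted mean of the defined subtask indexes; undefined (`NA`) indexes
#' are excluded with a warning.
#'
#' @param indexes Numeric vector of subtask percentages (may contain `NA`).
#' @return Global performance percentage.
#' @export
global_performance <- function(indexes) {
  if (all(is.na(indexes))) stop("No defined subtask indexes.", call. = FALSE)
  if (anyNA(indexes)) {
    warning("Undefined subtask indexes excluded from the global mean.",
            call. = FALSE)
  }
  mean(indexes, na.rm = TRUE)
}

#' Score one session's behavioral logs
#'
#' @param logs List with elements `trck`, `comm`, `sysm`, `rman` as produced
#'   by [simulate_behavior()] (or read from task logger CSVs).
#' @param weights COMM/SYSM accuracy/timeliness weights.
#' @param target RMAN fuel target, lbs.
#' @return One-row tibble of the four indexes and the global `performance`.
#' @export
score_session_behavior <- function(logs, weights = c(0.5, 0.5),
                                   target = 2500) {
  idx <- c(trck = trck_index(logs$trck),
           comm = comm_index(logs$comm, weights),
           sysm = sysm_index(logs$sysm, weights),
           rman = rman_index(logs$rman, target))
  tibble::tibble(trck = idx[["trck"]], comm = idx[["comm"]],
                 sysm = idx[["sysm"]], rman = idx[["rman"]],
                 performance = global_performance(idx))
}

#' Behavioral measures of a pair of consecutive sessions
#'
#' `mean_performance()` maps the average of the two sessions' global
#' performance to `[0, 1]`; `reference` is the normalizing maximum -- by
#' default the subject's best observed session performance, or pass 100 for
#' absolute normalization. `performance_stability()` maps the absolute
#' performance difference so that 1 means identical performance.
#'
#' @param p_n,p_n1 Global performance (0-100) of sessions `n` and `n+1`.
#' @param reference Normalizing maximum for the mean performance.
#' @return Value(s) in `[0, 1]`.
#' @name behavioral-measures
NULL

#' @rdname behavioral-measures
#' @export
mean_performance <- function(p_n, p_n1, reference = max(c(p_n, p_n1))) {
  check_percent(c(p_n, p_n1))
  if (any(reference <= 0)) stop("`reference` must be positive.", call. = FALSE)
  pmin(((p_n + p_n1) / 2) / reference, 1)
}

#' @rdname behavioral-measures
#' @export
performance_stability <- function(p_n, p_n1) {
  check_percent(c(p_n, p_n1))
  1 - abs(p_n - p_n1) / 100
}

check_percent <- function(p) {
  if (any(p < 0 | p > 100)) {
    stop("Performance values must lie in [0, 100].", call. = FALSE)
  }
  invisible(TRUE)
}

#' Cognitive Stability Index of a session pair
#'
#' Raw index: the average of the two paired t statistics comparing each
#' session's intra-session fold AUCs with the shared inter-session AUCs.
#' Values near zero indicate stable brain-feature patterns across the pair.
#'
#' @param t_n,t_n1 Paired t values (see [session_pair_stats()]).
#' @return Raw Cognitive Stability Index (vectorized).
#' @export
cognitive_stability_index <- function(t_n, t_n1) {
  if (any(!is.finite(t_n)) || any(!is.finite(t_n1))) {
    stop("t values must be finite.", call. = FALSE)
  }
  (t_n + t_n1) / 2
}

#' Normalize raw Cognitive Stability Indexes to [0, 1]
#'
#' Maps a subject's raw indexes so that 1 is fully stable: distance from zero
#' is measured as `|raw|`, normalized by the subject's maximum `|raw|` across
#' session pairs (or an explicit `reference`), and inverted:
#' `C = 1 - min(|raw|, ref) / ref`. If every raw value is zero the subject
#' was stable from the start and all values map to 1, with a warning.
#'
#' @param raw Numeric vector of raw indexes across a subject's session pairs.
#' @param reference Normalizing maximum; defaults to `max(abs(raw))`.
#' @return Values in `[0, 1]`.
#' @export
normalize_cognitive_stability <- function(raw, reference = NULL) {
  if (any(!is.finite(raw))) stop("Raw indexes must be finite.", call. = FALSE)
  reference <- reference %||% max(abs(raw))
  if (reference == 0) {
    warning("All raw Cognitive Stability Indexes are zero; treating the ",
            "subject as fully stable throughout.", call. = FALSE)
    return(rep(1, length(raw)))
  }
  1 - pmin(abs(raw), reference) / reference
}

#' Triangle-area training-level metric
#'
#' The three normalized measures -- mean performance `a`, performance
#' stability `b`, cognitive stability `c` -- are laid out as distances from a
#' common centroid, 120 degrees apart; the training level is the summed area
#' of the three sub-triangles,
#' `area = 1/2 sin(120) (ab + ac + cb)`,
#' normalized by its maximum `(3/2) sin(120) = 1.299` attained when all three
#' measures equal 1. `sin(120)` is evaluated exactly as `sqrt(3)/2`.
#'
#' @param a,b,c Measures in `[0, 1]` (vectorized).
#' @return Tibble with `area` (in `[0, 1.299]`) and `area_normalized`
#'   (in `[0, 1]`).
#' @examples
#' triangle_area(1, 1, 1)       # maximum: area 1.299, normalized 1
#' triangle_area(0.91, 0.98, 1)
#' @export
triangle_area <- function(a, b, c) {
  vals <- c(a, b, c)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("Measures must lie in [0, 1].", call. = FALSE)
  }
  s120 <- sqrt(3) / 2
  area <- 0.5 * s120 * (a * b + a * c + c * b)
  tibble::tibble(area = area, area_normalized = area / (1.5 * s120))
}
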