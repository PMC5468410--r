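#' Stepwise feature-selection path for linear discriminant calibration
#'
#' Classical stepwise regression of the class labels (coded -1/+1) on the
#' feature columns: at each iteration the candidate with the smallest
#' partial-F p-value enters if it is below `alpha_enter`; after each entry,
#' included features whose partial-F p-value exceeds `alpha_remove` are
#' removed (backward elimination), least significant first. After every
#' completed iteration (entry plus any removals) the p-value of the overall
#' model F statistic (`pModel`) is recorded in log10 space, which is the curve
#' the automatic stop of [auto_stop()] operates on.
#'
#' Candidates collinear with the current model are skipped, never entered.
#' Ties in p-value are broken toward the lowest column index, so the path is
#' deterministic.
#'
#' @param x An `eeg_features` object or a numeric matrix (rows = epochs).
#' @param y Binary condition labels (taken from `x` if it is an
#'   `eeg_features` object). The positive class is `"HARD"` when present,
#'   otherwise the last factor level.
#' @param alpha_enter Entry threshold on the partial-F p-value (default 0.05).
#' @param alpha_remove Removal threshold (default 0.1).
#' @param max_iter Maximum number of entry iterations; defaults to
#'   `min(n_features, floor(n_samples / 3))` as a saturation guard -- the
#'   automatic stop, not this cap, is the intended terminator.
#' @return An `asswlda_trace`: `steps` (tibble: iteration, action, feature,
#'   p_value), `iterations` (tibble: iteration, n_features, log10_p_model),
#'   and the per-iteration selected sets.
#' @export
fit_stepwise <- function(x, y = NULL, alpha_enter = 0.05, alpha_remove = 0.1,
                         max_iter = NULL) {
  prep <- prepare_xy(x, y)
  stepwise_path(prep$X, prep$yv, alpha_enter, alpha_remove, max_iter,
                positive_class = prep$positive)
}

stepwise_path <- function(X, yv, alpha_enter, alpha_remove, max_iter,
                          positive_class = NA_character_) {
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(max_iter)) max_iter <- min(p, floor(n / 3))
  Q <- matrix(1 / sqrt(n), n, 1)
  ry <- as.vector(yv - Q %*% crossprod(Q, yv))
  rss <- sum(ry^2)
  tss <- rss
  RX <- X - Q %*% crossprod(Q, X)
  cnorm0 <- pmax(colSums(X^2), .Machine$double.xmin)
  included <- integer(0)
  steps <- list()
  log10_pmodel <- numeric(0)
  sets <- list()
  iter <- 0L

  rebuild <- function() {
    Z <- cbind(1, X[, included, drop = FALSE])
    Q <<- qr.Q(qr(Z))
    ry <<- as.vector(yv - Q %*% crossprod(Q, yv))
    rss <<- sum(ry^2)
    RX <<- X - Q %*% crossprod(Q, X)
  }

  repeat {
    q <- length(included)
    if (iter >= max_iter) break
    df2 <- n - q - 2
    if (df2 < 1) break
    cand <- setdiff(seq_len(p), included)
    if (length(cand) == 0) break
    Rc <- RX[, cand, drop = FALSE]
    d <- colSums(Rc^2)
    valid <- d > 1e-10 * cnorm0[cand]
    if (!any(valid)) break
    num <- as.vector(crossprod(Rc, ry))
    ssr <- rep(0, length(cand))
    ssr[valid] <- num[valid]^2 / d[valid]
    rss_new <- pmax(rss - ssr, 0)
    Fv <- ssr / pmax(rss_new / df2, .Machine$double.xmin)
    pv <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
    pv[!valid] <- Inf
    pv[is.na(pv)] <- Inf
    j_rel <- which.min(pv)
    if (length(j_rel) == 0 || !is.finite(pv[j_rel]) ||
        pv[j_rel] >= alpha_enter) break
    j <- cand[j_rel]
    qnew <- RX[, j] / sqrt(sum(RX[, j]^2))
    Q <- cbind(Q, qnew)
    ry <- ry - qnew * sum(qnew * ry)
    rss <- sum(ry^2)
    RX <- RX - tcrossprod(qnew, as.vector(crossprod(RX, qnew)))
    included <- c(included, j)
    iter <- iter + 1L
    steps[[length(steps) + 1L]] <-
      list(iteration = iter, action = "enter", feature = j,
           p_value = pv[j_rel])

    # backward elimination, least significant first
    repeat {
      q <- length(included)
      dfr <- n - q - 1
      if (q == 0 || dfr < 1) break
      pr <- partial_p_included(X, yv, included, dfr)
      w_rel <- which.max(pr)
      if (pr[w_rel] <= alpha_remove) break
      rem <- included[w_rel]
      included <- setdiff(included, rem)
      steps[[length(steps) + 1L]] <-
        list(iteration = iter, action = "remove", feature = rem,
             p_value = pr[w_rel])
      rebuild()
    }

    q <- length(included)
    log10_pmodel[iter] <- if (q >= 1) {
      Fm <- ((tss - rss) / q) / max(rss / (n - q - 1), .Machine$double.xmin)
      # computed in log space; clamped at the double floor so a numerically
      # perfect fit cannot poison the stopping curve with -Inf
      max(stats::pf(Fm, q, n - q - 1, lower.tail = FALSE, log.p = TRUE) /
            log(10), -320)
    } else 0
    sets[[iter]] <- included
  }

  steps <- if (length(steps)) {
    dplyr::bind_rows(lapply(steps, tibble::as_tibble))
  } else {
    tibble::tibble(iteration = integer(), action = character(),
                   feature = integer(), p_value = numeric())
  }
  feature_names <- colnames(X) %||% paste0("x", seq_len(p))
  steps$feature <- feature_names[steps$feature]
  structure(
    list(steps = steps,
         iterations = tibble::tibble(
           iteration = seq_len(iter),
           n_features = vapply(sets, length, integer(1)),
           log10_p_model = log10_pmodel),
         sets = sets, feature_names = feature_names,
         alpha_enter = alpha_enter, alpha_remove = alpha_remove,
         positive_class = positive_class),
    class = "asswlda_trace"
  )
}

# partial-F p-value of every included feature in the current model
partial_p_included <- function(X, yv, included, dfr) {
  Z <- cbind(1, X[, included, drop = FALSE])
  qz <- qr(Z)
  cf <- qr.coef(qz, yv)
  res <- yv - Z %*% cf
  sigma2 <- sum(res^2) / dfr
  covd <- diag(chol2inv(qr.R(qz))) * sigma2
  tval <- cf / sqrt(pmax(covd, .Machine$double.xmin))
  stats::pf(tval[-1]^2, 1, dfr, lower.tail = FALSE)
}

#' @export
print.asswlda_trace <- function(x, ...) {
  cat(sprintf("<asswlda_trace> %d iterations, %d actions, %d features in final set\n",
              nrow(x$iterations), nrow(x$steps),
              if (length(x$sets)) length(x$sets[[length(x$sets)]]) else 0L))
  invisible(x)
}

#' Automatic stopping iteration of a stepwise trace
#'
#' The realized `(iteration, log10 pModel)` points are min-max normalized to
#' the unit square so the two axes are commensurable, and the stopping
#' iteration is the point closest (Euclidean) to the origin -- the elbow where
#' adding features stops improving the model's overall significance.
#' `method = "elbow"` instead returns the first iteration after which the
#' successive difference of the normalized log10 pModel falls below `tol`
#' (the convergence-to-zero reading of the same criterion); raw differences
#' are used, unsmoothed.
#'
#' @param trace An `asswlda_trace`, or directly the numeric vector of
#'   log10 pModel values per iteration.
#' @param method `"distance"` (default) or `"elbow"`.
#' @param tol Tolerance for the elbow method on normalized differences.
#' @return The stopping iteration (0 for an empty trace, 1 for length-1).
#' @export
auto_stop <- function(trace, method = c("distance", "elbow"), tol = 1e-3) {
  method <- match.arg(method)
  L <- if (is.numeric(trace)) trace else trace$iterations$log10_p_model
  J <- length(L)
  if (J == 0) return(0L)
  if (J == 1) return(1L)
  jn <- (seq_len(J) - 1) / (J - 1)
  rng <- range(L)
  Ln <- if (diff(rng) == 0) rep(0, J) else (L - rng[1]) / diff(rng)
  if (method == "distance") {
    return(which.min(jn^2 + Ln^2))
  }
  dd <- abs(diff(Ln))
  hit <- which(dd < tol)
  if (length(hit)) hit[1] else J
}

#' Fit an automatic-stop stepwise linear discriminant (asSWLDA)
#'
#' Composes the stepwise selection path ([fit_stepwise()]), the automatic
#' stop ([auto_stop()]) truncating the path at the elbow of the model
#' p-value curve, and a least-squares refit of the linear discriminant
#' function on the retained features. The fit is fully deterministic.
#'
#' @inheritParams fit_stepwise
#' @param stop_method,elbow_tol Passed to [auto_stop()].
#' @return An object of class `asswlda` with elements `features` (selected
#'   feature names, in entry order), `weights`, `intercept`,
#'   `stop_iteration`, `trace`, `alpha_enter`, `alpha_remove`,
#'   `positive_class`. [predict()] returns the discriminant score
#'   `w . x + b`, higher = more like the positive ("HARD") class.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
#' y <- rep(c("EASY", "HARD"), each = 25)
#' x[y == "HARD", 2] <- x[y == "HARD", 2] + 3
#' fit <- asswlda(x, y)
#' fit$features
#' @export
asswlda <- function(x, y = NULL, alpha_enter = 0.05, alpha_remove = 0.1,
                    max_iter = NULL, stop_method = c("distance", "elbow"),
                    elbow_tol = 1e-3) {
  prep <- prepare_xy(x, y)
  trace <- stepwise_path(prep$X, prep$yv, alpha_enter, alpha_remove, max_iter,
                         positive_class = prep$positive)
  stop_it <- auto_stop(trace, method = stop_method, tol = elbow_tol)
  sel <- if (stop_it >= 1) trace$sets[[stop_it]] else integer(0)
  if (length(sel)) {
    Z <- cbind(1, prep$X[, sel, drop = FALSE])
    cf <- qr.coef(qr(Z), prep$yv)
    intercept <- cf[1]
    weights <- cf[-1]
    names(weights) <- trace$feature_names[sel]
  } else {
    intercept <- mean(prep$yv)
    weights <- numeric(0)
  }
  structure(
    list(features = trace$feature_names[sel], weights = weights,
         intercept = unname(intercept), stop_iteration = stop_it,
         trace = trace, alpha_enter = alpha_enter,
         alpha_remove = alpha_remove, positive_class = prep$positive),
    class = "asswlda"
  )
}

#' @export
print.asswlda <- function(x, ...) {
  cat(sprintf("<asswlda> %d features (stopped at iteration %d of %d); positive class: %s\n",
              length(x$features), x$stop_iteration, nrow(x$trace$iterations),
              x$positive_class))
  if (length(x$features)) {
    cat("  ", paste(utils::head(x$features, 8), collapse = ", "),
        if (length(x$features) > 8) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Discriminant scores for new epochs
#'
#' @param object An `asswlda` model.
#' @param newdata An `eeg_features` object or a numeric matrix whose column
#'   names include every selected feature. Unknown selected features raise an
#'   error (no silent reindexing).
#' @param ... Unused.
#' @return Numeric vector of scores, higher = more like the positive class.
#' @export
predict.asswlda <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "eeg_features")) newdata$x else as.matrix(newdata)
  if (length(object$features) == 0) {
    return(rep(object$intercept, nrow(X)))
  }
  idx <- match(object$features, colnames(X))
  if (anyNA(idx)) {
    stop("New data lacks selected features: ",
         paste(object$features[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  as.vector(X[, idx, drop = FALSE] %*% object$weights + object$intercept)
}

#' @rdname asswlda-tidiers
#' @export
tidy.asswlda <- function(x, ...) {
  entered <- x$trace$steps[x$trace$steps$action == "enter", ]
  tibble::tibble(
    term = x$features,
    estimate = unname(x$weights),
    entry_iteration = entered$iteration[match(x$features, entered$feature)],
    entry_p_value = entered$p_value[match(x$features, entered$feature)]
  )
}

#' Tidiers for asSWLDA models
#'
#' `tidy()` returns one row per selected feature with its discriminant weight
#' and entry statistics; `glance()` returns a one-row model summary.
#'
#' @param x An `asswlda` model.
#' @param ... Unused.
#' @name asswlda-tidiers
#' @export
glance.asswlda <- function(x, ...) {
  it <- x$trace$iterations
  tibble::tibble(
    n_features = length(x$features),
    stop_iteration = x$stop_iteration,
    iterations_run = nrow(it),
    log10_p_model = if (x$stop_iteration >= 1) {
      it$log10_p_model[x$stop_iteration]
    } else NA_real_,
    alpha_enter = x$alpha_enter,
    alpha_remove = x$alpha_remove
  )
}

prepare_xy <- function(x, y) {
  if (inherits(x, "eeg_features")) {
    if (is.null(y)) y <- x$condition
    X <- x$x
  } else {
    X <- as.matrix(x)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (is.null(y)) stop("Class labels `y` are required.", call. = FALSE)
  if (nrow(X) != length(y)) stop("`x` rows and `y` length differ.", call. = FALSE)
  if (nrow(X) <= 2) stop("Need more than 2 epochs.", call. = FALSE)
  y <- as.factor(y)
  lev <- levels(droplevels(y))
  if (length(lev) != 2) {
    stop("Exactly two classes must be present.", call. = FALSE)
  }
  positive <- if ("HARD" %in% lev) "HARD" else lev[2]
  list(X = X, yv = ifelse(as.character(y) == positive, 1, -1),
       positive = positive)
}
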