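# Stepwise selection path, automatic stop, and the fitted discriminant.

random_instance <- function(seed, n = NULL, p = NULL, informative = 1,
                            effect = 1.5) {
  set.seed(seed)
  n <- n %||% sample(20:60, 1)
  p <- p %||% sample(3:10, 1)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rep(c("EASY", "HARD"), length.out = n)
  for (j in seq_len(min(informative, p))) {
    X[y == "HARD", j] <- X[y == "HARD", j] + effect * runif(1, 0.5, 1.5)
  }
  list(X = X, y = y)
}

test_that("selection path matches the brute-force lm() stepwise oracle", {
  for (seed in 1:12) {
    inst <- random_instance(seed, informative = sample(0:3, 1))
    trace <- fit_stepwise(inst$X, inst$y)
    got <- as.matrix(trace$steps[, c("action", "feature")])
    dimnames(got) <- NULL
    want <- oracle_stepwise_path(inst$X, inst$y)
    if (is.null(want)) {
      expect_equal(nrow(trace$steps), 0, label = paste("seed", seed))
    } else {
      dimnames(want) <- NULL
      expect_equal(got, want, label = paste("seed", seed))
    }
  }
})

test_that("a feature identical to the labels enters first; alpha_enter = 0 selects nothing", {
  set.seed(7)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c("EASY", "HARD"), each = 20)
  X[, 3] <- ifelse(y == "HARD", 1, -1)
  trace <- fit_stepwise(X, y)
  expect_equal(trace$steps$feature[1], "f3")
  expect_equal(trace$steps$action[1], "enter")

  empty <- fit_stepwise(X, y, alpha_enter = 0)
  expect_equal(nrow(empty$iterations), 0)
  fit0 <- asswlda(X, y, alpha_enter = 0)
  expect_equal(length(fit0$features), 0)
  expect_equal(fit0$stop_iteration, 0L)
})

test_that("collinear candidates are skipped, never entered", {
  set.seed(11)
  X <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "dup")))
  y <- rep(c("EASY", "HARD"), each = 20)
  X[, 1] <- X[, 1] + ifelse(y == "HARD", 2, 0)
  X[, 3] <- 2 * X[, 1] + 1          # exactly collinear with column a
  trace <- fit_stepwise(X, y)
  sel <- trace$steps$feature[trace$steps$action == "enter"]
  expect_true("a" %in% sel)
  expect_false("dup" %in% sel)
})

test_that("model p-value trace stays finite in log space and trends downward", {
  # strongly separable data underflows p to 0 in linear space; the log-space
  # trace must remain finite and representable
  set.seed(13)
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("EASY", "HARD"), each = 50)
  X[, 2] <- X[, 2] + ifelse(y == "HARD", 12, 0)
  trace <- fit_stepwise(X, y)
  expect_true(all(is.finite(trace$iterations$log10_p_model)))
  expect_true(all(trace$iterations$log10_p_model < 0))
  if (nrow(trace$iterations) > 1) {
    expect_lte(tail(trace$iterations$log10_p_model, 1),
               trace$iterations$log10_p_model[1])
  }

  # a feature identical to the coded labels yields a finite, clamped trace
  Xp <- X
  Xp[, 3] <- ifelse(y == "HARD", 1, -1)
  trace_p <- fit_stepwise(Xp, y)
  expect_true(all(is.finite(trace_p$iterations$log10_p_model)))
  expect_equal(trace_p$steps$feature[1], "f3")
})

test_that("auto stop finds the elbow of the log10 pModel curve", {
  # strictly constant after iteration k, steeply decreasing before -> k
  curve <- c(-2, -10, -25, -25, -25, -25)
  expect_equal(auto_stop(curve), 3L)
  expect_equal(auto_stop(curve, method = "elbow"), 3L)
  # single iteration -> 1
  expect_equal(auto_stop(-5), 1L)
  expect_equal(auto_stop(numeric(0)), 0L)
  # monotone linear decrease: exhaustive normalized-distance scan as oracle
  lin <- seq(-1, -40, length.out = 17)
  jn <- (seq_along(lin) - 1) / (length(lin) - 1)
  Ln <- (lin - min(lin)) / diff(range(lin))
  expect_equal(auto_stop(lin), which.min(sqrt(jn^2 + Ln^2)))
  # flat curve stops immediately
  expect_equal(auto_stop(rep(-3, 6)), 1L)
})

test_that("auto stop keeps informative features and trims the noisy tail", {
  # wide feature pool: the forward path keeps entering chance features long
  # after the informative ones; the stop must retain the informative features
  # while cutting the path well short of the full trace
  res <- vapply(1:8, function(seed) {
    set.seed(seed + 500)
    n <- 210
    p <- 120
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- rep(c("EASY", "HARD"), length.out = n)
    for (j in 1:3) X[y == "HARD", j] <- X[y == "HARD", j] + 1.2
    fit <- asswlda(X, y)
    c(informative_kept = sum(fit$features %in% paste0("f", 1:3)),
      kept = length(fit$features),
      iters = nrow(fit$trace$iterations))
  }, numeric(3))
  # statistical property: most runs keep all informative features, and the
  # kept set stays within two chance features of the truth
  expect_gte(mean(res["informative_kept", ] == 3), 0.8)
  expect_true(all(res["kept", ] <= 5))
  expect_true(all(res["kept", ] <= res["iters", ]))
})

test_that("the fitted discriminant is deterministic and orientation-correct", {
  set.seed(42)
  inst <- list(
    X = matrix(rnorm(360), 60, 6, dimnames = list(NULL, paste0("f", 1:6))),
    y = rep(c("EASY", "HARD"), each = 30))
  inst$X[inst$y == "HARD", 4] <- inst$X[inst$y == "HARD", 4] + 8
  fit1 <- asswlda(inst$X, inst$y)
  fit2 <- asswlda(inst$X, inst$y)
  expect_identical(fit1[c("features", "weights", "intercept")],
                   fit2[c("features", "weights", "intercept")])
  s <- predict(fit1, inst$X)
  expect_gt(min(s[inst$y == "HARD"]), max(s[inst$y == "EASY"]))
  expect_equal(auc_roc(s, inst$y), 1)

  # adding a constant to a non-selected feature leaves scores unchanged
  other <- setdiff(colnames(inst$X), fit1$features)[1]
  X2 <- inst$X
  X2[, other] <- X2[, other] + 100
  expect_equal(predict(fit1, X2), s)

  # unseen selected feature errors (no silent reindexing)
  X3 <- inst$X[, setdiff(colnames(inst$X), fit1$features[1]), drop = FALSE]
  expect_error(predict(fit1, X3), "lacks selected features")
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(60), 20, 3)
  expect_error(asswlda(X, rep("EASY", 20)), "two classes")
  expect_error(asswlda(X[1:2, ], c("EASY", "HARD")), "more than 2")
})

test_that("tidy() and glance() summarize the fit", {
  inst <- random_instance(9, n = 50, p = 6, informative = 2, effect = 3)
  fit <- asswlda(inst$X, inst$y)
  td <- tidy(fit)
  expect_equal(td$term, fit$features)
  expect_equal(td$estimate, unname(fit$weights))
  expect_true(all(td$entry_p_value < fit$alpha_enter))
  gl <- glance(fit)
  expect_equal(gl$n_features, length(fit$features))
  expect_lte(gl$stop_iteration, gl$iterations_run)
})
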