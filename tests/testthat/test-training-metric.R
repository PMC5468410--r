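# MATB subtask indexes, session-pair measures, CSI and the triangle metric.

test_that("subtask indexes hit their closed-form endpoints", {
  # cursor glued to center
  expect_equal(trck_index(tibble::tibble(distance = rep(0, 50),
                                         max_distance = 80)), 100)
  # every COMM event missed at the timeout
  missed <- tibble::tibble(correct = rep(FALSE, 5),
                           reaction_time = rep(20, 5), max_time = 20)
  expect_equal(comm_index(missed), 0)
  # perfect instant answers
  perfect <- tibble::tibble(correct = rep(TRUE, 5),
                            reaction_time = rep(0, 5), max_time = 5)
  expect_equal(sysm_index(perfect), 100)
  # tanks held exactly on target
  expect_equal(rman_index(tibble::tibble(level = rep(2500, 100))), 100)
  # half accuracy, half timeliness
  mixed <- tibble::tibble(correct = c(TRUE, FALSE),
                          reaction_time = c(10, 10), max_time = 20)
  expect_equal(comm_index(mixed), 100 * (0.5 * 0.5 + 0.5 * 0.5))
  # asymmetric weights
  expect_equal(comm_index(mixed, weights = c(1, 0)), 50)
})

test_that("global performance averages the defined indexes", {
  expect_equal(global_performance(c(80, 90, 100, 70)), 85)
  expect_warning(g <- global_performance(c(80, NA, 100, 70)), "excluded")
  expect_equal(g, mean(c(80, 100, 70)))
  expect_warning(ci <- comm_index(tibble::tibble(correct = logical(),
                                                 reaction_time = numeric(),
                                                 max_time = numeric())),
                 "no events")
  expect_true(is.na(ci))
})

test_that("global performance equals the mean of defined indexes on random logs", {
  set.seed(55)
  for (i in 1:10) {
    p <- runif(1, 20, 99)
    logs <- withr::with_seed(i, neurotrain:::simulate_session_logs(p, 2))
    scored <- score_session_behavior(logs)
    expect_equal(scored$performance,
                 mean(c(scored$trck, scored$comm, scored$sysm, scored$rman)))
    expect_true(all(unlist(scored) >= 0 & unlist(scored) <= 100))
  }
})

test_that("mean performance and performance stability map to [0, 1]", {
  expect_equal(mean_performance(100, 100, reference = 100), 1)
  expect_equal(performance_stability(100, 100), 1)
  expect_equal(mean_performance(90, 92, reference = 100), 0.91)
  expect_equal(performance_stability(90, 92), 0.98)
  expect_equal(performance_stability(100, 0), 0)
  # default normalization: the subject's own best session
  expect_equal(mean_performance(90, 92), 0.91 / 0.92)
  expect_error(mean_performance(101, 90), "0, 100")
  expect_error(performance_stability(-1, 50), "0, 100")
})

test_that("CSI averages the two t values and normalizes against the subject max", {
  expect_equal(cognitive_stability_index(0, 0), 0)
  expect_equal(cognitive_stability_index(4, 2), 3)
  expect_error(cognitive_stability_index(Inf, 1), "finite")

  raw <- c(6, 3, 0.6, 0)
  cs <- normalize_cognitive_stability(raw)
  expect_equal(cs, 1 - c(6, 3, 0.6, 0) / 6)
  expect_equal(cs[1], 0)            # the maximum maps to 0
  expect_equal(cs[4], 1)            # raw zero maps to fully stable
  # sign is discarded before normalizing
  expect_equal(normalize_cognitive_stability(c(-4, 2)), c(0, 0.5))
  expect_warning(all_stable <- normalize_cognitive_stability(c(0, 0, 0)),
                 "fully stable")
  expect_equal(all_stable, c(1, 1, 1))
})

test_that("triangle area follows the sub-triangle formula and its bounds", {
  full <- triangle_area(1, 1, 1)
  expect_equal(full$area, 1.299, tolerance = 1e-4)
  expect_equal(full$area, 1.5 * sqrt(3) / 2)
  expect_equal(full$area_normalized, 1)
  expect_equal(triangle_area(0, 0, 0)$area, 0)
  expect_equal(triangle_area(1, 1, 0)$area, 0.5 * sqrt(3) / 2)

  # symmetric in its arguments, homogeneous of degree 2
  set.seed(8)
  for (i in 1:20) {
    v <- runif(3)
    perms <- list(v, v[c(2, 3, 1)], v[c(3, 1, 2)], v[c(2, 1, 3)])
    areas <- vapply(perms, function(q) triangle_area(q[1], q[2], q[3])$area,
                    numeric(1))
    expect_equal(max(areas) - min(areas), 0, tolerance = 1e-12)
    s <- runif(1)
    expect_equal(triangle_area(s * v[1], s * v[2], s * v[3])$area,
                 s^2 * areas[1], tolerance = 1e-12)
    expect_true(areas[1] >= 0 && areas[1] <= 1.299039)
  }
  expect_error(triangle_area(-0.1, 0.5, 0.5), "0, 1")
  expect_error(triangle_area(0.5, 1.2, 0.5), "0, 1")
})

test_that("session pair statistics assemble t values and the raw CSI", {
  set.seed(14)
  intra_a <- tibble::tibble(fold = 1:10, auc = runif(10, 0.9, 1))
  intra_b <- tibble::tibble(fold = 1:10, auc = runif(10, 0.85, 1))
  inter <- tibble::tibble(fold = 1:10, auc = runif(10, 0.7, 0.9))
  out <- session_pair_stats(intra_a, intra_b, inter)
  # independent check against R's own paired t test
  expect_equal(out$t_n,
               unname(t.test(intra_a$auc, inter$auc, paired = TRUE)$statistic))
  expect_equal(out$t_n, paired_t(intra_a$auc, inter$auc))
  expect_equal(out$t_n1, paired_t(intra_b$auc, inter$auc))
  expect_equal(out$csi_raw, (out$t_n + out$t_n1) / 2)
})
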