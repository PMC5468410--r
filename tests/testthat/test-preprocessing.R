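# Band-pass filtering, epoching geometry, and the three artifact criteria.

# squared (zero-phase) low-pass Butterworth magnitude response in closed
# form; the bilinear-transform frequency warping tan(pi f / fs) makes this
# exact for the digital filter as well
butter_mag2 <- function(f, fc, order, fs) {
  ratio <- tan(pi * f / fs) / tan(pi * fc / fs)
  1 / (1 + ratio^(2 * order))
}

test_that("band-pass removes DC and matches the analytic Butterworth response", {
  fs <- 256
  rec <- toy_recording(matrix(50, 1, fs * 8), fs)
  out <- bandpass_filter(rec)
  mid <- (fs * 2):(fs * 6)
  expect_lt(max(abs(out$data[1, mid])), 0.5)

  amp_after <- function(freq) {
    rec <- sine_recording(freq, fs = fs, dur = 16)
    out <- bandpass_filter(rec)
    seg <- out$data[1, (4 * fs):(12 * fs)]
    (max(seg) - min(seg)) / 2
  }
  # 10 Hz sits in the passband: amplitude preserved within 5%
  expect_equal(amp_after(10), 1, tolerance = 0.05)
  # 40 Hz vs 10 Hz attenuation follows the closed-form |H|^2 ratio
  expected_ratio <- butter_mag2(40, 30, 5, fs) / butter_mag2(10, 30, 5, fs)
  expect_equal(amp_after(40) / amp_after(10), expected_ratio, tolerance = 0.05)
})

test_that("filtering is linear and rejects invalid cutoffs", {
  fs <- 128
  set.seed(42)
  x <- matrix(rnorm(fs * 4), 1)
  y <- matrix(rnorm(fs * 4), 1)
  fx <- bandpass_filter(toy_recording(x, fs))$data
  fy <- bandpass_filter(toy_recording(y, fs))$data
  fxy <- bandpass_filter(toy_recording(2 * x - 3 * y, fs))$data
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-8)

  expect_error(bandpass_filter(toy_recording(x, 50)), "fs/2")
  expect_error(bandpass_filter(toy_recording(x, fs), low = 30, high = 1))
})

test_that("epoch counts follow floor((T - L)/S) + 1 within condition blocks", {
  fs <- 64
  rec <- toy_recording(matrix(0, 1, fs * 60), fs, conditions = "EASY")
  es <- segment_epochs(rec, 2, 0.125)
  expect_equal(nrow(es$info), 465)
  expect_equal(es$info$onset, (seq_len(465) - 1) * 0.125)

  # exactly one epoch from a block of exactly the epoch length
  rec1 <- toy_recording(matrix(0, 1, fs * 2), fs, conditions = "HARD")
  expect_equal(nrow(segment_epochs(rec1, 2, 0.125)$info), 1)

  # a too-short block yields zero epochs with a warning; all-short errors
  rec_mix <- eeg_recording(matrix(0, 1, fs * 4), fs, "ch1",
                           tibble::tibble(onset = c(0, 3), duration = c(3, 1),
                                          condition = c("EASY", "HARD")))
  expect_warning(es_mix <- segment_epochs(rec_mix, 2, 0.5), "shorter")
  expect_true(all(es_mix$info$condition == "EASY"))
  rec0 <- toy_recording(matrix(0, 1, fs), fs, conditions = "EASY")
  expect_error(suppressWarnings(segment_epochs(rec0, 2, 0.125)), "No epochs")
})

test_that("epoch-count formula holds on a randomized (T, L, S) grid", {
  fs <- 64
  set.seed(99)
  for (i in 1:25) {
    T <- round(runif(1, 2, 30), 2)
    L <- round(runif(1, 0.5, 2), 2)
    S <- sample(c(0.125, 0.25, 0.5, 0.75, 1), 1)
    rec <- toy_recording(matrix(0, 1, round(fs * T)), fs, conditions = "EASY")
    n_expected <- floor((ncol(rec$data) / fs - L) / S + 1e-9) + 1
    es <- segment_epochs(rec, L, S)
    expect_equal(nrow(es$info), n_expected,
                 label = sprintf("T=%g L=%g S=%g", T, L, S))
  }
})

test_that("epochs never straddle condition-block boundaries", {
  fs <- 64
  rec <- toy_recording(matrix(0, 1, fs * 10), fs,
                       conditions = c("EASY", "HARD"))
  es <- segment_epochs(rec, 2, 0.75)
  ends <- es$info$onset + 2
  easy <- es$info$condition == "EASY"
  expect_true(all(ends[easy] <= 5 + 1e-9))
  expect_true(all(es$info$onset[!easy] >= 5 - 1e-9))
})

test_that("each artifact criterion fires exactly when intended", {
  fs <- 256
  n <- 2 * fs
  zero <- matrix(0, 1, n)

  # smooth bump to 150 uV: amplitude criterion only (steps stay < 25 uV/sample,
  # symmetric so the fitted slope is ~0)
  bump <- zero
  bump[1, ] <- 150 * exp(-((seq_len(n) - n / 2) / (0.2 * fs))^2)
  # linear ramp at 4 uV/s (peak 4 uV): trend criterion only
  ramp <- zero
  ramp[1, ] <- 4 * (seq_len(n) - 1) / fs - 4
  # centered 30 uV pulse: step criterion only (slope ~0, amplitude < 100)
  pulse <- zero
  pulse[1, (n / 2):(n / 2 + 8)] <- 30

  es <- mark_artifacts(manual_epochs(list(zero, bump, ramp, pulse), fs))
  expect_equal(es$info$artifact, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(es$info$criterion,
               c(NA_character_, "threshold", "trend", "step"))
  expect_equal(es$info$amp_exceeded, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(es$info$slope_exceeded, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(es$info$step_exceeded, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("artifact marking is idempotent and flags any offending channel", {
  fs <- 128
  n <- fs * 2
  clean <- matrix(rnorm(2 * n), 2)
  bad <- clean
  bad[2, n / 2] <- 200   # second channel only
  es <- mark_artifacts(manual_epochs(list(clean, bad), fs))
  expect_equal(es$info$artifact, c(FALSE, TRUE))
  es2 <- mark_artifacts(es)
  expect_identical(es$info, es2$info)
  expect_equal(nrow(drop_artifacts(es)$info), 1)
})
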