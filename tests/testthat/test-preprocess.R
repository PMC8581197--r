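sinusoid_session <- function(freqs_by_channel, nsamp = 4096, fs = 256) {
  tt <- (0:(nsamp - 1)) / fs
  data <- t(vapply(freqs_by_channel, function(f) sin(2 * pi * f * tt),
                   numeric(nsamp)))
  make_session(data, data.frame(onset = 1L, condition = "rest", run = 1L),
               fs = fs)
}

test_that("band-pass filter passes 10 Hz and suppresses 1 and 60 Hz", {
  ses <- sinusoid_session(c(10, 1, 60, 10, 10, 10, 10, 10))
  out <- bandpass_filter(ses)
  mid <- 1000:3000   # away from filtfilt edge transients
  amp <- apply(out$data[, mid], 1, function(x) max(abs(x)))
  expect_equal(amp[1], 1, tolerance = 0.05)
  expect_lt(amp[2], 0.10)
  expect_lt(amp[3], 0.10)
  expect_error(bandpass_filter(ses, lp_hz = 128), "Nyquist",
               class = "bad_filter")
})

test_that("re-referencing commutes with band-pass filtering", {
  sc <- default_scenario()
  ses <- simulate_session(small_model(), sc, conditions = c("rest", "left"),
                          seed = 14)
  a <- average_reference(extract_trials(bandpass_filter(ses))$rest)
  # reference first (sessions have no average_reference method, emulate)
  ses2 <- ses
  ses2$data <- sweep(ses2$data, 2, colMeans(ses2$data))
  b <- average_reference(extract_trials(bandpass_filter(ses2))$rest)
  expect_equal(a$data, b$data, tolerance = 1e-8)
})

test_that("trial extraction groups 10 trials per condition and validates counts", {
  ses <- simulate_session(small_model(), default_scenario(), seed = 15)
  sets <- extract_trials(ses)
  expect_named(sets, c("rest", "left"))
  expect_identical(dim(sets$rest$data)[1], 10L)
  expect_identical(dim(sets$rest$data)[3], 1024L)  # 4 s at 256 Hz
  all3 <- extract_trials(ses, conditions = c("rest", "left", "right"))
  expect_length(all3, 3L)
  # drop one rest event -> labeled error naming the set
  ses$events <- ses$events[-which(ses$events$condition == "rest")[1], ]
  expect_error(extract_trials(ses), "rest", class = "missing_trials")
})

test_that("trial/channel variance matches closed forms", {
  nsamp <- 1024
  data <- array(0, dim = c(2, 3, nsamp))
  data[1, 1, ] <- 5                                    # constant
  data[1, 2, ] <- sin(2 * pi * 8 * (0:(nsamp - 1)) / 256)  # whole periods
  data[1, 3, ] <- rnorm(nsamp)
  data[2, , ] <- 2 * data[1, , ]
  ts <- make_trial_set(data, channels = c("C3", "Cz", "C4"))
  v <- trial_channel_variance(ts)
  expect_equal(unname(v[1, 1]), 0)
  expect_equal(unname(v[1, 2]), 0.5, tolerance = 1e-3)
  expect_equal(v[2, ], 4 * v[1, ], tolerance = 1e-12)
})

test_that("bad-channel rule flags only strictly more than max_trials outliers", {
  nsamp <- 1024
  tt <- (0:(nsamp - 1)) / 256
  amp_for <- function(v) sqrt(2 * v)     # full-period sinusoid variance v
  data <- array(0, dim = c(10, 3, nsamp))
  base <- amp_for(100) * sin(2 * pi * 10 * tt)
  for (tr in 1:10) for (ch in 1:3) data[tr, ch, ] <- base
  # channel 2: variance 5 (below window) in 4 of 10 trials -> flagged
  for (tr in 1:4) data[tr, 2, ] <- amp_for(5) * sin(2 * pi * 10 * tt)
  # channel 3: variance 300 in exactly 3 trials -> NOT flagged
  for (tr in 1:3) data[tr, 3, ] <- amp_for(300) * sin(2 * pi * 10 * tt)
  ts <- make_trial_set(data, channels = c("C3", "Cz", "C4"))
  expect_identical(detect_bad_channels(ts), "Cz")
})

test_that("spline repair reconstructs a smooth scalp field", {
  hm <- small_model()
  nsamp <- 1024
  tt <- (0:(nsamp - 1)) / 256
  # two smooth (low spatial order) topographies with distinct time courses:
  # the repaired series is right only if both field values are recovered
  co <- hm$channel_coords
  f1 <- co[, 2]; f2 <- co[, 3]^2 - 0.5 * co[, 1]
  waves <- rbind(sin(2 * pi * 10 * tt), sin(2 * pi * 7 * tt))
  data <- array(0, dim = c(10, 16, nsamp))
  for (tr in 1:10) data[tr, , ] <- cbind(f1, f2) %*% waves
  ts <- make_trial_set(data)
  truth <- ts$data[1, 4, ]
  ts$data[, 4, ] <- 1e3 * rnorm(10 * nsamp)   # corrupt channel 4 (FC2)
  repaired <- repair_or_reject(ts, bads = "FC2")
  expect_gt(cor(repaired$data[1, 4, ], truth), 0.9)
  expect_lt(max(abs(repaired$data[1, 4, ] - truth)), 0.2 * max(abs(truth)))
  expect_identical(repaired$log$repaired, "FC2")
})

test_that("repair_or_reject returns a rejection value past the channel budget", {
  ts <- make_trial_set(array(rnorm(10 * 16 * 256), dim = c(10, 16, 256)))
  out <- repair_or_reject(ts, bads = default_montage()[1:5])
  expect_true(is_rejected(out))
  expect_identical(repair_or_reject(ts, character(0)), ts)
  expect_true(is_rejected(repair_or_reject(ts, bads = default_montage(),
                                           max_bads = 4)))
  expect_error(repair_or_reject(ts, "nope"), "unknown channel")
})

test_that("pruning keeps 7 of 10 trials (28 s) and breaks ties by index", {
  nsamp <- 1024
  data <- array(rnorm(10 * 4 * nsamp), dim = c(10, 4, nsamp))
  for (tr in 8:10) data[tr, , ] <- 5 * data[tr, , ]   # obvious outliers
  ts <- make_trial_set(data, channels = c("F5", "C3", "Cz", "C4"))
  pruned <- prune_trials(ts)
  expect_identical(dim(pruned$data)[1], 7L)
  expect_identical(pruned$log$dropped, 8:10)
  expect_equal(dim(pruned$data)[1] * nsamp / 256, 28)
  # exact ties: identical trials -> lowest indices dropped first
  tie <- make_trial_set(array(rep(sin(2 * pi * 10 * (0:(nsamp - 1)) / 256),
                                  each = 10 * 4),
                              dim = c(10, 4, nsamp)),
                        channels = c("F5", "C3", "Cz", "C4"))
  expect_identical(prune_trials(tie)$log$dropped, 1:3)
  expect_error(prune_trials(make_trial_set(data[1:3, , , drop = FALSE],
                                           channels = c("F5", "C3", "Cz", "C4"))),
               "cannot drop", class = "too_few_trials")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  data <- array(rnorm(5 * 6 * 512), dim = c(5, 6, 512))
  ts <- make_trial_set(data, channels = default_montage()[1:6])
  ref <- average_reference(ts)
  for (tr in 1:5)
    expect_lt(max(abs(colMeans(ref$data[tr, , ]))), 1e-12)
  expect_equal(average_reference(ref)$data, ref$data, tolerance = 1e-12)
  # invariance to a common-mode offset
  ts_off <- ts
  ts_off$data <- ts_off$data + 42
  expect_equal(average_reference(ts_off)$data, ref$data, tolerance = 1e-10)
})

test_that("clean synthetic sessions pass preprocessing untouched", {
  ses <- simulate_session(small_model(), default_scenario(),
                          conditions = c("rest", "left"), seed = 16)
  sets <- preprocess_session(ses)
  expect_false(is_rejected(sets))
  for (ts in sets) {
    expect_identical(dim(ts$data)[1], 7L)
    expect_length(ts$log$repaired, 0)
    for (tr in 1:7)
      expect_lt(max(abs(colMeans(ts$data[tr, , ]))), 1e-9)
  }
})

test_that("injected artifacts are found by the closed preprocessing loop", {
  ses <- simulate_session(small_model(), default_scenario(),
                          conditions = c("rest", "left"), seed = 17)
  # one noisy channel -> flagged exactly, repaired, not rejected
  bad1 <- inject_artifacts(ses, bad_channels = "CP1", seed = 3)
  filt <- bandpass_filter(bad1)
  sets <- extract_trials(filt)
  expect_identical(detect_bad_channels(sets$rest), "CP1")
  expect_identical(detect_bad_channels(sets$left), "CP1")
  out <- preprocess_session(bad1)
  expect_false(is_rejected(out))
  expect_identical(out$rest$log$repaired, "CP1")
  # a flat (dead) channel is flagged through the low-variance arm
  dead <- inject_artifacts(ses, bad_channels = "P6", kind = "flat", seed = 4)
  expect_identical(detect_bad_channels(extract_trials(bandpass_filter(dead))$rest),
                   "P6")
  # five bad channels -> the whole session is rejected
  bad5 <- inject_artifacts(ses, bad_channels = c("F5", "C3", "Cz", "C4", "P3"),
                           seed = 5)
  expect_true(is_rejected(preprocess_session(bad5)))
  # inflated trials are exactly the pruned set
  rest_events <- which(ses$events$condition == "rest")
  outl <- inject_artifacts(ses, outlier_trials = rest_events[c(2, 5, 8)],
                           seed = 6)
  sets <- extract_trials(bandpass_filter(outl))
  pruned <- prune_trials(sets$rest)
  expect_identical(pruned$log$dropped, c(2L, 5L, 8L))
})
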