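test_that("unstable coupling specs raise an error naming the spectral radius", {
  expect_error(
    sim_scenario(coupling = data.frame(from = 1L, to = 1L, lag = 1L,
                                       coef = 0.3, band = "mu")),
    "spectral radius", class = "unstable_coupling")
  # heavy cross-coupling ring that pushes the companion radius past 1
  ring <- data.frame(from = 1:10, to = c(2:10, 1L), lag = 1L, coef = 0.9,
                     band = "mu")
  expect_error(sim_scenario(coupling = ring), "spectral radius")
})

test_that("uncoupled ROI sources are mutually uncorrelated at any lag", {
  sc <- sim_scenario()   # empty coupling
  src <- simulate_source_dynamics(small_model(), sc, "rest", n_trials = 50,
                                  seed = 21)
  flat <- matrix(src, nrow = 10)   # pool samples across trials
  worst <- 0
  for (pair in list(c(1, 2), c(3, 7), c(7, 9), c(5, 10))) {
    for (lag in -5:5) {
      n <- ncol(flat)
      a <- flat[pair[1], seq_len(n - abs(lag))]
      b <- flat[pair[2], seq_len(n - abs(lag)) + abs(lag)]
      if (lag < 0) { tmp <- a; a <- b; b <- tmp }
      worst <- max(worst, abs(cor(a, b)))
    }
  }
  expect_lt(worst, 0.1)
})

test_that("an ERD amplitude multiplier m scales band power by m^2", {
  # Mu-only scenario so the measured 8-12 Hz power is purely the scaled
  # oscillator (no Beta-tail or broadband contamination of the ratio)
  sc <- sim_scenario(erd = data.frame(roi = 7L, band = "mu",
                                      multiplier = 0.5),
                     bands = list(mu = c(8, 12)),
                     osc_freq = c(mu = 10), osc_rho = c(mu = 0.96),
                     background_sd = 0)
  move <- simulate_source_dynamics(small_model(), sc, "left", 40, seed = 5)
  rest <- simulate_source_dynamics(small_model(), sc, "rest", 40, seed = 6)
  band_power <- function(x, lo = 8, hi = 12, fs = 256) {
    p <- Mod(stats::fft(x))^2 / length(x)
    fr <- (seq_along(x) - 1) * fs / length(x)
    sum(p[fr >= lo & fr <= hi])
  }
  ratio <- mean(apply(move[7, , ], 2, band_power)) /
    mean(apply(rest[7, , ], 2, band_power))
  expect_lt(abs(ratio - 0.25), 0.03)
  # an untouched ROI keeps its power
  ratio9 <- mean(apply(move[9, , ], 2, band_power)) /
    mean(apply(rest[9, , ], 2, band_power))
  expect_lt(abs(ratio9 - 1), 0.1)
})

test_that("source simulation is bitwise reproducible under a fixed seed", {
  sc <- default_scenario()
  a <- simulate_source_dynamics(small_model(), sc, "left", 3, seed = 9)
  b <- simulate_source_dynamics(small_model(), sc, "left", 3, seed = 9)
  expect_identical(a, b)
  expect_identical(simulate_session(small_model(), sc, seed = 4),
                   simulate_session(small_model(), sc, seed = 4))
})

test_that("scalp projection is linear and reduces to leadfield columns", {
  hm <- small_model()
  n_vox <- ncol(hm$leadfield)
  nsamp <- 1024
  wave <- sin(2 * pi * 10 * (0:(nsamp - 1)) / 256)
  src <- array(0, dim = c(n_vox, nsamp, 2))
  src[33, , 1] <- wave
  src[33, , 2] <- wave
  attr(src, "sampling_rate") <- 256
  ses <- project_to_scalp(hm, list(left = src), snr = Inf,
                          brain_noise_sd = 0, seed = 1)
  seg <- ses$data[, ses$events$onset[1] + seq_len(nsamp) - 1]
  expected <- erdconnect:::SENSOR_GAIN_UV * outer(hm$leadfield[, 33], wave)
  expect_equal(seg, expected, tolerance = 1e-10, ignore_attr = TRUE)
  # doubling source amplitude doubles the noiseless sensor signal
  ses2 <- project_to_scalp(hm, list(left = 2 * src), snr = Inf,
                           brain_noise_sd = 0, seed = 1)
  expect_equal(ses2$data, 2 * ses$data, tolerance = 1e-10)
})

test_that("a simulated screening phase contains 10 trials per condition in 2 runs", {
  ses <- simulate_session(small_model(), default_scenario(), seed = 2)
  tab <- table(ses$events$condition)
  expect_identical(as.integer(tab[c("rest", "left", "right")]),
                   c(10L, 10L, 10L))
  expect_identical(sort(unique(ses$events$run)), c(1L, 2L))
  per_run <- table(ses$events$condition, ses$events$run)
  expect_true(all(per_run == 5L))
  expect_error(project_to_scalp(small_model(),
                                list(left = array(0, c(7, 64, 2)))),
               "neither", class = "dimension_mismatch")
})

test_that("artifact injection with empty specs is the identity", {
  ses <- simulate_session(small_model(), default_scenario(), seed = 3)
  expect_identical(inject_artifacts(ses), ses)
  expect_error(inject_artifacts(ses, bad_channels = "Qq1"), "unknown channel")
  expect_error(inject_artifacts(ses, outlier_trials = 99L), "out of range")
})

test_that("behavior generator calibrates the requested correlation", {
  # null linkage at large n
  tb <- generate_behavior_table(1000, target_r = 0, seed = 11)
  expect_lt(abs(cor(tb$erd_change, tb$grip_change_lb)), 0.1)
  # degenerate noiseless case gives |r| = 1
  tb0 <- generate_behavior_table(8, target_r = 0.7, noise_sd = 0, seed = 12)
  expect_equal(abs(cor(tb0$erd_change, tb0$grip_change_lb)), 1,
               tolerance = 1e-5)   # 2-decimal rounding of the lb column
  expect_equal(sign(cor(tb0$erd_change, tb0$grip_change_lb)), 1)
  # Monte-Carlo calibration at the cohort design point (n = 16, r = 0.435);
  # the sample correlation at n = 16 carries a small negative bias
  # (E[r] ~ rho - rho (1 - rho^2) / (2n) ~ 0.424), so the band is 0.03 wide
  rs <- vapply(seq_len(500), function(s) {
    tt <- generate_behavior_table(16, target_r = 0.435, seed = 1000 + s)
    cor(tt$erd_change, tt$grip_change_lb)
  }, 0)
  expect_lt(abs(mean(rs) - 0.435), 0.03)
  # validation
  expect_error(generate_behavior_table(2, 0.3), "n_subjects")
  expect_error(generate_behavior_table(10, 1), "target_r")
  tb2 <- generate_behavior_table(200, target_r = 0.5, seed = 13)
  expect_true(all(tb2$arat_baseline >= 0 & tb2$arat_baseline <= 57))
  expect_true(all(tb2$arat_baseline + tb2$arat_change >= 0))
  expect_true(all(tb2$arat_baseline + tb2$arat_change <= 57))
  expect_true(all(tb2$grip_baseline_lb >= 0))
})

test_that("scenario and behavior-table serialization round-trip", {
  sc <- default_scenario(snr = 8)
  f <- withr::local_tempfile(fileext = ".json")
  scenario_to_json(sc, f)
  sc2 <- scenario_from_json(f)
  expect_equal(sc2$coupling$coef, sc$coupling$coef)
  expect_equal(sc2$erd$multiplier, sc$erd$multiplier)
  expect_equal(sc2$snr, 8)
  expect_identical(
    simulate_source_dynamics(small_model(), sc, "left", 2, seed = 1),
    simulate_source_dynamics(small_model(), sc2, "left", 2, seed = 1))

  tb <- generate_behavior_table(16, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_behavior_table(tb, csv)
  expect_identical(
    readLines(csv, n = 1),
    "subject_id,arat_baseline,arat_change,grip_baseline_lb,grip_change_lb")
  back <- read.csv(csv)
  expect_equal(back$grip_change_lb, tb$grip_change_lb)
})
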