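known_var2 <- function() {
  a1 <- matrix(c(0.5, 0.1, 0, 0.4, -0.2, 0.3, 0, 0.2, 0.3), 3, 3)
  a2 <- matrix(c(-0.2, 0, 0.1, 0, 0.1, 0, 0.15, 0, -0.1), 3, 3)
  list(a1, a2)
}

test_that("MVAR least squares recovers known coefficients", {
  a <- known_var2()
  set.seed(51)
  x <- mvar_sim_oracle(a, 20000)
  fit <- fit_mvar(x, 2)
  rmse <- sqrt(mean((unlist(fit$coef) - unlist(a))^2))
  expect_lt(rmse, 0.05)
  expect_equal(fit$sigma, diag(3), tolerance = 0.1)
  expect_lt(erdconnect:::companion_spectral_radius(fit$coef), 1)
})

test_that("white noise fits to near-zero coefficients", {
  set.seed(52)
  x <- matrix(rnorm(5 * 20000), 5)
  fit <- fit_mvar(x, 2)
  expect_lt(max(abs(unlist(fit$coef))), 0.05)
})

test_that("relabeling the series permutes the fitted matrices consistently", {
  a <- known_var2()
  set.seed(53)
  x <- mvar_sim_oracle(a, 5000)
  perm <- c(3, 1, 2)
  fit <- fit_mvar(x, 2)
  fitp <- fit_mvar(x[perm, , drop = FALSE], 2)
  for (k in 1:2)
    expect_equal(fitp$coef[[k]], fit$coef[[k]][perm, perm], tolerance = 1e-10)
})

test_that("multi-trial fitting never crosses trial boundaries", {
  a <- known_var2()
  set.seed(54)
  # two trials with wildly different offsets; a boundary-crossing fit
  # would be biased by the artificial jump
  x1 <- mvar_sim_oracle(a, 3000)
  x2 <- mvar_sim_oracle(a, 3000) + 500
  arr <- array(0, dim = c(3, 3000, 2))
  arr[, , 1] <- x1; arr[, , 2] <- x2 - 500
  fit_split <- fit_mvar(arr, 2)
  fit_cat <- fit_mvar(cbind(x1, x2 - 500), 2)
  expect_equal(unlist(fit_split$coef), unlist(a), tolerance = 0.07)
  # concatenation uses 2 more rows (the boundary) than the trial-aware fit
  expect_identical(fit_cat$n_observations - fit_split$n_observations, 2L)
})

test_that("information criteria select sensible orders", {
  a3 <- list(matrix(c(0.4, 0, 0, 0.3), 2), matrix(0, 2, 2),
             matrix(c(0, 0.3, 0, -0.35), 2))
  hits <- 0L
  set.seed(55)
  for (s in 1:50) {
    x <- mvar_sim_oracle(a3, 3000)
    if (select_order(x, p_max = 6) == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 45L)   # >= 90 % of seeds
  set.seed(56)
  wn <- matrix(rnorm(3 * 4000), 3)
  expect_identical(select_order(wn, p_max = 6), 1L)
  expect_identical(select_order(wn, p_max = 1), 1L)
})

test_that("iCoh matches the isolated-subsystem partial-coherence oracle", {
  set.seed(57)
  d <- 5; p <- 2; fs <- 256
  repeat {
    a <- lapply(1:p, function(k) matrix(rnorm(d * d, sd = 0.18), d, d))
    if (erdconnect:::companion_spectral_radius(a) < 0.95) break
  }
  l <- matrix(rnorm(d * d, sd = 0.3), d)
  sig <- crossprod(l) + diag(d) * 0.5
  mv <- structure(list(order = p, coef = a, sigma = sig,
                       sampling_rate = fs, n_observations = 10000L),
                  class = "mvar_model")
  freqs <- c(6, 10.25, 19)
  ic <- icoh(mv, freqs)
  oracle <- function(i, j, f) {
    aiso <- lapply(1:p, function(k) {
      m <- diag(diag(a[[k]])); m[i, j] <- a[[k]][i, j]; m
    })
    abar <- diag(d) + 0i
    for (k in 1:p) abar <- abar - aiso[[k]] * exp(-2i * pi * f * k / fs)
    h <- solve(abar)
    s <- h %*% diag(diag(sig)) %*% Conj(t(h))
    prec <- solve(s)
    Mod(prec[i, j])^2 / (Re(prec[i, i]) * Re(prec[j, j]))
  }
  for (fi in seq_along(freqs))
    for (i in 1:d) for (j in setdiff(1:d, i))
      expect_equal(ic[j, i, fi], oracle(i, j, freqs[fi]), tolerance = 1e-10)
})

test_that("independent univariate processes show no isolated coherence", {
  sc <- sim_scenario()       # no coupling anywhere
  src <- simulate_source_dynamics(small_model(), sc, "rest", 10, seed = 58)
  mv <- fit_mvar(src, select_order(src, 20, criterion = "aic"))
  ic <- icoh(mv)
  off <- unclass(ic)
  for (i in 1:10) off[i, i, ] <- NA
  expect_lt(max(off, na.rm = TRUE), 0.05)
})

test_that("iCoh lies in [0,1] and unstable or singular models are refused", {
  set.seed(59)
  for (rep in 1:30) {
    d <- sample(3:6, 1)
    p <- sample(1:3, 1)
    repeat {
      a <- lapply(seq_len(p), function(k) matrix(rnorm(d * d, sd = 0.25), d, d))
      if (erdconnect:::companion_spectral_radius(a) < 0.98) break
    }
    sig <- crossprod(matrix(rnorm(d * d), d)) + diag(d) * 0.1
    mv <- structure(list(order = p, coef = a, sigma = sig,
                         sampling_rate = 256, n_observations = 1000L),
                    class = "mvar_model")
    ic <- icoh(mv, freqs = seq(4, 30, by = 2))
    expect_true(all(ic >= 0 & ic <= 1))
  }
  unstable <- structure(list(order = 1L, coef = list(diag(2) * 1.05),
                             sigma = diag(2), sampling_rate = 256,
                             n_observations = 100L), class = "mvar_model")
  expect_error(icoh(unstable), "unstable", class = "unstable_model")
  sing <- structure(list(order = 1L, coef = list(diag(2) * 0.5),
                         sigma = matrix(1, 2, 2), sampling_rate = 256,
                         n_observations = 100L), class = "mvar_model")
  expect_error(icoh(sing), "singular", class = "singular_sigma")
})

test_that("planted Mu coupling 7->9 appears as band-limited directed coherence", {
  # matched model class (pure Mu-band MVAR source): the iCoh profile peaks
  # inside the band and the reverse direction is empty
  sc <- sim_scenario(coupling = data.frame(from = 7L, to = 9L, lag = 2L,
                                           coef = 0.25, band = "mu"),
                     bands = list(mu = c(8, 12)),
                     osc_freq = c(mu = 10), osc_rho = c(mu = 0.96),
                     background_sd = 0)
  src <- simulate_source_dynamics(small_model(), sc, "left", 10, seed = 60)
  mv <- fit_mvar(src, select_order(src, 8))
  ic <- icoh(mv)
  peak_i <- which.max(ic[7, 9, ])
  peak_f <- attr(ic, "freqs")[peak_i]
  expect_true(peak_f >= 8 && peak_f <= 12)
  expect_gt(ic[7, 9, peak_i], ic[9, 7, peak_i])
  expect_gt(max(ic[7, 9, ]), 0.5)
  # under the full default scenario (Beta band + broadband noise present)
  # the finite-order VAR approximation smears the profile, but the band-mean
  # direction is preserved
  sc2 <- default_scenario()
  for (s in 1:3) {
    src2 <- simulate_source_dynamics(small_model(), sc2, "left", 10,
                                     seed = 60 + s)
    mu <- band_mean_icoh(icoh(fit_mvar(src2, 20)), c(8, 12))
    expect_gt(mu[7, 9], mu[9, 7])
  }
})

test_that("band-mean iCoh averages the inclusive grid bins", {
  freqs <- seq(4, 30, by = 0.25)
  arr <- array(0.37, dim = c(10, 10, length(freqs)))
  for (i in 1:10) arr[i, i, ] <- 0
  ic <- structure(arr, freqs = freqs, order = 2L, class = "icoh_spectra")
  mu <- band_mean_icoh(ic, c(8, 12))
  expect_equal(mu[1, 2], 0.37, tolerance = 1e-12)
  expect_true(all(mu >= 0 & mu <= 1))
  expect_error(band_mean_icoh(ic, c(40, 50)), "no frequency bins",
               class = "empty_band")
})
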