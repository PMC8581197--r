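#' Define a simulation scenario for the forward EEG simulator
#'
#' A scenario specifies the ground truth of a simulated screening session:
#' per-ROI narrow-band oscillators in the Mu and Beta bands, directed
#' inter-ROI coupling as a multivariate autoregressive (MVAR) process,
#' event-related desynchronization (ERD) as condition-dependent amplitude
#' multipliers, and the sensor signal-to-noise ratio.
#'
#' Each band is generated by a 10-dimensional MVAR whose diagonal holds an
#' AR(2) resonator (pole radius `rho` at the band's center frequency) and
#' whose off-diagonal lags carry the edges of `coupling`. Oscillator outputs
#' are rescaled to unit stationary standard deviation at rest, so an ERD
#' multiplier `m` scales band amplitude by exactly `m` (power by `m^2`)
#' during movement.
#'
#' @param coupling data.frame with columns `from`, `to` (ROI numbers 1-10),
#'   `lag` (samples, >= 1), `coef`, and optionally `band` ("mu" or "beta",
#'   default "mu"): directed edges of the ground-truth MVAR source process.
#' @param erd data.frame with columns `roi`, `band`, `multiplier` (> 0):
#'   amplitude multipliers applied during movement conditions relative to
#'   rest.
#' @param snr Sensor signal-to-noise ratio (RMS of projected signal over RMS
#'   of added white sensor noise); `Inf` for noiseless.
#' @param sampling_rate Sampling rate in Hz.
#' @param trial_length_s Trial length in seconds.
#' @param bands Named list of band limits in Hz.
#' @param osc_freq,osc_rho Named numeric vectors: oscillator center frequency
#'   (Hz) and AR pole radius per band.
#' @param background_sd Standard deviation of the broadband source component.
#' @param seed Default seed attached to the scenario (used by convenience
#'   simulators when no explicit seed is given).
#' @return An object of class `sim_scenario`.
#' @seealso [default_scenario()], [simulate_source_dynamics()]
#' @export
sim_scenario <- function(coupling = NULL,
                         erd = NULL,
                         snr = 5,
                         sampling_rate = 256,
                         trial_length_s = 4,
                         bands = list(mu = c(8, 12), beta = c(18, 26)),
                         osc_freq = c(mu = 10, beta = 22),
                         osc_rho = c(mu = 0.96, beta = 0.94),
                         background_sd = 0.3,
                         seed = 1L) {
  if (is.null(coupling))
    coupling <- data.frame(from = integer(0), to = integer(0),
                           lag = integer(0), coef = numeric(0),
                           band = character(0))
  if (is.null(coupling$band)) coupling$band <- rep("mu", nrow(coupling))
  if (is.null(erd))
    erd <- data.frame(roi = integer(0), band = character(0),
                      multiplier = numeric(0))
  stopifnot(all(c("from", "to", "lag", "coef") %in% names(coupling)),
            all(c("roi", "band", "multiplier") %in% names(erd)) ||
              nrow(erd) == 0)
  if (nrow(erd) && any(erd$multiplier <= 0))
    stop_labeled("bad_argument", "erd multipliers must be > 0")
  if (nrow(coupling) && any(coupling$lag < 1))
    stop_labeled("bad_argument", "coupling lags must be >= 1 sample")
  sc <- structure(list(coupling = coupling, erd = erd, snr = snr,
                       sampling_rate = sampling_rate,
                       trial_length_s = trial_length_s, bands = bands,
                       osc_freq = osc_freq, osc_rho = osc_rho,
                       background_sd = background_sd, seed = seed),
                  class = "sim_scenario")
  for (b in names(bands)) {
    rad <- companion_spectral_radius(band_coef_matrices(sc, b))
    if (rad >= 1)
      stop_labeled("unstable_coupling",
                   "coupling_spec unstable in band '%s': companion spectral radius %.4f >= 1",
                   b, rad)
  }
  sc
}

#' Default simulation scenario: study conditions of the synthetic cohort
#'
#' Emulates the phenomenology the pipeline is built to detect for a cohort
#' with right-hemisphere lesions and impaired left hands: Mu-band ERD in the
#' right (ipsilesional) primary motor cortex (ROI 7, multiplier 0.5) and
#' somatosensory association area (ROI 8, multiplier 0.65) during movement,
#' and a directed Mu-band coupling from right primary motor (ROI 7) to right
#' premotor cortex (ROI 9).
#'
#' @param coupling_coef Coefficient of the ROI 7 -> ROI 9 Mu-band edge.
#' @param ... Passed on to [sim_scenario()].
#' @return A `sim_scenario`.
#' @export
default_scenario <- function(coupling_coef = 0.25, ...) {
  sim_scenario(
    coupling = data.frame(from = 7L, to = 9L, lag = 2L,
                          coef = coupling_coef, band = "mu"),
    erd = data.frame(roi = c(7L, 8L), band = "mu",
                     multiplier = c(0.5, 0.65)),
    ...)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: fs=%g Hz, trials %gs, snr=%g\n",
              x$sampling_rate, x$trial_length_s, x$snr))
  cat(sprintf("  %d coupling edge(s), %d ERD entrie(s)\n",
              nrow(x$coupling), nrow(x$erd)))
  invisible(x)
}

# MVAR coefficient matrices A_1..A_p for one band: diagonal AR(2) resonators
# plus the coupling edges assigned to that band.
band_coef_matrices <- function(scenario, band, d = 10L) {
  f0 <- scenario$osc_freq[[band]]
  rho <- scenario$osc_rho[[band]]
  w0 <- 2 * pi * f0 / scenario$sampling_rate
  edges <- scenario$coupling[scenario$coupling$band == band, , drop = FALSE]
  p <- max(2L, if (nrow(edges)) max(edges$lag) else 0L)
  a <- replicate(p, matrix(0, d, d), simplify = FALSE)
  diag(a[[1L]]) <- 2 * rho * cos(w0)
  diag(a[[2L]]) <- -rho^2
  for (i in seq_len(nrow(edges)))
    a[[edges$lag[i]]][edges$to[i], edges$from[i]] <-
      a[[edges$lag[i]]][edges$to[i], edges$from[i]] + edges$coef[i]
  a
}

# Stationary standard deviation of each component of a stable MVAR with unit
# innovation covariance, from the spectral integral of H(w) H(w)^H.
mvar_stationary_sd <- function(a_list, nf = 512L) {
  d <- nrow(a_list[[1L]])
  p <- length(a_list)
  w <- (seq_len(nf) - 0.5) * pi / nf
  acc <- numeric(d)
  for (j in seq_len(nf)) {
    abar <- diag(d) + 0i
    for (k in seq_len(p)) abar <- abar - a_list[[k]] * exp(-1i * w[j] * k)
    h <- solve(abar)
    acc <- acc + rowSums(Mod(h)^2)
  }
  sqrt(acc / nf)   # (1/pi) * integral over (0, pi)
}

# Simulate a stable MVAR, all trials in parallel; returns d x nsamp x ntrials.
# Time steps are contiguous column blocks of a d x (total*ntrials) matrix.
simulate_mvar <- function(a_list, nsamp, ntrials, burn = 256L) {
  d <- nrow(a_list[[1L]])
  p <- length(a_list)
  total <- nsamp + burn + p
  x <- matrix(rnorm(d * ntrials * total), d, total * ntrials)
  blk <- function(t) ((t - 1L) * ntrials + 1L):(t * ntrials)
  for (t in (p + 1L):total) {
    acc <- x[, blk(t), drop = FALSE]
    for (k in seq_len(p))
      acc <- acc + a_list[[k]] %*% x[, blk(t - k), drop = FALSE]
    x[, blk(t)] <- acc
  }
  keep <- (burn + p + 1L):total
  out <- array(0, dim = c(d, nsamp, ntrials))
  for (i in seq_along(keep)) out[, i, ] <- x[, blk(keep[i])]
  out
}

#' Simulate ground-truth ROI source dynamics
#'
#' Generates per-trial source time series for the ten ROIs under one
#' condition. Each ROI source is a sum of a Mu-band oscillation, a Beta-band
#' oscillation (both normalized to unit stationary standard deviation at
#' rest, with directed coupling per the scenario), and white background
#' noise. Under movement conditions (anything other than `"rest"`) the
#' scenario's ERD multipliers scale the band amplitudes.
#'
#' @param model A `head_model` (defines ROI count; currently 10).
#' @param scenario A `sim_scenario`.
#' @param condition `"rest"`, `"left"`, or `"right"`.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; defaults to the scenario seed.
#' @return Array `10 x samples x trials` with attributes `condition`,
#'   `sampling_rate`.
#' @export
simulate_source_dynamics <- function(model, scenario, condition = "left",
                                     n_trials = 10L, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"), n_trials >= 1)
  d <- 10L
  nsamp <- round(scenario$trial_length_s * scenario$sampling_rate)
  gains <- matrix(1, d, length(scenario$bands),
                  dimnames = list(NULL, names(scenario$bands)))
  if (condition != "rest" && nrow(scenario$erd))
    for (i in seq_len(nrow(scenario$erd)))
      gains[scenario$erd$roi[i], scenario$erd$band[i]] <-
        scenario$erd$multiplier[i]
  with_seed(seed, {
    out <- array(scenario$background_sd * rnorm(d * nsamp * n_trials),
                 dim = c(d, nsamp, n_trials))
    for (b in names(scenario$bands)) {
      a <- band_coef_matrices(scenario, b, d)
      rad <- companion_spectral_radius(a)
      if (rad >= 1)
        stop_labeled("unstable_coupling",
                     "unstable coupling in band '%s': spectral radius %.4f",
                     b, rad)
      sd_b <- mvar_stationary_sd(a)
      osc <- simulate_mvar(a, nsamp, n_trials)
      out <- out + (gains[, b] / sd_b) * osc
    }
    attr(out, "condition") <- condition
    attr(out, "sampling_rate") <- scenario$sampling_rate
    out
  })
}

# Effective ROI-level leadfield: coherent assignment of an ROI source to all
# member voxels, normalized by member count (mean of member columns).
roi_leadfield <- function(model) {
  sapply(1:10, function(r)
    rowMeans(model$leadfield[, roi_voxels(model, r), drop = FALSE]))
}

# Gain mapping unit-variance sources to scalp microvolts; together with the
# distributed brain-noise floor it is chosen so that the default scenario
# yields in-band channel variances of a few tens of uV^2, comfortably inside
# the (10, 250) uV^2 screening window.
SENSOR_GAIN_UV <- 3.8

#' Project source trials to the scalp and lay out a screening session
#'
#' Applies the leadfield (ROI-level or voxel-level sources), adds white
#' Gaussian sensor noise scaled to the requested signal-to-noise ratio, and
#' arranges the trials into the screening-session structure: 2 runs, 5 trials
#' per condition per run in seeded random order, separated by inter-trial
#' background gaps, so that 10 trials per condition exist per phase.
#'
#' @param model A `head_model`.
#' @param source_trials Named list of arrays (`rois x samples x trials` or
#'   `voxels x samples x trials`), one per condition; a bare array is treated
#'   as condition `"left"`.
#' @param snr Signal-to-noise ratio (RMS clean signal / RMS noise); `Inf`
#'   for noiseless.
#' @param phase `"Pre"` or `"Post"`.
#' @param subject_id Subject identifier.
#' @param gap_s Inter-trial gap in seconds (background activity only).
#' @param brain_noise_sd Overall scale (source units) of spatially
#'   distributed background activity: independent noise generated at every
#'   voxel with per-voxel standard deviation `brain_noise_sd / sqrt(n_voxels)`
#'   and projected through the full leadfield for the whole recording, so the
#'   sensor-level floor does not depend on the grid resolution. Gives all
#'   channels a comparable physiological noise floor; set to 0 for a
#'   noiseless forward projection.
#' @param seed Seed for trial order and noise.
#' @param scenario Optional `sim_scenario` stored as ground truth.
#' @return A `raw_session`: list with `data` (channels x samples, uV),
#'   `events` (data.frame onset/condition/run), `phase`, `subject_id`,
#'   `sampling_rate`, `channels`, `channel_coords`, `ground_truth`.
#' @export
project_to_scalp <- function(model, source_trials, snr = 5,
                             phase = "Pre", subject_id = "S01",
                             gap_s = 1, brain_noise_sd = 7,
                             seed = 1L, scenario = NULL) {
  stopifnot(inherits(model, "head_model"))
  if (!is.list(source_trials)) source_trials <- list(left = source_trials)
  n_vox <- ncol(model$leadfield)
  n_ch <- nrow(model$leadfield)
  lf_roi <- roi_leadfield(model)
  fs <- attr(source_trials[[1L]], "sampling_rate")
  if (is.null(fs)) fs <- if (!is.null(scenario)) scenario$sampling_rate else 256

  sensor_trials <- list()
  for (cond in names(source_trials)) {
    src <- source_trials[[cond]]
    if (length(dim(src)) == 2L) src <- array(src, dim = c(dim(src), 1L))
    lf <- if (dim(src)[1L] == 10L) lf_roi
      else if (dim(src)[1L] == n_vox) model$leadfield
      else stop_labeled("dimension_mismatch",
        "source rows (%d) match neither 10 ROIs nor %d voxels",
        dim(src)[1L], n_vox)
    st <- array(0, dim = c(n_ch, dim(src)[2L], dim(src)[3L]))
    for (tr in seq_len(dim(src)[3L]))
      st[, , tr] <- SENSOR_GAIN_UV * (lf %*% src[, , tr])
    sensor_trials[[cond]] <- st
  }

  nsamp <- dim(sensor_trials[[1L]])[2L]
  gap <- as.integer(round(gap_s * fs))
  clean_ss <- sum(vapply(sensor_trials, function(a) sum(a * a), 0))
  clean_rms <- sqrt(clean_ss / sum(vapply(sensor_trials, length, 0L)))
  noise_sd <- if (is.infinite(snr)) 0 else clean_rms / snr

  with_seed(seed, {
    n_trials <- vapply(sensor_trials, function(a) dim(a)[3L], 1L)
    n_runs <- 2L
    per_run <- n_trials / n_runs
    if (any(per_run != round(per_run)))
      stop_labeled("bad_argument", "trial counts must divide into 2 runs")
    order_tbl <- NULL
    for (run in seq_len(n_runs)) {
      slots <- unlist(lapply(names(sensor_trials), function(cond)
        rep(cond, per_run[[cond]])))
      slots <- sample(slots)
      idx <- integer(length(slots))
      order_tbl <- rbind(order_tbl,
        data.frame(condition = slots, run = run, stringsAsFactors = FALSE))
    }
    used <- stats::setNames(rep(0L, length(sensor_trials)),
                            names(sensor_trials))
    total <- nrow(order_tbl) * (nsamp + gap) + gap
    data <- matrix(rnorm(n_ch * total, sd = noise_sd), n_ch, total)
    if (brain_noise_sd > 0)
      data <- data + SENSOR_GAIN_UV * brain_noise_sd / sqrt(n_vox) *
        (model$leadfield %*% matrix(rnorm(n_vox * total), n_vox, total))
    rownames(data) <- model$channel_names
    onsets <- integer(nrow(order_tbl))
    pos <- gap
    for (i in seq_len(nrow(order_tbl))) {
      cond <- order_tbl$condition[i]
      used[cond] <- used[cond] + 1L
      seg <- pos + seq_len(nsamp)
      data[, seg] <- data[, seg] + sensor_trials[[cond]][, , used[cond]]
      onsets[i] <- pos + 1L
      pos <- pos + nsamp + gap
    }
    structure(list(
      data = data,
      events = data.frame(onset = onsets, condition = order_tbl$condition,
                          run = order_tbl$run, stringsAsFactors = FALSE),
      phase = phase, subject_id = subject_id, sampling_rate = fs,
      channels = model$channel_names,
      channel_coords = model$channel_coords,
      ground_truth = scenario), class = "raw_session")
  })
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("EEG session %s [%s]: %d channels x %d samples @ %g Hz, %d events\n",
              x$subject_id, x$phase, nrow(x$data), ncol(x$data),
              x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Simulate one full screening session
#'
#' Convenience wrapper: simulates 10 trials per condition from the scenario
#' and projects them to the scalp in the screening-session layout.
#'
#' @inheritParams project_to_scalp
#' @param scenario A `sim_scenario`.
#' @param conditions Conditions to include.
#' @param n_trials Trials per condition for the phase.
#' @param seed Integer seed.
#' @return A `raw_session`.
#' @export
simulate_session <- function(model, scenario, phase = "Pre",
                             subject_id = "S01",
                             conditions = c("rest", "left", "right"),
                             n_trials = 10L, seed = scenario$seed) {
  src <- with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, length(conditions) + 1L)
    st <- lapply(seq_along(conditions), function(i)
      simulate_source_dynamics(model, scenario, conditions[i], n_trials,
                               seed = seeds[i]))
    names(st) <- conditions
    attr(st, "proj_seed") <- seeds[length(seeds)]
    st
  })
  project_to_scalp(model, src, snr = scenario$snr, phase = phase,
                   subject_id = subject_id, seed = attr(src, "proj_seed"),
                   scenario = scenario)
}

#' Inject bad channels and high-variance trials into a session
#'
#' Bad channels are rewritten as high-amplitude broadband noise (or a
#' near-flat trace for `kind = "flat"`), which drives their per-trial
#' variance outside the screening window in every trial; outlier trials are
#' scaled up so that their total variance ranks highest within their
#' condition set.
#'
#' @param session A `raw_session`.
#' @param bad_channels Channel labels to corrupt.
#' @param outlier_trials Event indices (rows of `session$events`) to inflate.
#' @param kind `"noisy"` (high variance) or `"flat"` (low variance).
#' @param outlier_gain Multiplicative amplitude factor for outlier trials.
#' @param seed Integer seed.
#' @return The modified `raw_session` (unchanged if both specs are empty).
#' @export
inject_artifacts <- function(session, bad_channels = character(),
                             outlier_trials = integer(),
                             kind = "noisy", outlier_gain = 6, seed = 1L) {
  stopifnot(inherits(session, "raw_session"))
  bad_idx <- match(bad_channels, session$channels)
  if (anyNA(bad_idx))
    stop_labeled("bad_argument", "unknown channel(s): %s",
                 paste(bad_channels[is.na(bad_idx)], collapse = ", "))
  if (length(outlier_trials) &&
      (any(outlier_trials < 1) || any(outlier_trials > nrow(session$events))))
    stop_labeled("bad_argument", "outlier trial index out of range")
  if (!length(bad_idx) && !length(outlier_trials)) return(session)
  nsamp_trial <- round(4 * session$sampling_rate)
  with_seed(seed, {
    for (ch in bad_idx) {
      session$data[ch, ] <- if (kind == "flat")
        rnorm(ncol(session$data), sd = 0.5)
      else rnorm(ncol(session$data), sd = 60)
    }
    for (ev in outlier_trials) {
      seg <- session$events$onset[ev] + seq_len(nsamp_trial) - 1L
      seg <- seg[seg <= ncol(session$data)]
      session$data[, seg] <- outlier_gain * session$data[, seg]
    }
    session
  })
}

#' Generate a synthetic behavior table linked to an ERD-change covariate
#'
#' Produces per-subject ARAT and grip dynamometry columns emulating a chronic
#' stroke cohort, with the grip-strength change generated as a linear
#' function of a Mu-ERD change covariate plus Gaussian noise, the slope
#' calibrated so the population Pearson correlation between covariate and
#' grip change equals `target_r`.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param target_r Target correlation in (-1, 1).
#' @param noise_sd Noise standard deviation of the grip-change column (lb);
#'   `0` yields a perfect linear relation (sample `|r| = 1`).
#' @param erd_change Optional covariate vector (normalized ERD-change units,
#'   negative = stronger desynchronization Post); simulated if `NULL`.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `subject_id`, `arat_baseline`,
#'   `arat_change`, `grip_baseline_lb`, `grip_change_lb`, `erd_change`.
#' @export
generate_behavior_table <- function(n_subjects, target_r = 0.435,
                                    noise_sd = 4, erd_change = NULL,
                                    seed = 1L) {
  if (n_subjects < 3)
    stop_labeled("bad_argument", "n_subjects must be >= 3")
  if (abs(target_r) >= 1)
    stop_labeled("bad_argument", "|target_r| must be < 1, got %g", target_r)
  with_seed(seed, {
    pop_sd <- 0.12
    if (is.null(erd_change)) {
      erd_change <- rnorm(n_subjects, mean = -0.15, sd = pop_sd)
    } else {
      stopifnot(length(erd_change) == n_subjects)
      pop_sd <- stats::sd(erd_change)
      if (pop_sd == 0)
        stop_labeled("bad_argument", "erd_change covariate is constant")
    }
    if (noise_sd == 0) {
      # degenerate noiseless case: a perfect linear relation on the lb scale
      grip_change <- 1.7 + sign(target_r) * 50 * (erd_change - mean(erd_change))
    } else {
      slope <- target_r / sqrt(1 - target_r^2) * noise_sd / pop_sd
      grip_change <- 1.7 + slope * (erd_change - mean(erd_change)) +
        rnorm(n_subjects, sd = noise_sd)
    }
    high <- runif(n_subjects) < 0.3
    arat_baseline <- ifelse(high, sample(55:57, n_subjects, replace = TRUE),
                            floor(26 * runif(n_subjects)^2))
    arat_change <- round(rnorm(n_subjects, 1.4, 4))
    arat_change <- pmax(-arat_baseline, pmin(57 - arat_baseline, arat_change))
    grip_baseline <- ifelse(runif(n_subjects) < 0.5, 0,
                            round(rexp(n_subjects, 1 / 20), 2))
    data.frame(subject_id = seq_len(n_subjects),
               arat_baseline = as.integer(arat_baseline),
               arat_change = as.integer(arat_change),
               grip_baseline_lb = grip_baseline,
               grip_change_lb = round(grip_change, 2),
               erd_change = erd_change)
  })
}

#' Write a behavior table to CSV
#'
#' Writes the canonical columns
#' `subject_id,arat_baseline,arat_change,grip_baseline_lb,grip_change_lb`.
#'
#' @param table Behavior data.frame.
#' @param path Output path.
#' @export
write_behavior_table <- function(table, path) {
  cols <- c("subject_id", "arat_baseline", "arat_change",
            "grip_baseline_lb", "grip_change_lb")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
}

#' Serialize / restore a simulation scenario as JSON
#' @param scenario A `sim_scenario`.
#' @param path File path.
#' @return `scenario_from_json` returns the restored `sim_scenario`.
#' @export
scenario_to_json <- function(scenario, path) {
  stopifnot(inherits(scenario, "sim_scenario"))
  x <- unclass(scenario)
  x$osc_freq <- as.list(x$osc_freq)    # keep names through JSON
  x$osc_rho <- as.list(x$osc_rho)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scenario_to_json
#' @export
scenario_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_scenario(coupling = if (length(raw$coupling))
                 as.data.frame(raw$coupling) else NULL,
               erd = if (length(raw$erd)) as.data.frame(raw$erd) else NULL,
               snr = if (is.character(raw$snr)) Inf else as.numeric(raw$snr),
               sampling_rate = as.numeric(raw$sampling_rate),
               trial_length_s = as.numeric(raw$trial_length_s),
               bands = lapply(raw$bands, as.numeric),
               osc_freq = vapply(raw$osc_freq, as.numeric, 0),
               osc_rho = vapply(raw$osc_rho, as.numeric, 0),
               background_sd = as.numeric(raw$background_sd),
               seed = raw$seed)
}
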