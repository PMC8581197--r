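#' Zero-phase band-pass filter a session
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' (`signal::filtfilt`), giving zero phase shift so event latencies are
#' preserved. Defaults to the 4-30 Hz analysis band.
#'
#' @param session A `raw_session`.
#' @param hp_hz High-pass cutoff (Hz).
#' @param lp_hz Low-pass cutoff (Hz); must be below Nyquist.
#' @param order Filter order.
#' @return The filtered `raw_session`.
#' @export
bandpass_filter <- function(session, hp_hz = 4, lp_hz = 30, order = 4) {
  stopifnot(inherits(session, "raw_session"))
  nyq <- session$sampling_rate / 2
  if (lp_hz >= nyq)
    stop_labeled("bad_filter", "lp_hz (%g) must be below Nyquist (%g Hz)",
                 lp_hz, nyq)
  if (hp_hz <= 0 || hp_hz >= lp_hz)
    stop_labeled("bad_filter", "need 0 < hp_hz < lp_hz")
  bf <- signal::butter(order, c(hp_hz, lp_hz) / nyq, type = "pass")
  for (ch in seq_len(nrow(session$data)))
    session$data[ch, ] <- signal::filtfilt(bf, session$data[ch, ])
  session
}

new_trial_set <- function(data, condition, phase, subject_id, fs,
                          channels, channel_coords,
                          log = list(repaired = character(0),
                                     dropped = integer(0),
                                     rejected = FALSE)) {
  structure(list(data = data, condition = condition, phase = phase,
                 subject_id = subject_id, sampling_rate = fs,
                 channels = channels, channel_coords = channel_coords,
                 log = log),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Trial set (%s, %s): %d trials x %d channels x %d samples\n",
              x$condition, x$phase, d[1], d[2], d[3]))
  if (length(x$log$repaired))
    cat("  repaired:", paste(x$log$repaired, collapse = " "), "\n")
  if (length(x$log$dropped))
    cat("  dropped trials:", paste(x$log$dropped, collapse = " "), "\n")
  invisible(x)
}

#' Extract and group trials by condition
#'
#' Cuts fixed-length trials at each event onset and groups them by condition
#' for the session's phase. Right-hand trials are excluded by default, since
#' the analysis contrasts rest with impaired-hand movement.
#'
#' @param session A `raw_session` (typically already band-pass filtered).
#' @param conditions Conditions to extract.
#' @param trial_length_s Trial duration in seconds.
#' @param min_trials Minimum number of events required per condition.
#' @return Named list of `trial_set` objects (trials x channels x samples),
#'   one per condition.
#' @export
extract_trials <- function(session, conditions = c("rest", "left"),
                           trial_length_s = 4, min_trials = 10L) {
  stopifnot(inherits(session, "raw_session"))
  nsamp <- round(trial_length_s * session$sampling_rate)
  out <- list()
  for (cond in conditions) {
    onsets <- session$events$onset[session$events$condition == cond]
    onsets <- onsets[onsets + nsamp - 1L <= ncol(session$data)]
    if (length(onsets) < min_trials)
      stop_labeled("missing_trials",
                   "only %d complete '%s' trials in phase %s (need %d)",
                   length(onsets), cond, session$phase, min_trials)
    arr <- array(0, dim = c(length(onsets), nrow(session$data), nsamp))
    for (i in seq_along(onsets))
      arr[i, , ] <- session$data[, onsets[i] + seq_len(nsamp) - 1L]
    out[[cond]] <- new_trial_set(arr, cond, session$phase,
                                 session$subject_id, session$sampling_rate,
                                 session$channels, session$channel_coords)
  }
  out
}

#' Per-trial, per-channel sample variance
#'
#' @param trials A `trial_set`.
#' @return trials x channels matrix of sample variances (uV^2, denominator
#'   n-1), with channel names as columns.
#' @export
trial_channel_variance <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  d <- dim(trials$data)
  out <- matrix(0, d[1], d[2], dimnames = list(NULL, trials$channels))
  for (t in seq_len(d[1]))
    out[t, ] <- row_variances(trials$data[t, , , drop = TRUE])
  out
}

#' Variance-based bad-channel detection
#'
#' A channel is flagged as bad when its per-trial variance falls below `low`
#' or above `high` in strictly more than `max_trials` trials.
#'
#' @param trials A `trial_set`.
#' @param low,high Variance window in uV^2.
#' @param max_trials Maximum tolerated count of out-of-window trials.
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(trials, low = 10, high = 250,
                                max_trials = 3L) {
  v <- trial_channel_variance(trials)
  n_out <- colSums(v < low | v > high)
  trials$channels[n_out > max_trials]
}

#' Session rejection marker
#'
#' Returned (never thrown) by [repair_or_reject()] when too many channels are
#' bad; batch pipelines treat it as "this session is removed".
#'
#' @param reason Human-readable reason.
#' @param bads The offending channel labels.
#' @return An object of class `session_rejection`.
#' @export
session_rejection <- function(reason, bads = character(0)) {
  structure(list(reason = reason, bads = bads), class = "session_rejection")
}

#' @export
print.session_rejection <- function(x, ...) {
  cat("Session rejected:", x$reason, "\n")
  invisible(x)
}

#' Test for a rejection marker
#' @param x Any object.
#' @return `TRUE` if `x` is a `session_rejection`.
#' @export
is_rejected <- function(x) inherits(x, "session_rejection")

# Spherical-spline interpolation matrix (Perrin-style): returns a
# length(bad) x length(good) transfer matrix mapping good-channel samples to
# interpolated bad-channel samples. g(x) = sum_n (2n+1)/(n(n+1))^m P_n(x)/4pi.
spline_transfer <- function(coords, good, bad, m = 4, n_terms = 50,
                            lambda = 1e-5) {
  u <- coords / sqrt(rowSums(coords^2))
  gfun <- function(cosang) {
    n <- seq_len(n_terms)
    p <- legendre_table(as.vector(cosang), n_terms)
    w <- (2 * n + 1) / (n * (n + 1))^m
    matrix(p %*% w / (4 * pi), nrow = nrow(cosang))
  }
  gg <- gfun(u[good, , drop = FALSE] %*% t(u[good, , drop = FALSE]))
  gb <- gfun(u[bad, , drop = FALSE] %*% t(u[good, , drop = FALSE]))
  ng <- length(good)
  a <- rbind(cbind(gg + lambda * diag(ng), rep(1, ng)),
             c(rep(1, ng), 0))
  ainv <- solve(a)
  cbind(gb, rep(1, length(bad))) %*% ainv[, seq_len(ng), drop = FALSE]
}

#' Repair bad channels by spherical-spline interpolation, or reject
#'
#' If more than `max_bads` channels are bad the whole session's trial set is
#' rejected (a [session_rejection] value is returned, not an error).
#' Otherwise each bad channel is replaced, sample by sample, by a
#' spherical-spline interpolation of the remaining channels using the scalp
#' coordinates carried by the trial set.
#'
#' @param trials A `trial_set`.
#' @param bads Character vector of bad channel labels.
#' @param max_bads Maximum number of repairable channels.
#' @return The repaired `trial_set`, or a `session_rejection`.
#' @export
repair_or_reject <- function(trials, bads, max_bads = 4L) {
  stopifnot(inherits(trials, "trial_set"))
  if (!all(bads %in% trials$channels))
    stop_labeled("bad_argument", "unknown channel(s): %s",
                 paste(setdiff(bads, trials$channels), collapse = ", "))
  if (length(bads) > max_bads)
    return(session_rejection(
      sprintf("%d bad channels (> %d)", length(bads), max_bads), bads))
  if (!length(bads)) return(trials)
  bad_i <- match(bads, trials$channels)
  good_i <- setdiff(seq_along(trials$channels), bad_i)
  tr <- spline_transfer(trials$channel_coords, good_i, bad_i)
  for (t in seq_len(dim(trials$data)[1]))
    trials$data[t, bad_i, ] <- tr %*% trials$data[t, good_i, , drop = TRUE]
  trials$log$repaired <- union(trials$log$repaired, bads)
  trials
}

#' Drop the highest-variance trials
#'
#' Ranks trials by total variance (per-trial channel variances summed over
#' channels) and removes the `n_drop` largest; ties are broken by dropping
#' the lowest trial index first. With the standard 10-trial input this leaves
#' 7 trials (28 s) per condition set.
#'
#' @param trials A `trial_set`.
#' @param n_drop Number of trials to remove.
#' @return The pruned `trial_set`; dropped indices are recorded in the log.
#' @export
prune_trials <- function(trials, n_drop = 3L) {
  stopifnot(inherits(trials, "trial_set"))
  n <- dim(trials$data)[1]
  if (n < n_drop + 1L)
    stop_labeled("too_few_trials", "cannot drop %d of %d trials", n_drop, n)
  tot <- rowSums(trial_channel_variance(trials))
  drop_idx <- order(-tot, seq_len(n))[seq_len(n_drop)]
  trials$log$dropped <- sort(drop_idx)
  trials$data <- trials$data[-drop_idx, , , drop = FALSE]
  trials
}

#' Apply an average-reference montage
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean is zero afterwards. Idempotent.
#'
#' @param trials A `trial_set` (>= 2 channels).
#' @return The re-referenced `trial_set`.
#' @export
average_reference <- function(trials) {
  stopifnot(inherits(trials, "trial_set"), dim(trials$data)[2] >= 2)
  for (t in seq_len(dim(trials$data)[1])) {
    x <- trials$data[t, , , drop = TRUE]
    trials$data[t, , ] <- sweep(x, 2, colMeans(x))
  }
  trials
}

#' Preprocess one session end to end
#'
#' Runs the full preprocessing chain: band-pass filter, trial extraction,
#' bad-channel detection (union across condition sets), spline repair or
#' session rejection, pruning of the three highest-variance trials, and
#' average re-referencing.
#'
#' @param session A `raw_session`.
#' @param conditions Conditions to keep.
#' @param hp_hz,lp_hz Filter cutoffs (Hz).
#' @param low,high,max_trials Bad-channel variance rule (see
#'   [detect_bad_channels()]).
#' @param max_bads Session-rejection threshold on bad-channel count.
#' @param n_drop Trials to prune per set.
#' @return Named list of cleaned `trial_set` objects, or a
#'   `session_rejection`.
#' @export
preprocess_session <- function(session, conditions = c("rest", "left"),
                               hp_hz = 4, lp_hz = 30,
                               low = 10, high = 250, max_trials = 3L,
                               max_bads = 4L, n_drop = 3L) {
  filtered <- bandpass_filter(session, hp_hz, lp_hz)
  sets <- extract_trials(filtered, conditions)
  bads <- unique(unlist(lapply(sets, detect_bad_channels,
                               low = low, high = high,
                               max_trials = max_trials)))
  if (length(bads) > max_bads)
    return(session_rejection(
      sprintf("%d bad channels (> %d)", length(bads), max_bads), bads))
  lapply(sets, function(ts) {
    ts <- repair_or_reject(ts, bads, max_bads)
    ts <- prune_trials(ts, n_drop)
    average_reference(ts)
  })
}
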