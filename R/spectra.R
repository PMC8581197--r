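.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal matrix
#' whose top eigenvectors are the DPSS, normalized to unit energy. Results
#' are cached per `(n, nw)`.
#'
#' @param n Sequence length.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (default `2*nw - 1`).
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 2, k = max(1L, floor(2 * nw - 1))) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  if (k < 1) stop_labeled("bad_taper", "need at least one taper")
  w <- nw / n
  i <- seq_len(n) - 1
  m <- diag(((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w))
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  m[cbind(1:(n - 1), 2:n)] <- off
  m[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(m, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                       # conventional polarity
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) { if (s < 0) tap[, j] <- -tap[, j] }
    else if (tap[2, j] - tap[1, j] < 0) tap[, j] <- -tap[, j]
  }
  .dpss_cache[[key]] <- tap
  tap
}

#' Multitaper cross-spectral density of a trial set
#'
#' Per-trial, per-taper Fourier cross-products averaged over tapers and
#' trials. With 4-s trials the frequency bin spacing is 1/4 = 0.25 Hz. The
#' density is one-sided and normalized so that its integral over all
#' frequencies equals the signal variance (Parseval scaling).
#'
#' @param trials A `trial_set`.
#' @param bandwidth_hz Half-bandwidth W of the tapers in Hz; the
#'   time-bandwidth product is `W * T` (default 0.5 Hz x 4 s = 2, three
#'   tapers).
#' @param freq_range Frequencies to retain, inclusive (Hz).
#' @return A `cross_spectra` object: complex array channels x channels x
#'   frequencies (`matrix`), `freqs`, `n_trials_used`, `condition`, `phase`,
#'   taper parameters.
#' @export
multitaper_cross_spectra <- function(trials, bandwidth_hz = 0.5,
                                     freq_range = c(4, 30)) {
  stopifnot(inherits(trials, "trial_set"))
  d <- dim(trials$data)
  n_trials <- d[1]; n_ch <- d[2]; n <- d[3]
  fs <- trials$sampling_rate
  nw <- bandwidth_hz * n / fs
  k <- as.integer(floor(2 * nw - 1))
  if (k < 1)
    stop_labeled("bad_taper",
                 "bandwidth %g Hz too small for one taper (need >= %g Hz)",
                 bandwidth_hz, fs / n)
  tap <- dpss_tapers(n, nw, k)
  freqs_all <- (seq_len(n) - 1) * fs / n
  sel <- which(freqs_all >= freq_range[1] - 1e-9 &
                 freqs_all <= freq_range[2] + 1e-9)
  freqs <- freqs_all[sel]
  # one-sided density scaling: x2 except at DC and Nyquist
  side <- ifelse(freqs > 1e-12 & abs(freqs - fs / 2) > 1e-12, 2, 1)

  nf <- length(sel)
  fcoef <- array(0i, dim = c(nf, n_ch, n_trials * k))
  slot <- 0L
  for (t in seq_len(n_trials)) {
    x <- t(trials$data[t, , , drop = TRUE])       # samples x channels
    for (j in seq_len(k)) {
      slot <- slot + 1L
      fcoef[, , slot] <- stats::mvfft(x * tap[, j])[sel, , drop = FALSE]
    }
  }
  s <- array(0i, dim = c(n_ch, n_ch, nf),
             dimnames = list(trials$channels, trials$channels, NULL))
  for (f in seq_len(nf)) {
    xf <- matrix(fcoef[f, , ], n_ch, n_trials * k)
    s[, , f] <- side[f] * (xf %*% Conj(t(xf))) / (n_trials * k * fs)
  }
  structure(list(matrix = s, freqs = freqs, n_trials_used = n_trials,
                 condition = trials$condition, phase = trials$phase,
                 subject_id = trials$subject_id,
                 sampling_rate = fs, nw = nw, n_tapers = k),
            class = "cross_spectra")
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat(sprintf(
    "Cross-spectra (%s, %s): %d channels, %d bins [%g, %g] Hz, %d tapers, %d trials\n",
    x$condition, x$phase, dim(x$matrix)[1], length(x$freqs),
    min(x$freqs), max(x$freqs), x$n_tapers, x$n_trials_used))
  invisible(x)
}

#' Average cross-spectra over a frequency band
#'
#' Arithmetic mean of the cross-spectral slices whose frequency lies in
#' `[band[1], band[2]]`, endpoints inclusive. On the 0.25 Hz grid the Mu band
#' 8-12 Hz averages 17 bins and the Beta band 18-26 Hz averages 33.
#'
#' @param cs A `cross_spectra`.
#' @param band Length-2 numeric, Hz.
#' @param label Optional band label.
#' @return A `band_matrix`: Hermitian channels x channels complex matrix with
#'   attributes `band`, `label`, `n_bins`.
#' @export
band_average <- function(cs, band, label = NULL) {
  stopifnot(inherits(cs, "cross_spectra"), length(band) == 2)
  sel <- which(cs$freqs >= band[1] - 1e-9 & cs$freqs <= band[2] + 1e-9)
  if (!length(sel))
    stop_labeled("empty_band", "no frequency bins in [%g, %g] Hz",
                 band[1], band[2])
  m <- apply(cs$matrix[, , sel, drop = FALSE], c(1, 2), mean)
  structure(m, band = band, label = label, n_bins = length(sel),
            condition = cs$condition, phase = cs$phase,
            class = c("band_matrix", class(m)))
}
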