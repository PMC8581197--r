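#' eLORETA inverse operator
#'
#' Builds the weighted L2 minimum-norm inverse operator for fixed-orientation
#' (scalar) sources via the eLORETA fixed-point weight iteration: with
#' average-referenced leadfield `K` and per-voxel weights `w`,
#' `C = pinv(K diag(1/w) K' + alpha H)` and `w_v <- sqrt(k_v' C k_v)` until
#' convergence; the kernel is `diag(1/w) K' C`. In the noiseless,
#' zero-regularization limit the resulting operator localizes any single
#' point source exactly (zero localization error), which is the defining
#' property of eLORETA. `weights = "uniform"` disables the iteration and
#' yields the classical minimum-norm operator instead.
#'
#' @param model A `head_model`.
#' @param alpha Regularization; default `reg_frac` times the mean eigenvalue
#'   of the sensor-space matrix `K K'`. Use 0 for the exact-localization
#'   limit.
#' @param reg_frac Fraction used for the default `alpha`.
#' @param weights `"eloreta"` (iterated) or `"uniform"` (minimum norm).
#' @param max_iter,tol Iteration controls (relative weight change).
#' @return An `inverse_operator`: list with `kernel` (voxels x channels),
#'   `weights`, `alpha`, `n_iter`, `channels`.
#' @export
eloreta_operator <- function(model, alpha = NULL, reg_frac = 1e-2,
                             weights = c("eloreta", "uniform"),
                             max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(model, "head_model"))
  weights <- match.arg(weights)
  n_ch <- nrow(model$leadfield)
  h <- diag(n_ch) - matrix(1 / n_ch, n_ch, n_ch)
  k <- h %*% model$leadfield                   # average-referenced leadfield
  if (is.null(alpha))
    alpha <- reg_frac * mean(eigen(tcrossprod(k), symmetric = TRUE,
                                   only.values = TRUE)$values)
  if (alpha < 0) stop_labeled("bad_argument", "alpha must be >= 0")
  n_vox <- ncol(k)
  w <- rep(1, n_vox)
  n_iter <- 0L
  if (weights == "eloreta") {
    repeat {
      n_iter <- n_iter + 1L
      c_mat <- sym_pinv(k %*% (t(k) / w) + alpha * h)
      w_new <- sqrt(pmax(colSums(k * (c_mat %*% k)), 0))
      w_new[w_new == 0] <- .Machine$double.eps
      delta <- max(abs(w_new - w) / w)
      w <- w_new
      if (delta < tol) break
      if (n_iter >= max_iter)
        stop_labeled("no_convergence",
                     "eLORETA weights not converged after %d iterations (last relative change %.2e)",
                     n_iter, delta)
    }
  }
  c_mat <- sym_pinv(k %*% (t(k) / w) + alpha * h)
  kernel <- (t(k) / w) %*% c_mat
  structure(list(kernel = kernel, weights = w, alpha = alpha,
                 n_iter = n_iter, channels = model$channel_names,
                 weighting = weights),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("Inverse operator (%s): %d voxels x %d channels, alpha=%.3g, %d iteration(s)\n",
              x$weighting, nrow(x$kernel), ncol(x$kernel), x$alpha, x$n_iter))
  invisible(x)
}

#' Voxel band power from a band cross-spectral matrix
#'
#' Power at voxel v is the quadratic form `m_v S m_v^H` of the kernel row
#' with the Hermitian band cross-spectrum, real and non-negative up to
#' numerical tolerance.
#'
#' @param op An `inverse_operator`.
#' @param band_cs A `band_matrix` (or Hermitian channels x channels matrix).
#' @param band,condition,phase,subject_id Metadata (taken from `band_cs`
#'   attributes when present).
#' @return A `source_estimate`: list with `power` (voxel vector), metadata,
#'   and `normalized = FALSE`.
#' @export
voxel_band_power <- function(op, band_cs,
                             band = attr(band_cs, "band"),
                             condition = attr(band_cs, "condition"),
                             phase = attr(band_cs, "phase"),
                             subject_id = NULL) {
  stopifnot(inherits(op, "inverse_operator"))
  s <- unclass(band_cs)
  attributes(s) <- attributes(s)["dim"]
  if (nrow(s) != ncol(op$kernel))
    stop_labeled("dimension_mismatch", "channel count mismatch (%d vs %d)",
                 nrow(s), ncol(op$kernel))
  if (max(Mod(s - Conj(t(s)))) > 1e-6 * max(Mod(s), 1e-300))
    stop_labeled("not_hermitian", "band cross-spectrum is not Hermitian")
  ks <- op$kernel %*% s
  p <- Re(rowSums(ks * Conj(op$kernel)))
  p[p < 0 & p > -1e-12 * max(abs(p))] <- 0
  structure(list(power = p, band = band, condition = condition,
                 phase = phase, subject_id = subject_id,
                 normalized = FALSE, norm_scalar = NA_real_),
            class = "source_estimate")
}

#' Subject-wise normalization of source estimates
#'
#' Divides every estimate by one scalar: the grand mean over all voxels,
#' bands and conditions supplied for the subject, so the grand mean of the
#' returned set is exactly 1.
#'
#' @param estimates List of `source_estimate` objects sharing a voxel grid.
#' @return List of normalized `source_estimate` objects (with `norm_scalar`
#'   recorded).
#' @export
normalize_subject <- function(estimates) {
  if (inherits(estimates, "source_estimate")) estimates <- list(estimates)
  stopifnot(all(vapply(estimates, inherits, TRUE, "source_estimate")))
  nv <- vapply(estimates, function(e) length(e$power), 1L)
  if (length(unique(nv)) != 1L)
    stop_labeled("dimension_mismatch", "estimates use different voxel grids")
  g <- mean(unlist(lapply(estimates, `[[`, "power")))
  if (g == 0) stop_labeled("degenerate", "grand mean of estimates is zero")
  lapply(estimates, function(e) {
    e$power <- e$power / g
    e$normalized <- TRUE
    e$norm_scalar <- g
    e
  })
}

#' Movement-minus-rest ERD contrast
#'
#' Elementwise difference of normalized voxel power, movement minus rest:
#' negative values mean less band power during movement, i.e.
#' event-related desynchronization.
#'
#' @param move,rest `source_estimate` objects on the same grid and band,
#'   normalized by the same subject scalar.
#' @return An `erd_map`: numeric voxel vector with metadata attributes.
#' @export
erd_contrast <- function(move, rest) {
  stopifnot(inherits(move, "source_estimate"),
            inherits(rest, "source_estimate"))
  if (length(move$power) != length(rest$power))
    stop_labeled("dimension_mismatch", "voxel grids differ (%d vs %d)",
                 length(move$power), length(rest$power))
  structure(move$power - rest$power,
            band = move$band, phase = move$phase,
            subject_id = move$subject_id, class = "erd_map")
}

#' Aggregate a voxel map into the ten ROI means
#'
#' Unweighted mean over the member voxels of each ROI; unlabeled voxels are
#' excluded.
#'
#' @param map An `erd_map`, `source_estimate`, or numeric voxel vector.
#' @param model The `head_model` carrying the atlas.
#' @return Named numeric vector `ROI1`..`ROI10`.
#' @export
roi_aggregate <- function(map, model) {
  stopifnot(inherits(model, "head_model"))
  v <- if (inherits(map, "source_estimate")) map$power else as.numeric(map)
  if (length(v) != length(model$atlas))
    stop_labeled("dimension_mismatch", "map length %d != %d voxels",
                 length(v), length(model$atlas))
  out <- vapply(1:10, function(r) {
    idx <- roi_voxels(model, r)
    if (!length(idx)) stop_labeled("empty_roi", "ROI%d has no voxels", r)
    mean(v[idx])
  }, 0)
  names(out) <- paste0("ROI", 1:10)
  out
}

#' ROI source time series from sensor trials
#'
#' Applies the inverse kernel sample by sample and reduces each ROI's member
#' voxel series to one series: the first principal component (sign-aligned
#' with the ROI mean series) or the plain mean.
#'
#' @param op An `inverse_operator`.
#' @param trials An average-referenced `trial_set`.
#' @param model The `head_model` carrying the atlas.
#' @param method `"pc"` (first principal component) or `"mean"`.
#' @return Array `10 x samples x trials` with attribute `sampling_rate`.
#' @export
roi_timeseries <- function(op, trials, model, method = c("pc", "mean")) {
  stopifnot(inherits(op, "inverse_operator"), inherits(trials, "trial_set"),
            inherits(model, "head_model"))
  method <- match.arg(method)
  if (nrow(op$kernel) != length(model$atlas))
    stop_labeled("dimension_mismatch",
                 "operator voxel count %d != atlas length %d",
                 nrow(op$kernel), length(model$atlas))
  d <- dim(trials$data)
  members <- lapply(1:10, function(r) roi_voxels(model, r))
  out <- array(0, dim = c(10L, d[3], d[1]))
  for (t in seq_len(d[1])) {
    v <- op$kernel %*% trials$data[t, , , drop = TRUE]
    for (r in 1:10) {
      vm <- v[members[[r]], , drop = FALSE]
      if (method == "mean" || nrow(vm) == 1L) {
        out[r, , t] <- colMeans(vm)
      } else {
        sv <- svd(vm, nu = 1, nv = 1)
        series <- sv$d[1] * sv$v[, 1]
        ref <- colMeans(vm)
        if (sum(series * ref) < 0) series <- -series
        out[r, , t] <- series
      }
    }
  }
  attr(out, "sampling_rate") <- trials$sampling_rate
  out
}
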