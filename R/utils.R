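# Internal numerical helpers.

#' Evaluate a deterministic or seeded expression without disturbing the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Moore-Penrose pseudo-inverse of a symmetric PSD matrix via eigendecomposition.
#' @noRd
sym_pinv <- function(m, tol = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  v <- e$vectors[, keep, drop = FALSE]
  v %*% (t(v) / e$values[keep])
}

#' Legendre polynomials P_1..P_nmax evaluated at x (vector), by recurrence.
#' Returns a length(x) x nmax matrix.
#' @noRd
legendre_table <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x))   # P_0
  p <- x                     # P_1
  out[, 1] <- p
  if (nmax >= 2) {
    for (n in 2:nmax) {
      pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
      out[, n] <- pn
      pm1 <- p
      p <- pn
    }
  }
  out
}

#' Spectral radius of the companion matrix of MVAR coefficient matrices.
#' @param a_list list of d x d coefficient matrices A_1..A_p
#' @noRd
companion_spectral_radius <- function(a_list) {
  p <- length(a_list)
  d <- nrow(a_list[[1L]])
  comp <- matrix(0, d * p, d * p)
  comp[seq_len(d), ] <- do.call(cbind, a_list)
  if (p > 1L)
    comp[(d + 1L):(d * p), seq_len(d * (p - 1L))] <- diag(d * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Sample variance along rows of a channels x samples matrix.
#' @noRd
row_variances <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m^2) - n * mu^2) / (n - 1)
}

stop_labeled <- function(label, fmt, ...) {
  stop(structure(
    class = c(label, "erdconnect_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
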