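#' Critical Student-t threshold
#'
#' Upper quantile of the Student t distribution for a significance level;
#' two-tailed tests use `alpha/2` per tail. At `alpha = 0.05` with 15
#' degrees of freedom (16 paired subjects) the two-tailed threshold is 2.13.
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @param tail `"two"` or `"one"`.
#' @return Numeric threshold.
#' @export
critical_t <- function(alpha = 0.05, df, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_labeled("bad_argument", "alpha must be in (0, 1)")
  if (df < 1) stop_labeled("bad_argument", "df must be >= 1")
  stats::qt(1 - alpha / if (tail == "two") 2 else 1, df)
}

#' Paired-sample t test
#'
#' Post-minus-Pre paired t statistic with df = n - 1, delegated to
#' [stats::t.test()]. `tail = "greater"` tests Post > Pre, `"less"` tests
#' Post < Pre.
#'
#' @param pre,post Numeric vectors of per-subject values (equal length,
#'   n >= 2).
#' @param tail `"two"`, `"greater"`, or `"less"`.
#' @return A `stat_result`: list with `statistic`, `df`, `p`, `tail`,
#'   `mean_diff`, `n`.
#' @export
paired_t <- function(pre, post, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  d <- post - pre
  if (stats::sd(d) <= 10 * .Machine$double.eps * max(abs(mean(d)), 1e-300))
    stop_labeled("zero_variance", "paired differences have zero variance")
  alt <- c(two = "two.sided", greater = "greater", less = "less")[[tail]]
  tt <- stats::t.test(post, pre, paired = TRUE, alternative = alt)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, tail = tail,
                 mean_diff = mean(d), n = length(d)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %g, p = %.4g (%s-tailed)\n",
              x$statistic, x$df, x$p, x$tail))
  if (!is.null(x$corrected_threshold))
    cat(sprintf("  max-statistic corrected |t| threshold: %.4f (%d permutations)\n",
                x$corrected_threshold, x$n_perm))
  invisible(x)
}

#' Voxel-wise paired comparison with sign-flip max-statistic correction
#'
#' Statistical nonparametric mapping: the observed paired-t map over voxels
#' is compared against the permutation null distribution of the maximum
#' absolute t obtained by randomly sign-flipping each subject's difference
#' map; the family-wise corrected threshold is the `1 - alpha` quantile of
#' that max-null. When `2^n` distinct sign patterns do not exceed `n_perm`
#' the enumeration is exhaustive (and seed-independent).
#'
#' @param pre_maps,post_maps subjects x voxels matrices.
#' @param n_perm Number of random sign flips (>= 100).
#' @param alpha Family-wise error level.
#' @param seed Integer seed for the random flips.
#' @return A `stat_result` with `statistic` (voxel t vector), `df`,
#'   `corrected_threshold`, `significant` (logical vector),
#'   `p_corrected` (per-voxel FWE-corrected p), `max_null`, `exhaustive`.
#' @export
snpm_voxelwise <- function(pre_maps, post_maps, n_perm = 1000L,
                           alpha = 0.05, seed = 1L) {
  stopifnot(is.matrix(pre_maps), all(dim(pre_maps) == dim(post_maps)))
  if (n_perm < 100) stop_labeled("bad_argument", "n_perm must be >= 100")
  d <- post_maps - pre_maps
  n <- nrow(d)
  tmap <- function(dd) {
    mu <- colMeans(dd)
    s <- sqrt((colSums(dd^2) - n * mu^2) / (n - 1))
    mu / (s / sqrt(n))
  }
  t_obs <- tmap(d)
  exhaustive <- 2^n <= n_perm
  signs <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    with_seed(seed,
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), ncol = n))
  }
  ss <- colSums(d^2)                    # invariant under sign flips
  mu_perm <- (signs %*% d) / n          # perms x voxels
  sd_perm <- sqrt(sweep(-n * mu_perm^2, 2, ss, `+`) / (n - 1))
  max_null <- apply(abs(mu_perm / (sd_perm / sqrt(n))), 1, max)
  thr <- stats::quantile(max_null, 1 - alpha, type = 1, names = FALSE)
  structure(list(statistic = t_obs, df = n - 1,
                 corrected_threshold = thr,
                 significant = abs(t_obs) > thr,
                 p_corrected = vapply(abs(t_obs),
                                      function(t0) mean(max_null >= t0), 0),
                 max_null = max_null, n_perm = nrow(signs),
                 exhaustive = exhaustive, alpha = alpha, tail = "two"),
            class = "stat_result")
}

#' Paired t masks for iCoh change, per directed pair and frequency
#'
#' Computes a paired t statistic (Post vs Pre, across subjects) for every
#' (sender, receiver, frequency) cell and thresholds it at a fixed critical
#' value (default 2.13, the two-tailed p = 0.05 critical t at df = 15),
#' uncorrected for multiple comparisons. The mask holds +1 for significant
#' increases, -1 for decreases, 0 otherwise.
#'
#' @param pre_icoh,post_icoh Lists (one `icoh_spectra` or array per subject)
#'   or 4-D arrays `subjects x senders x receivers x frequencies`.
#' @param threshold_t Critical |t|.
#' @return List with `t` (senders x receivers x frequencies), `mask` (same
#'   shape, values -1/0/+1), `threshold_t`, `df`, `freqs`.
#' @export
icoh_change_test <- function(pre_icoh, post_icoh, threshold_t = 2.13) {
  as4d <- function(x) {
    if (is.list(x)) {
      freqs <- attr(x[[1]], "freqs")
      arr <- array(0, dim = c(length(x), dim(x[[1]])))
      for (s in seq_along(x)) arr[s, , , ] <- unclass(x[[s]])
      attr(arr, "freqs") <- freqs
      arr
    } else x
  }
  pre <- as4d(pre_icoh); post <- as4d(post_icoh)
  if (!all(dim(pre) == dim(post)))
    stop_labeled("dimension_mismatch", "Pre and Post iCoh grids differ")
  n <- dim(pre)[1]
  d <- post - pre
  mu <- apply(d, c(2, 3, 4), mean)
  s <- apply(d, c(2, 3, 4), stats::sd)
  t_arr <- mu / (s / sqrt(n))
  t_arr[!is.finite(t_arr)] <- 0          # constant cells (e.g. diagonal)
  mask <- array(0L, dim = dim(t_arr))
  mask[t_arr > threshold_t] <- 1L
  mask[t_arr < -threshold_t] <- -1L
  list(t = t_arr, mask = mask, threshold_t = threshold_t, df = n - 1,
       freqs = attr(pre, "freqs"))
}

#' Pearson correlation with two-tailed p value
#'
#' Product-moment correlation via [stats::cor.test()] (t transform with
#' df = n - 2).
#'
#' @param x,y Numeric vectors, equal length n >= 3.
#' @return List with `r`, `p`, `df`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop_labeled("bad_argument", "need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_labeled("zero_variance", "zero variance input")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(x))
}

#' Voxel-wise correlation of a behavior change with ERD change maps
#'
#' Pearson r across subjects between a behavior change score and each
#' voxel's ERD change, with a magnitude threshold mask. With the ERD sign
#' convention (negative = stronger desynchronization), a behavior gain that
#' accompanies stronger desynchronization produces negative voxel r.
#'
#' @param behavior_change Numeric vector, one value per subject.
#' @param erd_change_maps subjects x voxels matrix of ERD change values.
#' @param r_threshold Mask threshold on |r|.
#' @return List with `r` (voxel vector), `mask` (logical), `r_threshold`.
#' @export
voxel_correlation_map <- function(behavior_change, erd_change_maps,
                                  r_threshold = 0.5) {
  stopifnot(is.matrix(erd_change_maps),
            length(behavior_change) == nrow(erd_change_maps))
  if (stats::sd(behavior_change) == 0)
    stop_labeled("zero_variance", "behavior change vector is constant")
  r <- suppressWarnings(
    as.vector(stats::cor(behavior_change, erd_change_maps)))
  r[!is.finite(r)] <- 0
  list(r = r, mask = abs(r) >= r_threshold, r_threshold = r_threshold)
}

#' Hand-grip score from three dynamometer trials
#'
#' The score is the arithmetic mean of exactly three non-negative maximal
#' grasp measurements, in pounds.
#'
#' @param measurements Numeric vector of length 3, lb.
#' @return Mean grip score (lb).
#' @export
grip_score <- function(measurements) {
  if (length(measurements) != 3)
    stop_labeled("bad_argument", "need exactly 3 measurements, got %d",
                 length(measurements))
  if (any(measurements < 0))
    stop_labeled("bad_argument", "grip measurements must be >= 0")
  mean(measurements)
}

#' Column means and sample SDs of a behavior table
#'
#' Arithmetic mean and sample (n-1) standard deviation of every numeric
#' column, rounded to `digits`.
#'
#' @param table Behavior data.frame (>= 2 rows).
#' @param digits Rounding digits.
#' @return data.frame with rows `mean` and `sd`, one column per numeric
#'   input column.
#' @export
summarize_behavior <- function(table, digits = 2) {
  stopifnot(is.data.frame(table), nrow(table) >= 2)
  num <- vapply(table, is.numeric, TRUE)
  num["subject_id"] <- FALSE
  if (!any(num)) stop_labeled("bad_argument", "no numeric columns")
  cols <- table[num]
  if (anyNA(cols)) stop_labeled("bad_argument", "non-numeric or missing cells")
  out <- rbind(mean = round(vapply(cols, mean, 0), digits),
               sd = round(vapply(cols, stats::sd, 0), digits))
  as.data.frame(out)
}

#' Bundled example cohort behavior table
#'
#' Per-subject behavior measures for an example cohort of 16 stroke
#' survivors with left-hand motor impairment (total brain-computer-interface
#' runs completed, average BCI performance out of 10, ARAT baseline and
#' change on the 0-57 scale, and grip dynamometry baseline and change in
#' pounds), shipped as plain CSV and used by examples and tests.
#'
#' @return data.frame with 16 rows.
#' @export
cohort_behavior <- function() {
  utils::read.csv(system.file("extdata", "cohort_behavior.csv",
                              package = "erdconnect"))
}
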