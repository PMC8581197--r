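#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end synthetic-cohort
#' analysis: cohort and head-model scale, preprocessing thresholds, analysis
#' bands, regularization, MVAR order policy, permutation count and seeds.
#' Round-trips losslessly through JSON ([config_to_json()]).
#'
#' @param n_subjects Cohort size.
#' @param n_voxels Source-grid size of the toy head model.
#' @param montage Electrode labels.
#' @param sampling_rate Hz.
#' @param hp_hz,lp_hz Band-pass cutoffs (Hz).
#' @param var_low,var_high,max_bad_trials,max_bad_channels,n_drop
#'   Preprocessing variance rules (uV^2 window, tolerated out-of-window
#'   trials, session-rejection channel count, trials pruned per set).
#' @param bands Analysis bands (Hz).
#' @param reg_frac eLORETA regularization fraction.
#' @param mvar_order `"aic"`, `"bic"`, or a fixed integer order. AIC is the
#'   default because the simulated sources (narrow-band oscillators plus
#'   broadband noise) have no finite true order and BIC under-fits their
#'   spectra.
#' @param mvar_p_max Largest order tried under `"aic"`/`"bic"`.
#' @param n_perm Permutations for the voxel-wise SnPM test.
#' @param alpha Significance level.
#' @param threshold_t Critical |t| for the per-frequency iCoh change masks.
#' @param behavior_target_r Population correlation between measured ERD
#'   change (negative = stronger desynchronization Post) and simulated grip
#'   change; negative by default so that grip gains accompany stronger
#'   desynchronization.
#' @param erd_pre,erd_post Movement Mu-band amplitude multipliers for ROI 7
#'   and ROI 8 in the Pre and Post phases.
#' @param coupling_pre,coupling_post ROI7 -> ROI9 Mu coupling coefficients.
#'   The Pre default is 0 (no edge): iCoh normalizes the cross term by the
#'   sender's self-spectrum, which nearly vanishes at the oscillator
#'   resonance, so iCoh saturates for even small nonzero coefficients there
#'   and a Pre-to-Post *increase* is only expressible from a zero baseline.
#' @param erd_sd Between-subject SD of the multipliers.
#' @param snr Sensor signal-to-noise ratio.
#' @param artifacts Optional named list `subject_id -> list(phase,
#'   bad_channels, outlier_trials)` applied before preprocessing.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 16L, n_voxels = 500L,
                            montage = default_montage(),
                            sampling_rate = 256,
                            hp_hz = 4, lp_hz = 30,
                            var_low = 10, var_high = 250,
                            max_bad_trials = 3L, max_bad_channels = 4L,
                            n_drop = 3L,
                            bands = list(mu = c(8, 12), beta = c(18, 26)),
                            reg_frac = 1e-2,
                            mvar_order = "aic", mvar_p_max = 20L,
                            n_perm = 1000L, alpha = 0.05,
                            threshold_t = 2.13,
                            behavior_target_r = -0.435,
                            erd_pre = c(roi7 = 0.8, roi8 = 0.85),
                            erd_post = c(roi7 = 0.5, roi8 = 0.65),
                            coupling_pre = 0, coupling_post = 0.3,
                            erd_sd = 0.08, snr = 5,
                            artifacts = NULL, seed = 1L) {
  stopifnot(var_low > 0, var_high > var_low, n_drop >= 1,
            all(vapply(bands, function(b) b[1] >= 4 && b[2] <= 30, TRUE)))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration as JSON
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `config_from_json` returns the restored `pipeline_config`.
#' @export
config_to_json <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$erd_pre <- as.list(x$erd_pre)      # keep names through JSON
  x$erd_post <- as.list(x$erd_post)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$bands <- lapply(raw$bands, as.numeric)
  raw$erd_pre <- unlist(raw$erd_pre)
  raw$erd_post <- unlist(raw$erd_post)
  if (!length(raw$artifacts)) raw$artifacts <- NULL
  do.call(pipeline_config, raw)
}

# Per-subject scenario with jittered ERD multipliers for one phase.
subject_scenario <- function(config, phase, subject_seed) {
  erd0 <- if (phase == "Pre") config$erd_pre else config$erd_post
  coup <- if (phase == "Pre") config$coupling_pre else config$coupling_post
  with_seed(subject_seed, {
    mult <- pmax(0.1, erd0 + rnorm(2, sd = config$erd_sd))
    sim_scenario(
      coupling = data.frame(from = 7L, to = 9L, lag = 2L, coef = coup,
                            band = "mu"),
      erd = data.frame(roi = c(7L, 8L), band = "mu", multiplier = mult),
      snr = config$snr, sampling_rate = config$sampling_rate,
      bands = config$bands,
      seed = subject_seed)
  })
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a cohort of screening sessions (Pre and Post) from the
#' configured scenarios, then runs preprocessing, multitaper cross-spectra,
#' eLORETA band power with subject-wise normalization, movement-minus-rest
#' ERD contrasts with ROI aggregation, ROI-series MVAR + iCoh per phase, and
#' the statistical layer (ROI paired t, voxel-wise sign-flip max-statistic
#' correction, per-frequency and band-mean iCoh change masks, behavior
#' correlation). Deterministic for a fixed config seed.
#'
#' @param config A `pipeline_config`.
#' @param progress Print per-subject progress lines.
#' @return A `pipeline_report` list; see the elements `roi_erd`, `roi_tests`,
#'   `snpm`, `icoh_change`, `icoh_band_tests`, `behavior`, `behavior_cor`,
#'   `voxel_cor`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- toy_head_model(config$n_voxels, config$montage)
  op <- eloreta_operator(model, reg_frac = config$reg_frac)
  phases <- c("Pre", "Post")
  subj_seeds <- with_seed(config$seed,
    matrix(sample.int(2^30, config$n_subjects * 2L), ncol = 2L,
           dimnames = list(NULL, phases)))

  erd_roi <- list(Pre = NULL, Post = NULL)   # subjects x 10
  erd_vox <- list(Pre = NULL, Post = NULL)   # subjects x voxels
  icoh_arr <- list(Pre = list(), Post = list())
  manifest <- list(seed = config$seed, n_voxels = config$n_voxels,
                   rejected = character(0), repaired = list(),
                   dropped = list(), mvar_orders = list())
  kept <- logical(config$n_subjects)

  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    res <- list()
    rejected <- FALSE
    for (ph in phases) {
      sc <- subject_scenario(config, ph, subj_seeds[s, ph])
      ses <- simulate_session(model, sc, phase = ph, subject_id = sid,
                              conditions = c("rest", "left"),
                              seed = subj_seeds[s, ph])
      art <- config$artifacts[[sid]]
      if (!is.null(art) && (is.null(art$phase) || art$phase == ph))
        ses <- inject_artifacts(ses,
                                bad_channels = art$bad_channels %||% character(0),
                                outlier_trials = art$outlier_trials %||% integer(0),
                                seed = subj_seeds[s, ph])
      sets <- preprocess_session(ses, conditions = c("rest", "left"),
                                 hp_hz = config$hp_hz, lp_hz = config$lp_hz,
                                 low = config$var_low, high = config$var_high,
                                 max_trials = config$max_bad_trials,
                                 max_bads = config$max_bad_channels,
                                 n_drop = config$n_drop)
      if (is_rejected(sets)) {
        manifest$rejected <- c(manifest$rejected, sprintf("%s/%s", sid, ph))
        rejected <- TRUE
        break
      }
      for (cond in names(sets)) {
        lg <- sets[[cond]]$log
        if (length(lg$repaired))
          manifest$repaired[[sprintf("%s/%s/%s", sid, ph, cond)]] <- lg$repaired
        manifest$dropped[[sprintf("%s/%s/%s", sid, ph, cond)]] <- lg$dropped
      }
      res[[ph]] <- sets
    }
    if (rejected) next
    kept[s] <- TRUE

    # band power estimates across phase x condition, one normalization scalar
    est <- list()
    for (ph in phases) for (cond in c("rest", "left")) for (b in names(config$bands)) {
      cs <- multitaper_cross_spectra(res[[ph]][[cond]])
      bm <- band_average(cs, config$bands[[b]], label = b)
      est[[paste(ph, cond, b, sep = ".")]] <-
        voxel_band_power(op, bm, subject_id = sid)
    }
    est <- normalize_subject(est)
    for (ph in phases) {
      con <- erd_contrast(est[[paste(ph, "left", "mu", sep = ".")]],
                          est[[paste(ph, "rest", "mu", sep = ".")]])
      erd_vox[[ph]] <- rbind(erd_vox[[ph]], as.numeric(con))
      erd_roi[[ph]] <- rbind(erd_roi[[ph]], roi_aggregate(con, model))
      series <- roi_timeseries(op, res[[ph]][["left"]], model)
      ord <- if (config$mvar_order %in% c("aic", "bic"))
        select_order(series, config$mvar_p_max,
                     criterion = config$mvar_order)
      else as.integer(config$mvar_order)
      manifest$mvar_orders[[sprintf("%s/%s", sid, ph)]] <- ord
      mv <- fit_mvar(series, ord)
      icoh_arr[[ph]][[sid]] <- icoh(mv)
    }
    if (progress) message(sid, " done")
  }

  n_kept <- sum(kept)
  if (n_kept < 3)
    stop_labeled("pipeline_failed", "only %d subjects survived preprocessing",
                 n_kept)

  roi_tests <- lapply(1:10, function(r)
    paired_t(erd_roi$Pre[, r], erd_roi$Post[, r], tail = "less"))
  names(roi_tests) <- paste0("ROI", 1:10)
  snpm <- snpm_voxelwise(erd_vox$Pre, erd_vox$Post, n_perm = config$n_perm,
                         alpha = config$alpha,
                         seed = with_seed(config$seed, sample.int(2^30, 1)))
  icoh_change <- icoh_change_test(icoh_arr$Pre, icoh_arr$Post,
                                  threshold_t = config$threshold_t)
  icoh_band_tests <- lapply(config$bands, function(b) {
    pre <- t(vapply(icoh_arr$Pre, function(a) as.vector(band_mean_icoh(a, b)),
                    numeric(100)))
    post <- t(vapply(icoh_arr$Post, function(a) as.vector(band_mean_icoh(a, b)),
                     numeric(100)))
    tt <- rep(0, 100)
    for (k in seq_len(100))
      tt[k] <- if (stats::sd(post[, k] - pre[, k]) > 0)
        (mean(post[, k]) - mean(pre[, k])) /
          (stats::sd(post[, k] - pre[, k]) / sqrt(n_kept)) else 0
    list(t = matrix(tt, 10, 10),
         mask = matrix(as.integer(tt > config$threshold_t) -
                         as.integer(tt < -config$threshold_t), 10, 10))
  })

  erd7_change <- erd_roi$Post[, 7] - erd_roi$Pre[, 7]
  behavior <- generate_behavior_table(
    n_kept, target_r = config$behavior_target_r,
    erd_change = erd7_change,
    seed = with_seed(config$seed, sample.int(2^30, 1) + 1L))
  behavior_cor <- pearson_r(behavior$grip_change_lb, erd7_change)
  voxel_cor <- voxel_correlation_map(behavior$grip_change_lb,
                                     erd_vox$Post - erd_vox$Pre)

  structure(list(
    config = config, model = model,
    roi_erd = list(Pre = erd_roi$Pre, Post = erd_roi$Post),
    erd_maps = erd_vox,
    roi_tests = roi_tests, snpm = snpm,
    icoh = icoh_arr, icoh_change = icoh_change,
    icoh_band_tests = icoh_band_tests,
    behavior = behavior, behavior_cor = behavior_cor,
    voxel_cor = voxel_cor,
    manifest = manifest, n_kept = n_kept),
    class = "pipeline_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d/%d subjects analyzed, %d voxels\n",
              x$n_kept, x$config$n_subjects, x$config$n_voxels))
  if (length(x$manifest$rejected))
    cat("  rejected sessions:", paste(x$manifest$rejected, collapse = ", "), "\n")
  p <- vapply(x$roi_tests, `[[`, 0, "p")
  cat("  ROI one-tailed p (Post ERD > Pre):",
      paste(sprintf("%s=%.3f", names(p), p), collapse = " "), "\n")
  cat(sprintf("  behavior correlation r = %.3f (p = %.3g)\n",
              x$behavior_cor$r, x$behavior_cor$p))
  invisible(x)
}

#' Write the report bundle to disk
#'
#' CSV tables (ROI ERD values, ROI tests, band-mean iCoh change masks,
#' behavior) plus a JSON manifest of seeds, repaired channels, dropped
#' trials and rejected sessions.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ph in c("Pre", "Post"))
    utils::write.csv(as.data.frame(report$roi_erd[[ph]]),
                     file.path(dir, sprintf("roi_erd_%s.csv", ph)),
                     row.names = FALSE)
  tests <- data.frame(
    roi = names(report$roi_tests),
    t = vapply(report$roi_tests, `[[`, 0, "statistic"),
    df = vapply(report$roi_tests, `[[`, 0, "df"),
    p = vapply(report$roi_tests, `[[`, 0, "p"))
  utils::write.csv(tests, file.path(dir, "roi_tests.csv"), row.names = FALSE)
  for (b in names(report$icoh_band_tests)) {
    m <- report$icoh_band_tests[[b]]$mask
    dimnames(m) <- list(sender = paste0("ROI", 1:10),
                        receiver = paste0("ROI", 1:10))
    utils::write.csv(m, file.path(dir, sprintf("icoh_change_mask_%s.csv", b)))
  }
  write_behavior_table(report$behavior, file.path(dir, "behavior.csv"))
  jsonlite::write_json(
    c(report$manifest,
      list(n_kept = report$n_kept,
           behavior_r = report$behavior_cor$r,
           behavior_p = report$behavior_cor$p,
           snpm_threshold = report$snpm$corrected_threshold)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
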