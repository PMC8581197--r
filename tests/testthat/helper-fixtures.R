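# Shared fixtures, built once per test run.

# Small head model used throughout: 120 voxels keeps every ROI populated
# while staying fast.
small_model <- local({
  hm <- NULL
  function() {
    if (is.null(hm)) hm <<- toy_head_model(n_voxels = 120)
    hm
  }
})

# Default-scale model (500 voxels) with its eLORETA operator, for
# closed-loop source-recovery checks.
full_model <- local({
  env <- NULL
  function() {
    if (is.null(env)) {
      hm <- toy_head_model(n_voxels = 500)
      env <<- list(model = hm, op = eloreta_operator(hm))
    }
    env
  }
})

# 100-voxel single-shell model for exhaustive localization loops.
loc_model <- local({
  hm <- NULL
  function() {
    if (is.null(hm)) hm <<- toy_head_model(n_voxels = 100, shells = 0.85,
                                           shell_frac = 1)
    hm
  }
})

# Build a trial_set directly from a trials x channels x samples array.
make_trial_set <- function(data, fs = 256, condition = "rest", phase = "Pre",
                           channels = NULL, coords = NULL) {
  n_ch <- dim(data)[2]
  if (is.null(channels)) channels <- default_montage()[seq_len(n_ch)]
  if (is.null(coords)) {
    mon <- montage_1020()
    coords <- as.matrix(mon[match(channels, mon$label), c("x", "y", "z")])
  }
  erdconnect:::new_trial_set(data, condition, phase, "S01", fs,
                             channels, coords)
}

# Build a raw_session directly from a channels x samples matrix plus events.
make_session <- function(data, events, fs = 256, phase = "Pre",
                         channels = NULL) {
  if (is.null(channels)) channels <- default_montage()[seq_len(nrow(data))]
  mon <- montage_1020()
  coords <- as.matrix(mon[match(channels, mon$label), c("x", "y", "z")])
  structure(list(data = data, events = events, phase = phase,
                 subject_id = "S01", sampling_rate = fs,
                 channels = channels, channel_coords = coords,
                 ground_truth = NULL), class = "raw_session")
}

# Simulate a stable MVAR with a plain R loop: an oracle generator kept
# deliberately independent of the package's vectorized simulator.
mvar_sim_oracle <- function(a_list, n, d = nrow(a_list[[1]]), sd = 1,
                            burn = 200) {
  p <- length(a_list)
  x <- matrix(0, d, n + burn + p)
  for (t in (p + 1):(n + burn + p)) {
    x[, t] <- rnorm(d, sd = sd)
    for (k in seq_len(p)) x[, t] <- x[, t] + a_list[[k]] %*% x[, t - k]
  }
  x[, (burn + p + 1):(n + burn + p), drop = FALSE]
}
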