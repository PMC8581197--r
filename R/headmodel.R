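#' Idealized spherical 10-10 electrode coordinate table
#'
#' Electrode positions are constructed geometrically on a unit sphere from the
#' 10-10 grid rules: each label lies at the intersection of an
#' anterior-posterior row arc (Fp, AF, F, FC, C, CP, P, PO, O at 72, 54, 36,
#' 18, 0, -18, -36, -54, -72 degrees from the vertex) and a lateral arc (18
#' degrees per electrode step, odd numerals left, even right; `z` on the
#' midline). The axes follow the RAS convention: +x right, +y anterior, +z up.
#' This is an idealized montage for the built-in spherical head model, not a
#' digitized cap.
#'
#' @return A data.frame with columns `label`, `x`, `y`, `z` (unit sphere).
#' @export
montage_1020 <- function() {
  rows <- c(Fp = 72, AF = 54, F = 36, FC = 18, C = 0,
            CP = -18, P = -36, PO = -54, O = -72)
  labs <- character(0); ap <- numeric(0); lat <- numeric(0)
  for (r in names(rows)) {
    for (num in c("z", as.character(1:8))) {
      labs <- c(labs, paste0(r, num))
      ap <- c(ap, rows[[r]])
      lat <- c(lat, if (num == "z") 0 else {
        n <- as.integer(num)
        18 * ceiling(n / 2) * if (n %% 2 == 1L) -1 else 1
      })
    }
  }
  # 10-20 temporal-chain names on the central row
  labs <- c(labs, "T7", "T8"); ap <- c(ap, 0, 0); lat <- c(lat, -72, 72)
  a <- ap * pi / 180; b <- lat * pi / 180
  data.frame(label = labs,
             x = sin(b) * cos(a),
             y = sin(a),
             z = cos(b) * cos(a),
             stringsAsFactors = FALSE)
}

#' Default 16-channel sensorimotor montage
#'
#' The central-parietal 16-electrode subset used throughout the package:
#' F5, F6, FC1, FC2, C5, C3, Cz, C4, C6, CP1, CP2, P5, P3, Pz, P4, P6.
#'
#' @return Character vector of 16 electrode labels.
#' @export
default_montage <- function() {
  c("F5", "F6", "FC1", "FC2", "C5", "C3", "Cz", "C4", "C6",
    "CP1", "CP2", "P5", "P3", "Pz", "P4", "P6")
}

#' Descriptive labels for the ten sensorimotor regions of interest
#'
#' ROIs 1-5 are left-hemisphere, 6-10 right-hemisphere, each pairing a
#' Brodmann-style sensorimotor parcel: BA 1-3 (primary somatosensory), BA 4
#' (primary motor), BA 5 (somatosensory association), BA 6 (premotor), BA 7
#' (visuomotor coordination).
#'
#' @return Named character vector of length 10 (names `ROI1`..`ROI10`).
#' @export
roi_labels <- function() {
  base <- c("BA 1-3 (primary somatosensory)", "BA 4 (primary motor)",
            "BA 5 (somatosensory association)", "BA 6 (premotor)",
            "BA 7 (visuomotor coordination)")
  out <- c(paste("left", base), paste("right", base))
  names(out) <- paste0("ROI", 1:10)
  out
}

# Angular sector (degrees) of each parcel along the anterior-posterior arc,
# measured from the vertex (positive = anterior). Order: BA1-3, BA4, BA5,
# BA6, BA7 -> ROI offsets 1..5 within a hemisphere.
roi_sectors <- function() {
  list(lo = c(-8, 2, -20, 12, -52),
       hi = c(2, 12, -8, 40, -20))
}

#' Build a toy spherical head model
#'
#' Constructs an analytic single-sphere forward model: radial current dipoles
#' on one or two cortical shells inside a unit-radius homogeneous conducting
#' sphere, with electrode potentials given by the Legendre series solution for
#' a radial dipole. Voxels are placed deterministically on each shell with a
#' Fibonacci lattice restricted to the upper hemisphere, and outer-shell
#' voxels are labeled with ten sensorimotor regions of interest (ROI 1-5 left,
#' ROI 6-10 right) defined by angular sectors approximating pre/post-central
#' topography; remaining voxels (midline strip, far lateral rim, deep shell)
#' are unlabeled.
#'
#' @param n_voxels Total number of source voxels (>= 20).
#' @param electrodes Character vector of electrode labels drawn from
#'   [montage_1020()]; defaults to the 16-channel set of [default_montage()].
#' @param shells Radii of the source shells as fractions of the head radius.
#'   The first (outermost) shell carries the ROI atlas.
#' @param shell_frac Fraction of voxels allocated to each shell.
#' @param n_terms Number of Legendre terms in the potential series.
#' @return An object of class `head_model`: list with `leadfield`
#'   (channels x voxels, scaled so the mean column norm is 1),
#'   `voxel_coords` (voxels x 3), `atlas` (integer 1-10 or `NA` per voxel),
#'   `channel_names`, `channel_coords`.
#' @examples
#' hm <- toy_head_model(n_voxels = 120)
#' table(hm$atlas)
#' @export
toy_head_model <- function(n_voxels = 500,
                           electrodes = default_montage(),
                           shells = c(0.85, 0.60),
                           shell_frac = c(0.8, 0.2),
                           n_terms = 200) {
  if (n_voxels < 20)
    stop_labeled("bad_argument", "n_voxels must be >= 20, got %d", n_voxels)
  mon <- montage_1020()
  unknown <- setdiff(electrodes, mon$label)
  if (length(unknown))
    stop_labeled("unknown_electrode", "unknown electrode label(s): %s",
                 paste(unknown, collapse = ", "))
  if (anyDuplicated(electrodes))
    stop_labeled("bad_argument", "duplicated electrode labels")
  epos <- as.matrix(mon[match(electrodes, mon$label), c("x", "y", "z")])
  rownames(epos) <- electrodes

  stopifnot(length(shells) == length(shell_frac), all(shells > 0 & shells < 1))
  shell_frac <- shell_frac / sum(shell_frac)
  counts <- round(n_voxels * shell_frac)
  counts[1] <- n_voxels - sum(counts[-1])

  coords <- NULL
  shell_id <- integer(0)
  golden <- pi * (3 - sqrt(5))
  for (s in seq_along(shells)) {
    n <- counts[s]
    i <- seq_len(n)
    cz <- (i - 0.5) / n          # cos(theta), upper hemisphere
    st <- sqrt(1 - cz^2)
    phi <- i * golden
    coords <- rbind(coords, shells[s] * cbind(st * cos(phi), st * sin(phi), cz))
    shell_id <- c(shell_id, rep.int(s, n))
  }
  colnames(coords) <- c("x", "y", "z")

  atlas <- rep(NA_integer_, n_voxels)
  u <- coords / sqrt(rowSums(coords^2))
  ap <- atan2(u[, 2], u[, 3]) * 180 / pi      # anterior-posterior angle
  lat <- asin(pmin(1, abs(u[, 1]))) * 180 / pi
  sec <- roi_sectors()
  eligible <- shell_id == 1L & lat >= 6 & lat <= 65
  for (k in 1:5) {
    in_sec <- eligible & ap > sec$lo[k] & ap <= sec$hi[k]
    atlas[in_sec & u[, 1] < 0] <- k
    atlas[in_sec & u[, 1] > 0] <- k + 5L
  }
  missing <- setdiff(1:10, unique(atlas[!is.na(atlas)]))
  if (length(missing))
    stop_labeled("atlas_unpopulated",
                 "cannot populate 10 ROIs with n_voxels=%d (empty: %s)",
                 n_voxels, paste0("ROI", missing, collapse = ", "))

  lf <- radial_dipole_leadfield(epos, coords, n_terms)
  lf <- lf / mean(sqrt(colSums(lf^2)))
  dimnames(lf) <- list(electrodes, NULL)

  structure(list(leadfield = lf,
                 voxel_coords = coords,
                 atlas = atlas,
                 channel_names = electrodes,
                 channel_coords = epos,
                 shells = shells,
                 shell_id = shell_id),
            class = "head_model")
}

# Surface potential of radial dipoles in a homogeneous unit sphere:
# V(gamma) proportional to sum_n (2n+1) f^(n-1) P_n(cos gamma), with f the
# source radius fraction and gamma the angle between source and electrode.
radial_dipole_leadfield <- function(epos, coords, n_terms) {
  r <- sqrt(rowSums(coords^2))
  u <- coords / r
  cosg <- epos %*% t(u)                     # channels x voxels
  lf <- matrix(0, nrow(epos), nrow(coords))
  pm1 <- matrix(1, nrow(epos), nrow(coords))  # P_0
  p <- cosg                                   # P_1
  fpow <- rep(1, nrow(coords))                # f^(n-1)
  for (n in seq_len(n_terms)) {
    lf <- lf + (2 * n + 1) * sweep(p, 2, fpow, `*`)
    fpow <- fpow * r
    pn <- ((2 * n + 1) * cosg * p - n * pm1) / (n + 1)
    pm1 <- p
    p <- pn
  }
  lf
}

#' @export
print.head_model <- function(x, ...) {
  cat("Toy spherical head model\n")
  cat(sprintf("  %d channels: %s\n", length(x$channel_names),
              paste(x$channel_names, collapse = " ")))
  cat(sprintf("  %d voxels on shell(s) %s; %d labeled across 10 ROIs\n",
              ncol(x$leadfield), paste(x$shells, collapse = ", "),
              sum(!is.na(x$atlas))))
  invisible(x)
}

#' Indices of the voxels belonging to one ROI
#' @param model A `head_model`.
#' @param roi ROI number in 1..10.
#' @return Integer vector of voxel indices.
#' @export
roi_voxels <- function(model, roi) {
  stopifnot(inherits(model, "head_model"), roi %in% 1:10)
  which(!is.na(model$atlas) & model$atlas == roi)
}
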