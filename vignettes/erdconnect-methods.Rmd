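---
title: "Sensorimotor ERD and directed connectivity: models and methods"
author: "erdconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensorimotor ERD and directed connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erdconnect)
```

## The scientific problem

After a stroke, voluntary movement of the impaired hand is accompanied by
*event-related desynchronization* (ERD): a drop in the power of the Mu
rhythm (8–12 Hz) and Beta band (18–26 Hz) over sensorimotor cortex.
Rehabilitation protocols that couple a brain–computer interface to
functional electrical stimulation aim to strengthen this modulation, and two
electrophysiological questions follow:

1. **Where** does Mu ERD during impaired-hand movement localize on the
   cortex, and does its change from a Pre to a Post screening session track
   behavioral recovery (grip strength)?
2. Does the intervention change the **directed** coupling between
   sensorimotor areas, measured as frequency-resolved isolated effective
   coherence (iCoh) between ten regions of interest (ROIs) paired across
   hemispheres: BA 1–3, BA 4, BA 5, BA 6 and BA 7?

`erdconnect` implements the full analysis chain for 16-channel scalp EEG —
preprocessing, multitaper cross-spectra, an eLORETA inverse solution,
ROI-level ERD contrasts, MVAR/iCoh connectivity, and the statistical layer —
together with a forward simulator that generates sessions with *known*
ground truth, so that every stage is testable end to end without any
recorded data.

## The forward model

### Head model

The head is a homogeneous unit sphere. Electrodes sit at idealized 10-10
positions built from the grid rules (rows Fp…O at 72°…−72° from the vertex
along the anterior–posterior arc, 18° lateral steps); the default montage is
the 16-channel sensorimotor set F5, F6, FC1, FC2, C5, C3, Cz, C4, C6, CP1,
CP2, P5, P3, Pz, P4, P6. Sources are radial current dipoles on one or two
interior shells (default radii 0.85 and 0.60, with 80% of voxels on the
outer shell), laid out deterministically with a Fibonacci lattice on the
upper hemisphere. The potential of a radial dipole in a conducting sphere
has the classical Legendre series solution

$$V(\gamma) \propto \sum_{n\ge1} (2n+1)\, f^{\,n-1} P_n(\cos\gamma),$$

with $f$ the source radius fraction and $\gamma$ the source–electrode angle;
the series is truncated at 200 terms (the tail is $O(f^{200})\approx
10^{-12}$). The ten ROIs are angular sectors of the outer shell
approximating pre/post-central topography (per hemisphere, from anterior to
posterior: BA 6, BA 4, BA 1–3, BA 5, BA 7), with a midline strip, the far
lateral rim and the deep shell left unlabeled. This toy geometry preserves
what the analysis actually uses — left/right symmetry, anterior/posterior
ordering and a narrow primary-motor strip — while staying closed-form and
fast; it does not attempt realistic conductor geometry (skull, CSF) or an
anatomical atlas.

### Source dynamics

Each band (Mu, Beta) is generated by a 10-dimensional multivariate
autoregressive (MVAR) process: the diagonal holds AR(2) resonators with pole
radius $\rho$ at the band's center frequency (defaults: 10 Hz with $\rho =
0.96$, giving a ~3 Hz-wide Mu peak; 22 Hz with $\rho = 0.94$), and directed
coupling edges (sender, receiver, lag, coefficient) enter the off-diagonal
lag matrices. Scenarios are validated by the companion-matrix spectral
radius; anything $\ge 1$ is refused with the radius named in the error.
Band outputs are rescaled to unit stationary standard deviation at rest
(computed from the spectral integral of the fitted transfer function), so an
ERD multiplier $m$ applied during movement scales band amplitude by exactly
$m$ and band power by $m^2$. Each ROI source is the sum of its Mu component,
Beta component and white background noise (sd 0.3).

The default cohort scenario emulates the phenomenology the pipeline is
designed to detect in a right-lesioned cohort: movement-related Mu ERD in
right BA 4 (ROI 7) and right BA 5 (ROI 8), and a Mu-band directed edge from
right BA 4 to right premotor cortex (ROI 9) that strengthens from Pre to
Post.

### Projection and noise

ROI sources are assigned coherently to all member voxels (effective
leadfield = mean of member columns) and scaled to microvolts. Two noise
terms are added: spatially distributed background activity — independent
noise at *every* voxel with per-voxel sd `brain_noise_sd / sqrt(n_voxels)`,
projected through the leadfield, which gives every channel a comparable
floor regardless of grid resolution — and white sensor noise scaled so the
clean-signal RMS over noise RMS equals `snr` (default 5). The combined gain
and floor are calibrated so clean channels show in-band per-trial variances
of roughly 15–150 µV², comfortably inside the (10, 250) µV² screening
window used by the bad-channel rule: the simulator's artifacts, not its
healthy channels, should trip that rule.

Sessions follow the screening layout: 2 runs × 5 trials per condition in
seeded random order, 4-s trials, 1-s gaps, 10 trials per condition per
phase. The sampling rate defaults to 256 Hz (1024 samples per trial, a
power of two, typical for this amplifier class), and with 4-s trials the
spectral grid spacing is exactly 1/4 s = 0.25 Hz.

## Preprocessing

The chain mirrors standard sensorimotor-EEG practice: (1) 4–30 Hz band-pass
(4th-order Butterworth run forward–backward, so zero phase and no event
latency shift); (2) trial extraction and grouping by condition (rest and
impaired-hand movement by default); (3) variance screening — a channel is
bad if its per-trial variance leaves [10, 250] µV² in strictly more than 3
trials; bad channels are repaired by spherical-spline interpolation
(Perrin-style, order $m=4$, 50 Legendre terms, ridge $10^{-5}$) unless more
than 4 are bad, in which case the session is *rejected* — a value, not an
exception, so cohort runs continue; then the 3 highest-total-variance trials
are dropped (ties broken toward the lowest index, for determinism), leaving
7 trials = 28 s per condition set; (4) average re-referencing. Variance is
the n−1 sample convention, computed after filtering (the step order implies
screening operates on the analysis band). Detection runs per condition set
and the union of flagged channels is repaired consistently across sets.

A practical note on repair: spline interpolation reconstructs *smooth*
scalp fields almost perfectly, but topographies from single shallow sources
in the toy model are spatially sharp, and a 16-electrode montage cannot
recover them accurately. Repair here serves to keep a session usable, not
to restore single-channel truth.

## Spectra

Cross-spectral densities use multitapering with discrete prolate spheroidal
sequences computed from the standard tridiagonal eigenproblem. The default
half-bandwidth is 0.5 Hz, i.e. time–bandwidth product 2 and 3 tapers for a
4-s trial — a low-variance default that keeps the Mu band resolvable.
Taper–trial cross-products are averaged, the density is one-sided and
Parseval-normalized (its integral over frequency equals signal variance),
and band matrices are inclusive means over the 0.25 Hz grid: 17 bins for Mu
[8, 12], 33 for Beta [18, 26].

## Inverse solution

The eLORETA operator for fixed-orientation sources is the weighted
minimum-norm kernel obtained from the fixed-point iteration

$$C = \bigl(K W^{-1} K^{\mathsf T} + \alpha H\bigr)^{+}, \qquad
  w_v \leftarrow \sqrt{k_v^{\mathsf T} C\, k_v},$$

on the average-referenced leadfield $K$ (centering matrix $H$,
pseudo-inverse via eigendecomposition), iterated to a relative weight change
below $10^{-6}$. Its defining property — exact localization of any single
point source in the noiseless, zero-regularization limit — is verified
exhaustively over a 100-voxel model in the test suite; with uniform weights
the same code reduces to the classical minimum-norm solution, which
demonstrably loses that property. Regularization defaults to $10^{-2}$
times the mean sensor-space eigenvalue of $KK^{\mathsf T}$; localization
results were insensitive to this fraction over $10^{-4}$–$10^{-2}$ in our
checks.

Voxel band power is the quadratic form of each kernel row with the band
cross-spectral matrix. Estimates for all conditions and bands of a subject
are divided by one scalar — their grand mean — so the normalized grand mean
is 1 and contrasts are scale-free; the ERD contrast is then movement −
rest, with negative values meaning desynchronization. ROI values are
unweighted means over member voxels. ROI time series for connectivity apply
the kernel per sample and reduce member voxels to one series, by default the
first principal component sign-aligned with the ROI mean (robust to
polarity cancellation across a sector; a plain mean is available).

## Connectivity

MVAR models are fitted by ordinary least squares on lag-embedded rows
stacked across trials without crossing trial boundaries; the innovation
covariance comes from the residuals. Isolated effective coherence for the
directed pair $j \to i$ at frequency $\omega$ uses
$\bar A(\omega) = I - \sum_k A_k e^{-i\omega k}$ and the innovation
variances $s_{ii}$:

$$\mathrm{iCoh}_{j\to i}(\omega) =
  \frac{|\bar A_{ij}(\omega)|^2 / s_{ii}}
       {|\bar A_{ij}(\omega)|^2 / s_{ii} + |\bar A_{jj}(\omega)|^2 / s_{jj}},$$

the partial coherence of the system in which every connection other than
the $j \to i$ path (including the off-diagonal innovation covariances) is
set to zero. It is bounded in [0, 1] by construction and asymmetric in
general. The test suite verifies the closed form against an independent
numeric oracle (inverse spectral matrix of the isolated subsystem) to
machine precision; the value-axis annotations of published iCoh figures
sometimes suggest a [−1, 1] range, but the definition bounds it in [0, 1]
and that codomain is used here.

**Order selection.** `select_order()` offers BIC and AIC. BIC is
order-consistent when the truth is a finite-order VAR, but the simulated
sources are oscillators *plus* noise — a VARMA process with no finite true
order — and BIC's heavier penalty truncates near order 6, which smears the
iCoh profile toward low frequencies. The pipeline therefore defaults to AIC
with `p_max = 20`, which retains the spectral detail needed for band-resolved
coherence; on genuinely finite-order sources (as in the order-recovery
tests) BIC behaves as theory predicts. Even with AIC, the finite-order
approximation biases the iCoh peak of the mixed-band default scenario a few
bins below the 10 Hz resonance; on matched-model-class (single-band) sources
the peak sits on the resonance. Directionality — the substance of the
coupling analysis — is unaffected: in 100-seed runs the reverse direction of
a planted edge never had the larger band mean.

Two properties of iCoh matter when designing or reading simulations. First,
it **saturates**: the denominator's sender-self term $|\bar
A_{jj}(\omega)|^2$ nearly vanishes at the sender's own resonance, so even a
small nonzero coupling coefficient yields iCoh near 1 there, and coefficient
*increases* on an existing edge barely move the measure — an intervention
effect is therefore modeled as an edge that is absent Pre and present Post
(the cohort default). Second, on **reconstructed** (source-space) series the
instantaneous mixing of eLORETA leakage lets a genuine $7\to9$ edge also
raise the apparent reverse direction; with 16 channels this is unavoidable,
and directed findings in source space should be read at the group level with
that caveat.

## Statistics

* Paired t (Post vs Pre), df = n − 1; ROI-level ERD tests are one-tailed in
  the direction of increased desynchronization, per-frequency iCoh change
  tests are two-tailed at a fixed critical |t| (2.13 at df = 15, the
  p = 0.05 two-tailed threshold for a 16-subject cohort), uncorrected for
  multiple comparisons.
* Voxel-wise inference uses statistical nonparametric mapping: sign-flip
  permutations of the subject difference maps, null distribution of the
  maximum |t| over voxels, corrected threshold at its 95th percentile
  (1,000 flips by default, exhaustive enumeration when $2^n$ patterns are
  fewer — then seed-independent). The corrected threshold dominates the
  uncorrected critical t by construction, and the family-wise error
  calibrates to ~0.05 on simulated nulls.
* Pearson correlation (two-tailed, t transform with df = n − 2) links
  behavior change to ERD change; voxel-wise correlation maps are masked at
  |r| ≥ 0.5. Sign convention: stronger desynchronization Post is *more
  negative*, so a behavior gain that accompanies it produces negative r —
  the cohort generator's default `target_r` is negative for exactly this
  reason.
* Grip scores are means of exactly three non-negative dynamometer pulls
  (lb); behavior tables are summarized with means and n−1 SDs. A bundled
  16-subject example cohort CSV exercises these summaries in tests.

## What the synthetic data do and do not show

The generator produces band-limited oscillators with controlled ERD and
coupling, stationary within trials, with Gaussian backgrounds and exactly
known geometry. Passing tests therefore demonstrate that the *pipeline*
recovers planted effects under realistic noise levels — they do not
demonstrate performance on real EEG, which adds non-stationarity, ocular
and muscle artifacts, volume-conduction model error and inter-subject
anatomical variability. Two structural limitations are worth stating
plainly:

* **Single-session ROI-exact ERD localization is noise-limited.** With 16
  channels and 7 retained trials per condition, the most-negative-ROI
  assignment of a planted Mu ERD in the primary-motor strip succeeds in
  roughly 80–85% of seeded sessions (lower for some other parcels), not the
  ≥95% one might hope for. The limit persists with noiseless sensors, so it
  is driven by inverse-solution leakage between neighboring sectors plus
  the sampling variability of narrow-band power over 28 s of data; tripling
  the trial count brings the rate to ~1.0. Group-level inference across a
  cohort — what the statistical layer actually does — is the appropriate
  use of these per-session maps.
* **Channel repair accuracy** is limited to spatially smooth fields (see
  above).

## Problem sizes and determinism

Defaults: 500 voxels, 16 channels, 256 Hz, 10→7 trials per condition and
phase, 16-subject cohorts, 1,000 permutations. The test suite and the
acceptance script use these scales (with a 120-voxel model for
module-level closed loops and a 100-voxel single-shell model for the
exhaustive localization sweep); a full 16-subject pipeline run takes a few
minutes on one core. Every stochastic path takes an explicit integer seed,
restores the caller's RNG state, and is bitwise reproducible; EDF round
trips preserve samples to one 16-bit quantization step and all event
annotations exactly.
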