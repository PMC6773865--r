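---
title: "Methods: detecting and quantifying scission events in pulsed-pH TIRF recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying scission events in pulsed-pH TIRF recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pphevents)
```

## The assay and the analysis problem

In the pulsed-pH (ppH) assay a cell expressing a pH-sensitive
endocytosis reporter (transferrin receptor fused to superecliptic
pHluorin, TfR-SEP) is imaged by TIRF microscopy while the extracellular
solution alternates between pH 7.4 and pH 5.5 every acquisition frame
(0.5 Hz, so each pH is sampled every 4 s). Surface-exposed pHluorin is
quenched at pH 5.5; a fluorescent spot that appears in pH 5.5 frames
therefore marks a vesicle that has just separated from the plasma
membrane — a completed scission event of clathrin-mediated endocytosis
(CME). The analysis problem is to find these events automatically,
measure their fluorescence, and turn event streams into per-cell
endocytic-activity statistics. A companion set of binding models
(equilibrium hyperbola and 1:1 Langmuir kinetics) quantifies the
affinity and avidity of the peptide ligands whose effect on CME the
assay measures.

`pphevents` implements the full chain:

1. **Demultiplexing** (`demultiplex_ph`): frames are sorted by their pH
   label into a pH 7.4 movie (surface clathrin-coated structures, CCSs)
   and a pH 5.5 movie (internalized vesicles).
2. **Spot detection** (`a_trous_decompose`, `segment_frame`): per-frame
   detection of diffraction-limited objects with the undecimated
   ("à trous") cubic B-spline wavelet transform.
3. **Tracking** (`link_objects`, `filter_tracks`): frame-to-frame
   linking and a minimum-duration filter.
4. **Event calling** (`detect_candidates`): rule-based candidate
   scission events with per-criterion flags.
5. **Classification** (`train_event_classifier`, `classify_events`):
   an SVM that sorts candidate patch stacks into bona fide events and
   false positives, with `agreement_report` reproducing the
   operator-agreement metrics.
6. **Quantification** (`measure_fluorescence`, `align_traces`,
   `correct_bleedthrough`, `shift_null_envelope`,
   `register_channels`).
7. **Statistics** (`cumulative_curve`, `frequency_ratio`,
   `event_density_frequency`, `cluster_density`).
8. **Binding models** (`fit_hyperbola`, `fit_langmuir`,
   `steady_state_responses`).

Everything is validated against a synthetic-data module
(`simulate_pph_movie`, `simulate_sensorgram`,
`simulate_equilibrium_curve`, `simulate_event_stream`,
`simulate_patch_set`) that generates inputs with known ground truth.

## Spot detection

The à-trous transform smooths the image repeatedly with the separable
cubic B-spline kernel $[1,4,6,4,1]/16$, doubling the hole spacing at
each level; detail plane $j$ is the difference of successive
smoothings, so the planes plus the final residual reconstruct the input
exactly. A diffraction-limited spot (PSF sigma ~1.3 px) concentrates in
plane 2 (characteristic support ≈ 4 px), which is the plane segmented
at the default `wavelet_scale = 4`.

Foreground pixels are those whose plane-2 coefficient exceeds $k$ times
the local noise SD, with $k = 8$ by default. Two numerical choices
matter here:

* **Which noise the threshold refers to.** The noise SD is estimated
  on *the plane that is thresholded*, as the MAD (scaled by 1/0.6745)
  in 32×32-px tiles, bilinearly interpolated between tile centers.
  Band-pass filtering attenuates white noise strongly (plane-2 noise is
  roughly a quarter of the raw pixel noise), so calibrating the
  $k\sigma$ rule against the raw or first-plane noise would make
  $k = 8$ reject realistic spots wholesale; calibrating against the
  analyzed plane keeps $k = 8$ both sensitive and essentially
  false-positive-free (the tests bound false detections at < 0.01 per
  128×128 noise frame). The MAD makes the estimate robust to the sparse
  spots themselves.
* **Connectivity and borders.** Components are 8-connected; borders are
  mirror-extended. Components smaller than `min_object_area = 2` px are
  discarded. Centroids are wavelet-coefficient-weighted centers of
  mass; object intensity is the integrated raw intensity over the pixel
  set.

## Tracking

CCSs are essentially immobile at a 2–4 s frame interval, so linking is
greedy mutual-nearest-neighbour within `max_displacement = 3` px:
the globally closest unmatched pair between consecutive frames is
linked first, and so on. There is no gap closing and no
merging/splitting — an object that disappears for one frame starts a
new track. The duration filter keeps tracks covering at least
`min_frames` frames; "more than three frames" is read as ≥ 4, with ≥ 3
selectable, since three frames at the 2-s acquisition period equal the
quoted 6 s but "more than" implies a fourth.

## Candidate scission events

A new pH 5.5 track becomes a *candidate* clathrin-coated vesicle if

* it is visible for more than three pH 5.5 frames (≥ 4, i.e. 8–12 s of
  clock time depending on phase),
* its signal-to-noise ratio at the appearance frame is at least
  `snr_threshold`, and
* a pH 7.4 cluster existed within `colocalization_radius` (2 px) of the
  appearance site for at least five pH 7.4 frames (20–24 s) strictly
  before the appearance time.

The SNR threshold is not printed in the original description ("high
enough"); the default is 3.0 and the definition is peak pixel in the
2-px measurement circle minus the trimmed-annulus background, divided
by the trimmed-annulus SD — peak rather than integrated intensity,
because a newly appeared vesicle is a single diffraction-limited spot
and the peak is the quantity the annulus noise directly calibrates.
All candidates are returned with per-criterion flags, so downstream
consumers (and the classifier) see rejected candidates too.

## Classifier

Each candidate is represented by a 15 × 15 px window over 11
consecutive pH 5.5 frames with the detection frame sixth — 2475 pixel
values. Features are z-scored per feature with training-set statistics
stored in the model, and a soft-margin SVM (RBF kernel, $C = 1$,
$\gamma = 1/2475$; linear kernel selectable) produces the binary
accepted/rejected output. Candidate sets are typically ~80% positive,
so classes are weighted inversely to frequency. The original
description ("SVM type neural network") names no architecture or
kernel; no attempt is made to match the original decision boundary,
only the protocol and its evaluation metrics (`agreement_report`
computes, in exact integer arithmetic, the sorted fraction, the overlap
fraction and the candidate false-positive rate).

## Fluorescence quantification

The fluorescence of an event at a frame is the mean over pixels whose
centers lie within 2 px (300 nm at the default 150 nm pixel size) of
the event position, minus the local background: the mean of
annulus pixels (inner radius 2, outer 5 px) whose values lie between
the 20th and 80th percentiles of the annulus, which excludes
neighbouring objects. Quantiles use R's default linear-interpolation
definition (type 7); the percentile band makes the background robust
rather than exactly invariant to a replaced pixel, and the tests bound
the residual effect of an extreme hot pixel at < 0.5%. Membership is
decided by pixel-center distance — the simplest reproducible rule.
Adding a constant to a frame leaves the measured value unchanged
exactly.

Traces are aligned to their peak frame (or to an external scission
time) and averaged pointwise over the traces covering each relative
timepoint, optionally normalizing each trace to its peak first.
Green-to-red bleed-through is estimated by exploiting the fact that
the true red signal is pH-independent while the green reporter is
quenched at pH 5.5: the factor $g$ minimizes
$\sum\left((R_{7.4} - gG_{7.4}) - (R_{5.5} - gG_{5.5})\right)^2$, a 1-D
quadratic solved in closed form and clamped at $g \ge 0$.

The significance of average recruitment is assessed with a shift null:
the event coordinates are rigidly translated to a random offset inside
the cell mask 200 times, the mean trace is recomputed each time, and
the pointwise 2.5th/97.5th percentiles form the 95% envelope. Rigid
joint translation preserves the spatial pattern of the event set; the
original wording ("shifting the real event coordinates") is compatible
with independent per-event shifts too, so `mode = "per_event"` is
selectable.

Two-channel registration estimates a least-squares affine transform
from matched bead centroids, falling back to a pure translation (with a
warning) for fewer than three beads or a collinear layout.

## Event-frequency statistics

Cumulative event curves are normalized so that the count at 280 s of
cell-attached recording (the 70th cell-attached frame) equals 100,
which lets cells with very different basal activity be pooled. The
inhibition metric is $f = 100 \cdot F_{WC}/F_{CA}$ with the
cell-attached reference window at minutes 2–4 of the recording and the
whole-cell window at minutes 8–10 after break-in; windows are half-open
$[start, end)$ to avoid double counting, the whole-cell clock starts at
the mode boundary, and both windows are parameters (the figure legend
mentioning a 3–5 min reference is supported the same way; the printed
formula's 2–4 min is the default). $f$ is undefined when the reference
window is empty, and the package raises an explicit error rather than
returning a ratio.

## Binding models

Equilibrium curves are fitted by nonlinear least squares of
$Y = B_{max} X/(K_D + X)$ with positivity enforced by bounded (port)
optimization and a Levenberg–Marquardt fallback; $K_D$ is initialized
at the concentration of half-maximal observed response. Constant
responses are flagged non-identifiable instead of fitted.

Sensorgrams are fitted with the 1:1 Langmuir model
$dR/dt = k_{on} C(t)(R_{max} - R) - k_{off} R$ with the bulk
refractive-index term fixed at 0 and mass transport treated as
non-limiting (the standard constraints for single-cycle kinetics
evaluation; no transport compartment is modelled). Because Biacore-style
models are ill-conditioned near parameter boundaries, the fit runs on
$\log(k_{on}, k_{off}, R_{max})$ with Levenberg–Marquardt least
squares; $k_{on}$ is initialized at $10^5\ \mathrm{M^{-1}s^{-1}}$ and
$K_D$ from the half-maximal plateau. The model curve uses the exact
piecewise-exponential solution of the ODE, while the simulator
integrates with fixed-step RK4 — a genuinely independent dual route
that the tests exploit. Steady-state analysis averages the terminal
10% (`plateau_fraction`) of each injection and feeds the resulting
concentration–response curve to the hyperbola fit.

## What the simulator emulates — and what it does not

`simulate_pph_movie` generates the alternating-pH acquisition at 0.5 Hz
with a centered elliptical cell mask covering ~60% of the field
(configurable). Scission events are a homogeneous Poisson process in
time over the mask area; each event's parent cluster is born an
exponential time (mean `ccs_lifetime_mean = 40` s) before scission and
is visible in pH 7.4 frames until scission; the vesicle is visible in
pH 5.5 frames for 20 s after scission (post-scission fate is not
modelled — only the appearance matters for detection). Transient
clusters that never undergo scission are planted at a standing density
as distractors, and an `orphan_fraction` plants vesicles without a
parent cluster as negative controls for the pre-existence rule. Spots
are isotropic Gaussians (PSF sigma 1.3 px); camera noise is
Poisson(signal × gain) plus Gaussian read noise; a red channel with a
configurable green-to-red bleed-through factor can be rendered.

Default condition parameters: pixel size 150 nm (so the 2-px
quantification radius is 300 nm), frame period 2 s, scission rate
0.2 ev min⁻¹ µm⁻² (control recordings span roughly 0.025–0.34),
cluster/vesicle peak amplitudes 200/150 counts over a background of
100, read noise 5 counts. The spatial extent and lifetime distribution
of CCSs are not published; the defaults above are declared,
configurable placeholders chosen to resemble TIRF recordings of
fibroblasts, not assertions about the original data.

The simulator does **not** model photobleaching, blinking, 3-D PSF
structure, stage drift, or moving pH 5.5-visible vesicles. Passing
tests on simulated movies therefore demonstrate the correctness of the
algorithms under the stated statistical model, not detector performance
on real recordings — in particular the published miss rate (~30%) and
false-positive rate (~20%) of the original detector arise from real
noise structure the simulator does not reproduce.

## Problem sizes, determinism, degenerate inputs

The test and validation suites use deliberately small problem sizes —
movies of 32–96 px per side and 80–480 s, 60-cell frequency-ratio
cohorts, 12-point binding curves, 100–200-shift envelopes — chosen so
the full suite exercises every code path in a few minutes while keeping
Monte-Carlo tolerances (3 SE for Poisson-law checks, 2 SE for the
frequency-ratio recovery) meaningful at those sizes.

All stochastic functions funnel randomness through a single seed
argument and restore the caller's RNG state; identical configuration
and seed give bit-identical movies, curves, streams and pipeline CSV
outputs. Degenerate inputs fail loudly and specifically: zero-area
masks, unlabeled frames, empty reference windows, constant binding
curves and flat sensorgrams are either descriptive errors or
explicitly flagged non-identifiable fits. In files, coordinates are
0-based with x = column and y = row; in R they are 1-based matrix
indices, and the CSV writers convert.

Known limitations: the greedy tracker is not globally optimal (adequate
for immobile CCSs, not for fast-moving objects); the Eq.-2 per-cell
ratio is a small-count ratio estimator whose mean over cells is biased
upward when the reference window holds only a handful of events —
cohort-level summaries should use cells with adequate basal activity;
and the SVM reproduces the published protocol, not the original model's
weights.
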