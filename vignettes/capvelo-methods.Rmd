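---
title: "Measuring parafoveal capillary flow velocity: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring parafoveal capillary flow velocity: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capvelo)
```

# The measurement model

AOSLO resolves individual blood components in parafoveal capillaries:
leukocytes transmit the imaging laser and appear as bright plugs; the
aggregated erythrocytes trailing each plug absorb it and appear dark.  Both
move with the blood column.  Sampling every registered frame along the
vessel centreline at uniform metric steps produces a kymograph (row =
frame, column = arc length), in which a cell train of speed $v$ traces
bands of slope $m = 1/(v\,\Delta t)$ frames per µm.  The velocity estimate
is the unweighted mean of $1/(m_k \Delta t)$ over accepted bands $k$ —
unweighted because the number of candidate points per band varies with
band steepness, not with measurement quality.

The feature localised per row is the anterior (downstream) end of each dark
band, where the dark aggregate abuts the bright plug ahead of it: it is the
sharpest transition in the image and the feature a human grader traces.

## Angular to metric conversion

AOSLO fields are specified in degrees.  We convert with a Bennett-style
schematic-eye scaling, $q = 0.01306\,(AL - 1.82)$ mm/deg, isolated in
`deg_to_mm()`.  Any instrument-specific calibration can replace this one
function; everything downstream consumes micrometres.  Axial lengths
outside 20–30 mm are rejected as implausible rather than extrapolated.

## Stages and their numerical choices

* **Registration** (`register_frames()`): rigid, integer-pixel, by FFT
  cross-correlation against the first frame, with the peak search
  restricted to ±10 px.  The restriction matters: the photoreceptor mosaic
  is quasi-periodic, and an unrestricted search occasionally locks onto a
  lattice side-peak tens of pixels away.  Integer correction leaves ≤0.5 px
  residual jitter, well below the capillary cross-section.
* **Motion contrast** (`motion_contrast()`): per-pixel temporal SD divided
  by temporal mean + $10^{-3}$, normalised to [0, 1].  Perfused pixels
  fluctuate as cells pass; static background does not.  A temporally
  constant stack maps to all zeros by construction.
* **Vessel tracing** (`trace_vessel()`): consecutive seed points are joined
  by a minimum-cost path on the 8-connected pixel lattice (cost ∝ inverse
  map value, igraph shortest path), refined to subpixel by
  intensity-weighted centroids along the local normal, then smoothed.
  Seeds on background (map value < 0.1) are rejected rather than guessed.
* **Kymograph** (`build_kymograph()`): bilinear interpolation along the
  path at steps of one pixel pitch by default.  Halving the step changes
  velocities by <2 % on clean kymographs (verified in the tests), so the
  default is not load-bearing.
* **Band detection** (`detect_bands()`): per-row candidates are strong
  extrema of the smoothed spatial gradient (both signs tried — which sign
  marks the anterior edge depends on the flow direction relative to path
  orientation).  A Hough-style orientation search over trial advances
  $u$ (µm/frame, log-spaced over 0.2–8 mm/s, both directions) scores the
  concentration of intercepts $b = s - u f$; every local maximum is
  refined at fine bin width.  Bands are then "peeled" one intercept-peak at
  a time and fitted with least-absolute-deviation lines.  All tolerances
  are expressed in micrometres of arc length, where the localisation noise
  lives, so they are invariant to band steepness.
* **Alias rejection.** A quasi-periodic plug train can be explained by
  several orientations (a stroboscopic ambiguity).  Two safeguards pick the
  physical one: a band is only accepted when its inliers cover ≥67 % of the
  frames it spans (true bands are traced row after row; alias lines touch
  candidates only every few rows), and among orientations the one
  explaining the most accepted support wins.  A perfectly regular train
  with integer advance can still be genuinely ambiguous (e.g. an advance of
  40 µm/frame with exactly 100 µm spacing repeats every 5 frames); real
  capillary trains are irregular, and the synthetic fixtures deliberately
  are too.
* **Pulsatility and multi-pass peeling.** Cardiac modulation spreads band
  slopes around the mean; a single orientation collects only the bands
  near its own speed, which would bias the video mean toward whichever
  phase dominates the Hough peak.  Detection therefore repeats: accept the
  dominant orientation's bands, remove their candidates, and re-search the
  remainder within a factor 1.8 of the first-pass speed (same gradient
  sign and direction), so bands from all cardiac phases contribute.

`detect_bands()` on an empty or structureless kymograph returns
`n_bands = 0`, a flag distinct from a zero velocity; `estimate_velocity()`
propagates it as an `NA` velocity.

# The synthetic world

`simulate_capillary_video()` renders what the acquisition protocol
describes: 2-s, 64 frames/s videos of a 1.4° × 2.8° field (≈286 px/deg,
i.e. ~1 µm/px at emmetropic axial length) focused on the photoreceptor
layer, containing a single unbranched capillary of the innermost
parafoveal ring.  Choices the protocol leaves open were fixed once:

* **Background**: a quasi-regular bright-spot mosaic (photoreceptor-like,
  ~4 px spacing, jittered) on a mid-grey base plus frozen speckle.
* **Blood column**: bright plugs (10 µm, intensity 0.95) each trailing a
  dark aggregate (30 µm, intensity 0.08) with 3 µm smooth shoulders except
  at the sharp plug–aggregate boundary; Gaussian cross-section of σ 2.5 px
  (~7 µm capillary).  Plug spacing 100 µm with 15 % jitter — capillary
  leukocyte trains are irregular, and perfect regularity is the degenerate
  stroboscopic case discussed above.
* **Pulsatility**: $v(t) = \bar v\,(1 + a \sin 2\pi f_c t)$ with $a = 0.1$,
  $f_c = 1.2$ Hz — a resting heart rate and a modest capillary modulation
  depth.
* **Jitter/noise**: rigid per-frame translation (SD 0.5 px) and additive
  Gaussian noise (SD 5 % of mean background).  Intra-frame (scan-line)
  distortion is deliberately not modelled; a green recovery test therefore
  says nothing about torsional eye motion.

Ground truth records the exact per-frame arc position of every plug front,
so recovery tests compare against construction, not against a second
estimator.

`simulate_cohort()` draws a two-group study: 11 healthy subjects (baseline
only) and 11 treated POAG patients (baseline + weeks 1, 4, 12) with
per-group, per-visit means and SDs typical of such a study, compound-symmetry
within-subject correlation ρ = 0.5 (matching the power analysis
convention), and one subject missing week 12 (the study's dropout).
Systolic and diastolic pressure latents are coupled at r = 0.6 and floored
at sBP ≥ dBP + 2 mmHg — independent draws occasionally invert the
pressures, which the OPP formula rightly refuses; the floor affects ≈0.1 %
of records and is invisible at Monte-Carlo tolerances.  Variables are
otherwise mutually independent, which real clinical data are not; tests
built on this cohort validate the statistical machinery, not biological
covariance structure.  OPP is never stored — it is always derived from the
stored pressures, as in the analysis pipeline.

# Statistical engine

* **RM-ANOVA**: one-way within-subject decomposition on complete cases,
  sphericity assumed (ε = 1) by default — consistent with the convention
  of the a-priori power analysis; Greenhouse–Geisser is available as a
  switch.  Validated two ways in the tests: against a within-subject
  permutation oracle (10 000 draws; agreement tolerance 0.015 + 3
  Monte-Carlo SEs, chosen before measurement as parametric-vs-permutation
  slack at n = 11), and by type-I error 0.05 ± 0.01 over 2 000 exchangeable
  null simulations.
* **Post hoc**: paired t of baseline vs each follow-up on available pairs,
  significant at α/3 (Bonferroni over the three contrasts, the only
  multiplicity the design corrects).
* **Percent change** is per-subject, then averaged: on skewed data this
  differs from the change of group means, and the per-subject form is the
  one a paired design reports (the divergence is demonstrated in a test).
* **Group comparison**: equal-variance unpaired t by default (Welch behind
  a flag), chi-square without continuity correction for sex.
* **Sample size**: smallest n with noncentral-F power ≥ target, with
  λ = n·m·f²/(1−ρ), df₁ = (m−1)ε, df₂ = (n−1)(m−1)ε.  For f = 0.4,
  α = 0.05, power 0.8, m = 4, ρ = 0.5: n = 10.  Power is monotone in n, so
  the linear search is exact; a brute-force power-curve oracle confirms it
  on random specifications.

## 24-2 visual-field classification

The classifier returns `unreliable` above 15 % fixation loss / false
positives / false negatives, else `glaucomatous` on any of: GHT outside
normal limits (consumed as an input flag — the normative database is not
available to compute it), PSD probability <5 % (likewise a flag), or a
cluster of ≥3 adjacent non-edge points within one hemifield, all depressed
at P < 5 % with at least one at P < 1 %.  Grid conventions the criteria do
not pin down are constants in one place (`vf_grid_242()`): 8-neighbour
adjacency at 6° spacing, edge points = the outermost superior/inferior rows
plus the two nasal-most points, blind spot at (15°, ±3°) excluded.  The
"two consecutive plots" qualifier of the original criteria is out of scope:
the classifier judges a single test.  The test-suite oracle enumerates all
point triples exhaustively — a connected cluster of ≥3 with a P < 1 % point
exists iff some connected triple containing that point does.

# Design decisions that were genuinely open

* Baseline pBFV averaging across the three pre-treatment visits is not
  specified in the study design; the cohort simulator draws a single
  baseline and the analysis consumes whatever baseline column it is given,
  leaving multi-visit averaging to the caller.
* The proprietary angular-to-metric software is unpublished; absolute
  velocities scale linearly with the adopted schematic-eye constant, which
  is why it is isolated behind `deg_to_mm()`.
* How many bands per video the original graders measured is unknown; we
  average all accepted bands.
* OPP is linear, so it commutes with exact means; it does not commute with
  independently rounded summary tables, and the package never asserts that
  an OPP column of a rounded table equals OPP of its rounded means.

# Known limitations

* Velocities are axial speeds, not flow volumes: capillary diameter is
  below the instrument's resolving power, so no attempt is made to infer it.
* The recovery grid certifies 0.5–3 mm/s at the stated noise; far faster
  flow approaches the stroboscopic limit of a 64 fps acquisition.
* The simulator's green tests establish algorithmic correctness under its
  stated world (rigid jitter, additive noise, regular-ish plug trains),
  not robustness to scan distortion, defocus or vessel crossings.
* The cohort generator reproduces first and second moments and
  within-subject correlation, not the full joint distribution of real
  clinical variables.
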