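---
title: "Semantic wavelet-induced frequency tagging: models, parameters and design choices"
author: "swiftag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic wavelet-induced frequency tagging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swiftag)
```

swiftag builds periodic visual stimuli whose *semantic* content is revealed
at a fixed temporal frequency while their principal low-level features stay
constant, and analyses the frequency-tagged BOLD responses such stimuli
evoke. This vignette explains the models behind each stage, the parameters
that matter, the numerical choices we made where the design was genuinely
open, and what the bundled synthetic-data generator does and does not
emulate.

## The scrambling model

A square grayscale image (side $2^L$, intensities in $[0,1]$) is decomposed
with an orthonormal, periodized discrete wavelet transform into $L$ scales.
At every scale and location the three detail coefficients — horizontal,
vertical and diagonal — form a 3D *orientation vector* $w = (w_H, w_V,
w_D)$ whose Euclidean norm is the local contour energy at that position and
spatial frequency. The coarsest approximation band carries local luminance.

For each location we draw two additional vectors with random orientations
but the same norm as $w$. The three equal-norm points determine a unique
circle — the *isoenergetic circular path* — and, because all three lie on
the sphere of radius $\lVert w \rVert$, every point of that circle has
exactly the anchor's norm. Moving a coefficient along its path scrambles
local contour orientation while conserving local energy; since the
transform is orthonormal, the image's total detail energy (global contrast)
and its distribution over scales (local spatial frequency) are conserved,
and the untouched approximation band conserves local luminance.

Each location is also assigned a harmonic $h \in \{1, \dots, H\}$ (uniform,
default $H = 8$) and traverses its path with angle

$$\theta_c(t) = 2\pi \, h_c \, t / F, \qquad F = \texttt{frames\_per\_cycle},$$

so all locations return to their anchors simultaneously at frames $0, F,
2F, \dots$ (0-based) — the *semantic onsets*, the only frames at which the
original image is fully revealed — and partial alignments of harmonic
subsets produce only small similarity ripples in between.

Closeness to the original is quantified by the relative image similarity

$$\mathrm{RIS}_x = \frac{100}{n} \sum_{c=1}^{n}
  \left(1 - \lvert \Delta W_c \rvert\right),$$

where $\lvert \Delta W_c \rvert$ is the orientation-vector distance between
frame and reference at location $c$, divided by the maximum attainable on
that location's path, clipped at 1. RIS is 100 exactly at semantic onsets
and 0 when every location sits at its antipodal point.

Two readings of the normalization were possible: per scalar coefficient or
per orientation vector. We normalize the *vector* difference by the path
diameter $2\rho_c$: the chord length $2\rho_c \sin(\theta/2)$ is symmetric
about mid-cycle, which makes the single-harmonic RIS curve exactly
symmetric — a property the scalar reading lacks — and makes "maximal
deviation" geometrically attainable (the antipodal point). Locations with
zero path diameter (zero anchors) cannot deviate and contribute perfect
similarity.

### Parameters

| parameter          | default | units  | role |
|--------------------|---------|--------|------|
| `levels`           | 9       | scales | decomposition depth; forces side $\ge 512$ |
| `n_harmonics`      | 8       | —      | shapes the U-shaped RIS curve; 1 gives a sinusoidal cycle |
| `frames_per_cycle` | 200     | frames | cycle length at the generation resolution |
| `n_paths`          | 3       | —      | independent path geometries rotated across cycles |
| `seed`             | —       | —      | all randomness (paths, harmonics) flows from it |

The wavelet family (default `d4`, a 4-tap Daubechies filter) and the
periodic boundary rule are package choices, not constraints inherited from
any particular experiment: orthonormality is required for the energy
invariants, and periodization keeps the $(\text{side}/2^s)^2$ coefficient
bookkeeping exact. `haar` and `d6` are available through
`wavelet_filters()`.

"Independent scrambling cycles = 3" we interpret as three independently
randomized path geometries per location, rotated across successive cycles:
consecutive cycles traverse different scrambled frames, every cycle still
anchors at the original, and no spectral lines appear at subharmonics. This
is an interpretation — the generator that coined the phrase is external to
this package — and it is isolated in the `n_paths` argument.

## Composite runs

Several streams, each scrambling its own category's exemplars at its own
tagging frequency (defaults: faces 0.10 Hz, scenes 0.06 Hz, objects
0.08 Hz), are alpha blended frame by frame. At the default display rate of
12 fps all three frequencies give integer frames per cycle (120, 200, 150);
`schedule_run()` rejects rates that do not and suggests one. How the
original experiments multiplexed unequal cycle lengths onto one projector
refresh is not documented; the common-rate solution is our design choice.

Each stream's initial cycle phase is drawn uniformly from frames 30–100 out
of 200 (rescaled proportionally for other cycle lengths), so no semantic
onset occurs near the run start. Exemplars switch at segment boundaries
(default 180 s) *without* resetting the phase, so onsets stay strictly
periodic across the whole run and exemplar changes recur at
$1/180 \approx 0.0056$ Hz — far below, and not harmonically related to, the
tagging frequencies.

One caveat the tests document rather than hide: blending is linear in
coefficients, so a composite frame's detail energy is
$a^2 E_1 + b^2 E_2 + 2ab\,\langle C_1(t), C_2(t)\rangle$. The per-stream
energies $E_i$ are conserved to $10^{-9}$ relative, but the
cross-correlation term fluctuates across frames (several percent to ~20%
at desk-scale image sizes, because wavelet coefficient norms are heavy
tailed). Claims of constant global contrast therefore apply to each stream,
not to the blended sum.

## The synthetic BOLD generator

No scan data ship with the package; the generator emulates the *structure*
of a frequency-tagged study so every analysis stage can be tested
end-to-end:

* runs of 216 volumes at TR = 2.46 s (both configurable);
* a canonical double-gamma hemodynamic response (peak 6 s, undershoot 16 s,
  peak:undershoot 6:1, unit peak; all exposed), evaluated continuously so
  onsets need not align with the sampling grid;
* voxels that respond at every semantic onset of their category's tagging
  frequency with a per-voxel random onset phase, on top of baseline 100
  plus white Gaussian noise (optional AR(1) for stress tests, since the
  tagging statistic assumes exchangeable noise power across bins);
* an ROI layout along the visual hierarchy with tagged-voxel fractions
  (V1, V2, V3, V4) = (0, 0, 0.2, 0.4) and 1.0 in FFA/PPA/LOC.
  Functionally-defined category ROIs consist of voxels selected because
  they respond, so their tagged fraction is 1 by construction; response
  amplitudes default to 1% of baseline in retinotopic areas and 2% in
  category ROIs, the typical range of category-evoked BOLD responses.

Ground truth (tag flag, frequency, amplitude, phase per voxel) is recorded
in a sidecar that analysis functions never read. What the generator does
*not* emulate: physiological and scanner noise structure, motion, EPI
distortion, spatial autocorrelation, hemodynamic variability across voxels,
and anatomical geometry (ROIs are abstract voxel blocks). Passing tests
therefore validate the analysis machinery and its calibration under the
stated noise model — not robustness to everything real data contain.

## Frequency-tagged analysis

Per voxel and run: convert to percent signal change (mean 100), remove a
linear trend (the drift handling that a scanner pipeline's high-pass filter
would otherwise provide), Fourier transform, and take one-sided power on
the grid $\Delta f = 1/(n \cdot TR)$ ($1/531.36$ Hz at the defaults).

The spectral SNR at a bin is its power divided by the mean power of the 14
surrounding bins (7 per side, center excluded). The per-voxel tagging
statistic compares power at the tag bin across runs against power at the
noise bins across runs with a two-tailed two-sample t-test. Two details
deserve comment:

* **Noise set.** The packaged constant `swift_noise_freqs` lists the 22
  noise frequencies of the reference three-tag configuration. Their
  spacing (~1/539 s) is slightly inconsistent with a 216 × 2.46 s run;
  bins, not hertz, are treated as authoritative. The generative rule
  `noise_frequency_set()` — bins within 7.5 bins of a tag but more than
  2.5 bins from every tag, distances measured to the exact fractional tag
  position — reproduces the packaged set's 5/6/6/5 band structure on the
  1/540 Hz grid and adapts to any other grid. Requested frequencies are
  mapped to nearest bins, with a warning beyond $\Delta f/4$ (0.08 Hz sits
  exactly between two bins of the default grid; the warning is a feature).
* **Log power.** Raw spectral power is approximately exponential, and a
  pooled-variance t-test with 3 tag samples against 66 noise samples on
  such skewed data is measurably anticonservative (simulated null KS
  distance ≈ 0.04). The test is therefore applied to log power by default
  — the standard variance stabilization for spectra — which restores
  uniform null p-values; `log_power = FALSE` gives the raw-power variant.
  The replicate structure (tag group $n$ = runs, noise group $n$ = runs ×
  noise bins) is the only reading consistent with a two-sample test at a
  single tag bin.

Multiplicity is handled by Benjamini–Hochberg FDR at $q = 0.05$
(`fdr_bh()`, delegating to `stats::p.adjust`). Phase maps take the FFT
phase at the stimulation bin, masked at spectral SNR ≥ 2 — the criterion
used for phase-encoded retinotopy. Cycle averaging aligns epochs at
semantic onsets and averages across cycles (linear interpolation between
samples, exact when onsets sit on the grid; no baseline subtraction by
default).

## The localizer benchmark

The comparison pipeline is a block-design GLM: boxcars (default 20 s
blocks, as in a localizer with 15 s fixation gaps) convolved with the
canonical response, an intercept, optionally a discrete-cosine drift set
with 128 s cutoff. Contrasts are tested voxel-wise by OLS,
$t = c^\top\hat\beta / \sqrt{\hat\sigma^2\, c^\top (X^\top X)^{-1} c}$,
two-tailed on the residual degrees of freedom. Autocorrelation whitening is
deliberately absent (a known limitation; the simulator's default noise is
white). Category presets such as `"faces-gt-objects"` expand to contrast
vectors by condition name.

## Criterion-free ROC comparison

Because the tagging statistic and the GLM produce p-values by different
routes, comparisons between areas use a criterion-free construction: sweep
a p-value threshold over 20 steps (ten log-spaced from $10^{-10}$ to
$10^{-1}$, ten from $10^{-0.9}$ to 1), record at each step the proportion
of voxels with $p$ strictly below it in a signal ROI (hits) and a reference
ROI (false alarms), augment with (0,0) and (1,1), and integrate
trapezoidally. Strict inequality means ties at a threshold resolve to
exclusion; endpoint augmentation keeps the AUC well defined when the
stringent end never reaches (0,0). Multiple reference ROIs are pooled as
concatenated voxel lists, not averaged proportions. The 20-step AUC tracks
the Mann–Whitney statistic of the two p-value samples (tests bound the gap
at 0.05; a 2000-step ladder at 0.02).

Two overlap summaries complement the ROC: the percentage of
tagging-activated voxels also activated by the localizer (whole-brain
reading) and the percentage of a functionally-defined ROI activated by the
tagging analysis. The hierarchy profile divides each area's activated
proportion (default threshold $p < 0.001$) by the mean of the first two
(early visual) areas; a zero baseline is an explicit error, never silently
patched with an epsilon.

## Numerical choices and degenerate inputs

* All tolerances are stated at the invariant they guard: $10^{-8}$ for
  transform round trips, $10^{-9}$ relative for isoenergy, $10^{-6}$ for
  onset revelation.
* Zero anchors scramble to the constant path at the origin (documented,
  not an error); near-collinear random path triples are redrawn.
* Degenerate t-test inputs (zero variance in both groups) yield $p = 1$
  with a warning.
* Voxels with non-positive temporal mean are excluded from percent signal
  change with a warning.
* Cycle-average windows longer than the inter-onset gap are rejected
  unless overlap is explicitly allowed.
* Every random operation takes an explicit seed, and library code restores
  the caller's RNG state.

## Problem sizes used by the test suite

The suite exercises the full stimulus scale where the claim demands it —
isoenergy and onset revelation are verified on every frame of a two-cycle,
eight-harmonic, nine-level movie on a 512×512 fixture — and desk-scale
sizes elsewhere: 64–128 px images for scrambling properties, studies of
500–7000 voxels with 3 runs of 216 volumes for calibration and recovery,
2000 null voxels for the uniformity check, 50 random ROI pairs for the
ROC/Mann–Whitney equivalence. These sizes were chosen as the smallest at
which the respective statistical checks have useful power.

## Known limitations

* PNG and TIFF input only; color images are collapsed to luminance.
* Movie export writes PNG frame archives (8-bit) or lossless `.rds`
  archives with a JSON sidecar; no video encoding.
* The GLM assumes exchangeable white noise; no prewhitening.
* The synthetic generator's realism limits are listed above — in
  particular, spatial structure (smoothness, anatomy) is not modeled, so
  ROI-level results should be read as statistical, not anatomical,
  statements.
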