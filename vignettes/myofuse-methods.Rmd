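---
title: "Quantifying myoblast fusion from double-labeled live imaging: models and methods"
author: "myofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myoblast fusion from double-labeled live imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myofuse)
```

## The measurement problem

Myoblasts differentiate by fusing into elongated multinucleated myotubes.
The standard readout of differentiation is the **fusion index**: the
percentage of all nuclei in a field that sit inside fused fibers at one
time point. Immunostaining-based quantitation is sacrificial — every time
point costs a sample — whereas cultures carrying one fluorophore in the
cytoplasm and a second, histone-fused fluorophore in the nucleus can be
imaged live, day after day, in the same fields. `myofuse` automates the
image-analysis half of that assay: given a paired cytoplasm/nucleus image
of one field, it produces the nuclei count (a proxy for growth), the
fusion index (the readout of differentiation), and fiber-size summaries,
and it aggregates fields and wells into per-condition time courses that
can be compared statistically.

A fiber counts as **fused only with three or more nuclei**. A region
holding exactly two nuclei is ambiguous — it may be a young fiber or a
dividing cell — and deliberately contributes nothing. This rule is applied
identically in the pipeline, in the simulator's ground truth, and in the
brute-force oracle used to certify both, and the threshold is exposed as
`minNucleiFused` in `fusionIndex()` for sensitivity analysis.

## Pipeline

Each stage is a standalone exported function; `sceneMetrics()` composes
them.

**Nucleus detection** (`detectNuclei`). The nucleus channel is filtered
with a zero-mean, scale-matched Laplacian-of-Gaussian kernel
(`sigmaPx`, default 2 px), so bright blobs of nucleus scale give positive
peaks and constant offsets vanish. Local maxima above `relThreshold`
(default 0.15) of the filtered-image maximum are kept, greedily suppressed
to a minimum separation (`minSeparationPx`, default 5 px, strongest
response wins), trimmed of a border margin (default `2 * sigmaPx`, because
truncated spots bias centroids), and refined to sub-pixel coordinates by a
three-point parabolic fit per axis. Thresholding relative to the filtered
maximum makes the detection set invariant to the overall intensity scale —
a gain or exposure change does not alter the count. Touching nuclei closer
than the minimum separation are *not* split further (no watershed stage);
with the plate densities the package targets this is rare, and it is the
same failure mode a human annotator has.

**Fiber segmentation** (`segmentFibers`). The cytoplasm channel first
loses a large-radius Gaussian-smoothed background estimate
(`backgroundRadiusPx`, default 50 px) — this flattens the slowly varying
autofluorescence of collagen-coated scaffolds without touching
fiber-scale structure, and makes the subsequent Otsu threshold invariant
to constant intensity shifts. The residual is thresholded (Otsu by
default, a fixed value optionally), morphologically closed
(`closingRadiusPx`, default 2 px), hole-filled, and labeled by
8-connected components. Components are kept only if their area reaches
`minAreaPx` (default 120 px, roughly two fiber-widths squared) **and**
their elongation — major/minor axis ratio of the moment-equivalent
ellipse — reaches `minElongation` (default 3). Elongation is the
discriminator between myotubes and round mononucleated cell bodies: a
disk has elongation near 1, a myotube several fiber-widths long exceeds 3
comfortably. Touching fibers are not split; a merged region inherits all
contained nuclei, which matches how a human marks overlapping fibers.

**Assignment and index** (`assignNuclei`, `fusionIndex`). Nuclei are
points; a nucleus belongs to the region whose mask contains its rounded
centroid pixel. Masks live in one labeled matrix, so assignments are
unique by construction. The fusion index is then
`100 * fusedNuclei / totalNuclei` over regions with >= 3 assigned nuclei.
An empty scene (zero detections) raises an error rather than reporting
0%, so plate-level aggregation can never silently dilute a mean with
undefined values.

**Object contrast** (`objectContrast`). For label-combination and
scaffold work the package measures `(S - bgd) / bgd`, with `S` the mean
intensity over a marked object and `bgd` the mean over a marked
background region. The definition is dimensionless, invariant to
multiplying the image by a positive constant, and deliberately sensitive
to additive offsets — both properties are asserted by tests, and a zero
mean background raises an explicit division error.

## Experiment aggregation and statistics

Fields of a well pool by mean; **wells are the replicate unit** (three
replicate wells per condition is the standard design). `aggregateResults`
reconciles per-scene results against the plate manifest — results missing
from the manifest are an error, manifest days without results are flagged
and never imputed. `compareConditions` runs a one-way ANOVA across
conditions on one day and all pairwise two-sample pooled-variance t-tests
with Bonferroni adjustment (raw p times the number of pairs, capped at 1)
at `alpha = 0.05`. The base pairwise test is not dictated by the assay —
pooled t-tests are the conventional ANOVA post-hoc and are used here.
When every replicate in every group is identical there is nothing to
test: p is reported as 1 and nothing is flagged. Each day is treated
independently (no repeated-measures modeling across days), matching the
per-day comparisons the assay design implies; mixed-effects extensions
are out of scope.

`timeToFractionMax` summarizes fusion *dynamics*: the earliest linearly
interpolated day at which the mean fusion index reaches a fraction
(default 0.9) of its maximum over the course. Because the maximum is
attained at some imaged day, the threshold is always reached; a constant
course reports its first day. Conditions that accelerate fusion (e.g.
induced MYF5 overexpression) report strictly smaller values than their
controls.

## The simulator

`simulateScene`/`simulateTimecourse`/`simulatePlate` render synthetic
double-labeled fields with exact ground truth. The generator emulates,
in order:

* **Growth.** Nuclei per field grow geometrically,
  `n(d) = min(plateau, n0 * growthRate^d)` — default 40 nuclei at day 0,
  factor 1.35/day, plateau 130 per 384 x 384 px field, a sub-confluent to
  confluent culture at roughly 1 um/px scale.
* **Fusion kinetics.** The fused fraction follows saturating first-order
  kinetics `df/dt = fusionRate * effect(t) * (fMax - f)`, zero until the
  switch to differentiation medium (day 3), integrated exactly over each
  day with piecewise-constant drug effect. No functional form is dictated
  by the assay itself; this is the simplest monotone saturating model
  that reproduces the observed behavior that accelerated cultures "arrive
  quicker" at their maximal fusion index. Defaults `fusionRate = 0.35`/day
  and `fMax = 0.6` put the no-drug culture at ~55% fusion by day 10.
* **Drug schedules.** `exposureSchedule()` encodes the standard plate
  design — no drug, continuous (days 3–10), early (days 3–5), late (days
  7–9) — and `drugEffect` in [0, 1] multiplies the fusion rate on drug
  days. A fully blocking drug (`drugEffect = 0`) given continuously
  freezes fusion at its day-3 value (zero), while early and late windows
  each cost the same number of active fusion days — the early ≈ late <
  ND < blocked structure emerges from the kinetics rather than being
  painted in.
* **Geometry.** Fused nuclei are grouped into fibers of 3–7 nuclei and
  rendered as randomly oriented capsules (width 7 px) with nuclei spaced
  11 px along the axis; remaining nuclei become round cell bodies.
  Objects are placed by rejection sampling with an 8 px edge clearance
  between fibers and 6 px between cells, so distinct objects remain
  resolvable after rendering blur and morphological cleanup and
  ground-truth masks stay disjoint; placement that exhausts its retry cap
  is dropped (ground truth always reflects what was actually rendered).
  A configurable fraction of unfused nuclei (`twoNucleusFiberRate`,
  default 0.1) is paired into two-nucleus fibers that exercise the
  dividing-cell ambiguity — they carry masks and memberships but are
  never fused under the >= 3 rule.
* **Optics and noise.** Nuclei render as Gaussian spots
  (sigma = 0.6 * nucleusRadiusPx), cytoplasm bodies as filled masks
  softened by a 1 px Gaussian, both over a flat autofluorescent
  background (default 150 counts; raise it for the scaffold scenario).
  Poisson shot noise is applied to signal + background, then additive
  Gaussian read noise (sd 5 counts), then rounding and clipping to the
  camera range — the standard fluorescence camera model. Channel
  amplitudes default per label combination, giving the cytoplasmic-GFP +
  nuclear-mCherry combination roughly twice the cytoplasm
  signal-to-background of the reverse combination, so measured contrast
  reproduces the expected ordering between the two labeling schemes.
* **Reproducibility.** Every scene draws from a sub-stream seeded by a
  31-bit hash of (master seed, condition, well, day, field), so output is
  bit-identical for identical parameters and adding wells or conditions
  never perturbs existing ones. Well-level biological variability is a
  lognormal factor on the fusion rate (`wellCv`, default 0.08).

What the simulator does **not** emulate — and therefore what passing
validation does not show about real data: out-of-focus fields, uneven
illumination, photobleaching, cell motility, overlapping or crossing
myotubes, multi-layered growth (a single focal plane of a 3-D scaffold
culture), debris, and segmentation-relevant texture inside fibers. On
real images the detection and segmentation defaults will need tuning per
magnification and camera, which is why every scale-bearing parameter is
surfaced in `detectionConfig()`/`segmentationConfig()` rather than fixed.

## Numerical choices and edge policies

* Coordinates are 0-based with x = column, y = row; masks are
  pixel-aligned. Sub-pixel refinement offsets are clamped to half a pixel.
* Unknown TIFF bit depths are rejected, never rescaled — rescaling would
  silently corrupt contrast values. Round trips are bit-exact for 8- and
  16-bit grayscale.
* A constant image has zero blob response up to FFT round-off; responses
  below `1e-6 * max(image)` are treated as blank (the relative form
  preserves scale invariance).
* Detection peak ties are broken by raster order; labels and detection
  ids are assigned in raster order, so all outputs are deterministic and
  order-independent.
* Greedy nearest-neighbor matching in `matchDetections` breaks distance
  ties by lower truth id, then lower detection id; with no detections,
  precision is reported as 1 with `precisionDefined = FALSE`.
* Degenerate statistics: zero pooled variance with equal means gives
  p = 1, with unequal means p = 0; zero total variance reports the ANOVA
  p as 1 with no flags.

## Validation strategy and problem sizes

The test suite certifies the pipeline against computations that share no
code with it: a per-pixel brute-force recomputation of the fusion index
(50 random ground-truth scenes, exact agreement required), direct-
convolution peak enumeration for the detector, closed-form contrast
cases, and the simulator's exact ground truth. Default-condition recovery
runs 20 simulated 384 x 384 px fields (~130 nuclei, ~15 fibers each):
nucleus recall and precision must reach 0.95, every true fiber an IoU of
0.7, and the scene fusion index must sit within 5 percentage points of
truth. Dynamics checks use 4 schedules x 3 wells at day 10 plus two
8-day single-well time courses; statistical calibration uses 1000
simulated null plates and 400 powered plates at n = 3. These sizes keep
the whole suite around a minute on one core while leaving each check
enough resolution to fail visibly; `scripts/acceptance.R` re-runs the
same battery from scratch at any seed.

## Known limitations

* No nucleus splitting beyond minimum-separation suppression and no fiber
  splitting: dense cultures bias the nuclei count down and merged fibers
  inherit all contained nuclei.
* One focal plane; multi-layer growth is invisible.
* The fusion index is computed per field and pooled per well; the package
  does not model within-well field correlation.
* The simulator's well-to-well variability is a single multiplicative
  factor on the fusion rate; real replicate structure is richer.
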