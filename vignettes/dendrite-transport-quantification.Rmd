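---
title: "Quantifying dendritic receptor transport, surface puncta and locus enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dendritic receptor transport, surface puncta and locus enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrawave)
```

## The assay and the model

`dendrawave` implements the quantification pipeline of a photoconversion
pulse-chase assay for dendritic receptor transport, together with the 3D
puncta, nanodomain and colocalization measurements used on super-resolution
volumes of dendrite segments, and the enrichment statistics used to relate
differentially expressed (DE) gene lists to disease-associated loci.

In the pulse-chase assay a photoconvertible tag (e.g. Dendra2 fused to the
obligatory NMDA-receptor subunit GluN1) is switched within a region of
interest (ROI) on a primary dendrite, and the red (converted) pool is imaged
every 15 s for 3 min. The dendrite is divided into 5-µm arc-length bins on
either side of the ROI, the red fluorescence is integrated per bin and frame,
and each bin's intensity is normalised twice: by the bin's area, and by the
per-area intensity of bin zero (the ROI footprint) at time zero. The
resulting *wave matrix* `value(direction, bin, t)` equals 1 in bin zero at
t = 0 by construction and is invariant to any global intensity gain.

Two per-neuron velocity estimators summarise the wave:

* **Crest (time-to-peak) velocity** — for the 10- and 15-µm bins, the
  earliest time at which the bin's trace attains its maximum, converted as
  `v = label / t_peak` and averaged over the two bins. Bins whose maximum
  sits on the window boundary carry no interior peak and are excluded. This
  tracks the slow, bulk receptor pool (around 0.2 µm/s in control neurons).
* **Leading-edge velocity** — for the 25–40-µm bins, which only fast cargo
  reaches within the window, the earliest time at which the trace exceeds
  `baseline + k·sigma` for two consecutive frames (`k = 3`; `sigma` is the
  robust SD of t = 0 values across all bins at or beyond 25 µm), converted as
  `v = label / t_appear` and averaged over detected bins. This tracks the
  fast, vesicular pool (around 0.82 µm/s in control neurons).

`classify_populations()` then asks whether the two estimators describe
distinct kinematic classes across neurons (paired two-tailed t test at
alpha = 0.05, fast mean above slow mean).

### Conventions the assay leaves open

Published descriptions of this assay leave several conventions unstated;
the package fixes them explicitly and exposes each as an argument:

* **Bin origin and labels.** Bins are measured from the ROI *edge*, and a
  bin's label is the distance to its *outer* boundary, so the "10-µm bin"
  spans (5, 10] µm beyond the ROI. This keeps bin zero equal to the ROI
  footprint whatever the ROI length. Intervals are half-open and
  outer-boundary-inclusive; boundary pixels go to the more proximal bin.
* **Distance in v = d/t.** The bin label, matching the convention in which a
  peak at 50 s in the 10-µm bin is 0.2 µm/s; a bin-centre option exists.
* **Background.** Subtracted before normalisation, as the per-frame mean of
  an off-cell region (or a constant). On offset-free synthetic data this is
  an identity; on camera data it is required for the ratio to be meaningful.
* **Analysis window.** 120 s by default even when 180 s were acquired
  (`window` argument), reflecting the common practice of analysing the
  initial 2 min where the wave is within the binned extent.
* **"Appearance" of the leading edge.** Operator-judged in practice; here
  formalised as the k·sigma two-consecutive-frame rule above, which is
  deterministic and noise-robust. `k_sigma` is an argument.

## The synthetic-data generator

Because the assay's raw microscopy is not publicly deposited, the package
ships a generator whose defaults *are* the study conditions: 15-s frames for
180 s, a 5-µm ROI centred on a 100 × 2 µm dendrite, 0.2 µm pixels, and a
particle mixture whose two motile classes move at 0.2 and 0.82 µm/s.
`simulate_pulse_chase()` renders movies (Gaussian PSF, sigma 0.25 µm;
constant background; Poisson noise) and returns per-particle ground truth;
`simulate_wave_set()` integrates the same kinematics directly into bin
counts, skipping rendering, for simulation studies.

Choices the published conditions do not pin down, and why we set them so:

* **Population mix** — 20% stationary; of the motile particles, 80% slow and
  20% fast, split evenly between distal and proximal. The slow pool is the
  documented majority; the fast fraction is a minority pool large enough to
  carry a detectable leading edge.
* **Slow-pool dynamics** — advection at `v_slow` plus Brownian motion with
  D = 0.05 µm²/s. The diffusion term spreads the crest realistically without
  moving its centre, so the time-to-peak estimator still tracks `v_slow`.
* **Fast-pool dynamics** — advection with a per-particle speed drawn around
  `v_fast` (CV 0.18, sample-centred so the pool mean is exactly `v_fast`).
  A plug of identical speeds would cross a 5-µm bin in about 12 s — less
  than one frame interval — so the two-consecutive-frame appearance rule
  could never latch onto it; dispersion is also the physically expected
  behaviour of motor-driven cargo. The CV was calibrated (once, over a grid)
  so the leading-edge estimator tracks `v_fast` on default movies, which is
  precisely the generator's stated purpose.
* **Photon budget** — 50 photons per particle per frame against a background
  of 5 photons per pixel, putting the fast pool's edge-bin signal at roughly
  10–15× the per-bin background noise, the regime a 3-sigma detection rule
  needs. The ROI length is set to the bin width (5 µm), which makes the bin
  label equal the distance from the ROI centre to the bin centre and the
  label-based conversion unbiased for the crest.
* **Boundaries** — particles reaching a dendrite tip are absorbed and the
  ground truth flags it; conservation properties are only asserted on
  configurations whose particles stay in the field.

What the generator does *not* emulate: photoconversion photophysics
(conversion is instantaneous and complete), bleaching, dendrite branching or
curvature-dependent width, spine compartments, and camera read noise. Tests
passing on this generator therefore demonstrate that the *estimators recover
known kinematics through the full image path*, not that any particular
biological effect size is reproduced.

A practical note on the estimators' error structure, visible in simulation:
the 15-s frame grid quantises both estimators (time-to-peak can only land on
frames, so single-neuron crest estimates cluster at 10/45 and 15/75 µm/s),
and the 25-µm bin sits exactly where the slow pool arrives near the end of
the 120-s window, so when a neuron's fast pulse is missed there the rule can
latch onto the slow arrival instead. Averaging the four edge bins and twenty
neurons keeps the recovered means within a few percent of the configured
velocities, which is the accuracy claim the package makes.

## 3D puncta, nanodomains and colocalization

`make_coloc_volume()` builds two-channel volumes of a dendrite segment
(cylindrical mask) with ellipsoidal receptor puncta in channel A and
clustered scaffold nanodomains in channel B; a configurable fraction of A
puncta is co-placed on B nanodomains. Blob "radii" are half-max semi-axes,
so an isolated punctum's supra-half-max voxel volume approximates its
analytic ellipsoid volume — that is the ground truth the segmentation tests
recover.

`segment_puncta()` thresholds (Otsu within the mask by default), labels
supra-threshold voxels by 26-connectivity and, optionally, splits touching
objects by an intensity watershed on the Gaussian-smoothed volume; objects
below `min_volume` (default 8 voxels) are discarded. These defaults stand in
for the unpublished settings of commercial isosurface tools; all are
arguments, and only relative comparisons depend on them. `puncta_metrics()`
reports density, total and mean punctum volume, each normalised to the
dendrite mask volume. `detect_nanodomains()` finds smoothed local maxima
with non-maximum suppression; `cluster_nanodomains()` groups centres by
single linkage at 0.3 µm (about twice the lateral resolution of the
structured-illumination imaging this emulates; complete linkage available)
and returns the nanodomains-per-cluster histogram and the single-nanodomain
density. Pearson and Manders coefficients (`coloc()`) are computed within
the dendrite mask, with automatic per-channel Otsu thresholds for the
thresholded Manders variants by default; no randomisation significance test
is attempted.

Numerical notes: anisotropic voxel sizes are honoured in smoothing,
distances and non-maximum suppression; the watershed operates on the voxel
grid. Detection recovers planted layouts exactly when centre separations
exceed both twice the smoothing sigma and the suppression radius — the
regime the bundled tests exercise; closer layouts merge, as they would
optically.

## Group statistics and locus enrichment

`group_compare()` fronts the tests used for such imaging panels: two-tailed
t (pooled variance by default, Welch optional), one-way ANOVA with pairwise
Bonferroni post-tests, Kruskal–Wallis with Dunn's rank-based z post-test
(Bonferroni-adjusted across the reported pairs — the adjustment is not
always named alongside "Dunn's test", so it is stated here), and two-way
ANOVA with interaction. `paired_wave_test()` compares two groups of wave
matrices bin by bin, pairing on the timepoint: per bin, the per-timepoint
difference of group means is tested against zero. Because the pairing
dimension is time, this test is sensitive to *sustained* shifts in a bin's
occupancy and insensitive to purely multiplicative scaling of a transient
signal (the mean difference is diluted and the difference series inherits
the wave's own temporal structure); the bundled power analysis accordingly
plants an additive occupancy shift (0.05 normalised units on the 25-µm bin),
which 20 neurons per group detect with essentially full power.

`locus_enrichment()` reports two statistics deliberately: a gene-level
upper-tail hypergeometric probability P(X ≥ k) for the overlap k between K
DE genes and the n genes contained in the loci (universe N), and a
locus-level permutation test for the number of loci containing at least one
DE gene, with K genes redrawn uniformly `n_permutations` times (default
10,000, seeded; p = (1 + #{null ≥ observed}) / (n_permutations + 1)). A
published "hypergeometric probability" attached to a loci-with-at-least-one-
hit statement does not determine how loci were made exchangeable; reporting
both the well-defined gene-level test and a size-respecting locus-level null
avoids guessing. `make_enrichment_universe()` generates universes at the
study's scale (22,753 genes, 1,256 DE, 108 loci over 348 genes by default)
with DE genes drawn without replacement at a planted locus fold-enrichment
(default 1.7, the effect size implied by those counts; fold 1 is the null).

## Problem sizes and known limitations

The bundled simulation studies use 20 rendered movies (400 particles,
500 × 30 px, 13 frames) for velocity recovery, 50 analytic wave sets per arm
for power, and 64³-voxel volumes for the 3D analyses — sizes at which every
result in the test suite and the acceptance script reproduces in a couple of
minutes on one CPU, while leaving the estimators' noise regimes realistic.

Limitations to keep in mind: velocities are quantised by the 15-s frame
grid, so per-neuron values are coarse and only across-neuron means are
meaningful; the leading-edge rule can latch onto the slow pool's late
arrival in the innermost edge bin (see above); curved dendrites are
supported through traced polylines but the bundled generator renders
straight ribbons; and the locus-level permutation test conditions on the
observed locus definitions, not on genomic position or LD structure.
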