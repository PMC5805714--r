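---
title: "Quantifying tumor vasculature, junctions and nuclear markers with vasquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor vasculature, junctions and nuclear markers with vasquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasquant)
```

## What the package measures

Tumor angiogenesis studies quantify the vascular phenotype from multi-channel
2D fluorescence micrographs: how many vessels a field contains, how long and
wide they are and how often they branch (CD31 channel); which fraction is
functionally perfused (intravenously injected lectin); how leaky the network
is (extravasated dextran tracer); how continuous the endothelial adherens
junctions are (VE-cadherin, "VEC"); and how much of a transcription factor
such as HIF-2&alpha; accumulates in nuclei (DAPI plus a marker channel).
`vasquant` implements each of these measurements as an explicit, testable
pipeline, together with the surrounding assay arithmetic (caliper tumor
volume, qPCR 2^-ddCt relative quantities, immunohistochemistry H-scores,
standard-curve interpolation, ChIP enrichment relative to input, 2x2 Pearson
chi-square, Spearman rank correlation).

Because real animal and patient micrographs are rarely shareable, the package
ships a synthetic-microscopy generator that renders vessel, nucleus and
junction fields with exactly known geometry. Every pipeline is validated
against that ground truth, so the accuracy statements below are measured, not
assumed.

## Vessel morphometry

`vessel_pipeline()` follows the classical chain: global histogram
equalization (256-bin CDF mapping), multiscale Hessian vesselness, Otsu
segmentation, mask cleanup (hole filling and speck removal), homotopic
thinning to a 1-px skeleton, branch-point detection, and per-vessel length
and diameter.

The 2D vesselness at scale $\sigma$ uses the scale-normalized Hessian
($\sigma^2$-weighted Gaussian second derivatives); with eigenvalues ordered
$|\lambda_1| \le |\lambda_2|$ the response is zero where $\lambda_2 > 0$
(bright tubes have strongly negative principal curvature) and otherwise

$$ V_\sigma = \exp\!\left(-\frac{R_b^2}{2\beta^2}\right)
   \left(1 - \exp\!\left(-\frac{S^2}{2c^2}\right)\right),
   \qquad R_b = \frac{\lambda_1}{\lambda_2},\;
   S = \sqrt{\lambda_1^2 + \lambda_2^2}, $$

maximized over scales. Defaults: $\sigma \in \{1,2,3,4\}$ px, $\beta = 0.5$,
and $c$ set per scale to half the maximal Frobenius Hessian norm - the
conventional 2D settings, covering vessel radii of roughly 1-6 px at the
intended magnification. The truncated second-derivative kernel is
mean-centred so a flat image has exactly zero response.

Two design choices deserve explanation:

* **Detection vs. boundary.** The vesselness map is excellent at *finding*
  tubular structures but its Otsu mask does not delimit the lumen: the
  response decays gradually off-axis. In fluorescence the intensity
  half-maximum sits at the tube boundary, so by default the final mask is the
  Otsu mask of the *raw intensity*, restricted to connected structures that
  overlap the vesselness mask (`boundary = "intensity"`). Equalization feeds
  only the vesselness stage; a global equalization of a sparse field spreads
  the background over most of the dynamic range and would corrupt a direct
  intensity threshold.
* **Skeleton post-processing.** Zhang-Suen thinning leaves staircase corner
  pixels on oblique tubes; these are removed by a sequential redundant-pixel
  pass, and branch points are defined as skeleton pixels with at least three
  neighbours *and* Hilditch crossing number of at least three, with adjacent
  branch pixels (and branch clusters closer than the local vessel diameter)
  merged. Without these steps, straight oblique tubes sprout spurious
  branches.

**Length.** Chains are measured by chord resampling (anchors every 4 px)
rather than the 1/&radic;2 step rule, which overestimates oblique digital
lines by up to 8%; `vessel_length()` offers both. Thinning retracts the
skeleton from each tube end by roughly one radius, so open ends are extended
by marching along the chain direction to the mask boundary and subtracting
the in-image part of the rounded end cap (the full local radius at interior
ends; at a border exit, the fraction of the cap the field still contains).
Chain ends whose distance-transform value collapses below 0.6 of the
segment's median are trimmed first - inside an end cap the thinned skeleton
may curl unreliably.

**Diameter.** The Euclidean distance transform evaluated on the (trimmed)
skeleton gives the local radius; the per-vessel diameter is twice its mean.
No half-pixel correction is applied: the digital EDT's center-to-boundary
overestimate (about +0.5 px) and the skeleton's slight off-center wander
cancel almost exactly, a balance verified on hundreds of generated tubes
(residual bias about +1%). Centerline stretches running closer to the image
border than their own radius belong to tubes clipped by the field of view
and are excluded, because the EDT there reads the visible half-band.

Measured on the generator's default conditions (128 x 128 px fields, three
non-overlapping vessels of radius 3-5 px, 30% branching), per-vessel lengths
recover truth within 5%, diameters within 10% and branch counts exactly, over
hundreds of seeded fields; with the default acquisition noise, counts stay
exact and the metrics stay within 15%.

## Perfusion, leakage and VEC/CD31 area

Perfusion is object-based, as in intravital lectin experiments: CD31+
structures (8-connected, area above the particle-size threshold) count as
double-positive when at least `overlap_fraction` (default 0.3) of their
pixels are lectin-positive; the paper-style readout is the percentage of
double-positive structures. An any-overlap rule would be noise-fragile, so
the fraction is configurable and reported.

The leakage index divides background-subtracted extravascular dextran
intensity by the perfused-vessel count. "Extravascular" is everything
outside the vessel mask dilated by 1 px (absorbing boundary bleed);
background is a percentile (default the median) of the extravascular pixels.

`vec_area_fraction()` is the pixel-count ratio
$100\,|VEC \cap CD31| / |CD31|$.

## Nuclear marker quantification

`segment_nuclei()` smooths the DAPI channel, thresholds it with Otsu, then
refines the threshold to the midpoint of the two class *medians*: on a
sparse bimodal histogram Otsu settles below the half-maximum and inflates
every nucleus by a boundary ring (about 7% in area under default noise),
which propagates into the stained-area ratio. After hole filling and size
filtering, touching nuclei are split by a distance-transform watershed.
`nuclear_marker_metrics()` applies the same half-maximum logic to the marker
threshold (Otsu restricted to nuclear pixels, then class-median midpoint) and
reports the per-nucleus stained-area fraction and mean intensity;
`subtract_background()` provides the rolling-minimum (morphological opening)
background correction. `normalize_to_group_min()` implements normalization
to the reference-group minimum, a scale-invariant, idempotent transform.

Under default noise, the median absolute error of the recovered per-nucleus
marker fraction is about 0.045 (validated over 50 seeded fields, 8 nuclei
each), with nucleus counts exact for non-touching nuclei.

## Junction continuity

`junction_length()` restricts a hysteresis mask of the VEC channel (defaults:
high = Otsu within the CD31 compartment, low = half of it) to the CD31 area,
thins it, and measures each connected run with the chain rule plus flat-end
retraction correction (VEC runs terminate flat, unlike vessel caps).

`junction_pipeline()` reconstructs per-interface continuity: interface
centerlines are the pruned skeleton chains of the compartment mask; every
VEC-positive pixel projects onto its nearest chain pixel; a chain position is
stained when at least one pixel projects onto it. Uncovered stretches are
classified by image evidence - a stretch only counts as a gap when some of
its positions lie at least `gap_evidence_px` (default 2.6 px) away from all
VEC stain. That threshold sits in the middle of an empirically empty zone:
on generated fields, projection artifacts (dropout inside runs, slack at run
ends) never exceeded 1.5 px of stain distance while true gap remnants always
reached 3 px. Gap remnants split across two chains at a node are clustered
(within 5 px) and counted once. Runs of at least `min_run_um` (default 2 um)
count as continuous junction, shorter ones as discontinuous, and the gap
index is gaps per 100 um of interface; these thresholds are declared
assumptions surfaced in the configuration, not literature constants.

On noise-free generated monolayers (coverages 0.5-0.85), recovered gap
counts matched truth exactly in 180 of 180 fields and total stained length
stayed within 5%.

## The synthetic-microscopy generator

* **Vessels** are anti-aliased capsules around bounded-curvature random
  walks (optionally one child branch, which must clear its parent by a tube
  diameter so the two remain separable); the intensity profile is a flat
  core with a 1-px linear soft edge, putting the half-maximum contour at the
  true radius. Placement retries against an occupancy mask keep vessels
  non-overlapping; walk length relaxes as the field gets crowded.
* **Nuclei** are non-overlapping ellipses; the marker-positive region is the
  concentric sub-ellipse $u \le f$ of the squared normalized radius, whose
  area is *exactly* the requested fraction $f$ of the nucleus.
* **Junctions** form a jittered rectangular grid of cell interfaces; stained
  runs alternate with gaps of exactly `gap_length_px` (default 8 px), the
  number of gaps giving the closest achievable coverage. A wider band along
  every interface provides the compartment (CD31) channel.
* **Noise** is Gaussian PSF blur (mass-conserving), optional Poisson photon
  resampling (200 photons per intensity unit by default), constant
  background and additive Gaussian read noise - defaults 1 px PSF, 0.05
  background, 0.02 read noise, chosen as a mid-range fluorescence budget.
  All randomness flows through explicit seeds; global random state is saved
  and restored.

What the generator does *not* emulate: tissue autofluorescence texture,
uneven illumination, 3D projection effects, vessel tortuosity beyond bounded
curvature, overlapping or clustered nuclei, and irregular (non-grid) cell
mosaics. Passing the recovery suites therefore demonstrates correctness of
the measurement chain, not robustness to every real-microscopy artifact.

## Assay statistics

The toolkit reimplements only the arithmetic the imaging study itself
performs: tumor volume $V = w^2 l / 2$; 2^-ddCt relative quantities
calibrated to the lowest-expressing sample (so the calibrator's Rq is
exactly 1); H-scores (percent stained x intensity grade 1-3, range 0-300);
least-squares standard curves, optionally in log coordinates (a log2 qPCR
dilution series has slope in Ct per doubling), with inverse interpolation
and extrapolation flagging; ChIP signal relative to a 1% input after
subtracting the IgG mock; the 2x2 Pearson chi-square in product form with
the 1-df p-value; and Spearman's rank correlation with midranks, whose
two-sided p-value is exact (full permutation enumeration) up to n = 10 and a
t-approximation beyond. The chi-square applies no continuity correction by
default: on the vessel NO-staining classification counts (35/11 vs 17/17,
from 76% of 46 and 50% of 34 structures) the uncorrected statistic gives
p = 0.016 while Yates' correction gives 0.029; the uncorrected form is the
one matching the worked example, and the correction remains available via
`correct = TRUE`. General-purpose tests (t, ANOVA) are deliberately left to
base R.

## Numerical choices and degenerate inputs

* Otsu thresholding bins over the observed intensity range with exact
  per-bin value sums, making the chosen cut identical to an exhaustive
  search and exactly invariant to constant offsets; constant images are an
  error (no threshold exists).
* Histogram equalization returns constant images unchanged; it bins over
  the full normalized range so the CDF mapping is reproducible across
  images of one acquisition depth.
* Empty masks: particle analysis reports a *missing* mean area (never 0);
  nucleus segmentation returns zero labels; an empty CD31 mask is an error
  for ratios whose denominator it forms.
* An unstained interface reports missing continuity percentages and one
  whole-interface gap.
* Ties in Otsu's criterion resolve to the lowest threshold; ties in ranks
  use midranks.

## Known limitations

* Vessels clipped by the field of view hide part of their width; the
  diameter estimator excludes border-constrained stretches, but a vessel
  lying mostly along a border (or arcing through a corner) can still carry
  up to ~8% length and ~10% diameter error. Such fields should be measured
  at larger fields of view in practice.
* Junction metrics assume the stain sits on cell interfaces recoverable by
  thinning the compartment mask; strongly fragmented compartments would
  need a supplied cell mask (supported via the `cd31` argument taking a
  precomputed `binary_mask`).
* The thinning-based junction position migrates into acute branch angles by
  up to $r/\tan(\theta/2)$; branch *counts* are unaffected.

## Reproducing the verification

The demonstration scale used throughout the test-suite and the acceptance
script - 128 x 128 px fields, 3 vessels or 8 nuclei or a 3 x 3 cell grid per
field, tens to a hundred seeded replicates per claim - was chosen as the
smallest scale at which every estimator's error structure is visible.
`run_study()` executes the full two-arm workflow (control vs. treated
fields, all three modalities, group summaries, run manifest with a
configuration fingerprint) deterministically from one seed, and
`scripts/acceptance.R` recomputes the headline numbers from scratch.
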