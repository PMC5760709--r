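---
title: "Methods: models, estimators and the synthetic-data generator"
author: "memphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and the synthetic-data generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memphys)
```

# Scope

`memphys` analyses five kinds of membrane-biophysics measurements used to
compare control macrophages with glycosphingolipid-enriched (Gaucher-model)
macrophages: FRAP recovery curves, steady-state fluorometry (TMA-DPH
anisotropy and Laurdan generalized polarization), two-photon Laurdan GP
images, AFM force-vs-separation curves, and multi-channel confocal images
of endocytosed ligand or STAT1. Because such raw microscopy/AFM data are
rarely deposited, the package ships a synthetic-data generator whose named
presets (`"control"`, `"gaucher"`) encode the published condition values,
so every analysis stage is validated by parameter recovery: simulate with
known truth, analyse, compare.

# FRAP

## Double normalization

Raw records consist of the mean intensity of the bleached ROI $I(t)$, of
the whole membrane mask $T(t)$ and of a background ROI $bg(t)$.
`doubleNormalize()` computes

$$R(t) = \frac{I(t) - bg(t)}{I(0) - bg(0)} \cdot
         \frac{T(0) - bg(0)}{T(t) - bg(t)},$$

where the "$(0)$" quantities are means over all pre-bleach frames. The
first factor normalizes to the pre-bleach level; the second divides out
acquisition photobleaching, which affects $I$ and $T$ identically. Two
invariances follow and are enforced by tests: a global positive rescaling
of the signals leaves $R$ unchanged, and so does any shared per-frame
decay. Non-positive denominators abort with the offending frame named,
rather than propagating infinities.

## Recovery model and fitting

`fitRecovery()` fits the empirical single-exponential recovery

$$R(t) = R(0) - a + a\,(1 - b)\,(1 - e^{-t/\tau})$$

to the post-bleach frames ($t$ re-zeroed at the first post-bleach frame):
$a$ is the extent of bleaching, $b$ the immobile fraction and $\tau$ the
empirical recovery time constant. The fit is bounded
Levenberg-Marquardt least squares (`minpack.lm::nlsLM`) with
$a, b \in [0, 1]$, $\tau \in (0, 10\,t_{\max}]$, and a fixed start point
($a = 1 - R(\text{first post frame})$, $b = 0.2$, $\tau$ from the
half-rise time). Design choices:

* **$R(0)$ is fixed to the pre-bleach mean**, not fitted. The model has
  three unknowns; a free offset trades against $a$ and $b$ and degrades
  identifiability.
* **Confidence intervals** are 95% Wald intervals from the fit
  covariance, *plus* a delta-method term propagating the sampling
  variance of the fixed $R(0)$ (computed by a one-sided refit at
  $R(0) + h$). Without this term the intervals are markedly
  anticonservative, because an error in the pre-bleach mean shifts $a$
  and $b$ coherently across the entire fit; with it, simulated coverage
  for $b$ sits in the mid-90% range. Covariance-based intervals were
  chosen over profile likelihood for speed and because the model is
  near-quadratic around the optimum at the noise levels involved; the
  interval type is visible in the object documentation.
* **Fitting the averaged curve** is the default workflow
  (`averageCurves()` then `fitRecovery()`); per-record fitting works on
  any single normalized curve.
* A perfectly flat post-bleach curve (fully immobile pool) makes $\tau$
  unidentifiable; the fit then returns $a = R(0) - \bar R_{\text{post}}$,
  $b = 1$ and flags the degeneracy instead of failing.
* Condition comparisons use confidence-interval overlap
  (`ciOverlaps()`), mirroring how fitted-parameter differences are
  usually assessed when each condition yields one averaged-curve fit.

# Scalar photophysics

`anisotropy()` implements the L-format formula
$r = (I_{vv} - G I_{vh}) / (I_{vv} + 2 G I_{vh})$; the instrument factor
$G$ is always supplied by the user, never estimated, because it is a
property of the detection path. `generalizedPolarization()` implements
$GP = (I_{blue} - I_{red}) / (I_{blue} + I_{red})$, elementwise over
arrays; scalar zero-sum input is an error while array pixels with zero
sum become `NA` so single empty pixels cannot abort image processing.
Both quantities are invariant to common positive scaling, and GP is
antisymmetric under channel swap; both properties are tested.

# GP imaging and domain segmentation

`gpMap()` subtracts per-channel scalar backgrounds, clips negative
corrected intensities to zero, marks pixels with non-positive corrected
sum invalid, and applies the GP formula elsewhere. `segmentGpDomains()`
thresholds the map into a high-GP (ordered, raft-like) and a low-GP
(disordered) mask and reports the high-GP area fraction
$|high| / (|high| + |low|)$.

The original workflow chose the threshold by visual inspection, which is
not reproducible. The package's default replaces it with a deterministic
rule: **Otsu's threshold computed on the pooled GP histogram of all
images in a comparison set** (`pooledGpThreshold()`), then applied
identically to every image. This honours the crucial shared-threshold
contract - images being compared must be segmented with the same cutoff -
while removing the subjective step; a numeric threshold can always be
supplied instead and is recorded in the result. The display range of GP
colour maps is presentation only and plays no role in computation.

# AFM force curves

## Contact point and Hertz fit

`findContactPoint()` fits a piecewise model - flat baseline, then
quadratic contact region - and returns the breakpoint minimizing total
squared error, scanning a coarse-to-fine grid of sample positions and
finishing with a continuous optimization between samples. A constant
force offset is absorbed by the baseline. Curves with no
super-threshold deflection raise a "no contact" error.

`fitHertz()` uses the four-sided pyramidal indenter form of the Hertz
model,

$$F = \frac{E}{1 - \nu^2} \cdot \frac{\tan\alpha}{\sqrt 2} \cdot \delta^2,$$

with $\delta$ the indentation beyond the contact point, defaults
$\nu = 0.5$ (incompressible cell) and face half-angle $\alpha = 35°$,
both configurable. Given the contact point the model is linear in $E$,
so the fit is closed-form linear least squares with a free baseline
offset; a negative slope is clamped to $E = 0$ and flagged. The fit
range runs from the contact point to the 1 nN load cap, mirroring the
acquisition trigger. `modulusHeightProfile()` averages fitted moduli in
25 equal-width height bins by default; binning is relative to the
observed height range, which sidesteps any ambiguity about the height
zero reference.

## Tether step detection

Rupture of a membrane tether produces an abrupt force step on the
retraction segment. `detectSteps()` runs two independent detectors and
reports their consensus, replacing interactive visual correction with a
deterministic rule:

* **Algorithm A - iterative step-function fitting.** Binary
  segmentation: the breakpoint giving the largest variance reduction is
  added greedily while the implied jump exceeds $k\sigma$, where
  $\sigma$ is the robust noise scale (MAD of first differences divided
  by $\sqrt 2$); adjacent segments whose means differ by less than
  $k\sigma$ are then re-merged. On noiseless piecewise-constant traces
  this is exact and equals a brute-force enumeration of all jumps, which
  the tests assert.
* **Algorithm B - smoothed-derivative thresholding.** The difference of
  $w$-sample means after/before each boundary is thresholded at
  $k\sigma\sqrt{2/w}$ with non-maximum suppression at a minimum
  separation.
* **Consensus**: A-events with a B-event within a 10-sample matching
  window; positions and heights are taken from A. Both full event sets
  are retained in the result.

Defaults are $k = 3$, $w = 3$ and a 3-sample minimum separation -
deliberately small windows, because at the simulator's sampling density
(4 nm per sample) closely spaced ruptures must remain separable for
per-curve counts to stay unbiased at the higher tether numbers of the
Gaucher-like condition. The step *height* (magnitude of the force jump)
is reported as the tether force; adhesive forces are negative on
retraction by convention, so detachment steps rise toward the baseline.
`tetherStatistics()` pools step heights across curves (median force) and
summarizes per-curve counts (mean, SD) with histogram tables.

# Cell segmentation and intensity fractions

`detectNuclei()` follows the marker-controlled watershed recipe widely
used for clustered nuclei: Gaussian smoothing, Otsu foreground
detection, watershed on the smoothed intensity with an h-maxima-style
tolerance that merges seeds across weak boundaries, small-object
removal, and shape-based splitting of remaining clusters by a
distance-transform watershed. The shape test compares a component's
area with $\pi r_{\max}^2$ of its maximum inscribed radius (ratio above
1.35 triggers a split attempt); round single nuclei sit near 1.0-1.1 and
fused pairs well above.

`segmentCells()` shrinks each nucleus to its centroid pixel and grows a
seeded watershed (`EBImage::propagate`) over the thresholded,
hole-filled membrane-channel foreground, yielding one region per
nucleus. Each cell's boundary ring, thickened inward by `thickenPx`
pixels (default 5 at the simulator's pixel scale; no published width
exists, so the value is logged in results), forms the membrane mask; the
remainder is the intracellular mask. The two masks are disjoint and
tile the cell, so membrane + intracellular intensity equals the
whole-cell intensity exactly - a conservation law the tests assert.

`endocytosedFraction()` and `nuclearFraction()` subtract a scalar
background (negative pixels clipped to zero; the background comes from a
user ROI or a low-percentile estimate) and form per-cell ratios:
intracellular over total cellular signal, and nuclear over whole-cell
signal (membrane included), respectively. Cells touching the image
border are excluded by default since truncated masks bias fractions;
zero-total cells and nuclei outside any cell are flagged and excluded.
Fractions are invariant to global intensity rescaling.

# The synthetic-data generator

Every simulator takes a preset and an explicit integer seed, restores
the global RNG state afterwards, and emits its ground truth alongside
the record; identical (preset, seed) pairs are bit-identical. The preset
fields anchored to the published condition values are: immobile-fraction
ratio 3 (0.15 control vs 0.45 Gaucher-type), Young's modulus
median/mean 614/1031 vs 459/795 Pa, tether force median 30 vs 27 pN,
tether counts 4.8 ± 2.4 vs 11.1 ± 4.3 per curve, high-GP area fraction
0.13 vs 0.48, and endocytosed fractions 0.60 vs 0.30 (transferrin,
45 min) and 0.40 (cholera toxin B, both conditions).

Where only summary statistics are published, distribution shapes are
fixed design choices, used once and not revisited:

* **Young's modulus**: lognormal with $\sigma^2 = 2\ln(\text{mean}/\text{median})$,
  which reproduces both printed moments exactly
  ($\sigma \approx 1.02$ for the control pair).
* **Tether forces**: lognormal about the printed median with
  $\sigma_{\log} = 0.3$ - positive support, median preserved.
* **Tether counts**: rounded normal truncated at zero with the printed
  mean/SD (the truncation bias is below half a percent at these
  parameters).
* **FRAP**: absolute immobile fractions are published only graphically,
  so 0.15/0.45 preserves the printed 3-fold ratio; extent of bleaching
  0.6, recovery time constants 10 s (control) and 25 s (Gaucher-type,
  qualitatively slower), relative intensity noise 0.02, per-frame
  acquisition bleaching 0.003, 10 pre- and 100 post-bleach frames at
  1 s. The record is built by inverting the double-normalization formula
  so the noiseless curve reproduces the recovery model exactly;
  noise is applied last.
* **Force curves**: contact point uniform in 1.5-2.5 µm, approach from
  6 µm, 1 nN load cap, rupture positions uniform over 0.2-5.6 µm,
  Gaussian force noise 2 pN, 1500 samples per segment.
* **GP images**: the domain mask thresholds a Gaussian-smoothed random
  field (correlation length 8 px) at the quantile giving exactly the
  preset area fraction; GP levels are -0.60 (ordered) and -0.90
  (disordered) on the microscope-like display scale, with 5%
  multiplicative photon noise and an additive background of 10 recorded
  in the object.
* **Cell fields**: jittered-grid layout (no overlap), nucleus radius
  8 px, cell radius 20 px, membrane annulus 5 px. The endocytosed
  ligand share is placed in an interior disk kept 3 px clear of the
  membrane annulus, so a ±1-2 px segmentation-boundary error cannot
  reassign signal between compartments - intentionally favouring
  recovery accuracy over morphological realism.

What the generator does *not* emulate - and hence what passing tests do
not certify on real data: diffusion physics of the bleached spot (the
recovery curve is imposed, not simulated), optical point-spread and
shading, cantilever dynamics and hydrodynamic drag, tether force
plateaus between ruptures, irregular cell shapes, touching cells,
intensity gradients within compartments, and non-Gaussian detector
noise. Parameter recovery on these synthetics validates the estimators'
correctness and calibration, not their robustness to every real-world
artifact.

# Problem sizes and reproducibility

The shipped acceptance script (`scripts/acceptance.R`) regenerates all
headline quantities at the sizes used throughout: 500 retraction curves
per condition for tether statistics, 256 extension curves per condition
for modulus medians (the force-volume grid size), nine 512×512 image
pairs per condition for GP area fractions, one 100-cell field for
endocytosis, and ten averaged FRAP records per condition. One caveat is
worth stating: with the lognormal modulus spread implied by the printed
mean/median pair, the sample median of 256 draws has a relative SD of
about 8%, so the recovered modulus medians scatter around the published
values by several percent from run to run even though the Hertz fits
recover the drawn sample's median to better than 0.5%. The tether,
GP, endocytosis and FRAP targets are much more tightly determined at
their stated sizes.

# Known limitations

* The pooled-Otsu threshold assumes the pooled GP histogram is
  reasonably bimodal; sets dominated by one phase push the threshold
  toward the majority mode.
* The step detectors merge ruptures closer than a few samples;
  at physiological tether densities this costs at most a few percent of
  counts, but extremely clustered ruptures would be undercounted.
* Nucleus splitting assumes roughly convex nuclei; elongated or lobed
  nuclei may be over-split.
* `fitRecovery()` treats residuals as independent and homoscedastic;
  strongly autocorrelated acquisition noise would make the confidence
  intervals optimistic again.
* The Hertz model assumes small indentation of a homogeneous half-space;
  fitted moduli on real cells are effective values that mix membrane,
  cortex and cytoskeleton.
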