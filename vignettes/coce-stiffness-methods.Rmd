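---
title: "Methods: from compression OCT frames to mutation-predictive stiffness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from compression OCT frames to mutation-predictive stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elastoce)
```

## What the package models

Compression optical coherence elastography (C-OCE) derives tissue stiffness
from pairs of complex OCT B-scans acquired while the probe compresses the
sample quasi-statically. A reference silicone slab of pre-calibrated Young's
modulus (100 kPa) lies between the probe and the tissue. Because the slab and
the tissue column carry the same axial stress, the tangent Young's modulus of
the tissue is the silicone-to-tissue ratio of incremental strains scaled by
the silicone modulus:

E_tissue(x, z) = E_ref * eps_silicone / eps_tissue(x, z).

The package implements that chain end to end — speckle phantom, interframe
phase, phase-gradient ("vector" method) strain, pressure-standardized modulus
maps, ROI quantification — and, on top of it, the cohort-level question the
chain serves: whether per-ROI stiffness predicts the presence of KRAS / NRAS /
BRAF driver mutations in colorectal cancer better than histological growth
patterns do.

## Forward model (the phantom)

`build_phantom()` scatters point reflectors i.i.d. uniformly with
complex circular-Gaussian reflectivities (unit-mean exponential intensity).
At the default density of 10 scatterers per 10 x 15 um resolution cell this
produces fully developed speckle whose amplitudes follow a Rayleigh law — a
property the test suite checks with a Kolmogorov-Smirnov test against a
directly fitted Rayleigh distribution.

`simulate_compression_series()` treats the medium as a uniaxial stress
column with per-layer linear elasticity: at surface pressure P each layer
carries strain `eps = P / E`. Depth is measured from the probe contact (the
fixed boundary of the imaging frame); a scatterer resting at depth z appears
at the compressed depth `z - P * int_0^z dz'/E(z')`. Frames are formed by
depositing the displaced scatterers under a separable Gaussian PSF with FWHM
`(axial_resolution / n, lateral_resolution)` = (10/1.4, 15) um — matching the
stated resolutions without modeling the spectrometer — and adding complex
white Gaussian noise at a configurable SNR (default 25 dB). Scatterer phase
uses the analytic-signal convention `exp(-i (4 pi n / lambda0) d)` with
`n = 1.4` for both layers (the index cancels in the stiffness ratio, so only
phase realism depends on it); under compression the optical path shortens and
the interframe phase is `+(4 pi n / lambda0) * delta_u(z)`, positive slope
for compressive strain, which the package treats as positive throughout.

The simulator does not model wave propagation, spectral-domain detection,
3-D volumes, lateral displacement, or tissue viscoelasticity/nonlinearity.
Nonlinearity enters the real method only as the *motivation* for pressure
standardization, so the linear phantom can validate the standardization
mechanics (pressure inference from silicone strain) but not its benefit on
nonlinear tissue; the relative-variability comparison that would demonstrate
that benefit is deliberately out of scope.

## Strain estimation (the vector method)

`interframe_phase()` forms the pixelwise conjugate product of consecutive
frames; its argument is the wrapped interframe phase. `vector_strain()`
estimates the axial phase gradient per window by complex-vector averaging of
axial lag products, which is tolerant of phase wrapping because averaging
happens in the complex plane.

Two numerical points matter and are worth recording:

* **Lag-1 bias.** The windowed average of single-pixel lag products is biased
  toward zero phase: for lags inside the speckle correlation length
  (~1.5 axial pixels here) the product's expectation contains a real,
  positive speckle-autocorrelation cross-term in addition to the phase-ramp
  term. A pure lag-1 estimator under-read uniform strain by ~25% in our
  noiseless experiments. The implementation therefore uses the lag-1 product
  only as a wrap-safe coarse reference and forms the final estimate from lag
  products at lags 2..L — beyond the correlation length — each unwrapped
  about the coarse slope and weighted by `lag^2 * |vector sum|`
  (inverse-variance weighting, since speckle phase noise is independent of
  lag while the signal phase grows with it). L adapts so that the largest lag
  phase stays below ~0.7 pi, which keeps the estimator alias-free up to the
  strains the pipeline produces at its default pressure step.
* **Row alignment.** A lag-l product of rows (i, i+l) is centred at depth
  i + l/2; each lag map is shifted to the common half-pixel grid before
  combination, so layer boundaries do not migrate with the lag choice.

The default window is 8 x 8 px (40 x 60 um), matching an output resolution
roughly four times coarser than the native OCT images. The validity mask
flags pixels whose normalized lag-1 vector magnitude falls below 0.3 (a
standard decorrelation guard, configurable). At the default window and
SNR 25 dB the estimator recovers a uniform 5e-3 strain with < 2% bias;
per-pixel precision is speckle-limited (roughly 5-10% at 1 sigma), so the
pixelwise recovery check in the tests uses a 20 x 20 validation window where
>= 95% of valid pixels land within 5% of ground truth. `accumulate_strain()`
sums interframe strains at fixed pixel coordinates (a small-strain Eulerian
approximation; each increment is estimated in the configuration it refers
to) and refuses pairs whose expected phase change per resolution cell
exceeds pi.

## Stiffness mapping and pressure standardization

`segment_reference_layer()` finds the silicone band per column at the peak
of the axial strain gradient inside +/- 30% of the thickness hint — the
transition centre, which stays unbiased under window blur — with a running
median across columns (the layer is laterally continuous) and a documented
fallback to the hint thickness, with a warning, when the map has no layer
contrast. Note that the interface physically travels toward the probe by
3 um/kPa as the 300 um silicone compresses; the tests account for that.

`select_pressure_standard_pair()` reads the silicone as a local pressure
sensor (`pressure = E_ref * median cumulative silicone strain`) and returns
the first compression step inside the standardization window, 4 +/- 1 kPa by
default. `stiffness_from_strain()` then converts the *incremental* strain
map at that pair into Young's modulus. The silicone strain entering the
ratio is the global median over the reference mask by default (a per-column
mode exists for tilted contact); the choice between mean/median and
global/per-column is not dictated by the method description, so both are
implemented and the default is the more robust one. Moduli are capped at
2000 kPa (division guard; also the dark end of the display palette), and
quantification (`quantify_roi()`) averages only pixels above the 520 kPa
tumor-cell threshold, excluding the reference layer, reporting the masked
fraction alongside the mean.

## The synthetic cohort

`sample_cohort()` emulates the study cohort: 46 cases (33 low-grade, 13
high-grade) contributing 54 single-pattern ROIs (34 complex tubular, 6
mucinous, 14 solid). All categorical margins — pattern x mutation counts
(11/23, 3/3, 10/4), gene split (KRAS 20, NRAS 1, BRAF 3 among 24 mutant
ROIs; 16/1/3 among 20 mutant cases), MSI placement (3 high-grade cases, 4
ROIs) — are *assigned*, not sampled, so every cohort reproduces them
exactly; only the stiffness values are random. The case/ROI layout is
under-determined by the published margins, so the package fixes one
consistent assignment: eight dual-pattern cases, of which four are
tubular+solid with KRAS in both ROIs, one is the designated heterogeneous
case (id 21: tubular KRAS-mutant + mucinous wild-type, mirroring the
reported discordant case), and three are wild-type pairs.

Per-ROI stiffness is drawn from the mutation-group distributions — mutant
967 +/- 145 kPa, wild type 751 +/- 92 kPa — truncated by rejection at the
520 kPa floor (ROI stiffness is only defined over the >520 kPa mask, so
sub-floor means cannot occur). A `by_pattern` switch samples instead from
the per-pattern distributions (770 +/- 164, 968 +/- 234, 1039 +/- 270 kPa).
The generator emulates the *reported statistical structure* of the cohort,
not real tissue: it has no within-ROI heterogeneity, no correlation between
patterns within a case beyond the assigned labels, and normal (not skewed)
group distributions. Passing tests therefore show that the analysis chain
recovers the distributions it is pointed at, not that those distributions
describe new patients.

## Statistics and the classifier

Fisher's exact test (probability-mass two-sided rule) and the Mann-Whitney
U test are delegated to R's `fisher.test()` and `wilcox.test()` behind the
package's interfaces; the test suite validates both against independent
brute-force oracles (hypergeometric enumeration over all same-margin
tables; full label-assignment enumeration). The Mann-Whitney wrapper uses
exact enumeration for combined n <= 12 without ties and the tie-corrected
normal approximation with continuity correction otherwise; Bonferroni
adjustment is `min(1, m p)` with m always reported. The normal
approximation tracks the exact p to within 0.01 at group sizes around 10
and above; at n <= 6 the discrepancy can reach ~0.04 in the extreme tails,
which is inherent to the approximation, so the exact mode is the default
there.

`roc_curve()` sweeps all distinct values with the strict positive rule
"stiffness above threshold => mutant" (boundary equality is negative,
matching the way the cut-offs are phrased). AUC is trapezoidal and equals
U/(n_pos x n_neg) up to tie handling — asserted as an invariant.
`youden_threshold()` maximizes J = sensitivity + specificity - 1, breaking
ties toward the smallest threshold and reporting the midpoint of the
flanking observed values; the selection rule behind the published 803 / 850
kPa thresholds is not stated, and Youden's index is the standard,
reproducible choice. KRAS-specific evaluation counts NRAS/BRAF-mutant ROIs
as KRAS-wild-type negatives. All classifier metrics are in-sample (no
held-out set exists at n = 54), and are labelled as such in the report.

On cohorts drawn from the group distributions the mean AUC over 500
replicates sits near the binormal closed form
Phi(216 / sqrt(145^2 + 92^2)) ~ 0.896, the median Youden threshold lands
between the group means near the weighted density crossing (~874 kPa), and
the 803 kPa rule beats both pattern-as-marker baselines (33% / 67%
accuracy) in well over 95% of replicates — the package's quantitative
restatement of "stiffness predicts mutations better than morphology".

## Problem sizes and reproducibility

Simulation-based checks run on phantoms of 0.5-1 mm laterally and
0.6-1.2 mm in depth (5 x 7.5 um pixels), 2-21 frames per sweep, and on
100-500 cohort replicates — sizes chosen so the whole validation suite
completes in about a minute while keeping Monte-Carlo margins comfortable.
Every stochastic step takes an explicit integer seed; identical seeds give
bit-identical phantoms, cohorts and reports, and each report embeds its
seed and a configuration hash.

## Known limitations

* The strain estimator is speckle-limited; per-pixel values at the default
  window carry ~5-10% noise even without detector noise. Medians over
  blocks or ROIs are accurate to a few percent.
* The uniaxial-stress column ignores lateral mechanical coupling, friction
  at the probe, and incompressibility; it is the same idealization that
  justifies the stiffness ratio, so the phantom cannot detect violations of
  that assumption in real tissue.
* The vector method here is the standard wrap-tolerant complex-lag
  formulation; equivalence is to the described behaviour, not to any
  proprietary implementation.
* MSI labels are carried through the cohort but never modelled against
  stiffness (three MSI cases are too few to support inference).
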