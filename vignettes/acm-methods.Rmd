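---
title: "Spatially normalized anatomical connectivity mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially normalized anatomical connectivity mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(acmap)
```

## The problem

Anatomical connectivity mapping (ACM) turns probabilistic diffusion-MRI
tractography into a voxel-wise index of whole-brain connectedness: a fixed
number of probabilistic streamlines is launched from *every* brain voxel,
and each voxel's ACM value is the number of streamlines that pass through
it. Unlike localized microstructural indices such as fractional anisotropy
(FA), an ACM voxel is sensitive to damage anywhere along the pathways that
traverse it — attractive in diffuse diseases such as multiple sclerosis,
where focal lesion load correlates only weakly with disability.

Because streamline counts depend on brain shape and size, group comparison
requires a common space. This package follows the *normalize-then-track*
strategy: the fitted per-voxel fiber models are warped into a common atlas
grid (with proper tensor reorientation) and tractography is run there, so
every subject's ACM lives on the identical grid with comparable counts. The
alternative — tracking in native space and warping the scalar ACM — inherits
inter-subject shape variability in the counts themselves.

## Fiber model

Each voxel carries a multi-tensor model with at most two compartments,

$$S(\mathbf g, b) = S_0 \sum_{i=1}^{n} f_i
  \exp(-b\, \mathbf g^\top D_i \mathbf g), \qquad n \le 2,$$

with volume fractions $f_i \ge 0$, $\sum f_i = 1$. Two tensors is the
practical ceiling for a single shell near $b = 1000\text{–}1200$ s/mm².
Fitting proceeds in two stages: ordinary least squares on $\log S$ (exact on
noise-free data) and a Levenberg–Marquardt refinement in which each tensor
is parameterized by its Cholesky factor (positive semidefinite by
construction) and the fraction by a logistic transform (simplex by
construction). Convergence: relative RSS change below `1e-10` or 200
iterations.

The number of compartments per voxel is chosen by a nested-model F-test on
the residual sums of squares of the 7-parameter single-tensor and
14-parameter two-tensor fits, at level `alpha = 0.05`. The software suite
used in the original workflow selects model order with a spherical-harmonic
classification whose internals are not published alongside the method; the
F-test is this package's documented substitution and is exactly testable
(noise-free one-fiber data are classified 1, noise-free crossings 2).

## Spatial normalization and PPD

Deformations are consumed, not estimated: a `deformation_field` stores, on
the atlas grid, the displacement (mm) mapping each atlas position to its
subject position (pull-back convention). Analytic constructors (rigid,
affine, radial bump) ship with the package so every warp test runs without
any external registration tool.

Warping a tensor field samples the subject model at the mapped position by
*nearest neighbour* — interpolating model parameters between voxels with
different fiber counts is ill-defined — and reorients every component
tensor with the preservation-of-principal-direction (PPD) rule using the
local affine $F$ of the deformation (central finite differences at voxel
spacing; one-sided at grid edges):

1. $\mathbf n_1 = F \mathbf e_1 / \lVert F \mathbf e_1 \rVert$;
2. $\mathbf n_2 \propto F \mathbf e_2 - (\mathbf n_1^\top F \mathbf e_2)\,
   \mathbf n_1$;
3. $\mathbf n_3 = \mathbf n_1 \times \mathbf n_2$,

and the *original* eigenvalues are laid on the new frame — FA and MD are
preserved exactly, which the test suite asserts to $10^{-9}$.

The atrophy covariate for the group model is the atlas white-matter mask
modulated by $\det J$ of the atlas→subject deformation and divided by the
subject's intracranial volume (ICV, mm³). Whether head size should divide
or multiply is a free convention; division is this package's documented
choice, making the covariate a dimensionless relative tissue quantity.

## Orientation uncertainty (PICo) and tracking

Tracking noise-free tensors would be deterministic; the probabilistic
element is the uncertainty of the fitted fiber orientation at the
acquisition's SNR. Each fitted tensor becomes a Bingham lobe on the sphere,

$$p(\mathbf x) \propto \exp\!\big(\kappa_1 (\mathbf x^\top \mathbf u_1)^2 +
  \kappa_2 (\mathbf x^\top \mathbf u_2)^2\big),
  \qquad \kappa_1 \le \kappa_2 \le 0,$$

mode along $\mathbf u_3$ (the tensor's principal axis), antipodally
symmetric, with anisotropic dispersion ($\mathbf u_2$ = second eigenvector,
the less-suppressed direction). Concentrations come from Monte-Carlo
calibration: noise-free signals of a representative tensor are corrupted
with Rician noise ($\sigma = S_0/\mathrm{SNR}$, two Gaussian channels), a
single tensor is refit per trial, and a Bingham lobe is moment-matched to
the scatter of the refit principal axes. The moment equations
$E[(\mathbf x^\top \mathbf u_j)^2] = \tau_j$ are inverted numerically with
Gauss–Legendre × midpoint quadrature (64 × 128) of the normalizing
integral. Calibration is tabulated per tensor shape
($\lambda_1/\lambda_2$, $\lambda_2/\lambda_3$, bin width 0.5) and SNR;
lookup is nearest-bin. SNR = 16 is the default, matching the emulated acquisition.
$\kappa = -10^4$ is the documented floor, treated as a deterministic
direction. Calibration trials refit with the log-linear estimator by
default (`refine = TRUE` enables the nonlinear polish); the estimator
choice shifts the calibrated concentrations by far less than the
across-SNR differences the pipeline depends on.

Axes are drawn by rejection from an angular-central-Gaussian envelope
(Kent, Ganeiber & Mardia 2013) — an exact sampler whose acceptance stays
near 50% at any concentration. A plain uniform-sphere proposal is the
conceptually simplest correct sampler but its acceptance collapses like
$1/|\kappa|$ (measured 0.3% at the SNR-16 concentrations, a ~90× slowdown
of whole-phantom ACMs), so the ACG envelope is used throughout; both
samplers target the identical density, verified against quadrature moments.

Streamlines: seeds at voxel centers, bidirectional, step = 1/10 voxel.
At each step the fODF is sampled by *probabilistic nearest* interpolation
(one of the 8 surrounding voxels, chosen with its trilinear weight — per-axis
Bernoulli draws realize the product weight exactly), the lobe most aligned
with the heading is selected, an axis is drawn and flipped into the
heading's hemisphere. Termination: leaving the tracking mask, or more than
180° of cumulative turning *within the extent of one voxel* (the
doubling-back guard; the angular budget resets on voxel change — one
explicit reading of a rule that admits several), or a 2000-step cap
(plumbing, flagged in output).

## ACM and its precision

`compute_acm()` propagates `n_per_seed` streamlines from every seed voxel
and increments each *distinct* voxel a streamline visits (unique-visit
counting, step-size invariant; once-per-entry counting is available, and
never counts less). The seed mask follows the FA > 0 rule on the atlas FA
map. Precision is quantified by re-estimating the ACM (default 5 times) at
each candidate streamline count and averaging the voxel-wise coefficient
of variation CV = SD/mean (n−1 denominator, zero-mean voxels excluded)
over the mask; the companion SNR is mean/SD. CV falls steeply and then
saturates as the count grows — the reference protocol selects 500 streamlines per seed
from this curve, and the phantom tests reproduce the same saturating trend
at desk scale (CV(150) < CV(10)/2).

## Group statistics

ACM (and FA) volumes are smoothed with a 4 mm FWHM Gaussian
(σ = FWHM/2.3548 per axis, zero-padded separable convolution; the source
describes smoothing for ACM — both modalities are treated symmetrically
here so their GLMs differ only in the response). The voxel-wise GLM uses
group indicators (healthy as reference), age (centered), gender (0/1) and
optionally the per-voxel atrophy covariate; contrasts are one-tailed in
the hypothesized direction (patients lower). A Welch variant on
covariate-adjusted residuals is provided for unequal group variances.

Small-volume multiple-comparison control is *permutation maxT* within the
ROI with Freedman–Lane covariate handling (permute reduced-model
residuals, add back the nuisance fit, refit, record the in-ROI maximum t),
replacing the original workflow's random-field-theory small-volume
correction: the permutation scheme is distribution-free and its family-wise
error control is verified empirically in the test suite (200 null cohorts,
rejection rate inside the 95% binomial band around α = 0.05). FWE p-values
use the (1 + count)/(1 + permutations) estimator.

ROI analyses take the median statistic per subject and region (even counts:
midpoint of the central pair), correlate it with the EDSS disability score
(Pearson, two-tailed), fit EDSS ~ median + age + gender and report the
fitted-vs-observed correlation and its r², with Bonferroni adjustment
across the examined ROIs (default 10). Lesion probability maps average the
normalized binary lesion masks; group lesion patterns are compared by a
per-voxel two-sample t-test on the binary indicators; overlap of
significant-voxel regions with lesion regions uses the Dice score
$2|A\cap B|/(|A|+|B|)$ (defined 0 for two empty masks).

## Synthetic data: the stated world

The generator emulates the acquisition and cohort structure the method was
designed for, not real anatomy:

* **Acquisition**: 10 b0 + 61 diffusion directions at b = 1200 s/mm²
  (deterministic Fibonacci-hemisphere direction set shipped as a text
  fixture), Rician noise at SNR 16.
* **Phantoms**: straight tube, 90° crossing, curved arc inside a
  24×16×16 grid of 2 mm voxels; in-tube tensors
  λ = (1.7, 0.3, 0.3)·10⁻³ mm²/s (FA ≈ 0.89, typical coherent white
  matter), isotropic background 0.7·10⁻³ mm²/s (FA exactly 0, so the
  FA > 0 mask rule reproduces the tube).
* **Cohorts**: three groups sized 20/19/15 by default with the emulated population's
  group age distributions, Bernoulli(0.5) gender, ICV ~ N(1.5·10⁶, 10⁵) mm³.
  Patients receive lesion blobs on random tract voxels in which the
  eigenvalues are blended toward the isotropic tensor of equal trace
  (MD preserved, FA reduced — a demyelination-like change); the SP-like
  group gets more and larger blobs (4 × r2.0 vs 2 × r1.5 voxels) and a
  stronger blend (0.4 vs 0.2). Disability: EDSS = 30 × (damaged tract
  fraction) + N(0, 0.5), clamped to [0, 10] and rounded to half steps;
  healthy subjects have no lesions and no EDSS. The slope 30 places the
  default groups in a clinically plausible EDSS range (≈3 vs ≈5); it was chosen
  once from the generator's geometry, not tuned to any test.

What a green test does *not* establish: phantoms have no gyral geometry,
no partial-volume CSF, no distortion or motion residuals, and lesions are
spheres with a single severity; cohort effect sizes are chosen for
detectability at desk scale, so passing the effect-recovery test says the
machinery localizes a known difference, not that clinical effect sizes
would reproduce.

## Numerical choices and conventions

* Voxel indexing is 0-based; voxel centers at integer coordinates; the
  4×4 affine maps voxel to world (mm). NIfTI-1 I/O is implemented in the
  package (sform preferred, qform fallback; float32/int32/float64/uint8).
* b0 detection: b < 50 s/mm² (tolerates header noise; exact zeros in the
  emulated scheme).
* "Tri-cubic" re-slicing is Keys cubic-convolution (a = −1/2) with mirror
  boundaries — local, reproduces linear ramps exactly; nearest-neighbour
  for labels/masks.
* Gradient rotation uses the rotation factor of the polar decomposition
  (SVD-based), renormalizing weighted directions.
* Two-tensor fits canonicalize component order (descending fraction,
  axis-lexicographic tie-break) so init permutations return one answer;
  if the two-tensor optimum is worse than the single fit, a duplicated
  single tensor is returned so RSS₂ ≤ RSS₁ always holds.
* The pipeline config is JSON (versioned schema); every stage's seed is
  derived from the run seed and recorded in the manifest together with
  MD5 checksums of outputs, making any stage re-runnable bit-identically.
* Thread count never affects results (single-threaded C++ core driven by
  R's RNG).

## Known limitations

Registration estimation, eddy/motion/field-map correction and lesion
segmentation are out of scope (deformations, masks and ICV are inputs).
Only two fibers per voxel; no crossing-aware interpolation of warped
models; calibration lookup does not interpolate between shape bins; the
`.trk` binary format is not written (a lossless plain-text streamline
format is). FA maps entering group analyses are computed from the warped
tensor models rather than warped independently — the two differ only
through the nearest-neighbour sampling of the warp.
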