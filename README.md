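# acmap — spatially normalized Anatomical Connectivity Mapping

`acmap` implements anatomical connectivity mapping (ACM) for diffusion
MRI, together with the spatial-normalization and group-statistics layers
needed to use it in a multi-subject study, and a synthetic phantom/cohort
generator so that every stage is testable with no external data.

**Who it is for.** Researchers comparing white-matter connectivity across
groups (e.g. multiple sclerosis phenotypes vs controls) who want a
voxel-wise *whole-brain connectedness* index rather than a purely local
microstructural one such as fractional anisotropy.

**The statistic.** Per-voxel fiber models (multi-tensor, at most two per
voxel)

    S(g, b) = S0 · Σᵢ fᵢ · exp(−b · gᵀ Dᵢ g)

are warped into a common atlas space with preservation-of-principal-
direction (PPD) reorientation. Orientation uncertainty at the acquisition
SNR is encoded as Bingham distributions

    p(x) ∝ exp(κ₁ (x·u₁)² + κ₂ (x·u₂)²),   κ₁ ≤ κ₂ ≤ 0,

whose concentrations are Monte-Carlo calibrated per tensor shape (PICo).
Probabilistic streamlines are launched from **every** brain voxel (step
1/10 voxel; termination on mask exit or >180° turning within a voxel) and

    ACM(v) = number of streamlines passing through voxel v.

The group layer provides Gaussian smoothing (4 mm FWHM), voxel-wise GLMs
(group + age + gender + Jacobian-modulated atrophy covariate), permutation
maxT small-volume FWE correction, ROI medians with EDSS correlations,
lesion probability maps and Dice overlap.

## Worked example

```r
library(acmap)
set.seed(42)

phantom <- make_tensor_phantom(phantom_spec("straight_tube"))
gtab  <- default_gradients()                 # 10 b0 + 61 dirs, b = 1200 s/mm^2
calib <- build_calibration_table(phantom$field, snr = 16, gtab = gtab,
                                 n_trials = 300, seed = 42)
calib$bins
#>    r1 r2          k1           k2
#> 1 1.0  1   -0.651342   -0.2474066
#> 2 5.5  1 -528.012169 -464.8493886

fodf <- build_fodf_field(phantom$field, calib)
mask <- acm_seed_mask(phantom$field)         # FA > 0 rule
set.seed(42)
acm  <- compute_acm(fodf, mask, n_per_seed = 50)
min(acm$data[mask$data > 0]); max(acm$data)
#> [1] 499
#> [1] 1197

set.seed(42)
acm_precision(fodf, mask, n_values = c(10, 50, 150), repeats = 5)
#>     n      avg_cv  avg_snr
#> 1  10 0.032168313 102.6213
#> 2  50 0.014928673 209.5715
#> 3 150 0.008661306 371.6838
```

Reading the output: the calibration table holds one Bingham concentration
pair per tensor-shape bin — the isotropic background bin (r1 = 1) is
nearly uniform (|κ| < 1) while the coherent tube bin (r1 = 5.5) is sharply
concentrated at SNR 16 (κ ≈ −500). Every one of the 288 seed voxels is
visited by at least its own 50 streamlines (minimum count 499 ≥ 50;
mid-tube voxels accumulate up to ~1200 because streams from many seeds
traverse them). The precision table reproduces the saturating
precision-vs-streamlines trend used to select the operating point: the
mask-average coefficient of variation over 5 repeated estimations falls
from 0.032 at 10 streamlines/seed to 0.009 at 150.

## Pipeline and CLI

```r
run_pipeline(list(version = 1, seed = 7, out_dir = "out",
  stages = list(
    list(name = "phantom", geometry = "straight_tube", snr = 16),
    list(name = "calibrate", n_trials = 500),
    list(name = "build_fodf"),
    list(name = "acm", n_per_seed = 500))))
```

writes each stage's outputs plus `out/manifest.json` (parameters,
per-stage seeds, MD5 checksums — reruns are bit-identical). The same
stages are reachable from the shell via `inst/cli/acmap`
(`phantom`, `cohort`, `fit-tensors`, `calibrate`, `build-fodf`, `track`,
`acm`, `acm-precision`, `dice`, `lesion-map`, `pipeline`).

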