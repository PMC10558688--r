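# fiberprior

Prior-informed, multi-task, meta-learned analysis of 3D second-harmonic-
generation (SHG) images of single striated muscle fibers — at desk scale,
fully testable, with a synthetic fiber generator standing in for a
proprietary database.

## What problem this addresses

SHG microscopy resolves the sarcomere banding of muscle fibers label-free.
Four handcrafted biomarkers computed from such volumes are established
predictors of pathology and contractile function:

* **CAS** (cosine angle sum): mean cosine between local myofibril
  orientation and the fiber main axis; 1 = perfectly parallel. For
  orientations dispersed von Mises(κ) about the axis,
  E[CAS] = I₁(κ)/I₀(κ).
* **VD** (vernier density): Y-shaped banding dislocations per µm² of fiber
  area.
* **SL** (sarcomere length): banding period, ≈ 2–3 µm.
* **CSA** (cross-sectional area): robust combination of three per-slice
  estimators (pixel counting after morphological cleaning, PCA ellipse,
  trimmed elliptic envelope); the two most concordant estimates are
  averaged.

Laboratory cohorts are small, multi-study, and sparsely labeled. The
package therefore trains a multi-task convolutional network on standardized
volumes with an uncertainty-weighted loss

    L = Σ_i ( L_i / σ_i² + log σ_i )

whose per-head σ are learned, and where missing labels are *masked*: they
contribute exactly zero to the loss and its gradients. The four biomarkers
enter as **priors** at five levels — `NoPriors`, `AuxLosses` (priors as
auxiliary regression targets), `Branches` (priors concatenated into the
fully connected head), `AuxLosses@Branches`, or `PriorsOnly` (feature-only
AutoML without images). An NSGA-II multi-objective search over data
representation (3D vs three 2.5D slices at 1/5/10/20 µm offsets,
downsampling, augmentation, random erasing), prior integration, and network
settings (capacity C1–C6, optimizer, learning rate, batch size, clipping,
imbalance sampling) minimizes per-task dev meta-losses (1 − AUC, 1 − R²).
Models are selected per task by dev meta-loss, or by the weighted *total*
meta-loss for scarce tasks (< 100 labeled samples). Shapley values over a
random-forest surrogate explain which configuration decisions mattered;
expected-gradients attribution explains which voxels and priors one model
used for one sample.

Everything runs on seeded synthetic fibers with known ground truth
(banding period, orientation dispersion, planted defects, cross-section,
sparse linked labels), so each stage is validated against analytic oracles.

## Worked example

Generate a fiber with known structure and recover its biomarkers:

```r
library(fiberprior)
sim <- generate_fiber(
  fiber_spec(sarcomere_length = 2.5, semi_axes = c(12, 8),
             dispersion_kappa = Inf, n_verniers = 6, snr = 20),
  spacing = c(0.5, 0.5, 0.5), shape = c(40, 128, 56), seed = 42)
compute_priors(sim$image)
#> <prior_vector>
#>    cas2d    cas3d       vd       sl      csa
#>   0.9945   0.9943   0.0048   2.4621 302.1008
```

Ground truth for this fiber: CAS 1 (no dispersion; the estimate is 0.994
after structure-tensor smoothing), SL 2.5 µm (estimated 2.462, within the
±0.1 µm detector tolerance; the planted dislocations perturb the local
banding period), VD 0.005 defects/µm² (all 6 planted verniers detected,
estimated 0.0048), CSA π·12·8 ≈ 301.6 µm² (estimated 302.1).

From there, `make_cohort()` builds a multi-study cohort with sparse linked
labels (`demo_design()` is a ready-made design), `standardize_cohort()`
runs resampling → denoising → Otsu zeroing → rigid registration (estimated
on a CLAHE-enhanced copy, applied to the non-enhanced image) →
probability-atlas cropping → standard scoring, `stratified_group_split()`
produces a leakage-free 2/4–1/4–1/4 bundle-level split, and
`run_self_enhancement()` runs the NSGA-II loop, returning per-task selected
models, a JSONL labbook, and the top-k performance summary. `fit_surrogate()`
+ `config_shapley()` and `sample_attribution()` provide the two explanation
levels.

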