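---
title: "Prior-informed multi-task analysis of SHG muscle-fiber volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-informed multi-task analysis of SHG muscle-fiber volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Second-harmonic-generation (SHG) microscopy images striated muscle label-free:
the myosin lattice produces a quasi-periodic banding whose period is the
sarcomere length (SL, roughly 2–3 µm). Structural biomarkers computed from
such volumes — the cosine angle sum (CAS, an alignment score of myofibrillar
orientations against the fiber main axis), the vernier density (VD, Y-shaped
band dislocations per unit fiber area), the 3D sarcomere length, and the
cross-sectional area (CSA) — correlate with pathology and contractile
function. Laboratory cohorts, however, are small, heterogeneous across
studies, and sparsely labeled: most fibers carry labels for only a subset of
the tasks of interest.

`fiberprior` implements a desk-scale version of a self-enhancing analysis
loop for this setting. A configurable multi-task convolutional network learns
all tasks jointly from standardized volumes; the four handcrafted biomarkers
can be integrated as *priors* at five levels (`NoPriors`, `AuxLosses`,
`Branches`, `AuxLosses@Branches`, `PriorsOnly`); and a multi-objective
NSGA-II search selects the data representation, prior-integration level, and
network settings that minimize per-task dev-set meta-losses. Two explanation
levels report which configuration decisions mattered (Shapley values over a
random-forest performance surrogate) and which voxels and priors a model used
for one sample (expected-gradients attribution).

Because no public fiber database is bundled, the package ships a first-class
synthetic generator with known ground truth; every downstream stage is tested
against that ground truth or against closed-form oracles.

## Synthetic fiber model

A fiber is an elliptical cylinder along the y axis (semi-axes `(a, b)` along
x and z) carrying axial banding

\[ I(\mathbf{r}) = E(\mathbf{r})\,\bigl(1 + m\cos(2\pi y/\mathrm{SL} + \varphi(\mathbf{r}))\bigr), \qquad m = 0.6, \]

with additive Gaussian noise of standard deviation `m/snr` (SNR is defined as
banding amplitude over noise sd). The phase field carries two kinds of
structure:

* **Myofibril dispersion.** Local band normals are tilted away from the axis
  by angles drawn from a von Mises distribution with concentration κ
  (κ → ∞ is perfectly parallel). Tilt angles are sampled through a Gaussian
  copula over a spatially correlated field (5 µm Gaussian correlation
  length), so the marginal is exactly von Mises while the field varies
  smoothly — a prerequisite for well-posed structure-tensor estimation. The
  tilt enters the phase through its tangent components; tilts are capped at
  75° so the frozen-phase approximation stays meaningful at κ = 1.
* **Verniers.** Each planted defect adds a full 2π phase winding
  `atan2(y − y₀, x − x₀)`: one extra band terminates at the core, the
  classic Y-shaped vernier. Defects run through the fiber depth as line
  dislocations and are rejection-sampled with a minimum in-plane separation
  (8 µm axially, 6 µm transversally) and alternating winding signs, so each
  is individually resolvable and the far fields of the windings cancel
  instead of biasing the apparent banding period. An
  earlier variant with z-windowed partial windings was discarded: a partial
  winding leaves a visible branch-cut seam that itself reads as spurious Y
  splits and breaks the planted-count ↔ detected-count link.

Ground truth retained per fiber: SL, κ, the realized mean cosine of the
sampled tilts, the analytic cross-section πab, defect coordinates and count,
and the noise regime. Labels are simulated from these parameters through a
link model (Bernoulli-sigmoid for binary tasks, linear-Gaussian for
continuous ones) with per-task availability fractions, reproducing a sparse
multi-study label design (the bundled demonstration design labels one task
for only 8% of samples).

What the generator deliberately does **not** emulate: SHG polarization
physics and phase matching, the microscope PSF, depth-dependent attenuation,
and fiber curvature. Tests passing on these phantoms therefore validate the
algorithmic contracts (detector calibration, masking, selection logic), not
instrument-level robustness on real acquisitions.

## Standardization pipeline

The fixed order is: isotropic resampling (default 0.5 µm, trilinear) →
median denoise (1 µm window; `round(size/spacing)` forced odd with a minimum
of 3 when the window covers at least one voxel) → Otsu background zeroing →
CLAHE-enhanced copy used only to estimate a rigid transform against a
canonical synthetic reference fiber → transform applied to the non-enhanced
image → crop to the bounding box of atlas voxels whose presence probability
exceeds 0.85 → sample-wise standard score. The processing history recorded on
every image, and the JSONL labbook, make the ordering assertable.

Choices worth noting:

* **CLAHE range.** The 3D CLAHE uses per-tile min–max histogram ranges
  (16 µm tiles, clip limit 0.01 of tile mass, trilinear mapping blend). A
  per-tile adaptive range is the stable choice on images whose background is
  exact zero.
* **Registration.** The default estimator maximizes a 32-bin mutual
  information metric over a multi-resolution schedule (up to 6 levels,
  at most 600 optimizer iterations per level) after center-of-gravity
  initialization, with a coarse ±15° rotation sweep at the coarsest level —
  fibers arrive roughly pre-aligned, so a bounded sweep is enough and avoids
  the flat-gradient region of the metric. A one-step principal-axes
  alignment (`method = "pca"`) is provided where speed matters; its sign
  ambiguity is resolved toward the rotation nearest the identity.
* **Standard score over foreground only.** Whether the background should
  enter the score is unspecified in the source material for this pipeline
  family; with background forced to exact zero, including it would let the
  background fraction dominate the statistic, so the score uses foreground
  voxels (population-sd convention) and leaves background at zero.

## Prior biomarkers

* **Orientations / CAS.** Structure tensor with 0.5 µm derivative scale and
  1 µm integration scale; gradients use fourth-order central differences
  because at 0.5 µm sampling the banding frequency sits near Nyquist and a
  second-order stencil biases orientations by several degrees. The dominant
  eigenvector (band normal) is extracted by vectorized power iteration;
  coherence is the normalized eigenvalue gap. The foreground mask is eroded
  before sampling so the fiber surface gradient does not contaminate the
  interior statistics. CAS is the mean cosine between local orientation and
  the main axis (2D on the centre plane, 3D over the volume); for a von
  Mises field the expectation is the Bessel ratio I₁(κ)/I₀(κ), which is the
  closed-form oracle used in the tests. Estimated orientations are axial
  (sign-free) and canonicalized to a nonnegative axial component; the
  Bessel-ratio checks are run on orientation fields built from signed draws,
  where the identity is exact.
* **SL.** Hann-windowed, zero-padded FFT of axial foreground profiles;
  dominant peak of the averaged power spectrum in the 1.5–4 µm band with
  parabolic sub-bin refinement; unavailable if the peak is below twice
  the in-band median power.
* **VD.** Per z-slice band-pass at 1/SL, crest skeletonization (Zhang–Suen
  thinning) inside the eroded foreground, branch-point extraction, then
  clustering: because a vernier is a dislocation line through the fiber
  depth, detections are projected to the (y, x) plane and merged within one
  banding period; a defect must be detected in at least two slices. The
  merge radius is calibrated on planted defects — a single dislocation's Y
  fork spans a few micrometres along the axis, so a half-SL radius
  double-counts while radii much beyond one SL chain neighbouring defects.
  VD is the defect count over the mean foreground slice area.
* **CSA.** Three estimators per y-slice stack (top and bottom 10 slices
  excluded): exact pixel counting after 1 µm opening/closing; a PCA ellipse
  with the uniform-ellipse convention radius = 2·√eigenvalue (unbiased on
  solid ellipses); and a robust elliptic envelope via iterative Mahalanobis
  trimming at contamination 0.2. The envelope divides the trimmed
  eigenvalues by an *effective* coverage estimated by a fixed-point count of
  points inside the implied boundary, so clean slices (where trimming
  removes real edge pixels) and contaminated slices (where it removes
  outliers) are both estimated without bias. The smart combiner returns the
  mean of the two most concordant estimators and records the discarded one.
  Registration already canonicalizes fiber orientation, so a separate
  oriented-bounding-box pre-rotation is a no-op guard here.

## Cohort handling

Continuous labels are median-dichotomized (ties to "low") into
stratification keys only — they are never learning tasks. Whole muscle
bundles are allocated greedily to train/dev/test targeting 2/4–1/4–1/4 *of
groups* (the splitter operates on groups, not samples, since bundle sizes
vary and leakage is defined at the bundle level), strata in decreasing size
order, groups shuffled by the seed, each group going to the set furthest
below target. Labels and priors are z-scored with train-only statistics
(population sd); missing entries stay missing and become `FALSE` entries of
the output mask, alongside unavailable priors.

## Multi-task network and training

The backbone is a compact convolutional family C1–C6 (widths 8–24, depths
2–4, channel growth capped at 4×), 2D for slice representations and 3D for
volumes, with a stride-2 stem pool in 3D; parameter counts increase strictly
with capacity. Forward and backward passes are exact analytic
backpropagation over compiled shift-accumulate convolution kernels, which
keeps CPU training deterministic and lets the attribution code differentiate
to the inputs. The claims exercised here concern prior integration and data
representation, not ImageNet-scale capacity, so a compact family is the
appropriate stand-in for a large scaled architecture family.

Heads: one output per task (binary cross-entropy with logits) and, for
`AuxLosses*` levels, one regression output per prior (squared error); for
`Branches*` levels the five normalized priors are concatenated into the
final fully connected layer. The total loss is the uncertainty weighting

\[ L = \sum_k \bigl( L_k/\sigma_k^2 + \log \sigma_k \bigr) \]

over heads with at least one supervised entry in the batch, with σ
parameterized as log σ initialized at 0 (σ = 1; the initialization is not
prescribed by the method description, so the neutral value is used). Masked
entries contribute exactly zero to the value and all gradients — verified by
direct gradient inspection.

Training options mirror the configuration space: SGD with momentum or Adam,
log-uniform learning rate in [1e-4, 1e-2], batch sizes {4, 8, 16} with
gradient accumulation to an effective batch of at least 8 in 3D mode,
optional global-norm clipping at 1.0 (the threshold is a package choice; the
technique, not its constant, is the decision being searched), optional
inverse-class-frequency sampling on the rarest-labeled classification task,
and optional augmentation (flips, ±10° in-plane rotation, small affine
jitter, Gaussian noise) and random erasing (1–3 boxes of 2–10% each).

After each epoch the dev meta-losses (1 − AUC for classification, 1 − R²
for regression — the minimized mapping of the dev metrics) and their
weighted total are computed. The total is smoothed by a 10-epoch moving
average (using the available history while shorter); training stops when the
smoothed series has made no new strict minimum for 50 consecutive epochs,
with the criterion counting only after epoch 75 — a never-improving trial
therefore runs exactly 125 epochs. Per-task best snapshots and a best-total
snapshot are kept.

## Self-enhancement loop

NSGA-II over the configuration space: fast non-dominated sorting on the
per-task meta-loss vectors, crowding-distance selection, binary tournaments,
uniform crossover with probability 0.9 and per-gene swap probability 0.5
(the natural reading of a per-gene "swapping probability"), mutation 0 by
default. `PriorsOnly` participates as the fifth value of the integration
gene; its representation and network genes are inert. Failed trials receive
worst-observed + 10% objectives so the population stays full while fronts
exclude them. Model selection: tasks with ≥ 100 labeled samples take the
per-task dev meta-loss argmin; scarcer tasks take the best *total*
meta-loss; ties break toward the earlier trial for determinism. A top-k
summary (default 50, or all trials when fewer) reports the mean dev metric
of the best trials per task.

The `PriorsOnly` path is a deliberately small AutoML: top-k univariate
feature selection (k ≤ 5) crossed with an L2 linear model, a 100-tree
forest, and k-nearest-neighbours (probability-capable estimators only),
scored by grouped two-fold cross-validation on train+dev — the fold ratio
mirroring the main split, bundles never straddling folds.

## Explanations

*Model level.* A 500-tree random forest maps encoded configurations
(ordinal for ordered genes, factors for unordered ones) to a task's dev
metric; interventional Shapley values per configuration dimension are
computed by exact coalition enumeration for small spaces and seeded
permutation sampling otherwise, in units of the metric. Stability is checked
by refitting with several seeds and ensemble sizes and comparing top-rank
overlap. *Sample level.* Expected-gradients attribution: gradients averaged
along straight paths from a reference (zeros or a train average) to the
sample, times input difference, jointly over voxels and the prior branch.
The implementation contract is the additivity axiom — exact for linear
models, within discretization error of the output gap otherwise; the
reference defaults to zeros (the standardized background), with a train-mean
option.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic cohorts:
fiber volumes of 24–64 slices for detector tests, a 64-sample cohort for
learning checks, and a 200-sample cohort of 16×32×24-voxel volumes with a
60-trial, population-10 search over 5 seeds (4-epoch trials) for the
mechanism-recovery check — sizes chosen so a laptop-class CPU reproduces
everything in well under an hour while the directional claims (prior
integration wins when labels are prior-driven) remain detectable. All
randomness flows from explicit integer seeds; RNG state is saved and
restored around every seeded operation, and CPU runs are bit-reproducible.

## Known limitations

* The generator's dispersion enters through a frozen-phase approximation;
  at κ = 1 the image-level CAS estimator is biased upward (tilt clipping,
  finite-difference dispersion), so image-level checks at strong dispersion
  are directional (monotonicity), while the Bessel-ratio identity is
  asserted on orientation fields directly.
* Registration assumes residual misorientations within ±15°.
* The elliptic envelope assumes gross (far) outliers; structured
  contamination hugging the fiber boundary would bias its coverage
  calibration.
* Early stopping and meta-loss smoothing assume per-epoch dev evaluation is
  affordable; the trainer does not subsample the dev set.
* The compact backbone family is not a drop-in for large pretrained
  architectures; conclusions about capacity transfer only directionally.
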