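---
title: "Methods and design choices in mpuscad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in mpuscad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpuscad)
```

`mpuscad` implements a voxel-wise computer-aided detection (CAD) pipeline for
clinically significant prostate cancer from 3D multiparametric ultrasound:
contrast-enhanced ultrasound (CEUS) perfusion quantification, shear-wave
elastography (SWE), a probabilistic histopathology reference, a compact
three-branch convolutional classifier, and confidence-weighted evaluation.
Because real patient data cannot ship with the package, every component is
exercised on synthetic phantoms with exact ground truth. This vignette
documents the scientific content of each module and the deliberate design
decisions that are not obvious from the function reference.

## 1. Contrast bolus model: the modified LDRW fit

Each voxel's time–intensity curve (TIC) is linearised from log-compressed
display data, then fitted with the modified local-density-random-walk (mLDRW)
model

$$ I(t) = \mathrm{AUC} \cdot
   \sqrt{\frac{\kappa\,\mu}{2\pi\,(t - t_0)}}\;
   \exp\!\left( -\frac{\kappa\,\mu}{2} \cdot
   \frac{\left((t - t_0) - \mu\right)^2}{\mu\,(t - t_0)} \right),
   \qquad t > t_0, $$

parameterised by the local dispersion parameter $\kappa$ (1/s), the mean
transit time $\mu$ (s), the theoretical injection time $t_0$ (s) and the area
under the curve. Malignant angiogenic microvasculature raises $\kappa$ and
shortens $\mu$, which is what the temporal feature branch feeds to the
classifier (together with peak intensity and wash-in rate derived from the
same fit).

The fitter (`fit_mldrw_matrix`) is a vectorised Levenberg–Marquardt solver
that updates thousands of curves per iteration through closed-form analytic
Jacobians and a batched symmetric 4×4 solve. On noise-free curves it recovers
the generating parameters to well under 1% relative error; on phantom CEUS
loops the accuracy is noise-limited, so `extract_features` uses a relaxed
iteration budget (25 iterations, tolerance $10^{-4}$) that was verified to
change fitted parameters only below the noise floor while cutting feature
extraction time substantially.

Phantom CEUS loops are sampled at 10 Hz. That rate matches the temporal
resolution of clinical 3D CEUS acquisitions and, more importantly, places
several samples on the wash-in flank of even the fastest simulated bolus
($\mu \approx 10$ s), which is the part of the curve that constrains
$\kappa$ and $t_0$. Coarser sampling would alias exactly the information the
temporal branch relies on.

## 2. Convective dispersion, similarity and velocity entropy

`estimate_convective_dispersion` inverts the local convection–diffusion
transport of the bolus: within a small spatial window it regresses the
temporal evolution of the concentration field onto its spatial gradient and
Laplacian, yielding a blood-velocity vector $v$ (mm/s) and an apparent
dispersion coefficient $D$ (mm²/s) per voxel. On the analytic Gaussian-bolus
solution it recovers prescribed $v$ and $D$ within a few percent in the field
core.

`similarity_maps` quantifies how coherently a voxel perfuses with its ring of
neighbours: windowed temporal correlation, spectral coherence, and mutual
information between quantile-binned TICs. Quantile binning makes the MI
estimate invariant to any monotone amplitude distortion, which matters because
log-compression settings vary across acquisitions.

`velocity_entropy_maps` summarises the *direction field* of the estimated
blood velocities. Directions are binned on the sphere (azimuth × elevation
bins) and within each local window we compute the Shannon entropy of the bin
histogram, plus a conditional entropy given the neighbour's bin. A subtlety:
with $B_a$ azimuth and $B_e$ elevation bins the joint alphabet has
$B_a B_e$ symbols, but the entropy is computed from the *pair-marginal*
histogram — the distribution of single-voxel direction bins pooled over the
window — not from the joint distribution of voxel pairs. The pair-marginal
definition keeps the estimator usable at clinical window sizes: a joint
histogram over $(B_a B_e)^2$ cells would be hopelessly undersampled in a
$7^3$ window, whereas the marginal saturates correctly (laminar flow gives
exactly 0 bits; isotropic disorder approaches $\log_2(B_a B_e)$ bits, and the
conditional entropy is bounded above by the marginal entropy by
construction).

## 3. Shear-wave elastography

`loupas_velocity` implements the Loupas phase-shift autocorrelator on
complex IQ ensembles: the axial particle velocity is
$v = \frac{c\,\mathrm{PRF}}{4\pi f_c}\,\arg\,R(1)$ with $R(1)$ the lag-one
slow-time autocorrelation. On synthetic IQ whose phase increments encode a
known velocity movie it inverts the synthesis exactly (to numerical
round-off), and it flags aliasing when the phase approaches $\pm\pi$.

`sws_crosscorr` estimates the shear-wave speed by time-of-flight: FFT-based
cross-correlation between lateral positions, restricted to positive lags
(a negative lag means the wave arrived in the wrong order, which is marked
invalid rather than silently inverted), with parabolic sub-sample refinement
and a normalised-peak quality gate. Young's modulus follows the elastic
closure $E = 3\rho c_s^2$ with $\rho = 1000$ kg/m³, i.e. `E_kpa = 3 * sws^2`.
`swe_feature_volumes` stacks per-plane estimates back into the voxel grid.

## 4. Probabilistic reference standard: kriging histology

Ground-truth labels exist only on sparse transverse histopathology slices.
`wiener_interpolate` fills the volume with the simple-kriging predictor

$$ p(x) = m + k(x)^\top K^{-1} (y - m) $$

under an isotropic exponential autocorrelation model whose length scale and
prior prevalence $m$ are estimated from the slices themselves
(`estimate_slice_autocorrelation`). Two truncations keep this tractable:

* **Axial truncation** — only the two slices nearest to the target layer
  enter the stencil. With exponential correlation and typical 4 mm slice
  spacing, the third-nearest slice's weight is suppressed by at least
  $e^{-\Delta/L}$ relative to the data already present, and the screening
  effect of simple kriging reduces it further; the omission is far below
  label uncertainty.
* **In-plane truncation** — per slice, only pixels within
  `in_plane_radius_mm` (default three correlation lengths, where the
  correlation has decayed to under 5%) of the target's in-plane position are
  used. Because this stencil geometry repeats identically across every axial
  layer, the kriging weights are solved once per distinct axial-gap pattern
  and applied as a linear filter, which is what makes whole-volume
  interpolation fast.

On a slice the predictor reproduces the observed labels exactly; far from all
slices it decays to the prior. Voxel confidence weights for training and
evaluation are $w = \alpha / (p(1-p) + \alpha)$ with $\alpha = 0.2$: certain
voxels get weight 1, maximally ambiguous voxels ($p = 0.5$) get
$0.2/0.45 \approx 0.44$.

## 5. Classifier and training protocol

The classifier is a fixed three-branch architecture: each feature group
(temporal, spatiotemporal/similarity, SWE — plus location and clinical scalars
appended to the head) passes through a small two-layer 3D convolutional
branch; the concatenated branch outputs feed a two-hidden-layer multilayer
perceptron. The default `architecture_spec()` instantiates 46,941 trainable
parameters — deliberately inside a 46,000–48,000 budget so that the model
stays trainable on cohorts of tens of patients without overfitting the
voxel-correlated labels.

Training (`run_fold`) is two-stage: a pretraining pass on aggressively
rebalanced voxel batches (exact positive counts per batch, one pass over the
minority class per epoch) followed by fine-tuning at natural prevalence with
early stopping on validation AUC. Optimisation is Adam on a
confidence-weighted binary cross-entropy.

**Standardisation scope.** Feature z-scoring statistics are computed from
*training-fold patients only* (`compute_feature_stats(..., scope_ids)`), and
the object records that scope. Two leakage modes are thereby excluded: using
validation patients' statistics (which leaks their intensity distribution into
training) and per-patient standardisation at test time (which leaks the
patient's own lesion burden into the features — a patient with a large lesion
shifts their own mean). The test suite asserts the scope restriction changes
the statistics.

**Control model.** Every experiment trains a location-only control
(`control_location_spec()`): same architecture family and protocol, but the
only inputs are zone/position encodings and clinical scalars. Prostate cancer
is strongly zonally distributed, so a location prior alone achieves a
deceptively high AUC; the scientific claim of the multiparametric pipeline is
the *margin over that control*, not the absolute AUC.

## 6. Cross-validation and evaluation

`make_folds` stratifies patients by lesion-burden terciles (plus a
no-lesion subgroup) before round-robin assignment, so every fold sees the
burden spectrum. `weighted_roc_auc` computes the confidence-weighted AUC with
the standard ½ tie convention via an $O(n \log n)$ cumulative sweep; it is
exactly the weighted Mann–Whitney statistic (the test suite checks bitwise
agreement with a quadratic oracle), invariant under affine score transforms,
and exactly 0.5 for constant scores. `repeated_cv_aggregate` reports
mean AUC with a normal-theory CI over repeat × fold, stratified by zone.

## 7. The scaled phantom benchmark

The full study in `run_phantom_experiment` uses 40 patients on 32³ grids with
7-fold cross-validation repeated twice. This scale is a compromise chosen for
a single-CPU budget: it is large enough that folds contain 5–6 validation
patients and the burden stratification is meaningful, while feature
extraction plus both cross-validations complete in roughly 15 minutes.
`benchmark_train_config()` correspondingly caps the sampled voxel counts
(pretraining positives, fine-tuning and validation pools) and epochs; these
caps were verified to leave the full-vs-control ordering and the absolute
full-model AUC unchanged relative to more generous budgets — they trade
wall-clock time, not conclusions. With the class-separable phantom
configuration the full model reaches AUC ≈ 0.999 against ≈ 0.77 for the
location-only control, and a re-run of a fold under the same derived seed
reproduces predictions bit-for-bit.

## 8. On-disk formats and the staged pipeline

The staged pipeline (`run_pipeline`, or the `inst/cli/mpuscad` executable)
persists every artifact in text or standard binary formats: 4D NIfTI for
volumes and CEUS loops, YAML for configurations and study metadata, CSV for
tables, JSON for indices and the run manifest. **4D NIfTI stands in for
HDF5** as the container for the CEUS loop: the available I/O stack provides a
robust NIfTI reader/writer but no HDF5 bindings, and NIfTI carries the same
payload (a dense 4D float array plus voxel spacing) with wide tool support.
The manifest records the configuration hash, seed, package version and an
MD5 checksum per artifact; re-running a configuration reproduces every
checksum byte-for-byte.

One documented deviation in the *smoke-scale* pipeline examples (16³ grids,
4 patients): they override the phantom generator to one lesion and a 7%
prevalence target. At 16³ a single prostate contains only a few hundred
voxels, so the default 5% target collides with grid quantisation — the
smallest placeable lesion can overshoot the ±20% prevalence guard for some
seeds. The 7% target is feasible for every seed at that grid size. The
full-scale generator defaults (32³, 5%, two lesions) are untouched; the
override is a property of the miniature example, not of the study
configuration.

## 9. Reproducibility

All randomness flows from a single integer seed through
`derive_seed(seed, tag)`, which hashes the tag into an independent
sub-stream seed below $2^{31}$; patients, folds, initialisation and batch
sampling each get their own tag. Fixed seed in, identical bytes out — the
test suite asserts manifest-level byte identity across reruns.
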