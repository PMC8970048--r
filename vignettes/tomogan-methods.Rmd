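---
title: "tomogan: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tomogan: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result; numbers come from
the test suite and `scripts/acceptance.R`.

## 1. The translation model

Subtomograms `s ∈ S` and density maps `d ∈ D` are cubic `n³` grayscale
volumes normalized to `[-1, 1]`. Two generators learn the unpaired mappings
`G_ds : D → S` and `G_sd : S → D`; two critics `D_A`, `D_B` score realism in
each domain. The training objective combines:

* **Adversarial terms**, one per direction. The default is the Wasserstein
  form: the critic minimizes `E[D(fake)] − E[D(real)]` (the negation
  estimates the Earth-Mover distance between the real and generated
  distributions), the generator minimizes `−E[D(fake)]`. The classical
  logistic form (`−E log σ(D(real)) − E log(1−σ(D(fake)))`, non-saturating
  generator loss `−E log σ(D(fake))`) is kept behind `advMode = "logistic"`
  because removing the Wasserstein machinery is one of the two ablation axes
  the package exposes; the other is `spectralNorm = FALSE` in `buildModel()`.
* **Cycle consistency**: L1 reconstruction of both round trips,
  `E‖G_sd(G_ds(d)) − d‖₁ + E‖G_ds(G_sd(s)) − s‖₁`, weighted by `lambdaCyc`.
  Without it, unpaired adversarial training can map any input to any
  plausible output; the cycle ties a generated subtomogram to its source
  structure.

**Lipschitz control.** Wasserstein critics must be (approximately)
1-Lipschitz. Two devices are on by default and independently switchable:
weight clipping to `[−c, c]` after every critic update (`clipValue`, default
`c = 0.01`, the customary value where none is prescribed), and spectral
normalization of every critic convolution — each weight tensor, viewed as an
`(out-channels × rest)` matrix, is divided by its largest singular value,
estimated by power iteration with vectors that persist across steps (6
iterations per forward pass; the persistent warm start makes this accurate
to well under 1e-3 during training, which `criticSpectralNorms()` verifies
against a full SVD).

**Mode collapse countermeasures.** A one-channel Gaussian noise volume is
concatenated to the generator representation after the residual trunk, so
the first upsampling layer consumes `4·baseFilters + 1` channels (129 at the
reference width). Different noise seeds can produce different subtomograms
from one density map. Additionally, generator *inputs* on the density-map
side are corrupted with zero-mean Gaussian noise of standard deviation
`inputNoiseStd × dynamic range` (default 0.2) during training; the cycle
target remains the clean map, so the corruption acts as a regularizer rather
than changing the reconstruction goal.

### Architecture

Generator: `c7s1-32 → d64 → d128 → 6 × R128 → [noise concat] → u64 → u32 →
c7s1-1(tanh)`. `d` blocks are 3³ stride-2 convolutions with instance norm +
ReLU; `u` blocks are fractional-stride (×2) convolutions implemented as the
exact adjoint of a stride-2 convolution (`k = 3`, `pad = 1`, output padding
1), not interpolation + convolution; 7³ stems use reflection padding so the
spatial size is preserved exactly; the output layer has tanh and no
normalization, fixing the range to `(−1, 1)`. The noise channel is inserted
where the channel arithmetic demands it — 128 + 1 = 129 feeding the *first*
upsampling stage.

Critic: `C64 → C128 → C256` with 4³ stride-1 convolutions, instance norm and
leaky ReLU (slope 0.2), spectral normalization on every convolution, then a
1-filter projection convolution and a spatial mean to produce the scalar
score (a Wasserstein critic needs a scalar; the plan is otherwise
convolutional).

`baseFilters` scales every width together; 32 is the reference plan, 4 is
the desk scale used in tests. Initialization is N(0, 0.02) for weights, zero
biases, deterministic per seed.

### Optimization

RMSProp (decay 0.99, epsilon 1e-8) at `lr = 0.0005` for all four networks;
`nCritic` critic updates (default 5) per generator update; batches are drawn
uniformly per step from each domain. Defaults where no value is prescribed
anywhere: `lambdaCyc = 10` (standard cycle weighting), `batchSize = 8`,
`epochs = 100` at fixture scale. A non-finite loss aborts with the step
number. The per-step history (adv_ds, adv_sd, cycle, both critic losses,
total = adv_ds + adv_sd + λ·cycle) is returned and optionally written as
CSV beside a checkpoint and the resolved config.

## 2. The classical simulator

`simulateSubtomogram()` composes, in physical acquisition order (pose →
optics → tomographic sampling → detection noise):

1. **Pose** — rotation about the volume centre (intrinsic Z-Y-Z Euler
   angles, or uniform over SO(3) via a random unit quaternion) and
   translation (given, or uniform in ±n/10 voxels), trilinear interpolation,
   out-of-support voxels filled with the background value (0 for raw
   density maps).
2. **MTF** — multiplication of the 3D Fourier transform by the radial
   Gaussian `exp(−f²/(2σ²))`, `f` in cycles/voxel. The MTF is named but not
   specified functionally in the source literature; a radial Gaussian is the
   simplest monotone low-pass with one width parameter. Default
   `mtfSigma = 0.25` attenuates Nyquist by `exp(−2) ≈ 0.14`, a realistic
   detector envelope.
3. **Missing wedge** — single-tilt geometry, tilt axis y: Fourier
   coefficients whose `(k_x, k_z)` direction lies within `wedgeAngle`
   degrees of the `k_z` axis are zeroed (default 30°, i.e. a ±60° tilt
   range). The `k_x = k_z = 0` line, which carries the DC term, is kept.
   The operator is a real, idempotent orthogonal projection.
4. **Noise** — zero-mean Gaussian with variance `var(signal)/snr`. SNR is
   defined as a variance ratio, the dominant cryo-ET convention (the
   alternative — amplitude ratio — would square all targets). Default
   `snr = 0.5`, typical of experimental subtomogram data.
5. **Normalization** — symmetric min-max to `[-1, 1]`. No intensity
   convention is prescribed by the source; min-max matched to the tanh
   output range is this package's convention, with the degenerate constant
   volume mapped to zeros so synthetic edge cases never abort a pipeline.
   `zscore_clip` (standardize, clip at ±3σ, rescale) is available for
   heavy-tailed experimental data.

Whether the classical baseline includes the wedge is configurable
(`wedgeAngle = 0` disables it), since published baselines differ.

## 3. The synthetic fixture

`generateFixtureDatasets()` stands in for archive-derived data so that
nothing is downloaded at test time. Four smooth-edged shape families —
solid sphere, concentric shell, two-lobe dumbbell, rod — play the role of
distinct macromolecule classes; per-instance seeds jitter size and
orientation so each class is a population. Domain D holds randomly posed,
normalized clean maps; domain S holds classically degraded subtomograms of
*independently drawn* instances (different structure seeds and poses), so
the domains are genuinely unpaired, class-balanced and labeled.

What it emulates: two unpaired domains with shared class structure, realistic
degradation physics (SNR 0.5, 30° wedge, MTF blur, random pose), linear
class separability of the clean domain. What it does not: the structural
complexity of real macromolecules, crowding and neighbouring densities,
non-Gaussian and correlated noise, CTF defocus ramps, alignment errors.
Tests passing on this fixture validate the machinery — losses, gradients,
invariants, metric definitions — not the realism of outputs on experimental
data; that judgement requires real subtomograms and a strong reference
classifier, which are deliberately outside this package.

## 4. Evaluation suite

All metrics operate on embeddings from a pluggable embedder. The default
(`trainEmbedder`) average-pools each volume to a `4³ = 64`-dimensional
feature vector and fits a single-hidden-layer softmax network on the labeled
real data; it exposes features and class probabilities and is deterministic
at prediction time. It is a lightweight stand-in for a deep 3D
classification network — any object with the same `$embed`/`$classProb`
interface can replace it, and the feature dimension is a parameter.

* **Inception score** `exp(E_x KL(p(y|x) ‖ p(y)))`, `p(y)` the row mean,
  `0·log 0 = 0`; bounded by `[1, C]`.
* **Fréchet distance** `‖μ_r − μ_g‖² + Tr(Σ_r + Σ_g − 2(Σ_r Σ_g)^{1/2})`;
  the matrix root uses the eigendecomposition of the symmetrized product
  `Σ_g^{1/2} Σ_r Σ_g^{1/2}` with negative eigenvalues clipped at zero (a
  warning is raised if they are more than rounding noise).
* **Manifold precision / recall / density / coverage** on k-NN balls
  (`k = 5` by default — small enough to stay local at the dataset sizes used
  here, large enough to be stable; no value is prescribed by the metric
  literature's sources for this data). A point is not its own neighbour;
  a distance exactly equal to the ball radius counts as *inside* — this
  boundary rule is what makes the identical-set identities
  (precision = recall = coverage = 1) exact. Cross-distances are computed
  with the same arithmetic as a naive double loop so oracle comparisons are
  bitwise exact.
* **3D SSIM** over fully interior sliding windows (default 7³, shrunk for
  tiny volumes), standard stabilizers `C1 = (0.01 L)²`, `C2 = (0.03 L)²`.
  Because the data are unpaired, Table-style SSIM needs a pairing
  convention: each generated volume is compared with its nearest same-class
  real exemplar in embedding space (nearest overall when labels are absent).
  This is a convention of this package and is reported as such.
* **Classification accuracy**: fraction of generated volumes whose predicted
  class matches their source density map's class.

`evaluateSuite()` reports exactly eight entries: `ssim, precision, recall,
density, coverage, classification_acc, inception_score, fid`.

## 5. Uncertainty maps

`mcUncertaintyMap()` runs `G_ds` repeatedly (default 20 draws) on one
density map with dropout active inside every residual block (placement
chosen because the trunk carries the structural representation; rate
configurable, 0 by default so ordinary training is dropout-free) and
reports the per-voxel standard deviation. Two conventions are fixed and
tested: the **population** standard deviation (divide by T; switching to the
sample convention multiplies every value by `sqrt(T/(T−1))`), and the noise
channel held **fixed** across draws by default so the map isolates dropout
variance (`noiseMode = "resample"` measures total stochastic variance
instead — whether the original procedure resampled it is unstated, so both
are exposed).

## 6. Determinism and problem sizes

A single user seed fans out to every component through a fixed polynomial
hash modulo a prime below 2³¹ (`deriveSeed`), and all stochastic layers draw
from R's RNG stream, so training runs, generation, simulation and the
acceptance script are bit-reproducible from one integer. The test suite and
`scripts/acceptance.R` use desk-scale sizes chosen as the smallest that
exercise every code path meaningfully: 16³ volumes, `baseFilters = 4`,
4 classes × 10 volumes per domain, 150 generator steps, batch 1, one critic
step per generator step. These sizes are the package's own choice for fast,
deterministic CPU verification; converged image quality needs the reference
width (32), thousands of steps and larger datasets.

## 7. Known limitations

* Weight-clipped Wasserstein training is stable but slow to converge; a
  gradient-penalty variant is deliberately out of scope.
* The critic plan shrinks the spatial grid by 3 voxels per 4³ stage
  (pad 1), so `n ≥ 8` is required; generators need `n` divisible by 4.
* The default embedder is linear-ish in practice (pooled features + shallow
  net): good for class-separable toys, far weaker than a deep 3D CNN on
  real data; metric *values* depend on the embedder and are comparable only
  within one embedder.
* The Earth-Mover distance itself is never computed — only the critic
  objective that estimates it; reported critic losses are estimates, not
  calibrated distances.
* MRC I/O supports modes 0/1/2/6, single-volume files, little-endian.
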