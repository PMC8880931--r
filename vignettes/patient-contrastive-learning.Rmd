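---
title: "Patient-contrastive representation learning for 12-lead ECGs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-contrastive representation learning for 12-lead ECGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pclr)
```

## The model

Patient Contrastive Learning of Representations (PCLR) pre-trains an ECG
encoder without diagnostic labels by exploiting a fact about longitudinal
clinical data: two ECGs acquired from the *same* patient at different times
share underlying biology, while ECGs from different patients mostly do not.
Each pre-training example is therefore a *positive pair* — two ECGs of one
patient — and every other ECG in the mini-batch is a negative.

Given a batch of $N$ patients, two ECGs per patient, the encoder
$f(\cdot)$ produces representations $h_i = f(x_i)$ and the projection head
$g(\cdot)$ produces projections $z_i = g(h_i)$. With $\mathrm{sim}$ the
cosine similarity and temperature $\tau$, the loss for a positive pair
$(i, j)$ is the normalized temperature-scaled cross-entropy (NT-Xent)

$$
\ell_{i,j} \;=\; -\log
\frac{\exp[\mathrm{sim}(z_i, z_j)/\tau]}
     {\sum_{k=1,\,k \neq i}^{2N} \exp[\mathrm{sim}(z_i, z_k)/\tau]},
$$

and the batch loss sums one term per patient,
$L_{\text{batch}} = \sum_{p=1}^{N} \ell_{p_1, p_2}$, where $p_1, p_2$ index
patient $p$'s two ECGs. Note the asymmetry: the sum runs over anchors $p_1$
only, not both orderings. The symmetric (SimCLR-style) variant
$\ell_{p_1,p_2} + \ell_{p_2,p_1}$ is available through
`lossConfig(symmetric = TRUE)`; the default is the asymmetric form. Default
$\tau = 0.1$.

After pre-training the projection head is discarded; downstream tasks use
the representations $h$ only, through ridge-regularized linear models
("linear evaluation").

### Numerical treatment of the loss

* Softmax denominators are computed with max-subtraction (log-sum-exp), so
  temperature sweeps down to very small $\tau$ cannot overflow.
* Projection norms are floored at $10^{-12}$ before normalization. An
  all-zero projection vector is reachable through a ReLU head, and training
  should not die when it happens; `cosineSimilarity()` itself, as a
  user-facing mathematical function, still rejects zero vectors.
* The analytic gradient of $L_{\text{batch}}$ with respect to the
  projection matrix is implemented in closed form and is checked against
  central finite differences in the test suite.

## Architecture

The encoder follows the familiar residual 1-D convolutional template used
for 12-lead ECG classification: an initial convolution, batch
normalization, ReLU and max-pool, then a chain of residual blocks (each two
conv/BN/ReLU stages plus an additive skip path, with temporal
downsampling), and finally global average pooling (GAP) over time so that
the representation width equals the last stage's channel count.

The full-size default — input $4096 \times 12$, kernel width 16 everywhere,
four residual blocks with channels $64, 128, 196, 256, 320$, downsampling 4
per block, stem pool 2 — yields 320-dimensional representations.
Block-internal details (where dropout sits, how the skip path downsamples)
vary between published residual ECG networks; this package uses max-pool +
1×1 convolution on the skip path and exposes every element of the
configuration (`encoderConfig()`), treating the full-size instance as a
faithful-in-spirit default rather than a byte-exact reproduction of any one
network. `describeModel()` prints the layer stack for audit.

The projection head is Dense(320) → ReLU → Dense(320), with no activation
after the final layer.

Because no deep-learning framework is assumed, the package implements the
network engine directly on BLAS matrix operations: im2col convolutions,
batch normalization with running statistics, max-pool with argmax routing,
inverted dropout, GAP, dense layers, hand-written reverse-mode gradients,
and an Adam optimizer. Every layer's backward pass is finite-difference
checked in `test-nn.R`; this engine is deliberately minimal and is the
package's core computational substrate, not a general-purpose autodiff.

## Preprocessing contract

Raw leads arrive as integer microvolt sequences (10 s at 250 or 500 Hz).
`preprocessRecord()`:

1. divides each lead by 1,000 (µV → mV) and converts to floating point;
2. linearly interpolates each lead from its native length $L$ onto 4,096
   points at positions $t_k = k\,(L-1)/4095$, $k = 0,\dots,4095$ — an
   *endpoint-inclusive* grid, so the first and last samples are preserved
   exactly. Endpoint inclusion is a design decision made for testability
   (the alternative conventions differ only in sub-sample phase);
3. stacks the leads column-wise in the fixed order I, II, III, AVR, AVL,
   AVF, V1–V6.

No filtering, detrending, or artifact removal is applied — robustness to
baseline wander and muscle noise is supposed to be *learned*, so the model
must train on the same noise it will see at evaluation time.

## Pair sampling

Patients with a single ECG admit no positive pair and are removed
(`filterEligible()`). Per epoch, `sampleBatches()` permutes the eligible
patients (seeded by `(seed, epoch)`), chunks them into groups of
`nPatientsPerBatch` (default 512 patients = 1,024 ECGs), and draws, for
each patient, two distinct records uniformly over that patient's unordered
record pairs — deliberately ignoring acquisition time and any health change
between visits. Patients with more than two records still contribute
exactly one pair per batch appearance, because the loss assumes one
positive pair per patient. A trailing incomplete chunk is dropped rather
than padded so the $2N$ structure stays exact; epoch-level sampling is
without replacement, so each patient appears in at most one batch per
epoch.

## Optimization

Adam (conventional moment parameters), 50 epochs by default, learning rate
decayed once per epoch along a half-period cosine:
$\mathrm{lr}(t) = \mathrm{lr}_0 \, (1 + \cos(\pi t / T)) / 2$ with
$\mathrm{lr}_0 = 0.1$ and $T = 50$, so the rate is halved at $T/2$ and
reaches exactly zero at $T$. The realization that vanishes at $T$ was
chosen over conventions that only decay asymptotically, because a
non-vanishing final rate contradicts the idea of a schedule that completes
in `epochs` steps; epochs beyond $T$ clamp to the final value with a
message.

The train/validation split is by *patient* (default 90/10), never by
record — splitting records would leak patient identity into checkpoint
selection, which for a patient-identity objective is precisely the thing
that must not leak. After each epoch the contrastive loss is evaluated on
batches drawn from the held-out patients (inference mode: batch-norm uses
running statistics), and the checkpoint with the lowest validation loss is
returned. Runs are bit-reproducible from the config seed under
single-threaded numerics; with a multi-threaded BLAS, reduction order may
perturb results at floating-point level.

### The from-scratch baseline

`trainScratch()` trains the identical encoder plus a linear output layer
(two softmax outputs with categorical cross-entropy for classification, one
output with mean squared error for regression) for every cell of a grid of
learning rates $\{10^{-2}, 10^{-3}, 10^{-4}\}$ × convolutional dropout
rates $\{0, 0.1, 0.2\}$, early-stopping each cell after 5 non-improving
validation epochs and restoring its best-validation checkpoint; the cell
with the lowest validation loss wins. Batch size (32) and the record-level
validation fraction (0.25) are not pinned down by the protocol this
reproduces and are documented defaults in `scratchConfig()`.

## Linear evaluation

1. `extractFeatures()` applies the frozen encoder to $n$ ECGs, giving an
   $n \times 320$ feature table; `normalizeFeatures()` standardizes each
   column by its **training** mean and SD. Holdout rows are always
   normalized with the training statistics (`normalizeWith()`); the
   statistics travel with the table, and a floor of $10^{-12}$ on the SD
   guards degenerate constant columns.
2. `fitProbe()` trains a linear (regression) or logistic (classification)
   ridge model. The $\ell_2$ penalty is selected from 10 values
   log-evenly spaced between $10^{-6}$ and $10^{5}$ (both endpoints
   included, consecutive values $10^{11/9} \approx 16.68$ apart) by seeded
   4-fold cross-validation. Folds are scored with the *task metric*
   (positive-class f1, or $r^2$) rather than the loss; ties take the first
   (smallest) penalty. Linear ridge is solved in closed form via SVD;
   logistic ridge by damped Newton iterations penalizing
   $\tfrac{\lambda}{2}\lVert\beta\rVert^2$ on the log-likelihood scale with
   an unpenalized intercept — the same grid therefore acts on both probe
   families with the same semantics (the glmnet-equivalent penalty is
   $\lambda / n$; a cross-check against glmnet is in the test suite).
3. `evaluateProbe()` reports the point estimate on the full holdout plus
   the SD over seeded bootstrap resamples (default 1,000, with
   replacement, holdout-sized). The f1 convention is positive-class f1; for
   roughly balanced binary labels the designated positive class is an
   explicit argument. A resample containing a single truth class (possible
   under class imbalance) is redrawn and the occurrence logged.

`compareModels()` performs the paired bootstrap used to flag best models:
all models are scored on the *same* seeded resamples, the highest point
estimate is flagged best, and another model ties when the paired metric
difference lies within one SD of zero — mirroring reporting conventions of
"± one standard deviation of the bootstrapped performances".

## The synthetic cohort generator

Real hospital ECG archives cannot ship inside a package, so everything is
exercised on a synthetic cohort whose *structure* — not waveform realism —
matches what patient-contrastive learning needs:

* **Patient-stable morphology.** Each patient draws a beat template once:
  P, Q, R, S, T waves as Gaussian bumps on a 3-component dipole, with
  per-patient amplitude offsets (SD 0.02–0.06 mV per wave) and duration
  offsets (SD 1–8 ms), a global log-normal amplitude scale
  ($\sigma = 0.2$), and a fixed full-rank $12 \times 3$ lead-projection
  matrix built from frontal limb-lead directions plus a precordial arc —
  correlated-but-distinct leads at trivial cost.
* **Visit-to-visit variability.** Heart rate varies per visit (patient
  baseline $\sim \mathcal{N}(72, 7)$ bpm plus visit jitter), sinusoidal
  baseline wander (0.12–0.40 Hz, default 0.08 mV, applied in dipole space
  so it correlates across leads) and white noise (default 25 µV RMS per
  lead) are added, and consecutive visits are 30–500 days apart (uniform —
  bracketing a typical mean inter-ECG gap of a few hundred days), with the
  per-record age advancing accordingly.
* **Labels of both kinds probed downstream.** *Patient-stable*: a sex-like
  binary class expressed as multiplicative morphology effects (R ×1.10,
  S ×1.08, T ×0.85, QRS width ×1.06) and a hypertrophy-like flag defined
  deterministically as amplitude scale > 1.25 (high-voltage criterion, so
  it is linearly recoverable from R-amplitudes by construction — verified
  as AUC > 0.95 in the tests). *Record-level*: age at visit, and an
  intermittent arrhythmia-like flag (10% of patients have a nonzero
  propensity) under which beat intervals are log-normally jittered
  (coefficient of variation ≈ 0.25, always ≥ 0.15) and the P-wave is
  absent — the two ECG hallmarks of atrial fibrillation.
* Amplitudes are emitted as integer microvolts saturated at the 16-bit
  signed range, at 250 or 500 Hz, 10 s per record, so the preprocessing
  contract is exercised on realistic raw types.

Records render beats covering one second beyond both edges of the 10 s
window, which removes boundary artifacts and makes the noiseless
fixed-rate case *exactly* circularly periodic — a property the tests
assert sample-for-sample.

What the generator does **not** emulate: realistic P/QRS/T morphology
families, pathologies beyond the four probed labels, electrode placement
variation, pediatric ECGs, or non-stationary noise. Passing tests on this
cohort therefore demonstrate that the machinery recovers patient-stable
structure when it exists; they do not certify clinical performance on real
ECGs.

The cohort store is a plain-text directory layout: `metadata.csv` (one row
per record), `signatures.csv` (per-patient latents, when available), and
one CSV per record holding the 12 integer microvolt lead columns behind a
commented attribute header. Integer amplitudes round-trip exactly.

## Desk-scale experiment sizes

The mechanism-recovery benchmark (`runBenchmark()`) uses problem sizes
chosen so the full experiment runs comfortably on one CPU while leaving the
qualitative comparison intact: 200 pre-training patients with 2–3 visits,
tensors thinned ×8 to 512 samples, a 512-input encoder with channels
12/24/48 (48-dimensional representations), 8 pre-training epochs at
initial rate 0.01 (32 patients per batch — Adam at the full-scale 0.1
initial rate is not a sensible setting for a 40k-parameter encoder on 6
batches per epoch), 64 labeled records for the probes, 200 holdout
records, and a reduced from-scratch grid (learning rates $10^{-2},
10^{-3}$; dropout $0, 0.2$; patience 3, ≤ 12 epochs). With these sizes the
pre-trained probe for the sex-like attribute beats both the
random-encoder probe and from-scratch training by a wide margin, and
same-patient projections are far more similar than cross-patient ones
(about 0.96 vs 0.0 mean cosine similarity on held-out patients).

## Known limitations

* The network engine is single-threaded R + BLAS; full-size pre-training at
  hospital scale is out of reach (and out of scope) — the full-size
  configuration is exercised for its inference contracts.
* Only binary classification heads are provided, matching the probed tasks.
* The logistic probe's Newton solver assumes the (n ≤ a few thousand,
  d ≤ 320) regime of linear evaluation; it is not a general GLM solver.
* Bit-level reproducibility assumes single-threaded numerics.
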