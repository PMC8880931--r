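# pclr — Patient Contrastive Learning of ECG Representations

Supervised deep learning on clinical ECGs is label-starved: archives hold
millions of 12-lead ECGs, but any given diagnosis is rare and expensively
labeled. **pclr** implements patient-contrastive pre-training (PCLR): a
self-supervised objective that needs no diagnostic labels at all, only the
fact that the archive links ECGs to patients. Two ECGs acquired from the
same patient at different times form a *positive pair*; ECGs from different
patients are negatives. A residual convolutional encoder $f$ and a
projection head $g$ are trained with the normalized temperature-scaled
cross-entropy (NT-Xent) loss

$$
\ell_{i,j} = -\log
\frac{\exp[\mathrm{sim}(z_i,z_j)/\tau]}
     {\sum_{k \ne i}^{2N} \exp[\mathrm{sim}(z_i,z_k)/\tau]},
\qquad
L_{\text{batch}} = \sum_{p=1}^{N} \ell_{p_1,p_2},
$$

with $z = g(f(x))$, cosine similarity $\mathrm{sim}$, and $\tau = 0.1$.
After pre-training the head is discarded and the 320-dimensional
representations $h = f(x)$ are used with plain ridge-regularized linear
models — so clinical researchers get a feature vector they can drop into
logistic regression or Cox models, with no deep-learning expertise needed.

The package is aimed at methods researchers and practitioners who want a
fully tested, self-contained reference implementation: every component —
synthetic multi-visit cohort generation, the exact raw-signal preprocessing
contract, patient-pair batch sampling, the encoder/head architectures with
hand-written backpropagation and Adam, the supervised from-scratch
baseline, and the linear-evaluation + bootstrap-comparison protocol — is
exercisable end-to-end on a synthetic cohort on one CPU.

## What's inside

| Module | Exported surface |
| --- | --- |
| Synthetic cohorts | `generateCohort()`, `writeCohort()` / `readCohort()`, `cleanBeatTemplate()` |
| Preprocessing | `preprocessRecord()`, `batchPreprocess()`, `thinTensorSet()` (µV→mV, linear interpolation to 4,096×12; no filtering) |
| Pair sampling | `filterEligible()`, `sampleBatches()`, `materializeBatch()` |
| Architecture | `encoderConfig()`, `buildEncoder()`, `projectionConfig()`, `buildProjectionHead()`, `encode()`, `project()`, `describeModel()` |
| Contrastive core | `cosineSimilarity()`, `pairLoss()`, `batchLoss()`, `lossConfig()` |
| Pre-training | `trainConfig()`, `lrAtEpoch()`, `pretrainPCLR()`; baseline: `scratchConfig()`, `trainScratch()`, `predictScratch()` |
| Linear evaluation | `extractFeatures()`, `normalizeFeatures()` / `normalizeWith()`, `penaltyGrid()`, `fitProbe()`, `evaluateProbe()`, `scorePredictions()`, `compareModels()` |
| Orchestration | `runPipeline()`, `demoConfig()`, `runBenchmark()`; CLI at `inst/scripts/pclr` |

## Worked example

Pre-train a desk-scale encoder on a synthetic multi-visit cohort and check
that projections separate patients:

```r
library(pclr)

cohort <- filterEligible(generateCohort(60, visits = c(2, 3), seed = 42))
tensors <- thinTensorSet(batchPreprocess(cohort)$tensors, 8)  # 512 x 12

fit <- pretrainPCLR(tensors, tinyEncoderConfig(),
                    trainCfg = trainConfig(epochs = 4, initialLr = 0.01,
                                           schedulePeriod = 4, seed = 42),
                    nPatientsPerBatch = 16)
print(trainingLog(fit))
#>   epoch          lr trainLoss  valLoss
#> 1     1 0.010000000  2.871117 1.836283
#> 2     2 0.008535534  2.430164 1.865049
#> 3     3 0.005000000  2.106879 2.797216
#> 4     4 0.001464466  1.951814 1.388050

val <- subsetTensorSet(tensors,
                       patientIds(tensors) %in% fit@configs$validationPatients)
unlist(alignmentStats(fit, val))
#>    within   between
#> 0.9618155 0.5543440
```

The training loss falls from 2.87 to 1.95 over four epochs and the best
validation loss (1.39) selects the final checkpoint. On the held-out
patients the mean cosine similarity of projections is 0.96 for
same-patient pairs versus 0.55 across patients: after even a short run the
encoder orders the latent space by patient identity without having seen a
single label (longer runs, as in `runBenchmark()`, push the cross-patient
similarity toward zero).

Probing the frozen representations with a ridge logistic model
(`extractFeatures()` → `normalizeFeatures()` → `fitProbe()` →
`evaluateProbe()`) follows the three-step linear-evaluation protocol; see
`vignettes/patient-contrastive-learning.Rmd` for the full methods account
and `runBenchmark()` for the packaged comparison against a random encoder
and from-scratch training.

## License

MIT.
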