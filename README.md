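# endoscreen

Screening support for flexible nasopharyngoscopy (FNS) video. An FNS exam
yields hundreds of frames per patient, most of them blurred, obscured by
secretions, or pointed away from the glottis; a referral decision (grade 1:
none, grade 2: non-urgent, grade 3: urgent — binarised 1 vs 2–3) must be
distilled from the informative remainder. `endoscreen` implements a
two-stage framework for that distillation, aimed at low-resource settings
where both specialist reading time and compute are scarce:

* **Image quality module (IQM).** Histogram-of-oriented-gradients (HOG)
  descriptors compared by correlation against an operator-chosen index
  frame drop off-target and redundant frames; a compact CNN, trained on
  *weak* labels derived from a U-Net glottis segmenter ("good" = the
  predicted glottis mask is large enough and clear of the frame border),
  scores the survivors.
* **Disease classification module (DCM).** A frame-level CNN classifies the
  selected frames; the patient-level referral probability is the arithmetic
  mean of the frame probabilities, thresholded at 0.5:
  `p(patient) = (1/n) Σᵢ p(frameᵢ)`.

Because efficiency is the point, the package builds and profiles four
backbones — a six-layer baseline CNN, ResNet50, MobileNetV2 and
GhostNet — and reports their analytic cost (1 MAC = 1 FLOP). A ghost module
with ratio *s* replaces a dense convolution producing *c* maps by *c/s*
dense "intrinsic" maps plus *(s−1)·c/s* cheap depthwise "ghost" maps,
cutting the multiply-accumulate count by nearly *s*.

Everything runs on a synthetic FNS-like cohort generated in-package (dark
glottal aperture on tissue texture; blur / secretion occlusion / off-target
corruptions; a subtle lesion adjacent to the glottis for referral-positive
patients), with ground-truth quality, masks and grades — so the whole
pipeline, including its evaluation, is reproducible on a laptop with no
clinical data. There is no deep-learning framework dependency: the package
carries its own small CPU engine (RcppArmadillo im2col convolutions, batch
norm, Adam, focal loss), gradient-checked in the test suite.

## Worked example

```r
library(endoscreen)

## a 24-patient synthetic cohort, 60 frames each, ~70% referral-positive
cohort <- generate_cohort(scene_params(seed = 1), n_patients = 24,
                          positive_fraction = 0.7, frames_per_patient = 60)
cohort
#> <synthetic_cohort> 24 patients (17 referral-positive), 1440 frames

## architecture cost accounting (224x224 input, batch 64)
count_flops(arch_spec("ghostnet"), c(224, 224), 64)
#> <flop_report> ghostnet @ 224x224, batch 64: 8.95 GFLOPs (96 layers)
count_flops(arch_spec("resnet50"), c(224, 224), 64)
#> <flop_report> resnet50 @ 224x224, batch 64: 261.58 GFLOPs (54 layers)

## frame-budget ablation: does quality filtering help the referral model?
res <- run_experiment(cohort, conditions = c(NA, 10, Inf), seeds = 1:2)
res
#> Frame-budget ablation (patient-level metrics, mean over seeds):
#>  condition accuracy weighted_f1 auroc auprc
#>       none      0.7       0.656 0.375 0.846
#>         10      0.8       0.711 0.500 0.877
#>  unlimited      0.8       0.711 0.625 0.902
```

The ablation table reads: training and evaluating the referral classifier
on all frames ("none") leaves patient-level ranking at or below chance —
60% of frames carry no disease signal and corrupt both training and the
averaged prediction — and performance improves monotonically as the quality
module's per-patient frame budget grows. This small demonstration (24
patients, two seeds, 5-patient test sets) is deliberately coarse; the
acceptance suite runs the study conditions (40 patients x 100 frames, five
seeds) and checks that the filtered conditions beat the unfiltered baseline
on all four metrics with seed-means non-decreasing in the frame budget.

The full pipeline — synthesis, HOG filtering, U-Net weak labelling, quality
classifier, frame selection, referral classifier, ablation, report — runs
with:

```r
run_full_pipeline(default_pipeline_config(seed = 1), "run1", verbose = TRUE)
```

and writes a self-describing run directory (`config.yaml`, stage CSVs,
`report.md`). A thin command-line front end with per-stage subcommands
lives at `inst/cli/endoscreen.R`.

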