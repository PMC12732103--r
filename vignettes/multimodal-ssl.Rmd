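---
title: "Multimodal self-supervised representations for multi-site neuroimaging: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal self-supervised representations for multi-site neuroimaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurossl)
```

## The problem

Early Alzheimer's disease (AD) diagnosis and the prognosis of conversion
from mild cognitive impairment (MCI) to AD rest on two imaging modalities
with complementary timing: structural MRI shows atrophy that accumulates
relatively late, while PET tracers report molecular change that precedes it.
Cohorts large enough to train deep models are assembled across many sites
and scanners, which injects non-biological intensity variation ("site
effects") that models readily overfit; labels are scarce relative to scans;
PET is missing for many visits; and subjects return for follow-up visits
whose temporal structure carries signal of its own.

`neurossl` implements a two-stage response to all four problems:

1. **Stage 1 — self-supervised pretraining.** Two modality-specific 3D
   convolutional encoders $f_\theta^{MRI}, f_{\theta'}^{PET}$ with a
   projection head map each volume $x$ to a unit-norm embedding
   $z = g_\phi(f(x)) / \lVert g_\phi(f(x))\rVert_2 \in \mathbb{R}^d$. The
   pretraining objective is the weighted sum
   $$\mathcal{L} = \lambda_1 \mathcal{L}_{intra}
     + \lambda_2 \mathcal{L}_{cross} + \lambda_3 \mathcal{L}_{byol}
     + \lambda_4 \mathcal{L}_{long} + \lambda_5 \mathcal{L}_{long\times}
     + \lambda_6 \mathcal{L}_{site},$$
   where $\mathcal{L}_{intra}$ is an InfoNCE instance-discrimination loss
   over augmented views at temperature $\tau$ (with a MoCo-style momentum
   key encoder and FIFO queue of negatives), $\mathcal{L}_{cross}$ is a
   symmetric InfoNCE aligning co-registered MRI–PET pairs of the same visit,
   $\mathcal{L}_{byol}$ is a BYOL-style regression of a predicted online
   embedding onto a stop-gradient momentum target, $\mathcal{L}_{long}$ and
   $\mathcal{L}_{long\times}$ penalize squared distances between a subject's
   embeddings across visits (within and across modalities; both activate
   only when repeat visits exist), and $\mathcal{L}_{site}$ is the
   cross-entropy of a site discriminator reached through a gradient-reversal
   layer (GRL), so the encoder is pushed to *remove* linearly decodable site
   information while the discriminator keeps hunting for it.

2. **Stage 2 — multi-task fine-tuning.** A learned availability gate
   $\alpha = \sigma(w^\top [1_{MRI}, 1_{PET}] + b)$ fuses the embeddings as
   $e = [\alpha z_{MRI} \,\Vert\, (1-\alpha) z_{PET} \,\Vert\, c]$ with
   clinical covariates $c$; a missing modality's block is exactly zero, so
   the representation keeps its length and MRI-only inference is always
   valid. On $e$ sit a class-weighted softmax diagnosis head, a Cox risk
   head trained by the partial log-likelihood (Breslow ties), and a
   PET→MRI distillation term
   $\frac{1}{N}\sum_n 1_{PET,n}\lVert z_n^{MRI} - \mathrm{sg}(z_n^{PET})\rVert_2^2$.
   Probabilities are calibrated post hoc by temperature scaling fitted on a
   validation fold, which is a monotone transform and therefore never
   changes the predicted class.

The evaluation battery covers diagnosis (balanced accuracy, macro F1, AUC,
sensitivity at fixed specificity), prognosis (Harrell's C-index,
cumulative/dynamic time-dependent AUC and the integrated Brier score, both
with inverse-probability-of-censoring weights from a Kaplan–Meier estimate
of the censoring distribution), calibration (expected calibration error
with equal-mass bins), test–retest reliability (ICC(3,1), within-subject
CV, standardized response mean), and inference (subject-level percentile
bootstrap, DeLong's paired AUC test).

## The synthetic cohort: what it emulates and what it does not

Clinical cohorts of this kind are access-restricted, so the package ships a
generator whose every latent quantity is known, making each downstream
stage testable end to end.

Each subject carries a latent **disease severity** drawn from a
CN/MCI/AD mixture (means 0.5/1.25/2.25, within-class SD 0.25) that
progresses linearly in time with a positive per-subject slope
(0.02 ± 0.01 units/month), so severity and the thresholded diagnosis labels
are monotone within subject. Conversion times come from an exponential
proportional-hazards model, $h = h_0 e^{\beta \cdot \text{severity}}$
($h_0 = 0.004$/month, $\beta = 0.9$ per severity unit by default), censored
administratively at 36 months — the simplest survival model with a
closed-form oracle, which the generator's tests exploit.

Volumes are ellipsoidal "brains" on a 16³ grid (a config knob) with an
interior target region whose mean intensity falls with severity on MRI
(−10 intensity units per severity unit from a healthy 80; the atrophy
surrogate) and rises on PET (+25 from 40; the tracer surrogate). The
steeper PET slope encodes the field's observation that molecular change is
the earlier, stronger signal. Three further ingredients were added because
without them the pretraining objectives have nothing to learn or nothing to
unlearn:

* **Per-subject anatomy fields** — a smooth low-order polynomial pattern,
  drawn once per subject, added to both modalities (PET scaled by 0.7).
  This gives each subject an identity that is shared across co-registered
  modalities and stable across visits. Without it, two subjects at the same
  severity are statistically identical, and cross-modal instance alignment
  is information-theoretically impossible rather than merely hard.
* **Per-site affine effects** (additive shift, multiplicative scale) — the
  classic location/scale scanner effect that z-scoring and ComBat target.
* **Per-site bias-field gradients** — a linear intensity gradient across
  one axis, emulating coil/scanner inhomogeneity. This matters because the
  pipeline's own first step, per-volume z-scoring, *removes* purely affine
  site effects; a spatial pattern is the realistic component of a site
  signature that survives normalization and therefore the component the
  adversarial term actually has to fight.

What the generator does **not** emulate: real neuroanatomy, lesions,
scanner physics, registration error, or non-monotone clinical trajectories.
A test passing on this cohort shows the machinery is correct and the
optimization dynamics behave as claimed; it does not show clinical-grade
accuracy, and the package nowhere claims the headline numbers reported on
restricted clinical cohorts.

## Harmonization

The offline pipeline is fixed as z-score (MRI) / SUVR (PET) → histogram
matching → ComBat, applied with parameters fitted on training subjects only
and then applied identically to every timepoint of every subject (the
transform depends only on site and covariates, never the visit, so
longitudinal consistency is preserved by construction).

* **Histogram matching** uses 101 quantile knots and a monotone
  piecewise-linear transfer, with tails clamped to the template extremes;
  rank order within a volume — the anatomy — is preserved.
* **ComBat** is the canonical empirical-Bayes location/scale model:
  feature-wise OLS on site indicators plus biological covariates (age,
  sex), standardization by pooled variance, normal/inverse-gamma priors
  with method-of-moments hyperparameters, and the usual fixed-point
  iteration for the shrunken site effects. It is implemented in-package
  because the pipeline must *fit on the training fold and apply to held-out
  subjects*, a split the reference implementations do not expose; the test
  suite cross-checks the full-fit case against `sva::ComBat` and verifies
  recovery of simulated site effects and covariate slopes. Site variances
  use maximum-likelihood (1/n) denominators consistently, which makes a
  single-site model an exact identity. ComBat operates on feature vectors
  (embeddings or regional summaries), not raw grids; the choice of feature
  granularity is deliberately left to the caller.

## Numerical and architectural choices

* **Backbone.** A three-stage residual 3D CNN (widths 16/32/64, GroupNorm,
  global average pooling, embedding dimension d = 32) behind a stride-2
  stem, so a 16³ input passes stages at 8³/4³/2³. All convolutions are
  im2col gathers plus BLAS GEMMs with hand-written backward passes; every
  gradient in the package is pinned to central finite differences in the
  test suite. This size runs a full pretrain–finetune cycle on one CPU in
  minutes; clinical-resolution backbones (3D ResNet-50, 3D Swin) are out of
  scope at desk scale.
* **Normalization.** GroupNorm by default; domain-specific batch
  normalization (DSBN — separate batch statistics and affine parameters per
  site) is available for the ablation comparing the two.
* **Optimizer.** AdamW (decoupled weight decay on weight matrices only),
  lr 1e-3 for SSL and 3e-4 for fine-tuning, cosine decay, weight decay
  1e-4, batches sampled site-aware (every batch sees ≥ 2 sites when the
  pool does) at the subject level with up to two visits per subject so
  longitudinal pairs occur inside batches.
* **Momentum machinery.** Key encoders are EMA copies with momentum 0.9 —
  deliberately lower than the 0.99+ used at scale, because with only a few
  hundred optimizer steps a slower EMA never leaves its initialization and
  the contrastive targets would be noise. Queues hold 256 keys per modality
  by default (a scaled-down stand-in for the ≥8k used at scale), stored per
  modality.
* **Adversarial schedule.** The GRL forwards the embedding unchanged and
  reverses (and scales) the gradient; in addition, the discriminator alone
  takes a few plain gradient steps per batch (`discSteps`, default 5). With
  a single optimizer and few steps the discriminator otherwise lags the
  encoder so far that the reversed gradient points nowhere useful — the
  usual alternating schedule of domain-adversarial training, made explicit.
* **Temperatures and weights.** $\tau = 0.1$ (the 0.05–0.2 regime);
  default loss weights (1, 1, 1, 0.1, 0.1, 1). The longitudinal sums count
  unordered pairs once; the doubled sum of a literal reading is a constant
  factor absorbed into $\lambda_4, \lambda_5$. The site term carries its
  own weight $\lambda_6$ so it can be ablated independently of the BYOL
  term.
* **Cox details.** Breslow handling of tied event times (simplest estimator
  consistent with risk sets $\{j : T_j \ge T_n\}$); with no events the loss
  is 0 with a warning; risk sets form within the minibatch over its
  baseline visits. Survival curves for the Brier score come from the
  Breslow baseline cumulative hazard fitted on the training fold.
* **Temperature fitting** is a bounded 1-D minimization of validation NLL
  over $\log T \in [\log 0.05, \log 20]$, tolerance 1e-4; it touches only
  logits.
* **Ties and conventions.** AUC and C-index count score ties 1/2; the
  C-index excludes tied event times (Harrell); equal-mass ECE bins give
  remainders to the lowest-confidence bins; sensitivity at fixed
  specificity takes the best TPR among thresholds meeting the specificity
  bound; the integrated Brier score is normalized by the horizon
  ($\frac{1}{\tau_{max}}\int_0^{\tau_{max}}$), and the time-dependent AUC
  is the cumulative/dynamic IPCW estimator — in both cases the standard
  form, chosen where the method description names the quantity without
  fixing the estimator.
* **Degenerate inputs** are errors, not silent results: constant volumes in
  z-scoring, non-positive SUVR references, empty masks, single-class probe
  or calibration sets, unseen sites at ComBat application, crops larger
  than the grid, metrics without both classes or without comparable pairs.

## The experimental protocol

Splits are always at the subject level, stratified by site and diagnosis
with greedy round-robin assignment; every subject sits in exactly one test
fold and all its visits follow it. Every training stage — template fitting,
ComBat, SSL, fine-tuning, temperature fitting — records the subject ids it
consumed, and `auditLeakage()` verifies programmatically that no test
subject touched any of them; `evaluateModel()` refuses test sets that
overlap a training stage. Checkpoint selection uses a linear probe (ridge
logistic separator with fixed penalty) on frozen embeddings; the probe
cannot modify the encoder, which a fingerprint test asserts. The ablation
runner re-runs the pipeline under config overrides with shared seeds and
splits and reports, alongside the metrics, a post-hoc linear site-probe
accuracy — the quantity the site-invariance claim is about.

Problem sizes in the shipped tests and acceptance script are chosen for a
single desk CPU: cohorts of 40–200 subjects on 8³–16³ grids, 20–180
optimizer steps per arm, bootstrap at B = 200. These sizes are stated here
as the package's study conditions; scaling any of them up is a config
change, not a code change.

## Findings from the package's own experiments

Two results of the shipped experiments deserve honest discussion.

**Site invariance trades representation richness for invariance.** With the
adversarial weight off, instance discrimination happily encodes the scanner
bias field and a linear probe recovers the site at ~0.97 accuracy; with a
strong adversarial weight the probe falls to chance, but embedding spread
collapses too. The GRL removes site information partly by making the
representation less expressive — which is exactly the trade-off
site-ablation studies report, here reproduced in a controlled setting.

**Distillation does not help MRI-only deployment at desk scale.** Across
every regime piloted (default and weak-MRI/strong-PET generators,
$\gamma \in \{0.05, \dots, 1\}$, up to 16 fine-tuning epochs), PET→MRI
distillation failed to improve — and at $\gamma \ge 0.2$ consistently
degraded — MRI-only balanced accuracy relative to $\gamma = 0$. The
mechanism appears structural: under zero-imputation gated fusion, once
distillation makes $z^{MRI} \approx z^{PET}$, the diagnosis head's MRI-block
weights are identified only through the $\alpha$-weighted *sum* of the two
blocks whenever PET is present, so the MRI-only path — which uses the MRI
block alone — is under-determined and degrades. The corresponding
acceptance test is implemented faithfully at the package default
$\gamma = 0.5$ and is expected to fail under these study conditions; we
consider the negative result informative rather than a defect to be tuned
away. At clinical scale, with orders of magnitude more steps and data, the
balance may differ; the package cannot test that regime.

## Known limitations

* The backbone is desk-scale; no mixed precision, no multi-device, no 3D
  attention.
* The synthetic anatomy is a 9-dimensional smooth field — rich enough to
  make instance discrimination meaningful, far poorer than real anatomy.
* Cox risk sets form within minibatches; with very small batches the
  partial likelihood is a noisy estimate of the full-cohort one.
* DSBN needs ≥ 2 samples of a site in a batch to use batch statistics and
  falls back to running statistics otherwise.
* The bias-field model is linear along one axis; real inhomogeneity is
  smoother and multiplicative.

## A minimal session

```{r example, eval = FALSE}
cfg <- cohortConfig(nSubjects = 40, nSites = 2, seed = 1)
cohort <- generateCohort(cfg)
harm <- harmonizeCohort(cohort, histogram = FALSE)

pre <- pretrainSSL(harm$cohort,
                   sslConfig(epochs = 8, stepsPerEpoch = 4, seed = 1),
                   subjects = subjectTable(cohort)$subject_id[1:30])
subs <- subjectTable(cohort)$subject_id
model <- finetuneModel(pre$model, harm$cohort,
                       trainSubjects = subs[1:24],
                       validSubjects = subs[25:30],
                       ftConfig(epochs = 8, seed = 1))
evaluateModel(model, harm$cohort, subs[31:40], B = 200)
```
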