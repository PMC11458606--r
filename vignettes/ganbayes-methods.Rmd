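---
title: "Methods: adversarial features and naive Bayes risk scoring on vessel phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adversarial features and naive Bayes risk scoring on vessel phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Coronary artery disease risk stratification from contrast-enhanced CT
angiography asks a binary question per patient: does the imaging (and a
small set of tabular findings) place this person in the high-risk group?
`ganbayes` implements one answer end to end: images are cleaned in the
frequency domain, a generative adversarial network (GAN) is trained on
them, the discriminator's intermediate layer is reused as a learned
feature extractor, and a naive Bayes classifier over those features
produces a class label and a posterior-odds risk score
\(S = P(\mathrm{high}\mid x)/P(\mathrm{low}\mid x)\).

Real angiography cohorts are not redistributable, so the package ships a
synthetic vessel-phantom generator that plays the role of the imaging
data. Everything downstream of the generator treats the images as
opaque grayscale input; nothing in the pipeline "knows" the phantoms'
construction.

## The phantom generator

`generate_phantom()` renders an idealized vessel cross-section on a
square grid: a bright annular wall (outer radius `vessel_radius`, wall
thickness 25% of the radius), a contrast-filled lumen disk, and an
eccentric plaque drawn as a circular segment whose chord offset is
solved by bisection so the occluded area fraction matches
`stenosis_fraction` to within 0.001 analytically (pixelation adds up to
a few percent; the realized value is re-measured from the masks and is
asserted to sit within 0.05 of the request). Optional features: spotty
calcifications rendered as bright speckles inside the plaque, and
positive remodeling rendered as a local outward bulge of the wall around
the plaque direction. Tissue intensities default to background 0.10,
wall 0.55, lumen 0.85, plaque 0.40, calcification 0.95 — chosen for
separability on the [0, 1] scale and configurable. Additive Gaussian
noise (default sd 0.02, a mild clinical-quality level) is clipped to
[0, 1]; ground-truth masks are unaffected by noise.

The high-risk rule (`label_risk()`) is the disjunction of four
criteria: stenosis fraction ≥ 0.70 (inclusive), two or more diseased
vessels, positive remodeling together with at least one spotty
calcification, or a prior major coronary event. The low-risk class is
the negation. Labels are computed from the *measured* features, so the
rule, not the request, is authoritative.

`generate_cohort()` constructs cohorts with an exact class mix. By
default the high-risk samples fire the stenosis criterion (drawn
uniformly in [0.72, 0.92], clear of the 0.70 boundary so pixel-level
re-measurement cannot flip a label), with a 30% subset additionally
carrying remodeling plus calcification; low-risk samples draw stenosis
in [0.05, 0.45] with all other criteria off. Multivessel disease and
event history default to off in cohorts because they are tabular-only:
they would change the label without changing the image, putting a hard
ceiling on any image-based classifier. Users studying that regime can
set the flags explicitly.

What the phantoms do *not* emulate: CT acquisition physics (beam
hardening, motion, partial volume), anatomical variability, surrounding
tissue, 3-D geometry, or multiple vessels per frame. A passing
benchmark on phantoms demonstrates that the pipeline's machinery works
and that its features carry morphological signal; it says nothing about
clinical performance on real angiography.

## Frequency-domain preprocessing

`preprocess_image()` composes: forward 2-D DFT (`stats::fft` under the
standard unnormalized kernel), a centering shift placing DC at the
(⌊M/2⌋, ⌊N/2⌋) index, multiplication by an ideal radial filter mask,
the inverse shift and inverse transform (real part, with the imaginary
residual asserted below 1e-8 of the output scale — radially symmetric
masks preserve conjugate symmetry), and min–max normalization to
[0, 255]. Conventions: filters are sharp {0, 1} indicators with the
boundary radius *inclusive* (a Gaussian roll-off variant is available
behind `rolloff = "gaussian"` for ringing-sensitive use); a constant
image normalizes to all zeros with a warning rather than dividing by
zero. The default filter is a band-pass with cutoffs (2, image_size/4):
it removes the DC/low-frequency illumination scale and the highest
frequencies where speckle noise lives, while keeping the mid-band that
encodes lumen/plaque morphology. Low-pass, high-pass and all-pass
variants are exposed; which band best suits a given imaging chain is an
empirical question.

## The adversarial pair

Both networks are small fully connected maps — generator: latent 32 →
128 ReLU → pixels with a sigmoid (outputs bounded to [0, 1]);
discriminator: pixels → 256 tanh → 1 sigmoid. At 32×32 desk scale dense
layers train in seconds in pure R and leave nothing under-determined;
convolutional blocks would buy translation equivariance the phantom
task does not need. Losses are the standard non-saturating pair,

\[ L_G = -\tfrac1m\sum \log D(G(z)), \qquad
   L_D = -\tfrac1m\sum \log D(X) - \tfrac1m\sum \log(1 - D(G(z))), \]

both *minimized*; one discriminator step then one generator step per
mini-batch. Loss values and output-layer gradients are computed from
logits via softplus, so saturation cannot produce non-finite values;
probabilities surfaced to the user are clamped to [1e-12, 1 − 1e-12].
Training is bit-reproducible from the config seed under single-threaded
execution; `epochs = 0` returns the initialized networks.

Optimization is deliberately two-time-scale: the generator uses Adam
(lr 0.005) and the discriminator plain SGD (lr 0.05), batch size 8.
This configuration came out of a design study on two fixed evaluation
tasks — a degenerate dataset of constant 0.7-intensity images, where
successful training must move the generated mean pixel from its 0.5
initialization toward 0.7, and the 200-phantom classification benchmark
below. Plain SGD everywhere barely moves the generator within a
300-epoch budget (gradients were verified against finite differences,
so this is slow adversarial dynamics, not an implementation error);
Adam everywhere trains the generator but lets the discriminator drift
at the full step size along weak gradient directions, saturating its
tanh units and erasing the within-class structure that feature
extraction depends on. Adam-for-G with SGD-for-D gives both a generator
that learns and a discriminator that stays informative. The same study
fixed the discriminator at width 256 with tanh activation: ReLU codes
and narrower layers measurably lose class separability after training.
An L2 `weight_decay` knob exists for the discriminator but defaults to
0 (it hurt both evaluation tasks).

## Discriminator features and augmentation

A feature vector is the flattened output of the first *i* discriminator
layers; the default is the penultimate layer (the final layer is a
single saturating probability). Outputs wider than 512 values are
block-averaged down to at most 512 columns to keep naive Bayes
well-conditioned at desk scale; with the default architecture the
feature dimension is 256 and no pooling occurs.

Synthetic augmentation (`augment_with_synthetic()`) requires one
generator per class, because an unconditional generator produces
unlabeled images that cannot enter a supervised fit; rows generated
from class *k*'s generator inherit label *k* and are flagged
`source = "synthetic"`. With augmentation off (the default) a single
unconditional GAN is trained.

## Naive Bayes and the risk score

Priors are class frequencies. The Gaussian family (default — the
discriminator features are continuous) fits per-class, per-feature
means and variances with a variance floor of
1e-9 × (global feature variance + 1e-12) against singular likelihoods.
The multinomial family operates on non-negative integer features (see
`discretize()`: uniform or quantile bins fitted on training data, with
out-of-range values clamped at prediction time) with Lidstone smoothing

\[ P(x_i \mid C_k) = \frac{count(x_i, C_k) + \alpha}
   {\sum_{x'} count(x', C_k) + \alpha V}. \]

A `smoothing_mode = "paper"` variant drops the \(V\) factor from the
denominator; its per-class conditionals then sum to
\((\sum count + V\alpha)/(\sum count + \alpha)\) rather than 1, which
the tests assert explicitly. The normalized form is the default. All
posterior arithmetic runs in log space with log-sum-exp normalization;
classification is argmax with ties broken toward the earlier class in
declared order; the risk score is computed as
\(\exp(\log P(\mathrm{high}|x) - \log P(\mathrm{low}|x))\) with a +Inf
sentinel once the low posterior underflows 1e-300.

## Metrics

Dice and IoU are computed per class on binarized masks; two empty masks
score 1 (agreement on absence) and empty-vs-nonempty scores 0. Mean IoU
averages only classes present in the truth mask (absent classes would
be 0/0). Recall, precision and accuracy come from confusion counts,
returning NA with a warning on zero denominators. The ROC sweeps a
threshold over unique score values (ties share a threshold) and
integrates trapezoidally; on ties-free data this equals the
Mann–Whitney concordant-pair fraction, which the tests verify by
enumeration. `aggregate_metrics()` averages per-structure rows and
rounds half-up to two decimals — rounding happens only in this
aggregate report, never in stored values. A bundled reference table of
per-structure segmentation quality for eleven cardiovascular structures
(`cardiac_structure_metrics()`) serves as the worked aggregation input;
its average row is 0.91 / 0.90 / 0.96 / 0.98.

The baseline segmenter `threshold_segment()` exists to exercise these
metrics end to end, not to compete: a first Otsu threshold separates
tissue from the dark background (which dominates the histogram), a
second Otsu within the foreground isolates the bright contrast-filled
structures, and the largest connected bright component is returned as
the lumen mask. The two-stage design is what makes the noiseless
phantom's lumen recoverable at Dice ≥ 0.9; a single global threshold
lands between background and tissue and returns the whole vessel.

## The pipeline and its evaluation sizes

`run_pipeline()` executes cohort → preprocessing → GAN → features →
naive Bayes → held-out metrics. The train/test split is stratified by
label at the phantom (patient) level *before* any training, so held-out
images never influence the discriminator. Every stage draws from its
own RNG stream derived from the global seed and the stage name, making
reports reproducible byte-for-byte (timings aside) and stages
independently re-runnable; with `out_dir` set, every intermediate
artifact (cohort archive, features, predictions, model archives,
metrics) is written out.

The package's own evaluations use: a 200-phantom cohort at 32×32 with a
50/50 mix and a 70/30 split for the classification benchmark (held-out
accuracy ≥ 0.85 and risk-score AUC ≥ 0.90 across the seeds we tested,
typically 0.88–0.98 accuracy); 300 epochs on 64 constant-0.7 images for
the moment-matching check (generated mean pixel 0.77–0.80 across
seeds); and grids up to 8×8 for the transform-oracle properties. These
sizes keep a full run in the tens of seconds while leaving each effect
comfortably clear of its acceptance margin.

## Known limitations

* Dense networks and desk-scale images only; no GPU path, no
  convolutions, no Wasserstein/spectral-norm variants, no mode-collapse
  diagnostics beyond the loss history.
* The phantom generator's realism limits (above) bound what any result
  on it can claim.
* The risk score is a raw posterior odds from naive Bayes — it is a
  ranking statistic, not a calibrated probability; the
  conditional-independence assumption is kept, not tested.
* Segmentation in this package is the threshold baseline; the
  adversarial networks synthesize and discriminate images but do not
  emit masks.
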