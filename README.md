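# ganbayes

GAN-augmented naive Bayes risk scoring for coronary angiography-like
images, in pure R.

Coronary artery disease (CAD) risk stratification from CT angiography is
a binary call — high-risk vs low-risk — driven by image morphology
(lumen stenosis, plaque, calcification) plus a few tabular findings.
`ganbayes` implements a complete, reproducible pipeline for that call on
2-D grayscale images:

1. **Frequency-domain preprocessing** — 2-D DFT, centering shift, ideal
   low/high/band-pass radial filters
   (mask `H(u,v) = 1` iff `D1 ≤ r(u,v) ≤ D2` on the centered grid),
   inverse transform, min–max normalization to [0, 255].
2. **Adversarial training** — a generator `G(z)` mapping Gaussian noise
   to images and a discriminator `D(x)` scoring realness, trained by
   alternating mini-batch descent on the non-saturating losses
   `L_G = −E[log D(G(z))]` and
   `L_D = −E[log D(X)] − E[log(1 − D(G(z)))]`.
3. **Feature extraction** — the flattened output of an intermediate
   (default: penultimate) discriminator layer, `φ(x) = g_i ∘ … ∘ g_1(x)`.
4. **Classification** — Gaussian or Lidstone-smoothed multinomial naive
   Bayes, `P(C_k|x) ∝ P(C_k) ∏_i P(x_i|C_k)`, with the posterior-odds
   risk score `S = P(high|x) / P(low|x)`.
5. **Metrics** — Dice, IoU/mIoU, recall, precision, accuracy,
   threshold-sweep ROC/AUC, and per-structure aggregation.

Because real CAD imaging cohorts are not redistributable, the package
bundles a seeded **vessel-phantom generator**: annular wall, contrast
lumen, eccentric plaque crescent occluding a prescribed area fraction,
optional spotty calcification and positive remodeling, pixel-accurate
ground-truth masks, and a deterministic high-risk rule (stenosis ≥ 70%,
multivessel disease, remodeling + spotty calcification, or prior major
event). See the methods vignette (`vignettes/ganbayes-methods.Rmd`) for
the model, the design choices and their rationale.

## Worked example

```r
library(ganbayes)

report <- run_pipeline(default_config())   # ~25 s on one core
print(report)
#> ganb_run: 140 train / 60 test
#> held-out accuracy 0.917  recall 0.900  precision 0.931  AUC 0.977
```

That run generates 200 phantoms (32×32, half high-risk via the stenosis
criterion), band-pass filters them, trains the adversarial pair for 150
epochs on the 140 training images, extracts penultimate-layer
discriminator features, fits Gaussian naive Bayes, and evaluates on the
60 held-out phantoms: 91.7% are labelled correctly and ranking the
held-out patients by posterior-odds risk score gives an AUC of 0.977.
Every number is reproducible from `config$seed`.

The stages are also usable piecemeal:

```r
ph  <- generate_phantom(phantom_spec(stenosis_fraction = 0.8, seed = 7))
ph$label                                  # "high"
img <- preprocess_image(ph$image, list(kind = "band", d1 = 2, d2 = 8))
seg <- threshold_segment(ph$image)
dice(seg, (ph$masks == 2) * 1L)           # lumen Dice vs ground truth
```

A thin CLI mirroring the stages (subcommands `phantom`, `preproc`,
`train-gan`, `extract`, `fit-nb`, `predict`, `eval`, `run-all`) ships at
`system.file("cli", "ganb.R", package = "ganbayes")`.

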