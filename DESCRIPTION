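Package: ganbayes
Title: GAN-Augmented Naive Bayes Risk Scoring for Coronary Angiography Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies high-risk coronary-artery-disease cases from
    two-dimensional angiography-like grayscale images. Provides
    frequency-domain preprocessing with ideal low-, high- and band-pass
    filters; a generative adversarial network (generator/discriminator
    pair with the non-saturating adversarial losses) trained by
    mini-batch gradient descent; feature extraction from intermediate
    discriminator layers; Gaussian and Lidstone-smoothed multinomial
    naive Bayes classification with a posterior-odds risk score; a
    segmentation and classification metric suite (Dice, IoU, recall,
    precision, ROC/AUC); and a seeded synthetic vessel cross-section
    phantom generator with pixel-accurate ground-truth masks for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    rlang,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
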