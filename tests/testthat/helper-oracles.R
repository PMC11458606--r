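# Independent oracles and small fixtures shared across the suite.

# Direct O(M^2 N^2) evaluation of the forward transform double sum:
# F(u,v) = sum_x sum_y f(x,y) exp(-2i pi (ux/M + vy/N)), 0-based indices.
dft2_reference <- function(f) {
  M <- nrow(f)
  N <- ncol(f)
  out <- matrix(complex(real = 0), M, N)
  for (u in 0:(M - 1)) for (v in 0:(N - 1)) {
    acc <- 0 + 0i
    for (x in 0:(M - 1)) for (y in 0:(N - 1)) {
      acc <- acc + f[x + 1, y + 1] *
        exp(-2i * pi * (u * x / M + v * y / N))
    }
    out[u + 1, v + 1] <- acc
  }
  out
}

# Mann-Whitney concordant-pair AUC: ties between a positive and a
# negative score count 1/2.
auc_pairs_reference <- function(scores, labels, positive = "high") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Plain-arithmetic Bayes posterior for a multinomial count model: direct
# products of smoothed conditionals, no logs (independent of the
# log-space implementation path).
nb_posterior_reference <- function(x, class_counts, priors, alpha = 1,
                                   mode = "standard") {
  V <- ncol(class_counts)
  scores <- numeric(nrow(class_counts))
  for (k in seq_len(nrow(class_counts))) {
    denom <- sum(class_counts[k, ]) +
      alpha * if (mode == "standard") V else 1
    cond <- (class_counts[k, ] + alpha) / denom
    scores[k] <- priors[k] * prod(cond^x)
  }
  scores / sum(scores)
}

# A tiny noiseless phantom used by several files.
tiny_phantom <- function(stenosis = 0.5, seed = 42, noise_sd = 0,
                         size = 32, ...) {
  generate_phantom(phantom_spec(image_size = size,
                                stenosis_fraction = stenosis,
                                noise_sd = noise_sd, seed = seed, ...))
}

# Features for label_risk with every criterion off.
base_risk_features <- function(...) {
  f <- list(stenosis_fraction = 0.3, n_vessels_diseased = 1,
            positive_remodeling = FALSE, n_calc_spots = 0,
            prior_mi = FALSE)
  mods <- list(...)
  f[names(mods)] <- mods
  f
}
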