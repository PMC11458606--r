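#' Naive Bayes risk classification with a posterior-odds score
#'
#' Classifies feature vectors under the conditional-independence
#' assumption
#' \deqn{P(C_k \mid x_1,\dots,x_n) \propto P(C_k)\prod_i P(x_i \mid C_k),}
#' with class priors estimated as class counts over the total. Two
#' likelihood families are provided:
#'
#' * `gaussian` (default): per-class, per-feature normal likelihoods with
#'   a variance floor, suited to continuous discriminator features;
#' * `multinomial`: count-valued features with Lidstone smoothing
#'   \eqn{(count(x_i, C_k) + \alpha) / (\sum_{x'} count(x', C_k) + \alpha V)}.
#'   The `smoothing_mode = "paper"` variant drops the \eqn{V} factor from
#'   the denominator, i.e. \eqn{(count + \alpha)/(\sum count + \alpha)};
#'   the resulting per-class conditionals then sum to
#'   \eqn{(\sum count + V\alpha)/(\sum count + \alpha)} rather than 1, so
#'   the default is the standard normalized form.
#'
#' All likelihood arithmetic runs in log space with log-sum-exp
#' normalization. For a binary high/low model the posterior-odds risk
#' score is \eqn{S = P(\mathrm{high} \mid x) / P(\mathrm{low} \mid x)}.
#'
#' @name ganb_classifier
NULL

#' Fit a naive Bayes model
#'
#' @param x feature matrix (`n x d`), or a `feature_table`.
#' @param y class labels, one per row; ignored (taken from the table) when
#'   `x` is a labelled `feature_table`. Class order is the factor level
#'   order, with `"high"` placed first for high/low risk labels.
#' @param family `"gaussian"` or `"multinomial"`.
#' @param alpha Lidstone smoothing pseudo-count (multinomial; >= 0).
#' @param smoothing_mode `"standard"` (normalized Lidstone) or `"paper"`
#'   (denominator without the vocabulary factor); see the package
#'   description of the two forms.
#' @param var_floor_scale the per-feature variance floor is
#'   `var_floor_scale * (global feature variance + 1e-12)`.
#' @return An `nb_model` with priors, per-class statistics and the fitted
#'   configuration.
#' @export
nb_fit <- function(x, y = NULL, family = c("gaussian", "multinomial"),
                   alpha = 1, smoothing_mode = c("standard", "paper"),
                   var_floor_scale = 1e-9) {
  family <- match.arg(family)
  smoothing_mode <- match.arg(smoothing_mode)
  if (inherits(x, "feature_table")) {
    if (is.null(y)) y <- x$labels
    x <- x$features
  }
  check_matrix(x, "x")
  if (length(y) != nrow(x)) stop_ganb("length(y) must match nrow(x)")
  if (any(is.na(y))) stop_ganb("labels contain missing values")
  if (!is.numeric(alpha) || alpha < 0)
    stop_ganb("alpha must be a non-negative smoothing parameter")
  classes <- if (is.factor(y)) levels(y) else unique(as.character(y))
  if (setequal(classes, risk_levels())) classes <- risk_levels()
  y <- as.character(y)
  counts <- table(factor(y, levels = classes))
  if (any(counts == 0))
    stop_ganb("class with 0 samples: ",
              paste(names(counts)[counts == 0], collapse = ", "))
  priors <- as.numeric(counts) / length(y)
  d <- ncol(x)
  model <- list(classes = classes, priors = priors, family = family,
                d = d, alpha = alpha, smoothing_mode = smoothing_mode)
  if (family == "gaussian") {
    gvar <- apply(x, 2, stats::var)
    gvar[is.na(gvar)] <- 0
    floor_ <- var_floor_scale * (gvar + 1e-12)
    mu <- matrix(0, length(classes), d)
    v <- matrix(0, length(classes), d)
    for (k in seq_along(classes)) {
      xk <- x[y == classes[k], , drop = FALSE]
      mu[k, ] <- colMeans(xk)
      vk <- apply(xk, 2, stats::var)
      vk[is.na(vk)] <- 0
      v[k, ] <- pmax(vk, floor_)
    }
    model$mean <- mu
    model$var <- v
    model$var_floor <- floor_
  } else {
    if (any(x < 0) || any(x != round(x)))
      stop_ganb("multinomial family requires non-negative integer ",
                "features; see discretize()")
    V <- d
    cnt <- matrix(0, length(classes), d)
    for (k in seq_along(classes))
      cnt[k, ] <- colSums(x[y == classes[k], , drop = FALSE])
    denom <- rowSums(cnt) + alpha * switch(smoothing_mode,
                                           standard = V, paper = 1)
    model$counts <- cnt
    model$V <- V
    model$cond_prob <- (cnt + alpha) / denom
    model$log_cond <- log(model$cond_prob)
  }
  structure(model, class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("nb_model (%s): %d classes [%s], %d features\n", x$family,
              length(x$classes), paste(x$classes, collapse = ", "), x$d))
  cat("priors:", paste(sprintf("%.3f", x$priors), collapse = ", "), "\n")
  invisible(x)
}

as_feature_matrix <- function(model, x) {
  if (inherits(x, "feature_table")) x <- x$features
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$d)
    stop_ganb("input has ", ncol(x), " features; model expects ", model$d)
  x
}

#' Per-class log posterior probabilities
#'
#' Computes `log P(C_k) + sum_i log P(x_i | C_k)` per class and normalizes
#' with log-sum-exp, so the exponentials sum to one.
#'
#' @param model an `nb_model`.
#' @param x a feature vector, `n x d` matrix or `feature_table`.
#' @return An `n x K` matrix of normalized log posteriors with class
#'   names as columns.
#' @export
predict_log_posterior <- function(model, x) {
  if (!inherits(model, "nb_model")) stop_ganb("model must be an nb_model")
  x <- as_feature_matrix(model, x)
  n <- nrow(x)
  K <- length(model$classes)
  joint <- matrix(0, n, K)
  for (k in seq_len(K)) {
    joint[, k] <- if (model$family == "gaussian") {
      ll <- stats::dnorm(x,
                         mean = matrix(model$mean[k, ], n, model$d,
                                       byrow = TRUE),
                         sd = matrix(sqrt(model$var[k, ]), n, model$d,
                                     byrow = TRUE), log = TRUE)
      rowSums(ll) + log(model$priors[k])
    } else {
      as.vector(x %*% model$log_cond[k, ]) + log(model$priors[k])
    }
  }
  mx <- apply(joint, 1, max)
  lse <- mx + log(rowSums(exp(joint - mx)))
  out <- joint - lse
  colnames(out) <- model$classes
  out
}

#' Classify by maximum posterior
#'
#' Ties are broken deterministically in favor of the earlier class in the
#' model's declared class order.
#'
#' @inheritParams predict_log_posterior
#' @return A character vector of predicted class labels.
#' @export
nb_classify <- function(model, x) {
  lp <- predict_log_posterior(model, x)
  model$classes[max.col(lp, ties.method = "first")]
}

#' Posterior-odds risk score
#'
#' For a binary high/low model,
#' `S = P(high | x) / P(low | x)`, computed in log space. When the low
#' posterior underflows below `1e-300` the score is `+Inf`.
#'
#' @inheritParams predict_log_posterior
#' @return A numeric vector of non-negative risk scores (possibly `Inf`).
#' @export
risk_score <- function(model, x) {
  if (!inherits(model, "nb_model")) stop_ganb("model must be an nb_model")
  if (length(model$classes) != 2 ||
      !identical(model$classes, risk_levels()))
    stop_ganb("risk_score requires a binary model with classes ",
              "ordered (high, low)")
  lp <- predict_log_posterior(model, x)
  s <- unname(exp(lp[, "high"] - lp[, "low"]))
  s[lp[, "low"] < log(1e-300)] <- Inf
  s
}

#' Discretize continuous features into integer bin codes
#'
#' Fits per-feature bin edges on training data (`"uniform"`: equal-width
#' over the observed range; `"quantile"`: equal-probability) and encodes
#' values as 0-based bin codes. The fitted edges are returned so the same
#' binning can be reapplied at prediction time with
#' [apply_discretizer()]; out-of-range values clamp to the first/last
#' bin.
#'
#' @param x numeric matrix (`n x d`) or `feature_table`.
#' @param n_bins number of bins per feature (>= 2).
#' @param strategy `"quantile"` or `"uniform"`. A constant feature cannot
#'   be cut by quantiles and falls back to uniform with a warning.
#' @return A `discretizer`: list with `codes` (integer matrix), `edges`
#'   (list of per-feature inner edges) and `strategy`.
#' @export
discretize <- function(x, n_bins = 8, strategy = c("quantile", "uniform")) {
  strategy <- match.arg(strategy)
  check_number(n_bins, "n_bins", 2, integer = TRUE)
  if (inherits(x, "feature_table")) x <- x$features
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  edges <- vector("list", ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    strat_j <- strategy
    if (strat_j == "quantile" && length(unique(v)) < 2) {
      warning("feature ", j,
              " is constant; falling back to uniform binning")
      strat_j <- "uniform"
    }
    e <- if (strat_j == "uniform") {
      rng <- range(v)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      seq(rng[1], rng[2], length.out = n_bins + 1)
    } else {
      unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                             names = FALSE, type = 7))
    }
    edges[[j]] <- e[-c(1, length(e))]  # inner edges only; outer bins clamp
  }
  disc <- structure(list(edges = edges, n_bins = n_bins,
                         strategy = strategy),
                    class = "discretizer")
  disc$codes <- apply_discretizer(disc, x)
  disc
}

#' Apply a fitted discretizer
#'
#' @param disc a `discretizer` from [discretize()].
#' @param x numeric matrix or `feature_table` with the same number of
#'   features the discretizer was fitted on.
#' @return Integer matrix of 0-based bin codes; values beyond the fitted
#'   range clamp to the extreme bins.
#' @export
apply_discretizer <- function(disc, x) {
  if (!inherits(disc, "discretizer")) stop_ganb("not a discretizer")
  if (inherits(x, "feature_table")) x <- x$features
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (ncol(x) != length(disc$edges))
    stop_ganb("input has ", ncol(x), " features; discretizer expects ",
              length(disc$edges))
  codes <- matrix(0L, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    codes[, j] <- as.integer(findInterval(x[, j], disc$edges[[j]],
                                          left.open = FALSE))
  }
  codes
}
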