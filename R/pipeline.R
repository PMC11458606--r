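#' End-to-end risk-classification pipeline
#'
#' Orchestrates the full chain on a synthetic cohort: phantom generation,
#' frequency-domain preprocessing, adversarial training on the training
#' split, discriminator-feature extraction, optional class-conditional
#' synthetic augmentation, naive Bayes fitting, and held-out evaluation
#' with the posterior-odds risk score.
#'
#' The train/test split happens at the patient (phantom) level, stratified
#' by risk label, *before* any adversarial training, so no held-out image
#' ever influences the discriminator features.
#'
#' @name pipeline_cli
NULL

#' Default pipeline configuration
#'
#' Nested blocks mirror the pipeline stages. Defaults: 200 phantoms of
#' 32x32 pixels with a 50/50 high/low mix and mild noise; an ideal
#' band-pass filter with cutoffs (2, image_size/4); a 150-epoch GAN
#' (Adam generator, SGD discriminator); penultimate-layer features
#' without augmentation; Gaussian naive Bayes; a stratified 70/30
#' split.
#'
#' @return A `pipeline_config` list.
#' @export
default_config <- function() {
  structure(list(
    phantom = list(n = 200, image_size = 32, class_mix = 0.5,
                   noise_sd = 0.02, vessel_radius = 12),
    preproc = list(kind = "band", d1 = 2, d2 = NULL, rolloff = "ideal"),
    gan = list(latent_dim = 32, hidden_g = 128, hidden_d = 256,
               learning_rate = 0.005, batch_size = 8, epochs = 150,
               optimizer = "adam", d_activation = "tanh",
               weight_decay = 0, d_optimizer = "sgd",
               d_learning_rate = 0.05),
    feature = list(layer_index = NULL, augment = FALSE, n_per_class = 0),
    nb = list(family = "gaussian", alpha = 1, smoothing_mode = "standard",
              n_bins = 8),
    split = 0.7,
    seed = 1,
    out_dir = NULL), class = "pipeline_config")
}

merge_block <- function(defaults, user, path) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop_ganb("config block '", path, "' must be a list")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop_ganb("unknown config key", if (length(unknown) > 1) "s" else "",
              " in '", path, "': ", paste(unknown, collapse = ", "))
  for (k in names(user)) defaults[[k]] <- user[[k]]
  defaults
}

#' Validate a raw configuration against the schema
#'
#' Unknown keys are rejected by name; missing keys take their defaults.
#'
#' @param raw a (possibly partial) nested list, e.g. parsed from YAML.
#' @return A complete, validated `pipeline_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.null(raw)) raw <- list()
  def <- default_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown) > 0)
    stop_ganb("unknown config key", if (length(unknown) > 1) "s" else "",
              ": ", paste(unknown, collapse = ", "))
  cfg <- def
  for (blk in c("phantom", "preproc", "gan", "feature", "nb"))
    cfg[[blk]] <- merge_block(def[[blk]], raw[[blk]], blk)
  for (k in c("split", "seed", "out_dir"))
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  check_number(cfg$split, "split", 0, 1)
  if (cfg$split <= 0 || cfg$split >= 1)
    stop_ganb("'split' must be strictly inside (0, 1)")
  check_number(cfg$seed, "seed", integer = TRUE)
  check_number(cfg$phantom$n, "phantom$n", 2, integer = TRUE)
  check_number(cfg$gan$epochs, "gan$epochs", 0, integer = TRUE)
  if (!cfg$preproc$kind %in% c("band", "low", "high", "allpass"))
    stop_ganb("preproc$kind must be one of band, low, high, allpass")
  if (!cfg$nb$family %in% c("gaussian", "multinomial"))
    stop_ganb("nb$family must be gaussian or multinomial")
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' An empty file yields the full default configuration.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_ganb("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(raw)
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stratified_split <- function(labels, frac, seed) {
  withr::with_seed(seed, {
    train_idx <- integer(0)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      n_train <- round(length(idx) * frac)
      train_idx <- c(train_idx, sample(idx, n_train))
    }
    sort(train_idx)
  })
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e)
    stop_ganb("pipeline stage '", name, "' failed: ",
              conditionMessage(e)))
  list(value = value, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes phantom generation, preprocessing, adversarial training (one
#' GAN overall, or one per risk class when augmentation is enabled),
#' feature extraction, naive Bayes fitting and held-out evaluation, all
#' seeded from `config$seed` (stage seeds are derived per stage name).
#'
#' @param config a `pipeline_config`, see [default_config()] and
#'   [validate_config()].
#' @return A `ganb_run` report: configuration and its hash, per-stage
#'   timings, held-out classification metrics (accuracy, recall,
#'   precision, risk-score ROC/AUC, confusion counts), a prediction table
#'   with posteriors and risk scores, and the GAN loss history. When
#'   `config$out_dir` is set, all intermediate artifacts (cohort files,
#'   features, predictions, metrics, model archive) are also written
#'   there.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(unclass(config))
  seed <- config$seed
  timings <- list()

  st <- run_stage("phantom", {
    base <- phantom_spec(image_size = config$phantom$image_size,
                         noise_sd = config$phantom$noise_sd,
                         vessel_radius = config$phantom$vessel_radius)
    generate_cohort(config$phantom$n, config$phantom$class_mix,
                    base_spec = base, seed = derive_seed(seed, "phantom"))
  })
  cohort <- st$value
  timings$phantom <- st$seconds
  labels <- vapply(cohort, function(x) x$label, character(1))

  st <- run_stage("preprocess", {
    t(vapply(cohort, function(s)
      pmin(pmax(as.vector(preprocess_image(s$image, config$preproc)) / 255,
                0), 1),
      numeric(config$phantom$image_size^2)))
  })
  images <- st$value
  timings$preprocess <- st$seconds

  train_idx <- stratified_split(labels, config$split,
                                derive_seed(seed, "split"))
  test_idx <- setdiff(seq_along(labels), train_idx)

  img_shape <- rep(config$phantom$image_size, 2)
  gcfg <- function(s) gan_config(
    latent_dim = config$gan$latent_dim, hidden_g = config$gan$hidden_g,
    hidden_d = config$gan$hidden_d,
    learning_rate = config$gan$learning_rate,
    batch_size = config$gan$batch_size, epochs = config$gan$epochs,
    optimizer = config$gan$optimizer,
    d_activation = config$gan$d_activation,
    weight_decay = config$gan$weight_decay,
    d_optimizer = config$gan$d_optimizer,
    d_learning_rate = config$gan$d_learning_rate, seed = s)

  st <- run_stage("train_gan", {
    if (isTRUE(config$feature$augment)) {
      gans <- lapply(risk_levels(), function(cls) {
        rows <- train_idx[labels[train_idx] == cls]
        train_gan(images[rows, , drop = FALSE],
                  gcfg(derive_seed(seed, paste0("gan-", cls))),
                  image_shape = img_shape)
      })
      names(gans) <- risk_levels()
      gans
    } else {
      list(all = train_gan(images[train_idx, , drop = FALSE],
                           gcfg(derive_seed(seed, "gan")),
                           image_shape = img_shape))
    }
  })
  gans <- st$value
  timings$train_gan <- st$seconds
  # the discriminator used for features: the single GAN's, or the first
  # class GAN's when training per class
  D <- gans[[1]]$discriminator

  st <- run_stage("features", {
    tr <- extract_features(D, images[train_idx, , drop = FALSE],
                           config$feature$layer_index,
                           labels = labels[train_idx])
    te <- extract_features(D, images[test_idx, , drop = FALSE],
                           config$feature$layer_index,
                           labels = labels[test_idx])
    if (isTRUE(config$feature$augment) && config$feature$n_per_class > 0) {
      syn <- augment_with_synthetic(
        lapply(gans, function(g) g$generator), D,
        config$feature$n_per_class, config$feature$layer_index,
        seed = derive_seed(seed, "augment"))
      tr <- combine_feature_tables(tr, syn)
    }
    list(train = tr, test = te)
  })
  feats <- st$value
  timings$features <- st$seconds

  st <- run_stage("classify", {
    if (config$nb$family == "multinomial") {
      disc <- discretize(feats$train$features, n_bins = config$nb$n_bins)
      x_train <- disc$codes
      x_test <- apply_discretizer(disc, feats$test$features)
    } else {
      disc <- NULL
      x_train <- feats$train$features
      x_test <- feats$test$features
    }
    model <- nb_fit(x_train, feats$train$labels,
                    family = config$nb$family, alpha = config$nb$alpha,
                    smoothing_mode = config$nb$smoothing_mode)
    lp <- predict_log_posterior(model, x_test)
    pred <- model$classes[max.col(lp, ties.method = "first")]
    list(model = model, discretizer = disc,
         predictions = data.frame(
           id = test_idx,
           truth = labels[test_idx],
           predicted = pred,
           p_high = exp(lp[, "high"]),
           risk_score = risk_score(model, x_test)))
  })
  cls <- st$value
  timings$classify <- st$seconds

  st <- run_stage("metrics", {
    pr <- cls$predictions
    counts <- confusion_counts(pr$predicted, pr$truth, positive = "high")
    roc <- roc_auc(pr$risk_score, pr$truth, positive = "high")
    list(accuracy = accuracy(counts), recall = recall(counts),
         precision = precision(counts), auc = roc$auc,
         roc_curve = roc$curve, confusion = counts)
  })
  metrics <- st$value
  timings$metrics <- st$seconds

  cfg_for_hash <- config
  report <- structure(list(
    config = config,
    config_hash = rlang::hash(unclass(cfg_for_hash)),
    n_train = length(train_idx), n_test = length(test_idx),
    metrics = metrics,
    predictions = cls$predictions,
    nb_model = cls$model,
    gan_history = gans[[1]]$history,
    timings = timings), class = "ganb_run")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    export_cohort(cohort, file.path(config$out_dir, "cohort"))
    utils::write.csv(as.data.frame(feats$train),
                     file.path(config$out_dir, "features_train.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(feats$test),
                     file.path(config$out_dir, "features_test.csv"),
                     row.names = FALSE)
    utils::write.csv(cls$predictions,
                     file.path(config$out_dir, "predictions.csv"),
                     row.names = FALSE)
    gan_save(gans[[1]], file.path(config$out_dir, "gan"))
    nb_save(cls$model, file.path(config$out_dir, "nb_model.json"))
    jsonlite::write_json(
      list(config_hash = report$config_hash,
           accuracy = metrics$accuracy, recall = metrics$recall,
           precision = metrics$precision, auc = metrics$auc,
           confusion = unclass(metrics$confusion)),
      file.path(config$out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    save_config(config, file.path(config$out_dir, "config.yaml"))
  }
  report
}

#' @export
print.ganb_run <- function(x, ...) {
  cat("ganb_run:", x$n_train, "train /", x$n_test, "test\n")
  cat(sprintf(
    "held-out accuracy %.3f  recall %.3f  precision %.3f  AUC %.3f\n",
    x$metrics$accuracy, x$metrics$recall, x$metrics$precision,
    x$metrics$auc))
  invisible(x)
}
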