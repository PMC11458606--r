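#' Model serialization
#'
#' GAN parameters are written as a flat-array archive (one CSV per weight
#' matrix / bias vector) next to a JSON architecture descriptor, so the
#' archive stays plain text and diffable. Naive Bayes models round-trip
#' through a single JSON file.
#'
#' @name serialization
NULL

write_net <- function(net, dir, prefix) {
  arch <- list(sizes = net$sizes,
               acts = vapply(net$layers, `[[`, character(1), "act"))
  for (k in seq_along(net$layers)) {
    utils::write.table(net$layers[[k]]$W,
                       file.path(dir, sprintf("%s_W%d.csv", prefix, k)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(matrix(net$layers[[k]]$b, nrow = 1),
                       file.path(dir, sprintf("%s_b%d.csv", prefix, k)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  arch
}

read_net_layers <- function(dir, prefix, arch) {
  lapply(seq_along(arch$acts), function(k) {
    W <- as.matrix(utils::read.csv(
      file.path(dir, sprintf("%s_W%d.csv", prefix, k)), header = FALSE))
    dimnames(W) <- NULL
    b <- as.numeric(utils::read.csv(
      file.path(dir, sprintf("%s_b%d.csv", prefix, k)), header = FALSE))
    list(W = W, b = b, act = arch$acts[k])
  })
}

#' Save a trained GAN to a directory
#'
#' @param gan a `gan_model` from [train_gan()].
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
gan_save <- function(gan, dir) {
  if (!inherits(gan, "gan_model")) stop_ganb("gan must be a gan_model")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arch <- list(
    image_shape = gan$image_shape,
    config = unclass(gan$config),
    generator = c(write_net(gan$generator, dir, "G"),
                  list(latent_dim = gan$generator$latent_dim,
                       output_shape = gan$generator$output_shape)),
    discriminator = c(write_net(gan$discriminator, dir, "D"),
                      list(input_shape = gan$discriminator$input_shape,
                           feature_layer_default =
                             gan$discriminator$feature_layer_default)))
  jsonlite::write_json(arch, file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(gan$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a GAN saved with [gan_save()]
#'
#' @param dir directory containing `architecture.json` and the flat
#'   weight arrays.
#' @return A `gan_model` (history restored from `history.csv`).
#' @export
gan_load <- function(dir) {
  arch <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  G <- structure(list(layers = read_net_layers(dir, "G", arch$generator),
                      sizes = arch$generator$sizes,
                      latent_dim = arch$generator$latent_dim,
                      output_shape = arch$generator$output_shape),
                 class = "generator_net")
  D <- structure(list(layers = read_net_layers(dir, "D",
                                               arch$discriminator),
                      sizes = arch$discriminator$sizes,
                      input_shape = arch$discriminator$input_shape,
                      n_layers = length(arch$discriminator$acts),
                      feature_layer_default =
                        arch$discriminator$feature_layer_default),
                 class = "discriminator_net")
  history <- utils::read.csv(file.path(dir, "history.csv"))
  cfg <- arch$config
  config <- gan_config(latent_dim = cfg$latent_dim,
                       hidden_g = cfg$hidden_g, hidden_d = cfg$hidden_d,
                       learning_rate = cfg$learning_rate,
                       batch_size = cfg$batch_size, epochs = cfg$epochs,
                       optimizer = cfg$optimizer,
                       d_activation = cfg$d_activation %||% "tanh",
                       weight_decay = cfg$weight_decay %||% 0,
                       d_optimizer = cfg$d_optimizer,
                       d_learning_rate = cfg$d_learning_rate,
                       seed = cfg$seed)
  structure(list(generator = G, discriminator = D, history = history,
                 epoch_means = NULL, config = config,
                 image_shape = arch$image_shape),
            class = "gan_model")
}

#' Save a naive Bayes model as JSON
#' @param model an `nb_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
nb_save <- function(model, path) {
  if (!inherits(model, "nb_model")) stop_ganb("model must be an nb_model")
  obj <- unclass(model)
  for (f in c("mean", "var", "counts", "cond_prob", "log_cond"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.data.frame(obj[[f]])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a naive Bayes model saved with [nb_save()]
#' @param path JSON file path.
#' @return An `nb_model`.
#' @export
nb_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("mean", "var", "counts", "cond_prob", "log_cond"))
    if (!is.null(obj[[f]])) {
      obj[[f]] <- as.matrix(obj[[f]])
      dimnames(obj[[f]]) <- NULL
    }
  structure(obj, class = "nb_model")
}
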