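#' Discriminator-layer feature extraction
#'
#' After adversarial training the discriminator's intermediate layers
#' encode rich image descriptors. A feature vector for image `x` is the
#' flattened output of the composition of the first `i` discriminator
#' layers, \eqn{\varphi(x) = g_i \circ \cdots \circ g_1(x)}. The default
#' layer is the penultimate one: the final layer is a single saturating
#' probability and carries little information.
#'
#' @name feature_extract
NULL

# Feature vectors wider than this are block-averaged down, keeping the
# downstream naive Bayes model well conditioned at desk scale.
MAX_FEATURE_DIM <- 512L

new_feature_table <- function(features, labels, layer_index, source) {
  if (is.null(labels)) labels <- rep(NA_character_, nrow(features))
  stopifnot(length(labels) == nrow(features),
            length(source) == nrow(features))
  structure(list(features = features, labels = labels,
                 layer_index = as.integer(layer_index), source = source),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d x %d (layer %d; %d synthetic rows)\n",
              nrow(x$features), ncol(x$features), x$layer_index,
              sum(x$source == "synthetic")))
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  df <- as.data.frame(x$features)
  names(df) <- paste0("f", seq_len(ncol(x$features)))
  df$label <- x$labels
  df$source <- x$source
  df
}

pool_features <- function(a) {
  d <- ncol(a)
  if (d <= MAX_FEATURE_DIM) return(a)
  groups <- ceiling(seq_len(d) / (d / MAX_FEATURE_DIM))
  t(apply(a, 1, function(row) tapply(row, groups, mean)))
}

#' Extract feature vectors from a discriminator layer
#'
#' @param D a trained (or untrained) `discriminator_net`.
#' @param images an `n x d` matrix of flattened images, a list of image
#'   matrices, or a single image matrix.
#' @param layer_index which layer's output to use, `1 <= i <= K`;
#'   `NULL` selects the discriminator's default (penultimate) layer.
#'   `i = K` reproduces the final probability output.
#' @param labels optional per-image labels carried into the table.
#' @return A `feature_table` with one row per image (row order = input
#'   order). Outputs wider than 512 values are block-averaged down to at
#'   most 512 columns.
#' @export
extract_features <- function(D, images, layer_index = NULL, labels = NULL) {
  if (!inherits(D, "discriminator_net"))
    stop_ganb("D must be a discriminator_net")
  K <- length(D$layers)
  if (is.null(layer_index)) layer_index <- D$feature_layer_default
  check_number(layer_index, "layer_index", integer = TRUE)
  if (layer_index < 1 || layer_index > K)
    stop_ganb("layer_index must be in 1..", K, " (got ", layer_index, ")")
  x <- discriminator_input(images, D)
  fwd <- mlp_forward(D, x)
  a <- fwd$as[[layer_index + 1]]
  if (layer_index == K)
    a <- matrix(pmin(pmax(a, PROB_EPS), 1 - PROB_EPS), nrow(a), ncol(a))
  a <- pool_features(a)
  new_feature_table(a, labels, layer_index,
                    rep("real", nrow(a)))
}

#' Augment a feature table with class-conditional synthetic samples
#'
#' Draws `n_per_class` latent samples per class from that class's trained
#' generator, passes the generated images through the shared discriminator
#' feature map, and labels each row with its generating class. Rows are
#' flagged `source = "synthetic"` so downstream code can distinguish them
#' from real data.
#'
#' @param class_gans named list mapping class label to a `generator_net`
#'   trained on that class's images.
#' @param D the `discriminator_net` used for feature extraction.
#' @param n_per_class number of synthetic samples per class (0 gives an
#'   empty table).
#' @param layer_index feature layer, as in [extract_features()].
#' @param seed integer seed; per-class noise seeds are derived from it.
#' @return A `feature_table` with `length(class_gans) * n_per_class` rows.
#' @export
augment_with_synthetic <- function(class_gans, D, n_per_class,
                                   layer_index = NULL, seed = 1) {
  check_number(n_per_class, "n_per_class", 0, integer = TRUE)
  if (is.null(names(class_gans)) || any(names(class_gans) == ""))
    stop_ganb("class_gans must be a named list (class -> generator)")
  if (is.null(layer_index)) layer_index <- D$feature_layer_default
  tabs <- list()
  for (cls in names(class_gans)) {
    G <- class_gans[[cls]]
    if (!inherits(G, "generator_net"))
      stop_ganb("class_gans[['", cls, "']] is not a generator_net")
    if (n_per_class == 0) next
    z <- sample_noise(n_per_class, G$latent_dim,
                      seed = derive_seed(seed, paste0("augment-", cls)))
    imgs <- generator_forward(z, G)
    tab <- extract_features(D, imgs, layer_index,
                            labels = rep(cls, n_per_class))
    tab$source <- rep("synthetic", n_per_class)
    tabs[[cls]] <- tab
  }
  if (length(tabs) == 0) {
    d <- length(extract_features(D, matrix(0.5, 1, D$sizes[1]),
                                 layer_index)$features)
    return(new_feature_table(matrix(numeric(0), 0, d), character(0),
                             layer_index, character(0)))
  }
  out <- tabs[[1]]
  for (k in seq_along(tabs)[-1]) out <- combine_feature_tables(out, tabs[[k]])
  out
}

#' Row-bind two feature tables
#'
#' @param a,b `feature_table` objects with identical feature
#'   dimensionality and layer index.
#' @return The concatenated `feature_table`.
#' @export
combine_feature_tables <- function(a, b) {
  if (ncol(a$features) != ncol(b$features))
    stop_ganb("feature dimensionality mismatch: ", ncol(a$features),
              " vs ", ncol(b$features))
  if (a$layer_index != b$layer_index)
    stop_ganb("feature tables come from different layers")
  new_feature_table(rbind(a$features, b$features),
                    c(a$labels, b$labels), a$layer_index,
                    c(a$source, b$source))
}
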