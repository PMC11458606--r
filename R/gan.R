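#' Adversarial generator/discriminator pair
#'
#' A compact generative adversarial network for small grayscale images.
#' The generator maps standard-normal latent noise to images in `[0, 1]`
#' through fully connected layers with a sigmoid output; the discriminator
#' maps an image to a probability in `(0, 1)` that it is real. Training
#' alternates one discriminator step and one generator step per mini-batch
#' using the non-saturating generator loss
#' \deqn{L_G = -\mathbb{E}[\log D(G(z))]}
#' and the binary cross-entropy discriminator loss
#' \deqn{L_D = -\mathbb{E}[\log D(X)] - \mathbb{E}[\log(1 - D(G(z)))],}
#' both minimized by gradient descent (Adam by default, plain SGD
#' available).
#'
#' All computations run in log/logit space where saturation matters;
#' probabilities returned to the user are clamped to
#' `[1e-12, 1 - 1e-12]` so they are strictly inside `(0, 1)`.
#'
#' @name gan_core
NULL

PROB_EPS <- 1e-12

sigmoid <- function(z) 1 / (1 + exp(-z))
softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

act_forward <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         sigmoid = sigmoid(z),
         tanh = tanh(z),
         linear = z,
         stop_ganb("unknown activation ", act))
}

act_deriv <- function(z, a, act) {
  switch(act,
         relu = (z > 0) * 1,
         sigmoid = a * (1 - a),
         tanh = 1 - a^2,
         linear = matrix(1, nrow(z), ncol(z)))
}

# He-style initialization; biases start at zero.
mlp_new <- function(sizes, acts, seed = NULL) {
  stopifnot(length(sizes) == length(acts) + 1)
  build <- function() {
    lapply(seq_along(acts), function(k) {
      fan_in <- sizes[k]
      list(W = matrix(rnorm(fan_in * sizes[k + 1], 0,
                            sqrt(2 / fan_in)),
                      fan_in, sizes[k + 1]),
           b = rep(0, sizes[k + 1]),
           act = acts[k])
    })
  }
  layers <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  list(layers = layers, sizes = sizes)
}

# Forward pass keeping pre-activations and activations for backprop.
# X: m x sizes[1]. Returns list(out, zs, as); as[[1]] is the input.
mlp_forward <- function(net, X) {
  as <- list(X)
  zs <- list()
  a <- X
  for (k in seq_along(net$layers)) {
    ly <- net$layers[[k]]
    z <- sweep(a %*% ly$W, 2, ly$b, "+")
    a <- act_forward(z, ly$act)
    zs[[k]] <- z
    as[[k + 1]] <- a
  }
  list(out = a, zs = zs, as = as)
}

# Backward pass from dL/dz at the output layer (pre-activation gradient).
# Returns list(grads = per-layer list(W, b), dX = gradient wrt input).
mlp_backward <- function(net, fwd, delta_out) {
  K <- length(net$layers)
  grads <- vector("list", K)
  delta <- delta_out
  for (k in K:1) {
    ly <- net$layers[[k]]
    grads[[k]] <- list(W = crossprod(fwd$as[[k]], delta),
                      b = colSums(delta))
    delta <- if (k > 1) {
      (delta %*% t(ly$W)) * act_deriv(fwd$zs[[k - 1]], fwd$as[[k]],
                                      net$layers[[k - 1]]$act)
    } else {
      delta %*% t(ly$W)  # gradient wrt the network input
    }
  }
  list(grads = grads, dX = delta)
}

#' Sample a batch of latent noise vectors
#'
#' Draws i.i.d. standard-normal entries. With `seed = NULL` the current R
#' random stream is used (and advanced); a non-null seed gives a
#' reproducible batch without disturbing the caller's stream.
#'
#' @param m batch size.
#' @param latent_dim latent dimensionality.
#' @param seed optional integer seed.
#' @return An `m x latent_dim` numeric matrix.
#' @export
sample_noise <- function(m, latent_dim, seed = NULL) {
  check_number(m, "m", 1, integer = TRUE)
  check_number(latent_dim, "latent_dim", 1, integer = TRUE)
  draw <- function() matrix(rnorm(m * latent_dim), m, latent_dim)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Construct a generator network
#'
#' Fully connected: latent -> hidden (ReLU) -> pixels (sigmoid), so all
#' outputs are bounded to `[0, 1]`.
#'
#' @param latent_dim latent input dimensionality.
#' @param output_shape integer vector `c(rows, cols)` of generated images.
#' @param hidden hidden-layer width.
#' @param seed optional seed for weight initialization.
#' @return A `generator_net`.
#' @export
generator_new <- function(latent_dim = 32, output_shape = c(32, 32),
                          hidden = 128, seed = NULL) {
  out_dim <- prod(output_shape)
  net <- mlp_new(c(latent_dim, hidden, out_dim), c("relu", "sigmoid"),
                 seed = seed)
  structure(c(net, list(latent_dim = latent_dim,
                        output_shape = output_shape)),
            class = "generator_net")
}

#' Construct a discriminator network
#'
#' Fully connected: pixels -> hidden (tanh by default) -> 1 (sigmoid).
#' The hidden layer is the default feature-extraction layer (see
#' [extract_features()]).
#'
#' @param input_shape integer vector `c(rows, cols)` of input images, or a
#'   single flattened length.
#' @param hidden hidden-layer width.
#' @param activation hidden-layer nonlinearity (`"tanh"` default: bounded,
#'   saturating features suit the downstream Gaussian naive Bayes better
#'   than sparse ReLU codes; `"relu"` available).
#' @param seed optional seed for weight initialization.
#' @return A `discriminator_net` with `feature_layer_default` set to the
#'   penultimate layer.
#' @export
discriminator_new <- function(input_shape = c(32, 32), hidden = 64,
                              activation = "tanh", seed = NULL) {
  in_dim <- prod(input_shape)
  net <- mlp_new(c(in_dim, hidden, 1), c(activation, "sigmoid"),
                 seed = seed)
  structure(c(net, list(input_shape = input_shape,
                        n_layers = 2L,
                        feature_layer_default = 1L)),
            class = "discriminator_net")
}

#' Generate images from latent noise
#'
#' @param z an `m x latent_dim` noise matrix (see [sample_noise()]).
#' @param G a `generator_net`.
#' @return An `m x prod(output_shape)` matrix of flattened images in
#'   `[0, 1]`, with attribute `image_dim` giving the per-image shape.
#' @export
generator_forward <- function(z, G) {
  if (!inherits(G, "generator_net")) stop_ganb("G must be a generator_net")
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  if (ncol(z) != G$latent_dim)
    stop_ganb("noise has ", ncol(z), " columns; generator expects ",
              G$latent_dim)
  out <- mlp_forward(G, z)$out
  attr(out, "image_dim") <- G$output_shape
  out
}

#' Score images as real with the discriminator
#'
#' @param x an `n x d` matrix of flattened images (rows), a single image
#'   matrix of the discriminator's input shape, or a list of image
#'   matrices.
#' @param D a `discriminator_net`.
#' @return A numeric vector of probabilities strictly inside `(0, 1)`,
#'   one per image.
#' @export
discriminator_forward <- function(x, D) {
  x <- discriminator_input(x, D)
  p <- as.vector(mlp_forward(D, x)$out)
  pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
}

discriminator_input <- function(x, D) {
  if (!inherits(D, "discriminator_net"))
    stop_ganb("D must be a discriminator_net")
  in_dim <- D$sizes[1]
  if (is.list(x) && !is.data.frame(x))
    x <- t(vapply(x, as.vector, numeric(in_dim)))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (all(dim(x) == D$input_shape) && ncol(x) != in_dim)
    x <- matrix(as.vector(x), nrow = 1)
  if (ncol(x) != in_dim)
    stop_ganb("images have ", ncol(x), " pixels; discriminator expects ",
              in_dim)
  x
}

check_probs <- function(p, name) {
  if (!is.numeric(p) || length(p) == 0 || any(!is.finite(p)) ||
      any(p <= 0) || any(p >= 1))
    stop_ganb("'", name, "' must contain probabilities strictly in (0, 1)")
  p
}

#' Non-saturating generator loss
#'
#' `L_G = -mean(log d_fake)`: zero when the discriminator is fully fooled.
#'
#' @param d_fake discriminator outputs on generated images, in `(0, 1)`.
#' @return A scalar loss.
#' @export
#' @examples
#' generator_loss(c(0.5, 0.5))  # log 2
generator_loss <- function(d_fake) {
  check_probs(d_fake, "d_fake")
  -mean(log(d_fake))
}

#' Binary cross-entropy discriminator loss
#'
#' `L_D = -mean(log d_real) - mean(log(1 - d_fake))`: zero under perfect
#' discrimination.
#'
#' @param d_real discriminator outputs on real images, in `(0, 1)`.
#' @param d_fake discriminator outputs on generated images, in `(0, 1)`.
#' @return A scalar loss.
#' @export
discriminator_loss <- function(d_real, d_fake) {
  check_probs(d_real, "d_real")
  check_probs(d_fake, "d_fake")
  -mean(log(d_real)) - mean(log1p(-d_fake))
}

#' One gradient-descent step on a parameter set
#'
#' Applies `theta <- theta - eta * grad` to every array in a (possibly
#' nested) parameter list, or to a bare numeric vector. The `"adam"`
#' optimizer maintains first/second-moment state across calls.
#'
#' @param params numeric vector/matrix, or nested list of them (e.g. the
#'   `layers` of a network).
#' @param grads gradients with the same structure as `params`.
#' @param eta learning rate (> 0, or 0 for a no-op).
#' @param optimizer `"sgd"` or `"adam"`.
#' @param state optimizer state from a previous call (Adam only).
#' @return `list(params, state)` with the updated parameters.
#' @export
#' @examples
#' # quadratic (theta - 3)^2 at theta = 0: gradient -6, step 0.1 -> 0.6
#' gradient_step(0, -6, eta = 0.1)$params
gradient_step <- function(params, grads, eta, optimizer = c("sgd", "adam"),
                          state = NULL) {
  optimizer <- match.arg(optimizer)
  if (eta < 0) stop_ganb("eta must be >= 0")
  check_grads <- function(g, path) {
    if (is.list(g)) {
      for (nm in seq_along(g))
        check_grads(g[[nm]], paste0(path, "$",
                                    names(g)[nm] %||% as.character(nm)))
    } else if (any(!is.finite(g))) {
      stop_ganb("non-finite gradient in parameter ", path)
    }
  }
  check_grads(grads, "params")
  if (optimizer == "sgd") {
    step <- function(p, g) {
      if (is.list(p)) Map(step, p, g) else p - eta * g
    }
    return(list(params = step(params, grads), state = NULL))
  }
  # adam
  if (is.null(state)) state <- list(t = 0, m = zero_like(params),
                                    v = zero_like(params))
  state$t <- state$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      r <- Map(upd, p, g, m, v)
      return(list(p = lapply(r, `[[`, "p"), m = lapply(r, `[[`, "m"),
                  v = lapply(r, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^state$t)
    vh <- v / (1 - b2^state$t)
    list(p = p - eta * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(t = state$t, m = r$m, v = r$v))
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

layer_params <- function(net) lapply(net$layers, function(l)
  list(W = l$W, b = l$b))

set_layer_params <- function(net, params) {
  for (k in seq_along(net$layers)) {
    net$layers[[k]]$W <- params[[k]]$W
    net$layers[[k]]$b <- params[[k]]$b
  }
  net
}

#' Training configuration for the adversarial pair
#'
#' @param latent_dim latent dimensionality of the generator input.
#' @param hidden_g,hidden_d hidden-layer widths.
#' @param learning_rate gradient-descent learning rate (eta > 0).
#' @param batch_size mini-batch size m.
#' @param epochs full passes over the training set (>= 0).
#' @param optimizer `"adam"` (default) or `"sgd"` (plain descent).
#' @param d_activation hidden activation of the discriminator (`"tanh"`
#'   or `"relu"`).
#' @param weight_decay L2 penalty coefficient added to the discriminator
#'   weight gradients (biases exempt). 0 (default) disables.
#' @param d_optimizer,d_learning_rate optimizer and rate for the
#'   discriminator when they should differ from the generator's
#'   (two-time-scale training); `NULL` inherits `optimizer` /
#'   `learning_rate`.
#' @param seed master seed: initialization, shuffling and noise draws are
#'   all reproducible from it.
#' @return A validated `gan_config` list.
#' @export
gan_config <- function(latent_dim = 32, hidden_g = 128, hidden_d = 256,
                       learning_rate = 0.005, batch_size = 8, epochs = 100,
                       optimizer = c("adam", "sgd"), d_activation = "tanh",
                       weight_decay = 0, d_optimizer = "sgd",
                       d_learning_rate = 0.05, seed = 1) {
  check_number(latent_dim, "latent_dim", 1, integer = TRUE)
  check_number(hidden_g, "hidden_g", 1, integer = TRUE)
  check_number(hidden_d, "hidden_d", 1, integer = TRUE)
  if (learning_rate <= 0) stop_ganb("learning_rate must be > 0")
  check_number(batch_size, "batch_size", 1, integer = TRUE)
  check_number(epochs, "epochs", 0, integer = TRUE)
  optimizer <- match.arg(optimizer)
  check_number(seed, "seed", integer = TRUE)
  if (!d_activation %in% c("tanh", "relu"))
    stop_ganb("d_activation must be tanh or relu")
  if (!is.numeric(weight_decay) || weight_decay < 0)
    stop_ganb("weight_decay must be >= 0")
  if (is.null(d_optimizer)) d_optimizer <- optimizer
  else d_optimizer <- match.arg(d_optimizer, c("adam", "sgd"))
  if (is.null(d_learning_rate)) d_learning_rate <- learning_rate
  if (d_learning_rate <= 0) stop_ganb("d_learning_rate must be > 0")
  structure(list(latent_dim = latent_dim, hidden_g = hidden_g,
                 hidden_d = hidden_d, learning_rate = learning_rate,
                 batch_size = batch_size, epochs = epochs,
                 optimizer = optimizer, d_activation = d_activation,
                 weight_decay = weight_decay, d_optimizer = d_optimizer,
                 d_learning_rate = d_learning_rate, seed = seed),
            class = "gan_config")
}

# Stable per-sample output-layer gradients, computed from logits.
# d/dz[-log sigmoid(z)] = p - 1 ; d/dz[-log(1 - sigmoid(z))] = p.

d_step <- function(D, x_real, x_fake, eta, optimizer, state,
                   weight_decay = 0) {
  m_r <- nrow(x_real)
  m_f <- nrow(x_fake)
  fr <- mlp_forward(D, x_real)
  ff <- mlp_forward(D, x_fake)
  zr <- fr$zs[[length(D$layers)]]
  zf <- ff$zs[[length(D$layers)]]
  loss <- mean(softplus(-zr)) + mean(softplus(zf))
  br <- mlp_backward(D, fr, (sigmoid(zr) - 1) / m_r)
  bf <- mlp_backward(D, ff, sigmoid(zf) / m_f)
  grads <- Map(function(a, b, ly)
    list(W = a$W + b$W + weight_decay * ly$W, b = a$b + b$b),
    br$grads, bf$grads, D$layers)
  st <- gradient_step(layer_params(D), grads, eta, optimizer, state)
  list(D = set_layer_params(D, st$params), state = st$state, loss = loss)
}

g_step <- function(G, D, z, eta, optimizer, state) {
  fg <- mlp_forward(G, z)
  x_fake <- fg$out
  m <- nrow(z)
  fd <- mlp_forward(D, x_fake)
  zf <- fd$zs[[length(D$layers)]]
  loss <- mean(softplus(-zf))
  bd <- mlp_backward(D, fd, (sigmoid(zf) - 1) / m)
  # chain into the generator through its sigmoid output layer
  KG <- length(G$layers)
  delta_g_out <- bd$dX * act_deriv(fg$zs[[KG]], fg$as[[KG + 1]], "sigmoid")
  bg <- mlp_backward(G, fg, delta_g_out)
  st <- gradient_step(layer_params(G), bg$grads, eta, optimizer, state)
  list(G = set_layer_params(G, st$params), state = st$state, loss = loss)
}

#' Train the adversarial pair by alternating mini-batch descent
#'
#' Per iteration: sample a real mini-batch, sample latent noise, generate
#' fakes, take one discriminator descent step on the cross-entropy loss,
#' then one generator descent step on the non-saturating loss (through the
#' freshly updated discriminator). The whole run, including weight
#' initialization and shuffling, is reproducible from `config$seed` under
#' single-threaded execution.
#'
#' @param dataset training images: an `n x d` matrix of flattened images
#'   in `[0, 1]` (rows), or a list of equally sized image matrices.
#' @param config a [gan_config()].
#' @param image_shape per-image dimensions `c(rows, cols)`; inferred from
#'   list input or assumed square for matrix input.
#' @return A list with `generator`, `discriminator`, `history` (data frame
#'   of per-step losses with epoch indices) and `epoch_means`.
#' @export
train_gan <- function(dataset, config = gan_config(), image_shape = NULL) {
  if (!inherits(config, "gan_config")) stop_ganb("config must be a gan_config")
  if (is.list(dataset) && !is.data.frame(dataset)) {
    image_shape <- dim(dataset[[1]])
    dataset <- t(vapply(dataset, as.vector, numeric(prod(image_shape))))
  }
  check_matrix(dataset, "dataset")
  if (nrow(dataset) == 0) stop_ganb("dataset is empty")
  if (min(dataset) < 0 || max(dataset) > 1)
    stop_ganb("dataset pixel values must lie in [0, 1]")
  d <- ncol(dataset)
  if (is.null(image_shape)) {
    side <- sqrt(d)
    if (side != round(side))
      stop_ganb("cannot infer a square image shape from ", d,
                " pixels; pass image_shape")
    image_shape <- c(side, side)
  }
  n <- nrow(dataset)
  m <- min(config$batch_size, n)

  withr::with_seed(config$seed, {
    G <- generator_new(config$latent_dim, image_shape, config$hidden_g)
    D <- discriminator_new(image_shape, config$hidden_d,
                           activation = config$d_activation)
    state_d <- NULL
    state_g <- NULL
    steps_per_epoch <- ceiling(n / m)
    total <- config$epochs * steps_per_epoch
    loss_d <- numeric(total)
    loss_g <- numeric(total)
    epoch_of <- integer(total)
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(n)
      for (b in seq_len(steps_per_epoch)) {
        take <- idx[(((b - 1) * m) %% n + 1):min(((b - 1) * m) %% n + m, n)]
        x_real <- dataset[take, , drop = FALSE]
        z <- sample_noise(length(take), config$latent_dim)
        x_fake <- mlp_forward(G, z)$out
        step <- step + 1L
        ds <- d_step(D, x_real, x_fake,
                     config$d_learning_rate %||% config$learning_rate,
                     config$d_optimizer %||% config$optimizer, state_d,
                     weight_decay = config$weight_decay %||% 0)
        D <- ds$D
        state_d <- ds$state
        gs <- g_step(G, D, z, config$learning_rate, config$optimizer,
                     state_g)
        G <- gs$G
        state_g <- gs$state
        if (!is.finite(ds$loss) || !is.finite(gs$loss))
          stop_ganb("non-finite loss at training step ", step)
        loss_d[step] <- ds$loss
        loss_g[step] <- gs$loss
        epoch_of[step] <- ep
      }
    }
  })
  history <- data.frame(step = seq_len(total), epoch = epoch_of,
                        loss_d = loss_d, loss_g = loss_g)
  epoch_means <- if (total > 0) {
    data.frame(epoch = unique(epoch_of),
               loss_d = tapply(loss_d, epoch_of, mean),
               loss_g = tapply(loss_g, epoch_of, mean),
               row.names = NULL)
  } else {
    data.frame(epoch = integer(0), loss_d = numeric(0),
               loss_g = numeric(0))
  }
  structure(list(generator = G, discriminator = D, history = history,
                 epoch_means = epoch_means, config = config,
                 image_shape = image_shape),
            class = "gan_model")
}

#' @export
print.gan_model <- function(x, ...) {
  cat(sprintf(
    "gan_model: G latent %d -> %s image; D hidden %d; %d training steps\n",
    x$config$latent_dim, paste(x$image_shape, collapse = "x"),
    x$config$hidden_d, nrow(x$history)))
  if (nrow(x$history) > 0)
    cat(sprintf("final losses: L_D %.4f  L_G %.4f\n",
                utils::tail(x$history$loss_d, 1),
                utils::tail(x$history$loss_g, 1)))
  invisible(x)
}
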