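# Adversarial core: noise sampling, forward passes, loss closed forms,
# optimizer steps and the training loop.

tiny_cfg <- function(...) {
  defaults <- list(latent_dim = 4, hidden_g = 8, hidden_d = 6,
                   epochs = 2, batch_size = 4, seed = 11)
  args <- utils::modifyList(defaults, list(...))
  do.call(gan_config, args)
}

tiny_data <- function(n = 12, side = 6, seed = 3) {
  withr::with_seed(seed, matrix(runif(n * side * side), n, side * side))
}

test_that("noise batches are reproducible standard normals of the right
          shape", {
  z1 <- sample_noise(5, 3, seed = 42)
  z2 <- sample_noise(5, 3, seed = 42)
  expect_identical(z1, z2)
  expect_equal(dim(z1), c(5, 3))
  big <- sample_noise(10000, 1, seed = 7)
  expect_lt(abs(mean(big)), 0.05)       # 3 sigma CLT bound
  expect_true(var(big) > 0.94 && var(big) < 1.06)
})

test_that("generator outputs are bounded, deterministic and
          shape-checked", {
  G <- generator_new(4, c(6, 6), hidden = 8, seed = 1)
  z <- sample_noise(10, 4, seed = 2)
  x <- generator_forward(z, G)
  expect_true(all(x >= 0 & x <= 1))
  expect_equal(dim(x), c(10, 36))
  expect_identical(x, generator_forward(z, G))
  expect_error(generator_forward(matrix(0, 2, 5), G), "expects 4")
  # zero final weights with a sigmoid output give exactly 0.5
  G$layers[[2]]$W[] <- 0
  G$layers[[2]]$b[] <- 0
  expect_true(all(generator_forward(z, G) == 0.5))
})

test_that("discriminator outputs are probabilities with batching
          consistency", {
  D <- discriminator_new(c(6, 6), hidden = 8, seed = 4)
  x <- tiny_data(8)
  p <- discriminator_forward(x, D)
  expect_length(p, 8)
  expect_true(all(p > 0 & p < 1))
  # per-image evaluation equals the batch
  one_by_one <- vapply(seq_len(8), function(i)
    discriminator_forward(x[i, ], D), numeric(1))
  expect_equal(p, one_by_one)
  D0 <- D
  D0$layers[[2]]$W[] <- 0
  D0$layers[[2]]$b[] <- 0
  expect_true(all(discriminator_forward(x, D0) == 0.5))
  expect_error(discriminator_forward(matrix(0, 2, 10), D), "expects 36")
})

test_that("loss closed forms hold to 1e-9", {
  expect_equal(generator_loss(c(1 - 1e-12)), 0, tolerance = 1e-9)
  expect_equal(generator_loss(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(generator_loss(c(0.8, 0.3)), -(log(0.8) + log(0.3)) / 2,
               tolerance = 1e-12)
  expect_equal(round(generator_loss(c(0.8, 0.3)), 6), 0.713558)
  expect_equal(discriminator_loss(1 - 1e-12, 1e-12), 0, tolerance = 1e-9)
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2),
               tolerance = 1e-12)
  expect_equal(discriminator_loss(0.8, 0.3), -log(0.8) - log(0.7),
               tolerance = 1e-12)
  expect_error(generator_loss(c(0.5, 1)), "\\(0, 1\\)")
  expect_error(discriminator_loss(0, 0.5), "\\(0, 1\\)")
})

test_that("gradient steps descend, adam keeps state, and non-finite
          gradients are named", {
  expect_equal(gradient_step(1.5, 10, eta = 0)$params, 1.5)
  # quadratic (theta - 3)^2 at 0: gradient 2(0 - 3) = -6
  expect_equal(gradient_step(0, -6, eta = 0.1)$params, 0.6)
  params <- list(list(W = matrix(1, 2, 2), b = c(1, 1)))
  grads <- list(list(W = matrix(0.5, 2, 2), b = c(0.5, 0.5)))
  out <- gradient_step(params, grads, eta = 0.1)
  expect_equal(out$params[[1]]$W, matrix(0.95, 2, 2))
  a1 <- gradient_step(params, grads, eta = 0.1, optimizer = "adam")
  expect_equal(a1$state$t, 1)
  a2 <- gradient_step(a1$params, grads, eta = 0.1, optimizer = "adam",
                      state = a1$state)
  expect_equal(a2$state$t, 2)
  expect_true(all(a2$params[[1]]$W < a1$params[[1]]$W))
  bad <- grads
  bad[[1]]$W[1, 1] <- NaN
  expect_error(gradient_step(params, bad, 0.1), "W")
})

test_that("repeated discriminator steps on a fixed batch drive its loss
          down", {
  d_step <- ganbayes:::d_step
  D <- discriminator_new(c(6, 6), hidden = 8, seed = 21)
  x_real <- tiny_data(6, seed = 1)
  x_fake <- tiny_data(6, seed = 2) * 0.3
  losses <- numeric(40)
  state <- NULL
  for (i in seq_len(40)) {
    st <- d_step(D, x_real, x_fake, eta = 0.05, optimizer = "sgd",
                 state = state)
    D <- st$D
    state <- st$state
    losses[i] <- st$loss
  }
  expect_gte(mean(diff(losses) < 0), 0.95)
  expect_lt(losses[40], losses[1])
})

test_that("training runs reproducibly, records losses, and honors
          epochs = 0", {
  ds <- tiny_data(12)
  g0 <- train_gan(ds, tiny_cfg(epochs = 0), image_shape = c(6, 6))
  expect_equal(nrow(g0$history), 0)
  expect_s3_class(g0$generator, "generator_net")
  a <- train_gan(ds, tiny_cfg(epochs = 3), image_shape = c(6, 6))
  b <- train_gan(ds, tiny_cfg(epochs = 3), image_shape = c(6, 6))
  expect_identical(a$generator$layers, b$generator$layers)
  expect_identical(a$discriminator$layers, b$discriminator$layers)
  expect_identical(a$history, b$history)
  expect_true(all(is.finite(a$history$loss_d)))
  expect_equal(nrow(a$history), 3 * ceiling(12 / 4))
  expect_error(train_gan(matrix(2, 4, 36), tiny_cfg()), "\\[0, 1\\]")
})

test_that("gan archives round-trip through the flat-array format", {
  ds <- tiny_data(8)
  gan <- train_gan(ds, tiny_cfg(epochs = 2), image_shape = c(6, 6))
  dir <- withr::local_tempdir()
  gan_save(gan, dir)
  back <- gan_load(dir)
  z <- sample_noise(4, 4, seed = 3)
  expect_equal(generator_forward(z, back$generator),
               generator_forward(z, gan$generator), tolerance = 1e-12)
  expect_equal(discriminator_forward(ds, back$discriminator),
               discriminator_forward(ds, gan$discriminator),
               tolerance = 1e-12)
  expect_equal(nrow(back$history), nrow(gan$history))
})
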