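# Naive Bayes: priors, smoothing modes, posteriors against a brute-force
# oracle, the risk score, parameter recovery, and discretization.

toy_count_model <- function(smoothing_mode = "standard") {
  # vocabulary {a, b}; class H docs contain a=2, b=1; class L a=1, b=3
  x <- rbind(c(2, 1), c(1, 3))
  y <- c("H", "L")
  nb_fit(x, y, family = "multinomial", alpha = 1,
         smoothing_mode = smoothing_mode)
}

test_that("priors are class frequencies", {
  x <- matrix(rnorm(8), 4, 2)
  m <- nb_fit(x, c("H", "H", "H", "L"))
  expect_equal(m$priors, c(0.75, 0.25))
  m2 <- nb_fit(x, c("H", "L", "H", "L"))
  expect_equal(m2$priors, c(0.5, 0.5))
  expect_error(nb_fit(x, factor(c("H", "H", "H", "H"),
                                levels = c("H", "L"))), "0 samples")
  expect_error(nb_fit(x, c("H", "H", "L", "L"), alpha = -1), "alpha")
})

test_that("the two smoothing modes give the printed conditionals", {
  std <- toy_count_model("standard")
  expect_equal(std$cond_prob[1, 1], 3 / 5)  # (2+1)/(3+1*2)
  pap <- toy_count_model("paper")
  expect_equal(pap$cond_prob[1, 1], 3 / 4)  # (2+1)/(3+1)
  # standard conditionals normalize; paper-mode ones sum to
  # (sum count + V alpha)/(sum count + alpha)
  expect_equal(rowSums(std$cond_prob), c(1, 1))
  expect_equal(rowSums(pap$cond_prob),
               (rowSums(pap$counts) + pap$V * 1) / (rowSums(pap$counts) + 1))
})

test_that("posterior matches the hand-worked two-word example", {
  m <- toy_count_model()
  lp <- predict_log_posterior(m, c(2, 0))  # the document "a a"
  post <- exp(lp)
  expect_equal(sum(post), 1, tolerance = 1e-9)
  expect_equal(unname(post[1, "H"]), 0.18 / (0.18 + 0.5 * (1 / 3)^2),
               tolerance = 1e-9)
  expect_equal(round(unname(post[1, "H"]), 4), 0.7642)
  expect_equal(nb_classify(m, c(2, 0)), "H")
})

test_that("posteriors agree with plain-arithmetic enumeration on every
          small discrete input", {
  counts <- rbind(c(2, 1, 4), c(1, 3, 2))
  x <- rbind(c(2, 1, 0), c(1, 3, 1), c(0, 0, 1), c(1, 1, 1))
  y <- c("H", "H", "L", "L")
  # training matrix whose class sums equal `counts`
  xtr <- rbind(c(2, 1, 4), c(0, 0, 0), c(1, 3, 2), c(0, 0, 0))
  ytr <- c("H", "H", "L", "L")
  for (mode in c("standard", "paper")) {
    m <- nb_fit(xtr, ytr, family = "multinomial", alpha = 1,
                smoothing_mode = mode)
    # every enumerable input with entries 0..3 over 3 features
    grid <- expand.grid(0:3, 0:3, 0:3)
    for (i in seq_len(nrow(grid))) {
      xi <- as.numeric(grid[i, ])
      want <- nb_posterior_reference(xi, counts, m$priors, 1, mode)
      got <- exp(predict_log_posterior(m, xi))[1, ]
      expect_equal(unname(got), want, tolerance = 1e-9)
      expect_equal(nb_classify(m, xi),
                   m$classes[which.max(want + c(1e-15, 0))])
    }
  }
})

test_that("symmetric models are indifferent and ties break to the first
          class", {
  x <- rbind(c(1, 2), c(1, 2))
  m <- nb_fit(x, c("A", "B"), family = "multinomial")
  post <- exp(predict_log_posterior(m, c(3, 1)))
  expect_equal(unname(post[1, ]), c(0.5, 0.5))
  expect_equal(nb_classify(m, c(3, 1)), "A")
  # gaussian midpoint symmetry
  g <- nb_fit(rbind(matrix(0, 5, 1), matrix(1, 5, 1)) +
                rep(c(-0.01, 0.01), 5),
              rep(c("A", "B"), each = 5))
  expect_equal(unname(exp(predict_log_posterior(g, 0.5))[1, ]),
               c(0.5, 0.5), tolerance = 1e-6)
})

test_that("risk score is posterior odds, increasing, with an infinity
          sentinel", {
  m <- toy_count_model()
  # relabel classes to the risk convention
  m$classes <- c("high", "low")
  s <- risk_score(m, c(2, 0))
  expect_equal(s, 0.18 / (0.5 * (1 / 3)^2), tolerance = 1e-9)
  expect_equal(round(s, 2), 3.24)
  # strictly increasing in P(high)
  xs <- rbind(c(2, 0), c(1, 1), c(0, 2))
  p <- exp(predict_log_posterior(m, xs))[, "high"]
  sc <- risk_score(m, xs)
  expect_equal(order(sc), order(p))
  # sentinel when the low posterior underflows
  g <- nb_fit(rbind(matrix(0, 3, 1), matrix(1, 3, 1)) +
                c(-0.001, 0, 0.001),
              rep(c("high", "low"), each = 3))
  expect_equal(risk_score(g, -1e4), Inf)
  expect_error(risk_score(nb_fit(matrix(rnorm(4), 2, 2), c("A", "B")),
                          c(0, 0)), "high, low")
})

test_that("gaussian fit recovers known class parameters", {
  set.seed(2024)
  n <- 2000
  mu <- c(high = -1, low = 2)
  sd_ <- c(high = 0.5, low = 1.5)
  x <- matrix(c(rnorm(n, mu[1], sd_[1]), rnorm(n, mu[2], sd_[2])),
              ncol = 1)
  y <- rep(c("high", "low"), each = n)
  m <- nb_fit(x, y)
  for (k in 1:2) {
    se <- sd_[k] / sqrt(n)
    expect_lt(abs(m$mean[k, 1] - mu[k]), 3 * se)
    expect_lt(abs(m$var[k, 1] - sd_[k]^2) / sd_[k]^2, 0.10)
  }
})

test_that("gaussian posteriors agree with an established implementation", {
  skip_if_not_installed("e1071")
  set.seed(5)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- rep(c("high", "low"), each = 30)
  x[y == "high", ] <- x[y == "high", ] + 1
  m <- nb_fit(x, y)
  ref <- e1071::naiveBayes(x, factor(y, levels = c("high", "low")))
  got <- exp(predict_log_posterior(m, x))[, "high"]
  want <- predict(ref, x, type = "raw")[, "high"]
  expect_equal(unname(got), unname(want), tolerance = 1e-6)
})

test_that("discretize bins, clamps and respects monotone transforms", {
  d <- discretize(matrix(c(1, 2, 3, 4), ncol = 1), n_bins = 2,
                  strategy = "uniform")
  expect_equal(as.vector(d$codes), c(0, 0, 1, 1))
  # prediction-time clamping
  expect_equal(as.vector(apply_discretizer(d, matrix(c(-10, 10)))),
               c(0, 1))
  set.seed(3)
  v <- matrix(rnorm(40), ncol = 1)
  dq <- discretize(v, n_bins = 4, strategy = "quantile")
  dq2 <- discretize(exp(v), n_bins = 4, strategy = "quantile")
  expect_equal(dq$codes, dq2$codes)  # rank invariance
  expect_warning(discretize(matrix(1, 5, 1), strategy = "quantile"),
                 "constant")
  expect_error(nb_fit(matrix(c(0.5, 1.5), 2, 1), c("A", "B"),
                      family = "multinomial"), "integer")
})
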