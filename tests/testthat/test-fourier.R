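# Frequency-domain preprocessing: forward/inverse transforms, shifts,
# ideal filters, normalization and the composed chain.

test_that("forward transform matches the direct double-sum oracle", {
  expect_equal(Re(dft2(rbind(c(1, 2), c(3, 4)))$values),
               rbind(c(10, -2), c(-4, 0)), tolerance = 1e-12)
  set.seed(101)
  for (i in 1:8) {
    m <- sample(2:8, 1)
    n <- sample(2:8, 1)
    f <- matrix(rnorm(m * n), m, n)
    got <- dft2(f)$values
    want <- dft2_reference(f)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-9)
  }
})

test_that("constant image has a DC-only spectrum", {
  s <- dft2(matrix(3, 4, 6))
  expect_equal(Re(s$values[1, 1]), 3 * 4 * 6)
  expect_lt(max(abs(s$values[-1])), 1e-9)
})

test_that("energy is conserved (Parseval) and non-increasing under masks", {
  set.seed(7)
  f <- matrix(rnorm(64), 8, 8)
  s <- dft2(f)
  expect_equal(sum(f^2), sum(Mod(s$values)^2) / 64, tolerance = 1e-9)
  mask <- matrix(runif(64), 8, 8)  # entries in [0, 1]
  filtered <- apply_filter(fft_shift(s), mask)
  expect_lte(sum(Mod(filtered$values)^2), sum(Mod(s$values)^2) + 1e-9)
})

test_that("centering shift rolls DC to the center and round-trips", {
  s <- dft2(rbind(c(1, 2), c(3, 4)))
  sh <- fft_shift(s)
  expect_equal(Re(sh$values), rbind(c(0, -4), c(-2, 10)), tolerance = 1e-12)
  expect_error(fft_shift(sh), "already shifted")
  expect_error(ifft_shift(s), "not shifted")
  for (m in c(4, 5)) for (n in c(4, 7)) {
    f <- matrix(rnorm(m * n), m, n)
    sp <- dft2(f)
    back <- ifft_shift(fft_shift(sp))
    expect_equal(back$values, sp$values)
    # DC lands at the centered index
    expect_equal(fft_shift(sp)$values[floor(m / 2) + 1, floor(n / 2) + 1],
                 sp$values[1, 1])
  }
})

test_that("ideal filters follow the centered-radius rule", {
  lp <- build_filter("low", d2 = 1, m = 5, n = 5)
  expect_equal(sum(lp$mask), 5)  # center + 4-neighborhood
  expect_equal(lp$mask[3, 3], 1)
  expect_true(all(build_filter("band", 0, Inf, 6, 6)$mask == 1))
  expect_true(all(build_filter("allpass", m = 4, n = 4)$mask == 1))
  # complement: low(D) + high(D) covers everything, double counts r == D
  lo <- build_filter("low", d2 = 3, m = 9, n = 9)$mask
  hi <- build_filter("high", d1 = 3, m = 9, n = 9)$mask
  expect_true(all(lo + hi >= 1))
  expect_true(all((lo + hi == 2) == (lo == 1 & hi == 1)))
  expect_error(build_filter("band", d1 = 5, d2 = 2, m = 4, n = 4),
               "d1 <= d2")
})

test_that("gaussian roll-off variant stays within [0, 1]", {
  g <- build_filter("band", 2, 8, 16, 16, rolloff = "gaussian")
  expect_true(all(g$mask >= 0 & g$mask <= 1))
  expect_false(all(g$mask %in% c(0, 1)))
})

test_that("filter application is elementwise with shape/stage guards", {
  set.seed(11)
  f <- matrix(rnorm(36), 6, 6)
  sh <- fft_shift(dft2(f))
  expect_equal(apply_filter(sh, build_filter("allpass", m = 6, n = 6))$values,
               sh$values)
  expect_true(all(apply_filter(sh, matrix(0, 6, 6))$values == 0))
  expect_error(apply_filter(dft2(f), matrix(1, 6, 6)), "fft_shift")
  expect_error(apply_filter(sh, matrix(1, 3, 3)), "does not match")
  # keeping only DC reconstructs the image mean everywhere
  dc_only <- matrix(0, 6, 6)
  dc_only[4, 4] <- 1
  rec <- idft2(ifft_shift(apply_filter(sh, dc_only)))
  expect_equal(rec, matrix(mean(f), 6, 6), tolerance = 1e-9)
})

test_that("inverse transform round-trips, is linear, and guards stage", {
  set.seed(13)
  f <- matrix(rnorm(64), 8, 8)
  expect_equal(idft2(dft2(f)), f, tolerance = 1e-9)
  expect_equal(idft2(dft2(rbind(c(1, 2), c(3, 4)))),
               rbind(c(1, 2), c(3, 4)), tolerance = 1e-12)
  g <- matrix(rnorm(64), 8, 8)
  Fa <- dft2(f)$values
  Fb <- dft2(g)$values
  lin <- ganbayes:::new_spectrum(2 * Fa + 3 * Fb, FALSE)
  expect_equal(idft2(lin), 2 * f + 3 * g, tolerance = 1e-9)
  expect_error(idft2(fft_shift(dft2(f))), "unshifted")
})

test_that("intensity normalization maps to [0, 255] with the degenerate
          convention", {
  expect_equal(normalize_intensity(rbind(c(2, 4), c(6, 10))),
               rbind(c(0, 63.75), c(127.5, 255)))
  expect_warning(out <- normalize_intensity(matrix(5, 3, 3)), "constant")
  expect_true(all(out == 0))
  set.seed(17)
  r <- normalize_intensity(matrix(rnorm(30), 5, 6))
  expect_equal(range(r), c(0, 255))
})

test_that("preprocess_image equals the manual stage composition", {
  set.seed(19)
  img <- matrix(runif(256), 16, 16)
  filt <- build_filter("band", 2, 4, 16, 16)
  manual <- normalize_intensity(
    idft2(ifft_shift(apply_filter(fft_shift(dft2(img)), filt))))
  expect_identical(preprocess_image(img, filt), manual)
  # all-pass chain is just normalization
  expect_equal(preprocess_image(img, list(kind = "allpass")),
               normalize_intensity(img), tolerance = 1e-9)
})

test_that("band-pass filtering reduces out-of-band spectral energy on a
          speckled phantom", {
  ph <- tiny_phantom(stenosis = 0.4, noise_sd = 0.08, seed = 5)
  d2 <- 8
  hf_energy <- function(img) {
    sp <- fft_shift(dft2(img))
    outside <- build_filter("high", d1 = d2 + 1e-9, m = 32, n = 32)$mask
    sum(Mod(sp$values * outside))
  }
  out <- preprocess_image(ph$image, list(kind = "band", d1 = 2, d2 = d2))
  # compare on a common intensity scale
  expect_lt(hf_energy(out / max(out)),
            hf_energy(ph$image / max(ph$image)))
})
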