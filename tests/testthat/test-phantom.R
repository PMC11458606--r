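# Synthetic phantom generator: risk rule, geometry, cohorts, export.

test_that("high-risk rule fires on each criterion and only then", {
  # substantial stenosis, boundary inclusive
  expect_equal(label_risk(base_risk_features(stenosis_fraction = 0.70)),
               "high")
  expect_equal(label_risk(base_risk_features(stenosis_fraction = 0.699)),
               "low")
  expect_equal(label_risk(base_risk_features()), "low")
  # multivessel disease
  expect_equal(label_risk(base_risk_features(n_vessels_diseased = 2)),
               "high")
  # vulnerable plaque: remodeling together with spotty calcification
  expect_equal(label_risk(base_risk_features(positive_remodeling = TRUE,
                                             n_calc_spots = 2)), "high")
  expect_equal(label_risk(base_risk_features(positive_remodeling = TRUE)),
               "low")
  expect_equal(label_risk(base_risk_features(n_calc_spots = 2)), "low")
  # event history
  expect_equal(label_risk(base_risk_features(prior_mi = TRUE)), "high")
})

test_that("risk rule validates inputs and names missing fields", {
  f <- base_risk_features()
  f$n_calc_spots <- NULL
  expect_error(label_risk(f), "n_calc_spots")
  expect_error(label_risk(base_risk_features(stenosis_fraction = 1.2)),
               "stenosis_fraction")
})

test_that("risk rule is monotone in stenosis", {
  grid <- seq(0, 1, by = 0.05)
  labs <- vapply(grid, function(s)
    label_risk(base_risk_features(stenosis_fraction = s)), character(1))
  # once high, never back to low as stenosis rises
  expect_true(all(diff(labs == "high") >= 0))
})

test_that("phantom generation is deterministic and hits the requested
          stenosis", {
  a <- tiny_phantom(stenosis = 0.5, seed = 9, noise_sd = 0.03)
  b <- tiny_phantom(stenosis = 0.5, seed = 9, noise_sd = 0.03)
  expect_identical(a$image, b$image)
  expect_identical(a$masks, b$masks)
  for (sf in c(0.1, 0.3, 0.5, 0.8, 1)) {
    ph <- tiny_phantom(stenosis = sf, seed = 21)
    expect_lt(abs(ph$features$stenosis_fraction - sf), 0.05)
  }
  expect_true(all(tiny_phantom()$masks %in% 0:4))
})

test_that("noiseless phantoms take only the configured tissue intensities", {
  ph <- tiny_phantom(stenosis = 0.4, noise_sd = 0)
  expect_true(all(ph$image %in% c(0.10, 0.55, 0.85, 0.40, 0.95)))
  # mask <-> intensity correspondence
  expect_true(all(ph$image[ph$masks == 2] == 0.85))
  expect_true(all(ph$image[ph$masks == 3] == 0.40))
})

test_that("mask areas are invariant to pixel noise", {
  spec0 <- phantom_spec(stenosis_fraction = 0.6, noise_sd = 0, seed = 4)
  spec1 <- phantom_spec(stenosis_fraction = 0.6, noise_sd = 0.1, seed = 4)
  expect_identical(table(generate_phantom(spec0)$masks),
                   table(generate_phantom(spec1)$masks))
})

test_that("calcification spots are drawn inside plaque and counted", {
  ph <- generate_phantom(phantom_spec(stenosis_fraction = 0.5,
                                      n_calc_spots = 2, noise_sd = 0,
                                      seed = 8))
  expect_gt(sum(ph$masks == 4), 0)
  expect_error(generate_phantom(phantom_spec(stenosis_fraction = 0,
                                             n_calc_spots = 1, seed = 1)),
               "plaque")
})

test_that("geometrically unattainable stenosis errors", {
  expect_error(
    generate_phantom(phantom_spec(image_size = 16, vessel_radius = 4,
                                  stenosis_fraction = 0.5, seed = 1)),
    "unattainable")
})

test_that("cohorts realize the class mix exactly and deterministically", {
  co <- generate_cohort(10, 0.5, phantom_spec(), seed = 31)
  labs <- vapply(co, function(x) x$label, character(1))
  expect_equal(sum(labs == "high"), 5)
  co2 <- generate_cohort(10, 0.5, phantom_spec(), seed = 31)
  expect_identical(attr(co, "manifest"), attr(co2, "manifest"))
  one <- generate_cohort(1, 0, phantom_spec(), seed = 2)
  expect_equal(one[[1]]$label, "low")
  all_high <- generate_cohort(4, 1, phantom_spec(), seed = 3)
  expect_true(all(vapply(all_high, function(x) x$label, "") == "high"))
})

test_that("export writes a complete, lossless, hash-stamped archive", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(3, 1 / 3, phantom_spec(image_size = 24,
                                               vessel_radius = 9),
                        seed = 7)
  man <- export_cohort(co, dir)
  expect_equal(man$n, 3)
  feats <- read.csv(file.path(dir, "features.csv"))
  expect_equal(nrow(feats), 3)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # 16-bit round-trip within one quantization step
  im <- tiff::readTIFF(file.path(dir, "sample_001_image.tiff"))
  expect_lt(max(abs(im - co[[1]]$image)), 1 / 65535 + 1e-9)
  # flat mask array round-trips exactly
  msk <- as.matrix(read.csv(file.path(dir, "sample_001_mask.csv"),
                            header = FALSE))
  dimnames(msk) <- NULL
  expect_equal(msk, co[[1]]$masks)
  # spec hash responds to any spec change
  co_b <- generate_cohort(3, 1 / 3, phantom_spec(image_size = 24,
                                                 vessel_radius = 9,
                                                 noise_sd = 0.05),
                          seed = 7)
  man_b <- export_cohort(co_b, withr::local_tempdir())
  expect_false(identical(man$spec_hash, man_b$spec_hash))
})
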