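#' Synthetic vessel cross-section phantoms
#'
#' The phantom module generates seeded synthetic coronary cross-section
#' images with pixel-accurate ground-truth masks, standing in for real
#' contrast-enhanced angiography data. Each phantom shows a bright annular
#' vessel wall around a contrast-filled lumen; an eccentric plaque crescent
#' occludes a configurable fraction of the lumen area, optionally carrying
#' bright calcification speckles, with Gaussian pixel noise on top.
#'
#' Mask labels are integers: 0 background, 1 wall, 2 patent lumen,
#' 3 plaque, 4 calcification.
#'
#' @name phantom
NULL

# mask label codes
MASK_BACKGROUND <- 0L
MASK_WALL <- 1L
MASK_LUMEN <- 2L
MASK_PLAQUE <- 3L
MASK_CALC <- 4L

#' Specify a synthetic vessel phantom
#'
#' @param image_size pixels per side of the square image (>= 16).
#' @param stenosis_fraction fraction of the nominal lumen area occluded by
#'   plaque, in `[0, 1]`. A fraction of 0.70 or more marks substantial
#'   stenosis in the high-risk rule (see [label_risk()]).
#' @param n_vessels_diseased number of diseased vessels in the (tabular)
#'   patient record; two or more is a high-risk criterion. Only one vessel
#'   is ever rendered.
#' @param positive_remodeling logical; outward bulging of the wall around
#'   the plaque. Rendered as a local widening of the outer wall radius.
#' @param n_calc_spots number of spotty calcifications drawn inside the
#'   plaque crescent.
#' @param prior_mi logical; history of myocardial infarction or comparable
#'   major coronary event.
#' @param noise_sd standard deviation of additive Gaussian pixel noise, in
#'   intensity units of the `[0, 1]` image scale.
#' @param vessel_radius outer wall radius in pixels; must be smaller than
#'   `image_size / 2`.
#' @param intensities named numeric vector of tissue intensities on the
#'   `[0, 1]` scale with entries `background`, `wall`, `lumen`, `plaque`,
#'   `calcification`.
#' @param seed integer seed; the phantom is a deterministic function of its
#'   spec including the seed.
#'
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(stenosis_fraction = 0.8, seed = 7)
#' ph <- generate_phantom(spec)
#' ph$label
phantom_spec <- function(image_size = 32,
                         stenosis_fraction = 0,
                         n_vessels_diseased = 1,
                         positive_remodeling = FALSE,
                         n_calc_spots = 0,
                         prior_mi = FALSE,
                         noise_sd = 0.02,
                         vessel_radius = NULL,
                         intensities = c(background = 0.10, wall = 0.55,
                                         lumen = 0.85, plaque = 0.40,
                                         calcification = 0.95),
                         seed = 1) {
  check_number(image_size, "image_size", lower = 16, integer = TRUE)
  check_number(stenosis_fraction, "stenosis_fraction", 0, 1)
  check_number(n_vessels_diseased, "n_vessels_diseased", 0, integer = TRUE)
  check_flag(positive_remodeling, "positive_remodeling")
  check_number(n_calc_spots, "n_calc_spots", 0, integer = TRUE)
  check_flag(prior_mi, "prior_mi")
  check_number(noise_sd, "noise_sd", 0)
  if (is.null(vessel_radius)) vessel_radius <- floor(0.38 * image_size)
  check_number(vessel_radius, "vessel_radius", 2, image_size / 2 - 1e-9)
  need <- c("background", "wall", "lumen", "plaque", "calcification")
  if (!all(need %in% names(intensities)))
    stop_ganb("intensities must name: ", paste(need, collapse = ", "))
  check_number(seed, "seed", integer = TRUE)
  structure(list(image_size = as.integer(image_size),
                 stenosis_fraction = stenosis_fraction,
                 n_vessels_diseased = as.integer(n_vessels_diseased),
                 positive_remodeling = positive_remodeling,
                 n_calc_spots = as.integer(n_calc_spots),
                 prior_mi = prior_mi,
                 noise_sd = noise_sd,
                 vessel_radius = vessel_radius,
                 intensities = intensities[need],
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Deterministic high-risk labelling rule
#'
#' A patient-level record is labelled `"high"` when any of the four
#' high-risk criteria fires: substantial stenosis (lumen narrowing of 70%
#' or more, boundary inclusive), multivessel disease (two or more diseased
#' coronary arteries), vulnerable-plaque morphology (positive remodeling
#' together with at least one spotty calcification), or a history of a
#' major coronary event. Otherwise the label is `"low"`.
#'
#' @param features a `phantom_spec`, or any list carrying the fields
#'   `stenosis_fraction`, `n_vessels_diseased`, `positive_remodeling`,
#'   `n_calc_spots` and `prior_mi`.
#' @return `"high"` or `"low"`.
#' @export
#' @examples
#' label_risk(list(stenosis_fraction = 0.7, n_vessels_diseased = 1,
#'                 positive_remodeling = FALSE, n_calc_spots = 0,
#'                 prior_mi = FALSE))
label_risk <- function(features) {
  need <- c("stenosis_fraction", "n_vessels_diseased",
            "positive_remodeling", "n_calc_spots", "prior_mi")
  for (f in need) {
    if (is.null(features[[f]]) || length(features[[f]]) != 1 ||
        is.na(features[[f]]))
      stop_ganb(sprintf("missing risk feature '%s'", f))
  }
  check_number(features$stenosis_fraction, "stenosis_fraction", 0, 1)
  high <- features$stenosis_fraction >= 0.70 ||
    features$n_vessels_diseased >= 2 ||
    (isTRUE(features$positive_remodeling) && features$n_calc_spots >= 1) ||
    isTRUE(features$prior_mi)
  if (high) "high" else "low"
}

#' Admissible risk labels, high first
#' @return `c("high", "low")`.
#' @export
risk_levels <- function() c("high", "low")

# Analytic area fraction of the circular segment {x : x >= d} of a disk of
# radius r, as a fraction of the disk area.
segment_fraction <- function(d, r) {
  d <- max(-r, min(r, d))
  (r^2 * acos(d / r) - d * sqrt(max(r^2 - d^2, 0))) / (pi * r^2)
}

# Chord offset whose segment occludes `frac` of the lumen disk, solved by
# bisection to within 1e-3 on the fraction.
solve_chord_offset <- function(frac, r) {
  if (frac <= 0) return(r)
  if (frac >= 1) return(-r)
  lo <- -r
  hi <- r
  mid <- 0
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (abs(segment_fraction(mid, r) - frac) < 1e-6) break
    if (segment_fraction(mid, r) > frac) lo <- mid else hi <- mid
  }
  mid
}

#' Generate one synthetic vessel phantom
#'
#' Renders the annular wall, patent lumen, eccentric plaque crescent and
#' calcification speckles described by a [phantom_spec()], adds clipped
#' Gaussian noise, measures the realized stenosis from the masks, and
#' labels the sample with [label_risk()]. The output is a deterministic
#' function of the spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_sample`: a list with `image`
#'   (numeric matrix in `[0, 1]`), `masks` (integer matrix, labels 0-4),
#'   `features` (realized patient-level quantities; `stenosis_fraction` is
#'   re-measured from the masks), `label` (`"high"`/`"low"`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_ganb("spec must be a phantom_spec")
  s <- spec$image_size
  R <- spec$vessel_radius
  wall_t <- max(2, round(0.25 * R))
  r_lumen <- R - wall_t
  if (r_lumen < 3 && spec$stenosis_fraction > 0 && spec$stenosis_fraction < 1)
    stop_ganb("stenosis geometrically unattainable: lumen radius ",
              r_lumen, " px is too coarse for a partial occlusion")
  withr::with_seed(spec$seed, {
    ctr <- (s - 1) / 2
    xs <- matrix(rep(0:(s - 1), each = s), s, s) - ctr   # column coord
    ys <- matrix(rep(0:(s - 1), times = s), s, s) - ctr  # row coord
    r <- sqrt(xs^2 + ys^2)
    theta <- atan2(ys, xs)
    theta_p <- runif(1, -pi, pi)  # plaque direction

    r_out <- matrix(R, s, s)
    if (spec$positive_remodeling) {
      dtheta <- atan2(sin(theta - theta_p), cos(theta - theta_p))
      r_out <- R * (1 + 0.25 * exp(-dtheta^2 / (2 * 0.5^2)))
    }

    masks <- matrix(MASK_BACKGROUND, s, s)
    masks[r <= r_out] <- MASK_WALL
    in_lumen <- r <= r_lumen
    masks[in_lumen] <- MASK_LUMEN

    if (spec$stenosis_fraction > 0) {
      d <- solve_chord_offset(spec$stenosis_fraction, r_lumen)
      proj <- xs * cos(theta_p) + ys * sin(theta_p)
      masks[in_lumen & proj >= d] <- MASK_PLAQUE
    }

    if (spec$n_calc_spots > 0) {
      plaque_idx <- which(masks == MASK_PLAQUE)
      if (length(plaque_idx) == 0)
        stop_ganb("calcification spots require a plaque region; ",
                  "increase stenosis_fraction")
      centers <- sample(plaque_idx,
                        min(spec$n_calc_spots, length(plaque_idx)))
      for (cc in centers) {
        ci <- (cc - 1) %% s
        cj <- (cc - 1) %/% s
        spot <- sqrt((ys - (ci - ctr))^2 + (xs - (cj - ctr))^2) <= 1
        masks[spot & masks == MASK_PLAQUE] <- MASK_CALC
      }
    }

    iv <- spec$intensities
    lut <- c(iv[["background"]], iv[["wall"]], iv[["lumen"]],
             iv[["plaque"]], iv[["calcification"]])
    image <- matrix(lut[masks + 1L], s, s)
    if (spec$noise_sd > 0)
      image <- image + matrix(rnorm(s * s, 0, spec$noise_sd), s, s)
    image <- pmin(pmax(image, 0), 1)
  })

  n_patent <- sum(masks == MASK_LUMEN)
  n_occl <- sum(masks == MASK_PLAQUE | masks == MASK_CALC)
  nominal <- n_patent + n_occl
  measured <- if (nominal > 0) n_occl / nominal else 0
  features <- list(stenosis_fraction = measured,
                   n_vessels_diseased = spec$n_vessels_diseased,
                   positive_remodeling = spec$positive_remodeling,
                   n_calc_spots = spec$n_calc_spots,
                   prior_mi = spec$prior_mi)
  structure(list(image = image, masks = masks, features = features,
                 label = label_risk(features), spec = spec),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf(
    "phantom_sample %dx%d  stenosis %.3f  label %s\n",
    nrow(x$image), ncol(x$image), x$features$stenosis_fraction, x$label))
  invisible(x)
}

#' Generate a labelled phantom cohort with an exact class mix
#'
#' Draws `round(n * class_mix)` high-risk and the remaining low-risk
#' samples. High-risk specs always fire the substantial-stenosis criterion
#' (stenosis drawn uniformly in `[0.72, 0.92]`, clear of the 0.70 decision
#' boundary so that pixel-level re-measurement cannot flip the label); a
#' subset additionally carries positive remodeling with spotty
#' calcification. Low-risk specs draw stenosis in `[0.05, 0.45]` with all
#' other criteria off. Per-sample seeds are derived deterministically from
#' the master seed.
#'
#' @param n cohort size (>= 1).
#' @param class_mix fraction of high-risk samples in `[0, 1]`.
#' @param base_spec a [phantom_spec()] supplying image size, radius, noise
#'   and intensities for every sample.
#' @param seed master seed.
#' @return A list of `phantom_sample` objects with attribute `manifest`, a
#'   data frame of per-sample features, labels and seeds.
#' @export
generate_cohort <- function(n, class_mix = 0.5, base_spec = phantom_spec(),
                            seed = 1) {
  check_number(n, "n", 1, integer = TRUE)
  check_number(class_mix, "class_mix", 0, 1)
  n_high <- round(n * class_mix)
  want <- c(rep("high", n_high), rep("low", n - n_high))
  draws <- withr::with_seed(derive_seed(seed, "cohort"), {
    list(seeds = sample.int(.Machine$integer.max - 1, n),
         sten_high = runif(n, 0.72, 0.92),
         sten_low = runif(n, 0.05, 0.45),
         remod = runif(n) < 0.3,
         spots = sample(1:2, n, replace = TRUE))
  })
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    hi <- want[i] == "high"
    sp <- base_spec
    sp$seed <- draws$seeds[i]
    sp$stenosis_fraction <- if (hi) draws$sten_high[i] else draws$sten_low[i]
    sp$positive_remodeling <- hi && draws$remod[i]
    sp$n_calc_spots <- if (hi && draws$remod[i]) draws$spots[i] else 0L
    sp$n_vessels_diseased <- 1L
    sp$prior_mi <- FALSE
    samp <- generate_phantom(sp)
    # the rule must fire as intended; re-draw the seed if pixelation flipped
    # the measured stenosis across the boundary (kept deterministic)
    tries <- 0
    while (samp$label != want[i] && tries < 20) {
      tries <- tries + 1
      sp$seed <- derive_seed(sp$seed, paste0("retry", tries))
      samp <- generate_phantom(sp)
    }
    if (samp$label != want[i])
      stop_ganb("could not realize intended label for sample ", i)
    samples[[i]] <- samp
  }
  manifest <- data.frame(
    id = seq_len(n),
    seed = vapply(samples, function(x) x$spec$seed, integer(1)),
    stenosis_fraction = vapply(samples, function(x)
      x$features$stenosis_fraction, numeric(1)),
    n_vessels_diseased = vapply(samples, function(x)
      x$features$n_vessels_diseased, integer(1)),
    positive_remodeling = vapply(samples, function(x)
      x$features$positive_remodeling, logical(1)),
    n_calc_spots = vapply(samples, function(x)
      x$features$n_calc_spots, integer(1)),
    prior_mi = vapply(samples, function(x)
      x$features$prior_mi, logical(1)),
    label = vapply(samples, function(x) x$label, character(1)))
  attr(samples, "manifest") <- manifest
  samples
}

#' Export a phantom cohort to disk
#'
#' Writes, per sample, a lossless 16-bit grayscale TIFF and an 8-bit PNG
#' preview of the image, the mask as an 8-bit PNG (label codes stored as
#' raw gray levels 0-4) and as a flat CSV array, one features/label CSV
#' row per sample, and a JSON manifest listing files, seeds and a spec
#' hash.
#'
#' @param samples list of `phantom_sample` objects (e.g. from
#'   [generate_cohort()]).
#' @param directory output directory, created if missing.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
export_cohort <- function(samples, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop_ganb("cannot create directory ", directory)
  n <- length(samples)
  files <- vector("list", n)
  for (i in seq_len(n)) {
    stem <- sprintf("sample_%03d", i)
    im <- samples[[i]]$image
    msk <- samples[[i]]$masks
    f_tif <- file.path(directory, paste0(stem, "_image.tiff"))
    f_png <- file.path(directory, paste0(stem, "_image.png"))
    f_msk <- file.path(directory, paste0(stem, "_mask.png"))
    f_arr <- file.path(directory, paste0(stem, "_mask.csv"))
    ok <- tryCatch({
      tiff::writeTIFF(im, f_tif, bits.per.sample = 16L)
      png::writePNG(im, f_png)
      png::writePNG(msk / 255, f_msk)
      utils::write.table(msk, f_arr, sep = ",", row.names = FALSE,
                         col.names = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop_ganb("failed writing sample ", i, " under ", directory, ": ",
                conditionMessage(ok))
    files[[i]] <- list(image_tiff = basename(f_tif),
                       image_png = basename(f_png),
                       mask_png = basename(f_msk),
                       mask_csv = basename(f_arr))
  }
  manifest_df <- attr(samples, "manifest")
  if (is.null(manifest_df)) {
    manifest_df <- data.frame(
      id = seq_len(n),
      seed = vapply(samples, function(x) x$spec$seed, integer(1)),
      stenosis_fraction = vapply(samples, function(x)
        x$features$stenosis_fraction, numeric(1)),
      label = vapply(samples, function(x) x$label, character(1)))
  }
  f_feat <- file.path(directory, "features.csv")
  utils::write.csv(manifest_df, f_feat, row.names = FALSE)
  spec_hash <- rlang::hash(lapply(samples, function(x)
    unclass(x$spec)))
  manifest <- list(n = n,
                   spec_hash = spec_hash,
                   seeds = vapply(samples, function(x) x$spec$seed,
                                  integer(1)),
                   features_csv = basename(f_feat),
                   files = files)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
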