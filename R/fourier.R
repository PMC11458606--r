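#' Frequency-domain preprocessing
#'
#' Implements the preprocessing chain applied to angiography-like images
#' before adversarial training: forward 2-D discrete Fourier transform,
#' centering shift, ideal radial frequency filtering, inverse transform,
#' and min-max intensity normalization to `[0, 255]`.
#'
#' The forward transform follows the standard unnormalized convention
#' \deqn{F(u,v) = \sum_{x=0}^{M-1}\sum_{y=0}^{N-1} f(x,y)\,
#'   e^{-j 2\pi (ux/M + vy/N)}}
#' with the inverse carrying the \eqn{1/(MN)} factor.
#'
#' @name fourier_preproc
NULL

new_spectrum <- function(values, shifted) {
  structure(list(values = values, shifted = shifted,
                 M = nrow(values), N = ncol(values)),
            class = "spectrum_image")
}

#' @export
print.spectrum_image <- function(x, ...) {
  cat(sprintf("spectrum_image %dx%d (%s)\n", x$M, x$N,
              if (x$shifted) "shifted" else "unshifted"))
  invisible(x)
}

#' Forward 2-D discrete Fourier transform
#'
#' @param img numeric matrix of pixel values (all finite, at least 2x2).
#' @return A `spectrum_image` holding the complex spectrum, unshifted
#'   (zero-frequency term at index `[1, 1]`).
#' @export
#' @examples
#' dft2(rbind(c(1, 2), c(3, 4)))$values  # [[10,-2],[-4,0]]
dft2 <- function(img) {
  check_matrix(img, "img")
  if (nrow(img) < 2 || ncol(img) < 2)
    stop_ganb("image must be at least 2x2")
  new_spectrum(stats::fft(img), shifted = FALSE)
}

shift_indices <- function(n, inverse = FALSE) {
  h <- if (inverse) floor(n / 2) else ceiling(n / 2)
  c((h + 1):n, 1:h)
}

#' Move the zero-frequency term to the center
#'
#' Cyclically rolls the spectrum so the DC coefficient sits at (0-based)
#' index `(floor(M/2), floor(N/2))`. Applying it to an already-shifted
#' spectrum is an error; use [ifft_shift()] to undo.
#'
#' @param spec an unshifted `spectrum_image`.
#' @return The shifted `spectrum_image`.
#' @export
fft_shift <- function(spec) {
  if (!inherits(spec, "spectrum_image")) stop_ganb("not a spectrum_image")
  if (spec$shifted)
    stop_ganb("spectrum is already shifted; use ifft_shift() to undo")
  v <- spec$values[shift_indices(spec$M), shift_indices(spec$N)]
  new_spectrum(v, shifted = TRUE)
}

#' Undo the centering shift
#' @param spec a shifted `spectrum_image`.
#' @return The unshifted `spectrum_image`.
#' @export
ifft_shift <- function(spec) {
  if (!inherits(spec, "spectrum_image")) stop_ganb("not a spectrum_image")
  if (!spec$shifted) stop_ganb("spectrum is not shifted")
  v <- spec$values[shift_indices(spec$M, inverse = TRUE),
                   shift_indices(spec$N, inverse = TRUE)]
  new_spectrum(v, shifted = FALSE)
}

#' Build a radial frequency filter on the centered grid
#'
#' Ideal (sharp indicator) filters by default: the mask is 1 where the
#' centered radius \eqn{r(u,v) = \sqrt{(u - \lfloor M/2\rfloor)^2 +
#' (v - \lfloor N/2\rfloor)^2}} satisfies the cutoff condition, 0
#' elsewhere, with the boundary `r == cutoff` inclusive. A Gaussian
#' roll-off variant is available for ringing-sensitive use.
#'
#' @param kind `"band"` (pass `d1 <= r <= d2`), `"low"` (`r <= d2`),
#'   `"high"` (`r >= d1`) or `"allpass"`.
#' @param d1,d2 lower and upper cutoff radii in pixels, `0 <= d1 <= d2`.
#' @param m,n spectrum dimensions.
#' @param rolloff `"ideal"` or `"gaussian"`.
#' @return A `frequency_filter`: list with the `mask` matrix (entries in
#'   `[0, 1]`), `kind` and cutoffs.
#' @export
build_filter <- function(kind = c("band", "low", "high", "allpass"),
                         d1 = 0, d2 = Inf, m, n,
                         rolloff = c("ideal", "gaussian")) {
  kind <- match.arg(kind)
  rolloff <- match.arg(rolloff)
  if (!is.numeric(d1) || !is.numeric(d2) || d1 < 0 || d1 > d2)
    stop_ganb("cutoffs must satisfy 0 <= d1 <= d2 (got d1=", d1,
              ", d2=", d2, ")")
  cu <- floor(m / 2)
  cv <- floor(n / 2)
  u <- matrix(rep(0:(m - 1), times = n), m, n)
  v <- matrix(rep(0:(n - 1), each = m), m, n)
  r <- sqrt((u - cu)^2 + (v - cv)^2)
  mask <- if (rolloff == "ideal") {
    switch(kind,
           allpass = matrix(1, m, n),
           low = (r <= d2) * 1,
           high = (r >= d1) * 1,
           band = (r >= d1 & r <= d2) * 1)
  } else {
    lo <- if (is.finite(d2)) exp(-r^2 / (2 * max(d2, 1e-9)^2)) else
      matrix(1, m, n)
    hi <- if (d1 > 0) 1 - exp(-r^2 / (2 * d1^2)) else matrix(1, m, n)
    switch(kind,
           allpass = matrix(1, m, n),
           low = lo, high = hi, band = lo * hi)
  }
  structure(list(mask = mask, kind = kind, d1 = d1, d2 = d2,
                 rolloff = rolloff),
            class = "frequency_filter")
}

#' Apply a frequency filter to a centered spectrum
#'
#' Elementwise product of the shifted spectrum with the filter mask.
#'
#' @param spec a shifted `spectrum_image`.
#' @param filt a `frequency_filter` (or bare numeric mask) of matching
#'   shape.
#' @return The filtered, still shifted, `spectrum_image`.
#' @export
apply_filter <- function(spec, filt) {
  if (!inherits(spec, "spectrum_image")) stop_ganb("not a spectrum_image")
  if (!spec$shifted)
    stop_ganb("filters apply to the centered spectrum; call fft_shift() first")
  mask <- if (inherits(filt, "frequency_filter")) filt$mask else filt
  if (!all(dim(mask) == dim(spec$values)))
    stop_ganb("filter shape ", paste(dim(mask), collapse = "x"),
              " does not match spectrum ",
              paste(dim(spec$values), collapse = "x"))
  new_spectrum(spec$values * mask, shifted = TRUE)
}

#' Inverse 2-D discrete Fourier transform
#'
#' Returns the real part of the inverse transform. Radially symmetric
#' filters preserve the conjugate symmetry of real input images, so the
#' imaginary residual must be negligible (at most `1e-8` of the output
#' magnitude); a larger residual is an error.
#'
#' @param spec an unshifted `spectrum_image` (apply [ifft_shift()] first
#'   when coming from the filtering stage).
#' @return A numeric matrix in the spatial domain.
#' @export
idft2 <- function(spec) {
  if (!inherits(spec, "spectrum_image")) stop_ganb("not a spectrum_image")
  if (spec$shifted)
    stop_ganb("inverse transform requires an unshifted spectrum; ",
              "call ifft_shift() first")
  z <- stats::fft(spec$values, inverse = TRUE) / (spec$M * spec$N)
  re <- Re(z)
  tol <- 1e-8 * max(abs(re), 1e-12)
  if (max(abs(Im(z))) > tol)
    stop_ganb("imaginary residual after inversion exceeds tolerance; ",
              "was a non-symmetric filter applied to a real image?")
  re
}

#' Min-max intensity normalization to [0, 255]
#'
#' @param img numeric matrix.
#' @return `255 * (img - min) / (max - min)`; a constant image maps to
#'   all zeros (with a warning).
#' @export
normalize_intensity <- function(img) {
  check_matrix(img, "img")
  rng <- range(img)
  if (diff(rng) == 0) {
    warning("constant image: normalized output set to all zeros")
    return(matrix(0, nrow(img), ncol(img)))
  }
  255 * (img - rng[1]) / (rng[2] - rng[1])
}

#' Full frequency-domain preprocessing chain
#'
#' Composes [dft2()], [fft_shift()], [apply_filter()], [ifft_shift()],
#' [idft2()] and [normalize_intensity()], exactly as running the stages by
#' hand.
#'
#' @param img numeric matrix.
#' @param filter_spec a `frequency_filter` from [build_filter()], or a
#'   list with elements `kind`, `d1`, `d2` (and optionally `rolloff`)
#'   from which one is built at the image's dimensions.
#' @return The processed image, normalized to `[0, 255]`.
#' @export
preprocess_image <- function(img,
                             filter_spec = list(kind = "band", d1 = 2,
                                                d2 = NULL)) {
  check_matrix(img, "img")
  if (!inherits(filter_spec, "frequency_filter")) {
    d2 <- filter_spec$d2
    if (is.null(d2)) d2 <- max(dim(img)) / 4
    filter_spec <- build_filter(kind = filter_spec$kind %||% "band",
                                d1 = filter_spec$d1 %||% 2,
                                d2 = d2,
                                m = nrow(img), n = ncol(img),
                                rolloff = filter_spec$rolloff %||% "ideal")
  }
  spec <- fft_shift(dft2(img))
  filtered <- apply_filter(spec, filter_spec)
  normalize_intensity(idft2(ifft_shift(filtered)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
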