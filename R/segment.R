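#' Baseline intensity-threshold segmenter
#'
#' A deliberately simple segmenter used to exercise the segmentation
#' metrics end-to-end: a first Otsu threshold separates tissue from the
#' dark background, a second Otsu threshold within the foreground
#' isolates the bright contrast-filled structures, connected components
#' are labelled, and the largest bright component is returned as the
#' lumen-class mask. Otsu thresholds are computed on the intensity
#' histogram, so the segmentation is invariant to linear intensity
#' rescaling (up to histogram binning).
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @return An integer matrix of the same shape: 1 on the largest bright
#'   component, 0 elsewhere. A constant (blank) image yields an empty
#'   mask with a warning.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(stenosis_fraction = 0.4,
#'                                     noise_sd = 0, seed = 2))
#' seg <- threshold_segment(ph$image)
#' dice(seg, (ph$masks == 2) * 1L)
threshold_segment <- function(image) {
  check_matrix(image, "image")
  if (min(image) < 0 || max(image) > 1)
    stop_ganb("image values must lie in [0, 1]")
  empty <- matrix(0L, nrow(image), ncol(image))
  if (diff(range(image)) == 0) {
    warning("blank image: returning an empty mask")
    return(empty)
  }
  t1 <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  fg <- image > t1
  vals <- image[fg]
  if (length(unique(vals)) < 2) {
    bright <- fg
  } else {
    t2 <- EBImage::otsu(EBImage::Image(matrix(vals, nrow = 1)),
                        range = c(0, 1))
    bright <- fg & image > t2
    if (!any(bright)) bright <- fg
  }
  labs <- EBImage::bwlabel(EBImage::Image(bright * 1))
  labs <- matrix(as.integer(EBImage::imageData(labs)), nrow(image))
  if (max(labs) == 0) {
    warning("no bright component found: returning an empty mask")
    return(empty)
  }
  sizes <- tabulate(labs[labs > 0])
  (labs == which.max(sizes)) * 1L
}
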