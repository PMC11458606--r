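# Internal helpers shared across modules.

#' @importFrom stats rnorm runif var quantile
#' @importFrom utils read.csv write.csv
NULL

# Round half away from zero, as used in aggregate reporting. base::round()
# rounds half to even, which would turn 0.905 into 0.90.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic sub-seed derived from a master seed and a stage label, so
# every stage draws from its own stream. Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483587
  as.integer((abs(seed) * 2654435 + h) %% 2147483587 + 1)
}

stop_ganb <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (is.null(x) || length(x) != 1 || !is.numeric(x) || !is.finite(x))
    stop_ganb(sprintf("'%s' must be a single finite number", name))
  if (x < lower || x > upper)
    stop_ganb(sprintf("'%s' must be in [%s, %s], got %s",
                      name, lower, upper, x))
  if (integer && x != round(x))
    stop_ganb(sprintf("'%s' must be an integer, got %s", name, x))
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x))
    stop_ganb(sprintf("'%s' must be TRUE or FALSE", name))
  invisible(x)
}

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_ganb(sprintf("'%s' must be a numeric matrix", name))
  if (!all(is.finite(x)))
    stop_ganb(sprintf("'%s' contains non-finite values", name))
  invisible(x)
}

# images argument normalization: a numeric matrix is one image; a list of
# matrices or an n x d matrix with attribute "image_dim" is a batch.
as_image_batch <- function(images, dim_expected = NULL) {
  if (is.list(images)) {
    flat <- t(vapply(images, function(im) as.vector(im),
                     numeric(length(images[[1]]))))
    return(flat)
  }
  if (is.matrix(images) && !is.null(dim_expected) &&
      ncol(images) == dim_expected)
    return(images)
  if (is.matrix(images) && is.null(dim_expected))
    return(images)
  stop_ganb("images must be a list of matrices or an n x d numeric matrix")
}
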