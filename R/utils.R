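# shared helpers: value clipping, image container checks, transfer curves

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Undo the sRGB transfer curve
#'
#' Converts display-encoded (gamma-compressed) sRGB values to linear
#' intensity. The pipeline assumes linear imagery throughout (raw decodes
#' with gamma = 1); this helper is for 8-bit display-referred inputs only.
#'
#' @param x numeric vector, matrix or array of sRGB-encoded values in
#'   \[0, 1\].
#' @return object of the same shape with linear intensities in \[0, 1\].
#' @seealso [linear_to_srgb()]
#' @export
srgb_to_linear <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0 & x <= 1))
  out <- ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
  out[] <- pmin(pmax(out, 0), 1)
  attributes(out) <- attributes(x)
  out
}

#' Apply the sRGB transfer curve
#'
#' Inverse of [srgb_to_linear()]: encodes linear intensities for display.
#'
#' @param x numeric vector, matrix or array of linear values in \[0, 1\].
#' @return object of the same shape, sRGB-encoded.
#' @export
linear_to_srgb <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0 & x <= 1))
  out <- ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
  out[] <- pmin(pmax(out, 0), 1)
  attributes(out) <- attributes(x)
  out
}

# An image is a height x width x 3 numeric array in [0, 1]; a single-channel
# matrix is accepted where stated and promoted to 3 identical channels.
as_image <- function(x, arg = "image") {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!(is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L))
    stop(sprintf("'%s' must be an h x w x 3 array or an h x w matrix", arg))
  if (!is.numeric(x) || anyNA(x) || min(x) < 0 || max(x) > 1)
    stop(sprintf("'%s' must contain finite values in [0, 1]", arg))
  x
}

# Run code with a private RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards so generators are reproducible without
# disturbing the session.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Read a PNG image as a linear RGB array
#'
#' @param path file path to a PNG image.
#' @param srgb_encoded if `TRUE`, the file holds display-encoded sRGB (the
#'   usual case for 8-bit PNG) and the inverse transfer curve is applied;
#'   if `FALSE` the stored values are taken as already linear.
#' @return an h x w x 3 linear-RGB array in \[0, 1\].
#' @export
read_image_png <- function(path, srgb_encoded = FALSE) {
  px <- png::readPNG(path)
  if (is.matrix(px)) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (srgb_encoded) px <- srgb_to_linear(px)
  as_image(px)
}

#' Write a linear RGB array to PNG
#'
#' @param image h x w x 3 array (or matrix) of linear values in \[0, 1\].
#' @param path output file path.
#' @param srgb_encode encode with the sRGB transfer curve before writing
#'   (recommended for viewing); `FALSE` stores raw linear values.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path, srgb_encode = FALSE) {
  image <- as_image(image)
  if (srgb_encode) image <- linear_to_srgb(image)
  png::writePNG(image, path)
  invisible(path)
}
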