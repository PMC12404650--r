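#' Depth-tagged image container
#'
#' Couples a linear-RGB raster with the depth at which it was taken and
#' its illumination mode (flash vs ambient).
#'
#' @param pixels h x w x 3 linear-RGB array in \[0, 1\] (a matrix is
#'   promoted to gray).
#' @param depth depth in meters, >= 0.
#' @param illumination `"flash"` or `"ambient"`.
#' @return object of class `depth_tagged_image`.
#' @export
depth_tagged_image <- function(pixels, depth,
                               illumination = c("flash", "ambient")) {
  pixels <- as_image(pixels, "pixels")
  illumination <- match.arg(illumination)
  stopifnot(length(depth) == 1L, is.finite(depth))
  if (depth < 0) stop("depth must be non-negative")
  structure(list(pixels = pixels, depth = depth,
                 illumination = illumination),
            class = "depth_tagged_image")
}

#' @export
print.depth_tagged_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("%s-lit image %dx%d at %.1f m\n", x$illumination, d[2], d[1],
              x$depth))
  invisible(x)
}

#' Simulate the ambient-light appearance of a flash image at depth
#'
#' Multiplies each channel of a flash-lit (full-spectrum) image by the
#' attenuation model's per-channel light scale at the stated depth,
#' removing long-wavelength information the way the water column does.
#' With `renormalize = TRUE` the result is rescaled by one global factor
#' so its maximum channel value matches the input's maximum: the hue shift
#' is preserved but overall exposure is restored. Output is clipped to
#' \[0, 1\].
#'
#' @param image a flash-lit [depth_tagged_image()] or a bare linear-RGB
#'   array (treated as flash-lit).
#' @param model an `attenuation_model` from [fit_attenuation()].
#' @param depth simulation depth in meters, >= 0; defaults to the image's
#'   own depth tag.
#' @param renormalize restore overall exposure after the spectral scaling.
#' @return an ambient-tagged `depth_tagged_image` at `depth`.
#' @examples
#' m <- fit_attenuation(render_card_series(water_optics()))
#' px <- array(runif(48), dim = c(4, 4, 3))
#' sim <- simulate_at_depth(px, m, depth = 10)
#' @export
simulate_at_depth <- function(image, model, depth = NULL,
                              renormalize = FALSE) {
  if (!inherits(image, "depth_tagged_image"))
    image <- depth_tagged_image(as_image(image), depth = if (is.null(depth)) 0 else depth,
                                illumination = "flash")
  if (image$illumination != "flash")
    stop("simulate_at_depth expects a flash-lit input image")
  stopifnot(inherits(model, "attenuation_model"))
  if (is.null(depth)) depth <- image$depth
  if (length(depth) != 1L || !is.finite(depth) || depth < 0)
    stop("depth must be a single non-negative number")
  scale <- predict_channel_scale(model, depth)
  px <- image$pixels
  for (c in 1:3) px[, , c] <- px[, , c] * scale[c]
  if (renormalize) {
    mx <- max(px)
    if (mx > 0) px <- px * (max(image$pixels) / mx)
  }
  depth_tagged_image(clip01(px), depth, "ambient")
}

# circular absolute difference of hue angles in degrees
hue_diff_deg <- function(h1, h2) {
  d <- abs(h1 - h2) %% 360
  pmin(d, 360 - d)
}

#' Quantify the discrepancy between a simulated and a true ambient image
#'
#' Computes per-channel mean-absolute and root-mean-square error plus a
#' chromaticity error: the mean absolute CIELAB hue-angle difference over
#' pixels bright enough for hue to be meaningful (max channel >= the
#' brightness floor in both images) and with defined hue (non-negligible
#' chroma) in both.
#'
#' @param sim,truth images of equal dimensions (`depth_tagged_image` or
#'   bare arrays).
#' @param brightness_floor pixels with max channel below this value in
#'   either image are excluded from the hue comparison (default 0.02).
#' @return list with `mae` and `rmse` (named per-channel vectors),
#'   `hue_mae_deg` (NA when no pixel qualifies) and `n_hue_pixels`.
#' @export
compare_simulation <- function(sim, truth, brightness_floor = 0.02) {
  if (inherits(sim, "depth_tagged_image")) sim <- sim$pixels
  if (inherits(truth, "depth_tagged_image")) truth <- truth$pixels
  sim <- as_image(sim, "sim"); truth <- as_image(truth, "truth")
  if (!identical(dim(sim), dim(truth)))
    stop("sim and truth must have identical dimensions")
  diff <- sim - truth
  mae <- apply(abs(diff), 3L, mean)
  rmse <- sqrt(apply(diff^2, 3L, mean))
  names(mae) <- names(rmse) <- c("R", "G", "B")

  flat_s <- matrix(sim, ncol = 3L); flat_t <- matrix(truth, ncol = 3L)
  bright <- pmax(flat_s[, 1], flat_s[, 2], flat_s[, 3]) >= brightness_floor &
            pmax(flat_t[, 1], flat_t[, 2], flat_t[, 3]) >= brightness_floor
  hue_mae <- NA_real_; n_hue <- 0L
  if (any(bright)) {
    hs <- rgb_to_hue_chroma(flat_s[bright, , drop = FALSE])
    ht <- rgb_to_hue_chroma(flat_t[bright, , drop = FALSE])
    ok <- hs$hue_defined & ht$hue_defined
    n_hue <- sum(ok)
    if (n_hue > 0)
      hue_mae <- mean(hue_diff_deg(hs$hue[ok], ht$hue[ok]))
  }
  list(mae = mae, rmse = rmse, hue_mae_deg = hue_mae, n_hue_pixels = n_hue)
}
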