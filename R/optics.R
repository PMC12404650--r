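#' Water-optics parameters for synthetic rendering
#'
#' Describes a three-channel Beer-Lambert model of downwelling light:
#' ambient intensity in channel c at depth z is
#' `surface_illuminant[c] * exp(-k[c] * z)`. Longer wavelengths attenuate
#' faster in seawater, so k is largest for red. The defaults correspond to
#' clear tropical coastal water in which red light is effectively gone
#' within the first ~10 m.
#'
#' @param k per-channel attenuation coefficient (R, G, B), units 1/m,
#'   all >= 0.
#' @param surface_illuminant per-channel relative downwelling intensity at
#'   depth 0, each in (0, 1].
#' @param noise_sd standard deviation of additive Gaussian pixel noise in
#'   linear-intensity units, >= 0.
#' @return an object of class `water_optics`.
#' @examples
#' water_optics()                      # defaults
#' water_optics(k = c(0.6, 0.08, 0.05))
#' @export
water_optics <- function(k = c(0.5, 0.07, 0.04),
                         surface_illuminant = c(1, 1, 1),
                         noise_sd = 0) {
  k <- as.numeric(k); surface_illuminant <- as.numeric(surface_illuminant)
  stopifnot(length(k) == 3L, all(is.finite(k)), all(k >= 0),
            length(surface_illuminant) == 3L,
            all(surface_illuminant > 0), all(surface_illuminant <= 1),
            length(noise_sd) == 1L, is.finite(noise_sd), noise_sd >= 0)
  structure(list(k = stats::setNames(k, c("R", "G", "B")),
                 surface_illuminant = stats::setNames(surface_illuminant,
                                                      c("R", "G", "B")),
                 noise_sd = noise_sd),
            class = "water_optics")
}

#' @export
print.water_optics <- function(x, ...) {
  cat("Water optics (Beer-Lambert, 3 broadband channels)\n")
  cat(sprintf("  k (1/m):            R %.4g  G %.4g  B %.4g\n",
              x$k[1], x$k[2], x$k[3]))
  cat(sprintf("  surface illuminant: R %.3g  G %.3g  B %.3g\n",
              x$surface_illuminant[1], x$surface_illuminant[2],
              x$surface_illuminant[3]))
  cat(sprintf("  pixel noise sd:     %.4g\n", x$noise_sd))
  invisible(x)
}

#' Color-card layout: panel reflectances and image regions
#'
#' A card layout lists each panel's surface reflectance per channel and its
#' rectangular region in image coordinates (1-based pixel indices, row =
#' y down, column = x right; regions are inclusive and must not overlap).
#' At least one neutral panel (equal reflectance in all channels) is
#' required: neutral panels isolate the illuminant change from panel
#' chromaticity and are the default set used to fit attenuation.
#'
#' @param panels data.frame with columns `panel_id`, `refl_R`, `refl_G`,
#'   `refl_B` (each in \[0, 1\]), `x0`, `x1`, `y0`, `y1` (integer pixel
#'   bounds, `x0 <= x1`, `y0 <= y1`).
#' @return object of class `card_layout` (a validated data.frame).
#' @seealso [default_card_layout()]
#' @export
card_layout <- function(panels) {
  need <- c("panel_id", "refl_R", "refl_G", "refl_B", "x0", "x1", "y0", "y1")
  stopifnot(is.data.frame(panels), all(need %in% names(panels)))
  if (nrow(panels) < 2L) stop("a card layout needs at least 2 panels")
  refl <- as.matrix(panels[, c("refl_R", "refl_G", "refl_B")])
  stopifnot(all(refl >= 0), all(refl <= 1),
            all(panels$x0 <= panels$x1), all(panels$y0 <= panels$y1),
            all(panels$x0 >= 1), all(panels$y0 >= 1))
  if (anyDuplicated(panels$panel_id))
    stop("panel_id values must be unique")
  neutral <- abs(refl[, 1] - refl[, 2]) < 1e-12 &
             abs(refl[, 2] - refl[, 3]) < 1e-12
  if (!any(neutral))
    stop("layout must contain at least one neutral (equal-reflectance) panel")
  # pairwise rectangle overlap check
  n <- nrow(panels)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (panels$x0[i] <= panels$x1[j] && panels$x0[j] <= panels$x1[i] &&
        panels$y0[i] <= panels$y1[j] && panels$y0[j] <= panels$y1[i])
      stop(sprintf("panel regions '%s' and '%s' overlap",
                   panels$panel_id[i], panels$panel_id[j]))
  }
  panels$neutral <- neutral
  structure(panels, class = c("card_layout", "data.frame"))
}

#' Default synthetic 24-panel dive color chart
#'
#' 24 panels in a 4 x 6 grid: 18 chromatic panels spanning the hue circle
#' at two saturation levels plus a 6-step neutral ramp on the bottom row
#' (the usual composition of a waterproof dive color chart; the reflectance
#' values are synthetic placeholders, not measurements of any physical
#' chart).
#'
#' @param panel_px side length of each square panel region in pixels.
#' @param margin_px gap between panels and border, in pixels.
#' @return a [card_layout()] with 24 panels; image extent is recorded in
#'   attributes `width` and `height`.
#' @export
default_card_layout <- function(panel_px = 40L, margin_px = 10L) {
  stopifnot(panel_px >= 1L, margin_px >= 0L)
  refl <- rbind(
    # row 1-3: chromatic panels (R, G, B surface reflectance)
    c(0.85, 0.10, 0.10), c(0.90, 0.45, 0.10), c(0.90, 0.75, 0.10),
    c(0.55, 0.80, 0.10), c(0.15, 0.75, 0.15), c(0.10, 0.75, 0.45),
    c(0.10, 0.70, 0.70), c(0.10, 0.45, 0.80), c(0.10, 0.15, 0.80),
    c(0.45, 0.15, 0.80), c(0.70, 0.15, 0.70), c(0.80, 0.15, 0.45),
    c(0.55, 0.25, 0.20), c(0.60, 0.50, 0.25), c(0.30, 0.50, 0.20),
    c(0.20, 0.45, 0.55), c(0.25, 0.25, 0.60), c(0.55, 0.30, 0.50),
    # row 4: neutral ramp, bright to dark
    c(0.95, 0.95, 0.95), c(0.75, 0.75, 0.75), c(0.55, 0.55, 0.55),
    c(0.36, 0.36, 0.36), c(0.19, 0.19, 0.19), c(0.06, 0.06, 0.06))
  ids <- c(sprintf("C%02d", 1:18), sprintf("N%d", 1:6))
  row <- rep(1:4, each = 6L); col <- rep(1:6, times = 4L)
  step <- panel_px + margin_px
  x0 <- margin_px + (col - 1L) * step + 1L
  y0 <- margin_px + (row - 1L) * step + 1L
  lay <- card_layout(data.frame(
    panel_id = ids,
    refl_R = refl[, 1], refl_G = refl[, 2], refl_B = refl[, 3],
    x0 = x0, x1 = x0 + panel_px - 1L, y0 = y0, y1 = y0 + panel_px - 1L,
    stringsAsFactors = FALSE))
  attr(lay, "width") <- margin_px + 6L * step
  attr(lay, "height") <- margin_px + 4L * step
  lay
}

#' The measured depth grid of the card photograph series
#'
#' The eleven depths (meters) at which the color card was photographed,
#' from the surface to 25.7 m; 11.7 and 11.8 m are genuinely distinct
#' measurements and are both kept.
#'
#' @return numeric vector of 11 depths in meters.
#' @export
card_series_depths <- function() {
  c(0.0, 4.6, 6.0, 11.7, 11.8, 14.0, 17.2, 19.4, 21.1, 22.2, 25.7)
}

# noiseless panel color under the optics model, one row per panel
panel_truth <- function(optics, layout, depth, flash) {
  refl <- as.matrix(layout[, c("refl_R", "refl_G", "refl_B")])
  scale <- if (flash) optics$surface_illuminant
           else optics$surface_illuminant * exp(-optics$k * depth)
  sweep(refl, 2L, scale, `*`)
}

#' Render a synthetic color-card series under known water optics
#'
#' Generates per-panel mean colors of the card at each depth. Ambient
#' rendering (`flash = FALSE`) follows the Beer-Lambert model: channel c of
#' a panel with reflectance rho at depth z is
#' `rho * illuminant_c * exp(-k_c * z)` plus Gaussian noise, clipped to
#' \[0, 1\]. Flash rendering omits the depth term: the strobe restores
#' full-spectrum illumination (the short camera-to-subject water path is
#' neglected).
#'
#' @param optics a [water_optics()] object.
#' @param layout a [card_layout()]; defaults to [default_card_layout()].
#' @param depths depths in meters, all >= 0; defaults to
#'   [card_series_depths()].
#' @param flash logical; `TRUE` renders under full-spectrum flash.
#' @param seed optional integer seed for the noise stream.
#' @return a `color_card_series`: data.frame with columns `depth`,
#'   `panel_id`, `R`, `G`, `B`, sorted by depth, with the layout attached
#'   as attribute `layout`.
#' @examples
#' s <- render_card_series(water_optics(), depths = c(0, 5, 10))
#' head(s)
#' @export
render_card_series <- function(optics, layout = default_card_layout(),
                               depths = card_series_depths(),
                               flash = FALSE, seed = NULL) {
  stopifnot(inherits(optics, "water_optics"), inherits(layout, "card_layout"),
            is.logical(flash), length(flash) == 1L)
  depths <- as.numeric(depths)
  if (length(depths) == 0L) stop("'depths' must be non-empty")
  if (anyNA(depths) || any(depths < 0)) stop("depths must be non-negative")
  depths <- sort(depths)
  # a panel entry is the mean over the panel's pixel region, so pixel noise
  # averages down by the square root of the panel area — matching what
  # extract_panel_colors() measures on a rendered raster
  n_px <- (layout$x1 - layout$x0 + 1) * (layout$y1 - layout$y0 + 1)
  out <- with_seed(seed, {
    do.call(rbind, lapply(depths, function(z) {
      col <- panel_truth(optics, layout, z, flash)
      if (optics$noise_sd > 0)
        col <- col + matrix(rnorm(length(col), sd = optics$noise_sd / sqrt(n_px)),
                            nrow = nrow(col))
      col[] <- clip01(col)
      data.frame(depth = z, panel_id = layout$panel_id,
                 R = col[, 1], G = col[, 2], B = col[, 3],
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(out) <- NULL
  structure(out, layout = layout,
            class = c("color_card_series", "data.frame"))
}

#' Render one raster image of the color card
#'
#' Pixel-level counterpart of [render_card_series()]: panels are drawn on a
#' dark background and per-pixel Gaussian noise is added, giving a raster
#' suitable for [extract_panel_colors()].
#'
#' @inheritParams render_card_series
#' @param depth single depth in meters, >= 0.
#' @param background background linear intensity.
#' @return an h x w x 3 linear-RGB array in \[0, 1\].
#' @export
render_card_image <- function(optics, layout = default_card_layout(),
                              depth = 0, flash = FALSE, background = 0.05,
                              seed = NULL) {
  stopifnot(inherits(optics, "water_optics"), inherits(layout, "card_layout"),
            length(depth) == 1L, is.finite(depth))
  if (depth < 0) stop("depth must be non-negative")
  w <- attr(layout, "width")
  h <- attr(layout, "height")
  if (is.null(w)) w <- max(layout$x1) + 10L
  if (is.null(h)) h <- max(layout$y1) + 10L
  truth <- panel_truth(optics, layout, depth, flash)
  # the background is a scene surface: it sees the same illumination as the
  # panels (attenuated ambient, or full-spectrum flash)
  bg <- background * (if (flash) optics$surface_illuminant
                      else optics$surface_illuminant * exp(-optics$k * depth))
  img <- array(rep(bg, each = h * w), dim = c(h, w, 3L))
  for (i in seq_len(nrow(layout))) {
    img[layout$y0[i]:layout$y1[i], layout$x0[i]:layout$x1[i], 1L] <- truth[i, 1]
    img[layout$y0[i]:layout$y1[i], layout$x0[i]:layout$x1[i], 2L] <- truth[i, 2]
    img[layout$y0[i]:layout$y1[i], layout$x0[i]:layout$x1[i], 3L] <- truth[i, 3]
  }
  with_seed(seed, {
    if (optics$noise_sd > 0)
      img <- img + array(rnorm(length(img), sd = optics$noise_sd), dim = dim(img))
    clip01(img)
  })
}
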