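# Colorimetry: linear RGB (sRGB/Rec.709 primaries, D65 white) -> CIEXYZ ->
# CIELAB. Authored here so the conversion is explicit about the linear-input
# convention; agreement with the display-referred reference path is covered
# by the test suite.

.rgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                     0.2126729, 0.7151522, 0.0721750,
                     0.0193339, 0.1191920, 0.9503041),
                   nrow = 3, byrow = TRUE)
# D65 white taken as the matrix row sums so that exactly equal RGB maps to
# exactly zero (a, b): neutrals are achromatic to machine precision.
.d65 <- rowSums(.rgb2xyz)

.lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

# n x 3 linear RGB -> n x 3 matrix of L, a, b
linear_rgb_to_lab <- function(rgb) {
  xyz <- rgb %*% t(.rgb2xyz)
  fx <- .lab_f(xyz[, 1] / .d65[1])
  fy <- .lab_f(xyz[, 2] / .d65[2])
  fz <- .lab_f(xyz[, 3] / .d65[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Convert linear RGB to CIELAB hue and chroma
#'
#' Converts linear RGB (sRGB primaries, D65 white) to CIELAB via CIEXYZ,
#' then to the polar form of the (a, b) opponent plane: chroma is
#' `sqrt(a^2 + b^2)` and hue is `atan2(b, a)` in degrees mapped to
#' \[0, 360). Hue is undefined for near-neutral colors; rows with chroma
#' below `chroma_tol` get `hue = NA` and `hue_defined = FALSE`.
#'
#' @param color length-3 vector or n x 3 matrix/data.frame of linear RGB
#'   in \[0, 1\].
#' @param chroma_tol chroma below which hue is flagged undefined.
#' @return data.frame with columns `L`, `a`, `b`, `chroma`, `hue`,
#'   `hue_defined`.
#' @examples
#' rgb_to_hue_chroma(c(1, 0, 0))        # saturated red: hue ~ 40 deg
#' rgb_to_hue_chroma(c(0.5, 0.5, 0.5))  # neutral: chroma 0, hue undefined
#' @export
rgb_to_hue_chroma <- function(color, chroma_tol = 1e-6) {
  if (is.data.frame(color)) color <- as.matrix(color)
  if (is.null(dim(color))) color <- matrix(color, nrow = 1)
  stopifnot(is.numeric(color), ncol(color) == 3L)
  if (anyNA(color) || min(color) < 0 || max(color) > 1)
    stop("colors must be linear RGB in [0, 1]")
  lab <- linear_rgb_to_lab(color)
  chroma <- sqrt(lab[, "a"]^2 + lab[, "b"]^2)
  hue <- (atan2(lab[, "b"], lab[, "a"]) * 180 / pi) %% 360
  defined <- chroma >= chroma_tol
  hue[!defined] <- NA_real_
  data.frame(L = lab[, "L"], a = lab[, "a"], b = lab[, "b"],
             chroma = chroma, hue = hue, hue_defined = defined)
}

# shoelace area of an ordered polygon (n x 2 matrix)
polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Convex gamut polygon of a set of colors at one depth
#'
#' Builds the convex hull of the points in the CIELAB (a, b) plane and its
#' area (squared-chroma units, via the shoelace formula). Collinear or
#' degenerate point sets return area 0 with `degenerate = TRUE`.
#'
#' @param points data.frame or matrix with columns `a` and `b` (e.g. from
#'   [rgb_to_hue_chroma()]); at least one point.
#' @param depth optional depth label (meters) carried in the result.
#' @return object of class `gamut_polygon`: list with `vertices` (ordered
#'   m x 2 matrix of hull vertices), `area`, `degenerate`, `depth`,
#'   `n_points`.
#' @export
gamut_polygon <- function(points, depth = NA_real_) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("a", "b")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  stopifnot(is.numeric(points), ncol(points) == 2L)
  if (nrow(points) == 0L) stop("gamut_polygon needs at least one point")
  colnames(points) <- c("a", "b")
  uniq <- unique(points)
  idx <- chull(points[, 1], points[, 2])
  verts <- points[idx, , drop = FALSE]
  area <- polygon_area(verts)
  structure(list(vertices = verts, area = area,
                 degenerate = nrow(uniq) < 3L || area <= 0,
                 depth = depth, n_points = nrow(points)),
            class = "gamut_polygon")
}

#' @export
print.gamut_polygon <- function(x, ...) {
  cat(sprintf("Gamut polygon%s: %d hull vertices, area %.4g%s\n",
              if (is.na(x$depth)) "" else sprintf(" at %.1f m", x$depth),
              nrow(x$vertices), x$area,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Depth-by-hue gamut profile with sighting overlay
#'
#' Summarizes the available color gamut at each measured depth of a card
#' series — hue span, chroma range and convex-hull area in the (a, b)
#' plane — and counts animal sightings against the depth rows. Each row
#' covers a half-open depth bracket reaching halfway to the neighboring
#' measured depths (extended to 0 and infinity at the ends); a sighting is
#' assigned to the row whose bracket contains its depth.
#'
#' @param series a `color_card_series`.
#' @param sightings optional data.frame with a `depth_m` column (e.g. from
#'   [simulate_dive_logs()]).
#' @return data.frame with one row per measured depth: `depth`,
#'   `n_panels`, `hue_min`, `hue_max` (degrees, over defined hues),
#'   `chroma_min`, `chroma_max`, `mean_chroma`, `gamut_area`,
#'   `n_sightings`; the sighting depths are attached as attribute
#'   `sighting_depths`.
#' @export
depth_gamut_profile <- function(series, sightings = NULL) {
  stopifnot(inherits(series, "color_card_series"))
  depths <- sort(unique(series$depth))
  sdep <- if (!is.null(sightings) && nrow(sightings)) sightings$depth_m
          else numeric()
  # half-open brackets between midpoints of consecutive measured depths
  edges <- c(0, (depths[-1] + depths[-length(depths)]) / 2, Inf)
  rows <- lapply(seq_along(depths), function(i) {
    z <- depths[i]
    sub <- series[series$depth == z, ]
    hc <- rgb_to_hue_chroma(as.matrix(sub[, c("R", "G", "B")]))
    poly <- gamut_polygon(hc, depth = z)
    hues <- hc$hue[hc$hue_defined]
    data.frame(
      depth = z, n_panels = nrow(sub),
      hue_min = if (length(hues)) min(hues) else NA_real_,
      hue_max = if (length(hues)) max(hues) else NA_real_,
      chroma_min = min(hc$chroma), chroma_max = max(hc$chroma),
      mean_chroma = mean(hc$chroma),
      gamut_area = poly$area,
      n_sightings = sum(sdep >= edges[i] & sdep < edges[i + 1L]))
  })
  out <- do.call(rbind, rows)
  attr(out, "sighting_depths") <- sdep
  out
}
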