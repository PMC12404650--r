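#' Render a synthetic paired-laser scene
#'
#' Draws two bright, green-dominant Gaussian dots on a background texture,
#' with sub-pixel centers a known physical separation apart, emulating the
#' parallel-laser rig used to put a physical scale on texture photographs.
#'
#' @param mm_per_px true scale, millimeters per pixel (> 0).
#' @param dot_separation_mm physical beam separation; default 100 mm
#'   (the rig's fixed 10 cm).
#' @param width,height image size in pixels (ignored when `background`
#'   is an image).
#' @param background constant gray level, matrix, or h x w x 3 array.
#' @param dot_intensity peak added intensity of each dot.
#' @param dot_sigma_px Gaussian radius of a dot in pixels.
#' @param noise_sd additive Gaussian pixel noise sd.
#' @param center dot-pair midpoint `c(x, y)`; defaults to image center.
#' @param angle_deg orientation of the dot pair.
#' @param seed optional seed for the noise stream.
#' @return h x w x 3 linear-RGB array in \[0, 1\] with the true sub-pixel
#'   dot centers in attribute `centers` (2 x 2, rows = dots, cols = x, y).
#' @examples
#' img <- render_laser_scene(mm_per_px = 0.2)
#' attr(img, "centers")
#' @export
render_laser_scene <- function(mm_per_px = 0.2, dot_separation_mm = 100,
                               width = 800L, height = 400L,
                               background = 0.15, dot_intensity = 0.85,
                               dot_sigma_px = 2.5, noise_sd = 0,
                               center = NULL, angle_deg = 0, seed = NULL) {
  stopifnot(mm_per_px > 0, dot_separation_mm > 0, dot_sigma_px > 0,
            noise_sd >= 0)
  if (is.array(background) || is.matrix(background)) {
    img <- as_image(background, "background")
    height <- dim(img)[1]; width <- dim(img)[2]
  } else {
    stopifnot(is.numeric(background), background >= 0, background <= 1)
    img <- array(background, dim = c(height, width, 3L))
  }
  if (is.null(center)) center <- c(width / 2, height / 2)
  sep_px <- dot_separation_mm / mm_per_px
  th <- angle_deg * pi / 180
  half <- sep_px / 2 * c(cos(th), sin(th))
  centers <- rbind(center - half, center + half)  # (x, y) rows
  margin <- 3 * dot_sigma_px
  if (any(centers[, 1] < margin) || any(centers[, 1] > width - margin) ||
      any(centers[, 2] < margin) || any(centers[, 2] > height - margin))
    stop("laser dots fall outside the image frame")
  xs <- matrix(seq_len(width), nrow = height, ncol = width, byrow = TRUE)
  ys <- matrix(seq_len(height), nrow = height, ncol = width)
  for (d in 1:2) {
    g <- exp(-((xs - centers[d, 1])^2 + (ys - centers[d, 2])^2) /
               (2 * dot_sigma_px^2))
    img[, , 1] <- img[, , 1] + 0.35 * dot_intensity * g
    img[, , 2] <- img[, , 2] + dot_intensity * g        # green laser
    img[, , 3] <- img[, , 3] + 0.25 * dot_intensity * g
  }
  img <- with_seed(seed, {
    if (noise_sd > 0)
      img <- img + array(rnorm(length(img), sd = noise_sd), dim = dim(img))
    img
  })
  structure(clip01(img), centers = centers)
}

#' Detect the two laser dots in an image
#'
#' Thresholds a weighted-channel brightness map at a high quantile, labels
#' the connected components above threshold, discards speckle components
#' below `min_area` pixels and keeps the two largest; their
#' intensity-weighted centroids are returned with sub-pixel precision.
#' The quantile threshold makes detection invariant to a uniform
#' background offset.
#'
#' @param image h x w x 3 array (or matrix).
#' @param channel_weights weights of the R, G, B channels in the detection
#'   map; the default emphasizes green (green lasers).
#' @param threshold_quantile quantile of the map used as threshold.
#' @param min_area minimum component area in pixels.
#' @return 2 x 2 matrix of centroids (rows = dots, columns = x, y),
#'   ordered left to right.
#' @export
detect_laser_dots <- function(image, channel_weights = c(0.25, 0.6, 0.15),
                              threshold_quantile = 0.999, min_area = 5L) {
  image <- as_image(image)
  stopifnot(length(channel_weights) == 3L, all(channel_weights >= 0),
            sum(channel_weights) > 0, threshold_quantile > 0,
            threshold_quantile < 1)
  map <- channel_weights[1] * image[, , 1] +
         channel_weights[2] * image[, , 2] +
         channel_weights[3] * image[, , 3]
  thr <- quantile(map, threshold_quantile, names = FALSE)
  mask <- map > thr
  labels <- EBImage::bwlabel(mask)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) != 2L)
    stop(sprintf("expected 2 laser-dot candidates, found %d", length(keep)))
  keep <- keep[order(sizes[keep], decreasing = TRUE)][1:2]
  cent <- t(vapply(keep, function(lb) {
    idx <- which(labels == lb, arr.ind = TRUE)   # (row = y, col = x)
    w <- map[idx]
    c(x = sum(idx[, 2] * w) / sum(w), y = sum(idx[, 1] * w) / sum(w))
  }, numeric(2)))
  cent[order(cent[, 1]), , drop = FALSE]
}

#' Laser-pair scale calibration record
#'
#' @param centroid_1,centroid_2 `c(x, y)` sub-pixel image coordinates of
#'   the two dots.
#' @param separation_mm physical beam separation (default 100 mm).
#' @return object of class `laser_calibration` with the derived
#'   `mm_per_px`.
#' @seealso [reference_object_calibration()] for the fallback method.
#' @export
laser_calibration <- function(centroid_1, centroid_2, separation_mm = 100) {
  stopifnot(length(centroid_1) == 2L, length(centroid_2) == 2L,
            separation_mm > 0)
  d <- sqrt(sum((centroid_1 - centroid_2)^2))
  if (d <= 0) stop("laser-dot centroids are coincident")
  structure(list(centroid_1 = centroid_1, centroid_2 = centroid_2,
                 separation_mm = separation_mm, distance_px = d,
                 mm_per_px = separation_mm / d, method = "laser_pair"),
            class = "laser_calibration")
}

#' Scale calibration from a reference object of known size
#'
#' Fallback when no laser pair is visible: a user-measured pixel span of
#' an object of known physical length.
#'
#' @param span_px measured extent of the object in pixels (> 0).
#' @param length_mm known physical length (> 0).
#' @return object of class `laser_calibration` with
#'   `method = "reference_object"`.
#' @export
reference_object_calibration <- function(span_px, length_mm) {
  stopifnot(span_px > 0, length_mm > 0)
  structure(list(centroid_1 = NULL, centroid_2 = NULL,
                 separation_mm = length_mm, distance_px = span_px,
                 mm_per_px = length_mm / span_px,
                 method = "reference_object"),
            class = "laser_calibration")
}

#' @export
print.laser_calibration <- function(x, ...) {
  cat(sprintf("Scale calibration (%s): %.4g mm/px (%g mm over %.2f px)\n",
              x$method, x$mm_per_px, x$separation_mm, x$distance_px))
  invisible(x)
}

#' Millimeters per pixel from a calibration
#'
#' @param calib a `laser_calibration`.
#' @return mm per pixel: physical separation divided by the Euclidean
#'   pixel distance between the centroids.
#' @export
mm_per_pixel <- function(calib) {
  stopifnot(inherits(calib, "laser_calibration"))
  calib$mm_per_px
}

#' Detect the laser pair and calibrate scale in one step
#'
#' @param image h x w x 3 array containing the two laser dots.
#' @param separation_mm physical beam separation (default 100 mm).
#' @param ... passed to [detect_laser_dots()].
#' @return a `laser_calibration`.
#' @export
calibrate_scale <- function(image, separation_mm = 100, ...) {
  cent <- detect_laser_dots(image, ...)
  laser_calibration(cent[1, ], cent[2, ], separation_mm)
}

#' Scale-bar annotation for an image of known scale
#'
#' Computes the pixel length of a physical scale bar (default 20 mm) and
#' returns it as a sidecar annotation record; source pixels are never
#' modified.
#'
#' @param mm_per_px image scale (> 0), e.g. from [mm_per_pixel()].
#' @param bar_length_mm physical bar length, default 20 mm.
#' @param position optional `c(x, y)` anchor for drawing downstream.
#' @return list of class `scalebar_annotation` with `length_px` (rounded
#'   to the nearest integer), `length_mm`, `mm_per_px`, `position`.
#' @examples
#' scalebar_pixels(0.2)$length_px   # 100 px
#' @export
scalebar_pixels <- function(mm_per_px, bar_length_mm = 20, position = NULL) {
  stopifnot(is.numeric(mm_per_px), mm_per_px > 0)
  if (!is.numeric(bar_length_mm) || bar_length_mm <= 0)
    stop("bar length must be positive")
  structure(list(length_px = as.integer(round(bar_length_mm / mm_per_px)),
                 length_mm = bar_length_mm, mm_per_px = mm_per_px,
                 position = position),
            class = "scalebar_annotation")
}

#' @export
print.scalebar_annotation <- function(x, ...) {
  cat(sprintf("Scale bar: %g mm = %d px at %.4g mm/px\n",
              x$length_mm, x$length_px, x$mm_per_px))
  invisible(x)
}
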