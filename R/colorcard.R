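#' Extract per-panel mean colors from a color-card image
#'
#' Returns the arithmetic mean of linear intensities over each panel's
#' rectangular region, per channel. Input is assumed linear (raw decoded
#' with unit gamma); set `srgb_encoded = TRUE` for display-referred 8-bit
#' imagery.
#'
#' @param image h x w x 3 linear-RGB array (or matrix, promoted to gray).
#' @param layout a [card_layout()]; every region must lie inside the image.
#' @param srgb_encoded if `TRUE`, undo the sRGB transfer curve first.
#' @return data.frame with columns `panel_id`, `R`, `G`, `B`.
#' @export
extract_panel_colors <- function(image, layout, srgb_encoded = FALSE) {
  image <- as_image(image)
  stopifnot(inherits(layout, "card_layout"))
  if (srgb_encoded) image <- srgb_to_linear(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (any(layout$x1 > w) || any(layout$y1 > h))
    stop("panel region extends outside the image")
  if (any(layout$x1 < layout$x0) || any(layout$y1 < layout$y0))
    stop("zero-area panel region")
  means <- t(vapply(seq_len(nrow(layout)), function(i) {
    block <- image[layout$y0[i]:layout$y1[i], layout$x0[i]:layout$x1[i], ,
                   drop = FALSE]
    apply(block, 3L, mean)
  }, numeric(3)))
  data.frame(panel_id = layout$panel_id,
             R = means[, 1], G = means[, 2], B = means[, 3],
             stringsAsFactors = FALSE)
}

#' Assemble a color-card series from per-depth panel colors
#'
#' Stacks per-depth [extract_panel_colors()] tables (or equivalent
#' pre-extracted panel color tables) into the container consumed by
#' [fit_attenuation()].
#'
#' @param depths numeric depths in meters, one per table; near-duplicate
#'   depths are kept as independent measurements.
#' @param panel_tables list of data.frames with `panel_id`, `R`, `G`, `B`.
#' @param layout optional [card_layout()] carried along for panel metadata.
#' @return a `color_card_series` data.frame (depth, panel_id, R, G, B).
#' @export
color_card_series <- function(depths, panel_tables, layout = NULL) {
  stopifnot(length(depths) == length(panel_tables), !anyNA(depths),
            all(depths >= 0))
  ord <- order(depths)
  out <- do.call(rbind, lapply(ord, function(i) {
    tb <- panel_tables[[i]]
    stopifnot(all(c("panel_id", "R", "G", "B") %in% names(tb)))
    data.frame(depth = depths[i], tb[, c("panel_id", "R", "G", "B")],
               stringsAsFactors = FALSE)
  }))
  vals <- as.matrix(out[, c("R", "G", "B")])
  stopifnot(all(vals >= 0), all(vals <= 1))
  rownames(out) <- NULL
  structure(out, layout = layout,
            class = c("color_card_series", "data.frame"))
}

#' Fit the per-channel attenuation model to a card series
#'
#' Per channel, the attenuation coefficient k is the negated slope of an
#' ordinary least-squares fit of log(intensity) against depth, pooled over
#' the selected panels with one intercept per panel (the intercept is the
#' log of the fitted surface intensity). Intensities at or below the dark
#' floor `eps` are excluded from the fit and counted in the diagnostics:
#' below sensor quantization, log intensity is meaningless. Channels with
#' fewer than 3 usable (depth, intensity) points are flagged unfit (k =
#' NA). A fitted negative k on physical data is retained but sets a
#' warning flag.
#'
#' @param series a `color_card_series` with >= 3 distinct depths.
#' @param panels panel ids to pool in the fit; default is the neutral
#'   panels of the attached layout (ids starting "N" when no layout is
#'   attached), falling back to all panels.
#' @param eps dark floor in linear units (default 1/255).
#' @param mode prediction mode stored in the model: `"exponential"`
#'   (Beer-Lambert, the default) or `"piecewise"` (empirical linear
#'   interpolation of measured per-channel ratios).
#' @return an `attenuation_model`: list with per-channel `k` (1/m),
#'   `surface_color` (fitted panel intensities at z = 0), `diagnostics`
#'   (per-channel residual RMSE in log units, points used/excluded, unfit
#'   and negative-k flags), `mode`, and the measured `ratio_table` backing
#'   piecewise prediction.
#' @examples
#' s <- render_card_series(water_optics(k = c(0.5, 0.07, 0.04)))
#' fit_attenuation(s)$k
#' @export
fit_attenuation <- function(series, panels = NULL, eps = 1 / 255,
                            mode = c("exponential", "piecewise")) {
  stopifnot(inherits(series, "color_card_series"))
  mode <- match.arg(mode)
  if (length(unique(series$depth)) < 3L)
    stop("need at least 3 distinct depths to fit attenuation")
  if (is.null(panels)) {
    lay <- attr(series, "layout")
    panels <- if (!is.null(lay) && any(lay$neutral))
      lay$panel_id[lay$neutral]
    else if (any(grepl("^N", series$panel_id)))
      unique(series$panel_id[grepl("^N", series$panel_id)])
    else unique(series$panel_id)
  }
  dat <- series[series$panel_id %in% panels, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no rows match the selected fit panels")
  z0 <- min(dat$depth)
  shallow <- dat[dat$depth == z0, ]
  if (any(as.matrix(shallow[, c("R", "G", "B")]) <= 0))
    stop("selected panels must have positive intensity at the shallowest depth")

  chans <- c("R", "G", "B")
  k <- stats::setNames(rep(NA_real_, 3), chans)
  rmse <- k; n_used <- stats::setNames(integer(3), chans); n_excl <- n_used
  unfit <- stats::setNames(rep(FALSE, 3), chans)
  surface <- matrix(NA_real_, nrow = length(unique(dat$panel_id)), ncol = 3,
                    dimnames = list(unique(dat$panel_id), chans))
  if (all(as.matrix(dat[, chans]) <= eps)) stop("all-dark series: nothing to fit")

  for (ch in chans) {
    y <- dat[[ch]]
    keep <- y > eps
    n_excl[ch] <- sum(!keep)
    d <- dat[keep, , drop = FALSE]
    if (nrow(d) < 3L || length(unique(d$depth)) < 2L) {
      unfit[ch] <- TRUE
      next
    }
    n_used[ch] <- nrow(d)
    pid <- factor(d$panel_id)
    fit <- if (nlevels(pid) > 1L) lm(log(d[[ch]]) ~ d$depth + pid)
           else lm(log(d[[ch]]) ~ d$depth)
    k[ch] <- -coef(fit)[["d$depth"]]
    rmse[ch] <- sqrt(mean(fit$residuals^2))
    # per-panel intercepts -> fitted surface intensity
    ic <- coef(fit)[[1]]
    lv <- levels(pid)
    addl <- c(0, if (nlevels(pid) > 1L)
      coef(fit)[paste0("pid", lv[-1])] else NULL)
    surface[lv, ch] <- exp(ic + addl)
  }
  if (all(unfit)) stop("no channel had enough usable points to fit")

  # measured per-channel ratios vs the shallowest depth, for piecewise mode
  agg <- stats::aggregate(dat[, chans], by = list(depth = dat$depth), mean)
  base <- as.numeric(agg[which.min(agg$depth), chans])
  ratio <- sweep(as.matrix(agg[, chans]), 2L, base, `/`)
  ratio_table <- data.frame(depth = agg$depth, ratio)

  structure(list(
    k = k, surface_color = surface,
    diagnostics = list(rmse_log = rmse, n_used = n_used,
                       n_excluded = n_excl, unfit = unfit,
                       negative_k = !is.na(k) & k < 0, eps = eps,
                       fit_panels = panels),
    mode = mode, ratio_table = ratio_table),
    class = "attenuation_model")
}

#' @export
print.attenuation_model <- function(x, ...) {
  cat("Per-channel water attenuation model (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  k (1/m): R %.5g  G %.5g  B %.5g\n",
              x$k[1], x$k[2], x$k[3]))
  cat(sprintf("  log-RMSE: R %.3g  G %.3g  B %.3g; excluded below eps: %d\n",
              x$diagnostics$rmse_log[1], x$diagnostics$rmse_log[2],
              x$diagnostics$rmse_log[3], sum(x$diagnostics$n_excluded)))
  if (any(x$diagnostics$unfit))
    cat("  unfit channels:", paste(names(x$k)[x$diagnostics$unfit],
                                   collapse = ", "), "\n")
  if (any(x$diagnostics$negative_k, na.rm = TRUE))
    cat("  warning: negative fitted k in",
        paste(names(x$k)[which(x$diagnostics$negative_k)], collapse = ", "),
        "\n")
  invisible(x)
}

#' Per-channel multiplicative light scale at depth
#'
#' In exponential mode returns `exp(-k_c * z)` per channel (1 at the
#' surface). In piecewise mode linearly interpolates the measured
#' per-channel intensity ratios between the bracketing measured depths,
#' clamped to the shallowest/deepest measurement outside the measured
#' range.
#'
#' @param model an `attenuation_model`.
#' @param depth depth(s) in meters, >= 0.
#' @return for a single depth, a named numeric vector (R, G, B); for
#'   several depths, a matrix with one row per depth.
#' @export
predict_channel_scale <- function(model, depth) {
  stopifnot(inherits(model, "attenuation_model"), is.numeric(depth))
  if (anyNA(depth) || any(depth < 0)) stop("depth must be non-negative")
  out <- if (model$mode == "exponential") {
    k <- ifelse(is.na(model$k), 0, model$k)
    exp(-outer(depth, k))
  } else {
    rt <- model$ratio_table
    vapply(c("R", "G", "B"), function(ch)
      approx(rt$depth, rt[[ch]], xout = depth, rule = 2, ties = mean)$y,
      numeric(length(depth)))
  }
  out <- matrix(out, nrow = length(depth), ncol = 3L,
                dimnames = list(NULL, c("R", "G", "B")))
  if (length(depth) == 1L) out[1L, ] else out
}
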