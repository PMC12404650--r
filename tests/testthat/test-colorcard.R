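test_that("panel extraction returns arithmetic region means", {
  lay <- card_layout(data.frame(
    panel_id = c("L", "R"), refl_R = c(0.2, 0.8), refl_G = c(0.2, 0.8),
    refl_B = c(0.2, 0.8), x0 = c(1, 121), x1 = c(100, 220),
    y0 = c(1, 1), y1 = c(100, 100)))
  # uniform field: every panel mean equals the field value
  uni <- array(0.37, dim = c(120, 240, 3))
  m <- extract_panel_colors(uni, lay)
  expect_equal(m$R, c(0.37, 0.37))
  # two panels with zero-mean noise, >= 1e4 px each: means within 0.001
  set.seed(7)
  img <- array(0, dim = c(120, 240, 3))
  img[1:100, 1:100, ] <- 0.2
  img[1:100, 121:220, ] <- 0.8
  img <- pmin(pmax(img + array(rnorm(length(img), sd = 0.01), dim = dim(img)),
                   0), 1)
  m <- extract_panel_colors(img, lay)
  expect_lt(max(abs(m[m$panel_id == "L", c("R", "G", "B")] - 0.2)), 0.001)
  expect_lt(max(abs(m[m$panel_id == "R", c("R", "G", "B")] - 0.8)), 0.001)
})

test_that("degenerate 1x1 panel returns that pixel; bad regions rejected", {
  img <- array(runif(300), dim = c(10, 10, 3))
  lay1 <- card_layout(data.frame(
    panel_id = c("p", "q"), refl_R = c(0.5, 0.5), refl_G = c(0.5, 0.5),
    refl_B = c(0.5, 0.5), x0 = c(3, 7), x1 = c(3, 7), y0 = c(4, 4),
    y1 = c(4, 4)))
  m <- extract_panel_colors(img, lay1)
  expect_equal(unlist(m[1, c("R", "G", "B")]), img[4, 3, ],
               ignore_attr = TRUE)
  layout_out <- card_layout(data.frame(
    panel_id = c("p", "q"), refl_R = c(0.5, 0.5), refl_G = c(0.5, 0.5),
    refl_B = c(0.5, 0.5), x0 = c(3, 9), x1 = c(3, 20), y0 = c(4, 4),
    y1 = c(4, 4)))
  expect_error(extract_panel_colors(img, layout_out), "outside")
})

test_that("attenuation coefficients are recovered exactly from a noiseless series", {
  truth <- c(0.5, 0.07, 0.04)
  s <- render_card_series(water_optics(k = truth))
  m <- fit_attenuation(s)
  expect_equal(unname(m$k), truth, tolerance = 1e-10)
  # fitted surface intensities match the neutral-panel reflectances
  lay <- attr(s, "layout")
  neu <- lay[lay$neutral, ]
  expect_equal(m$surface_color[neu$panel_id, "G"], setNames(neu$refl_G, neu$panel_id),
               tolerance = 1e-8)
})

test_that("a depth-constant series fits k = 0 and ordering is preserved", {
  s <- render_card_series(water_optics(k = c(0, 0, 0)),
                          depths = c(0, 5, 10, 20))
  expect_equal(unname(fit_attenuation(s)$k), c(0, 0, 0), tolerance = 1e-12)
  # physical ordering k_R > k_G > k_B survives the fit
  s2 <- render_card_series(water_optics(k = c(0.45, 0.08, 0.05),
                                        noise_sd = 0.002), seed = 21)
  k2 <- fit_attenuation(s2)$k
  expect_true(k2["R"] > k2["G"] && k2["G"] > k2["B"])
})

test_that("noisy recovery stays within 5% for channels above the dark floor", {
  # the 11-depth measurement grid, noise sd 0.005, 20 seeds; red decays
  # below the 1/255 floor at depth so only G and B are held to 5%
  truth <- c(0.5, 0.07, 0.04)
  for (seed in 1:20) {
    s <- render_card_series(water_optics(k = truth, noise_sd = 0.005),
                            seed = seed)
    k <- fit_attenuation(s)$k
    expect_lt(abs(k["G"] - truth[2]) / truth[2], 0.05)
    expect_lt(abs(k["B"] - truth[3]) / truth[3], 0.05)
  }
})

test_that("fit guards: too few depths, dark series, dark-floor exclusion", {
  s <- render_card_series(water_optics(), depths = c(0, 10))
  expect_error(fit_attenuation(s), "3 distinct depths")
  sdark <- render_card_series(water_optics(k = c(2, 2, 2)),
                              depths = c(20, 25, 30))
  # all channels below floor at 20+ m for every panel
  expect_error(fit_attenuation(sdark))
  # red values below 1/255 are excluded and counted
  s2 <- render_card_series(water_optics(k = c(0.5, 0.07, 0.04)))
  m <- fit_attenuation(s2)
  expect_gt(m$diagnostics$n_excluded["R"], 0)
  expect_identical(unname(m$diagnostics$n_excluded["B"]), 0L)
})

test_that("channel scale prediction: closed form, knots, monotonicity", {
  s <- render_card_series(water_optics(k = c(0.5, 0.07, 0.04)))
  m <- fit_attenuation(s)
  expect_equal(unname(predict_channel_scale(m, 0)), c(1, 1, 1))
  expect_equal(unname(predict_channel_scale(m, 10)),
               c(exp(-5), exp(-0.7), exp(-0.4)), tolerance = 1e-9)
  # non-increasing in depth for k >= 0
  sc <- predict_channel_scale(m, seq(0, 25, by = 0.5))
  expect_true(all(diff(sc[, "R"]) <= 0) && all(diff(sc[, "B"]) <= 0))
  expect_error(predict_channel_scale(m, -1), "non-negative")
  # piecewise mode reproduces the measured ratio exactly at a knot
  mp <- fit_attenuation(s, mode = "piecewise")
  z <- 14.0
  got <- predict_channel_scale(mp, z)
  rt <- mp$ratio_table
  expect_equal(unname(got), unname(unlist(rt[rt$depth == z, c("R", "G", "B")])),
               tolerance = 1e-12)
  # clamped outside the measured range
  expect_equal(predict_channel_scale(mp, 40), predict_channel_scale(mp, 25.7))
})

test_that("extracted raster colors round-trip through the fit", {
  opt <- water_optics(k = c(0.5, 0.07, 0.04))
  lay <- default_card_layout()
  depths <- c(0, 3, 6, 9, 12)
  tabs <- lapply(depths, function(z)
    extract_panel_colors(render_card_image(opt, lay, depth = z), lay))
  s <- color_card_series(depths, tabs, layout = lay)
  k <- fit_attenuation(s)$k
  expect_equal(unname(k), c(0.5, 0.07, 0.04), tolerance = 1e-8)
})
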