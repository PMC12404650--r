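test_that("ambient rendering follows the Beer-Lambert rule", {
  # neutral 0.9 panel at 10 m, closed-form channel values
  lay <- card_layout(data.frame(
    panel_id = c("N", "C"), refl_R = c(0.9, 0.3), refl_G = c(0.9, 0.6),
    refl_B = c(0.9, 0.2), x0 = c(1, 11), x1 = c(5, 15),
    y0 = c(1, 1), y1 = c(5, 5)))
  opt <- water_optics(k = c(0.5, 0.07, 0.04))
  s <- render_card_series(opt, lay, depths = c(0, 10))
  surf <- s[s$depth == 0 & s$panel_id == "N", c("R", "G", "B")]
  expect_equal(unlist(surf), c(R = 0.9, G = 0.9, B = 0.9), tolerance = 1e-12)
  deep <- s[s$depth == 10 & s$panel_id == "N", c("R", "G", "B")]
  expect_equal(unlist(deep),
               c(R = 0.9 * exp(-5), G = 0.9 * exp(-0.7), B = 0.9 * exp(-0.4)),
               tolerance = 1e-12)
  # flash omits the depth term entirely
  f <- render_card_series(opt, lay, depths = c(0, 10), flash = TRUE)
  expect_equal(f[f$depth == 10, c("R", "G", "B")],
               f[f$depth == 0, c("R", "G", "B")], ignore_attr = TRUE)
})

test_that("default depth grid is the 11-depth series from 0 to 25.7 m", {
  d <- card_series_depths()
  expect_length(d, 11L)
  expect_equal(min(d), 0)
  expect_equal(max(d), 25.7)
  s <- render_card_series(water_optics())
  expect_setequal(unique(s$depth), d)
})

test_that("ambient intensity strictly decreases with depth when k > 0", {
  s <- render_card_series(water_optics(k = c(0.5, 0.07, 0.04)),
                          depths = seq(0, 20, by = 2))
  for (ch in c("R", "G", "B")) {
    m <- tapply(s[[ch]], s$depth, mean)
    expect_true(all(diff(m) < 0))
  }
})

test_that("rendering rejects bad depth inputs", {
  expect_error(render_card_series(water_optics(), depths = numeric()),
               "non-empty")
  expect_error(render_card_series(water_optics(), depths = c(0, -1)),
               "non-negative")
  expect_error(water_optics(k = c(-0.1, 0.1, 0.1)))
})

test_that("card layout enforces neutral panel and non-overlap", {
  base <- data.frame(panel_id = c("a", "b"),
                     refl_R = c(0.5, 0.2), refl_G = c(0.5, 0.3),
                     refl_B = c(0.5, 0.4),
                     x0 = c(1, 11), x1 = c(5, 15), y0 = c(1, 1), y1 = c(5, 5))
  expect_s3_class(card_layout(base), "card_layout")
  bad <- base; bad$x0[2] <- 3
  expect_error(card_layout(bad), "overlap")
  nochrome <- base; nochrome[1, c("refl_R", "refl_G", "refl_B")] <- c(0.1, 0.5, 0.2)
  expect_error(card_layout(nochrome), "neutral")
  expect_error(card_layout(base[1, ]), "at least 2")
})

test_that("encounter counts are Poisson with mean rate x exposure", {
  # 0.8 per hour over 38.2 h: lambda = 30.56, 2000 replicates
  set.seed(101)
  counts <- replicate(2000, cuttleoptics:::sample_encounter_counts(0.8, 38.2))
  lam <- 0.8 * 38.2
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / 2000))
  # variance within 4 SE (Poisson: var(s^2) ~ (lambda + 2 lambda^2)/n)
  expect_lt(abs(var(counts) - lam), 4 * sqrt((lam + 2 * lam^2) / 2000))
})

test_that("zero true rate yields zero sightings", {
  st <- default_strata(); st$rate <- 0
  sim <- simulate_dive_logs(effort_spec(strata = st, seed = 3))
  expect_identical(nrow(sim$sightings), 0L)
})

test_that("dive-log simulation is bit-identical under the same seed", {
  a <- simulate_dive_logs(effort_spec(seed = 11))
  b <- simulate_dive_logs(effort_spec(seed = 11))
  expect_identical(a, b)
  c <- simulate_dive_logs(effort_spec(seed = 12))
  expect_false(identical(a$logs$depth_m, c$logs$depth_m))
})

test_that("simulated logs respect stratum structure", {
  sim <- simulate_dive_logs(effort_spec(seed = 4))
  st <- default_strata()
  for (i in seq_len(nrow(st))) {
    sel <- sim$logs$habitat == st$habitat[i] & sim$logs$diel == st$diel[i]
    expect_true(all(sim$logs$depth_m[sel] >= st$depth_min[i] - 1e-9))
    expect_true(all(sim$logs$depth_m[sel] <= st$depth_max[i] + 1e-9))
  }
  # sightings only in strata with positive rate (night reef by default)
  expect_true(all(sim$sightings$habitat == "reef"))
  expect_true(all(sim$sightings$diel == "night"))
})

test_that("laser scene places dot centroids at the stated separation", {
  img <- render_laser_scene(mm_per_px = 0.2, dot_separation_mm = 100)
  cent <- attr(img, "centers")
  expect_equal(sqrt(sum((cent[1, ] - cent[2, ])^2)), 500, tolerance = 1e-12)
  expect_error(render_laser_scene(mm_per_px = 0.01, dot_separation_mm = 100,
                                  width = 200, height = 100),
               "outside the image")
})
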