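# Generators: stated expected values, determinism, and input validation.

test_that("survival table reproduces the LQ expectation and is seed-stable", {
  d <- generate_survival_table(0.173, 0.032, doses = c(0, 2, 4), noise = FALSE)
  sf4 <- d$surviving_fraction[d$dose_Gy == 4][1]
  expect_equal(sf4, exp(-0.173 * 4 - 0.032 * 16), tolerance = 1e-12)
  expect_equal(round(sf4, 3), 0.300)
  expect_equal(unique(d$surviving_fraction[d$dose_Gy == 0]), 1.0)

  d2 <- generate_survival_table(0.332, 0, doses = c(0, 2), noise = FALSE)
  expect_equal(d2$surviving_fraction[d2$dose_Gy == 2][1], exp(-0.664),
               tolerance = 1e-12)

  a <- generate_survival_table(0.3, 0.01, seed = 42)
  b <- generate_survival_table(0.3, 0.01, seed = 42)
  expect_identical(a, b)
  expect_error(generate_survival_table(NaN, 0.03), "finite")
  expect_error(generate_survival_table(0.2, 0.03, doses = -1), ">= 0")
  expect_error(generate_survival_table(0.2, 0.03, plating_efficiency = 0), "0, 1")
})

test_that("nuclear areas follow the requested mean/CV and degenerate cleanly", {
  expect_equal(generate_nuclear_areas(1000, 90, 0), rep(90, 1000))
  a <- generate_nuclear_areas(1e5, 90, 0.3, seed = 1)
  expect_lt(abs(mean(a) / 90 - 1), 0.01)
  expect_lt(abs(sd(a) / mean(a) - 0.3), 0.01)
  expect_true(all(a > 0))
  # default calibration: fluence x mean area gives the transport-code hit mean
  a2 <- generate_nuclear_areas(1239, seed = 5)
  expect_equal(3.8e6 * 89.5 * 1e-8, 3.401, tolerance = 1e-3)
  expect_error(generate_nuclear_areas(0, 90, 0.3), ">= 1")
  expect_error(generate_nuclear_areas(10, -5, 0.3), "> 0")
})

test_that("FNTD image generator obeys fluence scaling and placement", {
  blank <- generate_fntd_image(0, field = c(30, 30), seed = 1)
  expect_equal(nrow(blank$truth), 0)
  expect_equal(nrow(detect_track_spots(blank)), 0)

  # expected spot count: unit conversion um^2 -> cm^2
  f <- generate_fntd_image(3.8e6, noise = FALSE, seed = 2)
  expect_equal(nrow(f$truth), round(3.8e6 * (212.55e-4)^2))
  expect_equal(round(3.8e6 * (212.55e-4)^2), 1717)

  # 10 well-separated spots -> 10 local maxima survive detection
  px <- 0.118
  img <- matrix(0, 200, 200)
  pos <- expand.grid(x = c(30, 70, 110, 150, 190) - 10, y = c(60, 140))
  img <- ionbeamqc:::render_blobs(img, pos$x, pos$y, rep(50, 10), 0.3 / px)
  s <- detect_track_spots(img, pixel_size = px, dwell_time = 7.2)
  expect_equal(nrow(s), 10)

  expect_error(generate_fntd_image(-1), ">= 0")
  expect_error(generate_fntd_image(1e6, field = c(0.05, 0.05), pixel_size = 0.2),
               "smaller than one pixel")
})

test_that("cell layer honours translation, rates and placement limits", {
  tracks <- data.frame(x_um = c(20, 40, 60), y_um = c(30, 30, 30),
                       class = "primary", rate_MHz = 7, peak_counts = 50)
  cl <- generate_cell_layer(areas = rep(100, 3), field = c(80, 60),
                            tracks = tracks, foci_per_track = 1,
                            focus_jitter = 0, translation = c(3, 0),
                            background_foci_rate = 0, noise = FALSE, seed = 1)
  tf <- cl$truth$foci
  if (nrow(tf) > 0) {
    src <- tracks[tf$source_track, ]
    expect_equal(tf$x_um - src$x_um, rep(3, nrow(tf)), tolerance = 1e-9)
    expect_equal(tf$y_um - src$y_um, rep(0, nrow(tf)), tolerance = 1e-9)
  }
  # no tracks, no background -> focus channel empty
  cl0 <- generate_cell_layer(areas = rep(90, 2), field = c(50, 50), tracks = NULL,
                             background_foci_rate = 0, noise = FALSE, seed = 2)
  expect_equal(nrow(cl0$truth$foci), 0)
  expect_equal(max(cl0$foci), 0)
  # unplaceable request reported
  expect_error(
    generate_cell_layer(50, field = c(30, 30), tracks = NULL, seed = 3,
                        max_retries = 50),
    "without overlap")
})

test_that("time course follows the residual-plus-decay law", {
  tc0 <- generate_timecourse(20, 0.153, halflife = 6, timepoints = 0,
                             background = 0, noise = FALSE)
  expect_equal(unique(tc0$foci), 20)
  tc1 <- generate_timecourse(20, 0, halflife = 6, timepoints = 6,
                             background = 0, noise = FALSE)
  expect_equal(unique(tc1$foci), 10)
  # late-time expectation converges to the residual fraction
  tc2 <- generate_timecourse(20, 0.153, halflife = 6, timepoints = 1000,
                             background = 0, noise = FALSE)
  expect_equal(unique(tc2$foci) / 20, 0.153, tolerance = 1e-9)
  expect_error(generate_timecourse(20, 1.2), "0, 1")
  expect_error(generate_timecourse(20, 0.1, timepoints = c(-1, 2)), "negative")
})

test_that("generators are bit-reproducible for a fixed seed", {
  f1 <- generate_fntd_image(1e6, field = c(50, 50), seed = 9)
  f2 <- generate_fntd_image(1e6, field = c(50, 50), seed = 9)
  expect_identical(f1$image, f2$image)
  c1 <- generate_cell_layer(3, field = c(60, 60), tracks = f1$truth, seed = 9)
  c2 <- generate_cell_layer(3, field = c(60, 60), tracks = f2$truth, seed = 9)
  expect_identical(c1$nuclear, c2$nuclear)
  expect_identical(c1$foci, c2$foci)
  t1 <- generate_timecourse(15, 0.1, seed = 9)
  t2 <- generate_timecourse(15, 0.1, seed = 9)
  expect_identical(t1, t2)
})
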