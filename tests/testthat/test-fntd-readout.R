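# FNTD spot detection, count-rate conversion and classification.
# Paper-scale recall/precision/accuracy live in test-acceptance.R; here the
# fields are small for speed.

test_that("blank and sub-threshold images yield no spots", {
  expect_equal(nrow(detect_track_spots(matrix(0, 64, 64), pixel_size = 0.1)), 0)
  img <- matrix(0, 64, 64); img[32, 32] <- 5
  expect_warning(
    s <- detect_track_spots(img, pixel_size = 0.1, detection_threshold = 100),
    "threshold above")
  expect_equal(nrow(s), 0)
})

test_that("noise-free well-separated spots are recovered exactly", {
  px <- 0.118
  img <- matrix(0, 256, 256)
  pos <- expand.grid(x = c(40, 120, 200), y = c(60, 190))
  amp <- seq(30, 55, length.out = 6)
  img <- ionbeamqc:::render_blobs(img, pos$x, pos$y, amp, 0.3 / px)
  s <- detect_track_spots(img, pixel_size = px, dwell_time = 7.2)
  expect_equal(nrow(s), 6)
  # centroids within 0.5 px, amplitudes round-trip the rendered peaks
  for (r in seq_len(6)) {
    d <- sqrt((s$x_px - pos$x)^2 + (s$y_px - pos$y)^2)
    expect_lt(min(d), 0.5)
  }
  expect_equal(sort(s$amplitude), sort(amp), tolerance = 0.02)
  expect_equal(sort(s$count_rate_MHz), sort(amp) / 7.2, tolerance = 0.02)
})

test_that("detection is equivariant under whole-pixel shifts", {
  px <- 0.2
  img <- matrix(0, 128, 128)
  img <- ionbeamqc:::render_blobs(img, c(40, 80, 60), c(40, 90, 64),
                                  c(40, 50, 45), 0.3 / px)
  sh <- 7L
  shifted <- matrix(0, 128, 128)
  shifted[, (sh + 1):128] <- img[, 1:(128 - sh)]
  s0 <- detect_track_spots(img, pixel_size = px)
  s1 <- detect_track_spots(shifted, pixel_size = px)
  expect_equal(nrow(s0), nrow(s1))
  expect_equal(sort(s1$x_px), sort(s0$x_px) + sh, tolerance = 1e-6)
  expect_equal(sort(s1$y_px), sort(s0$y_px), tolerance = 1e-6)
})

test_that("count-rate conversion is plain division with validation", {
  expect_equal(intensity_to_count_rate(38, 7.2), 5.278, tolerance = 1e-3)
  expect_equal(intensity_to_count_rate(0, 3), 0)
  expect_equal(intensity_to_count_rate(31.7, 7.2), 4.403, tolerance = 1e-3)
  expect_error(intensity_to_count_rate(10, 0), "> 0")
  expect_error(intensity_to_count_rate(-1, 2), ">= 0")
})

test_that("classification thresholds behave and are monotone", {
  s <- data.frame(count_rate_MHz = c(6.0, 4.0, 5.3, 4.4))
  expect_equal(classify_spots(s, 5.3)$class,
               c("primary", "fragment", "primary", "fragment"))
  expect_equal(classify_spots(s, 4.4)$class,
               c("primary", "fragment", "primary", "primary"))
  expect_equal(classify_spots(s, 1e-9)$class, rep("primary", 4))
  # raising the threshold never increases the primary count
  thr <- seq(0.5, 8, by = 0.5)
  counts <- vapply(thr, function(t) attr(classify_spots(s, t), "n_primary"),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(classify_spots(s, 0), "> 0")
  expect_error(classify_spots(data.frame(count_rate_MHz = NA_real_), 5), "finite")
})

test_that("histogram threshold separates bimodal rates and warns when unimodal", {
  set.seed(21)
  for (i in 1:5) {
    x <- c(rnorm(200, 2, 0.4), rnorm(200, 6, 0.4))
    thr <- histogram_threshold(x)
    expect_gt(thr, 3.2); expect_lt(thr, 4.8)
  }
  # unbalanced carbon-like mixture: threshold near the 5.3 MHz operating value
  for (i in 1:5) {
    frag <- runif(1500) < 0.08
    x <- ifelse(frag, rnorm(1500, 3.8, 0.6), rnorm(1500, 6.8, 0.6))
    thr <- histogram_threshold(x)
    expect_lt(abs(thr - 5.3), 0.5)
  }
  expect_warning(histogram_threshold(rnorm(300, 5, 0.4)), "unimodal")
  expect_error(histogram_threshold(rnorm(10)), ">= 20")
})

test_that("noise-free generator image round-trips detection and classes", {
  f <- generate_fntd_image(1.2e6, field = c(60, 60), noise = FALSE, seed = 13)
  s <- detect_track_spots(f)
  met <- detection_metrics(s, f$truth, limit = 2 * f$pixel_size)
  expect_equal(met$recall, 1)
  expect_equal(met$precision, 1)
  cs <- classify_spots(s, 5.3)
  # classes recovered perfectly: noise-free rates sit at the class means
  nt <- apply(outer(cs$x_um, f$truth$x_um, "-")^2 +
              outer(cs$y_um, f$truth$y_um, "-")^2, 1, which.min)
  expect_equal(cs$class, f$truth$class[nt])
  expect_equal(median(cs$count_rate_MHz[cs$class == "primary"]), 6.8,
               tolerance = 0.02)
})
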