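# Detector-to-cell-layer registration and track/focus pairing.

test_that("noise-free translations are recovered exactly", {
  set.seed(3)
  sp <- data.frame(x_um = runif(20, 5, 95), y_um = runif(20, 5, 95))
  for (shift in list(c(3, 0), c(-2.5, 4.1), c(0.123456789, -6))) {
    fo <- data.frame(x_um = sp$x_um + shift[1], y_um = sp$y_um + shift[2])
    tr <- estimate_translation(sp, fo)
    expect_lt(abs(tr$dx - shift[1]), 1e-9)
    expect_lt(abs(tr$dy - shift[2]), 1e-9)
    expect_true(tr$reliable)
  }
  expect_error(estimate_translation(sp[1:3, ], sp), ">= 5")
})

test_that("estimation is robust to jitter and outliers", {
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    sp <- data.frame(x_um = runif(50, 0, 100), y_um = runif(50, 0, 100))
    fo <- data.frame(x_um = sp$x_um + 2.1 + rnorm(50, 0, 0.3),
                     y_um = sp$y_um - 2.2 + rnorm(50, 0, 0.3))
    out <- sample(50, 10)  # 20% of foci unrelated to any track
    fo$x_um[out] <- runif(10, 0, 100)
    fo$y_um[out] <- runif(10, 0, 100)
    tr <- estimate_translation(sp, fo)
    max(abs(tr$dx - 2.1), abs(tr$dy + 2.2))
  }, numeric(1))
  expect_lt(max(errs), 0.15)
})

test_that("unrelated point sets are flagged unreliable", {
  set.seed(8)
  sp <- data.frame(x_um = runif(60, 0, 200), y_um = runif(60, 0, 200))
  fo <- data.frame(x_um = runif(60, 0, 200), y_um = runif(60, 0, 200))
  tr <- estimate_translation(sp, fo)
  expect_false(tr$reliable)
})

test_that("pairing is one-to-one, bounded and symmetric", {
  set.seed(5)
  sp <- data.frame(x_um = runif(10, 5, 95), y_um = runif(10, 5, 95))
  fo <- data.frame(x_um = sp$x_um[1:8] + 3, y_um = sp$y_um[1:8])
  mm <- match_tracks_to_foci(sp, fo, c(3, 0))
  expect_equal(nrow(mm$pairs), 8)
  expect_equal(length(mm$unmatched_spots), 2)
  expect_equal(length(mm$unmatched_foci), 0)
  expect_lt(max(mm$pairs$separation_um), 1e-9)
  expect_equal(anyDuplicated(mm$pairs$spot), 0)
  expect_equal(anyDuplicated(mm$pairs$focus), 0)
  # zero match radius -> no pairs
  mm0 <- match_tracks_to_foci(sp, fo, c(3, 0), max_match_distance = 0)
  expect_equal(nrow(mm0$pairs), 0)
  # exchanging roles with the inverse translation gives the same pairs
  rev <- match_tracks_to_foci(fo, sp, c(-3, 0))
  expect_equal(nrow(rev$pairs), 8)
  ab <- mm$pairs[order(mm$pairs$spot), c("spot", "focus")]
  ba <- rev$pairs[order(rev$pairs$focus), c("focus", "spot")]
  expect_equal(unname(as.matrix(ab)), unname(as.matrix(ba)))
  expect_error(match_tracks_to_foci(sp, fo, c(NA, 0)), "finite")
})

test_that("pair separations on generator data stay within the jitter scale", {
  f <- generate_fntd_image(2.5e6, field = c(90, 90), seed = 15)
  cl <- generate_cell_layer(10, field = c(90, 90), tracks = f$truth,
                            foci_per_track = 1, focus_jitter = 0.3,
                            translation = c(3, 0), background_foci_rate = 0,
                            seed = 16)
  tf <- cl$truth$foci
  sp <- f$truth[unique(tf$source_track[tf$source_track > 0]), ]
  tr <- estimate_translation(sp, tf)
  expect_lt(abs(tr$dx - 3), 0.2)
  expect_lt(abs(tr$dy - 0), 0.2)
  mm <- match_tracks_to_foci(sp, tf, tr)
  expect_gte(mean(mm$pairs$separation_um <= 3 * 0.3), 0.95)
})
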