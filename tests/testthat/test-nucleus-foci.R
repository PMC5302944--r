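# Nucleus segmentation, focus quantification, QC, kinetics, correlation.

test_that("segmentation recovers analytic disc areas within 5%", {
  cl <- generate_cell_layer(areas = 100, field = c(40, 40), tracks = NULL,
                            noise = FALSE, seed = 1)
  seg <- segment_nuclei(cl)
  expect_equal(nrow(seg$nuclei), 1)
  expect_lt(abs(seg$nuclei$area_um2 / 100 - 1), 0.05)
  # random placements, noisy rendering
  cl2 <- generate_cell_layer(areas = c(60, 90, 130), field = c(70, 70),
                             tracks = NULL, seed = 2)
  seg2 <- segment_nuclei(cl2)
  expect_equal(nrow(seg2$nuclei), 3)
  expect_equal(sort(seg2$nuclei$area_um2), sort(cl2$truth$nuclei$area_um2),
               tolerance = 0.05)
})

test_that("watershed splits touching nuclei and blank stacks warn", {
  img <- matrix(0, 200, 200)
  m1 <- ionbeamqc:::ellipse_mask(200, 200, 80, 100, 30, 30)
  m2 <- ionbeamqc:::ellipse_mask(200, 200, 134, 100, 30, 30)  # 20% overlap
  img[m1 | m2] <- 100
  seg <- segment_nuclei(img, pixel_size = 0.322, rolling_ball_radius = 60)
  expect_equal(nrow(seg$nuclei), 2)
  expect_warning(empty <- segment_nuclei(matrix(0, 64, 64), pixel_size = 0.3),
                 "no nuclei")
  expect_equal(nrow(empty$nuclei), 0)
  expect_error(segment_nuclei(array(0, c(0, 0, 0)), pixel_size = 0.3), "empty")
})

test_that("foci are counted exactly in clean conditions", {
  cl <- generate_cell_layer(areas = 120, field = c(30, 30), tracks = NULL,
                            background_foci_rate = 5, seed = 9)
  seg <- segment_nuclei(cl)
  fx <- detect_foci(cl, seg)
  expect_equal(nrow(fx), nrow(cl$truth$foci))
  expect_true(all(fx$nucleus == 1))
  # zero-signal channel
  cl0 <- generate_cell_layer(areas = c(90, 90), field = c(50, 50), tracks = NULL,
                             background_foci_rate = 0, seed = 4)
  s0 <- segment_nuclei(cl0)
  expect_equal(nrow(detect_foci(cl0, s0)), 0)
  expect_error(detect_foci(array(0, c(10, 10, 3)), seg), "different shapes")
})

test_that("measured focus area scales with the generated focus size", {
  meas <- function(fr, seed) {
    cl <- generate_cell_layer(areas = rep(110, 6), field = c(60, 60),
                              tracks = NULL, background_foci_rate = 1e-9,
                              seed = seed)
    px <- cl$pixel_size
    ctr <- cl$truth$nuclei
    blob <- matrix(0, dim(cl$foci)[1], dim(cl$foci)[2])
    blob <- ionbeamqc:::render_blobs(blob, ctr$x_um / px - 0.5,
                                     ctr$y_um / px - 0.5,
                                     rep(80, nrow(ctr)), fr / px)
    for (z in 1:5) cl$foci[, , z] <- pmax(cl$foci[, , z] +
                                            blob * exp(-((z - 3)^2) / 2), 0)
    seg <- segment_nuclei(cl)
    mean(detect_foci(cl, seg)$area_um2)
  }
  ratios <- vapply(1:3, function(s) meas(0.8, s) / meas(0.4, s), numeric(1))
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})

test_that("QC flags pan-stained and apoptotic nuclei, keeps normal ones", {
  cl <- generate_cell_layer(areas = c(100, 100), field = c(60, 30), tracks = NULL,
                            background_foci_rate = 3, seed = 6)
  seg <- segment_nuclei(cl)
  # make nucleus 1 uniformly bright in the focus channel (pan staining)
  k <- seg$nuclei$nucleus[1]
  for (z in 1:5) {
    pl <- cl$foci[, , z]
    pl[seg$label == k] <- 70
    cl$foci[, , z] <- pl
  }
  seg <- qc_filter_nuclei(seg, cl)
  tab <- seg$nuclei
  expect_true(grepl("pan_stained", tab$qc_flags[tab$nucleus == k]))
  expect_false(tab$qc_pass[tab$nucleus == k])
  expect_true(any(tab$qc_pass))
  # tiny ragged nucleus is apoptotic by the area proxy
  cl2 <- generate_cell_layer(areas = c(20, 100), field = c(60, 30), tracks = NULL,
                             seed = 7)
  seg2 <- qc_filter_nuclei(segment_nuclei(cl2, min_area = 10), cl2)
  small <- which.min(seg2$nuclei$area_um2)
  expect_true(grepl("apoptotic", seg2$nuclei$qc_flags[small]))
})

test_that("focus statistics subtract background with a floor", {
  nuc <- structure(list(nuclei = data.frame(nucleus = 1:25, x_um = 0, y_um = 0,
                                            area_um2 = 90, n_pixels = 900,
                                            solidity = 1, on_border = FALSE),
                        label = matrix(0L, 1, 1), pixel_size = 0.3),
                   class = "nucleus_set")
  foci <- data.frame(nucleus = rep(1:25, length.out = 129),
                     area_um2 = 0.5)  # raw mean 5.16
  st <- foci_statistics(foci, nuc, background_per_nucleus = 0.16)
  expect_equal(st$mean_foci, 5.0)
  expect_false(st$floored)
  st0 <- foci_statistics(foci, nuc, background_per_nucleus = 0)
  expect_equal(st0$mean_foci, st0$mean_foci_raw)
  low <- data.frame(nucleus = c(1, 13), area_um2 = 0.5)  # raw mean 0.08
  stf <- foci_statistics(low, nuc, background_per_nucleus = 0.16)
  expect_equal(stf$mean_foci, 0)
  expect_true(stf$floored)
})

test_that("repair kinetics reports residual fractions against baseline", {
  flat <- data.frame(time_h = rep(c(0.5, 24, 72), each = 10),
                     nucleus = rep(1:10, 3), foci = 8)
  rk <- repair_kinetics(flat, background = 0)
  expect_equal(rk$residual_fraction, c(1, 1, 1))
  # hand-derived ratio: 20 -> 3.06 at 72 h is a 15.3% residual
  two <- data.frame(time_h = rep(c(0.5, 72), each = 5), nucleus = rep(1:5, 2),
                    foci = rep(c(20, 3.06), each = 5))
  rk2 <- repair_kinetics(two, background = 0)
  expect_equal(rk2$residual_fraction[2], 0.153, tolerance = 1e-9)
  expect_error(repair_kinetics(flat[flat$time_h > 1, ], background = 0),
               "baseline")
  # generator round-trip at the photon-like residual fraction
  est <- vapply(1:20, function(s) {
    tc <- generate_timecourse(20, 0.023, timepoints = c(0.5, 72),
                              n_nuclei = 150, seed = s)
    rk <- repair_kinetics(tc)
    rk$residual_fraction[rk$time_h == 72]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.023), 0.01)
})

test_that("survival correlation flags degeneracy and finds perfect lines", {
  m <- c(2, 4, 6, 8)
  r <- correlate_with_survival(m, 0.9 - 0.05 * m)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_lt(r$slope, 0)
  expect_error(correlate_with_survival(c(3, 3, 3), c(0.1, 0.5, 0.9)),
               "constant")
  expect_error(correlate_with_survival(c(1, 2), c(0.1, 0.2)), ">= 3")
})
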