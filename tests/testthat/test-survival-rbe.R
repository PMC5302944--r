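# Survival fitting, isosurvival inversion, model selection and RBE.

test_that("noise-free round-trips recover generating parameters exactly", {
  d <- generate_survival_table(0.173, 0.032, doses = c(0, 1, 2, 4, 6, 8),
                               noise = FALSE)
  f <- fit_lq(d)
  expect_equal(f$alpha, 0.173, tolerance = 1e-6)
  expect_equal(f$beta, 0.032, tolerance = 1e-6)
  for (a in c(0.332, 1.041)) {
    fl <- fit_linear(generate_survival_table(a, 0, noise = FALSE))
    expect_equal(fl$alpha, a, tolerance = 1e-6)
  }
})

test_that("degenerate and under-determined inputs are handled", {
  ones <- survival_dataset(dose_Gy = c(0, 1, 2, 4),
                           surviving_fraction = c(1, 1, 1, 1))
  f <- fit_lq(ones)
  expect_equal(f$alpha, 0)
  expect_equal(f$beta, 0)
  const <- survival_dataset(dose_Gy = c(0, 1, 2, 4),
                            surviving_fraction = c(0.5, 0.5, 0.5, 0.5))
  expect_error(fit_lq(const), "degenerate")
  two <- survival_dataset(dose_Gy = c(0, 1, 2),
                          surviving_fraction = c(1, 0.8, 0.6))
  expect_error(fit_lq(two), "distinct nonzero doses")
  expect_warning(sel <- select_model(two), "unfittable")
  expect_equal(sel$selection, "L")
})

test_that("SF = 0 wells are replaced by half a colony with a warning", {
  d <- generate_survival_table(0.8, 0, doses = c(0, 1, 2, 6), noise = FALSE)
  d$surviving_fraction[d$dose_Gy == 6] <- 0
  expect_warning(f <- fit_linear(d), "0.5")
  expect_gt(f$alpha, 0)
})

test_that("dose_at_survival matches closed forms and a bisection oracle", {
  expect_equal(dose_at_survival(survival_fit(0.173, 0.032), 0.30), 4.00,
               tolerance = 1e-3)
  expect_equal(dose_at_survival(survival_fit(0.332), 0.30),
               -log(0.30) / 0.332, tolerance = 1e-12)
  expect_equal(dose_at_survival(survival_fit(1, 0), exp(-1)), 1, tolerance = 1e-12)
  # pure-quadratic edge case
  expect_equal(dose_at_survival(survival_fit(0, 0.05), 0.5),
               sqrt(-log(0.5) / 0.05), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:200) {
    a <- runif(1, 0.05, 1.2); b <- runif(1, 0, 0.08); lv <- runif(1, 0.05, 0.9)
    expect_equal(dose_at_survival(survival_fit(a, b), lv),
                 bisect_dose(a, b, lv), tolerance = 1e-9)
  }
  expect_error(dose_at_survival(survival_fit(0.2), 1), "0, 1")
  expect_error(dose_at_survival(survival_fit(0.2), 0), "0, 1")
})

test_that("RBE is the isosurvival dose ratio with sane propagation", {
  ph <- survival_fit(0.173, 0.032, 0.026, 0.004)
  expect_equal(rbe_at_survival(ph, ph, 0.3)$rbe, 1, tolerance = 1e-12)
  r <- rbe_at_survival(ph, survival_fit(0.332, 0, 0.011), 0.3)
  expect_equal(r$rbe, r$reference_dose / r$test_dose, tolerance = 1e-12)
  expect_gt(r$rbe_se, 0)
  # strictly increasing in the test alpha (the RBE-LET ordering)
  alphas <- c(0.332, 0.521, 0.809, 1.041)
  rbes <- vapply(alphas, function(a)
    rbe_at_survival(ph, survival_fit(a), 0.3)$rbe, numeric(1))
  expect_true(all(diff(rbes) > 0))
})

test_that("model selection keeps beta only when it earns its keep", {
  # beta = 0 truth: L selected in >= 90% of seeds (F-test at 5% + boundary)
  sel <- vapply(1:60, function(s)
    select_model(generate_survival_table(0.332, 0, seed = s))$selection,
    character(1))
  expect_gte(mean(sel == "L"), 0.9)
  # strong curvature, low noise: LQ selected
  sel2 <- vapply(1:20, function(s)
    select_model(generate_survival_table(0.1, 0.05, doses = c(0, 1, 2, 4, 6, 8),
                                         cells_seeded = 2000,
                                         seed = s))$selection, character(1))
  expect_gte(mean(sel2 == "LQ"), 0.9)
})

test_that("boundary solutions are flagged instead of going negative", {
  # concave-up noise pattern that would push beta below zero
  d <- survival_dataset(dose_Gy = c(0, 1, 2, 4, 4),
                        surviving_fraction = c(1, 0.55, 0.38, 0.23, 0.25))
  f <- fit_lq(d)
  expect_gte(f$beta, 0)
  if (f$boundary) expect_equal(f$beta, 0)
})
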