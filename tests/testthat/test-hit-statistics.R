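# Mixed-Poisson intranuclear hit model.

test_that("expected hits applies the unit conversion exactly once", {
  expect_equal(expected_hits(100, 3.8e6), 3.8, tolerance = 1e-12)
  expect_equal(expected_hits(123, 0), 0)
  expect_equal(expected_hits(89.5, 2.8e6), 2.506, tolerance = 1e-3)
  expect_error(expected_hits(-1, 1e6), ">= 0")
  expect_error(expected_hits(10, -1), ">= 0")
})

test_that("hit distribution reduces to the right closed forms", {
  # single area: plain Poisson
  m1 <- hit_model(3.8e6, 100)
  h1 <- hit_distribution(m1)
  expect_equal(h1$p[1], exp(-3.8), tolerance = 1e-12)
  # two areas: hand-computed mean
  m2 <- hit_model(2.8e6, c(50, 150))
  h2 <- hit_distribution(m2)
  expect_equal(h2$mean, 2.8, tolerance = 1e-12)
  # zero fluence: all mass at zero
  h0 <- hit_distribution(hit_model(0, c(80, 90, 100)))
  expect_equal(h0$p[1], 1)
  expect_error(hit_model(1e6, numeric(0)), "non-empty")
})

test_that("mixture satisfies normalisation and moment identities", {
  areas <- generate_nuclear_areas(500, 89.5, 0.3, seed = 3)
  m <- hit_model(3.8e6, areas)
  h <- hit_distribution(m)
  expect_gte(sum(h$p), 1 - 1e-9)
  expect_lte(sum(h$p), 1 + 1e-12)
  phi <- 3.8e6 * 1e-8
  expect_equal(h$mean, phi * mean(areas), tolerance = 1e-6)
  n <- length(areas)
  pop_var <- var(areas) * (n - 1) / n
  expect_equal(h$variance, phi * mean(areas) + phi^2 * pop_var, tolerance = 1e-6)
  # distribution moments agree with the stated identities
  mu_k <- sum(h$k * h$p)
  var_k <- sum(h$k^2 * h$p) - mu_k^2
  expect_equal(mu_k, h$mean, tolerance = 1e-6)
  expect_equal(var_k, h$variance, tolerance = 1e-5)
})

test_that("mixture pmf matches an independent log-space summation oracle", {
  # oracle: explicit exp(k log l - l - lgamma(k+1)) summed over areas
  oracle <- function(k, lambdas)
    mean(exp(k * log(lambdas) - lambdas - lgamma(k + 1)))
  areas <- c(60, 95, 140)
  m <- hit_model(3.0e6, areas)
  h <- hit_distribution(m)
  for (k in 1:12)
    expect_equal(h$p[k + 1], oracle(k, m$lambda), tolerance = 1e-12)
})

test_that("sampler converges to the analytic law", {
  areas <- generate_nuclear_areas(1e5, 89.5, 0.3, seed = 4)
  m <- hit_model(3.8e6, areas)
  h <- hit_distribution(m)
  x <- sample_hits(m, seed = 5)
  expect_identical(x, sample_hits(m, seed = 5))
  expect_lt(abs(mean(x) - h$mean), 0.02)
  emp <- tabulate(x + 1L, nbins = length(h$k)) / length(x)
  expect_lt(sum(abs(emp - h$p)) / 2, 0.01)  # total-variation distance
  expect_true(all(sample_hits(hit_model(0, rep(100, 50)), seed = 1) == 0))
})

test_that("histogram comparison reports like-for-like means and calibrated tests", {
  areas <- generate_nuclear_areas(500, 89.5, 0.3, seed = 6)
  m <- hit_model(3.8e6, areas)
  h <- hit_distribution(m)
  obs <- sample_hits(m, seed = 7)
  cmp <- compare_hit_histograms(obs, h)
  expect_equal(cmp$n, 500)
  expect_equal(cmp$observed_mean, mean(obs))
  expect_equal(cmp$model_sem, h$sd / sqrt(500), tolerance = 1e-12)
  expect_gt(cmp$p_value, 0.01)
  # gross shift is detected with power
  cmp_shift <- compare_hit_histograms(obs + 2L, h)
  expect_lt(cmp_shift$p_value, 1e-3)
  # counts-per-k input form
  tab <- table(obs)
  cmp2 <- compare_hit_histograms(setNames(as.numeric(tab), names(tab)), h)
  expect_equal(cmp2$chisq, cmp$chisq, tolerance = 1e-9)
  expect_error(compare_hit_histograms(integer(0), h), "empty")
})
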