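#' Expected intranuclear hits for one nucleus
#'
#' The mean number of primary particles traversing a nucleus of a given
#' cross-sectional area under a uniform fluence:
#' `fluence [/cm^2] x area [um^2] x 1e-8 [cm^2/um^2]`.
#'
#' @param area Nuclear cross-sectional area, um^2 (>= 0).
#' @param fluence Particle fluence, particles/cm^2 (>= 0).
#' @return Expected hit count (dimensionless), vectorised over `area`.
#' @examples
#' expected_hits(100, 3.8e6)  # 3.8
#' @export
expected_hits <- function(area, fluence) {
  if (any(!is.finite(area)) || any(area < 0)) stop("'area' must be >= 0", call. = FALSE)
  if (!is.finite(fluence) || fluence < 0) stop("'fluence' must be >= 0", call. = FALSE)
  fluence * area * 1e-8
}

#' Build an intranuclear hit model
#'
#' Couples a particle fluence with a sample of nuclear cross-sectional
#' areas; each nucleus i receives hits as Poisson(lambda_i) with
#' lambda_i = fluence x area_i. The population hit-count law is the
#' equal-weight Poisson mixture over the area sample.
#'
#' @param fluence Particle fluence, particles/cm^2.
#' @param areas Nuclear areas, um^2 (non-empty).
#' @return A `hit_model`: list with `fluence`, `areas`, `lambda`.
#' @examples
#' m <- hit_model(3.8e6, generate_nuclear_areas(1239, seed = 1))
#' mean(m$lambda)
#' @export
hit_model <- function(fluence, areas) {
  if (length(areas) == 0) stop("'areas' must be non-empty", call. = FALSE)
  lambda <- expected_hits(areas, fluence)
  structure(list(fluence = fluence, areas = as.numeric(areas), lambda = lambda),
            class = "hit_model")
}

#' Analytic hit-count distribution
#'
#' The probability of k = 0..k_max hits per nucleus under the mixed
#' Poisson model: `P(k) = mean_i dpois(k, lambda_i)`. Its mean is exactly
#' `fluence x mean(areas)` and its variance
#' `fluence x E[A] + fluence^2 x Var(A)` (law of total variance).
#'
#' @param model A [hit_model()].
#' @param k_max Largest hit count tabulated, or `NULL` for the smallest
#'   K with mixture tail mass below 1e-9.
#' @return A `hit_distribution`: list with `k`, `p`, `mean`, `variance`,
#'   and `sem(n)`-ready `sd`.
#' @export
hit_distribution <- function(model, k_max = NULL) {
  stopifnot(inherits(model, "hit_model"))
  lam <- model$lambda
  if (is.null(k_max)) {
    # tail bound from the largest component; the mixture tail is no larger
    k_max <- max(10, qpois(1e-10, max(lam), lower.tail = FALSE) + 5)
    while (mean(ppois(k_max, lam, lower.tail = FALSE)) > 1e-9)
      k_max <- k_max * 2
  }
  k <- 0:k_max
  p <- vapply(k, function(kk) mean(dpois(kk, lam)), numeric(1))
  m <- mean(lam)
  v <- m + var(lam) * (length(lam) - 1) / length(lam)  # population variance
  structure(list(k = k, p = p, mean = m, variance = v, sd = sqrt(v),
                 fluence = model$fluence, n_areas = length(lam)),
            class = "hit_distribution")
}

#' Sample hit counts per nucleus
#'
#' Monte-Carlo draw k_i ~ Poisson(lambda_i), one count per nucleus in the
#' model's area sample.
#'
#' @param model A [hit_model()].
#' @param seed Integer seed.
#' @return Integer vector of hit counts.
#' @export
sample_hits <- function(model, seed = NULL) {
  stopifnot(inherits(model, "hit_model"))
  if (!is.null(seed)) set.seed(seed)
  rpois(length(model$lambda), model$lambda)
}

#' Compare a measured hit histogram with the model
#'
#' Reports observed and model means with like-for-like standard errors
#' (the model SEM uses the observed nucleus count) and a chi-square
#' goodness-of-fit statistic over bins pooled so every expected count is
#' at least `min_expected`.
#'
#' @param observed Either a vector of per-nucleus hit counts, or a named
#'   table of counts per k (`names` = k).
#' @param model A `hit_distribution`.
#' @param min_expected Minimum expected count per pooled chi-square bin.
#' @return List with `observed_mean`, `observed_sem`, `model_mean`,
#'   `model_sem`, `n`, `chisq`, `df`, `p_value`.
#' @examples
#' m <- hit_model(3.8e6, generate_nuclear_areas(300, seed = 2))
#' hd <- hit_distribution(m)
#' compare_hit_histograms(sample_hits(m, seed = 3), hd)
#' @export
compare_hit_histograms <- function(observed, model, min_expected = 5) {
  stopifnot(inherits(model, "hit_distribution"))
  if (!is.null(names(observed))) {
    k_obs <- as.integer(names(observed))
    counts <- as.numeric(observed)
    observed <- rep(k_obs, counts)
  }
  n <- length(observed)
  if (n < 1 || all(is.na(observed))) stop("empty observation vector", call. = FALSE)
  if (sum(observed) < 1 && all(model$p[1] < 1))
    stop("all-zero observation vector", call. = FALSE)
  obs_mean <- mean(observed)
  obs_sem <- sd(observed) / sqrt(n)
  model_sem <- model$sd / sqrt(n)

  k_top <- max(max(observed), max(model$k))
  obs_tab <- tabulate(observed + 1L, nbins = k_top + 1L)
  exp_p <- c(model$p, rep(0, k_top + 1 - length(model$p)))[seq_len(k_top + 1)]
  exp_tab <- n * exp_p / sum(exp_p)

  # pool adjacent bins until every expected count reaches min_expected
  pooled_o <- numeric(0); pooled_e <- numeric(0)
  acc_o <- 0; acc_e <- 0
  for (i in seq_along(exp_tab)) {
    acc_o <- acc_o + obs_tab[i]; acc_e <- acc_e + exp_tab[i]
    if (acc_e >= min_expected) {
      pooled_o <- c(pooled_o, acc_o); pooled_e <- c(pooled_e, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0 && length(pooled_e) > 0) {
    pooled_o[length(pooled_o)] <- pooled_o[length(pooled_o)] + acc_o
    pooled_e[length(pooled_e)] <- pooled_e[length(pooled_e)] + acc_e
  } else if (acc_e > 0) {
    pooled_o <- acc_o; pooled_e <- acc_e
  }
  chisq <- sum((pooled_o - pooled_e)^2 / pooled_e)
  df <- max(length(pooled_e) - 1L, 1L)
  list(observed_mean = obs_mean, observed_sem = obs_sem,
       model_mean = model$mean, model_sem = model_sem, n = n,
       chisq = chisq, df = df,
       p_value = pchisq(chisq, df, lower.tail = FALSE))
}

#' @export
print.hit_distribution <- function(x, ...) {
  cat(sprintf("Mixed-Poisson hit distribution: mean %.3f, sd %.3f (fluence %.3g /cm2, %d areas)\n",
              x$mean, x$sd, x$fluence, x$n_areas))
  invisible(x)
}
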