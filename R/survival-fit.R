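#' Construct a survival fit object directly from parameters
#'
#' Wraps known linear-quadratic (LQ) or linear (L) parameters into the
#' `survival_fit` container that [dose_at_survival()] and
#' [rbe_at_survival()] consume — useful to compute isosurvival doses and
#' RBE from published fit parameters rather than raw data.
#'
#' @param alpha Linear coefficient, 1/Gy (>= 0).
#' @param beta Quadratic coefficient, 1/Gy^2 (>= 0); 0 gives model "L".
#' @param alpha_se,beta_se Standard errors (>= 0, default 0).
#' @param cov Optional 2x2 covariance of (alpha, beta); defaults to
#'   diagonal from the standard errors.
#' @param quality Optional [beam_quality()].
#' @return A `survival_fit`.
#' @examples
#' photon <- survival_fit(0.173, 0.032)
#' dose_at_survival(photon, 0.30)
#' @export
survival_fit <- function(alpha, beta = 0, alpha_se = 0, beta_se = 0,
                         cov = NULL, quality = NULL) {
  if (!all(is.finite(c(alpha, beta, alpha_se, beta_se))))
    stop("survival_fit: parameters must be finite", call. = FALSE)
  if (alpha < 0 || beta < 0) stop("'alpha' and 'beta' must be >= 0", call. = FALSE)
  if (alpha_se < 0 || beta_se < 0) stop("standard errors must be >= 0", call. = FALSE)
  if (is.null(cov)) cov <- diag(c(alpha_se^2, beta_se^2))
  structure(list(model = if (beta > 0) "LQ" else "L",
                 alpha = alpha, alpha_se = alpha_se,
                 beta = beta, beta_se = beta_se, cov = cov,
                 rss = NA_real_, df = NA_integer_, sigma = NA_real_,
                 n = NA_integer_, boundary = FALSE, quality = quality),
            class = "survival_fit")
}

## Shared preparation: log-transform surviving fractions, replace SF = 0
## observations (no surviving colonies) by half a colony, build weights.
prepare_survival <- function(data, min_distinct) {
  df <- as.data.frame(data)
  stopifnot(all(c("dose_Gy", "surviving_fraction") %in% names(df)))
  df <- df[is.finite(df$dose_Gy), , drop = FALSE]
  zero_sf <- !is.na(df$surviving_fraction) & df$surviving_fraction <= 0
  if (any(zero_sf)) {
    cells <- attr(data, "cells_seeded"); pe <- attr(data, "plating_efficiency")
    if (!is.null(cells) && !is.null(pe)) {
      repl <- 0.5 / (cells * pe)
      warning(sprintf("%d observation(s) with SF <= 0 replaced by 0.5/(cells x PE) = %.3g",
                      sum(zero_sf), repl))
      df$surviving_fraction[zero_sf] <- repl
    } else {
      warning(sprintf("%d observation(s) with SF <= 0 dropped", sum(zero_sf)))
      df <- df[!zero_sf, , drop = FALSE]
    }
  }
  df <- df[is.finite(df$surviving_fraction), , drop = FALSE]
  nz <- unique(df$dose_Gy[df$dose_Gy > 0])
  if (length(nz) < min_distinct)
    stop(sprintf("need >= %d distinct nonzero doses, got %d",
                 min_distinct, length(nz)), call. = FALSE)
  df$y <- log(df$surviving_fraction)
  # Poisson counting noise gives Var(ln SF) ~ 1/colonies: weight by the
  # per-dose mean count when counts are available (inverse-variance
  # weighting that avoids correlating weights with individual-well noise),
  # else equal weights
  w <- rep(1, nrow(df))
  if ("colonies" %in% names(df) && all(is.finite(df$colonies)) &&
      all(df$colonies > 0))
    w <- stats::ave(df$colonies, df$dose_Gy, FUN = mean)
  df$w <- w
  df
}

finish_fit <- function(fm, model, terms, quality, boundary = FALSE) {
  cf <- coef(fm)
  # noise-free round-trips fit perfectly; summary.lm warns about that
  vc <- suppressWarnings(vcov(fm))
  alpha <- unname(cf["d1"])
  beta <- if ("d2" %in% names(cf)) unname(cf["d2"]) else 0
  cov <- matrix(0, 2, 2, dimnames = list(c("alpha", "beta"), c("alpha", "beta")))
  cov[1, 1] <- vc["d1", "d1"]
  if ("d2" %in% names(cf)) {
    cov[2, 2] <- vc["d2", "d2"]
    cov[1, 2] <- cov[2, 1] <- vc["d1", "d2"]
  }
  structure(list(model = model, alpha = alpha, alpha_se = sqrt(cov[1, 1]),
                 beta = beta, beta_se = if (model == "LQ") sqrt(cov[2, 2]) else NA_real_,
                 cov = cov,
                 rss = sum(fm$weights * fm$residuals^2),
                 df = fm$df.residual,
                 sigma = suppressWarnings(summary(fm)$sigma),
                 n = length(fm$residuals), boundary = boundary, quality = quality),
            class = "survival_fit")
}

#' Fit the linear-quadratic survival model
#'
#' Weighted least squares of ln SF against `c - alpha*D - beta*D^2`. The
#' free intercept `c` absorbs the shared normalisation error of the 0 Gy
#' control (all points in a dataset are divided by the same control mean,
#' so omitting it correlates the residuals and understates the parameter
#' errors); the survival curve itself remains `exp(-alpha*D - beta*D^2)`.
#' The model is linear in its parameters so the fit is closed-form;
#' weights are per-dose mean colony counts when counts are present (the
#' inverse variance of ln SF under Poisson counting noise), equal
#' otherwise. `beta >= 0` is enforced: a negative unconstrained estimate
#' is refit at the `beta = 0` boundary and flagged.
#'
#' @param data A `survival_dataset` (see [generate_survival_table()],
#'   [survival_dataset()]).
#' @return A `survival_fit` with parameter estimates, standard errors from
#'   the fit curvature, the (alpha, beta) covariance and residual
#'   goodness-of-fit.
#' @examples
#' d <- generate_survival_table(0.173, 0.032, noise = FALSE)
#' fit_lq(d)
#' @export
fit_lq <- function(data) {
  df <- prepare_survival(data, min_distinct = 3)
  quality <- attr(data, "quality")
  if (all(df$y == 0))
    return(structure(list(model = "LQ", alpha = 0, alpha_se = 0, beta = 0,
                          beta_se = 0, cov = matrix(0, 2, 2), rss = 0,
                          df = nrow(df) - 2L, sigma = 0, n = nrow(df),
                          boundary = FALSE, quality = quality),
                     class = "survival_fit"))
  if (length(unique(df$y)) == 1)
    stop("degenerate fit: all surviving fractions identical", call. = FALSE)
  d1 <- -df$dose_Gy; d2 <- -df$dose_Gy^2
  fm <- lm(df$y ~ 1 + d1 + d2, weights = df$w)
  if (coef(fm)["d2"] < 0) {
    fm0 <- lm(df$y ~ 1 + d1, weights = df$w)
    fit <- finish_fit(fm0, "LQ", 1, quality, boundary = TRUE)
    fit$beta <- 0; fit$beta_se <- NA_real_
    return(fit)
  }
  if (coef(fm)["d1"] < 0) {
    # alpha at its boundary: pure-quadratic fall-back, alpha fixed at 0
    fmq <- lm(df$y ~ 1 + d2, weights = df$w)
    cf <- coef(fmq); vc <- suppressWarnings(vcov(fmq))
    cov <- matrix(0, 2, 2); cov[2, 2] <- vc["d2", "d2"]
    return(structure(list(model = "LQ", alpha = 0, alpha_se = NA_real_,
                          beta = unname(cf["d2"]), beta_se = sqrt(vc["d2", "d2"]),
                          cov = cov, rss = sum(fmq$weights * fmq$residuals^2),
                          df = fmq$df.residual,
                          sigma = suppressWarnings(summary(fmq)$sigma),
                          n = nrow(df), boundary = TRUE, quality = quality),
                     class = "survival_fit"))
  }
  finish_fit(fm, "LQ", 2, quality)
}

#' Fit the linear survival model
#'
#' As [fit_lq()] with the quadratic term fixed to zero — the model found
#' statistically preferable for ion beams over the clinical dose range.
#'
#' @inheritParams fit_lq
#' @return A `survival_fit` with `model = "L"`.
#' @examples
#' d <- generate_survival_table(0.332, 0, quality = beam_quality("proton"),
#'                              noise = FALSE)
#' fit_linear(d)
#' @export
fit_linear <- function(data) {
  df <- prepare_survival(data, min_distinct = 2)
  quality <- attr(data, "quality")
  if (all(df$y == 0))
    return(structure(list(model = "L", alpha = 0, alpha_se = 0, beta = 0,
                          beta_se = NA_real_, cov = matrix(0, 2, 2), rss = 0,
                          df = nrow(df) - 1L, sigma = 0, n = nrow(df),
                          boundary = FALSE, quality = quality),
                     class = "survival_fit"))
  if (length(unique(df$y)) == 1)
    stop("degenerate fit: all surviving fractions identical", call. = FALSE)
  d1 <- -df$dose_Gy
  fm <- lm(df$y ~ 1 + d1, weights = df$w)
  fit <- finish_fit(fm, "L", 1, quality)
  if (fit$alpha < 0) {
    fit$alpha <- 0
    fit$boundary <- TRUE
  }
  fit$beta_se <- NA_real_
  fit
}

#' Choose between the linear and linear-quadratic model
#'
#' Nested-model F-test: the quadratic term is kept only when it improves
#' the weighted residual sum of squares significantly (default p < 0.05).
#' A `beta` estimate at its non-negativity boundary counts as no
#' improvement. With fewer than 3 distinct nonzero doses the LQ model is
#' unfittable and "L" is returned with a warning.
#'
#' @inheritParams fit_lq
#' @param significance F-test significance level for keeping `beta`.
#' @return A list with `selection` ("L" or "LQ"), the chosen `fit`, both
#'   candidate fits, `f_statistic` and `p_value`.
#' @export
select_model <- function(data, significance = 0.05) {
  fit_l <- fit_linear(data)
  fit_q <- tryCatch(fit_lq(data), error = function(e) NULL)
  if (is.null(fit_q)) {
    warning("LQ model unfittable (fewer than 3 distinct nonzero doses); returning L")
    return(list(selection = "L", fit = fit_l, fit_l = fit_l, fit_lq = NULL,
                f_statistic = NA_real_, p_value = NA_real_))
  }
  if (fit_q$boundary || fit_q$df < 1 || fit_q$rss <= 0) {
    return(list(selection = "L", fit = fit_l, fit_l = fit_l, fit_lq = fit_q,
                f_statistic = NA_real_, p_value = NA_real_))
  }
  f_stat <- (fit_l$rss - fit_q$rss) / (fit_q$rss / fit_q$df)
  p <- pf(f_stat, 1, fit_q$df, lower.tail = FALSE)
  sel <- if (is.finite(p) && p < significance) "LQ" else "L"
  list(selection = sel, fit = if (sel == "LQ") fit_q else fit_l,
       fit_l = fit_l, fit_lq = fit_q, f_statistic = f_stat, p_value = p)
}

#' Dose producing a given surviving fraction
#'
#' Inverts the fitted survival curve at an isosurvival level: for the LQ
#' model the positive root of `beta*D^2 + alpha*D + ln(level) = 0`, for
#' the linear model `D = -ln(level)/alpha`.
#'
#' @param fit A `survival_fit`.
#' @param level Surviving fraction in (0, 1); 0.30 is the conventional
#'   RBE reporting level.
#' @param se Return a list with the delta-method standard error as well?
#' @return Dose in Gy (or list `dose`, `se` when `se = TRUE`).
#' @examples
#' dose_at_survival(survival_fit(0.173, 0.032), 0.30)  # 4.00 Gy
#' @export
dose_at_survival <- function(fit, level, se = FALSE) {
  stopifnot(inherits(fit, "survival_fit"))
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)", call. = FALSE)
  lnS <- log(level)
  a <- fit$alpha; b <- fit$beta
  if (a <= 0 && b <= 0)
    stop("no solution: alpha = beta = 0", call. = FALSE)
  if (b > 0) {
    D <- (-a + sqrt(a^2 - 4 * b * lnS)) / (2 * b)
    grad <- c(-D / (2 * b * D + a), -D^2 / (2 * b * D + a))
  } else {
    D <- -lnS / a
    grad <- c(-D / a, 0)
  }
  if (!se) return(D)
  v <- as.numeric(t(grad) %*% fit$cov %*% grad)
  list(dose = D, se = sqrt(max(v, 0)))
}

#' Relative biological effectiveness at an isosurvival level
#'
#' RBE = (reference dose) / (test dose) at equal surviving fraction, with
#' first-order (delta-method) uncertainty propagated from both parameter
#' covariances, the fits being treated as independent.
#'
#' @param reference `survival_fit` of the reference radiation (photons).
#' @param test `survival_fit` of the test radiation.
#' @param level Isosurvival level in (0, 1), default 0.30.
#' @return An `rbe_result`: list with `level`, `reference_dose`,
#'   `test_dose`, `rbe`, `rbe_se`.
#' @examples
#' rbe_at_survival(survival_fit(0.173, 0.032), survival_fit(0.332))$rbe
#' @export
rbe_at_survival <- function(reference, test, level = 0.30) {
  dr <- dose_at_survival(reference, level, se = TRUE)
  dt <- dose_at_survival(test, level, se = TRUE)
  rbe <- dr$dose / dt$dose
  rel_var <- (dr$se / dr$dose)^2 + (dt$se / dt$dose)^2
  structure(list(level = level, reference_dose = dr$dose, test_dose = dt$dose,
                 rbe = rbe, rbe_se = rbe * sqrt(rel_var)),
            class = "rbe_result")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Survival fit (%s model)%s\n", x$model,
              if (isTRUE(x$boundary)) " [boundary]" else ""))
  cat(sprintf("  alpha = %.4f +/- %.4f 1/Gy\n", x$alpha, x$alpha_se))
  if (x$model == "LQ")
    cat(sprintf("  beta  = %.4f +/- %.4f 1/Gy^2\n", x$beta, x$beta_se))
  if (is.finite(x$rss))
    cat(sprintf("  weighted RSS = %.4g on %d df (n = %d)\n", x$rss, x$df, x$n))
  invisible(x)
}

#' @export
print.rbe_result <- function(x, ...) {
  cat(sprintf("RBE at %.0f%% survival: %.2f +/- %.2f (D_ref = %.3f Gy, D_test = %.3f Gy)\n",
              100 * x$level, x$rbe, x$rbe_se, x$reference_dose, x$test_dose))
  invisible(x)
}
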