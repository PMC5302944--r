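## Per-spot Gaussian amplitude: the raw peak of a noisy pixel read is both
## noisy and biased, so the count rate is taken from a least-squares
## Gaussian amplitude instead — the spot width is chosen from a small grid
## by residual, amplitude and offset then solve in closed form.
fit_spot_amplitude <- function(win, cy, cx, use = NULL) {
  ii <- seq_len(nrow(win)) - 1
  jj <- seq_len(ncol(win)) - 1
  d2 <- outer((ii - cy)^2, (jj - cx)^2, "+")
  y <- as.numeric(win)
  keep <- if (is.null(use)) rep(TRUE, length(y)) else as.logical(use)
  y <- y[keep]
  d2v <- as.numeric(d2)[keep]
  if (length(y) < 8) return(c(NA_real_, NA_real_))
  best <- c(NA_real_, NA_real_, Inf)
  for (s in c(0.8, 1.1, 1.5, 2.0, 2.6, 3.4, 4.5)) {
    g <- exp(-d2v / (2 * s^2))
    X <- cbind(g, 1)
    cf <- tryCatch(qr.solve(crossprod(X), crossprod(X, y)),
                   error = function(e) NULL)
    if (is.null(cf)) next
    rss <- sum((y - X %*% cf)^2)
    if (rss < best[3]) best <- c(cf[1], s, rss)
  }
  best[1:2]
}

#' Detect ion track spots in an FNTD plane
#'
#' Spot enhancement by white top-hat filtering (disc structuring element)
#' followed by light Gaussian smoothing (a matched-filter step that
#' suppresses pixel noise without moving peaks), robust thresholding, and
#' per-component peak extraction. The auto threshold is
#' `median + threshold_k x MAD` of the working image — a robust
#' background mean + k SD rule; a separate amplitude quality cut keeps the
#' false-positive rate low at this permissive detection level. Local
#' maxima closer than `min_separation` pixels merge into the brighter one;
#' each spot is reported at the intensity-weighted centroid of the working
#' image around its maximum, with the raw-image peak value, a
#' least-squares Gaussian peak amplitude, and, when the dwell time is
#' known, the photon count rate from that amplitude (the fitted amplitude
#' is an unbiased, noise-averaged estimate of the peak, which a single
#' noisy pixel read is not).
#'
#' With `deblend = TRUE` one matching-pursuit round is added: fitted spots
#' are subtracted and the residual searched once more, recovering the
#' partner of close pairs whose maxima merged.
#'
#' Components touching the image border are kept: fluence statistics need
#' edge spots.
#'
#' @param image An `fntd_image` from [generate_fntd_image()], or a numeric
#'   matrix (then give `pixel_size` and `dwell_time`).
#' @param tophat_radius Disc radius of the top-hat filter, pixels.
#' @param detection_threshold Threshold on the smoothed top-hat image, raw
#'   counts; `NULL` for the robust auto rule.
#' @param threshold_k Auto-threshold factor in robust-SD units.
#' @param min_separation Minimum peak separation in pixels.
#' @param smooth_sigma Gaussian sigma of the smoothing step, pixels; 0
#'   disables it.
#' @param min_amplitude Spot quality cut: fitted amplitudes below this are
#'   discarded as noise excursions. `NULL` (default) uses 3.5 x the robust
#'   noise level (MAD) of the raw image; 0 disables the cut.
#' @param deblend Run the fit-subtract-redetect round?
#' @param pixel_size,dwell_time Metadata overrides for plain matrices
#'   (um/pixel and us).
#' @return A `track_spots` data frame: `x_um`, `y_um`, `x_px`, `y_px`
#'   (0-based pixel-centre coordinates), `peak` (raw image maximum),
#'   `amplitude` (fitted Gaussian peak), `count_rate_MHz`, `class` (all
#'   `"unclassified"`).
#' @examples
#' f <- generate_fntd_image(2e6, field = c(60, 60), seed = 1)
#' s <- detect_track_spots(f)
#' head(s)
#' @export
detect_track_spots <- function(image, tophat_radius = 3,
                               detection_threshold = NULL,
                               threshold_k = 2.5,
                               min_separation = 2,
                               smooth_sigma = tophat_radius / 3,
                               min_amplitude = NULL, deblend = TRUE,
                               pixel_size = NULL, dwell_time = NULL) {
  if (inherits(image, "fntd_image")) {
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
    if (is.null(dwell_time)) dwell_time <- image$dwell_time
    img <- image$image
  } else {
    img <- image
    if (is.null(pixel_size)) stop("'pixel_size' required for a bare matrix", call. = FALSE)
  }
  if (length(img) == 0) stop("empty image", call. = FALSE)
  if (tophat_radius < 1) stop("'tophat_radius' must be >= 1", call. = FALSE)

  th <- gaussian_smooth(tophat_white(img, tophat_radius), smooth_sigma)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0), x_px = numeric(0),
                      y_px = numeric(0), peak = numeric(0),
                      amplitude = numeric(0), count_rate_MHz = numeric(0),
                      class = character(0))
  class(empty) <- c("track_spots", "data.frame")
  if (is.null(detection_threshold)) {
    detection_threshold <- median(th) + threshold_k * mad(th)
    if (mad(th) == 0) {
      # noise-free image: anything clearly above the flat background is signal
      if (max(th) <= 0) return(empty)
      detection_threshold <- median(th) + 0.05 * (max(th) - median(th))
    }
  }
  if (detection_threshold > max(th)) {
    warning("detection threshold above the image maximum; no spots")
    return(empty)
  }

  pk1 <- find_spot_peaks(th, detection_threshold, min_separation)
  if (is.null(pk1)) return(empty)
  peak_i <- pk1$i; peak_j <- pk1$j
  med_img <- median(img)
  med_th <- median(th)
  w <- max(3L, as.integer(2 * tophat_radius))
  m <- measure_spots(img, th, peak_i, peak_j, w, med_th, med_img)

  if (deblend && mad(img) > 0 && length(peak_i) > 0) {
    # one matching-pursuit round: subtract the fitted spots and look for
    # peaks hiding under their skirts (close pairs merge at first pass)
    model <- matrix(0, nrow(img), ncol(img))
    okf <- is.finite(m$amp) & is.finite(m$sig) & m$amp > 0
    model <- render_blobs(model, m$cx[okf] - 1, m$cy[okf] - 1,
                          m$amp[okf], m$sig[okf])
    th_r <- gaussian_smooth(tophat_white(img - model, tophat_radius),
                            smooth_sigma)
    thr_r <- median(th_r) + threshold_k * mad(th_r)
    pk2 <- find_spot_peaks(th_r, thr_r, min_separation)
    if (!is.null(pk2)) {
      d2min <- vapply(seq_along(pk2$i), function(t)
        min((pk2$i[t] - peak_i)^2 + (pk2$j[t] - peak_j)^2), numeric(1))
      fresh <- d2min > min_separation^2
      if (any(fresh)) {
        # vet candidates on the residual image: a genuine hidden partner
        # carries its own amplitude there, a subtraction artefact does not
        resid <- img - model
        m2 <- measure_spots(resid, th_r, pk2$i[fresh], pk2$j[fresh], w,
                            median(th_r), median(resid))
        genuine <- is.finite(m2$amp) & m2$amp >= 3.5 * mad(img)
        if (any(genuine)) {
          peak_i <- c(peak_i, pk2$i[fresh][genuine])
          peak_j <- c(peak_j, pk2$j[fresh][genuine])
          m <- measure_spots(img, th, peak_i, peak_j, w, med_th, med_img)
        }
      }
    }
  }

  amp <- pmax(m$amp, 0)
  if (is.null(min_amplitude)) min_amplitude <- 3.5 * mad(img)
  ok <- amp >= min_amplitude
  if (!any(ok)) return(empty)
  cx <- m$cx[ok]; cy <- m$cy[ok]; pk <- m$pk[ok]; amp <- amp[ok]
  # 1-based matrix indices -> 0-based pixel coordinates
  x_px <- cx - 1; y_px <- cy - 1
  out <- data.frame(x_um = px_to_um(x_px, pixel_size),
                    y_um = px_to_um(y_px, pixel_size),
                    x_px = x_px, y_px = y_px, peak = pk, amplitude = amp,
                    count_rate_MHz = if (is.null(dwell_time)) NA_real_
                                     else intensity_to_count_rate(amp, dwell_time),
                    class = "unclassified", stringsAsFactors = FALSE)
  out <- out[order(out$y_um, out$x_um), ]
  rownames(out) <- NULL
  class(out) <- c("track_spots", "data.frame")
  out
}

## Plateau-safe local maxima of a working image above a threshold, merged
## greedily so no two kept peaks are within min_separation pixels.
find_spot_peaks <- function(th, threshold, min_separation) {
  mask <- th >= threshold
  if (!any(mask)) return(NULL)
  maxf <- morph_dilate(th, max(1L, as.integer(min_separation)))
  is_max <- mask & (th >= maxf - 1e-12)
  if (!any(is_max)) return(NULL)
  plat <- cpp_label_components(is_max)
  npk <- max(plat)
  idx <- which(plat > 0)
  pi_ <- ((idx - 1) %% nrow(th)) + 1
  pj_ <- ((idx - 1) %/% nrow(th)) + 1
  lab <- plat[idx]
  peak_i <- round(tapply(pi_, lab, mean))
  peak_j <- round(tapply(pj_, lab, mean))
  peak_v <- th[cbind(peak_i, peak_j)]
  ord <- order(peak_v, decreasing = TRUE)
  ki <- kj <- numeric(0)
  for (t in ord) {
    if (length(ki) == 0 ||
        min((peak_i[t] - ki)^2 + (peak_j[t] - kj)^2) > min_separation^2) {
      ki <- c(ki, peak_i[t]); kj <- c(kj, peak_j[t])
    }
  }
  list(i = ki, j = kj)
}

## Sub-pixel centroid (pedestal-removed, neighbour-excluded) plus raw peak
## and fitted Gaussian amplitude/width for every peak position.
measure_spots <- function(img, th, peak_i, peak_j, w, med_th, med_img) {
  nr <- nrow(th); ncy <- ncol(th)
  n <- length(peak_i)
  cx <- cy <- pk <- amp <- sig <- numeric(n)
  for (s in seq_len(n)) {
    i0 <- max(1L, peak_i[s] - w); i1 <- min(nr, peak_i[s] + w)
    j0 <- max(1L, peak_j[s] - w); j1 <- min(ncy, peak_j[s] + w)
    # remove the background pedestal so the centroid is not pulled toward
    # the window centre (sub-pixel quantisation bias)
    win <- th[i0:i1, j0:j1, drop = FALSE] - med_th
    win[win < 0] <- 0
    # exclude pixels closer to a neighbouring peak than to this one
    nb <- which(abs(peak_i - peak_i[s]) <= 2 * w + 2 &
                abs(peak_j - peak_j[s]) <= 2 * w + 2)
    nb <- setdiff(nb, s)
    own <- matrix(TRUE, nrow(win), ncol(win))
    if (length(nb)) {
      ri <- row(win) + i0 - 1; rj <- col(win) + j0 - 1
      d_self <- (ri - peak_i[s])^2 + (rj - peak_j[s])^2
      for (t in nb)
        own <- own & (d_self <= (ri - peak_i[t])^2 + (rj - peak_j[t])^2)
    }
    wgt <- win * own
    tot <- sum(wgt)
    if (tot <= 0) { cy[s] <- peak_i[s]; cx[s] <- peak_j[s] }
    else {
      cy[s] <- sum(row(win) * wgt) / tot + i0 - 1
      cx[s] <- sum(col(win) * wgt) / tot + j0 - 1
    }
    raw_win <- img[i0:i1, j0:j1, drop = FALSE]
    pk[s] <- max(raw_win[own])
    fitres <- fit_spot_amplitude(raw_win, cy[s] - i0, cx[s] - j0, use = own)
    amp[s] <- fitres[1]; sig[s] <- fitres[2]
    if (!is.finite(amp[s])) { amp[s] <- pk[s] - med_img; sig[s] <- 1.5 }
  }
  list(cx = cx, cy = cy, pk = pk, amp = amp, sig = sig)
}

#' Convert a photon-counting peak to a count rate
#'
#' Peak intensity of an avalanche-photo-diode pixel in photon counts,
#' divided by the pixel dwell time in microseconds, gives the count rate
#' in MHz (counts per microsecond).
#'
#' @param peak_value Photon counts (>= 0), vectorised.
#' @param dwell_time Pixel dwell time, us (> 0).
#' @return Count rate in MHz.
#' @examples
#' intensity_to_count_rate(38, 7.2)  # 5.28 MHz
#' @export
intensity_to_count_rate <- function(peak_value, dwell_time) {
  if (!is.finite(dwell_time) || dwell_time <= 0)
    stop("'dwell_time' must be > 0", call. = FALSE)
  if (any(peak_value < 0, na.rm = TRUE))
    stop("'peak_value' must be >= 0", call. = FALSE)
  peak_value / dwell_time
}

#' Classify track spots as primary ions or fragments
#'
#' Count rates at or above the threshold are primary particles (which for
#' clinical beams include indistinguishable heavy projectile-like
#' fragments); below are light fragments. The operating thresholds used
#' clinically are 5.3 MHz for carbon and 4.4 MHz for oxygen beams.
#'
#' @param spots A `track_spots` data frame with `count_rate_MHz`.
#' @param threshold Count-rate threshold, MHz (> 0).
#' @return The spot table with `class` filled in; attributes
#'   `n_primary`, `n_fragment`, `primary_fraction`.
#' @examples
#' s <- data.frame(count_rate_MHz = c(6.0, 4.0))
#' classify_spots(s, threshold = 5.3)$class
#' @export
classify_spots <- function(spots, threshold) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("'threshold' must be > 0", call. = FALSE)
  if (!"count_rate_MHz" %in% names(spots) || any(!is.finite(spots$count_rate_MHz)))
    stop("spots lack finite count rates; run the read-out with a dwell time",
         call. = FALSE)
  spots$class <- ifelse(spots$count_rate_MHz >= threshold, "primary", "fragment")
  attr(spots, "n_primary") <- sum(spots$class == "primary")
  attr(spots, "n_fragment") <- sum(spots$class == "fragment")
  attr(spots, "primary_fraction") <-
    if (nrow(spots)) attr(spots, "n_primary") / nrow(spots) else NA_real_
  spots
}

## Two-component 1D Gaussian mixture by EM (quantile-initialised).
em_two_normals <- function(x, iter = 200) {
  q <- as.numeric(quantile(x, c(0.1, 0.9)))
  m <- q
  s <- rep(max(sd(x) / 2, 1e-3), 2)
  w <- c(0.5, 0.5)
  for (it in seq_len(iter)) {
    d1 <- w[1] * dnorm(x, m[1], s[1])
    d2 <- w[2] * dnorm(x, m[2], s[2])
    r <- d1 / (d1 + d2)
    r[!is.finite(r)] <- 0.5
    n1 <- sum(r); n2 <- length(x) - n1
    if (n1 < 1e-6 || n2 < 1e-6) break
    w <- c(n1, n2) / length(x)
    m_new <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    s <- sqrt(pmax(c(sum(r * (x - m_new[1])^2) / n1,
                     sum((1 - r) * (x - m_new[2])^2) / n2), 1e-6))
    if (max(abs(m_new - m)) < 1e-8) { m <- m_new; break }
    m <- m_new
  }
  list(w = w, mean = sort(m), sd = s[order(m)])
}

#' Histogram-based primary/fragment threshold
#'
#' Data-driven split of a bimodal count-rate sample. Otsu's
#' between-class-variance-maximising threshold is used when it sits in a
#' genuine valley of the kernel-smoothed density; with very unbalanced
#' classes (a clinical mid-SOBP field is >90% primaries) Otsu drifts into
#' the dominant mode, and the threshold falls back to the midpoint of the
#' two component means of a Gaussian-mixture fit, which is insensitive to
#' the class weights. A sample whose mixture components are not separated
#' (by at least two pooled SDs) yields a warning and the sample boundary.
#'
#' @param count_rates Count rates, MHz (>= 20 values).
#' @return Threshold in MHz, with attribute `method` one of
#'   `"otsu"`, `"mixture"`, `"boundary"`.
#' @examples
#' x <- c(rnorm(200, 2, 0.4), rnorm(200, 6, 0.4))
#' histogram_threshold(x)
#' @export
histogram_threshold <- function(count_rates) {
  x <- count_rates[is.finite(count_rates)]
  if (length(x) < 20)
    stop("need >= 20 spots for a histogram threshold", call. = FALSE)
  em <- em_two_normals(x)
  sep <- diff(em$mean) / mean(em$sd)
  if (!is.finite(sep) || sep < 2) {
    warning("count-rate histogram looks unimodal; returning the sample boundary")
    return(structure(max(x), method = "boundary"))
  }
  ot <- otsu_threshold(x)
  d <- density(x, n = 512, adjust = 1.5)
  mid <- mean(em$mean)
  # trust Otsu only inside the between-means region and in a real valley
  near <- function(v) d$y[which.min(abs(d$x - v))]
  ot_ok <- ot > em$mean[1] && ot < em$mean[2] &&
    near(ot) <= 0.6 * min(near(em$mean[1]), near(em$mean[2]))
  if (ot_ok) structure(ot, method = "otsu")
  else structure(mid, method = "mixture")
}
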