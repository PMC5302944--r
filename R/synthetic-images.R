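## Synthetic microscopy generators. Conventions shared with the read-out
## modules: image matrices are indexed [row = y, col = x]; the centre of the
## 0-based pixel (i, j) sits at ((j + 0.5), (i + 0.5)) * pixel_size in um;
## x runs right, y runs down.

um_to_px <- function(u, pixel_size) u / pixel_size - 0.5
px_to_um <- function(p, pixel_size) (p + 0.5) * pixel_size

#' Simulate an FNTD track-spot plane
#'
#' Renders one fluorescent nuclear track detector (FNTD) read-out plane for
#' a perpendicular irradiation: ion track spots are isotropic Gaussian
#' blobs whose peak photon count encodes an avalanche-photo-diode count
#' rate, with a bimodal rate mixture — bright primary ions and dimmer
#' light fragments. The number of spots is Poisson with mean
#' `fluence x field area`; positions are uniform over the field.
#'
#' Default geometry matches a clinical detector read-out: a
#' 212.55 x 212.55 um^2 plane at 1800 x 1800 pixels, 7.2 us pixel dwell
#' time. Default rate mixtures are carbon-like (primary 6.8 +/- 0.6 MHz vs
#' fragment 3.8 +/- 0.6 MHz, valley near the 5.3 MHz operating threshold);
#' `oxygen_rates()` gives the oxygen-like pair with a valley near 4.4 MHz.
#'
#' @param fluence Particle fluence in particles/cm^2 (>= 0).
#' @param field Field size c(width, height) in um.
#' @param pixel_size Pixel pitch in um (> 0).
#' @param spot_sigma Gaussian spot width (sigma) in um.
#' @param primary_rate,fragment_rate c(mean, sd) of the count-rate law per
#'   class, MHz; draws are truncated at zero.
#' @param fragment_fraction Fraction of spots that are light fragments.
#' @param dwell_time Pixel dwell time in us; peak counts = rate x dwell.
#' @param snr Peak signal-to-noise ratio: Gaussian read-out noise with
#'   sd = mean primary peak / snr is added when `noise = TRUE`.
#' @param noise If `FALSE` the image is rendered without noise and the
#'   spot count is the rounded expectation rather than a Poisson draw.
#' @param seed Integer seed.
#' @return An `fntd_image`: list with `image` (counts matrix), `pixel_size`,
#'   `dwell_time`, `field`, and `truth` — a data frame of ground-truth spots
#'   (`x_um`, `y_um`, `class`, `rate_MHz`, `peak_counts`).
#' @examples
#' f <- generate_fntd_image(3.8e6, field = c(50, 50), seed = 1)
#' nrow(f$truth)
#' @export
generate_fntd_image <- function(fluence, field = c(212.55, 212.55),
                                pixel_size = 212.55 / 1800, spot_sigma = 0.3,
                                primary_rate = c(6.8, 0.6),
                                fragment_rate = c(3.8, 0.6),
                                fragment_fraction = 0.08, dwell_time = 7.2,
                                snr = 10, noise = TRUE, seed = NULL) {
  if (!is.finite(fluence) || fluence < 0) stop("'fluence' must be >= 0", call. = FALSE)
  if (pixel_size <= 0) stop("'pixel_size' must be > 0", call. = FALSE)
  if (any(field < pixel_size)) stop("field smaller than one pixel", call. = FALSE)
  if (any(c(primary_rate, fragment_rate) < 0))
    stop("rate distributions must be non-negative", call. = FALSE)
  if (fragment_fraction < 0 || fragment_fraction > 1)
    stop("'fragment_fraction' must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  nc <- max(1L, round(field[1] / pixel_size))
  nr <- max(1L, round(field[2] / pixel_size))
  area_cm2 <- (field[1] * 1e-4) * (field[2] * 1e-4)
  expected <- fluence * area_cm2
  n <- if (noise) rpois(1, expected) else round(expected)

  truth <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      class = character(0), rate_MHz = numeric(0),
                      peak_counts = numeric(0))
  img <- matrix(0, nr, nc)
  if (n > 0) {
    x <- runif(n, 0, field[1])
    y <- runif(n, 0, field[2])
    frag <- if (noise) runif(n) < fragment_fraction
            else seq_len(n) <= round(n * fragment_fraction)
    rate <- ifelse(frag,
                   rnorm(n, fragment_rate[1], if (noise) fragment_rate[2] else 0),
                   rnorm(n, primary_rate[1], if (noise) primary_rate[2] else 0))
    rate <- pmax(rate, 0)
    peak <- rate * dwell_time
    img <- render_blobs(img, um_to_px(x, pixel_size), um_to_px(y, pixel_size),
                        peak, spot_sigma / pixel_size)
    truth <- data.frame(x_um = x, y_um = y,
                        class = ifelse(frag, "fragment", "primary"),
                        rate_MHz = rate, peak_counts = peak)
  }
  if (noise) {
    # Gaussian read-out noise; values may dip below zero, as on an
    # offset-subtracted detector
    noise_sd <- primary_rate[1] * dwell_time / snr
    img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  }
  structure(list(image = img, pixel_size = pixel_size, dwell_time = dwell_time,
                 field = field, truth = truth,
                 params = list(fluence = fluence, spot_sigma = spot_sigma,
                               primary_rate = primary_rate,
                               fragment_rate = fragment_rate,
                               fragment_fraction = fragment_fraction,
                               snr = snr, noise = noise, seed = seed)),
            class = "fntd_image")
}

#' Oxygen-beam count-rate mixture defaults
#'
#' Primary/fragment count-rate pairs whose histogram valley lands near the
#' 4.4 MHz oxygen operating threshold.
#' @return List with `primary_rate` and `fragment_rate` c(mean, sd), MHz.
#' @export
oxygen_rates <- function() {
  list(primary_rate = c(5.6, 0.5), fragment_rate = c(3.2, 0.5))
}

## Render one filled ellipse (soft 1-px edge) and return the logical mask.
ellipse_mask <- function(nr, nc, cx_px, cy_px, a_px, b_px, theta = 0) {
  j0 <- max(0L, floor(cx_px - a_px - 2)); j1 <- min(nc - 1L, ceiling(cx_px + a_px + 2))
  i0 <- max(0L, floor(cy_px - a_px - 2)); i1 <- min(nr - 1L, ceiling(cy_px + a_px + 2))
  mask <- matrix(FALSE, nr, nc)
  if (j0 > j1 || i0 > i1) return(mask)
  jj <- j0:j1; ii <- i0:i1
  xr <- outer(rep(1, length(ii)), jj - cx_px)
  yr <- outer(ii - cy_px, rep(1, length(jj)))
  xp <- xr * cos(theta) + yr * sin(theta)
  yp <- -xr * sin(theta) + yr * cos(theta)
  inside <- (xp / a_px)^2 + (yp / b_px)^2 <= 1
  mask[ii + 1L, jj + 1L] <- inside
  mask
}

#' Simulate a two-channel cell-layer stack over a track field
#'
#' Builds the biological compartment of a hybrid detector: a nuclear-stain
#' channel containing non-overlapping ellipse-shaped nuclei and a
#' DNA-damage (focus) channel with Gaussian foci placed at
#' `track position + translation` for tracks that fall inside a nucleus,
#' plus Poisson background foci. The global translation emulates the
#' cell-layer movement between detector and microscope read-outs (~3 um in
#' the clinical data).
#'
#' @param n_nuclei Number of nuclei to place (ignored when `areas` is
#'   given).
#' @param areas Optional vector of target nuclear areas in um^2, one
#'   nucleus each; overrides `n_nuclei`.
#' @param field Field size c(width, height) um; defaults to the FNTD field.
#' @param pixel_size Pixel pitch, um (default 0.322, the wide-field focus
#'   scoring geometry).
#' @param tracks Ground-truth spot table from [generate_fntd_image()]
#'   (`$truth`), or `NULL` for an unirradiated control.
#' @param track_classes Which spot classes seed foci (default primaries).
#' @param foci_per_track Mean foci per intranuclear track (Poisson).
#' @param focus_radius Gaussian sigma of a rendered focus, um.
#' @param focus_jitter Positional jitter (sd, um) of a focus around its
#'   translated track position.
#' @param background_foci_rate Mean spontaneous foci per nucleus (Poisson);
#'   default 0.16, a low-background cell line.
#' @param translation c(dx, dy) um applied from detector to cell layer.
#' @param mean_area,area_cv Nuclear-area law when `n_nuclei` is a count
#'   (see [generate_nuclear_areas()]).
#' @param n_planes Number of z planes; foci concentrate in the central
#'   planes with a Gaussian z profile.
#' @param nucleus_intensity,focus_amplitude Signal levels, arbitrary counts.
#' @param snr Peak signal-to-noise ratio of both channels when `noise = TRUE`.
#' @param noise Disable all noise (and Poisson placement counts) if `FALSE`.
#' @param max_retries Rejection-sampling retries for non-overlapping
#'   nucleus placement before giving up.
#' @param seed Integer seed.
#' @return A `cell_layer`: list with `nuclear` and `foci` (3D arrays
#'   [y, x, z]), `pixel_size`, `field`, and `truth` — `nuclei` (table),
#'   `label` (ground-truth label mask), `foci` (table with `x_um`, `y_um`,
#'   `nucleus`, `source_track`), `translation`.
#' @examples
#' f <- generate_fntd_image(3e6, field = c(60, 60), seed = 2)
#' cl <- generate_cell_layer(5, field = c(60, 60), tracks = f$truth, seed = 3)
#' dim(cl$nuclear)
#' @export
generate_cell_layer <- function(n_nuclei = NULL, field = c(212.55, 212.55),
                                areas = NULL,
                                pixel_size = 0.322, tracks = NULL,
                                track_classes = "primary", foci_per_track = 1,
                                focus_radius = 0.5, focus_jitter = 0.2,
                                background_foci_rate = 0.16,
                                translation = c(3, 0), mean_area = 89.5,
                                area_cv = 0.3, n_planes = 5,
                                nucleus_intensity = 100, focus_amplitude = 80,
                                snr = 10, noise = TRUE, max_retries = 1000,
                                seed = NULL) {
  if (foci_per_track < 0) stop("'foci_per_track' must be >= 0", call. = FALSE)
  if (background_foci_rate < 0) stop("'background_foci_rate' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nc <- max(1L, round(field[1] / pixel_size))
  nr <- max(1L, round(field[2] / pixel_size))

  if (is.null(areas)) {
    if (is.null(n_nuclei) || length(n_nuclei) != 1 || n_nuclei < 1)
      stop("give 'n_nuclei' (a count >= 1) or 'areas'", call. = FALSE)
    areas <- generate_nuclear_areas(n_nuclei, mean_area, area_cv)
  }
  areas <- as.numeric(areas)
  n <- length(areas)

  # ellipse axes: area = pi a b, eccentricity e ~ U[0, 0.6], b/a = sqrt(1-e^2)
  ecc <- if (noise) runif(n, 0, 0.6) else rep(0, n)
  ratio <- sqrt(1 - ecc^2)
  a_um <- sqrt(areas / (pi * ratio))
  b_um <- a_um * ratio
  theta <- if (noise) runif(n, 0, pi) else rep(0, n)

  # rejection-sampled non-overlapping placement (bounding-circle test)
  cx <- cy <- numeric(n)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      px <- runif(1, a_um[k], field[1] - a_um[k])
      py <- runif(1, a_um[k], field[2] - a_um[k])
      if (k == 1 ||
          all(sqrt((px - cx[seq_len(k - 1)])^2 + (py - cy[seq_len(k - 1)])^2) >
              a_um[k] + a_um[seq_len(k - 1)] + 0.5)) {
        cx[k] <- px; cy[k] <- py; placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf("could not place nucleus %d without overlap after %d retries",
                   k, max_retries), call. = FALSE)
  }

  label <- matrix(0L, nr, nc)
  for (k in seq_len(n)) {
    m <- ellipse_mask(nr, nc, um_to_px(cx[k], pixel_size), um_to_px(cy[k], pixel_size),
                      a_um[k] / pixel_size, b_um[k] / pixel_size, theta[k])
    label[m & label == 0L] <- k
  }

  nuclei <- data.frame(nucleus = seq_len(n), x_um = cx, y_um = cy,
                       area_um2 = areas, a_um = a_um, b_um = b_um, theta = theta)

  inside_nucleus <- function(x, y) {
    j <- round(um_to_px(x, pixel_size)); i <- round(um_to_px(y, pixel_size))
    ok <- i >= 0 & i < nr & j >= 0 & j < nc
    out <- integer(length(x))
    out[ok] <- label[cbind(i[ok] + 1L, j[ok] + 1L)]
    out
  }

  # track-induced foci at translated positions
  fx <- fy <- numeric(0); fnuc <- integer(0); fsrc <- integer(0)
  if (!is.null(tracks) && nrow(tracks) > 0 && foci_per_track > 0) {
    sel <- which(tracks$class %in% track_classes)
    for (s in sel) {
      tx <- tracks$x_um[s] + translation[1]
      ty <- tracks$y_um[s] + translation[2]
      nucl <- inside_nucleus(tx, ty)
      if (nucl == 0) next
      nf <- if (noise) rpois(1, foci_per_track) else round(foci_per_track)
      if (nf < 1) next
      jx <- tx + if (noise) rnorm(nf, 0, focus_jitter) else rep(0, nf)
      jy <- ty + if (noise) rnorm(nf, 0, focus_jitter) else rep(0, nf)
      fx <- c(fx, jx); fy <- c(fy, jy)
      fnuc <- c(fnuc, rep(nucl, nf)); fsrc <- c(fsrc, rep(s, nf))
    }
  }
  # spontaneous background foci, uniform inside each nucleus
  if (background_foci_rate > 0 && noise) {
    for (k in seq_len(n)) {
      nb <- rpois(1, background_foci_rate)
      got <- 0
      while (got < nb) {
        bx <- runif(1, cx[k] - a_um[k], cx[k] + a_um[k])
        by <- runif(1, cy[k] - a_um[k], cy[k] + a_um[k])
        if (inside_nucleus(bx, by) == k) {
          fx <- c(fx, bx); fy <- c(fy, by)
          fnuc <- c(fnuc, k); fsrc <- c(fsrc, 0L)
          got <- got + 1
        }
      }
    }
  }
  foci <- data.frame(x_um = fx, y_um = fy, nucleus = fnuc, source_track = fsrc)

  # render the stack: nuclei in all planes (parabolic z profile), foci with
  # a Gaussian z profile centred mid-stack
  zc <- (n_planes + 1) / 2
  zprof_nuc <- 1 - 0.3 * ((seq_len(n_planes) - zc) / max(zc - 1, 1))^2
  zprof_foc <- exp(-((seq_len(n_planes) - zc)^2) / (2 * 1.0^2))
  nuc_plane <- (label > 0) * nucleus_intensity
  foc_plane <- matrix(0, nr, nc)
  if (nrow(foci) > 0)
    foc_plane <- render_blobs(foc_plane, um_to_px(foci$x_um, pixel_size),
                              um_to_px(foci$y_um, pixel_size),
                              rep(focus_amplitude, nrow(foci)),
                              focus_radius / pixel_size)
  nuclear <- array(0, c(nr, nc, n_planes))
  fochan <- array(0, c(nr, nc, n_planes))
  for (z in seq_len(n_planes)) {
    nuclear[, , z] <- nuc_plane * zprof_nuc[z]
    fochan[, , z] <- foc_plane * zprof_foc[z]
    if (noise) {
      nuclear[, , z] <- pmax(nuclear[, , z] +
        matrix(rnorm(nr * nc, 0, nucleus_intensity / snr), nr, nc), 0)
      fochan[, , z] <- pmax(fochan[, , z] +
        matrix(rnorm(nr * nc, 0, focus_amplitude / snr), nr, nc), 0)
    }
  }

  structure(list(nuclear = nuclear, foci = fochan, pixel_size = pixel_size,
                 field = field,
                 truth = list(nuclei = nuclei, label = label, foci = foci,
                              translation = translation),
                 params = list(foci_per_track = foci_per_track,
                               focus_radius = focus_radius,
                               background_foci_rate = background_foci_rate,
                               snr = snr, noise = noise, seed = seed)),
            class = "cell_layer")
}
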