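## Nucleus segmentation and gamma-H2AX focus quantification.

as_stack <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

max_project <- function(stack, planes = NULL) {
  stack <- as_stack(stack)
  if (is.null(planes)) planes <- seq_len(dim(stack)[3])
  apply(stack[, , planes, drop = FALSE], c(1, 2), max)
}

## Least-squares Gaussian width of one focus: continuous sigma by golden
## section on the profile RSS, amplitude and offset solved in closed form.
fit_focus_sigma <- function(ii, jj, vv, ci, cj) {
  d2 <- (ii - ci)^2 + (jj - cj)^2
  rss <- function(s) {
    g <- exp(-d2 / (2 * s^2))
    X <- cbind(g, 1)
    cf <- tryCatch(qr.solve(crossprod(X), crossprod(X, vv)),
                   error = function(e) NULL)
    if (is.null(cf)) return(Inf)
    sum((vv - X %*% cf)^2)
  }
  stats::optimize(rss, c(0.4, 8))$minimum
}

poly_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

region_solidity <- function(i, j) {
  # pixel-count area over convex-hull area (pixels as unit squares)
  if (length(i) < 3) return(1)
  h <- chull(j, i)
  ha <- poly_area(j[h], i[h])
  if (ha <= 0) return(1)
  min(length(i) / ha, 1)
}

#' Segment nuclei from a nuclear-stain z-stack
#'
#' Reproduces the standard automated pipeline for nuclear-area
#' measurement: per-plane rolling-ball style background subtraction,
#' maximum-intensity projection, median filtering, a global Otsu
#' threshold, and a distance-transform marker-based watershed to split
#' touching nuclei, followed by an area filter.
#'
#' @param stack A `cell_layer` (its nuclear channel is used), a 3D array
#'   `[y, x, z]`, or a matrix.
#' @param pixel_size Pixel pitch in um (taken from a `cell_layer`).
#' @param rolling_ball_radius Background scale in pixels.
#' @param median_radius Median-filter half-width in pixels.
#' @param min_area Smallest reportable nucleus, um^2.
#' @param marker_min_distance Minimum distance between watershed seed
#'   maxima, pixels; defaults to 4 um worth of pixels (roughly a nuclear
#'   radius), which keeps near-circular nuclei whole while still splitting
#'   touching pairs.
#' @return A `nucleus_set`: list with `nuclei` (data frame: `nucleus`,
#'   `x_um`, `y_um`, `area_um2`, `n_pixels`, `solidity`, `on_border`),
#'   `label` (integer label image) and `pixel_size`.
#' @examples
#' cl <- generate_cell_layer(4, field = c(60, 60), tracks = NULL, seed = 1)
#' seg <- segment_nuclei(cl)
#' seg$nuclei$area_um2
#' @export
segment_nuclei <- function(stack, pixel_size = NULL, rolling_ball_radius = 50,
                           median_radius = 2, min_area = 25,
                           marker_min_distance = NULL) {
  if (inherits(stack, "cell_layer")) {
    if (is.null(pixel_size)) pixel_size <- stack$pixel_size
    stack <- stack$nuclear
  }
  if (is.null(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be given and > 0", call. = FALSE)
  stack <- as_stack(stack)
  if (length(stack) == 0 || dim(stack)[3] < 1) stop("empty stack", call. = FALSE)
  if (is.null(marker_min_distance))
    marker_min_distance <- max(3L, round(4 / pixel_size))

  for (z in seq_len(dim(stack)[3]))
    stack[, , z] <- subtract_background(stack[, , z], rolling_ball_radius)
  mip <- max_project(stack)
  sm <- median_filter(mip, median_radius)
  thr <- tryCatch(otsu_threshold(as.numeric(sm)), error = function(e) Inf)
  mask <- sm > thr
  empty <- list(nuclei = data.frame(nucleus = integer(0), x_um = numeric(0),
                                    y_um = numeric(0), area_um2 = numeric(0),
                                    n_pixels = integer(0), solidity = numeric(0),
                                    on_border = logical(0)),
                label = matrix(0L, nrow(sm), ncol(sm)), pixel_size = pixel_size)
  class(empty) <- "nucleus_set"
  if (!any(mask)) {
    warning("no nuclei found")
    return(empty)
  }

  edt <- distance_transform(mask)
  # seed maxima of the distance map, plateau-labelled then distance-merged
  maxf <- morph_dilate(edt, marker_min_distance)
  seeds <- mask & edt >= maxf - 1e-9 & edt > 1.5
  plat <- cpp_label_components(seeds)
  if (max(plat) == 0) {
    warning("no nuclei found")
    return(empty)
  }
  idx <- which(plat > 0)
  si <- ((idx - 1) %% nrow(edt)) + 1
  sj <- ((idx - 1) %/% nrow(edt)) + 1
  lab <- plat[idx]
  mi <- tapply(si, lab, function(v) round(mean(v)))
  mj <- tapply(sj, lab, function(v) round(mean(v)))
  mv <- edt[cbind(mi, mj)]
  ord <- order(mv, decreasing = TRUE)
  ki <- kj <- numeric(0)
  for (t in ord) {
    if (length(ki) == 0 ||
        min((mi[t] - ki)^2 + (mj[t] - kj)^2) > marker_min_distance^2) {
      ki <- c(ki, mi[t]); kj <- c(kj, mj[t])
    }
  }
  markers <- matrix(0L, nrow(edt), ncol(edt))
  markers[cbind(ki, kj)] <- seq_along(ki)
  label <- cpp_watershed(-edt, markers, mask)

  # measure, filter, relabel 1..n
  nr <- nrow(label); ncl <- ncol(label)
  keep <- integer(0)
  rows <- list()
  for (k in sort(unique(label[label > 0]))) {
    idx <- which(label == k)
    npix <- length(idx)
    area <- npix * pixel_size^2
    if (area < min_area) { label[idx] <- 0L; next }
    i <- ((idx - 1) %% nr) + 1
    j <- ((idx - 1) %/% nr) + 1
    keep <- c(keep, k)
    rows[[length(rows) + 1]] <- data.frame(
      nucleus = k,
      x_um = px_to_um(mean(j) - 1, pixel_size),
      y_um = px_to_um(mean(i) - 1, pixel_size),
      area_um2 = area, n_pixels = npix,
      solidity = region_solidity(i, j),
      on_border = any(i == 1 | i == nr | j == 1 | j == ncl))
  }
  if (length(keep) == 0) {
    warning("no nuclei above the area filter")
    return(empty)
  }
  remap <- integer(max(keep)); remap[keep] <- seq_along(keep)
  label[label > 0] <- remap[label[label > 0]]
  nuclei <- do.call(rbind, rows)
  nuclei$nucleus <- seq_len(nrow(nuclei))
  rownames(nuclei) <- NULL
  structure(list(nuclei = nuclei, label = label, pixel_size = pixel_size),
            class = "nucleus_set")
}

#' Detect gamma-H2AX foci within segmented nuclei
#'
#' Background-subtracts and maximum-projects the focus channel over the
#' central planes, thresholds per nucleus at `median + k x MAD` of the
#' in-nucleus signal (robust to the signal contributed by the foci
#' themselves, which inflates a mean/SD rule until bright foci fall below
#' their own threshold), and extracts connected components above a minimum
#' area, each assigned to its containing nucleus. The per-nucleus relative
#' rule makes counts invariant under uniform intensity scaling. Focus size
#' is reported as the half-maximum area corrected for the smoothing
#' kernel's own footprint, so it scales with the physical focus area.
#'
#' @param stack A `cell_layer` (its focus channel is used) or 3D array.
#' @param nuclei A `nucleus_set` from [segment_nuclei()] on the same grid.
#' @param rolling_ball_radius Background scale, pixels.
#' @param threshold_k Per-nucleus threshold in robust-SD (MAD) units
#'   above the median.
#' @param min_focus_area Smallest reportable focus, um^2.
#' @param smooth_sigma Gaussian sigma (pixels) applied to the projection
#'   before thresholding; suppresses single-pixel noise excursions.
#' @param central_planes Plane indices to project; default the middle
#'   plane plus one on each side.
#' @return A `focus_set` data frame: `nucleus`, `x_um`, `y_um`,
#'   `area_um2`, `peak`.
#' @export
detect_foci <- function(stack, nuclei, rolling_ball_radius = 10,
                        threshold_k = 5, min_focus_area = 0.1,
                        smooth_sigma = 0.8, central_planes = NULL) {
  stopifnot(inherits(nuclei, "nucleus_set"))
  if (inherits(stack, "cell_layer")) stack <- stack$foci
  stack <- as_stack(stack)
  if (!all(dim(stack)[1:2] == dim(nuclei$label)))
    stop("focus channel and nucleus labels have different shapes", call. = FALSE)
  px <- nuclei$pixel_size
  nz <- dim(stack)[3]
  if (is.null(central_planes)) {
    mid <- ceiling(nz / 2)
    central_planes <- max(1, mid - 1):min(nz, mid + 1)
  }
  for (z in seq_len(nz))
    stack[, , z] <- subtract_background(stack[, , z], rolling_ball_radius)
  mip <- gaussian_smooth(max_project(stack, central_planes), smooth_sigma)

  out <- list()
  nr <- nrow(mip)
  for (k in nuclei$nuclei$nucleus) {
    idx <- which(nuclei$label == k)
    v <- mip[idx]
    # with mad = 0 (noise-free channel) anything above the flat median is signal
    thr <- median(v) + threshold_k * mad(v)
    if (!is.finite(thr)) next
    sub <- matrix(FALSE, nr, ncol(mip))
    sub[idx] <- v > thr
    comp <- cpp_label_components(sub)
    for (f in seq_len(max(comp))) {
      fi <- which(comp == f)
      i <- ((fi - 1) %% nr) + 1
      j <- ((fi - 1) %/% nr) + 1
      w <- mip[fi]
      # split touching foci at the local maxima of the projection
      # (plateau-tolerant: maxima closer than 2 px merge to the brighter)
      loc <- vapply(seq_along(fi), function(t) {
        nbh <- mip[max(1, i[t] - 2):min(nr, i[t] + 2),
                   max(1, j[t] - 2):min(ncol(mip), j[t] + 2)]
        w[t] >= max(nbh) - 1e-12
      }, logical(1))
      mi <- i[loc]; mj <- j[loc]; mv <- w[loc]
      keep_i <- keep_j <- numeric(0)
      for (t in order(mv, decreasing = TRUE)) {
        if (length(keep_i) == 0 ||
            min((mi[t] - keep_i)^2 + (mj[t] - keep_j)^2) > 4) {
          keep_i <- c(keep_i, mi[t]); keep_j <- c(keep_j, mj[t])
        }
      }
      if (length(keep_i) == 0) { keep_i <- i[which.max(w)]; keep_j <- j[which.max(w)] }
      part <- max.col(-(outer(i, keep_i, "-")^2 + outer(j, keep_j, "-")^2),
                      ties.method = "first")
      for (p in seq_along(keep_i)) {
        sel <- part == p
        wp <- w[sel]
        pk <- max(wp)
        ci <- sum(i[sel] * wp) / sum(wp)
        cj <- sum(j[sel] * wp) / sum(wp)
        # size from a fitted Gaussian width on a window around the focus
        # (in-nucleus pixels, other foci excluded), deconvolved for the
        # smoothing kernel: physical half-maximum area
        # = 2 pi ln2 (sigma^2 - sigma_smooth^2)
        bi <- max(1, round(ci) - 5):min(nr, round(ci) + 5)
        bj <- max(1, round(cj) - 5):min(ncol(mip), round(cj) + 5)
        bg <- as.matrix(expand.grid(bi = bi, bj = bj))
        bgidx <- (bg[, 2] - 1) * nr + bg[, 1]
        pidx <- (j[sel] - 1) * nr + i[sel]
        use <- nuclei$label[bgidx] == k & !(sub[bgidx] & !(bgidx %in% pidx))
        sig <- if (sum(use) >= 8)
          fit_focus_sigma(bg[use, 1], bg[use, 2], mip[bgidx[use]], ci, cj)
        else sqrt(sum(sel) / pi)
        area <- 2 * pi * log(2) *
          max(sig^2 - smooth_sigma^2, 0.05) * px^2
        if (area < min_focus_area) next
        out[[length(out) + 1]] <- data.frame(
          nucleus = k,
          x_um = px_to_um(cj - 1, px),
          y_um = px_to_um(ci - 1, px),
          area_um2 = area, peak = pk)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(nucleus = integer(0), x_um = numeric(0),
                         y_um = numeric(0), area_um2 = numeric(0),
                         peak = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("focus_set", "data.frame")
  res
}

#' Quality-control filter for segmented nuclei
#'
#' Flags nuclei to exclude from focus statistics: `pan_stained` when the
#' thresholded focus-channel area covers more than `pan_fraction` of the
#' nucleus (pan-stained nuclei cannot be scored focus-by-focus),
#' `apoptotic` when the nucleus is small (`area < apoptotic_area`) or
#' ragged (`solidity < min_solidity`), and `border` for nuclei touching
#' the field edge (kept for hit assignment, excluded from area
#' statistics). The focus-channel stain threshold is the robust global
#' background level (`median + 4 x MAD` of the projected channel).
#'
#' @param nuclei A `nucleus_set`.
#' @param foci_channel A `cell_layer`, 3D array or matrix (focus channel).
#' @param pan_fraction Stained-area fraction above which a nucleus is
#'   pan-stained.
#' @param apoptotic_area Area below which a nucleus is called apoptotic,
#'   um^2.
#' @param min_solidity Solidity below which a nucleus is called apoptotic.
#' @return The `nucleus_set` with columns `qc_flags` (comma-separated) and
#'   `qc_pass` added to `$nuclei`.
#' @export
qc_filter_nuclei <- function(nuclei, foci_channel, pan_fraction = 0.4,
                             apoptotic_area = 25, min_solidity = 0.7) {
  stopifnot(inherits(nuclei, "nucleus_set"))
  if (inherits(foci_channel, "cell_layer")) foci_channel <- foci_channel$foci
  mip <- max_project(foci_channel)
  if (!all(dim(mip) == dim(nuclei$label)))
    stop("focus channel and nucleus labels have different shapes", call. = FALSE)
  thr <- median(mip) + 4 * mad(mip)
  tab <- nuclei$nuclei
  flags <- character(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    k <- tab$nucleus[r]
    idx <- which(nuclei$label == k)
    fl <- character(0)
    if (mean(mip[idx] > thr) > pan_fraction) fl <- c(fl, "pan_stained")
    if (tab$area_um2[r] < apoptotic_area || tab$solidity[r] < min_solidity)
      fl <- c(fl, "apoptotic")
    if (tab$on_border[r]) fl <- c(fl, "border")
    flags[r] <- paste(fl, collapse = ",")
  }
  tab$qc_flags <- flags
  tab$qc_pass <- !grepl("pan_stained|apoptotic", flags)
  nuclei$nuclei <- tab
  nuclei
}

#' Per-condition focus statistics with background correction
#'
#' Mean foci per QC-passing nucleus minus the spontaneous background rate
#' (floored at zero and flagged), the mean focus area, and standard
#' errors over nuclei / foci.
#'
#' @param foci A `focus_set` (or any data frame with a `nucleus` column
#'   and optionally `area_um2`).
#' @param nuclei A `nucleus_set`; nuclei failing QC (if
#'   [qc_filter_nuclei()] was run) are excluded.
#' @param background_per_nucleus Spontaneous foci per nucleus subtracted
#'   from the raw mean (default 0.16).
#' @param time_h Optional timepoint tag carried into [repair_kinetics()].
#' @return A `foci_stats` list: `n_nuclei`, `mean_foci_raw`, `mean_foci`
#'   (corrected), `sem_foci`, `mean_focus_area`, `sem_focus_area`,
#'   `floored`, `time_h`.
#' @export
foci_statistics <- function(foci, nuclei, background_per_nucleus = 0.16,
                            time_h = NA_real_) {
  stopifnot(inherits(nuclei, "nucleus_set"))
  tab <- nuclei$nuclei
  if ("qc_pass" %in% names(tab)) tab <- tab[tab$qc_pass, , drop = FALSE]
  if (nrow(tab) == 0) stop("all nuclei flagged by QC", call. = FALSE)
  counts <- vapply(tab$nucleus, function(k) sum(foci$nucleus == k), numeric(1))
  raw <- mean(counts)
  corrected <- raw - background_per_nucleus
  floored <- corrected < 0
  corrected <- max(corrected, 0)
  in_pass <- foci$nucleus %in% tab$nucleus
  areas <- if ("area_um2" %in% names(foci)) foci$area_um2[in_pass] else numeric(0)
  structure(list(n_nuclei = nrow(tab), mean_foci_raw = raw,
                 mean_foci = corrected,
                 sem_foci = sd(counts) / sqrt(length(counts)),
                 mean_focus_area = if (length(areas)) mean(areas) else NA_real_,
                 sem_focus_area = if (length(areas) > 1)
                   sd(areas) / sqrt(length(areas)) else NA_real_,
                 floored = floored, time_h = time_h,
                 background = background_per_nucleus),
            class = "foci_stats")
}

#' Residual focus fractions over a repair time course
#'
#' Residual fraction at each timepoint relative to the first (baseline,
#' by default 0.5 h): the ratio of background-corrected mean focus counts.
#' In the clinical reference data photons resolve 97.7% of foci by 72 h
#' (residual 0.023) while carbon and oxygen ions leave 15.3% and 17.6%.
#'
#' @param x Either a time-course data frame with columns `time_h` and
#'   `foci` (per-nucleus counts, e.g. from [generate_timecourse()]), or a
#'   list of `foci_stats` each carrying `time_h`.
#' @param baseline_time Baseline timepoint, hours.
#' @param background Spontaneous foci per nucleus subtracted from raw
#'   means (data-frame input only; `foci_stats` are already corrected).
#' @return Data frame: `time_h`, `mean_foci` (corrected),
#'   `residual_fraction`.
#' @examples
#' tc <- generate_timecourse(20, 0.153, seed = 1)
#' repair_kinetics(tc)
#' @export
repair_kinetics <- function(x, baseline_time = 0.5, background = 0.16) {
  if (is.data.frame(x)) {
    stopifnot(all(c("time_h", "foci") %in% names(x)))
    agg <- aggregate(foci ~ time_h, x, mean)
    agg$mean_foci <- pmax(agg$foci - background, 0)
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "foci_stats"))) {
    agg <- data.frame(time_h = vapply(x, `[[`, numeric(1), "time_h"),
                      mean_foci = vapply(x, `[[`, numeric(1), "mean_foci"))
  } else stop("'x' must be a time-course data frame or a list of foci_stats",
              call. = FALSE)
  agg <- agg[order(agg$time_h), c("time_h", "mean_foci")]
  base <- agg$mean_foci[agg$time_h == baseline_time]
  if (length(base) != 1 || !is.finite(base) || base <= 0)
    stop("baseline timepoint missing or its corrected mean is zero", call. = FALSE)
  agg$residual_fraction <- agg$mean_foci / base
  if (any(agg$residual_fraction > 1.5))
    warning("residual fraction above 1.5; check background correction")
  rownames(agg) <- NULL
  agg
}

#' Correlate a focus metric with clonogenic survival
#'
#' Ordinary least-squares line of surviving fraction against a
#' per-condition focus metric (count or size), with the Pearson R^2 and
#' the two-sided p-value of the slope. Foci metrics that increase with
#' LET while survival decreases give a negative slope.
#'
#' @param metric Per-condition focus metric (>= 3 values).
#' @param survival Per-condition surviving fractions, same length.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
correlate_with_survival <- function(metric, survival) {
  ok <- is.finite(metric) & is.finite(survival)
  metric <- metric[ok]; survival <- survival[ok]
  if (length(metric) < 3) stop("need >= 3 conditions", call. = FALSE)
  if (sd(metric) == 0) stop("metric is constant; correlation undefined", call. = FALSE)
  fm <- lm(survival ~ metric)
  s <- suppressWarnings(summary(fm))  # exact collinearity is a valid input
  list(slope = unname(coef(fm)[2]), intercept = unname(coef(fm)[1]),
       r_squared = s$r.squared, p_value = s$coefficients[2, 4],
       n = length(metric))
}

#' @export
print.foci_stats <- function(x, ...) {
  cat(sprintf("Foci statistics (n = %d nuclei%s): %.2f foci/nucleus (raw %.2f, bg %.2f)%s\n",
              x$n_nuclei,
              if (is.finite(x$time_h)) sprintf(", t = %g h", x$time_h) else "",
              x$mean_foci, x$mean_foci_raw, x$background,
              if (isTRUE(x$floored)) " [floored]" else ""))
  if (is.finite(x$mean_focus_area))
    cat(sprintf("  mean focus area %.3f um^2\n", x$mean_focus_area))
  invisible(x)
}
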