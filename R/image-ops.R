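## Thin R wrappers around the compiled morphology kernels. Images are
## numeric matrices indexed [row, col] = [y, x], 0-based pixel centres when
## converted to physical coordinates.

disc_offsets <- function(radius) {
  r <- as.integer(radius)
  stopifnot(r >= 0)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
  g
}

#' Grayscale morphology with a disc structuring element
#'
#' Erosion, dilation, opening and white top-hat with a disc of the given
#' pixel radius, replicate-padded at the image border. The white top-hat
#' (image minus its opening) is the spot-enhancement filter used by the
#' FNTD read-out.
#'
#' @param img Numeric matrix.
#' @param radius Disc radius in pixels (>= 1).
#' @return Numeric matrix of the same size.
#' @export
morph_erode <- function(img, radius) {
  o <- disc_offsets(radius)
  cpp_morph(img, o$dr, o$dc, dilate = FALSE)
}

#' @rdname morph_erode
#' @export
morph_dilate <- function(img, radius) {
  o <- disc_offsets(radius)
  cpp_morph(img, o$dr, o$dc, dilate = TRUE)
}

#' @rdname morph_erode
#' @export
morph_open <- function(img, radius) {
  morph_dilate(morph_erode(img, radius), radius)
}

#' @rdname morph_erode
#' @export
tophat_white <- function(img, radius = 3) {
  img - morph_open(img, radius)
}

## Opening with a large square structuring element via separable 1D passes;
## O(n) in radius is not needed at these sizes, the naive window is fine.
open_square <- function(img, half_width) {
  e <- cpp_morph_line(img, half_width, dilate = FALSE, along_rows = TRUE)
  e <- cpp_morph_line(e, half_width, dilate = FALSE, along_rows = FALSE)
  d <- cpp_morph_line(e, half_width, dilate = TRUE, along_rows = TRUE)
  cpp_morph_line(d, half_width, dilate = TRUE, along_rows = FALSE)
}

#' Rolling-ball style background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image
#' (separable square structuring element of half-width `radius`) and
#' subtracts it — the standard morphological stand-in for ImageJ's
#' rolling-ball filter; for structures smaller than `radius` the two
#' agree closely.
#'
#' @param img Numeric matrix.
#' @param radius Background scale in pixels; structures larger than this
#'   survive into the background estimate.
#' @return Background-subtracted matrix (non-negative).
#' @export
subtract_background <- function(img, radius = 50) {
  stopifnot(radius >= 1)
  bg <- open_square(img, as.integer(radius))
  pmax(img - bg, 0)
}

#' Median filter
#'
#' @param img Numeric matrix.
#' @param radius Half-width of the square window in pixels.
#' @return Filtered matrix.
#' @export
median_filter <- function(img, radius = 2) {
  cpp_median_filter(img, as.integer(radius))
}

#' Label connected components of a binary mask
#'
#' 8-connectivity; labels are 1..n in scan order.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  storage.mode(mask) <- "logical"
  cpp_label_components(mask)
}

#' Euclidean distance transform
#'
#' Exact distance in pixels from each `TRUE` pixel to the nearest `FALSE`
#' pixel (0 outside the mask).
#'
#' @param mask Logical matrix.
#' @return Numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  storage.mode(mask) <- "logical"
  cpp_edt(mask)
}

#' Gaussian smoothing
#'
#' Separable Gaussian convolution (replicate padding), the matched-filter
#' style denoising step used before spot detection.
#'
#' @param img Numeric matrix.
#' @param sigma Gaussian sigma in pixels.
#' @return Smoothed matrix.
#' @export
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  cpp_convolve_sep(img, k / sum(k))
}

#' Otsu's threshold
#'
#' Between-class-variance-maximising split of an intensity sample,
#' computed on a fixed-width histogram.
#'
#' @param x Numeric vector.
#' @param n_bins Number of histogram bins.
#' @return Threshold value (midpoint of the optimal split bin edge).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || diff(range(x)) == 0)
    stop("otsu_threshold: need a non-degenerate sample", call. = FALSE)
  br <- seq(min(x), max(x), length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  # the criterion is flat across an empty gap: take the plateau centre
  best <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))
  k <- round(mean(range(best)))
  br[k + 1]
}

## Gaussian blob accumulation: adds amplitude*exp(-d^2/(2 sigma^2)) blobs at
## subpixel centres (in pixel units) onto an image. Vectorised per blob over
## a +-4 sigma window.
render_blobs <- function(img, x_px, y_px, amplitude, sigma_px) {
  nr <- nrow(img); nc <- ncol(img)
  sigma_px <- rep_len(sigma_px, length(x_px))
  for (s in seq_along(x_px)) {
    w <- max(1L, ceiling(4 * sigma_px[s]))
    cx <- x_px[s]; cy <- y_px[s]
    j0 <- max(0L, floor(cx) - w); j1 <- min(nc - 1L, ceiling(cx) + w)
    i0 <- max(0L, floor(cy) - w); i1 <- min(nr - 1L, ceiling(cy) + w)
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    gx <- exp(-((jj - cx)^2) / (2 * sigma_px[s]^2))
    gy <- exp(-((ii - cy)^2) / (2 * sigma_px[s]^2))
    img[ii + 1L, jj + 1L] <- img[ii + 1L, jj + 1L] + amplitude[s] * outer(gy, gx)
  }
  img
}
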