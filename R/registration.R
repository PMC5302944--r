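## Registration of the FNTD spot plane to the cell-layer focus image by a
## single global translation, and one-to-one track/focus pairing.

nearest_displacements <- function(sx, sy, fx, fy, max_search) {
  n <- length(sx)
  dx <- dy <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    d2 <- (fx - sx[s])^2 + (fy - sy[s])^2
    j <- which.min(d2)
    if (length(j) && d2[j] <= max_search^2) {
      dx[s] <- fx[j] - sx[s]
      dy[s] <- fy[j] - sy[s]
    }
  }
  cbind(dx, dy)
}

#' Estimate the detector-to-cell-layer translation
#'
#' The cell layer moves by a few micrometres between the detector
#' irradiation and the microscope read-out, so every track/focus pair is
#' offset by one common vector (~3 um in the clinical data). The estimate
#' is the component-wise median of nearest-neighbour displacement vectors
#' within `max_search`, iterated twice (after applying the current
#' estimate the matches are recomputed), which is robust to foci without
#' tracks and tracks without foci.
#'
#' @param spots Primary track spots: data frame with `x_um`, `y_um`.
#' @param foci Foci: data frame with `x_um`, `y_um`.
#' @param max_search Largest displacement considered, um.
#' @return A `translation_estimate`: list with `dx`, `dy` (um),
#'   `n_pairs`, `n_inliers`, `residual_spread` (median residual norm,
#'   um), and `reliable` (FALSE when the inlier excess over chance is
#'   poor).
#' @examples
#' s <- data.frame(x_um = runif(20, 0, 50), y_um = runif(20, 0, 50))
#' f <- data.frame(x_um = s$x_um + 3, y_um = s$y_um)
#' estimate_translation(s, f)
#' @export
estimate_translation <- function(spots, foci, max_search = 10) {
  if (nrow(spots) < 5 || nrow(foci) < 5)
    stop("need >= 5 spots and >= 5 foci", call. = FALSE)
  sx <- spots$x_um; sy <- spots$y_um
  fx <- foci$x_um; fy <- foci$y_um
  est <- c(0, 0)
  for (it in 1:2) {
    d <- nearest_displacements(sx + est[1], sy + est[2], fx, fy, max_search)
    ok <- complete.cases(d)
    if (sum(ok) < 5)
      stop("fewer than 5 candidate displacement pairs within max_search",
           call. = FALSE)
    est <- est + c(median(d[ok, 1]), median(d[ok, 2]))
  }
  d <- nearest_displacements(sx + est[1], sy + est[2], fx, fy, max_search)
  ok <- complete.cases(d)
  resid <- sqrt(d[ok, 1]^2 + d[ok, 2]^2)
  mar <- median(resid)
  inl <- resid <= 3 * max(mar, 1e-9)
  # polish with the inlier mean: the median is robust but statistically
  # inefficient once outliers are excluded
  if (sum(inl) >= 5) {
    est <- est + c(mean(d[ok, 1][inl]), mean(d[ok, 2][inl]))
    d <- nearest_displacements(sx + est[1], sy + est[2], fx, fy, max_search)
    ok <- complete.cases(d)
    resid <- sqrt(d[ok, 1]^2 + d[ok, 2]^2)
    mar <- median(resid)
    inl <- resid <= 3 * max(mar, 1e-9)
  }
  # chance level: expected nearest-neighbour hits if foci were unrelated
  # (uniform) — compare the inlier radius disc to the search disc
  chance <- sum(ok) * min(1, (3 * max(mar, 1e-9) / max_search)^2)
  structure(list(dx = est[1], dy = est[2], n_pairs = sum(ok),
                 n_inliers = sum(inl), residual_spread = mar,
                 reliable = sum(inl) > max(5, 2 * chance)),
            class = "translation_estimate")
}

#' Pair tracks with foci after registration
#'
#' Greedy one-to-one nearest-neighbour assignment: candidate pairs within
#' `max_match_distance` of the translated spot positions are taken in
#' order of increasing separation, each spot and each focus used at most
#' once.
#'
#' @param spots Track spots: data frame with `x_um`, `y_um`.
#' @param foci Foci: data frame with `x_um`, `y_um`.
#' @param translation A `translation_estimate` or c(dx, dy) um.
#' @param max_match_distance Largest accepted pair separation, um
#'   (default 5, the clinical ~3 um offset plus focus-position
#'   uncertainty).
#' @return List with `pairs` (data frame: `spot`, `focus`,
#'   `separation_um` — row indices into the inputs), `unmatched_spots`,
#'   `unmatched_foci`.
#' @export
match_tracks_to_foci <- function(spots, foci, translation,
                                 max_match_distance = 5) {
  tr <- if (inherits(translation, "translation_estimate"))
    c(translation$dx, translation$dy) else as.numeric(translation)
  if (length(tr) != 2 || any(!is.finite(tr)))
    stop("'translation' must be a finite (dx, dy)", call. = FALSE)
  ns <- nrow(spots); nf <- nrow(foci)
  pairs <- data.frame(spot = integer(0), focus = integer(0),
                      separation_um = numeric(0))
  if (ns > 0 && nf > 0 && max_match_distance > 0) {
    sx <- spots$x_um + tr[1]; sy <- spots$y_um + tr[2]
    d <- sqrt(outer(sx, foci$x_um, "-")^2 + outer(sy, foci$y_um, "-")^2)
    cand <- which(d <= max_match_distance, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_s <- logical(ns); used_f <- logical(nf)
      for (r in seq_len(nrow(cand))) {
        s <- cand[r, 1]; f <- cand[r, 2]
        if (used_s[s] || used_f[f]) next
        used_s[s] <- TRUE; used_f[f] <- TRUE
        pairs <- rbind(pairs, data.frame(spot = s, focus = f,
                                         separation_um = d[s, f]))
      }
    }
  }
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_spots = setdiff(seq_len(ns), pairs$spot),
       unmatched_foci = setdiff(seq_len(nf), pairs$focus))
}

#' @export
print.translation_estimate <- function(x, ...) {
  cat(sprintf("Translation (%.3f, %.3f) um; %d pairs, %d inliers, spread %.3f um%s\n",
              x$dx, x$dy, x$n_pairs, x$n_inliers, x$residual_spread,
              if (!x$reliable) " [unreliable]" else ""))
  invisible(x)
}
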