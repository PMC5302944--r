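# Shared evaluation helpers: one-to-one greedy matching of detections to
# ground truth within a distance limit, and the derived recall/precision.

match_one_to_one <- function(xa, ya, xb, yb, limit) {
  if (length(xa) == 0 || length(xb) == 0) return(0L)
  d <- sqrt(outer(xa, xb, "-")^2 + outer(ya, yb, "-")^2)
  used_a <- logical(length(xa))
  used_b <- logical(length(xb))
  tp <- 0L
  for (r in order(d)) {
    if (d[r] > limit) break
    i <- (r - 1) %% length(xa) + 1
    j <- (r - 1) %/% length(xa) + 1
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- used_b[j] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

detection_metrics <- function(spots, truth, limit) {
  tp <- match_one_to_one(spots$x_um, spots$y_um, truth$x_um, truth$y_um, limit)
  list(recall = tp / nrow(truth), precision = tp / nrow(spots), tp = tp)
}

# independent bisection root-finder for the isosurvival dose
bisect_dose <- function(alpha, beta, level, lo = 0, hi = 1000, tol = 1e-12) {
  f <- function(d) exp(-alpha * d - beta * d^2) - level
  stopifnot(f(lo) > 0, f(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
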