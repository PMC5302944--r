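#' Simulate a clonogenic survival experiment
#'
#' Draws colony counts for a dose series under the linear-quadratic (LQ)
#' cell-survival model SF(D) = exp(-alpha*D - beta*D^2) with Poisson
#' counting noise, mimicking a plated clonogenic assay scored in
#' triplicate. The expected colony count per well is
#' `cells_seeded * plating_efficiency * SF(D)`; surviving fractions are
#' normalised to the mean colony count of the 0 Gy control, which is
#' added to the dose series if absent.
#'
#' @param alpha LQ linear coefficient, 1/Gy (>= 0).
#' @param beta LQ quadratic coefficient, 1/Gy^2 (>= 0; 0 gives the pure
#'   linear model used for ion beams).
#' @param doses Dose levels in Gy (>= 0). Default is the clinical QC
#'   series 0.25, 1, 2, 4 Gy.
#' @param cells_seeded Cells plated per well.
#' @param plating_efficiency Fraction of unirradiated cells that form a
#'   colony (> 0, <= 1).
#' @param replicates Wells per dose (default 3, triplicates).
#' @param noise If `FALSE`, expected (non-integer) colony counts are
#'   emitted exactly, so surviving fractions equal the model values.
#' @param quality A [beam_quality()] tag carried through to the fit stage.
#' @param seed Integer seed; every draw is reproducible given it.
#' @return A `survival_dataset`: a data frame with columns `dose_Gy`,
#'   `replicate`, `colonies`, `surviving_fraction`, plus attributes
#'   `quality`, `truth` (the generating `alpha`/`beta`), `cells_seeded`
#'   and `plating_efficiency`.
#' @examples
#' d <- generate_survival_table(0.173, 0.032, seed = 1)
#' head(d)
#' @export
generate_survival_table <- function(alpha, beta, doses = c(0, 0.25, 1, 2, 4),
                                    cells_seeded = 500, plating_efficiency = 0.5,
                                    replicates = 3, noise = TRUE,
                                    quality = beam_quality("photon"),
                                    seed = NULL) {
  if (!all(is.finite(c(alpha, beta, doses, cells_seeded, plating_efficiency))))
    stop("generate_survival_table: all parameters must be finite", call. = FALSE)
  if (alpha < 0 || beta < 0) stop("'alpha' and 'beta' must be >= 0", call. = FALSE)
  if (any(doses < 0)) stop("'doses' must be >= 0", call. = FALSE)
  if (plating_efficiency <= 0 || plating_efficiency > 1)
    stop("'plating_efficiency' must be in (0, 1]", call. = FALSE)
  if (!0 %in% doses) doses <- c(0, doses)
  doses <- sort(unique(doses))
  if (!is.null(seed)) set.seed(seed)

  grid <- expand.grid(replicate = seq_len(replicates), dose_Gy = doses)
  grid <- grid[order(grid$dose_Gy, grid$replicate), c("dose_Gy", "replicate")]
  expected <- cells_seeded * plating_efficiency *
    exp(-alpha * grid$dose_Gy - beta * grid$dose_Gy^2)
  grid$colonies <- if (noise) rpois(nrow(grid), expected) else expected

  ref <- mean(grid$colonies[grid$dose_Gy == 0])
  if (ref <= 0) {
    # pathological control plate: fall back to the design expectation so
    # downstream normalisation stays finite
    warning("0 Gy control yielded no colonies; normalising by the expected count")
    ref <- cells_seeded * plating_efficiency
  }
  grid$surviving_fraction <- grid$colonies / ref
  rownames(grid) <- NULL
  structure(grid,
            class = c("survival_dataset", "data.frame"),
            quality = quality,
            truth = list(alpha = alpha, beta = beta),
            cells_seeded = cells_seeded,
            plating_efficiency = plating_efficiency)
}

#' Assemble a survival dataset from dose / surviving-fraction values
#'
#' Wraps a plain table (e.g. read from CSV) into the `survival_dataset`
#' container the fitting functions expect. Either `surviving_fraction` or
#' `colonies` (with a 0 Gy control present for normalisation) must be
#' given.
#'
#' @param dose_Gy Dose per observation, Gy.
#' @param surviving_fraction Surviving fraction per observation (0, 1].
#' @param colonies Optional colony counts; carried along for weighting.
#' @param replicate Optional replicate ids.
#' @param quality A [beam_quality()].
#' @return A `survival_dataset` data frame.
#' @export
survival_dataset <- function(dose_Gy, surviving_fraction = NULL, colonies = NULL,
                             replicate = NULL, quality = beam_quality("photon")) {
  dose_Gy <- as.numeric(dose_Gy)
  if (any(!is.finite(dose_Gy)) || any(dose_Gy < 0))
    stop("'dose_Gy' must be finite and >= 0", call. = FALSE)
  if (is.null(surviving_fraction)) {
    if (is.null(colonies)) stop("need 'surviving_fraction' or 'colonies'", call. = FALSE)
    ref <- mean(colonies[dose_Gy == 0])
    if (!is.finite(ref) || ref <= 0)
      stop("normalising by colonies requires a 0 Gy control with colonies > 0",
           call. = FALSE)
    surviving_fraction <- colonies / ref
  }
  if (any(surviving_fraction[dose_Gy > 0] <= 0, na.rm = TRUE))
    warning("surviving fractions <= 0 present; they are dropped at fit time")
  df <- data.frame(dose_Gy = dose_Gy,
                   replicate = if (is.null(replicate)) seq_along(dose_Gy) else replicate,
                   colonies = if (is.null(colonies)) NA_real_ else colonies,
                   surviving_fraction = surviving_fraction)
  structure(df, class = c("survival_dataset", "data.frame"), quality = quality,
            truth = NULL)
}
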