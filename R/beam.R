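#' Describe a radiation quality
#'
#' A light-weight record of the beam a dataset belongs to: particle
#' species, dose-averaged linear energy transfer (LETd) and the planned
#' particle fluence. Photons carry no LET or fluence.
#'
#' @param species One of `"photon"`, `"proton"`, `"helium"`, `"carbon"`,
#'   `"oxygen"`.
#' @param let_d Dose-averaged LET in keV/um, or `NA` (photons).
#' @param fluence Planned particle fluence in particles/cm^2, or `NA`.
#' @return An object of class `beam_quality`.
#' @examples
#' beam_quality("carbon", let_d = 95.2, fluence = 3.8e6)
#' @export
beam_quality <- function(species = c("photon", "proton", "helium", "carbon", "oxygen"),
                         let_d = NA_real_, fluence = NA_real_) {
  species <- match.arg(species)
  let_d <- as.numeric(let_d)
  fluence <- as.numeric(fluence)
  if (!is.na(let_d) && (!is.finite(let_d) || let_d <= 0))
    stop("'let_d' must be positive when given", call. = FALSE)
  if (!is.na(fluence) && (!is.finite(fluence) || fluence < 0))
    stop("'fluence' must be non-negative when given", call. = FALSE)
  structure(list(species = species, let_d = let_d, fluence = fluence),
            class = "beam_quality")
}

#' @export
format.beam_quality <- function(x, ...) {
  sprintf("<beam_quality: %s%s%s>", x$species,
          if (is.na(x$let_d)) "" else sprintf(", LETd %.1f keV/um", x$let_d),
          if (is.na(x$fluence)) "" else sprintf(", fluence %.3g /cm2", x$fluence))
}

#' @export
print.beam_quality <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
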