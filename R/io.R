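## Plain-text I/O. The environment this package targets has no TIFF
## library, so images travel as portable graymap (PGM, P2 ASCII) files
## with a JSON sidecar for physical metadata; object tables are CSV.

#' Write / read an image as ASCII PGM with a JSON metadata sidecar
#'
#' Values are rounded to integers after scaling to the stated maximum.
#' The sidecar (`<path>.json`) records `pixel_size_um` and, if given,
#' `dwell_time_us`, so a round-trip restores physical coordinates.
#'
#' @param img Numeric matrix.
#' @param path Output file path (`.pgm`).
#' @param pixel_size_um Pixel pitch, um.
#' @param dwell_time_us Optional dwell time, us.
#' @param max_value PGM maximum gray value.
#' @return `write_pgm` returns `path` invisibly; `read_pgm` returns a
#'   list with `image`, `pixel_size_um`, `dwell_time_us`.
#' @export
write_pgm <- function(img, path, pixel_size_um, dwell_time_us = NULL,
                      max_value = 65535) {
  scale <- if (max(img) > 0) max_value / max(img) else 1
  m <- round(pmax(img, 0) * scale)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(max_value)), con)
  write(t(m), file = con, ncolumns = ncol(img))
  meta <- list(pixel_size_um = pixel_size_um, intensity_scale = scale)
  if (!is.null(dwell_time_us)) meta$dwell_time_us <- dwell_time_us
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("only ASCII PGM (P2) supported", call. = FALSE)
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  img <- matrix(vals, nr, nc, byrow = TRUE)
  meta <- list(pixel_size_um = NA_real_, dwell_time_us = NULL, intensity_scale = 1)
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- utils::modifyList(meta, jsonlite::read_json(side))
  list(image = img / meta$intensity_scale,
       pixel_size_um = meta$pixel_size_um,
       dwell_time_us = meta$dwell_time_us)
}

#' Read a clonogenic survival table from CSV
#'
#' Expected columns: `dose_Gy`, optionally `replicate`, and either
#' `surviving_fraction` or `colonies` (normalised to the 0 Gy control).
#' An optional `quality` column (species name) tags the dataset.
#'
#' @param path CSV file path.
#' @return A `survival_dataset`.
#' @export
read_survival_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"dose_Gy" %in% names(df)) stop("CSV must have a 'dose_Gy' column", call. = FALSE)
  quality <- if ("quality" %in% names(df)) beam_quality(df$quality[1])
             else beam_quality("photon")
  survival_dataset(dose_Gy = df$dose_Gy,
                   surviving_fraction = df[["surviving_fraction"]],
                   colonies = df[["colonies"]],
                   replicate = df[["replicate"]],
                   quality = quality)
}
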