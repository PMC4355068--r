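#' Read and write qPCR plate CSVs
#'
#' Plate files have columns `sample_id`, `target`, `role` (`standard` or
#' `unknown`), `ct` and `standard_mass` (ng; empty for unknowns).
#'
#' @param path CSV file path.
#' @return `read_qpcr_plate` returns a `qpcr_plate` data frame.
#' @export
read_qpcr_plate <- function(path) {
  plate <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "target", "role", "ct", "standard_mass")
  if (!all(req %in% names(plate))) {
    stop(sprintf("plate CSV must have columns: %s",
                 paste(req, collapse = ", ")), call. = FALSE)
  }
  bad <- plate$role == "standard" &
    (is.na(plate$standard_mass) | plate$standard_mass <= 0)
  if (any(bad)) {
    stop("standard wells must carry a positive standard_mass", call. = FALSE)
  }
  class(plate) <- c("qpcr_plate", "data.frame")
  plate
}

#' @rdname read_qpcr_plate
#' @param plate A qPCR plate data frame.
#' @export
write_qpcr_plate <- function(plate, path) {
  write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' Read and write mechanics records as CSV
#'
#' Column layouts by maneuver kind: snapshot `time, volume, flow, pressure`;
#' spectrum `frequency, z_real, z_imag`; pv `limb, pressure, volume`.
#'
#' @param path CSV file path.
#' @param kind One of `"snapshot"`, `"spectrum"`, `"pv"`.
#' @return `read_mechanics_record` returns a `mechanics_record`.
#' @export
read_mechanics_record <- function(path, kind = c("snapshot", "spectrum",
                                                 "pv")) {
  kind <- match.arg(kind)
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- switch(kind,
                snapshot = c("time", "volume", "pressure"),
                spectrum = c("frequency", "z_real", "z_imag"),
                pv = c("limb", "pressure", "volume"))
  if (!all(req %in% names(d))) {
    stop(sprintf("%s CSV must have columns: %s", kind,
                 paste(req, collapse = ", ")), call. = FALSE)
  }
  mechanics_record(kind, d)
}

#' @rdname read_mechanics_record
#' @param record A `mechanics_record`.
#' @export
write_mechanics_record <- function(record, path) {
  stopifnot(inherits(record, "mechanics_record"))
  write.csv(record$data, path, row.names = FALSE)
  invisible(path)
}

#' Write and read tissue masks and field images as grayscale PNG
#'
#' Masks are stored as 8-bit grayscale with tissue white (255); any pixel
#' above half intensity reads back as tissue. Field images are rescaled to
#' the 8-bit range.
#'
#' @param mask A [tissue_mask()].
#' @param path PNG file path.
#' @param pixel_size Micrometres per pixel (needed when reading, since PNG
#'   carries no physical calibration).
#' @return `read_mask_png` returns a `tissue_mask`.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "tissue_mask"))
  png::writePNG(mask$pixels * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, pixel_size) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  tissue_mask(img > 0.5, pixel_size)
}

#' @rdname write_mask_png
#' @param field A `histology_field`.
#' @export
write_field_png <- function(field, path) {
  stopifnot(inherits(field, "histology_field"))
  hi <- max(field$image, 1)
  png::writePNG(pmin(pmax(field$image / hi, 0), 1), path)
  invisible(path)
}
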