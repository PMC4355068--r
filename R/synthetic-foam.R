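#' Parameters of the synthetic alveolar foam generator
#'
#' Describes one synthetic histology field: a two-dimensional Voronoi foam
#' whose cell boundaries play the role of alveolar septal walls. The mean
#' airspace size is controlled through the nucleus density (`n_seeds` per
#' field area), and the septal thickness through `wall_thickness`.
#'
#' The default geometry, 1050.0 x 698.5 um sampled at 0.5 um per pixel, is
#' calibrated so that the default morphometry grid of 7 horizontal plus 6
#' vertical lines (see [build_grid()]) has a total length of exactly
#' 11,541 um.
#'
#' @param field_width,field_height Field dimensions in micrometres.
#' @param pixel_size Micrometres per pixel.
#' @param n_seeds Number of airspace nuclei (Voronoi seeds); at least 2.
#' @param wall_thickness Septal wall thickness in micrometres.
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @return An object of class `foam_params`.
#' @seealso [generate_alveolar_field()]
#' @export
foam_params <- function(field_width = 1050.0, field_height = 698.5,
                        pixel_size = 0.5, n_seeds = 400L,
                        wall_thickness = 8, seed = 1L) {
  stop_if_not_scalar_pos(field_width, "field_width")
  stop_if_not_scalar_pos(field_height, "field_height")
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  stop_if_not_scalar_pos(wall_thickness, "wall_thickness")
  if (!is.numeric(n_seeds) || length(n_seeds) != 1L || n_seeds < 1) {
    stop("'n_seeds' must be a single count >= 1", call. = FALSE)
  }
  structure(list(field_width = field_width, field_height = field_height,
                 pixel_size = pixel_size, n_seeds = as.integer(n_seeds),
                 wall_thickness = wall_thickness, seed = as.integer(seed)),
            class = "foam_params")
}

#' Binary tissue mask
#'
#' A rectangular boolean pixel grid in which `TRUE` encodes tissue and
#' `FALSE` airspace, together with the physical pixel size. This is the
#' substrate of all morphometry operations.
#'
#' @param pixels Logical matrix (rows = image rows).
#' @param pixel_size Micrometres per pixel.
#' @return An object of class `tissue_mask`.
#' @export
tissue_mask <- function(pixels, pixel_size) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix", call. = FALSE)
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  storage.mode(pixels) <- "logical"
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("tissue_mask: %d x %d px at %.3g um/px (%.0f x %.0f um), tissue fraction %.3f\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              ncol(x$pixels) * x$pixel_size, nrow(x$pixels) * x$pixel_size,
              mean(x$pixels)))
  invisible(x)
}

#' Generate a synthetic alveolar histology field with known tissue mask
#'
#' Places `n_seeds` airspace nuclei uniformly in the field and marks as
#' tissue every pixel lying within half a wall thickness of the Voronoi
#' boundary between its two nearest nuclei. The grayscale image renders the
#' tissue at `tissue_intensity` on a dark airspace background and adds a
#' smooth planar illumination gradient; the returned blank field carries the
#' same gradient, emulating the per-slide blank used for background
#' correction.
#'
#' @param params A [foam_params()] object.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise on
#'   the image (intensity units); the blank stays noise-free and the mask is
#'   always exact.
#' @param tissue_intensity Intensity added on tissue pixels.
#' @param gradient_amplitude Peak-to-trough amplitude of the shared
#'   background gradient.
#' @param slide_id,field_id Labels carried through to the field object.
#' @return A list with components `field` (class `histology_field`: `image`,
#'   `blank`, `pixel_size`, `slide_id`, `field_id`) and `mask` (class
#'   `tissue_mask`), the exact ground truth.
#' @examples
#' fm <- generate_alveolar_field(foam_params(n_seeds = 50, pixel_size = 2))
#' mean(fm$mask$pixels)   # tissue fraction
#' @export
generate_alveolar_field <- function(params, noise_sd = 0,
                                    tissue_intensity = 180,
                                    gradient_amplitude = 40,
                                    slide_id = "slide1", field_id = "field1") {
  stopifnot(inherits(params, "foam_params"))
  if (params$n_seeds < 2) {
    stop("degenerate geometry: n_seeds = 1 yields no Voronoi boundary",
         call. = FALSE)
  }
  nx <- as.integer(round(params$field_width / params$pixel_size))
  ny <- as.integer(round(params$field_height / params$pixel_size))
  out <- with_seed(params$seed, {
    sx <- runif(params$n_seeds, 0, params$field_width)
    sy <- runif(params$n_seeds, 0, params$field_height)
    px <- foam_wall_mask_cpp(nx, ny, sx, sy, params$pixel_size,
                             params$wall_thickness)
    # shared planar illumination gradient (same for image and blank)
    gx <- runif(1, -1, 1); gy <- runif(1, -1, 1)
    xs <- (seq_len(nx) - 0.5) / nx
    ysv <- (seq_len(ny) - 0.5) / ny
    grad <- gradient_amplitude *
      (outer(ysv, xs, function(y, x) (gx * x + gy * y + 1) / 2))
    img <- tissue_intensity * px + grad
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    img[img < 0] <- 0
    list(px = px, img = img, grad = grad)
  })
  field <- structure(list(image = out$img, blank = out$grad,
                          pixel_size = params$pixel_size,
                          slide_id = slide_id, field_id = field_id),
                     class = "histology_field")
  list(field = field, mask = tissue_mask(out$px, params$pixel_size))
}

#' Remove septal wall segments to emulate emphysematous destruction
#'
#' Identifies the distinct septal wall segments of a tissue mask — each
#' segment being the sheet of tissue separating one specific pair of
#' airspaces — and deletes a given proportion of them at random, merging the
#' adjacent airspaces. This emulates the alveolar tissue obliteration seen
#' in emphysema; the mean free chord length across airspaces can only grow.
#'
#' Segments are found from the mask alone: airspaces are labelled as
#' 4-connected components and every tissue pixel is attributed to its two
#' nearest airspace components by geodesic distance through tissue. Tissue
#' reachable from fewer than two airspaces (e.g. walls clipped by the image
#' frame) is never removed.
#'
#' @param mask A [tissue_mask()].
#' @param fraction Proportion of wall segments to remove, in \[0, 1\].
#' @param seed Integer RNG seed for the segment draw.
#' @return A `tissue_mask` with a tissue pixel count no larger than the
#'   input's.
#' @export
apply_septal_destruction <- function(mask, fraction, seed = 1L) {
  stopifnot(inherits(mask, "tissue_mask"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1) {
    stop("'fraction' must be a single number in [0, 1]", call. = FALSE)
  }
  if (fraction == 0) return(mask)
  seg <- wall_segments_cpp(mask$pixels)
  if (seg$n_segments == 0L) return(mask)
  n_remove <- round(fraction * seg$n_segments)
  if (n_remove == 0) return(mask)
  removed <- with_seed(seed, sample.int(seg$n_segments, n_remove))
  px <- mask$pixels
  px[seg$segment %in% removed] <- FALSE
  tissue_mask(px, mask$pixel_size)
}

#' Monte-Carlo chord-length oracle for a tissue mask
#'
#' Casts random test lines across the mask and returns the total test-line
#' length divided by the total number of tissue intercepts (maximal tissue
#' runs along a line). This estimates the same quantity as the grid-based
#' mean linear intercept, but by exhaustive random sampling rather than a
#' fixed grid, and serves as the independent ground truth for the
#' morphometry pipeline.
#'
#' @param mask A [tissue_mask()] containing both tissue and airspace.
#' @param n_chords Number of test lines.
#' @param seed Integer RNG seed.
#' @param orientation `"alternate"` (default; horizontal and vertical lines
#'   interleaved), `"horizontal"` or `"vertical"`.
#' @return Estimated mean linear intercept in micrometres.
#' @export
oracle_mean_chord_length <- function(mask, n_chords = 2000L, seed = 1L,
                                     orientation = c("alternate",
                                                     "horizontal",
                                                     "vertical")) {
  stopifnot(inherits(mask, "tissue_mask"))
  orientation <- match.arg(orientation)
  px <- mask$pixels
  ny <- nrow(px); nx <- ncol(px)
  if (!any(px)) stop("no tissue intersected", call. = FALSE)
  horiz <- switch(orientation,
                  alternate  = rep(c(TRUE, FALSE), length.out = n_chords),
                  horizontal = rep(TRUE, n_chords),
                  vertical   = rep(FALSE, n_chords))
  res <- with_seed(seed, {
    rows <- sample.int(ny, n_chords, replace = TRUE)
    cols <- sample.int(nx, n_chords, replace = TRUE)
    total_len <- 0
    total_int <- 0L
    for (i in seq_len(n_chords)) {
      v <- if (horiz[i]) px[rows[i], ] else px[, cols[i]]
      r <- rle(as.vector(v))
      total_int <- total_int + sum(r$values)
      total_len <- total_len + length(v) * mask$pixel_size
    }
    list(len = total_len, int = total_int)
  })
  if (res$int == 0L) stop("no tissue intersected", call. = FALSE)
  res$len / res$int
}
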