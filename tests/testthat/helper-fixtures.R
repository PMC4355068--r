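# Small, fast fixture generators shared across test files. Unit tests use a
# reduced field (300 x 200 um at 1 um/px) so each foam builds in a few
# milliseconds; the acceptance tests exercise the full default geometry.

small_foam_params <- function(seed = 1L, n_seeds = 60L, wall_thickness = 6) {
  foam_params(field_width = 300, field_height = 200, pixel_size = 1,
              n_seeds = n_seeds, wall_thickness = wall_thickness,
              seed = seed)
}

# vertical tissue stripes of a given pitch and width (um), 1 um/px
striped_mask <- function(nx = 1000, ny = 200, pitch = 100, wall_px = 6) {
  px <- matrix(FALSE, ny, nx)
  starts <- seq(1, nx, by = pitch)
  for (s in starts) px[, s:min(s + wall_px - 1, nx)] <- TRUE
  tissue_mask(px, 1)
}

make_fields <- function(n, params_fn = small_foam_params, ...) {
  lapply(seq_len(n), function(i) {
    generate_alveolar_field(params_fn(seed = i), ...,
                            field_id = sprintf("f%02d", i))$field
  })
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
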