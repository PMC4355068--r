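test_that("field selection is uniform, deterministic and bounded", {
  fields <- make_fields(5)
  expect_length(select_fields(fields, k = 20, seed = 1), 5)
  expect_error(select_fields(list(), k = 5), "empty")

  dummy <- lapply(1:100, function(i) list(field_id = i))
  s1 <- select_fields(dummy, k = 20, seed = 99)
  s2 <- select_fields(dummy, k = 20, seed = 99)
  expect_identical(s1, s2)

  # uniformity: selection frequency of each field is 0.20 +/- 0.02
  hits <- integer(100)
  for (s in 1:10000) {
    idx <- vapply(select_fields(dummy, k = 20, seed = s),
                  function(f) f$field_id, numeric(1))
    hits[idx] <- hits[idx] + 1L
  }
  freq <- hits / 10000
  expect_true(all(abs(freq - 0.20) <= 0.02))
})

test_that("field QC rejects empty fields and dominant lumina", {
  empty <- tissue_mask(matrix(FALSE, 100, 100), 1)
  qc <- field_qc(empty)
  expect_false(qc$accepted)
  expect_identical(qc$reason, "insufficient_tissue")

  fm <- generate_alveolar_field(small_foam_params(seed = 4))
  expect_true(field_qc(fm$mask)$accepted)

  # carve a lumen covering ~30% of the field: rejected at the 10% rule
  px <- fm$mask$pixels
  ny <- nrow(px); nx <- ncol(px)
  px[seq_len(round(0.55 * ny)), seq_len(round(0.55 * nx))] <- FALSE
  qc2 <- field_qc(tissue_mask(px, 1), max_lumen_fraction = 0.10)
  expect_false(qc2$accepted)
  expect_identical(qc2$reason, "large_lumen")

  expect_error(field_qc(fm$mask, min_tissue_fraction = 0), "thresholds")
})

test_that("background subtraction is pixelwise with zero clipping", {
  fm <- generate_alveolar_field(small_foam_params(seed = 6))
  f <- fm$field
  same <- f; same$blank <- f$image
  expect_true(all(subtract_background(same) == 0))
  nob <- f; nob$blank <- f$blank * 0
  expect_equal(as.vector(subtract_background(nob)), as.vector(f$image))
  bad <- f; bad$blank <- f$blank[-1, ]
  expect_error(subtract_background(bad), "shape")
})

test_that("segmentation recovers the mask exactly at zero noise and well under noise", {
  # two-level image: both methods return the bright-level set exactly
  img <- matrix(0, 50, 80); img[10:20, 30:60] <- 200
  attr(img, "pixel_size") <- 1
  m_otsu <- segment_tissue(img, "otsu")
  m_fix <- segment_tissue(img, "fixed", threshold = 100)
  truth <- unname(img > 100)
  expect_identical(unname(m_otsu$pixels), truth)
  expect_identical(unname(m_fix$pixels), truth)

  expect_error(segment_tissue(matrix(5, 10, 10), "otsu", pixel_size = 1),
               "no threshold")
  expect_error(segment_tissue(img, "fixed"), "threshold")

  fm0 <- generate_alveolar_field(small_foam_params(seed = 8), noise_sd = 0)
  seg0 <- segment_tissue(subtract_background(fm0$field), "otsu")
  expect_identical(seg0$pixels, fm0$mask$pixels)

  fmn <- generate_alveolar_field(small_foam_params(seed = 8), noise_sd = 20)
  segn <- segment_tissue(subtract_background(fmn$field), "otsu")
  jac <- sum(segn$pixels & fmn$mask$pixels) /
    sum(segn$pixels | fmn$mask$pixels)
  expect_gte(jac, 0.95)
})

test_that("grid construction conserves total length", {
  g <- build_grid(10, 10, n_horizontal = 1, n_vertical = 1)
  expect_equal(g$total_length, 20)
  for (i in 1:20) {
    w <- runif(1, 50, 2000); h <- runif(1, 50, 2000)
    nh <- sample(1:9, 1); nv <- sample(1:9, 1)
    g <- build_grid(w, h, nh, nv)
    per_line <- c(rep(w, nh), rep(h, nv))
    expect_equal(g$total_length, sum(per_line))
    expect_true(all(g$horizontal_y > 0 & g$horizontal_y < h))
    expect_true(all(g$vertical_x > 0 & g$vertical_x < w))
  }
  expect_error(build_grid(100, 100, n_horizontal = 0), "at least one")
})

test_that("intercept counting matches exhaustive counts on constructed masks", {
  g <- build_grid(100, 100)
  empty <- tissue_mask(matrix(FALSE, 100, 100), 1)
  expect_equal(count_intercepts(empty, g, "runs")$total, 0)
  expect_equal(count_intercepts(empty, g, "object_emulation")$total, 0)
  expect_error(compute_mli(g, count_intercepts(empty, g)), "undefined")

  # one vertical wall away from any vertical grid line: one run per
  # horizontal line, no tissue-covered crossings
  px <- matrix(FALSE, 100, 100); px[, 2:4] <- TRUE
  wall <- tissue_mask(px, 1)
  expect_equal(count_intercepts(wall, g, "runs")$total, 7)
  em <- count_intercepts(wall, g, "object_emulation")
  expect_equal(em$crossing_corrections, 0)
  expect_equal(em$total, 7)

  # all tissue: 13 full-line runs; emulation sees one fused object plus one
  # correction per grid crossing (7 x 6)
  full <- tissue_mask(matrix(TRUE, 100, 100), 1)
  expect_equal(count_intercepts(full, g, "runs")$total, 13)
  emf <- count_intercepts(full, g, "object_emulation")
  expect_equal(emf$line_intercepts, 1)
  expect_equal(emf$crossing_corrections, 42)
  expect_equal(emf$total, 43)
})

test_that("counting modes agree on sparse masks", {
  fm <- generate_alveolar_field(small_foam_params(seed = 12, n_seeds = 30,
                                                  wall_thickness = 4))
  expect_lt(mean(fm$mask$pixels), 0.25)
  g <- build_grid(300, 200)
  runs <- count_intercepts(fm$mask, g, "runs")$total
  em <- count_intercepts(fm$mask, g, "object_emulation")$total
  expect_lte(abs(runs - em) / runs, 0.02)
})

test_that("MLI arithmetic, aggregation and invariances", {
  g <- build_grid(1050, 698.5)
  cnt <- structure(list(line_intercepts = 100L, crossing_corrections = 0L,
                        total = 100L), class = "intercept_count")
  expect_equal(compute_mli(g, cnt), 115.41)
  cnt$total <- 1L
  expect_equal(compute_mli(g, cnt), g$total_length)
  half <- cnt; half$total <- 50L
  dbl <- cnt; dbl$total <- 100L
  expect_equal(compute_mli(g, half), 2 * compute_mli(g, dbl))

  expect_equal(aggregate_lung(c(60, 80))$lung_mli, 70)
  expect_equal(aggregate_lung(42)$lung_mli, 42)
  expect_error(aggregate_lung(numeric(0)), "no field")

  # rotation robustness: transpose the mask, swap grid orientation
  fm <- generate_alveolar_field(small_foam_params(seed = 13))
  g1 <- build_grid(300, 200, 7, 6)
  g2 <- build_grid(200, 300, 6, 7)
  tm <- tissue_mask(t(fm$mask$pixels), fm$mask$pixel_size)
  expect_equal(count_intercepts(fm$mask, g1)$total,
               count_intercepts(tm, g2)$total)

  # scale covariance: pixel_size x s scales MLI by s exactly
  s <- 2.5
  scaled <- tissue_mask(fm$mask$pixels, fm$mask$pixel_size * s)
  expect_equal(mask_mli(scaled), s * mask_mli(fm$mask))
})

test_that("pipeline lung MLI agrees with the chord oracle on a small foam", {
  masks <- lapply(1:20, function(i) {
    generate_alveolar_field(small_foam_params(seed = 100 + i,
                                              n_seeds = 40))$mask
  })
  mli <- aggregate_lung(vapply(masks, mask_mli, numeric(1)))$lung_mli
  oracle <- mean(vapply(masks, oracle_mean_chord_length,
                        numeric(1), n_chords = 2000, seed = 5))
  expect_lt(rel_err(mli, oracle), 0.05)
})

test_that("the full pipeline runs end to end from images", {
  fields <- make_fields(8, noise_sd = 10)
  out <- run_mli_pipeline(fields, k = 6, seed = 2)
  expect_s3_class(out$result, "mli_result")
  expect_equal(out$result$n_fields, sum(out$per_field$accepted))
  expect_true(all(out$per_field$mli[out$per_field$accepted] > 0))
})
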