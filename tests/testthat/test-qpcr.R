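test_that("a perfect-doubling standard curve gives slope -3.3219 and 100% efficiency", {
  masses <- 50 / 2^(0:5)
  plate <- data.frame(sample_id = paste0("std", 1:6), target = "telomere",
                      role = "standard",
                      ct = 40 - (1 / log10(2)) * log10(masses),
                      standard_mass = masses)
  curve <- fit_standard_curve(plate, "telomere")
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(curve$efficiency, 1, tolerance = 1e-9)
  expect_equal(curve$r2, 1, tolerance = 1e-12)
})

test_that("standard-curve fitting validates its inputs", {
  one_level <- data.frame(sample_id = paste0("s", 1:4), target = "t",
                          role = "standard", ct = c(20, 20.1, 19.9, 20),
                          standard_mass = rep(10, 4))
  expect_error(fit_standard_curve(one_level, "t"), "distinct")

  inverted <- data.frame(sample_id = paste0("s", 1:4), target = "t",
                         role = "standard", ct = c(10, 12, 14, 16),
                         standard_mass = c(1, 10, 100, 1000))
  expect_error(fit_standard_curve(inverted, "t"), "inverted")

  noisy <- data.frame(sample_id = paste0("s", 1:6), target = "t",
                      role = "standard", ct = c(18, 22, 20, 26, 24, 30),
                      standard_mass = 50 / 2^(0:5))
  expect_warning(fit_standard_curve(noisy, "t"), "below 0.98")
})

test_that("Ct-to-quantity inverts the curve", {
  curve <- structure(list(slope = -1 / log10(2), intercept = 25, r2 = 1,
                          efficiency = 1, target = "t", n_standards = 6),
                     class = "standard_curve")
  expect_equal(ct_to_quantity(curve, 25), 1)
  expect_equal(ct_to_quantity(curve, 25 + curve$slope), 10)
  expect_equal(ct_to_quantity(curve, 25 + 2 * curve$slope), 100,
               tolerance = 1e-12)
})

test_that("curve slope is recovered from a noisy printed-range series", {
  true_slope <- -3.4
  reps <- vapply(1:50, function(s) {
    sim <- qpcr_sim_params(slope = true_slope, intercept = 24,
                           ct_noise_sd = 0.1, seed = s)
    pl <- simulate_qpcr_plate(sim, data.frame(sample_id = "m", target = "t",
                                              mass = 10))
    fit_standard_curve(pl, "t")$slope
  }, numeric(1))
  expect_lt(rel_err(median(reps), true_slope), 0.05)
})

test_that("ATLR arithmetic and invariances", {
  expect_equal(compute_atlr(5, 5)$atlr, 1)
  expect_equal(compute_atlr(10, 5)$atlr, 2)
  expect_error(compute_atlr(0, 5), "> 0")

  # ATLR is invariant to rescaling both standard series by a common factor
  sim <- qpcr_sim_params(ct_noise_sd = 0)
  sm <- data.frame(sample_id = rep("m1", 2),
                   target = c("telomere", "36B4"), mass = c(18, 20))
  a1 <- plate_atlr(simulate_qpcr_plate(sim, sm))$atlr
  scaled <- simulate_qpcr_plate(sim, sm)
  scale_rows <- scaled$role == "standard"
  scaled$standard_mass[scale_rows] <- scaled$standard_mass[scale_rows] * 3
  a2 <- plate_atlr(scaled)$atlr
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a1, 0.9, tolerance = 1e-9)
})

test_that("group mean ATLR is recovered without bias under Ct noise", {
  atlr_true <- 0.85
  ratios <- vapply(1:200, function(s) {
    sim <- qpcr_sim_params(ct_noise_sd = 0.1, seed = s)
    s_mass <- rep(20, 12)
    sm <- rbind(data.frame(sample_id = paste0("ctl", 1:6),
                           target = "telomere", mass = s_mass[1:6]),
                data.frame(sample_id = paste0("ctl", 1:6),
                           target = "36B4", mass = s_mass[1:6]),
                data.frame(sample_id = paste0("trt", 1:6),
                           target = "telomere",
                           mass = atlr_true * s_mass[7:12]),
                data.frame(sample_id = paste0("trt", 1:6),
                           target = "36B4", mass = s_mass[7:12]))
    res <- plate_atlr(simulate_qpcr_plate(sim, sm))
    trt <- grepl("^trt", res$sample_id)
    mean(res$atlr[trt]) / mean(res$atlr[!trt])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - atlr_true), 0.05 * atlr_true)
})

test_that("relative expression normalizes to the reference and the controls", {
  sim <- qpcr_sim_params(ct_noise_sd = 0)
  sm <- rbind(data.frame(sample_id = c("c1", "c2", "t1", "t2"),
                         target = "p16", mass = c(5, 5, 10, 10)),
              data.frame(sample_id = c("c1", "c2", "t1", "t2"),
                         target = "GAPDH", mass = 8))
  res <- relative_expression(simulate_qpcr_plate(sim, sm), "p16",
                             control_samples = c("c1", "c2"))
  expect_equal(res$fold_vs_control[res$sample_id %in% c("c1", "c2")],
               c(1, 1), tolerance = 1e-9)
  expect_equal(res$fold_vs_control[res$sample_id %in% c("t1", "t2")],
               c(2, 2), tolerance = 1e-9)

  same <- rbind(data.frame(sample_id = paste0("s", 1:4), target = "p16",
                           mass = 6),
                data.frame(sample_id = paste0("s", 1:4), target = "GAPDH",
                           mass = 8))
  res2 <- relative_expression(simulate_qpcr_plate(sim, same), "p16",
                              control_samples = "s1")
  expect_true(all(abs(res2$fold_vs_control - 1) < 1e-9))

  expect_error(relative_expression(simulate_qpcr_plate(sim, sm), "p16",
                                   reference = "actin",
                                   control_samples = "c1"),
               "reference")
})

test_that("a simulated one-week p16 induction is recovered", {
  folds <- vapply(1:40, function(s) {
    sim <- qpcr_sim_params(ct_noise_sd = 0.1, seed = 1000 + s)
    sm <- rbind(data.frame(sample_id = paste0("c", 1:7), target = "p16",
                           mass = 4),
                data.frame(sample_id = paste0("t", 1:7), target = "p16",
                           mass = 4 * 1.8),
                data.frame(sample_id = c(paste0("c", 1:7), paste0("t", 1:7)),
                           target = "GAPDH", mass = 10))
    res <- relative_expression(simulate_qpcr_plate(sim, sm), "p16",
                               control_samples = paste0("c", 1:7))
    mean(res$fold_vs_control[grepl("^t", res$sample_id)])
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1.8), 0.15)
})
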