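#' Parameters of the qPCR plate simulator
#'
#' Log-linear amplification model: `Ct = intercept + slope * log10(ng)` plus
#' Gaussian Ct noise. A slope of `-1/log10(2)` (about -3.3219 Ct per decade)
#' corresponds to perfect doubling efficiency.
#'
#' @param slope Ct change per log10(ng); must be negative.
#' @param intercept Ct at 1 ng of template.
#' @param ct_noise_sd Standard deviation of per-well Ct noise.
#' @param dilution_series Standard-series template masses in ng, strictly
#'   positive and strictly decreasing. The default is the six-point 2-fold
#'   lung series from 50 down to 1.5625 ng.
#' @param seed Integer RNG seed.
#' @return An object of class `qpcr_sim_params`.
#' @export
qpcr_sim_params <- function(slope = -1 / log10(2), intercept = 22,
                            ct_noise_sd = 0,
                            dilution_series = 50 / 2^(0:5), seed = 1L) {
  if (slope >= 0) stop("'slope' must be negative", call. = FALSE)
  if (ct_noise_sd < 0) stop("'ct_noise_sd' must be >= 0", call. = FALSE)
  if (any(dilution_series <= 0) || any(diff(dilution_series) >= 0)) {
    stop("'dilution_series' must be strictly positive and strictly decreasing",
         call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 ct_noise_sd = ct_noise_sd,
                 dilution_series = dilution_series,
                 seed = as.integer(seed)),
            class = "qpcr_sim_params")
}

#' Simulate a qPCR plate with standards and unknown samples
#'
#' For every target appearing in `sample_masses`, lays down one standard
#' series (role `"standard"`, masses from `sim$dilution_series`) and one
#' well per sample (role `"unknown"`), generating each Ct from the
#' log-linear model in [qpcr_sim_params()]. All targets share the same curve
#' unless `target_offsets` shifts a target's intercept, which mimics
#' reactions of differing baseline yield run on the same plate.
#'
#' @param sim A [qpcr_sim_params()].
#' @param sample_masses Data frame with columns `sample_id`, `target`,
#'   `mass` (ng of template per well); one row per sample well.
#' @param target_offsets Optional named numeric vector of per-target
#'   intercept shifts (Ct units).
#' @return A `qpcr_plate` data frame (columns `sample_id`, `target`, `role`,
#'   `ct`, `standard_mass`).
#' @seealso [fit_standard_curve()], [ct_to_quantity()]
#' @export
simulate_qpcr_plate <- function(sim, sample_masses, target_offsets = NULL) {
  stopifnot(inherits(sim, "qpcr_sim_params"))
  req <- c("sample_id", "target", "mass")
  if (!all(req %in% names(sample_masses))) {
    stop("'sample_masses' needs columns sample_id, target, mass",
         call. = FALSE)
  }
  if (any(sample_masses$mass <= 0)) {
    stop("all sample masses must be > 0", call. = FALSE)
  }
  targets <- unique(as.character(sample_masses$target))
  std <- do.call(rbind, lapply(targets, function(tg) {
    data.frame(sample_id = sprintf("std_%s_%d", tg,
                                   seq_along(sim$dilution_series)),
               target = tg, role = "standard",
               mass = sim$dilution_series,
               standard_mass = sim$dilution_series,
               stringsAsFactors = FALSE)
  }))
  unk <- data.frame(sample_id = as.character(sample_masses$sample_id),
                    target = as.character(sample_masses$target),
                    role = "unknown", mass = sample_masses$mass,
                    standard_mass = NA_real_, stringsAsFactors = FALSE)
  wells <- rbind(std, unk)
  off <- rep(0, nrow(wells))
  if (!is.null(target_offsets)) {
    hit <- wells$target %in% names(target_offsets)
    off[hit] <- target_offsets[wells$target[hit]]
  }
  ct <- sim$intercept + off + sim$slope * log10(wells$mass)
  if (sim$ct_noise_sd > 0) {
    ct <- ct + with_seed(sim$seed, rnorm(length(ct), 0, sim$ct_noise_sd))
  }
  plate <- data.frame(sample_id = wells$sample_id, target = wells$target,
                      role = wells$role, ct = ct,
                      standard_mass = wells$standard_mass,
                      stringsAsFactors = FALSE)
  class(plate) <- c("qpcr_plate", "data.frame")
  plate
}
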