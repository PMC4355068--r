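#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(template mass, ng) over the
#' standard wells of one target. The amplification efficiency implied by
#' the slope is `10^(-1/slope) - 1`: a slope of -3.3219 Ct per decade means
#' perfect doubling (100%).
#'
#' @param plate A qPCR plate data frame (columns `sample_id`, `target`,
#'   `role`, `ct`, `standard_mass`), e.g. from [simulate_qpcr_plate()] or
#'   [read_qpcr_plate()].
#' @param target Target label whose standards to fit.
#' @return An object of class `standard_curve`: `slope`, `intercept`
#'   (Ct at 1 ng), `r2`, `efficiency`, `target`, `n_standards`. A curve
#'   r-squared below 0.98 raises a warning.
#' @export
fit_standard_curve <- function(plate, target) {
  std <- plate[plate$target == target & plate$role == "standard", ]
  std <- std[is.finite(std$ct) & !is.na(std$standard_mass), ]
  if (length(unique(std$standard_mass)) < 3) {
    stop(sprintf("need >= 3 distinct standard masses for target '%s'",
                 target), call. = FALSE)
  }
  fit <- lm(ct ~ log10(standard_mass), data = std)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) stop("inverted curve: slope >= 0", call. = FALSE)
  r2 <- 1 - sum(fit$residuals^2) / sum((std$ct - mean(std$ct))^2)
  if (r2 < 0.98) {
    warning(sprintf("standard curve r2 = %.4f below 0.98 for target '%s'",
                    r2, target), call. = FALSE)
  }
  structure(list(slope = slope, intercept = unname(coef(fit)[1]), r2 = r2,
                 efficiency = 10^(-1 / slope) - 1, target = target,
                 n_standards = nrow(std)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve [%s]: Ct = %.4f %+.4f * log10(ng), r2 = %.4f, efficiency = %.1f%%\n",
              x$target, x$intercept, x$slope, x$r2, 100 * x$efficiency))
  invisible(x)
}

#' Convert Ct values to template quantities via a standard curve
#'
#' Inverts the fitted log-linear curve: `ng = 10^((ct - intercept)/slope)`.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param ct Numeric vector of Ct values.
#' @return Template quantities in ng (vectorized over `ct`).
#' @export
ct_to_quantity <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Average telomere length ratio (T/S)
#'
#' Ratio of the telomere-reaction template quantity to the single-copy-gene
#' (36B4) quantity for the same sample, both in ng as read off their
#' standard curves.
#'
#' @param t_mass Telomere-reaction quantity, ng (> 0).
#' @param s_mass Single-copy (36B4) quantity, ng (> 0).
#' @return An object of class `atlr_result` with `T`, `S` and `atlr = T/S`.
#' @export
compute_atlr <- function(t_mass, s_mass) {
  if (any(t_mass <= 0) || any(s_mass <= 0)) {
    stop("T and S quantities must be > 0", call. = FALSE)
  }
  structure(list(T = t_mass, S = s_mass, atlr = t_mass / s_mass),
            class = "atlr_result")
}

#' Per-sample ATLR from a plate
#'
#' Fits the telomere and single-copy standard curves, converts each
#' sample's Ct values to ng (replicate wells averaged on the mass scale)
#' and returns T, S and their ratio per sample.
#'
#' @param plate A qPCR plate data frame.
#' @param telomere,single_copy Target labels of the telomere and
#'   single-copy-gene reactions.
#' @return Data frame with columns `sample_id`, `T`, `S`, `atlr`.
#' @export
plate_atlr <- function(plate, telomere = "telomere", single_copy = "36B4") {
  curve_t <- fit_standard_curve(plate, telomere)
  curve_s <- fit_standard_curve(plate, single_copy)
  mean_mass <- function(target, curve) {
    unk <- plate[plate$target == target & plate$role == "unknown", ]
    tapply(ct_to_quantity(curve, unk$ct), unk$sample_id, mean)
  }
  tq <- mean_mass(telomere, curve_t)
  sq <- mean_mass(single_copy, curve_s)
  ids <- intersect(names(tq), names(sq))
  if (length(ids) == 0) stop("no sample has both reactions", call. = FALSE)
  data.frame(sample_id = ids, T = unname(tq[ids]), S = unname(sq[ids]),
             atlr = unname(tq[ids] / sq[ids]), stringsAsFactors = FALSE)
}

#' Reference-normalized relative expression from standard curves
#'
#' Standard-curve relative quantification: target and reference (GAPDH)
#' quantities are read off their own curves, replicate wells are averaged on
#' the mass scale, the per-sample ratio is target/reference, and fold
#' change is that ratio divided by the mean ratio of the control samples.
#'
#' @param plate A qPCR plate data frame.
#' @param target Target gene label (e.g. `"p16"`).
#' @param reference Reference gene label (default `"GAPDH"`).
#' @param control_samples Character vector of control-group sample ids.
#' @return Data frame with columns `sample_id`, `target_qty`,
#'   `reference_qty`, `ratio`, `fold_vs_control`.
#' @export
relative_expression <- function(plate, target, reference = "GAPDH",
                                control_samples) {
  if (length(control_samples) == 0) {
    stop("'control_samples' is empty", call. = FALSE)
  }
  if (!any(plate$target == reference)) {
    stop(sprintf("no wells for reference '%s'", reference), call. = FALSE)
  }
  curve_t <- fit_standard_curve(plate, target)
  curve_r <- fit_standard_curve(plate, reference)
  get_q <- function(tg, curve) {
    unk <- plate[plate$target == tg & plate$role == "unknown", ]
    tapply(ct_to_quantity(curve, unk$ct), unk$sample_id, mean)
  }
  tq <- get_q(target, curve_t)
  rq <- get_q(reference, curve_r)
  ids <- intersect(names(tq), names(rq))
  ratio <- tq[ids] / rq[ids]
  ctrl <- intersect(ids, as.character(control_samples))
  if (length(ctrl) == 0) {
    stop("no control sample present on the plate", call. = FALSE)
  }
  data.frame(sample_id = ids, target_qty = unname(tq[ids]),
             reference_qty = unname(rq[ids]), ratio = unname(ratio),
             fold_vs_control = unname(ratio / mean(ratio[ctrl])),
             stringsAsFactors = FALSE)
}
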