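#' Fit the single-compartment model to a snapshot record
#'
#' Ordinary least squares of the equation of motion
#' `P = E*V + R*Vdot + P0` on the recorded pressure; compliance is the
#' reciprocal of the fitted elastance, so `E = 1/C` holds exactly in every
#' returned fit. When the record lacks a flow column it is derived from
#' volume by central differences.
#'
#' @param record A `mechanics_record` of kind `"snapshot"` (>= 10 samples).
#' @return An object of class `snapshot_fit`: `R` (cmH2O.s/mL), `C`
#'   (mL/cmH2O), `E` (cmH2O/mL), `P0` (cmH2O), `r2`.
#' @export
fit_snapshot <- function(record) {
  stopifnot(inherits(record, "mechanics_record"), record$kind == "snapshot")
  d <- record$data
  if (nrow(d) < 10) stop("need >= 10 samples", call. = FALSE)
  if (is.null(d$flow)) {
    d$flow <- central_diff(d$volume, d$time[2] - d$time[1])
  }
  if (sd(d$volume) == 0) {
    stop("rank-deficient design: constant volume", call. = FALSE)
  }
  fit <- lm(pressure ~ volume + flow, data = d)
  E <- unname(coef(fit)["volume"])
  R <- unname(coef(fit)["flow"])
  r2 <- 1 - sum(fit$residuals^2) /
    sum((d$pressure - mean(d$pressure))^2)
  structure(list(R = R, C = 1 / E, E = E,
                 P0 = unname(coef(fit)["(Intercept)"]), r2 = r2),
            class = "snapshot_fit")
}

# residual sum of squares of the constant-phase model at a given alpha,
# with (Rn, I, G) solved linearly and H tied as G * tan(alpha * pi / 2)
cp_profile <- function(alpha, w, zr, zi) {
  t_a <- tan(alpha * pi / 2)
  wa <- w^(-alpha)
  # stacked real/imag system in (Rn, G, I):
  #   Re(Z) = Rn + G * w^-alpha
  #   Im(Z) = I * w - G * t_a * w^-alpha
  X <- rbind(cbind(1, wa, 0),
             cbind(0, -t_a * wa, w))
  y <- c(zr, zi)
  b <- tryCatch(unname(qr.solve(qr(X), y)), error = function(e) NULL)
  if (is.null(b)) return(list(rss = Inf))
  rss <- sum((y - X %*% b)^2)
  list(rss = rss, Rn = b[1], G = b[2], I = b[3], H = b[2] * t_a)
}

#' Fit the constant-phase model to an impedance spectrum
#'
#' Minimizes the summed squared modulus of the complex residual
#' `Z_obs - [Rn + i*w*I + (G - i*H)/w^alpha]` with the phase exponent tied
#' to the tissue parameters, `alpha = (2/pi)*atan(H/G)`. The non-convex
#' problem is solved by profiling: for fixed `alpha` the model is linear in
#' `(Rn, G, I)` with `H = G*tan(alpha*pi/2)`, so the fit reduces to a 1-D
#' search over `alpha`, scanned from multiple starts (including those
#' implied by hysteresivity values 0.05, 0.1, 0.2 and 0.5) and refined by
#' golden-section optimization. Hysteresivity `eta = G/H` and the alpha tie
#' hold to machine precision in the result.
#'
#' @param record A `mechanics_record` of kind `"spectrum"` with at least 5
#'   frequencies.
#' @return An object of class `constant_phase_fit`: `Rn`, `I`, `G`, `H`,
#'   `alpha`, `eta`, `r2`.
#' @export
fit_constant_phase <- function(record) {
  stopifnot(inherits(record, "mechanics_record"), record$kind == "spectrum")
  d <- record$data
  if (nrow(d) < 5) stop("need >= 5 frequencies", call. = FALSE)
  w <- 2 * pi * d$frequency
  zr <- d$z_real; zi <- d$z_imag
  eta_starts <- c(0.05, 0.1, 0.2, 0.5)
  alphas <- sort(unique(c((2 / pi) * atan(1 / eta_starts),
                          seq(0.05, 0.98, by = 0.015))))
  rss <- vapply(alphas, function(a) cp_profile(a, w, zr, zi)$rss, numeric(1))
  ok <- is.finite(rss)
  if (!any(ok)) stop("constant-phase fit failed to converge at any start",
                     call. = FALSE)
  best <- which.min(rss)
  lo <- alphas[max(1, best - 1)]
  hi <- alphas[min(length(alphas), best + 1)]
  opt <- optimize(function(a) cp_profile(a, w, zr, zi)$rss, c(lo, hi),
                  tol = 1e-10)
  sol <- cp_profile(opt$minimum, w, zr, zi)
  if (!is.finite(sol$rss) || sol$G <= 0 || sol$H <= 0) {
    stop(sprintf(paste0("constant-phase fit non-convergent: best alpha %.4f",
                        " gives G = %.4g, H = %.4g"),
                 opt$minimum, sol$G, sol$H), call. = FALSE)
  }
  y <- c(zr, zi)
  r2 <- 1 - sol$rss / sum((y - mean(y))^2)
  structure(list(Rn = sol$Rn, I = sol$I, G = sol$G, H = sol$H,
                 alpha = opt$minimum, eta = sol$G / sol$H, r2 = r2),
            class = "constant_phase_fit")
}

# shoelace area of a closed polygon
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Fit the Salazar-Knowles equation to a pressure-volume loop
#'
#' Nonlinear least squares of `V = A - B*exp(-K*P)` on the deflation limb
#' (Levenberg-Marquardt). Derived quantities: static compliance
#' `Cst = B*K*exp(-K*p_ref)` — the slope of the fitted deflation limb at the
#' reference pressure — static elastance `Est = 1/Cst` (exact), inspiratory
#' capacity `IC` as the fitted volume excursion from P = 0 to the maneuver
#' maximum, and the hysteresis area enclosed between the limbs (shoelace
#' formula on the recorded loop).
#'
#' @param record A `mechanics_record` of kind `"pv"` whose deflation limb
#'   has at least 5 points and reaches P = 0.
#' @param p_ref Reference pressure (cmH2O) at which `Cst` is evaluated;
#'   default 5.
#' @return An object of class `pv_fit`: `A`, `B`, `K`, `Cst`, `Est`, `IC`,
#'   `hysteresis_area`, `r2`.
#' @export
fit_salazar_knowles <- function(record, p_ref = 5) {
  stopifnot(inherits(record, "mechanics_record"), record$kind == "pv")
  d <- record$data
  dn <- d[d$limb == "deflation", ]
  if (nrow(dn) < 5) stop("deflation limb needs >= 5 points", call. = FALSE)
  if (min(dn$pressure) > 1e-8) {
    stop("deflation limb must span down to P = 0", call. = FALSE)
  }
  A0 <- max(dn$volume)
  B0 <- max(A0 - min(dn$volume), 1e-3)
  K0 <- 0.1
  fit <- minpack.lm::nlsLM(volume ~ A - B * exp(-K * pressure), data = dn,
                           start = list(A = A0 + 0.05 * B0, B = B0, K = K0),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  p <- coef(fit)
  if (p["K"] <= 0) stop("non-physiological fit: K <= 0", call. = FALSE)
  A <- unname(p["A"]); B <- unname(p["B"]); K <- unname(p["K"])
  res <- dn$volume - (A - B * exp(-K * dn$pressure))
  r2 <- 1 - sum(res^2) / sum((dn$volume - mean(dn$volume))^2)
  Cst <- B * K * exp(-K * p_ref)
  pmax <- max(d$pressure)
  IC <- (A - B * exp(-K * pmax)) - (A - B)
  up <- d[d$limb == "inflation", ]
  hyst <- if (nrow(up) > 0) {
    ord_up <- up[order(up$pressure), ]
    ord_dn <- dn[order(dn$pressure, decreasing = TRUE), ]
    polygon_area(c(ord_up$pressure, ord_dn$pressure),
                 c(ord_up$volume, ord_dn$volume))
  } else 0
  structure(list(A = A, B = B, K = K, Cst = Cst, Est = 1 / Cst, IC = IC,
                 hysteresis_area = hyst, r2 = r2),
            class = "pv_fit")
}

#' Quality-controlled average of repeated measurements
#'
#' Implements the instrument acceptance rule: fits with a coefficient of
#' determination below `r2_min` are discarded, and each parameter is
#' averaged over the first `n_required` accepted measurements (in the order
#' supplied, which is the acquisition order; the result depends on input
#' order only through this "first n accepted" rule).
#'
#' @param fits Non-empty list of fit objects, each carrying numeric
#'   parameters and an `r2` element (e.g. [fit_snapshot()] results).
#' @param r2_min Acceptance threshold on r-squared (default 0.95).
#' @param n_required Number of accepted measurements to average (default 3).
#' @return A list of class `qc_average` with the averaged parameters plus
#'   `n_used`, `n_discarded` and `r2_min`.
#' @export
qc_average <- function(fits, r2_min = 0.95, n_required = 3L) {
  if (length(fits) == 0) stop("'fits' is empty", call. = FALSE)
  r2s <- vapply(fits, function(f) f$r2, numeric(1))
  accepted <- fits[r2s >= r2_min]
  n_discarded <- length(fits) - length(accepted)
  if (length(accepted) < n_required) {
    stop(sprintf(
      "insufficient acceptable measurements: %d accepted at r2 >= %.2f, %d required",
      length(accepted), r2_min, n_required), call. = FALSE)
  }
  used <- accepted[seq_len(n_required)]
  nums <- names(used[[1]])[vapply(used[[1]], function(x)
    is.numeric(x) && length(x) == 1L, logical(1))]
  avg <- lapply(nums, function(nm)
    mean(vapply(used, function(f) f[[nm]], numeric(1))))
  names(avg) <- nums
  structure(c(avg, list(n_used = n_required, n_discarded = n_discarded,
                        r2_min = r2_min)),
            class = "qc_average")
}
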