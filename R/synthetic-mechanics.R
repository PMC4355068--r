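#' Ground-truth respiratory-mechanics parameters for simulation
#'
#' Holds the true parameter values from which synthetic maneuver records are
#' generated: the single-compartment resistance `R` (cmH2O.s/mL) and
#' compliance `C` (mL/cmH2O); the constant-phase airway resistance `Rn`
#' (cmH2O.s/mL), inertance `I` (cmH2O.s^2/mL), tissue damping `G` and tissue
#' elastance `H` (both cmH2O/mL); and the exponential deflation-limb
#' parameters `A` (maximal capacity, mL), `B` (inspiratory capacity from
#' zero pressure, mL) and `K` (curvature, 1/cmH2O). `noise_sd` is the
#' standard deviation of the additive Gaussian noise applied to the
#' simulated signal, in the units of that signal.
#'
#' @param R,C,Rn,I,G,H,A,B,K Physical parameters as described above; all
#'   must be positive except `I`, which may be zero.
#' @param noise_sd Non-negative noise standard deviation.
#' @return An object of class `mechanics_ground_truth`.
#' @export
mechanics_ground_truth <- function(R = 0.5, C = 0.05, Rn = 0.3, I = 1e-4,
                                   G = 4, H = 28, A = 1.2, B = 0.9,
                                   K = 0.11, noise_sd = 0) {
  for (nm in c("R", "C", "Rn", "G", "H", "A", "B", "K")) {
    stop_if_not_scalar_pos(get(nm), nm)
  }
  if (I < 0) stop("'I' must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(list(R = R, C = C, Rn = Rn, I = I, G = G, H = H,
                 A = A, B = B, K = K, noise_sd = noise_sd),
            class = "mechanics_ground_truth")
}

mechanics_record <- function(kind, data, meta = list()) {
  structure(list(kind = kind, data = data, meta = meta),
            class = "mechanics_record")
}

#' @export
print.mechanics_record <- function(x, ...) {
  cat(sprintf("mechanics_record (%s): %d samples\n", x$kind, nrow(x$data)))
  print(head(x$data, 3))
  invisible(x)
}

central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Simulate a snapshot (single-frequency) perturbation record
#'
#' Generates pressure from the single-compartment equation of motion,
#' `P(t) = V(t)/C + R * Vdot(t) + P0`, plus additive Gaussian noise of
#' standard deviation `truth$noise_sd` (cmH2O). Flow is obtained from the
#' volume waveform by central differences.
#'
#' @param truth A [mechanics_ground_truth()].
#' @param time Sample times in seconds (regular spacing assumed).
#' @param volume Volume waveform in mL; the default is one tidal sinusoid
#'   of 0.25 mL amplitude at 2.5 Hz, the typical snapshot maneuver shape.
#' @param P0 Baseline pressure offset, cmH2O.
#' @param seed Integer RNG seed.
#' @return A `mechanics_record` of kind `"snapshot"` with columns
#'   `time`, `volume`, `flow`, `pressure`.
#' @export
simulate_snapshot <- function(truth, time = seq(0, 1.2, by = 0.005),
                              volume = NULL, P0 = 3, seed = 1L) {
  stopifnot(inherits(truth, "mechanics_ground_truth"))
  if (length(time) < 3) stop("waveform needs >= 3 samples", call. = FALSE)
  dt <- time[2] - time[1]
  if (is.null(volume)) {
    volume <- 0.25 * (1 - cos(2 * pi * 2.5 * time)) / 2
  }
  flow <- central_diff(volume, dt)
  pressure <- volume / truth$C + truth$R * flow + P0
  if (truth$noise_sd > 0) {
    pressure <- pressure +
      with_seed(seed, rnorm(length(pressure), 0, truth$noise_sd))
  }
  mechanics_record("snapshot",
                   data.frame(time = time, volume = volume, flow = flow,
                              pressure = pressure),
                   meta = list(P0 = P0, dt = dt))
}

#' Simulate a forced-oscillation impedance spectrum
#'
#' Input impedance follows the constant-phase model
#' `Z(f) = Rn + i*2*pi*f*I + (G - i*H) / (2*pi*f)^alpha` with
#' `alpha = (2/pi) * atan(H/G)`. Complex Gaussian noise of standard
#' deviation `truth$noise_sd` per component is added.
#'
#' @param truth A [mechanics_ground_truth()] with `G, H > 0`.
#' @param frequencies Oscillation frequencies in Hz (>= 5 distinct values);
#'   the default is 13 frequencies spanning 1 to 20.5 Hz, as in a
#'   broadband ("primewave") forced-oscillation perturbation.
#' @param seed Integer RNG seed.
#' @return A `mechanics_record` of kind `"spectrum"` with columns
#'   `frequency`, `z_real`, `z_imag`.
#' @export
simulate_impedance <- function(truth,
                               frequencies = seq(1, 20.5, length.out = 13),
                               seed = 1L) {
  stopifnot(inherits(truth, "mechanics_ground_truth"))
  if (truth$G <= 0 || truth$H <= 0) stop("G and H must be > 0", call. = FALSE)
  if (length(unique(frequencies)) < 5 || any(frequencies <= 0)) {
    stop("need >= 5 distinct positive frequencies", call. = FALSE)
  }
  w <- 2 * pi * frequencies
  alpha <- (2 / pi) * atan(truth$H / truth$G)
  z <- truth$Rn + 1i * w * truth$I +
    (truth$G - 1i * truth$H) / w^alpha
  if (truth$noise_sd > 0) {
    z <- z + with_seed(seed, {
      complex(real = rnorm(length(w), 0, truth$noise_sd),
              imaginary = rnorm(length(w), 0, truth$noise_sd))
    })
  }
  mechanics_record("spectrum",
                   data.frame(frequency = frequencies,
                              z_real = Re(z), z_imag = Im(z)),
                   meta = list(alpha = alpha))
}

#' Simulate a quasi-static pressure-volume loop
#'
#' The deflation limb follows the exponential Salazar-Knowles form
#' `V = A - B * exp(-K * P)`; the inflation limb sits below it by
#' `hysteresis_offset * sin(pi * P / Pmax)`, which vanishes at both ends of
#' the pressure range so the loop closes, and encloses positive area
#' whenever `hysteresis_offset > 0`. Gaussian volume noise of standard
#' deviation `truth$noise_sd` (mL) is added to both limbs.
#'
#' @param truth A [mechanics_ground_truth()].
#' @param pressures Pressure support in cmH2O, spanning from 0 up to the
#'   maneuver maximum.
#' @param hysteresis_offset Peak inflation-deflation volume separation, mL.
#' @param seed Integer RNG seed.
#' @return A `mechanics_record` of kind `"pv"` with columns `limb`
#'   (`"inflation"` rows in ascending pressure first, then `"deflation"`
#'   rows in descending pressure), `pressure`, `volume`.
#' @export
simulate_pv_loop <- function(truth, pressures = seq(0, 30, length.out = 31),
                             hysteresis_offset = 0.1, seed = 1L) {
  stopifnot(inherits(truth, "mechanics_ground_truth"))
  pmax <- max(pressures)
  if (min(pressures) > 0 || pmax <= 0) {
    stop("'pressures' must span [0, Pmax] with Pmax > 0", call. = FALSE)
  }
  p_up <- sort(pressures)
  p_dn <- rev(p_up)
  v_dn <- truth$A - truth$B * exp(-truth$K * p_dn)
  v_up <- (truth$A - truth$B * exp(-truth$K * p_up)) -
    hysteresis_offset * sin(pi * p_up / pmax)
  if (truth$noise_sd > 0) {
    noise <- with_seed(seed, rnorm(length(p_up) + length(p_dn), 0,
                                   truth$noise_sd))
    v_up <- v_up + noise[seq_along(p_up)]
    v_dn <- v_dn + noise[length(p_up) + seq_along(p_dn)]
  }
  mechanics_record("pv",
                   data.frame(limb = rep(c("inflation", "deflation"),
                                         c(length(p_up), length(p_dn))),
                              pressure = c(p_up, p_dn),
                              volume = c(v_up, v_dn)),
                   meta = list(pmax = pmax,
                               hysteresis_offset = hysteresis_offset))
}
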