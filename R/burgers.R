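#' Burgers viscoelastic material parameters
#'
#' Constructs the four-element Burgers material state used throughout the
#' package: a Maxwell element (spring + dashpot) in series with a
#' Kelvin-Voigt element. In creep language the four parameters are two
#' compliances, a retardation time and the zero-shear viscosity. In
#' spring/dashpot language the moduli are `E1 = 1/J1` (instantaneous spring)
#' and `E2 = 1/J2` (retarded spring), with the Kelvin dashpot viscosity
#' `eta2 = tau/J2`; both views are reported by [format()] for convenience.
#'
#' @param J1 Instantaneous elastic compliance, 1/Pa. Must be > 0.
#' @param J2 Retarded compliance amplitude, 1/Pa. Must be >= 0.
#' @param tau Retardation time, s. Must be > 0.
#' @param eta0 Zero-shear viscosity, Pa s. Must be > 0; `Inf` denotes a
#'   viscoelastic solid (no steady flow), kept as an exact sentinel rather
#'   than a large finite number so the solid limit is exact.
#'
#' @return An object of class `burgers_params` (a named list with fields
#'   `J1`, `J2`, `tau`, `eta0`).
#' @examples
#' p <- burgers_params(J1 = 0.1, J2 = 0.05, tau = 2, eta0 = 200)
#' steady_state_compliance(p)  # 0.15 1/Pa
#' @export
burgers_params <- function(J1, J2, tau, eta0) {
  stopifnot(is.numeric(J1), is.numeric(J2), is.numeric(tau), is.numeric(eta0),
            length(J1) == 1L, length(J2) == 1L, length(tau) == 1L,
            length(eta0) == 1L)
  if (!is.finite(J1) || J1 <= 0) stop("J1 must be finite and > 0")
  if (!is.finite(J2) || J2 < 0) stop("J2 must be finite and >= 0")
  if (!is.finite(tau) || tau <= 0) stop("tau must be finite and > 0")
  if (is.na(eta0) || eta0 <= 0) stop("eta0 must be > 0 (Inf allowed for a solid)")
  structure(list(J1 = J1, J2 = J2, tau = tau, eta0 = eta0),
            class = "burgers_params")
}

#' @export
format.burgers_params <- function(x, ...) {
  solid <- is.infinite(x$eta0)
  sprintf(
    "Burgers material: J1 = %.4g 1/Pa, J2 = %.4g 1/Pa, tau = %.4g s, eta0 = %s\n  Je0 = %.4g 1/Pa; moduli E1 = %.4g Pa, E2 = %s Pa; %s",
    x$J1, x$J2, x$tau,
    if (solid) "Inf (viscoelastic solid)" else sprintf("%.4g Pa s", x$eta0),
    steady_state_compliance(x), 1 / x$J1,
    if (x$J2 > 0) sprintf("%.4g", 1 / x$J2) else "Inf",
    if (solid) "solid (complete recovery)" else "liquid (steady flow)")
}

#' @export
print.burgers_params <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Steady-state compliance of a Burgers material
#'
#' The recoverable (elastic) part of the creep compliance, `Je0 = J1 + J2`:
#' the intercept of the long-time linear flow asymptote of `J(t)` and the
#' standard scalar measure of gel softness.
#'
#' @param params A [burgers_params()] object.
#' @return Steady-state compliance, 1/Pa.
#' @export
steady_state_compliance <- function(params) {
  stopifnot(inherits(params, "burgers_params"))
  params$J1 + params$J2
}

#' Creep compliance of a Burgers material
#'
#' Evaluates the creep compliance under a unit step stress applied at t = 0:
#' \deqn{J(t) = J_1 + J_2 (1 - e^{-t/\tau}) + t/\eta_0}
#' The three terms are the instantaneous elastic jump, the retarded elastic
#' rise, and steady viscous flow. For a viscoelastic solid (`eta0 = Inf`)
#' the flow term vanishes and J(t) saturates at `Je0 = J1 + J2`.
#'
#' @param params A [burgers_params()] object.
#' @param t Time since stress onset, s. Vectorised; all values must be >= 0.
#' @return Compliance J(t), 1/Pa, same length as `t`.
#' @examples
#' p <- burgers_params(0.1, 0.05, 2, 200)
#' burgers_creep_compliance(p, c(0, 2, 10))
#' @export
burgers_creep_compliance <- function(params, t) {
  stopifnot(inherits(params, "burgers_params"), is.numeric(t))
  if (any(t < 0)) stop("t must be >= 0 (time since force onset)")
  params$J1 + params$J2 * (1 - exp(-t / params$tau)) + t / params$eta0
}

#' Step-force protocol for a creep experiment
#'
#' Describes the on/off square-wave force applied to the microwire. The
#' default reproduces the experimental protocol: a step force held for 10 s,
#' then off for 20 s, repeated twice over one minute, sampled every 500 ms.
#'
#' @param F0 Applied force magnitude during the on phase, N. If omitted and
#'   `current` plus `cal` are given, derived via [force_from_current()].
#' @param t_on On-phase duration, s.
#' @param t_off Off-phase duration, s.
#' @param n_cycles Number of on/off cycles.
#' @param dt Sampling interval, s; must be smaller than `t_on`.
#' @param current Optional coil current, A (stored; used to derive `F0` when
#'   a calibration is supplied).
#' @param cal Optional [calibration()] used to convert `current` to `F0`.
#' @return An object of class `force_protocol`.
#' @examples
#' prot <- force_protocol(F0 = 110e-9)  # 110 nN, default timings
#' @export
force_protocol <- function(F0 = NULL, t_on = 10, t_off = 20, n_cycles = 2,
                           dt = 0.5, current = NULL, cal = NULL) {
  if (is.null(F0)) {
    if (is.null(current) || is.null(cal))
      stop("supply F0, or current together with a calibration")
    F0 <- force_from_current(cal, current)
  }
  stopifnot(is.numeric(F0), length(F0) == 1L)
  if (F0 < 0) stop("F0 must be >= 0")
  if (t_on <= 0 || t_off < 0) stop("t_on must be > 0 and t_off >= 0")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (dt <= 0 || dt >= t_on) stop("dt must satisfy 0 < dt < t_on")
  structure(list(F0 = F0, t_on = t_on, t_off = t_off,
                 n_cycles = as.integer(n_cycles), dt = dt, current = current),
            class = "force_protocol")
}

#' Sample times and force waveform of a protocol
#'
#' @param protocol A [force_protocol()].
#' @return A data.frame with columns `time_s`, `force_N` and `phase`
#'   (`"on"`/`"off"`). A sample at time t is "on" when t modulo the cycle
#'   period falls in `[0, t_on)`: the first off sample sits at `t_on`.
#' @export
protocol_waveform <- function(protocol) {
  stopifnot(inherits(protocol, "force_protocol"))
  period <- protocol$t_on + protocol$t_off
  t <- seq(0, protocol$n_cycles * period - protocol$dt, by = protocol$dt)
  phase_t <- t - period * floor(t / period + 1e-9)
  on <- phase_t < protocol$t_on - 1e-9
  data.frame(time_s = t,
             force_N = ifelse(on, protocol$F0, 0),
             phase = ifelse(on, "on", "off"),
             stringsAsFactors = FALSE)
}

#' Microwire displacement response of a Burgers material
#'
#' Forward model of the creep experiment: the displacement of the wire under
#' the protocol's on/off force history, obtained from the creep compliance by
#' Boltzmann superposition. Each force step of height +F0 at cycle onset
#' contributes `(F0/C) J(t - t_onset)` and each cessation a matching negative
#' step, so after a single on phase of length `t1` the recovery is
#' `x(t) = (F0/C) [J(t) - J(t - t1)]`, leaving the residual `(F0/C) t1/eta0`
#' as t grows (zero for a solid: complete recoil).
#'
#' @param params A [burgers_params()] object.
#' @param C Geometric drag coefficient of the wire, m (see
#'   [drag_coefficient()]).
#' @param protocol A [force_protocol()].
#' @return A data.frame with columns `time_s`, `displacement_m`, `force_N`,
#'   `phase`.
#' @examples
#' p <- burgers_params(0.1, 0.05, 2, 200)
#' x <- burgers_displacement_response(p, C = 0.03, force_protocol(F0 = 110e-9))
#' @export
burgers_displacement_response <- function(params, C, protocol) {
  stopifnot(inherits(params, "burgers_params"),
            inherits(protocol, "force_protocol"))
  if (!is.numeric(C) || length(C) != 1L || C <= 0) stop("C must be > 0")
  wav <- protocol_waveform(protocol)
  period <- protocol$t_on + protocol$t_off
  x <- numeric(nrow(wav))
  if (protocol$F0 > 0) {
    scale <- protocol$F0 / C
    for (k in seq_len(protocol$n_cycles) - 1L) {
      t_up <- k * period
      t_dn <- t_up + protocol$t_on
      du <- wav$time_s - t_up
      dd <- wav$time_s - t_dn
      iu <- du >= 0
      id <- dd >= 0
      x[iu] <- x[iu] + scale * burgers_creep_compliance(params, du[iu])
      x[id] <- x[id] - scale * burgers_creep_compliance(params, dd[id])
    }
  }
  data.frame(time_s = wav$time_s, displacement_m = x,
             force_N = wav$force_N, phase = wav$phase,
             stringsAsFactors = FALSE)
}
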