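# Shared fixtures: the experimental wire geometry, the default step-force
# protocol, and a reference liquid-like material.
fix_geom <- function() wire_geometry(r = 12.3e-6, L = 5.3e-3, h = 57e-6)
fix_protocol <- function(F0 = 110e-9, ...) force_protocol(F0 = F0, ...)
fix_liquid <- function() burgers_params(J1 = 0.1, J2 = 0.05, tau = 2, eta0 = 200)

# Independent oracle for the Burgers response: numerical integration of the
# spring-dashpot network ODEs under an arbitrary force history. The Maxwell
# arm is a spring E1 = 1/J1 in series with a dashpot eta0; the Kelvin-Voigt
# arm adds a retarded strain x3 with E2 = 1/J2 and dashpot eta2 = tau/J2.
# Total compliance-scaled displacement: x/sigma0 = J1*u(t) + x2 + x3 with
#   dx2/dt = u(t) / eta0,  dx3/dt = (J2*u(t) - x3) / tau
# where u(t) is the unit force waveform. Integrates with deSolve at tight
# tolerance; returns compliance-units displacement at the requested times.
ode_burgers_response <- function(params, times, step_times, step_signs) {
  u_of <- function(t) {
    s <- 0
    for (j in seq_along(step_times)) if (t >= step_times[j] - 1e-12) s <- s + step_signs[j]
    s
  }
  # integrate segment-by-segment between force steps (u constant within a
  # segment) so the forcing discontinuities are handled exactly
  knots <- sort(unique(c(0, step_times, max(times))))
  y <- c(x2 = 0, x3 = 0)
  t_all <- numeric(0); x2_all <- numeric(0); x3_all <- numeric(0)
  for (seg in seq_len(length(knots) - 1L)) {
    a <- knots[seg]; b <- knots[seg + 1L]
    u <- u_of(a)
    deriv <- function(t, y, parms) {
      list(c(u / params$eta0,
             (u * params$J2 - y[2]) / params$tau))
    }
    seg_times <- sort(unique(c(a, times[times > a & times <= b], b)))
    out <- deSolve::ode(y = y, times = seg_times, func = deriv, parms = NULL,
                        rtol = 1e-12, atol = 1e-14)
    t_all <- c(t_all, out[, "time"]); x2_all <- c(x2_all, out[, "x2"])
    x3_all <- c(x3_all, out[, "x3"])
    y <- c(x2 = unname(out[nrow(out), "x2"]), x3 = unname(out[nrow(out), "x3"]))
  }
  x2 <- stats::approx(t_all, x2_all, xout = times, ties = "ordered")$y
  x3 <- stats::approx(t_all, x3_all, xout = times, ties = "ordered")$y
  u <- vapply(times, u_of, numeric(1))
  params$J1 * u + x2 + x3
}

# Convenience: noiseless compliance curve for a material under a protocol.
fix_curve <- function(params = fix_liquid(), protocol = fix_protocol(),
                      geom = fix_geom()) {
  tr <- burgers_displacement_response(params, geom$C, protocol)
  compliance_from_displacement(tr, F0 = protocol$F0, C = geom$C)
}
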