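#' Convert wire displacement to creep compliance
#'
#' The creep compliance of the gel is obtained from the measured wire
#' displacement by \deqn{J(t) = C\, x(t) / F_0} where `x(t)` is the wire
#' displacement, `F0` the magnitude of the applied magnetic force and `C`
#' the geometric drag coefficient of the wire ([drag_coefficient()]).
#' The conversion is exactly linear in `x` and inversely proportional to
#' `F0`.
#'
#' @param x Displacement, m: either a numeric vector or a trace data.frame
#'   with columns `time_s`, `displacement_m` and (optionally) `phase`.
#' @param F0 Applied force magnitude, N; must be > 0.
#' @param C Drag coefficient, m; must be > 0.
#' @param time_s Sample times, s (required when `x` is a bare vector).
#' @param phase Optional per-sample `"on"`/`"off"` labels.
#' @return A `compliance_curve`: a data.frame with columns `time_s`, `J`
#'   (1/Pa) and `phase`.
#' @export
compliance_from_displacement <- function(x, F0, C, time_s = NULL, phase = NULL) {
  if (!is.numeric(F0) || length(F0) != 1L || F0 <= 0)
    stop("F0 must be a single value > 0")
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("C must be a single value > 0")
  if (is.data.frame(x)) {
    if (is.null(time_s)) time_s <- x$time_s
    if (is.null(phase) && !is.null(x$phase)) phase <- x$phase
    x <- x$displacement_m
  }
  stopifnot(is.numeric(x), is.numeric(time_s), length(time_s) == length(x))
  if (is.null(phase)) phase <- rep(NA_character_, length(x))
  out <- data.frame(time_s = time_s, J = C * x / F0, phase = phase,
                    stringsAsFactors = FALSE)
  class(out) <- c("compliance_curve", "data.frame")
  out
}

#' Segment a sampled force series into on/off windows
#'
#' Thresholds the force at half its maximum and returns the ordered on/off
#' windows of the step protocol. Runs shorter than `min_duration` are
#' treated as glitches and merged into their neighbours (debouncing), so
#' single-sample spikes or dropouts do not split a window.
#'
#' @param force Sampled force series, N (or any proportional unit).
#' @param time_s Sample times, s (default: index-based, unit spacing).
#' @param min_duration Minimum credible phase duration, s (default 1).
#' @return A data.frame of windows with columns `phase`, `cycle`,
#'   `start`, `end` (sample indices, inclusive), `t_start`, `t_end`.
#' @export
segment_protocol <- function(force, time_s = NULL, min_duration = 1) {
  stopifnot(is.numeric(force), length(force) >= 2L)
  if (is.null(time_s)) time_s <- seq_along(force) - 1
  stopifnot(length(time_s) == length(force))
  thr <- max(force) / 2
  if (max(force) <= 0) stop("force series contains no applied-force phase")
  on <- force > thr
  if (!any(on)) stop("force series contains no applied-force phase")
  dt <- stats::median(diff(time_s))
  min_samples <- max(1L, ceiling(min_duration / dt))
  # debounce: flip runs shorter than min_samples (interior glitches)
  repeat {
    r <- rle(on)
    short <- which(r$lengths < min_samples)
    # never flip the leading/trailing run solely for being clipped by the
    # record boundary
    short <- setdiff(short, c(1L, length(r$lengths)))
    if (!length(short)) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i <- short[1L]
    on[starts[i]:ends[i]] <- !r$values[i]
  }
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  phase <- ifelse(r$values, "on", "off")
  cycle <- cumsum(r$values)          # cycle counter increments at each on-run
  cycle[!r$values] <- cumsum(r$values)[!r$values]  # off-run belongs to preceding cycle
  data.frame(phase = phase, cycle = as.integer(cycle),
             start = starts, end = ends,
             t_start = time_s[starts], t_end = time_s[ends],
             stringsAsFactors = FALSE)
}

# Burgers creep response under a known step-force history, and its Jacobian
# in log-parameters q = log(c(J1, J2, tau, eta0)). By Boltzmann
# superposition the compliance-scaled response at time t is
#   sum_j s_j * J(t - t_j)  over steps (t_j, s_j) with t_j <= t,
# which for on-phase samples collapses to
#   J1 + J2 * b(t, tau) + c(t) / eta0
# with b(t, tau) = sum_j s_j (1 - exp(-(t - t_j)/tau)) and c(t) the
# accumulated force-on time. Fitting against this exact form makes later
# cycles free of bias from the still-relaxing retarded element of earlier
# cycles. `steps` is a data.frame with columns t (step times) and s (+1/-1).
burgers_step_basis <- function(t, tau, steps) {
  b <- numeric(length(t))
  db <- numeric(length(t))   # d b / d tau
  cc <- numeric(length(t))
  a <- numeric(length(t))
  for (j in seq_len(nrow(steps))) {
    dtj <- t - steps$t[j]
    act <- dtj >= 0
    e <- exp(-dtj[act] / tau)
    b[act] <- b[act] + steps$s[j] * (1 - e)
    db[act] <- db[act] - steps$s[j] * e * dtj[act] / tau^2
    cc[act] <- cc[act] + steps$s[j] * dtj[act]
    a[act] <- a[act] + steps$s[j]
  }
  list(a = a, b = b, db = db, c = cc)
}

burgers_resid_logpar <- function(q, t, J_obs, w, steps) {
  p <- exp(q)
  bs <- burgers_step_basis(t, p[3], steps)
  w * (p[1] * bs$a + p[2] * bs$b + bs$c / p[4] - J_obs)
}

burgers_jac_logpar <- function(q, t, J_obs, w, steps) {
  p <- exp(q)
  bs <- burgers_step_basis(t, p[3], steps)
  cbind(w * p[1] * bs$a,
        w * p[2] * bs$b,
        w * p[2] * bs$db * p[3],
        w * (-bs$c / p[4]))
}

fit_window_init <- function(t, J) {
  t_max <- max(t)
  Jmax <- max(J)
  J1_0 <- max(J[1], 1e-3 * Jmax)
  tail_idx <- t >= (2 / 3) * t_max
  fit_tail <- stats::lm.fit(cbind(1, t[tail_idx]), J[tail_idx])
  slope <- fit_tail$coefficients[2]
  icpt <- fit_tail$coefficients[1]
  eta0_0 <- if (is.finite(slope) && slope > 0) 1 / slope else 1e4 * t_max / Jmax
  J2_0 <- max(icpt - J1_0, 1e-3 * Jmax)
  # time at which the retarded term reaches half its amplitude
  detrended <- J - t / eta0_0 - J1_0
  half_idx <- which(detrended >= J2_0 / 2)
  tau_0 <- if (length(half_idx)) t[half_idx[1]] / log(2) else t_max / 4
  tau_0 <- min(max(tau_0, min(diff(t)) / 2), 5 * t_max)
  c(J1 = J1_0, J2 = J2_0, tau = tau_0, eta0 = eta0_0)
}

# Profile (variable-projection) solve: for fixed tau the Burgers creep
# response is linear in theta = (J1, J2, 1/eta0), so the profiled residual
# sum of squares RSS(tau) is found by one weighted linear solve. Returns
# the solve for one tau.
burgers_profile_solve <- function(log_tau, t, J, w, steps) {
  bs <- burgers_step_basis(t, exp(log_tau), steps)
  X <- cbind(bs$a, bs$b, bs$c) * w
  fit <- stats::lm.fit(X, J * w)
  theta <- fit$coefficients
  theta[is.na(theta)] <- 0
  list(theta = theta, rss = sum(fit$residuals^2))
}

fit_burgers_window <- function(t, J, steps = NULL, J_base = 0, weights = NULL,
                               n_starts = 8, start_jitter = 0.7) {
  stopifnot(length(t) == length(J))
  if (length(t) < 8L) stop("on-phase must contain at least 8 samples")
  if (is.null(steps)) steps <- data.frame(t = 0, s = 1)
  w <- if (is.null(weights)) rep(1, length(t)) else sqrt(weights)
  t_span <- max(t) - min(t) + 1
  dt_min <- min(diff(sort(unique(t))))
  scale2 <- sum((w * J)^2)

  # stage 1 - profile over tau: coarse log grid, then 1-D refinement of the
  # profiled RSS. This is immune to the J2/eta0 collinearity that traps a
  # joint 4-parameter descent when tau is comparable to the window length.
  lt_range <- c(log(dt_min / 4), log(20 * t_span))
  grid <- seq(lt_range[1], lt_range[2], length.out = 60)
  rss_g <- vapply(grid, function(lt) burgers_profile_solve(lt, t, J, w, steps)$rss,
                  numeric(1))
  i0 <- which.min(rss_g)
  lo <- grid[max(i0 - 1L, 1L)]
  hi <- grid[min(i0 + 1L, length(grid))]
  opt <- stats::optimize(function(lt) burgers_profile_solve(lt, t, J, w, steps)$rss,
                         interval = c(lo, hi), tol = 1e-12)
  sol <- burgers_profile_solve(opt$minimum, t, J, w, steps)
  tau_hat <- exp(opt$minimum)
  theta <- sol$theta
  floor_J <- 1e-14 * max(abs(J), 1e-300)
  p_hat <- c(J1 = max(theta[1], floor_J), J2 = max(theta[2], floor_J),
             tau = tau_hat,
             eta0 = if (theta[3] > 0) 1 / theta[3] else 1e12 * t_span / max(abs(J), floor_J))
  clamped <- any(theta[1:2] < 0) || theta[3] <= 0

  # stage 2 - Levenberg-Marquardt polish in log-parameters (keeps
  # positivity); multi-start only if the polish fails or the profile stage
  # was clamped and left a poor residual.
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     gtol = 0, maxiter = 1024)
  run1 <- function(q0) {
    tryCatch(minpack.lm::nls.lm(par = q0, fn = burgers_resid_logpar,
                                jac = burgers_jac_logpar,
                                t = t, J_obs = J, w = w, steps = steps,
                                control = ctrl),
             error = function(e) NULL)
  }
  best <- run1(log(p_hat))
  best_dev <- if (is.null(best)) Inf else best$deviance
  # the profile solution is already the (profiled) global optimum; a full
  # multi-start is only worth running when the linear solve violated
  # positivity and the polish from the clamped start is still poor
  if (clamped && (!is.finite(best_dev) || best_dev > 1e-12 * scale2)) {
    seed_state <- preserve_rng(8191L)
    on.exit(restore_rng(seed_state), add = TRUE)
    q_init <- log(fit_window_init(t - t[1L], pmax(J - J_base, floor_J)))
    for (s in seq_len(n_starts)) {
      q0 <- if (s == 1L) q_init else q_init + stats::rnorm(4L, sd = start_jitter)
      f <- run1(q0)
      if (!is.null(f) && is.finite(f$deviance) && f$deviance < best_dev) {
        best <- f
        best_dev <- f$deviance
      }
      if (best_dev <= 1e-16 * scale2) break
    }
  }
  if (is.null(best) && !all(is.finite(p_hat)))
    stop("Burgers fit failed to converge from any start")
  if (!is.null(best) && best_dev <= sol$rss + 1e-16 * scale2) {
    p <- exp(best$par)
    dev <- best_dev
  } else {
    p <- p_hat
    dev <- sol$rss
  }
  list(params = burgers_params(p[[1]], p[[2]], p[[3]], p[[4]]),
       residual_norm = sqrt(dev / length(t)),
       niter = if (!is.null(best)) best$niter else 0L)
}

#' Fit the Burgers model to a creep compliance curve
#'
#' The inference step of the creep experiment: the force-on compliance
#' samples, taken relative to the first force onset, are fitted with the
#' four-parameter Burgers creep form under the exact step-force history
#' (Boltzmann superposition), so later cycles carry no bias from the
#' still-relaxing retarded element of earlier ones. The solver profiles the
#' retardation time (the model is linear in `J1`, `J2`, `1/eta0` at fixed
#' `tau`) and polishes with Levenberg-Marquardt in log-parameter space
#' (positivity for free), falling back to a seeded multi-start when needed.
#' Only the on phase is fitted; the off phase feeds the recovery ratio and
#' the liquid/solid classification.
#'
#' With `pooling = "joint"` (default) all on windows are fitted jointly
#' with shared parameters - the accumulated flow between cycles then pins
#' the viscosity far more precisely than any single 10-s window can. With
#' `pooling = "percycle"` each cycle is fitted separately and the reported
#' parameters are per-cycle means. Per-cycle fits are computed either way
#' (unless `qc_cycles = FALSE`) and kept in `$cycles`: their agreement is a
#' quality-control metric.
#'
#' A fitted zero-shear viscosity above `eta0_cap_factor * t_on / Je0`
#' (default 1e6) is reported with `solid_flag = TRUE`: beyond that the flow
#' term is unresolvable within the on window and the material is effectively
#' a viscoelastic solid.
#'
#' @param curve A `compliance_curve` from [compliance_from_displacement()],
#'   with `phase` labels (or supply `force` to segment internally).
#' @param force Optional force series used to derive phase labels via
#'   [segment_protocol()] when `curve$phase` is absent.
#' @param weights Optional per-sample weights for the least squares.
#' @param n_starts Number of multi-start attempts in the fallback stage
#'   (default 8, seeded and deterministic).
#' @param pooling `"joint"` (one fit over all on windows, default) or
#'   `"percycle"` (mean of independent per-cycle fits).
#' @param qc_cycles Compute per-cycle QC fits even under joint pooling
#'   (default TRUE; disable in large Monte-Carlo runs for speed).
#' @param eta0_cap_factor Solid-limit cap factor (see Details).
#' @param recovery_threshold Recovery-ratio threshold passed to
#'   [classify_gel()] (default 0.9).
#' @param force_applied Force magnitude, N, recorded in the result (for
#'   stress sweeps).
#' @return An object of class `burgers_fit`: a list with `params`
#'   (cycle-mean [burgers_params()]), `Je0`, `eta0`, `residual_norm`,
#'   `recovery_ratio`, `classification`, `solid_flag`, `force_applied` and
#'   `cycles` (per-cycle fits).
#' @examples
#' p <- burgers_params(0.1, 0.05, 2, 200)
#' prot <- force_protocol(F0 = 110e-9)
#' tr <- burgers_displacement_response(p, C = 0.03, prot)
#' cc <- compliance_from_displacement(tr, F0 = prot$F0, C = 0.03)
#' fit <- fit_burgers(cc)
#' fit$Je0   # ~0.15
#' fit$eta0  # ~200
#' @export
fit_burgers <- function(curve, force = NULL, weights = NULL, n_starts = 8,
                        pooling = c("joint", "percycle"), qc_cycles = TRUE,
                        eta0_cap_factor = 1e6, recovery_threshold = 0.9,
                        force_applied = NA_real_) {
  pooling <- match.arg(pooling)
  stopifnot(is.data.frame(curve), all(c("time_s", "J") %in% names(curve)))
  phase <- curve$phase
  if (is.null(phase) || all(is.na(phase))) {
    if (is.null(force)) stop("curve has no phase labels and no force series was given")
    seg <- segment_protocol(force, curve$time_s)
    phase <- rep(NA_character_, nrow(curve))
    for (i in seq_len(nrow(seg))) phase[seg$start[i]:seg$end[i]] <- seg$phase[i]
  }
  runs <- rle(phase == "on")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  on_runs <- which(runs$values)
  if (!length(on_runs)) stop("no on-phase windows found in curve")

  # step-force history reconstructed from the phase labels: a +1 step at the
  # first sample of each on-run, a -1 step at the first sample of the
  # following off-run. Times are taken relative to the first force onset so
  # fitting is invariant to the absolute time axis.
  t_origin <- curve$time_s[starts[on_runs[1L]]]
  steps_all <- data.frame(t = numeric(0), s = numeric(0))
  for (i in seq_along(runs$values)) {
    if (runs$values[i]) {
      steps_all <- rbind(steps_all,
                         data.frame(t = curve$time_s[starts[i]] - t_origin, s = 1))
      if (i < length(runs$values))
        steps_all <- rbind(steps_all,
                           data.frame(t = curve$time_s[starts[i] + runs$lengths[i]] - t_origin,
                                      s = -1))
    }
  }

  cycles <- list()
  t_on_k <- numeric(length(on_runs))
  if (identical(pooling, "percycle") || qc_cycles) {
    for (k in seq_along(on_runs)) {
      idx <- starts[on_runs[k]]:ends[on_runs[k]]
      t_abs <- curve$time_s[idx] - t_origin
      steps_k <- steps_all[steps_all$t <= max(t_abs), , drop = FALSE]
      base <- if (idx[1L] > 1L) curve$J[idx[1L] - 1L] else 0
      cycles[[k]] <- fit_burgers_window(t_abs, curve$J[idx], steps = steps_k,
                                        J_base = base, weights = weights,
                                        n_starts = n_starts)
      dt_k <- if (length(idx) > 1L) t_abs[2L] - t_abs[1L] else 0
      t_on_k[k] <- max(t_abs) - min(t_abs) + dt_k
      cycles[[k]]$t_on <- t_on_k[k]
    }
  }
  if (identical(pooling, "joint")) {
    idx_all <- unlist(lapply(on_runs, function(i) starts[i]:ends[i]))
    t_all <- curve$time_s[idx_all] - t_origin
    main <- fit_burgers_window(t_all, curve$J[idx_all], steps = steps_all,
                               J_base = 0, weights = weights,
                               n_starts = n_starts)
    dt1 <- if (length(t_all) > 1L) t_all[2L] - t_all[1L] else 0
    t_on <- (max(t_all) - min(t_all) + dt1) / length(on_runs)
    params <- main$params
    residual_norm <- main$residual_norm
  } else {
    mean_of <- function(f) mean(vapply(cycles, function(cy) f(cy$params), numeric(1)))
    params <- burgers_params(mean_of(function(p) p$J1),
                             mean_of(function(p) p$J2),
                             mean_of(function(p) p$tau),
                             mean_of(function(p) p$eta0))
    residual_norm <- mean(vapply(cycles, `[[`, numeric(1), "residual_norm"))
    t_on <- mean(t_on_k)
  }
  Je0 <- steady_state_compliance(params)
  solid_flag <- params$eta0 > eta0_cap_factor * t_on / Je0
  rr <- tryCatch(recovery_ratio(curve), error = function(e) NA_real_)
  res <- list(params = params,
              Je0 = Je0,
              eta0 = params$eta0,
              residual_norm = residual_norm,
              recovery_ratio = rr,
              solid_flag = solid_flag,
              force_applied = force_applied,
              pooling = pooling,
              n_cycles = length(on_runs),
              cycles = cycles)
  res$classification <- classify_gel(rr, threshold = recovery_threshold)
  class(res) <- "burgers_fit"
  res
}

#' @export
print.burgers_fit <- function(x, ...) {
  cat(sprintf(
    "Burgers creep fit (%d cycle%s)\n  Je0  = %.4g 1/Pa\n  eta0 = %.4g Pa s%s\n  recovery ratio = %.3f -> %s\n  residual RMS = %.3g\n",
    x$n_cycles, if (x$n_cycles > 1) "s" else "",
    x$Je0, x$eta0, if (x$solid_flag) " [solid-limit flag]" else "",
    x$recovery_ratio, x$classification, x$residual_norm))
  invisible(x)
}

#' Creep recovery ratio
#'
#' Fraction of the on-phase deformation recovered after force cessation,
#' computed per cycle as
#' `R = (x_end_of_on - x_end_of_off) / (x_end_of_on - x_pre_cycle)` using
#' the last sample of each phase, then averaged over complete cycles and
#' clipped to \[0, 1\]. The pre-cycle baseline (0 for the first cycle)
#' removes residual flow accumulated in earlier cycles so each cycle's ratio
#' matches the single-step closed form `1 - (t_on/eta0)/J(t_on)` once the
#' retarded element has relaxed. `R = 1` means complete recoil
#' (viscoelastic solid); a liquid recoils only partially.
#'
#' @param curve A `compliance_curve` (or any data.frame with `J` and
#'   `phase`); displacement series work identically since `R` is scale
#'   invariant.
#' @return Mean recovery ratio over complete cycles, with per-cycle values
#'   in attribute `"per_cycle"`. `NA` (with a warning) when the end-of-on
#'   deformation is not positive.
#' @export
recovery_ratio <- function(curve) {
  stopifnot(is.data.frame(curve), "phase" %in% names(curve))
  y <- if ("J" %in% names(curve)) curve$J else curve$displacement_m
  phase <- curve$phase
  runs <- rle(phase)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ratios <- numeric(0)
  for (i in seq_along(runs$values)) {
    if (runs$values[i] != "on") next
    if (i + 1L > length(runs$values) || runs$values[i + 1L] != "off") next
    base <- if (starts[i] > 1L) y[starts[i] - 1L] else 0
    x_on <- y[ends[i]] - base
    x_off <- y[ends[i + 1L]] - base
    if (!is.finite(x_on) || x_on <= 0) {
      warning("end-of-on deformation is not positive; recovery ratio undefined")
      return(NA_real_)
    }
    ratios <- c(ratios, (x_on - x_off) / x_on)
  }
  if (!length(ratios)) stop("no complete on/off cycle found")
  ratios <- pmin(pmax(ratios, 0), 1)
  structure(mean(ratios), per_cycle = ratios)
}

#' Classify a gel as viscoelastic liquid or solid
#'
#' Operationalizes the qualitative creep-recovery distinction: a
#' viscoelastic solid recoils (nearly) completely after force cessation
#' while a liquid flows and recoils only partially. A gel is called solid
#' when its recovery ratio meets the threshold.
#'
#' @param result A `burgers_fit` object, or a bare recovery ratio.
#' @param threshold Recovery-ratio threshold for the solid call, in
#'   \[0, 1\] (default 0.9).
#' @return `"viscoelastic_solid"` or `"viscoelastic_liquid"` (`NA` when the
#'   recovery ratio is unavailable).
#' @export
classify_gel <- function(result, threshold = 0.9) {
  r <- if (inherits(result, "burgers_fit")) result$recovery_ratio else result
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
  if (is.na(r)) return(NA_character_)
  if (r >= threshold) "viscoelastic_solid" else "viscoelastic_liquid"
}

#' Check the linear viscoelastic regime across a stress sweep
#'
#' In the linear regime the fitted steady-state compliance and zero-shear
#' viscosity are independent of the applied force. Given fits at three or
#' more distinct forces, computes the coefficient of variation of `Je0` and
#' of `eta0` across forces and the slope of `log(Je0)` versus `log(F)`;
#' the sweep is declared linear when both CVs and the absolute slope are
#' within their bounds.
#'
#' @param results List of `burgers_fit` objects with `force_applied` set.
#' @param cv_bound Upper bound on both CVs (default 0.2).
#' @param slope_bound Upper bound on `|d log Je0 / d log F|` (default 0.1).
#' @return A list with `verdict` (`"linear"`/`"nonlinear"`), `cv_Je0`,
#'   `cv_eta0`, `slope`, and the per-force table.
#' @export
stress_sweep_linearity <- function(results, cv_bound = 0.2, slope_bound = 0.1) {
  stopifnot(is.list(results))
  F <- vapply(results, `[[`, numeric(1), "force_applied")
  Je0 <- vapply(results, `[[`, numeric(1), "Je0")
  eta0 <- vapply(results, `[[`, numeric(1), "eta0")
  if (length(unique(F[is.finite(F)])) < 3L)
    stop("stress sweep requires fits at >= 3 distinct forces")
  cv <- function(v) stats::sd(v) / mean(v)
  cv_J <- cv(Je0)
  cv_e <- if (all(is.finite(eta0))) cv(eta0) else Inf
  slope <- unname(stats::coef(stats::lm(log(Je0) ~ log(F)))[2L])
  verdict <- if (cv_J <= cv_bound && cv_e <= cv_bound && abs(slope) <= slope_bound)
    "linear" else "nonlinear"
  list(verdict = verdict, cv_Je0 = cv_J, cv_eta0 = cv_e, slope = slope,
       table = data.frame(force_N = F, Je0 = Je0, eta0 = eta0))
}
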