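#' Simulate a microwire displacement trace
#'
#' Forward-models the wire displacement of a Burgers material under the
#' step-force protocol and adds i.i.d. Gaussian measurement noise. The
#' noise standard deviation is expressed as a fraction of the elastic
#' plateau displacement `(F0/C) * Je0`, so noise levels are comparable
#' across materials and forces. Deterministic given `seed`; the caller's
#' RNG state is left untouched.
#'
#' @param params A [burgers_params()] object (the ground truth).
#' @param geom A [wire_geometry()] (its `C` sets the displacement scale).
#' @param protocol A [force_protocol()].
#' @param noise_sigma Noise SD as a fraction of the plateau displacement
#'   (default 0 = noiseless).
#' @param seed Integer seed for the noise stream.
#' @return A trace data.frame (`time_s`, `displacement_m`, `force_N`,
#'   `phase`) with the generating parameters attached as attribute
#'   `"truth"`.
#' @export
simulate_trace <- function(params, geom, protocol, noise_sigma = 0, seed = 1) {
  stopifnot(inherits(params, "burgers_params"),
            inherits(protocol, "force_protocol"))
  C <- if (inherits(geom, "wire_geometry")) geom$C else geom$C
  if (is.null(C) || C <= 0) stop("geometry must carry a drag coefficient C > 0")
  tr <- burgers_displacement_response(params, C, protocol)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (noise_sigma > 0) {
    scale <- (protocol$F0 / C) * steady_state_compliance(params)
    noise <- with_seed(seed, stats::rnorm(nrow(tr), sd = noise_sigma * scale))
    tr$displacement_m <- tr$displacement_m + noise
  }
  attr(tr, "truth") <- params
  tr
}

#' Specification of a synthetic donor cohort
#'
#' Describes the paired experimental design the generator emulates: each
#' donor contributes mucus gels measured under several conditions
#' (control, IL-13 activation, IL-13 + DTT by default), with 2 or 3
#' transwell-insert replicates per condition. Donors draw latent material
#' parameters from log-normal population distributions; condition effects
#' act multiplicatively on steady-state compliance `Je0` and zero-shear
#' viscosity `eta0`, with the retardation time and the J1:J2 split held at
#' control values. Inserts within a donor share the latent parameters up to
#' an independent log-normal replicate perturbation of CV `insert_cv`.
#'
#' Default effects: IL-13 multiplies `Je0` by 0.3 and `eta0` by 20 (less
#' compliant, more viscous, crossing the solid classification threshold);
#' DTT restores control values exactly. Default forces follow the
#' experimental currents: 110 nN for control and DTT, 460 nN for IL-13.
#'
#' @param n_donors Number of donors (default 5).
#' @param inserts_per_donor Replicate inserts per (donor, condition); 2 or 3.
#' @param control_Je0_meanlog,control_Je0_sdlog Log-normal location/scale of
#'   the control steady-state compliance, 1/Pa.
#' @param control_eta0_meanlog,control_eta0_sdlog Log-normal location/scale
#'   of the control zero-shear viscosity, Pa s.
#' @param tau Retardation time shared by all donors, s.
#' @param J1_fraction Fraction of `Je0` assigned to the instantaneous
#'   compliance `J1` (rest goes to `J2`).
#' @param il13_effect Named multiplicative factors `c(Je0 = ..., eta0 = ...)`
#'   for the IL-13 condition; `Je0` factor must be < 1 and `eta0` factor > 1.
#' @param dtt_effect Factors for IL-13 + DTT, relative to control
#'   (`c(1, 1)` = full restoration).
#' @param insert_cv Log-normal SD of the per-insert replicate perturbation.
#' @param noise_sigma Displacement noise fraction passed to
#'   [simulate_trace()].
#' @param condition_forces Named vector of applied forces per condition, N.
#' @param seed Cohort seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_donors = 5,
                        inserts_per_donor = 2,
                        control_Je0_meanlog = log(0.15),
                        control_Je0_sdlog = 0.4,
                        control_eta0_meanlog = log(200),
                        control_eta0_sdlog = 0.4,
                        tau = 2,
                        J1_fraction = 2 / 3,
                        il13_effect = c(Je0 = 0.3, eta0 = 20),
                        dtt_effect = c(Je0 = 1, eta0 = 1),
                        insert_cv = 0.10,
                        noise_sigma = 0.02,
                        condition_forces = c(control = 110e-9, il13 = 460e-9,
                                             il13_dtt = 110e-9),
                        seed = 1) {
  if (!inserts_per_donor %in% c(2L, 3L))
    stop("inserts_per_donor must be 2 or 3")
  if (n_donors < 2) stop("n_donors must be >= 2")
  il13_effect <- il13_effect[c("Je0", "eta0")]
  dtt_effect <- dtt_effect[c("Je0", "eta0")]
  if (any(is.na(il13_effect)) || any(is.na(dtt_effect)))
    stop("effects must be named vectors with Je0 and eta0 entries")
  if (!(il13_effect[["Je0"]] <= 1 && il13_effect[["eta0"]] >= 1))
    stop("IL-13 must not raise Je0 nor lower eta0 (compliance down, viscosity up)")
  if (J1_fraction <= 0 || J1_fraction >= 1) stop("J1_fraction must be in (0, 1)")
  structure(list(n_donors = as.integer(n_donors),
                 inserts_per_donor = as.integer(inserts_per_donor),
                 control_Je0_meanlog = control_Je0_meanlog,
                 control_Je0_sdlog = control_Je0_sdlog,
                 control_eta0_meanlog = control_eta0_meanlog,
                 control_eta0_sdlog = control_eta0_sdlog,
                 tau = tau, J1_fraction = J1_fraction,
                 effects = list(control = c(Je0 = 1, eta0 = 1),
                                il13 = il13_effect,
                                il13_dtt = dtt_effect),
                 insert_cv = insert_cv,
                 noise_sigma = noise_sigma,
                 condition_forces = condition_forces,
                 seed = seed),
            class = "cohort_spec")
}

#' Simulate a paired donor cohort with ground truth
#'
#' Generates the full input of a cohort experiment: one displacement trace
#' per (donor, condition, insert), each produced by [simulate_trace()] from
#' that insert's true material parameters. Ground truth is carried in the
#' returned table so downstream recovery can be scored exactly.
#'
#' @param spec A [cohort_spec()].
#' @param geom A [wire_geometry()] (default: the experimental wire at
#'   h = 57 um).
#' @param protocol_template A [force_protocol()] whose timings are reused
#'   for every trace; its `F0` is replaced by the condition force.
#' @return A list with `table` (data.frame: donor, condition, insert,
#'   force_N, seed, true Je0/eta0/J1/J2/tau) and `traces` (named list of
#'   trace data.frames, names matching `table$trace_id`).
#' @export
simulate_cohort <- function(spec,
                            geom = wire_geometry(h = 57e-6),
                            protocol_template = force_protocol(F0 = 110e-9)) {
  stopifnot(inherits(spec, "cohort_spec"))
  conditions <- names(spec$effects)
  missing_F <- setdiff(conditions, names(spec$condition_forces))
  if (length(missing_F))
    stop("condition_forces lacks entries for: ", paste(missing_F, collapse = ", "))

  n_traces <- spec$n_donors * length(conditions) * spec$inserts_per_donor
  seeds <- derive_seeds(spec$seed, spec$n_donors * 2 + n_traces * 3)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  rows <- list()
  traces <- list()
  for (d in seq_len(spec$n_donors)) {
    Je0_d <- with_seed(next_seed(), stats::rlnorm(1, spec$control_Je0_meanlog,
                                                  spec$control_Je0_sdlog))
    eta0_d <- with_seed(next_seed(), stats::rlnorm(1, spec$control_eta0_meanlog,
                                                   spec$control_eta0_sdlog))
    for (cond in conditions) {
      eff <- spec$effects[[cond]]
      Je0_c <- Je0_d * eff[["Je0"]]
      eta0_c <- eta0_d * eff[["eta0"]]
      F0 <- spec$condition_forces[[cond]]
      for (ins in seq_len(spec$inserts_per_donor)) {
        jitter <- if (spec$insert_cv > 0)
          with_seed(next_seed(), exp(stats::rnorm(2, sd = spec$insert_cv)))
        else {
          next_seed()  # keep the seed stream aligned across insert_cv settings
          c(1, 1)
        }
        Je0_i <- Je0_c * jitter[1]
        eta0_i <- eta0_c * jitter[2]
        params <- burgers_params(J1 = spec$J1_fraction * Je0_i,
                                 J2 = (1 - spec$J1_fraction) * Je0_i,
                                 tau = spec$tau, eta0 = eta0_i)
        prot <- force_protocol(F0 = F0, t_on = protocol_template$t_on,
                               t_off = protocol_template$t_off,
                               n_cycles = protocol_template$n_cycles,
                               dt = protocol_template$dt)
        trace_seed <- next_seed()
        tr <- simulate_trace(params, geom, prot,
                             noise_sigma = spec$noise_sigma, seed = trace_seed)
        id <- sprintf("d%02d_%s_i%d", d, cond, ins)
        traces[[id]] <- tr
        rows[[id]] <- data.frame(trace_id = id, donor = d, condition = cond,
                                 insert = ins, force_N = F0, seed = trace_seed,
                                 true_Je0 = Je0_i, true_eta0 = eta0_i,
                                 true_J1 = params$J1, true_J2 = params$J2,
                                 true_tau = params$tau,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       traces = traces, geom = geom, spec = spec)
}

#' Simulate multi-channel z-intensity profiles
#'
#' Renders Gaussian intensity peaks at the stated layer positions in the
#' corresponding channels (membrane stain at the cell surface, bright field
#' at the wire centre, particles at the mucus top) plus additive Gaussian
#' noise, emulating the axial localization scans.
#'
#' @param layout Named list/vector of layer positions in um with entries
#'   `cell_surface`, `wire_center` and optionally `mucus_top`; must be
#'   ordered `cell_surface < wire_center <= mucus_top`.
#' @param widths Gaussian SD of each peak, um (recycled; default 4).
#' @param z z grid, um (default 0 to 120 by 0.5).
#' @param noise Noise SD as a fraction of peak amplitude (default 0).
#' @param seed Integer seed.
#' @return A [zprofile_set()] with channels `ch_647`, `ch_bf` and (when
#'   `mucus_top` is given) `ch_488`.
#' @export
simulate_zprofiles <- function(layout, widths = 4,
                               z = seq(0, 120, by = 0.5),
                               noise = 0, seed = 1) {
  layout <- as.list(layout)
  need <- c("cell_surface", "wire_center")
  if (!all(need %in% names(layout)))
    stop("layout must name cell_surface and wire_center positions")
  has_mucus <- "mucus_top" %in% names(layout)
  pos <- c(layout$cell_surface, layout$wire_center,
           if (has_mucus) layout$mucus_top)
  if (is.unsorted(pos, strictly = FALSE) ||
      layout$wire_center <= layout$cell_surface)
    stop("layer layout must be ordered cell_surface < wire_center <= mucus_top")
  widths <- rep_len(widths, length(pos))
  gauss <- function(mu, sd) exp(-(z - mu)^2 / (2 * sd^2))
  channels <- list(ch_647 = gauss(layout$cell_surface, widths[1]),
                   ch_bf = gauss(layout$wire_center, widths[2]))
  if (has_mucus) channels$ch_488 <- gauss(layout$mucus_top, widths[3])
  if (noise > 0) {
    channels <- with_seed(seed, lapply(channels, function(ch)
      pmax(ch + stats::rnorm(length(z), sd = noise), 0)))
  }
  zprofile_set(z, channels)
}

#' Render a synthetic image stack of a moving microwire
#'
#' Produces the imaging ground truth for tracker validation: each frame
#' shows the wire as a Gaussian-profile ridge (finite length, ends smoothed
#' by the point-spread function) displaced along its axis according to the
#' supplied trace, over a uniform background with additive Gaussian noise.
#' Pixel centres sit at integer coordinates; the wire is horizontal (along
#' image columns).
#'
#' @param displacement_px Per-frame axial displacement, px, relative to
#'   frame 1.
#' @param frame_shape `c(rows, cols)` of each frame (default c(32, 96)).
#' @param wire_length_px Wire length, px (default 56).
#' @param wire_sigma_px Gaussian SD of the wire cross-section, px.
#' @param psf_sigma_px Gaussian SD smoothing the wire ends, px.
#' @param amplitude Peak wire intensity above background.
#' @param background Constant background level.
#' @param noise_sd Additive Gaussian noise SD (SNR = amplitude/noise_sd).
#' @param seed Integer seed.
#' @return 3-D array `[row, col, frame]`.
#' @export
simulate_image_stack <- function(displacement_px,
                                 frame_shape = c(32, 96),
                                 wire_length_px = 56,
                                 wire_sigma_px = 5,
                                 psf_sigma_px = 1,
                                 amplitude = 1,
                                 background = 0.05,
                                 noise_sd = 0,
                                 seed = 1) {
  stopifnot(is.numeric(displacement_px), length(displacement_px) >= 1L)
  H <- frame_shape[1]; W <- frame_shape[2]
  y <- seq_len(H); x <- seq_len(W)
  y0 <- (H + 1) / 2
  x_mid <- (W + 1) / 2
  margin <- 3 * psf_sigma_px + 1
  xs <- x_mid + displacement_px - wire_length_px / 2
  xe <- x_mid + displacement_px + wire_length_px / 2
  if (any(xs < 1 + margin) || any(xe > W - margin))
    stop("wire leaves the frame for at least one displacement; enlarge frame_shape")
  yprof <- exp(-(y - y0)^2 / (2 * wire_sigma_px^2))
  stack <- array(0, dim = c(H, W, length(displacement_px)))
  for (f in seq_along(displacement_px)) {
    ridge <- stats::pnorm(x, xs[f], psf_sigma_px) -
      stats::pnorm(x, xe[f], psf_sigma_px)
    stack[, , f] <- background + amplitude * outer(yprof, ridge)
  }
  if (noise_sd > 0) {
    stack <- stack + with_seed(seed,
      array(stats::rnorm(length(stack), sd = noise_sd), dim = dim(stack)))
  }
  stack
}
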