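#' Microwire geometry above a no-slip surface
#'
#' Wire radius and length together with the height of the wire centre above
#' the epithelial cell surface, which is treated as a no-slip plane for drag
#' purposes. Defaults match the probes used experimentally: glass-coated
#' ferromagnetic microwires of 24.6 um mean diameter and 5.3 mm length.
#'
#' @param r Wire radius, m (default 12.3e-6).
#' @param L Wire length, m (default 5.3e-3).
#' @param h Height of the wire centre above the no-slip surface, m. Must
#'   exceed `r` (a wire touching the surface has divergent drag).
#' @return An object of class `wire_geometry` with fields `r`, `L`, `h` and
#'   the derived drag coefficient `C` (m).
#' @examples
#' geom <- wire_geometry(h = 57e-6)
#' geom$C  # ~0.03007 m
#' @export
wire_geometry <- function(r = 12.3e-6, L = 5.3e-3, h) {
  stopifnot(is.numeric(r), is.numeric(L), is.numeric(h),
            length(r) == 1L, length(L) == 1L, length(h) == 1L)
  if (r <= 0 || L <= 0) stop("r and L must be > 0")
  if (h <= r) stop("h must exceed the wire radius r (wire cannot touch the surface)")
  g <- structure(list(r = r, L = L, h = h), class = "wire_geometry")
  g$C <- drag_coefficient(g)
  g
}

#' Drag coefficient of a cylinder translating parallel to a no-slip plane
#'
#' Geometric resistance factor for a cylinder of radius `r` and length `L`
#' moving along its longitudinal axis at height `h` above a no-slip surface,
#' from lubrication theory:
#' \deqn{C = \frac{4 \pi L}{\mathrm{arccosh}(h/r)}}
#' `C` has units of length and converts force and displacement into stress
#' and strain, so that compliance is `J(t) = C x(t) / F0`. It diverges as
#' the wire approaches contact (`h -> r`) and decreases as the wire moves
#' away from the surface.
#'
#' @param geom A [wire_geometry()] object, or a list with fields `r`, `L`,
#'   `h`.
#' @return Drag coefficient, m.
#' @examples
#' drag_coefficient(list(r = 12.3e-6, L = 5.3e-3, h = 57e-6))
#' @export
drag_coefficient <- function(geom) {
  r <- geom$r; L <- geom$L; h <- geom$h
  stopifnot(is.numeric(r), is.numeric(L), is.numeric(h))
  if (r <= 0 || L <= 0) stop("r and L must be > 0")
  if (h <= r) stop("h must exceed r: drag diverges at contact (arccosh(h/r) undefined for h/r <= 1)")
  4 * pi * L / acosh(h / r)
}

#' Linear force-current calibration of the electromagnet pair
#'
#' The anti-Helmholtz coil pair produces a uniform field gradient, hence a
#' magnetic force on the wire proportional to the coil current. The
#' calibration is a line `F = slope * I + intercept`, through the origin by
#' default.
#'
#' @param slope Force per unit current, N/A. Must be > 0.
#' @param intercept Force offset at zero current, N (default 0).
#' @return An object of class `calibration`.
#' @examples
#' cal <- calibration_from_point(current = 0.6, force = 110e-9)
#' force_from_current(cal, 2.5)  # ~458 nN
#' @export
calibration <- function(slope, intercept = 0) {
  stopifnot(is.numeric(slope), length(slope) == 1L,
            is.numeric(intercept), length(intercept) == 1L)
  if (slope <= 0) stop("calibration slope must be > 0")
  structure(list(slope = slope, intercept = intercept), class = "calibration")
}

#' @rdname calibration
#' @param current Coil current of the anchor point, A.
#' @param force Force of the anchor point, N.
#' @details `calibration_from_point()` builds a through-origin calibration
#'   from a single (current, force) pair.
#' @export
calibration_from_point <- function(current, force) {
  if (current <= 0 || force <= 0) stop("anchor current and force must be > 0")
  calibration(slope = force / current, intercept = 0)
}

#' Convert coil current to magnetic force
#'
#' @param cal A [calibration()] object.
#' @param current Coil current, A; vectorised, values must be >= 0.
#' @return Force, N.
#' @export
force_from_current <- function(cal, current) {
  stopifnot(inherits(cal, "calibration"), is.numeric(current))
  if (any(current < 0)) stop("current must be >= 0")
  cal$slope * current + cal$intercept
}

#' Read and write calibrations as JSON
#'
#' Calibrations are interchanged as JSON objects
#' `{"slope_nN_per_A": ..., "intercept_nN": ...}` (nanonewton units, as the
#' instrument reports them).
#'
#' @param path File path.
#' @param cal A [calibration()] object (SI units internally).
#' @return `read_calibration_json()` returns a [calibration()];
#'   `write_calibration_json()` returns `path` invisibly.
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$slope_nN_per_A)) stop("calibration JSON lacks slope_nN_per_A")
  intercept <- if (is.null(obj$intercept_nN)) 0 else obj$intercept_nN
  calibration(slope = obj$slope_nN_per_A * 1e-9, intercept = intercept * 1e-9)
}

#' @rdname read_calibration_json
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "calibration"))
  jsonlite::write_json(list(slope_nN_per_A = cal$slope * 1e9,
                            intercept_nN = cal$intercept * 1e9),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
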