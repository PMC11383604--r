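#' Track axial microwire displacement in an image stack
#'
#' Recovers the frame-by-frame displacement of the wire along its
#' longitudinal axis from a time-lapse stack. Each frame's intensity is
#' projected onto the wire axis and the resulting 1-D profile is
#' cross-correlated against the first frame (the reference); the integer-lag
#' correlation peak is then refined to sub-pixel precision by maximizing the
#' correlation of the spline-interpolated profile (a three-point parabolic
#' refinement is used as fallback when the peak sits at the search-range
#' boundary). Pixel centres are at integer coordinates and displacement is
#' positive along increasing pixel index of the stated axis.
#'
#' Frames whose peak normalized correlation falls below `min_correlation`
#' are flagged as tracking failures (`ok = FALSE`, displacement `NA`), never
#' silently interpolated.
#'
#' @param stack 3-D numeric array `[row, col, frame]`, or a 2-frame-or-more
#'   list of matrices.
#' @param axis Wire orientation: `"x"` (wire along image columns, the
#'   default) or `"y"`.
#' @param pixel_size Physical pixel size, um/px.
#' @param max_lag Integer search half-range in pixels for the correlation
#'   peak (default one quarter of the profile length).
#' @param min_correlation Confidence threshold on the peak normalized
#'   correlation, in (0, 1] (default 0.5).
#' @return A data.frame with one row per frame: `frame`, `displacement_px`,
#'   `displacement_um`, `correlation`, `ok`. Frame 1 is the reference
#'   (displacement 0 by construction).
#' @examples
#' fr <- outer(exp(-(seq_len(24) - 12)^2 / 8),
#'             pnorm(seq_len(64), 16, 2) - pnorm(seq_len(64), 48, 2))
#' stack <- array(c(fr, fr), dim = c(24, 64, 2))
#' track_wire_displacement(stack, pixel_size = 0.65)
#' @export
track_wire_displacement <- function(stack, axis = c("x", "y"), pixel_size = 1,
                                    max_lag = NULL, min_correlation = 0.5) {
  axis <- match.arg(axis)
  if (is.list(stack)) stack <- simplify2array(stack)
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  n_frames <- dim(stack)[3]
  if (n_frames < 2L) stop("stack must contain at least 2 frames")
  if (pixel_size <= 0) stop("pixel_size must be > 0")

  # matched projection: weight pixels across the wire by the wire's own
  # cross-section profile (estimated from the reference frame) so rows far
  # from the wire contribute no noise to the 1-D profile
  cross <- if (axis == "x") rowMeans(stack[, , 1L]) else colMeans(stack[, , 1L])
  wts <- pmax(cross - stats::median(cross), 0)
  if (sum(wts) == 0) wts <- rep(1, length(cross))
  wts <- wts / sum(wts)
  project <- function(frame) {
    if (axis == "x") as.vector(crossprod(wts, frame)) else as.vector(frame %*% wts)
  }
  ref <- project(stack[, , 1L])
  n <- length(ref)
  # the search range must cover the largest expected motion, but the excluded
  # margin must stay small enough that the wire ends (the axial structure the
  # correlation locks onto) remain inside the window
  if (is.null(max_lag)) max_lag <- max(2L, floor(n / 8))
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || 2L * max_lag >= n - 4L)
    stop("max_lag must be >= 1 and leave a usable overlap window")

  # fixed central window of the reference; shifted frame samples stay in
  # bounds for any |s| <= max_lag + 1
  win <- seq.int(max_lag + 2L, n - max_lag - 1L)
  ref_w <- ref[win]
  if (max(ref_w) - min(ref_w) <= 0)
    stop("reference profile is flat; nothing to track")

  lags <- seq.int(-max_lag, max_lag)
  profiles <- lapply(seq_len(n_frames), function(f) project(stack[, , f]))
  splines <- lapply(profiles, function(p)
    stats::splinefun(seq_along(p), p, method = "fmm"))

  track_pass <- function(ref_w) {
    ref_c <- ref_w - mean(ref_w)
    ref_ss <- sqrt(sum(ref_c^2))
    if (ref_ss == 0) stop("reference profile is flat; nothing to track")
    disp <- numeric(n_frames)
    corr <- numeric(n_frames)
    ok <- logical(n_frames)
    for (f in seq_len(n_frames)) {
      prof <- profiles[[f]]
      ncc <- vapply(lags, function(k) {
        y <- prof[win + k]
        yc <- y - mean(y)
        ss <- sqrt(sum(yc^2))
        if (ss == 0) return(-1)
        sum(ref_c * yc) / (ref_ss * ss)
      }, numeric(1))
      i0 <- which.max(ncc)
      peak <- ncc[i0]
      corr[f] <- peak
      if (!is.finite(peak) || peak < min_correlation) {
        disp[f] <- NA_real_
        ok[f] <- FALSE
        next
      }
      k0 <- lags[i0]
      if (i0 == 1L || i0 == length(lags)) {
        # peak at the search boundary: no bracketing, keep integer estimate
        disp[f] <- k0
        ok[f] <- TRUE
        next
      }
      s_hat <- refine_shift_spline(splines[[f]], win, ref_c, ref_ss, k0)
      if (is.na(s_hat)) {
        # parabolic fallback through the three lags around the peak
        y0 <- ncc[i0 - 1L]; y1 <- ncc[i0]; y2 <- ncc[i0 + 1L]
        den <- y0 - 2 * y1 + y2
        s_hat <- k0 + if (den < 0) max(min(0.5 * (y0 - y2) / den, 0.5), -0.5) else 0
      }
      disp[f] <- s_hat
      ok[f] <- TRUE
    }
    list(disp = disp, corr = corr, ok = ok)
  }

  # pass 1: every frame against frame 1
  p1 <- track_pass(ref_w)
  # pass 2: re-track against an ensemble reference - the average of all
  # successfully tracked frames shifted back to the frame-1 position. This
  # removes the reference frame's own noise from every estimate (it would
  # otherwise appear as a common bias of order the single-frame error).
  good <- which(p1$ok & is.finite(p1$disp))
  res <- p1
  if (length(good) >= 2L) {
    ref_ens <- rowMeans(vapply(good, function(f) splines[[f]](win + p1$disp[f]),
                               numeric(length(win))))
    p2 <- track_pass(ref_ens)
    # the ensemble reference carries an arbitrary small offset common to all
    # frames; re-anchor so frame 1 has displacement 0
    if (p2$ok[1L] && is.finite(p2$disp[1L])) {
      p2$disp <- p2$disp - p2$disp[1L]
      res <- p2
    }
  }
  data.frame(frame = seq_len(n_frames),
             displacement_px = res$disp,
             displacement_um = res$disp * pixel_size,
             correlation = res$corr,
             ok = res$ok)
}

# Continuous-shift refinement: maximize the normalized correlation between
# the fixed reference window and the spline-interpolated frame profile over
# s in [k0 - 1, k0 + 1].
refine_shift_spline <- function(sf, win, ref_c, ref_ss, k0) {
  obj <- function(s) {
    y <- sf(win + s)
    yc <- y - mean(y)
    ss <- sqrt(sum(yc^2))
    if (ss == 0) return(-1)
    sum(ref_c * yc) / (ref_ss * ss)
  }
  opt <- tryCatch(stats::optimize(obj, interval = c(k0 - 1, k0 + 1),
                                  maximum = TRUE, tol = 1e-6),
                  error = function(e) NULL)
  if (is.null(opt)) return(NA_real_)
  opt$maximum
}

#' Read and write image stacks as multi-frame TIFF
#'
#' Thin wrappers over the tiff package mapping between multi-frame TIFF
#' files and the `[row, col, frame]` arrays used by
#' [track_wire_displacement()]. Intensities are scaled to `[0, 1]` on write
#' (TIFF stores normalized floats/ints); the scale factor is irrelevant to
#' tracking, which is intensity-scale invariant.
#'
#' @param path TIFF file path.
#' @param stack 3-D numeric array `[row, col, frame]`.
#' @return `read_stack_tiff()` returns a 3-D array; `write_stack_tiff()`
#'   returns `path` invisibly.
#' @export
read_stack_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF stacks")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  simplify2array(frames)
}

#' @rdname read_stack_tiff
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF stacks")
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  rng <- range(stack)
  scaled <- if (diff(rng) > 0) (stack - rng[1]) / diff(rng) else stack * 0
  frames <- lapply(seq_len(dim(stack)[3]), function(i) scaled[, , i])
  tiff::writeTIFF(frames, path)
  invisible(path)
}
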