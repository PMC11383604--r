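# RNG hygiene: simulators and the seeded multi-start take an explicit seed
# and must not disturb (or depend on) the caller's RNG stream. preserve_rng
# saves the global state and seeds; restore_rng puts it back.
preserve_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  old <- preserve_rng(seed)
  on.exit(restore_rng(old), add = TRUE)
  expr
}

# Derive a stream of child seeds from one parent seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 48271 + seq_len(n) * 16807) %% 2147483647
}

#' Read and write displacement traces as CSV
#'
#' Traces are interchanged as CSV with columns `time_s`,
#' `displacement_um`, `force_nN` and `phase`; internally the package works
#' in SI units (m, N).
#'
#' @param path CSV file path.
#' @param trace A trace data.frame with columns `time_s`,
#'   `displacement_m`, `force_N`, `phase`.
#' @return `read_trace_csv()` returns a trace data.frame in SI units;
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "displacement_um", "force_nN")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns time_s, displacement_um, force_nN")
  data.frame(time_s = df$time_s,
             displacement_m = df$displacement_um * 1e-6,
             force_N = df$force_nN * 1e-9,
             phase = if ("phase" %in% names(df)) df$phase else NA_character_,
             stringsAsFactors = FALSE)
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(all(c("time_s", "displacement_m", "force_N") %in% names(trace)))
  out <- data.frame(time_s = trace$time_s,
                    displacement_um = trace$displacement_m * 1e6,
                    force_nN = trace$force_N * 1e9,
                    phase = if ("phase" %in% names(trace)) trace$phase else NA)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and write Burgers parameter sets as JSON
#'
#' Parameter sets are interchanged as JSON objects
#' `{"J1": ..., "J2": ..., "tau": ..., "eta0": ..., "units": ...}` with
#' `J1`, `J2` in 1/Pa, `tau` in s and `eta0` in Pa s (the string `"Inf"`
#' encodes a viscoelastic solid).
#'
#' @param path JSON file path.
#' @param params A [burgers_params()] object.
#' @return `read_burgers_json()` returns a [burgers_params()];
#'   `write_burgers_json()` returns `path` invisibly.
#' @export
read_burgers_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  eta0 <- if (identical(obj$eta0, "Inf")) Inf else as.numeric(obj$eta0)
  burgers_params(obj$J1, obj$J2, obj$tau, eta0)
}

#' @rdname read_burgers_json
#' @export
write_burgers_json <- function(params, path) {
  stopifnot(inherits(params, "burgers_params"))
  jsonlite::write_json(
    list(J1 = params$J1, J2 = params$J2, tau = params$tau,
         eta0 = if (is.infinite(params$eta0)) "Inf" else params$eta0,
         units = list(J1 = "1/Pa", J2 = "1/Pa", tau = "s", eta0 = "Pa*s")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
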