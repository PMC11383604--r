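#' Fit every trace of a simulated or measured cohort
#'
#' Runs the creep inference chain (displacement -> compliance -> Burgers
#' fit -> recovery/classification) over each trace and assembles the cohort
#' table consumed by the comparison statistics.
#'
#' @param cohort A list with `table` and `traces` as returned by
#'   [simulate_cohort()] (the table must carry `trace_id`, `donor`,
#'   `condition`, `insert`, `force_N`).
#' @param C Drag coefficient, m; defaults to the cohort's geometry.
#' @param ... Passed to [fit_burgers()].
#' @return A `data.frame` (the cohort table) with fitted `Je0`, `eta0`,
#'   `recovery_ratio`, `classification`, `solid_flag` and `residual_norm`
#'   columns appended.
#' @export
fit_cohort <- function(cohort, C = NULL, ...) {
  stopifnot(is.list(cohort), !is.null(cohort$table), !is.null(cohort$traces))
  if (is.null(C)) C <- cohort$geom$C
  if (is.null(C) || C <= 0) stop("drag coefficient C is required")
  tab <- cohort$table
  n <- nrow(tab)
  tab$Je0 <- tab$eta0 <- tab$recovery_ratio <- tab$residual_norm <- NA_real_
  tab$classification <- NA_character_
  tab$solid_flag <- NA
  for (i in seq_len(n)) {
    tr <- cohort$traces[[tab$trace_id[i]]]
    cc <- compliance_from_displacement(tr, F0 = tab$force_N[i], C = C)
    fit <- fit_burgers(cc, force_applied = tab$force_N[i], ...)
    tab$Je0[i] <- fit$Je0
    tab$eta0[i] <- fit$eta0
    tab$recovery_ratio[i] <- fit$recovery_ratio
    tab$classification[i] <- fit$classification
    tab$solid_flag[i] <- fit$solid_flag
    tab$residual_norm[i] <- fit$residual_norm
  }
  tab
}

#' Aggregate insert replicates to per-donor condition means
#'
#' Each donor's value for a condition is the arithmetic mean of its 2-3
#' transwell-insert replicates, mirroring how individual donors are
#' summarized before the paired comparison. QC flags (solid-limit,
#' undefined recovery) propagate worst-case.
#'
#' @param table A cohort table from [fit_cohort()] (columns `donor`,
#'   `condition`, `Je0`, `eta0`, and optionally `recovery_ratio`,
#'   `solid_flag`).
#' @return A data.frame with one row per (donor, condition): mean `Je0`,
#'   `eta0`, `recovery_ratio`, `n_inserts`, `solid_flag` (any).
#' @export
aggregate_donor <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("donor", "condition", "Je0", "eta0") %in% names(table)))
  if (any(!is.finite(table$Je0)) || any(table$Je0 <= 0) || any(table$eta0 <= 0))
    stop("cohort table contains nonpositive or missing Je0/eta0")
  key <- interaction(table$donor, table$condition, drop = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  first <- function(v) as.vector(tapply(v, key, `[`, 1L))
  out <- data.frame(
    donor = first(table$donor),
    condition = first(table$condition),
    Je0 = agg(table$Je0, mean),
    eta0 = agg(table$eta0, mean),
    n_inserts = as.integer(agg(table$Je0, length)),
    stringsAsFactors = FALSE)
  if ("recovery_ratio" %in% names(table))
    out$recovery_ratio <- agg(table$recovery_ratio, mean)
  if ("solid_flag" %in% names(table))
    out$solid_flag <- as.logical(agg(table$solid_flag, any))
  out[order(out$donor, out$condition), , drop = FALSE]
}

#' Ratio paired t test
#'
#' The paired comparison used for per-donor condition contrasts: a
#' two-sided paired Student's t test on the log-transformed within-donor
#' ratios, testing whether the geometric-mean ratio `b/a` differs from 1.
#' \deqn{t = \frac{\overline{\log(b/a)}}{s_{\log(b/a)}/\sqrt{n}}, \quad
#'   df = n - 1}
#' The statistic is invariant to rescaling either condition by a positive
#' constant.
#'
#' @param a,b Paired positive per-donor values (condition A and B, same
#'   donor order).
#' @param label Optional comparison label carried into the result.
#' @return An object of class `ratio_ttest`: a list with `t`, `df`,
#'   `p_value`, `gm_ratio` (geometric-mean ratio b/a), `n`, `direction`
#'   and a `degenerate` flag for zero-variance log ratios.
#' @examples
#' ratio_paired_ttest(c(1, 1, 1, 1), c(2.0, 2.2, 1.8, 2.1))
#' @export
ratio_paired_ttest <- function(a, b, label = NULL) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  if (any(a <= 0) || any(b <= 0)) stop("ratio paired t test requires positive values")
  lr <- log(b / a)
  m <- mean(lr)
  s <- stats::sd(lr)
  degenerate <- s == 0
  if (degenerate) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(list(label = label, t = t_stat, df = n - 1L, p_value = p,
                 gm_ratio = exp(m), n = n,
                 direction = if (m > 0) "increase" else if (m < 0) "decrease" else "none",
                 degenerate = degenerate),
            class = "ratio_ttest")
}

#' @export
print.ratio_ttest <- function(x, ...) {
  cat(sprintf("Ratio paired t test%s: GM ratio = %.4g (%s), t = %.3f, df = %d, p = %.4g%s\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              x$gm_ratio, x$direction, x$t, x$df, x$p_value,
              if (x$degenerate) " [degenerate: zero-variance log ratios]" else ""))
  invisible(x)
}

#' Compare conditions across a cohort
#'
#' Runs the cohort analysis: aggregate inserts to per-donor means first,
#' then form within-donor ratios and apply the ratio paired t test to each
#' planned condition pair, for both steady-state compliance and zero-shear
#' viscosity. Donors missing either condition of a pair are dropped with a
#' warning. No multiplicity correction is applied; comparisons are reported
#' per pair, and the report says so.
#'
#' @param table Cohort table from [fit_cohort()] (insert-level rows).
#' @param plan List of 2-element character vectors `c(reference, test)`;
#'   ratios are test/reference.
#' @return A list of comparison results, one per plan entry, each holding
#'   `ratio_ttest` objects for `Je0` and `eta0` plus direction labels
#'   ("less/more compliant", "less/more viscous").
#' @export
compare_conditions <- function(table,
                               plan = list(c("control", "il13"),
                                           c("il13", "il13_dtt"),
                                           c("control", "il13_dtt"))) {
  if (!length(plan)) stop("comparison plan is empty")
  per_donor <- aggregate_donor(table)
  out <- list()
  for (pair in plan) {
    stopifnot(length(pair) == 2L)
    ref <- per_donor[per_donor$condition == pair[1], ]
    tst <- per_donor[per_donor$condition == pair[2], ]
    donors <- intersect(ref$donor, tst$donor)
    dropped <- setdiff(union(ref$donor, tst$donor), donors)
    if (length(dropped))
      warning(sprintf("dropping donor(s) %s from %s vs %s (condition missing)",
                      paste(dropped, collapse = ", "), pair[2], pair[1]))
    if (length(donors) < 2L)
      stop(sprintf("fewer than 2 complete donors for %s vs %s", pair[2], pair[1]))
    ref <- ref[match(donors, ref$donor), ]
    tst <- tst[match(donors, tst$donor), ]
    lab <- paste(pair[2], "vs", pair[1])
    res_J <- ratio_paired_ttest(ref$Je0, tst$Je0, label = paste(lab, "(Je0)"))
    res_e <- ratio_paired_ttest(ref$eta0, tst$eta0, label = paste(lab, "(eta0)"))
    out[[lab]] <- list(
      pair = pair, n_donors = length(donors),
      Je0 = res_J, eta0 = res_e,
      compliance_direction = if (res_J$gm_ratio < 1) "less compliant" else "more compliant",
      viscosity_direction = if (res_e$gm_ratio > 1) "more viscous" else "less viscous")
  }
  out
}
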