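# Per-residue difference maps between ligand states, empirical
# significance rules, and box-plot distribution summaries.

#' Per-residue differences between two ligand states
#'
#' Computes `delta = value_A - value_B` on the intersection of assigned
#' residues, with combined error `sigma_delta = sqrt(sigma_A^2 +
#' sigma_B^2)` where both are known.  Residues present in only one state
#' are reported in the `missing_a` / `missing_b` attributes, never
#' silently dropped.
#'
#' @param table_a,table_b Data frames with columns `residue_id`, `value`
#'   and optionally `sigma`, for states A and B.
#' @param observable Label for the observable (`"r1"`, `"r2"`, `"noe"`,
#'   `"rex"`, `"csp"`, ...).
#' @return Data frame of difference records (`residue_id`, `observable`,
#'   `delta`, `sigma_delta`) with attributes `missing_a` and `missing_b`
#'   (residues absent from the respective state).
#' @export
diff_states <- function(table_a, table_b, observable = "value") {
  stopifnot(is.data.frame(table_a), is.data.frame(table_b),
            all(c("residue_id", "value") %in% names(table_a)),
            all(c("residue_id", "value") %in% names(table_b)))
  shared <- intersect(table_a$residue_id, table_b$residue_id)
  if (length(shared) == 0L)
    stop("input error: no shared residues between the two states")
  ia <- match(shared, table_a$residue_id)
  ib <- match(shared, table_b$residue_id)
  sa <- if ("sigma" %in% names(table_a)) table_a$sigma[ia] else NA_real_
  sb <- if ("sigma" %in% names(table_b)) table_b$sigma[ib] else NA_real_
  out <- data.frame(residue_id = shared, observable = observable,
                    delta = table_a$value[ia] - table_b$value[ib],
                    sigma_delta = sqrt(sa^2 + sb^2))
  out <- out[order(out$residue_id), ]
  rownames(out) <- NULL
  attr(out, "missing_a") <- sort(setdiff(table_b$residue_id, shared))
  attr(out, "missing_b") <- sort(setdiff(table_a$residue_id, shared))
  out
}

#' Residues with strong exchange contributions
#'
#' Returns the residues whose exchange contribution exceeds the cutoff,
#' strictly (`Rex > cutoff`); the default cutoff of 7.5 1/s marks
#' "strong" microsecond-millisecond exchange.
#'
#' @param table Data frame with columns `residue_id` and `value` (fitted
#'   Rex, 1/s).
#' @param cutoff Strict threshold (1/s), default 7.5.
#' @return Sorted integer vector of residue ids.
#' @export
threshold_rex <- function(table, cutoff = 7.5) {
  stopifnot(is.data.frame(table),
            all(c("residue_id", "value") %in% names(table)))
  if (all(is.na(table$value))) stop("no Rex values present")
  sort(table$residue_id[!is.na(table$value) & table$value > cutoff])
}

#' Flag significant state differences
#'
#' Flags difference records whose magnitude exceeds `k` standard
#' deviations of the empirical delta distribution for that observable
#' (default `k = 2`), i.e. "exceeding two standard deviations relative to
#' the experimental distribution".  The threshold uses `|delta|` about
#' zero (no centering); per-residue z-scores against the propagated
#' `sigma_delta` are available as a secondary column.
#'
#' @param diffs Data frame from [diff_states()] (may contain several
#'   observables; the SD is computed per observable).
#' @param k Positive multiplier (default 2).
#' @return `diffs` with added columns `significant` (logical) and
#'   `z_residue` (`delta / sigma_delta`); attribute `thresholds` is a
#'   named vector of per-observable thresholds, and
#'   `expected_false_flags` the count expected from pure Gaussian noise
#'   at this `k`.
#' @export
significant_set <- function(diffs, k = 2) {
  stopifnot(is.data.frame(diffs),
            all(c("residue_id", "observable", "delta") %in% names(diffs)),
            k > 0)
  thresholds <- c()
  diffs$significant <- FALSE
  for (obs in unique(diffs$observable)) {
    idx <- diffs$observable == obs & !is.na(diffs$delta)
    if (sum(idx) < 5L)
      stop("insufficient data: need >= 5 difference records per observable")
    thr <- k * stats::sd(diffs$delta[idx])
    thresholds[obs] <- thr
    # a degenerate (zero-spread) distribution has no outliers
    diffs$significant[idx] <- thr > 0 & abs(diffs$delta[idx]) > thr
  }
  diffs$z_residue <- if ("sigma_delta" %in% names(diffs))
    diffs$delta / diffs$sigma_delta else NA_real_
  attr(diffs, "thresholds") <- thresholds
  # no multiple-testing correction is applied; annotate what pure noise
  # would produce at this k under normality
  attr(diffs, "expected_false_flags") <-
    2 * stats::pnorm(k, lower.tail = FALSE) * nrow(diffs)
  diffs
}

#' Box-plot summary of a distribution
#'
#' Tukey convention: quartiles by linear interpolation
#' (`quantile(type = 7)`), whiskers at the most extreme observations
#' within `1.5 * IQR` of the quartiles, everything beyond is an outlier.
#'
#' @param values Numeric vector (NAs dropped), `n >= 1`.
#' @return An object of class `distribution_summary` with fields `n`,
#'   `median`, `q1`, `q3`, `whisker_low`, `whisker_high`, `outliers`.
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  in_low <- values[values >= q[1] - 1.5 * iqr]
  in_high <- values[values <= q[3] + 1.5 * iqr]
  wl <- min(in_low)
  wh <- max(in_high)
  structure(list(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = wl, whisker_high = wh,
                 outliers = sort(values[values < wl | values > wh])),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("n = %d  median = %.4g  [Q1, Q3] = [%.4g, %.4g]\n",
              x$n, x$median, x$q1, x$q3))
  cat(sprintf("whiskers [%.4g, %.4g], %d outlier(s)\n",
              x$whisker_low, x$whisker_high, length(x$outliers)))
  invisible(x)
}

#' Write difference records as TSV
#'
#' @param diffs Data frame from [significant_set()] (or [diff_states()]).
#' @param path Output path.
#' @export
write_diff_table <- function(diffs, path) {
  utils::write.table(diffs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
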