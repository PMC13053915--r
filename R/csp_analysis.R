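# Chemical-shift perturbation analysis: peak matching between two ligand
# states, the weighted CSP statistic, and the empirical significance
# threshold.

#' Assigned peak list
#'
#' Validates a per-state assigned 1H-15N peak list.  One row per backbone
#' amide: residue number, 3-letter residue name, 1H and 15N chemical
#' shifts (ppm), peak intensity and intensity noise.
#'
#' @param df Data frame with columns `residue_id`, `residue_name`,
#'   `delta_h`, `delta_n`, `intensity`, `sigma` (the last three optional;
#'   filled with `NA`/defaults if absent).
#' @return The validated data frame, classed `peak_list`.
#' @export
peak_list <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("residue_id", "delta_h", "delta_n") %in% names(df)))
  if (anyDuplicated(df$residue_id))
    stop("input error: duplicate residue_id in peak list")
  if (any(!is.finite(df$delta_h)) || any(!is.finite(df$delta_n)))
    stop("input error: non-finite chemical shift")
  if (any(df$residue_id < 1)) stop("input error: residue_id must be >= 1")
  if (is.null(df$residue_name)) df$residue_name <- NA_character_
  if (is.null(df$intensity)) df$intensity <- NA_real_
  if (is.null(df$sigma)) df$sigma <- NA_real_
  df <- df[order(df$residue_id),
           c("residue_id", "residue_name", "delta_h", "delta_n",
             "intensity", "sigma")]
  rownames(df) <- NULL
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Match assigned peaks between two ligand states
#'
#' Pairs peaks by residue number.  Residues present only in the reference
#' list `list_a` are called `disappeared` (their peak is lost in state B,
#' e.g. through exchange broadening); residues present only in `list_b`
#' are called `appeared`; the rest are `matched`.
#'
#' @param list_a,list_b [peak_list()]s (or data frames acceptable to it)
#'   for the two states; `list_a` is the reference (apo) state.
#' @return A data frame with one row per residue in the union: columns
#'   `residue_id`, `status`, and the shifts of both states
#'   (`delta_h_a`, `delta_n_a`, `delta_h_b`, `delta_n_b`, `NA` where
#'   absent).
#' @export
match_peaks <- function(list_a, list_b) {
  a <- peak_list(as.data.frame(list_a))
  b <- peak_list(as.data.frame(list_b))
  ids <- sort(union(a$residue_id, b$residue_id))
  ia <- match(ids, a$residue_id)
  ib <- match(ids, b$residue_id)
  status <- ifelse(!is.na(ia) & !is.na(ib), "matched",
                   ifelse(!is.na(ia), "disappeared", "appeared"))
  data.frame(residue_id = ids, status = status,
             delta_h_a = a$delta_h[ia], delta_n_a = a$delta_n[ia],
             delta_h_b = b$delta_h[ib], delta_n_b = b$delta_n[ib])
}

#' Chemical-shift perturbation
#'
#' Combined amide CSP between two states,
#' \deqn{CSP = \sqrt{(\Delta\delta_H)^2 + (\Delta\delta_N)^2 / w}}
#' with the 15N difference down-weighted by `n_weight` (default 10)
#' inside the root.  Vectorized.
#'
#' @param dh_a,dn_a 1H and 15N shifts in state A (ppm).
#' @param dh_b,dn_b Shifts in state B (ppm).
#' @param n_weight Positive 15N down-weighting factor applied to
#'   `(delta N)^2`; the default 10 divides the squared nitrogen change by
#'   10 (i.e. scales the nitrogen axis by `1/sqrt(10)`).
#' @return CSP in ppm (non-negative), same length as the inputs.
#' @examples
#' compute_csp(8.30, 119.5, 8.20, 119.2)  # sqrt(0.01 + 0.09/10)
#' @export
compute_csp <- function(dh_a, dn_a, dh_b, dn_b, n_weight = 10) {
  stopifnot(is.numeric(n_weight), length(n_weight) == 1L, n_weight > 0)
  sqrt((dh_a - dh_b)^2 + (dn_a - dn_b)^2 / n_weight)
}

#' Empirical CSP significance threshold
#'
#' Threshold = `k` standard deviations of the CSP distribution over the
#' matched residues (default `k = 2`).  By default the SD is computed over
#' all matched residues without trimming; `trim = TRUE` iteratively
#' excludes values above the current threshold until stable, giving a
#' background-driven variant.
#'
#' @param csps Numeric vector of matched-residue CSPs (ppm).
#' @param k Positive multiplier (default 2).
#' @param trim Iteratively exclude above-threshold values when estimating
#'   the SD (default `FALSE`).
#' @return Threshold in ppm.
#' @export
significance_threshold <- function(csps, k = 2, trim = FALSE) {
  csps <- csps[!is.na(csps)]
  if (length(csps) < 5L)
    stop("insufficient data: need >= 5 matched CSP records")
  stopifnot(k > 0)
  if (!trim) return(k * stats::sd(csps))
  keep <- rep(TRUE, length(csps))
  repeat {
    thr <- k * stats::sd(csps[keep])
    new_keep <- csps <= thr
    if (sum(new_keep) < 5L || identical(new_keep, keep)) break
    keep <- new_keep
  }
  thr
}

#' Per-residue CSP records between two states
#'
#' Convenience wrapper: matches two peak lists, computes CSPs for matched
#' residues, derives the `k`-SD significance threshold, and returns the
#' full record table.
#'
#' @inheritParams match_peaks
#' @inheritParams compute_csp
#' @inheritParams significance_threshold
#' @return Data frame with columns `residue_id`, `csp` (ppm, `NA` for
#'   unmatched), `status`, `significant`; attribute `threshold` holds the
#'   threshold in ppm.
#' @export
csp_records <- function(list_a, list_b, n_weight = 10, k = 2, trim = FALSE) {
  m <- match_peaks(list_a, list_b)
  matched <- m$status == "matched"
  m$csp <- NA_real_
  m$csp[matched] <- compute_csp(m$delta_h_a[matched], m$delta_n_a[matched],
                                m$delta_h_b[matched], m$delta_n_b[matched],
                                n_weight)
  thr <- significance_threshold(m$csp[matched], k = k, trim = trim)
  m$significant <- !is.na(m$csp) & m$csp > thr
  out <- m[, c("residue_id", "csp", "status", "significant")]
  attr(out, "threshold") <- thr
  out
}

#' Read an assigned peak list
#'
#' `read_peaklist()` reads the package's TSV dialect (columns
#' `residue_id`, `residue_name`, `delta_h_ppm`, `delta_n_ppm`,
#' `intensity`, `sigma`).  `read_sparky_list()` reads a Sparky-style
#' assigned list: a header line then one line per peak with an assignment
#' token (e.g. `V102N-H`), the 15N shift (w1), the 1H shift (w2) and
#' optionally a height; the residue number is parsed from the assignment
#' token.
#'
#' @param path File path.
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue_id", "delta_h_ppm", "delta_n_ppm")
  if (!all(need %in% names(df)))
    stop("input error: peak list TSV must have columns ",
         paste(need, collapse = ", "))
  names(df)[names(df) == "delta_h_ppm"] <- "delta_h"
  names(df)[names(df) == "delta_n_ppm"] <- "delta_n"
  peak_list(df)
}

#' @rdname read_peaklist
#' @export
read_sparky_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- grep("^Assignment", lines, invert = TRUE, value = TRUE)
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 3L) return(NULL)
    m <- regmatches(f[1], regexec("^([A-Za-z]{1,3})?(\\d+)N", f[1]))[[1]]
    if (length(m) == 0)
      stop("input error: cannot parse Sparky assignment token '", f[1], "'")
    data.frame(residue_id = as.integer(m[3]),
               residue_name = if (nzchar(m[2])) m[2] else NA_character_,
               delta_n = as.numeric(f[2]), delta_h = as.numeric(f[3]),
               intensity = if (length(f) >= 4L) as.numeric(f[4]) else NA_real_,
               sigma = NA_real_)
  })
  peak_list(do.call(rbind, rows))
}

#' Write a peak list in the package TSV dialect
#'
#' @param peaks A [peak_list()].
#' @param path Output path.
#' @export
write_peaklist <- function(peaks, path) {
  df <- as.data.frame(peaks)
  names(df)[names(df) == "delta_h"] <- "delta_h_ppm"
  names(df)[names(df) == "delta_n"] <- "delta_n_ppm"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
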