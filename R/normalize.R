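#' Cycle specification for per-cycle z-scoring
#'
#' Half-open intervals of ZT hours, each treated as one daily cycle.
#' The default splits a 48-h, two-cycle course into `[0,24)` and
#' `[24,48)`.
#'
#' @param boundaries List of numeric length-2 vectors `(start, end)`;
#'   intervals must be disjoint.
#' @return Object of class `cycle_spec`.
#' @export
cycle_spec <- function(boundaries = list(c(0, 24), c(24, 48))) {
  stopifnot(is.list(boundaries), length(boundaries) >= 1)
  b <- do.call(rbind, lapply(boundaries, function(x) {
    stopifnot(length(x) == 2, x[2] > x[1])
    as.numeric(x)
  }))
  b <- b[order(b[, 1]), , drop = FALSE]
  if (nrow(b) > 1 && any(b[-1, 1] < b[-nrow(b), 2])) {
    stop("cycle intervals must be disjoint")
  }
  structure(list(boundaries = b), class = "cycle_spec")
}

cycle_index <- function(timepoints, cycles) {
  b <- cycles$boundaries
  idx <- rep(NA_integer_, length(timepoints))
  for (k in seq_len(nrow(b))) {
    idx[timepoints >= b[k, 1] & timepoints < b[k, 2]] <- k
  }
  if (anyNA(idx)) {
    stop("cycle intervals do not cover timepoint(s): ",
         paste(timepoints[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Fraction-of-total normalization of iBAQ intensities
#'
#' Converts raw iBAQ (or any nonnegative intensity) columns to FOT:
#' each sample column is divided by its total over non-missing
#' entries, so every column sums to 1 (a compositional, per-run
#' normalization). Scale-invariant per column.
#'
#' @param m A raw [omics_matrix()].
#' @return The matrix with `norm_state = "fot"`.
#' @export
ibaq_to_fot <- function(m) {
  stopifnot(inherits(m, "OmicsMatrix"))
  if (m$norm_state != "raw") {
    stop("ibaq_to_fot expects norm_state 'raw', got '", m$norm_state, "'")
  }
  tot <- colSums(m$values, na.rm = TRUE)
  bad <- which(tot <= 0 | !is.finite(tot))
  if (length(bad)) {
    stop("column ", colnames(m$values)[bad[1L]],
         " has no positive values; cannot compute FOT")
  }
  out <- m
  out$values <- sweep(m$values, 2L, tot, "/")
  out$norm_state <- "fot"
  out
}

#' Per-cycle z-scoring of a normalized matrix
#'
#' Within each cycle, each feature row is centred by its cycle mean
#' and scaled by its cycle standard deviation (sample sd, n-1):
#' z = (x - mu) / sigma. Cycles with fewer than 2 non-missing values
#' or zero variance for a feature are set entirely missing and the
#' feature is flagged degenerate for that cycle -- a constant feature
#' carries no rhythm information and must not enter the rank test as
#' fabricated ties.
#'
#' @param m An [omics_matrix()] with `norm_state` `"fot"` or
#'   `"fpkm"`.
#' @param cycles A [cycle_spec()]; pass
#'   `cycle_spec(list(range(m$timepoints) + c(0, 1)))`-style single
#'   interval for joint (whole-course) scoring.
#' @return The matrix with `norm_state` `"zscored"` (or
#'   `"fpkm_zscored"`); attribute `"degenerate_cycles"` records
#'   flagged (feature, cycle) pairs.
#' @export
zscore_per_cycle <- function(m, cycles = cycle_spec()) {
  stopifnot(inherits(m, "OmicsMatrix"), inherits(cycles, "cycle_spec"))
  if (!m$norm_state %in% c("fot", "fpkm")) {
    stop("zscore_per_cycle expects norm_state 'fot' or 'fpkm', got '",
         m$norm_state, "'")
  }
  idx <- cycle_index(m$timepoints, cycles)
  vals <- m$values
  flagged <- character(0)
  for (k in sort(unique(idx))) {
    cols <- which(idx == k)
    sub <- vals[, cols, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    nobs <- rowSums(!is.na(sub))
    sdv <- apply(sub, 1L, sd, na.rm = TRUE)
    ok <- nobs >= 2 & !is.na(sdv) & sdv > 0
    z <- (sub - mu) / sdv
    z[!ok, ] <- NA_real_
    vals[, cols] <- z
    if (any(!ok)) {
      flagged <- c(flagged, paste0(rownames(vals)[!ok], "@cycle", k))
    }
  }
  out <- m
  out$values <- vals
  out$norm_state <- if (m$norm_state == "fpkm") "fpkm_zscored" else "zscored"
  out$degenerate <- rowSums(!is.na(vals)) < 2
  attr(out, "degenerate_cycles") <- flagged
  out
}
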