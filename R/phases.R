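# Time-phase machinery: the 24-h day is split into four 6-h phases
# anchored at lights-on (TP1 = [ZT0, 6), TP2 = [6, 12), TP3 =
# [12, 18), TP4 = [18, 24)); daytime is ZT0-12 (lights on).

#' Assign ZT timepoints to time phases
#'
#' @param timepoints Numeric ZT hours (reduced mod 24).
#' @return Character vector `"TP1".."TP4"`, named by the input
#'   hours.
#' @export
assign_time_phases <- function(timepoints) {
  h <- timepoints %% 24
  tp <- paste0("TP", floor(h / 6) + 1L)
  names(tp) <- paste0("ZT", fmt_num(timepoints))
  tp
}

#' Time-phase-specific features by the strict fold rule
#'
#' A feature is TP_k-specific iff its mean abundance over the TP_k
#' samples (both cycles pooled) strictly exceeds `fold` times its
#' mean over *each* other phase separately (the stronger reading of
#' "more than twofold greater than in the rest of the phases", which
#' guarantees at most one phase per feature). Computed on the FOT
#' scale -- fold ratios are meaningless on zero-centred values. A
#' pooled-rest variant (`mode = "pooled"`) compares against the mean
#' of all non-TP_k samples instead.
#'
#' @param m An [omics_matrix()] on a ratio scale (`"fot"`, `"raw"`
#'   or `"fpkm"`).
#' @param fold Positive fold threshold (default 2).
#' @param mode `"each"` (default) or `"pooled"`.
#' @return Data frame with `feature_id`, the four phase means and
#'   `tp` (`"TP1".."TP4"` or `NA`); features lacking a value in some
#'   phase are skipped with a message.
#' @export
tp_specific_features <- function(m, fold = 2, mode = c("each", "pooled")) {
  stopifnot(inherits(m, "OmicsMatrix"))
  mode <- match.arg(mode)
  if (fold < 0) stop("fold must be nonnegative")
  if (m$norm_state %in% c("zscored", "fpkm_zscored")) {
    stop("tp_specific_features needs a ratio-scale matrix ",
         "(fot/raw/fpkm), not z-scores")
  }
  tp <- assign_time_phases(m$timepoints)
  X <- m$values
  means <- sapply(paste0("TP", 1:4), function(k) {
    cols <- which(tp == k)
    if (!length(cols)) return(rep(NA_real_, nrow(X)))
    rowMeans(X[, cols, drop = FALSE], na.rm = TRUE)
  })
  means[is.nan(means)] <- NA_real_
  skipped <- apply(means, 1L, anyNA)
  if (any(skipped)) {
    message(sum(skipped), " feature(s) skipped: no non-missing ",
            "value in some time phase")
  }
  assigned <- rep(NA_character_, nrow(X))
  for (f in which(!skipped)) {
    mu <- means[f, ]
    for (k in 1:4) {
      others <- mu[-k]
      ok <- if (mode == "each") all(mu[k] > fold * others)
            else mu[k] > fold * mean(others)
      if (ok) { assigned[f] <- paste0("TP", k); break }
    }
  }
  out <- data.frame(feature_id = rownames(X), means,
                    tp = assigned, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Peak time and day/night grouping of features
#'
#' Rhythmic features peak at their best template lag; non-rhythmic
#' features peak at the argmax of their cycle-averaged profile (values
#' at the same ZT mod 24 averaged across cycles, which also resolves
#' cross-cycle argmax ties). Daytime is `[ZT0, 12)`.
#'
#' @param m An [omics_matrix()].
#' @param rt The layer's `RhythmTable` from [jtk_cycle()].
#' @return Data frame with `feature_id`, `peak_zt_h` in `[0, 24)`,
#'   `tp` and `day_peak`.
#' @export
peak_time <- function(m, rt) {
  stopifnot(inherits(m, "OmicsMatrix"), is.data.frame(rt))
  rt <- rt[match(rownames(m$values), rt$feature_id), ]
  h24 <- m$timepoints %% 24
  grp <- sort(unique(h24))
  peak <- numeric(nrow(m$values))
  for (f in seq_len(nrow(m$values))) {
    if (isTRUE(rt$rhythmic[f]) && !is.na(rt$best_lag_h[f])) {
      peak[f] <- rt$best_lag_h[f] %% 24
    } else {
      avg <- vapply(grp, function(h) {
        mean(m$values[f, h24 == h], na.rm = TRUE)
      }, numeric(1))
      peak[f] <- grp[which.max(avg)]
    }
  }
  data.frame(feature_id = rownames(m$values),
             peak_zt_h = peak,
             tp = unname(assign_time_phases(peak)),
             day_peak = peak >= 0 & peak < 12,
             stringsAsFactors = FALSE)
}

#' Day/night fold-change screen
#'
#' Fold change between the day (`ZT mod 24` in `[0, 12)`) and night
#' mean of each feature: `max(mean_day, mean_night) / min(...)`,
#' missing values excluded; a zero minimum gives infinite fold change
#' (selected and flagged). Selection is strict (`fc > threshold`).
#'
#' @param m An [omics_matrix()] on a ratio scale.
#' @param threshold Fold-change threshold (default 5).
#' @return Data frame with `feature_id`, `mean_day`, `mean_night`,
#'   `fc`, `selected`, `degenerate_zero`.
#' @export
day_night_fold_change <- function(m, threshold = 5) {
  stopifnot(inherits(m, "OmicsMatrix"))
  if (m$norm_state %in% c("zscored", "fpkm_zscored")) {
    stop("day_night_fold_change needs a ratio-scale matrix")
  }
  h24 <- m$timepoints %% 24
  day <- h24 >= 0 & h24 < 12
  if (!any(day) || all(day)) {
    stop("need both day (ZT0-12) and night samples")
  }
  md <- rowMeans(m$values[, day, drop = FALSE], na.rm = TRUE)
  mn <- rowMeans(m$values[, !day, drop = FALSE], na.rm = TRUE)
  lo <- pmin(md, mn); hi <- pmax(md, mn)
  fc <- ifelse(lo == 0, Inf, hi / lo)
  data.frame(feature_id = rownames(m$values),
             mean_day = md, mean_night = mn, fc = fc,
             selected = fc > threshold,
             degenerate_zero = lo == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}
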