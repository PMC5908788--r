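#' Run configuration
#'
#' Bundles every tunable threshold of the pipeline, with defaults
#' matching the study design the package targets: a JTK-family test
#' over periods 20-28 h on 3-h sampling, rhythmicity cut-offs p < 0.1
#' for proteome layers and p < 0.05 for transcripts, a strict twofold
#' rule for time-phase-specific TFs, Pearson r thresholds +0.5/-0.5
#' for activator/repressor calls, three top-correlated Mediator
#' subunits per TF, and a day/night fold-change screen at 5.
#'
#' @param period_range_h Numeric length-2, admissible period range in
#'   hours (default `c(20, 28)`).
#' @param sampling_interval_h Sampling interval in hours (default 3).
#' @param alpha_proteome Rhythmicity threshold for proteome-type
#'   layers (default 0.1, strict `<`).
#' @param alpha_transcript Rhythmicity threshold for the transcriptome
#'   (default 0.05).
#' @param tp_fold Fold threshold of the time-phase-specific rule
#'   (default 2, must be > 1).
#' @param activator_r,repressor_r Pearson r thresholds for
#'   activator/repressor edge labels (defaults 0.5 and -0.5).
#' @param mediator_k Number of Mediator subunits linked per TF
#'   (default 3).
#' @param day_night_fc Day/night fold-change screen threshold
#'   (default 5, strict `>`).
#' @param min_tg Minimum number of measured target genes for a TF to
#'   be eligible as dominant rhythmic (default 3).
#' @param enrich_alpha One-sided hypergeometric threshold for
#'   target-set rhythm enrichment (default 0.05).
#' @param seed Integer seed driving every stochastic step.
#'
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(period_range_h = c(20, 28),
                       sampling_interval_h = 3,
                       alpha_proteome = 0.1,
                       alpha_transcript = 0.05,
                       tp_fold = 2,
                       activator_r = 0.5,
                       repressor_r = -0.5,
                       mediator_k = 3L,
                       day_night_fc = 5,
                       min_tg = 3L,
                       enrich_alpha = 0.05,
                       seed = 1L) {
  stopifnot(length(period_range_h) == 2, period_range_h[1] > 0,
            period_range_h[2] >= period_range_h[1],
            sampling_interval_h > 0)
  for (a in c(alpha_proteome, alpha_transcript, enrich_alpha)) {
    if (!(a > 0 && a <= 1)) {
      stop("alpha thresholds must lie in (0, 1]")
    }
  }
  if (!(tp_fold > 1)) stop("tp_fold must be > 1")
  if (day_night_fc <= 0) stop("day_night_fc must be positive")
  if (mediator_k < 1) stop("mediator_k must be >= 1")
  if (min_tg < 1) stop("min_tg must be >= 1")
  pmin_ <- ceiling(period_range_h[1] / sampling_interval_h)
  pmax_ <- floor(period_range_h[2] / sampling_interval_h)
  if (pmin_ > pmax_) {
    stop("no admissible period (multiple of the sampling interval) ",
         "in the stated range")
  }
  structure(
    list(period_range_h = as.numeric(period_range_h),
         sampling_interval_h = as.numeric(sampling_interval_h),
         alpha_proteome = alpha_proteome,
         alpha_transcript = alpha_transcript,
         tp_fold = tp_fold,
         activator_r = activator_r,
         repressor_r = repressor_r,
         mediator_k = as.integer(mediator_k),
         day_night_fc = day_night_fc,
         min_tg = as.integer(min_tg),
         enrich_alpha = enrich_alpha,
         seed = as.integer(seed)),
    class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
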