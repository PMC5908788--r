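# Dominant-rhythmic-TF (DR-TF) nomination and ubiquitylation
# coupling. A DR-TF must (a) be rhythmic in DNA-binding activity,
# (b) have enough measured target genes, and (c) show one-sided
# hypergeometric enrichment of rhythmic targets against the
# transcriptome background -- the package's concretization of
# "controls the diurnal rhythmicity of its downstream target genes".

#' Nominate dominant rhythmic TFs
#'
#' @param tf_rhythms `RhythmTable` of the TF DNA-binding-activity
#'   layer (its `rhythmic` flags define condition (a)).
#' @param tg_rhythms `RhythmTable` of the transcriptome (defines the
#'   rhythmicity of targets and the background).
#' @param net Directed TF-to-target igraph (or 2/3-column edge data
#'   frame).
#' @param min_tg Minimum measured targets (default 3).
#' @param enrich_alpha One-sided hypergeometric threshold
#'   (default 0.05).
#' @return Data frame with one row per TF present in both the
#'   network and `tf_rhythms`: `tf_id`, `tf_rhythmic`, `n_targets`
#'   (network targets measured in the transcriptome),
#'   `n_rhythmic_targets`, `target_rhythm_p`, `is_dr_tf`,
#'   `insufficient_targets`.
#' @export
nominate_dr_tfs <- function(tf_rhythms, tg_rhythms, net,
                            min_tg = 3L, enrich_alpha = 0.05) {
  targets <- edge_target_list(net)
  if (!length(targets)) stop("empty TF-to-target network")
  tfs <- intersect(names(targets), tf_rhythms$feature_id)
  if (!length(tfs)) stop("no network TF measured in tf_rhythms")
  bg <- tg_rhythms$feature_id
  bg_rhy <- tg_rhythms$feature_id[tg_rhythms$rhythmic]
  N <- length(bg); K <- length(bg_rhy)
  rows <- lapply(tfs, function(tf) {
    tg <- intersect(targets[[tf]], bg)
    n <- length(tg)
    k <- length(intersect(tg, bg_rhy))
    p <- if (n > 0) {
      phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    } else 1
    rhy <- tf_rhythms$rhythmic[match(tf, tf_rhythms$feature_id)]
    data.frame(tf_id = tf, tf_rhythmic = rhy, n_targets = n,
               n_rhythmic_targets = k, target_rhythm_p = p,
               is_dr_tf = isTRUE(rhy) && n >= min_tg &&
                 p < enrich_alpha,
               insufficient_targets = n < min_tg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

edge_target_list <- function(net) {
  if (inherits(net, "igraph")) {
    return(regulator_targets(net))
  }
  stopifnot(is.data.frame(net), ncol(net) >= 2)
  lapply(split(net[[2]], net[[1]]), unique)
}

#' Activator/repressor classification of TF-to-target edges
#'
#' An edge is labelled `activator` when the Pearson correlation of
#' the TF's (z-scored) DNA-binding activity with the target's
#' (z-scored) transcript across the timepoints exceeds `r_act`
#' (strict), `repressor` below `r_rep` (strict), else
#' `unclassified`. Correlations are pairwise-complete; edges with
#' fewer than 3 paired points or a zero-variance profile are
#' unclassified and flagged.
#'
#' @param tf_profile Numeric vector (one TF).
#' @param tg_profiles Numeric matrix, one row per target (or a
#'   single vector).
#' @param r_act,r_rep Thresholds (defaults 0.5 and -0.5).
#' @return Data frame with `target`, `r`, `label`, `flagged`.
#' @export
classify_regulator_sign <- function(tf_profile, tg_profiles,
                                    r_act = 0.5, r_rep = -0.5) {
  if (is.null(dim(tg_profiles))) {
    tg_profiles <- matrix(tg_profiles, nrow = 1)
  }
  if (is.null(rownames(tg_profiles))) {
    rownames(tg_profiles) <- sprintf("tg%d", seq_len(nrow(tg_profiles)))
  }
  res <- lapply(seq_len(nrow(tg_profiles)), function(i) {
    y <- tg_profiles[i, ]
    ok <- stats::complete.cases(tf_profile, y)
    r <- NA_real_; flagged <- FALSE
    if (sum(ok) < 3) {
      flagged <- TRUE
    } else if (sd(tf_profile[ok]) == 0 || sd(y[ok]) == 0) {
      flagged <- TRUE
    } else {
      r <- cor(tf_profile[ok], y[ok])
    }
    label <- if (is.na(r)) "unclassified"
             else if (r > r_act) "activator"
             else if (r < r_rep) "repressor"
             else "unclassified"
    data.frame(target = rownames(tg_profiles)[i], r = r,
               label = label, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Ubiquitylation rates of rhythmic vs non-rhythmic TFs and targets
#'
#' Four percentages: the ubiquitylated fraction among rhythmic TFs,
#' among non-rhythmic TFs, among the target-gene union of rhythmic
#' TFs and among the target union of non-rhythmic TFs (a target
#' shared by two TFs of a class is counted once). Empty denominators
#' yield `NA`, not 0.
#'
#' @param tf_rhythms `RhythmTable` of the TF layer.
#' @param net Directed TF-to-target igraph or edge data frame.
#' @param ubi_set Character vector of feature ids observed
#'   ubiquitylated.
#' @return Data frame with `group`, `n`, `n_ubiquitylated`,
#'   `percent`.
#' @export
ubiquitylation_crosstab <- function(tf_rhythms, net, ubi_set) {
  targets <- edge_target_list(net)
  tfs <- intersect(names(targets), tf_rhythms$feature_id)
  rhy <- tfs[tf_rhythms$rhythmic[match(tfs, tf_rhythms$feature_id)]]
  non <- setdiff(tfs, rhy)
  tg_rhy <- unique(unlist(targets[rhy], use.names = FALSE))
  tg_non <- unique(unlist(targets[non], use.names = FALSE))
  cell <- function(group, ids) {
    n <- length(ids)
    k <- length(intersect(ids, ubi_set))
    data.frame(group = group, n = n, n_ubiquitylated = k,
               percent = if (n > 0) 100 * k / n else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(cell("rhythmic_tfs", rhy),
               cell("nonrhythmic_tfs", non),
               cell("tgs_of_rhythmic_tfs", tg_rhy),
               cell("tgs_of_nonrhythmic_tfs", tg_non))
  rownames(out) <- NULL
  out
}

#' Resampling test for ubiquitylation of rhythmic TFs' targets
#'
#' The statistic is the number of ubiquitylated genes in the target
#' union of the rhythmic TFs; the null redraws same-size TF sets
#' uniformly without replacement from all network TFs. The empirical
#' p uses the add-one estimator `(1 + #(null >= observed)) /
#' (n_iter + 1)`, which never reports 0.
#'
#' @param net Directed TF-to-target igraph or edge data frame.
#' @param ubi_set Ubiquitylated feature ids.
#' @param rhythmic_tfs TF ids (must be a subset of the network's
#'   TFs, at most all of them).
#' @param n_iter Resampling iterations (>= 100; default 10000).
#' @param seed Optional integer seed.
#' @return List with `observed`, `null` (numeric vector), `p`.
#' @export
random_tf_resample_test <- function(net, ubi_set, rhythmic_tfs,
                                    n_iter = 10000L, seed = NULL) {
  if (n_iter < 100) stop("n_iter must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  targets <- edge_target_list(net)
  all_tfs <- names(targets)
  rhythmic_tfs <- intersect(rhythmic_tfs, all_tfs)
  if (length(rhythmic_tfs) > length(all_tfs)) {
    stop("more rhythmic TFs than network TFs")
  }
  count_ubi <- function(tfs) {
    length(intersect(unique(unlist(targets[tfs], use.names = FALSE)),
                     ubi_set))
  }
  obs <- count_ubi(rhythmic_tfs)
  m <- length(rhythmic_tfs)
  null <- vapply(seq_len(n_iter), function(b) {
    count_ubi(sample(all_tfs, m))
  }, numeric(1))
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs)) / (n_iter + 1))
}
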