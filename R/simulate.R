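# Synthetic multi-layer circadian study generator. The stated world:
# 16 samples at 3-h spacing over two daily cycles; ~27% of TFs
# rhythmic (80/297 in the motivating design); 57.5% of rhythmic TFs
# dominant-rhythmic (46/80); target genes sign-coupled to their TF's
# DNA-binding activity by shared (activator) or 12-h-shifted
# (repressor) acrophase; ubiquitylation rates 5%/2% for
# rhythmic/other TFs and 8%/6% for their target genes.

#' Planted rhythm parameters for one feature
#'
#' @param baseline Positive mean level.
#' @param amplitude Nonnegative cosine amplitude (0 for non-rhythmic
#'   features).
#' @param period_h Period in hours (default 24).
#' @param acrophase_h Peak time in `[0, 24)`.
#' @param noise_sd Nonnegative Gaussian noise sd.
#' @param is_rhythmic Flag; must agree with `amplitude > 0`.
#' @return Object of class `rhythm_params`.
#' @export
rhythm_params <- function(baseline, amplitude, period_h = 24,
                          acrophase_h = 0, noise_sd = 0,
                          is_rhythmic = amplitude > 0) {
  if (amplitude < 0) stop("amplitude must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (baseline <= 0) stop("baseline must be positive")
  if (is_rhythmic && amplitude == 0) {
    stop("rhythmic features require amplitude > 0")
  }
  if (!is_rhythmic && amplitude != 0) {
    stop("non-rhythmic features require amplitude = 0")
  }
  structure(list(baseline = baseline, amplitude = amplitude,
                 period_h = period_h,
                 acrophase_h = acrophase_h %% 24,
                 noise_sd = noise_sd, is_rhythmic = is_rhythmic),
            class = "rhythm_params")
}

#' Simulate one cosine rhythm profile
#'
#' x(t) = baseline + amplitude * cos(2 pi (t - acrophase) / period)
#' + N(0, noise_sd). Uses the current RNG state; seed with
#' `set.seed()` before calling for reproducibility.
#'
#' @param params A [rhythm_params()].
#' @param timepoints Numeric ZT hours.
#' @param nonneg_clip Clip the result at zero. The caller should keep
#'   `baseline > 3 * (amplitude + 3 * noise_sd)` so that clipping is
#'   a no-op in practice; a warning is raised otherwise.
#' @return Numeric vector, one value per timepoint.
#' @export
simulate_profile <- function(params, timepoints, nonneg_clip = FALSE) {
  stopifnot(inherits(params, "rhythm_params"))
  x <- params$baseline +
    params$amplitude *
      cos(2 * pi * (timepoints - params$acrophase_h) / params$period_h)
  if (params$noise_sd > 0) {
    x <- x + rnorm(length(timepoints), 0, params$noise_sd)
  }
  if (nonneg_clip) {
    if (params$baseline <= 3 * (params$amplitude + 3 * params$noise_sd)) {
      warning("baseline <= 3*(amplitude + 3*noise_sd); ",
              "clipping may distort the profile")
    }
    x <- pmax(x, 0)
  }
  x
}

# von-Mises-style bump used for planted time-phase-specific TFs: a
# nonnegative pure cosine can never pass a strict twofold rule on
# 6-h phase means (peak-phase mean b + 0.924 A must exceed 2 b while
# the trough mean b - 0.924 A stays nonnegative), so phase-specific
# regulators are planted as concentrated peaks instead.
bump_shape <- function(timepoints, acrophase_h, kappa = 4) {
  exp(kappa * (cos(2 * pi * (timepoints - acrophase_h) / 24) - 1))
}

tp_midpoints <- function() c(1.5, 7.5, 13.5, 19.5)

#' Simulate a full multi-layer circadian study with ground truth
#'
#' Generates a TF DNA-binding-activity layer (all TFs plus Mediator
#' subunits), a transcriptome of target genes sign-coupled to their
#' TF, optional additional layers, the directed TF-to-target network,
#' an ubiquitylated-feature set, and pathway annotation sets --
#' together with a truth record of every planted parameter.
#'
#' Rhythmic TFs receive 24-h cosines with acrophases cycling over the
#' four time-phase midpoints (ZT 1.5, 7.5, 13.5, 19.5) so that every
#' phase receives planted phase-specific TFs; a configurable fraction
#' of them are planted as phase-specific concentrated bumps (height
#' `2 * snr * noise_sd`, baseline one tenth of the height). Targets
#' of dominant-rhythmic TFs oscillate with their TF's acrophase
#' (activator edges) or shifted by 12 h (repressor edges) plus
#' independent noise; targets of decoy rhythmic TFs and of
#' non-rhythmic TFs are flat noise.
#'
#' @param n_tfs Number of TFs (default 300).
#' @param n_tgs_per_tf Distinct target genes per TF (default 10).
#' @param frac_rhythmic Fraction of TFs planted rhythmic
#'   (default 0.27).
#' @param frac_dr Fraction of rhythmic TFs that are dominant rhythmic
#'   (rhythmic, coupled targets; default 0.575).
#' @param frac_tp_specific Fraction of rhythmic TFs planted as
#'   phase-specific bumps (default 0.25).
#' @param snr Amplitude-to-noise ratio of planted rhythms
#'   (default 4).
#' @param noise_sd Gaussian noise sd (default 1).
#' @param activator_prob Probability that a TF-to-target edge is an
#'   activator (+1) rather than a repressor (-1) (default 0.5).
#' @param layers Layers to generate besides the mandatory `tf_dba`
#'   and `transcriptome`.
#' @param n_extra_features Features per additional layer
#'   (default 200).
#' @param missing_rate Uniform random missingness rate applied to the
#'   matrices (default 0).
#' @param n_mediators Mediator subunits added to the DBA layer
#'   (default 19).
#' @param ubi_rates Named ubiquitylation probabilities
#'   (`tf_rhythmic`, `tf_other`, `tg_rhythmic`, `tg_other`).
#' @param timepoints ZT hours of the two-cycle layers
#'   (default `seq(0, 45, by = 3)`).
#' @param seed Optional integer; when given, `set.seed(seed)` is
#'   called so the whole study is reproducible.
#'
#' @return List with elements `matrices` (named list of
#'   [omics_matrix()]), `networks` (list with the signed directed
#'   `tf_tg` igraph), `ubi_set` (character vector) and `truth` (TF
#'   table, edge table, per-feature parameters, mediator ids,
#'   annotation sets).
#' @export
simulate_study <- function(n_tfs = 300L, n_tgs_per_tf = 10L,
                           frac_rhythmic = 0.27, frac_dr = 0.575,
                           frac_tp_specific = 0.25,
                           snr = 4, noise_sd = 1,
                           activator_prob = 0.5,
                           layers = character(0),
                           n_extra_features = 200L,
                           missing_rate = 0,
                           n_mediators = 19L,
                           ubi_rates = c(tf_rhythmic = 0.05,
                                         tf_other = 0.02,
                                         tg_rhythmic = 0.08,
                                         tg_other = 0.06),
                           timepoints = seq(0, 45, by = 3),
                           seed = NULL) {
  if (!(frac_rhythmic >= 0 && frac_rhythmic <= 1)) {
    stop("frac_rhythmic must lie in [0, 1]")
  }
  if (snr <= 0) stop("snr must be positive")
  if (n_tgs_per_tf < 1 && frac_rhythmic > 0 && frac_dr > 0) {
    stop("n_tgs_per_tf = 0 is impossible with planted dominant ",
         "rhythmic TFs")
  }
  if (!is.null(seed)) set.seed(seed)
  tp <- timepoints
  A <- snr * noise_sd

  tf_ids <- sprintf("TF%03d", seq_len(n_tfs))
  n_rhy <- round(frac_rhythmic * n_tfs)
  rhythmic <- c(rep(TRUE, n_rhy), rep(FALSE, n_tfs - n_rhy))
  mids <- tp_midpoints()
  acro <- rep(NA_real_, n_tfs)
  tp_label <- rep(NA_integer_, n_tfs)
  if (n_rhy > 0) {
    acro[seq_len(n_rhy)] <- mids[((seq_len(n_rhy) - 1L) %% 4L) + 1L]
    tp_label[seq_len(n_rhy)] <- ((seq_len(n_rhy) - 1L) %% 4L) + 1L
  }
  n_dr <- round(frac_dr * n_rhy)
  is_dr <- c(rep(TRUE, n_dr), rep(FALSE, n_tfs - n_dr)) & rhythmic
  n_tp <- round(frac_tp_specific * n_rhy)
  is_tp <- rep(FALSE, n_tfs)
  if (n_tp > 0) is_tp[seq_len(n_tp)] <- TRUE

  base_tf <- runif(n_tfs, 25, 100)
  dba <- matrix(NA_real_, n_tfs, length(tp),
                dimnames = list(tf_ids, NULL))
  for (f in seq_len(n_tfs)) {
    if (rhythmic[f] && is_tp[f]) {
      H <- 2 * A
      dba[f, ] <- pmax(0, 0.1 * H + H * bump_shape(tp, acro[f]) +
                         rnorm(length(tp), 0, noise_sd))
    } else if (rhythmic[f]) {
      dba[f, ] <- pmax(0, base_tf[f] + A *
                         cos(2 * pi * (tp - acro[f]) / 24) +
                         rnorm(length(tp), 0, noise_sd))
    } else {
      dba[f, ] <- pmax(0, base_tf[f] + rnorm(length(tp), 0, noise_sd))
    }
  }

  med_ids <- character(0)
  if (n_mediators > 0) {
    med_ids <- sprintf("MED%02d", seq_len(n_mediators))
    med_acro <- sample(seq(0, 22.5, by = 1.5), n_mediators,
                       replace = TRUE)
    med_rhy <- runif(n_mediators) < 0.5
    med <- matrix(NA_real_, n_mediators, length(tp),
                  dimnames = list(med_ids, NULL))
    base_md <- runif(n_mediators, 25, 100)
    for (f in seq_len(n_mediators)) {
      med[f, ] <- pmax(0, base_md[f] +
                         (if (med_rhy[f]) A else 0) *
                           cos(2 * pi * (tp - med_acro[f]) / 24) +
                         rnorm(length(tp), 0, noise_sd))
    }
    dba <- rbind(dba, med)
  }

  # transcriptome: disjoint target-gene blocks per TF
  n_tg <- n_tfs * n_tgs_per_tf
  tg_ids <- sprintf("TG%05d", seq_len(n_tg))
  edge_tf <- rep(tf_ids, each = n_tgs_per_tf)
  edge_sign <- ifelse(runif(n_tg) < activator_prob, 1, -1)
  tg_rhythmic <- rep(rhythmic & is_dr, each = n_tgs_per_tf) &
    n_tgs_per_tf > 0
  tg_acro <- rep(acro, each = n_tgs_per_tf)
  tg_acro <- ifelse(edge_sign > 0, tg_acro, (tg_acro + 12) %% 24)
  base_tg <- runif(n_tg, 25, 100)
  trans <- matrix(NA_real_, n_tg, length(tp),
                  dimnames = list(tg_ids, NULL))
  for (f in seq_len(n_tg)) {
    amp <- if (isTRUE(tg_rhythmic[f])) A else 0
    mu <- base_tg[f] + if (amp > 0)
      amp * cos(2 * pi * (tp - tg_acro[f]) / 24) else 0
    trans[f, ] <- pmax(0, mu + rnorm(length(tp), 0, noise_sd))
  }

  mats <- list(
    tf_dba = omics_matrix(dba, "tf_dba", timepoints = tp,
                          norm_state = "raw"),
    transcriptome = omics_matrix(trans, "transcriptome",
                                 timepoints = tp,
                                 norm_state = "fpkm"))

  feature_truth <- list(
    data.frame(feature_id = tf_ids, layer = "tf_dba",
               baseline = base_tf,
               amplitude = ifelse(rhythmic, A, 0),
               acrophase_h = acro, noise_sd = noise_sd,
               is_rhythmic = rhythmic,
               profile = ifelse(!rhythmic, "flat",
                                ifelse(is_tp, "bump", "cosine")),
               stringsAsFactors = FALSE),
    data.frame(feature_id = tg_ids, layer = "transcriptome",
               baseline = base_tg,
               amplitude = ifelse(tg_rhythmic, A, 0),
               acrophase_h = ifelse(tg_rhythmic, tg_acro, NA_real_),
               noise_sd = noise_sd, is_rhythmic = tg_rhythmic,
               profile = ifelse(tg_rhythmic, "cosine", "flat"),
               stringsAsFactors = FALSE))

  extra_layers <- setdiff(layers, c("tf_dba", "transcriptome"))
  for (ly in extra_layers) {
    ly <- match.arg(ly, omics_layers())
    tp_ly <- switch(ly,
                    ubiquitylome = seq(0, 21, by = 3),
                    kc_proteome = c(0, 6, 12, 18),
                    tp)
    ids <- sprintf("%s_F%04d", toupper(substr(ly, 1, 2)),
                   seq_len(n_extra_features))
    rhy <- runif(n_extra_features) < frac_rhythmic
    ac <- sample(seq(0, 22.5, by = 1.5), n_extra_features,
                 replace = TRUE)
    bs <- runif(n_extra_features, 25, 100)
    v <- matrix(NA_real_, n_extra_features, length(tp_ly),
                dimnames = list(ids, NULL))
    for (f in seq_len(n_extra_features)) {
      v[f, ] <- pmax(0, bs[f] + (if (rhy[f]) A else 0) *
                       cos(2 * pi * (tp_ly - ac[f]) / 24) +
                       rnorm(length(tp_ly), 0, noise_sd))
    }
    mats[[ly]] <- omics_matrix(v, ly, timepoints = tp_ly,
                               norm_state = "raw")
    feature_truth[[length(feature_truth) + 1L]] <- data.frame(
      feature_id = ids, layer = ly, baseline = bs,
      amplitude = ifelse(rhy, A, 0),
      acrophase_h = ifelse(rhy, ac, NA_real_),
      noise_sd = noise_sd, is_rhythmic = rhy,
      profile = ifelse(rhy, "cosine", "flat"),
      stringsAsFactors = FALSE)
  }

  if (missing_rate > 0) {
    for (nm in names(mats)) {
      v <- mats[[nm]]$values
      drop <- matrix(runif(length(v)) < missing_rate, nrow(v))
      v[drop] <- NA_real_
      mats[[nm]]$values <- v
      mats[[nm]]$degenerate <- rowSums(!is.na(v)) < 2
    }
  }

  # ubiquitylated feature set drawn at the planted rates
  rhy_tf <- tf_ids[rhythmic]
  oth_tf <- tf_ids[!rhythmic]
  tg_rhy_ids <- tg_ids[edge_tf %in% rhy_tf]
  tg_oth_ids <- setdiff(tg_ids, tg_rhy_ids)
  ubi_set <- c(
    rhy_tf[runif(length(rhy_tf)) < ubi_rates[["tf_rhythmic"]]],
    oth_tf[runif(length(oth_tf)) < ubi_rates[["tf_other"]]],
    tg_rhy_ids[runif(length(tg_rhy_ids)) < ubi_rates[["tg_rhythmic"]]],
    tg_oth_ids[runif(length(tg_oth_ids)) < ubi_rates[["tg_other"]]])

  edges <- data.frame(from = edge_tf, to = tg_ids, sign = edge_sign,
                      stringsAsFactors = FALSE)
  tf_tg <- igraph::graph_from_data_frame(edges, directed = TRUE)

  pathways <- c("immune_response", "lipid_metabolism",
                "cell_cycle", "glucose_metabolism")
  annotation_sets <- list()
  for (k in 1:4) {
    tfs_k <- tf_ids[!is.na(tp_label) & tp_label == k]
    annotation_sets[[pathways[k]]] <-
      c(tfs_k, tg_ids[edge_tf %in% tfs_k])
  }

  tf_table <- data.frame(
    tf_id = tf_ids, is_rhythmic = rhythmic, is_dr = is_dr,
    is_tp_specific = is_tp, tp = tp_label, acrophase_h = acro,
    stringsAsFactors = FALSE)

  list(matrices = mats,
       networks = list(tf_tg = tf_tg),
       ubi_set = unique(ubi_set),
       truth = list(tf = tf_table, edges = edges,
                    features = do.call(rbind, feature_truth),
                    mediator_ids = med_ids,
                    annotation_sets = annotation_sets))
}

#' Simulate interaction networks for path analyses
#'
#' Draws an Erdos-Renyi undirected protein-protein interaction graph
#' over the given nodes and a directed kinase-to-substrate map whose
#' targets are restricted to the supplied substrate (phospho-layer)
#' ids.
#'
#' @param n_nodes Number of PPI nodes (ignored when `node_ids`
#'   given); must be >= 2.
#' @param node_ids Optional node identifiers.
#' @param edge_prob Edge probability in (0, 1].
#' @param n_kinases Number of kinases (0 gives an empty map).
#' @param substrate_ids Candidate substrate ids (default: the PPI
#'   nodes).
#' @param substrates_per_kinase Substrates drawn per kinase
#'   (default 5, capped at the candidate count).
#' @param seed Optional integer seed.
#' @return List with `ppi` (undirected simple igraph) and
#'   `kinase_map` (directed igraph, possibly edgeless).
#' @export
simulate_networks <- function(n_nodes = 100L, node_ids = NULL,
                              edge_prob = 0.05, n_kinases = 10L,
                              substrate_ids = NULL,
                              substrates_per_kinase = 5L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(node_ids)) {
    if (n_nodes < 2) stop("n_nodes must be >= 2")
    node_ids <- sprintf("N%04d", seq_len(n_nodes))
  }
  n <- length(node_ids)
  if (n < 2) stop("need at least 2 nodes")
  if (!(edge_prob > 0 && edge_prob <= 1)) {
    stop("edge_prob must lie in (0, 1]")
  }
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < edge_prob
  ppi <- igraph::graph_from_data_frame(
    data.frame(from = node_ids[pairs[keep, 1]],
               to = node_ids[pairs[keep, 2]],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = node_ids, stringsAsFactors = FALSE))
  if (is.null(substrate_ids)) substrate_ids <- node_ids
  if (n_kinases > 0) {
    kin_ids <- sprintf("KIN%02d", seq_len(n_kinases))
    kel <- do.call(rbind, lapply(kin_ids, function(k) {
      tgt <- sample(substrate_ids,
                    min(substrates_per_kinase, length(substrate_ids)))
      data.frame(from = k, to = tgt, stringsAsFactors = FALSE)
    }))
    kinase_map <- igraph::graph_from_data_frame(kel, directed = TRUE)
  } else {
    kinase_map <- igraph::make_empty_graph(directed = TRUE)
  }
  list(ppi = ppi, kinase_map = kinase_map)
}
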