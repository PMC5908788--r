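# Graph and correlation analyses: breadth-first shortest paths from
# phosphorylated substrates to TFs on a protein-interaction graph,
# top-k Pearson linking of TFs to Mediator subunits, bipartite edge
# counts between cell-type and whole-tissue protein sets, generic
# hypergeometric set enrichment, and the paired t comparisons the
# study reports.

#' Unweighted shortest-path lengths between node sets
#'
#' @param g Undirected igraph.
#' @param sources,targets Character vectors of node ids; ids absent
#'   from the graph are skipped with a message.
#' @return Numeric matrix of breadth-first path lengths
#'   (sources x targets); unreachable pairs are `Inf`.
#' @export
shortest_path_lengths <- function(g, sources, targets) {
  stopifnot(inherits(g, "igraph"))
  if (!length(sources) || !length(targets)) {
    stop("sources and targets must be non-empty")
  }
  known <- igraph::V(g)$name
  drop_s <- setdiff(sources, known)
  drop_t <- setdiff(targets, known)
  if (length(drop_s) || length(drop_t)) {
    message(length(drop_s) + length(drop_t),
            " node(s) absent from the graph skipped")
  }
  sources <- intersect(sources, known)
  targets <- intersect(targets, known)
  if (!length(sources) || !length(targets)) {
    stop("no source/target nodes present in the graph")
  }
  igraph::distances(g, v = sources, to = targets, weights = NA)
}

#' Per-substrate mean path lengths to pathway vs all TFs
#'
#' @param g Undirected igraph.
#' @param substrates Substrate node ids.
#' @param pathway_tfs,all_tfs TF id sets.
#' @return Data frame (one row per substrate) with
#'   `mean_path_to_pathway_tfs`, `mean_path_to_all_tfs` (means over
#'   reachable targets only; `NA` when none reachable) and the
#'   reachable-target counts.
#' @export
summarize_paths <- function(g, substrates, pathway_tfs, all_tfs) {
  dp <- shortest_path_lengths(g, substrates, pathway_tfs)
  da <- shortest_path_lengths(g, substrates, all_tfs)
  mean_fin <- function(x) {
    x <- x[is.finite(x)]
    if (length(x)) mean(x) else NA_real_
  }
  data.frame(
    substrate_id = rownames(dp),
    mean_path_to_pathway_tfs = apply(dp, 1L, mean_fin),
    mean_path_to_all_tfs = apply(da[rownames(dp), , drop = FALSE],
                                 1L, mean_fin),
    n_reachable_pathway = apply(dp, 1L, function(x) sum(is.finite(x))),
    n_reachable_all = apply(da[rownames(dp), , drop = FALSE], 1L,
                            function(x) sum(is.finite(x))),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Paired t-test on per-substrate path-length differences
#'
#' Two-sided paired Student t-test of mean path length to
#' pathway-specific TFs against mean path length to all TFs, paired
#' per substrate.
#'
#' @param ps Data frame from [summarize_paths()].
#' @return List with `statistic`, `df`, `p_two_sided`,
#'   `mean_difference`, `n`.
#' @export
compare_path_lengths <- function(ps) {
  ok <- stats::complete.cases(ps$mean_path_to_pathway_tfs,
                              ps$mean_path_to_all_tfs)
  d <- ps$mean_path_to_pathway_tfs[ok] - ps$mean_path_to_all_tfs[ok]
  if (length(d) < 3) stop("need >= 3 substrates with both means")
  if (sd(d) == 0) {
    stop("degenerate comparison: all paired differences identical")
  }
  tt <- t.test(d)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, mean_difference = mean(d),
       n = length(d))
}

#' Link each TF to its k most correlated Mediator subunits
#'
#' For every TF profile, the `k` Mediator profiles with the largest
#' Pearson correlation (pairwise-complete) are linked; ties on r are
#' broken by mediator id in lexicographic order. TFs facing fewer
#' than `k` mediators link all of them and are flagged.
#'
#' @param tf_profiles Numeric matrix, one row per TF (row names =
#'   TF ids).
#' @param mediator_profiles Numeric matrix, one row per Mediator
#'   subunit.
#' @param k Number of links per TF (default 3).
#' @return Data frame with `tf_id`, `mediator_id`, `r`, `rank`,
#'   `flagged_short`.
#' @export
top_k_correlated_mediators <- function(tf_profiles, mediator_profiles,
                                       k = 3L) {
  stopifnot(k >= 1, is.matrix(tf_profiles), is.matrix(mediator_profiles))
  meds <- rownames(mediator_profiles)
  rows <- lapply(rownames(tf_profiles), function(tf) {
    x <- tf_profiles[tf, ]
    r <- vapply(meds, function(md) {
      y <- mediator_profiles[md, ]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        return(NA_real_)
      }
      cor(x[ok], y[ok])
    }, numeric(1))
    o <- order(-r, meds, na.last = TRUE)
    take <- o[seq_len(min(k, length(meds)))]
    data.frame(tf_id = tf, mediator_id = meds[take], r = r[take],
               rank = seq_along(take),
               flagged_short = length(meds) < k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare correlation sets of pathway TFs vs all TFs with Mediators
#'
#' Reports the two pooled mean correlations and a two-sided paired
#' t-test with the Mediator subunit as the pairing unit: for each
#' mediator, its mean correlation over pathway TFs is paired with
#' its mean correlation over all TFs.
#'
#' @param r_pathway,r_all Numeric matrices of Pearson correlations
#'   (mediators x TFs; row names must agree).
#' @return List with `mean_pathway`, `mean_all`, `statistic`, `df`,
#'   `p_two_sided`, `n_mediators`.
#' @export
compare_correlation_sets <- function(r_pathway, r_all) {
  stopifnot(is.matrix(r_pathway), is.matrix(r_all))
  meds <- intersect(rownames(r_pathway), rownames(r_all))
  if (length(meds) < 3) stop("need >= 3 shared mediators")
  a <- rowMeans(r_pathway[meds, , drop = FALSE], na.rm = TRUE)
  b <- rowMeans(r_all[meds, , drop = FALSE], na.rm = TRUE)
  d <- a - b
  if (sd(d) == 0) {
    stop("degenerate comparison: zero variance of paired differences")
  }
  tt <- t.test(d)
  list(mean_pathway = mean(r_pathway, na.rm = TRUE),
       mean_all = mean(r_all, na.rm = TRUE),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, n_mediators = length(meds))
}

#' Count graph edges crossing two protein sets
#'
#' Number of edges with one endpoint in `set_a` and the other in
#' `set_b`; within-set edges are not counted, each crossing edge is
#' counted once. Symmetric in the two sets.
#'
#' @param set_a,set_b Character vectors of node ids (overlap
#'   allowed).
#' @param g Undirected igraph.
#' @return Integer edge count.
#' @export
bipartite_edge_count <- function(set_a, set_b, g) {
  el <- igraph::as_data_frame(g, what = "edges")
  cross <- (el$from %in% set_a & el$to %in% set_b) |
           (el$from %in% set_b & el$to %in% set_a)
  sum(cross)
}

#' Hypergeometric set over-representation (Fisher-style enrichment)
#'
#' One-sided hypergeometric p per annotation set from the 2x2 table
#' (foreground-in-set, foreground-out, background-in-set-out,
#' rest), Benjamini-Hochberg adjusted across sets. Foreground must
#' be a subset of the background; annotation ids outside the
#' background are clipped with a message.
#'
#' @param fg Foreground feature ids.
#' @param bg Background feature ids.
#' @param sets Named list of annotation feature-id sets.
#' @param bh Apply BH correction across sets (default TRUE).
#' @return Data frame with `set`, `n_set`, `n_fg`, `overlap`,
#'   `expected`, `p`, `q`.
#' @export
fisher_enrichment <- function(fg, bg, sets, bh = TRUE) {
  fg <- unique(fg); bg <- unique(bg)
  if (!length(fg)) stop("empty foreground set")
  extra <- setdiff(fg, bg)
  if (length(extra)) {
    message(length(extra), " foreground id(s) outside background clipped")
    fg <- intersect(fg, bg)
    if (!length(fg)) stop("empty foreground after clipping")
  }
  N <- length(bg); n <- length(fg)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), bg)
    K <- length(s)
    k <- length(intersect(fg, s))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, n_set = K, n_fg = n, overlap = k,
               expected = n * K / N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- if (bh) p.adjust(out$p, method = "BH") else out$p
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation with explicit degeneracy rules
#'
#' Pairwise-complete Pearson correlation; errors (rather than
#' returning `NA`) when fewer than 3 complete pairs remain or either
#' side has zero variance.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop("need >= 3 pairwise-complete observations")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    stop("undefined correlation: zero variance")
  }
  cor(x[ok], y[ok])
}
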