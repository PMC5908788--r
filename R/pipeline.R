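# End-to-end pipeline: normalization -> rhythm testing -> time-phase
# analysis -> DR-TF nomination -> network analyses, with a
# machine-readable manifest. Outputs are a pure function of
# (inputs, config, seed): no timestamps, fixed number formatting.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  path
}

load_matrix_input <- function(x, layer) {
  if (inherits(x, "OmicsMatrix")) x else read_omics_table(x, layer)
}

load_graph_input <- function(x, directed) {
  if (inherits(x, "igraph")) x else read_edge_list(x, directed)
}

load_id_input <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    readLines(x)
  } else {
    as.character(x)
  }
}

input_hash <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    unname(tools::md5sum(x))
  } else {
    paste0("in-memory:", class(x)[1])
  }
}

cycles_for <- function(timepoints) {
  starts <- seq(0, max(timepoints), by = 24)
  cycle_spec(lapply(starts, function(s) c(s, s + 24)))
}

#' Run the full circadian multi-omics pipeline
#'
#' Normalizes every supplied layer (iBAQ to FOT for MS layers, FPKM
#' taken as-is for the transcriptome, then per-cycle z-scores), runs
#' the JTK-family rhythm test per layer, derives time-phase-specific
#' TFs, peak times and the day/night fold-change screen, nominates
#' dominant rhythmic TFs and labels activator/repressor edges when a
#' TF-to-target network is supplied, and runs the ubiquitylation and
#' graph analyses when their inputs are present. All tables are
#' written as TSV under `out_dir` together with a JSON manifest
#' recording the configuration, seed, input hashes and analysis
#' conventions.
#'
#' @param config A [run_config()].
#' @param inputs Named list. Mandatory: `tf_dba` and `transcriptome`
#'   (paths or [omics_matrix()] objects). Optional: further layer
#'   matrices (`whole_proteome`, `phospho`, `nuclear`,
#'   `ubiquitylome`, `kc_proteome`), `tf_tg` (directed signed edge
#'   list path or igraph), `ppi` (undirected), `kinase` (directed),
#'   `mediators` and `ubi` (id vectors or one-id-per-line files),
#'   `annotations` (named list of id sets).
#' @param out_dir Output directory (created if needed).
#' @param resample_iter Iterations of the ubiquitylation resampling
#'   test (default 1000).
#' @return Invisibly, a list with the in-memory result tables and
#'   the manifest.
#' @export
run_pipeline <- function(config, inputs, out_dir,
                         resample_iter = 1000L) {
  stopifnot(inherits(config, "run_config"))
  for (need in c("tf_dba", "transcriptome")) {
    if (is.null(inputs[[need]])) {
      stop("mandatory input '", need, "' is missing")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  results <- list()
  outputs <- character(0)

  layer_names <- intersect(names(inputs), omics_layers())
  fot <- list(); zs <- list(); rhythms <- list()
  for (ly in layer_names) {
    m <- load_matrix_input(inputs[[ly]], ly)
    ratio <- if (m$norm_state == "raw") ibaq_to_fot(m) else m
    fot[[ly]] <- ratio
    z <- zscore_per_cycle(ratio, cycles_for(m$timepoints))
    zs[[ly]] <- z
    rt <- jtk_cycle(z, config)
    rhythms[[ly]] <- rt
    f <- file.path(out_dir, paste0("rhythm_", ly, ".tsv"))
    write_tsv(rt, f)
    outputs <- c(outputs, f)
  }

  tp_tab <- tp_specific_features(fot$tf_dba, fold = config$tp_fold)
  f <- file.path(out_dir, "tp_specific_tfs.tsv")
  write_tsv(tp_tab, f); outputs <- c(outputs, f)
  results$tp_specific <- tp_tab

  peaks <- peak_time(fot$tf_dba, rhythms$tf_dba)
  f <- file.path(out_dir, "phase_assignments_tf_dba.tsv")
  write_tsv(peaks, f); outputs <- c(outputs, f)
  results$peaks <- peaks

  for (ly in intersect(layer_names, c("kc_proteome", "whole_proteome"))) {
    fc <- day_night_fold_change(fot[[ly]], config$day_night_fc)
    f <- file.path(out_dir, paste0("day_night_fc_", ly, ".tsv"))
    write_tsv(fc, f); outputs <- c(outputs, f)
    results[[paste0("day_night_fc_", ly)]] <- fc
  }

  resample <- NULL
  if (!is.null(inputs$tf_tg)) {
    net <- load_graph_input(inputs$tf_tg, directed = TRUE)
    drtf <- nominate_dr_tfs(rhythms$tf_dba, rhythms$transcriptome,
                            net, min_tg = config$min_tg,
                            enrich_alpha = config$enrich_alpha)
    f <- file.path(out_dir, "drtf_table.tsv")
    write_tsv(drtf, f); outputs <- c(outputs, f)
    results$drtf <- drtf

    targets <- regulator_targets(net)
    ztf <- zs$tf_dba$values
    ztg <- zs$transcriptome$values
    edge_rows <- list()
    for (tf in intersect(names(targets), rownames(ztf))) {
      tg <- intersect(targets[[tf]], rownames(ztg))
      if (!length(tg)) next
      lab <- classify_regulator_sign(ztf[tf, ],
                                     ztg[tg, , drop = FALSE],
                                     config$activator_r,
                                     config$repressor_r)
      lab$source <- tf
      edge_rows[[tf]] <- lab[, c("source", "target", "r", "label",
                                 "flagged")]
    }
    if (length(edge_rows)) {
      signed <- do.call(rbind, edge_rows)
      rownames(signed) <- NULL
      f <- file.path(out_dir, "signed_edges.tsv")
      write_tsv(signed, f); outputs <- c(outputs, f)
      results$signed_edges <- signed
    }

    if (!is.null(inputs$ubi)) {
      ubi <- load_id_input(inputs$ubi)
      xt <- ubiquitylation_crosstab(rhythms$tf_dba, net, ubi)
      rhy_tfs <- rhythms$tf_dba$feature_id[rhythms$tf_dba$rhythmic]
      rhy_tfs <- intersect(rhy_tfs, names(targets))
      if (length(rhy_tfs)) {
        resample <- random_tf_resample_test(net, ubi, rhy_tfs,
                                            n_iter = resample_iter)
        resample$null <- NULL
      }
      f <- file.path(out_dir, "ubiquitylation_crosstab.tsv")
      write_tsv(xt, f); outputs <- c(outputs, f)
      results$ubiquitylation <- xt
      results$resample <- resample
    }
  } else {
    warning("no tf_tg network supplied; DR-TF stage skipped")
  }

  if (!is.null(inputs$mediators)) {
    med <- intersect(load_id_input(inputs$mediators),
                     rownames(zs$tf_dba$values))
    tf_rhy <- rhythms$tf_dba$feature_id[rhythms$tf_dba$rhythmic]
    tf_rhy <- setdiff(tf_rhy, med)
    if (length(med) && length(tf_rhy)) {
      links <- top_k_correlated_mediators(
        zs$tf_dba$values[tf_rhy, , drop = FALSE],
        zs$tf_dba$values[med, , drop = FALSE],
        k = config$mediator_k)
      f <- file.path(out_dir, "mediator_links.tsv")
      write_tsv(links, f); outputs <- c(outputs, f)
      results$mediator_links <- links
    } else {
      warning("mediator linking skipped: no mediators or no ",
              "rhythmic TFs in the DBA layer")
    }
  }

  path_test <- NULL
  if (!is.null(inputs$ppi) && !is.null(inputs$kinase)) {
    ppi <- load_graph_input(inputs$ppi, directed = FALSE)
    kin <- load_graph_input(inputs$kinase, directed = TRUE)
    substrates <- unique(igraph::as_data_frame(kin)$to)
    if ("phospho" %in% layer_names) {
      substrates <- intersect(substrates,
                              rownames(zs$phospho$values))
    }
    tf_all <- intersect(rhythms$tf_dba$feature_id,
                        igraph::V(ppi)$name)
    tf_path <- intersect(
      rhythms$tf_dba$feature_id[rhythms$tf_dba$rhythmic], tf_all)
    substrates <- intersect(substrates, igraph::V(ppi)$name)
    if (length(substrates) && length(tf_path) >= 1 &&
        length(tf_all) >= 1) {
      ps <- summarize_paths(ppi, substrates, tf_path, tf_all)
      f <- file.path(out_dir, "path_summary.tsv")
      write_tsv(ps, f); outputs <- c(outputs, f)
      results$path_summary <- ps
      path_test <- tryCatch(compare_path_lengths(ps),
                            error = function(e) NULL)
    } else {
      warning("shortest-path stage skipped: no usable substrates ",
              "or TFs on the interaction graph")
    }
  }

  if (!is.null(inputs$annotations)) {
    rhy <- rhythms$tf_dba$feature_id[rhythms$tf_dba$rhythmic]
    if (length(rhy)) {
      enr <- fisher_enrichment(rhy, rhythms$tf_dba$feature_id,
                               inputs$annotations)
      f <- file.path(out_dir, "enrichment_rhythmic_tfs.tsv")
      write_tsv(enr, f); outputs <- c(outputs, f)
      results$enrichment <- enr
    }
  }

  manifest <- list(
    package = "circomics",
    version = as.character(utils::packageVersion("circomics")),
    config = unclass(config),
    seed = config$seed,
    inputs = lapply(inputs[setdiff(names(inputs), "annotations")],
                    input_hash),
    outputs = basename(outputs),
    n_templates = lapply(rhythms, attr, "n_templates"),
    resample = resample,
    path_test = path_test,
    conventions = list(
      sd = "sample (n-1)",
      tp_rule = "strict fold vs each other phase, FOT scale",
      tp_boundaries = "TP1=[0,6) TP2=[6,12) TP3=[12,18) TP4=[18,24)",
      day = "ZT mod 24 in [0,12)",
      adjustment = "Bonferroni over deduplicated templates",
      fot = "plain fraction, no ppm scaling"))
  mf <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, null = "null"),
             mf)
  results$rhythms <- rhythms
  results$manifest <- manifest
  invisible(results)
}
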