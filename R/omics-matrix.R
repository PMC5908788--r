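#' @importFrom stats cor sd rnorm runif rbinom phyper t.test p.adjust pt
#'   complete.cases setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Recognised omics layers and normalization states
#'
#' `omics_layers()` returns the layer tags understood by the package:
#' TF DNA-binding activity (`tf_dba`), nuclear proteome, whole-liver
#' proteome, phosphoproteome, ubiquitylome, transcriptome (FPKM) and
#' the Kupffer-cell proteome. `norm_states()` returns the recognised
#' normalization states.
#'
#' @return Character vector of tags.
#' @export
omics_layers <- function() {
  c("tf_dba", "nuclear", "whole_proteome", "phospho",
    "ubiquitylome", "transcriptome", "kc_proteome")
}

#' @rdname omics_layers
#' @export
norm_states <- function() {
  c("raw", "fot", "zscored", "fpkm", "fpkm_zscored")
}

#' Feature-by-timepoint abundance matrix
#'
#' The central container of the package: one omics layer measured at a
#' series of Zeitgeber times (ZT, hours since lights-on). The default
#' design is 16 samples at 3-h spacing over two consecutive daily
#' cycles (ZT0..ZT45); single-cycle or 4-point designs (ubiquitylome,
#' Kupffer-cell proteome) are accepted.
#'
#' @param values Numeric matrix, rows = features (gene symbols, row
#'   names mandatory and unique), columns = timepoints. `NA` marks a
#'   missing measurement. Raw and FPKM values must be nonnegative.
#' @param layer One of [omics_layers()].
#' @param timepoints Numeric vector of strictly increasing ZT hours,
#'   one per column. If `NULL`, parsed from column names `"ZT<h>"`.
#' @param norm_state One of [norm_states()]. The transcriptome enters
#'   as `"fpkm"`, MS layers as `"raw"` (iBAQ).
#'
#' @return An object of class `OmicsMatrix`: a list with elements
#'   `values`, `layer`, `timepoints`, `norm_state` and a logical
#'   `degenerate` flag per feature (fewer than 2 non-missing values).
#' @export
omics_matrix <- function(values, layer, timepoints = NULL,
                         norm_state = "raw") {
  layer <- match.arg(layer, omics_layers())
  norm_state <- match.arg(norm_state, norm_states())
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    stop("'values' must carry feature ids as row names")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(timepoints)) {
    timepoints <- parse_zt(colnames(values))
  }
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) != ncol(values)) {
    stop("length(timepoints) must equal ncol(values)")
  }
  if (ncol(values) >= 2 && any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing")
  }
  if (norm_state %in% c("raw", "fpkm") &&
      any(values < 0, na.rm = TRUE)) {
    stop("raw/fpkm values must be nonnegative")
  }
  colnames(values) <- paste0("ZT", fmt_num(timepoints))
  degenerate <- rowSums(!is.na(values)) < 2
  structure(
    list(values = values, layer = layer, timepoints = timepoints,
         norm_state = norm_state, degenerate = degenerate),
    class = "OmicsMatrix"
  )
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf(
    "OmicsMatrix [%s, %s]: %d features x %d timepoints (ZT%s..ZT%s)\n",
    x$layer, x$norm_state, nrow(x$values), length(x$timepoints),
    fmt_num(min(x$timepoints)), fmt_num(max(x$timepoints))))
  if (any(x$degenerate)) {
    cat(sprintf("  %d degenerate feature(s) (<2 non-missing values)\n",
                sum(x$degenerate)))
  }
  invisible(x)
}

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

#' Feature identifiers of an OmicsMatrix
#' @param m An [omics_matrix()].
#' @return Character vector of feature ids (row order).
#' @export
feature_ids <- function(m) rownames(m$values)

parse_zt <- function(labels) {
  if (is.null(labels)) stop("column names with ZT labels required")
  ok <- grepl("^ZT[0-9]+(\\.[0-9]+)?$", labels)
  if (!all(ok)) {
    stop("malformed ZT header label(s): ",
         paste(labels[!ok], collapse = ", "))
  }
  as.numeric(sub("^ZT", "", labels))
}

fmt_num <- function(x) {
  # locale-independent "." decimal, integer-looking where possible
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
         format(x, scientific = FALSE, trim = TRUE, digits = 15))
}

#' Read an omics abundance table from TSV
#'
#' The TSV dialect is tab-separated, UTF-8, `"."` decimal, missing
#' values as empty strings, mandatory header row of ZT labels
#' (`"ZT0"`, `"ZT3"`, ...), first column the feature id.
#'
#' @param path Path to a TSV file.
#' @param layer One of [omics_layers()]; the transcriptome is read as
#'   `norm_state = "fpkm"`, everything else as `"raw"`.
#' @return An [omics_matrix()].
#' @export
read_omics_table <- function(path, layer) {
  layer <- match.arg(layer, omics_layers())
  raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("expected feature-id column plus ZT columns")
  tps <- parse_zt(colnames(raw)[-1])
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate feature id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(tps),
                 dimnames = list(ids, colnames(raw)[-1]))
  for (j in seq_along(tps)) {
    cell <- raw[[j + 1L]]
    empty <- !nzchar(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row '%s', column '%s': \"%s\"",
                   ids[bad[1L]], colnames(raw)[j + 1L], cell[bad[1L]]))
    }
    num[empty] <- NA_real_
    vals[, j] <- num
  }
  omics_matrix(vals, layer = layer, timepoints = tps,
               norm_state = if (layer == "transcriptome") "fpkm" else "raw")
}

#' Write an omics abundance table to TSV
#'
#' Inverse of [read_omics_table()]: values are serialised with 17
#' significant digits so that read-write-read round trips reproduce
#' the matrix exactly; missing values become empty cells.
#'
#' @param m An [omics_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(m, path) {
  stopifnot(inherits(m, "OmicsMatrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("feature", colnames(m$values)), collapse = "\t"),
             con, sep = "\n")
  body <- apply(m$values, 2L, function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col)] <- ""
    out
  })
  body <- matrix(body, nrow = nrow(m$values))
  lines <- paste(rownames(m$values),
                 apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a network edge list from TSV
#'
#' Reads a two- or three-column TSV (`source`, `target`, optional
#' `sign`) into an igraph graph. Directed lists are the TF-to-target
#' (CellNet-style) and kinase-to-substrate (PhosphoSitePlus-style)
#' inputs; undirected lists are STRING-style protein-protein
#' interactions. Self-loops are dropped (count reported via
#' `message()`), duplicate edges are deduplicated (first occurrence
#' kept; for undirected graphs the pair is unordered).
#'
#' @param path Path to a TSV with a header row.
#' @param directed Logical.
#' @return An `igraph` object; a `sign` edge attribute (+1/-1) is
#'   attached when the file carries one.
#' @export
read_edge_list <- function(path, directed) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE,
                   fileEncoding = "UTF-8")
  if (!ncol(df) %in% c(2L, 3L)) {
    stop("edge list must have 2 or 3 columns, got ", ncol(df))
  }
  src <- df[[1L]]; tgt <- df[[2L]]
  sign_col <- NULL
  if (ncol(df) == 3L) {
    sgn <- suppressWarnings(as.numeric(df[[3L]]))
    if (any(is.na(sgn)) || !all(sgn %in% c(-1, 1))) {
      bad <- df[[3L]][is.na(sgn) | !sgn %in% c(-1, 1)][1L]
      stop("sign column must be +1 or -1, got \"", bad, "\"")
    }
    sign_col <- sgn
  }
  loops <- src == tgt
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped from ", path)
    src <- src[!loops]; tgt <- tgt[!loops]
    if (!is.null(sign_col)) sign_col <- sign_col[!loops]
  }
  key <- if (directed) paste(src, tgt, sep = "\r") else
    paste(pmin(src, tgt), pmax(src, tgt), sep = "\r")
  keep <- !duplicated(key)
  edges <- data.frame(from = src[keep], to = tgt[keep],
                      stringsAsFactors = FALSE)
  if (!is.null(sign_col)) edges$sign <- sign_col[keep]
  igraph::graph_from_data_frame(edges, directed = directed)
}

#' Write a network edge list to TSV
#'
#' @param g An `igraph` object (optionally with a `sign` edge
#'   attribute).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("source", "target")
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Targets of each regulator in a directed network
#'
#' @param net Directed `igraph` (TF-to-target-gene edges).
#' @param tfs Optional character vector restricting the regulators;
#'   default: every node with out-degree > 0.
#' @return Named list mapping regulator id to character vector of
#'   target ids.
#' @export
regulator_targets <- function(net, tfs = NULL) {
  stopifnot(igraph::is_directed(net))
  el <- igraph::as_data_frame(net, what = "edges")
  if (is.null(tfs)) tfs <- unique(el$from)
  out <- split(el$to, factor(el$from, levels = tfs))
  lapply(out, unique)
}
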