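#' Read a genes x samples expression matrix from TSV
#'
#' The first column holds gene symbols, the header row sample ids. Duplicate
#' gene rows are collapsed by the configured probe-collapse rule: with
#' `collapse = "max_mean"` the row with the largest mean value is kept (the
#' usual convention when several microarray probes map to one symbol).
#' Counts-mode matrices must contain only finite non-negative integers.
#'
#' @param path TSV path (tab-delimited, UTF-8, header row).
#' @param mode `"intensity"` (real values, e.g. log-intensities) or
#'   `"counts"` (non-negative integers).
#' @param collapse rule for duplicate gene rows: `"max_mean"` or `"none"`
#'   (duplicates raise an error).
#' @return numeric matrix with gene row names, sample column names and a
#'   `"mode"` attribute.
#' @export
read_expression_matrix <- function(path, mode = c("intensity", "counts"),
                                   collapse = c("max_mean", "none")) {
  mode <- match.arg(mode)
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("cannot read expression matrix: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, fill = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  if (ncol(df) < 2L) stop("parse error: expected gene column plus samples")
  genes <- normalize_gene_labels(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("validation error: non-numeric values")
  rownames(values) <- genes
  if (anyDuplicated(colnames(values))) stop("duplicate sample labels")
  values <- collapse_duplicate_genes(values, collapse)
  validate_expression_values(values, mode)
  attr(values, "mode") <- mode
  values
}

normalize_gene_labels <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(!nzchar(x))) stop("empty gene labels")
  x
}

collapse_duplicate_genes <- function(values, collapse) {
  if (!anyDuplicated(rownames(values))) return(values)
  if (collapse == "none") stop("duplicate gene labels")
  means <- rowMeans(values)
  # keep, per symbol, the row with the largest mean
  ord <- order(rownames(values), -means)
  values <- values[ord, , drop = FALSE]
  values <- values[!duplicated(rownames(values)), , drop = FALSE]
  values[order(rownames(values)), , drop = FALSE]
}

validate_expression_values <- function(values, mode) {
  if (any(!is.finite(values))) stop("validation error: non-finite values")
  if (mode == "counts") {
    if (any(values < 0)) stop("validation error: negative counts")
    if (any(values != round(values))) {
      stop("validation error: counts mode requires integer values")
    }
  }
  invisible(values)
}

#' Write an expression matrix as TSV
#'
#' @param x numeric matrix with gene row names.
#' @param path output path.
#' @param gene_col name of the first (gene) column.
#' @return invisibly, the path.
#' @export
write_expression_matrix <- function(x, path, gene_col = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample annotation for the paired-biopsy design
#'
#' Validates a sample annotation table: unique sample ids, tissue in
#' {ILEAL, SIGMOID}, condition in {CD, UC, CI}, and the paired design
#' invariant that every patient contributing two samples contributes exactly
#' one ileal and one sigmoid biopsy.
#'
#' @param df data.frame with columns `sample_id`, `patient_id`, `tissue`,
#'   `condition` and optionally `sex`, `age`.
#' @return the validated data.frame with class `sample_annotation`.
#' @export
sample_annotation <- function(df) {
  required <- c("sample_id", "patient_id", "tissue", "condition")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("annotation missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  if (!all(df$tissue %in% c("ILEAL", "SIGMOID"))) {
    stop("tissue must be ILEAL or SIGMOID")
  }
  if (!all(df$condition %in% c("CD", "UC", "CI"))) {
    stop("condition must be CD, UC or CI")
  }
  tab <- table(df$patient_id)
  if (any(tab > 2L)) stop("patient with more than two samples")
  for (p in names(tab)[tab == 2L]) {
    tis <- df$tissue[df$patient_id == p]
    if (!setequal(tis, c("ILEAL", "SIGMOID"))) {
      stop("paired design violated for patient ", p,
           ": need one ILEAL and one SIGMOID sample")
    }
  }
  if (!"sex" %in% colnames(df)) df$sex <- "unknown"
  if (!"age" %in% colnames(df)) df$age <- NA_integer_
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' Read a sample annotation TSV
#'
#' @param path TSV with header columns `sample_id`, `patient_id`, `tissue`,
#'   `condition` and optionally `sex`, `age`.
#' @return sample_annotation data.frame.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if ("age" %in% colnames(df)) df$age <- suppressWarnings(as.integer(df$age))
  sample_annotation(df)
}

#' Protein-protein interaction networks
#'
#' An `interaction_network` is an undirected edge list with per-edge
#' confidence scores in [0, 1000] (the STRING combined-score scale). Each
#' unordered pair appears at most once and self-loops are forbidden. The
#' node universe (including isolated, degree-zero nodes) is carried in the
#' `"nodes"` attribute so that induced subnetworks keep disconnected module
#' members.
#'
#' @param edges data.frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param nodes optional character vector of node names; defaults to all
#'   edge endpoints.
#' @return interaction_network (a classed data.frame).
#' @export
interaction_network <- function(edges, nodes = NULL) {
  required <- c("protein1", "protein2", "combined_score")
  if (!all(required %in% colnames(edges))) {
    stop("format error: need columns ", paste(required, collapse = ", "))
  }
  edges <- edges[, required, drop = FALSE]
  edges$protein1 <- toupper(trimws(edges$protein1))
  edges$protein2 <- toupper(trimws(edges$protein2))
  edges$combined_score <- as.numeric(edges$combined_score)
  if (any(edges$combined_score < 0 | edges$combined_score > 1000)) {
    stop("combined_score must lie in [0, 1000]")
  }
  edges <- edges[edges$protein1 != edges$protein2, , drop = FALSE]
  # canonical orientation, then merge duplicate/reverse pairs keeping max score
  a <- pmin(edges$protein1, edges$protein2)
  b <- pmax(edges$protein1, edges$protein2)
  key <- paste(a, b, sep = "\r")
  score <- tapply(edges$combined_score, key, max)
  uniq <- !duplicated(key)
  edges <- data.frame(protein1 = a[uniq], protein2 = b[uniq],
                      combined_score = as.numeric(score[key[uniq]]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$protein1, edges$protein2), , drop = FALSE]
  rownames(edges) <- NULL
  endpoint_nodes <- sort(unique(c(edges$protein1, edges$protein2)))
  if (is.null(nodes)) {
    nodes <- endpoint_nodes
  } else {
    nodes <- normalize_symbols(nodes)
    if (!all(endpoint_nodes %in% nodes)) {
      stop("edge endpoints outside the declared node universe")
    }
  }
  structure(edges, nodes = nodes,
            class = c("interaction_network", "data.frame"))
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(attr(x, "nodes")), nrow(x)))
  invisible(x)
}

#' Read a STRING-dialect interaction TSV
#'
#' Expects columns `protein1`, `protein2`, `combined_score`. Edges below
#' `min_score` are dropped, duplicate and reverse pairs merged keeping the
#' maximum score, and self-loops removed. The default cutoff of 400 is the
#' STRING "medium confidence" level.
#'
#' @param path TSV path.
#' @param min_score minimum combined score to retain an edge.
#' @return interaction_network.
#' @export
read_interaction_tsv <- function(path, min_score = 400) {
  if (!file.exists(path)) stop("cannot read interaction file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  net <- interaction_network(df)
  keep <- net$combined_score >= min_score
  interaction_network(as.data.frame(net)[keep, , drop = FALSE])
}
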