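#' Module-induced interaction subnetwork
#'
#' Keeps edges whose both endpoints belong to the given gene set; module
#' members absent from any retained edge stay in the network as
#' degree-zero nodes.
#'
#' @param network [interaction_network()].
#' @param genes gene_set or character.
#' @return interaction_network whose node universe is `genes` (normalized).
#' @export
induced_subnetwork <- function(network, genes) {
  genes <- as_symbols(genes)
  keep <- network$protein1 %in% genes & network$protein2 %in% genes
  interaction_network(as.data.frame(network)[keep, , drop = FALSE],
                      nodes = genes)
}

#' Degree centrality of an interaction network
#'
#' Node degrees on the deduplicated, score-thresholded edge set, with
#' dense ranks by degree descending and ties broken by symbol for display
#' order. Hub selection is a separate step ([select_hubs()]).
#'
#' @param network interaction_network.
#' @return data.frame of class `hub_report` with columns `gene`, `degree`,
#'   `rank` (dense), `is_hub` (all `FALSE` until selection).
#' @export
degree_centrality <- function(network) {
  nodes <- attr(network, "nodes")
  g <- igraph::graph_from_data_frame(
    as.data.frame(network)[, c("protein1", "protein2")],
    directed = FALSE, vertices = nodes)
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))
  deg <- deg[ord]
  report <- data.frame(gene = names(deg), degree = as.integer(deg),
                       rank = match(-deg, sort(unique(-deg))),
                       is_hub = FALSE, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  attr(report, "cutoff_rule") <- NULL
  class(report) <- c("hub_report", "data.frame")
  report
}

#' Select hub genes
#'
#' Marks hubs on a degree report by one of three deterministic rules:
#' \describe{
#'   \item{`mean_plus_sd`}{hub iff degree exceeds mean + 1 sd of the
#'     network's node degrees (the default: "high degree nodes" without a
#'     fixed count).}
#'   \item{`top_k`}{the `k` highest-degree genes; ties at the boundary are
#'     all included, so more than `k` hubs may be reported (recorded in
#'     the cutoff rule).}
#'   \item{`degree_ge`}{hub iff degree >= `t`.}
#' }
#'
#' @param report `hub_report` from [degree_centrality()].
#' @param rule selection rule.
#' @param k number of hubs for `top_k` (> 0).
#' @param t degree threshold for `degree_ge` (>= 0).
#' @return the report with `is_hub` filled in and a `cutoff_rule`
#'   attribute recording the rule, its parameters and any boundary tie.
#' @export
select_hubs <- function(report, rule = c("mean_plus_sd", "top_k", "degree_ge"),
                        k = 21L, t = NULL) {
  rule <- match.arg(rule)
  deg <- report$degree
  if (rule == "top_k") {
    if (k <= 0) stop("k must be positive")
    k <- min(as.integer(k), nrow(report))
    threshold <- sort(deg, decreasing = TRUE)[k]
    is_hub <- deg >= threshold
    cutoff <- list(rule = "top_k", k = k, degree_threshold = threshold,
                   n_hubs = sum(is_hub),
                   boundary_tie = sum(is_hub) > k)
  } else if (rule == "degree_ge") {
    if (is.null(t) || t < 0) stop("t must be a non-negative degree threshold")
    is_hub <- deg >= t
    cutoff <- list(rule = "degree_ge", t = t, n_hubs = sum(is_hub))
  } else {
    threshold <- mean(deg) + stats::sd(deg)
    is_hub <- deg > threshold
    cutoff <- list(rule = "mean_plus_sd", degree_threshold = threshold,
                   n_hubs = sum(is_hub))
  }
  report$is_hub <- is_hub
  attr(report, "cutoff_rule") <- cutoff
  class(report) <- c("hub_report", "data.frame")
  report
}

#' @export
print.hub_report <- function(x, ...) {
  cutoff <- attr(x, "cutoff_rule")
  cat(sprintf("hub_report: %d nodes, %d edges' worth of degree\n",
              nrow(x), sum(x$degree) %/% 2L))
  if (!is.null(cutoff)) {
    cat(sprintf("  rule %s -> %d hub(s)\n", cutoff$rule, cutoff$n_hubs))
    print(utils::head(x[x$is_hub, c("gene", "degree", "rank")], 25L))
  }
  invisible(x)
}

#' Extract the hub genes of a report
#'
#' @param report selected `hub_report`.
#' @param name label for the gene set.
#' @return gene_set of hubs, in degree order.
#' @export
hub_genes <- function(report, name = "hubs") {
  gene_set(report$gene[report$is_hub], name = name)
}
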