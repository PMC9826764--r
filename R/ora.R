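#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, preserving input order
#' (delegates to [stats::p.adjust()]).
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values in the same order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests a query gene list against every term of a GMT collection on a
#' common background: for a term with `K` background genes, a query of
#' size `n` and an overlap of `x`, the p-value is the hypergeometric upper
#' tail `P(X >= x)` with `X ~ Hypergeom(N, K, n)`. P-values are
#' BH-adjusted across the tested terms.
#'
#' The background defaults to all genes appearing in the collection plus
#' the query. Query genes outside the background are dropped with a
#' warning; term membership is intersected with the background. Term-size
#' bounds (after intersection) are applied before testing and recorded in
#' the result's metadata.
#'
#' @param query gene_set or character.
#' @param collection [gene_set_collection()].
#' @param background optional gene_set or character; see above for the
#'   default.
#' @param min_term_size,max_term_size term-size bounds applied before
#'   testing.
#' @param drop_empty drop terms with zero overlap instead of reporting
#'   them with p = 1.
#' @return data.frame of class `ora_result`, sorted by `q` then `p`, with
#'   columns `term`, `overlap_count`, `term_size`, `query_size`,
#'   `background_n`, `gene_ratio`, `p`, `q`, `overlap_genes`
#'   (comma-joined).
#' @export
hypergeometric_ora <- function(query, collection, background = NULL,
                               min_term_size = 10L, max_term_size = 500L,
                               drop_empty = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- as_symbols(query)
  if (is.null(background)) {
    background <- unique(c(unlist(lapply(collection$sets, as_symbols),
                                  use.names = FALSE), query))
  } else {
    background <- as_symbols(background)
  }
  if (length(background) == 0L) stop("empty background")
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped")
    query <- intersect(query, background)
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(term) {
    members <- intersect(as_symbols(collection$sets[[term]]), background)
    K <- length(members)
    if (K < min_term_size || K > max_term_size) return(NULL)
    overlap <- intersect(query, members)
    x <- length(overlap)
    if (x == 0L && drop_empty) return(NULL)
    p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap_count = x, term_size = K,
               query_size = n, background_n = N,
               gene_ratio = if (n > 0) x / n else 0,
               p = p, overlap_genes = paste(overlap, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    out <- data.frame(term = character(), overlap_count = integer(),
                      term_size = integer(), query_size = integer(),
                      background_n = integer(), gene_ratio = numeric(),
                      p = numeric(), q = numeric(),
                      overlap_genes = character(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out$q <- bh_adjust(out$p)
    out <- out[order(out$q, out$p, out$term),
               c("term", "overlap_count", "term_size", "query_size",
                 "background_n", "gene_ratio", "p", "q", "overlap_genes")]
    rownames(out) <- NULL
  }
  attr(out, "term_size_bounds") <- c(min = min_term_size, max = max_term_size)
  class(out) <- c("ora_result", "data.frame")
  out
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("ora_result: %d term(s) tested, %d at q < 0.05\n",
              nrow(x), sum(x$q < 0.05)))
  print(utils::head(as.data.frame(x)[, c("term", "overlap_count",
                                         "gene_ratio", "p", "q")], 10L))
  invisible(x)
}
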