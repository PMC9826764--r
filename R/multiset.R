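#' k-of-n combination scheme
#'
#' The signature construction keeps a gene when it is significant in at
#' least `min_k` of `n_lists` cohorts. The study design uses (9, >=7) for
#' the Crohn's-disease pool and (5, >=4) for the other-fibrosis pool.
#'
#' @param n_lists number of cohort gene lists.
#' @param min_k minimum number of lists a gene must appear in.
#' @return list of class `combination_scheme`.
#' @export
combination_scheme <- function(n_lists, min_k) {
  n_lists <- as.integer(n_lists); min_k <- as.integer(min_k)
  if (n_lists < 1L) stop("n_lists must be >= 1")
  if (min_k < 1L || min_k > n_lists) stop("min_k must lie in [1, n_lists]")
  structure(list(n_lists = n_lists, min_k = min_k),
            class = "combination_scheme")
}

#' Enumerate the cohort subsets of a combination scheme
#'
#' All subsets of size at least `min_k`, each listed once, in deterministic
#' order (by size ascending, lexicographic within size). The (9, >=7)
#' scheme yields 46 subsets, the (5, >=4) scheme 6.
#'
#' @param scheme [combination_scheme()].
#' @return list of integer vectors (cohort indices).
#' @export
enumerate_combinations <- function(scheme) {
  stopifnot(inherits(scheme, "combination_scheme"))
  out <- list()
  for (k in scheme$min_k:scheme$n_lists) {
    combos <- utils::combn(scheme$n_lists, k, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

#' Build a genes x cohorts membership matrix
#'
#' @param gene_sets named list of `gene_set`s (or character vectors), one
#'   per cohort.
#' @param universe optional gene universe; defaults to the union of all
#'   sets.
#' @return logical matrix, genes as rows, cohorts as columns.
#' @export
membership_matrix <- function(gene_sets, universe = NULL) {
  if (is.null(names(gene_sets)) || anyDuplicated(names(gene_sets))) {
    stop("gene_sets must have unique names")
  }
  symbols <- lapply(gene_sets, as_symbols)
  if (is.null(universe)) universe <- unique(unlist(symbols, use.names = FALSE))
  else universe <- as_symbols(universe)
  m <- vapply(symbols, function(s) universe %in% s,
              logical(length(universe)))
  m <- matrix(m, nrow = length(universe),
              dimnames = list(universe, names(gene_sets)))
  m
}

#' Apply the k-of-n membership filter
#'
#' Retains genes present in at least `min_k` of the cohorts. This row-sum
#' filter equals the union, over all subsets of size >= `min_k`, of the
#' full within-subset intersections - the combination semantics of the
#' signature construction.
#'
#' @param membership logical genes x cohorts matrix
#'   (see [membership_matrix()]).
#' @param scheme [combination_scheme()]; `n_lists` must match the number of
#'   columns.
#' @param name label for the resulting gene set.
#' @return gene_set of retained genes.
#' @export
k_of_n_filter <- function(membership, scheme, name = "pool") {
  stopifnot(inherits(scheme, "combination_scheme"))
  if (ncol(membership) != scheme$n_lists) {
    stop("membership has ", ncol(membership), " cohorts but scheme expects ",
         scheme$n_lists)
  }
  keep <- rowSums(membership) >= scheme$min_k
  gene_set(rownames(membership)[keep], name = name)
}

#' Exact m-set intersection statistics
#'
#' Distribution of the intersection size of `m` random subsets of sizes
#' `n_1..n_m` drawn uniformly without replacement from a background of `N`
#' genes, computed by sequential hypergeometric conditioning: the running
#' intersection after one set is a point mass at `n_1`, and conditional on
#' a running intersection of `i` genes the next set hits `i'` of them with
#' hypergeometric probability `HG(i' | N, i, n_j)`. Hypergeometric masses
#' are evaluated in log space and exponentiated, so the recursion stays
#' stable for backgrounds of tens of thousands of genes.
#'
#' Reported alongside: `expected = N * prod(n_j / N)`, fold enrichment
#' `observed / expected`, and the upper-tail p-value `P(X >= observed)`.
#'
#' @param set_sizes integer vector `n_1..n_m`, each at most `background_n`.
#' @param observed observed intersection size, at most `min(set_sizes)`.
#' @param background_n background universe size `N`.
#' @return list of class `intersection_stat` with fields `set_sizes`,
#'   `background_n`, `observed`, `expected`, `fold_enrichment`, `p_value`
#'   and the full `distribution` (probabilities over 0..min(set_sizes)).
#' @export
exact_intersection_test <- function(set_sizes, observed, background_n) {
  n <- as.integer(set_sizes); N <- as.integer(background_n)
  observed <- as.integer(observed)
  if (length(n) < 1L || any(n < 0L)) stop("invalid set sizes")
  if (any(n > N)) stop("set sizes cannot exceed the background")
  if (observed < 0L || observed > min(n)) {
    stop("observed overlap must lie in [0, min(set_sizes)]")
  }
  d <- intersection_distribution(n, N)
  expected <- N * prod(n / N)
  p_value <- sum(d[(observed + 1L):length(d)])
  p_value <- min(max(p_value, 0), 1)
  structure(list(set_sizes = n, background_n = N, observed = observed,
                 expected = expected,
                 fold_enrichment = observed / expected,
                 p_value = p_value, distribution = d),
            class = "intersection_stat")
}

# exact pmf of the m-set intersection size over support 0..min(n)
intersection_distribution <- function(n, N) {
  d <- c(rep(0, n[1L]), 1)  # point mass at n_1 on support 0..n_1
  if (length(n) > 1L) {
    for (j in 2L:length(n)) {
      newmax <- min(min(n[1L:j]), length(d) - 1L)
      nd <- numeric(newmax + 1L)
      support <- which(d > 0) - 1L
      for (i in support) {
        hg <- exp(stats::dhyper(0:newmax, i, N - i, n[j], log = TRUE))
        nd <- nd + d[i + 1L] * hg
      }
      d <- nd
    }
  }
  names(d) <- 0:(length(d) - 1L)
  d
}

#' @export
print.intersection_stat <- function(x, ...) {
  cat(sprintf(
    "intersection of %d sets (sizes %s) on N = %d\n  observed %d, expected %.2f, fold %.2f, p = %.3g\n",
    length(x$set_sizes), paste(x$set_sizes, collapse = ", "),
    x$background_n, x$observed, x$expected, x$fold_enrichment, x$p_value))
  invisible(x)
}

#' Monte-Carlo oracle for the intersection-size distribution
#'
#' Draws uniform random fixed-size subsets and tallies intersection sizes;
#' a validation companion for [exact_intersection_test()].
#'
#' @inheritParams exact_intersection_test
#' @param draws number of Monte-Carlo draws (>= 1000).
#' @param seed RNG seed.
#' @return numeric vector of empirical probabilities over 0..min(set_sizes).
#' @export
mc_intersection_oracle <- function(set_sizes, background_n, draws = 1e5,
                                   seed = 1) {
  n <- as.integer(set_sizes); N <- as.integer(background_n)
  if (draws < 1e3) stop("draws must be >= 1000")
  counts <- with_seed(seed, {
    tallies <- integer(min(n) + 1L)
    for (r in seq_len(draws)) {
      inter <- sample.int(N, n[1L])
      for (j in seq_along(n)[-1L]) {
        inter <- intersect(inter, sample.int(N, n[j]))
        if (length(inter) == 0L) break
      }
      tallies[length(inter) + 1L] <- tallies[length(inter) + 1L] + 1L
    }
    tallies
  })
  stats::setNames(counts / draws, 0:min(n))
}

#' Intersect the two gene pools into a signature
#'
#' The cross-disease signature is the intersection of the disease pool
#' (`gs1`) and the other-fibrosis pool (`gs2`), with exact intersection
#' statistics on the supplied background.
#'
#' @param gs1,gs2 gene_set or character (the two pools).
#' @param background_n background universe size; must be at least the size
#'   of the union of the two pools.
#' @param name label for the signature gene set.
#' @return list of class `signature_result` with `geneset1`, `geneset2`,
#'   `fibsig` and `stats` (an `intersection_stat`).
#' @export
build_signature <- function(gs1, gs2, background_n, name = "FIBSig") {
  a <- as_symbols(gs1); b <- as_symbols(gs2)
  union_n <- length(unique(c(a, b)))
  if (background_n < union_n) {
    stop("background_n (", background_n, ") smaller than the pool union (",
         union_n, ")")
  }
  fib <- gs_intersect(a, b, name = name)
  stats <- exact_intersection_test(c(length(a), length(b)),
                                   observed = length(fib),
                                   background_n = background_n)
  structure(list(geneset1 = gene_set(a, "geneset1"),
                 geneset2 = gene_set(b, "geneset2"),
                 fibsig = fib, stats = stats),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("signature_result: |pool1| = %d, |pool2| = %d, |%s| = %d\n",
              length(x$geneset1), length(x$geneset2), x$fibsig$name,
              length(x$fibsig)))
  print(x$stats)
  invisible(x)
}
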