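#' Class-derived gene ranking
#'
#' Scores every gene by how elevated it is in one tissue-by-condition
#' stratum relative to all samples:
#' `score = (mean within class - mean overall) / (sd overall)`, with
#' zero-variance genes scored 0. Genes are returned ranked descending,
#' ties broken deterministically by symbol.
#'
#' @param norm genes x samples matrix.
#' @param annotation [sample_annotation()] covering the matrix columns.
#' @param tissue `"ILEAL"` or `"SIGMOID"`.
#' @param condition `"CD"`, `"UC"` or `"CI"`.
#' @return named numeric vector of scores, sorted descending.
#' @export
class_ranked_list <- function(norm, annotation, tissue, condition) {
  ids <- annotation$sample_id[annotation$tissue == tissue &
                              annotation$condition == condition]
  ids <- intersect(ids, colnames(norm))
  if (length(ids) == 0L) {
    stop("class ", condition, "-", tissue, " absent from the annotation")
  }
  if (length(ids) < 2L) stop("class needs at least 2 samples")
  overall_mean <- rowMeans(norm)
  overall_sd <- apply(norm, 1L, stats::sd)
  score <- (rowMeans(norm[, ids, drop = FALSE]) - overall_mean) /
    ifelse(overall_sd > 0, overall_sd, 1)
  score[overall_sd == 0] <- 0
  score[order(-score, names(score))]
}

# weighted Kolmogorov-Smirnov enrichment score (weight exponent 1 on the
# absolute ranking score); `hits` is a logical vector along the ranking
gsea_es <- function(scores, hits) {
  n <- length(scores)
  nh <- sum(hits)
  w <- abs(scores) * hits
  total_w <- sum(w)
  p_hit <- if (total_w > 0) cumsum(w) / total_w else cumsum(hits) / nh
  p_miss <- if (n > nh) cumsum(!hits) / (n - nh) else rep(0, n)
  dev <- p_hit - p_miss
  unname(dev[which.max(abs(dev))])
}

#' GSEA of a module against a class ranking
#'
#' Preranked gene set enrichment of a co-expression module against a
#' class-derived ranking: the running-sum enrichment score uses weight
#' exponent 1 on the absolute score; significance and normalization come
#' from gene-label permutations. `NES = ES / mean(|ES_perm|)` over
#' permutations whose ES sign matches, and the p-value is the matching-sign
#' permutation tail fraction with +1 smoothing. A positive NES means the
#' module is over-expressed in the class.
#'
#' @param ranking named scores from [class_ranked_list()] (sorted
#'   descending).
#' @param module_genes gene_set or character.
#' @param n_perm number of gene-label permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return list with `es`, `nes`, `p`, `n_genes`, `n_hits`, `n_perm`.
#' @export
gsea_module_class <- function(ranking, module_genes, n_perm = 1000L,
                              seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  genes <- names(ranking)
  hits <- toupper(genes) %in% as_symbols(module_genes)
  nh <- sum(hits)
  if (nh == 0L) stop("module has no overlap with the ranked genes")
  es <- gsea_es(ranking, hits)
  perm_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      gsea_es(ranking, sample(hits))
    }, numeric(1))
  })
  same_sign <- if (es >= 0) perm_es >= 0 else perm_es < 0
  n_same <- sum(same_sign)
  denom <- if (n_same > 0) mean(abs(perm_es[same_sign])) else mean(abs(perm_es))
  nes <- if (denom > 0) es / denom else 0
  p <- (1 + sum(same_sign & abs(perm_es) >= abs(es))) / (1 + n_same)
  list(es = es, nes = nes, p = min(p, 1), n_genes = length(genes),
       n_hits = nh, n_perm = n_perm)
}

#' Module-versus-stratum enrichment table
#'
#' Runs [gsea_module_class()] for every detected module against every
#' tissue-by-condition stratum present in the annotation (the six strata
#' of the paired-biopsy design: CD/UC/CI by ileal/sigmoid).
#'
#' @param norm genes x samples matrix.
#' @param annotation [sample_annotation()].
#' @param modules named list of gene_sets (e.g. `coexpression_result$modules`).
#' @param n_perm permutations per test.
#' @param seed RNG seed; each module-by-class cell uses a seed derived from
#'   it, so the table is reproducible as a whole.
#' @return data.frame of class `module_enrichment` with columns `module`,
#'   `tissue`, `condition`, `es`, `nes`, `p`.
#' @export
module_class_enrichment <- function(norm, annotation, modules,
                                    n_perm = 1000L, seed = 1L) {
  strata <- unique(annotation[, c("tissue", "condition")])
  strata <- strata[order(strata$condition, strata$tissue), , drop = FALSE]
  rows <- list()
  for (m in names(modules)) {
    for (i in seq_len(nrow(strata))) {
      tis <- strata$tissue[i]; cond <- strata$condition[i]
      ranking <- class_ranked_list(norm, annotation, tis, cond)
      cell_seed <- stage_seed(seed, paste("gsea", m, tis, cond))
      g <- gsea_module_class(ranking, modules[[m]], n_perm = n_perm,
                             seed = cell_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, tissue = tis, condition = cond,
        es = g$es, nes = g$nes, p = g$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("module_enrichment", "data.frame")
  out
}
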