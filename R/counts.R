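#' Median-of-ratios size factors
#'
#' Per-sample scaling factors for count matrices: each sample's factor is
#' the median, across genes with a positive geometric mean over samples, of
#' that sample's count divided by the gene's geometric mean. Genes with a
#' zero count in any sample drop out of the reference set (their geometric
#' mean is zero), the standard median-of-ratios convention.
#'
#' @param counts counts-mode expression matrix (genes x samples).
#' @return numeric vector of positive size factors, one per sample.
#' @export
median_ratio_size_factors <- function(counts) {
  validate_expression_values(counts, "counts")
  log_counts <- log(counts)
  log_geomean <- rowMeans(log_counts)  # -Inf when any count is zero
  ref <- is.finite(log_geomean)
  if (!any(ref)) stop("cannot normalize: no gene has positive counts in all samples")
  sf <- apply(log_counts[ref, , drop = FALSE], 2L, function(col) {
    exp(stats::median(col - log_geomean[ref]))
  })
  sf
}

#' Log-normalize counts
#'
#' Divides each sample by its size factor and applies `log2(x + 1)`, the
#' normalized-transform scale on which the co-expression and PCA stages
#' operate.
#'
#' @param counts counts-mode matrix.
#' @param size_factors per-sample positive factors, e.g. from
#'   [median_ratio_size_factors()].
#' @return numeric matrix with attributes `mode = "intensity"`,
#'   `transform = "log2_plus1"` and `size_factors`.
#' @export
log_normalize <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- median_ratio_size_factors(counts)
  if (length(size_factors) != ncol(counts) || any(size_factors <= 0)) {
    stop("size_factors must be positive, one per sample")
  }
  norm <- log2(sweep(counts, 2L, size_factors, "/") + 1)
  attr(norm, "mode") <- "intensity"
  attr(norm, "transform") <- "log2_plus1"
  attr(norm, "size_factors") <- size_factors
  norm
}

#' PCA of a normalized expression matrix
#'
#' Gene-centered singular value decomposition over samples. Component `i`
#' explains `sigma_i^2 / sum(sigma^2)` of the variance; signs follow the
#' convention that the first nonzero gene loading of each component is
#' positive. A matrix with no variance at all yields all-zero fractions
#' with a warning.
#'
#' @param norm genes x samples numeric matrix.
#' @param n_components number of components to return.
#' @param genes optional gene_set restricting the analysis (used to
#'   reproduce signature-restricted views).
#' @return list of class `pca_summary` with `scores` (samples x
#'   components), `variance_fraction`, and `loadings` (genes x components).
#' @export
pca_summary <- function(norm, n_components = 10L, genes = NULL) {
  if (!is.null(genes)) {
    keep <- rownames(norm) %in% as_symbols(genes)
    if (!any(keep)) stop("no requested genes present in the matrix")
    norm <- norm[keep, , drop = FALSE]
  }
  if (ncol(norm) < 2L) stop("PCA needs at least 2 samples")
  centered <- norm - rowMeans(norm)
  k <- min(n_components, ncol(norm) - 1L, nrow(norm))
  total_var <- sum(centered^2)
  if (total_var == 0) {
    warning("matrix has no variance; all variance fractions are 0")
    scores <- matrix(0, ncol(norm), k,
                     dimnames = list(colnames(norm), paste0("PC", seq_len(k))))
    loadings <- matrix(0, nrow(norm), k,
                       dimnames = list(rownames(norm), paste0("PC", seq_len(k))))
    return(structure(list(scores = scores, variance_fraction = rep(0, k),
                          loadings = loadings), class = "pca_summary"))
  }
  sv <- svd(centered, nu = k, nv = k)
  loadings <- sv$u
  scores <- sv$v %*% diag(sv$d[seq_len(k)], k, k)
  for (i in seq_len(k)) {
    first <- which(abs(loadings[, i]) > 1e-12)[1L]
    if (!is.na(first) && loadings[first, i] < 0) {
      loadings[, i] <- -loadings[, i]
      scores[, i] <- -scores[, i]
    }
  }
  dimnames(scores) <- list(colnames(norm), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(rownames(norm), paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 variance_fraction = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 loadings = loadings),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("pca_summary: %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              length(vf), 100 * vf[1L],
              if (length(vf) > 1L) 100 * vf[2L] else NA_real_))
  invisible(x)
}
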