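#' Co-expression configuration
#'
#' Parameters of the weighted co-expression module discovery: correlation
#' flavor, the soft-threshold grid and scale-free fit target, the minimum
#' module size, network sign, and the static tree-cut height on the
#' topological-overlap dissimilarity.
#'
#' @param correlation `"pearson"` or `"spearman"`.
#' @param beta_grid integer soft-threshold candidates.
#' @param rsq_target scale-free fit R-squared target for choosing beta.
#' @param min_module_size smallest cluster reported as a module (>= 3).
#' @param network_sign `"unsigned"` (`|r|^beta`) or `"signed"`
#'   (`((1+r)/2)^beta`).
#' @param merge_height static tree-cut height on `1 - TOM`, in (0, 1).
#' @return list of class `coexpression_config`.
#' @export
coexpression_config <- function(correlation = c("pearson", "spearman"),
                                beta_grid = 1:20, rsq_target = 0.8,
                                min_module_size = 20L,
                                network_sign = c("unsigned", "signed"),
                                merge_height = 0.8) {
  correlation <- match.arg(correlation)
  network_sign <- match.arg(network_sign)
  if (length(beta_grid) == 0L) stop("beta_grid must be nonempty")
  if (min_module_size < 3L) stop("min_module_size must be >= 3")
  if (merge_height <= 0 || merge_height >= 1) stop("merge_height must lie in (0, 1)")
  structure(list(correlation = correlation, beta_grid = as.integer(beta_grid),
                 rsq_target = rsq_target,
                 min_module_size = as.integer(min_module_size),
                 network_sign = network_sign, merge_height = merge_height),
            class = "coexpression_config")
}

#' Gene-gene correlation matrix
#'
#' @param norm genes x samples matrix with at least 4 samples.
#' @param method `"pearson"` or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   genes are removed with a warning.
#' @export
correlation_matrix <- function(norm, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(norm) < 4L) stop("need at least 4 samples for co-expression")
  sds <- apply(norm, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("removing ", sum(sds == 0), " zero-variance gene(s)")
    norm <- norm[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(norm), method = method)
  diag(r) <- 1
  r
}

# weighted adjacency from correlations
adjacency_from_cor <- function(r, beta, network_sign = "unsigned") {
  a <- if (network_sign == "signed") ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 1
  a
}

# scale-free topology fit over equal-width degree bins: R^2 of log10(freq)
# on log10(mean degree), signed by the slope (a scale-free law has frequency
# decreasing in connectivity, so an increasing fit counts as a bad fit).
# Requires at least `min_bins` occupied bins.
scale_free_rsq <- function(k, n_bins = 10L, min_bins = 5L) {
  k <- k[k > 0]
  if (length(k) < min_bins) return(NA_real_)
  if (diff(range(k)) == 0) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  occupied <- !is.na(freq) & freq > 0
  if (sum(occupied) < min_bins) return(NA_real_)
  r <- stats::cor(log10(mean_k[occupied]), log10(freq[occupied]))
  -sign(r) * r^2
}

# conventional unsigned-network default power by sample size, used when no
# candidate power reaches the scale-free fit target
default_beta <- function(n_samples) {
  if (n_samples < 20L) 9L
  else if (n_samples < 30L) 8L
  else if (n_samples < 40L) 7L
  else 6L
}

#' Choose the soft threshold
#'
#' For each candidate beta, forms the weighted adjacency and measures how
#' well the connectivity distribution fits a scale-free law: the squared
#' correlation of log frequency versus log mean connectivity over occupied
#' degree bins, signed by the slope (frequency must decrease with
#' connectivity for the fit to count). Picks the smallest beta reaching
#' `rsq_target`; when no beta reaches it - common for small,
#' signature-restricted matrices whose degree distribution is dominated by
#' one module - the conventional sample-size-based default power is used
#' (6 for 40+ samples, up to 9 below 20 samples) rather than chasing the
#' best fit into degenerate high powers. If no beta yields enough occupied
#' degree bins, beta = 6 is used with a warning.
#'
#' @param r correlation matrix.
#' @param config [coexpression_config()].
#' @param n_samples number of samples behind `r`, for the fallback power;
#'   defaults conservatively to the 40+ bracket.
#' @return list with `beta`, `rsq` (fit at the chosen beta) and the full
#'   `fit_table` (beta, rsq rows).
#' @export
select_soft_threshold <- function(r, config = coexpression_config(),
                                  n_samples = 40L) {
  betas <- config$beta_grid
  rsqs <- vapply(betas, function(beta) {
    a <- adjacency_from_cor(r, beta, config$network_sign)
    k <- rowSums(a) - 1
    scale_free_rsq(k)
  }, numeric(1))
  fit <- data.frame(beta = betas, rsq = rsqs)
  if (all(is.na(rsqs))) {
    warning("scale-free fit undefined at every beta; falling back to beta = 6")
    return(list(beta = 6L, rsq = NA_real_, fit_table = fit))
  }
  hit <- which(!is.na(rsqs) & rsqs >= config$rsq_target)
  if (length(hit)) {
    idx <- hit[1L]
    list(beta = betas[idx], rsq = rsqs[idx], fit_table = fit)
  } else {
    beta <- default_beta(n_samples)
    if (!beta %in% betas) beta <- betas[which.min(abs(betas - beta))]
    list(beta = beta, rsq = rsqs[match(beta, betas)], fit_table = fit)
  }
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, where
#' the shared-neighbor sum excludes `i` and `j`, connectivities `k` exclude
#' the diagonal, and `TOM_ii = 1`. TOM blends direct adjacency with shared
#' network neighborhood and is the similarity that module detection
#' clusters on.
#'
#' @param a symmetric adjacency in [0, 1] with unit diagonal.
#' @return TOM matrix, symmetric in [0, 1] with unit diagonal.
#' @export
adjacency_to_tom <- function(a) {
  stopifnot(nrow(a) == ncol(a))
  if (any(a < 0 | a > 1)) stop("adjacency must lie in [0, 1]")
  k <- rowSums(a) - 1
  shared <- a %*% a - 2 * a        # sum over u != i, j of a_iu a_uj (diag 1)
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  (tom + t(tom)) / 2
}

#' Cluster the TOM into modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut statically at
#' `merge_height`. Clusters below `min_module_size` become "unassigned";
#' surviving clusters are labeled M1, M2, ... by size descending (ties
#' broken by the alphabetically first member).
#'
#' @param tom topological overlap matrix with gene dimnames.
#' @param config [coexpression_config()].
#' @return named character vector gene -> module label.
#' @export
cluster_modules <- function(tom, config = coexpression_config()) {
  genes <- rownames(tom)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = config$merge_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= config$min_module_size]
  if (length(keep) == 0L) {
    warning("no cluster reaches min_module_size; all genes unassigned")
    return(stats::setNames(rep("unassigned", length(genes)), genes))
  }
  first_gene <- vapply(keep, function(id) min(genes[cl == id]), "")
  keep <- keep[order(-sizes[keep], first_gene)]
  labels <- stats::setNames(paste0("M", seq_along(keep)), keep)
  out <- rep("unassigned", length(genes))
  assigned <- as.character(cl) %in% keep
  out[assigned] <- labels[as.character(cl)[assigned]]
  stats::setNames(out, genes)
}

#' Module eigengene
#'
#' First right singular vector of the gene-standardized module submatrix:
#' a one-number-per-sample summary of the module's expression, oriented so
#' that it correlates positively with mean module expression.
#'
#' @param norm genes x samples matrix.
#' @param assignments gene -> module labels (see [cluster_modules()]).
#' @param module module label.
#' @return numeric vector of per-sample scores (unit norm).
#' @export
module_eigengene <- function(norm, assignments, module) {
  genes <- names(assignments)[assignments == module]
  genes <- intersect(genes, rownames(norm))
  if (length(genes) == 0L) stop("module ", module, " is empty")
  x <- norm[genes, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  x <- (x - rowMeans(x)) / ifelse(sds > 0, sds, 1)
  v <- svd(x, nu = 0L, nv = 1L)$v[, 1L]
  if (sum(v * colMeans(x)) < 0) v <- -v
  stats::setNames(v, colnames(norm))
}

#' Automatic co-expression module discovery
#'
#' End-to-end module discovery on a normalized, signature-restricted
#' matrix: correlation, soft-threshold selection, topological overlap,
#' clustering, and eigengenes for every detected module.
#'
#' @param norm genes x samples matrix.
#' @param config [coexpression_config()].
#' @return list of class `coexpression_result` with `beta`, `rsq`,
#'   `assignments`, `modules` (named list of gene_sets), `eigengenes`
#'   (module x sample matrix) and `tom`.
#' @export
find_modules <- function(norm, config = coexpression_config()) {
  r <- correlation_matrix(norm, config$correlation)
  st <- select_soft_threshold(r, config, n_samples = ncol(norm))
  a <- adjacency_from_cor(r, st$beta, config$network_sign)
  tom <- adjacency_to_tom(a)
  assignments <- cluster_modules(tom, config)
  labels <- setdiff(unique(assignments), "unassigned")
  labels <- labels[order(as.integer(sub("^M", "", labels)))]
  modules <- lapply(labels, function(m) {
    gene_set(names(assignments)[assignments == m], name = m)
  })
  names(modules) <- labels
  eigengenes <- if (length(labels)) {
    t(vapply(labels, function(m) module_eigengene(norm, assignments, m),
             numeric(ncol(norm))))
  } else {
    matrix(numeric(0), 0L, ncol(norm), dimnames = list(NULL, colnames(norm)))
  }
  structure(list(beta = st$beta, rsq = st$rsq, fit_table = st$fit_table,
                 assignments = assignments, modules = modules,
                 eigengenes = eigengenes, tom = tom, config = config),
            class = "coexpression_result")
}

#' @export
print.coexpression_result <- function(x, ...) {
  sizes <- vapply(x$modules, length, 1L)
  cat(sprintf("coexpression_result: beta = %d (R^2 = %.2f); %d module(s)\n",
              x$beta, x$rsq, length(x$modules)))
  if (length(sizes)) {
    cat("  ", paste(sprintf("%s: %d genes", names(sizes), sizes),
                    collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  unassigned: %d genes\n", sum(x$assignments == "unassigned")))
  invisible(x)
}
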