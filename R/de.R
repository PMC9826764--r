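#' Differential-expression configuration
#'
#' Per-cohort two-group tests are filtered at a raw p-value threshold by
#' default (no multiple-testing adjustment), with Benjamini-Hochberg
#' adjustment available via `adjust = "BH"`.
#'
#' @param p_threshold significance threshold in (0, 1).
#' @param adjust `"none"` (filter on raw p) or `"BH"`.
#' @return list of class `de_config`.
#' @export
de_config <- function(p_threshold = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      p_threshold <= 0 || p_threshold >= 1) {
    stop("p_threshold must lie in (0, 1)")
  }
  structure(list(p_threshold = p_threshold, adjust = adjust),
            class = "de_config")
}

#' Per-gene two-group summary statistics
#'
#' Computes, for every gene, the mean difference (group1 minus group2), the
#' pooled residual variance and the residual degrees of freedom
#' `d_g = n1 + n2 - 2` of the two-group design.
#'
#' @param x intensity-mode expression matrix (genes x samples).
#' @param group1,group2 column names (or indices) of the two groups; both
#'   need at least two samples.
#' @return list with vectors `diff`, `s_sq` and scalars `d_g`, `n1`, `n2`.
#' @export
fit_group_stats <- function(x, group1, group2) {
  mode <- attr(x, "mode")
  if (!is.null(mode) && mode == "counts") {
    stop("fit_group_stats expects an intensity-mode matrix")
  }
  x1 <- x[, group1, drop = FALSE]
  x2 <- x[, group2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop("insufficient replication: each group needs >= 2 samples")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  d_g <- n1 + n2 - 2L
  list(diff = m1 - m2, s_sq = (ss1 + ss2) / d_g, d_g = d_g, n1 = n1, n2 = n2)
}

#' Fit the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior of the moderated t-statistic by
#' moment matching on log variances: marginally the sample variances follow
#' `s^2 ~ s0^2 F(d_g, d0)`, so the mean and variance of `log(s^2)` identify
#' `(d0, s0^2)` through digamma/trigamma equations. The trigamma equation is
#' inverted by bisection on `d0` in (0.01, 1e6] to a tolerance of 1e-8.
#' When the empirical spread of the log variances does not exceed the
#' sampling spread implied by `d_g` alone the prior degrees of freedom are
#' infinite and `s0^2` is the exponentiated mean adjusted log-variance.
#'
#' Genes with zero sample variance carry no information about the prior and
#' are excluded from the fit; at least 10 positive variances are required.
#'
#' @param s_sq per-gene sample variances.
#' @param d_g residual degrees of freedom (scalar or per-gene vector).
#' @return list of class `moderated_t_params` with `d0` (possibly `Inf`)
#'   and `s0_sq`.
#' @export
estimate_prior <- function(s_sq, d_g) {
  if (all(s_sq <= 0)) stop("degenerate variances: all zero")
  keep <- s_sq > 0
  if (sum(keep) < 10L) stop("need at least 10 genes with positive variance")
  s_sq <- s_sq[keep]
  d_g <- if (length(d_g) == 1L) rep(d_g, length(s_sq)) else d_g[keep]
  z <- log(s_sq)
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  evar <- stats::var(e) - mean(trigamma(d_g / 2))
  lower <- 0.01; upper <- 1e6
  if (!is.finite(evar) || evar <= trigamma(upper / 2)) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- invert_trigamma_half(evar, lower, upper)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderated_t_params")
}

# solve trigamma(d0/2) = target for d0 in [lower, upper]; trigamma is
# strictly decreasing so plain bisection suffices
invert_trigamma_half <- function(target, lower, upper, tol = 1e-8) {
  if (trigamma(lower / 2) < target) return(lower)
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (trigamma(mid / 2) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Moderated t-statistics
#'
#' Shrinks each gene's variance towards the prior,
#' `s_tilde^2 = (d0 s0^2 + d_g s^2) / (d0 + d_g)`, forms
#' `t = diff / sqrt(s_tilde^2 (1/n1 + 1/n2))` and computes two-sided
#' p-values from a t distribution on `d0 + d_g` degrees of freedom.
#' `d0 = Inf` is the pooled/normal limit (`s_tilde^2 = s0^2`, Gaussian
#' tails); `d0 = 0` collapses to the ordinary two-sample pooled t-test.
#'
#' @param stats output of [fit_group_stats()].
#' @param params `moderated_t_params` from [estimate_prior()] (or supplied
#'   directly).
#' @param config [de_config()].
#' @return data.frame of class `de_result` with columns `gene`, `log_fc`,
#'   `s_sq`, `t_mod`, `df_total`, `p`, `significant` (and `q` when BH
#'   adjustment is on).
#' @export
moderated_t <- function(stats, params, config = de_config()) {
  d0 <- params$d0; s0 <- params$s0_sq
  stopifnot(d0 >= 0, s0 > 0)
  s_sq <- stats$s_sq
  s_tilde <- if (is.infinite(d0)) {
    rep(s0, length(s_sq))
  } else if (d0 == 0) {
    s_sq
  } else {
    (d0 * s0 + stats$d_g * s_sq) / (d0 + stats$d_g)
  }
  se <- sqrt(s_tilde * (1 / stats$n1 + 1 / stats$n2))
  t_mod <- stats$diff / se
  # a gene with zero difference and zero variance is uninformative, not extreme
  t_mod[stats$diff == 0 & se == 0] <- 0
  df_total <- d0 + stats$d_g
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  res <- data.frame(gene = names(stats$diff) %||% seq_along(stats$diff),
                    log_fc = unname(stats$diff), s_sq = unname(s_sq),
                    t_mod = unname(t_mod), df_total = df_total,
                    p = unname(p), stringsAsFactors = FALSE)
  if (config$adjust == "BH") {
    res$q <- bh_adjust(res$p)
    res$significant <- res$q < config$p_threshold
  } else {
    res$significant <- res$p < config$p_threshold
  }
  attr(res, "params") <- params
  attr(res, "config") <- config
  class(res) <- c("de_result", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the significant genes of a DE result
#'
#' @param result `de_result` from [moderated_t()].
#' @param name cohort label for the resulting gene set.
#' @return gene_set of genes passing the configured threshold.
#' @export
significant_genes <- function(result, name = "cohort") {
  gene_set(result$gene[result$significant], name = name)
}

#' Two-group differential expression with variance moderation
#'
#' Convenience wrapper: [fit_group_stats()], [estimate_prior()],
#' [moderated_t()] in sequence.
#'
#' @inheritParams fit_group_stats
#' @inheritParams moderated_t
#' @return `de_result` data.frame.
#' @export
de_analysis <- function(x, group1, group2, config = de_config()) {
  st <- fit_group_stats(x, group1, group2)
  params <- estimate_prior(st$s_sq, st$d_g)
  moderated_t(st, params, config)
}

#' @export
print.de_result <- function(x, ...) {
  params <- attr(x, "params")
  cat(sprintf("de_result: %d genes, %d significant (d0 = %s, s0^2 = %.4g)\n",
              nrow(x), sum(x$significant),
              format(params$d0, digits = 4), params$s0_sq))
  invisible(x)
}
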