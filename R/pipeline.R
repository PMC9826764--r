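#' Pipeline configuration
#'
#' A single nested configuration for the two-stage workflow. Defaults
#' reproduce the study design: a (9, >=7) scheme for the disease pool, a
#' (5, >=4) scheme for the other-fibrosis pool, raw p < 0.05 per-cohort
#' significance, and the default co-expression, hub and ORA settings.
#' Unknown fields in `overrides` are rejected, so typos fail loudly.
#'
#' @param overrides named list (possibly nested) of values replacing
#'   defaults, e.g. from [read_pipeline_config()].
#' @param seed global seed; per-stage seeds derive from it via
#'   [stage_seed()].
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list(), seed = 1L) {
  defaults <- list(
    seed = as.integer(seed),
    de = list(p_threshold = 0.05, adjust = "none"),
    scheme_cd = list(n_lists = 9L, min_k = 7L),
    scheme_other = list(n_lists = 5L, min_k = 4L),
    background_n = NULL,  # default: union of genes measured across cohorts
    coexpression = list(correlation = "pearson", beta_grid = 1:20,
                        rsq_target = 0.8, min_module_size = 20L,
                        network_sign = "unsigned", merge_height = 0.8),
    gsea = list(n_perm = 1000L),
    hubs = list(rule = "mean_plus_sd", k = 21L, min_score = 400),
    ora = list(min_term_size = 10L, max_term_size = 500L),
    synthetic = list(multi_cohort = list(), paired_biopsy = list(),
                     network = list(n_nodes = 500L, m_attach = 2L,
                                    n_planted_hubs = 10L))
  )
  config <- merge_config(defaults, overrides)
  config$seed <- as.integer(config$seed)
  structure(config, class = "pipeline_config")
}

merge_config <- function(defaults, overrides) {
  if (length(overrides) == 0L) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file mirroring the [pipeline_config()] structure.
#' @param seed global seed (overridden by a `seed` field in the file).
#' @return pipeline_config.
#' @export
read_pipeline_config <- function(path, seed = 1L) {
  overrides <- yaml::read_yaml(path)
  if (!is.null(overrides$seed)) seed <- overrides$seed
  overrides$seed <- NULL
  pipeline_config(overrides, seed = seed)
}

#' Run the signature-discovery stage
#'
#' Per-cohort moderated-t differential expression, k-of-n membership
#' filtering into the two pools, and intersection of the pools into the
#' signature with exact intersection statistics. Cohorts default to
#' synthetic data simulated from the configuration (with a stage-derived
#' seed), in which case the planted truth travels along in the result.
#' Precomputed per-cohort gene lists can be supplied instead to skip the
#' DE step.
#'
#' @param config [pipeline_config()].
#' @param cohorts optional list as produced by [simulate_cohorts()]
#'   (`$cohorts`); each element needs `matrix`, `group1`, `group2`,
#'   `pool`.
#' @param gene_lists optional named list of per-cohort gene_sets plus a
#'   `pool` assignment (`attr(gene_lists, "pool")` or names matched by
#'   prefix); skips DE entirely.
#' @param universe gene universe for membership matrices and the default
#'   background; required when only gene lists are given.
#' @param outdir optional output directory for TSV/JSON artifacts.
#' @return list of class `signature_stage` with `signature`
#'   (signature_result), `pool_cd`, `pool_other`, `de_sets`, `counts`
#'   (per-step sizes) and `truth` when simulated.
#' @export
run_signature_stage <- function(config = pipeline_config(), cohorts = NULL,
                                gene_lists = NULL, universe = NULL,
                                outdir = NULL) {
  truth <- NULL
  if (is.null(gene_lists)) {
    if (is.null(cohorts)) {
      spec_args <- config$synthetic$multi_cohort
      spec_args$seed <- stage_seed(config$seed, "signature")
      spec_args$n_cohorts_cd <- config$scheme_cd$n_lists
      spec_args$n_cohorts_other <- config$scheme_other$n_lists
      sim <- simulate_cohorts(do.call(multi_cohort_spec, spec_args))
      cohorts <- sim$cohorts
      truth <- sim$truth
    }
    de_cfg <- de_config(config$de$p_threshold, config$de$adjust)
    de_sets <- lapply(names(cohorts), function(nm) {
      co <- cohorts[[nm]]
      res <- de_analysis(co$matrix, co$group1, co$group2, de_cfg)
      significant_genes(res, name = nm)
    })
    names(de_sets) <- names(cohorts)
    pools <- vapply(cohorts, `[[`, "", "pool")
    if (is.null(universe)) {
      universe <- unique(unlist(lapply(cohorts,
                                       function(co) rownames(co$matrix)),
                                use.names = FALSE))
    }
  } else {
    de_sets <- gene_lists
    pools <- attr(gene_lists, "pool")
    if (is.null(pools)) stop("gene_lists needs a 'pool' attribute (CD/other)")
    if (is.null(universe)) {
      stop("universe is required when starting from precomputed gene lists")
    }
    universe <- as_symbols(universe)
  }
  cd_sets <- de_sets[pools == "CD"]
  other_sets <- de_sets[pools == "other"]
  scheme_cd <- combination_scheme(config$scheme_cd$n_lists,
                                  config$scheme_cd$min_k)
  scheme_other <- combination_scheme(config$scheme_other$n_lists,
                                     config$scheme_other$min_k)
  pool_cd <- k_of_n_filter(membership_matrix(cd_sets, universe), scheme_cd,
                           name = "pool_cd")
  pool_other <- k_of_n_filter(membership_matrix(other_sets, universe),
                              scheme_other, name = "pool_other")
  background_n <- config$background_n %||% length(universe)
  signature <- build_signature(pool_cd, pool_other, background_n)
  counts <- list(per_cohort = vapply(de_sets, length, 1L),
                 pool_cd = length(pool_cd), pool_other = length(pool_other),
                 fibsig = length(signature$fibsig),
                 background_n = background_n)
  result <- structure(list(signature = signature, pool_cd = pool_cd,
                           pool_other = pool_other, de_sets = de_sets,
                           counts = counts, truth = truth,
                           config = config),
                      class = "signature_stage")
  if (!is.null(outdir)) write_signature_stage(result, outdir)
  result
}

#' @export
print.signature_stage <- function(x, ...) {
  cat("signature stage\n")
  cat(sprintf("  per-cohort significant genes: %s\n",
              paste(x$counts$per_cohort, collapse = ", ")))
  cat(sprintf("  pool_cd: %d, pool_other: %d, signature: %d (N = %d)\n",
              x$counts$pool_cd, x$counts$pool_other, x$counts$fibsig,
              x$counts$background_n))
  invisible(x)
}

write_signature_stage <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- sprintf("fibsig config=%s seed=%d", config_hash(result$config),
                  result$config$seed)
  writeLines(c(paste0("# ", meta), result$signature$fibsig$genes),
             file.path(outdir, "fibsig.txt"))
  for (nm in names(result$de_sets)) {
    writeLines(c(paste0("# ", meta), result$de_sets[[nm]]$genes),
               file.path(outdir, paste0("genes_", nm, ".txt")))
  }
  st <- result$signature$stats
  jsonlite::write_json(
    list(meta = meta, set_sizes = st$set_sizes, background_n = st$background_n,
         observed = st$observed, expected = st$expected,
         fold_enrichment = st$fold_enrichment, p_value = st$p_value,
         counts = result$counts),
    file.path(outdir, "signature_stats.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Run the paired-biopsy validation stage
#'
#' Normalizes the count matrix (median-of-ratios, log2(x+1)), restricts it
#' to the signature, discovers co-expression modules, scores every module
#' against every tissue-by-condition stratum by GSEA, extracts the hubs of
#' the largest module from its induced interaction subnetwork, and (when a
#' GMT collection is supplied) runs ORA on the largest module. Inputs
#' default to synthetic data simulated from the configuration.
#'
#' @param config [pipeline_config()].
#' @param signature gene_set to restrict to; defaults to the planted truth
#'   in synthetic mode (so the restriction is meaningful), otherwise
#'   required.
#' @param counts counts-mode matrix; simulated when `NULL`.
#' @param annotation [sample_annotation()] matching `counts`.
#' @param network [interaction_network()]; simulated when `NULL`.
#' @param collection optional [gene_set_collection()] for ORA.
#' @param modules optional named list of gene_sets bypassing module
#'   discovery (fixture mode).
#' @param outdir optional output directory.
#' @return list of class `validation_stage` with `normalized`, `pca`,
#'   `coexpression`, `enrichment`, `hub_report`, `ora`, `truth`.
#' @export
run_validation_stage <- function(config = pipeline_config(), signature = NULL,
                                 counts = NULL, annotation = NULL,
                                 network = NULL, collection = NULL,
                                 modules = NULL, outdir = NULL) {
  truth <- NULL
  if (is.null(counts)) {
    spec_args <- config$synthetic$paired_biopsy
    spec_args$seed <- stage_seed(config$seed, "validation")
    sim <- simulate_paired_counts(do.call(paired_biopsy_spec, spec_args))
    counts <- sim$counts
    annotation <- sim$annotation
    truth <- sim$truth
  }
  if (is.null(annotation)) stop("annotation is required with explicit counts")
  if (is.null(signature)) {
    signature <- if (!is.null(truth)) truth$signature_universe
                 else gene_set(rownames(counts), "all_genes")
  }
  keep <- rownames(counts) %in% as_symbols(signature)
  if (!any(keep)) stop("signature has no overlap with the count matrix genes")
  norm_all <- log_normalize(counts)
  pca <- pca_summary(norm_all)
  norm <- norm_all[keep, , drop = FALSE]
  cx_cfg <- do.call(coexpression_config, config$coexpression)
  coexpr <- if (is.null(modules)) {
    find_modules(norm, cx_cfg)
  } else {
    assignments <- rep("unassigned", nrow(norm))
    names(assignments) <- rownames(norm)
    for (m in names(modules)) {
      assignments[names(assignments) %in% as_symbols(modules[[m]])] <- m
    }
    modules_gs <- lapply(names(modules), function(m) {
      gene_set(names(assignments)[assignments == m], name = m)
    })
    names(modules_gs) <- names(modules)
    structure(list(beta = NA_integer_, rsq = NA_real_,
                   assignments = assignments, modules = modules_gs,
                   eigengenes = NULL, tom = NULL, config = cx_cfg),
              class = "coexpression_result")
  }
  enrichment <- if (length(coexpr$modules)) {
    module_class_enrichment(norm, annotation, coexpr$modules,
                            n_perm = config$gsea$n_perm,
                            seed = stage_seed(config$seed, "gsea"))
  } else NULL
  hub_report <- NULL
  if (is.null(network) && length(coexpr$modules)) {
    # mirror the real workflow: the interaction network is built over the
    # genes of the discovered module, here with planted high-degree hubs
    main_genes <- coexpr$modules[[1L]]$genes
    net_args <- config$synthetic$network
    net_args$seed <- stage_seed(config$seed, "network")
    net_args$n_nodes <- length(main_genes)
    net_args$node_names <- main_genes
    net_args$n_planted_hubs <- min(net_args$n_planted_hubs,
                                   max(1L, length(main_genes) %/% 10L))
    net_sim <- do.call(simulate_scale_free_network, net_args)
    network <- net_sim$network
    if (!is.null(truth)) truth$hubs <- net_sim$truth$hubs
  }
  if (length(coexpr$modules) && !is.null(network)) {
    main <- coexpr$modules[[1L]]
    sub <- induced_subnetwork(network, main)
    report <- degree_centrality(sub)
    hub_report <- if (config$hubs$rule == "top_k") {
      select_hubs(report, "top_k", k = config$hubs$k)
    } else {
      select_hubs(report, config$hubs$rule, t = config$hubs$t %||% NULL)
    }
  }
  ora <- if (!is.null(collection) && length(coexpr$modules)) {
    hypergeometric_ora(coexpr$modules[[1L]], collection,
                       min_term_size = config$ora$min_term_size,
                       max_term_size = config$ora$max_term_size)
  } else NULL
  result <- structure(list(normalized = norm, pca = pca,
                           coexpression = coexpr, enrichment = enrichment,
                           hub_report = hub_report, ora = ora,
                           annotation = annotation, truth = truth,
                           config = config),
                      class = "validation_stage")
  if (!is.null(outdir)) write_validation_stage(result, outdir)
  result
}

#' @export
print.validation_stage <- function(x, ...) {
  cat("validation stage\n")
  print(x$coexpression)
  if (!is.null(x$enrichment)) {
    cat("  module-vs-stratum NES:\n")
    print(utils::head(as.data.frame(x$enrichment), 12L))
  }
  if (!is.null(x$hub_report)) {
    cutoff <- attr(x$hub_report, "cutoff_rule")
    cat(sprintf("  hubs of %s: %d\n", names(x$coexpression$modules)[1L],
                cutoff$n_hubs))
  }
  invisible(x)
}

write_validation_stage <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- sprintf("fibsig config=%s seed=%d", config_hash(result$config),
                  result$config$seed)
  assignments <- result$coexpression$assignments
  write_tsv_stamped(data.frame(gene = names(assignments),
                               module = unname(assignments)),
                    file.path(outdir, "module_assignments.tsv"), meta)
  if (!is.null(result$enrichment)) {
    write_tsv_stamped(as.data.frame(result$enrichment),
                      file.path(outdir, "module_enrichment.tsv"), meta)
  }
  if (!is.null(result$hub_report)) {
    write_tsv_stamped(as.data.frame(result$hub_report),
                      file.path(outdir, "hub_report.tsv"), meta)
  }
  if (!is.null(result$ora)) {
    write_tsv_stamped(as.data.frame(result$ora),
                      file.path(outdir, "ora.tsv"), meta)
  }
  jsonlite::write_json(
    list(meta = meta,
         variance_fraction = result$pca$variance_fraction),
    file.path(outdir, "pca_variance.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Run the full pipeline
#'
#' Signature discovery followed by validation, with the discovered
#' signature feeding the validation restriction in synthetic mode (the
#' planted module lives inside the synthetic signature universe, so the
#' stages are exercised end to end).
#'
#' @param config [pipeline_config()].
#' @param outdir optional output directory (per-stage subdirectories).
#' @return list with `signature_stage` and `validation_stage`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  sig <- run_signature_stage(config,
                             outdir = if (!is.null(outdir))
                               file.path(outdir, "signature"))
  val <- run_validation_stage(config,
                              outdir = if (!is.null(outdir))
                                file.path(outdir, "validation"))
  list(signature_stage = sig, validation_stage = val)
}
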