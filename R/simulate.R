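#' Multi-cohort simulation design
#'
#' Specification for synthetic microarray-like cohorts that mirror the
#' signature-discovery setting: a disease pool of 9 cohorts and an
#' other-fibrosis pool of 5, with a planted cross-disease core carried by
#' both pools and pool-specific planted genes on top. Every planted gene
#' carries its effect in a given cohort only with probability
#' `detect_prob`, so some cohorts genuinely miss it - exactly the
#' situation the k-of-n membership filter is built for.
#'
#' Defaults describe strong disease-versus-control expression shifts
#' (2 log-units at unit noise, about 98% per-cohort power at 10 vs 10
#' samples) with 5% cohort-level dropout of each planted effect; under the
#' (9, >=7) and (5, >=4) schemes this leaves the planted core recoverable
#' with high probability while still exercising the filter's tolerance for
#' cohorts that miss a gene.
#'
#' @param n_cohorts_cd,n_cohorts_other cohorts per pool.
#' @param genes total genes per cohort.
#' @param samples_per_group samples per arm (cases and controls).
#' @param n_core planted cross-disease core size.
#' @param n_cd_only,n_other_only pool-specific planted genes.
#' @param effect_size log-scale mean shift carried by a planted gene.
#' @param detect_prob per-cohort probability that a planted gene carries
#'   its effect.
#' @param noise_sd per-observation Gaussian noise sd.
#' @param seed integer seed.
#' @return list of class `multi_cohort_spec`.
#' @export
multi_cohort_spec <- function(n_cohorts_cd = 9L, n_cohorts_other = 5L,
                              genes = 5000L, samples_per_group = 10L,
                              n_core = 240L, n_cd_only = 200L,
                              n_other_only = 500L, effect_size = 2.0,
                              detect_prob = 0.95, noise_sd = 1.0,
                              seed = 1L) {
  if (n_core + n_cd_only + n_other_only > genes) {
    stop("planted genes exceed the gene universe")
  }
  if (detect_prob <= 0 || detect_prob > 1) stop("detect_prob must lie in (0, 1]")
  structure(list(n_cohorts_cd = as.integer(n_cohorts_cd),
                 n_cohorts_other = as.integer(n_cohorts_other),
                 genes = as.integer(genes),
                 samples_per_group = as.integer(samples_per_group),
                 n_core = as.integer(n_core), n_cd_only = as.integer(n_cd_only),
                 n_other_only = as.integer(n_other_only),
                 effect_size = effect_size, detect_prob = detect_prob,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "multi_cohort_spec")
}

#' Simulate the multi-cohort discovery data
#'
#' Gaussian log-intensities, cohort by cohort: cases of a cohort are
#' shifted by `effect_size` on the genes planted for that cohort's pool,
#' subject to per-cohort Bernoulli(`detect_prob`) carriage. Bit-identical
#' under a fixed spec (including its seed).
#'
#' @param spec [multi_cohort_spec()].
#' @return list with `cohorts` (per cohort: `matrix`, `group1` = cases,
#'   `group2` = controls, `pool`) and `truth` (planted `core`, `cd_only`,
#'   `other_only` gene sets and the carriage matrix).
#' @export
simulate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "multi_cohort_spec"))
  with_seed(spec$seed, {
    gene_names <- sprintf("G%05d", seq_len(spec$genes))
    planted <- sample(gene_names, spec$n_core + spec$n_cd_only + spec$n_other_only)
    core <- planted[seq_len(spec$n_core)]
    cd_only <- planted[spec$n_core + seq_len(spec$n_cd_only)]
    other_only <- planted[spec$n_core + spec$n_cd_only +
                          seq_len(spec$n_other_only)]
    pools <- c(rep("CD", spec$n_cohorts_cd), rep("other", spec$n_cohorts_other))
    cohort_names <- c(sprintf("CD%02d", seq_len(spec$n_cohorts_cd)),
                      sprintf("OTH%02d", seq_len(spec$n_cohorts_other)))
    spg <- spec$samples_per_group
    carriage <- matrix(FALSE, spec$genes, length(pools),
                       dimnames = list(gene_names, cohort_names))
    cohorts <- vector("list", length(pools))
    names(cohorts) <- cohort_names
    for (i in seq_along(pools)) {
      eligible <- if (pools[i] == "CD") c(core, cd_only) else c(core, other_only)
      carried <- eligible[stats::runif(length(eligible)) < spec$detect_prob]
      carriage[carried, i] <- TRUE
      samples <- c(paste0(cohort_names[i], "_case", seq_len(spg)),
                   paste0(cohort_names[i], "_ctrl", seq_len(spg)))
      m <- matrix(stats::rnorm(spec$genes * 2L * spg, sd = spec$noise_sd),
                  spec$genes, 2L * spg,
                  dimnames = list(gene_names, samples))
      m[carried, seq_len(spg)] <- m[carried, seq_len(spg)] + spec$effect_size
      attr(m, "mode") <- "intensity"
      cohorts[[i]] <- list(matrix = m, group1 = samples[seq_len(spg)],
                           group2 = samples[spg + seq_len(spg)],
                           pool = pools[i])
    }
    list(cohorts = cohorts,
         truth = list(core = gene_set(core, "planted_core"),
                      cd_only = gene_set(cd_only, "planted_cd_only"),
                      other_only = gene_set(other_only, "planted_other_only"),
                      carriage = carriage))
  })
}

#' Paired-biopsy simulation design
#'
#' Specification for negative-binomial paired-biopsy counts that mirror
#' the validation cohort: per-condition patient counts as in the study
#' design (7 CD, 6 UC, 9 CI), two samples per patient (one terminal-ileum,
#' one sigmoid), a signature-sized gene universe with one planted
#' co-expression module driven by a latent factor active in exactly one
#' tissue-by-condition stratum, per-sample sequencing-depth factors and a
#' per-patient random effect inducing the paired structure.
#'
#' @param n_cd,n_uc,n_ci patients per condition.
#' @param genes signature-universe size (the genes later restricted to for
#'   co-expression).
#' @param background_genes additional genes outside the signature universe,
#'   carried only so that normalization sees a realistic genome-wide matrix
#'   (size factors are estimated before any signature restriction, as in
#'   the real workflow; a matrix dominated by one strongly shifted module
#'   would otherwise bias the median-of-ratios).
#' @param module_genes planted module size.
#' @param module_tissue,module_condition the stratum where the module's
#'   latent factor is active.
#' @param factor_loading log-scale loading of the latent factor on module
#'   genes.
#' @param factor_mean latent-factor mean in the active stratum (inactive
#'   strata are centered at zero, common sd 0.3).
#' @param nb_dispersion negative-binomial dispersion (0 gives Poisson).
#' @param base_mean baseline mean count; per-gene baselines vary around it
#'   log-normally (sdlog 0.5).
#' @param patient_sd sd of the per-patient, per-gene log-scale random
#'   effect shared by a patient's two biopsies.
#' @param depth_range range of per-sample depth (size) factors, sampled
#'   log-uniformly.
#' @param seed integer seed.
#' @return list of class `paired_biopsy_spec`.
#' @export
paired_biopsy_spec <- function(n_cd = 7L, n_uc = 6L, n_ci = 9L,
                               genes = 241L, background_genes = 1000L,
                               module_genes = 112L,
                               module_tissue = "ILEAL",
                               module_condition = "CD",
                               factor_loading = 1.0, factor_mean = 2.0,
                               nb_dispersion = 0.1, base_mean = 200,
                               patient_sd = 0.15,
                               depth_range = c(0.5, 2), seed = 1L) {
  if (module_genes > genes) stop("module_genes cannot exceed genes")
  stopifnot(module_tissue %in% c("ILEAL", "SIGMOID"),
            module_condition %in% c("CD", "UC", "CI"),
            nb_dispersion >= 0, length(depth_range) == 2L,
            all(depth_range > 0))
  structure(list(n_cd = as.integer(n_cd), n_uc = as.integer(n_uc),
                 n_ci = as.integer(n_ci), genes = as.integer(genes),
                 background_genes = as.integer(background_genes),
                 module_genes = as.integer(module_genes),
                 module_tissue = module_tissue,
                 module_condition = module_condition,
                 factor_loading = factor_loading, factor_mean = factor_mean,
                 nb_dispersion = nb_dispersion, base_mean = base_mean,
                 patient_sd = patient_sd, depth_range = depth_range,
                 seed = as.integer(seed)),
            class = "paired_biopsy_spec")
}

#' Simulate paired-biopsy counts with a planted module
#'
#' Counts are negative binomial with mean
#' `base_g * s_j * exp(loading * f_j * [g in module] + u_{patient(j), g})`
#' where `base_g` is the gene baseline, `s_j` the sample depth factor,
#' `f_j` the latent module factor (elevated only in the active stratum)
#' and `u` the per-patient random effect shared by the two biopsies of a
#' patient. With `nb_dispersion = 0` counts are Poisson.
#'
#' @param spec [paired_biopsy_spec()].
#' @return list with `counts` (counts-mode matrix), `annotation`
#'   ([sample_annotation()]), and `truth` (module gene_set, latent factor,
#'   size factors).
#' @export
simulate_paired_counts <- function(spec) {
  stopifnot(inherits(spec, "paired_biopsy_spec"))
  with_seed(spec$seed, {
    conditions <- c(rep("CD", spec$n_cd), rep("UC", spec$n_uc),
                    rep("CI", spec$n_ci))
    n_pat <- length(conditions)
    patients <- sprintf("P%02d", seq_len(n_pat))
    annotation <- data.frame(
      sample_id = as.vector(rbind(paste0(patients, "_TI"),
                                  paste0(patients, "_SC"))),
      patient_id = rep(patients, each = 2L),
      tissue = rep(c("ILEAL", "SIGMOID"), n_pat),
      condition = rep(conditions, each = 2L),
      stringsAsFactors = FALSE)
    annotation <- sample_annotation(annotation)
    n_samp <- nrow(annotation)
    sig_genes <- sprintf("FG%04d", seq_len(spec$genes))
    gene_names <- c(sig_genes,
                    if (spec$background_genes > 0L)
                      sprintf("BG%04d", seq_len(spec$background_genes)))
    n_genes <- length(gene_names)
    module <- sample(sig_genes, spec$module_genes)
    base_g <- spec$base_mean * stats::rlnorm(n_genes, 0, 0.5)
    s_j <- exp(stats::runif(n_samp, log(spec$depth_range[1L]),
                            log(spec$depth_range[2L])))
    active <- annotation$tissue == spec$module_tissue &
      annotation$condition == spec$module_condition
    f_j <- stats::rnorm(n_samp, mean = ifelse(active, spec$factor_mean, 0),
                        sd = 0.3)
    u <- matrix(stats::rnorm(n_genes * n_pat, 0, spec$patient_sd),
                n_genes, n_pat, dimnames = list(gene_names, patients))
    in_module <- gene_names %in% module
    mu <- base_g * exp(u[, annotation$patient_id] +
                       outer(as.numeric(in_module),
                             spec$factor_loading * f_j))
    mu <- sweep(mu, 2L, s_j, "*")
    counts <- if (spec$nb_dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / spec$nb_dispersion),
             nrow(mu), ncol(mu))
    } else {
      matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    }
    dimnames(counts) <- list(gene_names, annotation$sample_id)
    attr(counts, "mode") <- "counts"
    list(counts = counts, annotation = annotation,
         truth = list(module = gene_set(module, "planted_module"),
                      signature_universe = gene_set(sig_genes,
                                                    "signature_universe"),
                      factor = stats::setNames(f_j, annotation$sample_id),
                      size_factors = stats::setNames(s_j,
                                                     annotation$sample_id)))
  })
}

#' Simulate a scale-free interaction network with planted hubs
#'
#' Preferential attachment: the planted hubs form the initial clique, and
#' each subsequent node attaches to `m_attach` distinct existing nodes
#' with probability proportional to degree (plus one, so isolated seeds
#' remain reachable). Edge confidence scores are sampled uniformly on
#' [400, 999].
#'
#' @param n_nodes total nodes.
#' @param m_attach edges added per new node (>= 1).
#' @param n_planted_hubs size of the initial clique (>= 1).
#' @param seed integer seed.
#' @param node_names optional vector of `n_nodes` names to use as node
#'   labels (e.g. the genes of a discovered module, so hub extraction
#'   operates on a shared namespace); hub positions are assigned to a
#'   random subset under the seed. Default labels are HUB/NODE
#'   placeholders.
#' @return list with `network` (interaction_network) and `truth`
#'   (gene_set of planted hubs).
#' @export
simulate_scale_free_network <- function(n_nodes, m_attach = 2L,
                                        n_planted_hubs = 5L, seed = 1L,
                                        node_names = NULL) {
  n_nodes <- as.integer(n_nodes); m_attach <- as.integer(m_attach)
  n_planted_hubs <- as.integer(n_planted_hubs)
  if (m_attach < 1L) stop("m_attach must be >= 1")
  if (n_planted_hubs < 1L || n_planted_hubs > n_nodes) {
    stop("n_planted_hubs must lie in [1, n_nodes]")
  }
  if (!is.null(node_names)) {
    node_names <- normalize_symbols(node_names)
    if (length(node_names) != n_nodes) {
      stop("node_names must supply exactly n_nodes unique names")
    }
  }
  with_seed(seed, {
    if (is.null(node_names)) {
      hubs <- sprintf("HUB%03d", seq_len(n_planted_hubs))
      others <- if (n_nodes > n_planted_hubs) {
        sprintf("NODE%04d", seq_len(n_nodes - n_planted_hubs))
      } else character(0)
    } else {
      shuffled <- sample(node_names)
      hubs <- shuffled[seq_len(n_planted_hubs)]
      others <- shuffled[-seq_len(n_planted_hubs)]
    }
    nodes <- c(hubs, others)
    deg <- stats::setNames(integer(n_nodes), nodes)
    from <- character(0); to <- character(0)
    if (n_planted_hubs > 1L) {
      clique <- utils::combn(hubs, 2L)
      from <- clique[1L, ]; to <- clique[2L, ]
      deg[hubs] <- n_planted_hubs - 1L
    }
    for (i in seq_along(others)) {
      existing <- seq_len(n_planted_hubs + i - 1L)
      m <- min(m_attach, length(existing))
      targets <- sample(nodes[existing], m,
                        prob = deg[existing] + 1)
      from <- c(from, rep(others[i], m)); to <- c(to, targets)
      deg[targets] <- deg[targets] + 1L
      deg[others[i]] <- m
    }
    edges <- data.frame(protein1 = from, protein2 = to,
                        combined_score = sample(400:999, length(from),
                                                replace = TRUE),
                        stringsAsFactors = FALSE)
    list(network = interaction_network(edges, nodes = nodes),
         truth = list(hubs = gene_set(hubs, "planted_hubs")))
  })
}
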