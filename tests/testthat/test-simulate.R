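test_that("generators are pure functions of their seed", {
  s1 <- simulate_cohorts(multi_cohort_spec(genes = 200, n_core = 20,
                                           n_cd_only = 10, n_other_only = 20,
                                           seed = 5))
  s2 <- simulate_cohorts(multi_cohort_spec(genes = 200, n_core = 20,
                                           n_cd_only = 10, n_other_only = 20,
                                           seed = 5))
  expect_identical(s1$cohorts$CD01$matrix, s2$cohorts$CD01$matrix)
  expect_identical(s1$truth$core$genes, s2$truth$core$genes)

  p1 <- simulate_paired_counts(paired_biopsy_spec(seed = 8))
  p2 <- simulate_paired_counts(paired_biopsy_spec(seed = 8))
  expect_identical(p1$counts, p2$counts)

  n1 <- simulate_scale_free_network(50, 2, 5, seed = 2)
  n2 <- simulate_scale_free_network(50, 2, 5, seed = 2)
  expect_identical(as.data.frame(n1$network), as.data.frame(n2$network))
})

test_that("full-carriage strong effects survive the strictest k-of-n filter", {
  sim <- simulate_cohorts(multi_cohort_spec(genes = 1000, n_core = 50,
                                            n_cd_only = 30, n_other_only = 60,
                                            detect_prob = 1, effect_size = 3,
                                            seed = 19))
  cd <- sim$cohorts[vapply(sim$cohorts, `[[`, "", "pool") == "CD"]
  sets <- lapply(names(cd), function(nm) {
    significant_genes(de_analysis(cd[[nm]]$matrix, cd[[nm]]$group1,
                                  cd[[nm]]$group2), name = nm)
  })
  names(sets) <- names(cd)
  universe <- rownames(cd[[1]]$matrix)
  pool <- k_of_n_filter(membership_matrix(sets, universe),
                        combination_scheme(9, 9))
  expect_gte(mean(sim$truth$core$genes %in% pool$genes), 0.99)
})

test_that("a zero effect size leaves only false positives", {
  sim <- simulate_cohorts(multi_cohort_spec(genes = 500, n_core = 30,
                                            n_cd_only = 10, n_other_only = 20,
                                            effect_size = 0, seed = 23))
  co <- sim$cohorts$CD01
  res <- de_analysis(co$matrix, co$group1, co$group2)
  expect_lt(mean(res$significant), 0.08)
})

test_that("paired counts respect the design and the planted factor", {
  sim <- simulate_paired_counts(paired_biopsy_spec(seed = 31))
  ann <- sim$annotation
  expect_equal(nrow(ann), 44L)
  expect_equal(sum(ann$condition == "CD"), 14L)
  expect_true(all(table(ann$patient_id) == 2L))
  expect_true(all(sim$counts == round(sim$counts)) && all(sim$counts >= 0))
  expect_length(sim$truth$module$genes, 112L)
  expect_true(all(sim$truth$module$genes %in%
                  sim$truth$signature_universe$genes))

  # the latent factor is elevated exactly in the planted stratum
  active <- ann$tissue == "ILEAL" & ann$condition == "CD"
  expect_gt(mean(sim$truth$factor[active]), 1)
  expect_lt(abs(mean(sim$truth$factor[!active])), 0.5)
})

test_that("zero loading leaves no recoverable module", {
  sim <- simulate_paired_counts(paired_biopsy_spec(factor_loading = 0,
                                                   seed = 37))
  norm <- log_normalize(sim$counts)[sim$truth$signature_universe$genes, ]
  res <- suppressWarnings(find_modules(norm))
  jac <- function(m) {
    length(intersect(m$genes, sim$truth$module$genes)) /
      length(union(m$genes, sim$truth$module$genes))
  }
  if (length(res$modules)) {
    expect_lt(max(vapply(res$modules, jac, 1)), 0.3)
  } else {
    succeed()
  }
})

test_that("vanishing dispersion approaches Poisson moments", {
  spec <- paired_biopsy_spec(nb_dispersion = 0, depth_range = c(1, 1),
                             patient_sd = 0, factor_loading = 0,
                             base_mean = 50, seed = 41)
  sim <- simulate_paired_counts(spec)
  # per gene, variance/mean should hover near 1 for Poisson counts
  vm <- apply(sim$counts, 1, var) / rowMeans(sim$counts)
  expect_lt(abs(median(vm) - 1), 0.1)
})

test_that("preferential attachment produces the expected edge counts", {
  tree <- simulate_scale_free_network(10, m_attach = 1, n_planted_hubs = 2,
                                      seed = 3)
  expect_equal(nrow(tree$network), 9L)  # a tree on 10 nodes
  expect_length(attr(tree$network, "nodes"), 10L)

  net <- simulate_scale_free_network(100, m_attach = 3, n_planted_hubs = 4,
                                     seed = 9)
  expect_equal(nrow(net$network), choose(4, 2) + 96 * 3)
  expect_true(all(net$network$combined_score >= 400 &
                  net$network$combined_score <= 999))
})
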