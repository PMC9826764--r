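test_that("group stats match hand-computed pooled variance", {
  m <- toy_matrix(c(1, 3, 2, 4,
                    5, 5, 5, 5), c("g1", "g2"),
                  c("a1", "a2", "b1", "b2"))
  st <- fit_group_stats(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(unname(st$diff["g1"]), -1)
  expect_equal(unname(st$s_sq["g1"]), 2)  # pooled: (2 + 2) / 2
  expect_equal(st$d_g, 2L)
  # identical values in both groups
  expect_equal(unname(st$diff["g2"]), 0)
  expect_equal(unname(st$s_sq["g2"]), 0)

  expect_error(fit_group_stats(m, "a1", c("b1", "b2")),
               "insufficient replication")
  counts <- m; attr(counts, "mode") <- "counts"
  expect_error(fit_group_stats(counts, c("a1", "a2"), c("b1", "b2")),
               "intensity")
})

test_that("prior estimation recovers planted hyperparameters and degenerate cases", {
  set.seed(402)
  n <- 1e4; d0 <- 4; s0 <- 1; dg <- 4
  sigma2 <- d0 * s0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, dg) / dg
  pr <- estimate_prior(s2, dg)
  expect_gt(pr$d0, 3); expect_lt(pr$d0, 5)
  expect_gt(pr$s0_sq, 0.8); expect_lt(pr$s0_sq, 1.2)

  # all variances equal: no excess spread, infinite prior df
  pr_flat <- estimate_prior(rep(2, 50), 4)
  expect_true(is.infinite(pr_flat$d0))
  expect_equal(pr_flat$s0_sq, 2 * exp(log(2) - digamma(2)), tolerance = 1e-8)

  expect_error(estimate_prior(rep(0, 50), 4), "degenerate variances")
})

test_that("prior estimation agrees with the limma moment estimator", {
  skip_if_not_installed("limma")
  set.seed(91)
  s2 <- 0.8 * rf(5000, 6, 5)
  pr <- estimate_prior(s2, 6)
  sq <- limma::squeezeVar(s2, 6)
  expect_equal(pr$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(pr$s0_sq, sq$var.prior, tolerance = 1e-6)
})

test_that("d0 = 0 collapses to the ordinary pooled t-test", {
  set.seed(7)
  for (rep in 1:20) {
    toy <- random_toy_de(15, 3, 4)
    st <- fit_group_stats(toy$matrix, toy$group1, toy$group2)
    res <- moderated_t(st, structure(list(d0 = 0, s0_sq = 1),
                                     class = "moderated_t_params"))
    oracle <- vapply(rownames(toy$matrix), function(g) {
      stats::t.test(toy$matrix[g, toy$group1], toy$matrix[g, toy$group2],
                    var.equal = TRUE)$p.value
    }, numeric(1))
    expect_equal(res$p, unname(oracle), tolerance = 1e-10)
  }
})

test_that("d0 = Inf gives the pooled normal limit", {
  toy <- random_toy_de(10, 3, 3)
  st <- fit_group_stats(toy$matrix, toy$group1, toy$group2)
  res <- moderated_t(st, structure(list(d0 = Inf, s0_sq = 0.5),
                                   class = "moderated_t_params"))
  expect_equal(res$t_mod, unname(st$diff / sqrt(0.5 * (1 / 3 + 1 / 3))),
               tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(res$t_mod)), tolerance = 1e-12)
})

test_that("moderated pipeline matches limma eBayes end to end", {
  skip_if_not_installed("limma")
  set.seed(11)
  toy <- random_toy_de(2000, 5, 5)
  toy$matrix[1:50, toy$group1] <- toy$matrix[1:50, toy$group1] + 1.5
  res <- de_analysis(toy$matrix, toy$group1, toy$group2)
  design <- cbind(1, colnames(toy$matrix) %in% toy$group1)
  fit <- limma::eBayes(limma::lmFit(toy$matrix, design))
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("null p-values are calibrated and approximately uniform", {
  set.seed(500)
  m <- matrix(rnorm(1e4 * 12), 1e4, 12,
              dimnames = list(sprintf("g%05d", 1:1e4),
                              sprintf("s%02d", 1:12)))
  attr(m, "mode") <- "intensity"
  res <- de_analysis(m, 1:6, 7:12)
  expect_gt(mean(res$p < 0.05), 0.04)
  expect_lt(mean(res$p < 0.05), 0.06)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("shrinkage and monotonicity invariants hold", {
  set.seed(13)
  toy <- random_toy_de(500, 4, 4)
  # heteroskedastic genes so the fitted prior has finite df
  toy$matrix <- toy$matrix * sqrt(4 / rchisq(500, 4))
  st <- fit_group_stats(toy$matrix, toy$group1, toy$group2)
  pr <- estimate_prior(st$s_sq, st$d_g)
  expect_true(is.finite(pr$d0))
  s_tilde <- (pr$d0 * pr$s0_sq + st$d_g * st$s_sq) / (pr$d0 + st$d_g)
  lower <- pmin(st$s_sq, pr$s0_sq); upper <- pmax(st$s_sq, pr$s0_sq)
  expect_true(all(s_tilde >= lower - 1e-12 & s_tilde <= upper + 1e-12))

  # |t| increases with |diff| at fixed variance; p decreases in |t|
  st2 <- list(diff = c(a = 0.5, b = 1, c = 2), s_sq = rep(1, 3), d_g = 6,
              n1 = 4, n2 = 4)
  res <- moderated_t(st2, pr)
  expect_true(all(diff(abs(res$t_mod)) > 0))
  expect_true(all(diff(res$p) < 0))
})

test_that("significant_genes respects the threshold and planted effects are found", {
  set.seed(21)
  n_genes <- 1000
  samples <- c(paste0("c", 1:10), paste0("t", 1:10))
  m <- matrix(rnorm(n_genes * 20, sd = 0.5), n_genes, 20,
              dimnames = list(sprintf("G%04d", 1:n_genes), samples))
  m[1:100, 1:10] <- m[1:100, 1:10] + 2  # |log_fc| = 2, sigma = 0.5
  attr(m, "mode") <- "intensity"
  res <- de_analysis(m, samples[1:10], samples[11:20])
  hits <- significant_genes(res, name = "cohort1")
  expect_gte(mean(sprintf("G%04d", 1:100) %in% hits$genes), 0.95)

  res_none <- res; res_none$significant <- res_none$p < 1e-300
  expect_length(significant_genes(res_none)$genes, 0L)
  res_all <- res; res_all$significant <- res_all$p < 1 - 1e-12
  expect_length(significant_genes(res_all)$genes, n_genes)
})
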