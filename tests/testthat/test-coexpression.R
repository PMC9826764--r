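test_that("correlation matrix handles duplicates, negation and the null", {
  set.seed(61)
  m <- matrix(rnorm(5 * 10), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  m[2, ] <- m[1, ]       # duplicate gene
  m[3, ] <- -m[1, ]      # negated gene
  r <- correlation_matrix(m)
  expect_equal(r["g1", "g2"], 1)
  expect_equal(r["g1", "g3"], -1)
  expect_true(isSymmetric(r))
  expect_true(all(diag(r) == 1))

  expect_error(correlation_matrix(m[, 1:3]), "4 samples")
  m0 <- m; m0[4, ] <- 7
  expect_warning(correlation_matrix(m0), "zero-variance")

  # independent noise at n = 50: off-diagonals stay inside the 3-sigma band
  noise <- matrix(rnorm(30 * 50), 30, 50,
                  dimnames = list(paste0("g", 1:30), paste0("s", 1:50)))
  rn <- correlation_matrix(noise)
  expect_lt(max(abs(rn[upper.tri(rn)])), 0.4)
})

test_that("TOM matches brute-force evaluation of the formula", {
  brute_tom <- function(a) {
    n <- nrow(a)
    tom <- diag(n)
    k <- rowSums(a) - 1
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      shared <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
      tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    tom
  }
  set.seed(8)
  a <- matrix(runif(36), 6, 6)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  expect_equal(unname(adjacency_to_tom(a)), brute_tom(a), tolerance = 1e-12)

  # two genes adjacent only to each other with full weight
  a2 <- diag(2); a2[1, 2] <- a2[2, 1] <- 1
  expect_equal(adjacency_to_tom(a2)[1, 2], 1)
  # disconnected genes with no shared neighbors
  a3 <- diag(4)
  expect_equal(adjacency_to_tom(a3)[1, 2], 0)
  # range and symmetry on a random case
  tom <- adjacency_to_tom(a)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_true(isSymmetric(tom))
})

test_that("soft threshold selection prefers scale-free fits and is monotone", {
  # latent hub-factor structure: a few hubs drive many genes with graded
  # strength, giving a heavy-tailed connectivity profile
  sim <- with_seed(17, {
    n_genes <- 300; n_samples <- 60
    hubs <- matrix(rnorm(3 * n_samples), 3, n_samples)
    strength <- rbeta(n_genes, 0.6, 1.8)
    which_hub <- sample(1:3, n_genes, replace = TRUE)
    t(vapply(seq_len(n_genes), function(g) {
      strength[g] * hubs[which_hub[g], ] +
        sqrt(1 - strength[g]^2) * rnorm(n_samples)
    }, numeric(n_samples)))
  })
  rownames(sim) <- sprintf("g%03d", seq_len(nrow(sim)))
  colnames(sim) <- sprintf("s%02d", seq_len(ncol(sim)))
  r <- correlation_matrix(sim)
  st <- select_soft_threshold(r, coexpression_config(), n_samples = 60)
  expect_gte(st$rsq, 0.8)

  # degenerate all-ones correlations fall back with a warning
  ones <- matrix(1, 30, 30)
  expect_warning(st_deg <- select_soft_threshold(ones), "falling back")
  expect_equal(st_deg$beta, 6L)

  # raising beta weakly decreases every off-diagonal adjacency
  a4 <- abs(r)^4; a5 <- abs(r)^5
  expect_true(all(a5 <= a4 + 1e-12))
})

test_that("planted two-block structure is recovered by clustering", {
  sim <- with_seed(29, {
    n <- 30
    f1 <- rnorm(n); f2 <- rnorm(n)
    block <- function(f, size, r) {
      t(vapply(seq_len(size), function(i) {
        sqrt(r) * f + sqrt(1 - r) * rnorm(n)
      }, numeric(n)))
    }
    rbind(block(f1, 40, 0.8), block(f2, 40, 0.8))
  })
  rownames(sim) <- sprintf("G%03d", 1:80)
  colnames(sim) <- sprintf("s%02d", 1:30)
  cfg <- coexpression_config()
  res <- find_modules(sim, cfg)
  expect_length(res$modules, 2L)
  truth1 <- rownames(sim)[1:40]; truth2 <- rownames(sim)[41:80]
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  best1 <- max(vapply(res$modules, function(m) jac(m$genes, truth1), 1))
  best2 <- max(vapply(res$modules, function(m) jac(m$genes, truth2), 1))
  expect_gte(best1, 0.9)
  expect_gte(best2, 0.9)

  # permutation of gene order leaves the partition invariant
  perm <- sample(nrow(sim))
  res_p <- find_modules(sim[perm, ], cfg)
  expect_equal(res_p$assignments[names(res$assignments)], res$assignments)

  # min_module_size larger than the gene count: everything unassigned
  expect_warning(
    tiny <- cluster_modules(res$tom[1:10, 1:10],
                            coexpression_config(min_module_size = 50)),
    "unassigned")
  expect_true(all(tiny == "unassigned"))
})

test_that("module eigengene tracks the latent factor", {
  sim <- with_seed(41, {
    n <- 40
    f <- rnorm(n)
    x <- t(vapply(1:30, function(i) 0.9 * f + 0.3 * rnorm(n), numeric(n)))
    rownames(x) <- paste0("g", 1:30)
    colnames(x) <- paste0("s", 1:n)
    list(x = x, f = f)
  })
  assignments <- setNames(rep("M1", 30), rownames(sim$x))
  eg <- module_eigengene(sim$x, assignments, "M1")
  expect_gte(cor(eg, sim$f), 0.95)

  # single-gene module: eigengene is the standardized profile
  one <- setNames("M1", "g1")
  eg1 <- module_eigengene(sim$x, one, "M1")
  expect_equal(abs(cor(eg1, sim$x["g1", ])), 1, tolerance = 1e-12)

  # duplicated gene gives the same eigengene up to the sign convention
  two <- setNames(c("M1", "M1"), c("g1", "g2"))
  x2 <- sim$x; x2["g2", ] <- x2["g1", ]
  eg2 <- module_eigengene(x2, two, "M1")
  expect_equal(abs(cor(eg1, eg2)), 1, tolerance = 1e-12)
})
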