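test_that("combination enumeration matches the design counts", {
  expect_length(enumerate_combinations(combination_scheme(9, 7)), 46L)
  expect_length(enumerate_combinations(combination_scheme(5, 4)), 6L)
  expect_length(enumerate_combinations(combination_scheme(3, 3)), 1L)
  combos <- enumerate_combinations(combination_scheme(4, 2))
  expect_false(any(duplicated(vapply(combos, paste, "", collapse = ","))))
  expect_error(combination_scheme(5, 6), "min_k")
})

test_that("k-of-n filter implements threshold semantics", {
  sets <- lapply(1:9, function(i) paste0("G", 1:20))
  names(sets) <- paste0("c", 1:9)
  m <- membership_matrix(sets)
  m["G1", 8:9] <- FALSE   # present in 7 of 9
  m["G2", 7:9] <- FALSE   # present in 6 of 9
  pool <- k_of_n_filter(m, combination_scheme(9, 7))
  expect_true("G1" %in% pool$genes)
  expect_false("G2" %in% pool$genes)
  # all-true membership keeps everything
  expect_length(k_of_n_filter(membership_matrix(sets),
                              combination_scheme(9, 7))$genes, 20L)
})

test_that("row-sum filter equals the brute-force subset-union oracle", {
  brute_force_pool <- function(membership, scheme) {
    combos <- enumerate_combinations(scheme)
    hits <- unlist(lapply(combos, function(cols) {
      rownames(membership)[rowSums(membership[, cols, drop = FALSE]) ==
                             length(cols)]
    }))
    sort(unique(hits))
  }
  set.seed(33)
  for (rep in 1:5) {
    m <- matrix(runif(50 * 9) < 0.6, 50, 9,
                dimnames = list(sprintf("G%02d", 1:50), paste0("c", 1:9)))
    scheme <- combination_scheme(9, 7)
    expect_setequal(k_of_n_filter(m, scheme)$genes, brute_force_pool(m, scheme))
  }
  # k = n is the plain intersection, k = 1 the union
  m <- matrix(runif(30 * 4) < 0.5, 30, 4,
              dimnames = list(sprintf("G%02d", 1:30), paste0("c", 1:4)))
  expect_setequal(k_of_n_filter(m, combination_scheme(4, 4))$genes,
                  rownames(m)[rowSums(m) == 4])
  expect_setequal(k_of_n_filter(m, combination_scheme(4, 1))$genes,
                  rownames(m)[rowSums(m) >= 1])
})

test_that("two-set exact test equals the hypergeometric tail", {
  st <- exact_intersection_test(c(672, 5271), 241, 20000)
  oracle <- phyper(240, 672, 20000 - 672, 5271, lower.tail = FALSE)
  expect_equal(st$p_value, oracle, tolerance = 1e-12)
  expect_equal(st$expected, 20000 * (672 / 20000) * (5271 / 20000))
  expect_equal(sum(st$distribution), 1, tolerance = 1e-9)
})

test_that("degenerate and invariance properties of the exact distribution", {
  # all sets equal to the background: intersection is N with certainty
  st <- exact_intersection_test(c(30, 30, 30), 30, 30)
  expect_equal(st$p_value, 1)
  expect_equal(unname(st$distribution["30"]), 1)

  # permutation invariance of the set order
  d1 <- exact_intersection_test(c(10, 12, 15), 4, 30)$distribution
  d2 <- exact_intersection_test(c(15, 10, 12), 4, 30)$distribution
  expect_equal(unname(d1), unname(d2[seq_along(d1)]), tolerance = 1e-12)

  # p monotone non-increasing in the observed overlap
  ps <- vapply(0:10, function(x) {
    exact_intersection_test(c(10, 12, 15), x, 30)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))

  # distribution sums to one across configurations
  for (cfg in list(list(c(5, 5), 20), list(c(10, 12, 15), 30),
                   list(c(100, 200, 150, 120), 1000))) {
    st <- exact_intersection_test(cfg[[1]], 0, cfg[[2]])
    expect_equal(sum(st$distribution), 1, tolerance = 1e-9)
  }
})

test_that("three-set exact test agrees with the Monte-Carlo oracle", {
  st <- exact_intersection_test(c(10, 12, 15), 4, 30)
  mc <- mc_intersection_oracle(c(10, 12, 15), 30, draws = 1e5, seed = 104)
  p_mc <- sum(mc[as.integer(names(mc)) >= 4])
  se <- sqrt(p_mc * (1 - p_mc) / 1e5)
  expect_lt(abs(st$p_value - p_mc), 3 * se)
})

test_that("Monte-Carlo oracle is reproducible and exact in the trivial case", {
  mc1 <- mc_intersection_oracle(c(8, 9), 20, draws = 1e3, seed = 5)
  mc2 <- mc_intersection_oracle(c(8, 9), 20, draws = 1e3, seed = 5)
  expect_identical(mc1, mc2)
  mc_full <- mc_intersection_oracle(c(20, 20), 20, draws = 1e3, seed = 5)
  expect_equal(unname(mc_full["20"]), 1)
})

test_that("fold enrichment of independent random sets centers at 1", {
  set.seed(77)
  N <- 500
  folds <- replicate(200, {
    a <- sample.int(N, 60); b <- sample.int(N, 80)
    obs <- length(intersect(a, b))
    exact_intersection_test(c(60, 80), obs, N)$fold_enrichment
  })
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 1), 3 * se + 1e-9)
})

test_that("build_signature intersects pools and validates the background", {
  a <- gene_set(paste0("g", 1:10), "a")
  res <- build_signature(a, a, background_n = 50)
  expect_setequal(res$fibsig$genes, a$genes)
  expect_equal(res$stats$fold_enrichment, 50 / 10)

  b <- gene_set(paste0("h", 1:10), "b")
  res2 <- build_signature(a, b, background_n = 100)
  expect_length(res2$fibsig$genes, 0L)
  expect_equal(res2$stats$p_value, 1)

  expect_error(build_signature(a, b, background_n = 15), "smaller")
})
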