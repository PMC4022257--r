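test_that("equal-width bins partition the observed range", {
  b <- make_bins(c(0, 0.2, 0.9, 1), M = 2)
  expect_equal(b$edges, c(0, 0.5, 1))
  expect_error(make_bins(rep(2, 5), 3), "constant")

  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1))
    M <- sample(1:6, 1)
    idx <- bin_index(x, make_bins(x, M))
    expect_true(all(idx >= 1 & idx <= M))       # every sample in exactly one bin
    expect_equal(length(idx), length(x))
  }
  xc <- c(1, 2, 3, 9)
  expect_equal(bin_index(xc, make_bins(xc, 1)), rep(1L, 4))
})

test_that("binned entropy evaluates the plug-in formula", {
  expect_equal(bin_entropy(c(5, 5.01, 5.02), M = 1), 0)
  expect_equal(bin_entropy(c(0, 0, 1, 1), M = 2), log(2))
  expect_equal(bin_entropy(c(0, 0.1, 0.2, 1), M = 2),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_equal(bin_entropy(c(0, 0, 1, 1), M = 2, base = 2), 1)
})

test_that("mutual information matches the brute-force contingency oracle", {
  expect_equal(mutual_information(c(1, 1, 2, 2), c(5, 5, 9, 9), M = 2), log(2))
  set.seed(12)
  for (i in 1:200) {
    S <- sample(4:20, 1)
    M <- sample(2:4, 1)
    x <- rnorm(S)
    y <- if (runif(1) < 0.5) rnorm(S) else x + rnorm(S, sd = 0.3)
    expect_equal(mutual_information(x, y, M), oracle_mi(x, y, M),
                 tolerance = 1e-12)
    expect_equal(bin_entropy(x, M = M),
                 oracle_entropy(oracle_bin_counts(x, M), S), tolerance = 1e-12)
    # symmetry and nonnegativity
    expect_equal(mutual_information(x, y, M), mutual_information(y, x, M),
                 tolerance = 1e-12)
    expect_gte(mutual_information(x, y, M), 0)
  }
})

test_that("MI of a variable with itself is its entropy; affine invariance holds", {
  set.seed(3)
  x <- rnorm(18)
  for (M in 2:4) {
    expect_equal(mutual_information(x, x, M), bin_entropy(x, M = M))
    y <- rnorm(18)
    expect_equal(mutual_information(3.7 * x + 11, y, M),
                 mutual_information(x, y, M), tolerance = 1e-12)
  }
})

test_that("permutation p-values use the add-one rule and are reproducible", {
  set.seed(6)
  x <- sort(rnorm(20))
  y <- x + rnorm(20, sd = 0.05)   # strong dependence
  r1 <- permutation_pvalue(x, y, M = 4, n_perm = 99, seed = 10)
  r2 <- permutation_pvalue(x, y, M = 4, n_perm = 99, seed = 10)
  expect_equal(r1, r2)
  expect_gte(r1$p_value, 1 / 100)
  expect_equal(r1$p_value, 0.01)  # obs exceeds all 99 null draws
  expect_equal(r1$I, mutual_information(x, y, M = 4))
  expect_error(permutation_pvalue(x, y, n_perm = 0), "n_perm")
})

test_that("permutation p-values are super-uniform under independence", {
  set.seed(21)
  pvals <- replicate(400, {
    permutation_pvalue(rnorm(15), rnorm(15), M = 4, n_perm = 49,
                       seed = sample.int(2^31 - 1, 1))$p_value
  })
  # P(p <= a) <= a for every a; check a grid with a one-sided binomial bound
  for (a in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / 400))
  }
})

test_that("network assembly applies the per-pair-type thresholds", {
  set.seed(30)
  sim <- simulate_abundance(n_otu = 6, n_env = 3, S = 24,
                            n_linked_pairs = 2, link_strength = 0.99, seed = 30)
  mat <- zero_mean_normalize(sim$matrix)
  net <- build_network(mat, n_perm = 200, seed = 5)
  expect_s3_class(net, "assoc_network")
  # planted pairs are recovered as edges
  found <- paste(pmin(net$edges$node_a, net$edges$node_b),
                 pmax(net$edges$node_a, net$edges$node_b))
  planted <- paste(pmin(sim$linked_pairs$a, sim$linked_pairs$b),
                   pmax(sim$linked_pairs$a, sim$linked_pairs$b))
  expect_true(all(planted %in% found))
  tests <- attr(net, "tests")
  kept <- ifelse(tests$pair_type == "env-env", tests$p_value <= 0.05,
                 tests$p_value <= 0.01)
  expect_equal(nrow(net$edges), sum(kept))

  # alpha = 1 keeps every testable pair
  full <- build_network(mat, n_perm = 20, alpha_otu = 1, alpha_env = 1, seed = 5)
  expect_equal(nrow(full$edges), choose(nrow(mat), 2))
})

test_that("duplicated variables always yield a maximal-MI edge", {
  set.seed(9)
  x <- rnorm(20)
  mat <- abundance_tibble(rbind(a = x, b = x, c = rnorm(20)),
                          rep("OTU", 3))
  names(mat)[-(1:2)] <- paste0("s", 1:20)
  net <- build_network(mat, M = 4, n_perm = 99, seed = 2)
  ab <- net$edges[net$edges$node_a == "a" & net$edges$node_b == "b", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$weight, bin_entropy(x, M = 4))
  expect_equal(ab$p_value, 0.01)
})

test_that("the network is invariant to variable ordering", {
  set.seed(14)
  sim <- simulate_abundance(n_otu = 5, n_env = 2, S = 18,
                            n_linked_pairs = 1, seed = 14)
  mat <- sim$matrix
  net1 <- build_network(mat, n_perm = 99, seed = 3)
  net2 <- build_network(mat[sample(nrow(mat)), ], n_perm = 99, seed = 3)
  ord <- sort(net1$nodes$node)
  expect_equal(adjacency_matrix(net2)[ord, ord], adjacency_matrix(net1)[ord, ord])
  e1 <- dplyr::arrange(net1$edges, .data$node_a, .data$node_b)
  e2 <- dplyr::arrange(net2$edges, .data$node_a, .data$node_b)
  expect_equal(e1, e2)
})

test_that("under the null the retained edge count tracks the alpha levels", {
  sim <- simulate_abundance(n_otu = 12, n_env = 0, S = 20,
                            n_linked_pairs = 0, seed = 77)
  net <- build_network(sim$matrix, M = 4, n_perm = 99, alpha_otu = 0.05,
                       seed = 8)
  n_pairs <- choose(12, 2)
  # expected ~ alpha * pairs; generous binomial band
  expect_lte(nrow(net$edges), qbinom(0.999, n_pairs, 0.05) + 1)
})
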