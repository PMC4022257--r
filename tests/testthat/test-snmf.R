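test_that("feature matrix modes return the documented constructions", {
  net <- fixture_barbell()
  A <- adjacency_matrix(net)
  expect_equal(feature_matrix(net), A)

  O <- feature_matrix(net, "row-normalized")
  expect_equal(O, t(O))
  expect_true(all(O >= 0))
  d <- rowSums(A)
  expect_equal(O, A * ((1 / sqrt(d)) %o% (1 / sqrt(d))), ignore_attr = TRUE)

  # 2-node single edge: normalized off-diagonal is exactly 1
  A2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  net2 <- network_from_adjacency(A2)
  expect_equal(feature_matrix(net2, "row-normalized")["a", "b"], 1)

  # isolated node breaks row normalization
  net3 <- assoc_network(tibble::tibble(node = c("a", "b", "c"),
                                       type = "OTU"),
                        tibble::tibble(node_a = "a", node_b = "b",
                                       weight = 1, p_value = NA_real_))
  expect_error(feature_matrix(net3, "row-normalized"), "isolated")
})

test_that("the multiplicative update keeps W nonnegative and F_G non-increasing", {
  set.seed(40)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    X <- matrix(runif(n * n), n, n)
    O <- (X + t(X)) / 2
    fit <- snmf_factorize(O, r = sample(2:4, 1), max_iter = 200, tol = 0,
                          seed = i)
    expect_true(all(fit$W >= 0))
    expect_true(all(diff(fit$F_trace) <= 1e-12))
  }
})

test_that("a planted exact factorization is recovered to near-zero objective", {
  Wstar <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  O <- t(Wstar) %*% Wstar
  best <- min(vapply(1:10, function(s) {
    snmf_factorize(O, 2, max_iter = 3000, tol = 1e-14, seed = s)$F_G
  }, numeric(1)))
  expect_lt(best, 1e-8)
})

test_that("larger r never fits worse on a fixed feature matrix", {
  net <- fixture_barbell()
  O <- feature_matrix(net)
  f_at <- function(r) min(vapply(1:6, function(s) {
    snmf_factorize(O, r, max_iter = 2000, tol = 1e-12, seed = s)$F_G
  }, numeric(1)))
  expect_lte(f_at(nrow(O)), f_at(1) + 1e-9)

  expect_error(snmf_factorize(O, nrow(O) + 1, seed = 1), "r must be")
  expect_error(snmf_factorize(matrix(runif(9), 3, 3), 2, seed = 1), "symmetric")
})

test_that("membership normalizes columns and flags empty ones", {
  W <- matrix(c(2, 2, 0, 3, 0, 0), 2, 3)
  expect_warning(U <- membership(W), "all-zero")
  expect_equal(colSums(U), rep(1, 3))
  expect_equal(U[, 1], c(0.5, 0.5))
  expect_equal(U[, 3], c(0.5, 0.5))
  expect_equal(attr(U, "flagged"), 3L)

  # already column-stochastic W is a fixed point
  Ws <- matrix(c(0.3, 0.7, 1, 0), 2, 2)
  expect_equal(membership(Ws), Ws, ignore_attr = TRUE)
})

test_that("hard assignment takes the column argmax with first-index ties", {
  U <- matrix(c(0.7, 0.3,
                0.5, 0.5,
                0, 1), 2, 3)
  expect_equal(hard_assign(U), c(1L, 1L, 2L))
  onehot <- one_hot(c(2L, 1L, 2L))
  expect_equal(hard_assign(onehot), c(2L, 1L, 2L))
})

test_that("fuzzy modularity reduces to Newman modularity for one-hot memberships", {
  # all nodes in one community -> 0
  net <- fixture_barbell()
  expect_equal(fuzzy_modularity(net, matrix(1, 1, 6)), 0)

  # two disconnected equal cliques -> exactly 1/2
  A <- matrix(0, 8, 8, dimnames = list(paste0("n", 1:8), paste0("n", 1:8)))
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  cl2 <- network_from_adjacency(A)
  U2 <- one_hot(rep(1:2, each = 4))
  expect_equal(fuzzy_modularity(cl2, U2), 0.5)

  # random weighted graphs: equality with the community-sum oracle over all
  # partitions
  set.seed(50)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    X <- matrix(rbinom(n * n, 1, 0.6) * runif(n * n, 0.5, 1.5), n, n)
    A <- X * upper.tri(X); A <- A + t(A)
    if (sum(A) == 0) next
    dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
    g <- network_from_adjacency(A)
    for (labels in all_partitions(n)) {
      expect_equal(fuzzy_modularity(g, one_hot(labels)),
                   oracle_newman_modularity(A, labels), tolerance = 1e-12)
    }
  }
})

test_that("model selection picks the planted community count", {
  # two disconnected cliques: r = 2 with Q_f ~ 1/2
  A <- matrix(0, 10, 10, dimnames = list(paste0("n", 1:10), paste0("n", 1:10)))
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1; diag(A) <- 0
  net <- network_from_adjacency(A)
  m <- detect_communities(net, r_min = 2, r_max = 4, restarts = 8, seed = 2)
  expect_equal(m$r, 2)
  expect_equal(m$Q_f, 0.5, tolerance = 1e-3)
  expect_equal(sort(unname(tapply(names(m$labels), m$labels, length))),
               c(5, 5))

  # a single clique has no community structure: Q_f <= 0 for every r, but a
  # model is still returned
  K <- matrix(1, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  diag(K) <- 0
  kn <- network_from_adjacency(K)
  mk <- detect_communities(kn, r_min = 2, r_max = 4, restarts = 5, seed = 3)
  expect_true(all(mk$selection$Q_f <= 1e-8))
  expect_s3_class(mk, "community_model")

  expect_error(detect_communities(net, r_min = 5, r_max = 3), "r_min")
})

test_that("detection is deterministic in the seed and invariant to node order", {
  pg <- planted_graph(c(8, 8), p_in = 0.9, p_out = 0.05, seed = 6)
  m1 <- detect_communities(pg$network, r_min = 2, r_max = 3, restarts = 5, seed = 9)
  m2 <- detect_communities(pg$network, r_min = 2, r_max = 3, restarts = 5, seed = 9)
  expect_equal(m1$labels, m2$labels)
  expect_equal(m1$Q_f, m2$Q_f)
})

test_that("tidy and glance expose the fuzzy and hard views", {
  net <- fixture_barbell()
  m <- detect_communities(net, r_min = 2, r_max = 3, restarts = 4, seed = 1)
  td <- tidy(m)
  expect_equal(nrow(td), m$r * 6)
  sums <- tapply(td$membership, td$node, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  gl <- glance(m)
  expect_equal(gl$r, m$r)
  expect_equal(gl$n_nodes, 6)
})
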