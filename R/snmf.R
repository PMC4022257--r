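#' Feature matrix of a network
#'
#' The node-node similarity matrix factorized by [snmf_factorize()]. By
#' default this is the weighted adjacency matrix A itself; the
#' `"row-normalized"` mode returns the symmetrically normalized
#' D^-1/2 A D^-1/2 with D the weighted-degree diagonal.
#'
#' @param net An [assoc_network] with at least one node.
#' @param mode `"adjacency"` (default) or `"row-normalized"`.
#' @return A symmetric nonnegative matrix with node dimnames.
#' @export
feature_matrix <- function(net, mode = c("adjacency", "row-normalized")) {
  mode <- match.arg(mode)
  A <- adjacency_matrix(net)
  if (nrow(A) == 0) abort("feature_matrix(): empty network")
  if (mode == "adjacency") return(A)
  d <- rowSums(A)
  if (any(d == 0)) {
    abort(sprintf(
      "isolated node(s) %s have zero degree; use mode = 'adjacency' or drop them",
      paste(head(rownames(A)[d == 0], 5), collapse = ", ")))
  }
  Dhalf <- 1 / sqrt(d)
  O <- A * (Dhalf %o% Dhalf)
  (O + t(O)) / 2
}

#' Symmetric nonnegative matrix factorization
#'
#' Minimizes F_G(O, W) = 1/2 ||O - W'W||_F^2 over nonnegative r x n
#' matrices W by the damped multiplicative update
#' W <- W * (1 - beta + beta (W O) / (W W' W)), elementwise. `beta = 1`
#' gives the plain multiplicative rule; the default `beta = 0.5` shares its
#' fixed points and keeps the objective non-increasing at every step. The
#' denominator is guarded by a machine-epsilon constant so 0/0 never occurs.
#'
#' W is initialized elementwise uniform on (0, 1) scaled by
#' `sqrt(mean(O)/r)` so that W'W matches O's magnitude at the start.
#'
#' @param O Symmetric nonnegative feature matrix (n x n).
#' @param r Number of cliques/communities, 1 <= r <= n.
#' @param max_iter Iteration cap (default 500).
#' @param tol Stop when the relative decrease of F_G falls below this
#'   (default 1e-6).
#' @param seed Integer seed for the random initialization.
#' @param beta Damping in (0, 1]; 1 recovers the undamped rule.
#' @return A list: `W` (r x n), `F_G` (final objective), `n_iter`,
#'   `F_trace` (objective after each iteration).
#' @export
snmf_factorize <- function(O, r, max_iter = 500, tol = 1e-6, seed = 1,
                           beta = 0.5) {
  if (!is.matrix(O) || nrow(O) != ncol(O)) abort("O must be square")
  n <- nrow(O)
  if (max(abs(O - t(O))) > 1e-8) abort("O must be symmetric")
  if (any(O < 0)) abort("O must be nonnegative")
  if (r < 1 || r > n) abort(sprintf("r must be in [1, %d]", n))
  if (beta <= 0 || beta > 1) abort("beta must be in (0, 1]")
  eps <- .Machine$double.eps
  scale0 <- sqrt(max(mean(O), eps) / r)
  W <- withr::with_seed(seed, matrix(runif(r * n), r, n) * scale0)
  fg <- function(W) 0.5 * sum((O - crossprod(W))^2)
  f_prev <- fg(W)
  trace <- numeric(0)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    WO <- W %*% O
    WWtW <- (W %*% t(W)) %*% W
    W <- W * (1 - beta + beta * WO / (WWtW + eps))
    f_cur <- fg(W)
    trace[it] <- f_cur
    if (abs(f_prev - f_cur) < tol * max(f_prev, eps)) {
      f_prev <- f_cur
      break
    }
    f_prev <- f_cur
  }
  list(W = W, F_G = f_prev, n_iter = it, F_trace = trace)
}

#' Fuzzy membership matrix from a clique-node matrix
#'
#' Normalizes each column of W to sum 1; U[k, i] is node i's degree of
#' belonging to clique k. All-zero columns (nodes the factorization
#' attached to no clique) become uniform 1/r and are reported in the
#' `flagged` attribute.
#'
#' @param W Nonnegative r x n matrix.
#' @return Column-stochastic r x n matrix `U` with attribute `flagged`
#'   (indices of all-zero columns, if any).
#' @export
membership <- function(W) {
  if (any(W < 0)) abort("W must be nonnegative")
  cs <- colSums(W)
  zero <- which(cs == 0)
  cs[zero] <- 1
  U <- sweep(W, 2, cs, "/")
  if (length(zero)) {
    U[, zero] <- 1 / nrow(W)
    warn(sprintf("%d node(s) had all-zero membership; set to uniform", length(zero)))
  }
  attr(U, "flagged") <- zero
  U
}

#' Hard community labels from a fuzzy membership matrix
#'
#' Each node gets the clique with the largest membership in its column;
#' ties go to the smallest clique index.
#'
#' @param U Column-normalized membership matrix (r x n).
#' @return Integer vector of length n with labels in `1..r` (some labels
#'   may be unused).
#' @export
hard_assign <- function(U) {
  apply(U, 2, which.max)
}

#' Fuzzy modularity of a soft community assignment
#'
#' Q_f = (1 / 2I) * sum_ij (A_ij - k_i k_j / 2I) s_ij with soft
#' co-membership s_ij = sum_k U[k,i] U[k,j], weighted degrees
#' k_i = sum_j A_ij and total edge weight I = 1/2 sum_ij A_ij. For a
#' one-hot U this reduces to Newman modularity of the hard partition.
#'
#' @param net An [assoc_network] with at least one edge.
#' @param U Membership matrix whose columns follow `net$nodes$node` order.
#' @param weighted Use edge weights (default); `FALSE` binarizes A, for
#'   comparison with edge-count-based reports.
#' @return The modularity value.
#' @export
fuzzy_modularity <- function(net, U, weighted = TRUE) {
  A <- adjacency_matrix(net, weighted = weighted)
  if (sum(A) == 0) abort("fuzzy_modularity(): network has no edges")
  if (ncol(U) != nrow(A)) abort("U columns must match network nodes")
  k <- rowSums(A)
  twoI <- sum(A)
  S <- crossprod(U)  # s_ij
  B <- A - (k %o% k) / twoI
  sum(B * S) / twoI
}

#' Community detection by symmetric NMF with modularity selection
#'
#' For each candidate community count r in `[r_min, r_max]` runs `restarts`
#' seeded factorizations of the network's feature matrix, keeps the restart
#' with the lowest objective F_G, and scores its fuzzy membership with
#' [fuzzy_modularity()]. The returned model is the r with the highest Q_f
#' (ties: smaller r). Fully deterministic for a fixed seed.
#'
#' @param net An [assoc_network] with at least one edge.
#' @param r_min,r_max Candidate range; defaults 2 to `min(n, 20)`.
#' @param restarts Random restarts per r (default 10).
#' @param seed Integer seed.
#' @param mode Feature-matrix mode, see [feature_matrix()].
#' @param weighted Passed to [fuzzy_modularity()].
#' @param max_iter,tol,beta Passed to [snmf_factorize()].
#' @return An object of class `community_model`: list with `r`, `W`, `U`,
#'   `labels` (named by node), `Q_f`, `F_G`, `n_iter`, `nodes`, and
#'   `selection` (tibble of Q_f and F_G per candidate r).
#' @export
detect_communities <- function(net, r_min = 2,
                               r_max = min(nrow(net$nodes), 20),
                               restarts = 10, seed = 1,
                               mode = c("adjacency", "row-normalized"),
                               weighted = TRUE, max_iter = 500, tol = 1e-6,
                               beta = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "assoc_network"))
  n <- nrow(net$nodes)
  if (n == 1) r_min <- 1
  if (r_min > r_max) abort("r_min must be <= r_max")
  if (r_max > n) abort("r_max cannot exceed the node count")
  O <- feature_matrix(net, mode)
  best <- NULL
  sel <- list()
  for (r in seq(r_min, r_max)) {
    fit_r <- NULL
    for (s in seq_len(restarts)) {
      fit <- snmf_factorize(O, r, max_iter = max_iter, tol = tol,
                            seed = derive_seed(seed, r, s), beta = beta)
      if (is.null(fit_r) || fit$F_G < fit_r$F_G) fit_r <- fit
    }
    U <- suppressWarnings(membership(fit_r$W))
    qf <- fuzzy_modularity(net, U, weighted = weighted)
    sel[[length(sel) + 1]] <- tibble::tibble(r = r, Q_f = qf,
                                             F_G = fit_r$F_G,
                                             n_iter = fit_r$n_iter)
    if (is.null(best) || qf > best$Q_f) {
      best <- list(r = r, W = fit_r$W, U = U,
                   labels = setNames(hard_assign(U), net$nodes$node),
                   Q_f = qf, F_G = fit_r$F_G, n_iter = fit_r$n_iter)
    }
  }
  best$nodes <- net$nodes$node
  best$selection <- dplyr::bind_rows(sel)
  colnames(best$W) <- best$nodes
  colnames(best$U) <- best$nodes
  structure(best, class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("<community_model> r = %d communities over %d nodes, Q_f = %.4f (F_G = %.4g)\n",
              x$r, length(x$nodes), x$Q_f, x$F_G))
  invisible(x)
}

#' Tidy a community model into a node-by-community table
#'
#' @param x A [detect_communities()] model.
#' @param ... Unused.
#' @return A long tibble: `node`, `community`, `membership`, `hard_label`.
#' @export
tidy.community_model <- function(x, ...) {
  tibble::tibble(
    node = rep(x$nodes, each = x$r),
    community = rep(seq_len(x$r), times = length(x$nodes)),
    membership = as.vector(x$U),
    hard_label = rep(unname(x$labels), each = x$r)
  )
}

#' One-row community-model summary
#'
#' @param x A [detect_communities()] model.
#' @param ... Unused.
#' @return A tibble with the selected r, Q_f, F_G, iterations and node count.
#' @export
glance.community_model <- function(x, ...) {
  tibble::tibble(r = x$r, Q_f = x$Q_f, F_G = x$F_G, n_iter = x$n_iter,
                 n_nodes = length(x$nodes),
                 n_used = length(unique(x$labels)))
}
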