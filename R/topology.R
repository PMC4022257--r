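#' Average degree of a graph
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param n_edges Number of edges.
#' @return 2 * n_edges / n_nodes.
#' @examples
#' average_degree(280, 793)  # 5.664
#' @export
average_degree <- function(n_nodes, n_edges) {
  if (any(n_nodes < 1)) abort("n_nodes must be >= 1")
  2 * n_edges / n_nodes
}

#' Average local clustering coefficient
#'
#' Mean over all nodes of the unweighted local clustering coefficient,
#' with edges binarized at weight > 0; nodes of degree < 2 contribute 0.
#'
#' @param net An [assoc_network].
#' @return Value in `[0, 1]`.
#' @export
average_clustering <- function(net) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0) return(0)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Degree-distribution power-law exponent
#'
#' Fits the degree distribution of the (binarized) network. The default
#' `"ls"` method is the least-squares slope magnitude of log(frequency)
#' versus log(degree) over positive degrees; `"mle"` is the continuous
#' Clauset-style maximum-likelihood estimate
#' 1 + n / sum(log(k / (kmin - 0.5))).
#'
#' @param x An [assoc_network], or directly a vector of node degrees.
#' @param method `"ls"` (default) or `"mle"`.
#' @return The fitted exponent (slope magnitude gamma).
#' @export
power_law_exponent <- function(x, method = c("ls", "mle")) {
  method <- match.arg(method)
  degs <- if (inherits(x, "assoc_network")) {
    rowSums(adjacency_matrix(x, weighted = FALSE) > 0)
  } else {
    as.numeric(x)
  }
  degs <- degs[degs > 0]
  if (length(unique(degs)) < 2) {
    abort("power_law_exponent(): need at least 2 distinct positive degrees")
  }
  if (method == "ls") {
    tab <- table(degs)
    k <- as.numeric(names(tab))
    f <- as.numeric(tab)
    fit <- stats::lm(log(f) ~ log(k))
    abs(unname(stats::coef(fit)[2]))
  } else {
    kmin <- min(degs)
    1 + length(degs) / sum(log(degs / (kmin - 0.5)))
  }
}

#' Uniform random reference graph with fixed node and edge counts
#'
#' Draws a simple graph uniformly among all graphs with exactly `n_nodes`
#' nodes and `n_edges` edges (the G(n, m) model), with unit edge weights.
#' This is the null reference used to judge whether an observed network's
#' clustering and modularity exceed chance at the same density.
#'
#' @param n_nodes,n_edges Graph size.
#' @param seed Integer seed.
#' @return An [assoc_network] with nodes `n1..n`.
#' @export
random_reference <- function(n_nodes, n_edges, seed = 1) {
  max_e <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_e) {
    abort(sprintf("n_edges = %d exceeds the simple-graph maximum %d",
                  n_edges, max_e))
  }
  g <- withr::with_seed(seed, igraph::sample_gnm(n_nodes, n_edges))
  igraph::V(g)$name <- paste0("n", seq_len(n_nodes))
  igraph::V(g)$type <- "OTU"
  from_igraph(g)
}

#' Topology report of an association network
#'
#' The six summary statistics used to characterize an association network
#' and compare it with same-size random references: node and edge counts,
#' average degree, average clustering coefficient, degree-distribution
#' power-law exponent, and the modularity Q_f of the selected community
#' model.
#'
#' @param net An [assoc_network].
#' @param community_model A [detect_communities()] model fitted on `net`;
#'   `NULL` leaves modularity `NA`.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `avg_degree`,
#'   `avg_clustering`, `power_law_exponent`, `modularity`.
#' @export
topology_report <- function(net, community_model = NULL) {
  stopifnot(inherits(net, "assoc_network"))
  n <- nrow(net$nodes)
  l <- nrow(net$edges)
  plexp <- tryCatch(power_law_exponent(net), error = function(e) NA_real_)
  modul <- NA_real_
  if (!is.null(community_model)) {
    stopifnot(inherits(community_model, "community_model"))
    if (!identical(community_model$nodes, net$nodes$node)) {
      abort("community model was not fitted on this network's node set")
    }
    modul <- community_model$Q_f
  }
  tibble::tibble(
    n_nodes = n, n_edges = l,
    avg_degree = average_degree(n, l),
    avg_clustering = average_clustering(net),
    power_law_exponent = plexp,
    modularity = modul
  )
}
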