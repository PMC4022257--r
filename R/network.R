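#' Association network constructor
#'
#' A weighted, undirected association network over typed nodes (OTUs and
#' environmental factors). Edge weights are mutual-information values of the
#' retained (significant) associations; the graph is simple (no self-loops,
#' one record per unordered pair, stored with `node_a < node_b`).
#'
#' @param nodes Data frame with columns `node` (unique ids) and `type`
#'   (`"OTU"` or `"env"`).
#' @param edges Data frame with columns `node_a`, `node_b`, `weight` and
#'   optionally `p_value`.
#' @return An object of class `assoc_network`: a list with tibbles `nodes`
#'   (including a computed `isolated` flag) and `edges`.
#' @export
assoc_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (!all(c("node", "type") %in% names(nodes))) {
    abort("nodes must have columns 'node' and 'type'")
  }
  if (anyDuplicated(nodes$node)) abort("duplicate node ids")
  bad <- setdiff(unique(nodes$type), c("OTU", "env"))
  if (length(bad)) abort(sprintf("unknown node type(s): %s", paste(bad, collapse = ", ")))
  if (!"p_value" %in% names(edges)) edges$p_value <- NA_real_
  needed <- c("node_a", "node_b", "weight", "p_value")
  if (!all(needed %in% names(edges))) {
    abort("edges must have columns node_a, node_b, weight (p_value optional)")
  }
  edges <- edges[, needed]
  if (nrow(edges)) {
    if (any(edges$node_a == edges$node_b)) abort("self-loops are not allowed")
    unknown <- setdiff(c(edges$node_a, edges$node_b), nodes$node)
    if (length(unknown)) {
      abort(sprintf("edge endpoints missing from node set: %s",
                    paste(head(unknown, 5), collapse = ", ")))
    }
    if (any(edges$weight < 0)) abort("edge weights must be nonnegative")
    flip <- edges$node_a > edges$node_b
    tmp <- edges$node_a[flip]
    edges$node_a[flip] <- edges$node_b[flip]
    edges$node_b[flip] <- tmp
    key <- paste(edges$node_a, edges$node_b, sep = "\x1f")
    if (anyDuplicated(key)) abort("duplicate edges for the same node pair")
    edges <- edges[order(edges$node_a, edges$node_b), ]
  }
  nodes$isolated <- !(nodes$node %in% c(edges$node_a, edges$node_b))
  structure(list(nodes = nodes, edges = edges), class = "assoc_network")
}

#' Build an association network from a symmetric adjacency matrix
#'
#' @param A Symmetric nonnegative matrix with zero diagonal; dimnames used as
#'   node ids (defaults to `n1..nn`).
#' @param type Node type for every node (`"OTU"` or `"env"`), recycled.
#' @return An [assoc_network].
#' @export
network_from_adjacency <- function(A, type = "OTU") {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-12) abort("adjacency must be symmetric")
  ids <- rownames(A) %||% paste0("n", seq_len(nrow(A)))
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    node_a = ids[idx[, 1]], node_b = ids[idx[, 2]],
    weight = A[idx], p_value = NA_real_
  )
  nodes <- tibble::tibble(node = ids, type = rep_len(type, length(ids)))
  assoc_network(nodes, edges)
}

#' Adjacency matrix of an association network
#'
#' @param net An [assoc_network].
#' @param weighted If `FALSE`, entries are binarized at weight > 0.
#' @return A symmetric numeric matrix with node ids as dimnames and zero
#'   diagonal.
#' @export
adjacency_matrix <- function(net, weighted = TRUE) {
  stopifnot(inherits(net, "assoc_network"))
  ids <- net$nodes$node
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    ia <- match(net$edges$node_a, ids)
    ib <- match(net$edges$node_b, ids)
    w <- if (weighted) net$edges$weight else rep(1, nrow(net$edges))
    A[cbind(ia, ib)] <- w
    A[cbind(ib, ia)] <- w
  }
  A
}

#' Convert to / from igraph
#'
#' @param net An [assoc_network].
#' @return `as_igraph()` returns an [igraph::graph]; `from_igraph()` an
#'   [assoc_network].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(net$edges),
    directed = FALSE,
    vertices = as.data.frame(net$nodes[, c("node", "type")])
  )
  g
}

#' @rdname as_igraph
#' @param g An undirected igraph graph; vertex attribute `type` and edge
#'   attributes `weight`, `p_value` are used when present.
#' @export
from_igraph <- function(g) {
  vn <- igraph::vertex_attr(g, "name") %||% as.character(seq_len(igraph::vcount(g)))
  vt <- igraph::vertex_attr(g, "type") %||% rep("OTU", igraph::vcount(g))
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble::tibble(
    node_a = as.character(ed$from), node_b = as.character(ed$to),
    weight = if ("weight" %in% names(ed)) ed$weight else rep(1, nrow(ed)),
    p_value = if ("p_value" %in% names(ed)) ed$p_value else rep(NA_real_, nrow(ed))
  )
  assoc_network(tibble::tibble(node = vn, type = vt), edges)
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("<assoc_network> %d nodes (%d OTU, %d env), %d edges, %d isolated\n",
              nrow(x$nodes), sum(x$nodes$type == "OTU"),
              sum(x$nodes$type == "env"), nrow(x$edges),
              sum(x$nodes$isolated)))
  invisible(x)
}

#' Tidy an association network into its edge table
#'
#' @param x An [assoc_network].
#' @param ... Unused.
#' @return A tibble of edges with endpoint types joined in.
#' @export
tidy.assoc_network <- function(x, ...) {
  type_of <- setNames(x$nodes$type, x$nodes$node)
  dplyr::mutate(x$edges,
                node_a_type = unname(type_of[.data$node_a]),
                node_b_type = unname(type_of[.data$node_b]))
}

#' One-row network summary
#'
#' @param x An [assoc_network].
#' @param ... Unused.
#' @return A tibble with node/edge counts and average degree.
#' @export
glance.assoc_network <- function(x, ...) {
  n <- nrow(x$nodes)
  l <- nrow(x$edges)
  tibble::tibble(
    n_nodes = n, n_edges = l,
    n_otu = sum(x$nodes$type == "OTU"),
    n_env = sum(x$nodes$type == "env"),
    n_isolated = sum(x$nodes$isolated),
    avg_degree = average_degree(n, l),
    total_weight = sum(x$edges$weight)
  )
}
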