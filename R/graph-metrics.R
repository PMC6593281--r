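# Topological metrics on binary undirected graphs. Graph algorithms are
# delegated to igraph; these wrappers fix the conventions used throughout
# the pipeline (degree-<2 clustering = 0, finite-pairs path length,
# ordered-pair efficiencies, unnormalized Brandes betweenness).

as_graph <- function(adj) {
  if (inherits(adj, "igraph")) return(adj)
  adj <- unclass(as.matrix(adj))
  stopifnot(nrow(adj) == ncol(adj))
  if (any(adj != 0 & adj != 1)) stop("adjacency must be binary")
  if (any(diag(adj) != 0)) stop("adjacency must have a zero diagonal")
  if (!isTRUE(all.equal(adj, t(adj)))) stop("adjacency must be symmetric")
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

edge_matrix <- function(adj) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  idx
}

#' Nodal degree
#'
#' @param adj binary symmetric adjacency matrix (or igraph object).
#' @return integer vector of per-node degrees.
#' @export
nodal_degree <- function(adj) {
  if (inherits(adj, "igraph")) return(igraph::degree(adj))
  as.integer(rowSums(unclass(as.matrix(adj))))
}

#' Binary clustering coefficient
#'
#' Per node: twice the number of triangles through it divided by
#' `deg * (deg - 1)`; nodes with degree < 2 contribute 0.
#'
#' @inheritParams nodal_degree
#' @return list with `per_node` and the mean `cp`.
#' @export
clustering_coef <- function(adj) {
  g <- as_graph(adj)
  per_node <- igraph::transitivity(g, type = "localundirected",
                                   isolates = "zero")
  list(per_node = per_node, cp = mean(per_node))
}

#' Pairwise shortest-path lengths
#'
#' Breadth-first-search distances; unreachable pairs are `Inf`.
#'
#' @inheritParams nodal_degree
#' @return N x N distance matrix.
#' @export
shortest_path_lengths <- function(adj) {
  igraph::distances(as_graph(adj))
}

#' Characteristic path length
#'
#' Mean shortest-path length. With `policy = "finite"` (default) the mean
#' runs over reachable pairs only and the number of unreachable unordered
#' pairs is attached as attribute `n_inf_pairs`; with `policy = "lcc"` the
#' mean is taken within the largest connected component.
#'
#' @inheritParams nodal_degree
#' @param policy `"finite"` or `"lcc"`.
#' @return scalar `lp` with attribute `n_inf_pairs`.
#' @export
char_path_length <- function(adj, policy = c("finite", "lcc")) {
  policy <- match.arg(policy)
  g <- as_graph(adj)
  if (policy == "lcc") {
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  d <- igraph::distances(g)
  finite <- is.finite(d) & upper.tri(d)
  n_inf <- sum(upper.tri(d)) - sum(finite)
  if (sum(finite) == 0) stop("graph has no connected node pair")
  lp <- mean(d[finite])
  attr(lp, "n_inf_pairs") <- if (policy == "finite") n_inf else 0L
  lp
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' `1/Inf = 0`, so disconnection needs no special policy.
#'
#' @inheritParams nodal_degree
#' @return scalar in `[0, 1]`.
#' @export
global_eff <- function(adj) {
  igraph::global_efficiency(as_graph(adj))
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced on its
#' neighbours (0 for degree < 2); `e_loc` is the mean over nodes.
#'
#' @inheritParams nodal_degree
#' @return list with `per_node` and mean `e_loc`.
#' @export
local_eff <- function(adj) {
  # the global efficiency of each node's neighbour-induced subgraph (paths
  # must stay inside the neighbourhood, unlike igraph::local_efficiency,
  # which routes through the rest of the graph); computed in compiled code
  if (inherits(adj, "igraph")) {
    edges <- igraph::as_edgelist(adj, names = FALSE)
    storage.mode(edges) <- "integer"
    n <- igraph::vcount(adj)
  } else {
    adj <- unclass(as.matrix(adj))
    stopifnot(nrow(adj) == ncol(adj))
    if (any(adj != 0 & adj != 1)) stop("adjacency must be binary")
    if (any(diag(adj) != 0)) stop("adjacency must have a zero diagonal")
    if (!isTRUE(all.equal(adj, t(adj)))) stop("adjacency must be symmetric")
    edges <- edge_matrix(adj)
    n <- nrow(adj)
  }
  per_node <- .local_eff_cpp(edges, n)
  list(per_node = per_node, e_loc = mean(per_node))
}

#' Nodal efficiency
#'
#' For node i, the mean over all other nodes of `1/d(i, j)`.
#'
#' @inheritParams nodal_degree
#' @return numeric vector per node.
#' @export
nodal_eff <- function(adj) {
  d <- shortest_path_lengths(adj)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (nrow(inv) - 1)
}

#' Betweenness centrality
#'
#' Brandes accumulation of shortest-path pass-through fractions, endpoints
#' excluded, reported unnormalized.
#'
#' @inheritParams nodal_degree
#' @return numeric vector per node.
#' @export
betweenness_centrality <- function(adj) {
  igraph::betweenness(as_graph(adj), directed = FALSE, normalized = FALSE)
}

#' All global metrics of one binary graph
#'
#' @inheritParams char_path_length
#' @return list: `cp`, `lp`, `e_glob`, `e_loc`, `n_inf_pairs`.
#' @export
global_metrics <- function(adj, policy = c("finite", "lcc")) {
  lp <- char_path_length(adj, policy)
  list(cp = clustering_coef(adj)$cp, lp = as.numeric(lp),
       e_glob = global_eff(adj), e_loc = local_eff(adj)$e_loc,
       n_inf_pairs = attr(lp, "n_inf_pairs"))
}

#' All nodal metrics of one binary graph
#'
#' @inheritParams nodal_degree
#' @return data.frame: `degree`, `efficiency`, `betweenness` (one row per
#'   node).
#' @export
nodal_metrics <- function(adj) {
  data.frame(degree = nodal_degree(adj),
             efficiency = nodal_eff(adj),
             betweenness = betweenness_centrality(adj))
}
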