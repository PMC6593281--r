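#' Null-ensemble configuration
#'
#' Settings for the degree-preserving random ensembles used to normalize
#' clustering and path length: 100 null networks per graph by default, each
#' produced by Maslov-Sneppen double-edge swaps at 10 attempted swaps per
#' edge.
#'
#' @param n_nulls number of null networks (>= 1).
#' @param swaps_per_edge attempted double-edge swaps per edge (>= 1).
#' @param seed optional integer seed for the ensemble.
#' @return object of class `null_config`.
#' @export
null_config <- function(n_nulls = 100L, swaps_per_edge = 10L, seed = NULL) {
  stopifnot(n_nulls >= 1, swaps_per_edge >= 1)
  structure(list(n_nulls = as.integer(n_nulls),
                 swaps_per_edge = swaps_per_edge, seed = seed),
            class = "null_config")
}

#' Degree-preserving rewiring (Maslov-Sneppen)
#'
#' Randomizes topology with double-edge swaps while keeping every node's
#' degree exactly fixed. Proposed swaps that would create a self-loop or a
#' duplicate edge are rejected and redrawn (up to `max_tries` per swap).
#' Saturated graphs with no legal swap (e.g. complete graphs) are returned
#' unchanged with a warning.
#'
#' @param adj binary symmetric adjacency matrix with >= 2 edges.
#' @param swaps_per_edge attempted swaps per edge.
#' @param seed optional integer seed.
#' @param max_tries redraw cap per swap.
#' @return rewired adjacency matrix with the same degree sequence.
#' @export
rewire_preserving_degree <- function(adj, swaps_per_edge = 10, seed = NULL,
                                     max_tries = 50L) {
  adj <- unclass(as.matrix(adj))
  n <- nrow(adj)
  em <- edge_matrix(adj)
  if (nrow(em) < 2) stop("graph must have at least 2 edges")
  if (nrow(em) == n * (n - 1) / 2) {
    warning("complete graph: no legal degree-preserving swap exists")
    return(adj)
  }
  new_edges <- with_seed(seed,
    .ms_rewire_cpp(em, n, swaps_per_edge, as.integer(max_tries)))
  out <- matrix(0L, n, n)
  out[new_edges] <- 1L
  out[new_edges[, 2:1, drop = FALSE]] <- 1L
  dimnames(out) <- dimnames(adj)
  out
}

#' Small-world coefficients via a null ensemble
#'
#' Computes `gamma = cp / <cp_null>`, `lambda = lp / <lp_null>` and
#' `sigma = gamma / lambda`, where the null means are taken over
#' `cfg$n_nulls` independent degree-preserving rewirings of the graph.
#' A network is called small-world when `gamma > 1`, `lambda` is close to
#' 1 and hence `sigma > 1`.
#'
#' @param adj binary symmetric adjacency matrix.
#' @param cfg a [null_config].
#' @return list: `gamma`, `lambda`, `sigma`, raw `cp` and `lp`, and the
#'   null-ensemble means and SDs (`null_cp_mean`, `null_cp_sd`,
#'   `null_lp_mean`, `null_lp_sd`).
#' @export
normalized_metrics <- function(adj, cfg = null_config()) {
  adj <- unclass(as.matrix(adj))
  n <- nrow(adj)
  em <- edge_matrix(adj)
  if (nrow(em) < 2) stop("graph must have at least 2 edges")
  obs <- .cp_lp_cpp(em, n)
  nulls <- with_seed(cfg$seed,
    .null_cp_lp_cpp(em, n, cfg$n_nulls, cfg$swaps_per_edge, 50L))
  cp_null <- mean(nulls[, "cp"])
  lp_null <- mean(nulls[, "lp"])
  if (!is.finite(cp_null) || cp_null == 0) {
    stop("degenerate null ensemble: mean null clustering is zero ",
         "(triangle-free nulls); gamma is undefined")
  }
  if (!is.finite(lp_null) || lp_null == 0) {
    stop("degenerate null ensemble: mean null path length is zero")
  }
  gamma <- obs[["cp"]] / cp_null
  lambda <- obs[["lp"]] / lp_null
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       cp = obs[["cp"]], lp = obs[["lp"]],
       null_cp_mean = cp_null, null_cp_sd = stats::sd(nulls[, "cp"]),
       null_lp_mean = lp_null, null_lp_sd = stats::sd(nulls[, "lp"]))
}
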