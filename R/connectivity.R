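#' Pearson functional connectivity matrix
#'
#' Sample Pearson correlation between every pair of regional signals. The
#' diagonal is set to 0 by convention; the Fisher r-to-z transform of the
#' off-diagonal entries is stored alongside.
#'
#' @param ts a [subject_ts] or T x N matrix with T >= 3.
#' @return object of class `fc_matrix`: list with `r` (N x N correlation
#'   matrix), `z` (Fisher transform), and `labels`.
#' @export
pearson_matrix <- function(ts) {
  ts <- as_subject_ts(ts)
  v <- ts$values
  if (nrow(v) < 3) stop("need at least 3 time points")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(v)[sds == 0] %||% which(sds == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(v)
  diag(r) <- 0
  z <- fisher_z(r, clip = TRUE)
  structure(list(r = r, z = z,
                 labels = colnames(v) %||% sprintf("R%03d", seq_len(ncol(v))),
                 subject_id = ts$subject_id),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("fc_matrix: %d x %d Pearson correlations\n",
              nrow(x$r), ncol(x$r)))
  invisible(x)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`, the variance-stabilizing transform applied to
#' correlation maps to promote normality.
#'
#' @param r correlations with `|r| < 1` (unless `clip`).
#' @param clip clip `|r| >= 1` to `1 - 1e-7` instead of erroring.
#' @return z values, same shape as `r`.
#' @export
fisher_z <- function(r, clip = FALSE) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    if (!clip) stop("|r| >= 1 not allowed (set clip = TRUE to clip)")
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  }
  atanh(r)
}

#' Sparsity grid
#'
#' Ordered sparsity fractions at which networks are thresholded; the
#' default 0.05 to 0.50 in steps of 0.01 gives 46 values.
#'
#' @param from,to,by grid bounds and step, all in (0, 1).
#' @return numeric vector of strictly increasing sparsities.
#' @export
sparsity_grid <- function(from = 0.05, to = 0.5, by = 0.01) {
  stopifnot(from > 0, to < 1, to > from, by > 0)
  g <- seq(from, to, by = by)
  if (any(diff(g) <= 0)) stop("grid must be strictly increasing")
  g
}

#' Threshold a connectivity matrix into a binary graph
#'
#' Keeps exactly `round(sp * N * (N - 1) / 2)` strongest edges (base R
#' round, i.e. round-half-even) so that every subject's network has the
#' same edge count at a given sparsity. By default edges are ranked by
#' signed correlation, so strong negative correlations are never selected;
#' `ranking = "absolute"` ranks by magnitude instead. Ties are broken by
#' lexicographic node order for determinism. Because the Fisher transform
#' is monotone, ranking on r and on z yields identical graphs.
#'
#' @param fc an `fc_matrix` or plain symmetric weight matrix.
#' @param sp sparsity fraction in (0, 1).
#' @param ranking `"signed"` (default) or `"absolute"`.
#' @return binary adjacency matrix of class `binary_graph` with attributes
#'   `sparsity` and `edge_count`.
#' @export
sparsity_binarize <- function(fc, sp, ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  w <- if (inherits(fc, "fc_matrix")) fc$r else as.matrix(fc)
  n <- nrow(w)
  stopifnot(ncol(w) == n, sp > 0, sp < 1)
  m_target <- round(sp * n * (n - 1) / 2)
  if (m_target < 1) stop(sprintf("sparsity %.4f yields no edges at N = %d", sp, n))
  ut <- which(upper.tri(w), arr.ind = TRUE)
  key <- if (ranking == "absolute") abs(w[ut]) else w[ut]
  ord <- order(-key, ut[, 1], ut[, 2])
  keep <- ut[ord[seq_len(m_target)], , drop = FALSE]
  adj <- matrix(0L, n, n)
  adj[keep] <- 1L
  adj[keep[, 2:1, drop = FALSE]] <- 1L
  dimnames(adj) <- dimnames(w)
  structure(adj, class = c("binary_graph", class(adj)),
            sparsity = sp, edge_count = m_target)
}

#' Binarize across a whole sparsity grid
#'
#' One binary graph per grid value; with the stable signed ranking the edge
#' sets are nested (each graph contains the previous one's edges).
#'
#' @inheritParams sparsity_binarize
#' @param grid vector from [sparsity_grid].
#' @return list of `binary_graph` objects, named by sparsity.
#' @export
build_graph_series <- function(fc, grid = sparsity_grid(),
                               ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  out <- lapply(grid, function(sp) sparsity_binarize(fc, sp, ranking))
  names(out) <- formatC(grid, format = "f", digits = 3)
  out
}

#' Export a binary graph as an edge list
#'
#' @param g a `binary_graph` (adjacency matrix).
#' @return two-column `data.frame` of region labels (or indices).
#' @export
graph_edge_list <- function(g) {
  idx <- which(upper.tri(g) & g == 1, arr.ind = TRUE)
  labs <- rownames(g) %||% as.character(seq_len(nrow(g)))
  data.frame(from = labs[idx[, 1]], to = labs[idx[, 2]],
             stringsAsFactors = FALSE)
}
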