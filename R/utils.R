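# Shared internal helpers: seeding, edge indexing, small numeric utilities.

#' Derive a reproducible stage seed from a master seed
#'
#' Stage seeds are a deterministic function of the master seed and a stage
#' name, so that independent pipeline stages draw from independent, fully
#' reproducible random streams.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # all arithmetic in doubles, exact below 2^53
  as.integer(((abs(seed) %% 94906265) * 69069 + h * 1013) %% 2147483629)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Canonical upper-triangle edge ordering
#'
#' All modules share one edge ordering: node pairs (i, j) with i < j,
#' row-major (sorted by i, then j), 1-based node ids.
#'
#' @param n_nodes Number of nodes.
#' @return Integer matrix with columns `i` and `j`, one row per edge.
#' @export
upper_tri_pairs <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(a) (a + 1L):n_nodes),
              use.names = FALSE)
  cbind(i = i, j = j)
}

#' Flatten a stack of symmetric matrices to a scans x edges matrix
#'
#' Extracts the upper triangle of every scan's matrix in the canonical
#' [upper_tri_pairs()] order.
#'
#' @param stack An n x n x S array of symmetric matrices.
#' @return S x n_edges numeric matrix.
#' @export
stack_to_edge_matrix <- function(stack) {
  n <- dim(stack)[1]
  pairs <- upper_tri_pairs(n)
  S <- dim(stack)[3]
  out <- matrix(NA_real_, S, nrow(pairs))
  idx <- pairs[, 1] + (pairs[, 2] - 1L) * n
  for (s in seq_len(S)) out[s, ] <- stack[, , s][idx]
  out
}

#' Canonical edge indices of node pairs
#'
#' Maps a 2-column node-pair matrix to positions in the canonical
#' upper-triangle ordering of [upper_tri_pairs()].
#'
#' @param pairs Two-column matrix of node ids (order within a row ignored).
#' @param n_nodes Total node count.
#' @return Integer vector of edge indices.
#' @export
edge_ids <- function(pairs, n_nodes) {
  pairs <- as.matrix(pairs)
  i <- pmin(pairs[, 1], pairs[, 2])
  j <- pmax(pairs[, 1], pairs[, 2])
  stopifnot(all(i >= 1), all(j <= n_nodes), all(i < j))
  # row-major rank of (i, j) in the upper triangle
  as.integer((i - 1) * n_nodes - i * (i - 1) / 2 + (j - i))
}
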