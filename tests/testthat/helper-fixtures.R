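# Shared fixtures and independent oracles, built in code at test time.

# Small study used by several module tests (memoised per session).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(n_subjects = 20, scans_per_subject = 3,
                             n_nodes = 30, n_timepoints = 200, seed = 77)
      cache <<- generate_study(spec)
    }
    cache
  }
})

# Independent breadth-first-search component oracle over an edge list
# (2-column node matrix). Returns the list of edge-index sets per component,
# ordered by decreasing edge count. Intentionally distinct from the package
# implementation (igraph / union-find).
bfs_components <- function(pairs) {
  m <- nrow(pairs)
  if (m == 0) return(list())
  adj <- list()
  for (e in seq_len(m)) {
    a <- as.character(pairs[e, 1]); b <- as.character(pairs[e, 2])
    adj[[a]] <- c(adj[[a]], pairs[e, 2])
    adj[[b]] <- c(adj[[b]], pairs[e, 1])
  }
  visited <- character(0)
  comps <- list()
  for (start in unique(as.integer(pairs))) {
    if (as.character(start) %in% visited) next
    queue <- start
    nodes <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (as.character(v) %in% visited) next
      visited <- c(visited, as.character(v))
      nodes <- c(nodes, v)
      queue <- c(queue, adj[[as.character(v)]])
    }
    edges <- which(pairs[, 1] %in% nodes | pairs[, 2] %in% nodes)
    comps[[length(comps) + 1L]] <- sort(edges)
  }
  comps[order(vapply(comps, length, integer(1)), decreasing = TRUE)]
}

# Classical equal-variance two-sample t statistic (closed form).
two_sample_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# OLS coefficients by the normal equations.
ols_oracle <- function(X, y) as.numeric(solve(crossprod(X), crossprod(X, y)))

# Realized Cohen's d of a group difference on one edge.
cohens_d <- function(a, b) {
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2)
}

edge_matrix_of <- function(stack) stack_to_edge_matrix(stack$matrices)
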