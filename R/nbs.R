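# Network-Based Statistic: edge-level GLM t statistics with a subject-aware
# design, suprathreshold connected components, and permutation-based
# family-wise error control of component extent.

parse_contrast <- function(contrast, levels) {
  parts <- strsplit(contrast, ">", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("contrast must be of the form 'A>B'")
  parts <- trimws(parts)
  if (!all(parts %in% levels))
    stop("contrast levels not found in group: ", paste(parts, collapse = ", "))
  parts  # c(high, low)
}

# Build the design matrix [intercept, group indicator, subject dummies] with
# one reference subject dropped. Errors if the group coefficient is not
# estimable (e.g., saturated by subject identity).
nbs_design_matrix <- function(g, subject_ids) {
  D <- cbind(intercept = 1, group = g)
  if (!is.null(subject_ids)) {
    f <- factor(subject_ids)
    if (nlevels(f) > 1) {
      dum <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(dum) <- paste0("subj_", levels(f)[-1])
      D <- cbind(D, dum)
    }
  }
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("design matrix rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  D
}

# Vectorized GLM t statistics for the group coefficient across all edges.
# Y: scans x edges, D: full-rank design with the group column named "group".
glm_group_t <- function(Y, D) {
  XtX <- crossprod(D)
  XtY <- crossprod(D, Y)
  B <- solve(XtX, XtY)
  rss <- colSums(Y^2) - colSums(XtY * B)
  df <- nrow(D) - ncol(D)
  inv_gg <- solve(XtX)[ "group", "group"]
  sigma2 <- pmax(rss, 0) / df
  se <- sqrt(sigma2 * inv_gg)
  t <- B["group", ] / se
  t[se == 0] <- 0
  list(t = as.numeric(t), df = df)
}

#' Edge-level GLM t statistics
#'
#' For each edge, ordinary least squares of edge strength on
#' `[intercept, group, subject dummies]`; returns the t statistic for the
#' group coefficient in the contrast direction (positive t = evidence for
#' the 'high' side of the contrast). Without subject dummies this equals the
#' classical equal-variance two-sample t test.
#'
#' @param edge_values Scans x edges matrix of connectivity strengths.
#' @param group Per-scan group labels (two levels used by the contrast).
#' @param contrast String `"A>B"` naming the two groups.
#' @param subject_ids Optional per-scan subject identifiers (adds subject
#'   dummies to absorb repeated-scan structure).
#' @return List with `t` (per-edge statistic), `df` (shared residual
#'   degrees of freedom).
#' @export
edge_statistics <- function(edge_values, group, contrast, subject_ids = NULL) {
  Y <- as.matrix(edge_values)
  group <- as.character(group)
  keep <- group %in% parse_contrast(contrast, unique(group))
  if (!all(keep)) {
    Y <- Y[keep, , drop = FALSE]
    group <- group[keep]
    if (!is.null(subject_ids)) subject_ids <- subject_ids[keep]
  }
  hl <- parse_contrast(contrast, unique(group))
  if (min(table(group)) < 2) stop("need at least 2 scans per group")
  g <- as.numeric(group == hl[1])
  D <- nbs_design_matrix(g, subject_ids)
  glm_group_t(Y, D)
}

# Union-find maximum component extent (edge count) for a set of edges given
# as a 2-column node matrix. Fast path used inside permutation loops.
max_component_extent <- function(pairs) {
  m <- nrow(pairs)
  if (m == 0) return(0L)
  if (m == 1) return(1L)
  nodes <- unique(as.integer(pairs))
  id <- match(as.integer(pairs), nodes)
  dim(id) <- dim(pairs)
  parent <- seq_along(nodes)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (e in seq_len(m)) {
    ra <- find(id[e, 1]); rb <- find(id[e, 2])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(id[, 1], find, integer(1))
  max(tabulate(roots))
}

#' Suprathreshold edges and their connected components
#'
#' Thresholds one-sided at the upper Student-t quantile for `edge_p`, forms
#' the graph of suprathreshold edges, and returns its maximal connected
#' components with extent = edge count (largest first).
#'
#' @param edge_t Per-edge t statistics (canonical edge order).
#' @param df Residual degrees of freedom.
#' @param edge_index Two-column node-pair matrix matching `edge_t`.
#' @param edge_p One-sided edge-level significance level (default 0.001).
#' @return List with `t_star`, `supra` (edge indices), `components` (list of
#'   lists: `edges` canonical indices, `nodes`, `extent`).
#' @export
threshold_and_components <- function(edge_t, df, edge_index, edge_p = 0.001) {
  stopifnot(df > 0, length(edge_t) == nrow(edge_index))
  t_star <- stats::qt(1 - edge_p, df)
  supra <- which(edge_t > t_star)
  comps <- list()
  if (length(supra)) {
    pairs <- edge_index[supra, , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      cbind(as.character(pairs[, 1]), as.character(pairs[, 2])),
      directed = FALSE)
    mem <- igraph::components(g)$membership
    vnames <- as.integer(names(mem))
    comp_of_edge <- mem[match(as.character(pairs[, 1]), names(mem))]
    for (cid in sort(unique(comp_of_edge))) {
      eidx <- supra[comp_of_edge == cid]
      nodes <- sort(unique(as.integer(edge_index[eidx, , drop = FALSE])))
      comps[[length(comps) + 1L]] <- list(edges = eidx, nodes = nodes,
                                          extent = length(eidx))
    }
    comps <- comps[order(vapply(comps, `[[`, integer(1), "extent"),
                         decreasing = TRUE)]
  }
  list(t_star = t_star, supra = supra, components = comps)
}

#' Network-Based Statistic permutation test
#'
#' Computes edge-level GLM t statistics for the given contrast, finds
#' suprathreshold connected components, and assesses each component's extent
#' against the permutation null distribution of the maximum component extent
#' (group labels freely permuted across scans; subject dummies held fixed).
#' Component FWE p-values use the +1-smoothed estimator
#' `(count(null >= observed) + 1) / (n_perm + 1)` and can never be 0.
#'
#' @param x A `connectivity_stack` or a scans x edges matrix.
#' @param group Per-scan group labels.
#' @param contrast String `"A>B"`.
#' @param subject_ids Optional per-scan subject identifiers.
#' @param n_perm Number of permutations (default 5000).
#' @param edge_p One-sided edge-level significance level (default 0.001).
#' @param component_alpha Component-level FWE threshold (default 0.05).
#' @param seed Integer seed for the permutations.
#' @param edge_index Needed when `x` is a plain matrix.
#' @return Object of class `nbs_result`: `edge_t`, `df`, `t_star`,
#'   `suprathreshold_edges`, `components` (with `p_fwe` each),
#'   `significant` (components with `p_fwe < component_alpha`),
#'   `null_max_extent`, parameters.
#' @export
nbs_test <- function(x, group, contrast, subject_ids = NULL, n_perm = 5000,
                     edge_p = 0.001, component_alpha = 0.05, seed = 1,
                     edge_index = NULL) {
  if (inherits(x, "connectivity_stack")) {
    edge_index <- x$edge_index
    Y <- stack_to_edge_matrix(x$matrices)
  } else {
    Y <- as.matrix(x)
    if (is.null(edge_index)) stop("edge_index required for matrix input")
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (1 / (n_perm + 1) > component_alpha)
    warning("n_perm too small to ever reach component_alpha = ", component_alpha)
  group <- as.character(group)
  hl <- parse_contrast(contrast, unique(group))
  keep <- group %in% hl
  Y <- Y[keep, , drop = FALSE]
  group <- group[keep]
  if (!is.null(subject_ids)) subject_ids <- subject_ids[keep]
  g <- as.numeric(group == hl[1])
  n <- length(g)

  D <- nbs_design_matrix(g, subject_ids)
  obs <- glm_group_t(Y, D)
  tc <- threshold_and_components(obs$t, obs$df, edge_index, edge_p)

  set.seed(derive_seed(seed, paste0("nbs-", contrast)))
  null_max <- integer(n_perm)
  if (is.null(subject_ids)) {
    # vectorized two-sample branch: all permutations via one matmul per chunk
    t_star <- tc$t_star
    n1 <- sum(g); n0 <- n - n1
    tot <- colSums(Y); totsq <- colSums(Y^2)
    chunk <- 250L
    done <- 0L
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      P <- matrix(0, n, b)
      for (k in seq_len(b)) P[sample(n, n1), k] <- 1
      S1 <- crossprod(Y, P)          # edges x b
      Q1 <- crossprod(Y^2, P)
      m1 <- S1 / n1
      m0 <- (tot - S1) / n0
      ss <- (Q1 - S1^2 / n1) + ((totsq - Q1) - (tot - S1)^2 / n0)
      se <- sqrt(pmax(ss, 0) / (n - 2) * (1 / n1 + 1 / n0))
      tmat <- (m1 - m0) / se
      tmat[se == 0] <- 0
      for (k in seq_len(b)) {
        supra <- which(tmat[, k] > t_star)
        null_max[done + k] <- if (length(supra) == 0) 0L else
          max_component_extent(edge_index[supra, , drop = FALSE])
      }
      done <- done + b
    }
  } else {
    for (p in seq_len(n_perm)) {
      gp <- sample(g)
      Dp <- D
      Dp[, "group"] <- gp
      tp <- tryCatch(glm_group_t(Y, Dp), error = function(e) NULL)
      if (is.null(tp)) { null_max[p] <- 0L; next }  # degenerate permutation
      supra <- which(tp$t > stats::qt(1 - edge_p, tp$df))
      null_max[p] <- if (length(supra) == 0) 0L else
        max_component_extent(edge_index[supra, , drop = FALSE])
    }
  }

  components <- lapply(tc$components, function(cp) {
    cp$p_fwe <- (sum(null_max >= cp$extent) + 1) / (n_perm + 1)
    cp
  })
  significant <- Filter(function(cp) cp$p_fwe < component_alpha, components)
  structure(
    list(edge_t = obs$t, df = obs$df, t_star = tc$t_star,
         suprathreshold_edges = tc$supra, components = components,
         significant = significant, null_max_extent = null_max,
         contrast = contrast, edge_p = edge_p,
         component_alpha = component_alpha, n_perm = n_perm,
         edge_index = edge_index),
    class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("Network-Based Statistic:", x$contrast, "\n")
  cat(sprintf("  edge p < %g (t* = %.3f, df = %d); %d suprathreshold edges\n",
              x$edge_p, x$t_star, x$df, length(x$suprathreshold_edges)))
  if (length(x$components) == 0) {
    cat("  no suprathreshold components\n")
  } else {
    for (cp in x$components[seq_len(min(5, length(x$components)))]) {
      cat(sprintf("  component: extent %d, %d nodes, p_FWE = %.4g%s\n",
                  cp$extent, length(cp$nodes), cp$p_fwe,
                  if (cp$p_fwe < x$component_alpha) " *" else ""))
    }
  }
  invisible(x)
}

#' Run the NBS contrast in both directions
#'
#' @inheritParams nbs_test
#' @return Named list of two `nbs_result`s (`A>B` and `B>A`), each run with
#'   an independent seed derived from `seed`.
#' @export
contrast_both_directions <- function(x, group, contrast, subject_ids = NULL,
                                     n_perm = 5000, edge_p = 0.001,
                                     component_alpha = 0.05, seed = 1,
                                     edge_index = NULL) {
  hl <- parse_contrast(contrast, unique(as.character(group)))
  fwd <- paste0(hl[1], ">", hl[2])
  rev <- paste0(hl[2], ">", hl[1])
  out <- list(
    nbs_test(x, group, fwd, subject_ids, n_perm, edge_p, component_alpha,
             seed = derive_seed(seed, "direction-forward"), edge_index),
    nbs_test(x, group, rev, subject_ids, n_perm, edge_p, component_alpha,
             seed = derive_seed(seed, "direction-reverse"), edge_index))
  names(out) <- c(fwd, rev)
  out
}

#' Jaccard overlap between two edge sets
#'
#' @param a,b Integer vectors of canonical edge indices.
#' @return `|a intersect b| / |a union b|` (0 when both empty).
#' @export
edge_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}
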