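# Functional-connectivity construction and graph summaries: Pearson FC from
# ROI time series, the motion-censoring QC rule, laterality of significant
# edges, and network-pair / degree tallies.

#' Toy atlas lookup table
#'
#' Builds an atlas for synthetic data: seven equally sized cortical networks
#' split into left/right hemispheres, plus a small subcortical block
#' (hemisphere `NA`). Mirrors, at toy scale, a 7-network cortical parcellation
#' augmented with subcortical regions.
#'
#' @param n_nodes Total node count (at least 16; the last
#'   `n_nodes - 7 * floor((n_nodes - 4) / 7)` nodes are subcortical, minimum 4).
#' @return Data frame with columns `node_id` (1-based, contiguous),
#'   `hemisphere` (`"L"`, `"R"` or `NA`), `network`.
#' @export
make_toy_atlas <- function(n_nodes = 60) {
  stopifnot(n_nodes >= 16)
  nets <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont", "Default")
  per <- (n_nodes - 4) %/% 7
  n_cort <- per * 7
  network <- c(rep(nets, each = per), rep("Subcort", n_nodes - n_cort))
  hemisphere <- rep(NA_character_, n_nodes)
  # within each cortical network, first half left, second half right
  for (k in seq_along(nets)) {
    idx <- which(network == nets[k])
    hemisphere[idx] <- c(rep("L", ceiling(length(idx) / 2)),
                         rep("R", floor(length(idx) / 2)))
  }
  data.frame(node_id = seq_len(n_nodes), hemisphere = hemisphere,
             network = network, stringsAsFactors = FALSE)
}

validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas),
            all(c("node_id", "hemisphere", "network") %in% names(atlas)))
  if (!identical(as.integer(atlas$node_id), seq_len(nrow(atlas))))
    stop("atlas node ids must be contiguous from 1")
  if (anyNA(atlas$network)) stop("every node needs a network label")
  invisible(atlas)
}

#' Mark invalid volumes from a relative-displacement trace
#'
#' A volume with relative displacement above `threshold` (mm) is invalid;
#' so are its preceding volume and the two following volumes (neighbours
#' outside the trace are ignored). A scan is rejected when 30% or more of
#' its volumes are invalid (boundary inclusive).
#'
#' @param displacement_trace Non-negative numeric vector, one value per volume.
#' @param threshold Displacement threshold in mm (default 0.3).
#' @return List (class `censor_report`): `invalid_mask` (logical),
#'   `frac_invalid`, `rejected`.
#' @export
censor_volumes <- function(displacement_trace, threshold = 0.3) {
  x <- as.numeric(displacement_trace)
  if (length(x) == 0) stop("empty displacement trace")
  if (any(!is.finite(x)) || any(x < 0)) stop("trace must be finite and non-negative")
  n <- length(x)
  bad <- which(x > threshold)
  mask <- rep(FALSE, n)
  if (length(bad)) {
    ext <- unique(c(bad - 1L, bad, bad + 1L, bad + 2L))
    mask[ext[ext >= 1L & ext <= n]] <- TRUE
  }
  frac <- mean(mask)
  structure(list(invalid_mask = mask, frac_invalid = frac,
                 rejected = frac >= 0.30),
            class = "censor_report")
}

#' Pearson functional-connectivity matrix from ROI time series
#'
#' @param timeseries Nodes x timepoints numeric matrix (at least 3
#'   timepoints; every node must have positive variance).
#' @return Symmetric node x node correlation matrix with unit diagonal.
#' @export
compute_fc <- function(timeseries) {
  ts <- as.matrix(timeseries)
  if (ncol(ts) < 3) stop("need at least 3 timepoints")
  v <- apply(ts, 1, stats::var)
  if (any(v <= 0)) {
    stop("zero-variance node(s): ", paste(which(v <= 0), collapse = ", "))
  }
  r <- stats::cor(t(ts))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Construct a connectivity stack
#'
#' @param matrices n x n x S array of per-scan symmetric FC matrices (unit
#'   diagonal), or a list of such matrices.
#' @param atlas Atlas data frame (see [make_toy_atlas()]).
#' @param scan_ids Optional per-scan identifiers.
#' @return Object of class `connectivity_stack` with elements `matrices`,
#'   `atlas`, `scan_ids`, `edge_index` (canonical i<j pairs).
#' @export
fc_stack <- function(matrices, atlas, scan_ids = NULL) {
  if (is.list(matrices)) {
    n <- nrow(matrices[[1]])
    arr <- array(NA_real_, c(n, n, length(matrices)))
    for (s in seq_along(matrices)) arr[, , s] <- matrices[[s]]
    matrices <- arr
  }
  stopifnot(length(dim(matrices)) == 3, dim(matrices)[1] == dim(matrices)[2])
  validate_atlas(atlas)
  if (nrow(atlas) != dim(matrices)[1]) stop("atlas / matrix node counts differ")
  S <- dim(matrices)[3]
  if (is.null(scan_ids)) scan_ids <- paste0("scan", seq_len(S))
  structure(list(matrices = matrices, atlas = atlas,
                 scan_ids = as.character(scan_ids),
                 edge_index = upper_tri_pairs(dim(matrices)[1])),
            class = "connectivity_stack")
}

#' @export
print.connectivity_stack <- function(x, ...) {
  cat(sprintf("Connectivity stack: %d scans x %d nodes (%d edges)\n",
              dim(x$matrices)[3], dim(x$matrices)[1], nrow(x$edge_index)))
  invisible(x)
}

#' Laterality index of a significant-edge set
#'
#' `(LL - RR) / (LL + RR)` where `LL` / `RR` count left / right
#' intra-hemispheric edges; ranges from -1 (right-dominant) to 1
#' (left-dominant). Inter-hemispheric and subcortical edges do not count.
#'
#' @param significant_edges Two-column matrix of node pairs.
#' @param atlas Atlas data frame with `hemisphere`.
#' @return Numeric scalar, or `NA` (with a warning) when `LL + RR == 0`.
#' @export
laterality_index <- function(significant_edges, atlas) {
  validate_atlas(atlas)
  e <- as.matrix(significant_edges)
  if (nrow(e) == 0) { warning("no edges; laterality undefined"); return(NA_real_) }
  h1 <- atlas$hemisphere[e[, 1]]
  h2 <- atlas$hemisphere[e[, 2]]
  LL <- sum(!is.na(h1) & !is.na(h2) & h1 == "L" & h2 == "L")
  RR <- sum(!is.na(h1) & !is.na(h2) & h1 == "R" & h2 == "R")
  if (LL + RR == 0) {
    warning("no intra-hemispheric edges; laterality undefined")
    return(NA_real_)
  }
  (LL - RR) / (LL + RR)
}

#' Within/between-network counts of a significant-edge set
#'
#' @param significant_edges Two-column matrix of node pairs.
#' @param atlas Atlas data frame with `network`.
#' @return Symmetric network x network count matrix; the total over unique
#'   unordered network pairs equals the number of edges.
#' @export
network_pair_counts <- function(significant_edges, atlas) {
  validate_atlas(atlas)
  nets <- sort(unique(atlas$network))
  cnt <- matrix(0L, length(nets), length(nets), dimnames = list(nets, nets))
  e <- as.matrix(significant_edges)
  if (nrow(e)) {
    a <- atlas$network[e[, 1]]
    b <- atlas$network[e[, 2]]
    lo <- pmin(a, b); hi <- pmax(a, b)
    tab <- table(factor(lo, nets), factor(hi, nets))
    cnt <- cnt + unclass(tab)
    cnt <- cnt + t(cnt) - diag(diag(cnt))
  }
  cnt
}

#' Degree of each node in a significant-edge set
#'
#' @param significant_edges Two-column matrix of node pairs.
#' @param n_nodes Total node count.
#' @return Integer vector of per-node edge counts (handshake: sums to twice
#'   the edge count).
#' @export
node_degree <- function(significant_edges, n_nodes) {
  e <- as.matrix(significant_edges)
  if (nrow(e) == 0) return(integer(n_nodes))
  tabulate(c(e[, 1], e[, 2]), nbins = n_nodes)
}
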