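# Seeded synthetic data with the statistical structure the analysis assumes:
# bounded non-Gaussian questionnaire responses driven by two latent thought
# patterns plus demographic confounds, multiple scans per subject with
# within-subject consistency, block-structured FC with a planted connected
# subnetwork group effect and a planted edge-sum <-> behaviour relation, and
# motion traces with occasional spikes.

QUESTIONNAIRE_ITEMS <- c("surroundings", "people", "myself", "past", "future",
                         "negative", "positive", "intrusive", "specific",
                         "words", "images")

#' Specification of a synthetic dataset
#'
#' Validates and packages the generator parameters. Defaults are the study
#' conditions used throughout the test suite: two latent thought patterns,
#' bounded responses on 11 items, a 60-node / 7-network + subcortical atlas,
#' 660 timepoints per scan, a 30-edge planted connected component with group
#' Cohen's d 1.0 on edge strength, and a planted behaviour relation of
#' aggregate correlation 0.7 concentrated on 10 edges.
#'
#' @param n_subjects Number of subjects.
#' @param scans_per_subject Scans per subject (1--4).
#' @param n_items Questionnaire items (default 11).
#' @param n_nodes Atlas nodes.
#' @param n_timepoints Volumes per scan.
#' @param d_true Number of latent thought patterns (default 2).
#' @param questionnaire_noise_sd Response noise sd (response units, 0--100 scale).
#' @param effect_edges Two-column matrix of node pairs forming one connected
#'   subgraph; `NULL` draws a random 30-edge connected subgraph from the seed.
#' @param group_effect_size Cohen's d of the planted group shift on
#'   `effect_edges`.
#' @param behavior_effect_r Target correlation (in `[-1, 1]`) between the sum
#'   of planted behaviour-edge strengths and the behavioural score.
#' @param n_behavior_edges Number of edges carrying the behaviour relation.
#' @param motion_spike_rate Probability per volume of a displacement spike.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 50, scans_per_subject = 3, n_items = 11,
                           n_nodes = 60, n_timepoints = 660, d_true = 2,
                           questionnaire_noise_sd = 5, effect_edges = NULL,
                           group_effect_size = 1.0, behavior_effect_r = 0.7,
                           n_behavior_edges = 10, motion_spike_rate = 0.01,
                           seed = 1) {
  stopifnot(n_subjects >= 1, scans_per_subject >= 1, scans_per_subject <= 4,
            n_items >= 2, n_nodes >= 16, n_timepoints >= 3, d_true >= 1,
            questionnaire_noise_sd >= 0,
            motion_spike_rate >= 0, motion_spike_rate <= 1,
            abs(behavior_effect_r) <= 1, n_behavior_edges >= 1)
  spec <- structure(
    list(n_subjects = n_subjects, scans_per_subject = scans_per_subject,
         n_items = n_items, n_nodes = n_nodes, n_timepoints = n_timepoints,
         d_true = d_true, questionnaire_noise_sd = questionnaire_noise_sd,
         effect_edges = effect_edges, group_effect_size = group_effect_size,
         behavior_effect_r = behavior_effect_r,
         n_behavior_edges = n_behavior_edges,
         motion_spike_rate = motion_spike_rate, seed = as.integer(seed)),
    class = "synthetic_spec")
  if (is.null(effect_edges)) {
    spec$effect_edges <- random_connected_edges(n_nodes, 30,
                                                derive_seed(seed, "effect-edges"))
  } else {
    spec$effect_edges <- as.matrix(effect_edges)
    validate_effect_edges(spec$effect_edges, n_nodes)
  }
  spec
}

# A random connected subgraph with `n_edges` edges: grow a random tree on
# ceiling(n_edges * 0.6) + 1 nodes, then add random extra edges among them.
random_connected_edges <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  k <- min(ceiling(n_edges * 0.6) + 1, n_nodes)
  nodes <- sample(n_nodes, k)
  edges <- matrix(NA_integer_, 0, 2)
  for (v in 2:k) {  # random spanning tree
    u <- sample(v - 1L, 1)
    edges <- rbind(edges, sort(c(nodes[u], nodes[v])))
  }
  while (nrow(edges) < n_edges) {
    uv <- sort(nodes[sample(k, 2)])
    if (!any(edges[, 1] == uv[1] & edges[, 2] == uv[2]))
      edges <- rbind(edges, uv)
  }
  dimnames(edges) <- list(NULL, c("i", "j"))
  edges[seq_len(n_edges), , drop = FALSE]
}

validate_effect_edges <- function(edges, n_nodes) {
  if (any(edges < 1) || any(edges > n_nodes))
    stop("effect_edges reference nodes outside 1..", n_nodes)
  g <- igraph::graph_from_edgelist(
    cbind(as.character(edges[, 1]), as.character(edges[, 2])), directed = FALSE)
  if (igraph::components(g)$no != 1)
    stop("effect_edges must induce a connected graph")
  invisible(edges)
}

#' Generate questionnaire, demographic and behavioural data
#'
#' Subjects are assigned to one of three latent profiles (high TP1 / high
#' TP2 / intermediate); each scan's true loadings are a small jitter around
#' the subject-level mean, so scans of one subject cluster together. The
#' response matrix is `clip([W_true, C] %*% t([Q_true, Qc_true]) + noise,
#' 0, 100)` -- bounded and, after clipping, non-Gaussian. The behavioural
#' score is the standardised TP2 loading; wakefulness is generated
#' independently and kept separate from the item matrix.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (class `experience_dataset`: `M`,
#'   `scan_ids`, `subject_ids`, `wakefulness`, `demographics`,
#'   `motion_mean` placeholder) and `truth` (class `synthetic_truth`:
#'   `W_true`, `Q_true`, `Qc_true`, `group_labels`, `target_true`,
#'   `subject_profile`).
#' @export
generate_experience <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, "experience"))
  ns <- spec$n_subjects; k <- spec$scans_per_subject
  S <- ns * k; d <- spec$d_true; m <- spec$n_items

  # Subject profiles: corners of the loading space plus an intermediate group.
  profile <- sample(rep_len(c("Image-Pos-Others", "Surr-Neg-Self", "Intermediate"), ns))
  centers <- rbind("Image-Pos-Others" = c(0.85, 0.15),
                   "Surr-Neg-Self"    = c(0.15, 0.85),
                   "Intermediate"     = c(0.50, 0.50))
  subj_mean <- matrix(0.5, ns, d)
  subj_mean[, seq_len(min(d, 2))] <-
    centers[profile, seq_len(min(d, 2)), drop = FALSE] +
    matrix(stats::rnorm(ns * min(d, 2), 0, 0.05), ns)
  if (d > 2) subj_mean[, 3:d] <- matrix(stats::runif(ns * (d - 2)), ns)
  subj_mean <- clip(subj_mean, 0.02, 0.98)

  subject_ids <- rep(sprintf("sub%03d", seq_len(ns)), each = k)
  scan_ids <- paste0(subject_ids, sprintf("_ses%02d", rep(seq_len(k), ns)))
  W_true <- clip(subj_mean[rep(seq_len(ns), each = k), , drop = FALSE] +
                   matrix(stats::rnorm(S * d, 0, 0.06), S), 0, 1)
  dimnames(W_true) <- list(scan_ids, paste0("TP", seq_len(d)))

  # Item weights: TP1 loads images/people/positive/specific; TP2 loads
  # surroundings/myself/negative/words/intrusive; past/future mixed.
  items <- if (m == 11) QUESTIONNAIRE_ITEMS else paste0("item", seq_len(m))
  Q_true <- matrix(8, m, d, dimnames = list(items, paste0("TP", seq_len(d))))
  if (m == 11 && d >= 2) {
    Q_true[c("images", "people", "positive", "specific"), 1] <- c(85, 70, 75, 60)
    Q_true[c("surroundings", "myself", "negative", "words", "intrusive"), 2] <-
      c(80, 65, 75, 60, 55)
    Q_true[c("past", "future"), ] <- matrix(c(35, 30, 30, 35), 2)
  } else {
    for (j in seq_len(d)) {
      idx <- which((seq_len(m) - 1) %% d == (j - 1))
      Q_true[idx, j] <- 70
    }
  }

  # Demographics (per subject) and their item weights.
  demo_subj <- data.frame(
    age_bin = sample(0:3, ns, replace = TRUE),
    gender = if (ns >= 2) sample(rep_len(c("F", "M"), ns))
             else sample(c("F", "M"), ns, replace = TRUE),
    stringsAsFactors = FALSE)
  demographics <- demo_subj[rep(seq_len(ns), each = k), , drop = FALSE]
  rownames(demographics) <- scan_ids
  C <- encode_confounds(demographics)
  Qc_true <- matrix(stats::runif(m * 5, 0, 12), m, 5,
                    dimnames = list(items, colnames(C)))

  noise <- matrix(stats::rnorm(S * m, 0, spec$questionnaire_noise_sd), S, m)
  M <- clip(W_true %*% t(Q_true) + C %*% t(Qc_true) + noise, 0, 100)
  dimnames(M) <- list(scan_ids, items)

  target_true <- as.numeric(scale(W_true[, min(2, d)]))
  wakefulness <- clip(stats::rnorm(S, 70, 15), 0, 100)

  dataset <- structure(
    list(M = M, scan_ids = scan_ids, subject_ids = subject_ids,
         wakefulness = wakefulness, demographics = demographics,
         motion_mean = rep(NA_real_, S)),
    class = "experience_dataset")
  truth <- structure(
    list(W_true = W_true, Q_true = Q_true, Qc_true = Qc_true,
         group_labels = profile[rep(seq_len(ns), each = k)],
         target_true = target_true, subject_profile = profile),
    class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' @export
print.experience_dataset <- function(x, ...) {
  cat(sprintf("Experience dataset: %d scans x %d items, %d subjects\n",
              nrow(x$M), ncol(x$M), length(unique(x$subject_ids))))
  invisible(x)
}

# Base block correlation: within-network correlation 0.35, zero between.
base_block_correlation <- function(atlas, rho = 0.35) {
  n <- nrow(atlas)
  Cb <- matrix(0, n, n)
  for (net in unique(atlas$network)) {
    idx <- which(atlas$network == net)
    Cb[idx, idx] <- rho
  }
  diag(Cb) <- 1
  Cb
}

# Approximate sampling sd of an empirical correlation around rho0 at T points.
r_sampling_sd <- function(rho0, T) (1 - rho0^2) / sqrt(T - 3)

#' Generate per-scan FC matrices with planted effects
#'
#' Each scan's node time series are drawn from a scan-specific latent
#' correlation matrix: a block structure (networks as blocks) plus (i) a
#' shift on `effect_edges` for scans in the high-TP2 group, calibrated so the
#' realised Cohen's d on the empirical edge strength matches
#' `group_effect_size`, and (ii) a contribution proportional to the
#' standardised behavioural score on a designated behaviour-edge subset,
#' calibrated so the edge-strength sum correlates with the score at
#' approximately `behavior_effect_r`. FC is computed with [compute_fc()].
#'
#' @param spec A [synthetic_spec()].
#' @param truth The `truth` component from [generate_experience()].
#' @param return_timeseries If `TRUE`, also return the raw node x timepoint
#'   series per scan.
#' @return A `connectivity_stack` with extra fields `planted`
#'   (`effect_edges`, `behavior_edges`, both as node-pair matrices and
#'   canonical edge ids) recorded for auditing.
#' @export
generate_connectivity <- function(spec, truth, return_timeseries = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "synthetic_truth"))
  S <- nrow(truth$W_true)
  n <- spec$n_nodes; T <- spec$n_timepoints
  validate_effect_edges(spec$effect_edges, n)
  set.seed(derive_seed(spec$seed, "connectivity"))

  atlas <- make_toy_atlas(n)
  Cb <- base_block_correlation(atlas)
  eidx <- upper_tri_pairs(n)

  # Behaviour edges: drawn away from the planted group component.
  eff_ids <- edge_ids(spec$effect_edges, n)
  pool <- setdiff(seq_len(nrow(eidx)), eff_ids)
  beh_ids <- sort(sample(pool, spec$n_behavior_edges))
  beh_edges <- eidx[beh_ids, , drop = FALSE]

  # Calibration (on the correlation scale): the across-scan sd of an
  # empirical edge strength is approximately its sampling sd at T points.
  rho0_eff <- Cb[as.matrix(spec$effect_edges)]
  delta <- spec$group_effect_size * mean(r_sampling_sd(rho0_eff, T))
  rho0_beh <- Cb[beh_edges]
  sd_beh <- mean(r_sampling_sd(rho0_beh, T))
  r_target <- spec$behavior_effect_r
  gamma <- if (r_target == 0) 0 else
    sd_beh / sqrt(spec$n_behavior_edges) * abs(r_target) / sqrt(1 - min(r_target^2, 0.99)) *
    sign(r_target)

  z <- truth$target_true
  in_group <- truth$group_labels == "Surr-Neg-Self"
  mats <- array(NA_real_, c(n, n, S))
  ts_list <- if (return_timeseries) vector("list", S) else NULL
  for (s in seq_len(S)) {
    Cs <- Cb
    if (in_group[s] && delta != 0) {
      Cs[as.matrix(spec$effect_edges)] <- Cs[as.matrix(spec$effect_edges)] + delta
      Cs[as.matrix(spec$effect_edges)[, 2:1, drop = FALSE]] <-
        Cs[as.matrix(spec$effect_edges)]
    }
    if (gamma != 0) {
      Cs[beh_edges] <- Cs[beh_edges] + gamma * z[s]
      Cs[beh_edges[, 2:1, drop = FALSE]] <- Cs[beh_edges]
    }
    # guard positive definiteness (perturbations are small)
    ev <- eigen(Cs, symmetric = TRUE)
    if (min(ev$values) < 1e-4) {
      Cs <- ev$vectors %*% (pmax(ev$values, 1e-4) * t(ev$vectors))
      Cs <- stats::cov2cor(Cs)
    }
    L <- chol(Cs)
    X <- t(matrix(stats::rnorm(T * n), T, n) %*% L)  # nodes x timepoints
    mats[, , s] <- compute_fc(X)
    if (return_timeseries) ts_list[[s]] <- X
  }

  stack <- fc_stack(mats, atlas, scan_ids = rownames(truth$W_true))
  stack$planted <- list(effect_edges = spec$effect_edges,
                        effect_edge_ids = eff_ids,
                        behavior_edges = beh_edges,
                        behavior_edge_ids = beh_ids)
  if (return_timeseries) stack$timeseries <- ts_list
  stack
}

#' Generate per-scan relative-displacement traces
#'
#' Baseline displacement stays below the 0.3 mm censoring threshold; spikes
#' above it occur independently per volume at `motion_spike_rate`.
#'
#' @param spec A [synthetic_spec()].
#' @return List of numeric traces (one per scan, `n_timepoints` values).
#' @export
generate_motion_traces <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, "motion"))
  S <- spec$n_subjects * spec$scans_per_subject
  T <- spec$n_timepoints
  lapply(seq_len(S), function(s) {
    base <- clip(abs(stats::rnorm(T, 0.08, 0.04)), 0, 0.25)
    spike <- stats::runif(T) < spec$motion_spike_rate
    base[spike] <- stats::runif(sum(spike), 0.35, 1.0)
    base
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_experience()],
#' [generate_connectivity()] and [generate_motion_traces()] and filling the
#' per-scan mean motion into the dataset.
#'
#' @param spec A [synthetic_spec()].
#' @param return_timeseries Passed to [generate_connectivity()].
#' @return List with `dataset`, `truth`, `stack`, `motion` (list of traces).
#' @export
generate_study <- function(spec, return_timeseries = FALSE) {
  ge <- generate_experience(spec)
  stack <- generate_connectivity(spec, ge$truth, return_timeseries)
  motion <- generate_motion_traces(spec)
  ge$dataset$motion_mean <- vapply(motion, mean, numeric(1))
  list(dataset = ge$dataset, truth = ge$truth, stack = stack, motion = motion)
}
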