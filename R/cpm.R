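# Connectome-based predictive modeling: motion residualization, sign-split
# edge selection, the two-sum linear model, grouped cross-validation repeated
# with fresh fold draws, subject-level permutation significance, FDR across
# targets, and consensus-edge extraction.

#' CPM configuration
#'
#' @param edge_p Edge-selection significance threshold (default 0.01,
#'   two-sided).
#' @param n_folds Cross-validation folds (default 10; subjects, not scans,
#'   are partitioned).
#' @param n_iters Repetitions of the whole CV with fresh fold draws
#'   (default 100).
#' @param n_null Null permutations for significance (default 10000).
#' @param consensus_frac Inclusion fraction for the consensus model
#'   (default 0.90, boundary inclusive).
#' @param seed Integer seed.
#' @return Object of class `cpm_config`.
#' @export
cpm_config <- function(edge_p = 0.01, n_folds = 10, n_iters = 100,
                       n_null = 10000, consensus_frac = 0.90, seed = 1) {
  stopifnot(edge_p > 0, edge_p < 1, n_folds >= 2, n_iters >= 1, n_null >= 1,
            consensus_frac > 0, consensus_frac <= 1)
  structure(list(edge_p = edge_p, n_folds = n_folds, n_iters = n_iters,
                 n_null = n_null, consensus_frac = consensus_frac,
                 seed = as.integer(seed)),
            class = "cpm_config")
}

#' Residualize a prediction target with respect to head motion
#'
#' Least-squares residual of `y` on `[intercept, motion]`; the result is
#' mean-zero and orthogonal to motion.
#'
#' @param y Numeric target vector.
#' @param motion Numeric per-scan head-motion summary.
#' @return Residual vector.
#' @export
residualize_target <- function(y, motion) {
  stopifnot(length(y) == length(motion), all(is.finite(motion)))
  if (stats::var(motion) == 0) {
    warning("zero-variance motion; returning demeaned target")
    return(y - mean(y))
  }
  stats::lm.fit(cbind(1, motion), y)$residuals
}

#' Select edges correlating with the target
#'
#' Per edge, Pearson correlation with `y`; two-sided p-value from the exact
#' Student-t transform; edges with `p < edge_p` split by correlation sign.
#' Constant edges are excluded (not errored).
#'
#' @param fc_train Training scans x edges matrix.
#' @param y_train Training target vector.
#' @param edge_p Selection threshold (default 0.01).
#' @return List with `pos_edges`, `neg_edges` (canonical edge indices),
#'   `r` (per-edge correlations, `NA` for constant edges).
#' @export
select_edges <- function(fc_train, y_train, edge_p = 0.01) {
  X <- if (is.matrix(fc_train)) fc_train else as.matrix(fc_train)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 training scans")
  r <- suppressWarnings(as.numeric(stats::cor(X, y_train)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  sel <- which(is.finite(p) & p < edge_p)
  list(pos_edges = sel[r[sel] > 0], neg_edges = sel[r[sel] < 0], r = r)
}

#' Fit the two-sum CPM linear model
#'
#' Ordinary least squares of `y` on `[1, X_pos, X_neg]`, where `X_pos` /
#' `X_neg` are per-scan sums of connectivity strength over the selected
#' positive / negative edge sets. An empty set drops its regressor and
#' reports a zero coefficient; both sets empty yields an intercept-only
#' model with a warning.
#'
#' @param fc_train Training scans x edges matrix.
#' @param y_train Training target vector.
#' @param pos_edges,neg_edges Canonical edge indices from [select_edges()].
#' @return Object of class `cpm_model`: `beta0`, `beta1`, `beta2`,
#'   `pos_edges`, `neg_edges`.
#' @export
fit_model <- function(fc_train, y_train, pos_edges, neg_edges) {
  X <- if (is.matrix(fc_train)) fc_train else as.matrix(fc_train)
  xp <- if (length(pos_edges)) rowSums(X[, pos_edges, drop = FALSE]) else NULL
  xn <- if (length(neg_edges)) rowSums(X[, neg_edges, drop = FALSE]) else NULL
  if (is.null(xp) && is.null(xn)) {
    warning("both edge sets empty; intercept-only model")
    betas <- c(mean(y_train), 0, 0)
  } else {
    Dm <- cbind(1, xp, xn)
    cf <- stats::lm.fit(Dm, y_train)$coefficients
    cf[is.na(cf)] <- 0
    betas <- c(cf[1],
               if (is.null(xp)) 0 else cf[2],
               if (is.null(xn)) 0 else cf[length(cf)])
  }
  structure(list(beta0 = unname(betas[1]), beta1 = unname(betas[2]),
                 beta2 = unname(betas[3]),
                 pos_edges = as.integer(pos_edges),
                 neg_edges = as.integer(neg_edges)),
            class = "cpm_model")
}

#' Predict from a CPM model
#'
#' @param object A `cpm_model`.
#' @param newdata Scans x edges matrix.
#' @param ... Unused.
#' @return Predicted values.
#' @export
predict.cpm_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else as.matrix(newdata)
  xp <- if (length(object$pos_edges))
    rowSums(X[, object$pos_edges, drop = FALSE]) else 0
  xn <- if (length(object$neg_edges))
    rowSums(X[, object$neg_edges, drop = FALSE]) else 0
  object$beta0 + object$beta1 * xp + object$beta2 * xn
}

# Deal subjects into folds: shuffled, round-robin. Returns per-subject fold.
subject_folds <- function(subjects, n_folds, seed) {
  set.seed(seed)
  if (length(subjects) < n_folds) {
    warning("fewer subjects than folds; reducing folds to ", length(subjects))
    n_folds <- length(subjects)
  }
  ord <- sample(subjects)
  stats::setNames(rep_len(seq_len(n_folds), length(ord)), ord)
}

#' Run connectome-based predictive modeling
#'
#' Repeats grouped k-fold cross-validation `n_iters` times with fresh fold
#' draws: subjects (never scans) are partitioned into folds, so no subject
#' ever spans the training and test side of a split; this is asserted
#' programmatically on every fold. Per iteration, out-of-fold predictions
#' are pooled over all scans and accuracy is their Pearson correlation with
#' the observed targets.
#'
#' @param fc Scans x edges matrix (or `connectivity_stack`).
#' @param y Prediction target (already residualized if desired).
#' @param subject_ids Per-scan subject identifiers.
#' @param config A [cpm_config()].
#' @return Object of class `cpm_result`: `r_obs` (per-iteration accuracy),
#'   `r_obs_median`, `per_fit_edges` (pos/neg edge sets for every
#'   fold x iteration fit), `folds` (per-iteration subject fold maps),
#'   `consensus` (consensus `cpm_model`), `config`.
#' @export
run_cpm <- function(fc, y, subject_ids, config = cpm_config()) {
  X <- if (inherits(fc, "connectivity_stack"))
    stack_to_edge_matrix(fc$matrices) else as.matrix(fc)
  stopifnot(nrow(X) == length(y), length(y) == length(subject_ids))
  subjects <- unique(subject_ids)

  r_obs <- numeric(config$n_iters)
  per_fit <- list()
  fold_maps <- vector("list", config$n_iters)
  for (it in seq_len(config$n_iters)) {
    fmap <- subject_folds(subjects, config$n_folds,
                          derive_seed(config$seed, paste0("cpm-iter-", it)))
    fold_maps[[it]] <- fmap
    fold_of_scan <- fmap[subject_ids]
    yhat <- rep(NA_real_, length(y))
    for (f in sort(unique(fold_of_scan))) {
      test <- fold_of_scan == f
      # grouped-CV leakage assertion: a subject is wholly in or wholly out
      stopifnot(length(intersect(subject_ids[test], subject_ids[!test])) == 0)
      sel <- select_edges(X[!test, , drop = FALSE], y[!test], config$edge_p)
      mod <- suppressWarnings(
        fit_model(X[!test, , drop = FALSE], y[!test],
                  sel$pos_edges, sel$neg_edges))
      yhat[test] <- predict(mod, X[test, , drop = FALSE])
      per_fit[[length(per_fit) + 1L]] <- list(pos = mod$pos_edges,
                                              neg = mod$neg_edges)
    }
    r_obs[it] <- if (stats::sd(yhat) == 0) 0 else stats::cor(y, yhat)
  }

  cons <- consensus_model(per_fit, config$consensus_frac)
  # coefficients of the consensus model refit on the full sample
  cons_fit <- suppressWarnings(
    fit_model(X, y, cons$pos_edges, cons$neg_edges))
  structure(
    list(r_obs = r_obs, r_obs_median = stats::median(r_obs),
         per_fit_edges = per_fit, folds = fold_maps, consensus = cons_fit,
         config = config),
    class = "cpm_result")
}

#' @export
print.cpm_result <- function(x, ...) {
  cat("Connectome-based predictive modeling\n")
  cat(sprintf("  %d iterations x %d folds; median accuracy r = %.3f\n",
              x$config$n_iters, x$config$n_folds, x$r_obs_median))
  cat(sprintf("  consensus model: %d positive, %d negative edges\n",
              length(x$consensus$pos_edges), length(x$consensus$neg_edges)))
  invisible(x)
}

#' Permutation null distribution of CPM accuracy
#'
#' Each null draw permutes the target at the subject level (all scans of a
#' subject receive one shared permuted value -- the subject's mean target
#' reassigned to another subject -- respecting the grouping the CV enforces)
#' and runs one full CPM pass (one CV repetition per draw).
#'
#' @inheritParams run_cpm
#' @return Numeric vector of `config$n_null` null accuracies.
#' @export
permutation_null <- function(fc, y, subject_ids, config = cpm_config()) {
  X <- if (inherits(fc, "connectivity_stack"))
    stack_to_edge_matrix(fc$matrices) else as.matrix(fc)
  subjects <- unique(subject_ids)
  subj_val <- tapply(y, factor(subject_ids, subjects), mean)
  r_null <- numeric(config$n_null)
  one_pass <- cpm_config(edge_p = config$edge_p, n_folds = config$n_folds,
                         n_iters = 1, n_null = 1,
                         consensus_frac = config$consensus_frac,
                         seed = config$seed)
  for (b in seq_len(config$n_null)) {
    set.seed(derive_seed(config$seed, paste0("cpm-null-", b)))
    y_null <- as.numeric(subj_val[sample(length(subjects))])[
      match(subject_ids, subjects)]
    cfg_b <- one_pass
    cfg_b$seed <- derive_seed(config$seed, paste0("cpm-null-cv-", b))
    r_null[b] <- run_cpm(X, y_null, subject_ids, cfg_b)$r_obs[1]
  }
  r_null
}

#' Non-parametric permutation p-value for CPM accuracy
#'
#' `(sum(r_null > median(r_obs)) + 1) / (n_null + 1)`: strict inequality,
#' +1 smoothing, always in `(0, 1]`.
#'
#' @param r_obs Observed per-iteration accuracies.
#' @param r_null Null accuracies.
#' @return The p-value.
#' @export
nonparametric_p <- function(r_obs, r_null) {
  stopifnot(length(r_obs) >= 1, length(r_null) >= 1)
  (sum(r_null > stats::median(r_obs)) + 1) / (length(r_null) + 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values across a family of prediction targets.
#'
#' @param p_values Vector of p-values in `(0, 1]`.
#' @return Adjusted q-values (monotone in rank).
#' @export
fdr_correct <- function(p_values) {
  stopifnot(all(p_values > 0), all(p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Consensus edge model across CPM fits
#'
#' An edge enters the consensus set (separately by sign) when its inclusion
#' fraction across all fold x iteration fits is at least `consensus_frac`
#' (boundary inclusive).
#'
#' @param per_fit_edge_sets List of fits, each `list(pos = ..., neg = ...)`.
#' @param consensus_frac Inclusion threshold (default 0.90).
#' @return List with `pos_edges`, `neg_edges`.
#' @export
consensus_model <- function(per_fit_edge_sets, consensus_frac = 0.90) {
  n_fit <- length(per_fit_edge_sets)
  stopifnot(n_fit >= 1)
  count_frac <- function(which_sign) {
    all_e <- unlist(lapply(per_fit_edge_sets, `[[`, which_sign))
    if (length(all_e) == 0) return(integer(0))
    tab <- table(all_e) / n_fit
    # tolerance so that an exact 90% inclusion is retained despite rounding
    as.integer(names(tab)[tab >= consensus_frac - 1e-12])
  }
  list(pos_edges = sort(count_frac("pos")), neg_edges = sort(count_frac("neg")))
}
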