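# Bounded, confound-aware questionnaire factorization.
#
# The model decomposes a scans x items response matrix M (entries in
# [0, 100]) as M ~ [W, C] %*% t([Q, Qc]) where W (scans x d, entries in
# [0, 1]) holds per-scan loadings on d latent thought patterns, C is a known
# scans x 5 confound matrix (intercept, age encoding, gender one-hot) and
# Q / Qc (items x d, items x 5, entries in [0, 100]) carry item weights for
# the latent patterns and the confounds. Fitting minimises
#   || M - [W,C] [Q,Qc]' ||_F^2 + beta_W ||W||_1 + beta_Q (||Q||_1 + ||Qc||_1)
# subject to the box constraints, by deterministic block proximal-gradient
# descent: each block takes majorization steps of size 1/L (L the spectral
# norm of the block Gram matrix) followed by the exact prox of the L1 term
# plus box projection. Because every variable is non-negative, the L1 prox is
# a constant shift before clipping, and each block step is guaranteed not to
# increase the objective.

#' Encode demographic confounds
#'
#' Builds the 5-column confound matrix: an intercept column of ones, two
#' columns holding a 2-bit binary encoding of the ordinal age bin (each bit
#' in \{0, 1\}), and a two-column one-hot encoding of gender (levels ordered
#' alphabetically).
#'
#' @param demographics Data frame with columns `age_bin` (integer index
#'   `0..K-1`, `K <= 4`) and `gender` (exactly two observed levels).
#' @return Numeric matrix with columns
#'   `intercept`, `age_1`, `age_2`, `gender_1`, `gender_2`.
#' @export
encode_confounds <- function(demographics) {
  stopifnot(is.data.frame(demographics))
  if (!all(c("age_bin", "gender") %in% names(demographics)))
    stop("demographics must have columns 'age_bin' and 'gender'")
  age <- demographics$age_bin
  gen <- as.character(demographics$gender)
  if (anyNA(age) || anyNA(gen)) stop("missing demographics")
  if (!all(age == floor(age)) || any(age < 0) || any(age > 3))
    stop("age_bin must be an ordinal index 0..3")
  lev <- sort(unique(gen))
  if (length(lev) != 2) stop("gender must have exactly two observed levels, got: ",
                             paste(lev, collapse = ", "))
  C <- cbind(
    intercept = rep(1, length(age)),
    age_1 = age %/% 2,
    age_2 = age %% 2,
    gender_1 = as.numeric(gen == lev[1]),
    gender_2 = as.numeric(gen == lev[2])
  )
  storage.mode(C) <- "double"
  C
}

# One full pass of exact column-wise (HALS-style) updates over the three
# blocks (Q, Qc, W), with optional observation mask (1 = observed). With a
# single factor column held out, the objective is an elementwise-separable
# box-constrained quadratic, so each column update is an exact minimisation
# (closed form: least-squares solution shifted by the L1 weight, then
# clipped) and the objective can never increase.
icqf_pass <- function(M, C, W, Q, Qc, beta_W, beta_Q, mask = NULL) {
  eps <- 1e-12
  R <- M - W %*% t(Q) - C %*% t(Qc)   # running residual
  if (is.null(mask)) {
    for (j in seq_len(ncol(Q))) {     # Q columns
      Rj <- R + W[, j] %*% t(Q[, j])
      den <- max(sum(W[, j]^2), eps)
      qn <- clip((crossprod(Rj, W[, j]) - beta_Q / 2) / den, 0, 100)
      Q[, j] <- qn
      R <- Rj - W[, j] %*% t(Q[, j])
    }
    for (j in seq_len(ncol(C))) {     # Qc columns
      Rj <- R + C[, j] %*% t(Qc[, j])
      den <- max(sum(C[, j]^2), eps)
      qn <- clip((crossprod(Rj, C[, j]) - beta_Q / 2) / den, 0, 100)
      Qc[, j] <- qn
      R <- Rj - C[, j] %*% t(Qc[, j])
    }
    for (j in seq_len(ncol(W))) {     # W columns
      Rj <- R + W[, j] %*% t(Q[, j])
      den <- max(sum(Q[, j]^2), eps)
      wn <- clip((Rj %*% Q[, j] - beta_W / 2) / den, 0, 1)
      W[, j] <- wn
      R <- Rj - W[, j] %*% t(Q[, j])
    }
  } else {
    # masked entries carry zero weight; rows/items decouple within a column
    for (j in seq_len(ncol(Q))) {
      Rj <- R + W[, j] %*% t(Q[, j])
      num <- crossprod(Rj * mask, W[, j]) - beta_Q / 2
      den <- pmax(crossprod(mask, W[, j]^2), eps)
      Q[, j] <- clip(num / den, 0, 100)
      R <- Rj - W[, j] %*% t(Q[, j])
    }
    for (j in seq_len(ncol(C))) {
      Rj <- R + C[, j] %*% t(Qc[, j])
      num <- crossprod(Rj * mask, C[, j]) - beta_Q / 2
      den <- pmax(crossprod(mask, C[, j]^2), eps)
      Qc[, j] <- clip(num / den, 0, 100)
      R <- Rj - C[, j] %*% t(Qc[, j])
    }
    for (j in seq_len(ncol(W))) {
      Rj <- R + W[, j] %*% t(Q[, j])
      num <- (Rj * mask) %*% Q[, j] - beta_W / 2
      den <- pmax(mask %*% Q[, j]^2, eps)
      W[, j] <- clip(num / den, 0, 1)
      R <- Rj - W[, j] %*% t(Q[, j])
    }
  }
  list(W = W, Q = Q, Qc = Qc)
}

# Confound re-attribution: structure in W that is linearly explainable by the
# non-intercept confound columns can equally be written through Qc (for
# W = C2 A + W_perp, W Q' = C2 (Q A')' + W_perp Q'), so the W/Qc split is
# only identified through the L1 penalty on W. This step proposes moving the
# C-explainable part of W into Qc and accepts the move only when it does not
# increase the penalised objective (box clipping can make it inexact).
icqf_reattribute <- function(M, C, W, Q, Qc, beta_W, beta_Q, mask, obj_now) {
  C2 <- C[, -1, drop = FALSE]
  A <- tryCatch(stats::lm.fit(cbind(1, C2), W)$coefficients[-1, , drop = FALSE],
                error = function(e) NULL)
  if (is.null(A)) return(list(W = W, Qc = Qc, obj = obj_now))
  keep <- !apply(is.na(A), 1, any)   # aliased columns (e.g. second one-hot)
  if (!any(keep)) return(list(W = W, Qc = Qc, obj = obj_now))
  A <- A[keep, , drop = FALSE]
  C2 <- C2[, keep, drop = FALSE]
  if (max(abs(A)) < 1e-10) return(list(W = W, Qc = Qc, obj = obj_now))
  # box clipping makes the full move inexact; back off until it helps
  for (step in c(1, 0.5, 0.25, 0.1)) {
    W_try <- clip(W - step * (C2 %*% A), 0, 1)
    Qc_try <- Qc
    Qc_try[, c(FALSE, keep)] <-
      clip(Qc[, c(FALSE, keep), drop = FALSE] + step * (Q %*% t(A)), 0, 100)
    obj_try <- icqf_objective(M, C, W_try, Q, Qc_try, beta_W, beta_Q, mask)
    if (obj_try <= obj_now)
      return(list(W = W_try, Qc = Qc_try, obj = obj_try))
  }
  list(W = W, Qc = Qc, obj = obj_now)
}

icqf_objective <- function(M, C, W, Q, Qc, beta_W, beta_Q, mask = NULL) {
  R <- M - W %*% t(Q) - C %*% t(Qc)
  if (!is.null(mask)) R <- R * mask
  sum(R^2) + beta_W * sum(W) + beta_Q * (sum(Q) + sum(Qc))
}

#' Fit the bounded confound-aware factorization
#'
#' @param M Scans x items response matrix, entries in `[0, 100]`.
#' @param C Confound matrix from [encode_confounds()].
#' @param d Number of latent dimensions (`>= 1`).
#' @param beta_W,beta_Q L1 sparsity weights for `W` and for `Q`/`Qc`.
#' @param max_iter Maximum outer iterations.
#' @param tol Relative objective-change stopping tolerance.
#' @param seed Integer seed (the solver is deterministic; the seed is kept in
#'   the interface for reproducibility bookkeeping and any future randomized
#'   restart).
#' @param mask Optional 0/1 matrix of observed entries (used by the
#'   entry-masking cross-validation); `NULL` fits all entries.
#' @return Object of class `icqf_fit` with elements `W`, `Q`, `Qc`, `d`,
#'   `beta_W`, `beta_Q`, `objective_trace`, `converged`, `iterations`.
#' @export
fit_icqf <- function(M, C, d = 2, beta_W = 0.0, beta_Q = 0.01,
                     max_iter = 500, tol = 1e-6, seed = 1, mask = NULL) {
  M <- as.matrix(M); C <- as.matrix(C)
  if (!all(is.finite(M)) || !all(is.finite(C))) stop("non-finite inputs")
  if (min(M) < 0 || max(M) > 100) stop("M entries must lie in [0, 100]")
  if (nrow(M) != nrow(C)) stop("M and C row counts differ")
  if (d < 1) stop("d must be >= 1")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    stopifnot(identical(dim(mask), dim(M)), all(mask %in% c(0, 1)))
  }

  # The W / Qc split is only partially identified: the free per-scan
  # loadings W can imitate any confound column, and only the L1 penalty on W
  # favours attributing shared structure to the confounds. Block descent
  # cannot migrate structure between the two blocks once settled, so both
  # attributions are tried from deterministic starts -- factors seeded from
  # the raw responses, or confounds regressed out first -- and the fit with
  # the lower final penalised objective is returned.
  fits <- lapply(c("factor-first", "confound-first"), function(init)
    icqf_fit_once(M, C, d, beta_W, beta_Q, max_iter, tol, mask, init))
  objs <- vapply(fits, function(f) utils::tail(f$objective_trace, 1), numeric(1))
  best <- fits[[which.min(objs)]]
  if (!best$converged)
    warning("fit_icqf: objective did not converge within max_iter = ", max_iter)
  W <- best$W; Q <- best$Q; Qc <- best$Qc
  dimnames(W) <- list(rownames(M), paste0("TP", seq_len(d)))
  dimnames(Q) <- list(colnames(M), paste0("TP", seq_len(d)))
  dimnames(Qc) <- list(colnames(M), colnames(C))
  structure(
    list(W = W, Q = Q, Qc = Qc, d = d, beta_W = beta_W, beta_Q = beta_Q,
         objective_trace = best$objective_trace, converged = best$converged,
         iterations = best$iterations, init = best$init, seed = seed),
    class = "icqf_fit"
  )
}

icqf_fit_once <- function(M, C, d, beta_W, beta_Q, max_iter, tol, mask, init) {
  n <- nrow(M); m <- ncol(M)
  Q <- matrix(0, m, d)
  Qc <- matrix(0, m, ncol(C))
  if (init == "confound-first") {
    for (k in 1:3) {
      st0 <- icqf_pass(M, C, matrix(0, n, d), matrix(0, m, d), Qc,
                       beta_W, beta_Q, mask)
      Qc <- st0$Qc
    }
  }
  # W starts from the leading left singular vectors of (the positive part
  # of) the current residual, rectified and scaled into [0, 1].
  R0 <- pmax(M - C %*% t(Qc), 0)
  if (!is.null(mask)) R0 <- R0 * mask
  sv <- svd(R0, nu = min(d, min(n, m)), nv = 0)
  W <- abs(sv$u)
  if (ncol(W) < d) W <- cbind(W, matrix(0.5, n, d - ncol(W)))
  mx <- apply(W, 2, max)
  W <- sweep(W, 2, pmax(mx, 1e-12), "/")

  obj <- icqf_objective(M, C, W, Q, Qc, beta_W, beta_Q, mask)
  trace <- numeric(max_iter + 1L); trace[1] <- obj
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    st <- icqf_pass(M, C, W, Q, Qc, beta_W, beta_Q, mask)
    W <- st$W; Q <- st$Q; Qc <- st$Qc
    new_obj <- icqf_objective(M, C, W, Q, Qc, beta_W, beta_Q, mask)
    if (it %% 5 == 0) {
      ra <- icqf_reattribute(M, C, W, Q, Qc, beta_W, beta_Q, mask, new_obj)
      W <- ra$W; Qc <- ra$Qc; new_obj <- ra$obj
    }
    trace[it + 1L] <- new_obj
    if (abs(obj - new_obj) <= tol * max(obj, 1e-12)) {
      converged <- TRUE
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  list(W = W, Q = Q, Qc = Qc, objective_trace = trace[seq_len(it + 1L)],
       converged = converged, iterations = it, init = init)
}

#' @export
print.icqf_fit <- function(x, ...) {
  cat("Bounded confound-aware factorization\n")
  cat(sprintf("  scans: %d  items: %d  d: %d\n", nrow(x$W), nrow(x$Q), x$d))
  cat(sprintf("  beta_W: %g  beta_Q: %g\n", x$beta_W, x$beta_Q))
  cat(sprintf("  objective: %.4g after %d iterations (converged: %s)\n",
              utils::tail(x$objective_trace, 1), x$iterations, x$converged))
  invisible(x)
}

# Infer W rows for new scans at fixed Q, Qc (bounded least squares by
# projected gradient). Used by the scan-fold CV scheme.
infer_W <- function(M_new, C_new, Q, Qc, beta_W = 0, n_steps = 200) {
  n <- nrow(M_new); d <- ncol(Q)
  W <- matrix(0.5, n, d)
  L <- 2 * max(eigen(crossprod(Q), symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  target <- M_new - C_new %*% t(Qc)
  for (k in seq_len(n_steps)) {
    G <- -2 * (target - W %*% t(Q)) %*% Q
    W_new <- clip(W - (G + beta_W) / L, 0, 1)
    if (max(abs(W_new - W)) < 1e-10) { W <- W_new; break }
    W <- W_new
  }
  W
}

#' Default hyperparameter exploration grid
#'
#' Dimensions 1--4 crossed with sparsity weights
#' \{0.0, 0.01, 0.1, 1, 2, 3\} for both `beta_W` and `beta_Q`.
#'
#' @return Data frame with columns `d`, `beta_W`, `beta_Q` (144 rows).
#' @export
icqf_default_grid <- function() {
  g <- expand.grid(beta_Q = c(0.0, 0.01, 0.1, 1, 2, 3),
                   beta_W = c(0.0, 0.01, 0.1, 1, 2, 3),
                   d = 1:4)
  g <- g[, c("d", "beta_W", "beta_Q")]
  g[order(g$d, g$beta_W, g$beta_Q), , drop = FALSE]
}

#' Cross-validated hyperparameter selection
#'
#' Scores every grid point by held-out reconstruction error and returns the
#' argmin (ties broken toward smaller `d`, then smaller `beta_W`, then
#' smaller `beta_Q`) together with the full table.
#'
#' Two fold schemes are available. The default, `method = "entry"`, masks a
#' random fold of matrix entries, fits on the remaining entries, and scores
#' squared error on the masked entries (Wold-style cross-validation; held-out
#' entries never touch the fit, so extra dimensions that only absorb noise
#' raise the score). `method = "scan"` holds out whole scans and infers their
#' loadings at fixed `Q`, `Qc` before scoring; because held-out loadings are
#' refit on the scored entries, this scheme is biased toward larger `d` and
#' is retained for comparison only.
#'
#' @param M,C As in [fit_icqf()].
#' @param grid Data frame of candidate `(d, beta_W, beta_Q)` rows; defaults
#'   to [icqf_default_grid()].
#' @param n_folds Number of folds (`>= 2`).
#' @param seed Integer seed controlling fold assignment.
#' @param method `"entry"` (default) or `"scan"`.
#' @param max_iter,tol Passed to the per-fold fits.
#' @return List with `d`, `beta_W`, `beta_Q` and `cv_table` (grid plus
#'   `cv_error`, mean held-out squared error per entry).
#' @export
select_hyperparameters <- function(M, C, grid = icqf_default_grid(),
                                   n_folds = 5, seed = 1,
                                   method = c("entry", "scan"),
                                   max_iter = 80, tol = 3e-4) {
  method <- match.arg(method)
  M <- as.matrix(M); C <- as.matrix(C)
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  if (n_folds < 2) stop("n_folds must be >= 2")
  n <- nrow(M); m <- ncol(M)

  set.seed(derive_seed(seed, "hyperparameter-cv"))
  if (method == "entry") {
    fold_of_entry <- matrix(sample(rep_len(seq_len(n_folds), n * m)), n, m)
  } else {
    fold_of_scan <- sample(rep_len(seq_len(n_folds), n))
  }

  cv_error <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    d <- grid$d[g]; bW <- grid$beta_W[g]; bQ <- grid$beta_Q[g]
    sse <- 0; n_held <- 0
    for (f in seq_len(n_folds)) {
      if (method == "entry") {
        mask <- (fold_of_entry != f) * 1
        fit <- suppressWarnings(
          fit_icqf(M, C, d = d, beta_W = bW, beta_Q = bQ,
                   max_iter = max_iter, tol = tol, seed = seed, mask = mask))
        Mhat <- fit$W %*% t(fit$Q) + C %*% t(fit$Qc)
        held <- fold_of_entry == f
        sse <- sse + sum((M[held] - Mhat[held])^2)
        n_held <- n_held + sum(held)
      } else {
        test <- fold_of_scan == f
        if (sum(!test) < d) {
          warning("fold ", f, " has fewer scans than d = ", d, "; skipped")
          next
        }
        fit <- suppressWarnings(
          fit_icqf(M[!test, , drop = FALSE], C[!test, , drop = FALSE],
                   d = d, beta_W = bW, beta_Q = bQ,
                   max_iter = max_iter, tol = tol, seed = seed))
        W_te <- infer_W(M[test, , drop = FALSE], C[test, , drop = FALSE],
                        fit$Q, fit$Qc, beta_W = bW)
        Mhat <- W_te %*% t(fit$Q) + C[test, , drop = FALSE] %*% t(fit$Qc)
        sse <- sse + sum((M[test, , drop = FALSE] - Mhat)^2)
        n_held <- n_held + sum(test) * m
      }
    }
    cv_error[g] <- sse / max(n_held, 1)
  }

  tab <- cbind(grid, cv_error = cv_error)
  # ties toward smaller d, then smaller betas: grid is ordered that way
  ord <- order(grid$d, grid$beta_W, grid$beta_Q)
  tab <- tab[ord, , drop = FALSE]
  best_err <- min(tab$cv_error)
  best <- which(tab$cv_error <= best_err * (1 + 1e-9))[1]
  list(d = tab$d[best], beta_W = tab$beta_W[best], beta_Q = tab$beta_Q[best],
       cv_table = tab)
}

#' Align recovered factor columns to a reference
#'
#' Finds the column permutation of `W_est` maximising the mean Pearson
#' correlation with the columns of `W_ref` (exhaustive over permutations;
#' `d <= 6`). Used to evaluate recovery of ground-truth loadings, whose
#' column order is not identified by the factorization.
#'
#' @param W_est,W_ref Matrices with the same number of columns.
#' @return List with `perm` (indices into `W_est` columns) and `cors`
#'   (per-column correlations after alignment).
#' @export
align_factors <- function(W_est, W_ref) {
  d <- ncol(W_ref)
  stopifnot(ncol(W_est) == d, d <= 6)
  cm <- suppressWarnings(stats::cor(W_est, W_ref))
  cm[!is.finite(cm)] <- 0
  perms <- permutations_of(d)
  score <- apply(perms, 1, function(p) mean(cm[cbind(p, seq_len(d))]))
  best <- perms[which.max(score), ]
  list(perm = best, cors = cm[cbind(best, seq_len(d))])
}

permutations_of <- function(d) {
  if (d == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(d - 1)
  do.call(rbind, lapply(seq_len(d), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
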