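# Connectome-based predictive modeling: residualization, selection, the
# two-sum model, grouped CV, permutation null, Eq.-style p arithmetic,
# FDR and consensus extraction.

test_that("motion residualization is exact, orthogonal and mean-zero", {
  set.seed(20)
  motion <- runif(100, 0.05, 0.3)
  expect_equal(residualize_target(2 * motion, motion), rep(0, 100),
               tolerance = 1e-10, ignore_attr = TRUE)

  y_orth <- rnorm(100)
  y_orth <- y_orth - mean(y_orth)
  y_orth <- y_orth - motion * sum(y_orth * (motion - mean(motion))) /
    sum((motion - mean(motion))^2)
  y_orth <- y_orth - mean(y_orth)
  expect_equal(residualize_target(y_orth, motion), y_orth,
               tolerance = 1e-8, ignore_attr = TRUE)

  y <- rnorm(100)
  res <- residualize_target(y, motion)
  expect_lt(abs(sum(res * motion)), 1e-8)
  expect_lt(abs(mean(res)), 1e-10)
  # closed-form check
  X <- cbind(1, motion)
  expect_equal(unname(res), unname(y - X %*% ols_oracle(X, y))[, 1],
               tolerance = 1e-10)

  expect_warning(r0 <- residualize_target(y, rep(0.1, 100)), "zero-variance")
  expect_equal(r0, y - mean(y))
})

test_that("edge selection splits by sign and matches a per-edge test oracle", {
  set.seed(21)
  n <- 60
  y <- rnorm(n)
  X <- matrix(rnorm(n * 200), n)
  X[, 7] <- y
  X[, 8] <- -y
  X[, 9] <- 0.5          # constant edge: excluded, not errored
  sel <- select_edges(X, y, edge_p = 0.01)
  expect_true(7 %in% sel$pos_edges)
  expect_true(8 %in% sel$neg_edges)
  expect_false(9 %in% c(sel$pos_edges, sel$neg_edges))
  expect_length(intersect(sel$pos_edges, sel$neg_edges), 0)

  oracle_sel <- which(vapply(seq_len(ncol(X)), function(j) {
    if (sd(X[, j]) == 0) return(FALSE)
    stats::cor.test(X[, j], y)$p.value < 0.01
  }, logical(1)))
  expect_setequal(sort(c(sel$pos_edges, sel$neg_edges)), oracle_sel)

  expect_error(select_edges(X[1:3, ], y[1:3]), "at least 4")
})

test_that("the two-sum model recovers exact and noisy coefficients", {
  set.seed(22)
  n <- 80
  X <- matrix(rnorm(n * 50), n)
  pos <- c(3, 10, 11); neg <- c(20, 30)
  xp <- rowSums(X[, pos]); xn <- rowSums(X[, neg])
  y <- 2 + 3 * xp - 1 * xn
  mod <- fit_model(X, y, pos, neg)
  expect_equal(c(mod$beta0, mod$beta1, mod$beta2), c(2, 3, -1),
               tolerance = 1e-8)
  expect_equal(predict(mod, X), y, tolerance = 1e-8)

  y_noisy <- y + rnorm(n)
  mod_n <- fit_model(X, y_noisy, pos, neg)
  cf <- ols_oracle(cbind(1, xp, xn), y_noisy)
  expect_equal(c(mod_n$beta0, mod_n$beta1, mod_n$beta2), cf, tolerance = 1e-8)

  const <- fit_model(X, rep(5, n), pos, neg)
  expect_equal(const$beta0, 5, tolerance = 1e-8)
  expect_equal(c(const$beta1, const$beta2), c(0, 0), tolerance = 1e-8)

  expect_warning(empty <- fit_model(X, y, integer(0), integer(0)),
                 "intercept-only")
  expect_equal(empty$beta0, mean(y))
})

test_that("grouped CV never leaks a subject and is deterministic", {
  set.seed(23)
  S <- 90
  subs <- rep(sprintf("s%02d", 1:30), each = 3)
  X <- matrix(rnorm(S * 100), S)
  y <- rnorm(S)
  cfg <- cpm_config(n_iters = 5, n_null = 1, n_folds = 6, seed = 7)
  res <- run_cpm(X, y, subs, cfg)
  for (fmap in res$folds) {
    fold_of_scan <- fmap[subs]
    for (f in unique(fold_of_scan)) {
      inside <- unique(subs[fold_of_scan == f])
      outside <- unique(subs[fold_of_scan != f])
      expect_length(intersect(inside, outside), 0)
    }
  }
  res2 <- run_cpm(X, y, subs, cfg)
  expect_identical(res$r_obs, res2$r_obs)
})

test_that("planted noiseless edge-sum signal is predicted almost perfectly", {
  set.seed(24)
  S <- 120
  subs <- rep(sprintf("s%02d", 1:40), each = 3)
  z <- rnorm(S)
  X <- matrix(rnorm(S * 435, 0, 0.1), S)
  pos <- 1:15; neg <- 400:407
  X[, pos] <- z + matrix(rnorm(S * 15, 0, 0.02), S)
  X[, neg] <- -0.5 * z + matrix(rnorm(S * 8, 0, 0.02), S)
  y <- 2 + 3 * rowSums(X[, pos]) - rowSums(X[, neg])
  res <- run_cpm(X, y, subs, cpm_config(n_iters = 10, n_null = 1, seed = 4))
  expect_gte(res$r_obs_median, 0.99)
  # and accuracy degrades monotonically along a noise ladder
  meds <- vapply(c(0, 2, 8), function(sdn) {
    yn <- y + rnorm(S, 0, sdn)
    run_cpm(X, yn, subs, cpm_config(n_iters = 3, n_null = 1, seed = 4))$r_obs_median
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("accuracy on a target unrelated to FC is near zero", {
  set.seed(25)
  S <- 200
  subs <- rep(sprintf("s%03d", 1:100), each = 2)
  X <- matrix(rnorm(S * 300), S)
  y <- rnorm(S)
  res <- run_cpm(X, y, subs, cpm_config(n_iters = 10, n_null = 1, seed = 5))
  expect_lt(abs(res$r_obs_median), 0.1)
})

test_that("the permutation null is subject-coherent and centred at zero", {
  set.seed(26)
  S <- 200
  subs <- rep(sprintf("s%03d", 1:100), each = 2)
  X <- matrix(rnorm(S * 300), S)
  y <- rnorm(S)
  cfg <- cpm_config(n_iters = 1, n_null = 500, seed = 8)
  rn <- permutation_null(X, y, subs, cfg)
  expect_length(rn, 500)
  expect_lt(abs(median(rn)), 0.05)
  cfg_small <- cpm_config(n_iters = 1, n_null = 20, seed = 8)
  expect_identical(permutation_null(X, y, subs, cfg_small),
                   permutation_null(X, y, subs, cfg_small))
  expect_length(permutation_null(X, y, subs,
                                 cpm_config(n_iters = 1, n_null = 1, seed = 9)), 1)
})

test_that("the non-parametric p-value is evaluated exactly", {
  r_null <- c(rep(0.9, 3), rep(-0.5, 9997))
  expect_equal(nonparametric_p(c(0.1, 0.2, 0.3), r_null), 4 / 10001)
  expect_equal(nonparametric_p(0, rep(1, 10000)), 1)
  expect_equal(nonparametric_p(0.99, rep(-1, 10000)), 1 / 10001)
  # invariant to permutations of the null vector
  set.seed(27)
  rn <- rnorm(500)
  expect_equal(nonparametric_p(0.1, rn), nonparametric_p(0.1, sample(rn)))
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(rep(0.02, 5)), rep(0.02, 5))
  # direct enumeration: q_i = min over j >= i of p_(j) * m / j
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(fdr_correct(p), c(0.04, 0.04, 0.04, 0.04))
  set.seed(28)
  p_r <- runif(20)
  m <- length(p_r)
  ord <- order(p_r)
  q_oracle <- numeric(m)
  q_sorted <- sort(p_r) * m / seq_len(m)
  q_oracle[ord] <- rev(cummin(rev(q_sorted)))
  expect_equal(fdr_correct(p_r), pmin(q_oracle, 1))
})

test_that("consensus retains edges at or above the inclusion fraction", {
  fits <- c(
    replicate(900, list(pos = c(1L, 2L), neg = 5L), simplify = FALSE),
    replicate(100, list(pos = 1L, neg = integer(0)), simplify = FALSE))
  cons <- consensus_model(fits, 0.90)
  expect_true(1L %in% cons$pos_edges)     # 100% included
  expect_true(2L %in% cons$pos_edges)     # exactly 90%: retained
  expect_equal(cons$neg_edges, 5L)        # exactly 90%: retained
  fits2 <- c(
    replicate(899, list(pos = 3L, neg = integer(0)), simplify = FALSE),
    replicate(101, list(pos = integer(0), neg = integer(0)), simplify = FALSE))
  cons2 <- consensus_model(fits2, 0.90)
  expect_false(3L %in% cons2$pos_edges)   # 89.9%: excluded
})
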