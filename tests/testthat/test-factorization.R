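# Confound encoding and the bounded factorization: exact contracts,
# recovery, hyperparameter selection, invariants.

test_that("confound encoding follows the fixed scheme", {
  demo <- data.frame(age_bin = c(0, 1, 2, 3), gender = c("F", "M", "M", "F"))
  C <- encode_confounds(demo)
  expect_equal(unname(C[, "intercept"]), rep(1, 4))
  expect_equal(unname(C[, "age_1"]), c(0, 0, 1, 1))   # high bit
  expect_equal(unname(C[, "age_2"]), c(0, 1, 0, 1))   # low bit
  expect_equal(unname(C[1, c("gender_1", "gender_2")]), c(1, 0))  # F first
  expect_equal(unname(C[2, c("gender_1", "gender_2")]), c(0, 1))
  expect_equal(unname(rowSums(C[, c("gender_1", "gender_2")])), rep(1, 4))

  expect_error(encode_confounds(data.frame(age_bin = 0, gender = "X")),
               "two observed levels")
  expect_error(encode_confounds(data.frame(age_bin = NA, gender = "F")),
               "missing")
})

test_that("exact noiseless decomposition is recovered to small error", {
  set.seed(5)
  n <- 120; m <- 11
  Wt <- matrix(runif(n * 2), n)
  Qt <- matrix(runif(m * 2, 0, 40), m)
  demo <- data.frame(age_bin = sample(0:3, n, TRUE),
                     gender = sample(c("F", "M"), n, TRUE))
  C <- encode_confounds(demo)
  Qct <- matrix(runif(m * 5, 0, 3), m)
  M <- Wt %*% t(Qt) + C %*% t(Qct)   # all entries already inside [0, 100]
  fit <- suppressWarnings(fit_icqf(M, C, d = 2, beta_W = 0, beta_Q = 0,
                                   max_iter = 2000, tol = 1e-14))
  rel <- sqrt(sum((M - fit$W %*% t(fit$Q) - C %*% t(fit$Qc))^2) / sum(M^2))
  expect_lt(rel, 1e-3)
})

test_that("box constraints hold exactly and the objective never increases", {
  stu <- small_study()
  C <- encode_confounds(stu$dataset$demographics)
  for (betas in list(c(0, 0.01), c(0.5, 1))) {
    fit <- suppressWarnings(fit_icqf(stu$dataset$M, C, d = 2,
                                     beta_W = betas[1], beta_Q = betas[2],
                                     max_iter = 300))
    expect_true(all(fit$W >= 0 & fit$W <= 1))
    expect_true(all(fit$Q >= 0 & fit$Q <= 100))
    expect_true(all(fit$Qc >= 0 & fit$Qc <= 100))
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
})

test_that("latent loadings are recovered on noisy synthetic data", {
  spec <- synthetic_spec(n_subjects = 50, scans_per_subject = 3,
                         questionnaire_noise_sd = 5, seed = 11)
  ge <- generate_experience(spec)
  C <- encode_confounds(ge$dataset$demographics)
  fit <- suppressWarnings(fit_icqf(ge$dataset$M, C, d = 2))
  al <- align_factors(fit$W, ge$truth$W_true)
  expect_gte(mean(al$cors), 0.8)
})

test_that("signal injected through confounds is absorbed by Qc, not W", {
  # paired check at a sparsity level where the W/Qc attribution is identified
  # (the L1 weight on W is what disambiguates the two representations);
  # confound weights kept inside [5, 20] so the confound-only product stays
  # strictly within the response bounds and is exactly C-representable
  set.seed(31)
  n <- 150; m <- 11
  demo <- data.frame(age_bin = sample(0:3, n, TRUE),
                     gender = sample(c("F", "M"), n, TRUE))
  C <- encode_confounds(demo)
  Qct <- matrix(runif(m * 5, 5, 20), m)
  set.seed(77)
  noise <- matrix(rnorm(n * m, 0, 2), n)
  M_conf <- pmin(pmax(C %*% t(Qct) + noise, 0), 100)       # W* = 0
  Wt <- matrix(runif(n * 2), n)
  Qt <- matrix(runif(m * 2, 10, 45), m)
  M_sig <- pmin(pmax(Wt %*% t(Qt) + noise, 0), 100)        # same noise via W
  fit_conf <- suppressWarnings(fit_icqf(M_conf, C, d = 2, beta_W = 2))
  fit_sig <- suppressWarnings(fit_icqf(M_sig, C, d = 2, beta_W = 2))
  v_conf <- mean(apply(fit_conf$W, 2, var))
  v_sig <- mean(apply(fit_sig$W, 2, var))
  expect_lte(v_conf, 0.05 * v_sig)
})

test_that("hyperparameter selection returns the grid argmin with stated ties", {
  stu <- small_study()
  C <- encode_confounds(stu$dataset$demographics)
  g1 <- data.frame(d = 2, beta_W = 0, beta_Q = 0.01)
  sel1 <- select_hyperparameters(stu$dataset$M, C, grid = g1, n_folds = 3,
                                 seed = 4)
  expect_equal(nrow(sel1$cv_table), 1)
  expect_equal(sel1$d, 2)

  sel_a <- select_hyperparameters(stu$dataset$M, C,
                                  grid = expand.grid(d = 1:3, beta_W = 0,
                                                     beta_Q = c(0, 0.1)),
                                  n_folds = 3, seed = 9)
  sel_b <- select_hyperparameters(stu$dataset$M, C,
                                  grid = expand.grid(d = 1:3, beta_W = 0,
                                                     beta_Q = c(0, 0.1)),
                                  n_folds = 3, seed = 9)
  expect_identical(sel_a$cv_table, sel_b$cv_table)  # deterministic under seed
})

test_that("the default grid matches the supported exploration ranges", {
  g <- icqf_default_grid()
  expect_setequal(unique(g$d), 1:4)
  expect_setequal(unique(g$beta_W), c(0.0, 0.01, 0.1, 1, 2, 3))
  expect_setequal(unique(g$beta_Q), c(0.0, 0.01, 0.1, 1, 2, 3))
  expect_equal(nrow(g), 144)
})

test_that("refitting the same data under the same seed reproduces the fit", {
  stu <- small_study()
  C <- encode_confounds(stu$dataset$demographics)
  f1 <- suppressWarnings(fit_icqf(stu$dataset$M, C, d = 2, seed = 3,
                                  max_iter = 100))
  f2 <- suppressWarnings(fit_icqf(stu$dataset$M * 1, C, d = 2, seed = 3,
                                  max_iter = 100))
  expect_identical(f1$W, f2$W)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("non-finite input and dimension mismatches are rejected", {
  stu <- small_study()
  C <- encode_confounds(stu$dataset$demographics)
  M <- stu$dataset$M
  M[1, 1] <- NA
  expect_error(fit_icqf(M, C, d = 2), "non-finite")
  expect_error(fit_icqf(stu$dataset$M[1:10, ], C, d = 2), "row counts")
  expect_error(fit_icqf(stu$dataset$M - 50, C, d = 2), "\\[0, 100\\]")
})
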