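# Synthetic-data generator: bounds, determinism, planted structure.

test_that("questionnaire generation respects shapes, bounds and determinism", {
  spec <- synthetic_spec(n_subjects = 50, scans_per_subject = 3, n_items = 11,
                         seed = 3)
  ge <- generate_experience(spec)
  expect_equal(dim(ge$dataset$M), c(150, 11))
  expect_true(all(ge$dataset$M >= 0 & ge$dataset$M <= 100))
  expect_true(all(ge$truth$W_true >= 0 & ge$truth$W_true <= 1))
  expect_true(all(ge$truth$Q_true >= 0 & ge$truth$Q_true <= 100))
  expect_length(ge$truth$group_labels, 150)

  # same seed: bitwise identical; different seed: different responses
  ge2 <- generate_experience(spec)
  expect_identical(ge$dataset$M, ge2$dataset$M)
  spec_b <- synthetic_spec(n_subjects = 50, scans_per_subject = 3, seed = 4)
  expect_false(identical(generate_experience(spec_b)$dataset$M, ge$dataset$M))
})

test_that("noiseless responses equal the clipped factor product and refit closely", {
  spec <- synthetic_spec(n_subjects = 40, scans_per_subject = 3,
                         questionnaire_noise_sd = 0, seed = 8)
  ge <- generate_experience(spec)
  C <- encode_confounds(ge$dataset$demographics)
  prod <- ge$truth$W_true %*% t(ge$truth$Q_true) + C %*% t(ge$truth$Qc_true)
  expect_equal(ge$dataset$M, pmin(pmax(prod, 0), 100), ignore_attr = TRUE)
  fit <- suppressWarnings(fit_icqf(ge$dataset$M, C, d = 2, beta_W = 0,
                                   beta_Q = 0, max_iter = 2000, tol = 1e-12))
  rel <- sqrt(sum((ge$dataset$M - fit$W %*% t(fit$Q) - C %*% t(fit$Qc))^2) /
                sum(ge$dataset$M^2))
  expect_lt(rel, 0.02)
})

test_that("scans of one subject cluster around a shared latent mean", {
  stu <- small_study()
  W <- stu$truth$W_true
  subj <- stu$dataset$subject_ids
  within <- mean(vapply(unique(subj), function(s)
    mean(dist(W[subj == s, , drop = FALSE])), numeric(1)))
  between <- mean(dist(do.call(rbind, lapply(unique(subj), function(s)
    colMeans(W[subj == s, , drop = FALSE])))))
  expect_lt(within, between / 2)
})

test_that("empirical FC converges to the block structure at large T", {
  spec <- synthetic_spec(n_subjects = 2, scans_per_subject = 1, n_nodes = 30,
                         n_timepoints = 5000, group_effect_size = 0,
                         behavior_effect_r = 0, seed = 12)
  ge <- generate_experience(spec)
  st <- generate_connectivity(spec, ge$truth)
  fc <- st$matrices[, , 1]
  atlas <- st$atlas
  same_net <- outer(atlas$network, atlas$network, "==")
  off <- fc[!same_net & upper.tri(fc)]
  within <- fc[same_net & upper.tri(fc)]
  expect_lt(max(abs(off)), 0.12)        # off-block near 0
  expect_gt(mean(within), 0.25)         # within-block near the planted 0.35
})

test_that("planted group effect realizes the requested Cohen's d within 0.25", {
  spec <- synthetic_spec(n_subjects = 100, scans_per_subject = 1, n_nodes = 60,
                         n_timepoints = 660, group_effect_size = 1.0, seed = 42)
  ge <- generate_experience(spec)
  st <- generate_connectivity(spec, ge$truth)
  Y <- edge_matrix_of(st)
  gi <- ge$truth$group_labels == "Surr-Neg-Self"
  expect_gte(sum(gi), 30)
  d_real <- vapply(st$planted$effect_edge_ids, function(e)
    cohens_d(Y[gi, e], Y[!gi, e]), numeric(1))
  expect_lt(abs(mean(d_real) - 1.0), 0.25)
})

test_that("planted behaviour relation approximates the requested correlation", {
  spec <- synthetic_spec(n_subjects = 75, scans_per_subject = 2, n_nodes = 60,
                         behavior_effect_r = 0.7, seed = 21)
  ge <- generate_experience(spec)
  st <- generate_connectivity(spec, ge$truth)
  Y <- edge_matrix_of(st)
  xsum <- rowSums(Y[, st$planted$behavior_edge_ids, drop = FALSE])
  expect_lt(abs(cor(xsum, ge$truth$target_true) - 0.7), 0.15)
})

test_that("effect edges referencing nodes outside the atlas are rejected", {
  expect_error(synthetic_spec(n_nodes = 20, effect_edges = cbind(1, 25)),
               "outside")
  expect_error(synthetic_spec(n_nodes = 20,
                              effect_edges = rbind(c(1, 2), c(5, 6))),
               "connected")
})

test_that("motion traces respect the spike rate", {
  spec0 <- synthetic_spec(n_subjects = 5, scans_per_subject = 2,
                          n_timepoints = 300, motion_spike_rate = 0, seed = 1)
  tr0 <- generate_motion_traces(spec0)
  expect_true(all(unlist(tr0) <= 0.3))
  expect_false(any(vapply(tr0, function(x) censor_volumes(x)$rejected, logical(1))))

  spec1 <- synthetic_spec(n_subjects = 2, scans_per_subject = 1,
                          n_timepoints = 100, motion_spike_rate = 1, seed = 1)
  tr1 <- generate_motion_traces(spec1)
  expect_true(all(unlist(tr1) > 0.3))
  expect_true(censor_volumes(tr1[[1]])$rejected)

  # rate 0.05, 600 volumes: spike count in the central 99% binomial interval
  spec2 <- synthetic_spec(n_subjects = 10, scans_per_subject = 1,
                          n_timepoints = 600, motion_spike_rate = 0.05, seed = 5)
  counts <- vapply(generate_motion_traces(spec2),
                   function(x) sum(x > 0.3), numeric(1))
  bounds <- qbinom(c(0.005, 0.995), 600, 0.05)
  expect_true(mean(counts) >= bounds[1] && mean(counts) <= bounds[2])
})
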