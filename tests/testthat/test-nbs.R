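# Network-Based Statistic: edge GLM, component finding vs an independent
# BFS oracle, permutation FWE behaviour, directional contrasts.

test_that("edge GLM without subject dummies equals the two-sample t", {
  set.seed(3)
  Y <- matrix(rnorm(60 * 50), 60)
  grp <- rep(c("A", "B"), each = 30)
  es <- edge_statistics(Y, grp, "A>B")
  oracle <- apply(Y, 2, function(col)
    two_sample_t_oracle(col[grp == "A"], col[grp == "B"]))
  expect_equal(es$t, oracle, tolerance = 1e-10)
  expect_equal(es$df, 58)

  # identical values in both groups: t = 0
  es0 <- edge_statistics(matrix(rep(1:30, 2), 60, 5),
                         rep(c("A", "B"), each = 30), "A>B")
  expect_equal(es0$t, rep(0, 5), tolerance = 1e-10)

  # direction flips the sign
  es_rev <- edge_statistics(Y, grp, "B>A")
  expect_equal(es_rev$t, -es$t, tolerance = 1e-12)
})

test_that("a group effect saturated by subject identity raises a rank error", {
  set.seed(4)
  Y <- matrix(rnorm(40 * 5), 40)
  grp <- rep(c("A", "B"), each = 20)
  subj <- rep(sprintf("s%02d", 1:10), each = 4)  # each subject in one group
  expect_error(edge_statistics(Y, grp, "A>B", subject_ids = subj),
               "rank deficient")
})

test_that("subject dummies absorb within-subject shifts", {
  # Construct data where a subject-mean confound masquerades as a group
  # effect for the naive test but not once subject identity is modeled:
  # subjects split across groups, with large subject offsets.
  set.seed(6)
  n_subj <- 20
  subj <- rep(sprintf("s%02d", 1:n_subj), each = 4)
  grp <- rep(c("A", "A", "B", "B"), n_subj)       # every subject split
  offsets <- rnorm(n_subj, 0, 3)[rep(1:n_subj, each = 4)]
  effect <- 0.5 * (grp == "A")
  Y <- matrix(effect + offsets + rnorm(80, 0, 0.5), 80, 20)
  with_dum <- edge_statistics(Y, grp, "A>B", subject_ids = subj)
  without <- edge_statistics(Y, grp, "A>B")
  # the subject-aware design recovers the within-subject effect far better
  expect_gt(median(with_dum$t), median(without$t) + 1)
})

test_that("components match the independent BFS oracle on random graphs", {
  set.seed(5)
  pairs_all <- upper_tri_pairs(50)
  for (rep in 1:50) {
    m <- sample(5:200, 1)
    sel <- sort(sample(nrow(pairs_all), m))
    t_fake <- rep(-1, nrow(pairs_all))
    t_fake[sel] <- 10
    tc <- threshold_and_components(t_fake, df = 100, edge_index = pairs_all,
                                   edge_p = 0.001)
    got <- lapply(tc$components, function(cp) sort(cp$edges))
    want <- lapply(bfs_components(pairs_all[sel, , drop = FALSE]),
                   function(e) sort(sel[e]))
    expect_setequal(got, want)
    # union-find max extent agrees as well
    expect_equal(restfc:::max_component_extent(pairs_all[sel, , drop = FALSE]),
                 max(vapply(want, length, integer(1))))
  }
})

test_that("simple component geometries give the stated extents", {
  pairs <- upper_tri_pairs(10)
  mk <- function(e) {
    t_fake <- rep(-1, nrow(pairs))
    t_fake[edge_ids(e, 10)] <- 10
    threshold_and_components(t_fake, 50, pairs)$components
  }
  chain <- mk(rbind(c(1, 2), c(2, 3)))
  expect_length(chain, 1)
  expect_equal(chain[[1]]$extent, 2)
  two <- mk(rbind(c(1, 2), c(3, 4)))
  expect_length(two, 2)
  expect_equal(vapply(two, `[[`, integer(1), "extent"), c(1L, 1L))
  none <- threshold_and_components(rep(-1, nrow(pairs)), 50, pairs)
  expect_length(none$components, 0)
})

test_that("stricter edge thresholds never grow a component", {
  set.seed(12)
  spec <- synthetic_spec(n_subjects = 40, scans_per_subject = 1, n_nodes = 30,
                         n_timepoints = 120, group_effect_size = 1.5, seed = 9)
  ge <- generate_experience(spec)
  st <- generate_connectivity(spec, ge$truth)
  Y <- edge_matrix_of(st)
  grp <- ifelse(ge$truth$group_labels == "Surr-Neg-Self", "hi", "lo")
  es <- edge_statistics(Y, grp, "hi>lo")
  prev_max <- Inf
  for (p_edge in c(0.01, 0.001, 1e-4)) {
    tc <- threshold_and_components(es$t, es$df, st$edge_index, p_edge)
    cur <- if (length(tc$components)) tc$components[[1]]$extent else 0
    expect_lte(cur, prev_max)
    prev_max <- cur
  }
})

test_that("permutation p-values respect the +1 floor and detect a big effect", {
  set.seed(13)
  spec <- synthetic_spec(n_subjects = 60, scans_per_subject = 1, n_nodes = 30,
                         n_timepoints = 300, group_effect_size = 2.0, seed = 14)
  ge <- generate_experience(spec)
  st <- generate_connectivity(spec, ge$truth)
  grp <- ifelse(ge$truth$group_labels == "Surr-Neg-Self", "hi", "lo")
  res <- nbs_test(st, grp, "hi>lo", n_perm = 200, seed = 2)
  expect_true(all(vapply(res$components, `[[`, numeric(1), "p_fwe") > 0))
  expect_gte(length(res$significant), 1)
  # observed extent beats every null maximum -> p at the permutation floor
  expect_equal(res$significant[[1]]$p_fwe, 1 / 201)
  # deterministic under seed
  res2 <- nbs_test(st, grp, "hi>lo", n_perm = 200, seed = 2)
  expect_identical(res$null_max_extent, res2$null_max_extent)
})

test_that("both directions swap under label swap and only the planted one fires", {
  set.seed(15)
  spec <- synthetic_spec(n_subjects = 60, scans_per_subject = 1, n_nodes = 30,
                         n_timepoints = 300, group_effect_size = 1.5, seed = 16)
  ge <- generate_experience(spec)
  st <- generate_connectivity(spec, ge$truth)
  grp <- ifelse(ge$truth$group_labels == "Surr-Neg-Self", "hi", "lo")
  both <- contrast_both_directions(st, grp, "hi>lo", n_perm = 200, seed = 3)
  expect_gte(length(both[["hi>lo"]]$significant), 1)
  expect_length(both[["lo>hi"]]$significant, 0)

  swapped <- ifelse(grp == "hi", "lo", "hi")
  both_sw <- contrast_both_directions(st, swapped, "hi>lo", n_perm = 200, seed = 3)
  expect_equal(both_sw[["lo>hi"]]$edge_t, both[["hi>lo"]]$edge_t,
               tolerance = 1e-12)
})

test_that("small n_perm for the requested alpha warns", {
  set.seed(17)
  Y <- matrix(rnorm(20 * 10), 20)
  grp <- rep(c("A", "B"), each = 10)
  expect_warning(nbs_test(Y, grp, "A>B", n_perm = 5, seed = 1,
                          edge_index = upper_tri_pairs(5)),
                 "too small")
})
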