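# Cross-study external validity: gold-standard projection and the
# bidirectional qualitative-replication procedure.

make_source_holdout <- function(co, seed = 13) {
  run_multiple_holdout(co, fast_config(seed = seed, n_reps = 2, k_pc = 8,
                                       d = 2, B_perm = 0))
}

test_that("projecting onto the source training set reproduces training", {
  co <- small_cohort(seed = 71, n = 240, p = 40, rho = 0.8)
  h <- make_source_holdout(co)
  r <- h$repetitions[[1]]
  # rebuild the training subset as a standalone target cohort
  tr <- co$site %in% r$split$train_sites
  target <- structure(list(brain = co$brain[tr, ],
                           symptoms = co$symptoms[tr, ],
                           covariates = co$covariates[tr, ],
                           site = droplevels(co$site[tr]),
                           subject_id = co$subject_id[tr]),
                      class = "two_view_cohort")
  res <- residualize_fit_transform(target$brain, target$covariates)
  pcs <- weighted_pca_transform(r$pca, res$residuals)
  proj <- scca_project(r$model, pcs, target$symptoms)
  expect_equal(proj$correlations, r$train_scores$correlations,
               tolerance = 1e-10)
})

test_that("gold-standard transfer succeeds under a shared generative model", {
  co <- small_cohort(seed = 72, n = 400, p = 60, rho = 0.8)
  h <- run_multiple_holdout(co, fast_config(seed = 14, n_reps = 3, k_pc = 10,
                                            d = 2, B_perm = 0))
  cfg2 <- simulation_config(n_subjects = 400, n_features = 60, n_sites = 6,
                            true_correlations = 0.8, seed = 73)
  target <- simulate_two_view(cfg2, loadings = list(A = co$truth$A,
                                                    B = co$truth$B))
  g <- gold_standard_test(h, target, B = 200, seed = 15)
  expect_gt(g$summary$mean_external_correlations[1], 0.2)
  expect_equal(g$summary$n_significant[1], 3)
})

test_that("gold-standard correlations vanish for an independent target", {
  co <- small_cohort(seed = 74, n = 300, p = 60, rho = 0.8)
  h <- make_source_holdout(co, seed = 16)
  # an unrelated cohort: independent loadings and no planted link
  target <- small_cohort(seed = 75, n = 300, p = 60, rho = 0)
  g <- gold_standard_test(h, target, B = 200, seed = 17)
  expect_lt(max(abs(g$summary$mean_external_correlations)), 0.15)
  expect_equal(sum(g$summary$n_significant), 0)
  # feature mismatch is refused
  bad <- small_cohort(seed = 76, n = 120, p = 30, sites = 4)
  expect_error(gold_standard_test(h, bad), "does not match")
})

test_that("gold-standard results are invariant to target row order", {
  co <- small_cohort(seed = 77, n = 240, p = 40, rho = 0.7)
  h <- make_source_holdout(co, seed = 18)
  target <- small_cohort(seed = 78, n = 200, p = 40, rho = 0.7)
  g1 <- gold_standard_test(h, target, B = 100, seed = 19)
  perm <- rev(seq_len(nrow(target$brain)))
  target2 <- target
  target2$brain <- target$brain[perm, ]
  target2$symptoms <- target$symptoms[perm, ]
  target2$covariates <- target$covariates[perm, ]
  target2$site <- target$site[perm]
  target2$subject_id <- target$subject_id[perm]
  g2 <- gold_standard_test(h, target2, B = 100, seed = 19)
  expect_equal(g1$summary$mean_external_correlations,
               g2$summary$mean_external_correlations, tolerance = 1e-10)
})

test_that("replicating a cohort against itself is perfect and symmetric", {
  co <- small_cohort(seed = 79, n = 240, p = 40, rho = 0.8)
  rep <- qualitative_replication(co, co, penalty_pair(0.8, 0.8),
                                 n_components = 2, k_pc = 8, B = 200,
                                 seed = 20)
  expect_equal(rep$direction_ab$behavior_r, c(1, 1), tolerance = 1e-8)
  expect_equal(rep$direction_ab$brain_r, c(1, 1), tolerance = 1e-8)
  expect_identical(rep$direction_ab$behavior_r, rep$direction_ba$behavior_r)
  expect_true(all(rep$generalizable))
})

test_that("the flag is a conjunction over directions", {
  # synthetic p-value frames exercise only the flag rule
  co <- small_cohort(seed = 80, n = 240, p = 40, rho = 0.8)
  other <- small_cohort(seed = 81, n = 240, p = 40, rho = 0)
  rep <- qualitative_replication(co, other, penalty_pair(0.8, 0.8),
                                 n_components = 2, k_pc = 8, B = 200,
                                 seed = 21)
  expect_equal(rep$generalizable,
               rep$direction_ab$behavior_p < 0.05 &
                 rep$direction_ba$behavior_p < 0.05)
})

test_that("shared behavior structure replicates while transfer fails", {
  # two cohorts share behavior loadings but have disjoint brain supports:
  # the qualitative replication flags the shared dimension while the
  # gold-standard projection finds nothing to transfer
  p <- 120
  cfg_a <- simulation_config(n_subjects = 400, n_features = p, n_sites = 6,
                             true_correlations = 0.8, seed = 82)
  co_a <- simulate_two_view(cfg_a)
  a_rot <- matrix(0, p, 1)
  support_a <- which(abs(co_a$truth$A[, 1]) > 0)
  free <- setdiff(seq_len(p), support_a)
  a_rot[free[seq_along(support_a)], 1] <- co_a$truth$A[support_a, 1]
  cfg_b <- simulation_config(n_subjects = 400, n_features = p, n_sites = 6,
                             true_correlations = 0.8, seed = 83)
  co_b <- simulate_two_view(cfg_b, loadings = list(A = a_rot,
                                                   B = co_a$truth$B))
  h <- run_multiple_holdout(co_a, fast_config(seed = 22, n_reps = 2,
                                              k_pc = 10, d = 2, B_perm = 0))
  g <- gold_standard_test(h, co_b, B = 200, seed = 23)
  rep <- qualitative_replication(co_a, co_b, penalty_pair(0.8, 0.8),
                                 n_components = 1, k_pc = 10, B = 500,
                                 seed = 24)
  expect_true(rep$generalizable[1])
  expect_equal(g$summary$n_significant[1], 0)
})
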