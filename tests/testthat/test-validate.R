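# Hold-out machinery: splits, folds, grid search, permutation inference,
# bootstrap stability, and the end-to-end pipeline contracts.

test_that("site splits partition the sites and are seed-deterministic", {
  sites <- sprintf("site%02d", 1:21)
  splits <- make_site_splits(sites, n_test_sites = 3, n_reps = 30, seed = 5)
  expect_length(splits, 30)
  for (s in splits) {
    expect_length(s$test_sites, 3)
    expect_length(intersect(s$train_sites, s$test_sites), 0)
    expect_setequal(c(s$train_sites, s$test_sites), sites)
  }
  expect_identical(splits,
                   make_site_splits(sites, n_test_sites = 3, n_reps = 30,
                                    seed = 5))
  # independently coded sampler with the same documented algorithm
  set.seed(5)
  ref <- lapply(1:30, function(r) sort(sample(sites, 3)))
  expect_identical(lapply(splits, `[[`, "test_sites"), ref)
  expect_error(make_site_splits(sites[1:3], n_test_sites = 3), "more sites")
})

test_that("disjoint folds tile the sites as evenly as possible", {
  sites <- sprintf("s%02d", 1:21)
  folds <- make_disjoint_folds(sites, n_folds = 5, seed = 2)
  test_sets <- lapply(folds, `[[`, "test_sites")
  expect_equal(sort(lengths(test_sets), decreasing = TRUE), c(5, 4, 4, 4, 4))
  expect_setequal(unlist(test_sets), sites)
  expect_equal(sum(lengths(test_sets)), 21) # pairwise disjoint
  expect_identical(folds, make_disjoint_folds(sites, n_folds = 5, seed = 2))
  expect_error(make_disjoint_folds(sites[1:3], n_folds = 5), "partition")
})

test_that("grid search respects the behavior constraint and the grid", {
  co <- small_cohort(seed = 61, n = 240, p = 40, rho = 0.8)
  res <- residualize_fit_transform(co$brain, co$covariates)
  w <- rank_weights(rowSums(co$symptoms))
  pca <- weighted_pca_fit(res$residuals, w, k = 8)
  x <- weighted_pca_transform(pca, res$residuals)
  gs <- grid_search_penalties(x, co$symptoms,
                              grid_brain = c(0.6, 0.8, 1),
                              grid_behavior = c(0.4, 0.6, 0.8, 1),
                              n_inner = 8, seed = 3)
  expect_true(all(gs$table$c_behavior > 0.5))
  expect_true(gs$penalties$c_brain %in% c(0.6, 0.8, 1))
  expect_true(gs$penalties$c_behavior %in% c(0.6, 0.8, 1))
  expect_error(grid_search_penalties(x, co$symptoms,
                                     grid_behavior = c(0.2, 0.5)),
               "empty penalty grid")
})

test_that("permutation p-values follow the add-one exceedance estimator", {
  # brain and behavior scores exactly orthogonal: every null draw exceeds
  # the observed |r| = 0, so p = (1 + B) / (B + 1) = 1
  x <- matrix(c(1, -1, 1, -1, 1, -1, 1, -1), ncol = 1)
  y <- matrix(c(1, 1, -1, -1, 1, 1, -1, -1), ncol = 1)
  model <- scca_model(u = matrix(1), v = matrix(1))
  res <- suppressWarnings(permutation_test(x, y, model, B = 50, seed = 1))
  expect_equal(res$p_values, 1)
  # perfect association at n = 100: no permutation ties it, p = 1/(B+1)
  set.seed(62)
  z <- matrix(rnorm(100), ncol = 1)
  res2 <- suppressWarnings(permutation_test(z, z, model, B = 200, seed = 2))
  expect_equal(res2$p_values, 1 / 201)
  expect_warning(permutation_test(z, z, model, B = 50, seed = 3),
                 "very small")
})

test_that("q-values match a hand-rolled Benjamini-Hochberg oracle", {
  p <- c(0.01, 0.02, 0.04)
  expect_equal(bh_oracle(p), c(0.03, 0.03, 0.04))
  expect_equal(p.adjust(p, method = "BH"), bh_oracle(p))
  set.seed(63)
  for (i in 1:10) {
    pr <- runif(7)
    expect_equal(p.adjust(pr, method = "BH"), bh_oracle(pr))
    expect_true(all(p.adjust(pr, method = "BH") >= pr))
  }
})

test_that("an empty gated component set returns an empty result", {
  set.seed(64)
  x <- matrix(rnorm(60), ncol = 2)
  y <- matrix(rnorm(60), ncol = 2)
  model <- scca_model(u = diag(2), v = diag(2))
  expect_message(res <- permutation_test(x, y, model, B = 200,
                                         components = integer(0)),
                 "no components")
  expect_length(res$p_values, 0)
})

test_that("refit-mode permutations hold penalties fixed and break signal", {
  co <- small_cohort(seed = 65, n = 240, p = 40, rho = 0.8)
  res <- residualize_fit_transform(co$brain, co$covariates)
  w <- rank_weights(rowSums(co$symptoms))
  pca <- weighted_pca_fit(res$residuals, w, k = 8)
  x <- weighted_pca_transform(pca, res$residuals)
  fit <- suppressWarnings(scca_fit(x, co$symptoms, c(0.8, 0.8),
                                   n_components = 2))
  pr <- suppressWarnings(permutation_test(x, co$symptoms, fit, B = 60,
                                          mode = "refit", components = 1,
                                          seed = 4))
  expect_lt(pr$p_values[1], 0.05)
  # null refit correlations concentrate well below the observed signal
  expect_lt(mean(abs(pr$null_draws[, 1])), abs(pr$observed[1]))
  expect_true(all(pr$q_values >= pr$p_values))
})

test_that("bootstrap matching undoes permutations and aligns signs", {
  co <- small_cohort(seed = 66, n = 200, p = 40, rho = 0.8)
  res <- residualize_fit_transform(co$brain, co$covariates)
  w <- rank_weights(rowSums(co$symptoms))
  pca <- weighted_pca_fit(res$residuals, w, k = 8)
  x <- weighted_pca_transform(pca, res$residuals)
  ref <- suppressWarnings(scca_fit(x, co$symptoms, c(0.8, 0.8),
                                   n_components = 3))
  # a known permutation + sign flip of the reference is exactly recovered
  perm <- c(3L, 1L, 2L)
  flips <- c(1, -1, 1)
  scrambled <- sweep(ref$v[, perm], 2, flips, "*")
  m <- match_components(ref$v, scrambled)
  expect_equal(m$perm, order(perm)) # the inverse permutation
  expect_equal(ref$v, sweep(scrambled[, m$perm], 2, m$signs, "*"),
               tolerance = 1e-12)
  bs <- bootstrap_stability(x, co$symptoms, ref, B = 25, seed = 7)
  for (b in seq_len(25)) {
    if (any(is.na(bs$match_permutations[b, ]))) next
    for (j in 1:3) {
      cs <- sum(bs$matched_v[b, , j] * ref$v[, j]) /
        sqrt(sum(bs$matched_v[b, , j]^2) * sum(ref$v[, j]^2))
      expect_gte(cs, 0) # post-alignment cosine is never negative
    }
  }
  # identity "resample": matching a refit of the same data is the identity
  m_id <- match_components(ref$v, ref$v)
  expect_equal(m_id$perm, 1:3)
  expect_equal(m_id$cosines, rep(1, 3))
})

test_that("the pipeline is deterministic and validates planted signal", {
  co <- small_cohort(seed = 67, n = 360, p = 60, rho = 0.8)
  cfg <- fast_config(seed = 9, n_reps = 3, k_pc = 10, d = 2, B_perm = 100)
  h1 <- run_multiple_holdout(co, cfg)
  h2 <- run_multiple_holdout(co, cfg)
  expect_identical(serialize(h1, NULL), serialize(h2, NULL))
  expect_equal(h1$summary$n_repetitions, 3)
  expect_gte(h1$summary$n_test_significant[1], 2)
  expect_gt(h1$summary$mean_train_correlations[1], 0.3)
  # the modal penalty helper returns a member of the configured pair set
  mp <- most_selected_penalties(h1)
  expect_s3_class(mp, "penalty_pair")
})

test_that("mutating held-out rows never changes training-fit parameters", {
  co <- small_cohort(seed = 68, n = 240, p = 40, rho = 0.7)
  cfg <- fast_config(seed = 11, n_reps = 2, k_pc = 8, d = 2, B_perm = 50)
  h_ref <- suppressWarnings(run_multiple_holdout(co, cfg))
  # mutate one repetition's held-out rows at a time (a site held out in one
  # repetition may train another), rerun, and compare that repetition's fit
  for (i in seq_along(h_ref$repetitions)) {
    co_mut <- co
    test_rows <- co$site %in% h_ref$repetitions[[i]]$split$test_sites
    co_mut$brain[test_rows, ] <- co_mut$brain[test_rows, ] + 5
    co_mut$symptoms[test_rows, ] <- co_mut$symptoms[test_rows,
                                                    ncol(co_mut$symptoms):1]
    h_mut <- suppressWarnings(run_multiple_holdout(co_mut, cfg))
    a <- h_ref$repetitions[[i]]
    b <- h_mut$repetitions[[i]]
    expect_identical(serialize(a$model, NULL), serialize(b$model, NULL))
    expect_identical(serialize(a$pca, NULL), serialize(b$pca, NULL))
    expect_identical(serialize(a$weights, NULL), serialize(b$weights, NULL))
    expect_identical(a$penalties, b$penalties)
  }
})
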