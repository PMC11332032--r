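# Sparse CCA core: penalized matrix decomposition against brute-force and
# singular-vector oracles, projection scoring, covariance-explained gate,
# classical CCA limits.

test_that("a perfectly shared column yields canonical correlation 1", {
  x <- orthonormal_block(30, 3, seed = 41) # centered orthogonal columns
  y <- x[, 2, drop = FALSE]
  fit <- scca_fit(x, y, c(1, 1), n_components = 1)
  expect_equal(fit$train_correlations[1], 1, tolerance = 1e-8)
  expect_equal(which.max(abs(fit$u[, 1])), 2L)
  expect_gt(abs(fit$u[2, 1]), 0.99)
})

test_that("an l1 bound of one forces a 1-sparse coordinate loading", {
  set.seed(42)
  x <- matrix(rnorm(50 * 6), 50, 6)
  y <- x[, 1, drop = FALSE] + matrix(rnorm(50), 50, 1)
  # c_brain = 0.2 maps to max(1, 0.2*sqrt(6)) = 1: the l1 = l2 = 1 vertex
  fit <- scca_fit(x, y, c(0.2, 1), n_components = 1)
  expect_equal(sum(abs(fit$u[, 1]) > 1e-12), 1L)
  expect_equal(sum(abs(fit$u[, 1])), 1, tolerance = 1e-12)
})

test_that("inactive penalties recover the leading singular pair of t(X)Y", {
  x <- orthonormal_block(30, 3, seed = 43)
  y <- orthonormal_block(30, 2, seed = 44)
  fit <- scca_fit(x, y, c(1, 1), n_components = 1, standardize = FALSE)
  sv <- svd(crossprod(x, y))
  expect_gt(abs(sum(fit$u[, 1] * sv$u[, 1])), 1 - 1e-6)
  expect_gt(abs(sum(fit$v[, 1] * sv$v[, 1])), 1 - 1e-6)
})

test_that("the fitted objective matches a brute-force mesh oracle", {
  x <- orthonormal_block(30, 3, seed = 45)
  y <- orthonormal_block(30, 2, seed = 46)
  scale_mat <- matrix(c(1.2, 0.3, -0.8, 0.5, 0.1, -0.4), 3, 2)
  y <- y + x %*% scale_mat # induce cross-covariance structure
  for (pen in list(c(0.7, 0.6), c(0.8, 0.9))) {
    fit <- scca_fit(x, y, pen, n_components = 1, standardize = FALSE)
    C <- crossprod(x, y) / (nrow(x) - 1)
    s_u <- max(1, pen[1] * sqrt(3))
    s_v <- max(1, pen[2] * sqrt(2))
    oracle <- brute_force_scca_objective(C, s_u, s_v)
    expect_lt(abs(fit$objective[1] - oracle), 1e-3)
    # the fit satisfies its own constraints
    expect_lte(sum(abs(fit$u[, 1])), s_u + 1e-6)
    expect_lte(sum(abs(fit$v[, 1])), s_v + 1e-6)
    expect_equal(sum(fit$u[, 1]^2), 1, tolerance = 1e-8)
  }
})

test_that("loading sparsity is monotone in the brain penalty", {
  grid <- seq(0.1, 1, by = 0.1)
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(80 * 12), 80, 12)
    y <- x[, 1:2] %*% matrix(rnorm(2 * 4), 2, 4) +
      matrix(rnorm(80 * 4), 80, 4)
    nnz <- vapply(grid, function(cb) {
      fit <- suppressWarnings(scca_fit(x, y, c(cb, 0.9), n_components = 1))
      sum(abs(fit$u[, 1]) > 1e-10)
    }, numeric(1))
    expect_true(all(diff(nnz) >= 0))
  }
})

test_that("correlations are invariant to positive rescaling of a block", {
  set.seed(47)
  x <- matrix(rnorm(60 * 5), 60, 5)
  y <- matrix(rnorm(60 * 3), 60, 3)
  a <- scca_fit(x, y, c(0.8, 0.8), n_components = 2)
  b <- scca_fit(7.3 * x, y, c(0.8, 0.8), n_components = 2)
  expect_equal(a$train_correlations, b$train_correlations, tolerance = 1e-8)
})

test_that("the sign convention is idempotent", {
  set.seed(48)
  x <- matrix(rnorm(40 * 4), 40, 4)
  y <- matrix(rnorm(40 * 3), 40, 3)
  fit <- scca_fit(x, y, c(0.9, 0.9), n_components = 2)
  expect_identical(mhscca:::fix_sign(fit$u), fit$u)
  expect_identical(mhscca:::fix_sign(fit$v), fit$v)
  expect_true(all(apply(fit$u, 2, function(col) col[which.max(abs(col))]) > 0))
})

test_that("projection reproduces training correlations and detects breaks", {
  set.seed(49)
  co <- small_cohort(seed = 49, n = 200, p = 40)
  res <- residualize_fit_transform(co$brain, co$covariates)
  w <- rank_weights(rowSums(co$symptoms))
  pca <- weighted_pca_fit(res$residuals, w, k = 10)
  x <- weighted_pca_transform(pca, res$residuals)
  fit <- scca_fit(x, co$symptoms, c(0.8, 0.8), n_components = 2)
  self <- scca_project(fit, x, co$symptoms)
  expect_equal(self$correlations, fit$train_correlations, tolerance = 1e-10)
  # oracle: explicit matrix product on the standardized blocks
  xs <- mhscca:::standardize_columns(x)
  expect_equal(self$brain_scores, xs %*% fit$u, tolerance = 1e-12)
  # shuffled pairing destroys the association
  shuffled <- scca_project(fit, x, co$symptoms[sample(nrow(x)), ])
  expect_lt(abs(shuffled$correlations[1]), 2.5 / sqrt(nrow(x)))
  expect_error(scca_project(fit, x[, 1:5], co$symptoms), "do not match")
})

test_that("covariance-explained shares normalize and gate above the mean", {
  set.seed(50)
  n <- 400
  base <- matrix(rnorm(n * 3), n, 3)
  # hand-built scores with covariances approximately (4, 1, 1)
  brain <- base
  behav <- base
  brain[, 1] <- base[, 1] * 2
  behav[, 1] <- base[, 1] * 2
  scores <- structure(list(brain_scores = brain, behavior_scores = behav,
                           correlations = rep(1, 3)),
                      class = "variate_scores")
  ce <- covariance_explained(scores)
  expect_equal(sum(ce$share), 1, tolerance = 1e-12)
  expect_equal(ce$share, c(2 / 3, 1 / 6, 1 / 6), tolerance = 0.05)
  expect_equal(ce$gate, c(TRUE, FALSE, FALSE))
  # single component: the share of 1 is not strictly above its own mean
  one <- structure(list(brain_scores = brain[, 1, drop = FALSE],
                        behavior_scores = behav[, 1, drop = FALSE],
                        correlations = 1),
                   class = "variate_scores")
  ce1 <- covariance_explained(one)
  expect_equal(ce1$share, 1)
  expect_false(ce1$gate)
})

test_that("exact covariance ratios give exact shares", {
  # deterministic score vectors with covariances exactly (4, 1, 1)
  v <- c(-1, 1, -1, 1, -1, 1)
  brain <- cbind(2 * v, v, v)
  behav <- cbind(2 * v, v, v)
  scores <- structure(list(brain_scores = brain, behavior_scores = behav,
                           correlations = rep(1, 3)),
                      class = "variate_scores")
  ce <- covariance_explained(scores)
  expect_equal(ce$share, c(2 / 3, 1 / 6, 1 / 6), tolerance = 1e-12)
})

test_that("classical CCA reduces to |Pearson r| in the univariate case", {
  set.seed(51)
  x <- rnorm(100)
  y <- 0.6 * x + rnorm(100)
  cc <- classical_cca(matrix(x), matrix(y), 1)
  expect_equal(cc$correlations, abs(cor(x, y)), tolerance = 1e-10)
})

test_that("classical CCA is invariant to invertible mixing", {
  set.seed(52)
  x <- matrix(rnorm(100 * 3), 100, 3)
  m <- matrix(c(1, 2, 0, 0, 1, 1, 1, 0, 1), 3, 3)
  cc <- classical_cca(x, x %*% m, 3)
  expect_equal(cc$correlations, rep(1, 3), tolerance = 1e-8)
})

test_that("classical CCA matches the cancor reference on a 5-dim toy", {
  set.seed(53)
  x <- matrix(rnorm(200 * 3), 200, 3)
  y <- cbind(x[, 1] + rnorm(200), rnorm(200))
  cc <- classical_cca(x, y, 2)
  ref <- cancor(x, y)
  expect_equal(cc$correlations, ref$cor, tolerance = 1e-8)
  expect_error(classical_cca(x[1:5, ], y[1:5, ]), "n >")
})
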