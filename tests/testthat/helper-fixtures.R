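# Shared fixtures and independent oracles used across the suite.

# centered matrix with orthonormal columns (for diagonal-covariance limits)
orthonormal_block <- function(n, k, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * k), n, k)
  m <- sweep(m, 2, colMeans(m), "-")
  qr.Q(qr(m))
}

# Brute-force oracle for the rank-1 sparse CCA objective max t(u) C v over
# unit vectors with l1 bounds, for ncol(u) == 3 and ncol(v) == 2 only.
# u is meshed on the 2-sphere, v candidates are either the meshed unit
# circle (bound > 1) or exactly the coordinate vectors (bound == 1, the
# only feasible points).
brute_force_scca_objective <- function(C, s_u, s_v,
                                       n_theta = 400L, n_phi = 800L) {
  stopifnot(nrow(C) == 3L, ncol(C) == 2L)
  theta <- seq(0, pi, length.out = n_theta)
  phi <- seq(0, 2 * pi, length.out = n_phi)
  grid <- expand.grid(theta = theta, phi = phi)
  U <- cbind(sin(grid$theta) * cos(grid$phi),
             sin(grid$theta) * sin(grid$phi),
             cos(grid$theta))
  U <- U[rowSums(abs(U)) <= s_u + 1e-9, , drop = FALSE]
  if (s_v <= 1 + 1e-9) {
    V <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    ang <- seq(0, 2 * pi, length.out = 4000L)
    V <- cbind(cos(ang), sin(ang))
    V <- V[rowSums(abs(V)) <= s_v + 1e-9, , drop = FALSE]
  }
  max(U %*% C %*% t(V))
}

# textbook Benjamini-Hochberg step-up, written independently of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# small default cohort for pipeline-level tests
small_cohort <- function(seed = 1, n = 300, p = 60, sites = 6, rho = 0.7,
                         ...) {
  simulate_two_view(simulation_config(
    n_subjects = n, n_features = p, n_sites = sites,
    true_correlations = rho, seed = seed, ...))
}

fast_config <- function(seed = 1, n_reps = 3, k_pc = 10, d = 2,
                        penalties = penalty_pair(0.8, 0.8), B_perm = 0,
                        n_test_sites = 2, ...) {
  holdout_config(n_reps = n_reps, n_test_sites = n_test_sites, k_pc = k_pc,
                 n_components = d, penalties = penalties, B_perm = B_perm,
                 seed = seed, ...)
}
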