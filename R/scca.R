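# Sparse CCA by penalized matrix decomposition: alternating
# soft-thresholded power iterations on the cross-covariance with unit-l2,
# bounded-l1 loading columns; deflation for further components; projection
# scoring; covariance-explained shares; and classical CCA for the
# unpenalized sensitivity arm.

#' Penalty pair for sparse CCA
#'
#' Grid values in `[0, 1]` controlling the l1 budget of each view's loading
#' vector via `bound = max(1, c * sqrt(dim))`; smaller values give sparser
#' loadings. The behavior-side penalty is constrained to be larger than 0.5
#' to keep the behavioral loadings interpretable.
#'
#' @param c_brain brain-side grid value in `[0, 1]`.
#' @param c_behavior behavior-side grid value in `(0.5, 1]`.
#' @return object of class `penalty_pair`.
#' @export
penalty_pair <- function(c_brain, c_behavior) {
  stopifnot(length(c_brain) == 1L, length(c_behavior) == 1L,
            c_brain >= 0, c_brain <= 1, c_behavior <= 1)
  if (c_behavior <= 0.5) {
    stop("the behavior-side penalty must be larger than 0.5")
  }
  structure(list(c_brain = c_brain, c_behavior = c_behavior),
            class = "penalty_pair")
}

as_penalty_pair <- function(x) {
  if (inherits(x, "penalty_pair")) return(x)
  if (is.numeric(x) && length(x) == 2L) {
    return(penalty_pair(x[1L], x[2L]))
  }
  stop("penalties must be a penalty_pair or a numeric pair (brain, behavior)")
}

l1_bound <- function(c_value, dim) max(1, c_value * sqrt(dim))

#' Fit a sparse CCA model by penalized matrix decomposition
#'
#' Finds loading columns `u` (brain side) and `v` (behavior side) that
#' maximize `t(u) %*% t(X) %*% Y %*% v` subject to unit l2 norms and l1
#' budgets mapped from the penalty pair. Each component is extracted by
#' alternating soft-thresholded power iterations initialized from the
#' leading singular pair of the cross-covariance; the rank-1 cross-product
#' term is deflated before the next component. Returned loading columns are
#' sign-fixed so their largest-magnitude entry is positive.
#'
#' @param X n x k numeric matrix (e.g. brain principal components); columns
#'   are standardized internally.
#' @param Y n x q numeric matrix (e.g. symptom scores); columns are
#'   standardized internally.
#' @param penalties a [penalty_pair()] or numeric pair
#'   `c(c_brain, c_behavior)`.
#' @param n_components number of components `d` to extract (default
#'   `min(ncol(X), ncol(Y))`).
#' @param standardize standardize columns internally (default `TRUE`).
#' @param max_iter,tol convergence controls for the alternating updates
#'   (maximum absolute loading change below `tol`, at most `max_iter`
#'   iterations; non-convergence yields a warning and a flagged component).
#' @return object of class `scca_model`: `u` (k x d), `v` (q x d),
#'   `penalties`, `train_correlations` (d), `converged` (d logicals),
#'   `objective` (d deflated cross-covariance values), `n_components`.
#' @export
scca_fit <- function(X, Y, penalties,
                     n_components = min(ncol(X), ncol(Y)),
                     standardize = TRUE, max_iter = 200L, tol = 1e-6) {
  pen <- as_penalty_pair(penalties)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), n_components >= 1L,
            n_components <= min(ncol(X), ncol(Y)))
  if (standardize) {
    X <- standardize_columns(X)
    Y <- standardize_columns(Y)
  }
  d <- as.integer(n_components)
  s_u <- l1_bound(pen$c_brain, ncol(X))
  s_v <- l1_bound(pen$c_behavior, ncol(Y))
  C <- crossprod(X, Y) / (nrow(X) - 1L)

  u <- matrix(0, ncol(X), d)
  v <- matrix(0, ncol(Y), d)
  converged <- logical(d)
  objective <- numeric(d)
  for (j in seq_len(d)) {
    sv <- svd(C, nu = 1L, nv = 1L)
    vj <- sv$v[, 1L]
    uj <- sv$u[, 1L]
    for (it in seq_len(max_iter)) {
      uj_new <- bound_l1_unit(drop(C %*% vj), s_u)
      vj_new <- bound_l1_unit(drop(crossprod(C, uj_new)), s_v)
      delta <- max(abs(uj_new - uj), abs(vj_new - vj))
      uj <- uj_new
      vj <- vj_new
      if (delta < tol) {
        converged[j] <- TRUE
        break
      }
    }
    if (!converged[j]) {
      warning("component ", j, " did not converge in ", max_iter,
              " iterations")
    }
    objective[j] <- drop(t(uj) %*% C %*% vj)
    C <- C - objective[j] * uj %*% t(vj)
    u[, j] <- uj
    v[, j] <- vj
  }
  u <- fix_sign(u)
  v <- fix_sign(v)
  bs <- X %*% u
  ys <- Y %*% v
  correlations <- vapply(seq_len(d), function(j) {
    if (stats::sd(bs[, j]) < 1e-12 || stats::sd(ys[, j]) < 1e-12) 0
    else stats::cor(bs[, j], ys[, j])
  }, numeric(1))
  structure(
    list(u = u, v = v,
         penalties = pen,
         train_correlations = correlations,
         converged = converged,
         objective = objective,
         n_components = d),
    class = "scca_model"
  )
}

#' Construct a sparse-CCA model object from explicit loading matrices
#'
#' Lightweight constructor used when loadings come from elsewhere (e.g.
#' averaged loadings, or fixed loadings for calibration studies) and only
#' projection is needed.
#'
#' @param u k x d brain-side loading matrix.
#' @param v q x d behavior-side loading matrix.
#' @param penalties optional penalty pair the loadings were fitted under.
#' @return an `scca_model` (without training correlations).
#' @export
scca_model <- function(u, v, penalties = NULL) {
  u <- as.matrix(u)
  v <- as.matrix(v)
  stopifnot(ncol(u) == ncol(v))
  structure(
    list(u = u, v = v,
         penalties = if (is.null(penalties)) NULL else as_penalty_pair(penalties),
         train_correlations = rep(NA_real_, ncol(u)),
         converged = rep(NA, ncol(u)),
         objective = rep(NA_real_, ncol(u)),
         n_components = ncol(u)),
    class = "scca_model"
  )
}

#' @export
print.scca_model <- function(x, ...) {
  cat(sprintf("scca_model: %d components, %d x %d loadings\n",
              x$n_components, nrow(x$u), nrow(x$v)))
  if (!is.null(x$penalties)) {
    cat(sprintf("penalties: brain %.2f, behavior %.2f\n",
                x$penalties$c_brain, x$penalties$c_behavior))
  }
  cat("train correlations:",
      paste(format(round(x$train_correlations, 4)), collapse = ", "), "\n")
  invisible(x)
}

#' Project data blocks onto fitted canonical loadings
#'
#' Computes canonical variate scores `X_new %*% u` and `Y_new %*% v` and
#' their per-component Pearson correlations; no re-fitting. Blocks are
#' standardized with their own internal statistics, mirroring the per-set
#' residualization stance of the hold-out framework.
#'
#' @param model an `scca_model`.
#' @param X_new,Y_new data blocks with column counts matching the model.
#' @param standardize standardize columns internally (default `TRUE`).
#' @return object of class `variate_scores`: `brain_scores` (n x d),
#'   `behavior_scores` (n x d), `correlations` (d).
#' @export
scca_project <- function(model, X_new, Y_new, standardize = TRUE) {
  stopifnot(inherits(model, "scca_model"))
  X_new <- as.matrix(X_new)
  Y_new <- as.matrix(Y_new)
  if (ncol(X_new) != nrow(model$u) || ncol(Y_new) != nrow(model$v)) {
    stop("data block dimensions do not match the model loadings (",
         ncol(X_new), " vs ", nrow(model$u), " brain; ",
         ncol(Y_new), " vs ", nrow(model$v), " behavior)")
  }
  if (standardize) {
    X_new <- standardize_columns(X_new)
    Y_new <- standardize_columns(Y_new)
  }
  bs <- X_new %*% model$u
  ys <- Y_new %*% model$v
  d <- model$n_components
  correlations <- vapply(seq_len(d), function(j) {
    if (stats::sd(bs[, j]) < 1e-12 || stats::sd(ys[, j]) < 1e-12) 0
    else stats::cor(bs[, j], ys[, j])
  }, numeric(1))
  structure(list(brain_scores = bs, behavior_scores = ys,
                 correlations = correlations),
            class = "variate_scores")
}

#' Covariance-explained shares and selection gate
#'
#' Each component's share of the total absolute cross-block covariance,
#' `|cov(Xu_j, Yv_j)| / sum_m |cov(Xu_m, Yv_m)|`, plus the boolean gate
#' marking components whose share strictly exceeds the mean share; only
#' gated components are carried into permutation testing.
#'
#' @param scores a `variate_scores` object.
#' @return list with `share` (d, summing to 1) and `gate` (d logicals).
#' @export
covariance_explained <- function(scores) {
  stopifnot(inherits(scores, "variate_scores"))
  d <- ncol(scores$brain_scores)
  covs <- abs(vapply(seq_len(d), function(j) {
    stats::cov(scores$brain_scores[, j], scores$behavior_scores[, j])
  }, numeric(1)))
  if (all(covs < .Machine$double.eps)) {
    warning("all cross-block covariances are zero; returning uniform shares")
    share <- rep(1 / d, d)
  } else {
    share <- covs / sum(covs)
  }
  list(share = share, gate = share > mean(share))
}

# symmetric inverse square root via eigendecomposition
inv_sqrt <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < tol * max(e$values)) {
    stop("singular within-view covariance; reduce the dimension first ",
         "(e.g. with PCA)")
  }
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

#' Classical (unpenalized) canonical correlation analysis
#'
#' Solves classical CCA by whitening both views with the inverse square
#' roots of their covariance matrices and taking the singular value
#' decomposition of the whitened cross-covariance. Used as the unpenalized
#' sensitivity arm; requires more observations than total variables and
#' full-rank within-view covariances.
#'
#' @param X,Y centered-internally data blocks, n x k and n x q.
#' @param n_components number of canonical pairs (default
#'   `min(ncol(X), ncol(Y))`).
#' @return list with `u` (k x d), `v` (q x d) loadings (sign-fixed) and
#'   `correlations` (d, non-increasing).
#' @export
classical_cca <- function(X, Y, n_components = min(ncol(X), ncol(Y))) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (nrow(X) <= ncol(X) + ncol(Y)) {
    stop("classical CCA needs n > ncol(X) + ncol(Y)")
  }
  d <- as.integer(n_components)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  Sxx <- crossprod(Xc) / (nrow(X) - 1L)
  Syy <- crossprod(Yc) / (nrow(Y) - 1L)
  Sxy <- crossprod(Xc, Yc) / (nrow(X) - 1L)
  Wx <- inv_sqrt(Sxx)
  Wy <- inv_sqrt(Syy)
  sv <- svd(Wx %*% Sxy %*% Wy)
  u <- fix_sign(Wx %*% sv$u[, seq_len(d), drop = FALSE])
  v <- fix_sign(Wy %*% sv$v[, seq_len(d), drop = FALSE])
  list(u = u, v = v,
       correlations = pmin(sv$d[seq_len(d)], 1))
}
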