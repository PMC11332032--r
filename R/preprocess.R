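# Preprocess: per-set covariate residualization, the rank-based subject
# weighting scheme, and weighted PCA with a strict fit/transform separation
# so held-out data never touch training-fit parameters.

#' Fit a per-feature covariate residualizer
#'
#' Ordinary least squares of every feature column on an intercept plus the
#' dummy-encoded covariates. The fitted model remembers the factor levels
#' seen at fit time and refuses to transform data with unseen levels, which
#' enforces the per-set residualization contract.
#'
#' @param features n x p numeric matrix.
#' @param covariates data frame of covariates (numeric and/or factor).
#' @return object of class `residualizer_model` with elements
#'   `coefficients` (design columns x p), `design_columns` and `xlevels`.
#' @export
residualize_fit <- function(features, covariates) {
  features <- as.matrix(features)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(features) == nrow(covariates))
  mf <- stats::model.frame(~ ., data = covariates)
  design <- stats::model.matrix(~ ., data = mf)
  if (nrow(features) <= ncol(design)) {
    stop("more encoded covariate columns than subjects")
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("rank-deficient covariate design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  coefficients <- qr.coef(qrd, features)
  structure(
    list(coefficients = coefficients,
         design_columns = colnames(design),
         xlevels = lapply(Filter(is.factor, covariates), levels),
         covariate_names = names(covariates)),
    class = "residualizer_model"
  )
}

build_design <- function(model, covariates) {
  covariates <- as.data.frame(covariates)
  if (!all(model$covariate_names %in% names(covariates))) {
    stop("covariate columns missing: ",
         paste(setdiff(model$covariate_names, names(covariates)),
               collapse = ", "))
  }
  covariates <- covariates[, model$covariate_names, drop = FALSE]
  for (nm in names(model$xlevels)) {
    vals <- as.character(covariates[[nm]])
    unseen <- setdiff(unique(vals), model$xlevels[[nm]])
    if (length(unseen) > 0) {
      stop("covariate '", nm, "' has level(s) unseen at fit time: ",
           paste(unseen, collapse = ", "))
    }
    covariates[[nm]] <- factor(vals, levels = model$xlevels[[nm]])
  }
  design <- stats::model.matrix(~ ., data = covariates)
  design[, model$design_columns, drop = FALSE]
}

#' Apply a fitted residualizer to (new) data
#' @param model a `residualizer_model` from [residualize_fit()].
#' @param features m x p matrix with the same feature columns as at fit.
#' @param covariates covariate data frame for the m rows.
#' @return m x p residual matrix.
#' @export
residualize_transform <- function(model, features, covariates) {
  stopifnot(inherits(model, "residualizer_model"))
  features <- as.matrix(features)
  if (ncol(features) != ncol(model$coefficients)) {
    stop("feature column count differs from fit")
  }
  design <- build_design(model, covariates)
  features - design %*% model$coefficients
}

#' Fit a residualizer and return the residuals of the same data
#' @inheritParams residualize_fit
#' @return list with `model` and `residuals`.
#' @export
residualize_fit_transform <- function(features, covariates) {
  model <- residualize_fit(features, covariates)
  list(model = model,
       residuals = residualize_transform(model, features, covariates))
}

#' Rank-based subject weights from total symptom scores
#'
#' Subjects are ranked by their total score (by default rank 1 = highest
#' total, so the most symptomatic subjects receive the largest weights; ties
#' get average fractional ranks). Pre-weights are
#' `ln(n) - ln(rank)`, then normalized to sum to one. The lowest-ranked
#' subject (rank n) receives pre-weight 0.
#'
#' @param total_scores non-negative numeric vector of length n >= 2.
#' @param descending if `TRUE` (default) rank 1 is the highest total score.
#' @return object of class `rank_weights`: list with `preweights`,
#'   `weights` (non-negative, summing to 1) and `ranks`.
#' @export
#' @examples
#' rank_weights(c(12, 0, 5, 3))
rank_weights <- function(total_scores, descending = TRUE) {
  n <- length(total_scores)
  if (n < 2L) stop("need at least 2 subjects (the weight normalizer degenerates)")
  if (anyNA(total_scores)) stop("total scores contain missing values")
  if (any(total_scores < 0)) stop("total scores must be non-negative")
  r <- if (descending) {
    rank(-total_scores, ties.method = "average")
  } else {
    rank(total_scores, ties.method = "average")
  }
  pre <- log(n) - log(r)
  w <- pre / sum(pre)
  structure(list(preweights = pre, weights = w, ranks = r),
            class = "rank_weights")
}

#' Weighted PCA fit on residualized features
#'
#' Columns are demeaned (unweighted means), each subject row is scaled by
#' its normalized rank weight, and the eigenvectors (variable loadings) and
#' explained-variance shares of the scaled matrix are extracted via its
#' singular value decomposition.
#'
#' @param residuals n x p residual matrix.
#' @param weights a [rank_weights()] object or numeric vector of n
#'   non-negative weights summing to 1.
#' @param k number of components to retain (default 100; must not exceed the
#'   rank of the weighted matrix).
#' @param row_scale `"w"` (default) scales row i by `w_i`; `"sqrtw"` scales
#'   by `sqrt(w_i)` (the variant under which the spectrum estimates the
#'   weighted covariance).
#' @return object of class `weighted_pca_model`: `feature_means` (p),
#'   `eigenvectors` (p x k, orthonormal columns), `explained_share` (k,
#'   non-increasing shares of the weighted spectrum), `k`, `row_scale`.
#' @export
weighted_pca_fit <- function(residuals, weights, k = 100L,
                             row_scale = c("w", "sqrtw")) {
  row_scale <- match.arg(row_scale)
  residuals <- as.matrix(residuals)
  w <- if (inherits(weights, "rank_weights")) weights$weights else weights
  stopifnot(length(w) == nrow(residuals), all(w >= 0))
  if (abs(sum(w) - 1) > 1e-8) {
    stop("weights must be normalized to sum to 1")
  }
  if (k > min(dim(residuals))) {
    stop("k exceeds min(n, p)")
  }
  feature_means <- colMeans(residuals)
  centered <- sweep(residuals, 2L, feature_means, "-")
  scaled <- centered * (if (row_scale == "w") w else sqrt(w))
  sv <- svd(scaled, nu = 0L, nv = min(dim(scaled)))
  rank <- sum(sv$d > sv$d[1L] * 1e-12)
  if (k > rank) {
    stop("k = ", k, " exceeds the rank (", rank, ") of the weighted matrix")
  }
  structure(
    list(feature_means = feature_means,
         eigenvectors = sv$v[, seq_len(k), drop = FALSE],
         explained_share = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
         singular_values = sv$d[seq_len(k)],
         k = as.integer(k),
         row_scale = row_scale),
    class = "weighted_pca_model"
  )
}

#' Project residualized data onto fitted weighted-PCA eigenvectors
#'
#' Projects (already per-set residualized, unweighted) data onto the
#' training-fit eigenvectors; no re-fitting, no re-centering by training
#' means (residuals are near-zero-mean by construction).
#'
#' @param model a `weighted_pca_model`.
#' @param residuals_new m x p residual matrix with p matching the fit.
#' @return m x k principal-component score matrix.
#' @export
weighted_pca_transform <- function(model, residuals_new) {
  stopifnot(inherits(model, "weighted_pca_model"))
  residuals_new <- as.matrix(residuals_new)
  if (ncol(residuals_new) != nrow(model$eigenvectors)) {
    stop("feature column count (", ncol(residuals_new),
         ") differs from fit (", nrow(model$eigenvectors), ")")
  }
  residuals_new %*% model$eigenvectors
}
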