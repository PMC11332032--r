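# Post-hoc characterization of fitted dimensions: per-edge contributions,
# network-module aggregation with z-scores and a global top-20% edge mask,
# and covariate-adjusted regression of brain variate scores on outcomes.

#' Per-edge contributions to a brain canonical variate
#'
#' Pearson correlation of every raw connectivity feature with the brain
#' canonical variate score, indicating the importance of each edge for the
#' fitted dimension. Zero-variance features contribute 0 with a warning.
#'
#' @param raw_features n x p matrix of raw (unweighted) connectivity
#'   features.
#' @param brain_scores length-n brain variate score vector (e.g. raw PCs
#'   times loadings averaged across the hold-out repetitions).
#' @return length-p numeric vector of contributions in `[-1, 1]`.
#' @export
edge_contributions <- function(raw_features, brain_scores) {
  raw_features <- as.matrix(raw_features)
  brain_scores <- as.numeric(brain_scores)
  stopifnot(nrow(raw_features) == length(brain_scores))
  sds <- apply(raw_features, 2L, stats::sd)
  zero <- sds < .Machine$double.eps
  out <- numeric(ncol(raw_features))
  if (any(!zero)) {
    out[!zero] <- drop(stats::cor(raw_features[, !zero, drop = FALSE],
                                  brain_scores))
  }
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s) assigned contribution 0")
  }
  out
}

#' Aggregate edge contributions into network modules
#'
#' Sums absolute edge contributions into an M x M module matrix according
#' to the network assignment of each edge's two parcels (within-network
#' cells on the diagonal, between-network off it), z-scores the unique
#' module cells (upper triangle including the diagonal), and marks the top
#' 20% of all edges globally by absolute contribution.
#'
#' @param contributions length-p edge contribution vector.
#' @param edge_index data frame with columns `i`, `j` (parcel pairs, as
#'   from [make_edge_index()]).
#' @param parcel_to_network network assignment: vector (indexed by parcel)
#'   or two-column data frame (`parcel`, `network`); every parcel must map
#'   to exactly one network.
#' @param top_frac fraction of edges in the top mask (default 0.2; the mask
#'   holds `ceiling(top_frac * p)` edges).
#' @param signed if `TRUE` aggregate signed contributions instead of
#'   absolute values.
#' @return object of class `network_contribution_table`: `edge_contribution`,
#'   `module_matrix` (M x M symmetric), `module_z` (z-scored over unique
#'   cells), `top_mask` (logical per edge), `networks`.
#' @export
aggregate_modules <- function(contributions, edge_index, parcel_to_network,
                              top_frac = 0.2, signed = FALSE) {
  stopifnot(length(contributions) == nrow(edge_index))
  if (is.data.frame(parcel_to_network)) {
    map <- as.character(parcel_to_network[[2L]])
    names(map) <- as.character(parcel_to_network[[1L]])
    assignment <- function(parcel) map[as.character(parcel)]
  } else {
    assignment <- function(parcel) as.character(parcel_to_network[parcel])
  }
  net_i <- assignment(edge_index$i)
  net_j <- assignment(edge_index$j)
  if (anyNA(net_i) || anyNA(net_j)) {
    bad <- unique(c(edge_index$i[is.na(net_i)], edge_index$j[is.na(net_j)]))
    stop("parcel(s) without a network assignment: ",
         paste(bad, collapse = ", "))
  }
  networks <- sort(unique(c(net_i, net_j)))
  m <- length(networks)
  module_matrix <- matrix(0, m, m, dimnames = list(networks, networks))
  vals <- if (signed) contributions else abs(contributions)
  for (e in seq_along(vals)) {
    a <- net_i[e]
    b <- net_j[e]
    # each edge lands in exactly one unordered module cell
    module_matrix[a, b] <- module_matrix[a, b] + vals[e]
    if (a != b) module_matrix[b, a] <- module_matrix[b, a] + vals[e]
  }
  cells <- module_matrix[upper.tri(module_matrix, diag = TRUE)]
  mu <- mean(cells)
  sdv <- stats::sd(cells)
  module_z <- (module_matrix - mu) / if (sdv > 0) sdv else 1
  p <- length(contributions)
  n_top <- ceiling(top_frac * p)
  cutoff_rank <- rank(-abs(contributions), ties.method = "first")
  structure(
    list(edge_contribution = contributions,
         module_matrix = module_matrix,
         module_z = module_z,
         top_mask = cutoff_rank <= n_top,
         networks = networks),
    class = "network_contribution_table"
  )
}

#' Covariate-adjusted association of a brain variate score with an outcome
#'
#' Standardizes the outcome and the score, fits an ordinary least squares
#' model of the outcome on the score plus covariates (complete cases only),
#' and returns the standardized beta with its 95% confidence interval.
#'
#' @param brain_scores length-n brain variate score vector.
#' @param outcome length-n outcome vector (e.g. cognitive ability).
#' @param covariates optional covariate data frame.
#' @return list of class `outcome_association`: `standardized_beta`,
#'   `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
outcome_regression <- function(brain_scores, outcome, covariates = NULL) {
  brain_scores <- as.numeric(brain_scores)
  outcome <- as.numeric(outcome)
  stopifnot(length(brain_scores) == length(outcome))
  df <- data.frame(outcome = outcome, score = brain_scores)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(outcome))
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (nrow(df) <= n_cov + 2L) {
    stop("too few complete cases (", nrow(df), ") for the covariate model")
  }
  df$outcome <- as.numeric(scale(df$outcome))
  df$score <- as.numeric(scale(df$score))
  fit <- stats::lm(outcome ~ ., data = df)
  ci <- stats::confint(fit, "score", level = 0.95)
  coefs <- summary(fit)$coefficients
  structure(
    list(standardized_beta = unname(coefs["score", "Estimate"]),
         ci_low = unname(ci[1L]),
         ci_high = unname(ci[2L]),
         p_value = unname(coefs["score", "Pr(>|t|)"]),
         n = nrow(df)),
    class = "outcome_association"
  )
}
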