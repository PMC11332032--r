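# Cross-study external validity: the gold-standard projection of a source
# cohort's full model chain onto an independent target cohort, and the
# bidirectional qualitative-replication procedure.

#' Gold-standard out-of-study generalizability test
#'
#' Projects every source repetition's full model chain onto an independent
#' target cohort: target brain features are residualized on the target's
#' own covariates, projected through the source repetition's weighted-PCA
#' eigenvectors, and scored with the source canonical loadings; the
#' resulting external canonical correlations are assessed with project-mode
#' permutation tests. Only source-cohort model parameters and target-cohort
#' data enter the computation.
#'
#' @param holdout a `holdout_result` trained on the source cohort.
#' @param target a `two_view_cohort` with the same brain feature space.
#' @param B permutations per repetition (default 2000).
#' @param alpha q-value threshold for the validated count (default 0.05).
#' @param seed integer seed.
#' @return object of class `generalizability_result` with `repetitions`
#'   (external correlations and permutation p/q per source repetition) and
#'   `summary` (mean external correlations, per-component count of
#'   repetitions with q < alpha).
#' @export
gold_standard_test <- function(holdout, target, B = 2000L, alpha = 0.05,
                               seed = 1L) {
  stopifnot(inherits(holdout, "holdout_result"))
  validate_two_view_cohort(target)
  reps <- holdout$repetitions
  if (length(reps) == 0L) stop("empty source holdout result")
  p_fit <- nrow(reps[[1L]]$pca$eigenvectors)
  if (ncol(target$brain) != p_fit) {
    stop("target brain feature count (", ncol(target$brain),
         ") does not match the source PCA (", p_fit, ")")
  }
  res <- residualize_fit_transform(target$brain, target$covariates)
  d <- reps[[1L]]$model$n_components
  out <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    r <- reps[[i]]
    pcs <- weighted_pca_transform(r$pca, res$residuals)
    perm <- permutation_test(pcs, target$symptoms, r$model, B = B,
                             mode = "project",
                             seed = derive_seed(seed, i))
    # align to a non-negative source training correlation (source-only flip)
    flip <- sign(r$train_scores$correlations)
    flip[flip == 0] <- 1
    out[[i]] <- list(repetition = r$split$repetition,
                     correlations = scca_project(r$model, pcs,
                                                 target$symptoms)$correlations *
                       flip,
                     p_values = perm$p_values,
                     q_values = perm$q_values)
  }
  ext_r <- t(vapply(out, `[[`, numeric(d), "correlations"))
  sig <- t(vapply(out, function(o) o$q_values < alpha, logical(d)))
  structure(
    list(repetitions = out,
         summary = list(
           mean_external_correlations = colMeans(ext_r),
           n_significant = colSums(sig),
           n_repetitions = length(out))),
    class = "generalizability_result"
  )
}

# shared preprocessing for one cohort in the replication procedure:
# own residualization, own rank weights, own weighted PCA
prepare_cohort_blocks <- function(cohort, k_pc, rank_descending = TRUE) {
  res <- residualize_fit_transform(cohort$brain, cohort$covariates)
  w <- rank_weights(rowSums(cohort$symptoms), descending = rank_descending)
  pca <- weighted_pca_fit(res$residuals, w, k = k_pc)
  list(X = weighted_pca_transform(pca, res$residuals),
       Y = cohort$symptoms, pca = pca)
}

perm_cor_p <- function(a, b, B, seed, two_sided = TRUE) {
  obs <- stats::cor(a, b)
  with_seed(seed, {
    null <- vapply(seq_len(B), function(i) {
      stats::cor(a[sample.int(length(a))], b)
    }, numeric(1))
  })
  exceed <- if (two_sided) sum(abs(null) >= abs(obs)) else sum(null >= obs)
  list(correlation = obs, p = (1 + exceed) / (B + 1))
}

#' Bidirectional qualitative replication across two cohorts
#'
#' Fits the sparse CCA independently in each cohort (each with its own
#' residualization and weighted PCA) using a shared penalty pair, matches
#' cohort B's components to cohort A's by the behavior-loading assignment
#' rule, then evaluates both directions: A->B projects B's blocks with A's
#' loadings and correlates the cross-projected variate scores with B's
#' natively trained scores (on B's subjects); B->A is symmetric.
#' Significance of each score correlation is assessed by permuting subject
#' rows. A component is flagged generalizable only when its behavior-side
#' score correlation is significant in both directions.
#'
#' @param cohort_a,cohort_b `two_view_cohort` objects.
#' @param penalties shared [penalty_pair()] (e.g. from
#'   [most_selected_penalties()]).
#' @param n_components number of components to fit in each cohort.
#' @param k_pc retained principal components per cohort.
#' @param B permutations per correlation (default 5000).
#' @param alpha significance level for the bidirectional flag (default
#'   0.05).
#' @param seed integer seed.
#' @return object of class `replication_result` with `direction_ab` and
#'   `direction_ba` (per-component brain- and behavior-side score
#'   correlations with permutation p-values), `generalizable` (per-component
#'   flag), and the two fitted models.
#' @export
qualitative_replication <- function(cohort_a, cohort_b, penalties,
                                    n_components = 3L, k_pc = 20L,
                                    B = 5000L, alpha = 0.05, seed = 1L) {
  validate_two_view_cohort(cohort_a)
  validate_two_view_cohort(cohort_b)
  if (ncol(cohort_a$symptoms) != ncol(cohort_b$symptoms)) {
    stop("cohorts must share the symptom dimension")
  }
  blocks_a <- prepare_cohort_blocks(cohort_a, k_pc)
  blocks_b <- prepare_cohort_blocks(cohort_b, k_pc)
  fit_a <- suppressWarnings(scca_fit(blocks_a$X, blocks_a$Y, penalties,
                                     n_components = n_components))
  fit_b <- suppressWarnings(scca_fit(blocks_b$X, blocks_b$Y, penalties,
                                     n_components = n_components))
  d <- min(fit_a$n_components, fit_b$n_components)
  if (fit_a$n_components != fit_b$n_components) {
    warning("component counts differ; truncating to ", d)
  }

  # align B's components to A's by the behavior-loading assignment rule
  m <- match_components(fit_a$v[, seq_len(d), drop = FALSE],
                        fit_b$v[, seq_len(d), drop = FALSE])
  fit_b_aligned <- scca_model(
    sweep(fit_b$u[, m$perm, drop = FALSE], 2L, m$signs, "*"),
    sweep(fit_b$v[, m$perm, drop = FALSE], 2L, m$signs, "*"),
    penalties = fit_b$penalties
  )
  fit_a_trunc <- scca_model(fit_a$u[, seq_len(d), drop = FALSE],
                            fit_a$v[, seq_len(d), drop = FALSE],
                            penalties = fit_a$penalties)

  direction <- function(source_fit, native_fit, blocks, seed_offset) {
    cross <- scca_project(source_fit, blocks$X, blocks$Y)
    native <- scca_project(native_fit, blocks$X, blocks$Y)
    res <- data.frame(component = seq_len(d),
                      brain_r = NA_real_, brain_p = NA_real_,
                      behavior_r = NA_real_, behavior_p = NA_real_)
    for (j in seq_len(d)) {
      pb <- perm_cor_p(cross$brain_scores[, j], native$brain_scores[, j],
                       B, derive_seed(seed, seed_offset + 2L * j))
      py <- perm_cor_p(cross$behavior_scores[, j],
                       native$behavior_scores[, j],
                       B, derive_seed(seed, seed_offset + 2L * j + 1L))
      res$brain_r[j] <- pb$correlation
      res$brain_p[j] <- pb$p
      res$behavior_r[j] <- py$correlation
      res$behavior_p[j] <- py$p
    }
    res
  }
  ab <- direction(fit_a_trunc, fit_b_aligned, blocks_b, 100L)
  ba <- direction(fit_b_aligned, fit_a_trunc, blocks_a, 200L)
  structure(
    list(direction_ab = ab,
         direction_ba = ba,
         generalizable = ab$behavior_p < alpha & ba$behavior_p < alpha,
         model_a = fit_a_trunc,
         model_b = fit_b_aligned,
         match = m),
    class = "replication_result"
  )
}
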