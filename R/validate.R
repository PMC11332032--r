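# The multiple hold-out engine: site-stratified train/test splits, the
# inner resampled penalty grid search, permutation significance with FDR,
# bootstrap stability with canonical-variate matching, and the end-to-end
# pipeline over repetitions.

site_levels <- function(x) {
  if (inherits(x, "two_view_cohort")) x <- x$site
  levels(factor(x))
}

#' Site-stratified train/test split schemes
#'
#' Each repetition samples `n_test_sites` test sites uniformly without
#' replacement (independently across repetitions, so a site may serve as a
#' test site in several repetitions); the remaining sites form the training
#' set. Deterministic under the seed.
#'
#' @param cohort a `two_view_cohort`, a factor, or a character vector of
#'   site labels.
#' @param n_test_sites number of held-out sites per repetition (default 3).
#' @param n_reps number of repetitions (default 30).
#' @param seed integer seed.
#' @return list of `split_scheme` objects with `repetition`, `train_sites`,
#'   `test_sites`.
#' @export
make_site_splits <- function(cohort, n_test_sites = 3L, n_reps = 30L, seed = 1L) {
  sites <- site_levels(cohort)
  if (length(sites) <= n_test_sites) {
    stop("need more sites (", length(sites), ") than test sites (",
         n_test_sites, ")")
  }
  with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      test <- sort(sample(sites, n_test_sites))
      structure(list(repetition = r,
                     train_sites = setdiff(sites, test),
                     test_sites = test,
                     seed = seed),
                class = "split_scheme")
    })
  })
}

#' Disjoint site-level cross-validation folds
#'
#' Partitions the sites into `n_folds` test folds with no site repeated
#' across folds, as evenly as possible (any remainder sites go to the
#' earliest folds; with 21 sites and 5 folds the test-fold sizes are
#' 5, 4, 4, 4, 4).
#'
#' @inheritParams make_site_splits
#' @param n_folds number of folds (default 5).
#' @return list of `split_scheme` objects whose `test_sites` partition the
#'   site set.
#' @export
make_disjoint_folds <- function(cohort, n_folds = 5L, seed = 1L) {
  sites <- site_levels(cohort)
  s <- length(sites)
  if (n_folds < 2L || n_folds > s) {
    stop("cannot partition ", s, " sites into ", n_folds, " folds")
  }
  with_seed(seed, {
    shuffled <- sample(sites)
    base <- s %/% n_folds
    sizes <- rep(base, n_folds)
    extra <- s %% n_folds
    if (extra > 0) sizes[seq_len(extra)] <- base + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    lapply(seq_len(n_folds), function(f) {
      test <- sort(shuffled[starts[f]:ends[f]])
      structure(list(repetition = f,
                     train_sites = setdiff(sites, test),
                     test_sites = test,
                     seed = seed),
                class = "split_scheme")
    })
  })
}

#' Penalty grid search by repeated inner resampling
#'
#' For every penalty pair on the grid (with the behavior-side values
#' restricted to be larger than 0.5), the sparse CCA model is fitted on
#' `n_inner` random inner-training subsets (a `train_frac` fraction of the
#' subjects) and projected onto the complementary validation subsets; the
#' pair with the highest first canonical correlation averaged over the
#' inner splits wins. Ties break toward sparser (smaller) penalties, brain
#' side first.
#'
#' @param X n x k training brain block (e.g. PC scores).
#' @param Y n x q training behavior block.
#' @param grid_brain,grid_behavior candidate grid values (defaults: 0 to 1
#'   by 0.1 for the brain side, 0.6 to 1 by 0.1 for the behavior side).
#' @param n_inner number of inner resamples (default 100).
#' @param train_frac inner-training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with `penalties` (the winning [penalty_pair()]) and `table`
#'   (mean validation first correlation per candidate pair).
#' @export
grid_search_penalties <- function(X, Y,
                                  grid_brain = seq(0, 1, by = 0.1),
                                  grid_behavior = seq(0.6, 1, by = 0.1),
                                  n_inner = 100L, train_frac = 0.8,
                                  seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  grid_behavior <- grid_behavior[grid_behavior > 0.5]
  if (length(grid_brain) == 0L || length(grid_behavior) == 0L) {
    stop("empty penalty grid after the behavior-side constraint")
  }
  n <- nrow(X)
  pairs <- expand.grid(c_brain = grid_brain, c_behavior = grid_behavior)
  # sorted so the first maximum encountered is the sparsest, brain first
  pairs <- pairs[order(pairs$c_brain, pairs$c_behavior), , drop = FALSE]
  scores <- matrix(NA_real_, nrow(pairs), n_inner)
  with_seed(seed, {
    inner_idx <- lapply(seq_len(n_inner), function(b) {
      sample.int(n, size = max(2L, round(train_frac * n)))
    })
    for (b in seq_len(n_inner)) {
      tr <- inner_idx[[b]]
      va <- setdiff(seq_len(n), tr)
      for (g in seq_len(nrow(pairs))) {
        fit <- tryCatch(
          suppressWarnings(scca_fit(X[tr, , drop = FALSE],
                                    Y[tr, , drop = FALSE],
                                    c(pairs$c_brain[g], pairs$c_behavior[g]),
                                    n_components = 1L)),
          error = function(e) NULL
        )
        if (is.null(fit)) next
        proj <- scca_project(fit, X[va, , drop = FALSE],
                             Y[va, , drop = FALSE])
        scores[g, b] <- proj$correlations[1L]
      }
    }
  })
  mean_scores <- rowMeans(scores, na.rm = TRUE)
  if (all(is.nan(mean_scores))) {
    stop("no penalty pair produced a usable fit")
  }
  best <- which.max(mean_scores) # first (sparsest) argmax wins on ties
  list(
    penalties = penalty_pair(pairs$c_brain[best], pairs$c_behavior[best]),
    table = data.frame(pairs,
                       mean_validation_correlation = mean_scores)
  )
}

#' Permutation significance test for canonical correlations
#'
#' Builds a null distribution by shuffling the subject rows of the behavior
#' block, breaking the brain-behavior pairing while leaving both marginal
#' structures intact. In `"refit"` mode (training sets) the sparse CCA is
#' refitted to every shuffled dataset with the same penalty pair; in
#' `"project"` mode (test/external sets) the fixed loadings are re-projected.
#' P-values use the add-one estimator `(1 + b) / (B + 1)` on the exceedance
#' count (two-sided: `|null| >= |observed|`), and q-values apply
#' Benjamini-Hochberg across the tested components.
#'
#' @param X,Y data blocks.
#' @param model the fitted `scca_model` being tested.
#' @param B number of permutations (default 2000; below 100 a warning is
#'   issued).
#' @param mode `"project"` (default) or `"refit"`.
#' @param components indices of components to test (e.g. those passing the
#'   covariance-explained gate); default all. An empty selection returns an
#'   empty result with a note.
#' @param seed integer seed.
#' @param two_sided exceed on absolute values (default `TRUE`); `FALSE`
#'   uses raw exceedance `null >= observed`.
#' @return object of class `permutation_result`: `observed`, `null_draws`
#'   (B x d), `p_values`, `q_values`, `B`, `mode`, `components`.
#' @export
permutation_test <- function(X, Y, model, B = 2000L,
                             mode = c("project", "refit"),
                             components = NULL, seed = 1L,
                             two_sided = TRUE) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(inherits(model, "scca_model"), nrow(X) == nrow(Y))
  d <- model$n_components
  if (is.null(components)) components <- seq_len(d)
  if (length(components) == 0L) {
    message("covariance-explained gate selected no components; ",
            "empty permutation result")
    return(structure(list(observed = numeric(0),
                          null_draws = matrix(numeric(0), B, 0L),
                          p_values = numeric(0), q_values = numeric(0),
                          B = as.integer(B), mode = mode,
                          components = integer(0)),
                     class = "permutation_result"))
  }
  if (B < 100L) warning("B = ", B, " permutations is very small")
  n <- nrow(X)
  proj <- scca_project(model, X, Y)
  observed <- proj$correlations[components]
  null_draws <- matrix(NA_real_, B, length(components))
  with_seed(seed, {
    if (mode == "project") {
      # shuffling Y's rows then projecting equals shuffling the behavior
      # score rows: standardization and the projection are row-wise
      bs <- proj$brain_scores[, components, drop = FALSE]
      ys <- proj$behavior_scores[, components, drop = FALSE]
      for (b in seq_len(B)) {
        perm <- sample.int(n)
        null_draws[b, ] <- vapply(seq_along(components), function(j) {
          if (stats::sd(ys[, j]) < 1e-12 || stats::sd(bs[, j]) < 1e-12) 0
          else stats::cor(bs[, j], ys[perm, j])
        }, numeric(1))
      }
    } else {
      if (is.null(model$penalties)) {
        stop("refit mode needs the model's penalty pair")
      }
      # standardize once: row permutation leaves column statistics intact
      Xs <- standardize_columns(X)
      Ys <- standardize_columns(Y)
      for (b in seq_len(B)) {
        perm <- sample.int(n)
        refit <- tryCatch(
          suppressWarnings(scca_fit(Xs, Ys[perm, , drop = FALSE],
                                    model$penalties,
                                    n_components = d,
                                    standardize = FALSE)),
          error = function(e) NULL
        )
        if (!is.null(refit)) {
          null_draws[b, ] <- refit$train_correlations[components]
        }
      }
    }
  })
  ok <- rowSums(is.na(null_draws)) == 0L
  nd <- null_draws[ok, , drop = FALSE]
  b_eff <- nrow(nd)
  exceed <- if (two_sided) {
    colSums(abs(nd) >= matrix(abs(observed), b_eff, length(observed),
                              byrow = TRUE))
  } else {
    colSums(nd >= matrix(observed, b_eff, length(observed), byrow = TRUE))
  }
  p <- (1 + exceed) / (b_eff + 1)
  structure(
    list(observed = observed,
         null_draws = null_draws,
         p_values = p,
         q_values = stats::p.adjust(p, method = "BH"),
         B = as.integer(B),
         n_failed = sum(!ok),
         mode = mode,
         components = as.integer(components)),
    class = "permutation_result"
  )
}

#' Bootstrap stability of canonical loadings
#'
#' Resamples subjects with replacement, refits the sparse CCA with the
#' reference penalties, and aligns every bootstrap solution to the
#' reference: components are matched one-to-one by maximal total absolute
#' cosine between the behavior-side (CBCL) loading columns, and signs are
#' flipped so the matched cosines are non-negative. Failed refits are
#' dropped and counted.
#'
#' @param X,Y the training blocks the reference model was fitted on.
#' @param reference the reference `scca_model`.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return object of class `bootstrap_result`: `matched_u` and `matched_v`
#'   (B x features x d arrays of aligned loadings), `correlations` (B x d),
#'   `match_permutations` (B x d), `n_dropped`.
#' @export
bootstrap_stability <- function(X, Y, reference, B = 1000L, seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(inherits(reference, "scca_model"), nrow(X) == nrow(Y))
  d <- reference$n_components
  n <- nrow(X)
  matched_u <- array(NA_real_, c(B, nrow(reference$u), d))
  matched_v <- array(NA_real_, c(B, nrow(reference$v), d))
  correlations <- matrix(NA_real_, B, d)
  match_perms <- matrix(NA_integer_, B, d)
  dropped <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, replace = TRUE)
      fit <- tryCatch(
        suppressWarnings(scca_fit(X[idx, , drop = FALSE],
                                  Y[idx, , drop = FALSE],
                                  reference$penalties,
                                  n_components = d)),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        dropped <- dropped + 1L
        next
      }
      m <- match_components(reference$v, fit$v)
      for (j in seq_len(d)) {
        matched_u[b, , j] <- fit$u[, m$perm[j]] * m$signs[j]
        matched_v[b, , j] <- fit$v[, m$perm[j]] * m$signs[j]
        correlations[b, j] <- fit$train_correlations[m$perm[j]]
      }
      match_perms[b, ] <- m$perm
    }
  })
  if (dropped > 0L) {
    message(dropped, " bootstrap resample(s) dropped after refit failure")
  }
  structure(
    list(matched_u = matched_u, matched_v = matched_v,
         correlations = correlations,
         match_permutations = match_perms,
         B = as.integer(B), n_dropped = dropped),
    class = "bootstrap_result"
  )
}

#' Configuration for the multiple hold-out pipeline
#'
#' @param n_reps number of train/test repetitions (default 30).
#' @param n_test_sites held-out sites per repetition (default 3).
#' @param k_pc retained principal components (default 100).
#' @param n_components sparse CCA components `d` (default 8, the symptom
#'   dimension).
#' @param grid_brain,grid_behavior penalty grids for the inner search.
#' @param n_inner inner resamples of the grid search (default 100).
#' @param inner_train_frac inner-training fraction (default 0.8).
#' @param B_perm permutations per significance test (default 2000; 0 skips
#'   permutation testing).
#' @param penalties optional fixed [penalty_pair()]; when supplied the grid
#'   search is skipped.
#' @param alpha q-value threshold declaring a component validated in a
#'   repetition (default 0.05).
#' @param rank_descending rank 1 = highest total symptom score (default
#'   `TRUE`).
#' @param seed master seed; all per-repetition randomness derives from it.
#' @param verbose log per-repetition progress and stage timings.
#' @return list of class `holdout_config`.
#' @export
holdout_config <- function(n_reps = 30L, n_test_sites = 3L, k_pc = 100L,
                           n_components = 8L,
                           grid_brain = seq(0, 1, by = 0.1),
                           grid_behavior = seq(0.6, 1, by = 0.1),
                           n_inner = 100L, inner_train_frac = 0.8,
                           B_perm = 2000L, penalties = NULL,
                           alpha = 0.05, rank_descending = TRUE,
                           seed = 1L, verbose = FALSE) {
  structure(as.list(environment()), class = "holdout_config")
}

run_holdout_repetition <- function(cohort, split, config) {
  rep_seed <- derive_seed(config$seed, split$repetition)
  tr <- cohort$site %in% split$train_sites
  te <- cohort$site %in% split$test_sites

  # per-set residualization (leakage separation: test set fits its own)
  res_tr <- residualize_fit_transform(cohort$brain[tr, , drop = FALSE],
                                      cohort$covariates[tr, , drop = FALSE])
  res_te <- residualize_fit_transform(cohort$brain[te, , drop = FALSE],
                                      cohort$covariates[te, , drop = FALSE])

  y_tr <- cohort$symptoms[tr, , drop = FALSE]
  y_te <- cohort$symptoms[te, , drop = FALSE]

  weights <- rank_weights(rowSums(y_tr), descending = config$rank_descending)
  pca <- weighted_pca_fit(res_tr$residuals, weights, k = config$k_pc)
  x_tr <- weighted_pca_transform(pca, res_tr$residuals)
  x_te <- weighted_pca_transform(pca, res_te$residuals)

  if (is.null(config$penalties)) {
    gs <- grid_search_penalties(x_tr, y_tr,
                                grid_brain = config$grid_brain,
                                grid_behavior = config$grid_behavior,
                                n_inner = config$n_inner,
                                train_frac = config$inner_train_frac,
                                seed = derive_seed(rep_seed, 1L))
    penalties <- gs$penalties
  } else {
    penalties <- as_penalty_pair(config$penalties)
  }

  model <- suppressWarnings(
    scca_fit(x_tr, y_tr, penalties, n_components = config$n_components)
  )
  train_scores <- scca_project(model, x_tr, y_tr)
  test_scores <- scca_project(model, x_te, y_te)
  gate <- covariance_explained(train_scores)$gate
  tested <- which(gate)

  train_perm <- test_perm <- NULL
  if (config$B_perm > 0L && length(tested) > 0L) {
    train_perm <- permutation_test(x_tr, y_tr, model, B = config$B_perm,
                                   mode = "refit", components = tested,
                                   seed = derive_seed(rep_seed, 2L))
    test_perm <- permutation_test(x_te, y_te, model, B = config$B_perm,
                                  mode = "project", components = tested,
                                  seed = derive_seed(rep_seed, 3L))
  }

  list(split = split,
       penalties = penalties,
       pca = pca,
       residualizer = res_tr$model,
       weights = weights,
       model = model,
       feature_loadings = pca$eigenvectors %*% model$u,
       train_scores = train_scores,
       test_scores = test_scores,
       gate = gate,
       train_perm = train_perm,
       test_perm = test_perm)
}

#' Run the site-stratified multiple hold-out pipeline
#'
#' For every repetition: split the cohort by site, residualize each set on
#' its own covariates, derive rank weights from the training symptom
#' totals, fit the weighted PCA on training residuals and project both
#' sets, select penalties by the inner resampled grid search (unless fixed
#' in the config), fit the sparse CCA, project onto the held-out sites, and
#' run permutation tests in both sets (refit mode in training, project mode
#' in test) for the components passing the covariance-explained gate.
#'
#' @param cohort a `two_view_cohort`.
#' @param config a [holdout_config()].
#' @return object of class `holdout_result` with `repetitions` (one full
#'   record per surviving repetition) and `summary` (per-component mean
#'   train/test correlations and validated-split counts, selected penalty
#'   table, failures).
#' @export
run_multiple_holdout <- function(cohort, config = holdout_config()) {
  validate_two_view_cohort(cohort)
  stopifnot(inherits(config, "holdout_config"))
  splits <- make_site_splits(cohort,
                             n_test_sites = config$n_test_sites,
                             n_reps = config$n_reps,
                             seed = config$seed)
  reps <- vector("list", length(splits))
  failures <- character(0)
  for (i in seq_along(splits)) {
    t0 <- Sys.time()
    reps[[i]] <- tryCatch(
      run_holdout_repetition(cohort, splits[[i]], config),
      error = function(e) {
        failures <<- c(failures,
                       sprintf("repetition %d: %s", i, conditionMessage(e)))
        NULL
      }
    )
    if (config$verbose) {
      message(sprintf("repetition %d/%d done in %.1fs%s", i, length(splits),
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      if (is.null(reps[[i]])) " (FAILED)" else ""))
    }
  }
  reps <- Filter(Negate(is.null), reps)
  if (length(reps) == 0L) {
    stop("every repetition failed:\n", paste(failures, collapse = "\n"))
  }
  d <- config$n_components
  train_r <- t(vapply(reps, function(r) r$train_scores$correlations,
                      numeric(d)))
  test_r <- t(vapply(reps, function(r) r$test_scores$correlations,
                     numeric(d)))
  # the sign of a canonical correlation is arbitrary under the per-column
  # loading sign convention; align each repetition's components to a
  # non-negative training correlation (the same training-determined flip is
  # applied to the test correlation, so no test information is used)
  flip <- sign(train_r)
  flip[flip == 0] <- 1
  train_r <- train_r * flip
  test_r <- test_r * flip
  sig <- matrix(FALSE, length(reps), d)
  for (i in seq_along(reps)) {
    pr <- reps[[i]]$test_perm
    if (!is.null(pr) && length(pr$components) > 0L) {
      sig[i, pr$components] <- pr$q_values < config$alpha
    }
  }
  summary <- list(
    n_repetitions = length(reps),
    mean_train_correlations = colMeans(train_r),
    mean_test_correlations = colMeans(test_r),
    n_test_significant = colSums(sig),
    selected_penalties = data.frame(
      repetition = vapply(reps, function(r) r$split$repetition, integer(1)),
      c_brain = vapply(reps, function(r) r$penalties$c_brain, numeric(1)),
      c_behavior = vapply(reps, function(r) r$penalties$c_behavior,
                          numeric(1))
    ),
    failures = failures
  )
  structure(list(repetitions = reps, summary = summary, config = config),
            class = "holdout_result")
}

#' @export
print.holdout_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("holdout_result: %d repetition(s), %d component(s)\n",
              s$n_repetitions, length(s$mean_train_correlations)))
  tab <- data.frame(
    component = seq_along(s$mean_train_correlations),
    mean_train_r = round(s$mean_train_correlations, 4),
    mean_test_r = round(s$mean_test_correlations, 4),
    n_test_significant = s$n_test_significant
  )
  print(tab, row.names = FALSE)
  if (length(s$failures) > 0) {
    cat("failed repetitions:\n", paste(s$failures, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Most frequently selected penalty pair across repetitions
#'
#' The modal penalty pair over the repetitions of a hold-out run; ties
#' break toward the sparser pair (smaller brain value, then smaller
#' behavior value).
#'
#' @param holdout a `holdout_result`.
#' @return a [penalty_pair()].
#' @export
most_selected_penalties <- function(holdout) {
  stopifnot(inherits(holdout, "holdout_result"))
  tab <- holdout$summary$selected_penalties
  key <- paste(tab$c_brain, tab$c_behavior, sep = "/")
  counts <- table(key)
  winners <- names(counts)[counts == max(counts)]
  parts <- do.call(rbind, strsplit(winners, "/"))
  ord <- order(as.numeric(parts[, 1L]), as.numeric(parts[, 2L]))
  best <- parts[ord[1L], ]
  penalty_pair(as.numeric(best[1L]), as.numeric(best[2L]))
}

#' Average brain loadings in feature space across repetitions
#'
#' Maps each repetition's brain-side loadings back through its own PCA
#' eigenvectors into the common feature space, aligns components across
#' repetitions to the first repetition's behavior loadings (one-to-one
#' absolute-cosine matching with sign flips), and averages. The result
#' feeds edge-level interpretation.
#'
#' @param holdout a `holdout_result`.
#' @return p x d matrix of averaged feature-space loadings.
#' @export
mean_feature_loadings <- function(holdout) {
  stopifnot(inherits(holdout, "holdout_result"))
  reps <- holdout$repetitions
  ref_v <- reps[[1L]]$model$v
  d <- ncol(ref_v)
  acc <- 0
  for (r in reps) {
    m <- match_components(ref_v, r$model$v)
    aligned <- r$feature_loadings[, m$perm, drop = FALSE]
    aligned <- sweep(aligned, 2L, m$signs, "*")
    acc <- acc + aligned
  }
  acc / length(reps)
}
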