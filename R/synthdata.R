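# Synthetic two-view cohort generator with planted sparse canonical
# structure: a paired brain-feature matrix and count-like symptom scales,
# additive site effects on the brain view, shared covariate effects, and a
# stored ground truth for recovery checks.

#' Configuration for the synthetic two-view cohort generator
#'
#' Defines the study conditions under which paired brain-connectivity-like
#' features and CBCL-like syndrome scores are simulated: cohort size,
#' dimensionality of both views, number of acquisition sites, the planted
#' canonical correlations, loading sparsity, and the scales of site,
#' covariate and residual noise.
#'
#' @param n_subjects number of subjects (must be at least `2 * n_sites`).
#' @param n_features number of brain features `p` (Fisher-z connectivity
#'   scale).
#' @param n_symptoms number of symptom scales `q` (default 8, the CBCL
#'   syndrome-scale count).
#' @param n_sites number of acquisition sites (default 21).
#' @param true_correlations numeric vector of planted canonical
#'   correlations, each in `[0, 1)`; its length is the number of planted
#'   components.
#' @param loading_sparsity fraction in `(0, 1]` of nonzero true loadings per
#'   view.
#' @param site_effect_sd standard deviation of the additive per-site,
#'   per-feature shifts applied to the brain view only (scanner-driven).
#' @param covariate_effect_sd standard deviation of the linear covariate
#'   effects applied to both views.
#' @param noise_sd standard deviation of the residual noise in each view.
#' @param seed integer seed fixing all randomness of the generator.
#' @return object of class `simulation_config`.
#' @seealso [simulate_two_view()]
#' @export
simulation_config <- function(n_subjects,
                              n_features,
                              n_symptoms = 8L,
                              n_sites = 21L,
                              true_correlations = 0.3,
                              loading_sparsity = 0.1,
                              site_effect_sd = 0.25,
                              covariate_effect_sd = 0.25,
                              noise_sd = 0.5,
                              seed = 1L) {
  stopifnot(
    length(n_subjects) == 1L, n_subjects >= 2,
    length(n_features) == 1L, n_features >= 1,
    length(n_symptoms) == 1L, n_symptoms >= 1,
    length(n_sites) == 1L, n_sites >= 1,
    is.numeric(true_correlations), length(true_correlations) >= 1L,
    length(loading_sparsity) == 1L,
    loading_sparsity > 0, loading_sparsity <= 1,
    site_effect_sd >= 0, covariate_effect_sd >= 0, noise_sd > 0,
    length(seed) == 1L, is.finite(seed)
  )
  if (any(true_correlations < 0)) {
    stop("true_correlations must be non-negative")
  }
  if (any(true_correlations >= 1)) {
    stop("true canonical correlations must be strictly below 1")
  }
  if (length(true_correlations) > min(n_features, n_symptoms)) {
    stop("more planted components than min(n_features, n_symptoms)")
  }
  if (n_subjects < 2 * n_sites) {
    stop("need at least 2 subjects per site: n_subjects >= 2 * n_sites")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_features = as.integer(n_features),
      n_symptoms = as.integer(n_symptoms),
      n_sites = as.integer(n_sites),
      true_correlations = as.numeric(true_correlations),
      loading_sparsity = loading_sparsity,
      site_effect_sd = site_effect_sd,
      covariate_effect_sd = covariate_effect_sd,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# sparse unit-norm loading matrix (dim x K); supports are disjoint across
# components when they fit, which makes the columns exactly orthogonal and
# deflation-based recovery well-posed
sparse_loading_matrix <- function(dim, k, sparsity) {
  nnz <- round(sparsity * dim)
  if (nnz < 1) {
    stop("infeasible loading sparsity: ", sparsity, " of ", dim,
         " loadings rounds to zero nonzeros")
  }
  m <- matrix(0, dim, k)
  if (k * nnz <= dim) {
    pool <- sample.int(dim)
    for (j in seq_len(k)) {
      sup <- pool[((j - 1L) * nnz + 1L):(j * nnz)]
      m[sup, j] <- stats::rnorm(nnz)
    }
  } else {
    for (j in seq_len(k)) {
      sup <- sample.int(dim, nnz)
      m[sup, j] <- stats::rnorm(nnz)
    }
    # Gram-Schmidt across overlapping supports (sparsity then approximate)
    for (j in seq_len(k)) {
      if (j > 1L) {
        for (l in seq_len(j - 1L)) {
          m[, j] <- m[, j] - sum(m[, j] * m[, l]) * m[, l]
        }
      }
    }
  }
  apply(m, 2L, unitize)
}

# monotone shifted-exponential transform of a standardized latent value to a
# non-negative right-skewed integer score, mimicking CBCL syndrome scales
# (means well below SDs, a mass at zero, long right tail)
count_transform <- function(g, location = 0.8, slope = 0.8, shift = 1) {
  pmax(round(exp(location + slope * g) - shift), 0)
}

#' Simulate a paired brain-symptom cohort with known canonical structure
#'
#' Draws, per planted component `k`, a pair of standard-normal latent scores
#' with the configured correlation; the brain view is `latent %*% t(A)` plus
#' per-site shifts, linear covariate effects and Gaussian noise, and the
#' symptom view is `latent %*% t(B)` plus covariate effects and noise,
#' monotonically transformed to non-negative right-skewed integer scores.
#' `A` (p x K) and `B` (q x K) are sparse unit-norm loading matrices stored
#' in the returned ground truth together with the latent scores and the
#' pre-transform symptom matrix.
#'
#' @param config a [simulation_config()].
#' @param loadings optional list with matrices `A` (p x K) and/or `B`
#'   (q x K) overriding the randomly drawn true loadings; used to construct
#'   paired cohorts that share structure in one view (e.g. replication
#'   experiments).
#' @return object of class `two_view_cohort`: list with `brain` (n x p),
#'   `symptoms` (n x q non-negative integers), `covariates` (data frame:
#'   age, sex, education), `site` (factor), `subject_id`, and `truth`
#'   (loadings `A`, `B`, `correlations`, latent scores, and the
#'   pre-transform `symptom_latent` matrix).
#' @export
#' @examples
#' cfg <- simulation_config(n_subjects = 120, n_features = 30, n_sites = 6,
#'                          true_correlations = 0.7, seed = 7)
#' cohort <- simulate_two_view(cfg)
#' dim(cohort$brain)
simulate_two_view <- function(config, loadings = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    p <- config$n_features
    q <- config$n_symptoms
    rho <- config$true_correlations
    k <- length(rho)

    A <- sparse_loading_matrix(p, k, config$loading_sparsity)
    B <- sparse_loading_matrix(q, k, config$loading_sparsity)
    if (!is.null(loadings)) {
      if (!is.null(loadings$A)) {
        stopifnot(nrow(loadings$A) == p, ncol(loadings$A) == k)
        A <- apply(loadings$A, 2L, unitize)
        if (k == 1L) A <- matrix(A, p, 1L)
      }
      if (!is.null(loadings$B)) {
        stopifnot(nrow(loadings$B) == q, ncol(loadings$B) == k)
        B <- apply(loadings$B, 2L, unitize)
        if (k == 1L) B <- matrix(B, q, 1L)
      }
    }

    # paired latent scores with the planted correlation per component
    xi <- matrix(stats::rnorm(n * k), n, k)
    eps <- matrix(stats::rnorm(n * k), n, k)
    eta <- sweep(xi, 2L, rho, "*") +
      sweep(eps, 2L, sqrt(1 - rho^2), "*")

    # sites: every site seeded with 2 subjects, remainder uniform
    site_idx <- c(rep(seq_len(config$n_sites), 2L),
                  sample.int(config$n_sites, n - 2L * config$n_sites,
                             replace = TRUE))
    site <- factor(sample(site_idx),
                   levels = seq_len(config$n_sites),
                   labels = sprintf("site%02d", seq_len(config$n_sites)))

    covariates <- data.frame(
      age = stats::rnorm(n, mean = 10, sd = 0.6),
      sex = factor(sample(c("F", "M"), n, replace = TRUE)),
      education = factor(sample(c("primary", "secondary", "higher"), n,
                                replace = TRUE, prob = c(0.2, 0.4, 0.4)))
    )
    design <- stats::model.matrix(~ age + sex + education, covariates)[, -1L,
                                                                       drop = FALSE]
    design <- standardize_columns(design)
    theta_x <- matrix(stats::rnorm(ncol(design) * p,
                                   sd = config$covariate_effect_sd),
                      ncol(design), p)
    theta_y <- matrix(stats::rnorm(ncol(design) * q,
                                   sd = config$covariate_effect_sd),
                      ncol(design), q)
    site_shift <- matrix(stats::rnorm(config$n_sites * p,
                                      sd = config$site_effect_sd),
                         config$n_sites, p)

    brain <- xi %*% t(A) +
      design %*% theta_x +
      site_shift[as.integer(site), , drop = FALSE] +
      matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)

    symptom_latent <- eta %*% t(B) +
      design %*% theta_y +
      matrix(stats::rnorm(n * q, sd = config$noise_sd), n, q)
    g <- standardize_columns(symptom_latent)
    symptoms <- count_transform(g)
    colnames(symptoms) <- sprintf("scale%d", seq_len(q))

    cohort <- structure(
      list(
        brain = brain,
        symptoms = symptoms,
        covariates = covariates,
        site = site,
        subject_id = sprintf("S%05d", seq_len(n)),
        truth = list(
          A = A, B = B,
          correlations = rho,
          latent_brain = xi,
          latent_symptom = eta,
          symptom_latent = symptom_latent
        ),
        config = config
      ),
      class = "two_view_cohort"
    )
    validate_two_view_cohort(cohort)
    cohort
  })
}

validate_two_view_cohort <- function(cohort) {
  n <- nrow(cohort$brain)
  stopifnot(
    nrow(cohort$symptoms) == n,
    nrow(cohort$covariates) == n,
    length(cohort$site) == n,
    length(cohort$subject_id) == n,
    !anyDuplicated(cohort$subject_id),
    all(cohort$symptoms >= 0)
  )
  if (any(table(cohort$site) < 2L)) {
    stop("every site must have at least 2 subjects")
  }
  invisible(cohort)
}

#' @export
print.two_view_cohort <- function(x, ...) {
  cat(sprintf(
    "two_view_cohort: %d subjects, %d brain features, %d symptom scales, %d sites\n",
    nrow(x$brain), ncol(x$brain), ncol(x$symptoms), nlevels(x$site)
  ))
  if (!is.null(x$truth)) {
    cat(sprintf("planted components: %d (r = %s)\n",
                length(x$truth$correlations),
                paste(format(x$truth$correlations), collapse = ", ")))
  }
  invisible(x)
}

#' Sign-invariant recovery metrics for estimated loading vectors
#'
#' Compares estimated loading columns against planted ground-truth columns:
#' per-component absolute cosine similarity (invariant to sign flips) and
#' support F1 (harmonic mean of precision and recall of the nonzero
#' pattern).
#'
#' @param truth numeric matrix (or vector) of true loadings, features x d.
#' @param estimate numeric matrix (or vector) of estimated loadings with the
#'   same dimensions.
#' @param zero_tol entries with absolute value at or below this are treated
#'   as structural zeros when computing support overlap.
#' @return data frame with one row per component: `cosine`, `support_f1`,
#'   `n_true_nonzero`, `n_est_nonzero`.
#' @export
recovery_metrics <- function(truth, estimate, zero_tol = 1e-8) {
  truth <- as.matrix(truth)
  estimate <- as.matrix(estimate)
  if (!all(dim(truth) == dim(estimate))) {
    stop("truth and estimate dimensions differ: ",
         paste(dim(truth), collapse = "x"), " vs ",
         paste(dim(estimate), collapse = "x"))
  }
  d <- ncol(truth)
  out <- data.frame(
    component = seq_len(d),
    cosine = NA_real_,
    support_f1 = NA_real_,
    n_true_nonzero = NA_integer_,
    n_est_nonzero = NA_integer_
  )
  for (j in seq_len(d)) {
    out$cosine[j] <- abs(cosine_similarity(truth[, j], estimate[, j]))
    ts <- abs(truth[, j]) > zero_tol
    es <- abs(estimate[, j]) > zero_tol
    tp <- sum(ts & es)
    prec <- if (sum(es) > 0) tp / sum(es) else 0
    rec <- if (sum(ts) > 0) tp / sum(ts) else 0
    out$support_f1[j] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out$n_true_nonzero[j] <- sum(ts)
    out$n_est_nonzero[j] <- sum(es)
  }
  out
}

#' Write a simulated cohort to delimited text tables
#'
#' Writes `brain.tsv`, `symptoms.tsv`, `covariates.tsv` (covariates plus
#' site and subject id) and, when present, a `truth.json` sidecar into a
#' directory, so downstream stages can run from plain files.
#'
#' @param cohort a `two_view_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  validate_two_view_cohort(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mat <- function(m, file) {
    utils::write.table(m, file.path(dir, file), sep = "\t",
                       row.names = FALSE, col.names = TRUE, quote = FALSE)
  }
  brain <- cohort$brain
  colnames(brain) <- sprintf("f%d", seq_len(ncol(brain)))
  write_mat(brain, "brain.tsv")
  write_mat(cohort$symptoms, "symptoms.tsv")
  covs <- cbind(subject_id = cohort$subject_id,
                site = as.character(cohort$site),
                cohort$covariates)
  write_mat(covs, "covariates.tsv")
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(
      list(A = cohort$truth$A, B = cohort$truth$B,
           correlations = cohort$truth$correlations),
      file.path(dir, "truth.json"),
      digits = NA
    )
  }
  invisible(dir)
}

#' Read a cohort previously written with [write_cohort()]
#' @param dir directory containing the delimited tables.
#' @return a `two_view_cohort` (without latent ground-truth scores).
#' @export
read_cohort <- function(dir) {
  brain <- as.matrix(utils::read.table(file.path(dir, "brain.tsv"),
                                       header = TRUE, sep = "\t"))
  symptoms <- as.matrix(utils::read.table(file.path(dir, "symptoms.tsv"),
                                          header = TRUE, sep = "\t"))
  covs <- utils::read.table(file.path(dir, "covariates.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = TRUE)
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    raw <- jsonlite::fromJSON(tf)
    truth <- list(A = as.matrix(raw$A), B = as.matrix(raw$B),
                  correlations = as.numeric(raw$correlations))
  }
  cohort <- structure(
    list(
      brain = unname(brain),
      symptoms = symptoms,
      covariates = covs[, setdiff(names(covs), c("subject_id", "site")),
                        drop = FALSE],
      site = factor(covs$site),
      subject_id = as.character(covs$subject_id),
      truth = truth
    ),
    class = "two_view_cohort"
  )
  validate_two_view_cohort(cohort)
  cohort
}
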