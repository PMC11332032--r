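# Ingest: regional time series -> confound-residualized Fisher-z
# connectivity edges; head-motion QC rules; CBCL-style syndrome scoring
# with the proration rule for missing items.

#' Edge index of the strict upper triangle, row-major
#'
#' Enumerates the region pairs `(i, j)` with `i < j` in row-major order
#' (`(1,2), (1,3), ..., (1,R), (2,3), ...`), the order in which a symmetric
#' R x R connectivity matrix is flattened to its `R*(R-1)/2` edge vector.
#' A 349-region parcellation yields 60,726 edges.
#'
#' @param n_regions number of regions R (>= 2).
#' @return data frame with integer columns `i`, `j`.
#' @export
make_edge_index <- function(n_regions) {
  stopifnot(n_regions >= 2)
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L),
                     function(a) (a + 1L):n_regions))
  data.frame(i = as.integer(i), j = as.integer(j))
}

#' Flatten a symmetric matrix to its strict upper triangle (row-major)
#' @param mat symmetric numeric matrix.
#' @return numeric vector of length `R*(R-1)/2` ordered as
#'   [make_edge_index()].
#' @export
flatten_connectivity <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  # row-major upper triangle of a symmetric matrix == column-major lower
  mat[lower.tri(mat)]
}

#' Rebuild the symmetric matrix from a flattened edge vector
#' @param values edge vector of length `R*(R-1)/2`.
#' @param diag value placed on the diagonal (default 0).
#' @return symmetric R x R matrix.
#' @export
unflatten_connectivity <- function(values, diag = 0) {
  m <- length(values)
  r <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(r - round(r)) > 1e-8) {
    stop("length ", m, " is not R*(R-1)/2 for any integer R")
  }
  r <- as.integer(round(r))
  out <- matrix(diag, r, r)
  out[lower.tri(out)] <- values
  out[upper.tri(out)] <- t(out)[upper.tri(out)]
  out
}

#' Confound-residualized Fisher-z connectivity from regional time series
#'
#' Residualizes each regional BOLD series on the supplied nuisance
#' regressors (ordinary least squares, intercept included), computes all
#' pairwise Pearson correlations between the residual series, applies the
#' Fisher z transform `atanh(r)` (with `|r|` clipped just below 1 to keep
#' edges finite), and flattens the strict upper triangle row-major.
#'
#' @param values T x R numeric matrix of time points x regions.
#' @param confounds optional T x m numeric matrix of nuisance regressors.
#' @param region_labels optional character vector of R region names, used in
#'   error messages.
#' @param clip correlations are clipped to `[-clip, clip]` before `atanh`.
#' @return object of class `connectivity_vector`: list with `values` (length
#'   `R*(R-1)/2`) and `edge_index`.
#' @export
connectivity_from_timeseries <- function(values, confounds = NULL,
                                         region_labels = NULL,
                                         clip = 1 - 1e-7) {
  values <- as.matrix(values)
  n_t <- nrow(values)
  n_r <- ncol(values)
  stopifnot(n_r >= 2)
  if (is.null(region_labels)) {
    region_labels <- colnames(values)
    if (is.null(region_labels)) {
      region_labels <- sprintf("region%d", seq_len(n_r))
    }
  }
  if (anyNA(values)) stop("time series contain missing values")
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (n_t <= ncol(confounds) + 2L) {
      stop("too few time points for the confound model")
    }
    design <- cbind(1, confounds)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      stop("confound matrix is rank-deficient")
    }
    resid <- qr.resid(qrd, values)
  } else {
    resid <- sweep(values, 2L, colMeans(values), "-")
  }
  sds <- apply(resid, 2L, stats::sd)
  if (any(sds < .Machine$double.eps)) {
    bad <- region_labels[which(sds < .Machine$double.eps)]
    stop("constant residual series (zero variance) in region(s): ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(resid)
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  structure(
    list(values = flatten_connectivity(z),
         edge_index = make_edge_index(n_r),
         region_labels = region_labels),
    class = "connectivity_vector"
  )
}

#' Head-motion inclusion mask from framewise-displacement summaries
#'
#' A subject is excluded when mean FD exceeds `mean_fd_thresh` (mm) or when
#' the fraction of volumes with FD above 0.2 mm exceeds `frac_thresh`; both
#' rules use strict inequalities ("higher than"), so a subject exactly at a
#' threshold is retained. Subjects with a missing motion summary are
#' excluded with a warning.
#'
#' @param motion data frame with columns `mean_fd_mm` and `frac_fd_above_02`
#'   (fractions in `[0, 1]`).
#' @param mean_fd_thresh mean-FD exclusion threshold in mm (default 0.25).
#' @param frac_thresh high-motion volume-fraction threshold (default 0.20).
#' @return logical inclusion mask, one entry per row of `motion`.
#' @export
qc_filter <- function(motion, mean_fd_thresh = 0.25, frac_thresh = 0.20) {
  stopifnot(mean_fd_thresh > 0, frac_thresh > 0,
            all(c("mean_fd_mm", "frac_fd_above_02") %in% names(motion)))
  fd <- motion$mean_fd_mm
  fr <- motion$frac_fd_above_02
  if (any(fr > 1 | fr < 0, na.rm = TRUE)) {
    stop("frac_fd_above_02 must lie in [0, 1]")
  }
  keep <- !(fd > mean_fd_thresh | fr > frac_thresh)
  missing <- is.na(keep)
  if (any(missing)) {
    warning(sum(missing), " subject(s) with missing motion summary excluded")
    keep[missing] <- FALSE
  }
  keep
}

#' Prorated CBCL-style syndrome sum scores with missingness rules
#'
#' For each syndrome scale: when the fraction of unanswered items is below
#' 0.25 the score is the mean of the answered items times the number of
#' items in the scale (a prorated sum; equal to the plain sum when nothing
#' is missing), otherwise the scale is flagged unavailable (`NA`). Subjects
#' whose overall item missingness exceeds 0.25 are flagged for exclusion.
#'
#' @param items n x m matrix/data frame of item responses in `{0, 1, 2}` or
#'   `NA` for unanswered.
#' @param scale_map assignment of items to scales: a character/factor vector
#'   of length m naming the scale of each item.
#' @param max_scale_missing per-scale missingness bound (default 0.25;
#'   scales at or above it are unavailable).
#' @param max_overall_missing overall missingness bound above which a
#'   subject is flagged for exclusion (default 0.25, strict).
#' @return list with `scores` (n x n_scales matrix, `NA` where unavailable),
#'   `missing_fraction` (same shape), and `exclude` (logical, per subject).
#' @export
syndrome_scores <- function(items, scale_map,
                            max_scale_missing = 0.25,
                            max_overall_missing = 0.25) {
  items <- as.matrix(items)
  ok <- is.na(items) | items %in% c(0, 1, 2)
  if (!all(ok)) {
    stop("item responses must be 0, 1, 2 or missing; found: ",
         paste(unique(items[!ok]), collapse = ", "))
  }
  if (length(scale_map) != ncol(items)) {
    stop("scale_map must assign every item column to a scale")
  }
  scales <- unique(as.character(scale_map))
  n <- nrow(items)
  scores <- matrix(NA_real_, n, length(scales),
                   dimnames = list(NULL, scales))
  miss <- matrix(NA_real_, n, length(scales),
                 dimnames = list(NULL, scales))
  for (s in scales) {
    cols <- which(as.character(scale_map) == s)
    sub <- items[, cols, drop = FALSE]
    frac_missing <- rowMeans(is.na(sub))
    miss[, s] <- frac_missing
    answered_mean <- rowMeans(sub, na.rm = TRUE)
    prorated <- answered_mean * length(cols)
    prorated[frac_missing >= max_scale_missing] <- NA_real_
    scores[, s] <- prorated
  }
  overall <- rowMeans(is.na(items))
  list(scores = scores,
       missing_fraction = miss,
       exclude = overall > max_overall_missing)
}
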