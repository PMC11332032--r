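# Shared numerical helpers: norms, soft-thresholding with an l1 budget on the
# unit sphere, sign conventions, component assignment, seeded evaluation.

l2norm <- function(x) sqrt(sum(x^2))

unitize <- function(x) {
  nx <- l2norm(x)
  if (nx < .Machine$double.eps) {
    stop("cannot normalize a zero vector")
  }
  x / nx
}

soft_threshold <- function(a, delta) {
  sign(a) * pmax(abs(a) - delta, 0)
}

#' Project a direction onto the unit l2 sphere subject to an l1 budget
#'
#' Returns the unit-l2 vector proportional to a soft-thresholded version of
#' `a` whose l1 norm does not exceed `s` (with `s >= 1`, which is always
#' attainable on the unit sphere). The threshold is found by bisection. This
#' is the inner step of the penalized matrix decomposition update.
#'
#' @param a numeric direction vector (not all zero).
#' @param s l1 budget, `s >= 1`.
#' @param tol relative bisection tolerance on the threshold.
#' @return unit-l2 numeric vector with `sum(abs(.)) <= s + 1e-6`.
#' @keywords internal
#' @noRd
bound_l1_unit <- function(a, s, tol = 1e-10) {
  amax <- max(abs(a))
  if (amax < .Machine$double.eps) {
    stop("all-zero direction: the loading was thresholded away; ",
         "try a larger penalty value (weaker sparsity)")
  }
  u <- a / l2norm(a)
  if (sum(abs(u)) <= s + 1e-12) {
    return(u)
  }
  if (s <= 1 + 1e-12) {
    # the l1 = l2 = 1 vertex: a coordinate vector at the largest entry
    out <- numeric(length(a))
    i <- which.max(abs(a))
    out[i] <- sign(a[i])
    return(out)
  }
  # exact threshold: with k entries active, l1/l2 of the soft-thresholded
  # vector is (c1 - k*delta) / sqrt(c2 - 2*delta*c1 + k*delta^2), a
  # continuous strictly decreasing function of delta; locate the crossing
  # segment on the sorted magnitudes, solve the quadratic there, and polish
  # with two Newton steps
  b <- sort(abs(a), decreasing = TRUE)
  c1 <- cumsum(b)
  c2 <- cumsum(b^2)
  p <- length(b)
  # ratio evaluated at delta = b[j] (active set = first j - 1 entries)
  j_seq <- 2:p
  l1_at <- c1[j_seq - 1L] - (j_seq - 1L) * b[j_seq]
  l2_at <- sqrt(pmax(c2[j_seq - 1L] - 2 * b[j_seq] * c1[j_seq - 1L] +
                       (j_seq - 1L) * b[j_seq]^2, 0))
  ratio_at <- ifelse(l2_at > 0, l1_at / l2_at, 1)
  cross <- which(ratio_at >= s)
  if (length(cross) > 0L) {
    k <- cross[1L] # crossing in [b[k+1], b[k]] with k active entries
    lo_k <- b[k + 1L]
    hi_k <- b[k]
  } else {
    k <- p
    lo_k <- 0
    hi_k <- b[p]
  }
  A <- k * (k - s^2)
  B <- 2 * c1[k] * (k - s^2)
  C <- c1[k]^2 - s^2 * c2[k]
  delta <- NA_real_
  if (abs(A) > .Machine$double.eps) {
    disc <- B^2 - 4 * A * C
    if (disc >= 0) {
      roots <- (B + c(-1, 1) * sqrt(disc)) / (2 * A)
      ok <- roots >= lo_k - 1e-9 & roots <= hi_k + 1e-9
      if (any(ok)) delta <- min(roots[ok])
    }
  } else if (abs(B) > .Machine$double.eps) {
    delta <- C / B
  }
  if (!is.na(delta)) {
    delta <- min(max(delta, lo_k), hi_k)
    for (it in 1:2) { # Newton polish of L1 - s*L2 = 0 on the segment
      l1_d <- c1[k] - k * delta
      l2_d <- sqrt(max(c2[k] - 2 * delta * c1[k] + k * delta^2, 0))
      if (l2_d <= 0) break
      g <- l1_d - s * l2_d
      gp <- -k + s * l1_d / l2_d
      if (abs(gp) < .Machine$double.eps) break
      delta <- min(max(delta - g / gp, lo_k), hi_k)
    }
    su <- soft_threshold(a, delta)
    if (any(su != 0)) {
      out <- unitize(su)
      if (sum(abs(out)) <= s + 1e-6) return(out)
    }
  }
  # numerically degenerate segments: fall back to bisection
  lo <- 0
  hi <- amax
  for (it in seq_len(500L)) {
    mid <- (lo + hi) / 2
    su <- soft_threshold(a, mid)
    if (all(su == 0)) {
      hi <- mid
      next
    }
    if (sum(abs(su / l2norm(su))) > s) lo <- mid else hi <- mid
    if ((hi - lo) < tol * amax) break
  }
  su <- soft_threshold(a, hi)
  if (all(su == 0)) su <- soft_threshold(a, lo)
  unitize(su)
}

#' Fix loading-column signs so the largest-magnitude entry is positive
#' @param m numeric matrix (columns are loading vectors).
#' @return matrix with deterministically signed columns.
#' @keywords internal
#' @noRd
fix_sign <- function(m) {
  for (j in seq_len(ncol(m))) {
    i <- which.max(abs(m[, j]))
    if (m[i, j] < 0) m[, j] <- -m[, j]
  }
  m
}

cosine_similarity <- function(x, y) {
  nx <- l2norm(x)
  ny <- l2norm(y)
  if (nx < .Machine$double.eps || ny < .Machine$double.eps) {
    return(0)
  }
  sum(x * y) / (nx * ny)
}

# all permutations of 1..n as an n!-row matrix (n <= 8 in practice)
all_permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Match two sets of loading columns by maximal total absolute cosine
#'
#' Finds the one-to-one assignment of the columns of `m_new` to the columns
#' of `m_ref` that maximizes the summed absolute cosine similarity, by exact
#' enumeration over permutations (intended for small component counts,
#' `d <= 8`). Used to undo the arbitrary component reordering and sign flips
#' induced by bootstrap resampling or independent refits.
#'
#' @param m_ref reference loading matrix (features x d).
#' @param m_new loading matrix to align (features x d).
#' @return list with `perm` (column `j` of the aligned solution is column
#'   `perm[j]` of `m_new`), `signs` (+1/-1 flips making the matched cosines
#'   non-negative) and `cosines` (the matched absolute cosines).
#' @export
#' @examples
#' ref <- diag(3)
#' new <- ref[, c(2, 3, 1)] * c(1, -1, 1)
#' match_components(ref, new)$perm
match_components <- function(m_ref, m_new) {
  d <- ncol(m_ref)
  if (ncol(m_new) != d || nrow(m_new) != nrow(m_ref)) {
    stop("loading matrices must have identical dimensions")
  }
  cs <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      cs[i, j] <- cosine_similarity(m_ref[, i], m_new[, j])
    }
  }
  perms <- all_permutations(d)
  totals <- apply(perms, 1L, function(p) sum(abs(cs[cbind(seq_len(d), p)])))
  p <- perms[which.max(totals), ]
  matched <- cs[cbind(seq_len(d), p)]
  signs <- ifelse(matched < 0, -1, 1)
  list(perm = as.integer(p), signs = signs, cosines = abs(matched))
}

#' Evaluate an expression under a fixed RNG seed, restoring the RNG state
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic sub-stream seeds below 2^31, so nested stages are
# reproducible independently of how much randomness other stages consume
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 2039 + 100003 * (offset %% 1000) + 7)
}

standardize_columns <- function(m, center = TRUE, scale = TRUE) {
  m <- as.matrix(m)
  if (center) m <- sweep(m, 2L, colMeans(m), "-")
  if (scale) {
    sds <- sqrt(colSums(m^2) / max(1, nrow(m) - 1))
    sds[sds < .Machine$double.eps] <- 1 # constant columns pass through as zero
    m <- sweep(m, 2L, sds, "/")
  }
  m
}
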