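# Aitchison-geometry core for 4-part time-use compositions.
#
# A composition here is a strictly positive vector (or matrix with one row per
# sample) whose parts carry only relative information; daily time-use
# compositions are closed to 1440 min. All log-ratio machinery below works for
# any number of parts D >= 2, although the pipeline uses D = 4
# (MVPA, LIPA, SB, SPT).

#' Canonical part names of the daily movement-behaviour composition
#' @export
MVB_PARTS <- c("mvpa", "lipa", "sb", "spt")

as_comp_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  storage.mode(x) <- "double"
  x
}

#' Close a composition to a fixed total
#'
#' Rescales each composition so its parts sum to `total`. Closure is the
#' fundamental operation of compositional data analysis: it discards absolute
#' size and keeps only relative information. The operation is idempotent.
#'
#' @param x numeric vector (one composition) or matrix/data.frame (one row per
#'   composition), strictly positive in strict mode.
#' @param total target sum, default 1440 (minutes in a day).
#' @param zero_policy `"strict"` (default) errors on non-positive parts;
#'   `"replace"` substitutes `zero_floor` for non-positive parts before closure
#'   and reports the number of replacements via a message.
#' @param zero_floor replacement value used when `zero_policy = "replace"`,
#'   default 1 (min/day).
#' @return matrix (or vector, matching the input shape) with rows summing to
#'   `total`.
#' @export
close_composition <- function(x, total = 1440, zero_policy = c("strict", "replace"),
                              zero_floor = 1) {
  zero_policy <- match.arg(zero_policy)
  vec_in <- is.null(dim(x)) && !is.data.frame(x)
  m <- as_comp_matrix(x)
  if (!all(is.finite(m))) stop("composition parts must be finite")
  bad <- m <= 0
  if (any(bad)) {
    if (zero_policy == "strict") {
      stop("non-positive parts in composition (use zero_policy = 'replace' to floor them)")
    }
    m[bad] <- zero_floor
    message(sum(bad), " non-positive part(s) replaced by floor ", zero_floor)
  }
  out <- m / rowSums(m) * total
  if (vec_in) out[1, ] else out
}

#' Compositional geometric mean
#'
#' Component-wise geometric mean across samples, re-closed to `total`. This is
#' the centre of a compositional sample in Aitchison geometry and equals the
#' back-transform of the mean ILR coordinate vector.
#'
#' @param x matrix/data.frame of strictly positive compositions, one per row.
#' @param total closure total for the result (default 1440).
#' @return numeric vector, one geometric-mean part per column, summing to
#'   `total`.
#' @export
geometric_mean_composition <- function(x, total = 1440) {
  m <- as_comp_matrix(x)
  if (nrow(m) < 1) stop("need at least one composition")
  if (any(m <= 0)) stop("compositions must be strictly positive")
  g <- exp(colMeans(log(m)))
  close_composition(g, total = total)
}

#' Variation matrix of a compositional sample
#'
#' Entry (i, j) is the sample variance of `log(x_i / x_j)` across rows. Small
#' entries indicate strongly co-dependent (nearly proportional) parts. The
#' matrix is symmetric with a zero diagonal and is equivariant under part
#' reordering.
#'
#' @param x matrix/data.frame of strictly positive compositions, one per row
#'   (at least 2 rows).
#' @return D x D symmetric matrix.
#' @export
variation_matrix <- function(x) {
  m <- as_comp_matrix(x)
  if (nrow(m) < 2) stop("variation matrix needs at least 2 compositions")
  if (any(m <= 0)) stop("compositions must be strictly positive")
  lm_ <- log(m)
  D <- ncol(lm_)
  v <- matrix(0, D, D, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(D - 1)) {
    for (j in (i + 1):D) {
      v[i, j] <- v[j, i] <- stats::var(lm_[, i] - lm_[, j])
    }
  }
  v
}

#' Build an orthonormal ILR contrast from a sequential binary partition
#'
#' A sequential binary partition (SBP) recursively splits the D parts into a
#' `+1` group and a `-1` group (0 = not involved), one row per split, yielding
#' D-1 balances. Each sign row maps to an orthonormal contrast row with
#' coefficient `+sqrt(s / (r (r + s)))` on the r plus-parts and
#' `-sqrt(r / (s (r + s)))` on the s minus-parts.
#'
#' @param signs (D-1) x D matrix of entries in {-1, 0, +1} encoding a valid SBP.
#' @return (D-1) x D orthonormal contrast matrix (rows are the ILR basis;
#'   row sums are 0).
#' @export
make_sbp_contrast <- function(signs) {
  signs <- as.matrix(signs)
  D <- ncol(signs)
  if (nrow(signs) != D - 1) stop("an SBP for D parts must have D-1 rows")
  if (!all(signs %in% c(-1, 0, 1))) stop("SBP entries must be -1, 0 or +1")
  V <- matrix(0, D - 1, D, dimnames = dimnames(signs))
  for (k in seq_len(D - 1)) {
    r <- sum(signs[k, ] == 1)
    s <- sum(signs[k, ] == -1)
    if (r == 0 || s == 0) stop("each SBP row needs both a +1 group and a -1 group")
    V[k, signs[k, ] == 1] <- sqrt(s / (r * (r + s)))
    V[k, signs[k, ] == -1] <- -sqrt(r / (s * (r + s)))
  }
  if (max(abs(V %*% t(V) - diag(D - 1))) > 1e-8) {
    stop("sign matrix is not a valid sequential binary partition (rows not orthonormal)")
  }
  V
}

#' Pivot-coordinate contrast matrix
#'
#' The pivot SBP places one part first and contrasts it against the geometric
#' mean of all remaining parts; subsequent rows pivot within the remainder.
#' The first coordinate then isolates the chosen behaviour's contribution
#' relative to the rest of the day, which is what the per-behaviour tests use.
#'
#' @param parts character vector giving the part order; the first element is
#'   the pivot. Defaults to `MVB_PARTS`.
#' @param all_parts the full set of part names, used to order the columns of
#'   the returned matrix so data columns need not be permuted. Defaults to
#'   `parts` itself.
#' @return (D-1) x D orthonormal contrast matrix with columns named by
#'   `all_parts`.
#' @export
pivot_contrast <- function(parts = MVB_PARTS, all_parts = parts) {
  D <- length(parts)
  if (!setequal(parts, all_parts) || length(all_parts) != D) {
    stop("`parts` must be a permutation of `all_parts`")
  }
  signs <- matrix(0, D - 1, D, dimnames = list(paste0("z", seq_len(D - 1)), parts))
  for (k in seq_len(D - 1)) {
    signs[k, k] <- 1
    signs[k, (k + 1):D] <- -1
  }
  V <- make_sbp_contrast(signs)
  V[, all_parts, drop = FALSE]
}

#' Isometric log-ratio transform
#'
#' Maps strictly positive compositions to D-1 unconstrained real coordinates,
#' `z = V log(x)`. Scale-invariant: closure of the input does not change the
#' result.
#'
#' @param x composition vector or matrix (rows = samples); columns must match
#'   the contrast's columns (by name when both are named).
#' @param contrast (D-1) x D orthonormal contrast matrix, e.g. from
#'   [pivot_contrast()] or [make_sbp_contrast()].
#' @return matrix of ILR coordinates (rows = samples, columns z1..z(D-1)), or a
#'   vector if the input was a vector.
#' @export
ilr_transform <- function(x, contrast = pivot_contrast()) {
  vec_in <- is.null(dim(x)) && !is.data.frame(x)
  m <- as_comp_matrix(x)
  if (any(m <= 0)) stop("ILR requires strictly positive parts")
  if (!is.null(colnames(m)) && !is.null(colnames(contrast))) {
    m <- m[, colnames(contrast), drop = FALSE]
  }
  z <- log(m) %*% t(contrast)
  colnames(z) <- rownames(contrast) %||% paste0("z", seq_len(ncol(z)))
  if (vec_in) z[1, ] else z
}

#' Inverse isometric log-ratio transform
#'
#' Back-transforms ILR coordinates to a composition closed to `total`:
#' `x = C(exp(t(V) z))`.
#'
#' @param z coordinate vector or matrix (rows = samples).
#' @param contrast the contrast matrix used in the forward transform.
#' @param total closure total (default 1440).
#' @return composition matrix (or vector for vector input).
#' @export
ilr_inverse <- function(z, contrast = pivot_contrast(), total = 1440) {
  vec_in <- is.null(dim(z)) && !is.data.frame(z)
  zm <- as_comp_matrix(z)
  if (!all(is.finite(zm))) stop("ILR coordinates must be finite")
  x <- exp(zm %*% contrast)
  colnames(x) <- colnames(contrast)
  out <- close_composition(x, total = total)
  if (vec_in) out[1, ] else out
}

#' Compositional perturbation
#'
#' The Aitchison-group operation: component-wise product followed by closure.
#' `ilr(perturb(x, p)) = ilr(x) + ilr(p)`.
#'
#' @param x,p compositions (vector or matrix; recycled row-wise).
#' @param total closure total.
#' @export
perturb_composition <- function(x, p, total = 1440) {
  xm <- as_comp_matrix(x)
  pm <- as_comp_matrix(p)
  close_composition(sweep(xm, 2, pm[1, ], `*`), total = total) ->
    out
  if (is.null(dim(x)) && !is.data.frame(x)) out[1, ] else out
}

#' Aitchison distance between compositions
#'
#' Euclidean distance between ILR coordinate vectors; invariant to the SBP
#' used to build the coordinates.
#'
#' @param x,y compositions (vectors).
#' @export
aitchison_distance <- function(x, y) {
  V <- pivot_contrast(paste0("p", seq_along(x)))
  sqrt(sum((ilr_transform(unname(x), V) - ilr_transform(unname(y), V))^2))
}

#' Mahalanobis-distance outlier screen on ILR coordinates
#'
#' Flags compositional outliers by squared Mahalanobis distance of the ILR
#' coordinates against a chi-square quantile with D-1 degrees of freedom.
#' Robust location/scatter (MCD via [MASS::cov.rob()]) is the default, so that
#' the outliers themselves do not mask the estimate; classical moment
#' estimates are available by flag.
#'
#' @param z matrix of ILR coordinates (rows = samples) or of compositions
#'   (detected by strictly positive entries with > D-1 columns is NOT
#'   attempted; pass coordinates).
#' @param quantile chi-square probability for the cutoff (default 0.975).
#' @param robust use MCD estimates (default TRUE); FALSE uses classical
#'   mean/covariance.
#' @return list with `distance2` (squared distances), `cutoff`, and `outlier`
#'   (logical flags).
#' @export
mahalanobis_outliers <- function(z, quantile = 0.975, robust = TRUE) {
  z <- as_comp_matrix(z)
  n <- nrow(z)
  d <- ncol(z)
  if (n <= d) stop("need more observations than coordinate dimensions")
  if (robust) {
    est <- MASS::cov.rob(z, method = "mcd")
    centre <- est$center
    scatter <- est$cov
  } else {
    centre <- colMeans(z)
    scatter <- stats::cov(z)
  }
  if (rcond_safe(scatter) < 1e-12) stop("singular scatter matrix")
  d2 <- stats::mahalanobis(z, centre, scatter)
  cutoff <- stats::qchisq(quantile, df = d)
  list(distance2 = d2, cutoff = cutoff, outlier = d2 > cutoff)
}

rcond_safe <- function(m) {
  tryCatch(1 / kappa(m, exact = TRUE), error = function(e) 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
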