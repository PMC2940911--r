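# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a master seed and a round counter, kept within
# 32-bit integer range so set.seed() accepts it on all platforms.
derive_seed <- function(master, counter) {
  (as.double(master) * 1000003 + counter * 7919) %% 2147483647
}

#' Random orthonormal basis
#'
#' Orthonormalizes k i.i.d. standard-normal n-vectors (QR decomposition),
#' giving a basis whose span is uniform on the Grassmannian. Used to
#' initialize the module-fitting iteration.
#'
#' @param n ambient dimension (number of samples).
#' @param k subspace dimension, 1 <= k < n.
#' @param seed optional integer; the result is deterministic given the seed
#'   and the caller's RNG state is left untouched.
#' @return n x k matrix with orthonormal columns.
#' @export
init_basis <- function(n, k, seed = NULL) {
  if (k >= n || k < 1) stop("need 1 <= k < n")
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * k), n, k)
    q <- qr.Q(qr(z))[, seq_len(k), drop = FALSE]
    # QR fixes column signs systematically; random signs restore uniformity
    q * rep(sample(c(-1, 1), k, replace = TRUE), each = n)
  })
}

# Gram-Schmidt a set of new columns against an existing orthonormal basis,
# dropping components already in span(basis) and renormalizing. Returns NULL
# if the candidate lies (numerically) inside the span.
orthogonalize_against <- function(v, basis) {
  v <- v - basis %*% crossprod(basis, v)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) return(NULL)
  v / nv
}

#' One weighted-SVD update of the module basis
#'
#' Rescales each row g_i by its weight w_i and takes the first k right
#' singular vectors of the weighted matrix. This maximizes the objective
#' sum_i (w_i l_i)^2 over orthonormal bases of dimension k, because the
#' objective equals the sum of squared projections of the weighted rows onto
#' the subspace. The sign of each singular vector is fixed so that the entry
#' of largest absolute value in its loading vector (weighted matrix times the
#' vector) is positive, for cross-platform reproducibility.
#'
#' @param x matrix (p x n), rows typically unit norm.
#' @param w weights, length p.
#' @param k number of singular vectors to retain.
#' @return n x k orthonormal basis.
#' @export
weighted_svd_step <- function(x, w, k) {
  x <- as.matrix(x)
  if (length(w) != nrow(x)) stop("need one weight per row")
  gs <- x * w
  sv <- svd(gs, nu = 0, nv = min(dim(gs)))
  rank <- sum(sv$d > max(dim(gs)) * .Machine$double.eps * sv$d[1])
  if (rank < k)
    stop("weighted matrix has rank ", rank, ", cannot extract ", k,
         " singular vectors")
  v <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention
  for (j in seq_len(k)) {
    load_j <- gs %*% v[, j]
    if (load_j[which.max(abs(load_j))] < 0) v[, j] <- -v[, j]
  }
  v
}

#' Subspace change between two orthonormal bases
#'
#' Regresses every column of the new basis on all columns of the old basis
#' and returns k minus the summed squared multiple correlations. The value is
#' 0 exactly when the two bases span the same subspace (rotations within the
#' span do not count as change) and k when the new basis is orthogonal to the
#' old span. Used as the convergence measure of the fitting iteration.
#'
#' @param new,old n x k matrices with orthonormal columns.
#' @return non-negative scalar.
#' @export
subspace_change <- function(new, old) {
  if (!all(dim(new) == dim(old))) stop("bases must have identical dimensions")
  # columns are unit norm, old is orthonormal: R^2_j = || old' new_j ||^2
  k <- ncol(new)
  k - sum(crossprod(old, new)^2)
}
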