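#' Projection lengths of rows onto a subspace
#'
#' For unit-norm rows g_i and an orthonormal basis B = (b_1, ..., b_k) of a
#' k-dimensional subspace of condition space, the projection length
#' l_i = sqrt(sum_j (g_i . b_j)^2) measures how well the subspace explains
#' row i: l_i^2 is the fraction of the row's variation explained.
#'
#' @param x standardized matrix (p x n), rows unit norm (row norms <= 1 are
#'   accepted for residual matrices).
#' @param basis n x k matrix with orthonormal columns.
#' @return numeric vector of length p, clipped to \[0, 1\].
#' @export
projection_lengths <- function(x, basis) {
  x <- as.matrix(x)
  basis <- as.matrix(basis)
  if (ncol(x) != nrow(basis))
    stop("dimension mismatch: matrix has ", ncol(x), " columns, basis has ",
         nrow(basis), " rows")
  l <- sqrt(rowSums((x %*% basis)^2))
  pmin(pmax(l, 0), 1)
}

#' F statistic for a projection length
#'
#' Under the null that a unit-norm row with n effectively free coordinates is
#' independent of a fixed k-dimensional subspace, the statistic
#' F = (l^2 / k) * ((n - k - 1) / (1 - l^2)) follows an F distribution with
#' (k, n - k - 1) degrees of freedom, by the theory of linear least squares.
#'
#' @param l projection length(s) in \[0, 1).
#' @param k subspace dimension.
#' @param n number of samples (columns).
#' @return F value(s).
#' @export
f_statistic <- function(l, k, n) {
  if (n - k - 1 < 1) stop("need n - k - 1 >= 1")
  if (any(l < 0) || any(l >= 1)) stop("projection length must lie in [0, 1)")
  (l^2 / k) * ((n - k - 1) / (1 - l^2))
}

#' Projection-length cutoff from an F quantile
#'
#' Inverts [f_statistic()]: returns the projection length delta whose F
#' statistic equals the 1 - alpha quantile of F(k, n - k - 1). Rows of a
#' matrix unrelated to the subspace exceed delta with probability alpha, so
#' delta serves as the inflection point of the sigmoid weight function.
#'
#' @param k subspace dimension.
#' @param n sample count.
#' @param alpha upper-tail probability, in (0, 1). A stringent level
#'   (default 0.001) accounts for the large number of rows tested.
#' @return delta in (0, 1).
#' @export
delta_cutoff <- function(k, n, alpha = 0.001) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n - k - 1 < 1) stop("need n - k - 1 >= 1")
  fq <- stats::qf(1 - alpha, k, n - k - 1)
  sqrt(k * fq / ((n - k - 1) + k * fq))
}

#' Weight function configuration
#'
#' The weight of a row encodes the current belief that it belongs to the
#' module, as a function of its projection length. The sigmoid weight
#' w = 1 - 1 / (1 + exp(phi * (l - delta))) approaches a step function at the
#' null cutoff delta for large steepness phi; the linear weight w = l lets
#' every row contribute in proportion to its projection.
#'
#' @param kind `"sigmoid"` or `"linear"`.
#' @param phi sigmoid steepness (> 0); large values (e.g. 50) give strong
#'   contrast between member and non-member rows.
#' @param alpha upper-tail level used to place the inflection point delta via
#'   [delta_cutoff()].
#' @return object of class `"weight_config"`.
#' @export
weight_config <- function(kind = c("sigmoid", "linear"), phi = 50, alpha = 0.001) {
  kind <- match.arg(kind)
  if (kind == "sigmoid") {
    if (phi <= 0) stop("phi must be > 0")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  }
  structure(list(kind = kind, phi = phi, alpha = alpha),
            class = "weight_config")
}

#' Row weights from projection lengths
#'
#' @param l projection lengths in \[0, 1\].
#' @param config a [weight_config()].
#' @param delta inflection point for the sigmoid weight (required when
#'   `config$kind == "sigmoid"`); typically from [delta_cutoff()].
#' @param phi optional override of the sigmoid steepness (used by the
#'   annealing schedule during fitting).
#' @return weights in \[0, 1\], same length as `l`.
#' @export
weight_values <- function(l, config, delta = NULL, phi = NULL) {
  stopifnot(inherits(config, "weight_config"))
  if (config$kind == "linear") return(l)
  if (is.null(delta)) stop("sigmoid weight requires delta")
  if (is.null(phi)) phi <- config$phi
  1 - 1 / (1 + exp(phi * (l - delta)))
}

#' Objective value of a weighted subspace fit
#'
#' The module basis maximizes the sum of squared weighted projection lengths,
#' sum_i (w_i l_i)^2, over orthonormal bases of the chosen dimension.
#'
#' @param w weights.
#' @param l projection lengths (same length).
#' @return scalar objective value.
#' @export
objective_value <- function(w, l) {
  if (length(w) != length(l)) stop("weights and lengths must have equal length")
  sum((w * l)^2)
}
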