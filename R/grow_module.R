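#' Configuration for forward selection of module dimension
#'
#' @param overlap_alpha significance level for the adjusted hypergeometric
#'   overlap test that decides whether a candidate factor joins the module.
#' @param global_fraction if the first factor's members exceed this fraction
#'   of all rows it is declared a global factor rather than a module
#'   (default 0.5).
#' @param max_k hard cap on module dimension, a guardrail against runaway
#'   growth.
#' @param min_factor_genes minimum number of rows that must be associated
#'   with a candidate factor for it to be considered at all (default 10).
#'   A direction fitted on member residuals can overfit a handful of the
#'   very rows it was fitted on; those few rows then overlap the member set
#'   "significantly" even though the direction carries no structure. A
#'   factor supported by fewer rows than a minimal module is treated as no
#'   evidence, mirroring the module-size stopping rule of discovery.
#' @return object of class `"growth_config"`.
#' @export
growth_config <- function(overlap_alpha = 0.01, global_fraction = 0.5,
                          max_k = 10, min_factor_genes = 10) {
  stopifnot(overlap_alpha > 0, overlap_alpha < 1,
            global_fraction > 0, global_fraction <= 1, max_k >= 1,
            min_factor_genes >= 1)
  structure(list(overlap_alpha = overlap_alpha,
                 global_fraction = global_fraction, max_k = max_k,
                 min_factor_genes = min_factor_genes),
            class = "growth_config")
}

#' Normalized residuals of member rows against a module basis
#'
#' Subtracts from each member row its projection onto the module subspace and
#' rescales by 1 / sqrt(1 - eta^2), restoring the residual norms to \[0, 1\]:
#' a row exactly at the membership cutoff eta gets a unit-norm residual. The
#' rescaling reflects that no prior assumption is made about the relative
#' strength of the factors not yet found.
#'
#' @param member_rows matrix of member rows (each with projection length >=
#'   eta under `basis`).
#' @param basis n x k orthonormal basis.
#' @param eta membership cutoff in \[0, 1).
#' @return residual matrix, same shape as `member_rows`, rows orthogonal to
#'   every basis column.
#' @export
residual_normalize <- function(member_rows, basis, eta) {
  if (eta >= 1) stop("eta must be < 1")
  member_rows <- as.matrix(member_rows)
  res <- member_rows - (member_rows %*% basis) %*% t(basis)
  res / sqrt(1 - eta^2)
}

#' Hypergeometric overlap test adjusted for FDR-contaminated sets
#'
#' Tests whether two row sets (members of the current basis and rows
#' associated with a candidate factor) overlap more than chance. Because both
#' sets were called at FDR level lambda, the counts are deflated before the
#' test: m1' = ceiling(m1 (1-lambda)), m2' = ceiling(m2 (1-lambda)),
#' r' = floor(r (1-lambda)^2), and the upper-tail hypergeometric probability
#' P(overlap >= r') is returned. With lambda = 0 this is the textbook
#' hypergeometric upper tail.
#'
#' @param m1 size of the first set.
#' @param m2 size of the second set.
#' @param r observed overlap (r <= min(m1, m2)).
#' @param p total number of rows.
#' @param lam FDR level lambda at which the sets were called.
#' @return p-value.
#' @export
adjusted_hypergeometric_test <- function(m1, m2, r, p, lam = 0) {
  stopifnot(r <= min(m1, m2), m1 <= p, m2 <= p, lam >= 0, lam < 1)
  m1a <- ceiling(m1 * (1 - lam))
  m2a <- ceiling(m2 * (1 - lam))
  ra <- floor(r * (1 - lam)^2)
  if (ra > min(m1a, m2a)) {
    warning("adjusted overlap exceeds adjusted set sizes; no valid evidence")
    return(1)
  }
  if (ra <= 0) return(1)
  stats::phyper(ra - 1, m1a, p - m1a, m2a, lower.tail = FALSE)
}

#' Find a module of unknown dimension by forward selection
#'
#' Starts from a one-dimensional fit. If that factor is associated with more
#' than `global_fraction` of all rows it is returned as a global factor.
#' Otherwise the dimension grows one factor at a time: member rows are
#' residualized against the current basis and range-restored, a new
#' one-dimensional direction is fitted on the residuals, the rows associated
#' with it (over the full matrix) are compared with the current member set by
#' the adjusted hypergeometric test, and the direction is appended (after
#' re-orthonormalization against the basis) only when the overlap is
#' significant. The final basis is obliquely rotated on the member loadings.
#'
#' @param x standardized matrix.
#' @param config a [fit_config()] (its `k` is ignored; growth starts at 1).
#' @param growth a [growth_config()].
#' @param seed integer seed governing all random restarts in this search.
#' @return a `"module_fit"` (with `$overlap_pvalues` recording the accepted
#'   factors' tests) or a `"global_factor"` object with the factor scores and
#'   associated rows.
#' @export
grow_module <- function(x, config = fit_config(), growth = growth_config(),
                        seed = NULL) {
  x <- assert_expression(x)
  p <- nrow(x); n <- ncol(x)
  lam <- config$fdr_threshold
  cfg1 <- config; cfg1$k <- 1L
  cfg1$seed <- if (is.null(seed)) NULL else derive_seed(seed, 0)

  fit1 <- fit_module(x, cfg1)
  if (length(fit1$members) / p > growth$global_fraction) {
    return(structure(list(factor = as.vector(fit1$basis),
                          basis = fit1$basis, lengths = fit1$lengths,
                          eta = fit1$eta, members = fit1$members,
                          fdr_at_eta = fit1$fdr_at_eta, n = n,
                          row_ids = rownames(x), col_ids = colnames(x)),
                     class = "global_factor"))
  }

  B <- fit1$basis
  pvals <- numeric(0)
  round_i <- 0L
  eta <- fit1$eta
  repeat {
    k <- ncol(B)
    l <- projection_lengths(x, B)
    mem <- membership_fdr(l, k, n, lam)
    eta <- mem$eta
    if (!is.finite(eta) || length(mem$members) < max(3L, k) ||
        k >= growth$max_k || n - (k + 1) - 1 < 1) break
    res <- residual_normalize(x[mem$members, , drop = FALSE], B,
                              min(eta, 1 - 1e-8))
    round_i <- round_i + 1L
    cfg1$seed <- if (is.null(seed)) NULL else derive_seed(seed, round_i)
    cand <- tryCatch(fit_module(res, cfg1, unit_rows = FALSE),
                     error = function(e) NULL)
    if (is.null(cand)) break
    b2 <- orthogonalize_against(cand$basis[, 1], B)
    if (is.null(b2)) break
    assoc <- membership_fdr(projection_lengths(x, b2), 1L, n, lam)
    if (length(assoc$members) < growth$min_factor_genes) break
    r <- length(intersect(mem$members, assoc$members))
    pv <- adjusted_hypergeometric_test(length(mem$members),
                                       length(assoc$members), r, p, lam)
    if (pv >= growth$overlap_alpha) break
    B <- cbind(B, b2)
    pvals <- c(pvals, pv)
  }

  k <- ncol(B)
  l <- projection_lengths(x, B)
  mem <- membership_fdr(l, k, n, lam)
  if (k > 1 && length(mem$members) >= k) {
    A <- x[mem$members, , drop = FALSE] %*% B
    rot <- oblique_rotate(B, A)
  } else {
    rot <- list(factors = t(B), rotation = diag(k), rotated = FALSE)
  }
  structure(list(basis = B, factors = rot$factors, rotation = rot$rotation,
                 rotated = rot$rotated, lengths = l, eta = mem$eta,
                 members = mem$members, fdr_at_eta = mem$fdr_at_eta,
                 fdr_curve = mem$curve, k = k, n = n,
                 row_ids = rownames(x), col_ids = colnames(x),
                 n_iter = NA_integer_, converged = TRUE,
                 objective_trace = fit1$objective_trace,
                 overlap_pvalues = pvals, config = config),
            class = "module_fit")
}
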