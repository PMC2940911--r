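#' Configuration for fitting a single module
#'
#' @param k subspace dimension to fit.
#' @param weight a [weight_config()].
#' @param fdr_threshold conservative FDR level for module membership
#'   (default 0.01).
#' @param tol convergence threshold on the subspace change (k minus summed
#'   R-squared between consecutive bases).
#' @param max_iter iteration cap.
#' @param seed optional integer seed controlling the random initial basis.
#' @param anneal_start_frac,anneal_rate sigmoid steepness schedule: the
#'   effective phi starts at `anneal_start_frac * phi` and is multiplied by
#'   `anneal_rate` each iteration until it reaches phi. Starting soft widens
#'   the search space before the weight hardens into a near step function.
#' @param n_starts number of random restarts; the fit with the most members
#'   (ties broken by objective value) is kept.
#' @return object of class `"fit_config"`.
#' @export
fit_config <- function(k = 1, weight = weight_config(), fdr_threshold = 0.01,
                       tol = 1e-6, max_iter = 200, seed = NULL,
                       anneal_start_frac = 0.1, anneal_rate = 1.25,
                       n_starts = 1) {
  stopifnot(tol > 0, max_iter >= 1, n_starts >= 1)
  structure(list(k = k, weight = weight, fdr_threshold = fdr_threshold,
                 tol = tol, max_iter = max_iter, seed = seed,
                 anneal_start_frac = anneal_start_frac,
                 anneal_rate = anneal_rate, n_starts = n_starts),
            class = "fit_config")
}

#' Module membership by a conservative FDR rule on projection lengths
#'
#' For every observed projection length l*, the false discovery rate of the
#' rule "assign all rows with l >= l*" is bounded by
#' FDR(l*) = p * P(F(k, n-k-1) >= F*) / #\{i : l_i >= l*\},
#' where F* is the F statistic of l*. The bound is conservative because the
#' total row count p stands in for the unknown number of null rows. The
#' membership cutoff eta is the smallest observed l* whose bound falls below
#' `fdr_threshold`; every row with l >= eta is assigned to the module.
#'
#' @param l projection lengths of all p rows.
#' @param k subspace dimension.
#' @param n sample count.
#' @param fdr_threshold FDR level.
#' @return list with `eta` (cutoff, `Inf` if no length qualifies), `members`
#'   (integer indices), `fdr_at_eta`, and `curve` (data frame of observed
#'   lengths, counts and FDR bounds).
#' @export
membership_fdr <- function(l, k, n, fdr_threshold = 0.01) {
  p <- length(l)
  lv <- sort(unique(l), decreasing = TRUE)
  cnt <- vapply(lv, function(z) sum(l >= z), integer(1))
  fsafe <- f_statistic(pmin(lv, 1 - 1e-12), k, n)
  fdr <- pmin(p * stats::pf(fsafe, k, n - k - 1, lower.tail = FALSE) / cnt, 1)
  ok <- which(fdr < fdr_threshold)
  if (!length(ok)) {
    return(list(eta = Inf, members = integer(0), fdr_at_eta = NA_real_,
                curve = data.frame(length = lv, count = cnt, fdr = fdr)))
  }
  eta <- min(lv[ok])
  list(eta = eta,
       members = which(l >= eta),
       fdr_at_eta = fdr[which(lv == eta)],
       curve = data.frame(length = lv, count = cnt, fdr = fdr))
}

#' Oblique rotation of a fitted basis toward simple structure
#'
#' Rotates the basis within its span using promax (power 4 by default)
#' computed from the member-row loading matrix, so that each member row tends
#' to load on few factors. The rotated factors may be correlated
#' (non-orthogonal); each rotated factor score vector is rescaled to unit
#' norm, with the scale absorbed into subsequent loading regressions.
#'
#' @param basis n x k orthonormal basis, k >= 2.
#' @param member_loadings m x k matrix of member-row loadings (g_i . b_j).
#' @param method `"promax"` (default) or `"oblimin"`-style quartimin via
#'   promax with power 2.
#' @return list with `factors` (k x n rotated factor scores, unit-norm rows),
#'   `rotation` (k x k transform applied to loadings), `rotated` (logical).
#' @export
oblique_rotate <- function(basis, member_loadings, method = c("promax", "oblimin")) {
  method <- match.arg(method)
  k <- ncol(basis)
  if (k < 2) stop("oblique rotation requires k >= 2")
  if (is.null(member_loadings) || nrow(member_loadings) < k) {
    warning("fewer member rows than factors; skipping rotation")
    return(list(factors = t(basis), rotation = diag(k), rotated = FALSE))
  }
  pw <- if (method == "promax") 4 else 2
  rot <- tryCatch(stats::promax(member_loadings, m = pw)$rotmat,
                  error = function(e) NULL)
  if (is.null(rot) || !all(is.finite(rot))) {
    warning("rotation failed; returning unrotated basis")
    return(list(factors = t(basis), rotation = diag(k), rotated = FALSE))
  }
  # loadings transform as A %*% rot, so factor scores transform as
  # solve(rot) %*% t(B); rescale score rows to unit norm
  f <- solve(rot) %*% t(basis)
  f <- f / sqrt(rowSums(f^2))
  list(factors = f, rotation = rot, rotated = TRUE)
}

#' Fit a single module of fixed dimension
#'
#' EM-like alternation for estimating a k-dimensional subspace that explains
#' a subset of rows very well, treating module membership as the latent
#' variable. Each iteration computes projection lengths on the current basis,
#' converts them to membership weights, rescales each row by its weight, and
#' replaces the basis with the top k right singular vectors of the weighted
#' matrix. With the linear weight the objective sum_i (w_i l_i)^2 is provably
#' non-decreasing across iterations; with the sigmoid weight the steepness is
#' annealed upward from a soft start. After convergence, membership is
#' decided by [membership_fdr()] and, for k > 1, the basis is obliquely
#' rotated toward simple structure on the member loadings.
#'
#' @param x standardized matrix (rows unit norm; rows of norm <= 1 accepted
#'   when `unit_rows = FALSE`, as for residual matrices).
#' @param config a [fit_config()].
#' @param unit_rows require exactly unit-norm rows (default TRUE).
#' @return object of class `"module_fit"`: basis (n x k, pre-rotation),
#'   factors (k x n rotated scores), rotation, lengths, eta, members,
#'   fdr_at_eta, n_iter, converged, objective_trace.
#' @export
fit_module <- function(x, config = fit_config(), unit_rows = TRUE) {
  x <- assert_expression(x, unit = unit_rows)
  best <- NULL
  for (s in seq_len(config$n_starts)) {
    seed_s <- if (is.null(config$seed)) NULL else derive_seed(config$seed, s - 1)
    fit <- fit_module_once(x, config, seed_s)
    if (is.null(best) ||
        length(fit$members) > length(best$members) ||
        (length(fit$members) == length(best$members) &&
         utils::tail(fit$objective_trace, 1) > utils::tail(best$objective_trace, 1)))
      best <- fit
  }
  best
}

fit_module_once <- function(x, config, seed) {
  k <- config$k
  n <- ncol(x)
  wcfg <- config$weight
  sig <- wcfg$kind == "sigmoid"
  delta <- if (sig) delta_cutoff(k, n, wcfg$alpha) else NULL
  phi_t <- if (sig) max(config$anneal_start_frac * wcfg$phi, 1e-3) else NULL

  B <- init_basis(n, k, seed)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    l <- projection_lengths(x, B)
    w <- weight_values(l, wcfg, delta = delta, phi = phi_t)
    trace[iter] <- objective_value(w, l)
    B_new <- weighted_svd_step(x, w, k)
    change <- subspace_change(B_new, B)
    B <- B_new
    phi_done <- !sig || phi_t >= wcfg$phi
    if (change < config$tol && phi_done) { converged <- TRUE; break }
    if (iter >= config$max_iter) break
    if (sig) phi_t <- min(phi_t * config$anneal_rate, wcfg$phi)
  }
  if (!converged)
    warning("module fit did not converge in ", config$max_iter, " iterations")

  l <- projection_lengths(x, B)
  mem <- membership_fdr(l, k, n, config$fdr_threshold)
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
                 n_iter = iter, converged = converged,
                 objective_trace = trace, config = config),
            class = "module_fit")
}

#' @export
print.module_fit <- function(x, ...) {
  cat("Module fit: k =", x$k, "| members:", length(x$members),
      "of", length(x$lengths), "rows\n")
  cat("  eta =", format(x$eta, digits = 4),
      "| iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}
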