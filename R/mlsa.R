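#' Modular latent structure analysis of an expression matrix
#'
#' Front end of the package: standardizes the matrix, discovers a series of
#' modules (low-dimensional subspaces of condition space each explaining a
#' subset of rows), and assembles the discovered factors into an overall
#' sparse factor model G = L F + E.
#'
#' @param x numeric p x n matrix (rows = genes/features, columns =
#'   samples/conditions), or an already standardized `"expression_matrix"`.
#' @param mode deflation between discovery rounds: `"residual"` (keep
#'   residuals of all rows; later factors strictly orthogonal to earlier
#'   ones) or `"remove"` (drop member rows).
#' @param weight `"sigmoid"` (membership-like step weight with annealed
#'   steepness) or `"linear"` (weight equals projection length; objective
#'   provably non-decreasing).
#' @param fdr conservative FDR level for module membership (default 0.01).
#' @param alpha upper-tail level placing the sigmoid inflection point at the
#'   null projection-length cutoff (default 0.001).
#' @param phi sigmoid steepness (default 50).
#' @param overlap_alpha significance level of the hypergeometric overlap test
#'   in forward selection (default 0.01).
#' @param global_fraction fraction of rows above which a single factor is a
#'   global factor (default 0.5).
#' @param min_module_genes discovery stopping rule (default 10).
#' @param max_modules,max_factors caps on discovery.
#' @param max_k cap on a single module's dimension (default 10).
#' @param loadings `"module_ols"` or `"lasso_bic"` loading fill for the
#'   overall factor model.
#' @param p_cutoff optional p-value prune for `"lasso_bic"` (e.g. 1e-3).
#' @param standardize standardize rows to unit norm first (default TRUE;
#'   set FALSE if `x` is already standardized).
#' @param remove_row_mean,column_normalization passed to
#'   [standardize_rows()].
#' @param n_starts random restarts per module fit.
#' @param seed master seed; the whole analysis is reproducible given it.
#' @return object of class `"mlsa"` with components `modules` (a
#'   `"module_set"`), `model` (a `"factor_model"`, or `NULL` when nothing was
#'   found), `x` (the standardized matrix) and `call`. Methods: `print`,
#'   `summary`, `coef` (sparse loadings), `fitted`, `residuals`, `predict`,
#'   `plot`, `simulate`.
#' @examples
#' sim <- gen_modular_dataset(n_modules = 2, genes_per_module = 60,
#'                            n_noise_genes = 100, n_samples = 50, seed = 1)
#' fit <- mlsa(sim$matrix, seed = 1)
#' fit
#' @export
mlsa <- function(x, mode = c("residual", "remove"),
                 weight = c("sigmoid", "linear"),
                 fdr = 0.01, alpha = 0.001, phi = 50,
                 overlap_alpha = 0.01, global_fraction = 0.5,
                 min_module_genes = 10, max_modules = 50, max_factors = Inf,
                 max_k = 10,
                 loadings = c("module_ols", "lasso_bic"), p_cutoff = NULL,
                 standardize = TRUE, remove_row_mean = FALSE,
                 column_normalization = "none", n_starts = 1, seed = NULL) {
  mode <- match.arg(mode)
  weight <- match.arg(weight)
  loadings <- match.arg(loadings)
  cl <- match.call()
  g <- if (standardize && !inherits(x, "expression_matrix"))
    standardize_rows(x, remove_row_mean = remove_row_mean,
                     column_normalization = column_normalization)
  else assert_expression(x)

  cfg <- discovery_config(
    mode = mode,
    min_module_genes = min_module_genes,
    max_modules = max_modules,
    max_factors = max_factors,
    fit = fit_config(weight = weight_config(weight, phi = phi, alpha = alpha),
                     fdr_threshold = fdr, n_starts = n_starts),
    growth = growth_config(overlap_alpha = overlap_alpha,
                           global_fraction = global_fraction, max_k = max_k),
    master_seed = seed)
  ms <- find_modules(g, cfg)
  model <- if (length(ms$modules) || length(ms$global_factors))
    build_factor_model(g, ms, method = loadings, p_cutoff = p_cutoff)
  else NULL
  structure(list(modules = ms, model = model, x = g, config = cfg,
                 call = cl),
            class = "mlsa")
}

#' Extract the assembled factor score matrix
#' @param object an `"mlsa"` fit.
#' @return K x n matrix of factor scores, or NULL when nothing was found.
#' @export
factor_scores <- function(object) {
  stopifnot(inherits(object, "mlsa"))
  if (is.null(object$model)) NULL else object$model$F
}

#' @export
print.mlsa <- function(x, ...) {
  cat("Modular latent structure analysis\n")
  cat("Call: "); print(x$call)
  nk <- vapply(x$modules$modules, function(m) m$k, integer(1))
  cat(length(nk), "module(s)",
      if (length(nk)) paste0("with dimensions ", paste(nk, collapse = ", "))
      else "", "\n")
  cat(length(x$modules$global_factors), "global factor(s)\n")
  if (!is.null(x$model))
    cat("Factor model:", nrow(x$model$F), "factors, loadings by",
        x$model$method, "\n")
  invisible(x)
}

#' @export
summary.mlsa <- function(object, ...) {
  ms <- object$modules
  tab <- if (length(ms$modules)) data.frame(
    module = seq_along(ms$modules),
    k = vapply(ms$modules, function(m) m$k, integer(1)),
    members = vapply(ms$modules, function(m) length(m$members), integer(1)),
    eta = vapply(ms$modules, function(m) m$eta, numeric(1)),
    fdr_at_eta = vapply(ms$modules, function(m) m$fdr_at_eta, numeric(1)))
  else data.frame(module = integer(0), k = integer(0), members = integer(0),
                  eta = numeric(0), fdr_at_eta = numeric(0))
  res <- list(call = object$call, modules = tab,
              n_global = length(ms$global_factors),
              n_factors = if (is.null(object$model)) 0L
                          else nrow(object$model$F),
              loading_method = if (is.null(object$model)) NA_character_
                               else object$model$method,
              nnz = if (is.null(object$model)) 0L
                    else Matrix::nnzero(object$model$L),
              var_explained = if (is.null(object$model)) NA_real_
                              else 1 - sum(object$model$E^2) /
                                       sum(object$x^2))
  class(res) <- "summary.mlsa"
  res
}

#' @export
print.summary.mlsa <- function(x, ...) {
  cat("Modular latent structure analysis\n")
  cat("Call: "); print(x$call)
  cat("\nModules:\n")
  print(x$modules, row.names = FALSE)
  cat("\nGlobal factors:", x$n_global, "\n")
  cat("Total factors:", x$n_factors,
      "| loadings:", x$loading_method,
      "| nonzero loadings:", x$nnz, "\n")
  if (is.finite(x$var_explained))
    cat("Fraction of total variation explained:",
        format(x$var_explained, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.mlsa <- function(object, ...) {
  if (is.null(object$model)) return(NULL)
  object$model$L
}

#' @export
fitted.mlsa <- function(object, ...) {
  if (is.null(object$model)) return(matrix(0, nrow(object$x), ncol(object$x)))
  as.matrix(object$model$L %*% object$model$F)
}

#' @export
residuals.mlsa <- function(object, ...) {
  if (is.null(object$model)) return(as.matrix(object$x))
  object$model$E
}

#' Loadings of new rows on the fitted factors
#'
#' Unit-normalizes the rows of `newdata` and regresses each on the full
#' factor score matrix (ordinary least squares, no intercept), giving the
#' loading each fitted factor would receive for the new rows. Also reports
#' each new row's projection length onto every module's subspace.
#'
#' @param object an `"mlsa"` fit.
#' @param newdata numeric matrix with the same number of columns as the
#'   training matrix.
#' @param ... unused.
#' @return list with `loadings` (rows x K) and `module_lengths` (rows x
#'   number of modules).
#' @export
predict.mlsa <- function(object, newdata, ...) {
  if (is.null(object$model)) stop("fit contains no factors")
  newdata <- standardize_rows(as.matrix(newdata))
  F <- object$model$F
  D <- t(F)
  B <- qr.coef(qr(D), t(newdata))
  ml <- vapply(object$modules$modules,
               function(m) projection_lengths(newdata, m$basis),
               numeric(nrow(newdata)))
  ml <- matrix(ml, nrow = nrow(newdata))
  list(loadings = t(B), module_lengths = ml)
}

#' @export
plot.mlsa <- function(x, which = NULL, ...) {
  if (is.null(x$model)) {
    warning("nothing to plot: no factors found")
    return(invisible(x))
  }
  F <- x$model$F
  mof <- x$model$module_of_factor
  sel <- if (is.null(which)) seq_len(nrow(F)) else which
  graphics::matplot(t(F[sel, , drop = FALSE]), type = "l", lty = 1,
                    col = mof[sel] + 1L,
                    xlab = "condition", ylab = "factor score", ...)
  graphics::legend("topright",
                   legend = paste0("f", sel, " (m", mof[sel], ")"),
                   col = mof[sel] + 1L, lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

#' Simulate matrices from a fitted factor model
#'
#' Draws new data G* = L F + E*, with E* i.i.d. Gaussian per row matched to
#' the fitted residual standard deviation of that row.
#'
#' @param object an `"mlsa"` fit with a factor model.
#' @param nsim number of matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of p x n matrices.
#' @export
simulate.mlsa <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$model)) stop("fit contains no factors")
  mu <- as.matrix(object$model$L %*% object$model$F)
  sds <- apply(object$model$E, 1L, stats::sd)
  with_seed(seed, lapply(seq_len(nsim), function(i)
    mu + matrix(stats::rnorm(length(mu)), nrow(mu)) * sds))
}
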