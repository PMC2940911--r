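#' Stack all discovered factors into a single factor score matrix
#'
#' Row-combines the (rotated) factor score vectors of every module and every
#' global factor into a K x n matrix F, preserving per-module ordering, and
#' records which module each factor came from (global factors get module
#' index 0).
#'
#' @param ms a `"module_set"` from [find_modules()].
#' @return list with `F` (K x n, unit-norm rows) and `module_of_factor`
#'   (integer vector of length K).
#' @export
assemble_factors <- function(ms) {
  stopifnot(inherits(ms, "module_set"))
  rows <- list(); mof <- integer(0)
  for (j in seq_along(ms$modules)) {
    f <- ms$modules[[j]]$factors
    rows[[length(rows) + 1L]] <- f
    mof <- c(mof, rep.int(j, nrow(f)))
  }
  for (g in ms$global_factors) {
    rows[[length(rows) + 1L]] <- matrix(g$factor, 1L)
    mof <- c(mof, 0L)
  }
  if (!length(rows)) stop("module set contains no factors")
  F <- do.call(rbind, rows)
  rownames(F) <- paste0("factor", seq_len(nrow(F)))
  colnames(F) <- ms$col_ids
  list(F = F, module_of_factor = mof)
}

#' Loadings by per-row regression on the row's own module factors
#'
#' Fills the sparse loading matrix L in G = L F + E: each row is regressed
#' (ordinary least squares, no intercept) on the rotated factors of the
#' module(s) it belongs to, other entries stay zero; rows in no module get a
#' zero loading row. The regression is needed because rotated factors are in
#' general oblique. Near-singular per-module designs fall back to a tiny
#' ridge penalty.
#'
#' @param x standardized p x n matrix.
#' @param F K x n factor score matrix.
#' @param module_of_factor factor-to-module map from [assemble_factors()].
#' @param membership list mapping each module index to the row identifiers of
#'   its members (global factors use module index 0 and their associated
#'   rows).
#' @return list with sparse `L` (p x K, `Matrix::dgCMatrix`) and dense
#'   residual `E`.
#' @export
fit_loadings_ols <- function(x, F, module_of_factor, membership) {
  x <- as.matrix(x)
  p <- nrow(x); K <- nrow(F)
  L <- matrix(0, p, K, dimnames = list(rownames(x), rownames(F)))
  mod_ids <- unique(module_of_factor)
  row_mods <- vector("list", p)  # modules claiming each row
  names(row_mods) <- rownames(x)
  for (mod in mod_ids) {
    ids <- membership[[as.character(mod)]]
    idx <- match(ids, rownames(x))
    idx <- idx[!is.na(idx)]
    for (i in idx) row_mods[[i]] <- c(row_mods[[i]], mod)
  }
  for (i in seq_len(p)) {
    mods <- row_mods[[i]]
    if (is.null(mods)) next
    cols <- which(module_of_factor %in% mods)
    Fi <- t(F[cols, , drop = FALSE])          # n x q design
    G <- crossprod(Fi)
    b <- tryCatch(solve(G, crossprod(Fi, x[i, ])),
                  error = function(e) {
                    warning("singular factor design for row ", rownames(x)[i],
                            "; using ridge fallback")
                    solve(G + diag(1e-8, ncol(G)), crossprod(Fi, x[i, ]))
                  })
    L[i, cols] <- b
  }
  E <- x - L %*% F
  list(L = methods::as(methods::as(Matrix::Matrix(L, sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix"),
       E = E)
}

# BIC of a no-intercept gaussian fit: n log(RSS/n) + df log(n)
bic_of <- function(rss, df, n) n * log(max(rss, 1e-12) / n) + df * log(n)

#' Loadings by lasso with BIC model selection
#'
#' For every row, an L1-regularized path over all K factors is computed; the
#' active set of the path point minimizing BIC (n log(RSS/n) + df log(n)) is
#' refit by ordinary least squares and written into the loading matrix.
#' Optionally the refit coefficients are pruned by a t-test p-value cutoff
#' before the final refit.
#'
#' @param x standardized p x n matrix.
#' @param F K x n factor score matrix.
#' @param p_cutoff if non-`NULL`, factors whose refit coefficient p-value
#'   exceeds this are dropped (sequential prune after BIC selection).
#' @return list with sparse `L` and residual `E`.
#' @export
fit_loadings_lasso_bic <- function(x, F, p_cutoff = NULL) {
  x <- as.matrix(x)
  K <- nrow(F); n <- ncol(x); p <- nrow(x)
  if (K >= n) warning("more factors than samples; lasso path may be unstable")
  Ft <- t(F)  # n x K design
  L <- matrix(0, p, K, dimnames = list(rownames(x), rownames(F)))
  for (i in seq_len(p)) {
    y <- x[i, ]
    fit <- glmnet::glmnet(Ft, y, intercept = FALSE, standardize = FALSE)
    beta <- as.matrix(fit$beta)
    # BIC over the path using the penalized coefficients' active sets
    act <- apply(beta != 0, 2L, which, simplify = FALSE)
    bics <- vapply(seq_along(act), function(j) {
      a <- act[[j]]
      if (!length(a)) return(bic_of(sum(y^2), 0, n))
      D <- Ft[, a, drop = FALSE]
      b <- qr.coef(qr(D), y)
      bic_of(sum((y - D %*% b)^2), length(a), n)
    }, numeric(1))
    null_bic <- bic_of(sum(y^2), 0, n)
    best <- which.min(c(null_bic, bics))
    a <- if (best == 1L) integer(0) else act[[best - 1L]]
    if (length(a)) {
      D <- Ft[, a, drop = FALSE]
      qrD <- qr(D)
      b <- qr.coef(qrD, y)
      if (!is.null(p_cutoff) && n - length(a) > 0) {
        resid <- y - D %*% b
        s2 <- sum(resid^2) / (n - length(a))
        XtXinv <- chol2inv(qr.R(qrD))
        se <- sqrt(pmax(diag(XtXinv) * s2, 1e-300))
        pv <- 2 * stats::pt(abs(b) / se, n - length(a), lower.tail = FALSE)
        keep <- pv <= p_cutoff
        a <- a[keep]
        b <- if (length(a)) qr.coef(qr(Ft[, a, drop = FALSE]), y) else numeric(0)
      }
      if (length(a)) L[i, a] <- b
    }
  }
  E <- x - L %*% F
  list(L = methods::as(methods::as(Matrix::Matrix(L, sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix"),
       E = E)
}

#' Assemble the overall sparse factor model G = L F + E
#'
#' @param x standardized matrix the modules were discovered from.
#' @param ms `"module_set"` from [find_modules()].
#' @param method `"module_ols"` (regression of each row on its own module's
#'   factors; loading rows are zero outside the row's modules) or
#'   `"lasso_bic"` (regularized regression of each row on all factors).
#' @param p_cutoff optional p-value prune for `"lasso_bic"` (e.g. 1e-3).
#' @return object of class `"factor_model"` with `F` (K x n), sparse `L`
#'   (p x K), residual `E`, `module_of_factor` and `method`.
#' @export
build_factor_model <- function(x, ms, method = c("module_ols", "lasso_bic"),
                               p_cutoff = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  af <- assemble_factors(ms)
  membership <- stats::setNames(
    lapply(seq_along(ms$modules), function(j) ms$modules[[j]]$member_ids),
    as.character(seq_along(ms$modules)))
  if (length(ms$global_factors))
    membership[["0"]] <- unique(unlist(lapply(ms$global_factors,
                                              function(g) g$member_ids)))
  fit <- if (method == "module_ols")
    fit_loadings_ols(x, af$F, af$module_of_factor, membership)
  else
    fit_loadings_lasso_bic(x, af$F, p_cutoff = p_cutoff)
  structure(list(F = af$F, L = fit$L, E = fit$E,
                 module_of_factor = af$module_of_factor,
                 method = method, p_cutoff = p_cutoff),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("Sparse factor model: G = L F + E\n")
  cat("  ", nrow(x$L), "rows,", nrow(x$F), "factors, method:", x$method, "\n")
  cat("  nonzero loadings:", Matrix::nnzero(x$L), "\n")
  invisible(x)
}
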