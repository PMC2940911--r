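#' Configuration for discovering a series of modules
#'
#' @param mode deflation mode between rounds: `"residual"` replaces every row
#'   by its residual against the found basis (later bases are then strictly
#'   orthogonal to earlier ones, recommended when factors influence many
#'   rows); `"remove"` drops the member rows (bases of different modules may
#'   then be weakly correlated).
#' @param min_module_genes stopping rule: discovery ends when a newly found
#'   module has fewer members than this (default 10, a deliberately small
#'   cutoff so late weak modules are still surfaced for the analyst to
#'   filter).
#' @param max_modules cap on the number of discovery rounds.
#' @param max_factors cap on the total number of factors (module dimensions
#'   plus global factors) collected; `Inf` disables the cap.
#' @param fit a [fit_config()] used inside every round.
#' @param growth a [growth_config()] used inside every round.
#' @param residual_floor rows whose residual norm falls below this after a
#'   residual deflation are dropped instead of renormalized, to avoid
#'   amplifying numerical noise (default 0.1).
#' @param master_seed integer; per-round seeds are derived from it by a
#'   counter so the whole discovery is reproducible.
#' @return object of class `"discovery_config"`.
#' @export
discovery_config <- function(mode = c("residual", "remove"),
                             min_module_genes = 10, max_modules = 50,
                             max_factors = Inf,
                             fit = fit_config(), growth = growth_config(),
                             residual_floor = 0.1, master_seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(min_module_genes >= 1, max_modules >= 1)
  structure(list(mode = mode, min_module_genes = min_module_genes,
                 max_modules = max_modules, max_factors = max_factors,
                 fit = fit, growth = growth,
                 residual_floor = residual_floor, master_seed = master_seed),
            class = "discovery_config")
}

#' Deflate a matrix after a module is found
#'
#' `"remove"` drops the module's member rows. `"residual"` replaces every row
#' by its component orthogonal to the module basis, drops rows whose residual
#' norm falls below `residual_floor`, and renormalizes the survivors to unit
#' length so the projection-length null distribution applies in later rounds.
#'
#' @param x matrix the module was fitted on.
#' @param basis the module's n x k basis.
#' @param members integer indices of member rows in `x`.
#' @param mode `"remove"` or `"residual"`.
#' @param residual_floor norm floor for residual mode.
#' @return the deflated matrix (possibly with zero rows).
#' @export
deflate <- function(x, basis, members, mode = c("remove", "residual"),
                    residual_floor = 0.1) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (mode == "remove") {
    if (!length(members)) return(x)
    return(x[-members, , drop = FALSE])
  }
  res <- x - (x %*% basis) %*% t(basis)
  nrm <- sqrt(rowSums(res^2))
  keep <- nrm >= residual_floor
  res <- res[keep, , drop = FALSE] / nrm[keep]
  res
}

#' Discover a series of modules from a standardized matrix
#'
#' Repeatedly runs forward-selection module search ([grow_module()]) and
#' deflates the matrix between rounds. Global factors (single factors
#' associated with more than the configured fraction of rows) are recorded
#' separately and deflated by residual in both modes. Discovery stops when a
#' new module falls below `min_module_genes` members, the factor or module
#' caps are reached, or too few rows remain.
#'
#' @param x standardized matrix (see [standardize_rows()]).
#' @param config a [discovery_config()].
#' @return object of class `"module_set"`: `modules` (list of module fits,
#'   members recorded as original row identifiers), `global_factors` (list),
#'   and `provenance` (per-round data frame of type, seed, k and size).
#' @export
find_modules <- function(x, config = discovery_config()) {
  x <- assert_expression(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  cur <- x
  modules <- list()
  globals <- list()
  prov <- list()
  round_i <- 0L
  n_factors <- 0L
  repeat {
    if (round_i >= config$max_modules) break
    if (nrow(cur) < max(config$min_module_genes, 3L)) break
    if (n_factors >= config$max_factors) break
    round_i <- round_i + 1L
    seed_r <- if (is.null(config$master_seed)) NULL
              else derive_seed(config$master_seed, round_i)
    m <- tryCatch(grow_module(cur, config$fit, config$growth, seed = seed_r),
                  error = function(e) NULL)
    if (is.null(m)) break
    if (inherits(m, "global_factor")) {
      m$member_ids <- rownames(cur)[m$members]
      globals[[length(globals) + 1L]] <- m
      n_factors <- n_factors + 1L
      prov[[length(prov) + 1L]] <- data.frame(
        round = round_i, type = "global", seed = if (is.null(seed_r)) NA else seed_r,
        k = 1L, n_members = length(m$members))
      cur <- deflate(cur, m$basis, m$members, "residual",
                     config$residual_floor)
      next
    }
    if (length(m$members) < config$min_module_genes) break
    m$member_ids <- rownames(cur)[m$members]
    modules[[length(modules) + 1L]] <- m
    n_factors <- n_factors + m$k
    prov[[length(prov) + 1L]] <- data.frame(
      round = round_i, type = "module", seed = if (is.null(seed_r)) NA else seed_r,
      k = m$k, n_members = length(m$members))
    cur <- deflate(cur, m$basis, m$members, config$mode,
                   config$residual_floor)
  }
  structure(list(modules = modules, global_factors = globals,
                 provenance = if (length(prov)) do.call(rbind, prov)
                              else data.frame(round = integer(0), type = character(0),
                                              seed = double(0), k = integer(0),
                                              n_members = integer(0)),
                 row_ids = rownames(x), col_ids = colnames(x),
                 config = config),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  nk <- vapply(x$modules, function(m) m$k, integer(1))
  cat("Module set:", length(x$modules), "module(s)",
      if (length(nk)) paste0("(k = ", paste(nk, collapse = ", "), ") ") else "",
      "and", length(x$global_factors), "global factor(s)\n")
  if (nrow(x$provenance)) print(x$provenance, row.names = FALSE)
  invisible(x)
}
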