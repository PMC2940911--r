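#' Read a feature-by-condition matrix from delimited text
#'
#' Expects a header row of column identifiers and a first column of row
#' identifiers. The delimiter is auto-detected (tab vs comma) unless forced.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` auto-detects from the header line.
#' @return numeric matrix with dimnames.
#' @export
read_expression <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(hdr, gregexpr("\t", hdr))) >=
               lengths(regmatches(hdr, gregexpr(",", hdr)))) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("matrix contains missing values")
  m
}

# 10 significant digits: reproducible round trips without bloated files
fmt_num <- function(x) trimws(formatC(x, digits = 10, format = "g"))

#' Write a matrix as TSV with row and column identifiers
#' @param m matrix.
#' @param path output path.
#' @param id_header name of the leading identifier column.
#' @export
write_expression <- function(m, path, id_header = "id") {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("col", seq_len(ncol(m)))
  out <- cbind(rownames(m), matrix(fmt_num(m), nrow = nrow(m)))
  colnames(out) <- c(id_header, colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis on a matrix file and write results
#'
#' Reads the matrix, runs [mlsa()], and writes to `output_dir`:
#' `modules.tsv` (row id, module index, projection length, membership FDR),
#' `factors.tsv` (factor x condition scores), `loadings.mtx` (sparse loading
#' matrix, MatrixMarket) with `loadings_rows.txt` / `loadings_cols.txt`
#' sidecars, optionally `residual.tsv`, and `manifest.json` (resolved
#' configuration, seeds, version, per-round summaries, wall time).
#'
#' @param input path to a TSV/CSV matrix.
#' @param output_dir directory to create/write into.
#' @param ... passed to [mlsa()].
#' @param write_residual also write the residual matrix E (default FALSE).
#' @param sep forced delimiter for the input (default auto).
#' @param quiet suppress progress messages.
#' @return the `"mlsa"` fit, invisibly.
#' @export
mlsa_run <- function(input, output_dir, ..., write_residual = FALSE,
                     sep = NULL, quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  m <- read_expression(input, sep = sep)
  if (!quiet) message("read ", nrow(m), " x ", ncol(m), " matrix from ", input)
  fit <- mlsa(m, ...)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  ms <- fit$modules
  mod_tab <- if (length(ms$modules)) do.call(rbind, lapply(
    seq_along(ms$modules), function(j) {
      mm <- ms$modules[[j]]
      data.frame(id = mm$member_ids, module = j,
                 projection_length = fmt_num(mm$lengths[mm$members]),
                 fdr_at_membership = fmt_num(mm$fdr_at_eta))
    }))
  else data.frame(id = character(0), module = integer(0),
                  projection_length = character(0),
                  fdr_at_membership = character(0))
  utils::write.table(mod_tab, file.path(output_dir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(fit$model)) {
    write_expression(fit$model$F, file.path(output_dir, "factors.tsv"),
                     id_header = "factor")
    Matrix::writeMM(fit$model$L, file.path(output_dir, "loadings.mtx"))
    writeLines(rownames(fit$x), file.path(output_dir, "loadings_rows.txt"))
    writeLines(rownames(fit$model$F), file.path(output_dir, "loadings_cols.txt"))
    if (write_residual)
      write_expression(fit$model$E, file.path(output_dir, "residual.tsv"))
  } else {
    # no modules found: still emit empty tables so downstream tooling parses
    write_expression(matrix(0, 0, ncol(m),
                            dimnames = list(NULL, colnames(m))),
                     file.path(output_dir, "factors.tsv"),
                     id_header = "factor")
    if (!quiet) message("no modules found; empty tables written")
  }

  args <- list(...)
  manifest <- list(
    package = "mlsa",
    version = as.character(utils::packageVersion("mlsa")),
    input = input,
    dims = dim(m),
    options = args[vapply(args, function(a)
      is.atomic(a) && length(a) == 1L, logical(1))],
    mode = ms$config$mode,
    master_seed = ms$config$master_seed,
    rounds = ms$provenance,
    global_factors_deflated = "residual",
    wall_time_sec = round(proc.time()[["elapsed"]] - t0, 2))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}

#' Write a simulated dataset bundle to disk
#'
#' Generates a modular or global-sparse dataset and writes `matrix.tsv`,
#' `truth_factors.tsv`, `truth_loadings.mtx` and `truth_map.json` (factor
#' groups, gene-module map, factor types, generator settings).
#'
#' @param output_dir output directory.
#' @param model `"modular"` or `"global"`.
#' @param ... passed to [gen_modular_dataset()] or
#'   [gen_global_sparse_dataset()].
#' @return the simulation list, invisibly.
#' @export
mlsa_simulate <- function(output_dir, model = c("modular", "global"), ...) {
  model <- match.arg(model)
  sim <- if (model == "modular") gen_modular_dataset(...)
         else gen_global_sparse_dataset(...)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$matrix, file.path(output_dir, "matrix.tsv"))
  tf <- sim$truth$true_factors
  rownames(tf) <- paste0("factor", seq_len(nrow(tf)))
  colnames(tf) <- colnames(sim$matrix)
  write_expression(tf, file.path(output_dir, "truth_factors.tsv"),
                   id_header = "factor")
  Matrix::writeMM(methods::as(Matrix::Matrix(sim$truth$true_loadings,
                                             sparse = TRUE), "CsparseMatrix"),
                  file.path(output_dir, "truth_loadings.mtx"))
  jsonlite::write_json(
    list(model = model,
         group_of_factor = sim$truth$group_of_factor,
         gene_module = sim$truth$gene_module,
         factor_types = sim$truth$factor_types,
         settings = list(...)),
    file.path(output_dir, "truth_map.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}

#' Read a simulation truth bundle written by [mlsa_simulate()]
#' @param dir bundle directory.
#' @return a `"sim_truth"` object.
#' @export
read_truth <- function(dir) {
  tf <- read_expression(file.path(dir, "truth_factors.tsv"))
  map <- jsonlite::read_json(file.path(dir, "truth_map.json"),
                             simplifyVector = TRUE)
  L <- as.matrix(Matrix::readMM(file.path(dir, "truth_loadings.mtx")))
  structure(list(true_factors = tf,
                 group_of_factor = map$group_of_factor,
                 true_loadings = L,
                 gene_module = map$gene_module,
                 factor_types = map$factor_types),
            class = "sim_truth")
}

#' Score an identified-factor file against a truth bundle
#'
#' @param factors_path TSV of identified factor score vectors (factors in
#'   rows), e.g. the `factors.tsv` written by [mlsa_run()].
#' @param truth_dir directory written by [mlsa_simulate()].
#' @param r2_threshold recovery threshold (default 0.49).
#' @param output optional path for a TSV report (per-factor R-squared plus a
#'   header line with the recovered fraction and threshold).
#' @return a `"recovery_report"`.
#' @export
mlsa_evaluate <- function(factors_path, truth_dir, r2_threshold = 0.49,
                          output = NULL) {
  idf <- tryCatch(read_expression(factors_path), error = function(e) NULL)
  truth <- read_truth(truth_dir)
  if (!is.null(idf) && ncol(idf) > 0 && nrow(idf) > 0 &&
      ncol(idf) != ncol(truth$true_factors))
    stop("sample dimension mismatch between identified factors and truth")
  rep <- evaluate_recovery(idf, truth, r2_threshold = r2_threshold)
  if (!is.null(output)) {
    con <- file(output, "w")
    writeLines(sprintf("# recovered_fraction\t%s\tr2_threshold\t%s",
                       fmt_num(rep$recovered_fraction),
                       fmt_num(r2_threshold)), con)
    utils::write.table(
      data.frame(true_factor = seq_along(rep$r2_per_true_factor),
                 r2 = fmt_num(rep$r2_per_true_factor)),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  rep
}
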