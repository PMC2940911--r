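#' Generate one hidden-factor score vector
#'
#' Four signal types are supported: `gaussian` (i.i.d. standard normal),
#' `sine` (sin(2 pi (t + phase) / tau)), `square` (sign of that sine) and
#' `sawtooth` (2 frac((t + phase)/tau) - 1), with t = 1..n. For the periodic
#' types the period tau is drawn uniformly on \[20, 40\] and the phase
#' uniformly on \[0, tau\] when not supplied. Every vector is centered and
#' scaled to unit variance so loading magnitudes carry the relative-strength
#' semantics.
#'
#' @param n length (number of samples).
#' @param type one of `"gaussian"`, `"sine"`, `"square"`, `"sawtooth"`.
#' @param tau,phase optional period and phase for the periodic types.
#' @param standardize center/scale to unit variance (default TRUE).
#' @return numeric vector of length n.
#' @export
gen_factor <- function(n, type = c("gaussian", "sine", "square", "sawtooth"),
                       tau = NULL, phase = NULL, standardize = TRUE) {
  type <- match.arg(type)
  if (n < 2) stop("need n >= 2")
  if (type != "gaussian") {
    if (is.null(tau)) tau <- stats::runif(1, 20, 40)
    if (is.null(phase)) phase <- stats::runif(1, 0, tau)
  }
  t <- seq_len(n)
  f <- switch(type,
    gaussian = stats::rnorm(n),
    sine = sin(2 * pi * (t + phase) / tau),
    square = sign(sin(2 * pi * (t + phase) / tau)),
    sawtooth = 2 * ((t + phase) / tau - floor((t + phase) / tau)) - 1)
  if (standardize) {
    s <- stats::sd(f)
    if (s < 1e-12) stop("degenerate factor signal (constant)")
    f <- (f - mean(f)) / s
  }
  attr(f, "type") <- type
  if (type != "gaussian") { attr(f, "tau") <- tau; attr(f, "phase") <- phase }
  f
}

#' Loading magnitudes from a random partition of the unit interval
#'
#' For a gene controlled by m factors, m - 1 uniform draws split \[0, 1\]
#' into m regions whose sizes become the loading magnitudes, so the absolute
#' loadings of each gene sum to 1. Signs are applied separately (a random
#' half of all nonzero loadings in a module is negated).
#'
#' @param m number of controlling factors (>= 1).
#' @return numeric vector of length m summing to 1.
#' @export
gen_loading_row <- function(m) {
  if (m < 1) stop("need m >= 1")
  if (m == 1) return(1)
  diff(c(0, sort(stats::runif(m - 1)), 1))
}

# Build one module block: sparsity pattern, loadings (signed), factors.
# Returns list(expr = genes x n, loadings = genes x k, factors = k x n,
# factor_types).
gen_module_block <- function(n_genes, k, n, nonzero_fraction, factor_types) {
  pat <- matrix(stats::rbinom(n_genes * k, 1L, nonzero_fraction) == 1L,
                n_genes, k)
  for (i in which(rowSums(pat) == 0L))
    pat[i, sample.int(k, 1L)] <- TRUE  # every gene needs >= 1 factor
  L <- matrix(0, n_genes, k)
  for (i in seq_len(n_genes)) {
    m <- sum(pat[i, ])
    L[i, pat[i, ]] <- gen_loading_row(m)
  }
  nz <- which(pat)
  neg <- sample(nz, floor(length(nz) / 2))
  L[neg] <- -L[neg]
  types <- if (identical(factor_types, "mixed"))
    sample(c("gaussian", "sine", "square", "sawtooth"), k, replace = TRUE)
  else rep("gaussian", k)
  F <- t(vapply(types, function(ty) as.numeric(gen_factor(n, ty)), numeric(n)))
  list(expr = L %*% F, loadings = L, factors = F, factor_types = types)
}

# Add per-gene Gaussian noise at the requested signal-to-noise variance ratio.
add_noise <- function(expr, snr) {
  sds <- apply(expr, 1L, stats::sd) / sqrt(snr)
  expr + matrix(stats::rnorm(length(expr)), nrow(expr)) * sds
}

#' Simulate a modular latent-structure dataset
#'
#' Generates `n_modules` independent modules, each with `genes_per_module`
#' genes controlled by a random number of hidden factors (uniform on
#' `k_min:k_max`). Within a module the loading sparsity pattern is Bernoulli
#' with probability `nonzero_fraction` (every gene forced to keep at least
#' one factor), magnitudes come from [gen_loading_row()], and half of the
#' nonzero loadings are negated. Pure-noise genes are appended as i.i.d.
#' standard normal rows, and Gaussian noise is added to every signal gene so
#' that var(signal)/var(noise) = `snr` per gene.
#'
#' @param n_samples number of conditions (default 100).
#' @param n_modules number of modules (default 10).
#' @param genes_per_module genes in each module (default 100).
#' @param k_min,k_max range of hidden factors per module (default 1..3).
#' @param nonzero_fraction within-module nonzero-loading probability
#'   (default 1).
#' @param n_noise_genes pure-noise genes appended (default 1000).
#' @param snr per-gene signal-to-noise variance ratio (default 1).
#' @param factor_types `"gaussian"` or `"mixed"` (types drawn uniformly from
#'   the four signal types).
#' @param seed optional integer seed; generation is deterministic given it.
#' @return list with `matrix` (raw p x n matrix with row/column ids) and
#'   `truth` (a `"sim_truth"`: `true_factors` K x n, `group_of_factor`,
#'   `true_loadings` p x K, `gene_module` with 0 for noise genes).
#' @export
gen_modular_dataset <- function(n_samples = 100, n_modules = 10,
                                genes_per_module = 100, k_min = 1, k_max = 3,
                                nonzero_fraction = 1, n_noise_genes = 1000,
                                snr = 1, factor_types = c("gaussian", "mixed"),
                                seed = NULL) {
  factor_types <- match.arg(factor_types)
  stopifnot(n_samples >= 3, n_modules >= 1, genes_per_module >= 1,
            k_min >= 1, k_max >= k_min, snr > 0,
            nonzero_fraction > 0, nonzero_fraction <= 1)
  with_seed(seed, {
    blocks <- lapply(seq_len(n_modules), function(j) {
      k <- sample(seq(k_min, k_max), 1L)
      gen_module_block(genes_per_module, k, n_samples, nonzero_fraction,
                       factor_types)
    })
    signal <- do.call(rbind, lapply(blocks, `[[`, "expr"))
    signal <- add_noise(signal, snr)
    noise <- matrix(stats::rnorm(n_noise_genes * n_samples),
                    n_noise_genes, n_samples)
    mat <- rbind(signal, noise)
    rownames(mat) <- c(
      unlist(lapply(seq_len(n_modules), function(j)
        sprintf("m%d_g%d", j, seq_len(genes_per_module)))),
      if (n_noise_genes) sprintf("noise_g%d", seq_len(n_noise_genes)))
    colnames(mat) <- sprintf("s%d", seq_len(n_samples))

    ks <- vapply(blocks, function(b) nrow(b$factors), integer(1))
    true_factors <- do.call(rbind, lapply(blocks, `[[`, "factors"))
    group_of_factor <- rep(seq_len(n_modules), ks)
    p <- nrow(mat); K <- sum(ks)
    true_loadings <- matrix(0, p, K)
    col0 <- cumsum(c(0, ks)); row0 <- 0
    for (j in seq_len(n_modules)) {
      rows <- row0 + seq_len(genes_per_module)
      true_loadings[rows, col0[j] + seq_len(ks[j])] <- blocks[[j]]$loadings
      row0 <- row0 + genes_per_module
    }
    gene_module <- c(rep(seq_len(n_modules), each = genes_per_module),
                     rep(0L, n_noise_genes))
    truth <- structure(list(true_factors = true_factors,
                            group_of_factor = group_of_factor,
                            true_loadings = true_loadings,
                            gene_module = gene_module,
                            factor_types = unlist(lapply(blocks, `[[`,
                                                         "factor_types"))),
                       class = "sim_truth")
    list(matrix = mat, truth = truth)
  })
}

#' Simulate a global sparse latent-structure dataset
#'
#' Generated as a single large module: `n_genes` genes controlled by
#' `n_factors` hidden factors through a sparse loading matrix whose per-cell
#' nonzero probability is `mean_factors_per_gene / n_factors`, plus noise
#' genes and per-gene SNR noise as in [gen_modular_dataset()]. In the ground
#' truth every hidden factor forms its own group.
#'
#' @inheritParams gen_modular_dataset
#' @param n_genes number of signal genes (default 2000).
#' @param n_factors number of hidden factors (default 20).
#' @param mean_factors_per_gene average number of factors governing each gene
#'   (default 5).
#' @return same shape as [gen_modular_dataset()].
#' @export
gen_global_sparse_dataset <- function(n_samples = 100, n_genes = 2000,
                                      n_factors = 20,
                                      mean_factors_per_gene = 5,
                                      n_noise_genes = 500, snr = 1,
                                      factor_types = c("gaussian", "mixed"),
                                      seed = NULL) {
  factor_types <- match.arg(factor_types)
  stopifnot(mean_factors_per_gene <= n_factors, snr > 0)
  with_seed(seed, {
    blk <- gen_module_block(n_genes, n_factors, n_samples,
                            mean_factors_per_gene / n_factors, factor_types)
    signal <- add_noise(blk$expr, snr)
    noise <- matrix(stats::rnorm(n_noise_genes * n_samples),
                    n_noise_genes, n_samples)
    mat <- rbind(signal, noise)
    rownames(mat) <- c(sprintf("g%d", seq_len(n_genes)),
                       if (n_noise_genes) sprintf("noise_g%d",
                                                  seq_len(n_noise_genes)))
    colnames(mat) <- sprintf("s%d", seq_len(n_samples))
    p <- nrow(mat)
    true_loadings <- rbind(blk$loadings, matrix(0, n_noise_genes, n_factors))
    truth <- structure(list(true_factors = blk$factors,
                            group_of_factor = seq_len(n_factors),
                            true_loadings = true_loadings,
                            gene_module = c(rep(1L, n_genes),
                                            rep(0L, n_noise_genes)),
                            factor_types = blk$factor_types),
                       class = "sim_truth")
    list(matrix = mat, truth = truth)
  })
}

# Multiple R^2 of y regressed (with intercept) on the rows of X (q x n).
r2_multiple <- function(y, X) {
  if (is.null(X) || nrow(X) == 0L) return(0)
  D <- cbind(1, t(X))
  res <- stats::lsfit(D, y, intercept = FALSE)$residuals
  tss <- sum((y - mean(y))^2)
  if (tss < 1e-12) return(0)
  max(0, min(1, 1 - sum(res^2) / tss))
}

#' Score factor recovery against simulation ground truth
#'
#' Two-step protocol. Step 1: every identified factor is regressed on each
#' true factor group and assigned to the group with the largest multiple
#' R-squared; the K_true identified factors with the largest R-squared are
#' retained. Step 2: every true hidden factor is regressed on the retained
#' identified factors assigned to its group, and that multiple R-squared is
#' the factor's level of recovery (0 when its group attracted none). A
#' factor with R-squared >= `r2_threshold` (default 0.49, i.e. multiple
#' correlation >= 0.7) counts as recovered.
#'
#' @param identified matrix of identified factor score vectors (rows), up to
#'   about 1.5 x K_true of them.
#' @param truth a `"sim_truth"`.
#' @param r2_threshold recovery threshold on R-squared.
#' @return object of class `"recovery_report"`: `r2_per_true_factor`,
#'   `recovered_fraction`, `assignment` (group of each retained identified
#'   factor), `r2_threshold`.
#' @export
evaluate_recovery <- function(identified, truth, r2_threshold = 0.49) {
  stopifnot(inherits(truth, "sim_truth"))
  TF <- truth$true_factors
  groups <- truth$group_of_factor
  K <- nrow(TF)
  ugroups <- unique(groups)
  if (is.null(identified) || NROW(identified) == 0L) {
    return(structure(list(r2_per_true_factor = rep(0, K),
                          recovered_fraction = 0,
                          assignment = integer(0),
                          r2_threshold = r2_threshold),
                     class = "recovery_report"))
  }
  identified <- as.matrix(identified)
  if (ncol(identified) != ncol(TF))
    stop("identified factors and truth have different sample counts")
  q <- nrow(identified)
  r2_grp <- matrix(0, q, length(ugroups))
  for (j in seq_along(ugroups))
    for (i in seq_len(q))
      r2_grp[i, j] <- r2_multiple(identified[i, ],
                                  TF[groups == ugroups[j], , drop = FALSE])
  best_g <- ugroups[max.col(r2_grp, ties.method = "first")]
  best_r2 <- r2_grp[cbind(seq_len(q), max.col(r2_grp, ties.method = "first"))]
  keep <- utils::head(order(best_r2, decreasing = TRUE), K)
  r2_true <- vapply(seq_len(K), function(t) {
    assigned <- keep[best_g[keep] == groups[t]]
    r2_multiple(TF[t, ], identified[assigned, , drop = FALSE])
  }, numeric(1))
  structure(list(r2_per_true_factor = r2_true,
                 recovered_fraction = mean(r2_true >= r2_threshold),
                 assignment = stats::setNames(best_g[keep], keep),
                 r2_threshold = r2_threshold),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Factor recovery:", round(100 * x$recovered_fraction, 1),
      "% of", length(x$r2_per_true_factor),
      "true factors at R^2 >=", x$r2_threshold, "\n")
  invisible(x)
}
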