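# Small discovered structure shared across tests
make_fitted_set <- function() {
  sim <- gen_modular_dataset(n_samples = 50, n_modules = 2,
                             genes_per_module = 60, k_min = 2, k_max = 2,
                             n_noise_genes = 80, snr = 4, seed = 55)
  x <- standardize_rows(sim$matrix)
  ms <- suppressWarnings(find_modules(x, discovery_config(mode = "remove",
                                                          master_seed = 3)))
  list(x = x, ms = ms, sim = sim)
}

test_that("factor assembly stacks module factors in order with unit norms", {
  fs <- make_fitted_set()
  af <- assemble_factors(fs$ms)
  expect_equal(nrow(af$F), sum(vapply(fs$ms$modules, `[[`, integer(1), "k")) +
                 length(fs$ms$global_factors))
  expect_equal(unname(rowSums(af$F^2)), rep(1, nrow(af$F)), tolerance = 1e-8)
  # per-module ordering preserved
  ks <- vapply(fs$ms$modules, `[[`, integer(1), "k")
  expect_equal(af$module_of_factor[seq_len(ks[1])], rep(1L, ks[1]))
  empty <- structure(list(modules = list(), global_factors = list()),
                     class = "module_set")
  expect_error(assemble_factors(empty), "no factors")
})

test_that("module OLS loadings reconstruct the matrix and respect blocks", {
  fs <- make_fitted_set()
  fm <- build_factor_model(fs$x, fs$ms, method = "module_ols")
  expect_lt(max(abs(fs$x - (as.matrix(fm$L %*% fm$F) + fm$E))), 1e-8)
  # loading rows are zero outside the row's own module's factors
  for (j in seq_along(fs$ms$modules)) {
    ids <- fs$ms$modules[[j]]$member_ids
    other_cols <- which(fm$module_of_factor != j)
    expect_equal(max(abs(fm$L[ids, other_cols])), 0)
  }
  # rows in no module keep a zero loading row and a full residual
  orphan <- setdiff(rownames(fs$x),
                    unlist(lapply(fs$ms$modules, `[[`, "member_ids")))
  if (length(orphan)) {
    expect_equal(max(abs(fm$L[orphan[1], ])), 0)
    expect_equal(fm$E[orphan[1], ], unclass(fs$x)[orphan[1], ],
                 tolerance = 1e-12)
  }
})

test_that("OLS equals dot-product loadings for orthonormal unrotated factors", {
  set.seed(8)
  B <- init_basis(30, 3, seed = 8)       # orthonormal factor scores (rows of t(B))
  x <- standardize_rows(matrix(rnorm(10 * 30), 10, 30))
  mof <- rep(1L, 3)
  membership <- list(`1` = rownames(x))
  fit <- fit_loadings_ols(x, t(B), mof, membership)
  expect_equal(as.matrix(fit$L), unname(x %*% B), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a row equal to a factor loads 1 on it with zero residual", {
  set.seed(2)
  F <- t(init_basis(24, 2, seed = 2))
  x <- rbind(F[1, ], standardize_rows(matrix(rnorm(3 * 24), 3, 24)))
  rownames(x) <- paste0("g", 1:4)
  fit <- fit_loadings_ols(x, F, c(1L, 1L), list(`1` = "g1"))
  expect_equal(as.numeric(fit$L["g1", ]), c(1, 0), tolerance = 1e-10)
  expect_lt(max(abs(fit$E["g1", ])), 1e-10)
})

test_that("lasso-BIC matches the best-subset-by-BIC oracle", {
  set.seed(19)
  n <- 100; K <- 5
  F <- t(init_basis(n, K, seed = 19)) * sqrt(n)  # unit-variance-ish factors
  # 30 signal rows (one dominant factor) and 30 pure-noise rows
  y_sig <- t(vapply(1:30, function(i) {
    0.9 * F[1 + (i %% K), ] + rnorm(n, sd = 0.3)
  }, numeric(n)))
  y_noise <- matrix(rnorm(30 * n), 30, n)
  x <- standardize_rows(rbind(y_sig, y_noise))
  Fn <- F / sqrt(rowSums(F^2))
  fit <- fit_loadings_lasso_bic(x, Fn)
  match_cnt <- 0
  for (i in 1:60) {
    active <- which(fit$L[i, ] != 0)
    oracle <- best_subset_bic(unclass(x)[i, ], Fn)
    expect_lte(length(active), length(oracle))
    if (identical(sort(active), sort(oracle))) match_cnt <- match_cnt + 1
  }
  expect_gte(match_cnt / 60, 0.9)
  # signal rows select their dominant factor; noise rows track the oracle,
  # which leaves most (though not all) null rows empty at this n and K
  sig_ok <- vapply(1:30, function(i)
    (1 + (i %% 5)) %in% which(fit$L[i, ] != 0), logical(1))
  expect_gte(mean(sig_ok), 0.95)
  noise_empty <- vapply(31:60, function(i) all(fit$L[i, ] == 0), logical(1))
  oracle_empty <- vapply(31:60, function(i)
    length(best_subset_bic(unclass(x)[i, ], Fn)) == 0, logical(1))
  expect_gte(mean(noise_empty), mean(oracle_empty) - 0.05)
  expect_lt(max(abs(x - (as.matrix(fit$L %*% Fn) + fit$E))), 1e-8)
})

test_that("p-value pruning drops weak refit coefficients", {
  set.seed(29)
  n <- 60
  F <- t(init_basis(n, 3, seed = 29))
  x <- standardize_rows(matrix(rnorm(5 * n, sd = 1), 5, n))
  fit_loose <- fit_loadings_lasso_bic(x, F)
  fit_tight <- fit_loadings_lasso_bic(x, F, p_cutoff = 1e-6)
  expect_lte(Matrix::nnzero(fit_tight$L), Matrix::nnzero(fit_loose$L))
})
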