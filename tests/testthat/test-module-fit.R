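test_that("membership FDR bound matches an independent F-tail oracle", {
  l <- c(0.9, 0.9, 0.1, 0.1)
  res <- membership_fdr(l, k = 1, n = 20, fdr_threshold = 0.01)
  # at l* = 0.9: 4 * S(F*) / 2 where S is the survival function (numeric)
  s_top <- f_survival_numeric(f_statistic(0.9, 1, 20), 1, 18)
  expect_equal(res$curve$fdr[res$curve$length == 0.9], 4 * s_top / 2,
               tolerance = 1e-8)
  expect_equal(res$members, c(1L, 2L))
  expect_equal(res$eta, 0.9)
  # smallest observed length: denominator is all p rows, so the bound is the
  # bare F tail probability -- far above any threshold, never selected
  s_bot <- f_survival_numeric(f_statistic(0.1, 1, 20), 1, 18)
  expect_equal(res$curve$fdr[res$curve$length == 0.1], 4 * s_bot / 4,
               tolerance = 1e-8)
  expect_false(3 %in% res$members)
})

test_that("membership is empty when nothing clears the threshold", {
  res <- membership_fdr(c(0.1, 0.2, 0.15), 1, 30, 0.01)
  expect_identical(res$members, integer(0))
  expect_identical(res$eta, Inf)
})

test_that("membership FDR is conservative on pure null data", {
  # fixed basis, i.i.d. Gaussian unit rows: datasets with any member at
  # threshold 0.01 should be rare
  B <- init_basis(20, 1, seed = 8)
  any_member <- vapply(1:200, function(s) {
    x <- make_unit_rows(200, 20, seed = 1e5 + s)
    length(membership_fdr(projection_lengths(x, B), 1, 20, 0.01)$members) > 0
  }, logical(1))
  expect_lt(mean(any_member), 0.05)
})

test_that("membership is monotone in the FDR threshold", {
  set.seed(15)
  l <- c(runif(50, 0, 0.4), runif(10, 0.7, 0.95))
  m_tight <- membership_fdr(l, 1, 40, 0.001)$members
  m_loose <- membership_fdr(l, 1, 40, 0.05)$members
  expect_true(all(m_tight %in% m_loose))
})

test_that("fit recovers a noiseless one-factor module exactly", {
  sim <- gen_modular_dataset(n_samples = 30, n_modules = 1,
                             genes_per_module = 50, k_min = 1, k_max = 1,
                             n_noise_genes = 50, snr = Inf, seed = 2)
  x <- standardize_rows(sim$matrix)
  fit <- fit_module(x, fit_config(k = 1, seed = 4))
  # oracle: direct SVD of the pure member block
  truth <- svd(unclass(x)[1:50, ])$v[, 1]
  expect_equal(abs(sum(fit$basis[, 1] * truth)), 1, tolerance = 1e-8)
  expect_true(all(fit$lengths[1:50] > 1 - 1e-6))
  expect_true(all(1:50 %in% fit$members))
  expect_true(fit$converged)
})

test_that("noiseless rank-k module rows are fully explained", {
  set.seed(31)
  F <- matrix(rnorm(3 * 25), 3, 25)
  L <- matrix(rnorm(40 * 3), 40, 3)
  x <- standardize_rows(rbind(L %*% F, matrix(rnorm(60 * 25), 60, 25)))
  fit <- fit_module(x, fit_config(k = 3, seed = 1))
  expect_true(all(fit$lengths[1:40] > 1 - 1e-6))
})

test_that("linear-weight objective trace is non-decreasing", {
  for (s in 1:5) {
    x <- standardize_rows(rank1_module_matrix(30, 40, 20, seed = 60 + s) +
                          matrix(rnorm(70 * 20, sd = 0.2), 70, 20))
    fit <- suppressWarnings(
      fit_module(x, fit_config(k = 2, weight = weight_config("linear"),
                               seed = s)))
    expect_true(all(diff(fit$objective_trace) >= -1e-9))
  }
})

test_that("fits are deterministic under a fixed seed", {
  x <- standardize_rows(rank1_module_matrix(20, 20, 15, seed = 5) +
                        matrix(rnorm(40 * 15, sd = 0.3), 40, 15))
  f1 <- fit_module(x, fit_config(k = 1, seed = 123))
  f2 <- fit_module(x, fit_config(k = 1, seed = 123))
  expect_identical(f1$basis, f2$basis)
  expect_identical(f1$members, f2$members)
})

test_that("oblique rotation recovers perfect simple structure", {
  set.seed(9)
  B <- init_basis(20, 3, seed = 9)
  # members loading on exactly one factor each
  A <- rbind(matrix(c(1, 0, 0), 30, 3, byrow = TRUE) * runif(30, 0.5, 1),
             matrix(c(0, 1, 0), 30, 3, byrow = TRUE) * runif(30, 0.5, 1),
             matrix(c(0, 0, 1), 30, 3, byrow = TRUE) * runif(30, 0.5, 1))
  rot <- oblique_rotate(B, A)
  expect_true(rot$rotated)
  # rotated factors match originals up to permutation and sign
  cc <- abs(stats::cor(t(rot$factors), B))
  expect_equal(sort(apply(cc, 1, max)), rep(1, 3), tolerance = 1e-3)
  expect_true(all(apply(cc > 0.999, 2, sum) == 1))
  # span is unchanged: each rotated factor is fully explained by the basis
  for (j in 1:3) {
    r2 <- sum(crossprod(B, rot$factors[j, ])^2) / sum(rot$factors[j, ]^2)
    expect_equal(r2, 1, tolerance = 1e-10)
  }
})

test_that("rotation is skipped with a warning when members are too few", {
  B <- init_basis(10, 2, seed = 1)
  expect_warning(rot <- oblique_rotate(B, B[1, , drop = FALSE] * 0 + 0.5),
                 "skipping")
  expect_identical(rot$rotation, diag(2))
  expect_error(oblique_rotate(B[, 1, drop = FALSE], NULL), "k >= 2")
})
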