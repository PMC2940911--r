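test_that("residual normalization restores range and stays orthogonal", {
  set.seed(301)
  B <- init_basis(12, 2, seed = 3)
  eta <- 0.6
  # a row with projection length exactly eta
  inplane <- (B[, 1] + B[, 2]) / sqrt(2)
  perp <- rnorm(12); perp <- perp - B %*% crossprod(B, perp)
  perp <- perp / sqrt(sum(perp^2))
  row_eta <- eta * inplane + sqrt(1 - eta^2) * perp
  # a row fully inside the span
  row_in <- as.vector(B[, 1])
  res <- residual_normalize(rbind(t(row_eta), t(row_in)), B, eta)
  expect_equal(sqrt(sum(res[1, ]^2)), 1, tolerance = 1e-10)
  expect_equal(sqrt(sum(res[2, ]^2)), 0, tolerance = 1e-10)
  expect_lt(max(abs(res %*% B)), 1e-10)
  expect_error(residual_normalize(t(row_in), B, 1), "eta")
})

test_that("adjusted hypergeometric test equals exhaustive enumeration", {
  # lambda = 0, tiny instances: exact tail by enumeration over all draws
  expect_equal(adjusted_hypergeometric_test(5, 4, 3, 10, 0),
               55 / 210, tolerance = 1e-12)
  for (case in list(c(10, 4, 6, 2), c(12, 6, 5, 3), c(9, 3, 3, 1))) {
    p <- case[1]; m1 <- case[2]; m2 <- case[3]; r <- case[4]
    expect_equal(adjusted_hypergeometric_test(m1, m2, r, p, 0),
                 hyper_tail_enum(p, m1, m2, r), tolerance = 1e-12)
  }
  expect_equal(adjusted_hypergeometric_test(5, 4, 0, 10, 0), 1)
})

test_that("overlap p-value is non-increasing in the overlap", {
  pv <- vapply(0:4, function(r)
    adjusted_hypergeometric_test(6, 4, r, 30, 0.01), numeric(1))
  expect_true(all(diff(pv) <= 1e-12))
  # overlap fully eroded by the adjustment: no evidence, p-value 1
  expect_equal(adjusted_hypergeometric_test(1, 1, 1, 10, 0.9), 1)
})

test_that("forward selection finds the true dimension of a 2-factor module", {
  set.seed(10)
  sim <- gen_modular_dataset(n_samples = 50, n_modules = 1,
                             genes_per_module = 80, k_min = 2, k_max = 2,
                             n_noise_genes = 150, snr = Inf, seed = 17)
  x <- standardize_rows(sim$matrix)
  m <- grow_module(x, fit_config(seed = 1), growth_config(), seed = 1)
  expect_s3_class(m, "module_fit")
  expect_equal(m$k, 2)
  # both true factors recovered: regress truth on the rotated factors
  for (t in 1:2) {
    r2 <- summary(lm(sim$truth$true_factors[t, ] ~ t(m$factors)))$r.squared
    expect_gte(r2, 0.99)
  }
  # oracle: fitted subspace equals the SVD of the pure member block
  sv <- svd(x[1:80, ])$v[, 1:2]
  expect_equal(sum(crossprod(sv, m$basis)^2), 2, tolerance = 1e-6)
})

test_that("a factor loading on most rows is flagged global", {
  set.seed(12)
  f <- gen_factor(40, "gaussian")
  L <- runif(160, 0.5, 1) * sample(c(-1, 1), 160, TRUE)
  x <- rbind(outer(L, f) + matrix(rnorm(160 * 40, sd = 0.2), 160, 40),
             matrix(rnorm(40 * 40), 40, 40))
  x <- standardize_rows(x)
  m <- grow_module(x, fit_config(seed = 2),
                   growth_config(global_fraction = 0.5), seed = 2)
  expect_s3_class(m, "global_factor")
  expect_gt(length(m$members) / nrow(x), 0.5)
})

test_that("pure-noise matrices rarely yield a sizeable module", {
  sizes <- vapply(1:50, function(s) {
    x <- make_unit_rows(200, 20, seed = 7000 + s)
    m <- suppressWarnings(grow_module(x, fit_config(seed = s),
                                      growth_config(), seed = s))
    length(m$members)
  }, numeric(1))
  expect_gte(mean(sizes < 10), 0.95)
})

test_that("appended factors keep the basis orthonormal and significant", {
  set.seed(22)
  sim <- gen_modular_dataset(n_samples = 60, n_modules = 1,
                             genes_per_module = 100, k_min = 3, k_max = 3,
                             n_noise_genes = 200, snr = 2, seed = 23)
  x <- standardize_rows(sim$matrix)
  m <- grow_module(x, fit_config(seed = 3), growth_config(), seed = 3)
  expect_true(all(abs(crossprod(m$basis) - diag(m$k)) < 1e-8))
  expect_lte(m$k, growth_config()$max_k)
  if (m$k > 1) expect_true(all(m$overlap_pvalues < growth_config()$overlap_alpha))
})
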