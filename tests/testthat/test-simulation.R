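test_that("signal generators produce the four waveform families", {
  set.seed(6)
  sq <- gen_factor(100, "square", tau = 25, phase = 3, standardize = FALSE)
  expect_lte(length(unique(sq)), 2)
  # sine with tau = n and zero phase completes exactly one cycle
  sn <- gen_factor(50, "sine", tau = 50, phase = 0, standardize = FALSE)
  expect_equal(sum(diff(sn > 0) != 0), 1)  # one sign change inside the window
  expect_equal(sn[50], sin(2 * pi), tolerance = 1e-12)
  # sawtooth is periodic with integer tau
  sw <- gen_factor(80, "sawtooth", tau = 20, phase = 7, standardize = FALSE)
  expect_equal(sw[1:60], sw[21:80], tolerance = 1e-12)
  # standardized output: mean 0, sd 1
  g <- gen_factor(200, "gaussian")
  expect_equal(mean(g), 0, tolerance = 1e-12)
  expect_equal(sd(g), 1, tolerance = 1e-12)
})

test_that("loading rows partition the unit interval", {
  set.seed(13)
  expect_equal(gen_loading_row(1), 1)
  for (m in c(2, 5, 9)) expect_equal(sum(gen_loading_row(m)), 1,
                                     tolerance = 1e-12)
  # m = 2: first spacing is uniform on [0, 1]
  first <- vapply(1:2000, function(i) gen_loading_row(2)[1], numeric(1))
  expect_gt(ks.test(first, "punif")$p.value, 0.01)
})

test_that("modular generator matches its declared structure", {
  sim <- gen_modular_dataset(n_samples = 60, n_modules = 4,
                             genes_per_module = 50, nonzero_fraction = 1,
                             n_noise_genes = 30, snr = 1, seed = 14)
  expect_equal(dim(sim$matrix), c(4 * 50 + 30, 60))
  expect_equal(sum(sim$truth$gene_module > 0), 200)
  # dense within-module loadings when nonzero_fraction = 1
  for (g in which(sim$truth$gene_module == 1))
    expect_true(all(sim$truth$true_loadings[
      g, sim$truth$group_of_factor == 1] != 0))
  # reproducibility
  sim2 <- gen_modular_dataset(n_samples = 60, n_modules = 4,
                              genes_per_module = 50, nonzero_fraction = 1,
                              n_noise_genes = 30, snr = 1, seed = 14)
  expect_identical(sim$matrix, sim2$matrix)
})

test_that("snr = 1 gives noise variance comparable to signal variance", {
  sim <- gen_modular_dataset(n_samples = 100, n_modules = 5,
                             genes_per_module = 60, n_noise_genes = 0,
                             snr = 1, seed = 26)
  clean <- sim$truth$true_loadings %*% sim$truth$true_factors
  noise <- sim$matrix - clean
  ratio <- apply(clean, 1, var) / apply(noise, 1, var)
  # per-gene ratios scatter around 1
  expect_equal(median(ratio), 1, tolerance = 0.15)
})

test_that("global sparse generator hits the target factors per gene", {
  sim <- gen_global_sparse_dataset(n_genes = 2000, n_factors = 20,
                                   mean_factors_per_gene = 5,
                                   n_noise_genes = 0, seed = 31)
  nnz_per_gene <- rowSums(sim$truth$true_loadings != 0)
  expect_equal(mean(nnz_per_gene), 5, tolerance = 0.25)
  expect_equal(sim$truth$group_of_factor, 1:20)
  # dense when every factor governs every gene
  sim_d <- gen_global_sparse_dataset(n_genes = 50, n_factors = 4,
                                     mean_factors_per_gene = 4,
                                     n_noise_genes = 0, seed = 32)
  expect_true(all(sim_d$truth$true_loadings[1:50, ] != 0))
})

test_that("recovery evaluation scores perfect and permuted answers as 1", {
  sim <- gen_modular_dataset(n_samples = 40, n_modules = 3,
                             genes_per_module = 30, n_noise_genes = 10,
                             seed = 44)
  tf <- sim$truth$true_factors
  rep1 <- evaluate_recovery(tf, sim$truth)
  expect_equal(rep1$r2_per_true_factor, rep(1, nrow(tf)), tolerance = 1e-8)
  expect_equal(rep1$recovered_fraction, 1)
  perm <- sample(nrow(tf))
  flip <- diag(sample(c(-1, 1), nrow(tf), TRUE))
  rep2 <- evaluate_recovery(flip %*% tf[perm, ], sim$truth)
  expect_equal(rep2$r2_per_true_factor, rep(1, nrow(tf)), tolerance = 1e-8)
})

test_that("random identified factors score near the known null R^2", {
  # truth: groups of size 1; q identified Gaussians assigned per group.
  # E[R^2] for one spurious regressor is 1/(n-1); most groups attract 0 or 1.
  set.seed(50)
  n <- 100
  truth <- structure(list(
    true_factors = t(vapply(1:10, function(i) rnorm(n), numeric(n))),
    group_of_factor = 1:10,
    true_loadings = diag(10), gene_module = 1:10), class = "sim_truth")
  reps <- replicate(30, {
    ident <- matrix(rnorm(10 * n), 10, n)
    r <- evaluate_recovery(ident, truth)
    c(mean(r$r2_per_true_factor), r$recovered_fraction)
  })
  # selection (arg-max group assignment) inflates the plain q/(n-1) null
  # mean somewhat, but recovery stays far below the 0.49 threshold
  expect_lt(mean(reps[1, ]), 0.1)
  expect_lt(mean(reps[2, ]), 0.02)
  expect_equal(evaluate_recovery(NULL, truth)$recovered_fraction, 0)
})
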