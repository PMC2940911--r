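# Shared fixture builders and independent oracles. Everything is generated in
# code; no data files.

# p unit-norm rows of i.i.d. Gaussian noise (the projection-length null)
make_unit_rows <- function(p, n, seed = NULL) {
  mlsa:::with_seed(seed, standardize_rows(matrix(rnorm(p * n), p, n)))
}

# Noiseless single-module matrix: n_mem rows lying exactly on a hidden unit
# factor (random signs/none), plus n_other unit rows orthogonal to it.
rank1_module_matrix <- function(n_mem = 50, n_other = 50, n = 30, seed = 1) {
  mlsa:::with_seed(seed, {
    f <- rnorm(n); f <- f / sqrt(sum(f^2))
    members <- outer(sample(c(-1, 1), n_mem, TRUE), f)
    others <- matrix(rnorm(n_other * n), n_other, n)
    others <- others - (others %*% f) %*% t(f)
    others <- others / sqrt(rowSums(others^2))
    rbind(members, others)
  })
}

# Exhaustive hypergeometric upper tail P(|draw of size m2 overlaps fixed set
# of size m1| >= r) by enumerating all C(p, m2) draws. Only for tiny p.
hyper_tail_enum <- function(p, m1, m2, r) {
  draws <- utils::combn(p, m2)
  hits <- colSums(draws <= m1)  # fixed set = {1..m1}
  mean(hits >= r)
}

# Numerical inversion of the F CDF (independent of qf): smallest x with
# P(F <= x) = q, by uniroot on pf.
f_quantile_numeric <- function(q, df1, df2) {
  stats::uniroot(function(x) stats::pf(x, df1, df2) - q,
                 lower = 0, upper = 1e6, tol = 1e-12)$root
}

# Numerical F survival function by integrating the density (independent of pf)
f_survival_numeric <- function(x, df1, df2) {
  stats::integrate(function(t) stats::df(t, df1, df2), lower = x,
                   upper = Inf, rel.tol = 1e-10)$value
}

# Best-subset-by-BIC oracle over all 2^K factor subsets (no-intercept fits)
best_subset_bic <- function(y, F) {
  n <- length(y); K <- nrow(F)
  best <- list(bic = n * log(max(sum(y^2), 1e-12) / n), set = integer(0))
  for (sz in 1:K) {
    combs <- utils::combn(K, sz)
    for (j in seq_len(ncol(combs))) {
      a <- combs[, j]
      D <- t(F[a, , drop = FALSE])
      rss <- sum(qr.resid(qr(D), y)^2)
      bic <- n * log(max(rss, 1e-12) / n) + sz * log(n)
      if (bic < best$bic) best <- list(bic = bic, set = a)
    }
  }
  best$set
}
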