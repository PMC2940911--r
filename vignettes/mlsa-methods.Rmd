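---
title: "Modular latent structure analysis: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular latent structure analysis: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsa)
```

## The problem and the model

An expression matrix G (p genes × n conditions) generated by a modular
regulatory system has a sparse, block-structured loading matrix: each latent
factor (e.g. a transcription-factor activity profile) influences a subset of
genes, and the genes of a module respond to linear combinations of their
module's factors. The analysis goal is a collection of orthonormal bases
B (n × k), each spanning a subspace of *condition space* that explains a
subset of rows very well, plus the factor scores and loadings that assemble
into G = L F + E.

After every row is scaled to unit norm, the projection length
l = ‖B'g‖ satisfies l² = fraction of the row's variation explained by the
subspace. For a row independent of a fixed k-dimensional subspace,
F = (l²/k)·((n−k−1)/(1−l²)) follows F(k, n−k−1); this single null
distribution drives the weight placement, the membership rule, and the
association tests throughout the package. The null is exact for the
least-squares geometry (centered rows on an (n−1)-sphere) and accurate to
O(1/n) for unit-normalized uncentered rows; the calibration test in the
suite confirms a Kolmogorov–Smirnov pass at n = 100 with 5000 null rows.

## Fitting one module (fixed k)

Membership is latent, so fitting alternates in EM style:

1. projection lengths on the current basis;
2. membership weights w = h(l);
3. weighted SVD: rescale row i by wᵢ and take the top-k right singular
   vectors as the new basis.

Two weight functions are provided. The *sigmoid* weight
w = 1 − 1/(1 + e^{φ(l−δ)}) approximates a membership indicator; its
inflection δ is placed where the null F statistic crosses the upper-α
quantile (`delta_cutoff()`), so non-member rows contribute almost nothing.
The *linear* weight w = l needs no cutoff and makes the objective
Σ(wᵢlᵢ)² provably non-decreasing across iterations (the weighted SVD step
cannot decrease it, and neither can re-weighting, since their difference is
a sum of squares); the suite asserts this trace property on every linear
fit. The sigmoid carries no such guarantee but converged in all our
simulations, typically in fewer iterations.

Convergence is declared when k − ΣR² between consecutive bases falls below
`tol` (default 1e-6; the measure is 0 exactly when the *span* is unchanged,
so rotations within the span do not delay termination), with `max_iter`
= 200 as a cap — non-convergence returns a flagged fit with a warning, not
an error.

Parameters that matter, with defaults:

* `phi = 50` (sigmoid steepness, dimensionless): large enough to act as a
  near-step function; beyond this the shape barely changes.
* `alpha = 0.001` (upper-tail level for δ): stringent because p rows are
  implicitly tested; a loose level lets unrelated rows tilt the basis
  toward global structure.
* annealing `anneal_start_frac = 0.1`, `anneal_rate = 1.25`: the effective
  φ starts at φ/10 and grows 25% per iteration to φ. Starting soft keeps
  early weights nearly uniform — the first step is then close to a plain
  SVD, centering the search on dominant structure before the weight
  hardens. The growth rate is a compromise between search breadth and
  iteration count; the qualitative behaviour is insensitive to it.
* `fdr_threshold = 0.01` for membership: conservative by construction,
  because the bound uses all p rows in place of the unknown null count.
* `n_starts = 1`: discovery uses a single seeded start per round, matching
  the view that missed local optima can be found in later rounds; restarts
  are available and keep the fit with most members.

Numerical conventions: projection lengths are clipped to [0, 1] to absorb
floating-point overshoot (the F statistic needs l < 1, and l = 1 rows are
handled by evaluating the F tail at 1 − 1e-12); the SVD sign ambiguity is
fixed by orienting each singular vector so the largest-magnitude entry of
its loading vector is positive; random initial bases are QR-orthonormalized
Gaussian vectors with column signs re-randomized (QR fixes signs
systematically, which would bias the initial direction).

## Membership and rotation

For every observed length l\*, FDR(l\*) = p·P(F ≥ F\*)/#{lᵢ ≥ l\*}; the
cutoff η is the smallest observed length whose bound is below the
threshold, and ties at η are included (closed threshold). If nothing
qualifies, the member set is empty and η = +∞.

For k ≥ 2 the basis is rotated toward simple structure with promax
(power 4, `stats::promax`; an oblimin-style power-2 variant is available
behind a flag), computed only from member-row loadings. Oblique rotation is
appropriate because real regulatory inputs can correlate; the span — and
hence every projection length — is unchanged. Rotated factor score vectors
are rescaled to unit norm, with scale absorbed into the loading
regressions, so that factor rows remain comparable across modules. With
fewer member rows than factors the rotation is skipped with a warning.

## Forward selection of the module dimension

Starting from k = 1, member rows are residualized against the current basis
and rescaled by 1/√(1−η²) — restoring residual norms to [0, 1] because no
prior assumption is made about the relative strength of factors not yet
found. A one-dimensional fit on those residuals proposes a direction β′;
the rows associated with β′ (same FDR machinery, over all rows) are
compared with the current member set by a hypergeometric overlap test whose
counts are first deflated for FDR contamination: m′ = ⌈m(1−λ)⌉ for each set
and r′ = ⌊r(1−λ)²⌋ for the overlap. Significant overlap appends β′
(re-orthonormalized against the basis — the F null requires a unit
direction, and orthogonalization prevents double-counting explained
variance); otherwise growth stops and the basis is rotated.

Two safeguards reflect genuinely open design territory:

* **Minimum factor support** (`min_factor_genes = 10`). A direction fitted
  on ~100 member residuals can overfit a handful of the rows it was fitted
  on; those few rows then overlap the member set "significantly" although
  the direction carries no structure (in noise experiments this admits a
  spurious factor about half the time). A factor associated with fewer
  rows than a minimal module (10 genes, the same scale as the discovery
  stopping rule) is therefore treated as no evidence. With this gate,
  noiseless data still selects the exact true dimension, while noise
  residuals stop growth reliably.
* `max_k = 10` caps runaway growth on pathological inputs; `overlap_alpha
  = 0.01` is the overlap significance level.

A first factor associated with more than `global_fraction` (default 0.5)
of all rows is reported as a *global factor*, kept outside the module list.
The effective sample dimension in the F reference stays at n throughout,
including in residual space; the alternative n−k is slightly more
conservative but the difference is O(k/n) and the same machinery is applied
at every stage.

## Discovering a series of modules

Rounds of forward selection alternate with deflation. `remove` drops member
rows (member sets of distinct modules are then disjoint; bases may be
weakly correlated). `residual` replaces every row by its component
orthogonal to the found basis and renormalizes, making successive bases
exactly orthogonal — recommended when factors influence many rows. Rows
whose residual norm falls below `residual_floor = 0.1` are dropped rather
than renormalized: renormalizing a nearly-explained row would amplify
numerical noise into an apparent unit-norm signal. Global factors are
deflated by residual in both modes (there is no member set to remove whose
removal would eliminate a global signal). Discovery stops when a new module
has fewer than `min_module_genes = 10` members — deliberately small, so
that weak late modules are surfaced and left to the analyst to filter by
size — or when `max_modules` (50) or an optional total-factor cap
`max_factors` is reached. Per-round seeds derive from one master seed by a
counter, so the whole analysis is reproducible bit for bit.

## The overall factor model

All rotated factor score vectors are stacked into F (K × n). Loadings are
filled either by per-row OLS on the row's own module factors (regression is
needed because rotated factors are oblique; rows outside every module get
zero loadings; near-singular designs fall back to a 1e-8 ridge), or by
lasso over all K factors with BIC selection: BIC = n·log(RSS/n) +
df·log(n) with df = active-set size, evaluated on OLS refits of each active
set along the glmnet path, the no-intercept null model included. An
optional p-value prune (e.g. 1e-3) applied *after* BIC selection drops
refit coefficients with weak t statistics — sequential rather than joint,
as the simplest defensible composition of the two rules. Either way
G = L·F + E holds identically by construction.

## The simulation framework

The generators emulate a modular (or globally sparse) linear latent system:

* factor score vectors of four types — Gaussian, sine, square, sawtooth —
  with period τ ~ U[20, 40] (drawn as a real number) and phase ~ U[0, τ];
  each vector is centered and scaled to unit variance so that loading
  magnitudes alone carry relative regulation strength;
* per-gene loadings from a random partition of [0, 1] (spacings of m − 1
  uniforms), so |loadings| sum to 1; a uniformly random half of each
  module's nonzero loading cells (rounded down) is negated;
* Bernoulli within-module sparsity with every gene forced to keep at least
  one factor (a redraw, since each simulated gene must have a controlling
  factor);
* appended pure-noise genes, i.i.d. standard normal;
* per-gene Gaussian noise scaled so var(signal)/var(noise) equals the SNR
  (at SNR 1 the two variances match); `snr = Inf` yields noiseless
  matrices for exact-recovery oracles.

Defaults follow the documented study conditions: modular — 100 samples, 10
modules × 100 genes, 1–3 factors per module, 1000 noise genes; global —
2000 genes, 20 factors, 500 noise genes, average 5 factors per gene. With
mixed-type factors about 10% of absolute pairwise factor correlations
exceed 0.5 (median of those ≈ 0.66) purely because of the waveform
families; correlated factors occupy overlapping subspaces that no
projection method can separate, which is the known reason mixed-type
recovery sits far below the Gaussian case.

Recovery is scored by a two-step protocol: each identified factor is
assigned to the true factor group with the largest multiple R², the best
K_true identified factors are retained, and each true factor is regressed
on the identified factors assigned to its group; R² ≥ 0.49 (multiple
correlation ≥ 0.7) counts as recovered. What passing these simulations
does *not* show about real data: real expression has heteroscedastic,
correlated noise, non-linear responses, overlapping module membership and
batch structure, none of which the generators emulate; the simulations
validate the estimation machinery under its own model class, no more.

## Problem sizes used in the checked results

The packaged acceptance run pools 4 replicates per SNR ∈ {0.5, 1, 2} for
each modular setting and 8 replicates (SNR cycling) for each global
setting, with 300 replicate pools of 20 factors for the correlation
structure — sizes chosen so a complete run finishes in minutes on one CPU
while keeping Monte-Carlo error on pooled fractions to a few percentage
points. The test suite uses smaller replicate counts of the same settings
under fixed seeds.

## Known limitations

* No guarantee of a global optimum in any round; missed optima are
  expected to resurface in later rounds, and residual mode makes rounds
  orthogonal by construction.
* Highly correlated hidden factors are merged, not separated.
* Membership FDR is a conservative bound, not an exact rate.
* The choice between removal and residual deflation is left to the
  analyst (removal preserves weak cross-module correlation; residual
  enforces orthogonality).
* No missing-value handling or annotation mapping; inputs must be
  complete numeric matrices.
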