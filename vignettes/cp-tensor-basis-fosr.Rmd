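---
title: "A CP tensor basis for Bayesian function-on-scalar regression of brain maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A CP tensor basis for Bayesian function-on-scalar regression of brain maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A group-level task-fMRI analysis asks which voxels of the brain are, on
average across subjects, differentially active under a task contrast (say,
2-back vs 0-back working memory), and whether that activation varies with
subject covariates such as sex. Each subject contributes one 3D contrast
volume; stacking `N` subjects gives a 4D tensor
`Y` of size `p1 x p2 x p3 x N`. The naive voxelwise regression of its mode-4
unfolding `Y (N x Nv)` on a covariate matrix `Z (N x p)`,

    Y = Z gamma + E,

is both statistically weak (hundreds of thousands of separate regressions,
massive multiplicity) and ignores spatial structure. `cpfosr` instead uses a
rank-`R` canonical polyadic (CP) decomposition of the tensor,

    Y ~ [[ lambda; A1, A2, A3, G ]],   Y = G L + eps,
    L = Lambda (A3 (x) A2 (x) A1)^T    (R x Nv, (x) = Khatri-Rao),

as a data-driven *spatial basis*. The three spatial factor matrices capture
structure common to all subjects; the subject factor `G (N x R)` carries what
is subject-specific. With `P = L^+` (Moore-Penrose pseudoinverse), each
subject's map is reduced from `Nv` voxels to `R` basis scores, and the
regression is carried out entirely in the basis space:

    G = Z gamma* + E*,   rows of E* iid N_R(0, Sigma_eps).

Because the columns of `G` are correlated by construction, `Sigma_eps` is a
full `R x R` covariance. Voxel-space coefficient maps are recovered as
`gamma = gamma* L`.

## Conjugate posterior

With the Matrix-Normal/Inverse-Wishart prior
`gamma* ~ MN(g0, L0^-1, Sigma_eps)`, `Sigma_eps ~ W^-1(V0, nu0)`, the
posterior factorizes in closed form:

    Ln  = Z'Z + L0
    gn  = Ln^-1 (Z'G + L0 g0)
    nun = nu0 + N
    Vn  = V0 + (G - Z gn)'(G - Z gn) + (gn - g0)' L0 (gn - g0)

`draw_posterior()` samples `Sigma_eps ~ W^-1(Vn, nun)` then
`gamma* | Sigma_eps ~ MN(gn, Ln^-1, Sigma_eps)`. Both blocks are the exact
marginal and conditional, so the draws are i.i.d. — there is no Markov chain
to converge. Burn-in and thinning arguments exist for interface parity with
MCMC-style workflows and default to 0 and 1. This is what makes the method
fast: the expensive object (the voxel grid) appears only in the two linear
maps `P` (projection) and `L` (back-projection).

## Simultaneous band scores

For a contrast `c` (length `p`), each draw yields a voxel map
`C^(m)(v) = c' gamma*^(m) L[, v]`. With `c_hat` the posterior mean map and
`c_sd` the voxelwise posterior sd (sample sd over draws, denominator `M - 1`),
the max statistics

    z^(m) = max_v | C^(m)(v) - c_hat(v) | / c_sd(v)

give a joint 100(1-alpha)% credible band
`I_alpha(v) = c_hat(v) +/- q_(1-alpha) c_sd(v)` with
`q_(1-alpha) = z_(ceil((1-alpha) M))`, the ascending order statistic. The
simultaneous band score

    P_SimBaS(v) = (1/M) #{ m : |c_hat(v)| / c_sd(v) <= z^(m) }

is the smallest alpha at which the band at `v` excludes zero; it controls the
experimentwise error rate across the whole volume. With the order-statistic
convention above the two views coincide *exactly* on the `1/M` alpha grid
(`P_SimBaS(v) <= alpha` iff `0` is outside `I_alpha(v)`), which the test
suite asserts for every voxel and every grid alpha. Voxels whose posterior sd
is zero cannot be standardized; they are excluded from the max, reported, and
assigned `P_SimBaS = 1` so they can never be flagged.

Significant voxels (`P_SimBaS < alpha`, default `alpha = 0.01`) are grouped
into connected components (default 26-neighbor connectivity, the usual choice
for volumetric fMRI cluster reporting; 6 and 18 are available) and components
smaller than `min_size` voxels (default 125, i.e. a 5 mm cube at 1 mm
isotropic resolution) are dropped.

## Rank selection

`cv_rank()` selects `R` by K-fold cross-validation over subjects (default
10 folds): CP factors and the posterior mean `gn` are estimated on training
subjects only, held-out scores are predicted as `Z_test gn`, held-out volumes
are reconstructed through the training basis, and the per-fold Frobenius
errors are averaged (the norm-of-stacked-residuals alternative is available
via `aggregate = "norm_of_mean"`). Ties are broken toward the smaller rank.
The training-set weights `lambda` are used verbatim in the reconstruction;
they are not refit on test data. CV uses the closed-form posterior mean, so
it is deterministic given the fold seed.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rank` (R) | chosen by CV | number of CP components / basis size |
| `M` | 2000 | posterior draws; i.i.d., so moderate M suffices (grid resolution of `P_SimBaS` is 1/M) |
| `alpha` | 0.01 | flagging level on `P_SimBaS` |
| `min_size` | 125 voxels | cluster extent threshold |
| `connectivity` | 26 | 3D neighborhood for clustering |
| `tol` | 1e-8 | ALS relative-fit-change stopping rule |
| `max_iter` | 500 | ALS sweep cap |
| `n_restarts` | 3 | ALS initializations (1 SVD-based + random) |
| `g0, L0, V0, nu0` | 0, 1e-6 I, I, R+2 | prior; weakly informative at the scale of typical contrast maps |

## Numerical choices

* **Conventions.** Unfolding puts the chosen mode along *columns*, remaining
  modes linearized with the first varying fastest; the Khatri-Rao order
  `A3 (x) A2 (x) A1` makes `L`'s voxel linearization identical to the mode-4
  unfolding's row order (plain column-major order of the grid). `L` is
  `R x Nv` and `P` is `Nv x R`, so `Y (N x Nv) = G L + eps` is conformable.
  Every map written to disk is re-folded with the same convention.
* **ALS.** Initialization from truncated SVDs of the unfoldings plus seeded
  random restarts; per-mode normal equations solved via Cholesky with a tiny
  ridge fallback; factor columns kept unit-norm with magnitudes in `lambda`
  (all nonnegative, sorted decreasing). Convergence is declared when the
  relative fit change drops below `tol`; non-convergence is recorded in the
  result (`converged`, `n_iter`), not raised.
* **Sampling.** `stats::rWishart` on `Vn^-1` provides Wishart draws whose
  inverses are the Inverse-Wishart draws; Cholesky factors get a `1e-10`
  diagonal jitter retry on near-singular input, and failures beyond that are
  raised rather than silently regularized.
* **Quantile index.** `ceil((1-alpha) M)` is computed with a guard against
  floating-point creep when `(1-alpha) M` is integral, so band inversion and
  the SimBaS count agree exactly.
* **Memory.** Back-projection streams over voxel chunks (`chunk_size`,
  default 4096), so the `M x Nv` draw-by-voxel matrix is never materialized;
  chunked and unchunked paths agree to 1e-12 in the tests.
* **Degenerate input.** All-zero voxels are retained in the CP fit (they
  yield zero basis columns) and counted; all-identical draws trigger a
  degenerate-inference flag instead of division by zero.

## The synthetic-data generator

`gen_multisubject()` emulates exactly the structure the model assumes:
unit-norm spatial components that are outer products of 1D Gaussian bumps
with distinct peak locations (guaranteeing exact CP rank while mimicking
focal activation blobs), linearly decreasing weights, a design with
intercept + binary `sex` (+ standardized continuous covariates), subject
scores `G = Z gamma*_true + E*`, and i.i.d. Gaussian voxel noise. SNR is
defined as `||Z gamma* L||_F / ||noise||_F`; `snr = 5` calibrates the voxel
noise to that ratio in expectation. Defaults (30x30x30 grid, N = 50,
R_true = 4, `sigma_subject = 0.2`, SNR 5) are the simulation conditions used
throughout the acceptance checks.

What the generator does *not* emulate: spatially autocorrelated or
physiological noise, drift, inter-subject misregistration, non-Gaussian
errors, or signal that is not exactly low-rank. Passing tests therefore
demonstrate correctness of the algorithmic chain and calibration under the
model's own assumptions, not robustness to real-data violations of them.

## Simulation sizes and a prior-sensitivity note

The package's own verification suite uses: exact-recovery fixtures at
20x20x20x15 (noiseless, rank 3); end-to-end recovery at 30x30x30x50
(R_true = 4, SNR 5), where the intercept map correlates with truth above
0.95 and a true-zero sex effect produces no clusters at `alpha = 0.01`,
`min_size = 125` in at least 19 of 20 replicates; rank-CV recovery at
12x12x12x60 (grid {2,3,4,5,6,8}, 5 folds, 8+/10 replicates select 4); and a
200-replicate null coverage study at 8x8x8x30 with `M = 500`.

The coverage study checks that the 95% joint band excludes zero *somewhere*
in about 5% of null replicates. This Bayes-frequentist agreement only holds
when the prior is vague relative to the likelihood. At this simulation's
scale the score-space residual sum of squares is about 0.04, so the default
`V0 = I` — weakly informative for real contrast maps — dominates `Vn` and
inflates the band by a factor of several, driving the exclusion rate to 0.
The coverage study therefore uses `V0 = 1e-6 I` (scale sent to zero, default
degrees of freedom), isolating the band construction itself; the observed
rate is ~7.5%, slightly above nominal, which is expected since the basis is
estimated from the same data and `nu0 = R + 2` mildly shrinks `Sigma_eps`.
Practical advice follows: match `V0`'s scale to the data (e.g. a small
multiple of the identity on standardized scores) when the absolute scale of
the maps is small.

## Design choices where the design was open

* The subject-level engine is a plain per-voxel OLS GLM with a canonical
  double-gamma HRF (`build_design()`, `fit_glm_contrast()`), with i.i.d.
  errors — no prewhitening, drift or motion terms. It exists to produce
  contrast volumes for the multi-subject stage; any external subject-level
  estimator can be substituted by supplying its contrast maps directly.
* Cross-validation aggregates per-fold Frobenius norms by averaging —
  standard CV practice and robust to fold-size imbalance.
* Cluster labeling builds neighbor-offset edge lists and lets
  `igraph::components` do the union; an independent flood-fill oracle checks
  it in the tests.
* Masking is optional; with a mask only in-mask voxels enter `L`, `P` and
  all inference. The default is the full grid.

## Limitations

* The CP basis applies to volumetric (gridded) data only; surface-based
  (CIFTI/GIFTI) geometries would reduce to one long spatial dimension, where
  a CP basis loses its advantage over generic bases.
* Rank selection by CV refits CP many times; for large grids use a coarse
  rank grid and/or 5 folds.
* The basis is estimated from the same data that are then projected onto it;
  uncertainty in `L` is not propagated, which can make inference slightly
  anti-conservative (visible in the coverage study above).
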