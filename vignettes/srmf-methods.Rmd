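---
title: "Methods: similarity-regularized factorization of drug-response matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-regularized factorization of drug-response matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmf)
```

## The model and its assumptions

A drug-response panel is an $m \times n$ matrix $Y$ (drugs by cell
lines) of log-IC50 or activity-area values, observed only where the
binary mask $W$ is 1. The package completes $Y$ by representing drug
$i$ and cell line $j$ as latent row vectors $u_i, v_j \in \mathbb{R}^K$
and minimizing

$$
\min_{U,V}\;
\lVert W \circ (Y - UV^\top)\rVert_F^2
+ \lambda_l\left(\lVert U\rVert_F^2 + \lVert V\rVert_F^2\right)
+ \lambda_d \lVert S_d - UU^\top\rVert_F^2
+ \lambda_c \lVert S_c - VV^\top\rVert_F^2 .
$$

The first term is a weighted low-rank approximation: only assayed pairs
contribute. The similarity terms encode the two modelling assumptions —
structurally similar drugs (Jaccard coefficient of fingerprint bit
sets, in $[0,1]$) and transcriptionally similar cell lines (Pearson
correlation of expression profiles, in $[-1,1]$) should have similar
latent representations, in the specific sense that latent inner
products approximate the precomputed similarities. Because inner
products of the factors must live on the similarity scale, the observed
responses are first divided by their maximum absolute value so they lie
in $[-1, 1]$; `predict()` multiplies the reconstruction back by that
constant. During cross-validation the constant is recomputed from each
training fold only, so held-out cells never influence the scaling.

The model does not use mutation data, tissue labels or drug targets;
associations with those (see `genotype_response_test()`) are downstream
read-outs of the completed matrix, not inputs.

## Tunable parameters

* `K` — latent dimensionality. Defaults to 45, the conventional choice
  for a GDSC-sized panel (135 × 652); CCLE-sized panels (23 × 491)
  conventionally use 12. Must satisfy $K \le \min(m, n)$. In
  simulations, matching `K` to the generating rank is what enables
  near-exact recovery.
* `lambda_l` (default $2^{-3}$) — L2 shrinkage on both factors; the
  main guard against overfitting sparse rows/columns.
* `lambda_d`, `lambda_c` (defaults 0 and $2^{-3}$) — weights of the
  drug- and cell-line-similarity terms. Setting a weight to zero
  removes the term entirely, and the corresponding similarity matrix
  need not be supplied; the defaults reflect that on large IC50 panels
  the expression-based cell-line similarity carries most of the usable
  signal while the chemical-structure term often contributes none. For
  real data the weights should be chosen by `grid_search()` over the
  conventional grid ($\lambda_l \in \{2^{-3},\dots,2^2\}$,
  $\lambda_d, \lambda_c \in \{2^{-5},\dots,2^1, 0\}$; 384 points).
* `tol` (default $10^{-4}$) — relative objective-change stopping rule;
  `max_iter` (default 500) caps the sweeps.
* `seed` — controls the random initialization when `init = "random"`;
  the default SVD initialization is deterministic, so identical calls
  give bitwise-identical fits.

## The optimization scheme

The objective is non-convex (quartic in each factor through the
similarity terms), so the package searches for a local minimum by
alternating minimization with three deliberate choices:

1. **Linearized row-wise least squares.** For the drug factors, the
   quartic term $\lambda_d\lVert S_d - UU^\top\rVert^2$ is replaced by
   the surrogate $2\lambda_d\lVert S_d - U B^\top\rVert^2$ with $B$
   frozen at the previous iterate; the surrogate's gradient matches the
   true term's gradient at $B$, and the resulting problem decouples
   into one $K \times K$ normal-equation solve per drug row (the
   per-row Gram matrix subtracts the contribution of that row's missing
   cells from the dense $V^\top V$). The cell-line update is the exact
   mirror image.
2. **Simultaneous (Jacobi-style) updates with a line search.** Both
   candidate factor blocks are computed from the *previous* iterate,
   then a single step-halving backtracking line search on the true
   objective accepts the largest step in $\{1, 1/2, 1/4, \dots\}$ that
   does not increase it. This guarantees a monotone non-increasing
   objective trace unconditionally — the contract the test suite
   enforces — and makes the algorithm exactly equivariant under
   transposing the problem (drugs ↔ cell lines, $S_d \leftrightarrow
   S_c$, $\lambda_d \leftrightarrow \lambda_c$), a symmetry that
   staggered updates would break. The slight loss of per-sweep progress
   relative to staggered updates is minor in practice (tens of sweeps
   to convergence at the reference problem sizes).
3. **Deterministic initialization.** $U$ and $V$ start from the top-$K$
   singular triplets of the mean-imputed scaled response (missing cells
   set to the observed mean), with each singular pair's sign fixed by
   making the largest-magnitude entry of the left vector positive.
   Joint sign flips of a factor column pair leave every term of the
   objective invariant, so this convention only pins a representative.
   A seeded random-normal initialization is available for robustness
   checks.

Numerical edge cases: an all-zero observed matrix has no defined
scaling and is rejected; non-finite factor values abort with the
iteration index; if no backtracking step decreases the objective after
30 halvings the factors are left unchanged for that sweep (the trace
then records a flat step and the relative-change rule terminates).

## Evaluation protocol

Per-drug metrics follow the field's convention of evaluating each drug
separately, because sensitivity ranges differ wildly across drugs and a
pooled correlation would be dominated by between-drug variance.
`evaluate_predictions()` reports, per drug: Pearson correlation (PCC)
and RMSE over the drug's held-out entries, plus PCC_S/R and RMSE_S/R
restricted to held-out entries in the drug's *sensitive* and
*resistant* cell lines. Those are the first and fourth quartiles of the
drug's observed responses — computed with R's default inclusive
linear-interpolation quantile (type 7), boundary values included in the
extreme groups; which quartile is "sensitive" follows the response
direction. S/R membership is always determined from the observed values
of the full matrix (not per training fold): the alternative per-fold
reading exists, but full-matrix membership keeps the cell-line groups
fixed across folds and is the reading implemented here. A drug needs at
least 8 observed cells and a non-degenerate spread (Q1 < Q3) for an S/R
split, at least 3 points and non-zero variance for a PCC; drugs failing
these are excluded from the drug-averaged means and counted, never
imputed as zero (silent zeros would bias the averages downward).

Cross-validation is *entry-wise*: `kfold_entries()` partitions observed
cells (not rows or columns) into k random folds of near-equal size
(differing by at most one), each fold is masked from training in turn,
and the pooled out-of-fold predictions are scored. `grid_search()`
scores each λ triple by internal cross-validation on whatever data it
is given; for honest model selection it must be called on training
folds only (nested), and the non-nested shortcut of tuning on the full
matrix is optimistic — the package leaves that nesting choice explicit
at the call site rather than hiding either behaviour.

## The Mann–Whitney test

Genotype–sensitivity comparisons use the one-sided Mann–Whitney U test.
Drug-response groups are small and heavily tied, and the classical
exact distribution is unavailable under ties, so `mwu_test()` computes
the exact permutation distribution of the rank sum by a shift-algorithm
dynamic program over doubled midranks whenever the combined sample size
is at most 50 — exact enumeration is cheap there and removes any
approximation ambiguity — and switches to the tie-corrected normal
approximation with continuity correction above. The test suite verifies
the exact branch against brute-force enumeration of all
$\binom{n_1+n_2}{n_1}$ assignments for every combined size up to 12,
and the normal branch against `wilcox.test()`. No multiple-testing
correction is applied by default (single-gene comparisons are the
primary use); `association_scan(adjust = "BH")` provides
Benjamini–Hochberg for panel scans.

## What the simulator emulates — and what it does not

`simulate_instance()` draws latent factors with independent standard
normal entries, forms the rank-`k_true` target $Y^\ast = U^\ast
V^{\ast\top}$, adds independent Gaussian noise with standard deviation
`noise_level` × sd$(Y^\ast)$, masks a `missing_fraction` of entries
uniformly at random, and derives $S_d$ and $S_c$ as Pearson
correlations between target rows and columns (diagonals set to 1). The
defaults are the package's reference study conditions: $m = 100$,
$n = 150$, noise swept over 0–0.5, `k_true = 10` and
`missing_fraction = 0.1` chosen once as a realistic mid-scale panel
(rank well below both dimensions; missingness comparable to large IC50
panels, where roughly a fifth of entries are unassayed). All of these
are config-exposed so alternative generative recipes can be swapped in.
Similarities are computed from the *clean* target, which makes them
informative the way chemical/expression similarities are assumed to be.

The simulator deliberately does not reproduce several features of real
panels: the truth is exactly low-rank (real response matrices are only
approximately so), noise is homoscedastic and Gaussian (real IC50 error
is drug-dependent and heavy-tailed), missingness is uniform rather than
structured by screening batches, and the similarity matrices are
noise-free functions of the truth (real fingerprint and expression
similarities are imperfect proxies). Passing the simulation-based tests
therefore demonstrates correctness of the machinery and graceful
degradation with noise — not performance on any real panel.

`run_noise_sweep()` scores each method's completed matrix against the
noise-free target over all entries (estimating the underlying response
surface, not the noisy measurements). Per-repeat seeds are derived
deterministically from (base seed, level index, repeat index), so sweep
tables are reproducible and order-free. The reference protocol uses 200
repeats; the test suite and acceptance script run 20 repeats per level
with comparisons stated within two standard errors, a problem size
chosen to keep the checks sharp at desk scale.

## Known limitations

* The update scheme is a standard linearized ALS with backtracking; the
  contract the package commits to is monotone descent and recovery
  behaviour, not a specific closed-form update, and other conforming
  schemes may reach different (equally valid) local minima.
* Hyperparameter grid search is embarrassingly expensive (384 CV runs
  at default settings); for large panels users should prune the grid or
  parallelize externally.
* Negative Pearson similarities are used as given; no positive
  semidefinite correction is applied, since the objective does not
  require one.
* Responses are scaled by one global constant; per-drug normalization
  before factorization is a defensible alternative the package does not
  apply silently — callers can pre-normalize their matrix if desired.
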