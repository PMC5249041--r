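---
title: "Models and methods behind mirdirect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirdirect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdirect)
```

`mirdirect` infers *direct* miRNA–mRNA association networks from matched
expression matrices. This vignette explains the statistical machinery, the
tunable parameters and their defaults, the numerical choices, what the
synthetic benchmark does and does not emulate, and the design decisions that
were genuinely open.

## The inference problem

Given an integrated features × samples matrix (miRNA rows first, all rows
z-scored), every method here produces a symmetric feature-association
matrix, of which only the bipartite miRNA × mRNA block is ranked, exported
and evaluated. "Direct" means an association that survives conditioning on
all remaining profiled features — a nonzero entry of the concentration
(inverse covariance) matrix in the Gaussian view — as opposed to marginal
correlation, which sums direct effects with products of effects along
indirect paths. Two caveats frame everything downstream: conditioning is
only on *measured* features (a hidden common regulator still induces an
apparent direct edge), and with n samples far below p features every
estimator leans on regularization whose strength is a bias choice, not a
free lunch.

## The three estimators

### Shrinkage partial correlation

The empirical correlation matrix $R$ is shrunk off-diagonally toward the
identity, $R^* = (1-\lambda)R$ (unit diagonal), with the analytic intensity

$$\lambda^* = \min\!\Big(1,\ \frac{\sum_{i\neq j}\widehat{\mathrm{Var}}(r_{ij})}
{\sum_{i\neq j} r_{ij}^2}\Big),$$

where $\widehat{\mathrm{Var}}(r_{ij}) = \frac{n}{(n-1)^3}\sum_s
(w_{sij}-\bar w_{ij})^2$ with $w_{sij} = z_{is}z_{js}$ on row-standardized
data. $R^*$ is inverted and rescaled to partial correlations
$p_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$. With $\lambda = 0$
this is the classical inverse-correlation estimate and requires $n > p$; the
automatic intensity keeps the matrix positive definite in the $n < p$
regime. `lambda` is the only tunable; `"auto"` is the default and the
estimated value is recorded in the result metadata.

### Sparse partial correlation (SPACE-type joint lasso)

Partial correlations $\rho_{ij}$ also parameterize the best linear
prediction of each variable from all others,
$X_i \approx \sum_{j\neq i}\rho_{ij}\sqrt{d_j/d_i}\,X_j$ with $d_i$ the
residual precision of $X_i$. The estimator minimizes

$$\tfrac12\sum_i w_i\Big\|X_i-\sum_{j\neq i}\rho_{ij}\sqrt{d_j/d_i}X_j\Big\|^2
+\lambda\sum_{i<j}|\rho_{ij}|$$

by cyclic coordinate descent with soft-thresholding over the symmetric
$\rho_{ij}$, alternating with the closed-form update $d_i = n/\mathrm{RSS}_i$.
Two properties matter in practice:

* **The alternation is run a fixed small number of times** (`max_outer`,
  default 3), not to joint convergence. It is not a descent on a single
  objective, and on real data the $(\rho, d)$ pair can enter a small
  two-cycle for highly predictable variables; each coordinate descent *is*
  run to convergence (tolerance `tol`, default 1e-6) given the current $d$,
  and the `converged` flag reports that inner status.
* **Exact zeros are meaningful.** Pairs whose evidence falls below
  $\lambda$ are exactly zero; in the rank stage all zero pairs share the
  worst average rank.

The default penalty is $\lambda = \sqrt{n}\,\Phi^{-1}(1-\alpha/(2p^2))$ with
$\alpha = 0.1$, the classical universal-threshold scaling under which the
chance of admitting any null edge is controlled as $p$ grows. Residual
weights are uniform by default; `weights = "precision"` ($w_i = d_i$) is the
variant whose unpenalized solution coincides with the inverse-correlation
partial correlations, which is how the implementation is cross-checked in
the tests. All inner products are precomputed as the $p\times p$ Gram
matrix, so a sweep is $O(p^3)$ regardless of $n$, and after each full sweep
the descent cycles only over the active (nonzero) set until stable.

### Mutual information + network deconvolution (MIND)

Pairwise dependence is measured by plug-in mutual information on
equal-frequency discretized profiles: $B$ bins per feature
($B = \lfloor\sqrt n\rfloor$ by default, at least 2), ties split
deterministically by first occurrence, MI in nats. MI captures monotone and
non-monotone dependence alike, complementing the two linear estimators in
the ensemble. Two estimator facts worth knowing:

* the plug-in estimate is biased upward by roughly $(B-1)^2/(2n)$ nats on
  independent features (about 0.45 nats at $n = 1000$, $B = 31$) — harmless
  here because only *ranks* of MI values feed the pipeline, and the bias is
  common to all pairs, but visible if MI values are read as absolute
  dependence strengths;
* a feature paired with an identical copy attains exactly $\log B$ when $B$
  divides $n$.

The observed MI network is then deconvolved under the transitive-closure
model $G_{obs} = G_{dir}(I-G_{dir})^{-1}$, inverted as
$G_{tru} = G_{obs}(I+G_{obs})^{-1}$, computed on the eigenvalues
($\lambda \to \lambda/(1+\lambda)$; eigenvectors are untouched). The map
diverges at $\lambda = -1$, so the input is first scaled to spectral radius
at most `delta` (default 0.9) — scaling preserves the weight ordering, and
the applied factor is recorded in the metadata. The diagonal is zeroed
before and after (`zero_diag = TRUE`): self-association carries no signal
and distorts the spectrum. Both protections can be disabled, which is what
the exact round-trip test does on composed matrices that already satisfy the
spectral condition (and whose diagonal, produced by the composition itself,
must be kept for the inversion to be exact).

## Bootstrap and rank aggregation

Each bootstrap replicate draws $\lceil 0.95\,n\rceil$ sample columns
uniformly with replacement (the most literal reading of resampling "95 % of
the dataset with replacement"; both the rate and the replacement flag are
configurable, so the conventional n-out-of-n bootstrap is one argument
away). Replicate $i$ uses the RNG stream `seed + i`, so any replicate is
reproducible in isolation and the aggregate is bit-identical regardless of
execution order. A draw yielding a constant feature row is redrawn from a
far-shifted stream (bounded retries), since no correlation estimator can
digest it.

Replicates — and, at the next level, the different estimators — are
combined by the inverse rank product

$$w'_{ij} = \frac{1}{\log \prod_{m\in G}(r^m_{ij}+1)},$$

with natural log and ranks over the bipartite block, 1 = strongest. Ranks
are taken on |weight| by default: miRNA-mediated repression makes strongly
*negative* correlations the biological signal of interest, and magnitude
ranking keeps them on top next to positive ones (a `signed` flag ranks
most-negative first for users who want repression only). Ranking, rather
than averaging weights, is what makes networks from incomparable weight
scales (partial correlations vs MI) mergeable. Ties get average ranks —
deterministic and order-independent. Two numerical details:

* weights are computed as $1/\sum_m\log(r^m_{ij}+1)$, so products over
  hundreds of networks cannot overflow;
* each pair's log addends are summed in sorted order, making the result
  bit-identical under any permutation of the input networks despite
  floating-point non-associativity.

Aggregate weights live in $(0, 1/\log 2]$; with $m$ networks the maximum is
$1/(m\log 2)$, attained by a pair ranked first everywhere.

## Edge extraction and evaluation

The top-N global pairs (and the top-k mRNAs per miRNA) are cut from the
aggregated weights; ties are broken lexicographically by (miRNA id, mRNA id)
with a warning when a tie crosses the cutoff, so runs are reproducible
across platforms. Predictions are scored by the overlap count between each
miRNA's top-k list and its validated targets. Identifier matching
case-folds by default but does *not* strip `-3p`/`-5p` arm suffixes unless
asked (`strip_arm_suffix`): silent fuzzy matching inflates precision.
miRNAs absent from the ground truth count zero and are listed in the
report, with the restricted total reported alongside, because whether such
miRNAs were excluded or zero-counted is a choice evaluators disagree on.

## The synthetic benchmark

`simulate_expression()` draws from a zero-mean Gaussian whose precision
matrix has unit diagonal and a chosen number of nonzero bipartite entries —
direct edges with known partial correlations, random or all-repressive
signs. If the requested weights make the matrix indefinite it is diagonally
loaded and rescaled to unit diagonal, which attenuates all partial
correlations by a common reported factor while preserving the pattern;
hopeless requests abort with advice to lower the weights. Marginal
correlations then contain transitive contributions by construction, which
is exactly what the estimators must suppress. The benchmark defaults —
10 miRNAs, 40 mRNAs, 30 edges, magnitudes in [0.25, 0.4], 500 samples, no
observation noise — are the package's fixed study conditions, sized so the
full bootstrap-plus-ensemble property checks complete in minutes on one
CPU.

`indirect_pairs()` enumerates the bipartite pairs with no direct edge but a
transitive connection. In a strictly bipartite graph a miRNA and an mRNA
can never share a neighbor, so the shortest indirect path has length 3
(miRNA–mRNA–miRNA–mRNA); the set is computed from powers of the bipartite
adjacency matrix ($A A^{\!\top}\! A > 0$ off the edge set).

What the generator does **not** emulate: platform/batch effects, probe
noise, non-Gaussian marginals, hidden confounders, the directionality of
regulation, or differential-expression feature selection. Passing the
benchmark therefore demonstrates correct recovery of conditional structure
from data matching the model class, not performance on any particular
microarray study.

## Degenerate inputs and error policy

Constant features are rejected at standardization (z-score undefined);
files with missing cells fail loudly unless per-feature mean imputation is
opted into; duplicate feature or sample identifiers, and identifier
collisions between the miRNA and mRNA namespaces, abort (silent renaming
would corrupt ground-truth matching); estimators refuse $n < 3$;
`bins > n`, `k` beyond the mRNA count and `n` beyond the pair count are
errors naming the bound. Bootstrap replicates that fail are skipped with a
warning and counted in the metadata; only all replicates failing is an
error.

## Known limitations

* The three estimators suppress, but cannot eliminate, indirect signal —
  the MIND deconvolution assumes the transitive-closure weight model, and
  the partial-correlation methods assume approximate Gaussianity.
* The SPACE-type solver's fixed alternation count means residual precisions
  are refined, not converged; this matches how such estimators are used in
  practice but means `meta$d` should not be read as maximum-likelihood
  precisions.
* Evaluation against curated target databases inherits their
  incompleteness; overlap counts are comparable across methods on the same
  data, not absolute accuracies.
* Everything is computed densely; the implementation targets the
  few-hundred-features scale of differentially-expressed panels, not
  genome-wide matrices.
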