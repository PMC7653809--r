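---
title: "Stability-selected elastic-net network inference: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-selected elastic-net network inference: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabnet)
```

## The problem and the model

Given a normalized expression matrix with $n$ observations (samples) in rows
and $p$ genes in columns, the goal is a directed network of
regulator $\to$ target calls: for each target gene, which other genes'
expression levels predict it. The package treats each target gene $y$ in
turn as the response of a sparse linear model over candidate regulator
genes $x_j$ and selects predictors with the elastic net, the penalized
least-squares estimator

$$\hat\beta(\lambda) \;=\; \arg\min_\beta \;
\frac{1}{2n}\sum_{i=1}^{n}\Big(y_i - \beta_0 - \sum_j x_{ij}\beta_j\Big)^2
\;+\; \lambda\Big[\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\Big],$$

whose $\ell_1$ part zeroes coefficients exactly (variable selection) while
the $\ell_2$ part keeps groups of correlated predictors together rather
than arbitrarily picking one — the relevant regime for co-expressed genes.
A gene with $\hat\beta_j \ne 0$ at the tuned penalty is *selected* as a
candidate regulator of the target.

A single cross-validated elastic-net fit selects too liberally for network
inference: the tuned penalty admits many weak, unstable predictors. The
package therefore wraps the selector in a resampling scheme. In each of
$n_\mathrm{iter}$ iterations the samples are randomly partitioned into $m$
disjoint subgroups (every sample used exactly once per iteration, no
within-iteration duplication), and an independent cross-validated
elastic-net is fitted in every subgroup, for every target. Each fit is one
*trial*, so a pair (target, candidate regulator) faces
$n_\mathrm{iter} \times m$ trials, and its **frequency score** is

$$\mathrm{score}(r \to t) \;=\; \frac{\#\{\text{trials in which } r
\text{ was selected for } t\}}{n_\mathrm{iter}\, m} \in [0, 1].$$

A score of 1 means the regulator survived every trial — the highest
confidence. The inferred network keeps the pairs whose score reaches a
high cutoff (default 0.95). Splitting into more subgroups makes each trial
see fewer samples and makes agreement across trials harder, so false
selections — which depend on the noise realization — are suppressed much
faster than true ones; raising $m$ (given enough samples per subgroup)
trades recall for precision.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `m` | 4 | disjoint subgroups per iteration; each subgroup must keep at least `kfolds` samples |
| `nIter` | 500 | resampling iterations; scores stabilize long before the default on moderate problems |
| `cutoff` | 0.95 | frequency-score threshold (inclusive, so a cutoff of 1 is attainable; a strict mode is available) |
| `alpha` | 0.5 | elastic-net mixing; 1 is the lasso, small values approach ridge |
| `kfolds` | 5 | cross-validation folds inside each trial |
| `nLambda`, `lambdaMinRatio` | 100, 0.01 | penalty path resolution and depth |
| `tol`, `maxIter` | 1e-4, 10000 | coordinate-descent stopping rule (largest squared standardized coefficient update) and sweep cap |
| `lambdaRule` | `"min"` | CV-minimum penalty; `"1se"` picks the sparsest fit within one SE |
| `seed` | 0 | master seed; every random stream derives from it |

The penalty is tuned per trial by $k$-fold cross-validation at the
CV-minimum rule. The minimum rule deliberately over-selects in any single
fit — under a pure-noise response roughly a quarter of fits admit two or
more spurious predictors — and relies on the frequency filter to prune
them; that division of labour is the design. The `"1se"` alternative is
the sparse per-fit selector: under the same null it returns at most one
spurious predictor in over 95% of fits. Both rules recover a true sparse
signal essentially always in our benchmarks; the default follows the
over-select-then-stabilize logic.

Candidate regulators default to every gene except the current target
(self-edges are excluded by construction: a gene trivially predicts
itself); a whitelist restricts candidates to, say, transcription factors.
Zero-variance genes are flagged at standardization and never enter the
candidate pool, but remain valid (null-regression) targets.

## Determinism and parallelism

Results are bitwise identical for any worker count. Each iteration's
partition stream is derived from `(seed, iteration)`, and each trial's CV
fold stream from `(seed, iteration, subgroup, target)`, via an integer
hash (`deriveStreamSeed()`); no stream depends on execution order.
Partition groups are returned as sorted index sets so that downstream fold
assignment depends only on group membership, not on the order the
permutation happened to produce. Edge output is sorted by descending
score with lexicographic tie-breaks, making written files byte-stable.

## Numerical choices

The coordinate-descent path solver is compiled and follows the canonical
glmnet conventions so the two are interchangeable on a shared path:
predictors are centred and scaled to unit $1/n$-variance inside each fit,
the response is centred and scaled by its $1/n$ standard deviation (the
penalty therefore acts on the unit-variance problem; coefficients and
penalties are reported on the original scale), and the path is 100
log-spaced values from the smallest $\lambda$ that zeroes every
coefficient down to 1% of it, solved with warm starts and covariance
updates. The test suite verifies coefficient agreement with glmnet to
$10^{-4}$ on shared paths and support agreement at the CV-selected
penalty. Cross-validation folds are contiguous blocks of a seeded
permutation, remainder rows spread one per fold from the first; fold fits
reuse the full-data path, and mean held-out squared error picks the
penalty.

Degenerate inputs are handled explicitly rather than by solver accident: a
constant response short-circuits to an empty selection; a constant
predictor column is excluded inside the solver; an empty candidate set is
a vacuous (empty) trial, not an error; a failed trial counts as an empty
selection and is logged, so one bad fit cannot abort an
$n_\mathrm{iter} \cdot m \cdot p$-fit run. When $m \nmid n$, the first
$n \bmod m$ subgroups take one extra sample — no observation is dropped,
since silently discarding data would change the effective sample size.

Input matrices are standardized column-wise before inference by default
(each fit also standardizes internally, so this mainly governs
constant-gene flagging); the package performs no count normalization and
should only be given already-normalized expression values.

## The synthetic benchmark

`simulateGRN()` emulates the role of an in-silico community benchmark with
a known gold standard, at desk scale. The first `nRegulators` genes are
independent standard-normal sources; each remaining gene is a linear
combination of `kPerTarget` distinct sources, with absolute effects drawn
uniformly from `betaRange` and random signs (so the sign-aggregation
output is exercised), plus $N(0, \sigma^2)$ noise. The defaults — 100
genes of which 20 sources, 400 observations, 2 regulators per target,
effects in $[1, 2]$, noise SD 0.5 — define the study conditions used by
the package's own validation: strong-but-noisy signals where single fits
still make mistakes that stability must remove.

The generator is deliberately a two-layer acyclic design matched to the
model the engine fits. Passing its benchmarks therefore demonstrates
correct implementation and calibration of the *procedure* — it does not
demonstrate that real regulatory networks (feedback loops, unmeasured
confounders, non-linear kinetics, technical noise) are recovered at the
same rates. The gold standard enumerates all source $\to$ target pairs,
labelling the drawn ones 1 and the rest 0, so precision, recall and AUC
are computed over a fully labelled universe.

```{r quick-example}
sim <- simulateGRN(syntheticSpec(pGenes = 20, nObs = 100, nRegulators = 5,
                                 kPerTarget = 1, noiseSd = 0.3, seed = 7))
cfg <- inferenceConfig(m = 2, nIter = 5, cutoff = 0.9, seed = 7,
                       regulators = geneIds(sim$matrix)[1:5],
                       targets = geneIds(sim$matrix)[-(1:5)])
net <- inferNetwork(sim$matrix, cfg)
confusionCounts(net, sim$gold)
```

## Evaluation conventions

Evaluation against a gold standard is directed throughout — $A \to B$ and
$B \to A$ are distinct calls. Two pair universes are supported: the
default `labeled` universe evaluates only pairs listed in the gold file
(unlisted calls are ignored, the DREAM-style convention), while `all`
counts unlisted calls as false positives. Precision at zero calls is
reported as `NA`, never silently 0, so sweep curves stay honest at extreme
cutoffs. The ROC-AUC is the rank-based (Mann–Whitney) estimator with
midrank tie handling; pairs the engine never selected enter the universe
with score 0. The test suite pins the estimator to the brute-force
pairwise comparison count on small instances.

## Benchmark problem sizes

The packaged validation runs at sizes a laptop handles in minutes: the
recovery benchmark at the generator defaults with $m = 4$ and 50
iterations; the cutoff-monotonicity sweep over 10 seeds at 20 iterations;
the subgroup trend ($m = 2$ vs $m = 8$, noise SD 1.0) over 10 seeds at 10
iterations; and the null calibration (no true edges) over 20 seeds at
$m = 2$, 10 iterations. Raising the iteration counts sharpens the score
estimates but does not change the qualitative outcomes; scores are
typically stable well before a few hundred iterations.

## Known limitations

* The linear, homoscedastic model is the method's lens; strongly
  non-linear regulation is invisible to it.
* The cutoff is a user knob, not an error-controlled threshold; no formal
  false-discovery bound is attached to it.
* Only squared-error regression is provided — no generalized linear
  families.
* The labelled-only evaluation universe inherits the biases of whatever
  gold standard it is given.
* Input must be pre-normalized; the package performs no normalization of
  raw counts.
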