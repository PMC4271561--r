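---
title: "Meta-sample regularized robust coding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-sample regularized robust coding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrrcc)
```

## The classification problem

A gene-expression profile is a vector of $n$ per-gene measurements; a study
delivers a matrix $X \in \mathbb{R}^{n \times m}$ of $m$ samples, each
carrying one of $k$ subclass labels (cancer types or subtypes). With
$n \gg m$, classical model-based classifiers overfit, and a handful of
grossly aberrant genes — probe artifacts, contamination, private mutations —
can dominate any least-squares comparison. `mrrcc` addresses both problems
at once: it represents a test sample as a linear combination of a small
*meta-sample* dictionary, and it measures representation fidelity with a
robust loss that adaptively downweights outlier genes.

## Meta-samples

For each subclass $i$, the training submatrix $A_i$ ($n \times m_i$, unit
$\ell_2$-normalized columns) is factored by SVD, and the leading $q_i$ left
singular vectors form the meta-sample block $M_i$; the matched patterns
$V_i$ (singular values times right singular vectors) make
$M_i V_i$ the best rank-$q_i$ approximation of $A_i$. The dictionary is the
concatenation $D = [M_1, \dots, M_k]$, with blocks in lexicographic label
order. Within a block the atoms are orthonormal, so all dictionary columns
live on the same scale as the normalized test sample.

Two conventions keep the factorization reproducible across platforms:
meta-samples are *unit-norm* left singular vectors (singular values stay in
$V_i$), and each singular vector is flipped so its largest-magnitude entry
is positive (ties to the lowest gene index). A subclass with fewer samples
than requested meta-samples has $q_i$ clamped to $m_i$, with a warning.

Training samples are unit-normalized before the SVD. The coding step
requires a unit-norm test sample, and a dictionary extracted from
unnormalized training data would mix scale differences between subclasses
into the atoms; normalizing both sides is the consistent choice.

## Robust coding

A normalized test sample $y$ is coded against $D$ by minimizing

$$\hat\alpha = \arg\min_\alpha \; \sum_{i=1}^n \rho_\theta(y_i - r_i\alpha)
  \; + \; \lambda \lVert \alpha \rVert_\beta^\beta,$$

where $r_i$ is the $i$-th row of $D$, $\beta = 2$ gives a ridge penalty
(the default, "MRRCC2") and $\beta = 1$ a lasso penalty ("MRRCC1"). The
residual loss derives from a logistic weight function

$$\omega(e_i) = \frac{1}{1 + \exp(\mu e_i^2 - \mu\delta)},$$

which is $\approx 1$ for well-fit genes, $1/2$ exactly at the demarcation
point $e_i^2 = \delta$, and decays rapidly beyond it. Setting
$\mu = s/\delta$ with $s = 8$ fixes $\omega(0) = 1/(1+e^{-8})
\approx 0.9997$ regardless of scale. The induced loss

$$\rho_\theta(e) = -\tfrac{1}{2\mu}\left[\ln(1 + e^{\mu\delta - \mu e^2})
  - \ln(1 + e^{\mu\delta})\right]$$

is even, zero at zero, monotone in $|e|$, and bounded — large residuals
stop contributing, which is exactly the robustness mechanism. Both
functions are evaluated in overflow-safe rearrangements.

### The residual scale $\delta$

$\delta$ is re-estimated every iteration as the
$\max(1, \lfloor\tau n\rfloor)$-th *order statistic* (i.e. essentially the
$\tau$-quantile) of the squared residuals, with $\tau = 0.9$ by default:
the worst-fitting $\approx 10\%$ of genes fall beyond the demarcation point
and are treated as outlier candidates. We note an ambiguity in how ranked
residual sets are sometimes described ("the $l$-th largest"): anchoring
$\delta$ at the *upper* tail instead would place the demarcation point at
the 10th percentile, downweight ~90% of the genes, and destroy the coding
(self-classification accuracy collapses to near chance — we verified this
directly). Only the quantile reading makes larger $\tau$ more permissive,
which is also the only reading under which accuracy should *improve* with
$\tau$ on mostly-clean data, as it does; the package therefore uses it.
$\delta$ is floored at `deltaFloor` ($10^{-12}$) so $\mu = s/\delta$ stays
finite when the reconstruction is near-perfect; in that regime all weights
are $\approx 1$, the correct limit.

### The iteration

`ir3c()` alternates: residual → ($\delta$, $\mu$) → weights $W$ → weighted
subproblem
$\alpha^\ast = \arg\min \lVert W^{1/2}(y - D\alpha)\rVert_2^2 +
\lambda\lVert\alpha\rVert_\beta^\beta$ → damped update
$\alpha^{(t)} = \alpha^{(t-1)} + v_t(\alpha^\ast - \alpha^{(t-1)})$. The
start is $\alpha^{(1)} = (1/Q, \dots, 1/Q)$, whose reconstruction is the
mean of all meta-samples; the first update takes $\alpha^\ast$ directly.
Subsequent steps pick $v_t$ by backtracking over
$\{1, 1/2, \dots, 2^{-10}\}$, accepting the first step that does not
increase the surrogate objective; if none is admissible the iterate is kept
and the loop stops (this prevents oscillation and makes the recorded
objective trace non-increasing by construction). Convergence is declared
when the relative change of the weight vector drops below $\varphi$
(default $10^{-2}$), or at `maxIter` (default 100).

The $\beta = 2$ subproblem is solved exactly via the normal equations
$(D^\top W D + \lambda I)\alpha = D^\top W y$; with $\lambda = 0$ and a
singular system, a documented `minNorm` flag selects the minimum-norm
solution (the iteration uses it, since exact-rank degeneracies are legal
there). The $\beta = 1$ subproblem is solved by cyclic coordinate descent
on the transformed problem $\tilde y = W^{1/2}y$, $\tilde D = W^{1/2}D$,
declared converged only when the subgradient (KKT) conditions hold within
$10^{-6}$; in particular $\alpha = 0$ is returned iff
$\lambda \ge 2\lVert \tilde D^\top \tilde y \rVert_\infty$. The test suite
checks both solvers against independent oracles (a black-box quasi-Newton
minimizer, a proximal-gradient scheme, and a hand conjugate-gradient
solve).

$\lambda$ has no published value; the default $10^{-3}$ is small enough
not to bias the coding of a unit-norm sample against unit-norm atoms and
large enough to keep the normal equations well-posed. All
distribution-specific constants of the generalized-Gaussian coefficient
prior are absorbed into $\lambda$. A $\tfrac12$ factor that appears in one
intermediate form of the objective is dropped consistently, so the
objective, KKT conditions, and normal equations all use the same scaling.

### Classification

After convergence, subclass $d$ receives the weighted block-restricted
residual $l_d = \lVert W_{\text{final}}^{1/2} (y - D_d \hat\alpha_d)
\rVert_2$, where $\hat\alpha_d$ zeroes every coefficient outside block $d$,
and the sample is assigned $\arg\min_d l_d$. A single shared
$W_{\text{final}}$ from the converged run is used for all subclasses (the
rule has one weight matrix; re-estimating per class would let each class
discount different genes and break comparability). Ties — residuals equal
up to a relative $10^{-9}$, which only merges float-level differences — go
to the lexicographically smallest label. Gene weights are used only as
continuous multipliers; no hard removal threshold is applied, since any
cutoff would be arbitrary and the logistic weight already drives clear
outliers to $\approx 0$.

## Evaluation harness

* `stratifiedKFold()` deals each class round-robin after a seeded shuffle,
  so per-class fold counts differ by at most one.
* `twoLayerCV()` is the nested protocol: the inner 10-fold layer selects
  the meta-sample count from a grid (ties to the smallest count — the more
  parsimonious dictionary), the outer 10-fold layer estimates accuracy with
  that count refit on the full outer-training portion. The reported figure
  is the mean of the outer-fold accuracies. Inner folds shrink
  automatically when a class is too small. Every index set used is recorded
  in an audit slot, and the tests assert the inner layer never touches
  outer-test samples.
* `bdmSplit()` draws a balanced training set of $q$ samples per subclass,
  the remainder forming the test set. The published protocol sweeps $q$
  from 5 to $\min(|c_{\min}|, 20)$ over 100 seeded randomizations (the
  `bdm-eval` subcommand's defaults); the function itself accepts any
  feasible $q \ge 1$ so that small desk-scale experiments remain possible.
* `kruskalWallisFilter()` ranks genes by the tie-corrected Kruskal–Wallis
  $H$ (computed by `stats::kruskal.test`; a gene tied across all samples is
  assigned $H = 0$, where the tie-corrected statistic is undefined) and
  keeps the top 300 by default. Only the ranking is used, so no p-values
  are reported.

## Synthetic data

`simulateExpression()` generates the structure the classifier assumes:
each subclass is a low-rank linear subspace. Per class, `factorsPerClass`
latent gene profiles are drawn i.i.d. standard normal; each sample mixes
them with positive weights (uniform on $[0.5, 1.5]$, renormalized to sum to
one — keeping samples away from the origin so unit normalization is stable)
plus i.i.d. Gaussian noise. `contaminateSamples()` then replaces a fixed
fraction of randomly chosen genes per sample with zero-mean noise at
`magnitude` times the sample's own standard deviation — the gross outlier
genes the weight function is designed to absorb. Contamination is applied
to test samples, not training data, matching the coding-residual setting
where the probe sample carries the corruption.

The reference conditions used throughout the tests and the acceptance
script are 500 genes, 3 subclasses, 40 samples per subclass, latent rank 3,
noise sd 0.1 (about one sixth of the per-gene signal sd), 70/30 balanced
splits, and — for robustness experiments — 10% contaminated genes at
magnitude 5, averaged over 20 seeded replicates. These sizes keep every
experiment at desk scale while leaving the subclass subspaces
distinguishable but noisy. What the generator deliberately does *not*
emulate: count-like marginals (negative binomial), probe/batch effects,
correlated noise, class imbalance. Passing tests therefore demonstrate the
method's behavior under its own structural assumptions, not performance on
any real cohort.

```{r example}
sim <- simulateExpression(nGenes = 300, nClasses = 3, samplesPerClass = 20,
                          factorsPerClass = 3, noiseSd = 0.1, seed = 7)
sp <- bdmSplit(sim$dataset, 14, seed = 7)
model <- mrrccFit(sp$train, q = 3)
preds <- predict(model, sp$test)
accuracyScore(vapply(preds, predictedLabel, character(1)),
              as.character(subclassLabels(sp$test)))
```

## Interfaces and conventions

Data live in a `GEPSet` (a `SummarizedExperiment` with an `exprs` assay and
a `subclass` column), always genes × samples; readers transpose
samples-in-rows input on request and reject missing or non-numeric cells
outright (imputation is out of scope). Fitted models serialize to a single
sectioned text container with a format-version string; numeric payloads are
written as hexadecimal floating-point literals, so a save/load round trip
is bit-exact. A thin command-line wrapper (`inst/cli/mrrcc`, subcommands
`simulate`, `fit`, `predict`, `cv`, `bdm-eval`) drives the same exported
functions; flags override an optional flat key=value config file, which
overrides defaults, and every random procedure takes an explicit seed.

## Limitations

* The method presumes each subclass is approximately a linear subspace of
  gene space; strongly nonlinear class structure violates the model.
* $k = 1$ training data is rejected by the fitting interface (a one-class
  dictionary is degenerate, though the low-level coder handles it).
* The lasso variant costs roughly $Q$ times more per iteration than the
  ridge variant and is rarely more accurate on clean low-rank data; the
  ridge variant is the default.
* No probability calibration: the classifier reports residual margins, not
  posteriors.
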