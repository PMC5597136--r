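---
title: "Stable sparse VAR inference of gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable sparse VAR inference of gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabvar)
```

## The model

`stabvar` reverse-engineers a signed, directed gene regulatory network
from a genes-by-observations expression matrix whose columns are ordered
in time (a time course, or a sequence of perturbation experiments taken
in experiment order). The generative assumption is a first-order vector
autoregression

$$ y_t = v + A\,y_{t-1} + u_t, $$

where $y_t \in \mathbb{R}^N$ holds the expression of the $N$ genes at
observation $t$, $A$ is the $N \times N$ coefficient matrix, $v$ an
intercept and $u_t$ white noise. A nonzero $a_{ij}$ means gene $j$ at lag
one helps predict gene $i$ now — a Granger-style orientation: the
regulator precedes its target. The package reads $a_{ij} \ne 0$ as the
directed edge $j \to i$ with sign $\mathrm{sign}(a_{ij})$ (activation
$+$, inhibition $-$). This convention is fixed everywhere, including the
file formats.

Two biological priors shape the estimator:

* **Sparsity.** Regulatory networks are loosely connected, so the fit is
  constrained by an entrywise L1 budget $\|A\|_1 \le \lambda$.
* **Stability.** Expression measured at or near equilibrium should be
  described by a dynamically stable system, so the fit is constrained to
  a convex stability region built from Geršgorin's disc theorem.

The fitted program is

$$ \min_A \tfrac12 \|Y - AZ\|_F^2 \quad \text{s.t.} \quad
   \|A\|_1 \le \lambda, \qquad
   a_{ii} \le -\sum_{j \ne i} \tfrac{v_j}{v_i}\,|a_{ij}| \ \ \forall i, $$

where $Z$ holds observations $1..T-1$, $Y$ observations $2..T$ (the
single-series lag alignment with no presample), and $v_i > 0$ are
per-gene weights. By Geršgorin applied to the similarity transform
$V^{-1} A V$, $V = \mathrm{diag}(v)$, the row constraints certify that
every eigenvalue of $A$ has non-positive real part. Note what this does
and does not certify: the classical VAR stationarity criterion is
$\max |\tau| < 1$ over the eigenvalues $\tau$, whereas the constraint
guarantees $\max \mathrm{Re}\,\tau \le 0$ (a Hurwitz-style half-plane
condition). The package implements the constraint exactly as written and
reports *both* stability notions (`is_stable()` modes `"modulus"` and
`"halfplane"`) in every run report rather than silently substituting one
for the other.

Because the row constraints force $a_{ii} \le 0$, every inferred
self-loop is an inhibition — the negative transcriptional
autoregulation typical of stress-response regulators.

### The weight schedule

With unit weights the constraint is plain diagonal dominance, which is
very conservative. The weights are therefore adapted to the current fit.
Let $R_i(A) = \sum_{j\ne i} |a_{ij}|$ (deleted absolute row sum),
$m_i = |a_{ii}| - R_i(A)$, and $\beta = \tfrac1N \sum_i m_i$. Then

$$ v_i = \begin{cases}
  1 + \dfrac{m_i - \beta}{\delta + (m_i - \beta)}, & m_i > \beta,\\[1ex]
  \dfrac{\delta}{\delta - (m_i - \beta)}, & m_i \le \beta,
\end{cases} $$

with shape parameter $\delta \in (0, 1]$ (default 0.5, exposed in
`solver_config()`). Rows more diagonally dominant than average get
$v_i \in (1, 2)$, loosening their discs; weaker rows get
$v_i \in (0, 1)$. All weights stay strictly inside $(0, 2)$ and depend on
$A$ only through the $m_i$. Equality $m_i = \beta$ is assigned to the
second branch; both branches give $v_i = 1$ there, so the schedule is
continuous and the all-equal case (for example any matrix with identical
row margins, or the zero matrix) yields unit weights — the canonical
first-iteration state.

`infer_network()` alternates solving the convex program at fixed weights
with recomputing the weights from the fitted matrix, starting from unit
weights, until the weights move less than `weight_tol` (default 1e-4) or
`max_outer_iters` (default 20) is reached. The alternation has no
general convergence guarantee; in practice it converges in a handful of
iterations or settles into a small oscillation between near-identical
solutions. Non-convergence is recorded in the result (with the last
iterate, which is feasible under the weights actually used for its
solve) rather than raised as an error.

## Solving the convex program

The constraint set is the intersection of the L1 ball of radius
$\lambda$ and $N$ row-separable weighted half-"cones"; both admit exact
Euclidean projections (soft-thresholding with an exactly computed
piecewise-linear root for a row; the classical sort-based projection for
the ball). The solver (compiled C++) is ADMM: the quadratic block is a
linear solve against the Cholesky-factored Gram matrix $ZZ' + \rho I$,
and the constraint block projects onto the intersection with Dykstra's
alternating projections run to a tolerance two orders tighter than the
outer `solver_tol` (default 1e-8). Because Dykstra's last step is the
ball projection and its row violation is monitored directly, every
returned iterate satisfies the budget exactly and the margins to ~1e-9.
The penalty parameter $\rho$ is adapted by residual balancing. The zero
matrix is always feasible, so the program is always solvable;
$\lambda = 0$ short-circuits to $A = 0$. The strict inequalities of the
mathematical formulation are implemented as non-strict (closed sets are
needed for a minimizer to be attained).

The contract is global optimality within tolerance, not a specific
algorithm: the test suite checks the solver against a closed-form
clipped-OLS oracle for $N = 1$, a dense refined grid search over the
feasible set for $N = 2$, and constraint/monotonicity invariants on
seeded instances.

Numerical conventions worth stating:

* Tie-break in edge extraction: `|coefficient| == threshold` is a
  non-edge.
* Rank-deficient $ZZ'$ (reciprocal condition below 1e-12) is an error
  for the unpenalized `ols_estimate()`; the constrained solver does not
  require invertibility.
* Constant expression rows center to zero and give $A = 0$ in one outer
  iteration.
* Stability verdicts use tolerance 1e-7 in both modes.

## Centering and the intercept

The constrained program carries no intercept, so the pipeline absorbs
$v$ by centering each gene's row before fitting and adding the training
row means back when forecasting. Whether the original analyses centered,
scaled or log-transformed their matrices is not stated; row-centering
only is this package's default. `solver_config(center = FALSE)` disables
it for data already on a zero-mean scale — that switch is also what
makes "zero forecast error on perfectly forecastable data" an exact
statement, because centering a finite window of a decaying noiseless
trajectory shifts the dynamics by a window-dependent constant that no
time-invariant coefficient matrix can reproduce exactly.

## Choosing the budget

Time dependence rules out ordinary cross-validation, so $\lambda$ is
selected by rolling one-step-ahead mean square forecast error. With
$T_1 = \lfloor T/3 \rfloor$ and $T_2 = \lfloor 2T/3 \rfloor$, for each
$t \in \{T_1, \dots, T_2 - 1\}$ the model is fitted on observations
$1..t$ and forecasts observation $t+1$:

$$ \mathrm{MSFE}(\lambda) = \frac{1}{T_2 - T_1 - 1}
   \sum_{t=T_1}^{T_2-1} \|\hat y_{t+1}^\lambda - y_{t+1}\|^2 . $$

The normalizer $T_2 - T_1 - 1$ (one less than the number of evaluated
windows) follows the criterion's published convention. The role of the
three thirds is implemented as: the first third is initialization mass
(fits at window $t$ always use all observations $1..t$), the middle
third is scored, and the final third stays untouched unless
`holdout = TRUE`, which reports the selected budget's error there.
`select_lambda()` evaluates an ascending grid (default
$\{0, 0.1, \dots, 1\}$), warm-starting each budget's weight iteration
from the previous budget's solution (a speed device only — the converged
answer is unchanged beyond `weight_tol`), and breaks exact ties towards
the smaller budget, i.e. the sparser model. Selection is fully
deterministic. The source analyses report both $\lambda = 0.3$ and
$\lambda = 0.4$ as selected for the same data at nearly equal MSFE
(5.20 vs 5.22); this package's rule is the argmin with the
smallest-budget tie-break, and no attempt is made to resolve that
ambiguity.

## Scoring against a reference network

Evaluation is sign-aware over all $N^2$ ordered pairs, self-pairs
included, each falling in exactly one confusion cell:

* inferred edge, reference edge, same sign — **TP**;
* inferred edge over an absent *or oppositely signed* reference pair —
  **FP** (sub-counted as false activation or false inhibition by the
  inferred sign);
* missed reference edge — **FN** (false no-interaction);
* shared non-interaction — **TN**.

Counting a wrong-sign recovery as FP rather than FN is forced by
requiring both a partition of the $N^2$ pairs and the rule that an
interaction is accurate only when its sign is correct; it is stated here
prominently because published descriptions leave it implicit.
`network_metrics()` reports sensitivity TP/(TP+FN), specificity
TN/(TN+FP) and precision TP/(TP+FP); zero-denominator metrics are
returned as `NA` and flagged, never coerced. `summary_rates()` adds the
false-identification percentage $100\,(FP+FN)/N^2$ and the net
connectivity $100\,(TP+FP)/N^2$, the latter fixed as the
inferred-interaction fraction (published prose and tables disagree on
this definition; the package documents the choice and keeps it).

For pathway-level comparisons, `collapse_complexes()` merges genes that
act as one regulatory unit (SWI4/SWI6-style complexes) into single
nodes: intra-complex edges are dropped, parallel inter-complex edges are
deduplicated, and a collapsed edge's sign comes from the
largest-magnitude contributing coefficient when magnitudes are
available, else the majority sign with exact ties resolved to `+` and a
warning.

## Synthetic data: what it emulates and what it does not

`random_stable_sparse_model()` draws off-diagonal support independently
at the requested density with random signs and magnitudes
`coeff_scale * U(0.5, 1.5)`. Regime `"gershgorin"` sets each diagonal to
$-(R_i(A) + s_i)$, $s_i \sim$ `coeff_scale * U(0.5, 1)`, so the truth is
strictly feasible for the estimator's constraint set under unit weights;
because that certifies only the half-plane property, the matrix is
additionally rescaled to spectral radius 0.9 whenever needed so
trajectories are stationary (rescaling preserves the sign pattern and
the strict negativity of the margins). Regime `"modulus"` draws signed
diagonals like the off-diagonals and rescales to spectral radius 0.9.

`generate_dataset()` produces either a stationary `"trajectory"` (the
VAR driven by Gaussian process noise, burn-in discarded) or
`"perturbation"` data: a chain of one-step responses to sparse random
impulses near the zero equilibrium, with additive observation noise on
the recordings. Perturbation columns are concatenated in experiment
order and the inference treats adjacent columns as lag pairs, mirroring
how steady-state perturbation panels are fed to a temporal model in this
method family; the manual fixes that ordering explicitly. With zero
observation noise the recorded columns satisfy
$y_{t+1} = A y_t + p_{t+1}$ exactly, and impulses restricted to one gene
propagate only along directed paths from it — both properties are
tested.

What the generator does **not** emulate: microarray platform noise
models, saturation/nonlinearity of regulation, unobserved regulators,
and irregular sampling. Passing the synthetic benchmarks therefore
demonstrates correctness of the estimator and its selection machinery
under the model's own assumptions, not performance on real expression
data.

## The recovery benchmark

`recovery_experiment()` is the end-to-end harness: per replicate it
draws a ground truth, simulates a stationary trajectory, selects
$\lambda$ by MSFE, fits, extracts edges and scores support (sign-
agnostic), sign accuracy and coefficient RMSE. Two of its defaults are
genuine design choices, fixed a priori:

* **Grid.** The published 0–1 budget lattice presumes normalized data;
  on unnormalized synthetic scales the benchmark uses fractions
  $\{0, 0.1, \dots, 1\}$ of $\|\hat A_{OLS}\|_1$, a data-driven
  generalization that spans the fully-constrained-to-unconstrained
  range whatever the scale.
* **Support threshold.** Edges are called at
  `|coefficient| > coeff_scale / 4` — half the generator's minimum true
  magnitude — separating estimation noise (entry errors of order
  $1/\sqrt{T}$) from true effects. With the spec-scale benchmark
  (6 genes, density 0.2, `coeff_scale` 0.3, noise sd 0.05, $T = 200$,
  20 replicates) this yields mean support sensitivity and specificity
  well above 0.8.

Problem sizes used by the shipped tests and the acceptance script —
5–6 genes, 30–200 observations, 20–50 seeded instances — were chosen so
the full suite re-runs in minutes on a single core while keeping the
estimation regime (moderate $T/N$) representative.

## Known limitations

* The half-plane stability certificate is one-sided: a fit can satisfy
  all margins yet have spectral radius above 1 (oscillatory modes). Both
  diagnostics are always reported; choosing between them is left to the
  analyst.
* The weight alternation can cycle; the result flags non-convergence
  and returns the last feasible iterate.
* The entrywise budget treats the diagonal and off-diagonal uniformly,
  so strong self-decay consumes budget that could describe
  cross-regulation.
* VAR order one only: regulation acting over longer lags is projected
  onto lag one. Higher orders, missing-value handling and structural
  identification of the noise covariance are out of scope.
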