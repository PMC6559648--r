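---
title: "Optimization methods for non-negative matrix tri-factorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimization methods for non-negative matrix tri-factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Non-negative matrix tri-factorization (NMTF) approximates a non-negative
data matrix $X \in \mathbb{R}^{n \times m}$ by a product of three
non-negative latent matrices,
$$X \approx U S V^T, \qquad U \in \mathbb{R}_+^{n \times k_1},\;
S \in \mathbb{R}_+^{k_1 \times k_2},\; V \in \mathbb{R}_+^{m \times k_2},$$
minimizing the squared Frobenius reconstruction error. No additional
regularization (orthogonality, sparsity penalties) or alternative
divergences (Kullback–Leibler, Alpha, Beta) are included: the objective
is the plain reconstruction error under non-negativity constraints.
Everything in this package — traces, stopping, reporting — works on the
normalized objective
$$D = \|X - U S V^T\|_F^2 \, / \, \|X\|_F^2,$$
which is $0$ at an exact factorization and $1$ for the all-zero model.
The unnormalized loss is recoverable as $D \cdot \|X\|_F^2$. The zero
matrix is rejected at load time ($D$ would be undefined), rather than
returning `NaN` downstream.

The problem is non-convex (and exact factorization is NP-hard), but
fixing two of the three factors makes it convex in the third. All four
optimization methods exploit this block structure and differ only in how
they solve or approximate the per-factor subproblems. Within one
iteration the factors are updated in the order $U$, then $V$, then $S$,
each sub-update seeing the already-updated earlier factors; the
objective is evaluated once per full iteration, which is what the traces
record (per-sub-update evaluation would triple the objective cost and
change the meaning of an "iteration").

## The four methods

**Multiplicative update rules (MUR)** rescale each entry by the ratio of
the negative to the positive part of the gradient, e.g.
$U \leftarrow U \odot (X V S^T \oslash U S V^T V S^T)$. They preserve
non-negativity by construction, never increase the objective, and keep
zero entries at zero (the multiplicative lock). Their drawbacks are slow
convergence and a long start-up plateau.

**Alternating least squares (ALS)** solves each factor's unconstrained
least-squares problem through its $k \times k$ normal equations and then
clips negative entries to zero, e.g.
$U \leftarrow [(X V S^T)(S V^T V S^T)^{-1}]_+$. The clipping is a
heuristic: the objective may increase across an iteration, and on dense
data the method frequently diverges — the package's tests deliberately do
*not* assert ALS monotonicity. Singular normal matrices (rank-deficient
factors) fall back to a Moore–Penrose pseudo-inverse with a warning
rather than crashing; the $k \times k$ systems are otherwise solved
directly, which is cheap and stabler than forming explicit inverses.

**Projected gradients (PG)** take an additive step along a rescaled
gradient $P$ with a step size $\eta$ chosen adaptively as a ratio of a
gradient-weighted sum to a trace expression, then project:
$U \leftarrow [U - \eta_u P_u]_+$. With $\eta$ pinned to $1$ the update
is algebraically identical to MUR — this equivalence is enforced to
$10^{-10}$ entrywise in the acceptance tests and is a strong end-to-end
check on both implementations. At an exact factorization $P = 0$ and the
step-size ratio degenerates to $0/0$; the update for that factor is then
skipped, preserving the fixed point.

**Cyclic coordinate descent (COD, HALS-style)** sweeps the columns of
$U$ (ascending), then the columns of $V$ (ascending), then the entries
of $S$ (row-major), replacing each block by its exact non-negative
one-dimensional least-squares minimizer given everything else, with
updated coordinates used immediately inside the sweep. The update
projects the *full* updated value, $u \leftarrow [\,u + \delta\,]_+$:
projecting the increment alone would make coordinates non-decreasing and
could not minimize anything, so the full-value projection — standard
HALS semantics, and the unique reading under which each update is a
coordinate minimizer — is used. An independent residual-form oracle in
the test suite confirms each update is the exact clipped 1-D minimizer.
Stochastic or greedy sweep orders and repeated inner updates per factor
are out of scope; the sweep order is fixed cyclic.

## Stopping, start-up guard, divergence

A run stops when the relative objective change between successive
iterations satisfies $|D_{i+1} - D_i|/D_i < \varepsilon$ (default
$\varepsilon = 10^{-6}$). The absolute value is kept exactly as stated:
a sufficiently small *increase* also stops the run; catching genuine
divergence is a separate detector's job. If the previous objective is
exactly zero the run is already optimal and stops immediately.

The stopping rule is guarded by a minimum iteration count `nStart`
(default 100) because MUR's slow start-up plateau can trigger the
relative-change criterion spuriously. This guard is MUR's problem: ALS
and COD routinely converge, genuinely, in well under 100 iterations. The
benchmark harness therefore applies the guard to MUR only by default
(`startGuard = "mur-only"`; the other methods run with `nStart = 1`),
while direct `factorize()` calls honor whatever `nStart` the
configuration carries. A run that reaches `nStop` (default 50000)
iterations is flagged `max_iter_reached` and excluded from iteration and
runtime averages in all reports, so the cap cannot bias comparisons.

Divergence is detected on the trailing 20-iteration window: a non-finite
objective, an objective that increased in more than half of the window's
steps (oscillation), or a latest value exceeding the window minimum by a
factor of 10 (escalation). Two numerical guards keep the detector honest
near solutions: values at the floating-point floor (latest
$D \le 10^{-12}$) are never flagged, and an "increase" only counts above
a $10^{-9}$ relative size — an ALS run that has converged to
$D \sim 10^{-16}$ jitters by rounding, and a flat plateau jitters in its
last bits, neither of which is divergence. The window length (20) and
factor (10) make an inherently qualitative criterion operational; the
oscillation example (0.5, 5.0, 0.5, 5.0, ...) and monotone traces behave
correctly under them, and MUR/COD — provably non-increasing — never
trigger the detector in property tests.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 1e-6 | relative-change stopping threshold (dimensionless) |
| `nStart` | 100 iterations | minimum iterations before stopping may fire (start-up guard) |
| `nStop` | 50000 iterations | iteration cap; capped runs are non-converged |
| `k1`, `k2` | 20 (CLI) | factorization ranks; synthetic benchmarks fit at the generator's true ranks instead |
| division floor | 1e-12 | Hadamard-division denominators are floored, so MUR/PG never produce NaN while zero entries stay locked |
| divergence window / factor | 20 / 10 | trailing window and escalation factor of the detector |
| restart seeds | seed + 0, 1, ... | reproducible independent initializations |

Initialization fills $U$, $V$, $S$ (in that order) with uniform(0,1)
draws from a generator seeded per run; identical seeds give bitwise
identical runs, and the caller's RNG state is never touched.

## The synthetic-data generator

The generator emulates the two data regimes on which the methods behave
qualitatively differently, at desk scale (presets with
$n \cdot m \le 250{,}000$, true ranks $k_1 = k_2 = 4$, no noise):

* **Dense regime** (`dense-small`, density 1): $X = U S V^T + \sigma E$
  with dense uniform(0,1) truth factors and uniform noise $E$. Additive
  uniform (rather than Gaussian) noise keeps $X$ non-negative without a
  clipping step that would distort the noise model. This regime mirrors
  flattened image data.
* **Sparse regime** (`sparse-1pct` at density 1.3%, `sparse-sub1pct` at
  0.1%): the truth factors have sparse supports — each latent component
  is an overlapping co-cluster, a rectangle
  $\mathrm{supp}(u_k) \times \mathrm{supp}(v_k)$ of uniform(0,1) values
  paired through a positive diagonal core — so $X$ is simultaneously
  sparse, exactly rank $\le k$, and non-negative. Support sizes are
  calibrated so the union of rectangles covers approximately the
  requested fraction of cells; the achieved number of stored non-zeros
  differs from `density * n * m` only by support overlap and rounding.
  These matrices are what a tri-factor model can actually recover, which
  is the relevant property of real sparse benchmark data (ratings,
  document–term matrices). Zeroing a uniformly random mask of cells was
  considered and rejected: a randomly masked low-rank matrix is not
  low-rank — its own generating factors score $D \approx (1-d)/d \gg 1$
  against it — so no optimizer can reach a small objective on it and
  every method plateaus immediately at an uninformative fixed point.
  Masked cells here are true zeros in the objective (which sums over all
  $n \cdot m$ cells), not missing data.

What passing tests on this generator do **not** show: real data are not
exactly low-rank, have structured (non-uniform) noise and heavy-tailed
value distributions, and are orders of magnitude larger. Iteration
counts and speed-ups measured on the presets are therefore directional,
not quantitative, statements about real datasets; runtime comparisons in
particular depend on BLAS, storage layout and hardware.

## Problem sizes used in the checks

Step-level identities (PG↔MUR equivalence, monotonicity, coordinate
minimizers, normal equations, fixed points) run on random instances up
to $30 \times 30$ with ranks up to 5, one hundred instances per
property. Storage-path agreement uses density-5% matrices up to
$100 \times 80$. Parameter recovery uses a noise-free $60 \times 40$
rank-4 instance with ten restarts: this size is representative of the
regime where all gradient-type methods converge reliably, while at the
very smallest sizes (e.g. $30 \times 20$) noise-free exact-rank problems
expose a stopping-rule artifact — COD keeps making *geometric* progress
($D$ shrinking by a near-constant factor per iteration, relative change
never falling below $\varepsilon$) until the floating-point floor at
$D \sim 10^{-28}$, beyond the 50000-iteration cap. That is an artifact
of exactly factorizable synthetic data; on noisy or real data the
objective plateaus at a positive value and the relative-change rule
fires normally. The benchmark comparison runs the full
four-method × three-preset protocol with ten restarts per cell, which is
what `scripts/acceptance.R` reproduces end to end.

## Design choices at genuinely open points

* **Sub-update propagation in PG:** whether the reconstruction terms are
  recomputed between the $U$, $V$, $S$ sub-updates is not forced by the
  update formulas; sequential propagation (recompute with the updated
  earlier factors) is used, matching MUR and ALS.
* **COD shape conventions:** the per-column curvature for the $u_{\cdot i}$
  update is the scalar $s_{i\cdot} V^T V s_{i\cdot}^T$, pairing column
  $i$ of $U$ with row $i$ of $S$ — the only shape-consistent reading.
* **ALS solves:** linear solves against the $k \times k$ normal matrices
  instead of explicit inverses; pseudo-inverse only on singularity.
* **Normalized objective everywhere:** traces, stopping and reports all
  use $D$; callers wanting the raw Frobenius loss multiply by
  $\|X\|_F^2$ once.
* **Benchmark fitting ranks:** synthetic benchmarks fit at the
  generator's true ranks (4) rather than a fixed 20 — at desk scale the
  interesting comparison is between methods on a recoverable problem,
  not between over-parameterized models.

## Known limitations

* The objective is non-convex: every method can converge to a local
  minimum. On the sparse presets, random initialization recovers the
  planted factors in roughly 60–80% of restarts (a missed co-cluster is
  a genuine local minimum); ALS additionally diverges outright on some
  starts, on dense data especially. No method is guaranteed the global
  optimum, and the package reports per-restart spans rather than hiding
  them.
* ALS's non-negativity heuristic (clip after solving) is exactly what
  makes it fast and exactly what makes it unstable; use COD when
  stability matters.
* Runtime measurements are wall-clock per iteration loop in R; they are
  comparable across methods within a run but not across machines.
* Only the Frobenius objective without constraints is implemented;
  KL/Alpha/Beta divergences, orthogonality and L1 penalties, stochastic
  mini-batch variants, and held-out-data evaluation are out of scope.
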