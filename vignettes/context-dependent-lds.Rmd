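---
title: "Inferring context-dependent computation with constrained linear dynamical systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring context-dependent computation with constrained linear dynamical systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxlds)
```

## The problem

During contextual decision-making, the same sensory evidence must be
integrated or ignored depending on a task rule. In the classic contextual
random-dots task, a subject reports either the net motion direction or the
dominant color of a dots display; motion and color coherence each take six
signed levels (three strengths by two directions), giving a 6 x 6 grid of
36 stimulus conditions presented under two contexts ("attend motion",
"attend color"). Prefrontal population recordings in this task are usually
summarized as condition-averaged, per-neuron z-scored firing-rate tensors
`Y[n, t, k, cx]` (neurons x 50-ms bins x conditions x contexts).

`ctxlds` fits discrete-time linear dynamical systems (LDS) jointly to the
two contexts of such a tensor and asks *which* parameters must change
across contexts to explain the data: the recurrent dynamics, the inputs,
or both. It then characterizes the fitted dynamics — eigenmode spectra,
non-normality, input loads, Gramians — and simulates the causal
perturbation experiments that would discriminate between mechanisms.

## The model

For condition $k$ and context $cx$,

$$x_k(t) = A_{cx}\, x_k(t-1) + B^m_{cx} u^m_k(t) + B^c_{cx} u^c_k(t),
\qquad y_k(t) = C\, x_k(t) + d,$$

with $x(0) = x_{0,cx}$. The observation map $C$ (orthonormal columns after
the post-hoc similarity transform in `orthonormalize()`) and bias $d$ are
always shared across contexts; the initial condition is always
per-context (it can shift trajectories between contexts but, being
condition-independent, cannot perform input selection). The four model
classes `{A,B}`, `{A,Bcx}`, `{Acx,B}`, `{Acx,Bcx}` free the dynamics
matrix and/or the input subspaces per context.

**Inputs.** Each input dimension of a modality carries two learned time
courses (one per evidence direction) and six coherence scalars, one per
signed level; a condition's input is
`course[direction](t) * scalar[level]`, shared with every other condition
containing that coherence. This is what makes leave-one-condition-out
generalization possible. With `time_varying = FALSE` the courses are fixed
at 1. Because a rescaling of `B` can always be absorbed by the inverse
rescaling of `u`, all reported input quantities use the product
`B u(t)`, never `u` alone.

**Parameter bookkeeping.** `count_parameters()` counts each slot exactly:
`A` ($L^2$, doubled per context), `B` ($LU$, doubled per context), loading
($NL$), bias ($N$), initial conditions ($2L$), and $2T + 6$ input
parameters per input dimension. The six coherence scalars are counted *per
input dimension*, not per modality; this is the parameterization under
which the standard published dimensionalities (e.g. 18 latents, 3+3
inputs, 727 neurons, 15 bins) give 14,605 parameters. A per-modality
sharing of the scalars is representable by constraining columns equal, but
it is not the default and is not what the counts assume.

**Objective.** Fits minimize

$$\mathrm{Cost} = \frac{1}{NTKC}\sum_{t,k,cx}\lVert y - \hat y\rVert_2^2
  + \lambda_{inp}\sum_{t,k,cx}\lVert B_{cx} u_{t,k,cx}\rVert_2^2 .$$

On z-scored data the MSE term is the fraction of unexplained variance. The
input penalty (default $\lambda_{inp} = 10^{-5}$) breaks the degeneracy
between input-driven and recurrently generated structure in favor of weak
inputs, so integration-like signals are encouraged to arise through `A`.
There is no observation-noise model and no latent posterior: the model is
a deterministic forward predictor fitted by gradient descent, which is the
appropriate reading when the data are trial averages.

## Tensor factor regression

`fit_tfr()` implements a low-rank factorization that strictly generalizes
the LDS: an orthonormal loading, a per-context core tensor indexed by
(latent, lag, input channel), and input regressors (direction courses,
coherence scalars) repeated across conditions by two fixed indicator
tensors — a causal convolution indicator (`T_ind[t, t', j] = 1` iff
`t - t' = j - 1`) and a condition-routing indicator (`Q_ind`: each
condition hits one motion cell, one color cell, and a shared baseline
cell). The LDS corresponds to the constraint `core[, lag, ] = A^lag B`,
with the baseline channel carrying `A^t x0`; `lds_to_core()` /
`as_tfr()` realize this embedding exactly (tested to 1e-9), so TFR
performance bounds what any LDS can achieve. The core is implemented as
causal by construction (lag-indexed through `T_ind`); acausal influence
is not representable, which is the intended design rather than a
limitation of the fit. The direction/coherence index counts use the real
input dimensions only — the baseline channel contributes a single course
and a single scalar.

TFR is fitted by the same ADAM route as the LDS (plain reconstruction
MSE). An alternating solver (`fit_tfr_als()`) — closed-form reduced-rank
regression for loading and core, gradient refinement of the input factors
— is provided as an independent cross-check; the two agree on toy
problems within the tolerance tested in `test-tfr.R`.

## Optimization

Gradients of the full objective are computed analytically by
backpropagation through the latent recursion in compiled code
(RcppArmadillo) and verified against central finite differences for every
model class in the test suite. Defaults (`fit_config()`): ADAM with
learning rate 0.009, initialization of every parameter from
$\mathcal N(0, 0.01^2)$, convergence when the cost changes by less than
$10^{-5}$ (checked every iteration on the training objective; no early
stopping on held-out data), minimum 5,000 and maximum 10,000 iterations.
Because the fitted latent basis is arbitrary, every fit is
orthonormalized post hoc; this is a similarity transformation, so
predictions and eigenvalues are unchanged (tested at 1e-10).

A normal-dynamics variant adds $\lambda_{dyn}\lVert AA^\top - A^\top
A\rVert_F^2$ with the loading frozen to a previously fitted orthonormal
map (`freeze_C`), so that normality of the latent dynamics is preserved in
the reconstructed responses.

**Restarts.** `multi_restart()` refits from independent seeded
initializations and sorts by training error. Summaries across restarts
average scalar derived quantities (norms, loads, angles, fractions) —
never raw eigenvectors, whose sign and within-pair rotation are not
identified.

## Model selection

`loocv()` removes one condition (both contexts) per fold — 36 folds on
the standard grid — refits, and forward-generates the held-out condition
from the refitted initial conditions and the coherence inputs inferred
from the remaining conditions (each level of the held-out condition still
appears in five other conditions). Held-out data never enter a gradient
step, which the suite verifies by corrupting the held-out condition and
checking the fold fit is bit-identical. Folds whose held-out coherence is
unique (possible only on reduced grids) are skipped with a warning. One
seed per fold is the default; the fold count, mean, and SEM across folds
are reported per grid point of a (latent, input) dimensionality sweep.

## Dynamics characterization

All analyses operate on orthonormalized parameters.

- `eigenmodes()`: eigenvalues with unit-norm right eigenvectors and left
  eigenvectors taken as rows of $R^{-1}$ (deliberately *not* unit
  normalized, so that per-mode input loads sum back to `B u(t)` exactly
  — the reconstruction identity tested to 1e-9). Ordering is by
  descending norm, ties broken by descending rotation frequency, then
  positive-imaginary member first. Matrices whose eigenvector condition
  number exceeds 1e6 warn; above 1e8 they are refused as near-defective.
- `time_constant()`: $\tau = 50\,\mathrm{ms} / (-\log\lvert\lambda\rvert)$;
  $\lvert\lambda\rvert = 1$ is an integration mode ($\tau = \infty$), norms
  above 1 return the signed growth constant. Slow modes are
  $\lvert\lambda\rvert > 0.8$ ($\tau > 224$ ms, about a third of a 750-ms
  trial); the slowest, $\lvert\lambda\rvert > 0.9$ ($\tau > 475$ ms).
- `rotation_frequency()`: $f = 20\,\omega/2\pi$ Hz at 50-ms bins; real
  negative eigenvalues alternate sign each bin and are reported at the
  Nyquist frequency (10 Hz).
- `henrici_index()`: normalized departure from normality in $[0, 1]$.
  Note that a numerically "zero" index is of order sqrt(machine
  precision), since it is the square root of a cancellation-limited
  difference.
- `input_loads()`: non-normalized projections of `B u(t)` onto left
  eigenvectors; conjugate pairs share one load. By default downstream
  summaries use the strongest positive coherence and average over the
  full trial; the averaging window is configurable since nothing in the
  method fixes it.
- `observability_gramian()`: solves $A^\top Q A - Q + C^\top C = 0$ by
  Kronecker vectorization (exact for the latent sizes in scope, residual
  checked at 1e-8); refuses unstable systems, reporting the spectral
  radius. Top eigenvectors of $Q$ are the most-amplifying directions.
- `cd_ci_decompose()`, `mode_alignment()`, `demix_input_plane()`,
  `summary_norms()`: condition-dependent vs condition-independent
  structure, alignments of data axes with right eigenvectors (absolute
  dot products for real modes; cosines of minimum subspace angles to the
  pair plane for complex modes — reported non-negative), the regression
  of inputs on (coh, |coh|) that exposes curved coherence manifolds, and
  input/output norm traces with optional across-condition mean
  subtraction (the mean is degenerate between `x0` and the inputs, so
  coherence-specific claims always subtract it).

## Perturbation experiments

`perturb()` simulates causal probes. State perturbations (default norm 10,
first analyzed bin) are injected along data PCs mapped into latent space
through $C^\top$ — with an orthonormal loading this is the unique
norm-consistent latent image of a neuron-space perturbation. For a linear
model the effect (perturbed minus unperturbed trajectory) is identical
across conditions and scales linearly with the norm; both are asserted in
tests. A response is *amplifying* when the effect norm rises above its
onset value before decaying. Input perturbations switch one modality off
over a 2-bin (100-ms) window, the length being configurable since no
canonical value exists. `amplification_screen()` counts amplifying PC
perturbations; on synthetic ground truths this discriminates
dynamics-switching (strongly non-normal) from input-switching
(near-normal) regimes in at least 19 of 20 seeded runs in the acceptance
suite.

## The synthetic-task generator

`sample_ground_truth()` + `generate_observations()` emulate the data
regime the method targets, so that every downstream stage is testable with
no external data:

- **Task structure:** the full 6 x 6 signed-coherence grid with default
  strengths 0.05 / 0.15 / 0.5 — values typical of random-dots work.
- **Dynamics:** the eigenvalue plan is realized *exactly* by construction
  (real block form conjugated by a basis that `non_normality` skews away
  from orthogonal; 0 gives a normal matrix). The default plan mixes a
  near-unity mode (0.97), slow real and rotational modes, and fast modes,
  with slow-mode fraction 1/2.
- **Inputs:** smooth transient bumps rising to their peak by bin 3 (the
  inputs are strong over the first third of the trial), with staggered
  peaks per dimension; dimension 1 scales with signed coherence,
  dimension 2 with coherence magnitude. This makes the input subspace
  genuinely multidimensional and identifiable, and reproduces the curved
  coh/|coh| layout that `demix_input_plane()` recovers.
- **Context regimes:** `input-switching` scales the irrelevant modality's
  input subspace by `input_gain_irrelevant` (default 0.6, a moderate
  attentional modulation); `dynamics-switching` redraws the eigenbasis per
  context with the same spectrum; `both` and `none` as named.
- **Observations:** `y = C x + d` plus i.i.d. Gaussian rate noise
  (default SD 0.1), then per-neuron z-scoring over all times, conditions,
  and contexts jointly — the single pooled window is the package's fixed
  convention. Zero-variance neurons error by default
  (`drop_degenerate = TRUE` drops them); real neurons always vary.
- **Sizes:** defaults are desk scale — 60 neurons, 15 bins, 8 latents,
  2+2 inputs — large enough to exercise every analysis while keeping a
  fit at seconds scale. Recording-scale dimensions (hundreds of neurons,
  18 latents) are a configuration choice, not a default.

What the generator does **not** emulate: spiking variability and
trial-level noise (noise is i.i.d. Gaussian on the rate scale),
pseudo-population assembly artifacts, nonlinear dynamics, and acausal or
time-varying effective connectivity. Passing recovery tests on this
generator therefore shows the estimator is correct and well-conditioned
under its own assumptions; it does not certify those assumptions for any
particular recording.

## Numerical choices and degenerate inputs

- Time indexing: `x(0) = x0` precedes the first observed bin; the first
  observation is built from `x(1)`.
- Rank-deficient loading maps are refused by `orthonormalize()`
  (tolerance 1e-10 relative to the top singular value).
- `mse()` on mismatched shapes, negative penalty weights, zero vectors in
  alignment queries, unstable systems in Gramian queries, onset outside
  the trial, and rank-deficient axis sets in projections are all explicit
  errors, not silent coercions.
- Unstable ground truths that overflow the simulation horizon raise an
  error naming the largest eigenvalue norm.
- Serialization uses JSON for tensors/parameters (full precision,
  validating constructors on read) and TSV for tables; indicator tensors
  are always rebuilt, never stored.

## Problem sizes in the test suite

The suite exercises recovery at the generator's desk scale (60 neurons, 8
latents, 36 conditions, noiseless for identifiability checks) with three
restarts, and reduced iteration budgets for the 36-fold cross-validation
ordering checks — noiseless fits converge well before the default
iteration caps, and the tested tolerances (slow-mode eigenvalue norms
within 0.02, input subspaces within 15 degrees) are met with margin at
these settings. Subspace comparisons between ground truth and fit are made
in the common z-scored observation space, where both are identified.

## Known limitations

- The fit is non-convex; different initializations can reach different
  mechanisms with near-identical error. That degeneracy is a property of
  the inference problem, which is why class comparison uses held-out
  error and why perturbation experiments are the proposed discriminator.
- The Kronecker Lyapunov solve is $O(L^6)$ and intended for latent
  dimensions in the tens, not hundreds.
- `{Acx,Bcx}` fits are supported throughout but interpretation of "which
  mechanism" is then a spectrum, not a dichotomy.
- No probabilistic state-space machinery (Kalman smoothing, EM,
  observation-noise models) is included, by design: the estimand is the
  deterministic dynamics of trial-averaged responses.
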