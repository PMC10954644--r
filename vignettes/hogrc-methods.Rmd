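---
title: "Higher-order Granger reservoir computing: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-order Granger reservoir computing: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Given only a regularly sampled multivariate time series
$\mathbf{x}(t) \in \mathbb{R}^N$ from an unknown dynamical system
$\dot{\mathbf{x}} = f(\mathbf{x})$, `hogrc` addresses two coupled tasks:

1. **Structure inference.** For every variable $u$, find its *higher-order
   neighbours*: the groups of variables that enter $\dot u = g(\mathbf{s}_u)$
   through inseparable terms.  Writing
   $g = g_1(\mathbf{s}_{u,1}) + \dots + g_{D_u}(\mathbf{s}_{u,D_u})$ with no
   set contained in another, each $\mathbf{s}_{u,i}$ of $k$ variables is a
   $(k-1)$-dimensional simplicial complex; the per-node collections
   $\mathcal{S}_u$ form a hypergraph on the variables.  For the Lorenz63
   system, for instance, $\dot z = -\beta z + xy$ gives
   $\mathcal{S}_z = \{\{z\}, \{x, y\}\}$: the product $xy$ is one
   inseparable pairwise term, not two independent links.
2. **Forecasting.** Use the inferred structure to build node-level
   reservoir computers whose input and adjacency matrices encode the
   complexes, and forecast the system closed-loop, feeding predictions back
   as inputs.

# The model

## Node-level structured reservoirs

A reservoir computer (echo-state network) evolves a hidden state by the
leaky-tanh recursion
$$\mathbf{r}(t+\Delta t) = (1-l)\,\mathbf{r}(t) +
  l\tanh\left[\mathbf{W}_{\mathrm{in}}\mathbf{x}(t) + \mathbf{A}\mathbf{r}(t)
  + \mathbf{b}\right],$$
and only a linear readout is trained.  The readout target is the one-step
residual: $\hat u(t+\Delta t) = u(t) + \mathbf{W}_{\mathrm{out}}
\mathbf{r}(t+\Delta t)$, so the readout approximates the flow increment.
The readout solves a Tikhonov-regularised least squares problem in closed
form (`fitReadout()`); the penalty is the squared Frobenius norm, the
standard ridge reading.

The higher-order model (`buildNodeReservoir()`) assigns each variable $u$
its own reservoir whose $D_u$ complexes each own an equal block of
$\lfloor n/D_u \rfloor$ neurons: block $i$'s input rows are nonzero only in
the columns of $\mathbf{s}_{u,i}$, and the adjacency is block-diagonal, so
hidden units can only mix information within one complex.  The classic
shared reservoir (`buildClassicRC()`) is the degenerate single-complex case
over all variables with a multivariate readout; the parallel-RC baseline
(`buildPRC()`) is the single-complex case over a node's pairwise
neighbours.  Every structured pair $(\mathbf{W}_{\mathrm{in}}, \mathbf{A})$
is a valid classic-reservoir pair — the structured model class is contained
in the unstructured one — which the test suite checks by driving the
unconstrained recursion with the structured matrices.

Three practical choices matter here:

* **Standardisation.** Raw chaotic states (Lorenz $|x| \approx 20$)
  saturate the tanh.  `trainForecaster()` standardises each variable by its
  training mean and standard deviation and de-standardises forecasts; this
  is equivalent to absorbing the scales into the input weights.
* **Common random numbers.** Each complex's input block, adjacency block
  and bias are drawn from a substream keyed by `(seed, node, complex)` and
  truncated to the block size in use.  Candidate sets sharing a complex
  therefore share its features, so error comparisons between candidate sets
  isolate the complex under test instead of comparing two fresh random
  models.  This removes almost all matrix-draw noise from the greedy
  decisions below.
* **Per-block spectral radius.** Each decoupled adjacency block is rescaled
  exactly (dense eigendecomposition; blocks are small) to the target
  spectral radius, which gives the whole block-diagonal matrix that radius.
  A target of zero removes the recurrence entirely.

## Forecasting

`multiStepForecast()` warms all reservoirs on true samples ending at the
anchor, then advances every node synchronously: each node predicts its next
value from the shared state, and the full predicted state is the next
input.  Divergence (non-finite states) truncates the forecast, which then
scores only the steps it produced.  Forecast quality is measured by the
$\sigma_i$-normalised RMSE and the *valid prediction steps* (VPS), the
first step at which that RMSE exceeds a threshold $\epsilon_r$
(conventionally 0.01).

# Structure inference

## The Granger test and the greedy search

A candidate complex set $\mathcal{C}$ for node $u$ is scored by the
held-out one-step error of a reservoir built from it
(`candidateError()`): the model is fitted on the first 80% of the supplied
window and evaluated on the remaining 20% (the paper-style definition
leaves the split unspecified; held-out evaluation is what gives deletions
of redundant-but-flexible complexes a fair chance).  A complex is judged
*non-causal* when removing it does not worsen this error beyond a
tolerance; `inferNeighbors()` alternates deletion sweeps with
dimensionality-reduction sweeps (replacing a complex by its facets, with
facets already covered by a larger retained complex absorbed) until the
set is stable.  Both sweeps are *best-first*: all eligible moves are
evaluated and the lowest-error acceptable move is applied first.  This
matters — a fixed traversal order can walk into side structures that fit
discretisation artefacts (below) and stall there.

## Why the evaluation reservoir is memoryless

The inference-stage reservoir (`inferenceConfig()`) uses leak 1 and
spectral radius 0: each block is a bank of static random tanh features of
its complex's *current* values.  With any recurrence, a block masked to one
variable can reconstruct the others from that variable's recent history —
for Lorenz $z$, $xy \approx \dot z + \beta z$ is encoded linearly in two
consecutive $z$ samples — and empirically even weak recurrence lets every
candidate reach a common error floor, destroying the discrimination the
deletion test depends on.  Memoryless blocks can only represent functions
of their own complex's variables, which is exactly the semantics the
Granger comparison needs.  (The forecasting models keep their recurrence;
only candidate scoring is memoryless.)

## Why the regression target is a symmetric increment

Data sampled at step $\Delta t$ obey the flow map, not the vector field:
the forward increment $u(t+\Delta t)-u(t)$ contains
$O(\Delta t^2)$ terms proportional to $\ddot u$, which mix variables beyond
the vector field's structure (for Lorenz $x$, $\ddot x$ contains an $xz$
product although $\dot x = \sigma(y-x)$ does not).  Scoring candidates on
forward increments therefore rewards spurious cross complexes.  The
inference stage instead regresses the symmetric increment
$(u(t+\Delta t) - u(t-\Delta t))/2$ on features of $\mathbf{x}(t)$ — a
central-difference derivative estimate whose even-order terms cancel,
leaving $O(\Delta t^3)$ contamination — and predicts
$\hat u(t+1) = u(t-1) + 2\,\mathbf{W}\mathbf{r}(t)$, still using only data
up to time $t$.

## Calibrated acceptance tolerances

Even with the symmetric target, refining towards the true vector-field
structure costs a small systematic error penalty (the residual
discretisation terms are fittable by coarser masks), while removing a
genuine leading-order term costs an error of the order of the one-step
increment itself.  The acceptance tolerances are therefore calibrated per
node between those two orders, as fractions of the node's mean one-step
*signal* increment (standardised): by default 0.003 for deletions (the
Granger test proper) and 0.03 for splits, which additionally pay the
factoring penalty.  A literal fixed threshold of $10^{-7}$ is supported
through the `epsE` argument, but at the error floors reachable by
random-feature regression it is far below both scales, and the search then
(correctly, by its own criterion) refuses every move; the calibrated
tolerances are the package default.

Two refinements make the calibration robust:

* **Noise-corrected scale.** White observation noise is estimated from the
  cascade of difference variances (the smooth-signal part of $k$-th
  differences decays geometrically while the noise part grows with the
  central binomial coefficients), the signal increment is denoised
  accordingly, and the tolerance is shrunk by the quadratic suppression
  that a noise floor applies to mean-absolute-error differences.
* **Per-node scaling.** All errors are reported on the standardised scale
  of the target variable (consistent with the $\sigma_i$-normalised RMSE
  convention), so tolerances transfer across variables and systems.

## Known limitations under observation noise

With noisy observations, *every* correlated variable becomes genuinely
predictive: conditioning on more noisy coordinates denoises the target, so
a structure that keeps an informative-but-non-causal variable can beat the
true sparse structure on held-out error.  In our experiments the showcased
Lorenz $z$ recovery survives noise up to roughly
$\sigma_n \approx 0.05$ (relative to each variable's scale), but exact
recovery of all three Lorenz neighbour sets fails well below
$\sigma_n = 0.2$, and no amount of smoothing, subsampling or threshold
tuning we tried restores it — the decision windows genuinely invert.  The
corresponding acceptance test is left failing rather than weakened; treat
noisy-data structure inference with caution and, where possible, reduce
noise at the source or validate complexes by forecasting.

# Study conditions and the synthetic generator

The simulators (`simulateSystem()`) integrate each benchmark system with
fixed-step RK4 at its conventional step size: Lorenz63
($\sigma=10, \rho=28, \beta=8/3$, $\Delta t = 0.02$), coupled Lorenz63
($\gamma = 0.5$, linear/sine/absolute $y$-coupling, per-subsystem scales
$h_i \sim U[0.9, 1.1]$), FitzHugh–Nagumo networks
($a=0.28, b=0.5, c=-0.04, \gamma=0.5$, $\Delta t=0.25$), coupled Rössler
($a=b=0.2, c=-6, \gamma=1$, $\Delta t = 0.1$), simplified Hodgkin–Huxley
networks with sigmoidal synapses ($\Delta t = 0.04$), and a higher-order
Kuramoto model whose triangle interactions come from the 3-cliques of the
pairwise graph ($\gamma_1=\gamma_2=0.4$, $\Delta t = 0.08$, natural
frequencies $U[-1,1]$).  Initial conditions are drawn uniformly from a
system-specific box and a 1000-step transient is discarded; coupling
weights are $U[0.5, 1.5]$ on generated topologies (ring, Erdős–Rényi,
Barabási–Albert via `igraph`, or an explicit edge list).  The stock
5-subsystem network (`defaultNetwork5()`) is a fixed directed 7-edge
topology with seeded weights, standing in for a coupling diagram whose
exact weights are not published.  Observation noise is i.i.d. Gaussian,
by default scaled per variable.

What the generator does *not* emulate: dynamical (process) noise, missing
data, irregular sampling, and non-stationary parameters.  Passing tests on
these data therefore demonstrate correctness of the algorithms under
clean, fully observed, stationary conditions — not robustness to the full
messiness of experimental recordings.

Problem sizes used in the test suite were chosen to keep a full run
comfortable on a single CPU: trajectories of 5000 samples (60% training),
inference reservoirs of $n = 300$, comparison forecasts over a 500-step
horizon from 50 anchors at $n = 300$ per node.  These are deliberate
scaled-down choices; all sizes are configuration arguments.

# Hyperparameters

| parameter | default | units / range | role |
|---|---|---|---|
| `n` | 600 (forecast), 300 (inference) | neurons | capacity per node; rounded down to a multiple of $D_u$ |
| `leak` | 0.6 (forecast), 1 (inference) | (0, 1] | update inertia; 1 = no leak memory |
| `spectralRadius` | 0.9 (forecast), 0 (inference) | ≥ 0 | recurrence strength / memory |
| `inputScale` | 0.5 (forecast), 0.7 (inference) | — | feature sharpness on standardised inputs |
| `density` | 0.05 | (0, 1] | nonzeros in each adjacency block |
| `ridge` | 1e-6 (forecast), 1e-8 (inference) | — | Tikhonov coefficient |
| `washout` | 200 / 50 | steps | discarded transient before regression |
| `epsScale` / `epsSplitScale` | 0.003 / 0.03 | fraction of signal step | deletion / split tolerances |
| `errorSplit` | 0.2 | fraction | held-out share of the inference window |

The comparison experiments use a shared reduced configuration for all
three methods (same $n$, leak, radius, scale, ridge), with the input scale
tuned per system (0.8 for the coupled-Lorenz runs, 1.0 for the smoother
FitzHugh–Nagumo runs) — per-system hyperparameter choices are conventional
for echo-state models.

# Numerical notes, degenerate inputs, tie-breaking

* Candidate sets are kept canonical: members sorted, sets ordered by
  decreasing dimension then lexicographically; duplicate and subsumed
  complexes are removed when sets are canonicalised, while intermediate
  candidate sets during the search may transiently contain subsumed
  members.  Ties among moves are broken by the canonical order through
  `which.min`, making the search fully deterministic given the seed.
* A constant variable (zero variance) standardises with scale 1 and fits
  trivially; `rmseAt()` refuses zero $\sigma_i$ instead.
* Ridge systems at $\lambda_W = 0$ fall back to the pseudoinverse with a
  warning.
* The closed-loop forecaster flags divergence and returns the finite
  prefix; comparison tables score such forecasts at their divergence
  point.
* Seeds: one master seed fans out into named substreams (initial
  conditions, weights, noise, anchors, per-complex matrices), so changing
  one stage never perturbs another.

# What the angle codec is for

Phase systems (the higher-order Kuramoto model) are handled through a
wrapped encoding: inputs $(\sin\theta_i, \cos\theta_i)$ per oscillator and
phase-velocity targets $\Delta\theta = (\theta(t+1) - \theta(t))/\Delta t$,
decoded by $\hat\theta(t+1) = \theta(t) + \Delta\theta\,\Delta t$
(`encodeAngles()` / `decodeDelta()`).  This avoids $2\pi$ wrap artefacts in
both the features and the error metric; evaluation of phase forecasts is
done on the encoded states for the same reason.
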