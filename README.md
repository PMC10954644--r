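# hogrc — higher-order Granger reservoir computing

`hogrc` infers the **higher-order interaction structure** of a dynamical
system from multivariate time series and uses it for **closed-loop
forecasting**, combining node-level reservoir computing (echo-state
networks) with a Granger-causality-style greedy search.

## The problem and who it is for

Many complex systems — coupled neuronal populations, oscillator networks,
chaotic flows — are governed by equations whose right-hand sides mix
variables through *inseparable* terms.  Writing each node's equation as a
sum of inseparable pieces,

```
du/dt = g1(s_u,1) + g2(s_u,2) + ... + g_D(s_u,D),     s_u,i ⊄ s_u,j,
```

each variable group `s_u,i` of k variables is a (k−1)-dimensional
simplicial complex, the node's *higher-order neighbour*.  For the Lorenz63
system, `dz/dt = −βz + xy` gives `S_z = {{z}, {x, y}}`: the product `xy`
is one pairwise complex, not two independent links.  Pairwise causal
network methods cannot make this distinction; this package is for
researchers who need it — either to understand the interaction structure
itself or to exploit it for better long-range forecasts.

## The method

1. **Structured reservoirs.**  Each variable gets its own echo-state
   reservoir `r_u(t+Δt) = (1−l) r_u(t) + l·tanh[W_in,u x(t) + A_u r_u(t) + b]`
   whose input matrix is partitioned into one row block per complex
   (block i sees only the variables of `s_u,i`) and whose adjacency is
   block-diagonal.  Only the linear readout is trained (ridge regression on
   one-step residuals, `û(t+Δt) = u(t) + W_out r_u(t+Δt)`).
2. **Granger-style structure search.**  Starting from a coarse candidate
   set (by default the single all-variables complex), the search deletes
   any complex whose removal does not worsen the held-out one-step error
   beyond a calibrated tolerance, and tries to split complexes into their
   facets, until the set is stable.  Candidate models share per-complex
   random features, so comparisons isolate the complex under test.
3. **Closed-loop forecasting.**  The trained per-node models advance
   synchronously, feeding the full predicted state back as the next input.
   Accuracy is scored by the σ-normalised RMSE and the number of valid
   prediction steps (VPS) before it crosses a threshold.

Three model families share this machinery and are compared by
`runComparison()`: the classic single shared reservoir (`rc`), parallel
node-level reservoirs over pairwise neighbours (`prc`), and the
higher-order structured model (`hogrc`).

Simulators for the benchmark systems are included: Lorenz63, coupled
Lorenz63, FitzHugh–Nagumo / Rössler / simplified Hodgkin–Huxley networks,
and a higher-order Kuramoto model with triangle interactions.

## Worked example

```r
library(hogrc)

sys   <- systemParams("lorenz63")                       # sigma=10, rho=28, beta=8/3
traj  <- simulateSystem(sys, steps = 5000, transient = 1000, seed = 1)  # dt = 0.02
train <- windowTrajectory(traj, 1:3000)                 # first 60%

structure <- inferStructure(train, cfg = inferenceConfig())
structure
#> HigherOrderStructure: 3 nodes
#>   S_x = {{x}, {y}}
#>   S_y = {{x,z}, {y}}
#>   S_z = {{x,y}, {z}}

model <- trainForecaster(train, "hogrc", structure,
                         reservoirConfig(n = 300, spectralRadius = 0.5,
                                         ridge = 1e-8, seed = 1))
fc  <- multiStepForecast(model, windowTrajectory(traj, 3301:3500), 500)
validPredictionSteps(fc, windowTrajectory(traj, 3501:4000), epsR = 0.01)
#> [1] 280
```

The inferred sets are exactly the inseparable terms of the Lorenz
equations — e.g. `S_y = {{y}, {x,z}}` because `dy/dt = ρx − y − xz` merges
`ρx` and `−xz` into one inseparable `(x,z)` pair.  The forecast stays
within 1% normalised RMSE of the true trajectory for 280 steps (5.6 time
units, several Lyapunov times).

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/hogrc.R pipeline --config run.yaml --seed 1 --out out/
```

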