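# driftlab

Simulation toolkit for **representational drift** modeled as random
diffusion restricted to the solution space of a feed-forward neural
network's synaptic weights.

Neural recordings show that the activity patterns encoding a fixed memory
or behavior keep changing over time even when the behavior itself is
stable. driftlab implements a framework that makes this phenomenon
tractable: a single-hidden-layer network

```
Z = W Φ(U X + B),    Φ(v) = min(max(v, 0), α)
```

with inputs `X` (Nx × P conditions), plastic weights `U` (Ny × Nx), a
clipped-threshold-linear activation `Φ`, and a fixed linear readout `W`
(Nz × Ny), must keep the readouts `Z` of its stored input conditions
exactly constant while `U` — and with it the hidden representation
`Y = Φ(UX + B)` — diffuses. The package is aimed at computational
neuroscientists studying drift, continual learning and the
robustness–learnability trade-off.

The machinery rests on a per-neuron change of basis: extending `X` to an
invertible `Xext = [X | Q]` gives coordinates `η = U Xext` whose first `P`
columns are exactly the input currents of the stored conditions. Drift
then decomposes into

* **unconstrained** coordinates (kernel of `X`) — free diffusion,
* **semiconstrained** coordinates of inactive (current ≤ 0) and saturated
  (current ≥ α) neurons — one-sided diffusion, clamped exactly at the
  threshold with a transition into the engaged set,
* **engaged** coordinates — diffusion inside the kernel of the engaged
  readout submatrix `Wμ`, rescaled so that no neuron crosses a threshold,

with an optional per-neuron weight-norm bound `Umax` acting as a
reflecting boundary. On top of the simulator sit an allocation procedure
(recentre a condition's η column in the engaged regime to restore
gradients), gradient-descent learners in weight- and η-coordinates (the
latter provably interference-free), and the evaluation protocols for
robustness to weight perturbations, sequential learnability, and
continual-learning interference.

## Worked example

Learn the eight standard mappings, drift for 50,000 steps, and compare
robustness before and after:

```r
library(driftlab)

task <- generate_task(network_config(), seed = 1)   # Nx=15 Ny=12 Nz=1 P=8 α=5
set.seed(2)
sol <- learn_solution(task)                         # allocate + Adam batch fit
cat("converged:", sol$report$converged, " RMS error:", signif(sol$report$final_rms, 3), "\n")
#> converged: TRUE  RMS error: 0.0375

st <- drift_state(sol$U, task, frame = sol$frame)
set.seed(3)
traj <- run_drift(st, drift_config(sigma = 0.05, Umax = 350, n_steps = 50000))
print(traj)
#> drift_trajectory: 50000 steps, 501 records
#>   engaged fraction: 1.000 (start) -> 0.167 (end)
#>   max cumulative readout change: 4.9e-13

before <- robustness_eval(sol$U, task, rho = 1, n = 100, seed = 4)
after  <- robustness_eval(weights(traj$state), task, rho = 1, n = 100, seed = 4)
cat(sprintf("perturbation RMS error: %.1f before drift, %.1f after\n", before$rms, after$rms))
#> perturbation RMS error: 36.9 before drift, 19.6 after
```

Three things happened, and they are the package's core results in
miniature. The stored readouts never moved (cumulative change 5e−13) even
though the weights diffused the whole time. The fraction of engaged
(neuron, condition) pairs fell from 1.0 to 0.17: unbiased exploration of
the solution space favors sparsely engaged representations, because
disengaged neurons contribute whole half-lines of weight space rather than
single points. And that sparsification pays off: the same weight
perturbations produce roughly half the readout error after drift.

The two-neuron worked example (`toy_demo()`) runs the full
allocate → learn → drift → allocate → learn pipeline on a task small
enough to visualize, and demonstrates exactly-zero interference of
η-coordinate learning with the stored mapping.

A thin command-line front end is included at
`inst/scripts/driftlab.R` (subcommands `toy-demo`, `drift-demo`,
`robustness-sweep`, `learnability-sweep`, `continual`), driven by YAML
configs via `load_config()` and writing checksummed run directories via
`persist_run()`.

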