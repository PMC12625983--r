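---
title: "Representational drift as restricted diffusion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representational drift as restricted diffusion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftlab)
```

## The model

driftlab studies a single-hidden-layer network in which an input population
$X$ drives a representation layer $Y$ through plastic synaptic weights $U$,
and a fixed linear readout $W$ turns the representation into behaviorally
relevant outputs:

$$Z = W\,\Phi(UX + B), \qquad
\Phi(v) = \begin{cases} 0 & v \le 0\\ v & 0 < v < \alpha\\ \alpha & v \ge \alpha,\end{cases}$$

with $X \in \mathbb{R}^{N_x \times P}$ holding $P$ input conditions,
$U \in \mathbb{R}^{N_y \times N_x}$, $W \in \mathbb{R}^{N_z \times N_y}$,
and a bias matrix $B$ repeating the bias vector $b$ across conditions.
$\Phi$ is the clipped-threshold-linear activation: a neuron whose input
current is at or below 0 is *inactive*, at or above the saturation
threshold $\alpha$ it is *saturated*, and strictly in between it is
*engaged*. Inactive and saturated neurons are collectively *disengaged*:
their activity does not respond to small current changes.

Representational drift is modeled as a random walk of $U$ restricted to the
*solution space* — the set of weight matrices that leave the stored
readouts $Z_{\cdot\mu}$, $\mu = 1..P$, exactly unchanged. The representation
$Y$ may change freely; the behavior may not.

## Eta-coordinates

The restriction is made tractable by a per-neuron change of basis. With
$P \le N_x$ and $X$ of full column rank, extend $X$ to an invertible
$N_x \times N_x$ matrix $X_{\mathrm{ext}} = [X \mid Q]$, where the columns
of $Q$ span the orthogonal complement of $\mathrm{col}(X)$. Then

$$\eta = U X_{\mathrm{ext}}, \qquad U = \eta X_{\mathrm{ext}}^{-1}.$$

The first $P$ columns of $\eta$ are exactly the input currents $UX$ of the
stored conditions; the remaining $N_x - P$ columns are *unconstrained*
coordinates along which the weights can move without affecting any stored
current ($N_y (N_x - P)$ dimensions in total). The package computes $Q$ by
a QR factorization and fixes signs so that each completion column's
largest-magnitude entry is positive; any spanning completion gives the same
first $P$ coordinates, so this choice only pins down reproducibility.

Within a stored column $\mu$, the coordinates split further by engagement:

* **inactive** coordinates may move freely below the zero-current bound
  (one-sided, "semiconstrained");
* **saturated** coordinates may move freely above $\alpha$;
* **engaged** coordinates must move inside the kernel of the *engaged
  submatrix* $W_\mu$ (the readout columns of the engaged neurons), leaving
  $(|E_\mu| - N_z)$ directions of genuine representational drift.

`engaged_kernel()` returns a column-orthonormal kernel basis via QR of
$W_\mu^\top$; it is recomputed from scratch whenever the engaged set
changes. At these problem sizes recomputation costs microseconds, and
avoiding incremental updates removes a whole class of staleness bugs.

## The drift step

Each step of `drift_step()` / `run_drift()` draws, for every coordinate
class, a zero-mean Gaussian increment with per-column standard deviation
$\sigma\, s_\mu$, where

$$s_\mu = 1 / \lVert \text{row } \mu \text{ of } X_{\mathrm{ext}}^{-1} \rVert_2 .$$

This scaling makes the induced physical increments
$\delta U = \delta\eta\, X_{\mathrm{ext}}^{-1}$ approximately
$\mathcal{N}(0, \sigma)$: pooled over all weight entries the variance is
exactly $\sigma^2$ for free diffusion, and the tests verify that even with
the constrained blocks active the pooled SD stays within a quarter of
$\sigma$. The parameter $\sigma$ is therefore the per-step weight
fluctuation scale, in weight units.

Threshold events are handled exactly, not with an epsilon band:

* an inactive (saturated) coordinate whose proposal would cross its bound
  is set to exactly $-b_i$ (resp. $\alpha - b_i$) and the neuron joins the
  engaged set;
* the engaged block's kernel proposal is rescaled by the largest
  $\gamma \in [0, 1]$ that keeps every engaged current inside $[0, \alpha]$
  (`rescale_to_threshold()`); scaling preserves kernel membership, which a
  naive clamp would not. Neurons sitting exactly at a bound at that
  $\gamma$ — possibly several, in a tie — transition out of the engaged
  set. Transitioned neurons participate in the *next* step under their new
  label; there is no same-step re-entry.

A per-neuron weight-norm bound $\lVert U_{j\cdot}\rVert_2 \le U_{\max}$
keeps the diffusion finite. The mechanism is a rejection (reflecting)
boundary: any row whose candidate update would exceed the bound is fully
reverted for that step, together with its set transitions. Because an
engaged-block update couples several rows through the kernel basis,
reverting one row of it would break readout conservation; the step
therefore also reverts the whole engaged-block update of any stored
condition in which a rejected row took part, iterating until no row
violates the bound. The result is that row norms grow toward $U_{\max}$
and fluctuate just below it, and stored readouts are conserved to
floating-point accuracy at every step. `run_drift()` monitors the
cumulative readout change at every recording and aborts beyond `cons_tol`
(default $10^{-6}$).

Two engines implement identical update rules: a reference R implementation
(`drift_step()`, used by the unit tests to pin down semantics) and a
compiled runner used by default, since trajectories of $5 \times 10^4$
steps are routine. A test checks that both produce the same trajectory
from the same seed to $10^{-10}$.

## Allocation and learning

A condition whose neurons are all disengaged provides no gradients.
`allocate()` resamples that condition's eta column i.i.d.
$\mathcal{N}(\alpha/2, 0.1)$, centering its currents in the engaged regime
without touching any other column — stored memories are unaffected by
construction.

Two learners are provided, both hand-coded gradients of the squared
readout error with $W$ and $b$ fixed:

* `learn_gd_U()` descends on the full weight matrix,
  $\Delta U \propto -(W^\top 2E \odot \Phi'(C))\, X^\top$;
* `learn_gd_eta()` descends on a single eta column,
  $\Delta \eta_{\cdot\mu} \propto -W^\top 2E_\mu \odot \Phi'(\eta_{\cdot\mu} + b)$.
  Because the error of condition $\mu$ depends only on its own column, the
  gradient of every other column is identically zero: eta-learning is
  interference-free, exactly.

$\Phi'$ is taken to be 0 at exactly 0 and exactly $\alpha$ (the disengaged
side), so clamped neurons contribute no gradient; this matches the
piecewise closure of $\Phi$ and keeps just-transitioned neurons silent.

Full-scale learning uses an Adam-style adaptive optimizer with learning
rate $10^{-3}$; at the scale of readout weights $\sim\mathcal{N}(0, 10)$
plain gradient descent at a usable rate is unstable, while Adam converges
in a few thousand iterations. The two-neuron worked example instead uses
plain gradient descent (rate 0.05), whose descent path is itself of
interest there. A mapping counts as *successfully learned* when the RMS
readout error is at or below $10^{-3} \times$ the RMS of the target
readouts (configurable via `learn_config(tol=)`); sequential protocols
train every mapping to the one pooled tolerance so that the success
criterion is consistent across columns.

## Experiment protocols

**Robustness** (`robustness_eval`, `robustness_sweep`): draw $n$
perturbations $\Delta U \sim \mathcal{N}(0, \rho)$ (defaults $n = 100$,
$\rho = 1$; the perturbation law is fixed, the sample count is this
package's choice), collect signed readout errors, and report their RMS.
Before/after comparisons reuse the same perturbation seed, so the
difference isolates the state, not the noise. The sweep learns once per
seed, then drifts the same learned state under each norm bound.

**Learnability** (`learnability_protocol`): mappings are added one at a
time — allocation (optional), then learning — and counted until the first
failure of the pooled success tolerance. The default learner is the
eta-learner for both arms, which makes the count a clean readout of
gradient availability at the initial weight scale: large initial weights
disengage neurons and stall learning regardless of interference. The
U-learner is available (`learner = "U"`) for protocols where cross-memory
interference should contribute to failures. No drift is interleaved here;
drift's effect on retention is measured by the continual protocol instead.

**Continual learning** (`continual_experiment`): from large initial
weights $U \sim \mathcal{N}(0, 15)$, memories are added sequentially by
allocation plus U-gradient descent on the new memory only; one arm drifts
(constrained to the memories stored so far, $10^4$ steps by default)
between additions, the other does not. Since drift never changes stored
readouts, all recorded interference — current perturbations,
representation changes, readout errors of stored memories — is
attributable to the learning steps. Arms share task and allocation
substreams (`substream_seed()`), so comparisons are paired.

## What the generator emulates — and what it does not

`generate_task()` draws $X_{i\mu} \sim \mathcal{N}(0,1)$,
$W_{ij} \sim \mathcal{N}(0,10)$, and teacher weights
$T \sim \mathcal{N}(0,1)$, with targets $Z = W\Phi(TX + B)$; the second
argument of every normal here is a standard deviation, and the teacher
scale is this package's choice (exposed as `teacher_sd`). Defaults are
$N_x = 15$, $N_y = 12$, $N_z = 1$, $P = 8$, $\alpha = 5$, zero bias.
Teacher-generated targets guarantee the solution space is nonempty.

The generator produces dense Gaussian inputs and an exactly realizable,
one-dimensional linear readout. Passing tests therefore demonstrate the
geometry of the solution space — entropic sparsification, the
robustness–learnability trade-off, interference-free eta-learning — under
those idealizations. They do not speak to spiking dynamics, nonlinear or
drifting readouts, structured (e.g. sparse or correlated) inputs,
biological noise processes, or memory loads beyond $P \le N_x$; the
framework requires $P \le N_x$ and an exact-solution manifold by
construction.

## Numerical choices and degenerate inputs

* Linear-algebra identities (frame inversion, kernel orthonormality) are
  held to $10^{-10}$; per-step readout conservation to $10^{-8}$ and
  $10^{-6}$ cumulatively over a run.
* Threshold comparisons are exact: clamped coordinates land at exactly
  $-b_i$ or $\alpha - b_i$, so classification needs no epsilon band. At
  initialization, a current exactly at a threshold is classified into the
  adjacent disengaged set; during drift, a just-transitioned neuron sits
  at the boundary under its new label.
* Simultaneous threshold ties all transition together (the maximal-
  $\gamma$ rule applies to every neuron at the bound).
* $|E_\mu| \le N_z$ yields an empty kernel and a zero engaged increment.
* A rank-deficient sampled $X$ is resampled with a warning; explicitly
  supplied rank-deficient inputs are an error.
* $U_{\max} = \infty$ disables the norm bound; a bound below the current
  row norms freezes those rows (every candidate is rejected), which is the
  intended reflecting behavior.
* Defaults $\sigma = 0.05$, $5 \times 10^4$ steps, recording every 100
  steps are package choices: $\sigma$ small enough that threshold events
  are resolved cleanly (a few percent of the engaged range per step),
  long enough that engagement fractions visibly equilibrate.

## Problem sizes

The test suite and examples run the standard network ($12 \times 15$,
eight conditions) with drift runs of $10^3$–$5 \times 10^4$ steps,
replicate counts of 5–10 seeds per protocol, and 100-sample perturbation
estimates; a full suite completes in about a minute on one core. These
sizes were chosen because every qualitative effect they probe —
sparsification, robustness gains, learnability decay, interference
reduction — is already stable at them; all are configurable upward.

## Known limitations

The eta construction needs all inputs in advance (the basis incorporates
$X$ wholesale), so it is a mathematical device for isolating drift, not a
biological learning proposal. Solution spaces with tolerated readout
error, $P > N_x$, plastic readout weights, and alternative activation
functions are out of scope. The norm-bound mechanism (rejection) is one of
several defensible choices; it was selected for exact readout conservation
and for producing norms that saturate just below the bound.
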