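---
title: "Target-based maximum-likelihood learning in recurrent spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-based maximum-likelihood learning in recurrent spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`spikelearn` trains discrete-time recurrent networks of leaky
integrate-and-fire (LIF) neurons to replay a prescribed spatio-temporal
spike pattern, and decodes that pattern into a continuous output through a
linear readout. The network state is a membrane potential $v_i^t$ and a
binary spike $s_i^t$ per neuron; with current-based (cuBa) synapses the
synchronous update is

$$\hat s^t = \Big(1-\tfrac{\Delta t}{\tau_s}\Big)\hat s^{t-1}
             + \tfrac{\Delta t}{\tau_s}\, s^t, \qquad
  v^t = \Big(1-\tfrac{\Delta t}{\tau_m}\Big) v^{t-1}
      + \tfrac{\Delta t}{\tau_m}\big(J\hat s^{t-1} + I^t + v_\mathrm{rest}\big)
      - J_\mathrm{res}\, s^{t-1},$$

with a *subtractive* reset (no floor) and the strictly causal $t-1$
convention throughout: the spike at $t+1$ is a function of $v^t$ only.
Spikes are always generated deterministically, $s_i^{t+1} =
\Theta(v_i^t - v_\mathrm{th})$, with the tie $v = v_\mathrm{th}$ resolved
as "no spike". The conductance-based (coBa) variant multiplies each
synaptic drive by its driving force $(E_\mathrm{exc}-v)$ or
$(E_\mathrm{inh}-v)$, requires an excitatory/inhibitory partition of the
population, and conserves synapse signs through learning by projecting the
weights after every update (Dale constraint). The reversal potentials
default to $E_\mathrm{exc}=5$, $E_\mathrm{inh}=-8$ model units — above
threshold and below rest respectively — and are configurable. All
potentials are dimensionless model units; $J_\mathrm{res}=20$ units (we
checked empirically that the tasks degrade with smaller resets, so the
printed value is used literally).

## Likelihood and the two plasticity rules

Learning maximizes the log-likelihood of the target raster
$s_\mathrm{targ}$ under a logistic spike model with noise scale $\delta v$,

$$\mathcal L = \sum_{t=1}^{T-1}\sum_i \log p\big(s_{i,\mathrm{targ}}^{t+1}
  \mid v_i^t\big), \qquad
  p(s=1\mid v) = \sigma\!\big((v-v_\mathrm{th})/\delta v\big),$$

where $v^t$ is computed with the spike history *clamped* to the target.
Because the clamped membrane is linear in $J$, its derivative is carried by
a single presynaptic eligibility trace
$p^{t+1} = (1-\Delta t/\tau_m)\,p^t + (\Delta t/\tau_m)\,\hat s_\mathrm{targ}^t$
(zero at $t=1$), shared across postsynaptic rows; for coBa neurons the
decay acquires the conductance load $|J|\hat s$ and the presynaptic term
the driving force, so the traces become full matrices. The gradient is the
three-factor product of a per-neuron error and this trace:

* **voltage-dependent rule** (finite $\delta v$):
  $\mathrm{err}_i^t = s_{i,\mathrm{targ}}^{t+1} - \sigma((v_i^t-v_\mathrm{th})/\delta v)$,
  never exactly zero — after a constraint is satisfied it keeps pushing the
  membrane away from threshold, building the safety margin that underlies
  noise robustness;
* **spike-dependent rule** ($\delta v \to 0$):
  $\mathrm{err}_i^t = s_{i,\mathrm{targ}}^{t+1} - s_{i,\mathrm{pred}}^{t+1}$
  with the prediction obtained by thresholding the clamped membrane;
  ternary, and exactly zero at satisfaction, so exact replay is a fixed
  point of this rule.

Updates are applied either once per trial (batch gradient ascent,
$\Delta J = \eta_0 \sum_t \mathrm{err}^t \otimes p^t$) or at every timestep
with the currently available quantities (the online approximation, which
uses the weights as already updated within the trial). At $\eta_0 \to 0$
the summed online updates converge to the batch direction; both facts are
verified by tests against central finite differences of $\mathcal L$.

## Building the target pattern

The target raster is the deterministic spiking of the *recurrence-free*
network driven by a clock current plus a random projection of the desired
output: $I^t = J_\mathrm{in} x^t + J_\mathrm{teach}\, y^t_\mathrm{targ}$,
with i.i.d. Gaussian projections (std `sigma_in`, `sigma_teach`; the
published magnitudes put the two currents within an order of magnitude of
each other). The clock is a box code: `clock_channels` (default 10)
channels tiling the trial in equal windows. The paper's clock is shown
only graphically, so the box code is a documented stand-in.

One construction detail matters a great deal. The recorded trial starts
from a uniform membrane $v^0$ and a given initial spike frame. If that
frame is empty, the first teacher-driven spikes of the target have *no
presynaptic history*: their eligibility is identically zero, no recurrent
weight can ever be credited for them, and the replayed trajectory diverges
from the second step onward. `build_target()` therefore runs a short
teacher-driven **warm-up** (default 50 steps, the signals wrapped
cyclically) and uses its final spike frame as the initial condition of the
recorded run — the recorded raster is then produced by exactly the
recursion that training replays, and every later target spike is causally
attributable. This realizes the published initial condition
$s^0 = s^0_\mathrm{teach}$.

## The readout

The decoded output is $y^t = J_\mathrm{out}\hat s_\mathrm{out}^t$, where
$\hat s_\mathrm{out}$ filters the raster with its own time constant
$\tau_\mathrm{rout}$ (initial value 0). During training the readout
decodes the *frozen target raster*; at retrieval it decodes the generated
raster. Three trainers are available:

* `"adam"` — per-timestep delta rule through Adam. Adam's steps are
  scale-free, so the step size must be small relative to the readout
  weight scale (~0.1 here): at the textbook default 0.001 the stochastic
  steady state floors near MSE 0.03, while `readout_lr = 1e-4` (the
  package default) converges faster *and* to ~3×10⁻⁴, consistent with the
  published final error. This is why the default deviates from "default
  Adam parameters".
* `"lsq"` — the minimum-norm least-squares solution on the frozen filtered
  target raster, i.e. the exact limit of the delta rule iterated from zero
  initialisation. Used for the short-trial and XOR experiments, where the
  handful of delta-rule passes available cannot converge and the quantity
  of interest is recurrent-learning speed, not decoder optimisation.
* `"plain"` — fixed-step delta rule, mostly for didactic use.

## Optimisation of the recurrent weights

Table parameters give the learning rate as $\eta/\delta v$ with an
"(Adam)" annotation. We found that per-timestep Adam at step 0.5 on the
recurrent weights is strongly divergent (weights grow without bound
because Adam normalizes even vanishing post-convergence errors back to
full-size steps), whereas the *plain* online rule at
$\eta_0 = \eta/\delta v$ reproduces the published learning curves
(generation MSE ≈ 0.02 after ~100 presentations of the 3D task). The
package therefore treats $\eta/\delta v$ as the plain online step and
reads the Adam annotation as describing the readout optimizer, which the
text specifies explicitly. Adam remains available for the recurrent rule
via `learn_control(optimizer = "adam")`.

## Tasks and experiments

**3D trajectories** (`run_trajectory_experiment`): three output channels,
each a superposition of sinusoids at 1, 2, 3, 5 Hz with amplitudes
$U[0.5,2]$ and phases $U[0,2\pi]$, normalized per channel to unit maximum
amplitude — all MSEs are on this normalized scale. Defaults are the
published column ($N=500$, $T=1000$, $\Delta t = 1$ ms, voltage rule at
$\delta v = 0.2$, online steps at 0.5, Adam readout). With these defaults
the generation-mode MSE falls below 0.001 within a few hundred
presentations.

**Few presentations** (`run_few_presentations_experiment`): the same task
compressed to 50 time bins (the full one-second waveform resampled, not a
50 ms excerpt — resampling is what makes the short trial a meaningful
trajectory), spike rule, $\eta_0 = 1$, batch gradient ascent versus the
online approximation, least-squares readout. In our hands the online
schedule reaches MSE < 0.01 in ~7–9 presentations and batch in ~14,
reproducing the qualitative online advantage (the original reports ~5 vs
~15; the residual factor on the online side resisted every convention
variant we tried — step size, reset size, clock resolution, update
ordering — and is documented as a limitation).

**Noise robustness** (`run_noise_experiment`): Gaussian noise added to the
clock signal, $I^t_\mathrm{clock} = J_\mathrm{in}(x^t + \sigma_\mathrm{noise}\xi^t)$,
reported against the variance ratio
$\sigma^2_\mathrm{noise}/\sigma^2_\mathrm{clock}$ (the clock variance is
that of the box-code entries). Noise draws are paired across grid points,
so degradation is monotone in expectation. Voltage-rule training retains
low MSE at ratios where spike-rule training has already degraded — the
margin mechanism at work.

**Temporal XOR** (`run_xor_experiment`): two bits presented as
square-wave pulses whose duty cycle encodes the bit (50% → 0, 25% → 1),
response a signed Gaussian bump; four conditions trained interleaved in
random order, classified by the sign of the decoded output inside the
response window. The pulse/response timings are shown only graphically in
the source figure; the defaults (pulse windows at steps 1 and 41 of length
30, bump at 110 with width 10) are configurable. A structural caveat
discovered during development: with targets built recurrence-free, the
target raster between the end of the second pulse and the response window
is silent (nothing drives the network there), so the teacher-driven
response spikes have no presynaptic support within membrane memory
($\tau_m = 8$ ms) and, worse, conditions sharing the second bit have
*identical* target history at response time with opposite required
responses. The trained network consequently replays every causally
supported slot of each target (overall mismatch < 1%) but omits the
response spikes themselves: the decoded window amplitude is numerically
zero and the 4-way classification degenerates to the sign of noise. The
`xor_experiment` object exposes the window `amplitude` so this is visible,
and the converged readout is verified to classify the *target* rasters
correctly (window amplitudes around ±0.46). Solving the task within this
framework would need targets that carry bit information through the gap --
for example targets recorded from a network with nonzero initial recurrent
weights -- which the source protocol does not specify.

## Numerical choices

* Leak factors $1-\Delta t/\tau$ are validated non-negative; $\delta v = 0$
  encodes the deterministic limit and is rejected wherever a likelihood is
  required.
* The compiled training loop flushes Adam moments and error entries that
  fall below $10^{-280}$ and $10^{-100}$ respectively: sigmoid tails reach
  sub-normal magnitudes where x86 arithmetic is microcode-assisted
  (~2× slower), and through the $\epsilon$-floor of Adam such entries
  contribute updates below $10^{-92}$ — far beneath any meaningful weight
  scale.
* Exact replay: the clamped membrane is linear in $J$ with the eligibility
  as fixed design, so each neuron's spike constraints form a perceptron
  problem. At the published step sizes a few tens of near-threshold
  constraints keep oscillating, and the generation raster retains a
  0.02–2% slot mismatch; the decoded output is nonetheless accurate
  because the readout averages over the population. The fixed-point
  property itself (exact replay ⇒ identically zero spike-rule update) is
  exact and is tested on a self-consistent raster.
* Derived seeds are kept below $2^{31}$; every source of randomness in the
  experiment drivers is derived from the user seed, making runs
  bit-reproducible.

## What the generator does and does not emulate

The synthetic tasks exercise precisely timed, low-dimensional, periodic
structure under a deterministic network — the regime the learning rule is
derived for. They do not emulate trial-to-trial biological variability,
correlated noise sources (the likelihood factorizes over neurons), slow
drifts, or high-dimensional natural signals; passing tests therefore
demonstrate the learning machinery and its robustness mechanism, not
performance on physiological recordings.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on reduced networks (N ≤ 300, trials ≤ 400
steps) chosen so the whole suite exercises every code path in a few
minutes; the benchmark script uses the full published sizes ($N = 500$,
$T = 1000$, 1000 presentations) with 3–10 realizations per quantity.
These replication counts are the package's own choice of a
statistics/compute trade-off; increase them for tighter intervals.
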