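---
title: "Mean-field reductions of heterogeneous adapting integrate-and-fire networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field reductions of heterogeneous adapting integrate-and-fire networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetmf)
```

## The model class

`hetmf` analyses all-to-all coupled networks of adapting two-dimensional
integrate-and-fire neurons. Each neuron carries a fast membrane potential
$v$ and a slow adaptation current $w$,

$$\dot v_i = F(v_i) - w_i + I_i + g_i s(t)\,(e_r - v_i), \qquad
  \dot w_i = a_i (b v_i - w_i),$$

with a spike rule: when $v_i$ reaches $v_{peak}$ it is reset to
$v_{reset}$, $w_i$ jumps by $w_{jump,i}$, and the shared synaptic gating
variable $s$ (a simple exponential synapse,
$\dot s = -s/\tau_s + \text{jumps}$) gains $s_{jump}/N$. The shipped
nonlinearity is the Izhikevich quadratic $F(v) = v(v-\alpha)$, for which
every quasi-steady quantity below has a closed form; `rate_by_quadrature()`
accepts any continuous $F$.

Parameters enter dimensionally (pA, nS, ms, mV) through `izh_params()` and
are nondimensionalized internally: voltages map through $v = 1 + V/|V_R|$,
currents scale by $k V_R^2$, conductances by $k |V_R|$, and time by
$C/(k|V_R|)$ ms (1.54 ms at the default CA3 pyramidal-cell fit). Two
conventions hold in every shipped configuration and can be overridden per
call: the synaptic reversal potential is $E_r = 0$ mV (excitatory,
AMPA-like), and the voltage-coupled adaptation term is off ($b = 0$,
i.e. `eta = 0`), while the threshold $V_T = -24.6$ mV retains the value
obtained from the fit with $\eta = -1$ nS. The default applied-current
range of interest is 1000–5000 pA and conductances 0–600 nS; the
dimensionless rheobase of the uncoupled quadratic neuron is
$\alpha^2/4$ (`rheobase()`, about 1020 pA here).

## Quasi-steady mean field and the switching manifold

For slow adaptation ($\tau_w \gg 1$) the voltage density relaxes fast and
the population firing rate becomes an algebraic function of $(w, s)$:
positive on one side of the switching manifold

$$H(w, s) = I - w + \min_v\left[F(v) + g (e_r - v) s\right]
          = I - w - \tfrac{(\alpha + g s)^2}{4} + g\, e_r s,$$

and zero on the other. On the firing branch the rate is the reciprocal
passage time from reset to peak (`firing_rate_izh()`), which vanishes like
$\sqrt{H}$ at onset — the vector field of every reduction below is
continuous but *not smooth* across $H = 0$. The companion mean voltage
(`mean_v_izh()`) is the time-averaged $v$ on the firing branch and the
stable subthreshold root on the quiescent branch.

## Three closures for heterogeneous networks

Heterogeneity in parameters $\beta$ (applied current, conductance,
adaptation increment, adaptation time constant; independent across
parameters) admits three distinct moment closures:

* **MFI** (`mfi_rhs()`): close over $\beta$ first; the homogeneous
  two-ODE system evaluated at the mean parameters. Cheapest, accurate for
  narrow spreads away from rheobase.
* **MFII** (`mfii_rhs()`): keep the $\beta$-resolved conditional rate and
  integrate it against the parameter density; still two ODEs, but the
  rate-current curve is smoothed by the heterogeneity (`smoothed_fI()`
  shows the square-root onset washing out as $\sigma_I$ grows). When the
  conditional rate does not depend on the heterogeneous parameter (for
  example heterogeneity only in $w_{jump}$), MFII reduces exactly to MFI.
* **MFIII** (`mfiii_rhs()`): retain the $\beta$-conditioned adaptation
  field $\langle w | \beta\rangle$. This is a transport-free PDE,
  discretized by the method of lines on a grid of $\beta$ nodes
  (`beta_grid()`); integrals become weighted node averages. MFIII is the
  only reduction that resolves which part of the population is doing what,
  which is what the rate-distribution and bursting-fraction machinery
  build on.

`integrate_mf()` integrates any of the three with adaptive
Dormand-Prince at `rtol = atol = 1e-8`; no event detection is needed
because the field is continuous at the switching manifold. A compiled
fixed-step RK4 core backs the attractor-hunting workloads
(`find_limit_cycle()`, criticality probing, cycle tracking) with a default
step of 0.05–0.1 dimensionless time units: adaptive error control rejects
its way across the dense square-root kinks of a many-node grid, at a
hundredfold cost and no accuracy benefit for limit-cycle amplitudes; the
two integrators are cross-checked on trajectories in the test suite.

## Grids: Monte-Carlo, Gauss-Hermite, dense

Three node constructions serve different jobs:

* `montecarlo` — i.i.d. density samples with uniform weights; the default
  for plain MFIII integration and the only option for multi-parameter
  heterogeneity (the integrals become high-dimensional). Seeds are
  explicit everywhere.
* `hermite` — Gauss-Hermite nodes for one-dimensional normal
  heterogeneity; excellent for smooth integrals (moments to 1e-10 with 20
  nodes).
* `dense` — a uniform grid over the ±8σ span with trapezoid density
  weights. This is the grid used for bifurcation work and anything
  involving derivatives of the field. The reason is numerical, and worth
  stating: each node contributes a square-root kink where it crosses
  firing onset, so the *pointwise* Jacobian of a few-node system is
  dominated by whichever node happens to sit near its kink — with 20
  Gauss-Hermite nodes the leading eigenvalue jumps by order one between
  nearby parameter values, which breaks root-finding and bisection. A
  dense grid (default $M = 2001$ for bifurcation factories) shrinks each
  kink's weight until the eigenvalue scan is smooth at the $10^{-3}$
  level. Residual ripple still biases the eigenvalue-crossing location by
  a nanosiemens or two relative to the dynamic onset of oscillation,
  which is why the criticality classifier below never trusts eigenvalues
  alone.

## Ground truth: the spiking network

`simulate_network()` integrates the full discontinuous network in
dimensional form (compiled forward Euler, default `dt = 0.025` ms; the
spike test runs after each step, all simultaneous spikes increment $s$ in
that step, and the threshold crossing is not interpolated — the
$O(\Delta t)$ error is covered by a step-halving convergence test).
Initial voltages are uniform on $[V_{reset}, V_{peak})$ for a
desynchronized start. What the simulator deliberately leaves out — sparse
or distance-dependent connectivity, conduction delays, inhibitory
subpopulations, channel noise — bounds what agreement with the
reductions can show about biological tissue: the tests validate the
closures against the model network, not the hippocampus.

Per-neuron steady rates use the reciprocal of the last interspike
interval (`steady_rates()`). The burst classifier
(`classify_neurons()`) labels a neuron bursting when its
interspike-interval spread in the analysis window satisfies
$\max/\min > 3$; the threshold separates the two interval scales
(within-burst milliseconds versus inter-burst hundreds of milliseconds)
by an order of magnitude on either side, so the label is insensitive to
its exact value.

## Rate distributions, inversion, parameter recovery

In a tonically firing heterogeneous network the steady-state rate of a
neuron is a function $g(\beta)$ of its parameters, tabulated by
`steady_rate_map()` either from a converged MFIII run or algebraically at
a frozen gating value $\bar s = \tau_s s_{jump} \langle R\rangle$ (the
two agree at self-consistency; the algebraic route needs only the
*mean* rate, which is what makes inversion from data possible).
Monotone maps push densities forward (`predict_rate_density()`) and
backward (`invert_rate_density()`) through the standard change of
variables; derivatives are central differences on the grid and the
inverse is monotone (Hyman-filtered) spline interpolation, which
preserves invertibility. Per-neuron recovery
(`recover_individual_params()`) clamps out-of-range rates to the map
image with a warning. Empirical rate densities default to
Freedman-Diaconis histograms — a robust choice at the thousand-neuron
scale — with a kernel option for mode counting. The inversion assumes a
single heterogeneous parameter with everything else known; with several
heterogeneous parameters the forward direction is still available by
sampling (`multiparam_rate_interpolation()`, local linear interpolation
in standardized coordinates), but the inverse problem is underdetermined
(one-dimensional data, multi-dimensional unknown) and is not attempted.

## Bursting fractions on the limit cycle

When the mean field oscillates, `find_limit_cycle()` integrates past the
transient (coarse then fine two-stage integration; the analysis window
auto-extends up to three times when it holds fewer than four Poincare
crossings of the gating variable), declares a fixed point below an
amplitude tolerance of $10^{-5}$, and otherwise reports the period from
the last three crossing intervals (0.5% agreement required; a warning
flags period-doubled or aperiodic attractors). Per-node rate envelopes
$m(\beta) = \min_t \langle R|\beta\rangle$ and
$M(\beta) = \max_t \langle R|\beta\rangle$ over one period partition the
population: tonic where $m > 0$, quiescent where $M = 0$ (Heaviside
convention $h(0) = 1$), bursting in between, with a floating-point zero
tolerance of $10^{-8}$ on the dimensionless rate; the three fractions sum
to one by construction. `sweep_pburst()` tiles the
$\langle I_{app}\rangle \times g_{syn}$ plane (shipped analyses use a
10 × 10 grid over 1500–4500 pA and 40–580 nS with 41 Gauss-Hermite nodes
per point; contours via marching squares in `pburst_contours()`).

## Bifurcation work without continuation

The reductions are non-smooth, so classical normal-form machinery is
unreliable near the events of interest; everything here is root-finding
plus simulation:

* `find_equilibrium()` — damped Newton with central-difference Jacobians,
  seeded by the balance relations $w^* = (\sum w_{jump}) R^*/a$,
  $s^* = \tau_s s_{jump} R^*$ reduced to a scalar fixed-point problem.
* `hopf_bisect()` — bisection on the sign of the leading eigenvalue's
  real part along a parameter scan.
* `track_unstable_cycle()` — time-reversed integration from a small
  perturbation of the stable equilibrium; an unstable cycle surrounding
  it is the reversed flow's attractor. Warm starts carry the cycle
  across bisection probes.
* `locate_nonsmooth_bifurcation()` — grazing: bisection on the sign of
  $\min_t H$ along the tracked unstable cycle; saddle-node of limit
  cycles: descent continuation of the bursting attractor (forward
  simulation from a bursting state, bisecting on the smallest parameter
  value at which a stable cycle with vanishing rate over part of its
  period persists). Probe integrations run 40000 dimensionless time
  units, long enough that saddle-node ghosts decay at the default 0.02–
  0.05 nS bisection tolerances.
* `classify_criticality()` — the genuinely open design point. The
  textbook square-root amplitude law is probed at relative offsets
  $10^{-3}$–$8\times10^{-3}$ and reported, but it is *not* decisive
  here: the reductions are slow-fast (adaptation rate $a \approx 0.008$),
  and on the supercritical side the newborn cycle explodes canard-style
  to order-one amplitude within a window far narrower than any resolvable
  offset, so measured amplitudes are large with ratios near one on both
  sub- and supercritical Hopfs. The decisive, assumption-light
  discriminator is bistability: on the stable side of the Hopf the flow
  is started both from a small equilibrium perturbation and from a
  large-amplitude state carried over from the oscillatory side, each
  settled in windows until its amplitude stabilizes or collapses.
  Subcritical: the large oscillation persists while the equilibrium also
  attracts (or the unstable side diverges outright). Supercritical: one
  attractor everywhere, amplitude falling continuously to zero. The
  classifier is exact on both cubic normal forms across two decades of
  offsets, and reproduces the heterogeneity-induced switch of the
  low-conductance Hopf from subcritical (homogeneous) to supercritical
  ($\sigma_I = 500$ pA) at 2000 pA mean drive.

On the low-conductance boundary at 2000 pA the homogeneous sequence, as
computed by these tools, is: saddle-node of limit cycles (≈ 51.9 nS,
creating the bursting attractor), grazing of the unstable cycle
(≈ 52.4 nS, where it smooths), and the subcritical Hopf (≈ 57.5 nS,
where it dies on the equilibrium) — collision below grazing below Hopf,
with a narrow bistable band between collision and Hopf.
`scripts/acceptance.R` recomputes the two non-smooth values from
scratch. Note the ordering is forced for a planar flow: the unstable
cycle born at the Hopf persists down to the collision and grazes on the
way, so the collision cannot sit above the grazing; any report placing
it there is mislabelling one of the events. The bursting attractor at
the collision point was verified to be genuine (constant oscillation
amplitude over $2\times10^5$ time units, with the stable and unstable
cycle amplitudes approaching each other), not a saddle-node ghost.

## Period doubling and grid determinism

At strong current heterogeneity near rheobase
($\langle I_{app}\rangle = 1100$ pA, $\sigma_I = 2000$ pA,
$g_{syn} = 200$ nS) the network oscillation period-doubles: successive
burst peaks alternate between two heights. MFIII reproduces this, but
with Monte-Carlo grids the outcome is realization-dependent — some node
draws settle on the period-one cycle. The deterministic dense grid
($M = 1001$) shows the period-doubled attractor robustly and is what the
shipped analysis uses; the full 5000-neuron network at the same
parameters period-doubles for every seed tried. This sensitivity is
worth knowing about whenever MFIII is run near a bifurcation of the
network oscillation.

## Problem sizes in the shipped analyses

Networks default to $N = 1000$ neurons (5000 for the period-doubling
comparison), 2–3 s of simulated time at `dt = 0.01`–0.025 ms; MFIII
grids to $M = 1000$ Monte-Carlo or 41 Gauss-Hermite nodes (2001 dense
nodes for bifurcation factories); plane sweeps to 10 × 10 points; and
parameter-recovery maps to 400 nodes. These sizes were chosen so that
each headline analysis converges well inside its statistical or
discretization error; all are arguments, not constants.

## Known limitations

* All closures assume the first-order moment factorization that drops
  $w$–$v$ correlations; during strongly synchronized bursts the network
  transiently violates it, visible as small amplitude errors in the mean
  traces.
* MFII loses accuracy at large $\sigma_I$ near rheobase (it returns to
  tonic firing before the network does); MFIII is the reduction to trust
  there.
* The inversion pipeline requires tonic firing, a monotone rate map, a
  single heterogeneous parameter, and all other parameters known — strong
  assumptions, stated here once and enforced by errors in code.
* Dimensional heterogeneity in $\tau_W$ feeds MFIII per-node; MFII uses
  the weighted-mean adaptation rate (the closure has a single $w$
  equation), which is exact only for narrow spreads.
* `tau_s` below one dimensionless unit violates the time-scale ordering
  behind the quasi-steady reduction; `integrate_mf()` warns.
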