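---
title: "Plastic spiking networks: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastic spiking networks: model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`plastnet` simulates excitatory networks of conductance-based leaky
integrate-and-fire (LIF) neurons in which three processes co-evolve on
separated timescales: sub-second spiking dynamics, minutes-scale synaptic
weight dynamics under additive spike-timing-dependent plasticity (STDP), and
hours-scale rewiring under a stochastic structural-plasticity (SP)
birth–death rule. The intended use is the study of synchronized and
desynchronized network states — as minimal models of pathological and
physiological activity in structures such as the subthalamic nucleus — and
of their robustness against desynchronizing stimulation.

## Spiking dynamics

$N = m \times m$ neurons sit on a jittered square lattice of side $L$
(spacing $h = L/(m-1)$). Each membrane obeys

$$C\,\dot V_i = g_{\mathrm{leak},i}(V_{\mathrm{rest}} - V_i)
  + g_{\mathrm{syn},i}(V_{\mathrm{syn}} - V_i)
  + I_{\mathrm{stim},i} + g_{\mathrm{noise},i}(V_{\mathrm{syn}} - V_i),$$

with a dynamic threshold $\tau_{th}\dot V_{th,i} = V_{th,\mathrm{rest}} -
V_{th,i}$. A spike is emitted when $V_i$ crosses $V_{th,i}$; both variables
are then clamped to their spike values for $\tau_{\mathrm{spike}}$, after
which $V_i$ is reset and $V_{th,i}$ relaxes back from $V_{th,\mathrm{spike}}$
through its own equation (the clamp-then-relax reading is what makes the
threshold equation dynamical at all). Each delivered presynaptic spike —
arriving one transmission delay $t_d$ after emission — increments the
postsynaptic conductance by $\kappa w_{ij}/N$, giving the conventional
exponential postsynaptic conductance of peak $\kappa w/N$ and time constant
$\tau_{\mathrm{syn}}$. Background input is an independent Poisson train per
neuron (rate $f_{\mathrm{noise}}$, jump $\kappa_{\mathrm{noise}}$). Default
parameter values are the reference set returned by `neuron_params()`
(e.g. $C = 3\,\mu F/cm^2$, $V_{\mathrm{rest}} = -38$ mV,
$V_{\mathrm{reset}} = -67$ mV, $t_d = 3$ ms, $\kappa = 8$ mS/cm$^2$,
$f_{\mathrm{noise}} = 20$ Hz, $\kappa_{\mathrm{noise}} = 0.06$ mS/cm$^2$).

Because $V_{\mathrm{rest}}$ lies above $V_{th,\mathrm{rest}}$, an isolated
neuron fires tonically; its *natural rate* is set by its leak conductance
and the noise. Heterogeneity is controlled by drawing natural rates from a
Gaussian with mean $f_0$ and SD $\sigma_f$ and mapping them to leak
conductances through the calibration described below.

## STDP

The weight change for a pre/post pair at lag $q = t_{\mathrm{post}} -
t_{\mathrm{pre}} - t_d$ is

$$\delta w(q) = \begin{cases}
  \eta\, e^{-|q|/\tau_+}, & q > 0,\\[2pt]
  -\eta\,(b/\tau_R)\, e^{-|q|/(\tau_R \tau_+)}, & q \le 0,
\end{cases}$$

so that $\int \delta w\, \mathrm{d}q = \eta\tau_+(1-b)$: with the default
$b = 1.4$ the rule is depression-dominant (net area $-0.08$), which is what
creates bistability between weakly and strongly coupled network states. Note
that $\tau_R$ is dimensionless: it widens the depression window to
$\tau_R\tau_+$ and divides its amplitude, leaving the area identity intact —
the identity is checked numerically in the test suite. The rule is
implemented with accumulating (all-to-all) pre- and post-synaptic traces;
at coincident events a weight update always uses the trace value from
*before* the same-side increment, so a spike never pairs with itself, and a
coincident pair ($q = 0$) falls into the depression branch. Weights are hard
clipped to $[0, 1]$ after every update, as additive STDP requires.

## Stochastic structural plasticity

Discrete structural updates are Bernoulli trials per ordered pair. An absent
contact $j \to i$ appears with probability

$$P_{\mathrm{add}} = P_h\, G(\hat f_i, f_-, -\nu)\, e^{-l_{ij}/l_0},$$

a live contact disappears with probability

$$P_{\mathrm{prn}} = P_w\, e^{-w_{ij}/w_{\min}} + P_h\, G(\hat f_i, f_+, \nu),$$

where $G$ is a logistic with midpoints $f_\pm = f_T \pm \Delta f/2$ and
slope $\nu = \Delta f / (2\ln[(1-\tilde p_T)/\tilde p_T])$, and $\hat f_i$
is a slow low-pass estimate of the postsynaptic rate (time constant
$\tau_{\mathrm{slow}}$, default 30 min). The homeostatic terms drive every
neuron towards the target rate $f_T$; the weight term preferentially removes
weak contacts (scale $w_{\min} = 0.001$). Both hazards are evaluated on the
pre-update snapshot, so one update never adds and removes the same pair, and
a contact added at iteration $n$ is first exposed to pruning at $n+1$. New
contacts receive uniform weights on $[0, 0.2]$ when STDP is active (they are
then potentiated or depressed by activity) and on $[0, 1]$ under
homeostatic-only rewiring, where no weight dynamics exist to shape them.

## Adiabatic orchestration

`run_adiabatic_sp()` alternates relaxation of the fast dynamics with one
structural update. Relaxation proceeds in convergence intervals of length
$T$ (default 60 s) until the symmetric relative changes of both the mean
weight and the mean rate drop below $\Upsilon = 10^{-3}$, with per-iteration
interval bounds (defaults 2 and 31). Between updates the structure is
strictly frozen. The slow rate filter cannot equilibrate from zero within
one relaxation window ($\tau_{\mathrm{slow}}$ comparable to or longer than
the window), so it is warm-started once, from the empirical per-neuron rates
of the first relaxation's final interval; afterwards it evolves only through
its own dynamics. An undefined mean weight (no live contacts, as in
growth-from-scratch runs) enters the convergence series as 0.

## UMRS stimulation

Uncorrelated multichannel random stimulation drives the network through four
electrodes at the quadrant centers of the plane. Each electrode delivers an
independent renewal train of charge-balanced events (positive pulse
$\tau_{sp} = 0.5$ ms of amplitude 1, gap $\tau_{sg} = 0.2$ ms, negative
pulse $\tau_{sn} = 1.5$ ms of amplitude $-\tau_{sp}/\tau_{sn}$); onset
intervals are $\tau_\Lambda + \mathrm{Exp}(\tau_{\mathrm{UMRS}})$ with the
hard floor $\tau_\Lambda = 1000/130$ ms, so the mean rate is $F_s =
(\tau_{\mathrm{UMRS}} + \tau_\Lambda)^{-1}$ and never exceeds 130 Hz. The
maximal intensity follows from charging the membrane from reset to the spike
threshold within one positive pulse, $I_0 = (V_{th,\mathrm{spike}} -
V_{\mathrm{reset}})\,C/\tau_{sp} = 402\ \mu A/cm^2$, scaled by $a_s \in
[0,1]$. Spatial falloff is Gaussian with $\sigma_s =
\tfrac13\sqrt{\gamma/\pi}\,L$, chosen so one electrode effectively reaches a
fraction $\gamma$ of the plane (the $D \ge 0.01$ footprint). Stimulation
current is applied only to unclamped membranes; during the spike clamp the
membrane is pinned regardless. `run_stimulation_protocol()` halts structural
updates during and after stimulation and classifies the outcome as
desynchronized when the post-epoch order parameter falls below 0.3 — the
outcome maps are strongly bimodal, so the classification is insensitive to
this cutoff within a wide band.

## Measures

Synchrony is the Kuramoto order parameter computed from piecewise-linear
spike phases (each inter-spike interval advances the phase by $2\pi$),
time-averaged over a trailing window. The window length is not prescribed by
the model; the default of 2 s covers several mean periods at the typical
4–5 Hz network rates, and the estimate is stable under both window and
quadrature refinement (tested). Neurons with undefined phase (before their
first or after their last spike) are excluded from the population mean at
the affected instants; at the default rates every neuron fires many times
per window, so the exclusion is immaterial. Other observables: per-interval
mean rate and population CV, mean incoming weight per neuron (undefined for
neurons with no incoming contacts, which are excluded from the average),
in/out node-degree densities, the four directed degree-assortativity
coefficients computed edge-wise as Pearson correlations, degree–frequency
correlations against natural rates, and contact lifetimes from the
structural event log.

# Calibration

`fit_rate_curve()` tabulates the long-time rate of a single noise-driven
neuron on a grid of leak conductances (default: 10 points on
$[0.005, 0.05]$ mS/cm$^2$, 500 s each — the curve is so close to linear,
$R^2 > 0.999$, that denser grids change nothing) and fits
$f = \alpha_1 g_{\mathrm{leak}} + \alpha_2$ by least squares.
`sample_gleak()` then inverts the line: requested rates
$\mathcal N(f_0, \sigma_f^2)$ map to conductances
$\mathcal N((f_0-\alpha_2)/\alpha_1, (\sigma_f/\alpha_1)^2)$, clipped to the
calibrated range with a warning (at the defaults, below 1% of draws). The
natural rate is deliberately noise-inclusive: it is the rate of an
uncoupled neuron *with* its background input, because that is the operating
point the network perturbs.

# Numerical choices

* **Integration.** Forward Euler with $dt = 0.1$ ms, which divides the spike
  clamp, the delay and all stimulus sub-durations, so every discrete event
  lands exactly on the grid. Halving $dt$ changes a tonic neuron's rate by
  well under 1% (tested). Spikes detected during a step are logged at the
  step's end time; simultaneous crossings are processed in neuron-index
  order — a fixed tie-break that makes runs bit-reproducible.
* **Event bookkeeping.** Synaptic deliveries use a ring buffer of depth
  $t_d/dt$; deliveries crossing an interval boundary are carried in the
  state object and honoured by the next call. STDP traces and the slow rate
  filter decay lazily (exact exponential decay applied at access time),
  which is both exact and cheap.
* **Denormal flush.** Conductances decaying exponentially toward zero are
  flushed to 0 below $10^{-12}$ mS/cm$^2$; otherwise they reach the denormal
  float range, where the FPU slows down by more than an order of magnitude.
  The threshold is some $10^{10}$ times smaller than a single noise kick.
* **Noise realization.** Per neuron and step, at most one Poisson event with
  probability $f_{\mathrm{noise}}\,dt$ ($= 0.002$ at the defaults), which is
  an accurate thinning at this rate.
* **Seed discipline.** A master seed expands into named streams (wiring,
  weights, membrane, noise, SP, stimulus, calibration), so the same wiring
  can be reused across initial-weight conditions — required for
  bistability experiments — and every record is bit-reproducible from its
  configuration plus master seed (tested).

# Design decisions on under-determined points

Several quantities are not pinned down by the model statement; the package
fixes them as follows.

* **Lattice jitter**: uniform on $[-0.05h, +0.05h]$ per coordinate — small
  relative to the spacing, so the lattice topology is preserved while exact
  degeneracies of the distance table are broken.
* **Initial wiring normalization**: pair probabilities are
  $c\,e^{-l_{ij}/l_0}$ with $c$ chosen so the *expected* density equals the
  requested $\beta_0$. The alternative (multiplying $\beta_0$ by the kernel
  without renormalizing) would systematically undershoot the requested
  density; the normalized reading reconciles "probability equal to the
  desired density" with distance dependence. Unachievable combinations
  (short $l_0$, high $\beta_0$) are rejected.
* **Initial weights**: uniform on the mean-preserving support
  $[\max(0, 2\bar w - 1), \min(1, 2\bar w)]$; only the mean is prescribed by
  the experiment definitions.
* **Threshold after the clamp**: $V_{th}$ relaxes from
  $V_{th,\mathrm{spike}}$ via its own equation rather than being reset,
  which yields the effective relative-refractory dynamics.
* **Rate for SP decisions**: the slow low-pass estimate at the end of the
  relaxation, warm-started as described above; the instantaneous interval
  rate is used only for convergence testing and summaries.
* **Pruning weight**: the weight at the moment of the structural update,
  i.e. after the last relaxation's final STDP update.

# What the scaled experiments do and do not show

Full-scale reproduction of the reference phenomenology uses 10 wiring
realizations, hundreds of structural iterations and multi-hour
post-stimulation epochs. The package's tests and the acceptance script run
scaled versions chosen to finish on a desk machine while preserving the
governing ratios:

* Steady-state synchronization runs use $N = 400$ with the standard 60-s
  convergence interval but a reduced minimum interval count (10 instead of
  60), applied only once the weight and rate series have visibly plateaued;
  order parameters are averaged over the final intervals of a single
  realization rather than ten.
* Scaled structural-plasticity runs use $N = 100$, 10-s relaxation
  intervals, a few dozen iterations, and $\tau_{\mathrm{slow}}$ shortened to
  2 min so that the ratio of the relaxation window to the rate-filter memory
  stays inside the regime the full-scale protocol operates in
  ($\Delta T_{sp}/\tau_{\mathrm{slow}}$ of order 0.1–1). They demonstrate
  the *directions* that define the mechanism — density decreasing with
  $P_w$ in desynchronized states, synchrony enhancement with rate
  convergence to $f_T$, longer lifetimes for contacts from faster onto
  slower neurons, depletion of the weak-weight mode relative to
  homeostatic-only rewiring — not the exact steady-state densities, which
  require runs to full birth–death equilibrium.
* Lifetime statistics use $P_w = 1$, where the weak-contact hazard is fast
  enough for lifetimes to decorrelate from the censoring window; the
  reference results state that $P_w = 0.1$ and $1$ behave like $P_w = 0.01$
  for this statistic.

What passing these tests shows is that the implemented mechanisms interact
as designed; what they do not show is quantitative agreement of slow
structural equilibria, realization-averaged phase diagrams, or behaviour of
real neural tissue — the model abstracts synaptic integration, uses a
single contact per ordered pair ($M = 1$), purely excitatory coupling, and
rate-based rather than molecularly grounded rewiring rules.

# Known limitations

* Forward Euler with delta-kick synapses is first-order accurate; spike
  times carry an $O(dt)$ quantization.
* The dense $N \times N$ connectivity representation is the right choice up
  to a few thousand neurons but not beyond.
* Only $M = 1$ contacts per ordered pair are implemented; the data model
  records a `max_contacts` field for forward compatibility but no multi-
  contact dynamics exist.
* Periodic boundaries, inhibitory populations and event-driven exact
  integration are out of scope.
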