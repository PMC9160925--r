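---
title: "Methods: desk-scale embodied spiking network simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale embodied spiking network simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it simulates, how the
numerics work, which parameters matter, and what the test suite does and
does not establish.

## The simulation stack

An embodied experiment couples three layers:

1. a **spiking network kernel** advancing neurons on a fixed grid,
2. a **musculoskeletal plant** advancing joint dynamics on its own inner
   step, and
3. a **closed-loop engine (CLE)** that advances both in lockstep exchange
   windows (default 20 ms) and runs **transfer functions** — spike sinks
   (population activity to muscle activation) and spike sources (rate to
   Poisson drive) — strictly after both sides complete a window.

A master-worker **control plane** wraps the kernel behind a small API
(`Create`, `Connect`, `Simulate`, `GetKernelStatus`, `SetStatus`,
`GetStatus`, `GetSpikes`). Workers are *logical*: the package reproduces
the semantics of distributed simulation — round-robin neuron ownership,
synapses stored with the post-synaptic owner, per-worker response views
combined into one consistent answer — without OS-level parallelism. The
combination heuristics are an explicit per-endpoint registry (identical
scalars collapse, additive counts sum, event lists merge-sort,
contradictions raise a divergence error); an explicit registry was chosen
over type-based guessing because it is enumerable and testable.

## Neuron models and numerics

All dynamics run at a fixed resolution `h` (default 0.1 ms). Spikes are
detected at step ends and therefore live on the grid; delays are positive
integer multiples of `h`.

**Current-based LIF** (`lif_current`). Membrane with alpha-shaped
post-synaptic currents. The linear system `(y1, y2, V, I_e)` is advanced
by the exact propagator `expm(A h)` computed once per population
(`Matrix::expm`), so the constant-input membrane trajectory matches the
closed form `V(t) = E_L + R I_e (1 - e^{-t/tau_m})` to rounding error
(the test bound is 1e-9 mV). Arriving weights are scaled by `e/tau_syn`
so a synapse of weight `w` produces a PSC peaking at exactly `w` pA.

**Conductance-based LIF** (`lif_conductance`). Four alpha conductance
channels (AMPA, NMDA, GABA_A, GABA_B), each with a reversal potential and
time constant; NMDA is modeled as a slow alpha conductance *without* a
voltage-dependent magnesium block — receptor classes are named in the
underlying model but their kinetics are not, so the simplest consistent
kinetics were chosen and documented here. Conductance states advance
exactly; the membrane uses exponential Euler where each channel
contributes its *exact within-step time average*
`(A g2 + B g1)/h` with `A = tau(1-d)`, `B = tau^2(1-d) - tau h d`,
`d = e^{-h/tau}`. This keeps the step second-order accurate with a small
constant: the test suite holds the trajectory after a unit synaptic event
within 1e-4 mV of a 1000x-oversampled independent RK4 reference.
Because the update interpolates between the current
potential and a convex combination of reversal potentials, the membrane
can never cross the excitatory reversal — a structural safety property
that is also tested.

**Refractoriness.** After a spike the potential is clamped to `V_reset`
for `round(t_ref/h)` steps (default 2 ms).

**Parrot neurons** re-emit every arriving spike at its arrival time; they
implement inter-region interfaces and rate-transparent relays.

**Poisson generators** deliver an independent realization per connection;
per step, counts are drawn from the device's stream keyed by the absolute
step index, so rate changes take effect exactly at the next step and
results are independent of how simulation time is chopped into calls.

**STDP (power-law).** Potentiation
`w -> w + lambda w0^(1-mu) w^mu e^{-dt/tau_+}` on post spikes using the
pre trace, multiplicative depression
`w -> w - lambda alpha w e^{-|dt|/tau_-}` on pre spikes using the post
trace. Weights are floored at `1e-12 w0`, preserving positivity under
floating point. The rule's constants are not fixed by the benchmark
description; the defaults (`lambda = 0.1`, `mu = 0.4`, `alpha = 0.05`,
`tau_+ = 15 ms`, `tau_- = 30 ms`) follow the common lineage for this rule
and are fully configurable; no acceptance quantity depends on them.
In-network updates are applied at spike *emission* times — the
axonal-delay correction of trace lookups is deliberately omitted at desk
scale; the scalar pair update (`stdp_update`) is exact and is what the
oracle tests check.

## Determinism and worker invariance

Every stochastic draw (connectivity sampling, Poisson counts, positions,
bias currents, optional initial potentials) goes through a stream keyed by
`(master seed, purpose, entity id, counter)`. Keys never involve the
worker index or iteration order: connectivity is sampled per post neuron
in ascending gid from that neuron's private stream, Poisson counts per
device per absolute step. Consequently the spike output is bitwise
identical for any worker count and across repeated runs — the central
invariant of the distribution layer, tested at 1, 2 and 4 workers. A
Lehmer-style hash alone left nearby step keys on an arithmetic
progression (visible as a few-per-mil bias in long Poisson counts), so
seeding passes through one generator draw as an avalanche round before
the stream is used.

## The plant surrogate

The rig reduces a rodent forelimb experiment to its behaviorally
meaningful degrees of freedom: three moving segments (humerus,
ulna/radius, foot), four actuated rotation axes (shoulder flexion and
abduction, elbow flexion, wrist flexion) with one antagonist muscle pair
per axis — 8 muscles, activations in [0,1] with first-order dynamics
(`tau_act = 10 ms`, `tau_deact = 40 ms`, exact exponential update) — and
a joystick with two revolute DOF (forward/backward, lateral/medial)
carrying a constant bias torque of −0.001 Nm. The foot's ball joint is
reduced to an elastic 2-DOF coupling `e = C q` between limb angles and
joystick angles; moment arms are constant and force-length/velocity
factors are 1. Per DOF, lumped inertia with semi-implicit Euler and
implicit damping at a 1 ms inner step. Because every passive force is the
gradient of a potential (joint stiffness, coupling spring, bias), total
energy is non-increasing without excitation — the passivity test — and
the rig settles to the bias equilibrium from rest. Segment masses and
lengths are documented surrogate constants, not measurements; nothing in
the acceptance set depends on them. Note that from the zero state the
bias torque initially dominates the joystick, so directional-response
properties are asserted from the settled equilibrium.

## The two benchmark networks

**Balanced random network.** `round(11250 * scale)` neurons, split 4:1
into excitatory and inhibitory pools; every neuron receives exactly
11,250 recurrent synapses regardless of scale (9,000 from E, 2,250 from
I — the census is independent of this split), E→E plastic, everything
else static. One external Poisson device with a single connection per
neuron completes the node and connection counts: at scale 20 the dry-run
census gives 225,000 neurons, 225,001 nodes and
225,000 × 11,250 + 225,000 = 2,531,475,000 connections. The device term
is reverse-engineered from those printed totals and documented as such.
At desk scales (0.01–0.1) the fixed indegree implies heavy multapses —
permitted and intended. Weights, delays and the drive rate are not part
of the printed configuration; package defaults (`J = 20 pA`, `g = 5`,
`delay = 1.5 ms`, `8 kHz` drive) are stable at desk scale and excluded
from acceptance. Builds above a synapse budget (default 5e7) are refused
with the dry-run census in the message.

**CBCT rodent brain.** The packaged composition
(`inst/extdata/cbct_composition.yaml`) reproduces the reference regional
summary exactly — M1 58,805 / S1 94,396 / VL 6,144 / VM 6,144 /
BG 10,976 / CB 2 × 414,720; 1,005,905 neurons, 33 layers — while the
breakdown *below* region level is unpublished and therefore a clearly
marked synthetic elaboration constrained by the summary: 4:1 E:I in every
non-L1 cortical layer, purely inhibitory L1, two thalamic zones of
3 × 1,024 cells per nucleus, MSN-dominated basal ganglia, and a
granule-dominated cerebellum whose Pons (mossy fiber) sheet is a parrot
interface. Type counts follow the only reading consistent with the
summary: layer-qualified labels in cortex (19 and 22), shared labels in
thalamus (3). The per-region type column then sums to 64 even though the
reference total row prints 65 — the package reports the computed sum.
Pathway parameters (Gaussian `p0`, `sigma`, weights, delays, receptors)
and bias-current moments are likewise packaged synthetic defaults tuned
only for stable desk-scale resting activity. Scaled counts round
half-even per sheet population, so scale-1 totals are exact and scaled
totals are sums of rounded parts.

**Mossy-fiber calibration.** Pons cells are parrots driven by independent
Poisson processes; `calibrate_resting_input()` performs a secant search
(with bracket expansion and bisection fallback) over the drive rate
against a simulated probe window. Through a parrot interface the response
is the identity up to Poisson noise, and the search returns 8 Hz for the
8 Hz resting target; that value is shipped in
`inst/extdata/cbct_calibration.yaml` and verified by simulation in the
tests (±0.5 Hz on a 2 s probe at scale 0.02) and by the acceptance run
(±1 Hz on a 5 s probe).

## Profiling metrics

Per CLE step the engine records brain, robot and transfer wall times. The
first step carries initialization and is kept in the profile but excluded
from derived metrics: real-time factor
`(exchange interval in s) / mean(wall of steps 2..N)`, brain-to-body step
ratio `mean(brain)/mean(robot)` (NA when the robot time is zero — an
undefined value is reported, never fabricated), and node-hours
`runtime_s/3600 * n_nodes`. The benchmark harness maps worker counts to
nodes as `ceiling(workers/2) + 1` (two workers per node plus a control
node). Because workers are logical, build times are flat rather than
decreasing in the worker count; the scaling property asserted is
accordingly "non-increasing up to timing noise".

## Problem sizes used by tests and acceptance

Simulation-backed checks run at reduced scale, chosen as the smallest
sizes at which each property is meaningfully exercised: the balanced
network at scales 0.005–0.02 (fixed indegree keeps the per-neuron synapse
count at full size), the cerebellar module at scale 0.02 with 2 s (tests)
and 5 s (acceptance) probes, M1-only embodiment at scale 0.01 for the
50-step protocol, and a 100-neuron two-population network for the
worker-invariance oracle.

## What the synthetic configuration does and does not show

The generators and packaged tables emulate the *structure* of the
reference models (census arithmetic, layer organization, topographic
pathways, interface relays, drive calibration) and the *protocol* of the
benchmark (exchange windows, step counts, rate schedules). They do not
emulate fitted physiology: pathway strengths are not tuned to
electrophysiological recordings, so passing tests demonstrate correctness
of the machinery and reproduction of the printed combinatorial and
protocol constants — not biological validity of emergent firing patterns
beyond the calibrated mossy-fiber rate.

## Known limitations

- Logical workers only; no MPI, threads or remote execution.
- No compartmental neurons, gap junctions or structural plasticity.
- STDP trace lookups ignore axonal delays (documented above).
- The plant has no contact dynamics, gravity or muscle force-length
  curves; it is an interface-faithful surrogate, not a biomechanical
  model.
- The full-scale CBCT synapse total is not reproducible from published
  information (per-pathway parameters are unpublished); the builders
  therefore guard instantiation by a synapse budget and report device
  censuses separately from the neuron census.
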