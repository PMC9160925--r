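# embsnn

Desk-scale embodied spiking neural network simulation in R: a clock-driven
spiking network kernel with the orchestration layers used for closed-loop
brain–body experiments, plus builders for two benchmark brain models and a
profiling harness.

## Who this is for

Computational neuroscientists and simulation engineers who want to study
the *mechanics* of distributed embodied simulation — master-worker control
planes, brain/body lockstep scheduling, transfer functions, scaling
censuses and profiling metrics — at a scale that runs on one CPU, with
every quantity reproducible bit for bit.

## What it implements

**Kernel** (`new_kernel`, `create`, `connect`, `simulate`, `get_spikes`):
leaky integrate-and-fire neurons with current-based alpha synapses
(exact matrix-exponential propagator) or conductance-based AMPA / NMDA /
GABA_A / GABA_B alpha channels (exponential Euler with the exact
within-step conductance average), parrot relays, Poisson generators and
spike recorders, on a fixed 0.1 ms grid. Synaptic plasticity on demand via
the power-law STDP rule

    potentiation:  w -> w + lambda * w0^(1-mu) * w^mu * exp(-dt / tau_plus)
    depression:    w -> w - lambda * alpha * w * exp(-|dt| / tau_minus)

Connectivity rules: `all_to_all`, `one_to_one`, `fixed_indegree(k)` (with
multapses) and `pairwise_gaussian(p0, sigma)` with connection probability
`p0 * exp(-d^2 / (2 sigma^2))` on 2D sheets. Neurons are assigned to
logical workers round-robin (`gid %% n_workers`), synapses live with the
post-synaptic owner, and every random draw comes from a stream keyed by
(master seed, purpose, neuron id, counter) — so spike output is bitwise
identical for any worker count.

**Control plane** (`start_server`, `server_call`, `combine`): a
NEST-Server-style master-worker API (`Create`, `Connect`, `Simulate`,
`GetKernelStatus`, `SetStatus`, `GetStatus`, `GetSpikes`) whose per-worker
responses are combined by an explicit registry — identical scalars
collapse, additive counts sum, event lists merge-sort, contradictions
raise a divergence error. An HTTP binding mirrors
`POST /api/<Endpoint>` with JSON bodies (`serve_http`, default port 5000).

**Closed-Loop Engine** (`cle_engine`, `cle_run`): advances brain and plant
in lockstep exchange windows (default 20 ms; 1 s = 50 steps), runs
transfer functions only after both complete, and profiles brain / robot /
transfer wall times per step. Metrics: real-time factor (simulated step
time over mean wall step time, first step excluded), brain-to-body step
ratio, node-hours (`runtime_s / 3600 * n_nodes`).

**Transfer functions** (`make_spike_sink`, `make_spike_source`): spike
sinks read the membrane potential of an infinite-threshold leaky
integrator fed by a whole population and emit a muscle activation
`clip((V - E_L) / v_span, 0, 1)`; spike sources inject independent
Poisson trains into every neuron of a target population.

**Plant** (`build_default_forelimb`, `plant_step`): a reduced rodent
forelimb — humerus, ulna/radius, foot — with 8 muscles (2 antagonists per
rotation axis, first-order activation dynamics, constant moment arms) and
a 2-DOF joystick carrying a constant −0.001 Nm bias torque, coupled
elastically to the limb. All passive elements derive from potentials, so
the unactuated rig is provably dissipative.

**Builders** (`count_brunel`, `build_brunel`, `census_cbct`,
`build_cbct`): the scale-parameterized balanced random network (11,250
neurons per unit scale, fixed recurrent indegree 11,250, plastic E→E) with
an exact dry-run census, and the multi-region CBCT rodent brain (M1, S1,
VL, VM, basal ganglia, two cerebellar modules; 1,005,905 neurons at scale
1) built from a packaged composition table, with uniform 2D placement,
Gaussian intra-regional wiring, ten topographic inter-regional pathways
over parrot interfaces, and a calibrated 8 Hz mossy-fiber drive
(`calibrate_resting_input`).

**Harness** (`benchmark_plan`, `run_benchmark`, `run_embodied_protocol`)
and a CLI (`exec/embsnn`): `embsnn count brunel --scale 20`,
`embsnn bench --plan plan.yaml`, `embsnn embodied --config rig.yaml`,
`embsnn serve --workers N --port P`.

## Worked example

```r
library(embsnn)

count_brunel(20)
#> $neurons     225000
#> $nodes       225001
#> $connections 2531475000

cz <- census_cbct(cbct_default_config(), scale = 1)
cz$per_region
#>   region neurons layers types
#> 1     M1   58805      5    19
#> 2     S1   94396      7    22
#> 3     VL    6144      2     3
#> 4     VM    6144      2     3
#> 5     BG   10976      5     5
#> 6  CB_M1  414720      6     6
#> 7  CB_S1  414720      6     6
cz$neurons
#> [1] 1005905

# reduced cerebellum at rest: the mossy fibers sit at their 8 Hz target
net <- build_cbct(scale = 0.02, kernel = new_kernel(seed = 1),
                  regions = "CB_M1")
simulate(net$kernel, 5000)
mf <- net$rows$handle[[which(net$rows$type == "MF")]]
pop_rate(net$kernel, net$recorder, mf, 0, 5000)
#> [1] 7.982261
```

The census numbers are exact combinatorial counts (no instantiation); the
mossy-fiber rate is a stochastic measurement over 575 parrot relays for
5 s driven by the packaged calibrated Poisson rate, and lands within the
±1 Hz calibration band of the 8 Hz resting target.

## Notes

- Everything is logical-worker parallelism: the package reproduces the
  *semantics* of distributed simulation (ownership, response combination,
  invariance of results), not MPI execution.
- The per-population CBCT composition below region level and all pathway
  parameters are packaged synthetic defaults (see
  `inst/extdata/cbct_*.yaml`); regional totals, layer counts and type
  counts are exact. See the methods vignette
  (`vignettes/embodied-snn-methods.Rmd`) for the model equations,
  parameter choices and limitations.
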