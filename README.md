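# nsinet

Mixed spiking/non-spiking neural network simulation with sub-threshold
encoding.

Locomotion controllers built from spiking central pattern generators need a
way to couple *analog* sensory information into an all-spiking circuit. In
insects this job is done by non-spiking interneurons (NSIs): neurons that
never fire, but whose graded membrane-potential displacement modulates
their post-synaptic targets. `nsinet` simulates this mechanism in a
16-neuron network: a half-center oscillator of two mutually inhibitory
populations of adaptive exponential integrate-and-fire (AdEx) neurons, a
motor population (MNP) whose 5 ms sliding-window spike count is the analog
output, and a single sub-threshold leaky-integrator NSI that shapes the
output's amplitude, frequency and phase from an input current.

The NSI's displacement from rest, `d = |V_rest − V_m|` (≤ 15 mV), drives
two graded channels:

* current injection `I = w · d` (nS × mV = pA), excitatory or inhibitory,
  into the motor and/or CPG populations — this scales output **amplitude**;
* a voltage-characteristic offset `V_cm = d / 3` applied to `V_th`,
  `V_reset` or `V_m` of the CPG populations — narrowing the
  threshold–reset gap of the AdEx bursters raises the output **frequency**.

A closed-loop mode regulates amplitude by feeding the motor output's rate
window back into the conductance,
`w = scaling_factor · (desired − current spike number)`.
An event-driven engine implements the same NSI asynchronously: it decays in
closed form between input events, and post-synaptic neurons reconstruct its
exact membrane potential from broadcast state snapshots
(`V(t) = V_rest + (V_m − V_rest) · decay^(t − t_updated)`), with analog
inputs encoded to spikes by Ben's Spiker Algorithm.

## Worked example

Run the baseline amplitude test (stepping NSI input, excitatory current
injection to the motor population) and decode the output:

```r
library(nsinet)

spec <- build_experiment(1, 0, seed = 1)  # test 1, excitatory subcategory
spec
#> <experiment_spec 1_0> MNP injection: stepping, sCPG injection: none,
#> voltage target: none, polarity: excitatory, sCPG targets: both

sim <- simulate_network(spec, seed = 1)
rs  <- rate_code(sim$spikes, population = "mnp")   # 5 ms sliding window
pk  <- detect_peaks(rs)

average_peak(pk)
#> [1] 36.87
estimate_frequency(pk, c(1000, 6000))$mean
#> [1] 8.83
```

36.87 is the mean burst-peak height in spikes per 5 ms window across the
five motor neurons (it grows through the trial as the stepping input raises
the injection); 8.83 Hz is the burst rhythm of the underlying CPG, which
current injection to the motor population leaves untouched. Other
experiments from the study's test matrix are one call away:
`build_experiment(7, 0)` manipulates `V_th` only (frequency control),
`run_feedback_loop(feedback_config(desired_spike_number = 10))` runs the
closed-loop amplitude regulation, and `run_event_demo(bsa_encode(
make_step_signal(c(0.2, 1), 3000)))` runs the event-driven two-neuron CPG.

A thin command-line runner ships in `inst/cli/`:

```sh
inst/cli/nsinet list
inst/cli/nsinet run test_1_0 --seeds 3 --out out/
inst/cli/nsinet run conductance-sweep --seeds 10 --out out/
```

Each run writes spike trains (two-column text), rate-signal CSVs, tidy
summaries, and a JSON manifest (config snapshot, seeds, package version,
calibration hash) sufficient to re-run bit-identically.

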