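# ca3net

Conductance-based simulation of a hippocampal CA3 microcircuit and the
analysis toolkit for studying how multi-target conductance manipulations
reshape its oscillations and information flow.

## The scientific problem

The CA3 microcircuit — pyramidal cells (PYR) recurrently coupled to
fast-spiking PV basket cells and to slow OLM interneurons, with rhythmic
medial-septal inhibition onto both interneuron classes — generates theta
(~7 Hz) oscillations with nested gamma (~30–40 Hz). Three conductances on
specific cell classes are candidate pharmacological targets in psychotic
disorders: the NMDA receptor conductance on OLM interneurons, the GABA_A
receptor conductance on pyramidal cells, and the HCN channel (I_h)
conductance of pyramidal and PV cells. This package implements the circuit
as a Hodgkin–Huxley network model (five-compartment PYR, single-compartment
PV and OLM; peak-normalized double-exponential AMPA/NMDA/GABA_A synapses;
Poisson background drive; 6.7 Hz septal pacing) and asks how scaling
ḡ_NMDAR(OLM), ḡ_GABA_A(PYR) and ḡ_h(PYR, PV) — alone or factorially —
changes:

* **gamma power** — the 25–50 Hz band of the Welch PSD of the model LFP
  (mean over PYR cells of distal-apical minus basal dendritic voltage);
* **information flow** — normalized transfer entropy
  `nTE = (TE − ⟨TE_shuffled⟩) / H(out_future | out_past)` with
  `TE = I(in_past ; out_future | out_past)` on 15 ms bins, from each
  pyramidal cell's driving-input event train to its spike train;
* **theta–gamma coupling** — the entropy-based modulation index
  `MI = (log N − H(P)) / log N` of the gamma-amplitude-by-theta-phase
  profile `P`;
* **population synchrony** — popCV, the coefficient of variation of a
  population's pooled interspike intervals (≈1 for Poisson firing,
  →√N for N-cell volleys); and per-population firing rates.

The characteristic finding this model reproduces at desk scale is the
*inverted-U*: information flow and theta–gamma coupling peak at intermediate
conductance scalings and intermediate gamma power, and collapse at both
extremes (silenced firing on one side, over-synchronization on the other).

## Worked example

A baseline desk-scale network (scale 0.25: 200 PYR, 50 PV, 50 OLM; synaptic
conductances compensated for the reduced convergence), simulated for 7 s at
dt = 0.1 ms and analysed on the 2–7 s window:

```r
library(ca3net)

net <- build_network(scale = 0.25, wiring_seed = 1)
sim <- run_simulation(net, sim_config(), input_seed = 1)

psd <- welch_psd(sim$lfp[2001:7000], sim$fs_hz)
band_peak(psd, 4, 12)    # 7      : theta LFP peak (Hz)
band_peak(psd, 25, 50)   # 28     : nested gamma peak (Hz)
band_power(psd, 25, 50)  # 0.428  : gamma band power ((mV)^2, per-cell LFP)

sp <- sim$spikes[sim$spikes$time >= 2000, ]
pop_rate(sp$time[sp$pop == "pyr"], 200, c(2000, 7000))  # 5.16 Hz
pop_rate(sp$time[sp$pop == "pv"],   50, c(2000, 7000))  # 39.2 Hz
pop_rate(sp$time[sp$pop == "olm"],  50, c(2000, 7000))  # 8.5  Hz
```

The LFP shows a 7 Hz theta peak and a nested gamma peak in the high
twenties to high thirties of Hz depending on the seed pair; pyramidal cells
fire at a few Hz, PV cells in the high tens, OLM cells around 8 Hz. Augmenting the OLM NMDA conductance 30× silences the
gamma rhythm:

```r
aug <- apply_scaling(net, scaling_set(nmdar_olm = 30))
sim30 <- run_simulation(aug, sim_config(), input_seed = 1)
psd30 <- welch_psd(sim30$lfp[2001:7000], sim30$fs_hz)
band_power(psd, 25, 50) / band_power(psd30, 25, 50)  # 7.5-fold reduction
# (9.3-fold averaged over the two seed pairs the acceptance script uses)
```

`sim_metrics(sim)` computes the full metrics row (band powers and peaks,
nTE, MI, rates, popCV); `build_design()` + `run_sweep()` +
`aggregate_sweep()` run the factorial manipulation designs and
`detect_inverted_u()` / `top_percentile_band()` characterize the
dose–response shapes. Every metric has a seed-deterministic synthetic
ground-truth generator (`gen_poisson_population()`, `gen_coupled_pair()`,
`gen_pac_signal()`, `gen_volley_population()`) so the estimators are tested
independently of the simulator. See the methods vignette
(`vignettes/ca3net-methods.Rmd`) for the model equations, parameter
defaults and design decisions.

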