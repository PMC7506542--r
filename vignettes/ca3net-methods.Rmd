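---
title: "A desk-scale CA3 microcircuit: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale CA3 microcircuit: model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
conductance-based CA3 microcircuit, the information-flow and oscillation
metrics, the synthetic ground-truth generators that validate those metrics,
and — importantly — the decisions we made wherever the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The circuit

The network contains three populations in a 4:1:1 ratio — pyramidal cells
(PYR, 800 at full scale), parvalbumin-positive fast-spiking basket cells
(PV, 200) and oriens-lacunosum moleculare interneurons (OLM, 200).
Pyramidal cells have five compartments (basal dendrite, soma, three apical
compartments); the interneurons are single compartments. All cells carry
leak, fast sodium (NaF), delayed-rectifier potassium (KDR) and
hyperpolarization-activated (I~h~) conductances; pyramidal cells add a
transient A-type potassium current and an I~h~ density that increases along
the apical dendrite; OLM cells add a high-threshold calcium current with
first-order intracellular calcium dynamics and a calcium-activated potassium
current, which gives them spike-frequency adaptation and a prominent sag.

Connectivity is random and convergent: each postsynaptic cell draws a fixed
number of distinct presynaptic partners (the *convergence*) per connection
type. PYR cells excite all three populations through AMPA and NMDA
receptors (mid-apical targets on other PYR cells, somatic targets on the
interneurons); PV cells inhibit PYR somata, each other, and OLM cells; OLM
cells inhibit the distal apical dendrites of PYR cells with slow (20 ms
decay) GABA~A~ synapses. The medial septum (MS) delivers rhythmic
GABA~A~ volleys at 6.7 Hz to PV and OLM cells only.

Two nested rhythms emerge. Gamma arises in the reciprocal PYR–PV loop
(PING) and in mutual PV inhibition (ING): fast PV inhibition of PYR somata
quantizes pyramidal firing at ~30–40 Hz. Theta arises from the OLM loop and
the MS pacing: OLM cells, driven by pyramidal activity and released
periodically by the MS volleys, gate the distal apical dendrites — exactly
where the strong background drive arrives — so pyramidal excitability waxes
and wanes at ~7 Hz, nesting the gamma bursts.

The model LFP is the per-sample mean over pyramidal cells of the distal
apical minus basal dendritic voltage, sampled at 1 kHz (a mean rather than a
sum: absolute band powers are therefore per-cell quantities, and all
acceptance checks use ratios or peak locations, never absolute power).

## Single-cell models

Hodgkin–Huxley rate functions are not uniquely pinned down by the circuit's
behaviour, so we adopt one published standard set and freeze it:

* NaF: `alpha_m = 0.32 (V+54)/(1-exp(-(V+54)/4))`,
  `beta_m = 0.28 (V+27)/(exp((V+27)/5)-1)`,
  `alpha_h = 0.128 exp(-(V+50)/18)`, `beta_h = 4/(1+exp(-(V+27)/5))`
  (Traub lineage), current `gbar m^3 h (V - 55 mV)`.
* KDR: `alpha_n = 0.032 (V+52)/(1-exp(-(V+52)/5))`,
  `beta_n = 0.5 exp(-(V+57)/40)`, current `gbar n^4 (V + 90 mV)`.
* KA (PYR only): steady states `a_inf = 1/(1+exp(-(V+25)/8))`,
  `b_inf = 1/(1+exp((V+70)/6))` with fixed time constants 1 ms and 15 ms,
  current `gbar a b (V + 90 mV)`.
* I~h~: activation `r_inf = 1/(1+exp((V+84)/10.2))` with
  `tau_r = 30 + 170/cosh((V+84)/15)` ms, reversal -30 mV. This produces the
  depolarizing sag the interneuron current-clamp tests assert.
* CaL (OLM): `alpha = 1.6/(1+exp(-0.072(V-5)))`,
  `beta = 0.02 (V+8.9)/(exp((V+8.9)/5)-1)`, power 2, reversal +120 mV;
  calcium follows `dCa/dt = -k I_Ca - (Ca - 50 nM)/80 ms`.
* KCa (OLM): instantaneous saturation `gbar Ca/(Ca + 5 uM) (V + 90 mV)`.

Membrane capacitance is 1 uF/cm^2 and axial resistivity 150 ohm cm.
Compartment geometries and conductance densities are defaults recorded in
`default_params()` and in the YAML parameter file, chosen so that every cell
type is quiescent without input, shows the qualitative electrophysiology
above, and has a monotone f–I curve (PV firing > 100 Hz without adaptation).
The NMDA conductance carries the Jahr–Stevens magnesium block
`1/(1 + ([Mg]/3.57) exp(-0.062 V))` with 1 mM magnesium by default.

Integration is exponential-Euler for gating variables and for the membrane
equation (synaptic and axial terms evaluated at the previous step) at a
default timestep of 0.1 ms. Gating updates use voltage-indexed lookup tables
(0.06 mV grid, linear interpolation) rebuilt for each dt. The
timestep-convergence tests assert that halving dt changes single-cell spike
times by less than 1 ms over a second and network population rates by less
than 5%.

## Synapses, background drive and the septal pacemaker

Synapses are peak-normalized double exponentials: an event of weight `gmax`
reaches exactly `gmax` at `t_p = tau_1 tau_2/(tau_2 - tau_1) ln(tau_2/tau_1)`;
events superpose linearly. Network spikes are delivered after a uniform
event-delivery delay. This delay is a free constant (it stands for axonal
conduction plus synaptic latency, and at desk scale also for the dispersion
of arrival times that a spatially extended network would have); we fixed it
at **6 ms** because the interneuron gamma rhythm it produces then falls at
~35–40 Hz, inside the nested-gamma band this circuit is known for, whereas
at 1–2 ms the PV network oscillates at 65–90 Hz and the slow gamma
disappears. It is configurable per run.

Background drive is an independent homogeneous Poisson event stream per
(cell, synapse) pair, with the conductances of the background parameter
table and *rates* that are calibration constants: the rates were tuned once
(`scripts/tune_background.R`) so the unmanipulated network sits in the
theta-nested-gamma regime, and are frozen across all manipulations. The
dominant driving input is the 6.5 nS dendritic NMDA stream onto pyramidal
cells; we attach it (and the other dendritic background synapses) to the
*distal* apical compartment, co-located with the OLM synapses, so OLM
inhibition gates the drive — the mechanism by which strong OLM recruitment
suppresses both pyramidal firing and gamma. These same NMDA event trains
are the "driving inputs" whose transfer entropy into each cell's spike
train we measure.

The medial-septal pacemaker is modelled as volleys on a shared
quasi-periodic clock: successive periods are 1000/6.7 ms plus a Gaussian
jitter (SD 14 ms), each cell receiving a Poisson number (mean 5) of 10 nS
GABA~A~ events per volley, jittered by 6 ms. Biological septal theta is not
clockwork; the period jitter also prevents the spectral analysis from
mistaking high theta harmonics (multiples of 6.7 Hz reach into the 25–50 Hz
band) for genuine gamma, because phase diffusion broadens the n-th harmonic
roughly in proportion to n^2 while leaving the self-generated gamma
oscillator sharp.

## Desk-scale networks

`build_network(scale = s)` multiplies population sizes and convergences by
`s` (rounded, minimum 1). Because a cell's total synaptic conductance per
connection type would otherwise shrink with the convergence, the builder
applies the standard downscaling correction: each edge conductance is
multiplied by the ratio of full-scale to scaled convergence, so mean
synaptic input matches the full-scale network and only the input
*fluctuations* grow (`compensate = FALSE` disables this). The package's
reference desk scale is 0.25 (200 PYR, 50 PV, 50 OLM) — small enough that a
7 s simulation takes seconds, large enough that theta and nested gamma
survive. Finite-size effects remain: the LFP averages 4x fewer cells, so
its incoherent noise floor is ~4x higher in power, which compresses
measured gamma-power ratios between conditions relative to the full-scale
network.

## Output measures

* **Welch PSD** — mean of Hann-tapered periodograms over 1 s segments with
  50% overlap after DC removal; one-sided density normalization (the
  integral approximates the variance, asserted by a Parseval test). Theta
  power/peak use 4–12 Hz, gamma 25–50 Hz; band powers integrate half-open
  bands so adjacent bands add exactly.
* **Normalized transfer entropy (nTE)** — both trains binned at 15 ms;
  with one-bin past/future embeddings,
  `TE = I(input_past ; output_future | output_past)` (plug-in, bits), and
  `nTE = (TE - mean TE over input-shuffled surrogates) /
  H(output_future | output_past)` with 30 surrogates by default. The
  estimator is validated against an independent brute-force entropy oracle
  (exact agreement to 1e-12) and against coupled-pair surrogates with known
  directed dependence. Per simulation we report the mean over sampled
  pyramidal cells of the nTE from each cell's driving-input train to its
  spike train (default 25 cells; the acceptance checks use the whole
  desk-scale population, 200, to tame estimator variance at these low
  firing rates). A silent or saturated output gives an undefined, flagged
  result, never an exception.
* **Modulation index (MI)** — zero-phase 2nd-order Butterworth band-passes
  (theta 4–10 Hz, gamma 25–50 Hz), Hilbert phase and amplitude, mean gamma
  amplitude in 18 theta-phase bins normalized to a distribution P, and
  `MI = (log N - H(P))/log N`: 0 for uniform, 1 for perfect concentration.
* **popCV** — all spikes of a population merged into one train;
  popCV = SD/mean of its inter-spike intervals. Independent Poisson trains
  give ~1; N cells firing in zero-jitter volleys give exactly sqrt(N-1).
* **Rates** — spikes / (neurons x window).

All metrics are computed on the analysis window (2–7 s of a 7 s run by
default); the first two seconds of network transient are retained in the
spike tables but excluded from analysis.

## The experiments

`apply_scaling()` implements the three pharmacological targets as pure
multiplicative changes: NMDA conductance of synapses onto OLM cells,
GABA~A~ conductance of synapses onto pyramidal cells (network synapses
only; a switch includes the background GABA~A~ streams), and the I~h~
density of pyramidal and PV cells (never OLM). `build_design("nmdar")` is
the 5 x 5 x 7 = 175-run augmentation design; `build_design("triscaling")`
the 3 x 3 x 7 x 5 x 5 = 1575-run interaction design. Default grids: NMDAR
{1, 1.5, 2.5, 5, 10, 20, 30} (control plus the 1.5x–30x augmentation
range); GABA~A~ and I~h~ {0.1, 0.33, 1, 3.3, 10}, log-spaced and
bidirectional. `run_sweep()` stores one metrics row per run (resumable,
idempotent), `aggregate_sweep()` pools mean ± SEM over seed replicates
only, and `detect_inverted_u()` calls a dose–response inverted-U when the
maximum is interior and both endpoints fall more than one pooled SEM below
it (the source literature never formalizes "inverted-U"; this is the
package's convention). `top_percentile_band()` implements the
"top-decile information flow occupies an intermediate gamma range"
analysis, and `surface_interpolate()` provides bilinear interpolation on
log-scaled scaling axes for surface plots.

The full factorial designs at full network scale are cluster-sized; the
shipped tests and the acceptance script run the scaled-down replications
(scale 0.25, 7 s runs, 2 seed pairs for the NMDAR profile, a 3 x 3 x 3
corner grid for the tri-scaling regimes), which take minutes on one CPU.

## Synthetic ground truth

Every metric is testable without the simulator:
`gen_poisson_population()` (popCV ~ 1), `gen_volley_population()`
(popCV -> sqrt(N-1), decreasing in jitter), `gen_coupled_pair()` (an output
that copies the input `lag` bins back with probability `p`, so nTE is 0 at
p = 0, increases with p, and approaches 1 for a deterministic binary copy),
and `gen_pac_signal()` (a theta carrier whose gamma amplitude is modulated
by theta phase with tunable coupling; MI < 0.01 at coupling 0 and increases
monotonically). All generators are seed-deterministic and emit the
simulator's columnar file dialects. What these surrogates do *not* emulate:
refractoriness, bursting, non-stationarity, 1/f LFP backgrounds — passing
the generator tests validates the estimators' math, not their behaviour on
arbitrary real data.

## Numerical and degenerate-input conventions

Spike detection is an upward 0 mV crossing with a 1 ms lockout. Initial
conditions are channel steady states at -65 mV plus a per-cell 2 mV
Gaussian jitter (symmetry breaking). Non-finite state aborts the
integration with the cell and time named. popCV with fewer than two pooled
intervals, MI with a zero envelope, and nTE with a deterministic output
future are all flagged undefined rather than thrown. Aggregation excludes
undefined rows and reports replicate counts; SEM over a single replicate is
undefined.

## Known limitations

Desk scale raises the LFP noise floor (see above), so absolute band powers
and extreme power ratios are not comparable to full scale. The 25-50 Hz
band also contains the tail of the theta-burst waveform spectrum (near the
fourth septal harmonic, ~27 Hz), so on some seeds the single-band argmax
falls in the high twenties even though the PV-paced gamma bump sits at
30-40 Hz; the nTE of
sparsely firing cells has high estimator variance (hence the
whole-population averaging in acceptance); PV and OLM are single
compartments without dendritic detail; channel kinetics are a standard
adopted set, not fits to this circuit; and the background-rate calibration
is a model choice — the oscillatory regime, not the rate values, is the
scientific content.
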