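---
title: "A conductance-based thalamocortical network for spindle and spike-wave dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based thalamocortical network for spindle and spike-wave dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`thalnet` simulates a 475-cell thalamocortical network of single-compartment
Hodgkin–Huxley neurons: 100 layer-5 pyramidal cells split between regular
spiking (RS, a parietal-like phenotype) and intrinsically bursting (IB, a
frontal-like phenotype), 75 layer-6 non-tufted regular-spiking pyramidal
cells (NRS, the only cortical output to the thalamus), 100 deep
low-threshold-spiking interneurons (LTS, the only cortical GABA source),
100 thalamocortical relay cells (TC) and 100 thalamic reticular cells (RE).

Each cell follows

$$C_m \frac{dV}{dt} = I_{hold} - \sum_{ion} I_{ion} - \sum_{syn} I_{syn},
\qquad I_{ion} = \bar g_{ion}\, m^N h^M \,(V - E_{ion}),$$

with $C_m$ = 0.9 µF/cm² for the pyramidal classes and 1.0 µF/cm² for
LTS/TC/RE. Cortical cells carry the full Traub-type current set (fast and
persistent Na; delayed-rectifier, transient, slowly inactivating, M-type and
two Ca-dependent K currents; low- and high-threshold Ca; anomalous
rectifier); TC cells carry leak, K-leak, Na, K, the low-threshold Ca current
and the anomalous rectifier; RE cells carry leak, Na, K and a slow
low-threshold Ca current. Gating kinetics live in a registry of
steady-state/time-constant functions (`gating_kinetics()`, evaluated in
compiled code) following the Traub-type single-compartment reduction for the
cortex and Destexhe-type relay/reticular models for the thalamus.

Synapses use the two-state kinetic receptor model: a presynaptic spike
releases a square transmitter pulse of concentration $C_{max}$ for
$C_{dur}$ ms, during which the open fraction relaxes toward
$s_\infty = \alpha C_{max}/(\alpha C_{max}+\beta)$ with time constant
$\tau_s = 1/(\alpha C_{max}+\beta)$, then decays as $e^{-\beta t}$. The
per-projection maximal conductances and rate constants are read from the
delimited tables under `inst/extdata/` (rows = presynaptic class); each
edge carries weight $\bar g_{syn}/n_{in}$ where the in-degree $n_{in}$
follows `in_degree()` and nearest-neighbour wiring on a line follows
`connect()`.

Three interventions define the experiment axes:

* **Cortical disinhibition** (`gaba_fraction`): the GABA-A maximal
  conductance onto cortical pyramidal cells is scaled to a fraction of
  baseline, modelling GABRG2-type loss-of-function mutations (10% is the
  diseased state).
* **Allopregnanolone** (`allo = TRUE`): every GABA-A synapse, cortical and
  thalamic, is transformed by fixed factors
  $\alpha \times 1.58$, $\beta \times 0.74$, $\bar g \times 1.11$,
  $C_{dur} \times 1.14$ — a positive allosteric modulation that increases
  the charge delivered per presynaptic spike by roughly 2–2.7×.
* **Frontocortical enhancement** (`enhancement = c(7, 5, 3)`): the IB→IB,
  IB→NRS and NRS→IB conductances are multiplied by the given factors,
  modelling the increased frontal connectivity reported in treatment
  non-responders.

## Protocol and analysis

`run_network()` integrates the coupled system with exact-exponential updates
for gates and synapses and an explicit voltage update at dt = 0.025 ms. The
default protocol settles the network for 2 s, then injects 1 nA for 100 ms
into the five layer-6 cells nearest the line's centre and records 6 s at
10 kHz. The simulator is fully deterministic — there is no noise process;
spontaneous activity arises from the intrinsic TC oscillators.

The local field potential is the point-source sum
$V_{ext} = (R_e/4\pi)\sum_i I_{syn,i}/r_i$ over a recorded subset of layer-5
cells (10 RS + 10 IB by default, 20 µm apart per population, electrode 50 µm
from the line centre, $R_e$ = 230 Ω·cm). The trace is linearly detrended,
band-passed 1–15 Hz with a zero-phase Butterworth cascade, and summarized by
a Welch PSD (Hann window, 20,000-sample segments, 1,000-sample overlap:
0.5 Hz bins). `band_metrics()` integrates the SWD (2.5–5 Hz) and spindle
(7–10 Hz) bands, normalizes by the 1–15 Hz total, and labels the state
*spindle* / *SWD* / *intermediate* (peak in band and band strictly
dominant; peak ties resolve to the lowest bin).

```{r example}
library(thalnet)
r <- run_scenario(scenario(nIB = 75, gaba_fraction = 1))
r$peak_frequency   # spindle-band peak
r$state
```

## Parameters that matter, and their defaults

* **Conductance densities** (S/cm², `cell_template()`): free parameters of
  the single-compartment reduction, calibrated so that each class expresses
  its canonical phenotype — RS/NRS tonic firing with spike-frequency
  adaptation, IB burst firing, LTS high-rate firing, TC spontaneous rhythmic
  bursting (the network's pacemaker), RE rebound bursting — and so that the
  network reproduces the qualitative state map (below). Every density is
  overridable per cell class.
* **Holding currents** (`calibrate_hold()`): bisection finds the constant
  current holding each isolated cortical cell's mean potential at its target
  (−65 mV for pyramidal classes, −56 mV for LTS, making the interneurons
  tonically active); the thalamic membrane equations carry no holding term.
  Slow conductances equilibrate over seconds, so precise subthreshold
  holding uses longer calibration runs (`duration`).
* **Synaptic kinetics**: $C_{max}$ = 0.5 mM and Control $C_{dur}$ = 0.3 ms
  for all receptors; $E_{AMPA}$ = 0 mV, $E_{GABA_A}$ = −85 mV,
  $E_{GABA_B}$ = −95 mV. We use −85 mV rather than the −80 mV of some parent
  models because at −80 mV the reticular→relay IPSP has almost no driving
  force at the relay cells' operating point; −85 mV is equally conventional
  for thalamic chloride reversal. GABA-B rows share their α/β with the
  GABA-A partner row of the same projection (the tables list one rate pair
  per projection); `network_config(gabab_alpha, gabab_beta)` can override
  this. We also evaluated canonical slow GABA-B kinetics (~150 ms decay)
  and found they tonically suppress the relay population and degrade every
  network state under the published conductances, so the shared-rate
  default stands.
* **Compartment area**: a cylindrical soma with length = diameter = 100 µm
  (≈3.14·10⁻⁴ cm²) converts nA inputs to current densities; overridable.
* **Calcium pool**: first-order, driven by the Ca currents with a 100 ms
  decay constant; it feeds the two Ca-dependent K currents that terminate
  cortical discharges and set the paroxysm cycle.
* **Burst classifier** (`classify_firing()`): a cell is "bursting" when at
  least 30% of its inter-spike intervals are shorter than 15 ms while the
  distribution also contains intervals longer than 50 ms.

## Numerical choices

Gate updates are exact-exponential with steady states and relaxation factors
tabulated on a 0.05 mV voltage grid; the synapse update exploits the fact
that all idle edges of a projection decay at the same rate, so only edges
inside a transmitter pulse are integrated individually (idle edges are
aggregated per postsynaptic cell and synced lazily on retrigger). Halving dt
moves reported peak frequencies by at most one 0.5 Hz bin (tested).
Simulations abort with a diagnostic if any membrane potential leaves
±150 mV. The 1–15 Hz Butterworth band-pass is applied as a cascade of an
order-4 high-pass and an order-4 low-pass (forward–backward each): a single
band-pass of this relative bandwidth is numerically unstable in
transfer-function form at 10 kHz. Repeated presynaptic spikes retrigger a
synapse: the pulse clock resets and the rise continues from the current open
fraction. Recurrent projections exclude self-edges; when the in-degree rule
returns the full population (only possible for 5-cell layer-5 minorities)
the in-degree is capped at one less than the population size.

## What the model reproduces, and what it does not

With the published synaptic parameter tables and the calibrated cell
templates, the model reproduces:

* a spindle-band network state (peak 8–8.5 Hz, spindle label) at 100%
  cortical GABA-A for all four layer-5 compositions;
* resolution by the ALLO transform at baseline connectivity: from the
  disinhibited state, applying the transform to every GABA-A synapse
  restores a 7 Hz spindle-labelled state in all four compositions;
* genuine 4.5–5 Hz spike-wave discharges under frontocortical enhancement
  (factors 7, 5, 3) at 10% cortical GABA-A, and — the central result — the
  failure of ALLO to restore the spindle state in the IB-dominant (95-5)
  and balanced (50-50) enhanced networks.

It does **not** reproduce two features of the reference behaviour, and the
acceptance suite reports these honestly as failures rather than papering
over them:

* at baseline connectivity, 10% cortical GABA-A yields an organized
  ~6.5 Hz discharge pattern rather than a 5 Hz SWD (the peak sits above the
  2.5–5 Hz band, so the SWD label, the sweep trend and the
  synchrony-increase property all miss);
* under enhancement, ALLO leaves the RS-dominant (5-95) network at an
  intermediate ~6 Hz state instead of restoring a 7.5 Hz spindle.

The two misses share one mechanism. In this reduction the disinhibited
cortex enters discharges whose length is terminated by a budget of
adaptation plus remaining inhibition that accumulates linearly during the
burst; that linearity caps the attainable ratio between discharge lengths at
10% versus at the ALLO-boosted effective inhibition (~2× of 10%) at about a
factor of two — less than what a 5 Hz SWD and a simultaneous 7 Hz
restoration require. The fitted cell models of the reference implementation
(not published in the main text) evidently supply an additional slow or
nonlinear process; the registry and templates are parameterized so such
values can be dropped in directly.

## Testing strategy and problem sizes

Unit tests validate each operation against independent oracles: closed-form
gate relaxation against a fine-step midpoint integration, the synapse
profile against a brute-force ODE oracle, the LFP against hand arithmetic,
the Welch implementation against pure tones and a variance-normalization
property, and the in-degree rule against the full published table. The
synthetic-signal generators (`make_tone_mixture()`, `make_spike_train()`)
make the spectral pipeline testable without simulations and are
deterministic under a stated seed (default 1234). Network-level tests run a
scaled-down protocol (1.5 s settle, 4 s record — still two full Welch
segments at the native 0.5 Hz resolution) and share runs through a cache;
the acceptance script uses the full 2 s + 6 s protocol. Passing tests on
this synthetic, noise-free network demonstrate internal consistency of the
implementation, not fidelity of any particular biological cortex: real
tissue has heterogeneous cells, conduction delays, stochastic release and
background drive, none of which are modelled here.
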