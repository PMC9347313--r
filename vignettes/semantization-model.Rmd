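---
title: "A spiking attractor model of episodic memory semantization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking attractor model of episodic memory semantization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(semnet)
```

## The scientific problem

Episodic memories bind *what* happened to *where and when* it happened.
With repeated exposures of an item across different contexts this binding
erodes: the item remains recognizable while its episodic context becomes
irretrievable — a "Know" rather than a "Remember" response in the classical
behavioural paradigm. `semnet` implements a two-network spiking cortical
model in which this *semantization* (item–context decoupling) emerges from
the normalizing arithmetic of a Bayesian–Hebbian synaptic learning rule
(BCPNN), and contrasts it with a conventional spike-timing-dependent
plasticity (STDP) rule that produces no such decoupling.

The model consists of an Item network and a Context network, each a
subsampled layer-2/3 cortical patch of hypercolumns (HCs) containing
minicolumns (MCs) of pyramidal cells plus basket cells that implement soft
winner-take-all competition. Long-term memories (items, contexts) are
*preloaded* as attractors — strong recurrent excitation among the cells of
a pattern, monosynaptically rendered inhibition between competing MCs.
Only the sparse *associative* projections between the two networks are
plastic during a simulation; they learn the item–context bindings.

## Neuron and synapse model

Membrane dynamics follow the adaptive exponential integrate-and-fire
(AdEx) equation with spike-triggered adaptation and no subthreshold
adaptation:

$$C_m \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V-V_t)/\Delta_T}
  - I_w + \beta + I_{ext} - I_{syn}, \qquad
  \dot I_w = -I_w/\tau_{I_w} + b\,\delta(t - t_{sp}).$$

Parameters (capacitance 280 pF, leak 14 nS to −70.6 mV, threshold −55 mV,
slope 3 mV, reset −60 mV, `b` 86 pA with 280 ms decay, 5 ms refractory
period) are shared by all cells. We deliberately keep the single table parameter
set for basket cells as well: in an early variant with
non-adapting (`b = 0`) basket cells, tonic basket drive from the baseline
firing of already-encoded patterns accumulated over the encoding phase and
progressively suppressed the ignition of later-encoded patterns; basket
adaptation absorbs tonic drive while preserving phasic winner-take-all
inhibition.

Synapses are conductance-based with exponential decay: AMPA (5 ms) and
NMDA (100 ms) at 0 mV, GABA (5 ms) at −75 mV. NMDA differs from AMPA only
by its slow kinetics and its own gain; no voltage-dependent magnesium
block is modelled. All glutamatergic synapses (recurrent, associative and
pyramidal→basket) additionally carry Tsodyks–Markram short-term dynamics:
utilization `u` (augmentation, decay 5 s) jumps by `U(1-u)` per spike and
resources `x` (depression, recovery 280 ms) are depleted by `U·x` — the
depletion uses the fixed fraction `U`, following the model's stated jump
terms rather than the classical `u·x` depletion. The conductance
transmitted by a spike is `w · u⁺ · x⁻` (`u` after its jump, `x` before
depletion), so a first spike from rest transmits `U = 0.2` of the bare
conductance.

Integration is forward Euler at `dt = 0.1` ms; a spike is registered when
the membrane crosses 0 mV (the exponential term diverges, so any ceiling
well above threshold gives sub-step-equivalent timing). Halving `dt`
moves single-neuron spike times by well under 0.5 ms over a second of
simulation, which we treat as sufficient integration stability for the
population-level quantities studied here.

## Spike-based BCPNN

Each plastic connection keeps two banks of traces, one per receptor
(AMPA `τ_z` = 5 ms, NMDA 100 ms). Spikes drive fast Z traces,

$$\tau_z \dot Z = \frac{S}{f_{max} t_{spike}} - Z + \epsilon,$$

where `S` is a rectangular pulse of `t_spike` = 1 ms per spike. The
normalization by the maximal rate (`f_max` = 25 Hz) calibrates the trace
so sustained firing at `f_max` saturates the time-averaged Z near 1 and
silence decays it to the probability floor `ε = 0.0026`. Slow P traces
(`τ_p` = 15 s) low-pass the Z traces and their product,

$$\tau_p \dot P_i = \kappa (Z_i - P_i), \quad
  \tau_p \dot P_{ij} = \kappa (Z_i Z_j - P_{ij}),$$

and the weight and intrinsic excitability are their log-odds and
log-prior:

$$w_{ij} = w^{syn}_{gain} \log \frac{P_{ij}}{P_i P_j}, \qquad
  \beta_j = \beta_{gain} \log P_j.$$

Negative weights (anti-correlated units) are delivered as `|w|` at the
GABA reversal, rendering the learned disynaptic inhibition between
competing populations monosynaptically. `κ` multiplies the learning rate:
1 during regular encoding and recall, 2 for the transiently boosted
pairing in the preferential-retention experiment, 0 to freeze all plastic
state exactly.

Semantization falls out of the weight formula: when an item is re-encoded
in a *new* context, its `P_i` keeps growing while the coactivation trace
`P_ij` with each *old* context decays, so every additional context
strictly weakens the existing bindings. The intrinsic excitability `β`
moves the other way — more active items become more excitable — which is
the bias/weight trade-off characteristic of a Bayesian estimator.

**Trace initialization.** Associative connections start from the naive
prior `P_i = P_j = ε`, `P_ij = ε²`, so initial weights are exactly zero —
bindings are learned, never preloaded. The per-neuron *bias* trace of the
full network instead starts at the pattern prior `1/n_MC = 0.1`: the
attractors are preloaded as the outcome of prior long-time-constant
learning, and the mean preloaded log-odds weight (≈ 2.1 ≈ log 10)
implies exactly that prior. Starting the bias at the naive floor instead
(−238 pA) silences the entire network, with no baseline activity and no
cue-driven recall — inconsistent with the ~1 Hz baseline the detection
threshold presupposes. With the pattern prior, the bias is −92 pA and the
network sits in the intended regime: a ~0.5–2 Hz baseline, reliable
stimulus-driven ignition, no spontaneous attractor reactivations.

## Multiplicative STDP (comparison condition)

In the STDP condition the associative projections instead use a
multiplicative, nearest-neighbour STDP rule: each presynaptic arrival
(spike time plus transmission delay) pairs with the most recent
postsynaptic spike and vice versa, with

$$\Delta w = \lambda (1-w)\, e^{-|\Delta t|/\tau_+} \;\;(\Delta t \ge 0),
 \qquad \Delta w = -\lambda \alpha w\, e^{-|\Delta t|/\tau_-}
 \;\;(\Delta t < 0),$$

`Δt = t_post − (t_pre + delay)`, `λ` = 0.01, `α` = 1.2, symmetric 20 ms
windows. `α τ_-/τ_+ > 1` makes the integral of the kernel negative
(stable competitive modification). Weights are normalised to `[0, 1]` and
scaled by `w_max` (AMPA 13.5 nS, NMDA 3.5 nS) on delivery. The conventional
written form of the branch condition involves the transmission delay
(`Δt ≥ τ_d`); we read this as an artefact of the delay already being
subtracted inside `Δt` and use `Δt ≥ 0`, with the literal variant
available behind `stdp_params(branch_at_delay = TRUE)`. Nearest-neighbour
(rather than all-to-all) pairing matches the referenced standard
implementation and keeps the single-pair semantics of the update rule.
There is no bias-current plasticity under STDP; pyramidal cells carry the
static pretrained bias (−92 pA) so that baseline excitability matches the
BCPNN condition.

## Architecture, preloading and calibration

Each network is 12 HCs (4 × 3 grid on a 2.0 × 1.5 mm patch) × 10 MCs ×
30 pyramidal cells, plus 2 basket cells per MC — 7200 pyramidal and 480
basket cells in total. Patterns are non-overlapping: pattern *p* occupies
MC *p* in every HC. Connectivity is Bernoulli: within-HC pyramidal pairs
at 0.2, cross-HC pairs at 0.25 (same pattern → excitatory attractor
class, different pattern → the inhibitory competing-MC class), a
pyramidal↔basket loop within each HC at 0.7 (+3 nS / −7 nS), and sparse
plastic associative projections between the networks at 0.02. Delays are
normal draws with mean `distance/speed + 1.5 ms` and 30 % relative SD,
truncated below at 1.5 ms; associative axons conduct at the myelinated
2 m/s, local axons at 0.2 m/s.

Attractors are preloaded by direct weight assignment in log-odds model
units — within-HC mean 2.15, cross-HC mean 2.05 ("slightly weaker", with
the pooled mean matching the reference value of 2.1), competing-MC mean −0.3 —
converted to conductance through the per-receptor gains and one global
scale. That scale is calibrated so that the mean within-HC same-pattern
EPSP, measured at rest from a single presynaptic spike *including* the
first-spike short-term-plasticity factor, equals 0.45 mV. We adopt the
first-spike convention for calibration because a paired recording from
silence includes release probability; the measurement harness
(`measure_psp`, `psp_distribution`) reports the bare-conductance variant
as well. The same passive machinery reproduces the unitary
basket-to-pyramidal IPSP of ≈ −1.18 mV at −60 mV holding from the −7 nS
table conductance, against the reference value of −1.160 mV.

## Task protocol

A trial consists of a 500 ms settling period, ten encoding epochs — each
pairing's item and context patterns driven simultaneously for 250 ms by
500 Hz/1.5 nS Poisson input, 500 ms interstimulus gaps — a 1 s delay, and
a test phase of 50 ms cues (400 Hz) at 500 ms spacing. The default
association map gives items 1–4 three, two, one and four contexts
respectively over ten distinct contexts, each context used exactly once.
Encoding order and cue order are shuffled per trial with the trial seed
(fixed-order mode available). The scoring window for a cue runs from its
onset to the next cue onset.

Background noise is delivered to every cell by two independent Poisson
generators with opposing driving potentials (one at the glutamatergic,
one at the GABA reversal, ±1.5 nS, rates applied per generator). The
elevated encoding-phase rate (650 Hz) accompanies the stimulation epochs;
settling, gaps, delay and test run at the recall rate (450 Hz). We chose
the stimulus-locked assignment after observing that elevated noise in the
interstimulus gaps pushes recently encoded (augmented) attractors into
spontaneous reactivation, which then outcompetes later stimulus-driven
encodings — a free-recall regime that this model class enters only under
substantially enhanced noise.

Recall is scored from the attractor-activation detector: per-pattern
exponential moving average of the firing rate of the pattern's MC in a
sample HC (30 cells, `τ` = 40 ms, 1 ms sampling), threshold 10 Hz,
events terminated only if the rate stays below threshold for 40 ms, and
events shorter than 40 ms discarded. A literal reading of the detector recursion decays by `ΔT/τ` per step, which cannot implement a 40 ms EMA;
we implement the standard leaky form (steady state equal to the true
rate) and keep the literal recursion available behind a flag. An item cue
whose item attractor activates together with any associated context is a
remember-like outcome; item activation alone is know-like; neither is a
miss. Context cues are scored symmetrically with the associated item as
target.

## The reduced microcircuit

`run_microcircuit()` applies the identical plasticity kernels to seven
neurons: item 1 pairs with contexts 3–4, item 2 with contexts 5–7, each
pairing co-stimulated at 20 Hz for 2 s in the epoch order (2,5), (1,3),
(2,6), (1,4), (2,7), with a readout spike to the items at 11 s.
Stimulation is supra-threshold current injection (6000 pA, 4 ms pulses at
20 Hz), which yields exactly one spike per pulse and hence deterministic
trajectories; weaker pulses fail to trigger the AdEx upstroke from the
bias-hyperpolarized rest. Under BCPNN the tracked synapse of the
two-association item converges on a higher weight than that of the
three-association item; under STDP the two converge to nearly identical
values — the microcircuit-scale statement of the semantization contrast.

## Scales, runtimes and what the tests show

The package's test tier runs the episodic task on a reduced model of 6
HCs per network (3840 cells, ≈ 1.9 M synapses, ≈ 130 k plastic), ten
seeds per condition; a trial simulates ≈ 10.5 s of biological time in
≈ 25 s on one CPU. At this scale the associative NMDA weight gradient is
strictly decreasing in association count (≈ 0.27, 0.22, 0.19, 0.16 nS
for 1–4 associations) — the synaptic trace of semantization — while
cued recall itself saturates near ceiling for all association counts:
halving the network halves the associative fan-in per cell (≈ 3.6
synapses), and the surviving bindings all remain above the ignition
threshold once encoding is reliable. The graded *recall* percentages are full-scale phenomena (12 HCs, ≈ 7 M synapses,
≈ 520 k plastic; a trial takes a few minutes) and are not asserted at
the reduced scale. Passing tests therefore demonstrate the mechanism (weight
decoupling, bias/weight trade-off, rule contrast, detector behaviour),
not the quantitative recall curves.

What the synthetic task also does *not* emulate about real data: there is
no perceptual front end (patterns are assigned, not learned from
stimuli), contexts never repeat across items, pattern overlap is zero,
and behavioural timescales beyond ~11 s (sleep, consolidation) are out of
scope.

## Numerical choices and degenerate inputs

* Conductance decay uses exact per-step exponential factors; membrane and
  trace updates are forward Euler. P traces and bias currents update at
  1 ms granularity (they evolve with `τ_p` = 15 s).
* At most one spike per neuron per step, guaranteed by `τ_ref ≫ dt`; one
  noise event per generator per step (event probability ≤ 0.065).
* Delays are truncated below at the minimal synaptic delay; delivery is
  via a ring buffer, so a zero-length delay is promoted to one step.
* Event detection bridges sub-threshold dips strictly shorter than the
  guard window; exact-equality ties at the threshold count as
  supra-threshold.
* `measure_psp` on an unconnected pair returns an explicit no-connection
  row (`connected = FALSE`, `psp = NA`), never a silent zero.
* Empty association maps produce settling-plus-delay schedules; empty
  trial sets produce empty summary tables.
* `f_min` (0.2 Hz) is stored in `bcpnn_params()` for completeness but
  appears in no update equation; it is unused by default.

## Known limitations

* Recurrent attractor weights are static during the task (they represent
  well-consolidated long-term memory); consolidation of new bindings into
  the recurrent structure is out of scope.
* At the reduced scale, STDP pairing weights carry a strong encoding-epoch
  recency gradient (declining late-epoch context encoding rates plus
  Hebbian crosstalk with baseline activity after a pairing's epoch).
  Group means per association count sample only one to four epoch
  positions per trial, so their spread across association counts
  (10–14 % over ten seeds) reflects this epoch gradient rather than any
  systematic association-count dependence of the rule — the
  deterministic microcircuit puts the rule's own association-count
  difference below 0.1 %. The corresponding acceptance check of a < 10 %
  band is asserted as stated and fails at this scale.
* The bias-prior and EPSP-convention choices are calibration decisions;
  both are exposed as arguments and documented above.
* Exact reproduction of full-scale recall percentages requires the
  12-HC model and many trials (hours of compute); the package supports
  it (`run_experiment` with the default layout) but does not test it.
* Double-bouquet cells are not explicitly simulated; their disynaptic
  inhibitory effect is carried by the learned negative weights.
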