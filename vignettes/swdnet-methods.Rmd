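---
title: "Modelling spike-and-wave discharges in a corticothalamic network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spike-and-wave discharges in a corticothalamic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Absence seizures are generalized, non-convulsive seizures whose EEG
hallmark is the spike-and-wave discharge (SWD): a repeating sharp transient
("spike") followed by a slow wave, at roughly 4 Hz in humans and 5-9 Hz in
rodent models. Both clinical and experimental evidence place the generator
in the corticothalamic loop: neocortex, thalamocortical (TC) relay neurons
of first-order (FO) and higher-order (HO) nuclei, and the GABAergic nucleus
reticularis thalami (NRT) that inhibits them.

`swdnet` implements (i) a conductance-based corticothalamic network in
which single-conductance changes - a 5% increase of the potassium leak of
TC_FO neurons (a proxy for raised tonic GABA-A inhibition), an increase of
extrasynaptic GABA-A conductance, a decrease of cortical phasic GABA-A, an
increase of cortical AMPA, added strongly-bursting cortical cells, or
T-type Ca2+ changes - can elicit, modulate or abolish SWD-like activity;
and (ii) the complete ictal-EEG analysis stack used to characterize such
activity: zero-phase Butterworth band-pass filtering, Hilbert phase and the
phase-synchronization index (PSI), ictal segmentation, SWD-spike-triggered
AP histograms (STAPs), burst/tonic/silent classification and
period-normalised averaging. A synthetic ground-truth generator makes the
whole analysis stack testable independently of the simulator.

## The network

The default network holds 900 neurons in six sectors: four cortical layers
(L2/3, L4, L5, L6), each split into two subsectors and holding 100
excitatory plus 50 fast-spiking (FS) inhibitory neurons per layer, and two
thalamic sectors (first- and higher-order), each with 75 TC and 75 NRT
neurons. Excitatory cortical cells come in six classes - regular spiking
(RS), intrinsically bursting (IB), early firing (EF), repetitive
intrinsically bursting (RIB), network driver (ND) and the substitutable
strongly intrinsically bursting (SIB) variant. Connections are topographic:
source and target rows are aligned by linear index rescaling and each
source contacts targets within a projection radius, never itself and at
most once per target.

The *desk scale* divides all counts by five (180 neurons) and shrinks the
radii accordingly. All structural invariants (no autapses, pair uniqueness,
topographic containment) are preserved, and every quantitative result in
the package's tests and acceptance script is computed at desk scale with
60-120 s simulations and three seeds. Rate- and frequency-type outcomes are
treated as scale-robust; amplitude-type claims are not reproduced at this
scale and are deliberately out of scope.

## Cell and synapse models

Each neuron is a single compartment with Hodgkin-Huxley spike currents
(Traub-type kinetics with a per-class threshold shift), a slow
non-inactivating K+ current for adaptation, a T-type Ca2+ current in relay
(TC) and reticular (NRT) kinetic variants, a hyperpolarization-activated
cation current, a Ca2+-activated non-selective cation current (CAN) driven
by a leaky intracellular Ca2+ pool, a persistent Na+ current in NRT cells,
a non-specific leak, a potassium leak `g_KL`, and (TC only) a tonic
extrasynaptic GABA-A chloride conductance. The rate equations are standard
published formulations; conductance densities were tuned so that every
class passes `classify_firing_signature()` under its standard current-clamp
protocol (depolarizing step for cortical classes, hyperpolarize-and-release
for thalamic ones): RS is regular spiking, IB/EF burst at stimulus onset,
RIB/ND/SIB burst repetitively, FS fires fast with < 20% adaptation and ISI
CV < 0.2, and all TC/NRT classes produce rebound bursts that disappear when
`g_T` is removed and return when it is restored.

Synapses are bi-exponential conductances (AMPA: 0.5/2.5 ms; GABA-A:
0.5/8 ms) plus a two-stage GABA-B G-protein cascade (receptor activation
`r`, G-protein `s`, conductance fraction `s^4/(s^4 + K_d)`) with the
standard constants K1 = 0.52 /mM/ms, K2 = 0.0013 /ms, K3 = 0.098 /ms,
K4 = 0.033 /ms, K_d = 100. The fourth-power nonlinearity makes the slow
IPSP burst-selective: a six-spike 300 Hz burst produces more than ten times
the conductance-time integral of a single spike. NMDA receptors,
short-term plasticity and gap junctions are deliberately omitted.

Two interchangeable implementations of increased tonic inhibition of TC
neurons are provided, matching the two experimental routes: a multiplier on
`g_KL` (potassium reversal) and a multiplier on the extrasynaptic GABA-A
conductance `g_eGABAa` (chloride reversal). Both hyperpolarize the cell;
both are exposed as perturbations.

## Behavioural states, background drive and perturbations

Every neuron receives an independent Poisson background of AMPA-like
events (rate and amplitude per population), which produces the
desynchronized low-amplitude EEG of relaxed wakefulness. The behavioural
state scales the potassium leak per population: the *sleep-wake-transition*
state - the state in which SWDs arise - lowers the input resistance of
thalamic and cortical neurons relative to wake. State parameters ship in
`default_network_config()` and were tuned once to place the transition
state near (but below) the synchronization threshold.

A perturbation is a named conductance, a population selector, a
multiplicative scale (0 = block) and an onset time. Intrinsic conductances
(`g_KL`, `g_T`, `g_CAN`, `g_eGABAa`) scale per-neuron parameters; receptor
conductances (`g_AMPA`, `g_GABAa`, `g_GABAb`) scale the receptor gain of
the target population. Perturbations are multiplicative, idempotent per
event, logged, and local: parameter arrays of unnamed populations are
bit-identical before and after.

## The EEG proxy and the integrator

The EEG is the negated sum of AMPA, GABA-A and GABA-B synaptic currents
onto cortical excitatory neurons, block-averaged to 1 kHz and
mean-subtracted - the standard local-field proxy for point-neuron
networks. It is linear in the synaptic currents by construction.

The engine integrates all cells at a fixed step with exponential Euler for
both gating variables (voltage-gridded lookup tables of steady state and
step factor, 0.05 mV grid) and the membrane equation (all current terms are
ohmic, so the update is unconditionally stable through the spike-time
conductance peaks). Spikes are upward crossings of 0 mV with a 2 ms
refractory period; each spike schedules delayed receptor events through a
ring buffer (per-connection latencies quantized to steps). The default step
is 0.05 ms for network runs (halving it changes population rates by < 5%
on a 5 s benchmark; a test asserts this) and 0.025 ms for single-cell
protocols. A table-interpolated `exp(-x)` (relative error < 1e-7) is used
in the membrane update. Simulations are bit-reproducible given (network,
config, seed); all randomness (placement, latencies, heterogeneity,
background drive, initial voltages) is seeded.

## The ictal analysis stack

**Band-pass design.** The SWD band-pass is a minimum-order Butterworth
band-pass with passband and stopband edges 2 and 4 Hz either side of the
SWD frequency, 0.5 dB passband ripple and 65 dB stopband attenuation. At a
4 Hz center the lower stopband edge sits at 0 Hz, where the band-pass zeros
give unbounded attenuation, so the order is set by the upper edge (order 18
at 1 kHz sampling). Because the poles of such a narrow low-frequency design
crowd z = 1, polynomial transfer-function coefficients are numerically
unusable; the whole pipeline therefore stays in zero-pole-gain /
second-order-section form: the analog prototype and band transform are
computed in zpk, bilinearly transformed, paired into biquads, evaluated
stably for the frequency response, and applied forward-backward
(zero-phase) with odd-reflection padding.

**Hilbert phase and PSI.** The analytic signal is computed in the
frequency domain; `PSI(t)` is the modulus of the windowed circular mean of
the phase difference, smoothed with a 1 s moving average. PSI is bounded in
[0, 1], equals 1 for any constant phase offset, and for independent phases
matches the Rayleigh expectation `sqrt(pi)/(2 sqrt(n))` (verified by Monte
Carlo). Population phases are taken from band-filtered population firing
rates.

**Ictal segmentation.** The detector thresholds the smoothed amplitude
envelope of the 2-10 Hz band at `baseline mean + 4 SD`, with baseline
statistics from the sub-median part of the envelope distribution (corrected
for truncation; robust up to roughly 50% ictal occupancy), merges gaps
shorter than 0.5 s, requires 0.75 s and three cycles, and then locates SWD
spike peaks as EEG local maxima separated by at least 60% of the dominant
period; the dominant frequency is the inverse median inter-peak interval,
refined once. Cycle boundaries are midpoints between consecutive peaks,
extended half a period at the ends. A single interval covering more than
90% of the trace is flagged as absence status. The paper-style timeline
figures never state a detector, so these thresholds are package design
decisions, exposed as arguments and validated against the synthetic
ground-truth generator (exact seizure counts at moderate noise, >= 90%
recall at SNR 3, frequency within 5%).

**STAPs and cycle firing.** The all-AP histogram bins every AP within
+/-125 ms of each EEG spike peak; the first-AP variant bins only each
neuron's earliest AP per cycle, guaranteeing at most one count per neuron
per trigger. Densities are normalised per trigger. Cycle firing is
classified as burst (>= 2 APs with ISIs <= 10 ms - the conventional
thalamic burst criterion), tonic (>= 1 AP), or silent, with
cycle-bootstrapped confidence intervals.

## The synthetic ground-truth generator

`synthetic_swd_spec()` describes an EEG with known seizures: each cycle is
a sharp Gaussian transient plus an opposite-sign half-sine wave at the
requested frequency, embedded in pink (1/f) interictal noise - pink rather
than white because real EEG baselines have a falling spectral slope, which
is what makes envelope-based detection non-trivial. Spike trains are
phase-locked with configured per-population lags, jitter, and firing modes.
The generator returns exact interval and spike-peak ground truth. It
emulates the morphology and lag structure of ictal recordings but not
their biophysics: passing round-trip tests shows the analysis stack is
correct, not that the simulator is realistic.

## What the simulator does and does not reproduce

With the shipped study conditions (desk scale, transition state, trigger
`g_KL` of TC_FO x1.05 at t = 5 s, seeds 1-3), the model produces recurring
large-amplitude SWD-like discharges several times per minute with a
dominant frequency near 3.3 Hz, seizure-correlated burst firing in NRT and
deep cortical layers, thalamic relay neurons that are mostly silent or
sparsely active ictally with their firing leading the EEG spike by roughly
10-20 ms, and an early secondary first-AP cluster tens of milliseconds
before the spike.
Removing the T-type conductance from all NRT neurons abolishes detected
seizures entirely, while removing it from first-order TC neurons does not
- the two knockout results that anchor the mechanism.

Known limitations, measured and deliberate to report:

* The dominant frequency sits ~0.7 Hz below the 4 Hz human-like value, and
  reducing the higher-order TC potassium leak does not shift the rhythm
  into the 7-8 Hz rodent-like band. In this implementation the inter-volley
  period is governed by the slow receptor stage of the GABA-B cascade,
  which saturates under convergent input; the TC_HO membrane is then
  conductance- rather than leak-dominated between volleys, and the leak
  dial loses its leverage on the period.
* T-type knockouts in higher-order TC neurons and in NRT neurons abolish
  detected seizures on the tested seeds, and the first-order TC knockout
  correctly does not; but cortical and first-order-TC GABA-B blocks only
  reduce the seizure count severalfold without always abolishing it: a
  cortically paced remnant of the rhythm can survive at desk scale.
* Ignition is not certain for every network realization: one of the three
  shipped seeds does not ignite under the 5% trigger within 120 s.
* The unperturbed transition state expresses brief fast (beta-band)
  synchronous events rather than 7-14 Hz spindle epochs; the spindle
  sanity check reports this honestly.
* The 5% leak increase raises the seizure rate severalfold rather than
  acting as an all-or-none switch; occasional discharges occur in the
  unperturbed transition state.

These gaps are properties of this re-implementation at desk scale - the
original model's exact conductance tables and kinetics live in its
companion description and are not reproduced here; all kinetics were
re-derived from standard published schemes and tuned to firing signatures
only.

## Numerical and design choices worth knowing

* dt in (0, 0.05] ms enforced; 0.05 ms network default (convergence
  tested), 0.025 ms single-cell default.
* Gating updates cannot leave [0, 1] by construction (exponential Euler
  toward a bounded steady state).
* The Ca2+ pool has a long time constant (1.5 s) so that CAN activation
  integrates across seizure cycles; CAN in NRT acts as the slow negative
  feedback that terminates discharges.
* Mild seeded heterogeneity (+/-5% in `g_T` and `g_KL`) desynchronizes
  pathological locking at the single-cell level.
* Ties in peak picking resolve greedily by height; degenerate inputs
  (constant signals, empty spike trains, zero-length intervals) raise
  informative errors or return empty results, as tested.
* Problem sizes: tests and the acceptance script use the 180-neuron desk
  network, 40-120 s simulations, three seeds; the full 900-neuron network
  is built and structurally validated in tests but not integrated there.
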