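# swdnet

Conductance-based simulation and analysis of absence-seizure
**spike-and-wave discharges (SWDs)** in a corticothalamic network.

SWDs — a sharp EEG "spike" followed by a slow "wave", repeating at ~4 Hz in
humans and 5–9 Hz in rodent models — arise from the loop formed by the
neocortex, thalamocortical (TC) relay neurons of first- and higher-order
nuclei (TC_FO, TC_HO), and the GABAergic nucleus reticularis thalami (NRT).
`swdnet` is for computational neuroscientists who want to study how *single
conductance changes* (potassium leak `g_KL`, tonic and phasic GABA-A,
GABA-B, AMPA, T-type Ca²⁺ `g_T`, the Ca²⁺-activated cation conductance
`g_CAN`) push this circuit from desynchronized activity into ictal states —
and who need the matching ictal-EEG analysis toolchain.

The package has three layers:

* **Simulator** — a 900-neuron (desk scale: 180) six-sector network of
  single-compartment Hodgkin–Huxley neurons (11 cell classes, Traub-type
  spike currents, Destexhe-type `I_T`, `I_h`, `I_CAN`, `I_NaP`), AMPA and
  phasic GABA-A bi-exponential synapses, tonic extrasynaptic GABA-A on TC
  cells, and a GABA-B G-protein cascade whose conductance follows
  `s⁴/(s⁴ + K_d)` — the burst-selective nonlinearity the slow "wave"
  depends on. Perturbations scale any named conductance of any population
  from a given onset (`scale = 0` blocks it). The EEG proxy is the negated
  sum of synaptic currents onto cortical excitatory cells at 1 kHz.
* **Analysis** — minimum-order Butterworth SWD band-pass (passband ±2 Hz,
  stopband ±4 Hz, 0.5 dB ripple, 65 dB attenuation; zero-phase,
  numerically designed and applied in zero-pole-gain / biquad form),
  FFT-based Hilbert phase, phase-synchronization index
  `PSI(t) = |⟨e^{i(φ_a−φ_b)}⟩|` with 1 s smoothing, envelope-threshold
  ictal segmentation, SWD-spike-triggered AP histograms (all-AP and
  first-AP-per-cycle variants), burst/tonic/silent cycle classification,
  period-normalised averaging and AP–EEG cross-correlation.
* **Fixtures & scenarios** — a synthetic ground-truth EEG/spike generator
  (known seizures, frequencies, per-population lags) for validating the
  analysis stack, and a catalogue of 30+ named perturbation scenarios with
  expected-outcome verdicts (`scenario_matrix()`, `run_scenario()`).

## Worked example

Generate a synthetic recording with known ground truth, segment it, and
measure the timing of a phase-locked population:

```r
library(swdnet)

spec <- synthetic_swd_spec(swd_frequency = 4, n_seizures = 2,
                           seizure_durations = 8, interictal_durations = 10,
                           noise_sd = 0.4, seed = 1)
fx  <- generate_synthetic_eeg(spec)
seg <- segment_ictal(fx$eeg, fx$fs)
seg
#> <swd_segmentation> 2 ictal interval(s)
#>  start   end dominant_freq n_spikes duration_s
#>   9963 18129             4       33      8.166
#>  27965 36125             4       34      8.160
```

Both seizures are recovered with the correct 4 Hz dominant frequency (the
inverse median inter-spike-peak interval); `n_spikes` counts the detected
EEG spike peaks. The SWD band-pass meets its published specification:

```r
filt <- design_swd_bandpass(4, 1000)
filt
#> <swd_bandpass> Butterworth order 18 (x2 poles), passband 2-6 Hz at fs = 1000 Hz
passband_ripple_db(filt)          # 0.5   (dB, peak-to-trough in 2-6 Hz)
filter_attenuation_db(filt, 8)    # 66.8  (dB at the upper stopband edge)
```

A population generated with a 30 ms lead relative to the EEG spike is
recovered by the spike-triggered AP histogram:

```r
sp <- generate_locked_spikes(spec, fx$truth)
st <- stap_histogram(sp$TC_FO, unlist(seg$spike_times), "all_APs", bin = 5)
stap_peak_lag(st)
#> [1] -27.5    # bin center; negative = precedes the EEG spike
```

Simulations use the same interfaces:

```r
net <- build_default_network(default_network_config("desk"), seed = 1)
cfg <- simulation_config(duration = 120000, seed = 1, state = "transition")
sim <- run_simulation(net, cfg,
         list(perturbation_event("TC_FO", "g_KL", 1.05, onset = 5000)))
seg <- segment_ictal(sim$eeg[-(1:5000)], sim$fs, t_offset = 5000)
```

which elicits recurring SWD-like discharges (the tonic-GABA-A-inhibition
route: a 5% potassium-leak increase in first-order TC neurons during the
sleep–wake-transition state). `scenario_matrix()` lists every registered
manipulation — trigger routes, knockouts, boosts and the frequency-switch —
and `run_scenario("gkl_tcfo_up_5pct")` runs one end to end with a verdict
against its expected outcome class.

See the methods vignette (`vignettes/swdnet-methods.Rmd`) for the model
equations, state parameters, detector design choices, and a frank account
of which paper-level behaviours the desk-scale re-implementation does and
does not reproduce.

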