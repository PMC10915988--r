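Package: swdnet
Title: Corticothalamic Network Simulation and Analysis of Spike-and-Wave Discharges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of a corticothalamic network
    (cortical, thalamocortical and reticular thalamic neurons) that generates
    absence-seizure spike-and-wave discharges (SWDs) under single-conductance
    perturbations, together with the ictal-EEG analysis stack used to
    characterise them: zero-phase Butterworth band-pass filtering, Hilbert
    phase and phase-synchronization index, ictal segmentation, spike-triggered
    action-potential histograms, burst/tonic/silent classification and
    period-normalised averaging. Includes a synthetic ground-truth EEG and
    spike-train generator for validating the analysis stack independently of
    the simulator, and a catalogue of perturbation scenarios (potassium leak,
    tonic and phasic GABA-A, GABA-B, AMPA, T-type calcium and CAN
    conductances).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
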