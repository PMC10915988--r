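test_that("synthetic EEG carries the specified number of cycles and is reproducible", {
  spec <- synthetic_swd_spec(swd_frequency = 4, n_seizures = 1,
                             seizure_durations = 10,
                             interictal_durations = 10, noise_sd = 0,
                             seed = 1)
  fx <- generate_synthetic_eeg(spec)
  expect_equal(length(fx$truth$spike_times[[1]]), 40)  # 4 Hz x 10 s
  fx2 <- generate_synthetic_eeg(spec)
  expect_identical(fx$eeg, fx2$eeg)
  spec_n <- synthetic_swd_spec(noise_sd = 0.5, seed = 7)
  expect_identical(generate_synthetic_eeg(spec_n)$eeg,
                   generate_synthetic_eeg(spec_n)$eeg)
})

test_that("the detector recovers the fixture frequency at 4 and 7 Hz", {
  for (fr in c(4, 7)) {
    spec <- synthetic_swd_spec(swd_frequency = fr, n_seizures = 2,
                               seizure_durations = 8,
                               interictal_durations = 9, noise_sd = 0.3,
                               seed = fr)
    fx <- generate_synthetic_eeg(spec)
    seg <- segment_ictal(fx$eeg, fx$fs)
    expect_equal(nrow(seg$intervals), 2)
    expect_equal(median(seg$intervals$dominant_freq), fr,
                 tolerance = 0.2 / fr * 1)
  }
})

test_that("locked spikes express the configured lags and modes", {
  spec <- synthetic_swd_spec(
    population_lags = c(TC_FO = -30, L4_PY = 0, NRT_FO = 8),
    firing_mode = c(TC_FO = "tonic", L4_PY = "burst", NRT_FO = "silent"),
    jitter_sd = 0, noise_sd = 0, interictal_rate = 0, n_seizures = 2,
    seizure_durations = 8, interictal_durations = 8, seed = 3)
  fx <- generate_synthetic_eeg(spec)
  sp <- generate_locked_spikes(spec, fx$truth)
  trig <- unlist(fx$truth$spike_times)
  st <- stap_histogram(sp$TC_FO, trig, "all_APs", bin = 5)
  expect_equal(stap_peak_lag(st), -30, tolerance = 3)
  # silent population emits nothing ictally
  expect_equal(length(unlist(sp$NRT_FO)), 0)
  # burst mode produces 100% burst cycles for the bursting population
  seg <- segment_ictal(fx$eeg, fx$fs)
  cyc <- do.call(rbind, seg$cycles)
  cls <- classify_cycle_firing(sp$L4_PY, cyc)
  expect_gt(cls$proportions$mean[cls$proportions$label == "burst"], 0.95)
})

test_that("round-trip: the analysis stack recovers lags within 5 ms and PSI extremes", {
  spec <- synthetic_swd_spec(
    population_lags = c(A = -25, B = -25, C = 0),
    firing_mode = c(A = "burst", B = "burst", C = "tonic"),
    jitter_sd = 2, noise_sd = 0.2, n_seizures = 3, seizure_durations = 10,
    interictal_durations = 8, n_per_population = 15, seed = 8)
  fx <- generate_synthetic_eeg(spec)
  sp <- generate_locked_spikes(spec, fx$truth)
  seg <- segment_ictal(fx$eeg, fx$fs)
  trig <- unlist(seg$spike_times)
  stA <- stap_histogram(sp$A, trig, "all_APs", bin = 2)
  expect_equal(stap_peak_lag(stA), -25, tolerance = 5)
  # PSI between two identically-locked populations is ~1 ictally
  dur <- fx$truth$duration_ms
  phA <- swdnet:::.population_phase(sp$A, dur, 200, spec$swd_frequency)
  phB <- swdnet:::.population_phase(sp$B, dur, 200, spec$swd_frequency)
  psi <- phase_synchronization_index(phA, phB, 200)
  i1 <- seg$intervals$start[1] / 1000 * 200
  i2 <- seg$intervals$end[1] / 1000 * 200
  expect_gt(mean(psi$psi[i1:i2]), 0.9)
})

test_that("seizure counts are exact at low noise across frequencies", {
  for (seed in 1:3) {
    spec <- synthetic_swd_spec(n_seizures = 3, seizure_durations = c(5, 8, 6),
                               interictal_durations = c(7, 9, 8),
                               noise_sd = 1, spike_amplitude = 5, seed = seed)
    fx <- generate_synthetic_eeg(spec)
    seg <- segment_ictal(fx$eeg, fx$fs)
    expect_equal(nrow(seg$intervals), 3, label = paste("seed", seed))
  }
})
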