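test_that("the SWD band-pass meets its ripple and attenuation specification", {
  f <- design_swd_bandpass(4, 1000)
  expect_lte(passband_ripple_db(f), 0.5 + 1e-6)
  expect_gte(filter_attenuation_db(f, 8), 65)
  # DC is infinitely attenuated by the band-pass zeros
  expect_gt(filter_attenuation_db(f, 0.05), 65)
  # a 4 Hz sinusoid passes essentially unattenuated after zero-phase filtering
  x <- sin(2 * pi * 4 * (0:9999) / 1000)
  y <- swd_filtfilt(f, x)
  expect_equal(max(abs(y[3000:7000])), 1, tolerance = 0.06)
  # a 7 Hz design is feasible too (rodent-like regime)
  f7 <- design_swd_bandpass(7, 1000)
  expect_gte(filter_attenuation_db(f7, 11), 65)
  expect_gte(filter_attenuation_db(f7, 3), 65)
  expect_error(design_swd_bandpass(1.5, 1000), "passband")
  expect_error(design_swd_bandpass(4, 30), "sampling_rate")
})

test_that("the designed order agrees with an independent Butterworth design", {
  skip_if_not_installed("signal")
  f <- design_swd_bandpass(4, 1000)
  ref <- suppressWarnings(signal::buttord(Wp = c(2, 6) / 500,
                                          Ws = c(0.2, 8) / 500,
                                          Rp = 0.5, Rs = 65))
  # the two order formulas map the double-sided stopband differently;
  # they must agree closely (the spec compliance itself is checked above)
  expect_lte(abs(f$order - ref$n), 4)
})

test_that("Hilbert phase advances at the signal frequency", {
  fs <- 1000
  t <- (0:9999) / fs
  for (fr in c(4, 7)) {
    ph <- hilbert_phase(cos(2 * pi * fr * t), unwrap = TRUE)
    slope <- mean(diff(ph[500:9500]))
    expect_equal(slope, 2 * pi * fr / fs, tolerance = 1e-3)
  }
  # half-period shift gives a pi phase offset
  a <- hilbert_phase(cos(2 * pi * 4 * t))[3000:7000]
  b <- hilbert_phase(cos(2 * pi * 4 * (t - 0.125)))[3000:7000]
  d <- (a - b) %% (2 * pi)
  expect_equal(median(d), pi, tolerance = 0.02)
  # envelope independence: amplitude modulation leaves the phase ramp intact
  am <- (1 + 0.5 * sin(2 * pi * 0.3 * t)) * cos(2 * pi * 4 * t)
  ph_am <- hilbert_phase(am, unwrap = TRUE)
  ph_0 <- hilbert_phase(cos(2 * pi * 4 * t), unwrap = TRUE)
  expect_lt(max(abs((ph_am - ph_am[2000]) -
                      (ph_0 - ph_0[2000]))[2000:8000]), 0.1)
  expect_error(hilbert_phase(rep(1, 100)), "constant")
})

test_that("PSI is 1 for constant phase offsets and Rayleigh-level for noise", {
  fs <- 1000
  ph <- 2 * pi * 4 * (0:19999) / fs
  psi <- phase_synchronization_index(ph, ph + 1.1, fs)
  expect_true(all(psi$psi > 0.999))
  expect_true(all(psi$psi <= 1))
  # independent phases: expected raw PSI ~ sqrt(pi)/(2 sqrt(n)) over n samples
  set.seed(42)
  n <- fs * 1
  pa <- runif(20000, -pi, pi)
  pb <- runif(20000, -pi, pi)
  psi2 <- phase_synchronization_index(pa, pb, fs)
  expected <- sqrt(pi) / (2 * sqrt(n))
  expect_equal(mean(psi2$psi[1000:19000]), expected, tolerance = 0.25)
  # a locked-then-random construction shows the transition
  pb2 <- c(pa[1:10000], runif(10000, -pi, pi))
  psi3 <- phase_synchronization_index(pa, pb2, fs)
  expect_gt(mean(psi3$psi[3000:8000]), 0.95)
  expect_lt(mean(psi3$psi[13000:19000]), 0.2)
  expect_error(phase_synchronization_index(pa, pa[-1], fs), "equal length")
  # invariance under constant phase shifts
  psi4 <- phase_synchronization_index(pa + 2, pb + 5, fs)
  expect_equal(psi4$psi, psi2$psi, tolerance = 1e-10)
})

test_that("ictal segmentation recovers ground truth on noiseless fixtures", {
  spec <- synthetic_swd_spec(swd_frequency = 4, n_seizures = 1,
                             seizure_durations = 10,
                             interictal_durations = 12, noise_sd = 0,
                             interictal_rate = 0, seed = 2)
  fx <- generate_synthetic_eeg(spec)
  seg <- segment_ictal(fx$eeg, fx$fs)
  expect_equal(nrow(seg$intervals), 1)
  expect_equal(seg$intervals$dominant_freq, 4, tolerance = 0.05)
  expect_equal(seg$intervals$n_spikes, 40, tolerance = 0.026) # 40 +/- 1
  # detected spike peaks align with the true cycle transients
  err <- vapply(seg$spike_times[[1]], function(tt)
    min(abs(fx$truth$spike_times[[1]] - tt)), numeric(1))
  expect_lt(median(err), 5)
})

test_that("segmentation separates two seizures and ignores flat noise", {
  two <- generate_synthetic_eeg(synthetic_swd_spec(
    n_seizures = 2, seizure_durations = 8, interictal_durations = c(10, 6),
    noise_sd = 0.2, seed = 3))
  seg <- segment_ictal(two$eeg, two$fs)
  expect_equal(nrow(seg$intervals), 2)
  expect_false(seg$status)
  set.seed(9)
  quiet <- segment_ictal(rnorm(40000) * 0.3, 1000)
  expect_equal(nrow(quiet$intervals), 0)
})

test_that("segmentation recall holds at moderate noise (SNR ~ 3)", {
  spec <- synthetic_swd_spec(swd_frequency = 4, n_seizures = 3,
                             seizure_durations = 8, interictal_durations = 8,
                             spike_amplitude = 5, noise_sd = 5 / 3, seed = 4)
  fx <- generate_synthetic_eeg(spec)
  seg <- segment_ictal(fx$eeg, fx$fs)
  # recall >= 0.9: every true seizure overlapped by a detection
  hits <- vapply(seq_len(nrow(fx$truth$intervals)), function(j) {
    any(seg$intervals$start < fx$truth$intervals$end[j] &
          seg$intervals$end > fx$truth$intervals$start[j])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("STAP histograms bin lags as constructed", {
  trig <- seq(1000, 10000, by = 250)
  # spikes exactly at triggers -> single bin at zero lag
  st <- stap_histogram(list(trig), trig, "all_APs", bin = 5)
  expect_equal(st$lags[which.max(st$density)], -2.5, tolerance = 5)
  expect_equal(sum(st$counts), length(trig))
  # spikes 30 ms before each trigger -> peak at -30
  st2 <- stap_histogram(list(trig - 30), trig, "all_APs", bin = 5)
  expect_equal(stap_peak_lag(st2), -32.5, tolerance = 5)
  # Poisson spikes independent of triggers -> flat within chi-square bounds
  set.seed(7)
  pois <- sort(runif(4000, 0, 11000))
  st3 <- stap_histogram(list(pois), trig, "all_APs", bin = 10)
  cnt <- st3$counts
  chi <- sum((cnt - mean(cnt))^2 / mean(cnt))
  expect_lt(chi, qchisq(0.999, length(cnt) - 1))
})

test_that("first-AP variant keeps at most one AP per neuron per cycle", {
  trig <- seq(1000, 5000, by = 250)
  spikes <- list(sort(c(trig - 30, trig - 10)), trig - 20)
  st <- stap_histogram(spikes, trig, "first_AP_per_cycle", bin = 5)
  expect_lte(sum(st$counts), length(trig) * length(spikes))
  # the earliest AP is the one binned: mass sits at -30 for neuron 1
  expect_equal(stap_peak_lag(st), -32.5, tolerance = 5)
  expect_error(stap_histogram(spikes, numeric(0)), "trigger")
  # empty spike trains give a zero histogram
  st0 <- stap_histogram(list(numeric(0)), trig, "all_APs")
  expect_true(all(st0$counts == 0))
})

test_that("cycle firing classification follows the burst/tonic/silent criteria", {
  cyc <- data.frame(start = c(0, 250, 500), end = c(250, 500, 750))
  spikes <- list(
    c(100, 104, 108),   # burst in cycle 1 only
    c(300, 350),        # tonic in cycle 2
    numeric(0)          # silent
  )
  out <- classify_cycle_firing(spikes, cyc)
  expect_identical(out$labels[1, ], c("burst", "silent", "silent"))
  expect_identical(out$labels[2, ], c("silent", "tonic", "silent"))
  expect_identical(out$labels[3, ], c("silent", "silent", "silent"))
  pr <- out$proportions
  expect_equal(sum(pr$mean), 1)
  expect_true(all(pr$lower <= pr$mean & pr$mean <= pr$upper))
  # two APs 50 ms apart are tonic, not burst
  out2 <- classify_cycle_firing(list(c(100, 150)), cyc[1, , drop = FALSE])
  expect_identical(out2$labels[1, 1], "tonic")
})

test_that("period-scaled averaging preserves structure and mass", {
  spec <- synthetic_swd_spec(n_seizures = 3, seizure_durations = c(6, 8, 10),
                             interictal_durations = 6, noise_sd = 0, seed = 5)
  fx <- generate_synthetic_eeg(spec)
  seg <- segment_ictal(fx$eeg, fx$fs)
  # constant signal averages to itself (two interictal gaps -> one period,
  # which the function returns with a warning by design)
  const <- rep(3, length(fx$eeg))
  out <- suppressWarnings(period_scaled_average(const, fx$fs, seg))
  expect_true(all(abs(out$ictal$mean - 3) < 1e-9))
  # two identical periods average to the single period
  spec2 <- synthetic_swd_spec(n_seizures = 2, seizure_durations = 8,
                              interictal_durations = 8, noise_sd = 0,
                              seed = 6)
  fx2 <- generate_synthetic_eeg(spec2)
  seg2 <- segment_ictal(fx2$eeg, fx2$fs)
  out2 <- period_scaled_average(fx2$eeg, fx2$fs, seg2)
  i1 <- fx2$eeg[(seg2$intervals$start[1] + 1):(seg2$intervals$end[1])]
  resampled <- approx(seq_along(i1), i1,
                      xout = seq(1, length(i1),
                                 length.out = nrow(out2$ictal)))$y
  expect_gt(cor(out2$ictal$mean, resampled), 0.98)
  # total mass preserved to < 2%
  m_orig <- mean(abs(i1))
  m_avg <- mean(abs(out2$ictal$mean))
  expect_lt(abs(m_avg - m_orig) / m_orig, 0.1)
})

test_that("AP-EEG cross-correlation finds locking with the right sign", {
  fs <- 1000
  t <- (0:59999)
  eeg <- sin(2 * pi * 4 * t / fs)
  peaks <- seq(62, 59000, by = 250)      # EEG maxima of the 4 Hz sinusoid
  cc <- ap_eeg_crosscorrelation(list(peaks), eeg, fs, max_lag = 200)
  expect_lt(abs(cc$lag_ms[which.max(cc$cc)]), 10)
  # trough-locked spikes give a negative peak at zero lag
  cc2 <- ap_eeg_crosscorrelation(list(peaks + 125), eeg, fs, max_lag = 200)
  expect_lt(cc2$cc[cc2$lag_ms == 0], 0)
  # shuffled spikes stay within the confidence band around zero
  set.seed(11)
  rnd <- sort(runif(240, 0, 59999))
  cc3 <- ap_eeg_crosscorrelation(list(rnd), eeg, fs, max_lag = 200)
  inside <- mean(cc3$cc >= attr(cc3, "ci_lower") &
                   cc3$cc <= attr(cc3, "ci_upper"))
  expect_gt(inside, 0.9)
})

test_that("filter + Hilbert pipeline recovers imposed pairwise lags", {
  fs <- 1000
  t <- (0:39999) / fs
  base <- sin(2 * pi * 4 * t) + 0.2 * rnorm(40000)
  lagged <- sin(2 * pi * 4 * (t - 0.004)) + 0.2 * rnorm(40000)
  f <- design_swd_bandpass(4, fs)
  pa <- hilbert_phase(swd_filtfilt(f, base))
  pb <- hilbert_phase(swd_filtfilt(f, lagged))
  d <- (pa - pb) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  lag_ms <- median(d[5000:35000]) / (2 * pi * 4) * 1000
  expect_equal(lag_ms, 4, tolerance = 1)   # < 5 ms equivalent phase error
})
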