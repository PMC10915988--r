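#' Specify a synthetic spike-and-wave ground-truth recording
#'
#' Describes an EEG with known seizures: each SWD cycle is a sharp Gaussian
#' transient (the "spike") followed by a slower half-sine of opposite sign
#' (the "wave"), repeated at `swd_frequency` for the given seizure durations,
#' embedded in pink-noise interictal background. Per-population firing is
#' phase-locked to the cycle with configured lags (negative = leads the EEG
#' spike), jitter and firing mode.
#'
#' @param swd_frequency SWD cycle frequency (Hz).
#' @param n_seizures Number of seizures.
#' @param seizure_durations Durations (s), recycled to `n_seizures`.
#' @param interictal_durations Gaps before each seizure (s), recycled; the
#'   first entry is also the lead-in.
#' @param spike_amplitude,wave_amplitude Component amplitudes (a.u.).
#' @param noise_sd Pink-noise SD (a.u.).
#' @param spike_sd Width (SD, ms) of the Gaussian spike transient.
#' @param population_lags Named numeric vector, ms (negative = leads).
#' @param firing_mode Named character vector over the same populations:
#'   `"burst"`, `"tonic"` or `"silent"`.
#' @param jitter_sd AP timing jitter (ms).
#' @param n_per_population Neurons per population.
#' @param interictal_rate Interictal Poisson rate per neuron (Hz).
#' @param fs Sampling rate (Hz).
#' @param seed Seed for all randomness.
#' @return Object of class `swd_synthetic_spec`.
#' @export
synthetic_swd_spec <- function(swd_frequency = 4, n_seizures = 3,
                               seizure_durations = 10,
                               interictal_durations = 10,
                               spike_amplitude = 5, wave_amplitude = 2,
                               noise_sd = 0.5, spike_sd = 12,
                               population_lags = c(TC_FO = -30, TC_HO = -20,
                                                   L4_PY = 0, NRT_FO = 8),
                               firing_mode = c(TC_FO = "tonic",
                                               TC_HO = "burst",
                                               L4_PY = "burst",
                                               NRT_FO = "burst"),
                               jitter_sd = 3, n_per_population = 10,
                               interictal_rate = 2, fs = 1000, seed = 1) {
  stopifnot(swd_frequency > 0, all(seizure_durations > 0),
            all(interictal_durations > 0))
  structure(as.list(environment()), class = "swd_synthetic_spec")
}

# pink (1/f) noise via spectral shaping, unit variance
.pink_noise <- function(n, seed) {
  .with_seed(seed, {
    w <- rnorm(n)
    W <- fft(w)
    f <- c(1, seq_len(n - 1))
    f <- pmin(f, n - f + 1)               # symmetric frequency index
    W <- W / sqrt(f)
    x <- Re(fft(W, inverse = TRUE) / n)
    (x - mean(x)) / sd(x)
  })
}

#' Generate a synthetic SWD EEG trace with ground truth
#'
#' @param spec `swd_synthetic_spec`.
#' @return List: `eeg` (numeric), `fs`, `truth` (list with `intervals` data
#'   frame in ms, `spike_times` list of EEG spike-peak times in ms, and the
#'   per-interval `frequency`).
#' @export
generate_synthetic_eeg <- function(spec) {
  stopifnot(inherits(spec, "swd_synthetic_spec"))
  fs <- spec$fs
  per_ms <- 1000 / spec$swd_frequency
  sz <- rep_len(spec$seizure_durations, spec$n_seizures)
  ii <- rep_len(spec$interictal_durations, spec$n_seizures)
  total_s <- sum(sz) + sum(ii) + tail(ii, 1)
  n <- ceiling(total_s * fs)
  tms <- (seq_len(n) - 1) / fs * 1000
  eeg <- if (spec$noise_sd > 0)
    spec$noise_sd * .pink_noise(n, spec$seed) else numeric(n)

  intervals <- data.frame(start = numeric(0), end = numeric(0))
  spike_times <- list()
  cursor <- 0
  for (s in seq_len(spec$n_seizures)) {
    cursor <- cursor + ii[s] * 1000
    start <- cursor
    end <- start + sz[s] * 1000
    # one spike per cycle, first spike half a period in
    spk <- seq(start + per_ms / 2, end - per_ms / 4, by = per_ms)
    for (tk in spk) {
      # sharp positive transient
      sel <- which(tms > tk - 4 * spec$spike_sd & tms < tk + 4 * spec$spike_sd)
      eeg[sel] <- eeg[sel] +
        spec$spike_amplitude * exp(-((tms[sel] - tk)^2) /
                                     (2 * spec$spike_sd^2))
      # slow wave of opposite sign filling most of the cycle
      wsel <- which(tms >= tk + 2 * spec$spike_sd &
                      tms < tk + 2 * spec$spike_sd + 0.6 * per_ms)
      ph <- (tms[wsel] - tk - 2 * spec$spike_sd) / (0.6 * per_ms)
      eeg[wsel] <- eeg[wsel] - spec$wave_amplitude * sin(pi * ph)
    }
    intervals <- rbind(intervals, data.frame(start = start, end = end))
    spike_times <- c(spike_times, list(spk))
    cursor <- end
  }
  list(eeg = eeg, fs = fs,
       truth = list(intervals = intervals, spike_times = spike_times,
                    frequency = spec$swd_frequency, duration_ms = n / fs * 1000))
}

#' Generate phase-locked spike trains matching a synthetic EEG
#'
#' Each population fires at `cycle spike time + lag` with Gaussian jitter:
#' burst mode emits 3 APs at 4 ms intervals, tonic mode a single AP, silent
#' populations emit none ictally. All populations fire at the interictal
#' Poisson rate between seizures.
#'
#' @param spec `swd_synthetic_spec`.
#' @param truth Ground truth from [generate_synthetic_eeg()].
#' @return Named list of populations, each a list of per-neuron spike-time
#'   vectors (ms).
#' @export
generate_locked_spikes <- function(spec, truth) {
  stopifnot(inherits(spec, "swd_synthetic_spec"))
  pops <- names(spec$population_lags)
  .with_seed(spec$seed + 1L, {
    out <- list()
    for (pp in pops) {
      lag <- spec$population_lags[[pp]]
      mode <- spec$firing_mode[[pp]]
      neurons <- vector("list", spec$n_per_population)
      for (ni in seq_len(spec$n_per_population)) {
        sp <- numeric(0)
        # ictal, phase-locked
        if (mode != "silent") {
          for (iv in seq_along(truth$spike_times)) {
            for (tk in truth$spike_times[[iv]]) {
              t0 <- tk + lag + rnorm(1, 0, spec$jitter_sd)
              sp <- c(sp, if (mode == "burst") t0 + c(0, 4, 8) else t0)
            }
          }
        }
        # interictal Poisson background
        if (spec$interictal_rate > 0) {
          gaps <- rbind(
            data.frame(a = 0, b = truth$intervals$start[1]),
            if (nrow(truth$intervals) > 1)
              data.frame(a = truth$intervals$end[-nrow(truth$intervals)],
                         b = truth$intervals$start[-1]),
            data.frame(a = truth$intervals$end[nrow(truth$intervals)],
                       b = truth$duration_ms))
          for (g in seq_len(nrow(gaps))) {
            len <- gaps$b[g] - gaps$a[g]
            k <- rpois(1, spec$interictal_rate * len / 1000)
            if (k > 0) sp <- c(sp, gaps$a[g] + runif(k) * len)
          }
        }
        neurons[[ni]] <- sort(sp[sp >= 0 & sp <= truth$duration_ms])
      }
      out[[pp]] <- neurons
    }
    out
  })
}
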