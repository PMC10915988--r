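# ---------------------------------------------------------------------------
# Butterworth band-pass design in zero-pole-gain form.
#
# The SWD band-pass (passband center +/- 2 Hz at a 1 kHz sampling rate) puts
# all poles very close to z = 1; expanding the transfer function into
# polynomial (b, a) coefficients at the required order (~2x18 poles) is
# numerically ruinous, so the design, the frequency response and the
# filtering all stay in zpk / second-order-section form throughout.
# ---------------------------------------------------------------------------

.bilinear_zpk <- function(z, p, k, fs) {
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  # poles in excess of zeros add zeros at z = -1
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  list(z = zd, p = pd, k = kd)
}

.zpk_response <- function(zpk, f, fs) {
  w <- exp(2i * pi * f / fs)
  vapply(w, function(wi) {
    h <- zpk$k + 0i
    np <- length(zpk$p); nz <- length(zpk$z)
    for (j in seq_len(max(np, nz))) {
      if (j <= nz) h <- h * (wi - zpk$z[j])
      if (j <= np) h <- h / (wi - zpk$p[j])
    }
    h
  }, complex(1))
}

# pair conjugate poles with one zero at +1 and one at -1 each -> biquads
.zpk_to_sos <- function(zpk) {
  p <- zpk$p
  pu <- p[Im(p) >= 0]
  pu <- pu[order(Mod(pu))]
  n <- length(pu)
  g <- abs(zpk$k)^(1 / n) * sign(zpk$k)^(1 / n)  # spread gain over sections
  gsec <- abs(zpk$k)^(1 / n)
  sos <- matrix(0, n, 6)
  for (j in seq_len(n)) {
    pj <- pu[j]
    sos[j, 1:3] <- gsec * c(1, 0, -1)            # zeros at +1 and -1
    sos[j, 4:6] <- c(1, -2 * Re(pj), Mod(pj)^2)  # conjugate pole pair
  }
  if (zpk$k < 0) sos[1, 1:3] <- -sos[1, 1:3]
  sos
}

.sos_filter_one <- function(x, s) {
  b <- s[1:3]; a <- s[4:6]
  xp <- c(0, 0, x)
  u <- stats::filter(xp, b, method = "convolution", sides = 1)[-(1:2)]
  as.numeric(stats::filter(u, -a[2:3], method = "recursive"))
}

.sos_filter <- function(x, sos) {
  for (j in seq_len(nrow(sos))) x <- .sos_filter_one(x, sos[j, ])
  x
}

#' Design the SWD band-pass filter
#'
#' Minimum-order Butterworth band-pass with passband and stopband edges at
#' `center_freq` plus/minus `passband_halfwidth` and `stopband_halfwidth`
#' respectively, meeting the given passband ripple and stopband attenuation.
#' When the lower stopband edge falls at or below 0 Hz the band-pass zero at
#' DC satisfies it automatically and the order is set by the upper edge. The
#' returned object filters with [swd_filtfilt()] (forward-backward, zero
#' phase).
#'
#' @param center_freq Center (SWD) frequency, Hz.
#' @param sampling_rate Sampling rate, Hz; must be at least 10x the center.
#' @param passband_halfwidth,stopband_halfwidth Band half-widths (Hz);
#'   defaults 2 and 4.
#' @param passband_ripple Maximum passband ripple (dB), default 0.5.
#' @param stopband_attenuation Minimum stopband attenuation (dB), default 65.
#' @return Object of class `swd_bandpass` with the digital zpk form, the
#'   second-order sections, the realized order and the design edges.
#' @export
design_swd_bandpass <- function(center_freq, sampling_rate,
                                passband_halfwidth = 2,
                                stopband_halfwidth = 4,
                                passband_ripple = 0.5,
                                stopband_attenuation = 65) {
  if (stopband_halfwidth <= passband_halfwidth)
    stop("stopband_halfwidth must exceed passband_halfwidth")
  if (center_freq - passband_halfwidth <= 0)
    stop("passband must lie above 0 Hz")
  if (sampling_rate < 10 * center_freq)
    stop("sampling_rate must be at least 10x center_freq")
  fp <- center_freq + c(-1, 1) * passband_halfwidth
  fstop <- center_freq + c(-1, 1) * stopband_halfwidth

  warp <- function(f) 2 * sampling_rate * tan(pi * f / sampling_rate)
  Wp <- warp(fp)
  w0sq <- Wp[1] * Wp[2]
  Bw <- Wp[2] - Wp[1]
  om_stop <- function(f) {
    Ws <- warp(f)
    abs((Ws^2 - w0sq) / (Bw * Ws))
  }
  edges <- fstop[fstop > 0]
  Om <- min(vapply(edges, om_stop, numeric(1)))
  if (!is.finite(Om) || Om <= 1) {
    ach <- 10 * log10(1 + (10^(passband_ripple / 10) - 1) * max(Om, 0)^2)
    stop(sprintf(
      "infeasible band-pass specification: achievable attenuation at the stopband edge is %.2f dB",
      ach))
  }
  eps2 <- 10^(passband_ripple / 10) - 1
  lam2 <- 10^(stopband_attenuation / 10) - 1
  n <- ceiling(log10(lam2 / eps2) / (2 * log10(Om)))
  # normalized lowpass cutoff meeting the passband ripple exactly at Omega = 1
  Oc <- eps2^(-1 / (2 * n))

  kk <- seq_len(n)
  p_lp <- Oc * exp(1i * pi * (2 * kk + n - 1) / (2 * n))
  # lowpass -> bandpass: s_lp = (s^2 + w0^2)/(Bw s)
  pb <- c()
  for (pl in p_lp) {
    disc <- sqrt((pl * Bw)^2 - 4 * w0sq + 0i)
    pb <- c(pb, (pl * Bw + disc) / 2, (pl * Bw - disc) / 2)
  }
  za <- rep(0 + 0i, n)
  ka <- (Oc * Bw)^n
  zpk <- .bilinear_zpk(za, pb, Re(ka), sampling_rate)
  # normalize unity gain at the (pre-warp) passband center
  f0 <- sampling_rate / pi * atan(sqrt(w0sq) / (2 * sampling_rate))
  h0 <- Mod(.zpk_response(zpk, f0, sampling_rate))
  zpk$k <- zpk$k / h0

  structure(list(zpk = zpk, sos = .zpk_to_sos(zpk), order = n,
                 fs = sampling_rate, center = center_freq,
                 passband = fp, stopband = fstop,
                 passband_ripple = passband_ripple,
                 stopband_attenuation = stopband_attenuation),
            class = "swd_bandpass")
}

#' @export
print.swd_bandpass <- function(x, ...) {
  cat("<swd_bandpass> Butterworth order", x$order, "(x2 poles), passband",
      paste(x$passband, collapse = "-"), "Hz at fs =", x$fs, "Hz\n")
  invisible(x)
}

# fixed-order Butterworth band-pass (for the 2-10 Hz detection band etc.)
.design_bandpass_fixed <- function(f_lo, f_hi, fs, order = 4) {
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  Wp <- warp(c(f_lo, f_hi))
  w0sq <- Wp[1] * Wp[2]; Bw <- Wp[2] - Wp[1]
  kk <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * kk + order - 1) / (2 * order))
  pb <- c()
  for (pl in p_lp) {
    disc <- sqrt((pl * Bw)^2 - 4 * w0sq + 0i)
    pb <- c(pb, (pl * Bw + disc) / 2, (pl * Bw - disc) / 2)
  }
  zpk <- .bilinear_zpk(rep(0 + 0i, order), pb, Bw^order, fs)
  f0 <- fs / pi * atan(sqrt(w0sq) / (2 * fs))
  zpk$k <- zpk$k / Mod(.zpk_response(zpk, f0, fs))
  structure(list(zpk = zpk, sos = .zpk_to_sos(zpk), order = order, fs = fs,
                 center = sqrt(f_lo * f_hi), passband = c(f_lo, f_hi),
                 stopband = c(NA, NA)), class = "swd_bandpass")
}

#' Complex frequency response of a designed filter
#'
#' Single-pass response, evaluated stably from the zero-pole-gain form.
#'
#' @param filt `swd_bandpass`.
#' @param f Frequencies (Hz).
#' @return Complex response values.
#' @export
filter_response <- function(filt, f) .zpk_response(filt$zpk, f, filt$fs)

#' Single-pass attenuation relative to the passband peak
#'
#' @param filt `swd_bandpass`.
#' @param f Frequencies (Hz).
#' @return Attenuation in dB (positive numbers = attenuated).
#' @export
filter_attenuation_db <- function(filt, f) {
  grid <- seq(filt$passband[1], filt$passband[2], length.out = 201)
  peak <- max(Mod(filter_response(filt, grid)))
  -20 * log10(Mod(filter_response(filt, f)) / peak)
}

#' Peak-to-trough passband ripple (dB) of a designed filter
#' @param filt `swd_bandpass`.
#' @param n_grid Grid resolution over the passband.
#' @return Ripple in dB.
#' @export
passband_ripple_db <- function(filt, n_grid = 401) {
  grid <- seq(filt$passband[1], filt$passband[2], length.out = n_grid)
  m <- Mod(filter_response(filt, grid))
  20 * log10(max(m) / min(m))
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the second-order-section cascade forward and backward with
#' odd-reflection padding, giving zero phase distortion and the squared
#' magnitude response.
#'
#' @param filt `swd_bandpass`.
#' @param x Signal sampled at `filt$fs`.
#' @return Filtered signal, same length as `x`.
#' @export
swd_filtfilt <- function(filt, x) {
  n <- length(x)
  pad <- min(n - 1, 6 * (2 * filt$order + 1), floor(3 * filt$fs))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- .sos_filter(xp, filt$sos)
  y <- rev(.sos_filter(rev(y), filt$sos))
  y[(pad + 1):(pad + n)]
}

# ---------------------------------------------------------------------------
# Hilbert phase and phase synchronization
# ---------------------------------------------------------------------------

#' Analytic signal via the frequency domain
#'
#' @param x Real signal.
#' @return Complex analytic signal (real part = `x`).
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous Hilbert phase
#'
#' Phase of the analytic signal; monotone increasing (mod 2 pi) for a pure
#' sinusoid. The signal should be band-limited (pre-filtered) and at least a
#' few cycles long.
#'
#' @param x Real signal.
#' @param unwrap Return the unwrapped phase?
#' @return Phase in radians (wrapped to (-pi, pi\] unless `unwrap = TRUE`).
#' @export
hilbert_phase <- function(x, unwrap = FALSE) {
  if (sd(x) == 0) stop("phase undefined for a constant signal")
  ph <- Arg(analytic_signal(x))
  if (unwrap) ph <- .unwrap(ph)
  ph
}

.unwrap <- function(ph) {
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(ph[1], ph[1] + cumsum(d))
}

# moving average with partial windows at the edges
.movavg <- function(x, n) {
  n <- max(1L, as.integer(n))
  half <- n %/% 2
  cs <- c(0, cumsum(x))
  i <- seq_along(x)
  lo <- pmax(i - half, 1); hi <- pmin(i + half, length(x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Hilbert phase synchronization index between two phase traces
#'
#' `PSI(t) = |mean over a sliding window of exp(i (phi_a - phi_b))|`,
#' then smoothed with a moving-average window of the same duration
#' (1 s by default). Bounded in \[0, 1\]; invariant under adding a constant
#' to either phase.
#'
#' @param phase_a,phase_b Phase traces (radians), equal length and sampling.
#' @param fs Sampling rate (Hz).
#' @param window Window duration (s), default 1.
#' @return Object of class `swd_psi`: data frame with `time` (s) and `psi`.
#' @export
phase_synchronization_index <- function(phase_a, phase_b, fs, window = 1) {
  if (length(phase_a) != length(phase_b))
    stop("phase traces must have equal length")
  n <- max(1L, round(fs * window))
  d <- phase_a - phase_b
  re <- .movavg(cos(d), n)
  im <- .movavg(sin(d), n)
  psi <- sqrt(re^2 + im^2)
  psi <- pmin(1, .movavg(psi, n))
  out <- data.frame(time = (seq_along(psi) - 0.5) / fs, psi = psi)
  class(out) <- c("swd_psi", class(out))
  out
}

# phase of a population firing-rate signal in the SWD band
.population_phase <- function(spike_times, duration_ms, fs, center_freq) {
  bins <- floor(duration_ms / 1000 * fs)
  rate <- tabulate(pmin(bins, floor(unlist(spike_times) / 1000 * fs) + 1),
                   nbins = bins)
  bp <- .design_bandpass_fixed(max(0.5, center_freq - 2), center_freq + 2,
                               fs, order = 3)
  hilbert_phase(swd_filtfilt(bp, rate - mean(rate)))
}

# ---------------------------------------------------------------------------
# Ictal segmentation
# ---------------------------------------------------------------------------

# local maxima above a height with a minimum separation (greedy by height)
.find_peaks <- function(x, min_sep, min_height = -Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-x[cand])]
  keep <- integer(0)
  for (c0 in cand) {
    if (!length(keep) || all(abs(keep - c0) >= min_sep)) keep <- c(keep, c0)
  }
  sort(keep)
}

#' Segment an EEG trace into ictal and interictal periods
#'
#' Ictal periods are intervals where the amplitude envelope of the
#' `band`-filtered EEG exceeds `baseline mean + threshold_sd * SD` for at
#' least `min_duration` seconds (gaps shorter than `merge_gap` merged,
#' intervals with fewer than `min_cycles` oscillation cycles dropped). The
#' baseline statistics come from the sub-threshold part of the envelope
#' distribution (below its `baseline_quantile`). Within each interval, SWD spike
#' times are EEG local maxima separated by at least 60% of the dominant
#' period, and the dominant frequency is the inverse median inter-peak
#' interval. Cycle boundaries are midpoints between consecutive spike peaks,
#' extended by half a period at the ends.
#'
#' If a single interval occupies more than 90% of the analysed trace the
#' segmentation is flagged as absence status.
#'
#' @param eeg Numeric EEG trace.
#' @param sampling_rate Sampling rate (Hz).
#' @param threshold_sd Envelope threshold in baseline SDs (default 4).
#' @param min_duration Minimum ictal duration (s), default 0.75.
#' @param merge_gap Merge sub-threshold gaps shorter than this (s).
#' @param min_cycles Minimum number of SWD cycles per interval.
#' @param band Detection band (Hz), default 2-10.
#' @param baseline_quantile Envelope quantile below which samples count as
#'   baseline (default 0.5, robust up to ~50% ictal occupancy).
#' @param t_offset Time (ms) of the first EEG sample (for trimmed traces).
#' @return Object of class `swd_segmentation`: `intervals` (data frame with
#'   `start`, `end` in ms, `dominant_freq` in Hz, `n_spikes`),
#'   `spike_times` (list, ms), `cycles` (list of data frames with `start`,
#'   `end`, `trigger`), `status` flag, and the call parameters.
#' @export
segment_ictal <- function(eeg, sampling_rate, threshold_sd = 4,
                          min_duration = 0.75, merge_gap = 0.5,
                          min_cycles = 3, band = c(2, 10), baseline_quantile = 0.5,
                          t_offset = 0) {
  if (length(eeg) < 30 * sampling_rate)
    stop("need at least 30 s of EEG for baseline estimation")
  fs <- sampling_rate
  bp <- .design_bandpass_fixed(band[1], band[2], fs, order = 4)
  xf <- swd_filtfilt(bp, eeg - mean(eeg))
  env <- Mod(analytic_signal(xf))
  env_s <- .movavg(env, round(0.25 * fs))

  base <- env_s[env_s <= quantile(env_s, baseline_quantile)]
  # the sub-quantile sample underestimates the baseline SD; correct for
  # truncation (lower half of a normal has SD ~ 0.60 sigma)
  thr <- mean(base) + threshold_sd * sd(base) / 0.60
  above <- env_s > thr

  # runs of above-threshold samples
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- cbind(starts[r$values], ends[r$values])
  if (length(iv)) {
    # merge short gaps
    merged <- list()
    cur <- iv[1, ]
    for (j in seq_len(nrow(iv))[-1]) {
      if ((iv[j, 1] - cur[2]) / fs < merge_gap) cur[2] <- iv[j, 2]
      else { merged <- c(merged, list(cur)); cur <- iv[j, ] }
    }
    merged <- c(merged, list(cur))
    iv <- do.call(rbind, merged)
    iv <- iv[(iv[, 2] - iv[, 1]) / fs >= min_duration, , drop = FALSE]
  } else iv <- matrix(numeric(0), 0, 2)

  intervals <- data.frame(start = numeric(0), end = numeric(0),
                          dominant_freq = numeric(0), n_spikes = integer(0))
  spike_times <- list(); cycles <- list()
  for (j in seq_len(nrow(iv))) {
    i1 <- iv[j, 1]; i2 <- iv[j, 2]
    seg <- eeg[i1:i2]
    # initial period estimate from the spectral peak in 1-15 Hz
    nn <- length(seg)
    sp <- Mod(fft(seg - mean(seg)))[1:(nn %/% 2)]
    fgrid <- (seq_len(nn %/% 2) - 1) * fs / nn
    sel <- fgrid >= 1 & fgrid <= 15
    if (!any(sel)) next
    f_dom <- fgrid[sel][which.max(sp[sel])]
    for (it in 1:2) {
      min_sep <- 0.6 * fs / f_dom
      pk <- .find_peaks(seg, min_sep,
                        min_height = quantile(seg, 0.75))
      if (length(pk) >= 2) {
        f_new <- fs / median(diff(pk))
        if (is.finite(f_new) && f_new > 0.5) f_dom <- f_new
      }
    }
    if (length(pk) < min_cycles) next
    pk_ms <- (i1 - 1 + pk - 1) / fs * 1000 + t_offset
    half <- 500 / f_dom
    mids <- (pk_ms[-1] + pk_ms[-length(pk_ms)]) / 2
    cyc <- data.frame(
      start = c(pk_ms[1] - half, mids),
      end = c(mids, pk_ms[length(pk_ms)] + half),
      trigger = pk_ms)
    intervals <- rbind(intervals, data.frame(
      start = (i1 - 1) / fs * 1000 + t_offset,
      end = (i2 - 1) / fs * 1000 + t_offset,
      dominant_freq = f_dom, n_spikes = length(pk)))
    spike_times <- c(spike_times, list(pk_ms))
    cycles <- c(cycles, list(cyc))
  }

  total_s <- length(eeg) / fs
  status <- nrow(intervals) == 1 &&
    (intervals$end[1] - intervals$start[1]) / 1000 > 0.9 * total_s
  structure(list(intervals = intervals, spike_times = spike_times,
                 cycles = cycles, status = status, fs = fs,
                 threshold = thr, t_offset = t_offset),
            class = "swd_segmentation")
}

#' @export
print.swd_segmentation <- function(x, ...) {
  cat("<swd_segmentation> ", nrow(x$intervals), " ictal interval(s)",
      if (x$status) " [absence status]", "\n", sep = "")
  if (nrow(x$intervals)) {
    df <- x$intervals
    df$duration_s <- (df$end - df$start) / 1000
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.swd_segmentation <- function(x, eeg = NULL, ...) {
  if (is.null(eeg)) stop("pass the EEG trace used for segmentation")
  t <- (seq_along(eeg) - 1) / x$fs
  plot(t, eeg, type = "l", xlab = "time (s)", ylab = "EEG", ...)
  if (nrow(x$intervals))
    rect(x$intervals$start / 1000, min(eeg), x$intervals$end / 1000,
         max(eeg), col = grDevices::adjustcolor("red", 0.15), border = NA)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Spike-triggered AP histograms and cycle firing
# ---------------------------------------------------------------------------

.as_spike_list <- function(spikes) {
  if (is.data.frame(spikes)) split(spikes$time, spikes$neuron)
  else if (is.list(spikes)) spikes
  else list(as.numeric(spikes))
}

#' SWD-spike-triggered action-potential histogram (STAP)
#'
#' For `variant = "all_APs"`, every AP within `window` ms of each EEG SWD
#' spike is binned by its lag (negative lag = AP precedes the EEG spike).
#' For `variant = "first_AP_per_cycle"`, only the earliest AP of each neuron
#' within each SWD cycle (midpoint-to-midpoint between consecutive EEG
#' spikes) is binned. Density is normalised per trigger, so that
#' `sum(density) * bin` equals the mean number of binned APs per trigger.
#'
#' @param spikes Per-neuron spike-time list (ms) or a data frame with
#'   `neuron` and `time`.
#' @param triggers EEG SWD spike-peak times (ms).
#' @param variant `"all_APs"` or `"first_AP_per_cycle"`.
#' @param bin Bin width (ms).
#' @param window Lag window half-width (ms); lags span plus/minus `window`.
#' @param cycles Optional cycle data frame (`start`, `end`, `trigger`);
#'   derived from `triggers` when missing.
#' @return Object of class `swd_stap`: `lags` (bin centers, ms), `density`
#'   (APs per trigger per ms), `counts`, `n_triggers`, `variant`.
#' @export
stap_histogram <- function(spikes, triggers,
                           variant = c("all_APs", "first_AP_per_cycle"),
                           bin = 5, window = 125, cycles = NULL) {
  variant <- match.arg(variant)
  if (length(triggers) < 1) stop("need at least one trigger")
  sl <- .as_spike_list(spikes)
  breaks <- seq(-window, window, by = bin)
  centers <- breaks[-1] - bin / 2
  counts <- numeric(length(centers))
  all_sp <- sort(unlist(sl, use.names = FALSE))

  if (variant == "all_APs") {
    for (tr in triggers) {
      d <- all_sp[all_sp >= tr - window & all_sp <= tr + window] - tr
      if (length(d))
        counts <- counts + hist(d, breaks = breaks, plot = FALSE)$counts
    }
  } else {
    if (is.null(cycles)) {
      tt <- sort(triggers)
      per <- if (length(tt) > 1) median(diff(tt)) else 2 * window
      mids <- (tt[-1] + tt[-length(tt)]) / 2
      cycles <- data.frame(start = c(tt[1] - per / 2, mids),
                           end = c(mids, tt[length(tt)] + per / 2),
                           trigger = tt)
    }
    for (ci in seq_len(nrow(cycles))) {
      tr <- cycles$trigger[ci]
      for (sp in sl) {
        spc <- sp[sp >= cycles$start[ci] & sp < cycles$end[ci]]
        if (length(spc)) {
          d <- min(spc) - tr
          if (d >= -window && d <= window) {
            b <- findInterval(d, breaks, rightmost.closed = TRUE)
            if (b >= 1 && b <= length(counts)) counts[b] <- counts[b] + 1
          }
        }
      }
    }
    triggers <- cycles$trigger
  }
  structure(list(lags = centers, density = counts / length(triggers) / bin,
                 counts = counts, n_triggers = length(triggers),
                 variant = variant, bin = bin),
            class = "swd_stap")
}

#' Lag of the histogram peak
#' @param stap `swd_stap`.
#' @param before Only consider lags strictly earlier than this (ms).
#' @return Peak-bin lag (ms); `NA` if the histogram is empty in range.
#' @export
stap_peak_lag <- function(stap, before = Inf) {
  sel <- stap$lags < before
  if (!any(sel) || all(stap$counts[sel] == 0)) return(NA_real_)
  stap$lags[sel][which.max(stap$density[sel])]
}

#' Largest local maximum of a STAP histogram before a lag bound
#'
#' Finds local maxima of the (lightly smoothed) histogram and returns the lag
#' of the tallest one earlier than `before` ms.
#'
#' @param stap `swd_stap`.
#' @param before Upper lag bound (ms), e.g. -40 for the early secondary peak.
#' @return Lag (ms) or `NA`.
#' @export
stap_secondary_peak <- function(stap, before = -40) {
  d <- .movavg(stap$density, 3)
  idx <- .find_peaks(d, min_sep = 2)
  idx <- idx[stap$lags[idx] < before]
  if (!length(idx)) {
    # no interior local maximum: fall back to the tallest early bin
    sel <- which(stap$lags < before)
    if (!length(sel) || all(stap$counts[sel] == 0)) return(NA_real_)
    return(stap$lags[sel[which.max(d[sel])]])
  }
  stap$lags[idx[which.max(d[idx])]]
}

#' @export
plot.swd_stap <- function(x, ...) {
  plot(x$lags, x$density, type = "h", xlab = "lag (ms)",
       ylab = "APs / trigger / ms", ...)
  abline(v = 0, lty = 2, col = "red")
  invisible(x)
}

#' Classify per-cycle firing as burst, tonic or silent
#'
#' Burst: at least two APs within a cycle with an inter-spike interval of at
#' most `isi_burst` ms; tonic: at least one AP but no burst; silent: none.
#' Proportions are cycle-averaged with bootstrap confidence intervals over
#' cycles.
#'
#' @param spikes Per-neuron spike lists (ms) or data frame.
#' @param cycles Data frame with `start` and `end` (ms).
#' @param isi_burst Burst ISI criterion (ms).
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Bootstrap seed.
#' @return List: `labels` (neurons x cycles character matrix) and
#'   `proportions` (data frame with `label`, `mean`, `lower`, `upper`).
#' @export
classify_cycle_firing <- function(spikes, cycles, isi_burst = 10,
                                  n_boot = 200, conf = 0.95, seed = 1) {
  sl <- .as_spike_list(spikes)
  nc <- nrow(cycles)
  lab <- matrix("silent", length(sl), nc)
  for (i in seq_along(sl)) {
    sp <- sl[[i]]
    for (j in seq_len(nc)) {
      spc <- sp[sp >= cycles$start[j] & sp < cycles$end[j]]
      if (length(spc) >= 2 && any(diff(sort(spc)) <= isi_burst))
        lab[i, j] <- "burst"
      else if (length(spc) >= 1) lab[i, j] <- "tonic"
    }
  }
  lv <- c("burst", "tonic", "silent")
  prop_per_cycle <- vapply(seq_len(nc), function(j)
    as.numeric(table(factor(lab[, j], levels = lv))) / length(sl),
    numeric(3))
  means <- rowMeans(prop_per_cycle)
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(nc, nc, replace = TRUE)
      rowMeans(prop_per_cycle[, pick, drop = FALSE])
    }, numeric(3))
  })
  a <- (1 - conf) / 2
  props <- data.frame(
    label = lv, mean = means,
    lower = apply(boot, 1, quantile, a),
    upper = apply(boot, 1, quantile, 1 - a))
  list(labels = lab, proportions = props)
}

# ---------------------------------------------------------------------------
# Period-normalised averaging and AP-EEG cross-correlation
# ---------------------------------------------------------------------------

#' Period-scaled (time-normalised) average over ictal and interictal periods
#'
#' Each ictal (respectively interictal) period of the signal is linearly
#' resampled to its class's mean duration, then averaged pointwise across
#' periods with bootstrap confidence intervals. Constant signals average to
#' themselves and total mass is preserved up to resampling error.
#'
#' @param x Signal sampled at `fs` (e.g. a firing-rate trace).
#' @param fs Sampling rate (Hz).
#' @param segmentation `swd_segmentation`.
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return List with `ictal` and `interictal` data frames (`time` in s,
#'   `mean`, `lower`, `upper`) or `NULL` where fewer than one period exists.
#'   With a single period the period itself is returned with a warning.
#' @export
period_scaled_average <- function(x, fs, segmentation, n_boot = 200,
                                  seed = 1) {
  iv <- segmentation$intervals
  t0 <- segmentation$t_offset
  n <- length(x)
  grab <- function(a_ms, b_ms) {
    i1 <- max(1, floor((a_ms - t0) / 1000 * fs) + 1)
    i2 <- min(n, floor((b_ms - t0) / 1000 * fs))
    if (i2 <= i1) NULL else x[i1:i2]
  }
  ictal <- lapply(seq_len(nrow(iv)),
                  function(j) grab(iv$start[j], iv$end[j]))
  inter <- list()
  if (nrow(iv) >= 2) {
    for (j in seq_len(nrow(iv) - 1))
      inter <- c(inter, list(grab(iv$end[j], iv$start[j + 1])))
  }
  ictal <- Filter(Negate(is.null), ictal)
  inter <- Filter(Negate(is.null), inter)

  avg_class <- function(periods) {
    if (!length(periods)) return(NULL)
    if (length(periods) == 1) {
      warning("single period: returning it unaveraged")
      p <- periods[[1]]
      return(data.frame(time = seq_along(p) / fs, mean = p,
                        lower = p, upper = p))
    }
    mlen <- round(mean(lengths(periods)))
    res <- vapply(periods, function(p)
      approx(seq_along(p), p, xout = seq(1, length(p),
                                         length.out = mlen))$y,
      numeric(mlen))
    mu <- rowMeans(res)
    boot <- .with_seed(seed, vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(ncol(res), ncol(res), replace = TRUE)
      rowMeans(res[, pick, drop = FALSE])
    }, numeric(mlen)))
    data.frame(time = seq_len(mlen) / fs, mean = mu,
               lower = apply(boot, 1, quantile, 0.025),
               upper = apply(boot, 1, quantile, 0.975))
  }
  list(ictal = avg_class(ictal), interictal = avg_class(inter))
}

# circular cross-correlation of two equal-length series via FFT,
# returned for lags -max_lag..max_lag (in samples)
.xcorr_fft <- function(a, b, max_lag) {
  n <- length(a)
  A <- fft(a - mean(a)); B <- fft(b - mean(b))
  cc <- Re(fft(A * Conj(B), inverse = TRUE)) / n
  cc <- cc / (sd(a) * sd(b) * (n - 1) / n) / n
  idx <- c((n - max_lag + 1):n, 1:(max_lag + 1))
  list(lag = -max_lag:max_lag, cc = cc[idx], full = cc)
}

#' Cross-correlation between the pooled spike train and the EEG
#'
#' All APs are binned at the EEG sampling rate, mean-subtracted, and
#' cross-correlated with the EEG. The confidence band is obtained from
#' random circular shifts of the spike train (equivalently, the correlation
#' at random lags), which preserves both autocorrelation structures.
#'
#' @param spikes Per-neuron spike lists (ms) or data frame.
#' @param eeg EEG trace.
#' @param fs Sampling rate (Hz).
#' @param max_lag Maximum lag (ms).
#' @param n_shuffle Number of shuffles for the confidence band.
#' @param conf Confidence level.
#' @param seed Shuffle seed.
#' @return Data frame with `lag_ms`, `cc`, and the shuffle band in
#'   attributes `ci_lower` / `ci_upper`.
#' @export
ap_eeg_crosscorrelation <- function(spikes, eeg, fs, max_lag = 500,
                                    n_shuffle = 200, conf = 0.95, seed = 1) {
  sl <- .as_spike_list(spikes)
  n <- length(eeg)
  bins <- tabulate(pmin(n, floor(unlist(sl) / 1000 * fs) + 1), nbins = n)
  ml <- round(max_lag / 1000 * fs)
  xc <- .xcorr_fft(as.numeric(bins), eeg, ml)
  samp <- .with_seed(seed, sample.int(n, min(n_shuffle * 10, n)))
  a <- (1 - conf) / 2
  band <- quantile(xc$full[samp], c(a, 1 - a))
  out <- data.frame(lag_ms = xc$lag / fs * 1000, cc = xc$cc)
  attr(out, "ci_lower") <- band[[1]]
  attr(out, "ci_upper") <- band[[2]]
  out
}
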