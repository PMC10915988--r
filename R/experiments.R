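# ---------------------------------------------------------------------------
# Scenario catalogue: every single-conductance manipulation that elicits,
# modulates or abolishes SWDs, plus the two control (trigger) scenarios they
# compose with. Composite scenarios are a control trigger + one extra event.
# ---------------------------------------------------------------------------

.scenario_table <- function() {
  s <- function(name, expected, base = NA_character_, ...) {
    data.frame(name = name, expected = expected, base = base,
               stringsAsFactors = FALSE)
  }
  rbind(
    s("control_wake", "no_swd"),
    s("control_transition", "no_swd"),
    s("gkl_tcfo_up_5pct", "swd_4hz"),
    s("gkl_tcfo_up_10pct", "swd_4hz"),
    s("gkl_tcfo_up_20pct", "swd_4hz"),
    s("egabaa_tcfo_up_low", "swd_4hz"),
    s("egabaa_tcfo_up_mid", "swd_4hz"),
    s("egabaa_tcfo_up_high", "swd_4hz"),
    s("ggabaa_cortex_down_10pct", "swd_4hz"),
    s("ggabaa_cortex_down_25pct", "swd_4hz"),
    s("gampa_cortex_up_5pct", "swd_4hz"),
    s("gampa_cortex_up_40pct", "swd_4hz"),
    s("sib_l5", "swd_small"),
    s("sib_l5_l6", "swd_small"),
    s("gt_nrt_up_mid", "swd_small"),
    s("gt_nrt_up_high", "no_swd"),
    s("gt_tcho_up_5pct", "swd_4hz"),
    s("gt_tcho_up_10pct", "absence_status"),
    s("gt_tcfo_block", "swd_4hz", base = "gkl_tcfo_up_5pct"),
    s("gt_tcho_block", "no_swd", base = "gkl_tcfo_up_5pct"),
    s("gt_nrt_block", "no_swd", base = "gkl_tcfo_up_5pct"),
    s("ggabab_cortex_block", "no_swd", base = "gkl_tcfo_up_5pct"),
    s("ggabab_tcfo_block", "no_swd", base = "gkl_tcfo_up_5pct"),
    s("ggabab_tcho_block", "no_swd", base = "gkl_tcfo_up_5pct"),
    s("gt_tcho_block_cortical_route", "no_swd",
      base = "ggabaa_cortex_down_25pct"),
    s("ggabab_cortex_up", "status_or_prolonged", base = "gkl_tcfo_up_5pct"),
    s("ggabab_tcfo_up", "swd_4hz", base = "gkl_tcfo_up_5pct"),
    s("ggabab_tcho_up", "absence_status", base = "gkl_tcfo_up_5pct"),
    s("gkl_tcho_down", "swd_7hz", base = "gkl_tcfo_up_5pct"),
    s("gkl_tcho_down_cortical_route", "swd_7hz",
      base = "ggabaa_cortex_down_25pct"),
    s("gcan_tc_block", "swd_4hz", base = "gkl_tcfo_up_5pct"),
    s("gcan_nrt_block", "status_or_prolonged", base = "gkl_tcfo_up_5pct")
  )
}

# the single extra perturbation each (non-control) scenario applies
.scenario_own_events <- function(name, onset) {
  ev <- function(pop, g, scale) perturbation_event(pop, g, scale, onset)
  switch(name,
    control_wake = ,
    control_transition = list(),
    gkl_tcfo_up_5pct = list(ev("TC_FO", "g_KL", 1.05)),
    gkl_tcfo_up_10pct = list(ev("TC_FO", "g_KL", 1.10)),
    gkl_tcfo_up_20pct = list(ev("TC_FO", "g_KL", 1.20)),
    egabaa_tcfo_up_low = list(ev("TC_FO", "g_eGABAa", 15)),
    egabaa_tcfo_up_mid = list(ev("TC_FO", "g_eGABAa", 25)),
    egabaa_tcfo_up_high = list(ev("TC_FO", "g_eGABAa", 40)),
    ggabaa_cortex_down_10pct = list(ev("cortex", "g_GABAa", 0.90)),
    ggabaa_cortex_down_25pct = list(ev("cortex", "g_GABAa", 0.75)),
    gampa_cortex_up_5pct = list(ev("cortex", "g_AMPA", 1.05)),
    gampa_cortex_up_40pct = list(ev("cortex", "g_AMPA", 1.40)),
    sib_l5 = list(),
    sib_l5_l6 = list(),
    gt_nrt_up_mid = list(ev("NRT", "g_T", 1.25)),
    gt_nrt_up_high = list(ev("NRT", "g_T", 1.6)),
    gt_tcho_up_5pct = list(ev("TC_HO", "g_T", 1.05)),
    gt_tcho_up_10pct = list(ev("TC_HO", "g_T", 1.10)),
    gt_tcfo_block = list(ev("TC_FO", "g_T", 0)),
    gt_tcho_block = ,
    gt_tcho_block_cortical_route = list(ev("TC_HO", "g_T", 0)),
    gt_nrt_block = list(ev("NRT", "g_T", 0)),
    ggabab_cortex_block = list(ev("cortex", "g_GABAb", 0)),
    ggabab_tcfo_block = list(ev("TC_FO", "g_GABAb", 0)),
    ggabab_tcho_block = list(ev("TC_HO", "g_GABAb", 0)),
    ggabab_cortex_up = list(ev("cortex", "g_GABAb", 1.5)),
    ggabab_tcfo_up = list(ev("TC_FO", "g_GABAb", 1.5)),
    ggabab_tcho_up = list(ev("TC_HO", "g_GABAb", 1.5)),
    gkl_tcho_down = ,
    gkl_tcho_down_cortical_route = list(ev("TC_HO", "g_KL", 0.75)),
    gcan_tc_block = list(ev("TC", "g_CAN", 0)),
    gcan_nrt_block = list(ev("NRT", "g_CAN", 0)),
    stop("unknown scenario: ", name)
  )
}

#' Table of all registered perturbation scenarios
#'
#' Each scenario names a manipulation (or control), its expected outcome
#' class, and - for combined manipulations - the control scenario it builds
#' on (composite scenarios are always a control plus one extra event).
#'
#' @return Data frame with `name`, `expected`, `base` and `n_events`.
#' @export
scenario_matrix <- function() {
  tab <- .scenario_table()
  tab$n_events <- vapply(seq_len(nrow(tab)), function(i) {
    own <- length(.scenario_own_events(tab$name[i], 0))
    base <- if (!is.na(tab$base[i]))
      length(.scenario_own_events(tab$base[i], 0)) else 0
    own + base + (tab$name[i] %in% c("sib_l5", "sib_l5_l6"))
  }, numeric(1))
  tab
}

#' Perturbation list of a scenario (including its base control)
#'
#' @param name Scenario name from [scenario_matrix()].
#' @param onset Perturbation onset (ms).
#' @return List of `swd_perturbation` events.
#' @export
scenario_perturbations <- function(name, onset = 5000) {
  tab <- .scenario_table()
  row <- tab[tab$name == name, ]
  if (!nrow(row)) stop("scenario not registered: ", name)
  base_ev <- if (!is.na(row$base))
    .scenario_own_events(row$base, onset) else list()
  c(base_ev, .scenario_own_events(name, onset))
}

#' Run one scenario across seeds and summarise the outcome
#'
#' Builds the default network at the requested scale, runs the simulation
#' per seed in the sleep-wake-transition state (wake for the wake control),
#' segments the post-onset EEG and aggregates seizure counts, durations and
#' dominant frequency. The verdict compares the observed outcome with the
#' scenario's expected class.
#'
#' @param name Scenario name from [scenario_matrix()].
#' @param seeds Integer seeds (one simulation each).
#' @param scale `"desk"` or `"full"`.
#' @param duration Simulated time (ms).
#' @param onset Perturbation onset (ms); the EEG before `onset` is excluded
#'   from segmentation.
#' @param ... Extra arguments to [segment_ictal()].
#' @return Object of class `swd_scenario_report`.
#' @export
run_scenario <- function(name, seeds = 1:3, scale = "desk",
                         duration = 120000, onset = 5000, ...) {
  tab <- .scenario_table()
  row <- tab[tab$name == name, ]
  if (!nrow(row)) stop("scenario not registered: ", name)
  state <- if (name == "control_wake") "wake" else "transition"

  per_seed <- list()
  for (sd_i in seeds) {
    net <- build_default_network(default_network_config(scale), seed = sd_i)
    if (name %in% c("sib_l5", "sib_l5_l6")) {
      net <- substitute_sib(net, if (name == "sib_l5") "L5" else
        c("L5", "L6"), fraction = 1, seed = sd_i)
    }
    cfg <- simulation_config(duration = duration, seed = sd_i, state = state)
    sim <- run_simulation(net, cfg,
                          scenario_perturbations(name, onset))
    post <- sim$eeg[(onset / 1000 * sim$fs + 1):length(sim$eeg)]
    seg <- segment_ictal(post, sim$fs, t_offset = onset, ...)
    per_seed[[as.character(sd_i)]] <- list(sim = sim, segmentation = seg)
  }

  iv <- do.call(rbind, lapply(per_seed, function(x) x$segmentation$intervals))
  n_seiz <- vapply(per_seed, function(x) nrow(x$segmentation$intervals),
                   numeric(1))
  status <- any(vapply(per_seed, function(x) x$segmentation$status,
                       logical(1)))
  analysed_ms <- duration - onset
  ictal_frac <- vapply(per_seed, function(x) {
    ivx <- x$segmentation$intervals
    if (!nrow(ivx)) 0 else sum(ivx$end - ivx$start) / analysed_ms
  }, numeric(1))

  med_freq <- if (nrow(iv)) median(iv$dominant_freq) else NA_real_
  mean_dur <- if (nrow(iv)) mean(iv$end - iv$start) / 1000 else NA_real_

  observed <- if (status || mean(ictal_frac) > 0.9) "absence_status"
    else if (sum(n_seiz) == 0) "no_swd"
    else if (!is.na(med_freq) && med_freq >= 6) "swd_7hz"
    else "swd_4hz"
  expected <- row$expected
  matches <- switch(expected,
    no_swd = observed == "no_swd",
    swd_4hz = observed == "swd_4hz",
    swd_7hz = observed == "swd_7hz",
    swd_small = observed %in% c("swd_4hz", "swd_7hz"),
    absence_status = observed == "absence_status" ||
      mean(ictal_frac) > 0.75,
    status_or_prolonged = observed == "absence_status" ||
      mean(ictal_frac) > 0.5,
    FALSE)

  structure(list(name = name, expected = expected, observed = observed,
                 verdict = if (matches) "matches" else "contradicts",
                 n_seizures = n_seiz, median_frequency = med_freq,
                 mean_duration_s = mean_dur, ictal_fraction = ictal_frac,
                 status = status, seeds = seeds, scale = scale,
                 runs = per_seed), class = "swd_scenario_report")
}

#' @export
print.swd_scenario_report <- function(x, ...) {
  cat("<swd_scenario_report> ", x$name, " (", x$scale, " scale)\n", sep = "")
  cat("  seizures/seed:", paste(x$n_seizures, collapse = ", "),
      "| median freq:", round(x$median_frequency, 2), "Hz",
      "| mean duration:", round(x$mean_duration_s, 1), "s\n")
  cat("  expected:", x$expected, "| observed:", x$observed, "->",
      x$verdict, "\n")
  invisible(x)
}

#' Sleep-spindle sanity check
#'
#' In the sleep-wake-transition state without any SWD perturbation the
#' thalamocortical loop should express transient waxing-and-waning
#' oscillations whose spectral peak falls in the spindle band (7-14 Hz),
#' and none in the wake state.
#'
#' @param scale Network scale.
#' @param duration Simulated time (ms).
#' @param seed Seed.
#' @param state Behavioural state to test.
#' @param perturbations Optional perturbations (e.g. a g_T block).
#' @return List: `ok` (peak inside 7-14 Hz), `peak_freq` (Hz), `n_epochs`,
#'   `epochs` (data frame, ms).
#' @export
spindle_sanity_check <- function(scale = "desk", duration = 30000, seed = 1,
                                 state = "transition",
                                 perturbations = list()) {
  net <- build_default_network(default_network_config(scale), seed = seed)
  cfg <- simulation_config(duration = duration, seed = seed, state = state)
  sim <- run_simulation(net, cfg, perturbations)
  eeg <- sim$eeg
  fs <- sim$fs
  bp <- .design_bandpass_fixed(6, 16, fs, order = 4)
  xf <- swd_filtfilt(bp, eeg)
  env <- .movavg(Mod(analytic_signal(xf)), round(0.1 * fs))
  thr <- mean(env) + 2 * sd(env)
  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- cbind(starts[r$values], ends[r$values])
  if (length(iv))
    iv <- iv[(iv[, 2] - iv[, 1]) / fs >= 0.25, , drop = FALSE]
  if (!length(iv) || nrow(iv) == 0)
    return(list(ok = FALSE, peak_freq = NA_real_, n_epochs = 0,
                epochs = data.frame(start = numeric(0), end = numeric(0))))
  seg <- unlist(lapply(seq_len(nrow(iv)), function(j) {
    s <- eeg[iv[j, 1]:iv[j, 2]]
    s - mean(s)
  }))
  spx <- spec.pgram(ts(seg, frequency = fs), spans = c(7, 7), plot = FALSE,
                    taper = 0.1)
  sel <- spx$freq >= 4 & spx$freq <= 20
  peak <- spx$freq[sel][which.max(spx$spec[sel])]
  list(ok = peak >= 7 && peak <= 14, peak_freq = peak, n_epochs = nrow(iv),
       epochs = data.frame(start = (iv[, 1] - 1) / fs * 1000,
                           end = (iv[, 2] - 1) / fs * 1000))
}

#' Attribute the onset site of each seizure
#'
#' For the first two seconds of each seizure, computes the first-AP-per-cycle
#' histogram per population and reports the population with the earliest
#' (most leading) peak.
#'
#' @param sim `swd_simulation`.
#' @param segmentation `swd_segmentation` of its EEG.
#' @return Character vector, one population per seizure (NA where
#'   undetermined).
#' @export
seizure_onset_population <- function(sim, segmentation) {
  pops <- unique(sim$neurons$population)
  out <- character(0)
  for (j in seq_along(segmentation$spike_times)) {
    trig <- segmentation$spike_times[[j]]
    trig <- trig[trig <= segmentation$intervals$start[j] + 2000]
    if (length(trig) < 2) { out <- c(out, NA_character_); next }
    lead <- vapply(pops, function(pp) {
      st <- stap_histogram(spike_trains(sim, pp), trig,
                           variant = "first_AP_per_cycle")
      stap_peak_lag(st)
    }, numeric(1))
    out <- c(out, if (all(is.na(lead))) NA_character_ else
      pops[which.min(lead)])
  }
  out
}
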