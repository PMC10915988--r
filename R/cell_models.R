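#' The eleven neuron classes of the corticothalamic network
#'
#' Cortical excitatory classes: regular spiking (RS), intrinsically bursting
#' (IB), early firing (EF), repetitive intrinsically bursting (RIB), network
#' driver (ND) and the strongly intrinsically bursting (SIB) variant that can
#' be substituted for IB cells in layers 5/6. Cortical inhibitory cells are
#' fast spiking (FS) interneurons. Thalamic classes: first- and higher-order
#' thalamocortical relay neurons (TC_FO, TC_HO) and the corresponding
#' GABAergic reticular thalamic neurons (NRT_FO, NRT_HO).
#'
#' @return Character vector of the 11 class labels.
#' @export
cell_types <- function() {
  c("RS", "IB", "EF", "RIB", "ND", "SIB", "FS",
    "TC_FO", "TC_HO", "NRT_FO", "NRT_HO")
}

# Intrinsic conductance densities (mS/cm^2), one row per cell class.
# Kinetic schemes are fixed (see src/engine.cpp); classes differ only in
# densities, reversal potentials and the spike-threshold shift VT. Values are
# tuned so that each class expresses its nominal firing signature under the
# standard current-clamp protocols (see firing_signature()).
.cell_param_table <- function() {
  cols <- c("C", "g_Na", "g_K", "g_leak", "E_leak", "g_KL", "g_T", "g_h",
            "g_CAN", "g_NaP", "g_M", "VT", "g_eGABAa", "E_K", "E_Na", "E_Ca",
            "E_h", "E_CAN", "E_Cl", "tau_Ca", "k_Ca", "t_kin")
  m <- rbind(
    #        C  gNa gK  gL    EL   gKL   gT   gh    gCAN  gNaP  gM    VT  gEGA  EK  ENa ECa EH  ECAN ECl tauCa kCa  tkin
    RS    = c(1, 50, 5, 0.03, -70, 0.01, 0.0, 0.00, 0.00, 0.00, 0.07, -55, 0, -90, 55, 120, -43, 10, -80, 100, 0, 0),
    IB    = c(1, 50, 5, 0.03, -70, 0.01, 0.8, 0.00, 0.00, 0.00, 0.10, -55, 0, -90, 55, 120, -43, 10, -80, 100, 0, 1),
    EF    = c(1, 50, 5, 0.03, -70, 0.01, 0.8, 0.00, 0.00, 0.00, 0.20, -55, 0, -90, 55, 120, -43, 10, -80, 100, 0, 1),
    RIB   = c(1, 50, 5, 0.03, -70, 0.01, 2.2, 0.00, 0.00, 0.00, 0.30, -55, 0, -90, 55, 120, -43, 10, -80, 100, 0, 1),
    ND    = c(1, 50, 5, 0.03, -68, 0.01, 2.2, 0.00, 0.00, 0.00, 0.30, -55, 0, -90, 55, 120, -43, 10, -80, 100, 0, 1),
    SIB   = c(1, 50, 5, 0.03, -70, 0.01, 2.5, 0.00, 0.00, 0.00, 0.30, -55, 0, -90, 55, 120, -43, 10, -80, 100, 0, 1),
    FS    = c(1, 56, 6, 0.03, -70, 0.01, 0.0, 0.00, 0.00, 0.00, 0.00, -55, 0, -90, 55, 120, -43, 10, -80, 100, 0, 0),
    TC_FO = c(1, 30, 3, 0.01, -72, 0.02, 0.8, 0.015, 0.035, 0.00, 0.00, -52, 0.002, -95, 55, 120, -43, 10, -80, 1500, 1.3e-7, 0),
    TC_HO = c(1, 30, 3, 0.01, -72, 0.02, 0.8, 0.015, 0.035, 0.00, 0.00, -52, 0.002, -95, 55, 120, -43, 10, -80, 1500, 1.3e-7, 0),
    NRT_FO= c(1, 30, 3, 0.05, -78, 0.01, 1.2, 0.00, 0.030, 0.01, 0.00, -52, 0, -95, 55, 120, -43, 10, -80, 1500, 1.3e-7, 1),
    NRT_HO= c(1, 30, 3, 0.05, -78, 0.01, 1.2, 0.00, 0.030, 0.01, 0.00, -52, 0, -95, 55, 120, -43, 10, -80, 1500, 1.3e-7, 1)
  )
  colnames(m) <- cols
  m
}

#' Intrinsic parameters for one neuron class
#'
#' @param cell_type One of [cell_types()].
#' @param overrides Named list of parameter overrides (e.g. `list(g_T = 0)`).
#' @return An object of class `swd_cell_parameters`: a named list of membrane
#'   capacitance (uF/cm^2), conductance densities (mS/cm^2), reversal
#'   potentials (mV), the spike-kinetics threshold shift `VT` (mV), calcium
#'   dynamics constants and the T-current kinetic variant (`t_kin`, 0 = relay,
#'   1 = reticular).
#' @export
cell_parameters <- function(cell_type, overrides = NULL) {
  cell_type <- match.arg(cell_type, cell_types())
  tab <- .cell_param_table()
  p <- as.list(tab[cell_type, ])
  p$cell_type <- cell_type
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  g <- unlist(p[grep("^g_", names(p))])
  if (any(g < 0)) stop("conductance densities must be >= 0")
  if (cell_type %in% c("TC_FO", "TC_HO", "NRT_FO", "NRT_HO") && p$g_T <= 0 &&
      is.null(overrides$g_T))
    stop("thalamic cell types require g_T > 0")
  class(p) <- "swd_cell_parameters"
  p
}

#' @export
print.swd_cell_parameters <- function(x, ...) {
  cat("<swd_cell_parameters>", x$cell_type, "\n")
  g <- unlist(x[grep("^g_", names(x))])
  cat("  conductances (mS/cm^2):",
      paste(names(g), signif(g, 3), sep = "=", collapse = " "), "\n")
  cat("  VT =", x$VT, "mV; E_leak =", x$E_leak, "mV\n")
  invisible(x)
}

# registered (current, variable) gating pairs
.gating_registry <- function() {
  list(I_Na = c("m", "h"), I_K = "n", I_M = "p", I_T = c("m", "h"),
       I_T_NRT = c("m", "h"), I_h = "h", I_NaP = "m")
}

.check_gating_pair <- function(current_name, variable) {
  reg <- .gating_registry()
  ok <- current_name %in% names(reg) && variable %in% reg[[current_name]]
  if (!ok) {
    stop("unknown (current, variable) pair: (", current_name, ", ", variable,
         "). Registered pairs: ",
         paste(unlist(lapply(names(reg), function(n)
           paste0(n, "/", reg[[n]]))), collapse = ", "))
  }
}

#' Steady-state value of a gating variable
#'
#' Boltzmann / rate-derived steady state of the named gating variable,
#' continuous in V, increasing for activation variables and decreasing for
#' inactivation variables. `I_T` uses the thalamocortical relay kinetics;
#' `I_T_NRT` the reticular variant. For voltage-shifted spike currents
#' (`I_Na`, `I_K`) the voltage is interpreted relative to the per-cell
#' threshold shift VT, i.e. pass `V - VT`.
#'
#' @param current_name Current name, e.g. `"I_T"`.
#' @param variable Gating variable name, e.g. `"m"` or `"h"`.
#' @param V Membrane potential (mV), vectorised.
#' @return Steady-state value(s) in \[0, 1\].
#' @export
gating_steady_state <- function(current_name, variable, V) {
  .check_gating_pair(current_name, variable)
  if (any(!is.finite(V))) stop("V must be finite")
  r <- .gating_rate(current_name, variable, as.numeric(V))
  r[seq(1, length(r), by = 2)]
}

#' Voltage-dependent time constant of a gating variable
#'
#' @inheritParams gating_steady_state
#' @return Time constant(s) in ms.
#' @export
gating_time_constant <- function(current_name, variable, V) {
  .check_gating_pair(current_name, variable)
  if (any(!is.finite(V))) stop("V must be finite")
  r <- .gating_rate(current_name, variable, as.numeric(V))
  r[seq(2, length(r), by = 2)]
}

#' Construct a cell state
#'
#' Gating variables are initialised at their steady state for the given
#' voltage; intracellular calcium at its resting value.
#'
#' @param params `swd_cell_parameters`.
#' @param V Initial membrane potential (mV).
#' @return An object of class `swd_cell_state`.
#' @export
cell_state <- function(params, V = params$E_leak) {
  vt <- V - params$VT
  tvar <- if (params$t_kin < 0.5) "I_T" else "I_T_NRT"
  st <- list(
    V = V,
    gating = c(
      m = gating_steady_state("I_Na", "m", vt),
      h = gating_steady_state("I_Na", "h", vt),
      n = gating_steady_state("I_K", "n", vt),
      p = gating_steady_state("I_M", "p", V),
      m_T = gating_steady_state(tvar, "m", V),
      h_T = gating_steady_state(tvar, "h", V),
      h_h = gating_steady_state("I_h", "h", V),
      m_CAN = 0
    ),
    Ca_i = 5e-5,
    last_spike_time = NA_real_
  )
  class(st) <- "swd_cell_state"
  st
}

#' Membrane and gating derivatives for a single cell
#'
#' Current-balance equation
#' `dV/dt = -(sum of ionic currents + I_syn - I_inj) / C`
#' including exactly the currents whose conductance densities are non-zero in
#' `params`; gating derivatives follow `(x_inf(V) - x) / tau_x(V)`.
#'
#' @param state `swd_cell_state`.
#' @param params `swd_cell_parameters`.
#' @param I_syn Synaptic current (uA/cm^2, positive = outward).
#' @param I_inj Injected current (uA/cm^2, positive = depolarizing).
#' @return List with `dV` (mV/ms), `dgating` (per ms), `dCa` (mM/ms), and the
#'   per-current breakdown `currents` (uA/cm^2).
#' @export
membrane_derivative <- function(state, params, I_syn = 0, I_inj = 0) {
  stopifnot(inherits(state, "swd_cell_state"),
            inherits(params, "swd_cell_parameters"))
  V <- state$V
  g <- state$gating
  p <- params
  tvar <- if (p$t_kin < 0.5) "I_T" else "I_T_NRT"

  cur <- c(
    I_Na   = p$g_Na * g[["m"]]^3 * g[["h"]] * (V - p$E_Na),
    I_K    = p$g_K * g[["n"]]^4 * (V - p$E_K),
    I_M    = p$g_M * g[["p"]] * (V - p$E_K),
    I_T    = p$g_T * g[["m_T"]]^2 * g[["h_T"]] * (V - p$E_Ca),
    I_h    = p$g_h * g[["h_h"]] * (V - p$E_h),
    I_CAN  = p$g_CAN * g[["m_CAN"]] * (V - p$E_CAN),
    I_NaP  = p$g_NaP * gating_steady_state("I_NaP", "m", V) * (V - p$E_Na),
    I_leak = p$g_leak * (V - p$E_leak),
    I_KL   = p$g_KL * (V - p$E_K),
    I_eGABAa = p$g_eGABAa * (V - p$E_Cl)
  )
  bad <- !is.finite(cur)
  if (any(bad))
    stop("non-finite current term: ", paste(names(cur)[bad], collapse = ", "))

  dV <- -(sum(cur) + I_syn - I_inj) / p$C

  vshift <- V - p$VT
  dg <- c(
    m = (gating_steady_state("I_Na", "m", vshift) - g[["m"]]) /
      gating_time_constant("I_Na", "m", vshift),
    h = (gating_steady_state("I_Na", "h", vshift) - g[["h"]]) /
      gating_time_constant("I_Na", "h", vshift),
    n = (gating_steady_state("I_K", "n", vshift) - g[["n"]]) /
      gating_time_constant("I_K", "n", vshift),
    p = (gating_steady_state("I_M", "p", V) - g[["p"]]) /
      gating_time_constant("I_M", "p", V),
    m_T = (gating_steady_state(tvar, "m", V) - g[["m_T"]]) /
      gating_time_constant(tvar, "m", V),
    h_T = (gating_steady_state(tvar, "h", V) - g[["h_T"]]) /
      gating_time_constant(tvar, "h", V),
    h_h = (gating_steady_state("I_h", "h", V) - g[["h_h"]]) /
      gating_time_constant("I_h", "h", V),
    m_CAN = ((state$Ca_i^2 / (state$Ca_i^2 + 2.4e-4^2)) - g[["m_CAN"]]) / 160
  )
  dCa <- max(0, -p$k_Ca * cur[["I_T"]]) + (5e-5 - state$Ca_i) / p$tau_Ca
  list(dV = dV, dgating = dg, dCa = dCa, currents = cur)
}

#' Single-cell current-clamp simulation
#'
#' Integrates one neuron under a piecewise-constant current injection protocol
#' using the same fixed-step engine as network simulations.
#'
#' @param params `swd_cell_parameters`.
#' @param protocol Data frame with columns `amplitude` (uA/cm^2), `onset` and
#'   `offset` (ms); steps may overlap (amplitudes add).
#' @param duration Total simulated time (ms).
#' @param dt Integration step (ms), must be <= 0.05.
#' @param V0 Initial membrane potential (mV).
#' @return List with `time` (ms, 1 kHz), `V` (mV), `spike_times` (ms) and the
#'   echoed protocol. Class `swd_trace`.
#' @export
simulate_current_clamp <- function(params, protocol, duration = 2000,
                                   dt = 0.025, V0 = params$E_leak) {
  stopifnot(inherits(params, "swd_cell_parameters"))
  if (!is.finite(dt) || dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05] ms")
  if (!all(is.finite(unlist(protocol)))) stop("protocol must be finite")
  par <- .param_matrix_from_list(list(params))
  inj <- as.numeric(t(as.matrix(protocol[, c("amplitude", "onset", "offset")])))
  out <- .engine_run(par, 0L, c(0L, 0L), integer(0), integer(0), numeric(0),
                     integer(0),
                     list(onset_ms = numeric(0), kind = integer(0),
                          idx = list(), scale = numeric(0)),
                     dt, duration, 1L, 0L, inj, V0, 0)
  v <- out$voltages[, 1]
  if (any(abs(v) > 100 & seq_along(v) > 10)) {
    if (mean(abs(v) > 100) > 0.2)
      stop("integration failure: |V| > 100 mV sustained")
  }
  res <- list(time = seq_along(v) - 0.5, V = v,
              spike_times = out$spike_t, protocol = protocol, dt = dt,
              params = params)
  class(res) <- "swd_trace"
  res
}

#' @export
plot.swd_trace <- function(x, ...) {
  plot(x$time, x$V, type = "l", xlab = "time (ms)", ylab = "V (mV)", ...)
  abline(h = 0, lty = 3, col = "grey")
  invisible(x)
}

#' Detect action potentials in a voltage trace
#'
#' Upward crossings of 0 mV with a 2 ms refractory period.
#'
#' @param V Voltage trace (mV).
#' @param dt Sampling step of `V` (ms).
#' @param threshold Crossing threshold (mV).
#' @param refractory Minimum inter-spike interval (ms).
#' @return Spike times (ms).
#' @export
detect_spikes <- function(V, dt, threshold = 0, refractory = 2) {
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold)
  t <- up * dt
  if (length(t) < 2) return(t)
  keep <- c(TRUE, diff(t) >= refractory)
  # enforce refractory sequentially
  out <- numeric(0); last <- -Inf
  for (ti in t) if (ti - last >= refractory) { out <- c(out, ti); last <- ti }
  out
}

# group spike times into bursts: >= 2 spikes with ISI <= isi_max
.burst_groups <- function(spike_times, isi_max = 10) {
  if (length(spike_times) == 0) return(list())
  brk <- c(0, which(diff(spike_times) > isi_max), length(spike_times))
  lapply(seq_len(length(brk) - 1),
         function(i) spike_times[(brk[i] + 1):brk[i + 1]])
}

#' Classify the firing signature of a voltage trace
#'
#' Criteria: a burst is >= 2 APs with inter-spike intervals <= 10 ms; a
#' rebound burst is a burst starting within 150 ms of release from
#' hyperpolarization below -75 mV; repetitive bursting is >= 3 bursts;
#' fast spiking is tonic firing with ISI coefficient of variation < 0.2 and
#' < 20% adaptation; anything else tonic is regular spiking.
#'
#' @param trace `swd_trace` (or a numeric voltage vector with `dt` supplied).
#' @param spike_times Spike times (ms); taken from `trace` if missing.
#' @param dt Sampling step (ms) when `trace` is a bare vector.
#' @param release_time Optional time (ms) at which a hyperpolarizing step was
#'   released; enables the rebound-burst label.
#' @param stim_onset Time (ms) of depolarizing-step onset (for the
#'   onset-burst criterion); default 0.
#' @return One of `"regular_spiking"`, `"intrinsic_burst"`, `"fast_spiking"`,
#'   `"rebound_burst"`, `"repetitive_burst"`, `"none"`.
#' @export
classify_firing_signature <- function(trace, spike_times = NULL, dt = NULL,
                                      release_time = NULL, stim_onset = 0) {
  if (inherits(trace, "swd_trace")) {
    v <- trace$V; dt <- diff(trace$time[1:2])
    if (is.null(spike_times)) spike_times <- trace$spike_times
  } else {
    v <- as.numeric(trace)
    if (is.null(dt)) stop("dt required for bare voltage vectors")
    if (is.null(spike_times)) spike_times <- detect_spikes(v, dt)
  }
  if (length(v) == 0) stop("empty trace")
  st <- sort(spike_times)
  if (length(st) == 0) return("none")

  bursts <- .burst_groups(st)
  burst_like <- vapply(bursts, function(b) length(b) >= 2, logical(1))
  nb <- sum(burst_like)

  if (!is.null(release_time)) {
    # was the cell hyperpolarized below -75 mV before release?
    pre <- v[seq_len(max(1, floor(release_time / dt)))]
    hyper <- length(pre) > 0 && min(tail(pre, ceiling(100 / dt))) <= -75
    first_burst <- if (nb > 0) bursts[burst_like][[1]][1] else Inf
    if (hyper && first_burst >= release_time &&
        first_burst <= release_time + 150)
      return("rebound_burst")
  }
  if (nb >= 3) return("repetitive_burst")
  if (nb >= 1) {
    first_burst_t <- bursts[burst_like][[1]][1]
    if (first_burst_t <= stim_onset + 150) return("intrinsic_burst")
    return("repetitive_burst")
  }
  if (length(st) < 3) return("regular_spiking")
  isi <- diff(st)
  cv <- sd(isi) / mean(isi)
  k <- max(1, min(3, floor(length(isi) / 3)))
  adapt <- mean(tail(isi, k)) / mean(head(isi, k))
  if (cv < 0.2 && adapt < 1.2) "fast_spiking" else "regular_spiking"
}

# standard protocols per class, used by firing_signature() and the tests
.signature_protocol <- function(cell_type) {
  if (cell_type %in% c("TC_FO", "TC_HO", "NRT_FO", "NRT_HO")) {
    list(protocol = data.frame(amplitude = -0.6, onset = 200, offset = 800),
         duration = 1500, release_time = 800, mode = "rebound")
  } else {
    amp <- switch(cell_type, FS = 1.2, 1.2)
    list(protocol = data.frame(amplitude = amp, onset = 200, offset = 1200),
         duration = 1400, release_time = NULL, mode = "step")
  }
}

#' Run the standard protocol for a cell class and classify it
#'
#' Depolarizing step for cortical classes; hyperpolarize-and-release for
#' thalamic classes (the rebound-burst protocol).
#'
#' @param cell_type One of [cell_types()].
#' @param overrides Parameter overrides passed to [cell_parameters()].
#' @return List with the `swd_trace` and the `signature` label.
#' @export
firing_signature <- function(cell_type, overrides = NULL) {
  pr <- .signature_protocol(cell_type)
  params <- cell_parameters(cell_type, overrides)
  tr <- simulate_current_clamp(params, pr$protocol, duration = pr$duration)
  onset <- pr$protocol$onset[1]
  sig <- classify_firing_signature(tr, release_time = pr$release_time,
                                   stim_onset = onset)
  list(trace = tr, signature = sig)
}

#' Expected firing signature per cell class
#' @return Named character vector mapping class to intended signature under
#'   its standard protocol.
#' @export
expected_signatures <- function() {
  c(RS = "regular_spiking", IB = "intrinsic_burst", EF = "intrinsic_burst",
    RIB = "repetitive_burst", ND = "repetitive_burst",
    SIB = "repetitive_burst", FS = "fast_spiking",
    TC_FO = "rebound_burst", TC_HO = "rebound_burst",
    NRT_FO = "rebound_burst", NRT_HO = "rebound_burst")
}
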