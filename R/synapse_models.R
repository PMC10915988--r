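#' Receptor kinds
#' @return Character vector of the four receptor models.
#' @export
receptor_kinds <- function() c("AMPA", "GABAA", "GABAA_tonic", "GABAB")

#' Specify a synaptic connection
#'
#' Ionotropic receptors (AMPA, phasic GABA-A) are bi-exponential
#' conductances; GABA-B is a two-stage G-protein cascade (see
#' [gabab_update()]); tonic GABA-A is a constant conductance (see
#' [tonic_gabaa_current()]).
#'
#' @param receptor One of [receptor_kinds()].
#' @param g_max Maximal conductance (nS).
#' @param E_rev Reversal potential (mV).
#' @param rise_tau,decay_tau Kinetic time constants (ms); `decay_tau` must
#'   exceed `rise_tau`.
#' @param latency Axonal plus synaptic delay (ms), > 0.
#' @param weight Dimensionless multiplier.
#' @return Object of class `swd_synapse_spec`.
#' @export
synapse_spec <- function(receptor, g_max, E_rev, rise_tau = 0.5,
                         decay_tau = 2.5, latency = 1, weight = 1) {
  receptor <- match.arg(receptor, receptor_kinds())
  if (g_max < 0) stop("g_max must be >= 0")
  if (latency <= 0) stop("latency must be > 0")
  if (decay_tau <= rise_tau) stop("decay_tau must exceed rise_tau")
  structure(list(receptor = receptor, g_max = g_max, E_rev = E_rev,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 latency = latency, weight = weight),
            class = "swd_synapse_spec")
}

#' Bi-exponential synaptic gate
#'
#' Normalised so that a single event at time 0 has peak gate value 1, reached
#' at `t_peak = rise_tau * decay_tau / (decay_tau - rise_tau) *
#' log(decay_tau / rise_tau)`.
#'
#' @param spec `swd_synapse_spec`.
#' @param event_times Presynaptic event arrival times (ms, post-latency).
#' @param t Evaluation time(s) (ms).
#' @return Gate value(s), dimensionless >= 0.
#' @export
synaptic_gate <- function(spec, event_times, t) {
  tr <- spec$rise_tau; td <- spec$decay_tau
  tp <- tr * td / (td - tr) * log(td / tr)
  norm <- 1 / (exp(-tp / td) - exp(-tp / tr))
  vapply(t, function(tt) {
    d <- tt - event_times
    d <- d[d >= 0]
    if (!length(d)) return(0)
    norm * sum(exp(-d / td) - exp(-d / tr))
  }, numeric(1))
}

#' Synaptic current of an ionotropic or GABA-B connection
#'
#' For ionotropic kinds `I = g_max * weight * g(t) * (V_post - E_rev)` with
#' the bi-exponential gate `g(t)`; for GABA-B the conductance is
#' `g_max * weight * s^4 / (s^4 + K_d)` from the cascade state. With `g_max`
#' in nS and potentials in mV, the returned current is in nA
#' (1 nS x 1 mV = 1e-3 nA).
#'
#' @param spec `swd_synapse_spec`.
#' @param state For ionotropic kinds, the event-time vector; for GABAB, a
#'   `swd_gabab_state`.
#' @param V_post Postsynaptic potential (mV).
#' @param t Evaluation time (ms).
#' @return Current (nA), positive = outward (hyperpolarizing for V > E_rev).
#' @export
synaptic_current <- function(spec, state, V_post, t) {
  g <- switch(spec$receptor,
    AMPA = ,
    GABAA = spec$g_max * spec$weight * synaptic_gate(spec, state, t),
    GABAB = spec$g_max * spec$weight * gabab_conductance_fraction(state),
    GABAA_tonic = spec$g_max * spec$weight
  )
  i <- g * (V_post - spec$E_rev) * 1e-3
  if (any(!is.finite(i))) stop("non-finite synaptic current")
  i
}

# cascade constants shared with the engine
.gabab_constants <- function() {
  list(K1 = 0.52, K2 = 0.0013, K3 = 0.098, K4 = 0.033, Kd = 100,
       n = 4, T_conc = 0.5, T_dur = 0.9)
}

#' Initial GABA-B cascade state
#' @return `swd_gabab_state` with receptor activation `r = 0` and G-protein
#'   concentration `s = 0`.
#' @export
gabab_state <- function() {
  structure(list(r = 0, s = 0), class = "swd_gabab_state")
}

#' One integration step of the GABA-B G-protein cascade
#'
#' Two-stage kinetics: transmitter drives receptor activation `r`
#' (`dr/dt = K1 * T * (1 - r) - K2 * r`), which drives G-protein `s`
#' (`ds/dt = K3 * r - K4 * s`). The conductance fraction is
#' `s^4 / (s^4 + K_d)`: single presynaptic spikes produce negligible current
#' while high-frequency bursts produce large, slow IPSPs.
#'
#' @param state `swd_gabab_state`.
#' @param transmitter_pulse Logical; is transmitter present during this step?
#' @param dt Step (ms), > 0.
#' @return Updated `swd_gabab_state`.
#' @export
gabab_update <- function(state, transmitter_pulse, dt) {
  if (dt <= 0) stop("dt must be > 0")
  k <- .gabab_constants()
  Tc <- if (isTRUE(transmitter_pulse)) k$T_conc else 0
  a <- k$K1 * Tc + k$K2
  rinf <- k$K1 * Tc / a
  state$r <- rinf + (state$r - rinf) * exp(-a * dt)
  f <- exp(-k$K4 * dt)
  state$s <- state$s * f + state$r * (k$K3 / k$K4) * (1 - f)
  state
}

#' Saturating conductance fraction of the GABA-B cascade
#' @param state `swd_gabab_state`.
#' @return `s^n / (s^n + K_d)` in \[0, 1\].
#' @export
gabab_conductance_fraction <- function(state) {
  k <- .gabab_constants()
  state$s^k$n / (state$s^k$n + k$Kd)
}

#' Simulate the GABA-B cascade response to a presynaptic spike train
#'
#' Each spike delivers a transmitter pulse of fixed duration; the cascade is
#' integrated at step `dt` and the conductance-fraction time course returned.
#'
#' @param spike_times Presynaptic spike times (ms).
#' @param duration Total time (ms).
#' @param dt Step (ms).
#' @return Data frame with `time` and conductance `fraction`.
#' @export
gabab_response <- function(spike_times, duration, dt = 0.1) {
  k <- .gabab_constants()
  n <- ceiling(duration / dt)
  st <- gabab_state()
  out <- numeric(n)
  tt <- (seq_len(n) - 1) * dt
  for (i in seq_len(n)) {
    active <- any(tt[i] >= spike_times & tt[i] < spike_times + k$T_dur)
    st <- gabab_update(st, active, dt)
    out[i] <- gabab_conductance_fraction(st)
  }
  data.frame(time = tt, fraction = out)
}

#' Tonic (extrasynaptic) GABA-A current
#'
#' Voltage-independent, always-on chloride conductance:
#' `I = g_eGABAa * (V - E_Cl)`. With `g_eGABAa` in nS and potentials in mV
#' the current is in nA.
#'
#' @param g_eGABAa Conductance (nS), >= 0.
#' @param V Membrane potential (mV).
#' @param E_Cl Chloride reversal potential (mV).
#' @return Current (nA).
#' @export
tonic_gabaa_current <- function(g_eGABAa, V, E_Cl) {
  if (any(g_eGABAa < 0)) stop("g_eGABAa must be >= 0")
  g_eGABAa * (V - E_Cl) * 1e-3
}
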