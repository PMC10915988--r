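# parameter-matrix column order; must match the enum in src/engine.cpp
.param_cols <- function() {
  c("C", "g_Na", "g_K", "g_leak", "E_leak", "g_KL", "g_T", "g_h", "g_CAN",
    "g_NaP", "g_M", "VT", "g_eGABAa", "E_K", "E_Na", "E_Ca", "E_h", "E_CAN",
    "E_Cl", "tau_Ca", "k_Ca", "g_GABAb_max", "noise_rate", "noise_w", "t_kin")
}

.param_matrix_from_list <- function(plist, noise_rate = 0, noise_w = 0,
                                    g_GABAb_max = 0) {
  cols <- .param_cols()
  m <- matrix(0, nrow = length(plist), ncol = length(cols),
              dimnames = list(NULL, cols))
  for (i in seq_along(plist)) {
    p <- plist[[i]]
    for (nm in setdiff(cols, c("g_GABAb_max", "noise_rate", "noise_w")))
      m[i, nm] <- p[[nm]]
  }
  m[, "noise_rate"] <- noise_rate
  m[, "noise_w"] <- noise_w
  m[, "g_GABAb_max"] <- g_GABAb_max
  m
}

#' Simulation configuration
#'
#' @param duration Simulated time (ms), > 0.
#' @param dt Integration step (ms), in (0, 0.05].
#' @param seed Integer seed controlling all run-time randomness (background
#'   drive, initial-voltage jitter).
#' @param state Behavioural state: `"transition"` (sleep-wake transition, the
#'   SWD-prone state) or `"wake"` (relaxed wakefulness). Controls the
#'   per-population potassium-leak scaling.
#' @param record_voltage_ids Neuron ids whose membrane potential is recorded
#'   at 1 kHz.
#' @return Object of class `swd_simulation_config`.
#' @export
simulation_config <- function(duration, dt = 0.05, seed = 1L,
                              state = c("transition", "wake"),
                              record_voltage_ids = integer(0)) {
  state <- match.arg(state)
  if (!is.finite(dt) || dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05]")
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  structure(list(duration = duration, dt = dt, seed = as.integer(seed),
                 state = state,
                 record_voltage_ids = as.integer(record_voltage_ids)),
            class = "swd_simulation_config")
}

#' A named conductance perturbation
#'
#' Multiplicative scaling of one conductance in one population from a given
#' onset time onward; `scale = 0` removes the current entirely.
#'
#' @param population Population selector: a population name (e.g. `"TC_FO"`,
#'   `"L5_PY"`) or a group: `"cortex"`, `"cortex_PY"`, `"cortex_IN"`,
#'   `"TC"`, `"NRT"`, `"thalamus"`.
#' @param conductance One of `g_KL`, `g_T`, `g_CAN`, `g_eGABAa` (intrinsic)
#'   or `g_AMPA`, `g_GABAa`, `g_GABAb` (receptor conductances of the target
#'   population).
#' @param scale Multiplier, >= 0.
#' @param onset Onset time (ms).
#' @return Object of class `swd_perturbation`.
#' @export
perturbation_event <- function(population, conductance, scale, onset = 0) {
  conductance <- match.arg(conductance,
    c("g_KL", "g_T", "g_CAN", "g_eGABAa", "g_AMPA", "g_GABAa", "g_GABAb"))
  if (!is.finite(scale) || scale < 0) stop("scale must be >= 0")
  structure(list(population = population, conductance = conductance,
                 scale = scale, onset = onset), class = "swd_perturbation")
}

# population selector -> neuron row indices (1-based)
.resolve_population <- function(network, population) {
  nd <- network$neurons
  idx <- switch(population,
    cortex = which(nd$is_cortical),
    cortex_PY = which(nd$is_cortical & nd$is_excitatory),
    cortex_IN = which(nd$is_cortical & !nd$is_excitatory),
    TC = which(nd$population %in% c("TC_FO", "TC_HO")),
    NRT = which(nd$population %in% c("NRT_FO", "NRT_HO")),
    thalamus = which(!nd$is_cortical),
    which(nd$population == population)
  )
  if (length(idx) == 0)
    stop("population not found in network: ", population)
  idx
}

.pert_kind <- function(conductance) {
  match(conductance,
        c("g_KL", "g_T", "g_CAN", "g_eGABAa", "g_AMPA", "g_GABAa",
          "g_GABAb")) - 1L
}

# check a conductance exists on every member of the population
.check_pert_applicable <- function(par, idx, conductance) {
  col <- switch(conductance, g_KL = "g_KL", g_T = "g_T", g_CAN = "g_CAN",
                g_eGABAa = "g_eGABAa", g_GABAb = "g_GABAb_max", NULL)
  if (!is.null(col) && any(par[idx, col] <= 0))
    stop("conductance ", conductance,
         " is not present on every neuron of the target population")
  invisible(TRUE)
}

#' Per-neuron intrinsic parameters of a network in a behavioural state
#'
#' Builds the per-neuron parameter matrix: class baselines from
#' [cell_parameters()], the state-dependent potassium-leak scaling, the
#' per-population background drive, GABA-B receptor density and mild (+/- 5%)
#' seeded heterogeneity in `g_T` and `g_KL`.
#'
#' @param network `swd_network`.
#' @param state `"transition"` or `"wake"`.
#' @return Object of class `swd_network_state`: list with the parameter
#'   `matrix` (one row per neuron), the network `neurons` table and an empty
#'   perturbation `log`.
#' @export
network_parameters <- function(network, state = "transition") {
  nd <- network$neurons
  sp <- network$config$state
  plist <- lapply(nd$cell_type, cell_parameters)
  m <- .param_matrix_from_list(plist)
  srow <- match(nd$population, sp$population)
  klf <- if (state == "transition") sp$g_KL_transition[srow] else
    sp$g_KL_wake[srow]
  m[, "g_KL"] <- m[, "g_KL"] * klf
  m[, "noise_rate"] <- sp$noise_rate[srow]
  m[, "noise_w"] <- sp$noise_w[srow]
  m[, "g_GABAb_max"] <- sp$g_GABAb_max[srow]
  het <- .with_seed(network$seed + 777L,
                    matrix(runif(2 * nrow(m), 0.95, 1.05), ncol = 2))
  m[, "g_T"] <- m[, "g_T"] * het[, 1]
  m[, "g_KL"] <- m[, "g_KL"] * het[, 2]
  structure(list(matrix = m, neurons = nd, network = network, log = list()),
            class = "swd_network_state")
}

#' Apply a perturbation to a network state
#'
#' Multiplicative and idempotent per event; `scale = 0` removes the current.
#' Parameters of all other populations are untouched.
#'
#' @param network_state `swd_network_state` from [network_parameters()].
#' @param event `swd_perturbation`.
#' @return Modified `swd_network_state` with the event appended to its log.
#' @export
apply_perturbation <- function(network_state, event) {
  stopifnot(inherits(network_state, "swd_network_state"),
            inherits(event, "swd_perturbation"))
  idx <- .resolve_population(network_state$network, event$population)
  m <- network_state$matrix
  .check_pert_applicable(m, idx, event$conductance)
  col <- switch(event$conductance,
                g_KL = "g_KL", g_T = "g_T", g_CAN = "g_CAN",
                g_eGABAa = "g_eGABAa", g_GABAb = "g_GABAb_max", NULL)
  if (!is.null(col)) {
    m[idx, col] <- m[idx, col] * event$scale
  } else {
    # receptor multipliers are realized inside the engine; record intent
    attr(m, "receptor_mult") <- c(attr(m, "receptor_mult"),
                                  list(list(idx = idx, event = event)))
  }
  network_state$matrix <- m
  network_state$log <- c(network_state$log, list(event))
  network_state
}

#' Run a network simulation
#'
#' Integrates all neurons and synapses at fixed step `dt`, applies each
#' perturbation by scaling the named conductance of every member of its
#' population from the onset onward, and records spikes, the EEG proxy
#' (negated sum of AMPA, GABA-A and GABA-B synaptic currents onto cortical
#' excitatory neurons, 1 kHz, mean-subtracted) and any requested membrane
#' potentials. Fully reproducible given (network, config, perturbations).
#'
#' @param network `swd_network`.
#' @param config `swd_simulation_config`.
#' @param perturbations List of [perturbation_event()] objects.
#' @return Object of class `swd_simulation`: `spikes` (data frame `neuron`,
#'   `time` in ms), `eeg` (1 kHz numeric), `fs`, `voltages` (matrix, one
#'   column per recorded id), `perturbation_log`, `config`, plus the neuron
#'   table and network hash.
#' @export
run_simulation <- function(network, config, perturbations = list()) {
  stopifnot(inherits(network, "swd_network"),
            inherits(config, "swd_simulation_config"))
  if (inherits(perturbations, "swd_perturbation"))
    perturbations <- list(perturbations)
  ns <- network_parameters(network, config$state)
  m <- ns$matrix

  # perturbation schedule for the engine
  onsets <- vapply(perturbations, function(e) e$onset, numeric(1))
  if (length(onsets) && any(onsets >= config$duration))
    stop("perturbation onsets must be earlier than the simulation end")
  ord <- order(onsets)
  perturbations <- perturbations[ord]
  sched <- list(onset_ms = numeric(0), kind = integer(0), idx = list(),
                scale = numeric(0))
  for (e in perturbations) {
    idx <- .resolve_population(network, e$population)
    .check_pert_applicable(m, idx, e$conductance)
    sched$onset_ms <- c(sched$onset_ms, e$onset)
    sched$kind <- c(sched$kind, .pert_kind(e$conductance))
    sched$idx <- c(sched$idx, list(as.integer(idx - 1L)))
    sched$scale <- c(sched$scale, e$scale)
  }

  # connections in CSR-by-source order
  ct <- network$connections
  ct <- ct[order(ct$pre_id), ]
  n <- nrow(network$neurons)
  rec_code <- match(ct$receptor, c("AMPA", "GABAA", "GABAB")) - 1L
  if (any(is.na(rec_code))) stop("unknown receptor in connection table")
  cnt <- tabulate(ct$pre_id, nbins = n)
  ptr <- c(0L, cumsum(cnt))
  dsteps <- pmax(1L, as.integer(round(ct$latency_ms / config$dt)))

  out <- .engine_run(m, as.integer(network$neurons$is_cortical &
                                     network$neurons$is_excitatory),
                     as.integer(ptr), as.integer(ct$post_id - 1L),
                     rec_code, as.numeric(ct$weight), dsteps,
                     sched, config$dt, config$duration, config$seed,
                     as.integer(config$record_voltage_ids - 1L),
                     numeric(0), -68, 3)

  eeg <- out$eeg - mean(out$eeg)
  spikes <- data.frame(neuron = out$spike_id + 1L, time = out$spike_t)
  spikes <- spikes[order(spikes$time, spikes$neuron), ]
  rownames(spikes) <- NULL
  res <- structure(list(
    spikes = spikes, eeg = eeg, fs = 1000,
    voltages = out$voltages, perturbation_log = perturbations,
    config = config, neurons = network$neurons,
    network_hash = network_hash(network)), class = "swd_simulation")
  res
}

#' @export
print.swd_simulation <- function(x, ...) {
  cat("<swd_simulation> ", x$config$duration / 1000, " s, ",
      nrow(x$spikes), " spikes, state=", x$config$state, ", seed=",
      x$config$seed, "\n", sep = "")
  if (length(x$perturbation_log)) {
    for (e in x$perturbation_log)
      cat("  perturbation: ", e$population, " ", e$conductance, " x",
          e$scale, " @ ", e$onset, " ms\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.swd_simulation <- function(x, ...) {
  t <- seq_along(x$eeg) / x$fs
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1)); on.exit(par(op))
  plot(t, x$eeg, type = "l", xlab = "time (s)", ylab = "EEG (a.u.)", ...)
  plot(x$spikes$time / 1000, x$spikes$neuron, pch = ".",
       xlab = "time (s)", ylab = "neuron")
  invisible(x)
}

#' Spike trains grouped by neuron
#'
#' @param sim `swd_simulation`.
#' @param population Optional population selector (as in
#'   [perturbation_event()]).
#' @return Named list of sorted spike-time vectors (ms), one per neuron id
#'   (including silent neurons as empty vectors).
#' @export
spike_trains <- function(sim, population = NULL) {
  ids <- sim$neurons$id
  if (!is.null(population)) {
    fake <- list(neurons = sim$neurons)
    ids <- sim$neurons$id[.resolve_population(fake, population)]
  }
  sp <- sim$spikes[sim$spikes$neuron %in% ids, ]
  out <- split(sp$time, factor(sp$neuron, levels = ids))
  lapply(out, function(v) if (is.null(v)) numeric(0) else sort(v))
}

#' EEG proxy from synaptic current recordings
#'
#' Pure form of the engine's EEG definition: negated sum over cortical
#' excitatory neurons of their AMPA, GABA-A and GABA-B synaptic currents,
#' block-averaged to the output rate and mean-subtracted.
#'
#' @param currents Matrix (time x neurons) of summed synaptic currents
#'   (uA/cm^2) onto cortical excitatory cells.
#' @param fs_in Sampling rate of `currents` (Hz).
#' @param fs_out Output rate (Hz), default 1000.
#' @return Numeric EEG trace.
#' @export
compute_eeg <- function(currents, fs_in, fs_out = 1000) {
  if (NCOL(currents) == 0) stop("no cortical cells recorded")
  x <- -rowSums(as.matrix(currents))
  stride <- max(1L, as.integer(round(fs_in / fs_out)))
  nb <- floor(length(x) / stride)
  y <- colMeans(matrix(x[seq_len(nb * stride)], nrow = stride))
  y - mean(y)
}
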