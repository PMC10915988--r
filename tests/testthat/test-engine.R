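test_that("simulation is deterministic given the seed and differs across seeds", {
  net <- desk_network()
  cfg <- simulation_config(duration = 2000, seed = 11)
  s1 <- run_simulation(net, cfg)
  s2 <- run_simulation(net, cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$eeg, s2$eeg)
  s3 <- run_simulation(net, simulation_config(duration = 2000, seed = 12))
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("perturbations are validated, multiplicative and local", {
  net <- desk_network()
  ns <- network_parameters(net, "transition")
  ev <- perturbation_event("TC_FO", "g_KL", 1.05)
  ns2 <- apply_perturbation(ns, ev)
  idx <- which(net$neurons$population == "TC_FO")
  expect_equal(ns2$matrix[idx, "g_KL"], ns$matrix[idx, "g_KL"] * 1.05)
  # all other rows bit-identical
  expect_identical(ns2$matrix[-idx, ], ns$matrix[-idx, ])
  # scale 1 changes nothing; scale 0 removes
  expect_equal(apply_perturbation(ns, perturbation_event("TC_FO", "g_KL", 1)
                                  )$matrix, ns$matrix)
  ns0 <- apply_perturbation(ns, perturbation_event("NRT", "g_T", 0))
  expect_true(all(ns0$matrix[net$neurons$population %in%
                               c("NRT_FO", "NRT_HO"), "g_T"] == 0))
  # conductances missing from a population are rejected
  expect_error(apply_perturbation(ns, perturbation_event("cortex",
                                                         "g_eGABAa", 2)),
               "not present")
  expect_error(perturbation_event("TC_FO", "g_KL", -1), "scale")
  expect_error(run_simulation(net, simulation_config(2000, seed = 1),
                              list(perturbation_event("TC_FO", "g_KL", 1.05,
                                                      onset = 3000))),
               "onset")
})

test_that("a cortical g_GABAa scaling reaches exactly the cortical targets", {
  net <- desk_network()
  ns <- network_parameters(net, "transition")
  ev <- perturbation_event("cortex", "g_GABAa", 0.75)
  ns2 <- apply_perturbation(ns, ev)
  # receptor multipliers are realized at run time; the event must be logged
  expect_length(ns2$log, 1)
  expect_identical(ns2$log[[1]]$conductance, "g_GABAa")
})

test_that("the EEG proxy is linear and mean-subtracted", {
  cur <- matrix(rnorm(3000), ncol = 3)
  e1 <- compute_eeg(cur, fs_in = 1000)
  e2 <- compute_eeg(2 * cur, fs_in = 1000)
  expect_equal(e2, 2 * e1, tolerance = 1e-10)
  expect_equal(mean(e1), 0, tolerance = 1e-12)
  expect_equal(compute_eeg(matrix(0, 100, 2), 1000), rep(0, 100))
  expect_error(compute_eeg(matrix(0, 100, 0), 1000), "no cortical")
  sim <- run_simulation(desk_network(), simulation_config(2000, seed = 5))
  expect_equal(mean(sim$eeg), 0, tolerance = 1e-9)
  expect_length(sim$eeg, 2000)
})

test_that("halving dt changes population firing rates by less than 5%", {
  net <- desk_network()
  r <- vapply(c(0.05, 0.025), function(dt) {
    sim <- run_simulation(net, simulation_config(duration = 5000, seed = 2,
                                                 dt = dt))
    nrow(sim$spikes) / 5
  }, numeric(1))
  expect_lt(abs(r[2] - r[1]) / r[1], 0.05)
})

test_that("with synapses and drive removed every neuron settles (no runaway)", {
  net <- desk_network()
  net$connections <- net$connections[0, ]
  cfg0 <- default_network_config("desk")
  cfg0$state$noise_rate[] <- 0
  net$config <- cfg0
  sim <- run_simulation(net, simulation_config(duration = 3000, seed = 1,
                                               record_voltage_ids = c(1, 90,
                                                                      170)))
  expect_true(all(is.finite(sim$voltages)))
  expect_true(all(abs(sim$voltages) < 130))
  # late-time drift is negligible or a bounded intrinsic oscillation
  late <- sim$voltages[2000:3000, ]
  expect_true(all(apply(late, 2, function(v) diff(range(v))) < 120))
})

test_that("spike times are within bounds and sorted per neuron", {
  sim <- run_simulation(desk_network(), simulation_config(2000, seed = 8))
  expect_true(all(sim$spikes$time >= 0 & sim$spikes$time <= 2000))
  st <- spike_trains(sim)
  expect_true(all(vapply(st, function(v) !is.unsorted(v), logical(1))))
  # refractoriness: no ISI below 2 ms
  isi <- unlist(lapply(st, diff))
  if (length(isi)) expect_gte(min(isi), 2)
})
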