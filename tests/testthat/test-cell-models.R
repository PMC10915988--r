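test_that("gating steady states are bounded, monotone and hit half-activation", {
  V <- seq(-120, 40, by = 0.5)
  for (pair in list(c("I_T", "m"), c("I_T", "h"), c("I_T_NRT", "m"),
                    c("I_h", "h"), c("I_NaP", "m"))) {
    x <- gating_steady_state(pair[1], pair[2], V)
    expect_true(all(x >= 0 & x <= 1), info = paste(pair, collapse = "/"))
  }
  # activation increases, inactivation decreases
  expect_true(all(diff(gating_steady_state("I_T", "m", V)) >= 0))
  expect_true(all(diff(gating_steady_state("I_T", "h", V)) <= 0))
  # extremes of the T current
  expect_lt(gating_steady_state("I_T", "m", -120), 0.01)
  expect_gt(gating_steady_state("I_T", "h", -120), 0.99)
  # the implemented half-activation voltage, found by root-finding, maps to 0.5
  vhalf <- uniroot(function(v) gating_steady_state("I_T", "m", v) - 0.5,
                   c(-90, -20))$root
  expect_equal(gating_steady_state("I_T", "m", vhalf), 0.5, tolerance = 1e-6)
  expect_error(gating_steady_state("I_T", "z", -60), "unknown")
  expect_error(gating_steady_state("I_X", "m", -60), "unknown")
})

test_that("membrane derivative reduces to the passive cases", {
  p0 <- cell_parameters("RS", list(g_Na = 0, g_K = 0, g_M = 0, g_leak = 0,
                                   g_KL = 0))
  st <- cell_state(p0, V = -63)
  expect_equal(membrane_derivative(st, p0)$dV, 0)
  pl <- cell_parameters("RS", list(g_Na = 0, g_K = 0, g_M = 0, g_KL = 0,
                                   g_leak = 0.05))
  st <- cell_state(pl, V = pl$E_leak)
  expect_equal(membrane_derivative(st, pl)$dV, 0)
})

test_that("passive step response matches the RC closed form within 1%", {
  g <- 0.05
  p <- cell_parameters("RS", list(g_Na = 0, g_K = 0, g_M = 0, g_KL = 0,
                                  g_leak = g))
  amp <- -0.5
  tr <- simulate_current_clamp(p, data.frame(amplitude = amp, onset = 200,
                                             offset = 1200),
                               duration = 1400)
  v_rest <- tr$V[190]
  v_step <- tr$V[1190]          # ~1 s into the step: fully settled
  expect_equal(v_step - v_rest, amp / g, tolerance = 0.01)
  # exponential time course: at one membrane time constant, ~63% of the step
  tau <- p$C / g
  v_tau <- tr$V[200 + round(tau)]
  expect_equal((v_tau - v_rest) / (amp / g), 1 - exp(-1), tolerance = 0.05)
})

test_that("every cell class expresses its intended firing signature", {
  want <- expected_signatures()
  for (ct in cell_types()) {
    got <- firing_signature(ct)$signature
    expect_identical(got, unname(want[ct]), label = ct)
  }
})

test_that("rebound bursting requires the T conductance and returns with it", {
  base <- firing_signature("TC_FO")
  expect_identical(base$signature, "rebound_burst")
  no_t <- firing_signature("TC_FO", list(g_T = 0))
  expect_false(identical(no_t$signature, "rebound_burst"))
  back <- firing_signature("TC_FO", list(g_T = cell_parameters("TC_FO")$g_T))
  expect_identical(back$signature, "rebound_burst")
})

test_that("raising the potassium leak hyperpolarizes the resting potential", {
  rest <- vapply(c(0.01, 0.02, 0.04), function(gkl) {
    p <- cell_parameters("TC_FO", list(g_KL = gkl))
    tr <- simulate_current_clamp(p, data.frame(amplitude = 0, onset = 0,
                                               offset = 0), duration = 2000)
    tail(tr$V, 1)
  }, numeric(1))
  expect_true(all(diff(rest) < 0))
})

test_that("single-cell integration stays bounded over long runs", {
  for (ct in c("TC_FO", "NRT_FO", "RS", "FS")) {
    p <- cell_parameters(ct)
    tr <- simulate_current_clamp(
      p, data.frame(amplitude = c(0.4, -0.4), onset = c(1000, 5000),
                    offset = c(4000, 8000)),
      duration = 10000, dt = 0.025)
    expect_true(all(is.finite(tr$V)), label = ct)
    expect_true(all(tr$V > -130 & tr$V < 80), label = ct)
  }
})

test_that("the firing classifier implements its stated criteria", {
  flat <- structure(list(time = 1:1000, V = rep(-70, 1000),
                         spike_times = numeric(0)),
                    class = "swd_trace")
  expect_identical(classify_firing_signature(flat), "none")
  # 3 APs at 4 ms ISIs at stimulus onset = burst
  expect_identical(
    classify_firing_signature(rep(-70, 2000), spike_times = c(210, 214, 218),
                              dt = 1, stim_onset = 200),
    "intrinsic_burst")
  # regular tonic spikes, low CV, no adaptation = fast spiking
  expect_identical(
    classify_firing_signature(rep(-70, 2000),
                              spike_times = seq(210, 1200, by = 25), dt = 1),
    "fast_spiking")
  expect_error(classify_firing_signature(numeric(0), numeric(0), dt = 1),
               "empty")
})

test_that("current-clamp rejects invalid steps and is deterministic", {
  p <- cell_parameters("RS")
  expect_error(simulate_current_clamp(p, data.frame(amplitude = 1, onset = 0,
                                                    offset = 100), dt = 0.2),
               "dt")
  expect_error(simulate_current_clamp(p, data.frame(amplitude = Inf,
                                                    onset = 0, offset = 100)),
               "finite")
  pr <- data.frame(amplitude = 0.8, onset = 100, offset = 600)
  t1 <- simulate_current_clamp(p, pr, duration = 800)
  t2 <- simulate_current_clamp(p, pr, duration = 800)
  expect_identical(t1$V, t2$V)
  expect_identical(t1$spike_times, t2$spike_times)
})
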