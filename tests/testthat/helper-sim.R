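# Shared light-weight objects for the unit tests. Heavy (multi-minute)
# simulations live only in test-acceptance.R, behind a per-session cache.

desk_network <- local({
  net <- NULL
  function(seed = 1L) {
    if (is.null(net) || net$seed != seed)
      net <<- build_default_network(default_network_config("desk"), seed)
    net
  }
})

# a small synthetic recording used across analysis tests
fixture_recording <- local({
  cache <- list()
  function(freq = 4, noise = 0.3, seed = 1) {
    key <- paste(freq, noise, seed)
    if (is.null(cache[[key]])) {
      spec <- synthetic_swd_spec(swd_frequency = freq, n_seizures = 3,
                                 seizure_durations = 8,
                                 interictal_durations = 8,
                                 noise_sd = noise, seed = seed)
      eeg <- generate_synthetic_eeg(spec)
      cache[[key]] <<- list(spec = spec, eeg = eeg)
    }
    cache[[key]]
  }
})
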