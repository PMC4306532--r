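# Shared fixtures, built in code. Small configurations keep the suite fast;
# the methods vignette documents the problem sizes used.

# minimal behavioral-only configuration (no sources, tiny epochs)
quick_config <- function(n_trials = 200, seed = 1, n_blocks = 4,
                         epoch_window = c(-1.1, 0.3), ...) {
  sim_config(n_trials = n_trials, n_blocks = n_blocks, seed = seed,
             epoch_window = epoch_window, n_channels = 12, ...)
}

# one coupled occipital-like source; short epochs for beamformer tests
coupled_config <- function(n_trials = 200, r = 0.2, seed = 1, n_channels = 30,
                           bandwidth = 10, ...) {
  src <- ground_truth_source(position = mni_to_head(c(8, -83, 6)),
                             center_freq = 10, bandwidth = bandwidth,
                             rt_coupling_r = r)
  sim_config(n_trials = n_trials, n_blocks = 4, seed = seed,
             epoch_window = c(-1.2, 0.2), n_channels = n_channels,
             source_specs = list(src), ...)
}

default_sensors <- function(epochs) {
  list(positions = epochs$channel_positions,
       orientations = epochs$channel_orientations)
}

# analytic two-sided power of the one-sample t-test
t_test_power <- function(mu, sd, n, alpha = 0.05) {
  ncp <- mu / (sd / sqrt(n))
  crit <- qt(1 - alpha / 2, df = n - 1)
  pt(-crit, df = n - 1, ncp = ncp) + 1 - pt(crit, df = n - 1, ncp = ncp)
}
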