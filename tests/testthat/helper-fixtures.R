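# Shared fixtures, built in code.  Simulations here are shortened relative to
# the reference protocols (100 s -> a few s) to keep the suite fast; the
# corresponding tolerances are widened accordingly and stated per test.

ngs_params <- function() neuron_params("NGS")
gs_params <- function() neuron_params("GS")

# a neuron with active conductances removed (passive membrane)
passive_params <- function() neuron_params("NGS", g_na = 0, g_k = 0)

# LN characterization shortcut: OU drive -> spikes -> STA -> nonlinearity
fit_ln <- function(params, dc, sigma, dur_s, seed, window = 75, bins = 25) {
  stim <- ou_process(dc, sigma, duration = dur_s * 1000, seed = seed)
  sim <- simulate_neuron(params, stim)
  sta <- compute_sta(stim, sim$spikes, window = window)
  fs <- filter_stimulus(stim, sta)
  nl <- estimate_nonlinearity(fs, sim$spikes, bins = bins)
  list(stim = stim, sim = sim, sta = sta, fs = fs, nl = nl)
}

# hand-made fi_family for synthetic map tests
make_fi_family <- function(dc_grid, sigma_grid, rates) {
  structure(list(dc_grid = dc_grid, sigma_grid = sigma_grid,
                 rates = rates, counts = rates, duration = Inf,
                 type = "synthetic"),
            class = "fi_family")
}

# fake ln_nonlinearity with prescribed normalized abscissa and rates
make_nl <- function(centers_norm, rate, occupancy = rep(1, length(rate))) {
  structure(list(bin_centers = centers_norm, bin_centers_norm = centers_norm,
                 rate = rate, occupancy = occupancy,
                 n_spike = rate, mean_rate = mean(rate), sigma_s = 1,
                 edges = NULL, dt = 0.025),
            class = "ln_nonlinearity")
}
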