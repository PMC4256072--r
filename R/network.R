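# Layered feedforward network of conductance-based neurons coupled by
# exponential conductance synapses.  Layer 1 receives the common stimulus;
# deeper layers receive synaptic input from the previous layer.  Every neuron
# receives independent OU noise.

#' Feedforward network configuration
#'
#' @param n_layers number of layers (reference: 10).
#' @param n_per_layer neurons per layer (reference: 2000; desk scale 200 with
#'   `w` rescaled so that `p * N * w` is preserved).
#' @param p connection probability between consecutive layers (reference 0.05).
#' @param w synaptic strength: conductance increment per presynaptic spike,
#'   pS/um^2.  `"weak"` and `"strong"` select the stored values.
#' @param tau_syn synaptic decay time constant, ms.
#' @param e_ex excitatory reversal potential, mV.
#' @param noise_sigma sd of per-neuron OU noise, pA.
#' @param seed integer seed for connectivity and noise streams.
#' @return an object of class `network_config`.
#' @export
network_config <- function(n_layers = NULL, n_per_layer = NULL, p = NULL,
                           w = c("strong", "weak"), tau_syn = NULL,
                           e_ex = NULL, noise_sigma = NULL, seed = 1) {
  const <- model_constants()
  net <- const$network
  syn <- const$synapse
  if (is.character(w)) {
    w <- match.arg(w)
    w <- if (w == "weak") syn$w_weak else syn$w_strong
  }
  cfg <- list(n_layers = n_layers %||% net$n_layers,
              n_per_layer = n_per_layer %||% net$n_per_layer,
              p = p %||% net$p_connect,
              w = w,
              tau_syn = tau_syn %||% syn$tau_syn,
              e_ex = e_ex %||% syn$e_ex,
              noise_sigma = noise_sigma %||% net$noise_sigma,
              seed = seed)
  stopifnot(cfg$p >= 0, cfg$p <= 1, cfg$w >= 0, cfg$tau_syn > 0,
            cfg$n_layers >= 1, cfg$n_per_layer >= 1, cfg$noise_sigma >= 0)
  class(cfg) <- "network_config"
  cfg
}

#' Rescale a network while preserving the mean-field drive
#'
#' Changes the layer size to `n_new` and rescales the synaptic strength so
#' that the product `p * N * w` (and hence the mean-field slope eta) is
#' unchanged.
#'
#' @param config a [network_config()].
#' @param n_new new layer size.
#' @return a rescaled `network_config`.
#' @export
scale_network <- function(config, n_new) {
  config$w <- config$w * config$n_per_layer / n_new
  config$n_per_layer <- as.integer(n_new)
  config
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> %d layers x %d neurons, p = %g, w = %g pS/um^2 (pNw = %.3g)\n",
              x$n_layers, x$n_per_layer, x$p, x$w, x$p * x$n_per_layer * x$w))
  cat(sprintf("  tau_syn %g ms, E_ex %g mV, noise sigma %g pA\n",
              x$tau_syn, x$e_ex, x$noise_sigma))
  invisible(x)
}

#' Draw random feedforward connectivity
#'
#' Each (pre, post) pair across consecutive layers is connected independently
#' with probability `p`.  No recurrence, no self-connections; layer 1 has no
#' presynaptic set.
#'
#' @param config a [network_config()].
#' @param seed integer seed (defaults to the config's).
#' @return a list over layers `2..L`; element `l-1` is a list over
#'   postsynaptic neurons of integer vectors of presynaptic indices.
#' @export
build_connectivity <- function(config, seed = config$seed) {
  N <- config$n_per_layer
  with_seed(derive_seed(seed, "connectivity"), {
    lapply(seq_len(config$n_layers - 1), function(l)
      lapply(seq_len(N), function(post) which(runif(N) < config$p)))
  })
}

#' Simulate the feedforward network
#'
#' Layer 1 receives the supplied stimulus plus per-neuron OU noise; deeper
#' layers receive conductance-based synaptic input (conductance jumps by `w`
#' at each presynaptic spike, decays with `tau_syn`; synaptic current is
#' `g_syn (E_ex - V)`) plus the same independent noise.  Spikes are delivered
#' with a one-integration-step delay; layers advance strictly feedforward.
#'
#' @param params a [neuron_params()] object (all neurons identical).
#' @param config a [network_config()].
#' @param stimulus a `stimulus` driving layer 1 (include any DC via
#'   [compose_stimuli()]).
#' @param connectivity output of [build_connectivity()]; drawn from the config
#'   seed when omitted.
#' @param seed integer seed for the noise streams.
#' @param burn_in discarded initial time, ms.
#' @param keep_spikes return per-neuron spike trains (set `FALSE` to save
#'   memory in large sweeps).
#' @param record_gsyn record the synaptic conductance trace of the first
#'   neuron of each layer (steps x layers matrix, pS/um^2).
#' @return an object of class `layer_activity`.
#' @export
simulate_network <- function(params, config, stimulus, connectivity = NULL,
                             seed = config$seed, burn_in = 1000,
                             keep_spikes = TRUE, record_gsyn = FALSE) {
  if (is.null(connectivity)) connectivity <- build_connectivity(config)
  stopifnot(length(connectivity) == config$n_layers - 1)
  dt <- stimulus$dt
  duration <- length(stimulus$values) * dt
  tau_ou <- model_constants()$stimulus$tau_ou
  out <- cpp_network(unclass(params), connectivity, config$n_layers,
                     config$n_per_layer, stimulus$values, config$noise_sigma,
                     tau_ou, config$w, config$tau_syn, config$e_ex, dt,
                     duration, derive_seed(seed, "network-noise"),
                     params$spike_threshold, params$refractory,
                     min(burn_in, duration / 2), keep_spikes, record_gsyn)
  spikes <- if (keep_spikes)
    lapply(out$spikes, function(layer)
      lapply(layer, spike_train, duration = duration))
  structure(list(spikes = spikes,
                 gsyn = if (record_gsyn) out$gsyn,
                 mean_rate = out$mean_rate, rates = out$rates,
                 isyn_mean = out$isyn_mean, isyn_sd = out$isyn_sd,
                 ev_mean = out$ev_mean, subv_sd = out$subv_sd,
                 duration = duration, burn_in = min(burn_in, duration / 2),
                 dt = dt, config = config),
            class = "layer_activity")
}

#' @export
print.layer_activity <- function(x, ...) {
  cat(sprintf("<layer_activity> %d layers x %d neurons, %.3g s\n",
              x$config$n_layers, x$config$n_per_layer, x$duration / 1000))
  cat("  mean rates (Hz):", paste(sprintf("%.1f", x$mean_rate), collapse = " "), "\n")
  invisible(x)
}

#' Population PSTH of one layer
#'
#' Population spike histogram divided by `N * bin_width` (Hz), then
#' z-normalized to zero mean and unit variance; the raw histogram is retained.
#'
#' @param activity a `layer_activity` with spikes kept.
#' @param layer layer index.
#' @param bin_width bin width, ms.
#' @param from start time, ms (defaults to the burn-in).
#' @return an object of class `psth`: `time` (bin centres, ms), `raw` (Hz),
#'   `values` (normalized), `bin_width`.
#' @export
compute_psth <- function(activity, layer, bin_width = 10, from = NULL) {
  if (is.null(activity$spikes)) stop("activity was simulated without spikes")
  from <- from %||% activity$burn_in
  sp <- unlist(lapply(activity$spikes[[layer]], `[[`, "times"))
  sp <- sp[sp >= from]
  edges <- seq(from, activity$duration, by = bin_width)
  if (length(edges) < 3) stop("need at least 2 bins")
  if (!length(sp)) stop("silent-layer: no spikes in layer ", layer)
  counts <- hist_counts(sp, edges)
  raw <- 1000 * counts / (activity$config$n_per_layer * bin_width)
  vals <- (raw - mean(raw)) / sd(raw)
  structure(list(time = (edges[-1] + edges[-length(edges)]) / 2, raw = raw,
                 values = vals, bin_width = bin_width), class = "psth")
}

#' Per-layer summary statistics
#'
#' Time-and-population averages after burn-in: mean firing rate, mean and sd
#' of the synaptic current (the sd feeds the effective-noise combination of
#' the mean field), mean subthreshold driving force `<E_ex - V>` and
#' subthreshold voltage sd (which feed the eta estimate).
#'
#' @param activity a `layer_activity`.
#' @return a data.frame with one row per layer.
#' @export
layer_statistics <- function(activity) {
  data.frame(layer = seq_along(activity$mean_rate),
             mean_rate = activity$mean_rate,
             isyn_mean = activity$isyn_mean,
             isyn_sd = activity$isyn_sd,
             ev_mean = activity$ev_mean,
             subv_sd = activity$subv_sd)
}
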