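# Single-neuron and population simulation: first-order Euler integration of
# the conductance-based model, spike detection, excitability classification
# and the noise-parameterized f-I surface.

#' Construct a spike train
#'
#' @param times spike times, ms, strictly increasing within `[0, duration)`.
#' @param duration recording length, ms.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  stopifnot(duration > 0)
  if (length(times)) {
    if (any(diff(times) <= 0)) stop("spike times must be strictly increasing")
    if (any(times < 0) || any(times >= duration))
      stop("spike times must lie in [0, duration)")
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3g s (%.2f Hz)\n",
              length(x$times), x$duration / 1000,
              1000 * length(x$times) / x$duration))
  invisible(x)
}

#' Integrate the conductance-based neuron
#'
#' Forward-Euler integration of the four-variable model driven by a current
#' stimulus.  The scheme keeps the gating variables inside `[0, 1]` without
#' clamping; a post-hoc check errors if any gate leaves the unit interval by
#' more than `1e-6`.
#'
#' @param params a [neuron_params()] object.
#' @param stimulus a `stimulus` object (current in pA).
#' @param init optional initial state `c(v, m, h, n)`; defaults to rest.
#' @param dt integration step, ms; defaults to the stimulus sampling step.
#' @return list with `time`, `v`, `m`, `h`, `n` traces and `spikes`
#'   (a [spike_train()]).
#' @export
simulate_neuron <- function(params, stimulus, init = NULL, dt = NULL) {
  if (is.null(dt)) dt <- stimulus$dt
  if (abs(dt - stimulus$dt) > 1e-12)
    stop("stimulus must be sampled at the integration step")
  if (is.null(init)) {
    r <- resting_state(params)
    init <- c(r$v_rest, r$m, r$h, r$n)
  }
  stopifnot(length(init) == 4, all(init[2:4] >= 0), all(init[2:4] <= 1))
  out <- cpp_integrate(unclass(params), stimulus$values, dt, init,
                       params$spike_threshold, params$refractory)
  gates <- c(out$m, out$h, out$n)
  if (any(gates < -1e-6) || any(gates > 1 + 1e-6))
    stop("gating variable left [0,1]: the integration step is too coarse")
  n <- length(out$v)
  list(time = seq_len(n) * dt, v = out$v, m = out$m, h = out$h, n = out$n,
       spikes = spike_train(out$spikes, n * dt))
}

#' Detect spikes in a voltage trace
#'
#' One spike per strict upward crossing of the threshold, with a refractory
#' lockout to avoid double counts on noisy upstrokes.
#'
#' @param v voltage trace, mV, uniformly sampled.
#' @param dt sample interval, ms.
#' @param threshold detection threshold, mV (default -20).
#' @param refractory lockout after a detected spike, ms.
#' @return a [spike_train()].
#' @export
detect_spikes <- function(v, dt, threshold = -20, refractory = 2) {
  above <- v >= threshold
  up <- which(above & !c(FALSE, above[-length(above)]))
  times <- (up - 1) * dt
  if (length(times) > 1) {
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= refractory) { keep[i] <- TRUE; last <- times[i] }
    }
    times <- times[keep]
  }
  spike_train(times, length(v) * dt)
}

#' Simulate a population of independent neurons
#'
#' Every neuron receives the same common current plus an independent
#' Ornstein-Uhlenbeck noise current generated internally (correlation time
#' `tau_ou`).  Used for population responses to ramps and slow signals and
#' as the source of subthreshold voltage statistics for the mean field.
#'
#' @param params a [neuron_params()] object.
#' @param n_neurons population size.
#' @param common optional shared `stimulus`; `NULL` means constant `dc`.
#' @param dc constant current added to every neuron, pA.
#' @param noise_sigma sd of the per-neuron OU noise, pA.
#' @param duration simulated time, ms (required when `common` is `NULL`).
#' @param seed integer seed; per-neuron streams are derived from it.
#' @param burn_in discarded initial time, ms.
#' @return list with per-neuron `spikes` (list of [spike_train()]), `rate`
#'   (Hz, after burn-in), and subthreshold voltage statistics `sub_mean`,
#'   `sub_sd` (mV).
#' @export
simulate_population <- function(params, n_neurons, common = NULL, dc = 0,
                                noise_sigma = 0, duration = NULL, seed = 1,
                                burn_in = 1000) {
  dt <- if (!is.null(common)) common$dt else params$dt
  if (is.null(duration)) {
    if (is.null(common)) stop("duration required without a common stimulus")
    duration <- length(common$values) * dt
  }
  tau_ou <- model_constants()$stimulus$tau_ou
  out <- cpp_population(unclass(params),
                        if (is.null(common)) numeric(1) else common$values,
                        dc, noise_sigma, tau_ou, n_neurons, dt, duration,
                        seed, params$spike_threshold, params$refractory,
                        min(burn_in, duration / 2))
  out$spikes <- lapply(out$spikes, spike_train, duration = duration)
  out$duration <- duration
  out$dt <- dt
  out
}

#' Noise-parameterized f-I surface
#'
#' Mean firing rate over a grid of mean current (DC) and noise amplitude
#' (sigma) values, each cell estimated from an independent OU-driven
#' simulation.  This surface is the object the mean-field iterated map and
#' the information analyses consume.
#'
#' @param params a [neuron_params()] object.
#' @param dc_grid mean currents, pA (paper grid: 0 to 120 by 2.5).
#' @param sigma_grid noise amplitudes, pA (paper grid: 5 to 150 by 2.5).
#' @param duration seconds simulated per cell (reference: 100 s).
#' @param burn_in seconds discarded per cell.
#' @param seed integer seed.
#' @param dt integration step, ms.
#' @return an object of class `fi_family` with fields `dc_grid`,
#'   `sigma_grid`, `rates` (Hz, dc x sigma), `counts`, `duration`.
#' @export
fi_surface <- function(params, dc_grid, sigma_grid, duration = 100,
                       burn_in = 1, seed = 1, dt = params$dt) {
  stopifnot(length(dc_grid) >= 1, length(sigma_grid) >= 1,
            duration > burn_in, !is.unsorted(dc_grid), !is.unsorted(sigma_grid))
  tau_ou <- model_constants()$stimulus$tau_ou
  out <- cpp_fi(unclass(params), dc_grid, sigma_grid, duration * 1000, dt,
                burn_in * 1000, seed, tau_ou, params$spike_threshold,
                params$refractory)
  structure(list(dc_grid = dc_grid, sigma_grid = sigma_grid,
                 rates = out$rates, counts = out$counts,
                 duration = duration - burn_in, type = params$type),
            class = "fi_family")
}

#' @export
print.fi_family <- function(x, ...) {
  cat(sprintf("<fi_family> %s: %d DC x %d sigma cells, %.3g s each; rates %.2f-%.2f Hz\n",
              x$type %||% "?", length(x$dc_grid), length(x$sigma_grid),
              x$duration, min(x$rates), max(x$rates)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify excitability of a parameter set
#'
#' Deterministic (noise-free) classification: `spontaneous` if the neuron
#' fires tonically at zero current, `excitable` if silent at zero current but
#' driven to fire by some tested DC, `silent` otherwise.
#'
#' @param params a [neuron_params()] object.
#' @param dc_max largest tested DC, pA.
#' @param dc_step grid step for the tested DCs, pA.
#' @param duration test length per DC, s.
#' @param settle initial time ignored when looking for tonic firing, s.
#' @return one of `"spontaneous"`, `"excitable"`, `"silent"`.
#' @export
classify_excitability <- function(params, dc_max = 120, dc_step = 10,
                                  duration = 2, settle = 0.5) {
  fires_at <- function(dc) {
    sim <- simulate_population(params, 1, dc = dc, noise_sigma = 0,
                               duration = duration * 1000, seed = 1,
                               burn_in = settle * 1000)
    any(sim$spikes[[1]]$times > settle * 1000)
  }
  if (fires_at(0)) return("spontaneous")
  for (dc in seq(dc_step, dc_max, by = dc_step))
    if (fires_at(dc)) return("excitable")
  "silent"
}
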