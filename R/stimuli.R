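# Synthetic stimulus generators: the pipeline's only data source.  Every
# stimulus records its generator name, parameters and seed so that it can be
# regenerated bit-identically.

new_stimulus <- function(values, dt, kind, pars, seed = NULL) {
  stopifnot(length(values) >= 1, all(is.finite(values)), dt > 0)
  structure(list(values = as.numeric(values), dt = dt,
                 metadata = list(kind = kind, pars = pars, seed = seed)),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus> %s: %d samples at dt = %g ms (%.3g s), mean %.3g pA, sd %.3g pA\n",
              x$metadata$kind, length(x$values), x$dt,
              length(x$values) * x$dt / 1000, mean(x$values), sd(x$values)))
  invisible(x)
}

#' Ornstein-Uhlenbeck current noise
#'
#' Gaussian noise with exponential autocorrelation (correlation time `tau`,
#' default 1 ms to mimic fast synaptic fluctuations).  Uses the exact
#' discretization `x[t+1] = mu + rho (x[t]-mu) + sigma sqrt(1-rho^2) xi`,
#' `rho = exp(-dt/tau)`, so the process is stationary from the first sample
#' with stationary sd exactly `sigma` for any `dt`.
#'
#' @param mean stationary mean, pA.
#' @param sd stationary standard deviation, pA.
#' @param tau correlation time, ms.
#' @param duration length, ms.
#' @param dt sample interval, ms (must be < tau/2).
#' @param seed integer seed.
#' @return a `stimulus` object.
#' @export
ou_process <- function(mean = 0, sd, tau = 1, duration, dt = 0.025, seed = 1) {
  stopifnot(sd >= 0, tau > 0, dt < tau / 2)
  n <- round(duration / dt)
  if (sd == 0) {
    vals <- rep(mean, n)
  } else {
    rho <- exp(-dt / tau)
    sq <- sd * sqrt(1 - rho^2)
    vals <- with_seed(seed, {
      innov <- rnorm(n)
      drive <- c(sd * innov[1], sq * innov[-1])
      as.numeric(stats::filter(drive, rho, method = "recursive")) + mean
    })
  }
  new_stimulus(vals, dt, "ou",
               list(mean = mean, sd = sd, tau = tau, duration = duration, dt = dt),
               seed)
}

#' Band-limited slow common signal
#'
#' Sum of harmonics of `1/T` up to the cutoff frequency (default 1 Hz, giving
#' a correlation time of order 1 s), with equal amplitudes and independent
#' random phases uniform in `[0, 2pi)`, scaled to a requested standard
#' deviation.  The spectrum is exactly zero above the cutoff and the mean over
#' the full window is zero to machine precision.
#'
#' @param duration length, s.
#' @param cutoff highest frequency component, Hz.
#' @param sd target standard deviation, pA.
#' @param dt sample interval, ms.
#' @param seed integer seed.
#' @return a `stimulus` object.
#' @export
slow_signal <- function(duration, cutoff = 1, sd = 1, dt = 0.025, seed = 1) {
  stopifnot(duration >= 2 / cutoff, sd >= 0)
  n <- round(duration * 1000 / dt)
  t_s <- (seq_len(n) - 1) * dt / 1000
  n_harm <- max(1, floor(cutoff * duration))
  vals <- with_seed(seed, {
    phases <- runif(n_harm, 0, 2 * pi)
    x <- numeric(n)
    for (j in seq_len(n_harm))
      x <- x + cos(2 * pi * j * t_s / duration + phases[j])
    x
  })
  raw_sd <- sqrt(n_harm / 2)          # analytic sd of the equal-amplitude comb
  vals <- vals * (sd / raw_sd)
  new_stimulus(vals, dt, "slow",
               list(duration = duration, cutoff = cutoff, sd = sd, dt = dt),
               seed)
}

#' Triangular ramp stimulus
#'
#' Piecewise-linear rise to `peak` over `rise_time` followed by a symmetric
#' linear fall, zero afterwards.
#'
#' @param rise_time time to peak, ms.
#' @param peak peak current, pA.
#' @param duration total length, ms.
#' @param dt sample interval, ms.
#' @return a `stimulus` object.
#' @export
ramp_stimulus <- function(rise_time = 50, peak, duration, dt = 0.025) {
  stopifnot(rise_time <= duration, rise_time > 0)
  tt <- (seq_len(round(duration / dt)) - 1) * dt
  vals <- ifelse(tt <= rise_time, peak * tt / rise_time,
                 ifelse(tt <= 2 * rise_time, peak * (2 - tt / rise_time), 0))
  new_stimulus(vals, dt, "ramp",
               list(rise_time = rise_time, peak = peak, duration = duration, dt = dt))
}

#' Low-pass-filtered Gaussian stimulus
#'
#' White Gaussian noise passed through a single-pole exponential filter with
#' time constant `tau_filter` (default 500 ms), recentred to zero mean and
#' rescaled to the requested post-filter standard deviation.
#'
#' @param duration length, s.
#' @param tau_filter filter time constant, ms.
#' @param sd post-filter standard deviation, pA.
#' @param dt sample interval, ms.
#' @param seed integer seed.
#' @return a `stimulus` object.
#' @export
lowpass_gaussian <- function(duration, tau_filter = 500, sd, dt = 0.025, seed = 1) {
  stopifnot(duration * 1000 > 4 * tau_filter, sd >= 0)
  n <- round(duration * 1000 / dt)
  if (sd == 0) return(new_stimulus(rep(0, n), dt, "lowpass",
                                   list(duration = duration, tau_filter = tau_filter,
                                        sd = sd, dt = dt), seed))
  a <- exp(-dt / tau_filter)
  vals <- with_seed(seed, {
    innov <- rnorm(n)
    as.numeric(stats::filter(c(innov[1], (1 - a) * innov[-1]), a,
                             method = "recursive"))
  })
  vals <- vals - mean(vals)
  vals <- vals * (sd / sd(vals))
  new_stimulus(vals, dt, "lowpass",
               list(duration = duration, tau_filter = tau_filter, sd = sd, dt = dt),
               seed)
}

#' Combine stimuli and a DC offset
#'
#' Pointwise sum of stimuli sharing the same `dt` and length, plus a constant
#' offset.  Metadata of the parts is concatenated so the composite remains
#' regenerable.
#'
#' @param dc constant offset, pA.
#' @param ... `stimulus` objects of identical `dt` and length.
#' @return a `stimulus` object.
#' @export
compose_stimuli <- function(dc = 0, ...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  dts <- vapply(parts, function(p) p$dt, 0)
  lens <- vapply(parts, function(p) length(p$values), 0L)
  if (length(unique(dts)) != 1 || length(unique(lens)) != 1)
    stop("incompatible-stimuli: parts differ in dt or length")
  vals <- Reduce(`+`, lapply(parts, `[[`, "values")) + dc
  new_stimulus(vals, dts[1], "composite",
               list(dc = dc, parts = lapply(parts, `[[`, "metadata")))
}

#' Regenerate a stimulus from its metadata
#'
#' @param stim a `stimulus` object.
#' @return a new `stimulus`, bit-identical to the original.
#' @export
regenerate <- function(stim) {
  md <- stim$metadata
  p <- md$pars
  switch(md$kind,
    ou = ou_process(p$mean, p$sd, p$tau, p$duration, p$dt, md$seed),
    slow = slow_signal(p$duration, p$cutoff, p$sd, p$dt, md$seed),
    ramp = ramp_stimulus(p$rise_time, p$peak, p$duration, p$dt),
    lowpass = lowpass_gaussian(p$duration, p$tau_filter, p$sd, p$dt, md$seed),
    stop("cannot regenerate stimulus of kind ", md$kind))
}
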