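# Voltage-dependent gating kinetics.  Rates are linoid ("trap") functions of
# voltage; amplitudes are stored in s^-1 mV^-1 in the parameter file and
# converted to ms^-1 here.  The inactivation gate h has, in addition to its
# alpha/beta rates (which set tau_h), a dedicated steady-state sigmoid.

linoid <- function(v, amplitude, v_half, k, up = TRUE) {
  A <- amplitude / 1000
  x <- if (up) v - v_half else v_half - v
  out <- A * x / (1 - exp(-x / k))
  sing <- !is.finite(out) | abs(x) < 1e-9
  out[sing] <- A * k    # analytic limit at the removable singularity
  out
}

.rate_eval <- function(v, spec) {
  linoid(v, spec$amplitude, spec$v_half, spec$k, up = spec$form == "linoid_up")
}

#' Opening and closing rate coefficients of a gate
#'
#' Evaluates the voltage-dependent forward (`alpha`) and backward (`beta`)
#' rate coefficients of one gating variable.  Linoid singularities are
#' evaluated by their analytic limit.
#'
#' @param v membrane potential(s), mV.
#' @param gate one of `"m"`, `"h"`, `"n"`.
#' @param kinetics kinetic constants, e.g. `neuron_params(...)$kinetics`.
#' @return a list with vectors `alpha` and `beta` in ms^-1.
#' @export
rate_coefficients <- function(v, gate, kinetics = model_constants()$kinetics) {
  if (!gate %in% c("m", "h", "n")) stop("invalid-gate: ", gate)
  g <- kinetics[[gate]]
  list(alpha = .rate_eval(v, g$alpha), beta = .rate_eval(v, g$beta))
}

#' Steady-state value and time constant of a gate
#'
#' For `m` and `n`, `x_inf = alpha/(alpha+beta)`; for `h`, the steady state
#' comes from its dedicated sigmoid while `tau_h = 1/(alpha+beta)` still comes
#' from the rates.
#'
#' @inheritParams rate_coefficients
#' @return a list with vectors `x_inf` (dimensionless) and `tau` (ms).
#' @export
gate_steady_state <- function(v, gate, kinetics = model_constants()$kinetics) {
  r <- rate_coefficients(v, gate, kinetics)
  tot <- r$alpha + r$beta
  x_inf <- if (gate == "h") {
    ss <- kinetics$h$steady_state
    1 / (1 + exp((v - ss$v_half) / ss$k))
  } else r$alpha / tot
  list(x_inf = x_inf, tau = 1 / tot)
}

# Steady-state membrane current density (uA/cm^2) with all gates relaxed;
# positive values depolarize.  Used for resting state and fixed-point work.
steady_state_current <- function(p, v, i_pA = 0) {
  kin <- p$kinetics
  minf <- gate_steady_state(v, "m", kin)$x_inf
  hinf <- gate_steady_state(v, "h", kin)$x_inf
  ninf <- gate_steady_state(v, "n", kin)$x_inf
  to_dens <- 1e-6 / (p$area * 1e-8)
  -0.1 * p$g_leak * (v - p$e_leak) -
    0.1 * p$g_na * minf^3 * hinf * (v - p$e_na) -
    0.1 * p$g_k * ninf * (v - p$e_k) + i_pA * to_dens
}

#' Resting state of the model
#'
#' Locates the resting potential (zero of the steady-state current at zero
#' injected current) and the corresponding gate values.
#'
#' @param params a [neuron_params()] object.
#' @param i_pA constant injected current, pA.
#' @param window voltage bracket to search, mV.
#' @return list with `v_rest` and gate values `m`, `h`, `n`.
#' @export
resting_state <- function(params, i_pA = 0, window = c(-95, -30)) {
  f <- function(v) steady_state_current(params, v, i_pA)
  vs <- seq(window[1], window[2], by = 0.1)
  fv <- f(vs)
  sc <- which(diff(sign(fv)) != 0)
  if (!length(sc)) stop("no resting state in window")
  r <- uniroot(f, c(vs[sc[1]], vs[sc[1] + 1]), tol = 1e-10)$root
  list(v_rest = r,
       m = gate_steady_state(r, "m", params$kinetics)$x_inf,
       h = gate_steady_state(r, "h", params$kinetics)$x_inf,
       n = gate_steady_state(r, "n", params$kinetics)$x_inf)
}

#' Resting membrane time constant
#'
#' Applies a small voltage perturbation at rest and fits the dominant
#' exponential relaxation of the full model (all gates dynamic).  The leak
#' conductance in the parameter file is set so that this is 40 ms.
#'
#' @param params a [neuron_params()] object.
#' @param perturb_mv perturbation amplitude, mV.
#' @param fit_window time window (ms) of the decay used for the log-linear fit.
#' @param duration_ms simulated relaxation length, ms.
#' @return fitted time constant in ms.
#' @export
membrane_time_constant <- function(params, perturb_mv = 2,
                                   fit_window = c(30, 150), duration_ms = 250) {
  rest <- resting_state(params)
  dt <- params$dt
  n <- round(duration_ms / dt)
  out <- cpp_integrate(unclass(params), rep(0, n), dt,
                       c(rest$v_rest + perturb_mv, rest$m, rest$h, rest$n),
                       params$spike_threshold, params$refractory)
  tt <- seq_len(n) * dt
  keep <- tt >= fit_window[1] & tt <= fit_window[2]
  dv <- out$v[keep] - rest$v_rest
  if (any(dv <= 0)) dv <- pmax(dv, 1e-12)
  fit <- stats::lm.fit(cbind(1, tt[keep]), log(dv))
  -1 / unname(fit$coefficients[2])
}
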