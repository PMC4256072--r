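# Mean-field iterated map.  The layer-averaged synaptic current is linear in
# the previous layer's rate with slope eta; composed with the noise-selected
# f-I curve it yields the update nu[L+1] = Phi_sigma(eta * nu[L]), whose fixed
# points organize firing-rate propagation.

#' Interpolate an f-I family
#'
#' Monotone piecewise-cubic interpolation in DC at each stored sigma, linear
#' interpolation between sigma rows.  Extrapolation is forbidden.
#'
#' @param fi an `fi_family` from [fi_surface()].
#' @param current mean current(s), pA.
#' @param sigma noise amplitude, pA.
#' @return firing rate(s), Hz.
#' @export
fi_rate <- function(fi, current, sigma) {
  dg <- fi$dc_grid; sg <- fi$sigma_grid
  if (any(current < dg[1] - 1e-9) || any(current > dg[length(dg)] + 1e-9))
    stop("extrapolation: current outside the f-I family's DC range")
  if (sigma < sg[1] - 1e-9 || sigma > sg[length(sg)] + 1e-9)
    stop("extrapolation: sigma outside the f-I family's range")
  current <- pmin(pmax(current, dg[1]), dg[length(dg)])
  sigma <- min(max(sigma, sg[1]), sg[length(sg)])
  row_rate <- function(js) {
    f <- splinefun(dg, fi$rates[, js], method = "monoH.FC")
    f(current)
  }
  if (length(sg) == 1) return(pmax(0, row_rate(1)))
  j <- findInterval(sigma, sg, rightmost.closed = TRUE)
  j <- min(max(j, 1), length(sg) - 1)
  wt <- (sigma - sg[j]) / (sg[j + 1] - sg[j])
  pmax(0, (1 - wt) * row_rate(j) + wt * row_rate(j + 1))
}

#' Estimate the mean-field scaling coefficient eta
#'
#' The average synaptic current into a neuron is
#' `<I_syn> = p N w tau_syn <E_ex - V> nu_prev`, so the current per unit
#' presynaptic rate is `eta = p N w tau_syn <E_ex - V>` converted to pA/Hz
#' through the membrane area.  The uncertainty band substitutes the
#' subthreshold voltage sd for the mean driving force.
#'
#' @param config a [network_config()].
#' @param v_stats list with `ev_mean` (mean subthreshold `E_ex - V`, mV) and
#'   `v_sd` (subthreshold voltage sd, mV), from a representative simulation.
#' @param params the receiving neuron's [neuron_params()] (for the area).
#' @return list with `eta` and `eta_sd`, pA/Hz.
#' @export
estimate_eta <- function(config, v_stats, params) {
  pnw <- config$p * config$n_per_layer * config$w      # pS/um^2 per spike
  # conductance-density * mV -> pA: x0.1 (mS/cm^2) * area_cm2 * 1e6;
  # rate Hz -> per ms: x1e-3
  conv <- 0.1 * (params$area * 1e-8) * 1e6 * 1e-3
  eta <- pnw * config$tau_syn * v_stats$ev_mean * conv
  eta_sd <- pnw * config$tau_syn * (v_stats$v_sd %||% 0) * conv
  list(eta = eta, eta_sd = eta_sd)
}

#' Combine independent noise sources
#'
#' Effective noise amplitude seen by a layer: quadrature combination of the
#' injected OU noise and the measured synaptic-current fluctuations
#' (independent sources).
#'
#' @param sigma_injected injected noise sd, pA.
#' @param sigma_synaptic synaptic-current sd, pA.
#' @return effective sigma, pA.
#' @export
effective_sigma <- function(sigma_injected, sigma_synaptic) {
  stopifnot(all(sigma_injected >= 0), all(sigma_synaptic >= 0))
  sqrt(sigma_injected^2 + sigma_synaptic^2)
}

#' Build the iterated rate map
#'
#' @param fi an `fi_family`.
#' @param eta current per unit rate, pA/Hz (see [estimate_eta()]).
#' @param eta_sd uncertainty of `eta`, pA/Hz.
#' @param sigma_injected per-neuron injected noise sd, pA.
#' @return an object of class `iterated_map`.
#' @export
iterated_map <- function(fi, eta, eta_sd = 0, sigma_injected) {
  stopifnot(eta >= 0, eta_sd >= 0)
  structure(list(fi = fi, eta = eta, eta_sd = eta_sd,
                 sigma_injected = sigma_injected), class = "iterated_map")
}

map_value <- function(map, nu, sigma_eff, eta = map$eta) {
  fi_rate(map$fi, pmin(pmax(eta * nu, map$fi$dc_grid[1]),
                       map$fi$dc_grid[length(map$fi$dc_grid)]), sigma_eff)
}

#' Fixed points of the iterated map
#'
#' Solves `Phi_sigma(eta nu) = nu` by sign-change bracketing on a rate
#' lattice refined by bisection.  Stability follows from the map slope:
#' `|d Phi(eta nu)/d nu| < 1` at the fixed point.
#'
#' @param map an [iterated_map()].
#' @param sigma_eff effective noise, pA.
#' @param lattice rate lattice step, Hz.
#' @param tol bisection tolerance, Hz.
#' @return a data.frame with columns `rate`, `stable`, `slope` (one row per
#'   fixed point); zero rows when activity cannot propagate.
#' @export
find_fixed_points <- function(map, sigma_eff, lattice = 0.1, tol = 1e-3) {
  dc_max <- map$fi$dc_grid[length(map$fi$dc_grid)]
  nu_max <- min(max(map$fi$rates) * 1.2, if (map$eta > 0) dc_max / map$eta else Inf)
  nu <- seq(0, nu_max, by = lattice)
  Fv <- map_value(map, nu, sigma_eff) - nu
  roots <- numeric(0)
  if (abs(Fv[1]) < 1e-9) roots <- 0          # exact fixed point at zero rate
  sc <- which(Fv[-1] * Fv[-length(Fv)] < 0)
  for (j in sc) {
    lo <- nu[j]; hi <- nu[j + 1]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if ((map_value(map, lo, sigma_eff) - lo) *
          (map_value(map, mid, sigma_eff) - mid) <= 0) hi <- mid else lo <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  if (!length(roots))
    return(data.frame(rate = numeric(0), stable = logical(0), slope = numeric(0)))
  d <- lattice / 2
  slope <- vapply(roots, function(r) {
    lo <- max(r - d, 0)
    (map_value(map, r + d, sigma_eff) - map_value(map, lo, sigma_eff)) / (r + d - lo)
  }, 0)
  data.frame(rate = roots, stable = abs(slope) < 1, slope = slope)
}

#' Classify the attractor structure of the map
#'
#' `"line-like"` when `|Phi(eta nu) - nu|` stays below `tol` over a contiguous
#' rate interval wider than `min_span` (an effective line of fixed points
#' supporting stable propagation of a whole range of rates), `"point"` when
#' only isolated stable fixed points exist, `"none"` without any stable fixed
#' point.
#'
#' @param map an [iterated_map()].
#' @param sigma_eff effective noise, pA.
#' @param tol tangency tolerance, Hz.
#' @param min_span minimum interval width, Hz.
#' @param lattice rate lattice step, Hz.
#' @return list with `kind` and `interval` (Hz; `NULL` unless line-like).
#' @export
classify_attractor <- function(map, sigma_eff, tol = 0.5, min_span = 5,
                               lattice = 0.1) {
  fps <- find_fixed_points(map, sigma_eff, lattice = lattice)
  dc_max <- map$fi$dc_grid[length(map$fi$dc_grid)]
  nu_max <- min(max(map$fi$rates) * 1.2, if (map$eta > 0) dc_max / map$eta else Inf)
  nu <- seq(0, nu_max, by = lattice)
  close <- abs(map_value(map, nu, sigma_eff) - nu) < tol
  r <- rle(close)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  spans <- (r$lengths - 1) * lattice
  ok <- which(r$values & spans >= min_span)
  if (length(ok)) {
    best <- ok[which.max(spans[ok])]
    return(list(kind = "line-like",
                interval = c(nu[starts[best]], nu[ends[best]]),
                fixed_points = fps))
  }
  if (any(fps$stable)) list(kind = "point", interval = NULL, fixed_points = fps)
  else list(kind = "none", interval = NULL, fixed_points = fps)
}

#' Mean-field prediction of layer rates
#'
#' Layer 1 responds to the injected DC through the f-I curve at the injected
#' noise; each subsequent layer receives current `eta * nu_prev` and the f-I
#' curve selected by the effective noise (injected plus measured synaptic,
#' combined in quadrature).  The uncertainty band propagates `eta +/- eta_sd`.
#'
#' @param map an [iterated_map()].
#' @param initial_dc DC inputs into layer 1, pA.
#' @param n_layers number of layers.
#' @param sigma_synaptic per-layer synaptic-current sd, pA: scalar, vector of
#'   length `n_layers`, or `NULL` for none.
#' @param clamp saturate iterated currents at the f-I family's DC edge
#'   instead of signalling `extrapolation` (useful for scaled-down networks
#'   whose fixed point sits near the grid edge).
#' @return an object of class `layer_prediction`: data.frame with `layer`,
#'   `dc`, `rate`, `rate_lo`, `rate_hi`, `sigma_eff`.
#' @export
predict_layer_rates <- function(map, initial_dc, n_layers,
                                sigma_synaptic = NULL, clamp = FALSE) {
  if (is.null(sigma_synaptic)) sigma_synaptic <- rep(0, n_layers)
  if (length(sigma_synaptic) == 1) sigma_synaptic <- rep(sigma_synaptic, n_layers)
  stopifnot(length(sigma_synaptic) == n_layers)
  out <- vector("list", length(initial_dc))
  for (k in seq_along(initial_dc)) {
    dc <- initial_dc[k]
    nu <- nu_lo <- nu_hi <- numeric(n_layers)
    se <- numeric(n_layers)
    se[1] <- map$sigma_injected
    r1 <- tryCatch(fi_rate(map$fi, dc, se[1]),
                   error = function(e) stop("extrapolation at layer 1: ",
                                            conditionMessage(e)))
    nu[1] <- nu_lo[1] <- nu_hi[1] <- r1
    if (n_layers > 1) for (L in 2:n_layers) {
      se[L] <- effective_sigma(map$sigma_injected, sigma_synaptic[L])
      step <- function(prev, eta) map_value(map, prev, se[L], eta = eta)
      nu[L] <- if (clamp) map_value(map, nu[L - 1], se[L])
               else tryCatch(fi_rate(map$fi, map$eta * nu[L - 1], se[L]),
                             error = function(e)
                               stop("extrapolation at layer ", L, ": ",
                                    conditionMessage(e)))
      etas <- c(max(map$eta - map$eta_sd, 0), map$eta + map$eta_sd)
      cand <- c(step(nu_lo[L - 1], etas[1]), step(nu_lo[L - 1], etas[2]),
                step(nu_hi[L - 1], etas[1]), step(nu_hi[L - 1], etas[2]))
      nu_lo[L] <- min(cand); nu_hi[L] <- max(cand)
    }
    out[[k]] <- data.frame(layer = seq_len(n_layers), dc = dc, rate = nu,
                           rate_lo = nu_lo, rate_hi = nu_hi, sigma_eff = se)
  }
  res <- do.call(rbind, out)
  class(res) <- c("layer_prediction", "data.frame")
  res
}
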