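# Two-variable reduction of the four-variable model (Abbott-Kepler
# construction): the fast activation gate is slaved to its steady state,
# m = m_inf(V), while the slow gates h and n are read out at an auxiliary
# voltage U, h = h_inf(U), n = n_inf(U).  The drift of U is chosen so that
# the slow-gate-induced change of dV/dt at constant V matches the full model.

#' Build the reduced (V, U) system
#'
#' @param params a [neuron_params()] object.
#' @return an object of class `reduced_system` with vectorized right-hand
#'   sides `fV(v, u, i_pA)` (mV/ms) and `gU(v, u)` (mV/ms).
#' @export
build_reduced <- function(params) {
  kin <- params$kinetics
  gna <- 0.1 * params$g_na; gk <- 0.1 * params$g_k; gl <- 0.1 * params$g_leak
  ena <- params$e_na; ek <- params$e_k; el <- params$e_leak
  cm <- params$c_m
  to_dens <- 1e-6 / (params$area * 1e-8)
  minf <- function(v) gate_steady_state(v, "m", kin)$x_inf
  hss <- function(v) gate_steady_state(v, "h", kin)
  nss <- function(v) gate_steady_state(v, "n", kin)
  hv <- kin$h$steady_state$v_half; hk <- kin$h$steady_state$k
  hinf <- function(v) 1 / (1 + exp((v - hv) / hk))
  dhinf <- function(v) { h <- hinf(v); -h * (1 - h) / hk }
  ninf <- function(v) nss(v)$x_inf
  dninf <- function(v) (ninf(v + 1e-5) - ninf(v - 1e-5)) / 2e-5
  fV <- function(v, u, i_pA = 0) {
    (-gl * (v - el) - gna * minf(v)^3 * hinf(u) * (v - ena) -
       gk * ninf(u) * (v - ek) + i_pA * to_dens) / cm
  }
  gU <- function(v, u) {
    Fh <- -gna * minf(v)^3 * (v - ena)
    Fn <- -gk * (v - ek)
    num <- Fh * (hinf(v) - hinf(u)) / hss(v)$tau +
           Fn * (ninf(v) - ninf(u)) / nss(v)$tau
    den <- Fh * dhinf(u) + Fn * dninf(u)
    den <- ifelse(abs(den) < 1e-4, sign(den + .Machine$double.xmin) * 1e-4, den)
    num / den
  }
  structure(list(params = params, fV = fV, gU = gU), class = "reduced_system")
}

#' Right-hand side of the reduced system
#'
#' @param sys a [build_reduced()] system.
#' @param v,u state, mV.
#' @param i_pA injected current, pA.
#' @return `c(dV/dt, dU/dt)` in mV/ms.
#' @export
reduced_derivs <- function(sys, v, u, i_pA = 0) {
  c(sys$fV(v, u, i_pA), sys$gU(v, u))
}

reduced_jacobian <- function(sys, v, u, i_pA, eps = 1e-4) {
  matrix(c((sys$fV(v + eps, u, i_pA) - sys$fV(v - eps, u, i_pA)) / (2 * eps),
           (sys$fV(v, u + eps, i_pA) - sys$fV(v, u - eps, i_pA)) / (2 * eps),
           (sys$gU(v + eps, u) - sys$gU(v - eps, u)) / (2 * eps),
           (sys$gU(v, u + eps) - sys$gU(v, u - eps)) / (2 * eps)),
         2, 2, byrow = TRUE)
}

classify_eigen <- function(ev, margin = 1e-6) {
  re <- Re(ev)
  cplx <- any(abs(Im(ev)) > 1e-12)
  marginal <- any(abs(re) < margin)
  stable <- all(re < 0)
  type <- if (cplx) {
    if (stable) "stable focus" else "unstable focus"
  } else if (prod(re) < 0) "saddle"
  else if (stable) "stable node" else "unstable node"
  list(type = type, stable = stable && !marginal, marginal = marginal,
       eigenvalues = ev)
}

#' Fixed points of the reduced system at one DC
#'
#' At a fixed point `U = V` (both gate-mismatch terms vanish) and the net
#' steady-state membrane current is zero, so candidates are located on the
#' diagonal by bracketing the steady-state current and refined by bisection;
#' each is classified by the eigenvalues of the 2x2 Jacobian.
#'
#' @param sys a [build_reduced()] system.
#' @param dc injected current, pA.
#' @param window voltage search window, mV.
#' @param margin stability margin on `Re(lambda)` (ms^-1); points inside the
#'   margin are flagged `marginal`, never silently classified.
#' @return a data.frame with `v`, `u`, `type`, `stable`, `marginal`.
#' @export
fixed_points_2d <- function(sys, dc, window = c(-95, 20), margin = 1e-6) {
  p <- sys$params
  vs <- seq(window[1], window[2], by = 0.05)
  fv <- steady_state_current(p, vs, dc)
  sc <- which(fv[-1] * fv[-length(fv)] <= 0)
  rows <- lapply(sc, function(j) {
    r <- uniroot(function(v) steady_state_current(p, v, dc),
                 c(vs[j], vs[j + 1]), tol = 1e-10)$root
    cls <- classify_eigen(eigen(reduced_jacobian(sys, r, r, dc))$values, margin)
    data.frame(v = r, u = r, type = cls$type, stable = cls$stable,
               marginal = cls$marginal)
  })
  if (!length(rows))
    return(data.frame(v = numeric(0), u = numeric(0), type = character(0),
                      stable = logical(0), marginal = logical(0)))
  unique(do.call(rbind, rows))
}

#' Nullclines of the reduced system
#'
#' Samples the `dV/dt = 0` and `dU/dt = 0` curves over a `(V, U)` window.
#' The U-nullcline is the diagonal `U = V`; the V-nullcline is traced by
#' solving `fV(v, u) = 0` in `u` for each `v` on the grid.
#'
#' @param sys a [build_reduced()] system.
#' @param dc injected current, pA.
#' @param window voltage window, mV.
#' @param n grid resolution.
#' @return list with data.frames `v_nullcline` (`v`, `u`) and `u_nullcline`.
#' @export
nullclines <- function(sys, dc, window = c(-95, 20), n = 400) {
  vs <- seq(window[1], window[2], length.out = n)
  us <- seq(window[1], window[2], length.out = n)
  vn <- lapply(vs, function(v) {
    fu <- sys$fV(v, us, dc)
    sc <- which(fu[-1] * fu[-length(fu)] <= 0)
    if (!length(sc)) return(NULL)
    data.frame(v = v, u = vapply(sc, function(j)
      uniroot(function(u) sys$fV(v, u, dc), c(us[j], us[j + 1]),
              tol = 1e-8)$root, 0))
  })
  list(v_nullcline = do.call(rbind, vn),
       u_nullcline = data.frame(v = vs, u = vs))
}

#' DC bifurcation sweep of the reduced system
#'
#' Classifies the fixed points along a DC grid and localizes the smallest DC
#' at which no stable fixed point remains (loss of fixed-point stability,
#' onset of continuous spiking) by bisection between grid neighbours.
#'
#' @param sys a [build_reduced()] system.
#' @param dc_grid DC grid, pA (step <= 0.5 pA near suspected transitions).
#' @param tol bisection tolerance on the transition DC, pA.
#' @param check_cycle confirm a limit cycle just past the transition by a
#'   forward simulation.
#' @return an object of class `bifurcation_diagram`: `points` (data.frame
#'   `dc`, `v`, `type`, `stable`, `marginal`), `dc_loss` (pA or `NA`),
#'   `limit_cycle` (logical or `NA`).
#' @export
bifurcation_sweep <- function(sys, dc_grid = seq(0, 120, by = 0.5),
                              tol = 1e-3, check_cycle = TRUE) {
  rows <- lapply(dc_grid, function(dc) {
    fp <- fixed_points_2d(sys, dc)
    if (!nrow(fp)) return(NULL)
    cbind(dc = dc, fp)
  })
  pts <- do.call(rbind, rows)
  has_stable <- vapply(dc_grid, function(dc) {
    any(pts$stable[pts$dc == dc])
  }, TRUE)
  dc_loss <- NA_real_
  if (any(!has_stable)) {
    i <- which(!has_stable)[1]
    if (i == 1) {
      dc_loss <- dc_grid[1]
    } else {
      lo <- dc_grid[i - 1]; hi <- dc_grid[i]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (any(fixed_points_2d(sys, mid)$stable)) lo <- mid else hi <- mid
      }
      dc_loss <- (lo + hi) / 2
    }
  }
  limit_cycle <- NA
  if (check_cycle && !is.na(dc_loss)) {
    limit_cycle <- has_limit_cycle(sys, dc_loss + 5)
  }
  structure(list(points = pts, dc_loss = dc_loss, limit_cycle = limit_cycle,
                 dc_grid = dc_grid), class = "bifurcation_diagram")
}

# Forward-simulate and declare a limit cycle if voltage peaks recur with
# period CV < 1% after discarding a transient.
has_limit_cycle <- function(sys, dc, duration_ms = 5000, transient_ms = 2000) {
  p <- sys$params
  stim <- new_stimulus(rep(dc, round(duration_ms / p$dt)), p$dt, "dc",
                       list(dc = dc))
  tr <- simulate_reduced(sys, stim)
  sp <- tr$spikes$times
  sp <- sp[sp > transient_ms]
  if (length(sp) < 5) return(FALSE)
  isi <- diff(sp)
  sd(isi) / mean(isi) < 0.01
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("<bifurcation_diagram> %d DC values; stability loss at %s pA; limit cycle: %s\n",
              length(x$dc_grid),
              if (is.na(x$dc_loss)) "none" else sprintf("%.2f", x$dc_loss),
              x$limit_cycle))
  invisible(x)
}

#' Simulate the reduced system
#'
#' Euler integration of `(V, U)` driven by a current stimulus; spike
#' detection as in the full model.
#'
#' @param sys a [build_reduced()] system.
#' @param stimulus a `stimulus` object.
#' @param init optional `c(v0, u0)`; defaults to the resting fixed point.
#' @return list with `time`, `v`, `u` and `spikes` (a [spike_train()]).
#' @export
simulate_reduced <- function(sys, stimulus, init = NULL) {
  p <- sys$params
  if (is.null(init)) {
    r <- resting_state(p)
    init <- c(r$v_rest, r$v_rest)
  }
  out <- cpp_integrate_reduced(unclass(p), stimulus$values, stimulus$dt,
                               init[1], init[2], p$spike_threshold,
                               p$refractory)
  n <- length(out$v)
  list(time = seq_len(n) * stimulus$dt, v = out$v, u = out$u,
       spikes = spike_train(out$spikes, n * stimulus$dt))
}
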