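test_that("eta scales with p*N*w and matches direct simulation", {
  p <- gs_params()
  vs <- list(ev_mean = 70, v_sd = 4)
  cfg <- network_config(w = 0.04, seed = 1)
  base <- estimate_eta(cfg, vs, p)
  # w = 0 -> eta = 0
  expect_equal(estimate_eta(network_config(w = 0), vs, p)$eta, 0)
  # (p, w) -> (p/2, 2w) leaves eta unchanged
  cfg2 <- network_config(p = cfg$p / 2, w = 2 * cfg$w)
  expect_equal(estimate_eta(cfg2, vs, p)$eta, base$eta)

  # simulation oracle: <I_syn>/nu_prev from a direct network run.  Layer size
  # 200 keeps the per-synapse conductance small enough for the factorized
  # mean-field average to hold at the stated tolerance.
  cfgs <- scale_network(network_config(w = 0.04, noise_sigma = 35, seed = 23,
                                       n_layers = 2), 200)
  stim <- compose_stimuli(30, ou_process(0, 0, duration = 6000))
  act <- simulate_network(p, cfgs, stim, seed = 23)
  st <- layer_statistics(act)
  eta_meas <- st$isyn_mean[2] / st$mean_rate[1]
  eta_pred <- estimate_eta(cfgs, list(ev_mean = st$ev_mean[2],
                                      v_sd = st$subv_sd[2]), p)$eta
  expect_equal(eta_meas, eta_pred, tolerance = 0.1)
})

test_that("effective noise combines independent sources in quadrature", {
  expect_equal(effective_sigma(15, 0), 15)
  expect_equal(effective_sigma(0, 7), 7)
  expect_equal(effective_sigma(3, 4), 5)
  expect_equal(effective_sigma(4, 3), effective_sigma(3, 4))
  expect_gte(effective_sigma(10, 2), 10)
})

test_that("fixed points and stability labels agree with direct map iteration", {
  # linear map through the origin with slope eta * Phi' < 1: only nu = 0
  lin <- make_fi_family(seq(0, 100, 5), 10, matrix(seq(0, 100, 5) * 0.3, ncol = 1))
  m1 <- iterated_map(lin, eta = 2, sigma_injected = 10)   # slope 0.6 < 1
  fp1 <- find_fixed_points(m1, 10)
  expect_equal(nrow(fp1), 1)
  expect_equal(fp1$rate, 0)
  expect_true(fp1$stable)

  # sigmoid map: three fixed points (0 stable, middle unstable, high stable)
  dc <- seq(0, 120, 2)
  sig <- 30 / (1 + exp(-(dc - 40) / 6))
  sig[1] <- 0
  fam <- make_fi_family(dc, 10, matrix(sig, ncol = 1))
  m2 <- iterated_map(fam, eta = 3, sigma_injected = 10)
  fp2 <- find_fixed_points(m2, 10)
  expect_equal(nrow(fp2), 3)
  expect_equal(fp2$stable, c(TRUE, FALSE, TRUE))
  # iteration oracle: +-5% perturbations converge iff labelled stable
  iterate <- function(nu0, n = 60) {
    nu <- nu0
    for (i in seq_len(n)) nu <- gainprop:::map_value(m2, nu, 10)
    nu
  }
  for (i in seq_len(nrow(fp2))) {
    r <- fp2$rate[i]
    pert <- unique(pmax(0, c(r * 0.95, r * 1.05 + 0.01)))
    ends <- vapply(pert, iterate, 0)
    if (fp2$stable[i]) {
      expect_true(all(abs(ends - r) < 0.5), info = paste("stable fp", r))
    } else {
      expect_true(all(abs(ends - r) > 1), info = paste("unstable fp", r))
    }
  }
})

test_that("attractor classification finds constructed tangencies", {
  # map exactly tangent on [10, 30] Hz: Phi(eta nu) = nu there
  # Phi(I) = I/eta exactly on I in [20, 60] (rates 10..30), bending below the
  # line on both sides, so the map is tangent over [10, 30] Hz only
  eta <- 2
  dc <- seq(0, 100, 1)
  phi <- ifelse(dc < 20, dc^2 / 40,
         ifelse(dc <= 60, dc / eta, 30 + (dc - 60) * 0.05))
  fam <- make_fi_family(dc, 10, matrix(phi, ncol = 1))
  mp <- iterated_map(fam, eta, sigma_injected = 10)
  cl <- classify_attractor(mp, 10, tol = 0.5, min_span = 5)
  expect_equal(cl$kind, "line-like")
  expect_lt(abs(cl$interval[1] - 10), 1.5)
  expect_gt(cl$interval[2], 25)

  # a steep map with one stable point is a point attractor
  lin <- make_fi_family(seq(0, 100, 5), 10,
                        matrix(pmin(seq(0, 100, 5) * 0.3, 20), ncol = 1))
  expect_equal(classify_attractor(iterated_map(lin, 2, sigma_injected = 10),
                                  10)$kind, "point")
})

test_that("layer-rate predictions respect fixed points and the pNw invariance", {
  dc <- seq(0, 120, 2)
  sig <- 30 / (1 + exp(-(dc - 40) / 6)); sig[1] <- 0
  fam <- make_fi_family(dc, 10, matrix(sig, ncol = 1))
  mp <- iterated_map(fam, 3, sigma_injected = 10)
  fps <- find_fixed_points(mp, 10)
  hi <- max(fps$rate[fps$stable])
  # starting exactly at a stable fixed point stays there
  pred <- predict_layer_rates(mp, initial_dc = 3 * hi, n_layers = 8)
  expect_true(all(abs(pred$rate - hi) < 0.2))
  # extrapolation is refused with a layer context
  tiny <- make_fi_family(seq(0, 10, 1), 10, matrix(seq(0, 10, 1) * 2, ncol = 1))
  expect_error(predict_layer_rates(iterated_map(tiny, 50, sigma_injected = 10),
                                   5, 4), "extrapolation")

  # predictions depend on p*N*w only (three factorizations, real neuron)
  p <- gs_params()
  vs <- list(ev_mean = 70, v_sd = 4)
  etas <- vapply(list(network_config(p = 0.05, n_per_layer = 2000, w = 0.02),
                      network_config(p = 0.025, n_per_layer = 2000, w = 0.04),
                      network_config(p = 0.05, n_per_layer = 1000, w = 0.04)),
                 function(cf) estimate_eta(cf, vs, p)$eta, 0)
  expect_equal(etas[2], etas[1])
  expect_equal(etas[3], etas[1])
  preds <- lapply(etas, function(e)
    predict_layer_rates(iterated_map(fam, e, sigma_injected = 10), 40, 6)$rate)
  expect_equal(preds[[2]], preds[[1]])
  expect_equal(preds[[3]], preds[[1]])
})
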