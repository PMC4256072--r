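test_that("the resting point of the full model is a fixed point with U = V", {
  for (mk in list(ngs_params, gs_params)) {
    p <- mk()
    sys <- build_reduced(p)
    rest <- resting_state(p)
    # residual of both right-hand sides at (V_rest, V_rest)
    expect_lt(abs(sys$fV(rest$v_rest, rest$v_rest, 0)), 1e-8)
    expect_lt(abs(sys$gU(rest$v_rest, rest$v_rest)), 1e-8)
    fp <- fixed_points_2d(sys, 0)
    expect_true(all(abs(fp$v - fp$u) < 1e-9))    # U = V at every fixed point
  }
})

test_that("reduced and full model agree on subthreshold voltage trajectories", {
  p <- ngs_params()
  sys <- build_reduced(p)
  stim <- compose_stimuli(20, ou_process(0, 0, duration = 300))  # subthreshold
  full <- simulate_neuron(p, stim)
  red <- simulate_reduced(sys, stim)
  expect_length(red$spikes$times, 0)
  expect_lt(max(abs(full$v - red$v)), 1.5)   # mV, before any spike
})

test_that("fixed-point classification matches forward-simulated basin behaviour", {
  p <- ngs_params()
  sys <- build_reduced(p)
  # low DC: a single stable fixed point (node or focus)
  fp0 <- fixed_points_2d(sys, 20)
  expect_equal(sum(fp0$stable), 1)
  expect_match(fp0$type[fp0$stable], "stable (node|focus)")

  probe <- function(dc, v0) {
    stim <- gainprop:::new_stimulus(rep(dc, 80000), p$dt, "dc", list())
    tr <- simulate_reduced(sys, stim, init = c(v0 + 1, v0))
    tail(tr$v, 1)
  }
  # stable: a small perturbation decays back
  vstar <- fp0$v[fp0$stable]
  expect_lt(abs(probe(20, vstar) - vstar), 0.5)
  # past the bifurcation: classification says unstable, trajectory leaves
  fp_hi <- fixed_points_2d(sys, 80)
  expect_false(any(fp_hi$stable))
  expect_gt(abs(probe(80, fp_hi$v[1]) - fp_hi$v[1]), 1)

  # a stable focus carries a complex eigenpair with negative real part
  cls <- gainprop:::classify_eigen(eigen(
    gainprop:::reduced_jacobian(sys, vstar, vstar, 20))$values)
  if (grepl("focus", cls$type)) {
    expect_true(any(Im(cls$eigenvalues) != 0))
    expect_true(all(Re(cls$eigenvalues) < 0))
  }
})

test_that("the bifurcation DC is grid-independent and followed by a limit cycle", {
  sys <- build_reduced(ngs_params())
  coarse <- bifurcation_sweep(sys, seq(55, 70, by = 0.5), check_cycle = TRUE)
  fine <- bifurcation_sweep(sys, seq(55, 70, by = 0.1), check_cycle = FALSE)
  expect_false(is.na(coarse$dc_loss))
  expect_lt(abs(coarse$dc_loss - fine$dc_loss), 0.01)
  expect_true(coarse$limit_cycle)
})

test_that("reduced-model firing is strongly noise-modulated below threshold", {
  p <- ngs_params()
  sys <- build_reduced(p)
  # at the stable fixed point with no noise the trajectory stays put
  fp <- fixed_points_2d(sys, 30)
  vs <- fp$v[fp$stable]
  still <- simulate_reduced(sys, gainprop:::new_stimulus(rep(30, 40000), p$dt,
                                                         "dc", list()),
                            init = c(vs, vs))
  expect_lt(max(abs(still$v - vs)), 0.1)
  # sigma = 15 vs 50 pA at subthreshold DC: spike count increases with sigma
  n15 <- length(simulate_reduced(sys, ou_process(30, 15, duration = 10000,
                                                 seed = 2))$spikes$times)
  n50 <- length(simulate_reduced(sys, ou_process(30, 50, duration = 10000,
                                                 seed = 2))$spikes$times)
  expect_gt(n50, n15 + 5)
})
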