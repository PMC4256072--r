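test_that("STA of stimulus-independent spikes vanishes; oracle average matches", {
  set.seed(7)
  n <- 200000; dt <- 0.1
  stim <- gainprop:::new_stimulus(rnorm(n, 0, 20), dt, "white", list())
  # Poisson spikes, independent of the stimulus
  sp_times <- sort(sample(seq(1000, n * dt - 1, by = dt), 400))
  spikes <- spike_train(sp_times, n * dt)
  sta <- compute_sta(stim, spikes, window = 20)
  se <- 20 / sqrt(sta$n_spikes)
  expect_gt(mean(abs(sta$raw) < 3 * se), 0.97)
  expect_lt(max(abs(sta$raw)), 5 * se)
  # unit norm
  expect_equal(sum(sta$values^2), 1, tolerance = 1e-12)

  # brute-force oracle: manual average of the extracted windows
  w <- round(20 / dt)
  x <- stim$values - mean(stim$values)
  idx <- round(sp_times / dt) + 1
  manual <- rowMeans(vapply(idx, function(i) x[(i - w + 1):i], numeric(w)))
  expect_equal(sta$raw, manual, tolerance = 1e-12)
})

test_that("stimulus filtering equals the naive dot-product loop", {
  set.seed(8)
  stim <- gainprop:::new_stimulus(rnorm(3000, 0, 10), 0.5, "white", list())
  sp <- spike_train(sort(sample(seq(100, 1400, by = 0.5), 150)), 1500)
  sta <- compute_sta(stim, sp, window = 10)
  fs <- filter_stimulus(stim, sta)
  w <- length(sta$values)
  x <- stim$values - mean(stim$values)
  naive <- vapply(seq_len(length(x) - w + 1),
                  function(i) sum(x[i:(i + w - 1)] * sta$values), 0)
  expect_equal(fs$values, naive, tolerance = 1e-9)

  # delta filter recovers the mean-subtracted stimulus
  delta <- sta; delta$values <- c(numeric(w - 1), 1)
  expect_equal(filter_stimulus(stim, delta)$values, x[w:length(x)],
               tolerance = 1e-9)

  # white Gaussian stimulus, unit-norm filter: var(s) ~ var(stimulus)
  expect_equal(var(fs$values), var(x), tolerance = 0.05)
})

test_that("Bayes-rule nonlinearity is identical to the direct conditional rate", {
  fit <- fit_ln(gs_params(), 10, 50, dur_s = 30, seed = 31)
  nl <- fit$nl
  # direct estimator: spikes in bin / time in bin
  direct <- ifelse(nl$occupancy > 0,
                   1000 * nl$n_spike / (nl$occupancy * nl$dt), NA_real_)
  expect_equal(nl$rate, direct, tolerance = 1e-12)
  # rate conservation: occupancy-weighted mean equals the measured mean rate
  ok <- !is.na(nl$rate)
  expect_equal(sum(nl$rate[ok] * nl$occupancy[ok]) / sum(nl$occupancy[ok]),
               nl$mean_rate, tolerance = 0.01)
})

test_that("spikes independent of the filtered stimulus give a flat nonlinearity", {
  set.seed(9)
  n <- 400000; dt <- 0.1
  stim <- gainprop:::new_stimulus(rnorm(n, 0, 15), dt, "white", list())
  sp_times <- sort(sample(seq(200, n * dt - 1, by = dt), 1200))
  spikes <- spike_train(sp_times, n * dt)
  # a fixed filter, not fitted to these spikes (a fitted STA would carry an
  # in-sample projection bias even for independent spikes)
  w <- round(10 / dt)
  shape <- exp(-((seq_len(w) - w) / 30)^2)
  sta <- structure(list(values = shape / sqrt(sum(shape^2)), raw = shape,
                        window = 10, dt = dt, n_spikes = length(sp_times)),
                   class = "sta_filter")
  fs <- filter_stimulus(stim, sta)
  nl <- estimate_nonlinearity(fs, spikes)
  ok <- !is.na(nl$rate)
  # every bin within sampling error of the mean rate (Poisson SE per bin)
  se <- nl$mean_rate / sqrt(pmax(nl$n_spike[ok], 1))
  expect_gt(mean(abs(nl$rate[ok] - nl$mean_rate) < 3.5 * se), 0.95)
})

test_that("collapse index behaves as a gain-scaling measure", {
  grid <- seq(-2, 2, length.out = 21)
  flat1 <- make_nl(grid, rep(10, 21))
  flat2 <- make_nl(grid, rep(20, 21))
  # identical curves collapse exactly
  expect_equal(gain_scaling_index(list(flat1, flat1))$collapse_index, 0)
  # two flat curves at r and 2r: RMS diff r, grand mean 1.5 r -> 2/3
  expect_equal(gain_scaling_index(list(flat1, flat2))$collapse_index, 2 / 3)
  # disjoint supports are rejected
  shifted <- make_nl(grid + 10, rep(10, 21))
  expect_error(gain_scaling_index(list(flat1, shifted)), "incompatible-conditions")
})

test_that("LN output entropy counts distinguishable rate levels", {
  grid <- seq(-2, 2, length.out = 16)
  # constant nonlinearity: one outcome, zero bits
  expect_equal(ln_output_entropy(make_nl(grid, rep(7, 16))), 0)
  # uniform occupancy over 16 distinct rate bins: 4 bits
  nl16 <- make_nl(grid, seq(1.25, 38.75, by = 2.5))   # one rate per 2.5-Hz bin
  expect_equal(ln_output_entropy(nl16), 4)
})
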