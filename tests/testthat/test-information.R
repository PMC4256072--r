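test_that("distribution entropy matches an independent computation", {
  expect_equal(distribution_entropy(c(0, 5, 0)), 0)
  expect_equal(distribution_entropy(rep(3, 16)), 4)
  expect_error(distribution_entropy(c(0, 0)), "empty-distribution")
  expect_error(distribution_entropy(c(-1, 2)), "negative")
  set.seed(4)
  for (i in 1:20) {
    h <- rpois(sample(2:40, 1), 5)
    if (sum(h) == 0) next
    p <- h / sum(h); p <- p[p > 0]
    expect_equal(distribution_entropy(h), -sum(p * log(p)) / log(2),
                 tolerance = 1e-12)
  }
})

test_that("DC mutual information has exact limits and a brute-force oracle", {
  # identical response distributions -> 0 bits
  same <- replicate(5, c(1, 2, 3, 4, 5), simplify = FALSE)
  expect_equal(dc_mutual_information(same, n_bins = 10)$mi, 0, tolerance = 1e-12)
  # 28 perfectly separable inputs -> log2(28)
  sep <- lapply(1:28, function(k) rep(k * 10, 20))
  expect_equal(dc_mutual_information(sep, n_bins = 28)$mi, log2(28),
               tolerance = 1e-9)
  expect_error(dc_mutual_information(list(1:3)), "at least 2")
  expect_error(dc_mutual_information(list(1:3, numeric(0))),
               "insufficient-samples")

  # brute-force double sum over the joint histogram
  set.seed(5)
  samples <- lapply(1:6, function(k) rnorm(200, mean = k * 2, sd = 2))
  res <- dc_mutual_information(samples, n_bins = 15)
  pj <- res$p_joint                       # K x bins, sums to 1
  px <- rowSums(pj); pr <- colSums(pj)
  direct <- 0
  for (i in seq_len(nrow(pj))) for (j in seq_len(ncol(pj)))
    if (pj[i, j] > 0)
      direct <- direct + pj[i, j] * log2(pj[i, j] / (px[i] * pr[j]))
  expect_equal(res$mi, direct, tolerance = 1e-12)
  # non-negativity and the log2(K) ceiling on random cases
  expect_gte(res$mi, 0)
  expect_lte(res$mi, log2(6))
})

test_that("Gaussian-channel information matches the closed form on a flat channel", {
  set.seed(6)
  # brick-wall band-limited signal with flat in-band spectrum
  n <- 20000; dt_s <- 0.01; fc <- 2            # 200 s at 100 Hz, band 0-2 Hz
  white <- rnorm(n)
  X <- fft(white)
  freq <- (seq_len(n) - 1) / (n * dt_s)
  keep <- freq <= fc | freq >= (1 / dt_s - fc)
  X[!keep] <- 0
  s <- Re(fft(X, inverse = TRUE)) / n
  s <- (s - mean(s)) / sd(s)
  sn <- 1.5                                    # white noise sd
  est <- s + rnorm(n, 0, sn)
  res <- slow_signal_info(s, est, dt_s, band = c(0.05, fc))
  # closed form: the z-normalized estimate is a(s + noise), a = 1/sqrt(1+sn^2),
  # so the Eq-19 residual has in-band PSD (1-a)^2 S_s + a^2 S_white
  a <- 1 / sqrt(1 + sn^2)
  S_s <- 1 / fc                                # unit variance, flat in band
  S_n <- (1 - a)^2 * S_s + a^2 * sn^2 * 2 * dt_s
  info_theory <- fc * 0.5 * log2(1 + S_s / S_n)
  expect_equal(res$info_rate, info_theory, tolerance = 0.1)

  # an independent estimate with strong in-band power carries far less
  w2 <- rnorm(n); X2 <- fft(w2)
  X2[!(freq <= 0.5 | freq >= (1 / dt_s - 0.5))] <- 0
  est0 <- Re(fft(X2, inverse = TRUE)) / n
  res0 <- slow_signal_info(s, est0, dt_s, band = c(0.05, fc))
  # the z-normalized residual keeps an S_s floor, so "zero" information is a
  # sizeable reduction, not literally zero
  expect_lt(res0$info_rate, 0.45 * res$info_rate)
  expect_error(slow_signal_info(s, est[-1], dt_s, band = c(0, fc)),
               "incompatible-series")
})
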