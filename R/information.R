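# Information measures: Gaussian-channel information carried about the slow
# common signal by population responses, discrete mutual information between
# a set of DC inputs and output firing rates, and distribution entropy.

#' Shannon entropy of a histogram
#'
#' @param counts non-negative counts or weights; at least one positive.
#' @return entropy in bits (`0 log 0 = 0`).
#' @export
distribution_entropy <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  tot <- sum(counts)
  if (tot == 0) stop("empty-distribution")
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

# Averaged windowed (Hann) periodogram.  Returns freq (Hz) and power so that
# sum(power) * df ~ variance of x.
averaged_periodogram <- function(x, dt_s, n_windows = 8, overlap = 0.5) {
  N <- length(x)
  nw <- floor(N / (1 + (n_windows - 1) * (1 - overlap)))
  nw <- max(nw, 8)
  step <- max(1, floor(nw * (1 - overlap)))
  starts <- seq(1, N - nw + 1, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1)))
  wnorm <- sum(win^2)
  nf <- floor(nw / 2)
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nw - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(fft(seg)[2:(nf + 1)])^2
    acc <- acc + sp
  }
  power <- acc / length(starts) / wnorm * dt_s * 2
  list(freq = seq_len(nf) / (nw * dt_s), power = power, df = 1 / (nw * dt_s))
}

#' Gaussian-channel information about a slow signal
#'
#' Treats the normalized population response (PSTH) as a reconstruction of
#' the normalized slow stimulus and computes the dynamic-Gaussian-channel
#' information `integral of 1/2 log2(1 + SNR(f)) df` over the stimulus band,
#' with the noise defined as the difference between reconstruction and
#' stimulus and spectra estimated by averaged windowed periodograms.  The
#' result is a lower bound on the true information transfer.
#'
#' @param stimulus_values slow-signal samples (will be z-normalized).
#' @param estimate_values response samples on the same time base (PSTH;
#'   z-normalized).
#' @param dt_s sample interval in seconds.
#' @param band frequency band of integration, Hz; default the occupied
#'   stimulus band `c(0, cutoff)` must be supplied by the caller.
#' @param n_windows number of averaged periodogram windows.
#' @return an object of class `spectral_info`: `freq`, `signal`, `noise`,
#'   `snr`, `info_rate` (bits/s), `band`.
#' @export
slow_signal_info <- function(stimulus_values, estimate_values, dt_s,
                             band, n_windows = 8) {
  if (length(stimulus_values) != length(estimate_values))
    stop("incompatible-series: lengths differ")
  z <- function(x) (x - mean(x)) / sd(x)
  s <- z(stimulus_values)
  r <- z(estimate_values)
  noise <- r - s
  ps <- averaged_periodogram(s, dt_s, n_windows)
  pn <- averaged_periodogram(noise, dt_s, n_windows)
  keep <- ps$freq >= band[1] & ps$freq <= band[2]
  snr <- ps$power[keep] / pmax(pn$power[keep], .Machine$double.eps)
  info_rate <- sum(0.5 * log2(1 + snr)) * ps$df
  structure(list(freq = ps$freq[keep], signal = ps$power[keep],
                 noise = pn$power[keep], snr = snr,
                 info_rate = info_rate, band = band),
            class = "spectral_info")
}

#' Mutual information between DC inputs and output rates
#'
#' Plug-in mutual information with a uniform prior over the inputs and
#' shared rate-bin edges across all inputs (the responses of every input are
#' binned into the same bins, edges spanning the pooled rate range).
#'
#' @param rate_samples list (one element per input value) of firing-rate
#'   samples, Hz (e.g. rates in consecutive 2-s bins).
#' @param n_bins number of shared rate bins (reference: 28).
#' @return an object of class `dc_info`: `mi` (bits), `n_inputs`,
#'   `edges`, `p_joint` (inputs x bins).
#' @export
dc_mutual_information <- function(rate_samples, n_bins = 28) {
  K <- length(rate_samples)
  if (K < 2) stop("need at least 2 inputs")
  if (any(vapply(rate_samples, length, 0L) == 0))
    stop("insufficient-samples: empty sample set")
  pooled <- unlist(rate_samples)
  lo <- min(pooled); hi <- max(pooled)
  if (hi <= lo) hi <- lo + 1e-9
  edges <- seq(lo - 1e-9, hi + 1e-9, length.out = n_bins + 1)
  cond <- t(vapply(rate_samples, function(x) {
    cnt <- hist_counts(x, edges)
    cnt / sum(cnt)
  }, numeric(n_bins)))
  marg <- colMeans(cond)            # uniform prior 1/K
  mi <- 0
  for (k in seq_len(K)) {
    nz <- cond[k, ] > 0
    mi <- mi + sum(cond[k, nz] / K * log2(cond[k, nz] / marg[nz]))
  }
  structure(list(mi = mi, n_inputs = K, edges = edges, p_joint = cond / K),
            class = "dc_info")
}
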