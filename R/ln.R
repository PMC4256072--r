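# Linear-nonlinear characterization of fast-fluctuation coding: the
# spike-triggered average as the linear feature, the Bayes-rule nonlinearity,
# gain-scaling quantification, and output entropy.

#' Spike-triggered average
#'
#' Average of the mean-subtracted stimulus segments preceding each spike
#' (window ending at the spike sample), normalized to unit Euclidean norm.
#'
#' @param stimulus a `stimulus` object.
#' @param spikes a [spike_train()] from the same recording.
#' @param window filter length before the spike, ms.
#' @param min_spikes minimum spike count required.
#' @return an object of class `sta_filter`: `values` (unit norm, time
#'   ascending toward the spike), `raw` (pre-normalization, pA), `window`,
#'   `dt`, `n_spikes`.
#' @export
compute_sta <- function(stimulus, spikes, window = 75, min_spikes = 100) {
  dt <- stimulus$dt
  w <- round(window / dt)
  x <- stimulus$values - mean(stimulus$values)
  idx <- round(spikes$times / dt) + 1          # spike sample, 1-based
  idx <- idx[idx >= w & idx <= length(x)]
  if (length(idx) < min_spikes)
    stop("insufficient-spikes: ", length(idx), " usable, need ", min_spikes)
  seg <- vapply(idx, function(i) x[(i - w + 1):i], numeric(w))
  avg <- rowMeans(seg)
  structure(list(values = avg / sqrt(sum(avg^2)), raw = avg,
                 window = window, dt = dt, n_spikes = length(idx)),
            class = "sta_filter")
}

#' Filter a stimulus with an STA feature
#'
#' Valid-region inner product of the mean-subtracted stimulus with the
#' unit-norm filter: `s[i]` is the projection of the window ending at sample
#' `i + w - 1`.  Output length is `length(stimulus) - w + 1`.
#'
#' @param stimulus a `stimulus` object.
#' @param sta an `sta_filter`.
#' @return list with `values` (filtered series), `offset` (samples by which
#'   the series start is delayed), `dt`.
#' @export
filter_stimulus <- function(stimulus, sta) {
  x <- stimulus$values - mean(stimulus$values)
  f <- sta$values
  w <- length(f)
  n <- length(x)
  if (n <= w) stop("stimulus shorter than the filter window")
  # FFT convolution padded to a highly composite length (a near-prime length
  # would make R's mixed-radix FFT quadratic)
  L <- stats::nextn(n + w - 1, c(2, 3, 5))
  X <- fft(c(x, numeric(L - n)))
  G <- fft(c(rev(f), numeric(L - w)))
  full <- Re(fft(X * G, inverse = TRUE)) / L
  s <- full[w:n]
  list(values = s, offset = w - 1L, dt = stimulus$dt)
}

#' Estimate the LN nonlinearity by Bayes' rule
#'
#' `rate(s) = rbar * P(s | spike) / P(s)` with both densities estimated as
#' histograms on identical bins of the filtered stimulus.  Equal-occupancy
#' bins of the prior are the default; bins with zero prior occupancy are
#' flagged, never interpolated.
#'
#' @param filtered output of [filter_stimulus()].
#' @param spikes a [spike_train()] aligned with the original stimulus.
#' @param bins number of bins (>= 8).
#' @param binning `"equal_occupancy"` or `"equal_width"`.
#' @return an object of class `ln_nonlinearity`: `bin_centers` (pA),
#'   `bin_centers_norm` (s/sd(s)), `rate` (Hz), `occupancy`, `n_spike`
#'   (spike-conditional counts), `mean_rate` (Hz), `sigma_s` (sd of the
#'   filtered series), `edges`, `dt`.
#' @export
estimate_nonlinearity <- function(filtered, spikes, bins = 25,
                                  binning = c("equal_occupancy", "equal_width")) {
  binning <- match.arg(binning)
  stopifnot(bins >= 8)
  s <- filtered$values
  dt <- filtered$dt
  # filtered index of the window ending at the spike sample
  idx <- round(spikes$times / dt) + 1 - filtered$offset
  idx <- idx[idx >= 1 & idx <= length(s)]
  if (!length(idx)) stop("insufficient-spikes: no spikes inside the filtered region")
  s_sp <- s[idx]
  edges <- if (binning == "equal_occupancy") {
    e <- quantile(s, probs = seq(0, 1, length.out = bins + 1), names = FALSE)
    unique(e)
  } else seq(min(s), max(s), length.out = bins + 1)
  edges[1] <- edges[1] - 1e-9
  edges[length(edges)] <- edges[length(edges)] + 1e-9
  occ <- hist_counts(s, edges)
  nsp <- hist_counts(s_sp, edges)
  mean_rate <- 1000 * length(idx) / (length(s) * dt)   # Hz over the valid region
  # Bayes: rbar * (nsp/sum(nsp)) / (occ/sum(occ)); zero-occupancy bins NA
  rate <- ifelse(occ > 0, mean_rate * (nsp / sum(nsp)) / (occ / sum(occ)), NA_real_)
  centers <- vapply(seq_len(length(edges) - 1), function(i) {
    inb <- s[s > edges[i] & s <= edges[i + 1]]
    if (length(inb)) mean(inb) else (edges[i] + edges[i + 1]) / 2
  }, 0)
  structure(list(bin_centers = centers, bin_centers_norm = centers / sd(s),
                 rate = rate, occupancy = occ, n_spike = nsp,
                 mean_rate = mean_rate, sigma_s = sd(s), edges = edges, dt = dt),
            class = "ln_nonlinearity")
}

hist_counts <- function(x, edges) {
  b <- findInterval(x, edges, rightmost.closed = TRUE, left.open = TRUE)
  tabulate(b[b >= 1 & b <= length(edges) - 1], nbins = length(edges) - 1)
}

#' Quantify gain scaling across noise conditions
#'
#' Compares nonlinearities measured at different stimulus standard deviations
#' on the shared sigma-normalized abscissa `s / sd(s)`.  The collapse index is
#' the mean pairwise RMS difference between rate curves interpolated on the
#' common `s/sigma` grid, divided by the grand mean rate: 0 means perfect
#' overlap (perfect gain scaling).
#'
#' @param nls list of `ln_nonlinearity` objects, one per sigma condition.
#' @param sigmas the stimulus sd of each condition, pA.
#' @param n_grid number of points of the common normalized grid.
#' @return an object of class `gain_scaling_report` with `collapse_index`,
#'   `sigma_list`, `grid`, `curves` (matrix, grid x condition).
#' @export
gain_scaling_index <- function(nls, sigmas = NULL, n_grid = 41) {
  stopifnot(length(nls) >= 2)
  ranges <- lapply(nls, function(nl) range(nl$bin_centers_norm[!is.na(nl$rate)]))
  lo <- max(vapply(ranges, `[`, 0, 1))
  hi <- min(vapply(ranges, `[`, 0, 2))
  if (lo >= hi) stop("incompatible-conditions: no common normalized support")
  grid <- seq(lo, hi, length.out = n_grid)
  curves <- vapply(nls, function(nl) {
    ok <- !is.na(nl$rate)
    approx(nl$bin_centers_norm[ok], nl$rate[ok], xout = grid, rule = 2)$y
  }, numeric(n_grid))
  pairs <- utils::combn(length(nls), 2)
  rms <- apply(pairs, 2, function(ij)
    sqrt(mean((curves[, ij[1]] - curves[, ij[2]])^2)))
  structure(list(collapse_index = mean(rms) / mean(curves),
                 sigma_list = sigmas, grid = grid, curves = curves),
            class = "gain_scaling_report")
}

#' Output entropy of the LN firing-rate distribution
#'
#' Shannon entropy (bits) of the distribution of predicted firing-rate values,
#' weighting each nonlinearity bin by its prior occupancy and discretizing the
#' predicted rates on a fixed rate grid.  For a gain-scaling neuron this is
#' approximately independent of the stimulus sd.
#'
#' @param nl an `ln_nonlinearity`.
#' @param rate_edges fixed rate-bin edges, Hz.  Supply the same edges across
#'   conditions when comparing entropies.
#' @return entropy in bits.
#' @export
ln_output_entropy <- function(nl, rate_edges = seq(0, 100, by = 2.5)) {
  ok <- !is.na(nl$rate)
  r <- pmin(pmax(nl$rate[ok], min(rate_edges)), max(rate_edges) - 1e-9)
  bin <- findInterval(r, rate_edges, rightmost.closed = TRUE)
  w <- nl$occupancy[ok]
  mass <- tapply(w, bin, sum)
  distribution_entropy(as.numeric(mass))
}
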