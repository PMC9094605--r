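#' Complex Morlet analytic signal
#'
#' Convolves the signal with a complex Morlet wavelet of width `n_cycles`
#' (default 7) centered at `center_freq`, returning the same-length
#' analytic series: the modulus is the instantaneous amplitude envelope,
#' the argument the instantaneous phase in (-pi, pi]. The wavelet is
#' normalized so that a unit-amplitude sinusoid at the center frequency
#' has unit envelope.
#'
#' @param x numeric signal vector.
#' @param sampling_rate Hz.
#' @param center_freq center frequency in Hz (must be below Nyquist).
#' @param n_cycles wavelet width in cycles, default 7.
#' @return Complex vector, same length as `x`.
#' @examples
#' fs <- 1000; t <- seq(0, 2, length.out = 2000)
#' a <- morlet_analytic(sin(2 * pi * 8 * t), fs, 8)
#' range(Mod(a)[500:1500]) # ~1
#' @export
morlet_analytic <- function(x, sampling_rate, center_freq, n_cycles = 7) {
  if (center_freq >= sampling_rate / 2) {
    abort(sprintf("center frequency %g Hz is at or above Nyquist (%g Hz)",
                  center_freq, sampling_rate / 2))
  }
  if (center_freq <= 0) abort("center frequency must be positive")
  sigma_t <- n_cycles / (2 * pi * center_freq)
  # +/- 3 sigma support: truncation < 1.2% of the Gaussian tail, and a
  # 2 Hz wavelet (sigma_t = 0.56 s) still fits inside one 4-s epoch
  half <- ceiling(3 * sigma_t * sampling_rate)
  tt <- (-half:half) / sampling_rate
  g <- exp(-tt^2 / (2 * sigma_t^2))
  w <- g * exp(2i * pi * center_freq * tt) * (2 / sum(g))
  n <- length(x)
  m <- length(w)
  if (n < m) {
    abort(sprintf(
      "signal (%d samples) shorter than the wavelet support (%d samples)",
      n, m))
  }
  nfft <- stats::nextn(n + m - 1, 2)
  X <- fft(c(x, rep(0, nfft - n)))
  W <- fft(c(w, rep(0, nfft - m)))
  full <- fft(X * W, inverse = TRUE) / nfft
  full[(half + 1):(half + n)]
}

# core MI on precomputed phase-bin indices; returns c(mi, empty_bins)
tort_mi_core <- function(bin_idx, amplitude, n_bins) {
  sums <- numeric(n_bins)
  cnts <- numeric(n_bins)
  agg <- rowsum(cbind(amplitude, 1), bin_idx)
  rows <- as.integer(rownames(agg))
  sums[rows] <- agg[, 1]
  cnts[rows] <- agg[, 2]
  empty <- sum(cnts == 0)
  means <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
  tot <- sum(means)
  if (tot == 0) return(c(0, empty)) # e.g. zero signal: uniform convention
  p <- means / tot
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  c((log(n_bins) - h) / log(n_bins), empty)
}

phase_bin_index <- function(phase, n_bins) {
  # equal bins over (-pi, pi]; phase exactly -pi folds into bin 1
  idx <- ceiling((phase + pi) / (2 * pi / n_bins))
  pmin(pmax(idx, 1L), n_bins)
}

#' Tort modulation index
#'
#' Bins the phase series into `n_bins` equal bins over (-pi, pi],
#' computes the mean amplitude per bin, normalizes the bin means to a
#' distribution P, and returns the normalized Kullback-Leibler divergence
#' from uniform: `MI = (ln(n_bins) - H(P)) / ln(n_bins)` with Shannon
#' entropy H in nats. MI is 0 iff P is uniform and 1 iff all amplitude
#' mass sits in one bin. An empty phase bin contributes zero mean
#' amplitude and raises a warning (a documented convention; impossible
#' for multi-second nondegenerate signals).
#'
#' @param phase numeric phase series in radians.
#' @param amplitude nonnegative amplitude series, same length.
#' @param n_bins number of phase bins, default 18.
#' @return MI in \[0, 1\].
#' @export
tort_mi <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude)) {
    abort("phase and amplitude must have equal length")
  }
  if (any(amplitude < 0)) abort("amplitude must be nonnegative")
  assert_scalar_num(n_bins, "n_bins", lower = 2)
  res <- tort_mi_core(phase_bin_index(phase, n_bins), amplitude, n_bins)
  if (res[2] > 0) {
    warn(sprintf("%d empty phase bin(s) set to zero mean amplitude", res[2]))
  }
  res[1]
}

#' Phase-amplitude comodulogram
#'
#' For every cell of the phase grid (2-12 Hz in 0.5 Hz steps) by
#' amplitude grid (10-200 Hz in 5 Hz steps): extract phase from the
#' phase-frequency Morlet convolution and amplitude from the
#' amplitude-frequency convolution, compute the Tort MI per epoch, and
#' average across epochs.
#'
#' @param epochs an [epoch_set()] of retained epochs.
#' @param channel channel label.
#' @param phase_freqs Hz grid for the phase-modulating signals.
#' @param amp_freqs Hz grid for the amplitude-modulated signals.
#' @param n_cycles Morlet width, default 7.
#' @param n_bins phase bins for the MI, default 18.
#' @return An object of class `comodulogram`: list with `phase_freqs`,
#'   `amp_freqs`, `mi` (phase x amplitude matrix), `n_epochs` and
#'   `empty_bins` (warning counter). Use [tidy.comodulogram()] for a long
#'   tibble and [autoplot.comodulogram()] for a heatmap.
#' @export
comodulogram <- function(epochs, channel, phase_freqs = seq(2, 12, 0.5),
                         amp_freqs = seq(10, 200, 5), n_cycles = 7,
                         n_bins = 18) {
  stopifnot(inherits(epochs, "epoch_set"))
  ci <- match(channel, epochs$channel_labels)
  if (is.na(ci)) abort(sprintf("unknown channel `%s`", channel))
  ne <- dim(epochs$epochs)[1]
  if (ne < 1) abort("at least one retained epoch is required")
  fs <- epochs$sampling_rate
  mi_sum <- matrix(0, length(phase_freqs), length(amp_freqs))
  empty <- 0L
  for (e in seq_len(ne)) {
    x <- epochs$epochs[e, ci, ]
    bins <- lapply(phase_freqs, function(f) {
      phase_bin_index(Arg(morlet_analytic(x, fs, f, n_cycles)), n_bins)
    })
    amps <- lapply(amp_freqs, function(f) {
      Mod(morlet_analytic(x, fs, f, n_cycles))
    })
    for (i in seq_along(phase_freqs)) {
      for (j in seq_along(amp_freqs)) {
        res <- tort_mi_core(bins[[i]], amps[[j]], n_bins)
        mi_sum[i, j] <- mi_sum[i, j] + res[1]
        empty <- empty + res[2]
      }
    }
  }
  structure(list(phase_freqs = phase_freqs, amp_freqs = amp_freqs,
                 mi = mi_sum / ne, n_epochs = ne,
                 empty_bins = as.integer(empty), channel = channel),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram> %d x %d cells, %d epoch(s), max MI %.4g at (%g Hz phase, %g Hz amp)\n",
              nrow(x$mi), ncol(x$mi), x$n_epochs, max(x$mi),
              x$phase_freqs[which(x$mi == max(x$mi), arr.ind = TRUE)[1, 1]],
              x$amp_freqs[which(x$mi == max(x$mi), arr.ind = TRUE)[1, 2]]))
  invisible(x)
}

#' Band-pair mean modulation indices
#'
#' Averages comodulogram cells over the four canonical theta-gamma band
#' pairs, using the band-edge convention of the spectral stage
#' (half-open; high gamma closed at 80 Hz): theta-1 phase bins are
#' 4-5.5 Hz, theta-2 6-7.5 Hz, low-gamma amplitude bins 30-45 Hz,
#' high-gamma 55-80 Hz on the default grids.
#'
#' @param comod a [comodulogram()].
#' @return A tibble with columns `pair`, `value`, `n_cells`.
#' @export
band_pair_mi <- function(comod) {
  stopifnot(inherits(comod, "comodulogram"))
  bd <- band_definitions()
  pick <- function(name) bd[bd$band == name, ]
  pairs <- tidyr::expand_grid(theta = c("Theta1", "Theta2"),
                              gamma = c("LowGamma", "HighGamma"))
  purrr::pmap_dfr(pairs, function(theta, gamma) {
    tb <- pick(theta); gb <- pick(gamma)
    pi_ <- band_bins(comod$phase_freqs, tb$low, tb$high, tb$closed_right)
    ai <- band_bins(comod$amp_freqs, gb$low, gb$high, gb$closed_right)
    tibble::tibble(pair = paste0(theta, "-", gamma),
                   value = mean(comod$mi[pi_, ai, drop = FALSE]),
                   n_cells = length(pi_) * length(ai))
  })
}
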