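#' Canonical frequency-band definitions
#'
#' Delta 1-4 Hz, theta-1 4-6, theta-2 6-8, low gamma 30-50 and high gamma
#' 51-80 Hz. Bands are half-open on the right (`low <= f < high`) so that
#' the abutting edges at 4, 6 and 8 Hz are disjoint; high gamma is closed
#' at 80 Hz. The 50-51 Hz gap between the gamma bands is kept as defined.
#'
#' @return A tibble with columns `band`, `low`, `high`, `closed_right`.
#' @export
band_definitions <- function() {
  tibble::tibble(
    band = c("Delta", "Theta1", "Theta2", "LowGamma", "HighGamma"),
    low = c(1, 4, 6, 30, 51),
    high = c(4, 6, 8, 50, 80),
    closed_right = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Welch power spectral density of one epoch
#'
#' Averaged modified periodograms over Hamming-windowed segments of
#' `segment_length` samples with fractional `overlap` (defaults: 1-s
#' segments, 50% overlap, so a 4-s epoch at 1000 Hz yields 7 segments and
#' a 1 Hz grid from 0 to Nyquist). One-sided density in signal-units^2/Hz;
#' the integral over (0, Nyquist] is consistent with the signal variance
#' up to window correction.
#'
#' @param x numeric vector, one epoch of one channel.
#' @param sampling_rate Hz.
#' @param segment_length samples per segment, default 1000.
#' @param overlap fractional overlap in \[0, 1), default 0.5.
#' @return A tibble with columns `freq` (Hz) and `power` (density).
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 4, length.out = 4000))
#' psd <- welch_psd(x, 1000)
#' psd$freq[which.max(psd$power)] # 10
#' @export
welch_psd <- function(x, sampling_rate, segment_length = 1000,
                      overlap = 0.5) {
  n <- length(x)
  if (segment_length > n) {
    abort(sprintf("segment_length (%d) exceeds epoch length (%d)",
                  segment_length, n))
  }
  assert_scalar_num(overlap, "overlap", 0, 1 - 1e-9)
  hop <- round(segment_length * (1 - overlap))
  starts <- seq(1, n - segment_length + 1, by = hop)
  w <- hamming_window(segment_length)
  u <- sum(w^2) # window power normalization
  nf <- segment_length %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment_length - 1)] * w
    p <- Mod(fft(seg))^2 / (sampling_rate * u)
    half <- p[seq_len(nf)]
    scale <- rep(2, nf)
    scale[1] <- 1
    if (segment_length %% 2 == 0) scale[nf] <- 1
    acc <- acc + half * scale
  }
  tibble::tibble(freq = (seq_len(nf) - 1) * sampling_rate / segment_length,
                 power = acc / length(starts))
}

#' Median-filter a power spectrum across frequency bins
#'
#' Running median with an odd kernel (5 bins by default); edges are
#' handled by reflection, so a constant spectrum is unchanged and a
#' single-bin line-noise spike is removed. Kernel 1 is the identity.
#'
#' @param power numeric density vector on the frequency grid.
#' @param kernel_bins odd positive kernel width, default 5.
#' @return A numeric vector of the same length.
#' @export
median_smooth <- function(power, kernel_bins = 5) {
  assert_scalar_num(kernel_bins, "kernel_bins", lower = 1)
  if (kernel_bins %% 2 != 1) abort("`kernel_bins` must be odd")
  if (kernel_bins == 1 || length(power) == 1) return(power)
  h <- (kernel_bins - 1) / 2
  n <- length(power)
  # reflection padding (without repeating the edge sample)
  pad <- c(power[(h + 1):2], power, power[(n - 1):(n - h)])
  vapply(seq_len(n), function(i) median(pad[i:(i + 2 * h)]), numeric(1))
}

#' Natural-log transform of a power spectrum
#'
#' `ln(max(power, floor))` with the floor defaulting to the smallest
#' positive normalized double, keeping the transform total (zero density
#' maps to a large negative but finite value) and order-preserving.
#'
#' @param power nonnegative density vector.
#' @param floor positive lower clamp before the log.
#' @return Numeric vector of log densities (ln units).
#' @export
log_transform <- function(power, floor = .Machine$double.xmin) {
  if (any(power < 0)) abort("power density must be nonnegative")
  log(pmax(power, floor))
}

#' Per-epoch log spectra of one channel
#'
#' Runs the fixed spectral pipeline order on every retained epoch: Welch
#' PSD, median filter, natural log.
#'
#' @param epochs an [epoch_set()].
#' @param channel channel label.
#' @param segment_length,overlap,kernel_bins stage parameters.
#' @return A list with `freq` (Hz grid) and `log_power`, an
#'   epochs x bins matrix.
#' @export
epoch_spectra <- function(epochs, channel, segment_length = 1000,
                          overlap = 0.5, kernel_bins = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  ci <- match(channel, epochs$channel_labels)
  if (is.na(ci)) abort(sprintf("unknown channel `%s`", channel))
  ne <- dim(epochs$epochs)[1]
  first <- welch_psd(epochs$epochs[1, ci, ], epochs$sampling_rate,
                     segment_length, overlap)
  lp <- matrix(0, ne, nrow(first))
  lp[1, ] <- log_transform(median_smooth(first$power, kernel_bins))
  if (ne > 1) {
    for (i in 2:ne) {
      p <- welch_psd(epochs$epochs[i, ci, ], epochs$sampling_rate,
                     segment_length, overlap)$power
      lp[i, ] <- log_transform(median_smooth(p, kernel_bins))
    }
  }
  list(freq = first$freq, log_power = lp)
}

#' Animal-average power spectrum
#'
#' Arithmetic mean of the per-epoch log spectra per frequency bin; the
#' number of epochs averaged is recorded.
#'
#' @param spectra result of [epoch_spectra()], or an epochs x bins matrix
#'   of log power with a shared `freq` grid.
#' @param freq frequency grid (required when `spectra` is a bare matrix).
#' @return A tibble with columns `freq`, `log_power`, `n_epochs`.
#' @export
animal_average <- function(spectra, freq = NULL) {
  if (is.list(spectra) && !is.null(spectra$log_power)) {
    freq <- spectra$freq
    lp <- spectra$log_power
  } else {
    lp <- as.matrix(spectra)
  }
  if (is.null(freq) || length(freq) != ncol(lp)) {
    abort("a frequency grid matching the spectra is required")
  }
  if (nrow(lp) < 1) abort("at least one epoch is required")
  tibble::tibble(freq = freq, log_power = colMeans(lp),
                 n_epochs = nrow(lp))
}

band_bins <- function(freq, low, high, closed_right = FALSE) {
  sel <- freq >= low & (if (closed_right) freq <= high else freq < high)
  if (!any(sel)) {
    abort(sprintf("band [%g, %g%s has no bins on the frequency grid",
                  low, high, if (closed_right) "]" else ")"))
  }
  which(sel)
}

#' Band power from an averaged log spectrum
#'
#' Mean of the log-power bins falling in the band (half-open right edge;
#' high gamma closed at 80 Hz), i.e. mean log density rather than the log
#' of integrated power; `method = "integrated"` gives the natural log of
#' the integrated linear-scale density instead.
#'
#' @param spectrum tibble with `freq` and `log_power` (see
#'   [animal_average()]).
#' @param band a band name from [band_definitions()], or `c(low, high)`.
#' @param method `"mean_log"` (default) or `"integrated"`.
#' @return Scalar band power in ln units.
#' @export
band_power <- function(spectrum, band, method = c("mean_log", "integrated")) {
  method <- match.arg(method)
  if (is.character(band)) {
    bd <- band_definitions()
    row <- bd[bd$band == band, ]
    if (nrow(row) != 1) {
      abort(sprintf("unknown band `%s`; known: %s", band,
                    paste(bd$band, collapse = ", ")))
    }
    low <- row$low; high <- row$high; cr <- row$closed_right
  } else {
    low <- band[1]; high <- band[2]; cr <- FALSE
  }
  idx <- band_bins(spectrum$freq, low, high, cr)
  if (method == "mean_log") {
    mean(spectrum$log_power[idx])
  } else {
    df <- if (length(spectrum$freq) > 1) diff(spectrum$freq[1:2]) else 1
    log(sum(exp(spectrum$log_power[idx])) * df)
  }
}

#' Band-power table for all channels and bands
#'
#' Convenience wrapper running Welch, median filter, log, epoch averaging
#' and band extraction for every channel of a retained epoch set.
#'
#' @param epochs an [epoch_set()] of retained epochs.
#' @param bands band-definition tibble, default [band_definitions()].
#' @inheritParams epoch_spectra
#' @return A tibble with columns `channel`, `band`, `value` (ln units),
#'   `n_epochs`.
#' @export
band_power_table <- function(epochs, bands = band_definitions(),
                             segment_length = 1000, overlap = 0.5,
                             kernel_bins = 5) {
  purrr::map_dfr(epochs$channel_labels, function(ch) {
    avg <- animal_average(epoch_spectra(epochs, ch, segment_length, overlap,
                                        kernel_bins))
    tibble::tibble(
      channel = ch, band = bands$band,
      value = purrr::map_dbl(bands$band, ~ band_power(avg, .x)),
      n_epochs = avg$n_epochs[1]
    )
  })
}
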