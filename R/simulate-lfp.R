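#' Specification for a synthetic LFP signal
#'
#' Describes a 1/f ("pink-ish") background with optional band-limited
#' oscillations, optional theta-gamma phase-amplitude coupling, and
#' optional artifacts. The defaults mirror a typical rodent depth-electrode
#' recording: 1000 Hz sampling, a 1/f^1 background, and band structure that
#' respects the delta (1-4 Hz), theta-1 (4-6), theta-2 (6-8), low-gamma
#' (30-50) and high-gamma (51-80) bands the analysis quantifies.
#'
#' Coupling is synthesized by multiplicative envelope modulation: a
#' narrowband slow oscillation in `phase_band` is generated, its
#' instantaneous phase \eqn{\theta(t)} extracted, and a narrowband carrier
#' in `amp_band` is multiplied by the envelope
#' \deqn{g(t) = (1 + m \cos(\theta(t) - \phi_0)) / 2,}
#' so the modulation depth `m` in \[0, 1\] controls the Tort modulation
#' index monotonically: `m = 0` gives no coupling, `m = 1` full-depth
#' modulation.
#'
#' @param duration signal duration in seconds (> 0).
#' @param sampling_rate Hz, default 1000.
#' @param noise_exponent slope alpha >= 0 of the 1/f^alpha background.
#' @param noise_rms RMS amplitude of the background, microvolts.
#' @param oscillations list of `list(freq =, bandwidth =, rms =)` entries,
#'   each a band-limited oscillation added to the background.
#' @param coupling optional `list(phase_band = c(lo, hi), amp_band =
#'   c(lo, hi), depth = m, preferred_phase = phi0, phase_rms =, amp_rms =)`.
#' @param artifacts optional `list(spike_rate =, spike_amplitude =,
#'   flatline_rate =, flatline_length =)`; rates are events per minute.
#' @param seed integer seed; identical spec + seed is bit-reproducible.
#' @return A validated list of class `lfp_spec`.
#' @seealso [simulate_lfp()]
#' @export
lfp_spec <- function(duration, sampling_rate = 1000, noise_exponent = 1,
                     noise_rms = 30, oscillations = list(), coupling = NULL,
                     artifacts = NULL, seed = 1) {
  assert_scalar_num(duration, "duration", lower = .Machine$double.eps)
  assert_scalar_num(sampling_rate, "sampling_rate", lower = 1)
  assert_scalar_num(noise_exponent, "noise_exponent", lower = 0)
  assert_scalar_num(noise_rms, "noise_rms", lower = 0)
  nyq <- sampling_rate / 2
  for (osc in oscillations) {
    if (is.null(osc$freq) || is.null(osc$rms)) {
      abort("each oscillation needs `freq` and `rms` (and optional `bandwidth`)")
    }
    if (osc$freq >= nyq) {
      abort(sprintf("oscillation frequency %g Hz is at or above Nyquist (%g Hz)",
                    osc$freq, nyq))
    }
  }
  if (!is.null(coupling)) {
    assert_scalar_num(coupling$depth, "coupling$depth", 0, 1)
    bands <- c(coupling$phase_band, coupling$amp_band)
    if (length(bands) != 4 || any(bands <= 0)) {
      abort("coupling needs `phase_band` and `amp_band` as positive Hz pairs")
    }
    if (any(bands >= nyq)) {
      abort(sprintf("coupling band edge at or above Nyquist (%g Hz)", nyq))
    }
    coupling$preferred_phase <- coupling$preferred_phase %||% 0
    coupling$phase_rms <- coupling$phase_rms %||% 20
    coupling$amp_rms <- coupling$amp_rms %||% 10
  }
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 noise_exponent = noise_exponent, noise_rms = noise_rms,
                 oscillations = oscillations, coupling = coupling,
                 artifacts = artifacts, seed = seed),
            class = "lfp_spec")
}

# 1/f^alpha noise by spectral shaping of complex white noise, scaled to a
# target RMS. Exact, fast and fully determined by the RNG stream.
colored_noise <- function(n, sampling_rate, alpha, rms) {
  if (rms == 0) return(numeric(n))
  freqs <- seq(0, n - 1) / n * sampling_rate
  freqs <- pmin(freqs, sampling_rate - freqs) # two-sided, symmetric
  amp <- ifelse(freqs > 0, freqs^(-alpha / 2), 0)
  spec <- amp * complex(real = rnorm(n), imaginary = rnorm(n))
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / sqrt(mean(x^2))
}

# Band-limited Gaussian oscillation: white noise shaped by a Gaussian
# spectral bump centered at `freq` with sd `bandwidth/2`, scaled to RMS.
narrowband_noise <- function(n, sampling_rate, freq, bandwidth, rms) {
  if (rms == 0) return(numeric(n))
  f <- seq(0, n - 1) / n * sampling_rate
  f <- pmin(f, sampling_rate - f)
  amp <- exp(-0.5 * ((f - freq) / (bandwidth / 2))^2)
  spec <- amp * complex(real = rnorm(n), imaginary = rnorm(n))
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / sqrt(mean(x^2))
}

# Instantaneous phase of a (narrowband) real signal via the FFT analytic
# signal.
analytic_phase <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Arg(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Simulate a multi-channel LFP recording
#'
#' Generates one independent realization of the spec per channel: 1/f
#' background plus oscillations, plus the phase-amplitude-coupled pair if
#' `coupling` is set, plus artifact transients/flatlines if requested.
#'
#' @param spec an [lfp_spec()].
#' @param channel_labels channels to synthesize (default the canonical
#'   four-electrode montage).
#' @param meta optional [animal_meta()] attached to the result.
#' @return A [recording()].
#' @examples
#' spec <- lfp_spec(duration = 8, coupling = list(
#'   phase_band = c(6, 8), amp_band = c(50, 70), depth = 0.8))
#' rec <- simulate_lfp(spec, channel_labels = "HPC")
#' @export
simulate_lfp <- function(spec,
                         channel_labels = c("HPC", "RSC", "MEC", "Tha"),
                         meta = NULL) {
  stopifnot(inherits(spec, "lfp_spec"))
  n <- round(spec$duration * spec$sampling_rate)
  fs <- spec$sampling_rate
  with_seed(spec$seed, {
    samples <- do.call(rbind, lapply(channel_labels, function(ch) {
      x <- colored_noise(n, fs, spec$noise_exponent, spec$noise_rms)
      for (osc in spec$oscillations) {
        bw <- osc$bandwidth %||% 1
        x <- x + narrowband_noise(n, fs, osc$freq, bw, osc$rms)
      }
      cp <- spec$coupling
      if (!is.null(cp)) {
        slow <- narrowband_noise(n, fs, mean(cp$phase_band),
                                 diff(cp$phase_band), cp$phase_rms)
        carrier <- narrowband_noise(n, fs, mean(cp$amp_band),
                                    diff(cp$amp_band), 1)
        theta <- analytic_phase(slow)
        g <- (1 + cp$depth * cos(theta - cp$preferred_phase)) / 2
        fast <- carrier * g
        fast <- fast * cp$amp_rms / sqrt(mean(fast^2))
        x <- x + slow + fast
      }
      ar <- spec$artifacts
      if (!is.null(ar)) {
        n_spikes <- round((ar$spike_rate %||% 0) * spec$duration / 60)
        if (n_spikes > 0) {
          at <- sample.int(n, n_spikes)
          x[at] <- x[at] + sample(c(-1, 1), n_spikes, TRUE) *
            (ar$spike_amplitude %||% 2000)
        }
        n_flat <- round((ar$flatline_rate %||% 0) * spec$duration / 60)
        if (n_flat > 0) {
          len <- round((ar$flatline_length %||% 0.2) * fs)
          for (s in sample.int(max(1, n - len), n_flat)) {
            x[s:(s + len - 1)] <- x[s]
          }
        }
      }
      x
    }))
    recording(samples, fs, channel_labels, meta)
  })
}
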