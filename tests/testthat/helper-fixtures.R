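# Shared fixture builders; everything is generated in code at test time.

# recording holding a pure sinusoid (plus optional noise) on every channel
sine_recording <- function(freq = 10, duration = 8, fs = 1000, amp = 1,
                           channels = "HPC", noise_sd = 0) {
  n <- duration * fs
  t <- (seq_len(n) - 1) / fs
  x <- amp * sin(2 * pi * freq * t)
  samples <- do.call(rbind, lapply(seq_along(channels), function(i) {
    x + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  }))
  recording(samples, fs, channels)
}

# epoch_set straight from an epochs x channels x samples array
epochs_from_array <- function(arr, fs = 1000, channels = NULL) {
  channels <- channels %||% paste0("ch", seq_len(dim(arr)[2]))
  epoch_set(arr, fs, channels, dim(arr)[3] / fs)
}

# independent straight-line Tort MI oracle (no shared code with the package)
oracle_tort_mi <- function(phase, amplitude, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  means <- numeric(n_bins)
  for (j in seq_len(n_bins)) {
    inbin <- phase > edges[j] & phase <= edges[j + 1]
    if (j == 1) inbin <- inbin | phase <= edges[1]
    means[j] <- if (any(inbin)) mean(amplitude[inbin]) else 0
  }
  p <- means / sum(means)
  h <- 0
  for (j in seq_len(n_bins)) if (p[j] > 0) h <- h - p[j] * log(p[j])
  (log(n_bins) - h) / log(n_bins)
}

# independent double-loop Higuchi oracle
oracle_higuchi <- function(x, kmax = 13) {
  n <- length(x)
  lk <- numeric(kmax)
  for (k in 1:kmax) {
    lm <- numeric(k)
    for (m in 1:k) {
      ni <- floor((n - m) / k)
      s <- 0
      for (i in 1:ni) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      lm[m] <- s * (n - 1) / (ni * k) / k
    }
    lk[k] <- mean(lm)
  }
  fit <- stats::lm(log(lk) ~ log(1 / (1:kmax)))
  unname(coef(fit)[2])
}

# brute-force averaged Hamming periodogram (Welch oracle)
oracle_welch <- function(x, fs, L = 1000, overlap = 0.5) {
  hop <- round(L * (1 - overlap))
  starts <- seq(1, length(x) - L + 1, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  nf <- L %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    # direct DFT via vapply (slow but independent of fft conventions)
    sp <- Mod(stats::fft(seg))^2 / (fs * sum(w^2))
    one <- sp[1:nf] * c(1, rep(2, nf - 2), 1)
    acc <- acc + one
  }
  acc / length(starts)
}

# O(n^2) all-pairs dilation oracle
oracle_dilate <- function(mask, radius) {
  dims <- dim(mask)
  pos <- which(mask == 1, arr.ind = TRUE)
  out <- array(0L, dims)
  for (z in 1:dims[1]) for (y in 1:dims[2]) for (x in 1:dims[3]) {
    if (nrow(pos) > 0) {
      d2 <- (pos[, 1] - z)^2 + (pos[, 2] - y)^2 + (pos[, 3] - x)^2
      if (min(d2) <= radius^2) out[z, y, x] <- 1L
    }
  }
  out
}

# standard-design study spec used across the stats tests
histology_like_spec <- function(...) {
  study_spec(timepoints = c("1mpi", "3mpi", "5mpi"),
             regions = c("hippocampus", "entorhinal", "isocortex",
                         "thalamus"), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
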