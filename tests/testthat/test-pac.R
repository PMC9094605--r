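test_that("Morlet convolution behaves as an eigenfunction filter", {
  fs <- 1000
  t <- (0:3999) / fs
  a <- morlet_analytic(2.5 * sin(2 * pi * 8 * t), fs, 8)
  mid <- 1000:3000
  expect_true(all(abs(Mod(a)[mid] - 2.5) / 2.5 < 0.05))
  # phase advances by 2 pi f per second
  dphi <- diff(Arg(a)[mid])
  dphi <- dphi[dphi > -pi] # unwrap jumps
  expect_equal(mean(dphi) * fs / (2 * pi), 8, tolerance = 0.01)

  expect_equal(Mod(morlet_analytic(numeric(2000), fs, 40)), numeric(2000))
  expect_error(morlet_analytic(rnorm(1000), fs, 600), "Nyquist")
  expect_error(morlet_analytic(rnorm(10), fs, 8), "wavelet support")
})

test_that("tort_mi hits the analytic extremes and matches the brute-force oracle", {
  set.seed(31)
  ph <- runif(1e4, -pi, pi)
  expect_lt(tort_mi(ph, rep(1, 1e4)), 1e-12)

  # all amplitude mass in one phase bin
  amp <- ifelse(ph > 0 & ph <= pi / 9, 1, 0)
  expect_equal(tort_mi(ph, amp), 1)

  for (i in 1:3) {
    phase <- runif(1e4, -pi, pi)
    amplitude <- abs(rnorm(1e4))
    expect_lt(abs(tort_mi(phase, amplitude) -
                    oracle_tort_mi(phase, amplitude)), 1e-12)
  }
  expect_error(tort_mi(ph, rep(1, 10)), "equal length")
})

test_that("tort_mi is invariant to amplitude scaling and global phase rotation", {
  set.seed(32)
  ph <- runif(5000, -pi, pi)
  am <- abs(rnorm(5000))
  base <- tort_mi(ph, am)
  expect_equal(tort_mi(ph, am * 7.3), base)
  rot <- ((ph + 2 * pi / 18 + pi) %% (2 * pi)) - pi # one whole bin
  expect_equal(tort_mi(rot, am), base, tolerance = 1e-12)
})

test_that("comodulogram localizes simulated theta-gamma coupling and stays at the noise floor for white noise", {
  spec <- lfp_spec(duration = 24, seed = 41, noise_rms = 30,
                   coupling = list(phase_band = c(7, 9), amp_band = c(55, 65),
                                   depth = 0.9, phase_rms = 30, amp_rms = 15))
  rec <- simulate_lfp(spec, channel_labels = "HPC")
  ep <- segment_epochs(rec)
  com <- comodulogram(ep, "HPC")
  expect_equal(dim(com$mi), c(21L, 39L))
  expect_true(all(com$mi >= 0 & com$mi <= 1))
  peak <- which(com$mi == max(com$mi), arr.ind = TRUE)
  expect_lte(abs(com$phase_freqs[peak[1]] - 8), 0.5)
  expect_lte(abs(com$amp_freqs[peak[2]] - 60), 5)

  noise <- simulate_lfp(lfp_spec(duration = 16, noise_exponent = 0,
                                 seed = 43), channel_labels = "HPC")
  com0 <- comodulogram(segment_epochs(noise), "HPC")
  expect_lt(max(com0$mi), 0.05)
})

test_that("band-pair averaging matches the enumerated index sets", {
  com <- structure(list(phase_freqs = seq(2, 12, 0.5),
                        amp_freqs = seq(10, 200, 5),
                        mi = matrix(runif(21 * 39), 21, 39),
                        n_epochs = 1L, empty_bins = 0L, channel = "HPC"),
                   class = "comodulogram")
  pairs <- band_pair_mi(com)
  idx <- list(
    "Theta1-LowGamma" = list(p = c(4, 4.5, 5, 5.5), a = c(30, 35, 40, 45)),
    "Theta1-HighGamma" = list(p = c(4, 4.5, 5, 5.5),
                              a = c(55, 60, 65, 70, 75, 80)),
    "Theta2-LowGamma" = list(p = c(6, 6.5, 7, 7.5), a = c(30, 35, 40, 45)),
    "Theta2-HighGamma" = list(p = c(6, 6.5, 7, 7.5),
                              a = c(55, 60, 65, 70, 75, 80)))
  for (nm in names(idx)) {
    pi_ <- match(idx[[nm]]$p, com$phase_freqs)
    ai <- match(idx[[nm]]$a, com$amp_freqs)
    expect_equal(pairs$value[pairs$pair == nm], mean(com$mi[pi_, ai]))
    expect_equal(pairs$n_cells[pairs$pair == nm], length(pi_) * length(ai))
  }

  com$mi <- matrix(0.42, 21, 39)
  expect_equal(band_pair_mi(com)$value, rep(0.42, 4))
  com$mi <- matrix(0, 21, 39)
  expect_equal(band_pair_mi(com)$value, rep(0, 4))
})

test_that("epoch-averaged MI never exceeds the per-epoch maximum", {
  spec <- lfp_spec(duration = 16, seed = 44,
                   coupling = list(phase_band = c(6, 8), amp_band = c(50, 70),
                                   depth = 0.7))
  ep <- segment_epochs(simulate_lfp(spec, channel_labels = "HPC"))
  per_epoch <- vapply(seq_len(dim(ep$epochs)[1]), function(i) {
    x <- ep$epochs[i, 1, ]
    tort_mi(Arg(morlet_analytic(x, 1000, 7)),
            Mod(morlet_analytic(x, 1000, 60)))
  }, numeric(1))
  one <- epoch_set(ep$epochs, 1000, "HPC", 4)
  com <- comodulogram(one, "HPC", phase_freqs = 7, amp_freqs = 60)
  expect_equal(com$mi[1, 1], mean(per_epoch), tolerance = 1e-12)
  expect_lte(com$mi[1, 1], max(per_epoch))
})
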