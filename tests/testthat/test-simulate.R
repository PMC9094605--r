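test_that("simulated LFP is deterministic, rejects super-Nyquist bands, and a pure tone peaks at its bin", {
  spec <- lfp_spec(duration = 6, seed = 42,
                   oscillations = list(list(freq = 10, bandwidth = 0.5,
                                            rms = 20)))
  r1 <- simulate_lfp(spec, channel_labels = c("HPC", "RSC"))
  r2 <- simulate_lfp(spec, channel_labels = c("HPC", "RSC"))
  expect_identical(r1$samples, r2$samples)
  expect_equal(dim(r1$samples), c(2L, 6000L))

  expect_error(lfp_spec(duration = 1, oscillations =
                          list(list(freq = 600, rms = 1))), "Nyquist")
  expect_error(lfp_spec(duration = 1, coupling =
                          list(phase_band = c(6, 8), amp_band = c(400, 600),
                               depth = 0.5)), "Nyquist")
  expect_error(lfp_spec(duration = 1, coupling =
                          list(phase_band = c(6, 8), amp_band = c(50, 70),
                               depth = 1.5)), "depth")

  tone <- lfp_spec(duration = 4, noise_rms = 0, seed = 1,
                   oscillations = list(list(freq = 10, bandwidth = 0.2,
                                            rms = 10)))
  psd <- welch_psd(simulate_lfp(tone, channel_labels = "HPC")$samples[1, ],
                   1000)
  expect_equal(psd$freq[which.max(psd$power)], 10)
})

test_that("measured Tort MI is near zero without coupling and increases with depth", {
  mi_at_depth <- function(m, seed) {
    spec <- lfp_spec(duration = 60, seed = seed,
                     coupling = list(phase_band = c(6, 8),
                                     amp_band = c(50, 70), depth = m))
    x <- simulate_lfp(spec, channel_labels = "HPC")$samples[1, ]
    tort_mi(Arg(morlet_analytic(x, 1000, 7)),
            Mod(morlet_analytic(x, 1000, 60)))
  }
  expect_lt(mi_at_depth(0, 5), 0.01)
  for (seed in 1:2) {
    mis <- vapply(c(0, 0.3, 0.6, 0.9), mi_at_depth, numeric(1), seed = seed)
    expect_true(all(diff(mis) > 0))
  }
})

test_that("1/f spectral slope is recovered within 0.2 for alpha 0, 1, 2", {
  for (alpha in c(0, 1, 2)) {
    spec <- lfp_spec(duration = 60, noise_exponent = alpha, seed = 8)
    x <- simulate_lfp(spec, channel_labels = "HPC")$samples[1, ]
    psd <- welch_psd(x, 1000, segment_length = 4000)
    sel <- psd$freq >= 2 & psd$freq <= 100
    slope <- -coef(stats::lm(log(psd$power[sel]) ~ log(psd$freq[sel])))[2]
    expect_lt(abs(slope - alpha), 0.2)
  }
})

test_that("motion traces honor the active-bout fraction at the extremes and on average", {
  still <- simulate_motion(motion_spec(duration = 60,
                                       active_bout_fraction = 0, seed = 1))
  expect_true(all(still$displacement == 0))
  expect_warning(lab0 <- classify_activity(still, 15), "inactive")
  expect_identical(lab0, rep(0L, 15))

  busy <- simulate_motion(motion_spec(duration = 60,
                                      active_bout_fraction = 1, seed = 1))
  expect_identical(classify_activity(busy, 15), rep(1L, 15))

  fracs <- vapply(1:5, function(s) {
    tr <- simulate_motion(motion_spec(duration = 3600,
                                      active_bout_fraction = 0.5, seed = s))
    mean(classify_activity(tr, 900))
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.1)
})

test_that("study tables reproduce declared effects exactly when noiseless", {
  spec <- study_spec(coefficients = c("(Intercept)" = 2),
                     random_intercept_sd = 0, residual_sd = 0, seed = 1)
  tbl <- simulate_study_table(spec)
  expect_true(all(tbl$value == 2))

  spec2 <- study_spec(coefficients = c("(Intercept)" = 1, "genotypeWT" = -0.7,
                                       "genotypeWT:treatmenttau" = 0.3),
                      random_intercept_sd = 0, residual_sd = 0, seed = 1)
  tbl2 <- simulate_study_table(spec2)
  cell <- function(g, tr) unique(tbl2$value[tbl2$genotype == g &
                                              tbl2$treatment == tr])
  expect_equal(cell("TG", "buffer"), 1)
  expect_equal(cell("WT", "buffer"), 0.3)
  expect_equal(cell("WT", "tau"), 0.6)

  expect_error(simulate_study_table(study_spec(
    coefficients = c(nonsense = 1))), "valid terms")
})

test_that("pathology volumes respect geometry, affinity ordering and exact construction", {
  none <- simulate_pathology(pathology_spec(shape = c(16, 20, 20),
                                            plaque_count = 0, tau_count = 5,
                                            affinity = 1, seed = 3))
  expect_equal(sum(none$plaque_mask), 0)
  loads <- split_colocalized(none$tau_mask, none$plaque_mask, none$regions)
  expect_true(all(loads$colocalized_load == 0))
  expect_equal(loads$noncolocalized_load, loads$load)

  cf <- vapply(1:5, function(s) {
    vapply(c(0, 1), function(a) {
      sim <- simulate_pathology(pathology_spec(shape = c(24, 32, 32),
                                               plaque_count = 10,
                                               tau_count = 15, affinity = a,
                                               seed = s))
      sim$truth$colocalized_fraction
    }, numeric(1))
  }, numeric(2))
  expect_true(all(cf[2, ] > cf[1, ]))

  # single 3^3 cluster wholly inside a 10^3 region: ratio exactly 27/1000
  vol <- array(0L, c(12, 12, 22))
  labels <- array(0L, c(12, 12, 22))
  labels[2:11, 2:11, 2:11] <- 1L
  labels[2:11, 2:11, 13:22] <- 2L
  vol[5:7, 5:7, 5:7] <- 1L
  expect_identical(label_ratio(vol, labeled_volume(labels), 1), 27 / 1000)

  s1 <- simulate_pathology(pathology_spec(seed = 9))
  s2 <- simulate_pathology(pathology_spec(seed = 9))
  expect_identical(s1$tau_mask, s2$tau_mask)
  expect_identical(s1$plaque_mask, s2$plaque_mask)
})
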