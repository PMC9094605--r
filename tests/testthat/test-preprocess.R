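test_that("segmentation yields floor(duration/epoch) contiguous epochs and rejects short sessions", {
  rec <- recording(matrix(seq_len(10000), nrow = 1), 1000, "HPC")
  ep <- segment_epochs(rec)
  expect_equal(dim(ep$epochs), c(2, 1, 4000))
  expect_equal(ep$epochs[1, 1, ], as.numeric(1:4000))
  expect_equal(ep$epochs[2, 1, ], as.numeric(4001:8000))

  short <- recording(matrix(rnorm(3900), nrow = 1), 1000, "HPC")
  expect_error(segment_epochs(short), "shorter than one")

  hour <- recording(matrix(0, nrow = 1, ncol = 3600 * 250), 250, "HPC")
  expect_equal(dim(segment_epochs(hour)$epochs)[1], 900)
})

test_that("activity classification uses the relative threshold rule", {
  # constant displacement: every frame exceeds 30% of peak -> all active
  const <- motion_trace(rep(5, 1000), 25)
  expect_identical(classify_activity(const, 10), rep(1L, 10))

  # a single supra-threshold frame cannot carry an epoch (1/100 < 0.25)
  lone <- numeric(1000); lone[150] <- 10
  expect_identical(classify_activity(motion_trace(lone, 25), 10),
                   rep(0L, 10))

  # scale invariance: threshold is relative to the session peak
  tr <- simulate_motion(motion_spec(duration = 120,
                                    active_bout_fraction = 0.4, seed = 2))
  scaled <- motion_trace(tr$displacement * 17.3, tr$frame_rate)
  expect_identical(classify_activity(tr, 30), classify_activity(scaled, 30))
})

test_that("artifact flags catch spikes, outliers and flatlines, and are monotone in the limits", {
  set.seed(11)
  arr <- array(rnorm(6 * 1 * 4000, sd = 20), c(6, 1, 4000))
  arr[2, 1, 1000] <- 15000            # amplitude spike
  arr[4, 1, 101:300] <- arr[4, 1, 101] # flatline run of 200
  ep <- epochs_from_array(arr)
  flags <- detect_artifacts(ep, artifact_params())
  expect_identical(flags, c(0L, 1L, 0L, 1L, 0L, 0L))

  loose <- detect_artifacts(ep, artifact_params(amplitude_limit = 1e6,
                                                zscore_limit = 1e6,
                                                flatline_min_run = 4001))
  expect_true(all(loose <= flags))
  expect_identical(loose, rep(0L, 6))

  tight <- detect_artifacts(ep, artifact_params(amplitude_limit = 1))
  expect_true(all(tight >= flags))
})

test_that("epoch selection is exact set arithmetic and idempotent", {
  arr <- array(rnorm(10 * 1 * 400), c(10, 1, 400))
  ep <- epoch_set(arr, 100, "HPC", 4,
                  activity = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0),
                  artifact = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  sel <- select_analysis_epochs(ep)
  expect_equal(dim(sel$epochs)[1], 4)
  expect_equal(sel$index, 3:6)
  again <- select_analysis_epochs(sel)
  expect_identical(again$epochs, sel$epochs)
  expect_identical(again$index, sel$index)

  ep$activity <- rep(0L, 10)
  expect_error(select_analysis_epochs(ep), "excluded")
})

test_that("session inclusion respects the retained-epoch threshold at the boundary", {
  mk <- function(n_act) {
    arr <- array(0, c(40, 1, 400))
    epoch_set(arr, 100, "HPC", 4,
              activity = c(rep(1L, n_act), rep(0L, 40 - n_act)),
              artifact = rep(0L, 40))
  }
  expect_true(session_inclusion(mk(30)))
  expect_false(session_inclusion(mk(29)))
  expect_true(session_inclusion(mk(40), min_retained = 10))
})

test_that("preprocess_session gates epochs by simulated motion at the expected rate", {
  fracs <- vapply(1:3, function(s) {
    spec <- lfp_spec(duration = 120, seed = s)
    rec <- simulate_lfp(spec, channel_labels = "HPC")
    motion <- simulate_motion(motion_spec(duration = 120,
                                          active_bout_fraction = 0.5,
                                          seed = s + 50))
    pp <- preprocess_session(rec, motion)
    mean(pp$report$active)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.15)
})
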