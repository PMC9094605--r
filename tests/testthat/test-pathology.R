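test_that("label ratios cover the trivial cases exactly", {
  labels <- array(0L, c(8, 8, 8)); labels[2:7, 2:7, 2:7] <- 1L
  regions <- labeled_volume(labels)
  empty <- array(0L, c(8, 8, 8))
  expect_equal(label_ratio(empty, regions, 1), 0)
  expect_equal(label_ratio(labels, regions, 1), 1)
  expect_error(label_ratio(empty, regions, 9), "zero voxels")
  expect_error(label_ratio(array(0L, c(4, 4, 4)), regions, 1), "differ")
})

test_that("ball dilation matches the lattice count and the O(n^2) oracle", {
  # single positive voxel, radius 5: lattice points in a radius-5 ball
  lattice_count <- sum(outer(outer((-5:5)^2, (-5:5)^2, "+"), (-5:5)^2,
                             "+") <= 25)
  m <- array(0L, c(13, 13, 13)); m[7, 7, 7] <- 1L
  expect_equal(sum(dilate_mask(m, 5)), lattice_count)
  expect_equal(lattice_count, 515)

  set.seed(61)
  rnd <- array(as.integer(runif(8^3) < 0.05), c(8, 8, 8))
  for (r in c(0, 1.5, 3)) {
    expect_identical(dilate_mask(rnd, r), oracle_dilate(rnd, r))
  }
  expect_identical(dilate_mask(rnd, 0), rnd)
  # superset property
  d <- dilate_mask(rnd, 2)
  expect_true(all(d[rnd == 1] == 1))
})

test_that("colocalization split conserves the total load bit-exactly and is monotone in radius", {
  sim <- simulate_pathology(pathology_spec(shape = c(24, 32, 32),
                                           plaque_count = 8, tau_count = 12,
                                           affinity = 0.6, seed = 62))
  prev <- 0
  for (r in c(0, 2, 5)) {
    tbl <- split_colocalized(sim$tau_mask, sim$plaque_mask, sim$regions,
                             radius = r)
    expect_identical(tbl$colocalized_load + tbl$noncolocalized_load,
                     tbl$load)
    coloc <- sum(tbl$colocalized_load * tbl$n_voxels)
    expect_gte(coloc, prev)
    prev <- coloc
  }

  # tau entirely inside plaques
  tau <- array(0L, c(10, 10, 10)); tau[4:5, 4:5, 4:5] <- 1L
  labels <- array(1L, c(10, 10, 10))
  tbl <- split_colocalized(tau, tau, labeled_volume(labels), radius = 0)
  expect_equal(tbl$colocalized_load, tbl$load)
  expect_equal(tbl$noncolocalized_load, 0)
})

test_that("load correlation recovers perfect and known-rho relationships", {
  x <- c(0.1, 0.2, 0.35, 0.5)
  expect_equal(correlate_loads(x, 2 * x + 1)$r, 1.0)
  expect_equal(correlate_loads(x, -x)$r, -1.0)
  expect_error(correlate_loads(x, rep(1, 4)), "zero variance")
  expect_error(correlate_loads(x, x[1:3]), "equal length")

  set.seed(63)
  rs <- vapply(1:10, function(i) {
    z <- rnorm(200)
    x <- z + rnorm(200)
    y <- z + rnorm(200) # corr(x, y) = 0.5
    correlate_loads(x, y)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 2 / sqrt(200))
})

test_that("label_ratio is invariant under region-preserving permutation", {
  set.seed(64)
  labels <- array(sample(0:2, 6^3, TRUE), c(6, 6, 6))
  mask <- array(as.integer(runif(6^3) < 0.3), c(6, 6, 6))
  regions <- labeled_volume(labels)
  base <- label_ratio(mask, regions, 1)
  # permute voxels within each region
  perm <- seq_len(6^3)
  for (l in 0:2) {
    idx <- which(labels == l)
    perm[idx] <- sample(idx)
  }
  mask_p <- array(mask[perm], c(6, 6, 6))
  labels_p <- array(labels[perm], c(6, 6, 6))
  expect_identical(labels_p, labels)
  expect_equal(label_ratio(mask_p, regions, 1), base)
})
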