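test_that("noiseless fits recover the generating coefficients to 1e-8", {
  spec <- histology_like_spec(
    n_per_cell = 1,
    coefficients = c("(Intercept)" = 1, "genotypeWT" = -0.7,
                     "treatmenttau" = 0.4,
                     "genotypeWT:treatmenttau" = 0.25),
    random_intercept_sd = 0, residual_sd = 0, seed = 71)
  tbl <- simulate_study_table(spec)
  fit <- fit_lmm(tbl, model_spec())
  est <- tidy(fit)
  truth <- attr(tbl, "truth")$beta
  for (nm in names(truth)) {
    expect_equal(est$estimate[est$term == nm], unname(truth[nm]),
                 tolerance = 1e-8)
  }
})

test_that("a genotype main effect is recovered within 2 SE at n = 8 per cell", {
  spec <- study_spec(n_per_cell = 8, timepoints = "1mpi", regions = "HPC",
                     coefficients = c("(Intercept)" = 0, "genotypeWT" = 1.0),
                     random_intercept_sd = 0, residual_sd = 0.1, seed = 72)
  tbl <- simulate_study_table(spec)
  fit <- fit_lmm(tbl, model_spec())
  row <- dplyr::filter(tidy(fit), term == "genotypeWT")
  expect_lt(abs(row$estimate - 1.0), 2 * row$std_error)
})

test_that("variance components are recovered on average over seeds", {
  errs <- vapply(1:10, function(s) {
    spec <- study_spec(n_per_cell = 4,
                       coefficients = c("(Intercept)" = 0),
                       random_intercept_sd = 1, residual_sd = 1, seed = s)
    tbl <- simulate_study_table(spec)
    fit <- fit_lmm(tbl, model_spec())
    vc <- as.data.frame(lme4::VarCorr(fit$model))
    vc$sdcor
  }, numeric(2))
  expect_lt(abs(mean(errs[1, ]) - 1), 0.25) # animal intercept SD
  expect_lt(abs(mean(errs[2, ]) - 1), 0.25) # residual SD
})

test_that("interaction_df reproduces the factorial design ranks", {
  tbl <- histology_like_spec(n_per_cell = 1, seed = 1) |>
    simulate_study_table()
  # 2x2x2 factors, 3 timepoints, 4 regions
  expect_identical(
    interaction_df(tbl, "age:genotype:treatment:timepoint:region"), 6L)
  expect_identical(interaction_df(tbl, "age:genotype:treatment:timepoint"),
                   2L)
  ephys <- study_spec(n_per_cell = 1, timepoints = "Pre",
                      regions = c("HPC", "RSC", "MEC", "Tha"), seed = 1) |>
    simulate_study_table()
  expect_identical(interaction_df(ephys, "age:genotype:treatment:region"),
                   3L)
  expect_warning(df0 <- interaction_df(ephys,
                                       "age:genotype:treatment:timepoint"),
                 "single-level")
  expect_identical(df0, 0L)
  expect_error(interaction_df(tbl, "age:flavor"), "unknown factor")
})

test_that("interaction_df equals the model-matrix column-count difference", {
  set.seed(73)
  for (i in 1:20) {
    nlv <- sample(2:4, 3, replace = TRUE)
    d <- expand.grid(a = factor(seq_len(nlv[1])), b = factor(seq_len(nlv[2])),
                     c = factor(seq_len(nlv[3])))
    full <- ncol(stats::model.matrix(~ a * b * c, d))
    red <- ncol(stats::model.matrix(~ a * b * c - a:b:c, d))
    expect_identical(interaction_df(d, "a:b:c"), as.integer(full - red))
  }
})

test_that("likelihood-ratio statistics are nonnegative and null when the term is absent", {
  spec <- histology_like_spec(n_per_cell = 2,
                              coefficients = c("(Intercept)" = 1),
                              random_intercept_sd = 0.3, residual_sd = 1,
                              seed = 74)
  ms <- model_spec()
  for (s in 1:5) {
    spec$seed <- s
    tbl <- simulate_study_table(spec)
    r <- lrt_interaction(tbl, ms, "age:genotype:treatment:timepoint:region")
    expect_gte(r$chi2, 0)
    expect_identical(r$df, 6L)
    expect_true(r$p >= 0 && r$p <= 1)
  }
})

test_that("drop_and_refit walks down the interaction orders on ground-truth data", {
  # strong 4-way interaction, no 5-way
  spec <- histology_like_spec(
    n_per_cell = 3,
    coefficients = c("(Intercept)" = 1,
      "age6mo:genotypeWT:treatmenttau:timepoint3mpi" = 3,
      "age6mo:genotypeWT:treatmenttau:timepoint5mpi" = 3),
    random_intercept_sd = 0.2, residual_sd = 0.5, seed = 75)
  tbl <- simulate_study_table(spec)
  trail <- drop_and_refit(tbl, model_spec())
  five <- trail[trail$order == 5, ]
  expect_false(five$significant)
  four <- trail[trail$term == "age:genotype:treatment:timepoint", ]
  expect_true(four$significant)

  # main-effects-only spec: empty trail
  ms0 <- model_spec(interaction_factors = "genotype")
  expect_identical(nrow(drop_and_refit(tbl, ms0)), 0L)
})

test_that("marginal contrasts equal brute-force cell means on noiseless data", {
  spec <- study_spec(n_per_cell = 2, timepoints = "1mpi",
                     regions = c("HPC", "RSC"),
                     coefficients = c("(Intercept)" = 1, "genotypeWT" = -1,
                                      "regionRSC" = 0.5,
                                      "genotypeWT:regionRSC" = 0.25),
                     random_intercept_sd = 0, residual_sd = 0, seed = 76)
  tbl <- simulate_study_table(spec)
  fit <- fit_lmm(tbl, model_spec())
  ctr <- marginal_contrasts(fit, "genotype", by = "region")
  cellmean <- function(g, r) mean(tbl$value[tbl$genotype == g &
                                              tbl$region == r])
  for (r in c("HPC", "RSC")) {
    got <- ctr$estimate[ctr$region == r]
    expect_equal(got, cellmean("TG", r) - cellmean("WT", r),
                 tolerance = 1e-8)
  }
  expect_true(all(ctr$q >= ctr$p))
  expect_true(all(ctr$df == fit$df_residual))
})

test_that("BH adjustment matches the hand-computed step-up and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(77)
  p <- runif(20)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  perm <- sample(20)
  expect_equal(bh_adjust(p[perm]), q[perm])
  # step-up formula by hand
  o <- order(p)
  qs <- rev(cummin(rev(20 * p[o] / seq_len(20))))
  expect_equal(q[o], pmin(qs, 1))
})
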