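test_that("fragment matching is one-to-one with deterministic tie-breaks", {
  ions <- data.frame(ion_type = c("b", "b"), index = 1:2, charge = 1L,
                     n_water_loss = 0L, n_ammonia_loss = 0L,
                     mz = c(100.0, 100.4), fragment_seq = c("A", "AG"),
                     stringsAsFactors = FALSE)
  # one peak equidistant from both ions: exactly one match, lower
  # theoretical m/z wins
  sp <- make_spectrum(500, 1, 100.2, 10)
  m <- match_fragments(sp, ions, 0.5)
  expect_equal(nrow(m), 1L)
  expect_equal(m$mz, 100.0)
  expect_equal(m$mass_error, 0.2)
  # empty spectrum-side input
  none <- make_spectrum(500, 1, 400, 1)
  expect_equal(nrow(match_fragments(none, ions, 0.5)), 0L)
  # noiseless synthetic spectrum: every y/b ion matched at zero error
  w <- small_world()
  sp1 <- w$sim$spectra[[1]]
  seq1 <- w$sim$truth$sequence[1]
  prim <- ion_series(seq1, ions = c("y", "b"))
  mm <- match_fragments(sp1, prim, 0.5)
  expect_equal(nrow(mm), nrow(prim))
  expect_true(all(abs(mm$mass_error) < 1e-9))
})

test_that("metric 1 reproduces the fixed-0.5 worked example", {
  expect_equal(fragment_lod_metric1(0.25, 0.1), log(0.5 / 0.05))
  expect_equal(round(fragment_lod_metric1(0.25, 0.1), 1), 2.3)
  # p_random = 0.5 -> even odds
  expect_equal(fragment_lod_metric1(0.5, 0.5), 0)
  expect_equal(fragment_lod_metric1(0.5, 0.2), log(2.5))
  # floors keep the score finite at exact matches
  expect_true(is.finite(fragment_lod_metric1(0, 0.1)))
})

test_that("metric 1 p_random agrees with a Monte-Carlo placement oracle", {
  set.seed(123)
  lo <- 150; hi <- 1150; n_peaks <- 100; err <- 0.25
  density <- n_peaks / (hi - lo)
  target <- 650.0
  u <- runif(10000, lo, hi)
  p1_hat <- mean(abs(u - target) <= err)   # single uniform peak in window
  se <- sqrt(p1_hat * (1 - p1_hat) / 10000)
  p_rand <- 2 * err * density              # = n_peaks * P(single peak hits)
  expect_lt(abs(p_rand - n_peaks * p1_hat), 3 * n_peaks * se)
})

test_that("metric 2 looks up mass-specific correct probabilities", {
  correct <- list(`1` = c(`400` = 0.4, `1600` = 0.8), `2` = numeric(),
                  `3` = 0.6)
  random <- list(`1` = c(`400` = 0.5, `1600` = 0.5), `2` = numeric(),
                 `3` = 0.5)
  model <- metric_model(correct, random)
  expect_equal(fragment_lod_metric2(300, 0.25, model, 0.1), log(0.4 / 0.05))
  expect_equal(fragment_lod_metric2(1500, 0.25, model, 0.1), log(0.8 / 0.05))
  # missing bin falls back to the nearest populated one
  expect_equal(fragment_lod_metric2(800, 0.25, model, 0.1), log(0.4 / 0.05))
})

test_that("metric 2 with a constant 0.5 table reduces to metric 1", {
  bins <- seq(200, 2000, by = 200)
  flat <- stats::setNames(rep(0.5, length(bins)), bins)
  model <- metric_model(list(`1` = flat, `2` = flat, `3` = 0.5),
                        list(`1` = flat, `2` = flat, `3` = 0.5))
  set.seed(4)
  mzs <- runif(1000, 100, 1900)
  errs <- runif(1000, -0.5, 0.5)
  expect_lt(max(abs(fragment_lod_metric2(mzs, errs, model, 0.1) -
                      fragment_lod_metric1(errs, 0.1))), 1e-12)
})

test_that("metric 3 uses normalized distributions and is scale invariant", {
  correct <- list(`1` = c(`200` = 0.4, `400` = 0.8), `2` = numeric(),
                  `3` = 0.6)
  random <- list(`1` = c(`200` = 0.3, `400` = 0.1), `2` = numeric(),
                 `3` = 0.2)
  model <- metric_model(correct, random)
  expect_equal(fragment_lod_metric3(150, model), log((1 / 3) / 0.75))
  expect_equal(fragment_lod_metric3(350, model), log((2 / 3) / 0.25))
  expect_equal(round(fragment_lod_metric3(150, model), 3), -0.811)
  expect_equal(round(fragment_lod_metric3(350, model), 3), 0.981)
  # scaling raw tables by constants leaves the LODs unchanged
  scaled <- metric_model(
    list(`1` = correct[["1"]] * 7, `2` = numeric(), `3` = 0.6),
    list(`1` = random[["1"]] * 0.11, `2` = numeric(), `3` = 0.2))
  expect_equal(fragment_lod_metric3(c(150, 350), scaled),
               fragment_lod_metric3(c(150, 350), model))
  # identical distributions give zero everywhere
  same <- metric_model(correct, correct)
  expect_equal(fragment_lod_metric3(c(150, 350), same), c(0, 0))
})

test_that("metric 4 applies the per-bin Gaussian error weight", {
  correct <- list(`1` = c(`200` = 0.4, `400` = 0.8), `2` = numeric(),
                  `3` = 0.6)
  random <- list(`1` = c(`200` = 0.3, `400` = 0.1), `2` = numeric(),
                 `3` = 0.2)
  pdf <- data.frame(bin = c(100, 200, 300, 400),
                    mu = c(0.01, 0.02, 0.03, 0.04),
                    sigma = c(0.05, 0.05, 0.06, 0.06), n = 100L)
  model <- metric_model(correct, random, pdf)
  m3 <- fragment_lod_metric3(150, model)
  expect_equal(fragment_lod_metric4(150, 0.02, model), m3)  # error == mu
  expect_equal(fragment_lod_metric4(150, 0.02 + 0.05, model), m3 - 0.5)
  expect_equal(fragment_lod_metric4(150, 0.02 + 0.10, model), m3 - 2.0)
})

test_that("peptide LOD is the plain sum of fragment LODs", {
  expect_equal(peptide_lod(numeric()), 0)
  expect_equal(peptide_lod(c(2.3, 0.9, -0.5)), 2.7)
  expect_equal(peptide_lod(1.7), 1.7)
})

test_that("decoy Z score uses the sample standard deviation", {
  expect_equal(z_score(5, rep(5, 25)), 0)
  expect_equal(z_score(3, c(0, 2), min_decoys = 2L), 2 / sqrt(2))
  expect_true(is.na(z_score(3, rnorm(5))))  # fewer than min_decoys = 20
})

test_that("scoring is deterministic", {
  w <- small_world()
  sp <- w$sim$spectra[[3]]
  seq3 <- w$sim$truth$sequence[3]
  ions <- ion_series(seq3, ions = c("y", "b", "a"),
                     max_water_loss = 2L, max_ammonia_loss = 2L)
  m1 <- match_fragments(sp, ions, 0.5)
  m2 <- match_fragments(sp, ions, 0.5)
  expect_identical(m1, m2)
  expect_identical(fragment_lod(m1, 1, density = 0.1),
                   fragment_lod(m2, 1, density = 0.1))
})
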