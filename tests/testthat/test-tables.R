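fake_assignment <- function(mz, matched, charge = 1L, errors = NULL) {
  ft <- data.frame(ion_type = "y", index = seq_along(mz), charge = 1L,
                   n_water_loss = 0L, n_ammonia_loss = 0L, mz = mz,
                   fragment_seq = "K", matched = matched,
                   mass_error = if (is.null(errors)) NA_real_ else errors,
                   observed_intensity = NA_real_, stringsAsFactors = FALSE)
  list(spectrum_id = "s", sequence = "PEPTIDEK", parent_charge = charge,
       frag_table = ft)
}

test_that("match-proportion tables are matched over total per 200 Da bin", {
  a1 <- fake_assignment(rep(300, 10), c(rep(TRUE, 3), rep(FALSE, 7)))
  tab <- build_match_proportion_table(list(a1))
  expect_equal(unname(tab[["1"]][["400"]]), 0.3)
  # all matched -> 1.0 in every populated bin
  a2 <- fake_assignment(c(150, 350, 650), rep(TRUE, 3))
  tab2 <- build_match_proportion_table(list(a2))
  expect_true(all(tab2[["1"]] == 1))
  # the 3+ class is the fixed average of all 1+ and 2+ proportions
  b1 <- fake_assignment(rep(300, 10), rep(c(TRUE, FALSE), 5))           # 0.5
  b2 <- fake_assignment(rep(700, 10), c(rep(TRUE, 8), rep(FALSE, 2)),
                        charge = 2L)                                    # 0.8
  tab3 <- build_match_proportion_table(list(b1, b2))
  expect_equal(unname(tab3[["3"]]), mean(c(0.5, 0.8)))
  expect_error(build_match_proportion_table(list()), "no assignments")
})

test_that("normalization produces a scale-invariant unit-sum distribution", {
  expect_equal(normalize_distribution(c(a = 0.4, b = 0.8)),
               c(a = 1 / 3, b = 2 / 3))
  d <- c(x = 0.25, y = 0.75)
  expect_equal(normalize_distribution(d), d)
  expect_equal(normalize_distribution(d * 7), d)
  expect_error(normalize_distribution(c(0, 0)), "all-zero")
})

test_that("error PDFs fit per-bin sample moments with floors and fallbacks", {
  pdf <- fit_error_pdf(c(0.0, 0.2), c(150, 160), min_n = 2L)
  expect_equal(pdf$mu, 0.1)
  expect_equal(pdf$sigma, sd(c(0, 0.2)), tolerance = 1e-9)
  # identical errors degenerate to the sigma floor
  pdf2 <- fit_error_pdf(rep(0.05, 10), rep(250, 10), min_n = 2L)
  expect_equal(pdf2$sigma, 0.01)
  # thin bins are dropped
  pdf3 <- fit_error_pdf(c(rep(0.1, 10), 0.5), c(rep(150, 10), 950),
                        min_n = 5L)
  expect_equal(pdf3$bin, 200)
  # estimator recovery at n = 1000
  set.seed(8)
  errs <- rnorm(1000, 0.05, 0.02)
  pdf4 <- fit_error_pdf(errs, rep(450, 1000))
  expect_lt(abs(pdf4$mu - 0.05), 3 * 0.02 / sqrt(1000))
  expect_equal(pdf4$sigma, sd(errs), tolerance = 1e-9)
})

test_that("table building is a pure function of the assignment set", {
  set.seed(21)
  asn <- lapply(1:20, function(i)
    fake_assignment(runif(30, 100, 1500), runif(30) < 0.6,
                    charge = sample(1:2, 1)))
  t1 <- build_match_proportion_table(asn)
  t2 <- build_match_proportion_table(asn)
  expect_identical(t1, t2)
})

test_that("metric model JSON serialization round-trips", {
  correct <- list(`1` = c(`200` = 0.4, `400` = 0.8),
                  `2` = c(`200` = 0.5, `400` = 0.7), `3` = 0.6)
  random <- list(`1` = c(`200` = 0.3, `400` = 0.1),
                 `2` = c(`200` = 0.2, `400` = 0.2), `3` = 0.2)
  pdf <- data.frame(bin = c(200, 300), mu = c(0.01, 0.02),
                    sigma = c(0.05, 0.06), n = c(50L, 60L))
  model <- metric_model(correct, random, pdf)
  path <- withr::local_tempfile(fileext = ".json")
  write_metric_model(model, path)
  back <- read_metric_model(path)
  expect_equal(back$correct, model$correct, tolerance = 1e-12)
  expect_equal(back$random_norm, model$random_norm, tolerance = 1e-12)
  expect_equal(back$error_pdf$mu, model$error_pdf$mu, tolerance = 1e-12)
  mzs <- c(150, 350, 900)
  expect_equal(fragment_lod_metric4(mzs, 0.015, back),
               fragment_lod_metric4(mzs, 0.015, model), tolerance = 1e-12)
})

test_that("normalized model distributions sum to one", {
  correct <- list(`1` = c(`200` = 0.4, `400` = 0.8, `600` = 0.9),
                  `2` = c(`200` = 0.5), `3` = 0.6)
  random <- list(`1` = c(`200` = 0.3, `400` = 0.1, `600` = 0.2),
                 `2` = c(`200` = 0.2), `3` = 0.2)
  model <- metric_model(correct, random)
  for (cls in c("1", "2", "3")) {
    expect_equal(sum(model$correct_norm[[cls]]), 1, tolerance = 1e-9)
    expect_equal(sum(model$random_norm[[cls]]), 1, tolerance = 1e-9)
  }
})
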