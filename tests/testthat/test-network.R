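test_that("feature encoding follows the 8-input definitions", {
  codes <- hydrophobicity_codes()
  # ion-type codes 0..4
  expect_equal(unname(encode_features("none", NA, 1L, "AKRGH", 2L,
                                      "AKRGH")["ion_type_code"]), 0)
  expect_equal(unname(encode_features("iminium", NA, 1L, "AKRGH", 2L,
                                      "L" )["ion_type_code"]), 1)
  # y fragment "RGH" of parent "AKRGH": H+K+R ratio 2/3, length ratio 3/5
  f <- encode_features("y", 3L, 1L, "AKRGH", 2L, "RGH")
  expect_equal(unname(f["ion_type_code"]), 2)
  expect_equal(unname(f["hkr_ratio"]), 2 / 3)
  expect_equal(unname(f["length_ratio"]), 0.6)
  expect_equal(unname(f["parent_length"]), 5)
  # y3 cleaves between positions 2 and 3: flanks K then R
  expect_equal(unname(f["nterm_code"]), unname(codes["K"]))
  expect_equal(unname(f["cterm_code"]), unname(codes["R"]))
  fb <- encode_features("b", 2L, 1L, "AKRGH", 2L, "AK")
  expect_equal(unname(fb["ion_type_code"]), 4)
  expect_equal(unname(fb["nterm_code"]), unname(codes["K"]))
  expect_equal(unname(fb["cterm_code"]), unname(codes["R"]))
  # parent without H/K/R: ratio defined as 0
  expect_equal(unname(encode_features("b", 1L, 1L, "AGGA", 1L,
                                      "A")["hkr_ratio"]), 0)
})

test_that("training is deterministic and converges on constant targets", {
  set.seed(31)
  n <- 300
  X <- cbind(sample(0:4, n, TRUE), sample(1:2, n, TRUE), 1,
             sample(8:20, n, TRUE), runif(n), runif(n), runif(n), runif(n))
  y <- 1 + 0.8 * X[, 5] + 0.5 * X[, 6] + rnorm(n, 0, 0.05)
  net1 <- train_network(X, y, epochs = 20, seed = 7)
  net2 <- train_network(X, y, epochs = 20, seed = 7)
  expect_identical(net1$W1, net2$W1)
  expect_identical(net1$loss_trace, net2$loss_trace)
  expect_true(all(diff(net1$loss_trace) <= 1e-12))
  # constant targets converge to a constant predictor
  netc <- train_network(X, rep(2.5, n), epochs = 300, seed = 7)
  pred <- predict(netc, X)
  expect_lt(max(abs(pred - 2.5)), 1e-3)
  expect_lt(netc$loss_trace[length(netc$loss_trace)], 1e-6)
  expect_error(train_network(X[1:50, ], y[1:50]), "at least 100")
})

test_that("wrap-around rotations exclude identity and preserve multisets", {
  expect_equal(wraparound_rotations(c(1, 2, 3)),
               list(c(2, 3, 1), c(3, 1, 2)))
  expect_equal(wraparound_rotations(5), list())
  set.seed(12)
  v <- runif(9)
  rots <- wraparound_rotations(v)
  expect_length(rots, 8L)
  for (r in rots) {
    expect_identical(sort(r), sort(v))
    expect_false(identical(r, v))
  }
})

test_that("intensity Z score reproduces the worked rotation example", {
  z <- intensity_z_score(c(60, 30, 10), c(50, 40, 10))
  # true dot 4300, rotations 3200 and 2500: (4300-2850)/494.97
  expect_equal(z, (4300 - 2850) / sd(c(3200, 2500)), tolerance = 1e-12)
  expect_equal(round(z, 2), 2.93)
  # under the minimum match count the contribution is 0
  expect_equal(intensity_z_score(c(1, 2), c(1, 2)), 0)
  # constant predictions: all rotation dots equal the true dot -> 0 via floor
  expect_equal(intensity_z_score(c(5, 4, 3), c(10, 10, 10)), 0)
})

test_that("proportional predictions dominate every rotation", {
  set.seed(14)
  for (i in 1:20) {
    obs <- sort(runif(6, 1, 100), decreasing = TRUE)
    pred <- obs * 3.7
    obs_n <- 100 * obs / sum(obs)
    pred_n <- 100 * pred / sum(pred)
    true_dot <- sum(obs_n * pred_n)
    for (r in wraparound_rotations(pred_n))
      expect_gte(true_dot, sum(obs_n * r))
    expect_gt(intensity_z_score(obs, pred), 0)
  }
})
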