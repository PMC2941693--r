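test_that("DTA parsing follows the M+H/charge convention", {
  sp <- parse_dta(c("1001.0 2", "200.0 50.0", "300.0 25.0"))
  expect_equal(sp$precursor_mh, 1001.0)
  expect_equal(sp$parent_charge, 2L)
  expect_equal(sp$neutral_mass, 999.992724, tolerance = 1e-9)
  expect_equal(nrow(sp$peaks), 2L)
  # peaks stored by descending intensity
  expect_equal(sp$peaks$intensity, c(50, 25))
  expect_error(parse_dta("1001.0 2"), "no peaks")
  expect_error(parse_dta(c("abc 2", "200 1")), "line 1")
  expect_error(parse_dta(c("1001.0 2", "200 1 7")), "line 2")
})

test_that("noise filter removes sub-threshold peaks on the pre-filter sum", {
  sp <- make_spectrum(1000, 1, c(100, 200, 300), c(50, 30, 0.3))
  filtered <- noise_filter(sp)  # threshold 0.005 * 80.3 = 0.4015
  expect_equal(sort(filtered$peaks$intensity), c(30, 50))
  expect_equal(noise_filter(sp, 0)$peaks, sp$peaks)
  two <- make_spectrum(1000, 1, c(100, 200), c(1, 1))
  expect_equal(nrow(noise_filter(two)$peaks), 2L)
  expect_error(noise_filter(make_spectrum(1000, 1, c(100, 200), c(5, 5)),
                            0.99), "unscorable")
  # one-pass contract: re-applying to its own output with the original
  # threshold removes nothing further
  thr <- 0.005 * sum(sp$peaks$intensity)
  expect_true(all(filtered$peaks$intensity >= thr))
})

test_that("peak density is count over m/z range", {
  sp <- make_spectrum(2000, 1, seq(150, 1150, length.out = 100), rep(1, 100))
  expect_equal(peak_density(sp), 0.1)
  sp2 <- make_spectrum(2000, 1, seq(100, 300, length.out = 50), rep(1, 50))
  expect_equal(peak_density(sp2), 0.25)
  expect_error(peak_density(make_spectrum(2000, 1, 100, 1)), "density")
})

test_that("top 4N peak selection uses N = round(mass/114), floored at 1", {
  sp <- make_spectrum(1140 + 1.007276, 1, seq(100, 1100, length.out = 60),
                      seq(60, 1))
  top <- top_intense_peaks(sp)
  expect_equal(top$n, 10L)
  expect_equal(nrow(top$peaks), 40L)
  expect_equal(top$peaks$intensity, sort(sp$peaks$intensity,
                                         decreasing = TRUE)[1:40])
  few <- make_spectrum(1140 + 1.007276, 1, seq(100, 1100, length.out = 12),
                       seq(12, 1))
  expect_equal(nrow(top_intense_peaks(few)$peaks), 12L)
  tiny <- make_spectrum(114 + 1.007276, 1, c(50, 60, 70, 80, 90),
                        c(5, 4, 3, 2, 1))
  top_tiny <- top_intense_peaks(tiny)
  expect_equal(top_tiny$n, 1L)
  expect_equal(nrow(top_tiny$peaks), 4L)
  # intensity ties break by ascending m/z
  tied <- make_spectrum(114 + 1.007276, 1, c(90, 50, 70, 60), rep(1, 4))
  expect_equal(top_intense_peaks(tied)$peaks$mz, c(50, 60, 70, 90))
})

test_that("directory loader finds .dta case-insensitively one level down", {
  dir <- withr::local_tempdir()
  write_dta(make_spectrum(500, 1, c(100, 200), c(2, 1)),
            file.path(dir, "a.dta"))
  dir.create(file.path(dir, "sub"))
  write_dta(make_spectrum(600, 2, c(150, 250), c(3, 1)),
            file.path(dir, "sub", "b.DTA"))
  writeLines("not a spectrum", file.path(dir, "ignore.txt"))
  sps <- read_spectra_dir(dir)
  expect_length(sps, 2L)
  expect_equal(sort(vapply(sps, function(s) s$precursor_mh, numeric(1))),
               c(500, 600))
})

test_that("MGF reader maps to the same spectrum type", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=spec1", "PEPMASS=500.5", "CHARGE=2+",
               "100.0 10", "200.0 5", "END IONS"), path)
  sps <- read_mgf(path)
  expect_length(sps, 1L)
  expect_equal(sps[[1]]$parent_charge, 2L)
  expect_equal(sps[[1]]$precursor_mh, 2 * (500.5 - 1.007276) + 1.007276)
  expect_equal(nrow(sps[[1]]$peaks), 2L)
})
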