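test_that("peptide_mass matches hand-computed values and rejects bad input", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-6)
  expect_equal(peptide_mass("AG"), 146.06913, tolerance = 1e-6)
  # M + oxidation: 131.04049 + 18.010565 + 15.994915
  expect_equal(peptide_mass("M", c(15.994915)), 165.04597, tolerance = 1e-6)
  expect_equal(peptide_mass("M", list(mod_spec("ox", 15.994915, "M"))),
               165.04597, tolerance = 1e-6)
  expect_error(peptide_mass("AZB"), "Z")
  expect_error(peptide_mass(""), "non-empty")
})

test_that("ion series reproduces reference m/z values", {
  y <- ion_series("AK", ions = "y")
  expect_equal(y$mz, 147.11280, tolerance = 1e-6)
  ba <- ion_series("AG", ions = c("b", "a"))
  expect_equal(ba$mz[ba$ion_type == "b"], 72.04439, tolerance = 1e-6)
  expect_equal(ba$mz[ba$ion_type == "a"], 44.04948, tolerance = 1e-5)
  # standard Leu immonium
  imm <- ion_series("L", iminium = TRUE)
  expect_equal(imm$mz, 86.09642, tolerance = 1e-6)
  # y2+ only for parent charge >= 2
  expect_false(any(ion_series("PEPTIDEK", parent_charge = 1L)$charge == 2L))
  s2 <- ion_series("PEPTIDEK", parent_charge = 2L)
  y1 <- s2[s2$ion_type == "y" & s2$charge == 1L, ]
  y2 <- s2[s2$ion_type == "y" & s2$charge == 2L, ]
  expect_equal(y2$mz, (y1$mz[match(y2$index, y1$index)] + 1.007276) / 2)
})

test_that("y/b complementarity holds on random peptides", {
  peps <- rand_peptides(100, c(6, 20), seed = 42)
  for (p in peps) {
    n <- nchar(p)
    ions <- ion_series(p, ions = c("y", "b"))
    yv <- ions$mz[ions$ion_type == "y"][order(ions$index[ions$ion_type == "y"])]
    bv <- ions$mz[ions$ion_type == "b"][order(ions$index[ions$ion_type == "b"])]
    total <- peptide_mass(p)
    expect_true(all(abs(yv + rev(bv) - (total + 2 * 1.007276)) < 1e-4))
  }
})

test_that("loss variants are lighter by exact water/ammonia multiples", {
  full <- ion_series("MQPLAK", max_water_loss = 2L, max_ammonia_loss = 2L)
  base <- full[full$n_water_loss == 0L & full$n_ammonia_loss == 0L, ]
  key <- paste(full$ion_type, full$index, full$charge)
  bkey <- paste(base$ion_type, base$index, base$charge)
  parent_mz <- base$mz[match(key, bkey)]
  expect_equal(full$mz,
               parent_mz - (full$n_water_loss * 18.010565 +
                              full$n_ammonia_loss * 17.026549) / full$charge)
  # a < b at every index
  b <- full[full$ion_type == "b" & full$n_water_loss + full$n_ammonia_loss == 0, ]
  a <- full[full$ion_type == "a" & full$n_water_loss + full$n_ammonia_loss == 0, ]
  expect_true(all(a$mz[order(a$index)] < b$mz[order(b$index)]))
})

test_that("pre-computed y_series agrees with ion_series", {
  for (p in rand_peptides(20, seed = 3)) {
    ys <- y_series <- fraglod::y_series(p)
    ions <- ion_series(p, ions = "y")
    expect_equal(ys, ions$mz[order(ions$index)], tolerance = 1e-9)
  }
})

test_that("hydrophobicity codes are 20 evenly spaced values on [0,1]", {
  codes <- hydrophobicity_codes()
  expect_length(codes, 20)
  expect_equal(sort(unname(codes)), seq(0, 1, length.out = 20))
  expect_equal(unname(codes["R"]), 0)   # most hydrophilic
  expect_equal(unname(codes["I"]), 1)   # most hydrophobic
  expect_lt(codes["K"], codes["A"])
})

test_that("variable modification enumeration covers the stated cases", {
  ox <- list(mod_spec("oxidation", 15.994915, "M", max_per_peptide = 2L))
  expect_length(enumerate_modified_forms("AMK", ox), 2L)
  ox1 <- list(mod_spec("oxidation", 15.994915, "M", max_per_peptide = 1L))
  expect_length(enumerate_modified_forms("MM", ox1), 3L)
  expect_length(enumerate_modified_forms("AAA", default_mods()), 1L)
  # fixed mods always applied
  fx <- list(mod_spec("carbamidomethyl", 57.02146, "C", kind = "fixed"))
  forms <- enumerate_modified_forms("ACC", fx)
  expect_length(forms, 1L)
  expect_equal(forms[[1]]$deltas, c(0, 57.02146, 57.02146))
  # enumeration cap warns and truncates
  many <- list(mod_spec("m", 1, c("A", "G"), max_per_peptide = 8L))
  expect_warning(f <- enumerate_modified_forms("AGAGAGAGAG", many), "capped")
  expect_length(f, 64L)
})
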