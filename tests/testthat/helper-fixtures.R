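# Shared fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]]))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Random tryptic-looking peptides (K/R terminated, no internal K/R, no P
# after position 1 so the digest round-trips cleanly).
rand_peptides <- function(n, len_range = c(8, 16), seed = 1) {
  set.seed(seed)
  alphabet <- setdiff(names(fraglod::aa_table()$residue_mass),
                      c("K", "R"))
  vapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    paste(c(sample(alphabet, len - 1, replace = TRUE),
            sample(c("K", "R"), 1)), collapse = "")
  }, "")
}

# Noiseless, zero-error simulation config: every y/b ion present at its
# exact theoretical m/z.
noiseless_config <- function(seed = 1) {
  sim_config(seed = seed,
             bin_match_probs = stats::setNames(rep(1, 7),
                                               seq(200, 1400, by = 200)),
             error_sigma = 0, drift = c(slope = 0, intercept = 0),
             n_noise_peaks = 0, charge_probs = c(`1` = 1, `2` = 0, `3` = 0))
}

# A small shared world: proteome, target + decoy index, 12 noiseless
# spectra from known peptides.
small_world <- function() {
  fixture("small_world", function() {
    cfg <- sim_config(seed = 11, n_proteins = 35)
    proteome <- generate_proteome(cfg)
    index <- suppressWarnings(build_peptide_index(proteome))
    decoy <- suppressWarnings(build_decoy_index(proteome))
    recs <- index$records
    recs <- recs[recs$mod_desc == "" & nchar(recs$sequence) >= 8 &
                   nchar(recs$sequence) <= 16 &
                   !duplicated(recs$sequence), , drop = FALSE]
    set.seed(5)
    recs <- recs[sample(nrow(recs), 12), , drop = FALSE]
    sim <- simulate_spectra(recs, noiseless_config(seed = 11))
    list(proteome = proteome, index = index, decoy = decoy,
         peptides = recs, sim = sim)
  })
}

# Scored results on the small world (metric 1), reused across tests.
small_results <- function() {
  fixture("small_results", function() {
    w <- small_world()
    suppressWarnings(
      score_spectra(w$sim$spectra, w$index, w$decoy, metric = 1))
  })
}

make_spectrum <- function(mh, charge, mz, intensity) {
  parse_dta(c(sprintf("%.5f %d", mh, charge),
              sprintf("%.5f %.5f", mz, intensity)))
}
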