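#' Simulation configuration
#'
#' The stated world for the synthetic fixtures: random proteomes over the
#' 20-residue alphabet, spectra whose y/b fragments are included with a
#' mass-bin-dependent probability, Gaussian mass error with a
#' mass-proportional drift, a deterministic intensity model (log intensity
#' linear in length ratio and H/K/R ratio plus ion-type offsets, so the
#' intensity network has recoverable signal), and uniform noise peaks.
#' Defaults: match probabilities ramping 0.3 to 0.9 over the 200-1400 Da
#' bins, drift slope 2e-4 Da/Da, error sigma 0.05 Da, 20 noise peaks per
#' spectrum, charges 1/2/3 with probabilities 0.4/0.5/0.1.
#'
#' @param seed Integer master seed; every per-spectrum stream is derived
#'   from `(seed, spectrum ordinal)` so generation order does not matter.
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param protein_length_range Length bounds (residues).
#' @param bin_match_probs Named vector: 200 Da bin upper edge -> inclusion
#'   probability for y/b fragments (nearest bin used outside the range).
#' @param drift `c(slope, intercept)`: mean mass error is
#'   `slope * mz + intercept` (Da).
#' @param error_sigma Gaussian mass-error standard deviation (Da).
#' @param n_noise_peaks Uniform noise peaks added per spectrum.
#' @param noise_mz_range m/z range for noise peaks; the upper bound is also
#'   capped at the precursor M+H.
#' @param charge_probs Probabilities of parent charges 1, 2, 3.
#' @param intensity_coef Coefficients of the deterministic log-intensity
#'   model: intercept, length-ratio slope, H/K/R-ratio slope, and y/b
#'   ion-type offsets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_proteins = 80L,
                       protein_length_range = c(60L, 120L),
                       bin_match_probs = stats::setNames(
                         seq(0.3, 0.9, by = 0.1), seq(200, 1400, by = 200)),
                       drift = c(slope = 2e-4, intercept = 0),
                       error_sigma = 0.05,
                       n_noise_peaks = 20L,
                       noise_mz_range = c(100, 1500),
                       charge_probs = c(`1` = 0.4, `2` = 0.5, `3` = 0.1),
                       intensity_coef = c(intercept = 1, length_ratio = 2,
                                          hkr_ratio = 1.5, y = 1, b = 0.5)) {
  stopifnot(all(bin_match_probs >= 0 & bin_match_probs <= 1),
            error_sigma >= 0, n_noise_peaks >= 0)
  structure(
    list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
         protein_length_range = as.integer(protein_length_range),
         bin_match_probs = bin_match_probs, drift = drift,
         error_sigma = error_sigma, n_noise_peaks = as.integer(n_noise_peaks),
         noise_mz_range = noise_mz_range,
         charge_probs = charge_probs / sum(charge_probs),
         intensity_coef = intensity_coef),
    class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

# per-spectrum stream seed, kept below 2^31
stream_seed <- function(seed, ordinal) {
  as.integer((as.double(seed) * 48271 + as.double(ordinal) * 9973) %%
               2147483647)
}

#' Generate a synthetic proteome
#'
#' Random proteins over the 20 standard residues, deterministic given the
#' configuration seed.
#'
#' @param config A [sim_config()].
#' @param fasta Optional path; when given, the proteome is also written as
#'   FASTA.
#' @return Named character vector of protein sequences.
#' @export
generate_proteome <- function(config, fasta = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- with_seed(config$seed, {
    lens <- sample(config$protein_length_range[1L]:
                     config$protein_length_range[2L],
                   config$n_proteins, replace = TRUE)
    vapply(lens, function(L)
      paste(sample(names(RESIDUE_MASS), L, replace = TRUE), collapse = ""),
      "")
  })
  names(seqs) <- sprintf("SYN%04d", seq_along(seqs))
  if (!is.null(fasta)) write_fasta(seqs, fasta)
  seqs
}

# Deterministic intensity model: log intensity linear in length ratio and
# H/K/R ratio with ion-type offsets.
sim_intensity <- function(coef, ion_type, fragment_seq, parent_seq) {
  pres <- strsplit(parent_seq, "", fixed = TRUE)[[1L]]
  fres <- strsplit(fragment_seq, "", fixed = TRUE)[[1L]]
  hkr_parent <- sum(pres %in% c("H", "K", "R"))
  hkr <- if (hkr_parent > 0)
    sum(fres %in% c("H", "K", "R")) / hkr_parent else 0
  off <- if (ion_type %in% names(coef)) coef[[ion_type]] else 0
  exp(coef[["intercept"]] + coef[["length_ratio"]] *
        length(fres) / length(pres) + coef[["hkr_ratio"]] * hkr + off)
}

#' Simulate DTA spectra with known ground truth
#'
#' For each peptide, every theoretical y1+/b1+ ion is included with the
#' probability of its 200 Da mass bin; included ions are placed at the
#' expected m/z plus `Normal(drift(mz), error_sigma)` with intensities from
#' the deterministic model (normalized to a maximum of 100); uniform noise
#' peaks are added; and a DTA file records the singly protonated precursor
#' mass and the sampled charge. A truth manifest records the generating
#' peptide and the per-ion inclusions.
#'
#' @param peptides Character vector of peptide sequences (unmodified), or a
#'   data.frame with columns `sequence` and (optionally) list-column
#'   `mod_deltas`.
#' @param config A [sim_config()].
#' @param dir Optional output directory for DTA files and the tab-separated
#'   manifests (`truth_spectra.tsv`, `truth_ions.tsv`).
#' @param signal If `FALSE`, all true ions are suppressed and only noise
#'   peaks are emitted (decoy-only spectra for Z calibration checks).
#' @return List with `spectra` (list of `spectrum`), `truth` (per-spectrum
#'   data.frame), `ions` (per-ion data.frame) and `files` (DTA paths or
#'   `NULL`).
#' @export
simulate_spectra <- function(peptides, config, dir = NULL, signal = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.character(peptides))
    peptides <- data.frame(sequence = peptides, stringsAsFactors = FALSE)
  n <- nrow(peptides)
  spectra <- vector("list", n)
  truth <- vector("list", n)
  ion_rows <- vector("list", n)
  files <- if (is.null(dir)) NULL else character(n)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  prob_tab <- config$bin_match_probs
  for (i in seq_len(n)) {
    seqi <- peptides$sequence[i]
    mods <- if ("mod_deltas" %in% names(peptides))
      peptides$mod_deltas[[i]] else NULL
    sp <- with_seed(stream_seed(config$seed, i), {
      charge <- sample(as.integer(names(config$charge_probs)), 1L,
                       prob = config$charge_probs)
      ions <- ion_series(seqi, mods, ions = c("y", "b"), parent_charge = 1L)
      p <- lookup_binned(prob_tab, mass_bin(ions$mz, 200))
      keep <- if (signal) stats::runif(nrow(ions)) < p else
        rep(FALSE, nrow(ions))
      inten <- vapply(seq_len(nrow(ions)), function(r)
        sim_intensity(config$intensity_coef, ions$ion_type[r],
                      ions$fragment_seq[r], seqi), numeric(1))
      obs_mz <- ions$mz +
        stats::rnorm(nrow(ions),
                     config$drift[["slope"]] * ions$mz +
                       config$drift[["intercept"]],
                     config$error_sigma)
      sig <- data.frame(mz = obs_mz[keep], intensity = inten[keep])
      if (nrow(sig)) sig$intensity <- 100 * sig$intensity /
          max(sig$intensity)
      neutral <- peptide_mass(seqi, mods)
      mh <- neutral + PROTON_MASS
      if (config$n_noise_peaks > 0L) {
        hi <- min(config$noise_mz_range[2L], mh)
        noise <- data.frame(
          mz = stats::runif(config$n_noise_peaks,
                            config$noise_mz_range[1L], hi),
          intensity = stats::runif(config$n_noise_peaks, 0.5, 20))
        sig <- rbind(sig, noise)
      }
      if (!nrow(sig))
        sig <- data.frame(mz = mh / 2, intensity = 1)  # degenerate guard
      list(spec = new_spectrum(sprintf("sim%05d.dta", i), mh, charge, sig),
           ions = ions, keep = keep, obs_mz = obs_mz, neutral = neutral,
           charge = charge)
    })
    spectra[[i]] <- sp$spec
    truth[[i]] <- data.frame(
      file = sp$spec$source_file, sequence = seqi,
      mods = if (is.null(mods) || !any(mods != 0)) "" else
        paste(which(mods != 0), mods[mods != 0], sep = ":", collapse = ";"),
      neutral_mass = sp$neutral, parent_charge = sp$charge,
      n_ions_included = sum(sp$keep), stringsAsFactors = FALSE)
    ion_rows[[i]] <- data.frame(
      file = sp$spec$source_file, sequence = seqi,
      ion_type = sp$ions$ion_type, index = sp$ions$index,
      expected_mz = sp$ions$mz, included = sp$keep,
      observed_mz = ifelse(sp$keep, sp$obs_mz, NA_real_),
      stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      files[i] <- file.path(dir, sp$spec$source_file)
      write_dta(sp$spec, files[i])
    }
  }
  truth <- do.call(rbind, truth)
  ions <- do.call(rbind, ion_rows)
  if (!is.null(dir)) {
    utils::write.table(truth, file.path(dir, "truth_spectra.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ions, file.path(dir, "truth_ions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(spectra = spectra, truth = truth, ions = ions, files = files)
}
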