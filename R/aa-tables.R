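# Physical constants (Da). Monoisotopic throughout.
PROTON_MASS  <- 1.007276
WATER_MASS   <- 18.010565
AMMONIA_MASS <- 17.026549
CO_MASS      <- 27.994915
# immonium m/z = residue mass - CO + proton
IMMONIUM_DELTA <- CO_MASS - PROTON_MASS # 26.987639

# Monoisotopic residue (not amino acid) masses, Da.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Kyte-Doolittle hydropathy, used only to ORDER residues for the evenly
# spaced [0,1] coding fed to the intensity network.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# EMBOSS-style pKa set; termini of every fragment are treated as standard
# amino/carboxy groups (a documented simplification for b ions).
DEFAULT_PKA <- c(
  Nterm = 8.6, Cterm = 3.6,
  K = 10.8, R = 12.5, H = 6.5,      # basic side chains
  D = 3.9, E = 4.1, C = 8.5, Y = 10.1  # acidic side chains
)

#' Hydrophobicity codes for the 20 standard residues
#'
#' Residues are ranked by increasing Kyte-Doolittle hydropathy (ties broken
#' alphabetically for determinism) and assigned 20 distinct values evenly
#' spaced on \[0, 1\]: the most hydrophilic residue (R) codes to 0, the most
#' hydrophobic (I) to 1, with step 1/19.
#'
#' @return Named numeric vector of length 20, values in \[0, 1\].
#' @export
#' @examples
#' codes <- hydrophobicity_codes()
#' codes["R"]  # 0, most hydrophilic
#' codes["I"]  # 1, most hydrophobic
hydrophobicity_codes <- function() {
  kd <- KYTE_DOOLITTLE
  ord <- order(kd, names(kd))
  rank <- match(names(kd), names(kd)[ord])
  stats::setNames(seq(0, 1, length.out = length(kd))[rank], names(kd))
}

#' Amino-acid lookup tables
#'
#' Bundles the monoisotopic residue masses, the evenly spaced hydrophobicity
#' codes and the pKa table used for isoelectric-point calculations.
#'
#' @return A list with elements `residue_mass`, `hydrophobicity` and `pka`.
#' @export
aa_table <- function() {
  list(
    residue_mass = RESIDUE_MASS,
    hydrophobicity = hydrophobicity_codes(),
    pka = DEFAULT_PKA
  )
}

#' Define a peptide modification
#'
#' @param name Short label, e.g. `"oxidation"`.
#' @param delta_mass Monoisotopic mass shift in Da.
#' @param targets Character vector of 1-letter residue codes the modification
#'   can occupy.
#' @param kind `"variable"` (enumerated over target positions) or `"fixed"`
#'   (applied to every target residue).
#' @param max_per_peptide Maximum number of occurrences per peptide; must be
#'   at least 1 for variable modifications.
#' @return An object of class `mod_spec`.
#' @export
#' @examples
#' mod_spec("oxidation", 15.994915, "M")
mod_spec <- function(name, delta_mass, targets,
                     kind = c("variable", "fixed"), max_per_peptide = 2L) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(delta_mass), length(delta_mass) == 1L,
            is.finite(delta_mass))
  targets <- unique(as.character(targets))
  if (!all(targets %in% names(RESIDUE_MASS)))
    stop("unknown target residue(s): ",
         paste(setdiff(targets, names(RESIDUE_MASS)), collapse = ", "))
  max_per_peptide <- as.integer(max_per_peptide)
  if (kind == "variable" && max_per_peptide < 1L)
    stop("max_per_peptide must be >= 1 for variable modifications")
  structure(
    list(name = name, delta_mass = delta_mass, targets = targets,
         kind = kind, max_per_peptide = max_per_peptide),
    class = "mod_spec"
  )
}

#' Default modification set
#'
#' Variable oxidation on methionine (+15.994915 Da, up to 2 per peptide) and
#' variable methylation on lysine/arginine (+14.015650 Da, up to 2).
#'
#' @return List of [mod_spec()] objects.
#' @export
default_mods <- function() {
  list(
    mod_spec("oxidation", 15.994915, "M", "variable", 2L),
    mod_spec("methylation", 14.015650, c("K", "R"), "variable", 2L)
  )
}

# Split a sequence into residues, rejecting unknown codes.
split_residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty character scalar")
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(res, names(RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  res
}

# Coerce the `mods` argument to a per-position delta vector.
mod_deltas_for <- function(sequence_length, mods) {
  if (is.null(mods)) return(numeric(sequence_length))
  if (is.numeric(mods)) {
    if (length(mods) == sequence_length) return(as.numeric(mods))
    stop("numeric mods must be a per-position delta vector of length ",
         sequence_length)
  }
  stop("mods must be NULL or a per-position numeric delta vector")
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, plus any applied modification
#' deltas.
#'
#' @param sequence Peptide as a 1-letter residue string.
#' @param mods Either `NULL`, a numeric vector of per-position mass deltas
#'   (length `nchar(sequence)`), or a list of applied [mod_spec()] objects
#'   whose `delta_mass` values are summed.
#' @return Neutral mass in Da.
#' @export
#' @examples
#' peptide_mass("G")   # 75.03203
#' peptide_mass("AG")  # 146.06913
peptide_mass <- function(sequence, mods = NULL) {
  res <- split_residues(sequence)
  extra <- if (is.list(mods)) {
    sum(vapply(mods, function(m) m$delta_mass, numeric(1)))
  } else {
    sum(mod_deltas_for(length(res), mods))
  }
  sum(RESIDUE_MASS[res]) + WATER_MASS + extra
}
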