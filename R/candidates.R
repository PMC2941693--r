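# TRUE for each target m/z that has at least one peak within +/- tol.
has_peak_within <- function(target_mz, peak_mz, tol) {
  if (!length(peak_mz)) return(rep(FALSE, length(target_mz)))
  sorted <- sort(peak_mz)
  lo <- findInterval(target_mz - tol, sorted, left.open = TRUE)
  hi <- findInterval(target_mz + tol, sorted)
  hi > lo
}

#' Count y-ion series hits
#'
#' Number of entries of a peptide's pre-computed y1+ series with at least one
#' spectrum peak within the fragment mass tolerance; each y ion counts at
#' most once.
#'
#' @param spectrum A `spectrum`.
#' @param y_ions Numeric vector of theoretical y1+ m/z values (e.g. the
#'   `y_ions` column of a peptide index record, or [y_series()]).
#' @param tolerance Fragment tolerance in Da (> 0).
#' @return Integer hit count.
#' @export
count_y_matches <- function(spectrum, y_ions, tolerance) {
  stopifnot(inherits(spectrum, "spectrum"), tolerance > 0)
  sum(has_peak_within(y_ions, spectrum$peaks$mz, tolerance))
}

#' Preliminary intensity-proportion score
#'
#' The proportion of the total intensity of the spectrum's top 4N peaks that
#' is accounted for by peaks matching theoretical y1+, b1+ or immonium ions
#' (plus y2+ when the parent charge is 2 or higher). A peak may satisfy
#' several ions but its intensity enters the numerator once. A score of 0.5
#' means half of the top-4N intensity is explained by the candidate.
#'
#' @param spectrum A `spectrum`.
#' @param sequence Candidate peptide residue string.
#' @param mods `NULL` or per-position numeric mass deltas.
#' @param tolerance Fragment tolerance in Da.
#' @return Score in `[0, 1]`.
#' @export
preliminary_score <- function(spectrum, sequence, mods = NULL,
                              tolerance = 0.5) {
  top <- top_intense_peaks(spectrum)$peaks
  total <- sum(top$intensity)
  if (total <= 0) return(0)
  ions <- preliminary_ions(sequence, mods,
                           parent_charge = spectrum$parent_charge)
  if (!nrow(ions)) return(0)
  ion_mz <- sort(ions$mz)
  lo <- findInterval(top$mz - tolerance, ion_mz, left.open = TRUE)
  hi <- findInterval(top$mz + tolerance, ion_mz)
  matched <- hi > lo
  sum(top$intensity[matched]) / total
}

#' Select scoring candidates for a spectrum
#'
#' Three-stage pipeline: (1) precursor-mass window query against the
#' mass-ordered index; (2) require at least `min_y_hits` y-ion series hits;
#' (3) require a preliminary intensity-proportion score of at least
#' `min_prelim`. Defaults: precursor tolerance 2.5 Da, fragment tolerance
#' 0.5 Da, 2 y hits, preliminary score 0.05 (a threshold of about 0.30 can
#' suit MALDI data).
#'
#' @param spectrum A `spectrum`.
#' @param index A `peptide_index` (target database).
#' @param precursor_tol Precursor window half-width in Da.
#' @param fragment_tol Fragment tolerance in Da.
#' @param min_y_hits Minimum y-ion hits retained.
#' @param min_prelim Minimum preliminary score retained.
#' @return The matching index records with extra columns `y_hits` and
#'   `preliminary_score`, ordered as in the index; zero rows when nothing
#'   survives.
#' @export
select_candidates <- function(spectrum, index, precursor_tol = 2.5,
                              fragment_tol = 0.5, min_y_hits = 2L,
                              min_prelim = 0.05) {
  cands <- query_by_mass(index, spectrum$neutral_mass, precursor_tol)
  if (!nrow(cands)) {
    cands$y_hits <- integer()
    cands$preliminary_score <- numeric()
    return(cands)
  }
  cands$y_hits <- vapply(cands$y_ions, function(y)
    count_y_matches(spectrum, y, fragment_tol), integer(1))
  cands <- cands[cands$y_hits >= min_y_hits, , drop = FALSE]
  if (!nrow(cands)) {
    cands$preliminary_score <- numeric()
    return(cands)
  }
  cands$preliminary_score <- vapply(seq_len(nrow(cands)), function(i)
    preliminary_score(spectrum, cands$sequence[i], cands$mod_deltas[[i]],
                      fragment_tol), numeric(1))
  cands <- cands[cands$preliminary_score >= min_prelim, , drop = FALSE]
  rownames(cands) <- NULL
  cands
}
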