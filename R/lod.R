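# Numerical floors (documented in the methods vignette).
P_RANDOM_FLOOR <- 1e-4   # lower bound on the random-match probability
ERR_FLOOR <- 0.005       # Da; |mass error| floor so exact matches stay finite
SIGMA_FLOOR <- 0.01      # Da; error-PDF standard-deviation floor
SD_FLOOR <- 1e-6         # Z-score denominator floor
NORM_FLOOR <- 1e-9       # floor for normalized distribution bins

#' Match theoretical ions to observed peaks
#'
#' One-to-one greedy assignment: all (ion, peak) pairs within the fragment
#' tolerance are sorted by absolute mass error (ties broken by lower
#' theoretical m/z, then lower observed m/z) and claimed greedily, so each
#' peak and each theoretical ion is used at most once.
#'
#' @param spectrum A `spectrum`.
#' @param ions Data.frame of theoretical ions as produced by [ion_series()].
#' @param tolerance Fragment tolerance in Da.
#' @return The matched subset of `ions` with extra columns `observed_mz`,
#'   `observed_intensity` and `mass_error` (observed minus expected, Da).
#' @export
match_fragments <- function(spectrum, ions, tolerance = 0.5) {
  stopifnot(inherits(spectrum, "spectrum"), tolerance > 0)
  empty <- cbind(ions[0L, , drop = FALSE],
                 data.frame(observed_mz = numeric(),
                            observed_intensity = numeric(),
                            mass_error = numeric()))
  if (!nrow(ions) || !nrow(spectrum$peaks)) return(empty)
  peak_mz <- spectrum$peaks$mz
  err <- outer(ions$mz, peak_mz, function(e, o) o - e)
  ok <- which(abs(err) <= tolerance, arr.ind = TRUE)
  if (!nrow(ok)) return(empty)
  pairs <- data.frame(ion = ok[, 1L], peak = ok[, 2L],
                      abs_err = abs(err[ok]))
  pairs <- pairs[order(pairs$abs_err, ions$mz[pairs$ion],
                       peak_mz[pairs$peak]), , drop = FALSE]
  used_ion <- logical(nrow(ions))
  used_peak <- logical(nrow(spectrum$peaks))
  keep <- logical(nrow(pairs))
  ion_col <- pairs$ion
  peak_col <- pairs$peak
  for (i in seq_len(nrow(pairs))) {
    ii <- ion_col[i]; pp <- peak_col[i]
    if (used_ion[ii] || used_peak[pp]) next
    used_ion[ii] <- TRUE
    used_peak[pp] <- TRUE
    keep[i] <- TRUE
  }
  pairs <- pairs[keep, , drop = FALSE]
  out <- ions[pairs$ion, , drop = FALSE]
  out$observed_mz <- peak_mz[pairs$peak]
  out$observed_intensity <- spectrum$peaks$intensity[pairs$peak]
  out$mass_error <- out$observed_mz - out$mz
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random-match probability under the uniform peak model: the probability
# that a random peak lands within +/- |error| of the theoretical m/z.
p_random_uniform <- function(mass_error, density) {
  stopifnot(density > 0)
  err <- pmax(abs(mass_error), ERR_FLOOR)
  pmin(pmax(2 * err * density, P_RANDOM_FLOOR), 1)
}

#' Fragment LOD, metric 1 (fixed correct probability)
#'
#' The probability of a correct fragment match is fixed at 0.5 (about half
#' of the considered peaks are identifiable for correct peptides); the
#' random-match probability is `2 * |error| * density` under a uniform peak
#' model. LOD scores are natural logarithms: for a density of 0.1 peaks/Da
#' and an error of 0.25 Da, `p_random = 0.05` and the LOD is
#' `ln(0.5/0.05) = 2.3`.
#'
#' @param mass_error Signed mass error(s) in Da (vectorized).
#' @param density Spectrum peak density in peaks per Dalton
#'   (see [peak_density()]).
#' @param p_correct Fixed correct-match probability (default 0.5).
#' @return Fragment LOD score(s), natural log.
#' @export
#' @examples
#' fragment_lod_metric1(0.25, 0.1)  # 2.3026
fragment_lod_metric1 <- function(mass_error, density, p_correct = 0.5) {
  log(p_correct / p_random_uniform(mass_error, density))
}

#' Fragment LOD, metric 2 (mass-specific correct probability)
#'
#' Replaces metric 1's fixed 0.5 with the empirical probability of a correct
#' match for the fragment's 200 Da mass bin and parent charge class, looked
#' up from a [metric_model()].
#'
#' @param expected_mz Theoretical fragment m/z value(s).
#' @inheritParams fragment_lod_metric1
#' @param model A [metric_model()].
#' @param parent_charge Parent charge (class 3 uses the fixed average of all
#'   1+ and 2+ proportions).
#' @return Fragment LOD score(s).
#' @export
fragment_lod_metric2 <- function(expected_mz, mass_error, model, density,
                                 parent_charge = 1L) {
  p_c <- lookup_proportion(model, "correct", expected_mz, parent_charge)
  log(p_c / p_random_uniform(mass_error, density))
}

#' Fragment LOD, metric 3 (normalized correct vs random distributions)
#'
#' The correct and random (decoy) match-proportion tables are each
#' normalized to sum to one; the LOD for a matched fragment is the natural
#' log of the ratio of the normalized correct to the normalized random value
#' for its 200 Da mass bin, so the score is purely a function of fragment
#' mass.
#'
#' @inheritParams fragment_lod_metric2
#' @return Fragment LOD score(s).
#' @export
fragment_lod_metric3 <- function(expected_mz, model, parent_charge = 1L) {
  cn <- lookup_proportion(model, "correct_norm", expected_mz, parent_charge)
  rn <- lookup_proportion(model, "random_norm", expected_mz, parent_charge)
  log(pmax(cn, NORM_FLOOR) / pmax(rn, NORM_FLOOR))
}

#' Fragment LOD, metric 4 (metric 3 plus mass-error PDF)
#'
#' Metric 3 multiplied by a Gaussian weight for the observed mass error: the
#' mean and standard deviation of correctly assigned fragment mass errors
#' are modelled in 100 Da bins, and the correct-assignment probability is
#' multiplied by `w = exp(-(error - mu)^2 / (2 sigma^2))` (max-normalized,
#' so `w = 1` at the bin mean). On the log scale the metric is
#' `metric3 + ln(w)`.
#'
#' @inheritParams fragment_lod_metric2
#' @return Fragment LOD score(s).
#' @export
fragment_lod_metric4 <- function(expected_mz, mass_error, model,
                                 parent_charge = 1L) {
  base <- fragment_lod_metric3(expected_mz, model, parent_charge)
  pdf <- lookup_error_pdf(model, expected_mz)
  sigma <- pmax(pdf$sigma, SIGMA_FLOOR)
  base - (mass_error - pdf$mu)^2 / (2 * sigma^2)
}

#' Fragment LODs for a match table
#'
#' Dispatches to the metric implementations; `"nn4"` scores fragments with
#' metric 4 (the intensity-network contribution is added at the peptide Z
#' level, see [intensity_z_score()]).
#'
#' @param matches Data.frame from [match_fragments()].
#' @param metric One of `1`, `2`, `3`, `4`, `"nn4"`.
#' @param model A [metric_model()] (required for metrics 2-4).
#' @param density Peak density (required for metrics 1-2).
#' @param parent_charge Parent charge class.
#' @return Numeric vector of fragment LODs, one per match row.
#' @export
fragment_lod <- function(matches, metric = 1L, model = NULL, density = NULL,
                         parent_charge = 1L) {
  if (!nrow(matches)) return(numeric())
  metric <- as.character(metric)
  if (metric %in% c("2", "3", "4", "nn4") && is.null(model))
    stop("metrics 2-4 require a metric_model")
  switch(metric,
    "1" = fragment_lod_metric1(matches$mass_error, density),
    "2" = fragment_lod_metric2(matches$mz, matches$mass_error, model,
                               density, parent_charge),
    "3" = fragment_lod_metric3(matches$mz, model, parent_charge),
    "4" = ,
    "nn4" = fragment_lod_metric4(matches$mz, matches$mass_error, model,
                                 parent_charge),
    stop("unknown metric: ", metric)
  )
}

#' Peptide LOD
#'
#' The peptide-level LOD is the sum of the individual fragment LOD scores
#' (independence of features is assumed); an empty match list scores 0.
#'
#' @param frag_lods Numeric vector of fragment LODs.
#' @return Scalar peptide LOD.
#' @export
peptide_lod <- function(frag_lods) {
  if (!length(frag_lods)) return(0)
  sum(frag_lods)
}

#' Decoy-calibrated Z score
#'
#' Number of sample standard deviations the candidate's peptide LOD lies
#' above the mean LOD of decoy candidates drawn from the reversed database
#' for the same precursor window.
#'
#' @param candidate_lod Scalar peptide LOD.
#' @param decoy_lods Numeric vector of decoy peptide LODs.
#' @param min_decoys Minimum decoy count; fewer yields `NA` (default 20).
#' @param sd_floor Lower bound on the decoy standard deviation.
#' @return Z score, or `NA_real_` when decoys are insufficient.
#' @export
#' @examples
#' z_score(3, c(0, 2), min_decoys = 2)  # 1.4142
z_score <- function(candidate_lod, decoy_lods, min_decoys = 20L,
                    sd_floor = SD_FLOOR) {
  if (length(decoy_lods) < min_decoys) return(NA_real_)
  s <- max(stats::sd(decoy_lods), sd_floor)
  (candidate_lod - mean(decoy_lods)) / s
}
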