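# Primary-ion table (y/b 1+, plus y2+ for multiply charged parents) with
# match flags, used for match-proportion tables, error PDFs and the
# complementary-pair analysis.
build_frag_table <- function(ions, matches) {
  prim <- ions[ions$ion_type %in% c("y", "b") & ions$n_water_loss == 0L &
                 ions$n_ammonia_loss == 0L, , drop = FALSE]
  key <- function(df) paste(df$ion_type, df$index, df$charge,
                            df$n_water_loss, df$n_ammonia_loss)
  idx <- match(key(prim), key(matches))
  prim$matched <- !is.na(idx)
  prim$mass_error <- matches$mass_error[idx]
  prim$observed_intensity <- matches$observed_intensity[idx]
  prim
}

score_one_candidate <- function(spectrum, sequence, mods, metric, model,
                                density, fragment_tol) {
  ions <- scoring_ions(sequence, mods,
                       parent_charge = spectrum$parent_charge)
  matches <- match_fragments(spectrum, ions, fragment_tol)
  lods <- fragment_lod(matches, metric, model, density,
                       spectrum$parent_charge)
  matches$fragment_lod <- lods
  list(ions = ions, matches = matches, peptide_lod = peptide_lod(lods))
}

#' Score spectra against a peptide index
#'
#' The full pipeline: noise filtering, candidate selection (precursor
#' window, y-ion hits, preliminary score), full-ion-set fragment matching,
#' fragment and peptide LOD scoring under the chosen metric, and Z-score
#' calibration against decoy candidates drawn from the reversed database
#' for the same precursor window. With `metric = "nn4"` and a model carrying
#' a trained intensity network, the peptide-level intensity-prediction Z
#' score is added to the metric 4 Z score.
#'
#' If fewer than `min_decoys` decoys fall inside the precursor window, the
#' decoy window (only) is widened symmetrically (doubling, capped at
#' `decoy_tol_max`); if still short, the Z score is `NA`. At most
#' `max_decoys` decoys (nearest in mass) are scored per spectrum.
#'
#' @param spectra List of `spectrum` objects (see [read_spectra_dir()]).
#' @param index Target `peptide_index`.
#' @param decoy_index Decoy `peptide_index` ([build_decoy_index()]); `NULL`
#'   disables Z scores.
#' @param metric `1`, `2`, `3`, `4` or `"nn4"`.
#' @param model A [metric_model()]; required for metrics 2-4 and `"nn4"`.
#' @param precursor_tol,fragment_tol Mass tolerances in Da (defaults 2.5
#'   and 0.5).
#' @param min_y_hits,min_prelim Candidate-selection thresholds (defaults 2
#'   and 0.05).
#' @param noise_fraction Noise threshold as a fraction of summed intensity
#'   (default 0.005).
#' @param min_decoys,max_decoys,decoy_tol_max Decoy-population controls.
#' @param verbose Print progress every 1000 spectra.
#' @return An object of class `psm_results`: per-spectrum candidate lists
#'   (sorted by decreasing Z), decoy LODs and decoy fragment tables, plus
#'   the scoring parameters.
#' @export
score_spectra <- function(spectra, index, decoy_index = NULL, metric = 1L,
                          model = NULL, precursor_tol = 2.5,
                          fragment_tol = 0.5, min_y_hits = 2L,
                          min_prelim = 0.05, noise_fraction = 0.005,
                          min_decoys = 20L, max_decoys = 50L,
                          decoy_tol_max = 10, verbose = FALSE) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  out <- vector("list", length(spectra))
  for (si in seq_along(spectra)) {
    if (verbose && si %% 1000L == 0L)
      message("scored ", si, " / ", length(spectra), " spectra")
    raw <- spectra[[si]]
    rec <- list(spectrum_id = raw$source_file, source_file = raw$source_file,
                parent_charge = raw$parent_charge,
                neutral_mass = raw$neutral_mass, density = NA_real_,
                candidates = list(), decoy_lods = numeric(),
                decoy_records = list(), note = "")
    sp <- tryCatch(noise_filter(raw, noise_fraction), error = function(e) e)
    if (inherits(sp, "error")) {
      rec$note <- conditionMessage(sp)
      out[[si]] <- rec
      next
    }
    rec$density <- tryCatch(peak_density(sp), error = function(e) NA_real_)
    cands <- select_candidates(sp, index, precursor_tol, fragment_tol,
                               min_y_hits, min_prelim)
    if (nrow(cands) && is.na(rec$density) &&
        as.character(metric) %in% c("1", "2")) {
      rec$note <- "peak density undefined; metric needs >= 2 distinct peaks"
      out[[si]] <- rec
      next
    }

    # decoy population for Z calibration (scored once per spectrum)
    if (!is.null(decoy_index) && nrow(cands)) {
      tol <- precursor_tol
      repeat {
        pool <- query_by_mass(decoy_index, sp$neutral_mass, tol)
        if (nrow(pool) >= min_decoys || tol >= decoy_tol_max) break
        tol <- min(2 * tol, decoy_tol_max)
      }
      if (nrow(pool) > max_decoys) {
        ord <- order(abs(pool$neutral_mass - sp$neutral_mass))
        pool <- pool[ord[seq_len(max_decoys)], , drop = FALSE]
      }
      for (d in seq_len(nrow(pool))) {
        sc <- score_one_candidate(sp, pool$sequence[d], pool$mod_deltas[[d]],
                                  metric, model, rec$density, fragment_tol)
        rec$decoy_lods <- c(rec$decoy_lods, sc$peptide_lod)
        rec$decoy_records[[d]] <- list(
          sequence = pool$sequence[d],
          parent_charge = sp$parent_charge,
          peptide_lod = sc$peptide_lod,
          frag_table = build_frag_table(sc$ions, sc$matches))
      }
    }

    cand_records <- vector("list", nrow(cands))
    for (ci in seq_len(nrow(cands))) {
      sc <- score_one_candidate(sp, cands$sequence[ci],
                                cands$mod_deltas[[ci]], metric, model,
                                rec$density, fragment_tol)
      z_lod <- z_score(sc$peptide_lod, rec$decoy_lods, min_decoys)
      z_int <- NA_real_
      z_final <- z_lod
      if (identical(as.character(metric), "nn4")) {
        if (is.null(model$network))
          stop("metric 'nn4' requires a model with a trained network")
        m <- sc$matches
        if (nrow(m) >= 1L) {
          feats <- encode_feature_matrix(m, cands$sequence[ci],
                                         sp$parent_charge)
          pred <- exp(predict(model$network, feats))
          z_int <- intensity_z_score(m$observed_intensity, pred)
        } else z_int <- 0
        z_final <- if (is.na(z_lod)) NA_real_ else z_lod + z_int
      }
      cand_records[[ci]] <- list(
        sequence = cands$sequence[ci],
        mod_desc = cands$mod_desc[ci],
        mod_deltas = cands$mod_deltas[[ci]],
        neutral_mass = cands$neutral_mass[ci],
        protein_id = cands$protein_id[ci],
        flank_n = cands$flank_n[ci], flank_c = cands$flank_c[ci],
        y_hits = cands$y_hits[ci],
        preliminary_score = cands$preliminary_score[ci],
        matches = sc$matches,
        frag_table = build_frag_table(sc$ions, sc$matches),
        peptide_lod = sc$peptide_lod,
        z_lod = z_lod, z_intensity = z_int, z = z_final,
        max_peak_intensity = max(sp$peaks$intensity)
      )
    }
    if (length(cand_records)) {
      zs <- vapply(cand_records, function(cr)
        if (is.na(cr$z)) -Inf else cr$z, numeric(1))
      lods <- vapply(cand_records, `[[`, numeric(1), "peptide_lod")
      cand_records <- cand_records[order(-zs, -lods)]
    }
    rec$candidates <- cand_records
    out[[si]] <- rec
  }
  structure(
    list(spectra = out,
         params = list(metric = metric, precursor_tol = precursor_tol,
                       fragment_tol = fragment_tol, min_y_hits = min_y_hits,
                       min_prelim = min_prelim,
                       noise_fraction = noise_fraction,
                       min_decoys = min_decoys, max_decoys = max_decoys,
                       decoy_tol_max = decoy_tol_max)),
    class = "psm_results"
  )
}

#' @export
print.psm_results <- function(x, ...) {
  n_cand <- sum(vapply(x$spectra, function(s) length(s$candidates) > 0L,
                       logical(1)))
  cat(sprintf("psm_results: %d spectra (%d with candidates), metric %s\n",
              length(x$spectra), n_cand, as.character(x$params$metric)))
  invisible(x)
}

#' Per-spectrum summary table
#'
#' One row per spectrum: the best candidate (highest Z, ties by LOD) with
#' its scores, or NA columns when nothing survived selection.
#'
#' @param results A `psm_results` object.
#' @return Data.frame with columns `spectrum`, `sequence`, `mods`,
#'   `protein_id`, `parent_charge`, `neutral_mass`, `y_hits`,
#'   `preliminary_score`, `peptide_lod`, `z`, `n_candidates`.
#' @export
summary_table <- function(results) {
  stopifnot(inherits(results, "psm_results"))
  rows <- lapply(results$spectra, function(s) {
    if (!length(s$candidates)) {
      return(data.frame(spectrum = s$spectrum_id, sequence = NA_character_,
                        mods = NA_character_, protein_id = NA_character_,
                        parent_charge = s$parent_charge,
                        neutral_mass = s$neutral_mass, y_hits = NA_integer_,
                        preliminary_score = NA_real_, peptide_lod = NA_real_,
                        z = NA_real_, n_candidates = 0L,
                        stringsAsFactors = FALSE))
    }
    b <- s$candidates[[1L]]
    data.frame(spectrum = s$spectrum_id, sequence = b$sequence,
               mods = b$mod_desc, protein_id = b$protein_id,
               parent_charge = s$parent_charge,
               neutral_mass = s$neutral_mass, y_hits = b$y_hits,
               preliminary_score = b$preliminary_score,
               peptide_lod = b$peptide_lod, z = b$z,
               n_candidates = length(s$candidates),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract assignment records
#'
#' High-confidence assignments take the best candidate of each spectrum
#' with `Z > z_min` (default 6, the table-training threshold). With
#' `require_z = FALSE` every spectrum with a candidate contributes its best
#' candidate regardless of Z.
#'
#' @param results A `psm_results`.
#' @param z_min Z threshold (default 6).
#' @param require_z Apply the threshold (default `TRUE`).
#' @return List of assignment records (`spectrum_id`, `sequence`,
#'   `mod_deltas`, `mod_desc`, `parent_charge`, `frag_table`, `matches`,
#'   `peptide_lod`, `z`, `max_peak_intensity`).
#' @export
psm_assignments <- function(results, z_min = 6, require_z = TRUE) {
  stopifnot(inherits(results, "psm_results"))
  recs <- list()
  for (s in results$spectra) {
    if (!length(s$candidates)) next
    b <- s$candidates[[1L]]
    if (require_z && (is.na(b$z) || b$z <= z_min)) next
    recs[[length(recs) + 1L]] <- list(
      spectrum_id = s$spectrum_id, sequence = b$sequence,
      mod_deltas = b$mod_deltas, mod_desc = b$mod_desc,
      parent_charge = s$parent_charge, frag_table = b$frag_table,
      matches = b$matches, peptide_lod = b$peptide_lod, z = b$z,
      max_peak_intensity = b$max_peak_intensity)
  }
  recs
}

#' Decoy (random) assignment records
#'
#' Every scored decoy candidate, with no Z requirement: the random
#' assignment set used to build the metric 3 random match-proportion
#' tables.
#'
#' @param results A `psm_results` scored with a decoy index.
#' @return List of records with `spectrum_id`, `sequence`, `parent_charge`
#'   and `frag_table`.
#' @export
decoy_assignments <- function(results) {
  stopifnot(inherits(results, "psm_results"))
  recs <- list()
  for (s in results$spectra) {
    for (d in s$decoy_records) {
      recs[[length(recs) + 1L]] <- list(
        spectrum_id = s$spectrum_id, sequence = d$sequence,
        parent_charge = d$parent_charge, frag_table = d$frag_table)
    }
  }
  recs
}

#' Build a metric model from a scored run
#'
#' Convenience builder: correct tables from high-confidence assignments
#' (`Z > z_min`), random tables from all decoy candidates, error PDFs from
#' the matched primary fragments of the high-confidence set.
#'
#' @param results A `psm_results` scored with a decoy index (typically under
#'   metric 1).
#' @param z_min Training Z threshold (default 6).
#' @param network Optional trained intensity network to embed.
#' @return A [metric_model()].
#' @export
build_metric_model <- function(results, z_min = 6, network = NULL) {
  correct_set <- psm_assignments(results, z_min)
  if (!length(correct_set))
    stop("no assignments exceed Z > ", z_min, "; cannot build tables")
  random_set <- decoy_assignments(results)
  if (!length(random_set))
    stop("no decoy assignments; score with a decoy index first")
  correct <- build_match_proportion_table(correct_set)
  random <- build_match_proportion_table(random_set)
  errs <- do.call(rbind, lapply(correct_set, function(a)
    a$frag_table[a$frag_table$matched, c("mz", "mass_error")]))
  pdf <- fit_error_pdf(errs$mass_error, errs$mz)
  metric_model(correct, random, pdf, network)
}

#' Train the intensity network from high-confidence assignments
#'
#' Builds the 8-feature matrix from every matched fragment of the supplied
#' assignments and trains the 8-8-1 network on the log of peak intensity
#' after max-100 normalization of each spectrum.
#'
#' @param assignments Output of [psm_assignments()] (the training protocol
#'   uses `Z > 6` assignments from a held-out subset of the dataset).
#' @param epochs,seed Passed to [train_network()].
#' @return A trained `intensity_network`.
#' @export
train_intensity_network <- function(assignments, epochs = 20L, seed = 1L) {
  feats <- list()
  targets <- list()
  for (a in assignments) {
    m <- a$matches
    if (!nrow(m)) next
    feats[[length(feats) + 1L]] <-
      encode_feature_matrix(m, a$sequence, a$parent_charge)
    targets[[length(targets) + 1L]] <-
      log(100 * m$observed_intensity / a$max_peak_intensity)
  }
  train_network(do.call(rbind, feats), unlist(targets), epochs = epochs,
                seed = seed)
}
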