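pad_flank <- function(f) {
  f <- if (is.na(f)) "" else f
  paste0(strrep(".", 2L - nchar(f)), f)
}

ion_label <- function(m) {
  base <- ifelse(m$ion_type == "iminium",
                 paste0("imm(", m$fragment_seq, ")"),
                 paste0(m$ion_type, m$index))
  base <- paste0(base, ifelse(m$charge == 2L, "++", ""))
  loss <- paste0(
    ifelse(m$n_water_loss > 0L,
           paste0("-", ifelse(m$n_water_loss > 1L, m$n_water_loss, ""),
                  "H2O"), ""),
    ifelse(m$n_ammonia_loss > 0L,
           paste0("-", ifelse(m$n_ammonia_loss > 1L, m$n_ammonia_loss, ""),
                  "NH3"), ""))
  paste0(base, loss)
}

#' Format one identification as a text report block
#'
#' Human-readable block: source file, the peptide with two residues of
#' flanking protein context (dots stand for residues not present),
#' modifications, theoretical parent mass, charge, the matched fragments
#' ranked by descending observed intensity with observed (obsMZ) and
#' expected (expMZ) m/z and fragment LOD, then the peptide LOD and Z score.
#' m/z values print with 4 decimals, intensities and LOD/Z with 2. The
#' printed peptide LOD is the sum of the printed (2-decimal) fragment LODs,
#' so the rendered total always equals the sum of the rendered fragment
#' rows.
#'
#' @param candidate A candidate record from a `psm_results` spectrum entry.
#' @param spectrum_id Source file / spectrum identifier.
#' @param parent_charge Parent charge.
#' @param metric Metric identifier printed in the block.
#' @return Character vector of report lines.
#' @export
format_match_report <- function(candidate, spectrum_id, parent_charge,
                                metric = 1L) {
  m <- candidate$matches
  lines <- c(
    "match",
    sprintf("file    %s", spectrum_id),
    sprintf("seq     %s.%s.%s", pad_flank(candidate$flank_n),
            candidate$sequence, pad_flank(candidate$flank_c)),
    sprintf("mods    %s", if (nzchar(candidate$mod_desc))
      candidate$mod_desc else "-"),
    sprintf("pmass   %.4f", candidate$neutral_mass),
    sprintf("charge  %d", parent_charge),
    sprintf("metric  %s", as.character(metric)),
    sprintf("%-14s %-10s %-10s %-10s %s",
            "ion", "obsMZ", "expMZ", "intensity", "LOD"))
  if (nrow(m)) {
    m <- m[order(-m$observed_intensity, m$mz), , drop = FALSE]
    lines <- c(lines, sprintf("%-14s %-10.4f %-10.4f %-10.2f %.2f",
                              ion_label(m), m$observed_mz, m$mz,
                              m$observed_intensity, m$fragment_lod))
  }
  total <- sum(round(m$fragment_lod, 2))
  lines <- c(lines,
             sprintf("peptideLOD %.2f", if (nrow(m)) total else 0),
             sprintf("Z          %s",
                     if (is.na(candidate$z)) "NA"
                     else sprintf("%.2f", candidate$z)),
             "end", "")
  lines
}

#' Write the identification report and summary table
#'
#' One [format_match_report()] block per spectrum for the best candidate
#' (or every candidate with `top_only = FALSE`), plus an optional
#' tab-separated per-spectrum summary for scripting.
#'
#' @param results A `psm_results`.
#' @param path Report file path.
#' @param summary_path Optional TSV path (see [summary_table()]).
#' @param top_only Report only the best candidate per spectrum (default).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, summary_path = NULL,
                         top_only = TRUE) {
  stopifnot(inherits(results, "psm_results"))
  blocks <- character()
  for (s in results$spectra) {
    cands <- s$candidates
    if (!length(cands)) next
    if (top_only) cands <- cands[1L]
    for (cand in cands) {
      blocks <- c(blocks,
                  format_match_report(cand, s$spectrum_id, s$parent_charge,
                                      results$params$metric))
    }
  }
  writeLines(blocks, path)
  if (!is.null(summary_path)) {
    utils::write.table(summary_table(results), summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Parse an identification report back
#'
#' Recovers, for every block, the spectrum id, peptide sequence (the part
#' between the flanking dots), modification string, parent mass, charge,
#' number of fragment rows, the rendered peptide LOD and Z, and the sum of
#' the rendered fragment LODs.
#'
#' @param input Path to a report file, or its lines.
#' @return Data.frame with one row per block.
#' @export
parse_match_report <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input, warn = FALSE) else input
  starts <- which(lines == "match")
  ends <- which(lines == "end")
  stopifnot(length(starts) == length(ends))
  rows <- lapply(seq_along(starts), function(i) {
    blk <- lines[starts[i]:ends[i]]
    field <- function(key) sub(sprintf("^%s\\s+", key), "",
                               grep(sprintf("^%s\\s", key), blk,
                                    value = TRUE)[1L])
    seq_desc <- field("seq")
    hdr <- grep("^ion\\s", blk)[1L]
    stop_at <- grep("^peptideLOD", blk)[1L]
    frag_lines <- if (stop_at > hdr + 1L)
      blk[(hdr + 1L):(stop_at - 1L)] else character()
    frag_lines <- frag_lines[nzchar(frag_lines)]
    frag_lods <- if (length(frag_lines))
      as.numeric(vapply(strsplit(trimws(frag_lines), "\\s+"),
                        function(f) f[[length(f)]], "")) else numeric()
    data.frame(
      spectrum = field("file"),
      sequence = sub("^..\\.([A-Z]+)\\...$", "\\1", seq_desc),
      mods = field("mods"),
      pmass = as.numeric(field("pmass")),
      charge = as.integer(field("charge")),
      n_fragments = length(frag_lods),
      peptide_lod = as.numeric(field("peptideLOD")),
      fragment_lod_sum = if (length(frag_lods)) sum(frag_lods) else 0,
      z = suppressWarnings(as.numeric(field("Z"))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
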