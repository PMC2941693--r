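#' Tryptic digestion of a protein sequence
#'
#' Cleaves after K or R except when the next residue is P, and emits every
#' run of 1 to `max_missed + 1` consecutive segments.
#'
#' @param sequence Protein residue string (any alphabet; residues are not
#'   validated here).
#' @param max_missed Maximum number of missed cleavage sites (default 2).
#' @return A data.frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`; one row per unique coordinate span. An empty input
#'   yields zero rows.
#' @export
#' @examples
#' digest_protein("MKAKRPGK", max_missed = 0)$sequence  # MK, AK, RPGK
digest_protein <- function(sequence, max_missed = 2L) {
  stopifnot(max_missed >= 0L)
  if (!nzchar(sequence)) {
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), missed_cleavages = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  # cleavage after position i: res[i] in {K, R} and res[i+1] != P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut_after[cut_after < n], n))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  n_seg <- length(starts)
  rows <- list()
  for (i in seq_len(n_seg)) {
    for (m in 0:min(max_missed, n_seg - i)) {
      rows[[length(rows) + 1L]] <- c(starts[i], ends[i + m], m)
    }
  }
  mat <- do.call(rbind, rows)
  data.frame(
    sequence = substring(sequence, mat[, 1L], mat[, 2L]),
    start = as.integer(mat[, 1L]), end = as.integer(mat[, 2L]),
    missed_cleavages = as.integer(mat[, 3L]),
    stringsAsFactors = FALSE
  )
}

#' Enumerate modified forms of a peptide
#'
#' Fixed modifications are applied to every target residue. Variable
#' modifications are enumerated over subsets of target positions of size 0 to
#' `max_per_peptide` (per spec), combined across specifications by Cartesian
#' product. The unmodified form is always present when only variable mods
#' apply.
#'
#' @param sequence Peptide residue string.
#' @param mod_specs List of [mod_spec()] objects.
#' @param cap Maximum number of forms per base peptide; excess forms are
#'   truncated with a warning (default 64).
#' @return A list of forms, each a list with `deltas` (per-position numeric)
#'   and `desc` (compact text like `"M3+15.994915"`, `""` for unmodified).
#' @export
enumerate_modified_forms <- function(sequence, mod_specs = default_mods(),
                                     cap = 64L) {
  res <- split_residues(sequence)
  n <- length(res)
  base <- numeric(n)
  var_choices <- list()
  for (spec in mod_specs) {
    pos <- which(res %in% spec$targets)
    if (!length(pos)) next
    if (spec$kind == "fixed") {
      base[pos] <- base[pos] + spec$delta_mass
    } else {
      subsets <- list(integer())
      for (k in seq_len(min(spec$max_per_peptide, length(pos)))) {
        # combn(x, k) expands scalar x to seq_len(x); guard against it
        cmb <- if (length(pos) == 1L) list(pos) else
          utils::combn(pos, k, simplify = FALSE)
        subsets <- c(subsets, cmb)
      }
      var_choices[[length(var_choices) + 1L]] <-
        list(delta = spec$delta_mass, subsets = subsets)
    }
  }
  forms <- list(list(positions = list(), deltas = numeric(0)))
  for (ch in var_choices) {
    new_forms <- list()
    for (f in forms) {
      for (s in ch$subsets) {
        new_forms[[length(new_forms) + 1L]] <- list(
          positions = c(f$positions, list(s)),
          deltas = c(f$deltas, rep(ch$delta, length(s))),
          pos_flat = c(if (is.null(f$pos_flat)) integer() else f$pos_flat, s))
      }
    }
    forms <- new_forms
  }
  if (length(forms) > cap) {
    warning("modified-form enumeration capped at ", cap, " for ", sequence)
    forms <- forms[seq_len(cap)]
  }
  lapply(forms, function(f) {
    deltas <- base
    pos_flat <- if (is.null(f$pos_flat)) integer() else f$pos_flat
    if (length(pos_flat)) deltas[pos_flat] <- deltas[pos_flat] + f$deltas
    applied <- which(deltas != 0)
    desc <- sprintf("%s%d%+g", res[applied], applied, deltas[applied])
    list(deltas = deltas, desc = paste(desc, collapse = ";"))
  })
}

#' Read a FASTA proteome
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]; the protein identifier
#' is the first whitespace-delimited token of each header.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

flank_string <- function(protein, from, to) {
  if (from > to) return("")
  substring(protein, max(1L, from), min(nchar(protein), to))
}

#' Build a mass-ordered peptide index from a proteome
#'
#' Digests every protein with the trypsin rule, enumerates modified forms,
#' pre-computes the neutral mass and the singly charged y-ion series, and
#' sorts the records by non-decreasing neutral mass so precursor windows can
#' be answered by binary search.
#'
#' @param proteins Named character vector of protein sequences (see
#'   [read_fasta()]) or a path to a FASTA file.
#' @param mod_specs List of [mod_spec()] objects (default [default_mods()]).
#' @param max_missed Maximum missed cleavages (default 2).
#' @param length_range Peptide length bounds kept in the index (default
#'   `c(5, 60)`).
#' @param decoy Logical; if `TRUE` every protein is reversed before
#'   digestion and records are flagged as decoys with `DECOY_`-prefixed
#'   protein ids.
#' @param mod_cap Per-peptide cap on enumerated modified forms.
#' @return An object of class `peptide_index`: a list with `records` (a
#'   data.frame with list-columns `mod_deltas` and `y_ions`) and `metadata`.
#' @export
build_peptide_index <- function(proteins, mod_specs = default_mods(),
                                max_missed = 2L, length_range = c(5L, 60L),
                                decoy = FALSE, mod_cap = 64L) {
  if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins))
    proteins <- read_fasta(proteins)
  stopifnot(length(proteins) >= 1L)
  if (is.null(names(proteins)))
    names(proteins) <- sprintf("protein_%04d", seq_along(proteins))
  if (decoy) {
    proteins <- vapply(proteins, function(s)
      paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""), "")
    names(proteins) <- paste0("DECOY_", names(proteins))
  }
  acc <- list()
  for (pid in names(proteins)) {
    prot <- proteins[[pid]]
    pep <- digest_protein(prot, max_missed)
    len <- nchar(pep$sequence)
    pep <- pep[len >= length_range[1L] & len <= length_range[2L], , drop = FALSE]
    for (r in seq_len(nrow(pep))) {
      seqr <- pep$sequence[r]
      if (grepl(sprintf("[^%s]", paste(names(RESIDUE_MASS), collapse = "")),
                seqr))
        next  # non-standard residue (X, B, ...)
      forms <- enumerate_modified_forms(seqr, mod_specs, cap = mod_cap)
      ys <- lapply(forms, function(f) y_series(seqr, f$deltas))
      acc[[length(acc) + 1L]] <- data.frame(
        sequence = seqr,
        mod_desc = vapply(forms, `[[`, "", "desc"),
        neutral_mass = vapply(forms, function(f)
          peptide_mass(seqr, f$deltas), numeric(1)),
        protein_id = pid,
        flank_n = flank_string(prot, pep$start[r] - 2L, pep$start[r] - 1L),
        flank_c = flank_string(prot, pep$end[r] + 1L, pep$end[r] + 2L),
        missed_cleavages = pep$missed_cleavages[r],
        is_decoy = decoy,
        stringsAsFactors = FALSE
      )
      acc[[length(acc)]]$mod_deltas <- I(lapply(forms, `[[`, "deltas"))
      acc[[length(acc)]]$y_ions <- I(ys)
    }
  }
  records <- if (length(acc)) do.call(rbind, acc) else NULL
  if (is.null(records)) stop("no peptides produced from the input proteome")
  ord <- order(records$neutral_mass)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(
      records = records,
      metadata = list(
        format_version = 1L,
        enzyme = "trypsin (cleave after K/R, not before P)",
        max_missed = as.integer(max_missed),
        length_range = as.integer(length_range),
        mods = lapply(mod_specs, unclass),
        n_proteins = length(proteins),
        decoy = decoy
      )
    ),
    class = "peptide_index"
  )
}

#' Decoy index from reversed proteins
#'
#' Convenience wrapper: each protein is reversed whole, then digested and
#' indexed identically to the target database.
#'
#' @inheritParams build_peptide_index
#' @return A `peptide_index` with `is_decoy = TRUE` records.
#' @export
build_decoy_index <- function(proteins, mod_specs = default_mods(),
                              max_missed = 2L, length_range = c(5L, 60L),
                              mod_cap = 64L) {
  build_peptide_index(proteins, mod_specs, max_missed, length_range,
                      decoy = TRUE, mod_cap = mod_cap)
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf(
    "peptide_index: %d records (%s), mass %.2f..%.2f Da, %d proteins%s\n",
    nrow(x$records), x$metadata$enzyme,
    min(x$records$neutral_mass), max(x$records$neutral_mass),
    x$metadata$n_proteins, if (isTRUE(x$metadata$decoy)) " [decoy]" else ""))
  invisible(x)
}

#' Query peptides by precursor mass window
#'
#' Binary search (via [findInterval()]) on the mass-ordered records for all
#' peptides with `|neutral_mass - mass| <= tolerance`.
#'
#' @param index A `peptide_index`.
#' @param mass Neutral query mass in Da.
#' @param tolerance Symmetric window half-width in Da (must be >= 0).
#' @return The matching subset of `index$records` (possibly zero rows).
#' @export
query_by_mass <- function(index, mass, tolerance) {
  stopifnot(inherits(index, "peptide_index"))
  if (tolerance < 0) stop("tolerance must be non-negative")
  m <- index$records$neutral_mass
  first <- findInterval(mass - tolerance, m, left.open = TRUE) + 1L
  last <- findInterval(mass + tolerance, m)
  if (first > last) return(index$records[0L, , drop = FALSE])
  index$records[first:last, , drop = FALSE]
}

#' Serialize / load a peptide index
#'
#' The on-disk format is R's native serialization (version 3) of the
#' versioned index object; [read_peptide_index()] validates the class and
#' format version. Round-tripping is bitwise exact.
#'
#' @param index A `peptide_index`.
#' @param path File path.
#' @return `write_peptide_index` returns `path` invisibly;
#'   `read_peptide_index` returns the `peptide_index`.
#' @export
write_peptide_index <- function(index, path) {
  stopifnot(inherits(index, "peptide_index"))
  saveRDS(index, path, version = 3L)
  invisible(path)
}

#' @rdname write_peptide_index
#' @export
read_peptide_index <- function(path) {
  index <- readRDS(path)
  if (!inherits(index, "peptide_index") ||
      !identical(index$metadata$format_version, 1L))
    stop("not a version-1 peptide index file: ", path)
  index
}
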