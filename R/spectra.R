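new_spectrum <- function(source_file, precursor_mh, parent_charge, peaks) {
  ord <- order(-peaks$intensity, peaks$mz)
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL
  structure(
    list(
      source_file = source_file,
      precursor_mh = precursor_mh,
      parent_charge = as.integer(parent_charge),
      neutral_mass = precursor_mh - PROTON_MASS,
      peaks = peaks
    ),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum %s: M+H %.4f, charge %d, %d peaks\n",
              x$source_file, x$precursor_mh, x$parent_charge, nrow(x$peaks)))
  invisible(x)
}

#' Parse a DTA spectrum
#'
#' DTA convention: the first line holds the singly protonated precursor mass
#' (M+H, Da) and the parent charge; every following line holds an m/z and an
#' intensity. Peaks are stored in descending-intensity order (ties broken by
#' ascending m/z); the neutral mass is `M+H - 1.007276`.
#'
#' @param input Path to a `.dta` file, or its content as a character vector
#'   of lines (or a single string with embedded newlines).
#' @param source_file Label recorded on the spectrum (defaults to the path or
#'   `"<text>"`).
#' @return A `spectrum` object.
#' @export
#' @examples
#' parse_dta(c("1001.0 2", "200.0 50.0", "300.0 25.0"))
parse_dta <- function(input, source_file = NULL) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    if (is.null(source_file)) source_file <- basename(input)
    lines <- readLines(input, warn = FALSE)
  } else {
    if (is.null(source_file)) source_file <- "<text>"
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty DTA input: ", source_file)
  parse_two <- function(line, lineno) {
    fields <- strsplit(line, "[ \t]+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2L || anyNA(vals))
      stop(sprintf("malformed DTA line %d in %s: '%s'",
                   lineno, source_file, line))
    vals
  }
  header <- parse_two(lines[1L], 1L)
  if (length(lines) < 2L) stop("no peaks in DTA input: ", source_file)
  body <- vapply(seq_along(lines)[-1L],
                 function(i) parse_two(lines[i], i), numeric(2))
  peaks <- data.frame(mz = body[1L, ], intensity = body[2L, ])
  new_spectrum(source_file, header[1L], header[2L], peaks)
}

#' Load a directory of DTA spectra
#'
#' Accepts `.dta` files (case-insensitive extension), recursing one
#' directory level below `dir`.
#'
#' @param dir Directory path.
#' @return List of `spectrum` objects, ordered by file name.
#' @export
read_spectra_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.dta$", ignore.case = TRUE,
                      full.names = TRUE)
  subdirs <- list.dirs(dir, recursive = FALSE)
  for (d in subdirs) {
    files <- c(files, list.files(d, pattern = "\\.dta$", ignore.case = TRUE,
                                 full.names = TRUE))
  }
  files <- sort(files)
  lapply(files, parse_dta)
}

#' Read an MGF peak list
#'
#' Convenience reader for BEGIN IONS/END IONS blocks with `PEPMASS` and
#' `CHARGE` headers, mapped to the same `spectrum` type as [parse_dta()].
#' `PEPMASS` is interpreted as the precursor m/z; the stored `precursor_mh`
#' is the singly protonated mass `charge * (mz - proton) + proton`.
#'
#' @param path Path to an MGF file.
#' @return List of `spectrum` objects.
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends))
    stop("unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    pepmass <- as.numeric(strsplit(vals[match("PEPMASS", keys)], " ")[[1L]][1L])
    charge <- 1L
    if ("CHARGE" %in% keys)
      charge <- as.integer(sub("\\+$", "", vals[match("CHARGE", keys)]))
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      sprintf("%s#%d", basename(path), i)
    body <- block[!kv & nzchar(block)]
    mat <- vapply(strsplit(body, "[ \t]+"),
                  function(f) as.numeric(f[1:2]), numeric(2))
    mh <- charge * (pepmass - PROTON_MASS) + PROTON_MASS
    out[[i]] <- new_spectrum(title, mh, charge,
                             data.frame(mz = mat[1L, ], intensity = mat[2L, ]))
  }
  out
}

#' Remove low-intensity noise peaks
#'
#' Deletes every peak whose intensity is below `fraction` of the total sum
#' of peak intensities (the threshold is computed once, on the pre-filter
#' sum). The default of 0.5% follows sum-based signal-processing practice:
#' peak intensities reflect the proportion of fragmentation along the whole
#' peptide, so noise properties scale with the summed signal rather than the
#' base peak.
#'
#' @param spectrum A `spectrum`.
#' @param fraction Threshold fraction in `[0, 1)` (default 0.005).
#' @return The filtered `spectrum` (peak order preserved).
#' @export
noise_filter <- function(spectrum, fraction = 0.005) {
  stopifnot(inherits(spectrum, "spectrum"),
            fraction >= 0, fraction < 1)
  threshold <- fraction * sum(spectrum$peaks$intensity)
  keep <- spectrum$peaks$intensity >= threshold
  if (!any(keep))
    stop("noise filter removed every peak; spectrum unscorable: ",
         spectrum$source_file)
  spectrum$peaks <- spectrum$peaks[keep, , drop = FALSE]
  rownames(spectrum$peaks) <- NULL
  spectrum
}

#' Peak density of a spectrum
#'
#' Number of peaks divided by the observed m/z range, in peaks per Dalton.
#' Used as the uniform random-peak model in metric 1.
#'
#' @param spectrum A `spectrum` with at least 2 peaks of distinct m/z.
#' @return Peaks per Dalton.
#' @export
#' @examples
#' # 100 peaks spanning 150..1150 Da -> 0.1 peaks per Dalton
peak_density <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum"))
  mz <- spectrum$peaks$mz
  rng <- max(mz) - min(mz)
  if (nrow(spectrum$peaks) < 2L || rng <= 0)
    stop("peak density undefined: need >= 2 peaks with distinct m/z")
  nrow(spectrum$peaks) / rng
}

#' Top 4N most intense peaks
#'
#' N approximates the peptide length as `round(neutral_mass / 114)` (average
#' residue mass 114 Da), floored at 1; the `min(4N, #peaks)` most intense
#' peaks are returned (intensity ties broken by ascending m/z).
#'
#' @param spectrum A `spectrum` with positive neutral mass.
#' @return List with `peaks` (data.frame subset) and `n` (the value of N).
#' @export
top_intense_peaks <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum"), spectrum$neutral_mass > 0)
  n_est <- max(1L, as.integer(round(spectrum$neutral_mass / 114)))
  k <- min(4L * n_est, nrow(spectrum$peaks))
  # peaks are stored sorted by descending intensity, ties by ascending m/z
  list(peaks = spectrum$peaks[seq_len(k), , drop = FALSE], n = n_est)
}

#' Write a spectrum in DTA format
#'
#' @param spectrum A `spectrum`.
#' @param path Output path.
#' @param digits Number of decimal places for m/z and intensity (default 5).
#' @return `path`, invisibly.
#' @export
write_dta <- function(spectrum, path, digits = 5L) {
  fmt <- sprintf("%%.%df %%.%df", digits, digits)
  lines <- c(
    sprintf("%.5f %d", spectrum$precursor_mh, spectrum$parent_charge),
    sprintf(fmt, spectrum$peaks$mz, spectrum$peaks$intensity)
  )
  writeLines(lines, path)
  invisible(path)
}
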