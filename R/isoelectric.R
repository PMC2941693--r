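peptide_net_charge <- function(sequence, pH, pka = DEFAULT_PKA) {
  res <- split_residues(sequence)
  basic <- c(Nterm = 1, table(factor(res, levels = c("K", "R", "H"))))
  acidic <- c(Cterm = 1, table(factor(res, levels = c("D", "E", "C", "Y"))))
  pos <- sum(basic * 1 / (1 + 10^(pH - pka[names(basic)])))
  neg <- sum(acidic * 1 / (1 + 10^(pka[names(acidic)] - pH)))
  pos - neg
}

#' Isoelectric point of a peptide or fragment
#'
#' The pH at which the Henderson-Hasselbalch net charge (free N-terminus,
#' free C-terminus, and D/E/C/Y/H/K/R side chains) is zero, found by
#' bisection on \[0, 14\]. Net charge is monotone decreasing in pH, so a
#' root always exists; iteration stops when `|net charge| < tol`. Fragment
#' termini are treated as standard amino/carboxy groups (a documented
#' simplification for b ions).
#'
#' @param sequence Residue string.
#' @param pka Named pKa vector with entries `Nterm`, `Cterm`, `K`, `R`, `H`,
#'   `D`, `E`, `C`, `Y` (default: EMBOSS-style values).
#' @param tol Charge convergence tolerance (default 1e-4).
#' @return pI in pH units.
#' @export
#' @examples
#' isoelectric_point("GG")  # (8.6 + 3.6) / 2 = 6.1
isoelectric_point <- function(sequence, pka = DEFAULT_PKA, tol = 1e-4) {
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- peptide_net_charge(sequence, mid, pka)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Complementary y/b pair table
#'
#' For every fragmentation site of every assigned peptide, when exactly one
#' of the complementary pair `{y_(n-i), b_i}` was matched in the spectrum, a
#' record is emitted with the site's relative position (b-fragment length
#' over parent length), the theoretical pIs of both fragments, their ratio
#' (`pi_y / pi_b`) and difference, and which ion was observed. Sites where
#' both or neither ion matched produce no record.
#'
#' @param assignments List of assignment records (see [psm_assignments()]);
#'   each needs `spectrum_id`, `sequence` and a `frag_table` with primary
#'   y/b match flags.
#' @param pka pKa table passed to [isoelectric_point()].
#' @return Data.frame with columns `spectrum`, `site_fraction`, `pi_y`,
#'   `pi_b`, `relative_pi`, `delta_pi`, `observed_ion`.
#' @export
complementary_pair_table <- function(assignments, pka = DEFAULT_PKA) {
  rows <- list()
  for (a in assignments) {
    res <- split_residues(a$sequence)
    n <- length(res)
    ft <- a$frag_table
    primary <- ft[ft$charge == 1L & ft$ion_type %in% c("y", "b"), ,
                  drop = FALSE]
    for (i in seq_len(n - 1L)) {
      y_hit <- any(primary$matched[primary$ion_type == "y" &
                                     primary$index == (n - i)])
      b_hit <- any(primary$matched[primary$ion_type == "b" &
                                     primary$index == i])
      if (y_hit == b_hit) next
      y_seq <- paste(res[(i + 1L):n], collapse = "")
      b_seq <- paste(res[1:i], collapse = "")
      pi_y <- isoelectric_point(y_seq, pka)
      pi_b <- isoelectric_point(b_seq, pka)
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum = a$spectrum_id,
        site_fraction = i / n,
        pi_y = pi_y, pi_b = pi_b,
        relative_pi = pi_y / pi_b,
        delta_pi = pi_y - pi_b,
        observed_ion = if (y_hit) "y-only" else "b-only",
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows))
    return(data.frame(spectrum = character(), site_fraction = numeric(),
                      pi_y = numeric(), pi_b = numeric(),
                      relative_pi = numeric(), delta_pi = numeric(),
                      observed_ion = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
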