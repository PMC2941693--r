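#' Generate a theoretical fragment-ion series
#'
#' Produces singly charged y, b and a ions for every backbone cleavage site,
#' optionally doubly charged y ions (only when the parent charge is 2 or
#' higher), immonium ions (one per distinct residue), and water/ammonia
#' neutral-loss variants. Conventions: `b_i = sum(residues[1..i]) + proton`,
#' `y_i = sum(residues[(n-i+1)..n]) + water + proton`, `a_i = b_i - CO`,
#' `y2+ = (y1+ + proton) / 2`, immonium = residue mass - CO + proton. Loss
#' variants subtract `k * water + j * ammonia` from the neutral fragment
#' (divided by the fragment charge on the m/z scale).
#'
#' @param sequence Peptide residue string.
#' @param mods `NULL` or per-position numeric mass deltas.
#' @param ions Character subset of `c("y", "b", "a")`.
#' @param parent_charge Precursor charge; y2+ ions are emitted only when
#'   `>= 2`.
#' @param max_water_loss,max_ammonia_loss Maximum neutral losses per fragment
#'   (0 disables losses; the probability-scoring default is 2 and 2).
#' @param iminium Emit immonium ions (one per distinct modified residue
#'   mass)? Default `FALSE`; preliminary scoring turns this on.
#' @return A data.frame with columns `ion_type` (`"y"`, `"b"`, `"a"`,
#'   `"iminium"`), `index` (1-based fragment index, `NA` for immonium),
#'   `charge`, `n_water_loss`, `n_ammonia_loss`, `mz` and `fragment_seq`.
#' @export
#' @examples
#' ion_series("AK", ions = "y")        # y1 at 147.11280
#' ion_series("AG", ions = c("b", "a"))
ion_series <- function(sequence, mods = NULL, ions = c("y", "b", "a"),
                       parent_charge = 1L,
                       max_water_loss = 0L, max_ammonia_loss = 0L,
                       iminium = FALSE) {
  res <- split_residues(sequence)
  n <- length(res)
  deltas <- mod_deltas_for(n, mods)
  ions <- match.arg(ions, c("y", "b", "a"), several.ok = TRUE)
  masses <- RESIDUE_MASS[res] + deltas
  csum <- cumsum(masses)
  total <- csum[n]

  typ <- character(); index <- integer(); charge <- integer()
  mz <- numeric(); frag <- character()
  add <- function(ion_type, idx2, chg, mzs, frags) {
    k <- length(mzs)
    typ <<- c(typ, rep(ion_type, k)); index <<- c(index, idx2)
    charge <<- c(charge, rep(chg, k)); mz <<- c(mz, mzs)
    frag <<- c(frag, frags)
  }

  if (n >= 2L) {
    idx <- seq_len(n - 1L)
    prefix <- substring(sequence, 1L, idx)
    suffix <- substring(sequence, n - idx + 1L, n)
    b_mz <- unname(csum[idx] + PROTON_MASS)
    y_mz <- unname((total - csum[n - idx]) + WATER_MASS + PROTON_MASS)
    if ("y" %in% ions) {
      add("y", idx, 1L, y_mz, suffix)
      if (parent_charge >= 2L)
        add("y", idx, 2L, (y_mz + PROTON_MASS) / 2, suffix)
    }
    if ("b" %in% ions) add("b", idx, 1L, b_mz, prefix)
    if ("a" %in% ions) add("a", idx, 1L, b_mz - CO_MASS, prefix)
  }
  n_base <- length(mz)
  if (iminium) {
    imm_mz <- masses - IMMONIUM_DELTA
    keep <- !duplicated(paste(res, round(imm_mz, 6)))
    add("iminium", rep(NA_integer_, sum(keep)), 1L, unname(imm_mz[keep]),
        res[keep])
  }
  n_water <- integer(length(mz))
  n_ammonia <- integer(length(mz))

  if ((max_water_loss > 0L || max_ammonia_loss > 0L) && n_base) {
    loss_grid <- expand.grid(k = 0:max_water_loss, j = 0:max_ammonia_loss)
    loss_grid <- loss_grid[loss_grid$k + loss_grid$j > 0L, , drop = FALSE]
    base <- seq_len(n_base)  # iminium ions carry no loss variants
    rep_idx <- rep(base, times = nrow(loss_grid))
    k <- rep(loss_grid$k, each = n_base)
    j <- rep(loss_grid$j, each = n_base)
    typ <- c(typ, typ[rep_idx]); index <- c(index, index[rep_idx])
    charge <- c(charge, charge[rep_idx]); frag <- c(frag, frag[rep_idx])
    mz <- c(mz, mz[rep_idx] -
              (k * WATER_MASS + j * AMMONIA_MASS) / charge[rep_idx])
    n_water <- c(n_water, as.integer(k))
    n_ammonia <- c(n_ammonia, as.integer(j))
  }
  keep <- mz > 0
  frags <- data.frame(
    ion_type = typ[keep], index = index[keep], charge = charge[keep],
    n_water_loss = n_water[keep], n_ammonia_loss = n_ammonia[keep],
    mz = mz[keep], fragment_seq = frag[keep], stringsAsFactors = FALSE)
  frags
}

#' Pre-computed singly charged y-ion series
#'
#' @param sequence Peptide residue string (length >= 2 for a non-empty
#'   result).
#' @param mods `NULL` or per-position numeric mass deltas.
#' @return Numeric vector of y1+ m/z values, index 1 to n-1.
#' @export
y_series <- function(sequence, mods = NULL) {
  res <- split_residues(sequence)
  n <- length(res)
  if (n < 2L) return(numeric())
  masses <- RESIDUE_MASS[res] + mod_deltas_for(n, mods)
  csum <- cumsum(masses)
  unname((csum[n] - csum[n - seq_len(n - 1L)]) + WATER_MASS + PROTON_MASS)
}

# Ion set used in preliminary scoring: y1+, b1+, immonium, plus y2+ for
# parent charge >= 2. No losses.
preliminary_ions <- function(sequence, mods = NULL, parent_charge = 1L) {
  ion_series(sequence, mods, ions = c("y", "b"), parent_charge = parent_charge,
             iminium = TRUE)
}

# Full probability-scoring ion set: y, b, a (+ y2+ when charge >= 2), up to
# two water and two ammonia losses. Immonium optional (default off).
scoring_ions <- function(sequence, mods = NULL, parent_charge = 1L,
                         iminium = FALSE) {
  ion_series(sequence, mods, ions = c("y", "b", "a"),
             parent_charge = parent_charge,
             max_water_loss = 2L, max_ammonia_loss = 2L, iminium = iminium)
}
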