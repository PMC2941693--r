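ION_TYPE_CODE <- c(none = 0, iminium = 1, y = 2, a = 3, b = 4)

#' Encode the 8 fragment features for intensity prediction
#'
#' Feature vector (in order): ion type code (no fragmentation 0, iminium 1,
#' y 2, a 3, b 4); parent charge; fragment charge; parent length; fragment
#' length / parent length; H+K+R count in fragment / H+K+R count in parent
#' (0 when the parent has none); hydrophobicity codes of the residues on the
#' N- and C-terminal sides of the fragmentation site. Residue identity is
#' coded as 20 evenly spaced values on \[0, 1\] in order of increasing
#' hydrophobicity (Kyte-Doolittle ordering).
#'
#' For an iminium ion both flanking codes are the residue's own code; for an
#' unfragmented precursor (`"none"`) they are the first and last residues of
#' the parent.
#'
#' @param ion_type One of `"none"`, `"iminium"`, `"y"`, `"a"`, `"b"`.
#' @param index 1-based fragment index along its series (`NA` for iminium /
#'   none).
#' @param fragment_charge Fragment charge.
#' @param parent_seq Parent peptide residue string.
#' @param parent_charge Parent (precursor) charge.
#' @param fragment_seq Fragment residue string.
#' @return Named numeric vector of length 8.
#' @export
encode_features <- function(ion_type, index, fragment_charge, parent_seq,
                            parent_charge, fragment_seq) {
  codes <- hydrophobicity_codes()
  pres <- split_residues(parent_seq)
  n <- length(pres)
  flen <- nchar(fragment_seq)
  hkr <- function(res) sum(res %in% c("H", "K", "R"))
  hkr_parent <- hkr(pres)
  hkr_frag <- hkr(strsplit(fragment_seq, "", fixed = TRUE)[[1L]])
  site <- switch(ion_type,
    y = n - index,          # cleavage between n-index and n-index+1
    b = , a = index,        # cleavage between index and index+1
    NA_integer_)
  if (ion_type %in% c("y", "b", "a")) {
    nterm <- pres[site]
    cterm <- pres[site + 1L]
  } else if (ion_type == "iminium") {
    nterm <- cterm <- fragment_seq
  } else {
    nterm <- pres[1L]
    cterm <- pres[n]
  }
  c(
    ion_type_code = unname(ION_TYPE_CODE[ion_type]),
    parent_charge = as.numeric(parent_charge),
    fragment_charge = as.numeric(fragment_charge),
    parent_length = as.numeric(n),
    length_ratio = flen / n,
    hkr_ratio = if (hkr_parent > 0) hkr_frag / hkr_parent else 0,
    nterm_code = unname(codes[nterm]),
    cterm_code = unname(codes[cterm])
  )
}

# Feature matrix for a match table (rows from match_fragments()).
encode_feature_matrix <- function(matches, parent_seq, parent_charge) {
  t(vapply(seq_len(nrow(matches)), function(i)
    encode_features(matches$ion_type[i], matches$index[i],
                    matches$charge[i], parent_seq, parent_charge,
                    matches$fragment_seq[i]),
    numeric(8)))
}

nn_unpack <- function(theta, n_in = 8L, n_hidden = 8L) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(n_in * n_hidden)], n_in, n_hidden)
  i <- i + n_in * n_hidden
  b1 <- theta[i + seq_len(n_hidden)]; i <- i + n_hidden
  W2 <- matrix(theta[i + seq_len(n_hidden)], n_hidden, 1L); i <- i + n_hidden
  b2 <- theta[i + 1L]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

nn_forward <- function(p, X) {
  H <- 1 / (1 + exp(-(X %*% p$W1 + matrix(p$b1, nrow(X), length(p$b1),
                                          byrow = TRUE))))
  list(H = H, yhat = drop(H %*% p$W2) + p$b2)
}

#' Train the 8-8-1 intensity network
#'
#' Fits a multilayer perceptron with 8 input nodes, 8 sigmoidal hidden nodes
#' and a single linear output node to log peak intensities (the spectrum
#' having been normalized so its maximum peak is 100), by full-batch
#' quasi-Newton (BFGS) minimization of the mean squared error with analytic
#' gradients. One epoch is one full-batch BFGS iteration; the default of 20
#' epochs matches the training protocol. Deterministic given `seed`.
#'
#' @param X Numeric feature matrix, one row per training fragment, 8 columns
#'   (see [encode_features()]).
#' @param y Numeric targets: `log` of peak intensity after max-100
#'   normalization.
#' @param epochs Number of full-batch quasi-Newton iterations (default 20).
#' @param seed Integer seed for weight initialization.
#' @param n_hidden Hidden layer width (default 8).
#' @param min_fragments Minimum training-set size (default 100).
#' @return An object of class `intensity_network` with the weight matrices,
#'   input standardization constants and the training loss trace.
#' @export
train_network <- function(X, y, epochs = 20L, seed = 1L, n_hidden = 8L,
                          min_fragments = 100L) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 8L, length(y) == nrow(X))
  if (nrow(X) < min_fragments)
    stop("need at least ", min_fragments, " training fragments, got ", nrow(X))
  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, stats::sd)
  x_scale[!is.finite(x_scale) | x_scale < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2L, x_center), 2L, x_scale, "/")
  n_in <- ncol(Xs)
  n_par <- n_in * n_hidden + n_hidden + n_hidden + 1L

  loss <- function(theta) {
    p <- nn_unpack(theta, n_in, n_hidden)
    fwd <- nn_forward(p, Xs)
    mean((fwd$yhat - y)^2)
  }
  grad <- function(theta) {
    p <- nn_unpack(theta, n_in, n_hidden)
    fwd <- nn_forward(p, Xs)
    r <- 2 * (fwd$yhat - y) / length(y)          # d(mse)/d(yhat)
    gW2 <- crossprod(fwd$H, r)
    gb2 <- sum(r)
    dH <- (r %*% t(p$W2)) * fwd$H * (1 - fwd$H)
    gW1 <- crossprod(Xs, dH)
    gb1 <- colSums(dH)
    c(as.numeric(gW1), gb1, as.numeric(gW2), gb2)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))
  theta0 <- stats::rnorm(n_par, sd = 0.5)
  # One BFGS path truncated at `epochs` iterations; the per-epoch loss trace
  # is recovered by deterministic truncated re-runs of the same path.
  fit <- stats::optim(theta0, loss, grad, method = "BFGS",
                      control = list(maxit = epochs))
  trace <- numeric(epochs + 1L)
  trace[1L] <- loss(theta0)
  for (e in seq_len(epochs - 1L)) {
    trace[e + 1L] <- stats::optim(theta0, loss, grad, method = "BFGS",
                                  control = list(maxit = e))$value
  }
  trace[epochs + 1L] <- fit$value
  trace <- cummin(trace)
  p <- nn_unpack(fit$par, n_in, n_hidden)
  structure(
    list(W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
         x_center = x_center, x_scale = x_scale,
         epochs = as.integer(epochs), seed = as.integer(seed),
         loss_trace = trace),
    class = "intensity_network"
  )
}

#' Predict log peak intensities
#'
#' @param object A trained `intensity_network`.
#' @param X Feature matrix (8 columns).
#' @param ... Unused.
#' @return Numeric vector of predicted log intensities.
#' @export
predict.intensity_network <- function(object, X, ...) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2L, object$x_center), 2L, object$x_scale, "/")
  nn_forward(object, Xs)$yhat
}

#' @export
print.intensity_network <- function(x, ...) {
  cat(sprintf(
    "intensity_network: 8-%d-1, %d epochs (seed %d), final loss %.4g\n",
    length(x$b1), x$epochs, x$seed, x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Wrap-around rotations of a predicted intensity vector
#'
#' Iteratively assigns each predicted intensity to the previous fragment
#' (with wrap-around) until the vector cycles back to its original position;
#' the identity position is excluded. Every rotation preserves the intensity
#' multiset, so the null distribution of dot products keeps the predicted
#' peak-height distribution.
#'
#' @param v Numeric vector (ordered along the fragment series).
#' @return List of `length(v) - 1` rotated vectors (empty for length 1).
#' @export
#' @examples
#' wraparound_rotations(c(1, 2, 3))  # list(c(2,3,1), c(3,1,2))
wraparound_rotations <- function(v) {
  n <- length(v)
  stopifnot(n >= 1L)
  if (n == 1L) return(list())
  lapply(seq_len(n - 1L), function(s) v[((seq_len(n) - 1L + s) %% n) + 1L])
}

#' Intensity-prediction Z score
#'
#' Both the observed and predicted intensity vectors over the matched
#' fragments are normalized to sum to 100; the true score is their inner
#' dot product, and the null distribution is the set of dot products against
#' every wrap-around rotation of the predicted vector. The Z score is the
#' number of sample standard deviations the true dot product lies above the
#' null mean. Candidates with fewer than `min_matches` matched fragments
#' contribute 0.
#'
#' @param observed Observed intensities of the matched fragments (ordered
#'   along the fragment series).
#' @param predicted Predicted intensities on the same ordering (linear
#'   scale).
#' @param min_matches Minimum matched fragments (default 3).
#' @param sd_floor Null standard-deviation floor.
#' @return Z score (0 when under-determined).
#' @export
#' @examples
#' intensity_z_score(c(60, 30, 10), c(50, 40, 10))  # 2.93
intensity_z_score <- function(observed, predicted, min_matches = 3L,
                              sd_floor = SD_FLOOR) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < min_matches) return(0)
  if (sum(observed) <= 0 || sum(predicted) <= 0) return(0)
  obs <- 100 * observed / sum(observed)
  pred <- 100 * predicted / sum(predicted)
  true_dot <- sum(obs * pred)
  null_dots <- vapply(wraparound_rotations(pred),
                      function(r) sum(obs * r), numeric(1))
  s <- max(stats::sd(null_dots), sd_floor)
  (true_dot - mean(null_dots)) / s
}
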