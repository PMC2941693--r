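#' Fragment mass bin label
#'
#' Bins are lower-exclusive/upper-inclusive and labelled by their upper
#' edge; the first bin contains all fragments at or below `width` Da.
#'
#' @param mass Fragment mass(es) in Da.
#' @param width Bin width in Da (200 for match-proportion tables, 100 for
#'   error PDFs).
#' @return Numeric bin label(s) (the bin's upper edge).
#' @export
#' @examples
#' mass_bin(c(86, 200, 200.1, 1500), 200)  # 200 200 400 1600
mass_bin <- function(mass, width = 200) {
  pmax(width, width * ceiling(mass / width))
}

# Nearest-populated-bin lookup in a named (by upper edge) numeric table.
lookup_binned <- function(table, bins) {
  edges <- as.numeric(names(table))
  idx <- vapply(bins, function(b) which.min(abs(edges - b)), integer(1))
  unname(table[idx])
}

#' Build per-charge-class match-proportion tables
#'
#' For each parent charge class (1+ and 2+) and each 200 Da fragment mass
#' bin, the proportion of theoretical fragments that were matched to a peak
#' (matched / total theoretical fragments in the bin). Rare 3+ parents get a
#' fixed value: the average of all the 1+ and 2+ proportions.
#'
#' @param assignments A list of assignment records, each with elements
#'   `parent_charge` and `frag_table` (a data.frame with columns `mz` and
#'   `matched` covering the peptide's primary fragment ions); see
#'   [psm_assignments()].
#' @param bin_width Bin width in Da (default 200).
#' @return A list with named-vector tables `"1"` and `"2"` (possibly empty),
#'   scalar `"3"`, and matching `counts` tables.
#' @export
build_match_proportion_table <- function(assignments, bin_width = 200) {
  if (!length(assignments)) stop("no assignments supplied")
  props <- list()
  counts <- list()
  for (cls in c("1", "2")) {
    rows <- Filter(function(a) min(a$parent_charge, 3L) == as.integer(cls),
                   assignments)
    if (!length(rows)) {
      props[[cls]] <- stats::setNames(numeric(), character())
      counts[[cls]] <- stats::setNames(integer(), character())
      next
    }
    mz <- unlist(lapply(rows, function(a) a$frag_table$mz), use.names = FALSE)
    matched <- unlist(lapply(rows, function(a) a$frag_table$matched),
                      use.names = FALSE)
    bins <- mass_bin(mz, bin_width)
    tot <- tapply(matched, bins, length)
    hit <- tapply(matched, bins, sum)
    ord <- order(as.numeric(names(tot)))
    props[[cls]] <- (hit / tot)[ord]
    counts[[cls]] <- tot[ord]
  }
  pooled <- c(props[["1"]], props[["2"]])
  list(`1` = props[["1"]], `2` = props[["2"]],
       `3` = if (length(pooled)) mean(pooled) else NA_real_,
       counts = counts)
}

#' Normalize a binned table to a distribution
#'
#' Divides every bin by the table sum so the bins sum to one; scaling the
#' input by any constant leaves the output unchanged.
#'
#' @param table Named numeric vector of non-negative bin values.
#' @return Named numeric vector summing to 1.
#' @export
normalize_distribution <- function(table) {
  s <- sum(table)
  if (!length(table) || !is.finite(s) || s <= 0)
    stop("cannot normalize an empty or all-zero table")
  table / s
}

#' Fit per-bin Gaussian mass-error models
#'
#' Sample mean and sample standard deviation of signed fragment mass errors
#' (observed minus expected) in 100 Da fragment-mass bins, for correctly
#' assigned fragments. Bins with fewer than `min_n` errors are dropped
#' (lookup falls back to the nearest populated bin); the standard deviation
#' is floored at `sigma_floor`.
#'
#' @param errors Signed mass errors in Da.
#' @param masses Theoretical fragment masses in Da (same length).
#' @param bin_width Bin width in Da (default 100).
#' @param min_n Minimum errors per retained bin (default 5).
#' @param sigma_floor Standard-deviation floor in Da (default 0.01).
#' @return Data.frame with columns `bin`, `mu`, `sigma`, `n`.
#' @export
fit_error_pdf <- function(errors, masses, bin_width = 100, min_n = 5L,
                          sigma_floor = SIGMA_FLOOR) {
  stopifnot(length(errors) == length(masses))
  bins <- mass_bin(masses, bin_width)
  groups <- split(errors, bins)
  keep <- vapply(groups, length, integer(1)) >= min_n
  groups <- groups[keep]
  if (!length(groups)) stop("no error-PDF bin reaches min_n = ", min_n)
  out <- data.frame(
    bin = as.numeric(names(groups)),
    mu = vapply(groups, mean, numeric(1)),
    sigma = pmax(vapply(groups, stats::sd, numeric(1)), sigma_floor),
    n = vapply(groups, length, integer(1))
  )
  out$sigma[is.na(out$sigma)] <- sigma_floor
  out <- out[order(out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a metric model
#'
#' Bundles the empirical artefacts driving metrics 2-4 and the intensity
#' network: per-charge-class correct and random (decoy) match-proportion
#' tables (200 Da bins), their normalized distributions, the mass-error
#' PDFs (100 Da bins, pooled across charges), and optionally a trained
#' [train_network()] object.
#'
#' @param correct Output of [build_match_proportion_table()] on
#'   high-confidence assignments (Z > 6 by default).
#' @param random Output of [build_match_proportion_table()] on decoy
#'   assignments (no Z requirement).
#' @param error_pdf Output of [fit_error_pdf()], or `NULL` (scoring with
#'   metric 4 then raises an error).
#' @param network Optional trained intensity network.
#' @return An object of class `metric_model`.
#' @export
metric_model <- function(correct, random, error_pdf = NULL, network = NULL) {
  norm_or_empty <- function(tab) {
    if (length(tab) && sum(tab) > 0) normalize_distribution(tab) else tab
  }
  avg_tables <- function(t1, t2) {
    edges <- sort(unique(c(as.numeric(names(t1)), as.numeric(names(t2)))))
    if (!length(edges)) return(stats::setNames(numeric(), character()))
    v <- vapply(edges, function(e) {
      vals <- c(if (length(t1)) lookup_binned(t1, e),
                if (length(t2)) lookup_binned(t2, e))
      mean(vals)
    }, numeric(1))
    stats::setNames(v, edges)
  }
  model <- list(
    correct = list(`1` = correct[["1"]], `2` = correct[["2"]],
                   `3` = correct[["3"]]),
    random = list(`1` = random[["1"]], `2` = random[["2"]],
                  `3` = random[["3"]]),
    correct_norm = list(
      `1` = norm_or_empty(correct[["1"]]),
      `2` = norm_or_empty(correct[["2"]]),
      `3` = norm_or_empty(avg_tables(correct[["1"]], correct[["2"]]))),
    random_norm = list(
      `1` = norm_or_empty(random[["1"]]),
      `2` = norm_or_empty(random[["2"]]),
      `3` = norm_or_empty(avg_tables(random[["1"]], random[["2"]]))),
    error_pdf = error_pdf,
    network = network,
    format_version = 1L
  )
  class(model) <- "metric_model"
  model
}

#' @export
print.metric_model <- function(x, ...) {
  cat(sprintf(
    "metric_model: correct bins (1+/2+): %d/%d, random bins: %d/%d, %s, %s\n",
    length(x$correct[["1"]]), length(x$correct[["2"]]),
    length(x$random[["1"]]), length(x$random[["2"]]),
    if (is.null(x$error_pdf)) "no error PDF"
      else sprintf("%d error-PDF bins", nrow(x$error_pdf)),
    if (is.null(x$network)) "no network" else "trained network"))
  invisible(x)
}

charge_class <- function(parent_charge) {
  as.character(pmin(pmax(as.integer(parent_charge), 1L), 3L))
}

# proportion lookup with nearest-bin fallback; kind in
# c("correct", "random", "correct_norm", "random_norm")
lookup_proportion <- function(model, kind, expected_mz, parent_charge) {
  cls <- charge_class(parent_charge)
  tab <- model[[kind]][[cls]]
  bins <- mass_bin(expected_mz, 200)
  if (cls == "3" && kind %in% c("correct", "random")) {
    # fixed value for rare 3+ parents
    return(rep(tab, length(bins)))
  }
  if (!length(tab)) {
    # charge class never observed during table building: fall back to the
    # other class, then to the pooled constant
    other <- model[[kind]][[if (cls == "1") "2" else "1"]]
    if (length(other)) return(lookup_binned(other, bins))
    return(rep(model[[sub("_norm", "", kind)]][["3"]], length(bins)))
  }
  lookup_binned(tab, bins)
}

lookup_error_pdf <- function(model, expected_mz) {
  if (is.null(model$error_pdf) || !nrow(model$error_pdf))
    stop("metric 4 requires fitted error PDFs in the model")
  bins <- mass_bin(expected_mz, 100)
  idx <- vapply(bins, function(b)
    which.min(abs(model$error_pdf$bin - b)), integer(1))
  model$error_pdf[idx, , drop = FALSE]
}

#' Write / read a metric model as JSON
#'
#' Versioned plain-text serialization of the tables, error PDFs and network
#' weights, at full double precision.
#'
#' @param model A `metric_model`.
#' @param path File path.
#' @return `write_metric_model` returns `path` invisibly;
#'   `read_metric_model` returns the `metric_model`.
#' @export
write_metric_model <- function(model, path) {
  stopifnot(inherits(model, "metric_model"))
  payload <- unclass(model)
  to_kv <- function(v) list(bins = as.numeric(names(v)),
                            values = as.numeric(v))
  for (part in c("correct", "random", "correct_norm", "random_norm")) {
    for (cls in c("1", "2")) payload[[part]][[cls]] <- to_kv(payload[[part]][[cls]])
    if (part %in% c("correct_norm", "random_norm"))
      payload[[part]][["3"]] <- to_kv(payload[[part]][["3"]])
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_metric_model
#' @export
read_metric_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  from_kv <- function(kv) stats::setNames(as.numeric(kv$values),
                                          as.numeric(kv$bins))
  for (part in c("correct", "random", "correct_norm", "random_norm")) {
    for (cls in c("1", "2")) payload[[part]][[cls]] <- from_kv(payload[[part]][[cls]])
    if (part %in% c("correct_norm", "random_norm"))
      payload[[part]][["3"]] <- from_kv(payload[[part]][["3"]])
  }
  if (!is.null(payload$error_pdf))
    payload$error_pdf <- as.data.frame(payload$error_pdf)
  if (!is.null(payload$network)) {
    net <- payload$network
    net$W1 <- as.matrix(net$W1)
    net$W2 <- as.matrix(net$W2)
    net$b1 <- as.numeric(net$b1)
    net$b2 <- as.numeric(net$b2)
    net$x_center <- as.numeric(net$x_center)
    net$x_scale <- as.numeric(net$x_scale)
    class(net) <- "intensity_network"
    payload$network <- net
  }
  payload$format_version <- as.integer(payload$format_version)
  class(payload) <- "metric_model"
  payload
}
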