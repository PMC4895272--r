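#' Pearson interaction weights between miRNAs and mRNAs
#'
#' Computes the raw (pre-cutoff) p x q interaction weight matrix from an
#' aligned expression pair. Each entry is derived from the Pearson
#' correlation between one miRNA's and one mRNA's expression across the
#' shared samples:
#'
#' * `mode = "abs"` — the absolute value of the correlation. This caters for
#'   both up- and down-regulation: signed correlations would cancel in the
#'   downstream collaboration sums.
#' * `mode = "neg_abs"` — the absolute value where the correlation is
#'   negative, 0 otherwise. This restricts the graph to repression-consistent
#'   (anti-correlated) edges.
#'
#' A feature with zero variance across samples has an undefined correlation;
#' its weights are set to 0 with a warning rather than propagating NaN.
#' Weights are invariant to affine rescaling of any feature's expression
#' (a Pearson correlation property). The sample-covariance (n-1) convention
#' is used; the divisor cancels in the correlation, so this is a
#' documentation point only.
#'
#' @param pair A `matched_pair` from [align_samples()] (or the synthetic
#'   generator).
#' @param mode `"abs"` (default) or `"neg_abs"`.
#' @return A numeric p x q matrix in \[0, 1\], miRNA rows, mRNA columns, with
#'   attribute `mode`. Feed it to [apply_cutoff()].
#' @export
pearson_weights <- function(pair, mode = c("abs", "neg_abs")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pair, "matched_pair"))
  X <- pair$mirna
  Y <- pair$mrna
  sd_x <- apply(X, 1L, stats::sd)
  sd_y <- apply(Y, 1L, stats::sd)
  if (any(sd_x == 0) || any(sd_y == 0)) {
    warning(sprintf(
      "%d miRNA and %d mRNA feature(s) have zero variance; their weights are set to 0",
      sum(sd_x == 0), sum(sd_y == 0)))
  }
  r <- suppressWarnings(stats::cor(t(X), t(Y)))
  r[!is.finite(r)] <- 0
  w <- if (mode == "abs") abs(r) else ifelse(r < 0, -r, 0)
  # cor() can exceed 1 by a few ulp for exactly collinear features
  w <- pmin(w, 1)
  dimnames(w) <- list(rownames(X), rownames(Y))
  attr(w, "mode") <- mode
  w
}

#' Apply the magnitude cutoff eta to a weight matrix
#'
#' Entries below `eta` are set to 0; entries at or above `eta` are retained
#' at their value (the graph stays weighted, it is not binarized). `eta`
#' interpolates between fully weighted mining (`eta = 0`, nothing removed)
#' and unweighted-like sparsity (`eta = 1`, only perfect correlations
#' survive). Support is nested: raising `eta` can only remove entries.
#'
#' Any precomputed weight matrix with entries in \[0, 1\] is accepted, not
#' only the output of [pearson_weights()], so alternative weighting schemes
#' can be plugged in upstream (see [read_weights()]).
#'
#' @param raw Numeric matrix with entries in \[0, 1\], miRNA rows and mRNA
#'   columns (dimnames required).
#' @param eta Cutoff threshold in \[0, 1\].
#' @return An `interaction_weights` matrix with attributes `eta` and `mode`.
#' @export
apply_cutoff <- function(raw, eta) {
  assert_scalar_number(eta, "eta", lower = 0, upper = 1)
  if (!is.matrix(raw) || !is.numeric(raw)) {
    abort_mircore("`raw` must be a numeric matrix", "mircore_type_error")
  }
  if (is.null(rownames(raw)) || is.null(colnames(raw))) {
    abort_mircore("weight matrix must carry miRNA row names and mRNA column names",
                  "mircore_type_error")
  }
  if (any(raw < 0) || any(raw > 1) || any(!is.finite(raw))) {
    abort_mircore("raw weights must all lie in [0, 1]", "mircore_range_error")
  }
  w <- raw
  w[w < eta] <- 0
  structure(w,
            eta = eta,
            mode = attr(raw, "mode", exact = TRUE) %||% "precomputed",
            class = c("interaction_weights", class(matrix())))
}

#' Read a precomputed weight matrix from delimited text
#'
#' Same layout as an expression file (miRNA rows, mRNA columns, numeric
#' body); entries must lie in \[0, 1\]. Use when interaction weights come
#' from a source other than Pearson correlation.
#'
#' @inheritParams read_expression
#' @return A numeric matrix suitable for [apply_cutoff()].
#' @export
read_weights <- function(path, delimiter = "\t") {
  w <- read_expression(path, delimiter)
  if (any(w < 0) || any(w > 1)) {
    abort_mircore("weight file entries must lie in [0, 1]", "mircore_range_error")
  }
  w
}

#' Write a weight matrix for inspection
#'
#' @param w Weight matrix (miRNA rows, mRNA columns).
#' @param path Output TSV path.
#' @export
write_weights <- function(w, path) {
  write_expression(unclass_weights(w), path)
}

unclass_weights <- function(w) {
  attr(w, "eta") <- NULL
  attr(w, "mode") <- NULL
  class(w) <- class(matrix())
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
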