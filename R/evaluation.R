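#' Sequence-separation range classes
#'
#' CASP-style ranges: short = separation 6-11, medium = 12-23, long >= 24
#' (|i - j| >= 24, the usual convention for "separation over 24").
#'
#' @param rangeClass `"short"`, `"medium"` or `"long"`.
#' @return Numeric vector `c(min, max)` of |i - j| bounds (inclusive).
#' @export
separationRange <- function(rangeClass = c("long", "medium", "short")) {
  switch(match.arg(rangeClass),
         short = c(6, 11),
         medium = c(12, 23),
         long = c(24, Inf))
}

.rankedPairs <- function(pred, rangeClass) {
  L <- nrow(pred)
  rng <- separationRange(rangeClass)
  ij <- which(upper.tri(pred), arr.ind = TRUE)
  sep <- ij[, 2] - ij[, 1]
  keep <- sep >= rng[1] & sep <= rng[2]
  ij <- ij[keep, , drop = FALSE]
  # rank by probability, ties broken by (i, j) lexicographic order
  ord <- order(-pred[ij], ij[, 1], ij[, 2])
  ij[ord, , drop = FALSE]
}

#' Precision of the top-ranked predicted contacts
#'
#' Ranks residue pairs of the requested separation class by predicted
#' contact probability and reports the fraction of true contacts among
#' the top L/`fraction` pairs (k = round(L/fraction), at least 1). If
#' fewer candidate pairs exist than requested, precision is computed over
#' the available pairs and flagged.
#'
#' @param pred Numeric (L, L) contact-probability matrix.
#' @param truth Logical (L, L) contact matrix (NA = masked, excluded).
#' @param fraction Denominator of the top-L/k cut: 1, 2 or 5.
#' @param rangeClass Separation class (see [separationRange()]).
#' @return A list with `precision`, `k` (pairs taken), `nCandidates` and
#'   `truncated` (TRUE if fewer candidates than requested).
#' @export
contactPrecision <- function(pred, truth, fraction = 5,
                             rangeClass = "long") {
  stopifnot(identical(dim(pred), dim(truth)))
  L <- nrow(pred)
  ij <- .rankedPairs(pred, rangeClass)
  defined <- !is.na(truth[ij])
  ij <- ij[defined, , drop = FALSE]
  k <- max(1L, as.integer(round(L / fraction)))
  truncated <- nrow(ij) < k
  if (truncated)
    warning("fewer candidate pairs than requested; precision over available pairs")
  k <- min(k, nrow(ij))
  if (k == 0) return(list(precision = NA_real_, k = 0L, nCandidates = 0L,
                          truncated = TRUE))
  top <- ij[seq_len(k), , drop = FALSE]
  list(precision = mean(truth[top]), k = k, nCandidates = nrow(ij),
       truncated = truncated)
}

#' Mean probability of the top-L predicted contacts (PPC)
#'
#' The average predicted probability of the L top-ranked long-range
#' contacts — a confidence proxy that correlates with the quality of the
#' structures realized from the prediction.
#'
#' @param pred Numeric (L, L) contact-probability matrix.
#' @param rangeClass Separation class (default `"long"`).
#' @return Mean predicted probability of the top-L ranked pairs.
#' @export
ppc <- function(pred, rangeClass = "long") {
  L <- nrow(pred)
  ij <- .rankedPairs(pred, rangeClass)
  k <- min(L, nrow(ij))
  if (k == 0) return(NA_real_)
  mean(pred[ij[seq_len(k), , drop = FALSE]])
}

#' Pearson correlation with a zero-variance guard
#'
#' Thin wrapper over [stats::cor()] used for the PPC-versus-quality and
#' log(Meff)-versus-quality reports; errors on degenerate input instead of
#' returning NA.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The Pearson correlation coefficient.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance input")
  cor(x, y)
}

#' Full contact-precision report
#'
#' Evaluates all 9 precision cells (fractions L, L/2, L/5 by short,
#' medium, long range) plus PPC for one prediction.
#'
#' @param pred Numeric (L, L) contact-probability matrix.
#' @param truth Logical (L, L) contact matrix.
#' @return A data.frame with columns `fraction`, `range`, `precision`,
#'   `k`; PPC is attached as attribute `ppc`.
#' @export
contactEvalReport <- function(pred, truth) {
  rows <- expand.grid(fraction = c(1, 2, 5),
                      range = c("short", "medium", "long"),
                      stringsAsFactors = FALSE)
  rows$precision <- NA_real_
  rows$k <- NA_integer_
  for (r in seq_len(nrow(rows))) {
    cp <- suppressWarnings(
      contactPrecision(pred, truth, rows$fraction[r], rows$range[r]))
    rows$precision[r] <- cp$precision
    rows$k[r] <- cp$k
  }
  attr(rows, "ppc") <- ppc(pred)
  rows
}
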