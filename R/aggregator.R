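#' Channel count of the co-evolution aggregator
#'
#' With C embedding channels the pair feature h(i,j) concatenates f(i)
#' (C channels), f(j) (C channels) and the flattened outer-product block
#' g(i,j) (C^2 channels), so D = 2C + C^2; for the reference C = 64 this
#' gives 4224 channels. Without the outer products D = 2C.
#'
#' @param channels Embedding channels C.
#' @param includeOP Keep the outer-product block (default `TRUE`).
#' @return Integer channel count D.
#' @examples
#' aggregatedChannels(64)  # 4224
#' @export
aggregatedChannels <- function(channels, includeOP = TRUE) {
  C <- as.integer(channels)
  if (includeOP) 2L * C + C * C else 2L * C
}

.checkAgg <- function(X, w) {
  if (length(dim(X)) != 3L) stop("X must be a (C, L, K) array")
  if (dim(X)[3] != length(w@w))
    stop("weight vector length must match the number of homolog rows")
  if (w@mEff <= 0) stop("mEff must be positive")
}

#' Weighted average of per-homolog embeddings
#'
#' f(i) = (1/Meff) sum_k w_k X_k(i): average pooling of the residue
#' embeddings across homologs, weighted by the sequence weights.
#'
#' @param X Embedding array (C, L, K).
#' @param w A [WeightVector-class].
#' @return Numeric matrix (C, L).
#' @export
aggregateF <- function(X, w) {
  .checkAgg(X, w)
  d <- dim(X)
  f <- matrix(X, nrow = d[1] * d[2]) %*% w@w / w@mEff
  matrix(f, d[1], d[2])
}

#' Weighted average of embedding outer products
#'
#' g(i,j) = (1/Meff) sum_k w_k \[X_k(i) (x) X_k(j)\], the co-mutation
#' statistic between residues i and j: the outer product of the two
#' embedding vectors, averaged over homologs.
#'
#' @inheritParams aggregateF
#' @return Numeric array (C, C, L, L), `g[a, b, i, j]`.
#' @export
aggregateG <- function(X, w) {
  .checkAgg(X, w)
  C <- dim(X)[1]; L <- dim(X)[2]
  H <- aggregateHForwardCpp(X, w@w, w@mEff,
                            seq_len(L) - 1L, seq_len(L) - 1L, TRUE, 0L)
  g <- array(0, dim = c(C, C, L, L))
  for (m in seq_len(C * C)) {
    a <- (m - 1L) %% C + 1L
    b <- (m - 1L) %/% C + 1L
    g[a, b, , ] <- H[, , 2L * C + m]
  }
  g
}

#' Aggregated pair features h(i,j) = concat(f(i), f(j), g(i,j))
#'
#' Computes the full pair-feature tensor (or a crop of it) by streaming
#' over homolog chunks, so peak memory does not grow with K. The result is
#' independent of the chunk size (weighted sums are associative);
#' accumulation is in double precision.
#'
#' @inheritParams aggregateF
#' @param streamingChunk Homologs per accumulation chunk (default all).
#' @param rows,cols 1-based residue indices of the crop (default: all
#'   residues, the full L x L feature matrix).
#' @param includeOP Keep the C^2 outer-product channels (default `TRUE`;
#'   `FALSE` gives the concat(f(i), f(j)) reduction used by the
#'   outer-product ablation).
#' @return An [AggregatedFeatures-class] with an
#'   (length(rows), length(cols), D) array.
#' @export
aggregateH <- function(X, w, streamingChunk = 0L, rows = NULL, cols = NULL,
                       includeOP = TRUE) {
  .checkAgg(X, w)
  if (streamingChunk < 0L) stop("streamingChunk must be >= 1 (or 0 for all)")
  L <- dim(X)[2]
  if (is.null(rows)) rows <- seq_len(L)
  if (is.null(cols)) cols <- seq_len(L)
  H <- aggregateHForwardCpp(X, w@w, w@mEff, as.integer(rows) - 1L,
                            as.integer(cols) - 1L, includeOP,
                            as.integer(streamingChunk))
  new("AggregatedFeatures", h = H, channels = dim(X)[1],
      includeOP = includeOP, rows = as.integer(rows),
      cols = as.integer(cols))
}
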