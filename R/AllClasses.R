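#' Multiple sequence alignment in target coordinates
#'
#' An `Msa` holds a gap-free target sequence of length L and K homolog rows,
#' each of length L over the 20 amino-acid letters plus the gap character
#' `-` (insertions relative to the target have already been removed, as in
#' A3M practice). The target itself may be included as a homolog row, so a
#' single-sequence alignment still has K >= 1.
#'
#' @slot target Character scalar, the ungapped target sequence (length L).
#' @slot homologs Character vector of K aligned homolog sequences, each of
#'   length L.
#' @slot ids Character vector of K identifiers.
#' @export
setClass("Msa", representation(target = "character",
                               homologs = "character",
                               ids = "character"))

setValidity("Msa", function(object) {
  L <- nchar(object@target)
  if (length(object@target) != 1L || L < 1L)
    return("target must be a single non-empty string")
  if (grepl("-", object@target, fixed = TRUE))
    return("target must not contain gaps")
  if (length(object@homologs) < 1L)
    return("at least one homolog row is required (K >= 1)")
  if (any(nchar(object@homologs) != L))
    return("all homolog rows must have the target length L")
  if (length(object@ids) != length(object@homologs))
    return("ids must match the number of homolog rows")
  TRUE
})

#' Binary pairwise-alignment encoding of an MSA
#'
#' Each (homolog, position) is encoded as a binary vector of 41 elements:
#' channels 1-20 one-hot the target residue (order [aaAlphabet]), channels
#' 21-40 one-hot the homolog residue and channel 41 flags a gap in the
#' homolog. Nonstandard letters yield an all-zero amino-acid block.
#'
#' @slot values Numeric array of dimension (41, L, K).
#' @export
setClass("EncodedMsa", representation(values = "array"))

setValidity("EncodedMsa", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || d[1] != 41L)
    return("values must be a (41, L, K) array")
  TRUE
})

#' Sequence weights and effective alignment depth
#'
#' PSICOV-convention reweighting: each homolog's weight is the inverse of
#' the number of homologs (itself included) sharing at least the identity
#' threshold with it; `mEff`, the effective number of sequences, is the sum
#' of the weights.
#'
#' @slot w Numeric vector of K weights in (0, 1].
#' @slot mEff Numeric scalar, sum of the weights (1 <= mEff <= K).
#' @export
setClass("WeightVector", representation(w = "numeric", mEff = "numeric"))

setValidity("WeightVector", function(object) {
  if (any(object@w <= 0 | object@w > 1)) return("weights must lie in (0, 1]")
  if (abs(object@mEff - sum(object@w)) > 1e-8 * max(1, sum(object@w)))
    return("mEff must equal sum(w)")
  TRUE
})

#' Aggregated co-evolution pair features
#'
#' The pair-feature tensor h with h(i,j) = concat(f(i), f(j), g(i,j)):
#' channels 1..C carry the weighted-average embedding of residue i,
#' channels C+1..2C that of residue j, and (when outer products are kept)
#' the remaining C^2 channels the flattened weighted-average outer product
#' g(i,j), stored column-major so channel 2C + a + C*(b-1) is
#' mean_k w_k X_k\[a,i\] X_k\[b,j\] / Meff.
#'
#' @slot h Numeric array (nrow, ncol, D) with D = 2C + C^2 (or 2C without
#'   outer products).
#' @slot channels Integer C, the embedding channel count.
#' @slot includeOP Logical, whether the outer-product block is present.
#' @slot rows,cols Integer vectors of the residue indices (1-based) the
#'   feature block covers (a full matrix or a crop).
#' @export
setClass("AggregatedFeatures",
         representation(h = "array", channels = "integer",
                        includeOP = "logical", rows = "integer",
                        cols = "integer"))

setValidity("AggregatedFeatures", function(object) {
  C <- object@channels
  D <- if (object@includeOP) 2L * C + C * C else 2L * C
  d <- dim(object@h)
  if (length(d) != 3L || d[3] != D)
    return(sprintf("h must have %d channels (got %d)", D, d[3]))
  if (d[1] != length(object@rows) || d[2] != length(object@cols))
    return("h dimensions must match rows/cols")
  TRUE
})

#' Inter-residue distance distributions (distogram)
#'
#' Per residue pair, a probability distribution over the 37 distance bins
#' of [binSpec()]. Symmetric in (i, j) by construction (logit averaging).
#'
#' @slot p Numeric array (L, L, 37); each p\[i, j, \] sums to 1.
#' @export
setClass("Distogram", representation(p = "array"))

setValidity("Distogram", function(object) {
  d <- dim(object@p)
  if (length(d) != 3L || d[3] != 37L || d[1] != d[2])
    return("p must be an (L, L, 37) array")
  if (any(object@p < -1e-9)) return("probabilities must be non-negative")
  s <- apply(object@p, c(1, 2), sum)
  if (any(abs(s - 1) > 1e-4)) return("each p[i,j,] must sum to 1")
  TRUE
})

#' A synthetic benchmark target
#'
#' A toy structure (one point per residue), its contact map and a coupled
#' synthetic MSA whose column dependencies are planted at the contacts.
#'
#' @slot coords Numeric matrix (L, 3), chain coordinates in Angstrom.
#' @slot contactMap Logical matrix (L, L), distance < 8 A and |i-j| >= 2.
#' @slot msa An [Msa-class] sampled from the pairwise-coupled model.
#' @export
setClass("ToyTarget", representation(coords = "matrix",
                                     contactMap = "matrix",
                                     msa = "Msa"))

#' An encoder / distance-estimator model
#'
#' Container for a trainable model: the architecture variant, the encoder
#' and head configurations, a flat named list of parameter arrays and the
#' batch-norm running statistics. Variants: `"full"` (encoder + aggregator
#' with outer products + 2D residual head), `"no_R"` (no 2D head: per-pair
#' linear classifier), `"no_E_R"` (no encoder and no 2D head: aggregator on
#' raw 41-channel encodings + linear classifier), `"no_OP"` (full model but
#' h(i,j) = concat(f(i), f(j)) only).
#'
#' @slot variant Character scalar.
#' @slot encCfg,headCfg Configuration lists (see [encoderConfig()],
#'   [headConfig()]).
#' @slot params Named list of parameter arrays.
#' @slot bnState Named list of batch-norm running statistics.
#' @export
setClass("CoevModel",
         representation(variant = "character", encCfg = "list",
                        headCfg = "list", params = "list",
                        bnState = "list"))

setMethod("show", "Msa", function(object) {
  cat(sprintf("Msa: L = %d, K = %d homolog rows\n",
              nchar(object@target), length(object@homologs)))
  cat("  target: ", substr(object@target, 1, 60),
      if (nchar(object@target) > 60) "..." else "", "\n", sep = "")
})

setMethod("show", "WeightVector", function(object) {
  cat(sprintf("WeightVector: K = %d, Meff = %.3f\n",
              length(object@w), object@mEff))
})

setMethod("show", "Distogram", function(object) {
  cat(sprintf("Distogram: L = %d, %d distance bins\n",
              dim(object@p)[1], dim(object@p)[3]))
})

setMethod("show", "AggregatedFeatures", function(object) {
  cat(sprintf("AggregatedFeatures: %d x %d pairs, D = %d channels (C = %d%s)\n",
              dim(object@h)[1], dim(object@h)[2], dim(object@h)[3],
              object@channels,
              if (object@includeOP) ", with outer products" else ""))
})

setMethod("show", "CoevModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("CoevModel (variant '%s'): %d parameters\n",
              object@variant, np))
})

setMethod("show", "ToyTarget", function(object) {
  cat(sprintf("ToyTarget: L = %d, %d contacts, K = %d homologs\n",
              nrow(object@coords), sum(object@contactMap) / 2,
              length(object@msa@homologs)))
})

#' Accessors for the core classes
#'
#' `msaTarget`, `msaHomologs`, `msaIds`, `msaLength` and `msaDepth` read the
#' components of an [Msa-class]; `encodedValues` the array of an
#' [EncodedMsa-class]; `seqWeights` and `mEff` the components of a
#' [WeightVector-class]; `distogramArray` the array of a [Distogram-class];
#' `pairFeatures` the array of an [AggregatedFeatures-class];
#' `targetCoords`, `targetContacts`, `targetMsa` the slots of a
#' [ToyTarget-class]; `modelVariant` the variant of a [CoevModel-class].
#'
#' @param x The object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
msaTarget <- function(x) x@target
#' @rdname accessors
#' @export
msaHomologs <- function(x) x@homologs
#' @rdname accessors
#' @export
msaIds <- function(x) x@ids
#' @rdname accessors
#' @export
msaLength <- function(x) nchar(x@target)
#' @rdname accessors
#' @export
msaDepth <- function(x) length(x@homologs)
#' @rdname accessors
#' @export
encodedValues <- function(x) x@values
#' @rdname accessors
#' @export
seqWeights <- function(x) x@w
#' @rdname accessors
#' @export
mEff <- function(x) x@mEff
#' @rdname accessors
#' @export
distogramArray <- function(x) x@p
#' @rdname accessors
#' @export
pairFeatures <- function(x) x@h
#' @rdname accessors
#' @export
targetCoords <- function(x) x@coords
#' @rdname accessors
#' @export
targetContacts <- function(x) x@contactMap
#' @rdname accessors
#' @export
targetMsa <- function(x) x@msa
#' @rdname accessors
#' @export
modelVariant <- function(x) x@variant
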