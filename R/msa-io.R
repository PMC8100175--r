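#' Construct an MSA object
#'
#' @param target Ungapped target sequence (character scalar, length L).
#' @param homologs Character vector of aligned homolog rows (length L each,
#'   gaps as `-`). May be omitted to create a single-sequence alignment
#'   containing only the target.
#' @param ids Optional identifiers (defaults to `seq_1 ...`).
#' @return An [Msa-class] object.
#' @examples
#' msa <- Msa("MKTAYIA", c("MKTAYIA", "MRT-YLA"))
#' msaDepth(msa)
#' @export
Msa <- function(target, homologs = target, ids = NULL) {
  target <- unname(toupper(target))
  homologs <- unname(toupper(homologs))
  if (is.null(ids)) ids <- paste0("seq_", seq_along(homologs))
  new("Msa", target = target, homologs = homologs, ids = as.character(ids))
}

#' Read an alignment from FASTA or A3M
#'
#' The first record is taken as the target; any gaps in it are removed and
#' the corresponding columns are dropped from every row, so all rows end up
#' in target coordinates. For A3M, lowercase letters mark insertions
#' relative to the target and are deleted from each row (the standard A3M
#' convention), after which every row must have the target length.
#'
#' @param path File path.
#' @param format `"fasta"` or `"a3m"`. Defaults from the file extension
#'   (`.a3m` selects A3M, anything else aligned FASTA).
#' @param includeTarget If `TRUE` (default) the target is kept as the first
#'   homolog row, so K >= 1 even for a single-sequence file.
#' @return An [Msa-class] object.
#' @export
readMsa <- function(path, format = c("auto", "fasta", "a3m"),
                    includeTarget = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m" else "fasta"
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) stop("empty alignment file: ", path)
  seqs <- as.character(recs)
  ids <- names(recs)
  if (format == "a3m") {
    # lowercase columns are insertions relative to the target: delete them
    seqs <- gsub("[a-z.]", "", seqs)
  }
  target <- seqs[[1]]
  keep <- strsplit(target, "")[[1]] != "-"
  if (!all(keep)) {
    seqs <- vapply(strsplit(seqs, ""),
                   function(s) paste(s[keep], collapse = ""), "")
  }
  target <- gsub("-", "", target, fixed = TRUE)
  L <- nchar(target)
  if (any(nchar(seqs) != L))
    stop("malformed alignment: rows differ in length after insertion removal")
  if (!includeTarget && length(seqs) > 1) {
    seqs <- seqs[-1]
    ids <- ids[-1]
  }
  Msa(target, seqs, ids)
}

#' Write an MSA as aligned FASTA
#'
#' The target is written as the first record, followed by the homolog rows.
#'
#' @param msa An [Msa-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeMsa <- function(msa, path) {
  seqs <- msa@homologs
  ids <- msa@ids
  if (seqs[1] != msa@target) {
    seqs <- c(msa@target, seqs)
    ids <- c("target", ids)
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Integer codes (1-based) of a character vector of aligned rows; every
# distinct character gets its own code so identity comparisons treat the
# gap and nonstandard letters as ordinary characters.
.msaCodeMatrix <- function(rows) {
  chars <- strsplit(rows, "")
  alpha <- c(aaGapAlphabet, .wildcardLetters)
  t(vapply(chars, function(s) {
    i <- match(s, alpha)
    i[is.na(i)] <- length(alpha) + 1L
    i
  }, integer(nchar(rows[1]))))
}

#' Encode an MSA as a stack of pairwise alignments
#'
#' Each of the K homolog rows is paired with the target and every position
#' is encoded as a binary vector of 41 elements: 20 one-hot channels for the
#' target residue, 20 for the homolog residue and one gap channel
#' (channel order fixed by [aaAlphabet]). Nonstandard residues (B, Z, X, U,
#' O, ...) map to an all-zero amino-acid block.
#'
#' @param msa An [Msa-class].
#' @return An [EncodedMsa-class] with a (41, L, K) array.
#' @examples
#' enc <- encodePairwise(Msa("AAC", c("AAC", "A-C")))
#' dim(encodedValues(enc))  # 41 x 3 x 2
#' @export
encodePairwise <- function(msa) {
  validObject(msa)
  L <- msaLength(msa)
  K <- msaDepth(msa)
  tchars <- strsplit(msa@target, "")[[1]]
  tIdx <- match(tchars, aaAlphabet)  # NA -> wildcard, all-zero block
  arr <- array(0, dim = c(41L, L, K))
  tBlock <- matrix(0, 20L, L)
  ok <- !is.na(tIdx)
  tBlock[cbind(tIdx[ok], which(ok))] <- 1
  for (k in seq_len(K)) {
    hchars <- strsplit(msa@homologs[k], "")[[1]]
    hIdx <- match(hchars, aaGapAlphabet)  # gap -> 21
    hBlock <- matrix(0, 21L, L)
    okh <- !is.na(hIdx)
    hBlock[cbind(hIdx[okh], which(okh))] <- 1
    arr[1:20, , k] <- tBlock
    arr[21:41, , k] <- hBlock
  }
  new("EncodedMsa", values = arr)
}

#' Sequence weights and effective number of sequences (Meff)
#'
#' Following the PSICOV reweighting convention, the weight of homolog k is
#' the inverse of the number of homologs (k itself included) sharing at
#' least `identityThreshold` sequence identity with it, and Meff is the sum
#' of the weights. Identity is the fraction of the L target columns at
#' which the two rows carry the same character, the gap counting as an
#' ordinary character.
#'
#' @param msa An [Msa-class].
#' @param identityThreshold Identity fraction defining "similar" homologs
#'   (default 0.8).
#' @return A [WeightVector-class] with weights `w` and `mEff`.
#' @examples
#' w <- sequenceWeights(Msa("AAAA", c("AAAA", "AAAA", "CCCC")))
#' mEff(w)  # 2: two identical rows share one unit of weight
#' @export
sequenceWeights <- function(msa, identityThreshold = 0.8) {
  validObject(msa)
  S <- .msaCodeMatrix(msa@homologs)
  w <- as.numeric(seqWeightsCpp(S, identityThreshold))
  new("WeightVector", w = w, mEff = sum(w))
}
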