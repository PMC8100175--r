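#' Distance bin specification
#'
#' The inter-residue distance range is divided into 37 intervals:
#' (0, 2.5], (2.5, 3.0], ..., (19.5, 20.0] and (20.0, +Inf). Intervals are
#' left-open and right-closed.
#'
#' @return Numeric vector of 38 increasing bin edges (0, 2.5, 3.0, ...,
#'   20.0, Inf).
#' @examples
#' length(binSpec()) - 1  # 37 intervals
#' @export
binSpec <- function() {
  c(0, seq(2.5, 20, by = 0.5), Inf)
}

#' Map a distance to its bin index
#'
#' @param d Distance(s) in Angstrom, must be > 0.
#' @param edges Bin edges (default [binSpec()]).
#' @return Integer bin index in 1..37 (left-open, right-closed intervals,
#'   so d = 2.5 falls in bin 1).
#' @examples
#' distanceToBin(7.83)  # 12: the (7.5, 8.0] interval
#' @export
distanceToBin <- function(d, edges = binSpec()) {
  if (any(d <= 0)) stop("distances must be positive")
  idx <- findInterval(d, edges, left.open = TRUE)
  as.integer(idx)
}

#' Bin centers of the finite distance bins
#'
#' Midpoints of the 36 finite intervals plus a pseudo-center for the open
#' last bin (used as spline knots by the distance potential).
#'
#' @param edges Bin edges (default [binSpec()]).
#' @return Numeric vector of 37 representative distances.
#' @export
binCenters <- function(edges = binSpec()) {
  n <- length(edges) - 1L
  ctr <- (edges[-length(edges)] + edges[-1]) / 2
  ctr[n] <- edges[n] + 0.25  # open last bin: just beyond the last edge
  ctr
}

#' Contact probability map from a distogram
#'
#' For every residue pair, sums the predicted probability mass of the
#' distance bins at or below the contact threshold (8 A by default, i.e.
#' the first 12 bins), giving the probability that the pair is in contact.
#'
#' @param dist A [Distogram-class].
#' @param threshold Contact threshold in Angstrom; must coincide with a
#'   bin edge.
#' @return Numeric matrix (L, L) of contact probabilities.
#' @examples
#' # a uniform distogram gives 12/37 everywhere
#' @export
contactProbability <- function(dist, threshold = 8.0) {
  edges <- binSpec()
  nb <- which(abs(edges - threshold) < 1e-9) - 1L
  if (length(nb) != 1L)
    stop("contact threshold must coincide with a distance bin edge")
  p <- distogramArray(dist)
  apply(p[, , seq_len(nb), drop = FALSE], c(1, 2), sum)
}

#' Distance-head configuration
#'
#' The distance estimator is a 2D residual network over the pair-feature
#' matrix: an input projection D -> channels, `nBlocks` pre-activation
#' residual blocks (two batch-norms, two dilated convolutions, ELU) with
#' dilations cycling through `dilationCycle`, and a 37-channel output
#' convolution. Reference scale is 72 blocks and 96 channels; the
#' "shallow" variant uses 36 blocks.
#'
#' @param nBlocks Number of residual blocks (default 72).
#' @param channels Hidden channels (default 96).
#' @param dilationCycle Dilation schedule cycled across blocks (default
#'   1, 2, 4, 8 — the common contact-prediction practice; the two
#'   convolutions within a block share the block's dilation).
#' @param kernelSize Odd kernel size (default 3).
#' @return A configuration list.
#' @export
headConfig <- function(nBlocks = 72L, channels = 96L,
                       dilationCycle = c(1L, 2L, 4L, 8L), kernelSize = 3L) {
  nBlocks <- as.integer(nBlocks)
  channels <- as.integer(channels)
  if (is.na(nBlocks) || nBlocks < 1L) stop("nBlocks must be >= 1")
  if (is.na(channels) || channels < 1L) stop("channels must be >= 1")
  if (any(dilationCycle < 1L)) stop("dilations must be positive")
  if (kernelSize < 1L || kernelSize %% 2L == 0L)
    stop("kernelSize must be odd and positive")
  list(nBlocks = nBlocks, channels = channels,
       dilationCycle = as.integer(dilationCycle),
       kernelSize = as.integer(kernelSize))
}

#' Build a seeded distance head
#'
#' @param config From [headConfig()].
#' @param inChannels Input channel count D (e.g. [aggregatedChannels()]).
#' @param seed Integer seed for parameter initialization.
#' @return A list with `config`, `inChannels`, `params`, `bnState`.
#' @export
buildHead <- function(config = headConfig(), inChannels, seed = 1L) {
  set.seed(seed)
  Cc <- config$channels
  ks <- config$kernelSize
  params <- list()
  bnState <- list()
  params[["head.proj.W"]] <- .initConvW(Cc, as.integer(inChannels), 1L)
  params[["head.proj.b"]] <- rep(0, Cc)
  for (bl in seq_len(config$nBlocks)) {
    p <- sprintf("head.b%d.", bl)
    for (half in 1:2) {
      bn <- .newBnParams(Cc)
      params[[paste0(p, "bn", half, ".gamma")]] <- bn$gamma
      params[[paste0(p, "bn", half, ".beta")]] <- bn$beta
      params[[paste0(p, "conv", half, ".W")]] <- .initConvW(Cc, Cc, ks * ks)
      params[[paste0(p, "conv", half, ".b")]] <- rep(0, Cc)
      bnState[[paste0(p, "bn", half)]] <- .newBnState(Cc)
    }
  }
  params[["head.out.W"]] <- .initConvW(37L, Cc, 1L)
  params[["head.out.b"]] <- rep(0, 37L)
  list(config = config, inChannels = as.integer(inChannels),
       params = params, bnState = bnState)
}

.headDilation <- function(cfg, bl) {
  cyc <- cfg$dilationCycle
  cyc[(bl - 1L) %% length(cyc) + 1L]
}

# Forward pass of the 2D head. H: (n1, n2, D) array. Returns logits
# (n1, n2, 37), bn state and caches.
.headForward <- function(params, cfg, bnState, H, train = FALSE) {
  ks <- cfg$kernelSize
  caches <- list(projX = H)
  Y <- conv2dForwardCpp(H, params[["head.proj.W"]], params[["head.proj.b"]],
                        1L, 1L)
  for (bl in seq_len(cfg$nBlocks)) {
    p <- sprintf("head.b%d.", bl)
    dil <- .headDilation(cfg, bl)
    cb <- list(dil = dil)
    z <- Y
    for (half in 1:2) {
      bn <- .bnForward(z, params[[paste0(p, "bn", half, ".gamma")]],
                       params[[paste0(p, "bn", half, ".beta")]],
                       bnState[[paste0(p, "bn", half)]], train, 3L)
      bnState[[paste0(p, "bn", half)]] <- bn$state
      cb[[paste0("bn", half)]] <- bn$cache
      el <- .eluForward(bn$y)
      cb[[paste0("elu", half)]] <- el$cache
      cb[[paste0("convIn", half)]] <- el$y
      z <- conv2dForwardCpp(el$y, params[[paste0(p, "conv", half, ".W")]],
                            params[[paste0(p, "conv", half, ".b")]], ks, dil)
    }
    Y <- Y + z
    caches[[sprintf("b%d", bl)]] <- cb
  }
  caches$outX <- Y
  logits <- conv2dForwardCpp(Y, params[["head.out.W"]],
                             params[["head.out.b"]], 1L, 1L)
  list(logits = logits, bnState = bnState, caches = caches)
}

.headBackward <- function(params, cfg, caches, dLogits) {
  ks <- cfg$kernelSize
  grads <- list()
  cbk <- conv2dBackwardCpp(caches$outX, params[["head.out.W"]], dLogits,
                           1L, 1L)
  grads[["head.out.W"]] <- cbk$dW
  grads[["head.out.b"]] <- as.numeric(cbk$db)
  dY <- cbk$dX
  for (bl in rev(seq_len(cfg$nBlocks))) {
    p <- sprintf("head.b%d.", bl)
    cb <- caches[[sprintf("b%d", bl)]]
    dz <- dY
    for (half in 2:1) {
      wname <- paste0(p, "conv", half, ".W")
      cc <- conv2dBackwardCpp(cb[[paste0("convIn", half)]], params[[wname]],
                              dz, ks, cb$dil)
      grads[[wname]] <- cc$dW
      grads[[paste0(p, "conv", half, ".b")]] <- as.numeric(cc$db)
      dElu <- .eluBackward(cb[[paste0("elu", half)]], cc$dX)
      bnb <- .bnBackward(cb[[paste0("bn", half)]], dElu)
      grads[[paste0(p, "bn", half, ".gamma")]] <- bnb$dgamma
      grads[[paste0(p, "bn", half, ".beta")]] <- bnb$dbeta
      dz <- bnb$dx
    }
    dY <- dY + dz
  }
  cbk <- conv2dBackwardCpp(caches$projX, params[["head.proj.W"]], dY, 1L, 1L)
  grads[["head.proj.W"]] <- cbk$dW
  grads[["head.proj.b"]] <- as.numeric(cbk$db)
  list(grads = grads, dX = cbk$dX)
}

# Symmetrize pair logits by averaging z(i,j) and z(j,i), then softmax.
.logitsToDistogram <- function(logits) {
  zsym <- (logits + aperm(logits, c(2, 1, 3))) / 2
  d <- dim(zsym)
  zm <- matrix(zsym, ncol = d[3])
  zm <- zm - apply(zm, 1, max)
  ez <- exp(zm)
  p <- ez / rowSums(ez)
  new("Distogram", p = array(p, d))
}

#' Predict a distogram from aggregated pair features
#'
#' Runs the 2D head in evaluation mode (frozen normalization statistics)
#' on a full L x L pair-feature tensor, symmetrizes logits by averaging
#' the (i,j) and (j,i) entries, and applies a per-pair softmax over the 37
#' distance bins.
#'
#' @param head From [buildHead()].
#' @param feats An [AggregatedFeatures-class] covering the full matrix.
#' @return A [Distogram-class].
#' @export
predictDistogram <- function(head, feats) {
  H <- pairFeatures(feats)
  if (dim(H)[3] != head$inChannels)
    stop(sprintf("feature channels (%d) do not match head input (%d)",
                 dim(H)[3], head$inChannels))
  if (!identical(feats@rows, feats@cols))
    stop("predictDistogram needs a square feature block (rows == cols)")
  fw <- .headForward(head$params, head$config, head$bnState, H,
                     train = FALSE)
  .logitsToDistogram(fw$logits)
}

#' Save / load a distogram as a plain-text container
#'
#' `saveDistogram` writes a long-format CSV (`i`, `j`, `bin`, `p`) with
#' only the upper triangle stored (the distogram is symmetric) plus a JSON
#' manifest carrying L and the bin edges; `loadDistogram` reads it back.
#'
#' @param dist A [Distogram-class].
#' @param path Output CSV path (manifest written alongside as
#'   `<path>.json`).
#' @return `saveDistogram`: `path`, invisibly. `loadDistogram`: a
#'   [Distogram-class].
#' @export
saveDistogram <- function(dist, path) {
  p <- distogramArray(dist)
  L <- dim(p)[1]
  ut <- which(upper.tri(matrix(0, L, L), diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = rep(ut[, 1], each = 37L),
                   j = rep(ut[, 2], each = 37L),
                   bin = rep(1:37, nrow(ut)),
                   p = as.vector(apply(ut, 1, function(ij) p[ij[1], ij[2], ])))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(L = L, edges = binSpec()[1:37],
                            n_bins = 37L, format = "coevodist-distogram-v1"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveDistogram
#' @export
loadDistogram <- function(path) {
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(path)
  L <- man$L
  p <- array(0, dim = c(L, L, 37L))
  p[cbind(df$i, df$j, df$bin)] <- df$p
  p[cbind(df$j, df$i, df$bin)] <- df$p
  new("Distogram", p = p)
}

#' Export / import contact probabilities as CASP RR-like text
#'
#' Writes lines `i j 0 8 prob` for every pair i < j with separation >= 2,
#' sorted by decreasing probability (the conventional exchange format for
#' contact predictions).
#'
#' @param cmap Numeric contact-probability matrix (L, L).
#' @param path Output path.
#' @param minSeparation Smallest |i - j| exported (default 2).
#' @return `writeContactsRR`: `path` invisibly; `readContactsRR`: a
#'   data.frame with columns `i`, `j`, `prob`.
#' @export
writeContactsRR <- function(cmap, path, minSeparation = 2L) {
  L <- nrow(cmap)
  ij <- which(upper.tri(cmap), arr.ind = TRUE)
  ij <- ij[ij[, 2] - ij[, 1] >= minSeparation, , drop = FALSE]
  pr <- cmap[ij]
  ord <- order(-pr, ij[, 1], ij[, 2])
  lines <- sprintf("%d %d 0 8 %.6f", ij[ord, 1], ij[ord, 2], pr[ord])
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeContactsRR
#' @export
readContactsRR <- function(path) {
  df <- read.table(path, col.names = c("i", "j", "d0", "d1", "prob"))
  df[, c("i", "j", "prob")]
}
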