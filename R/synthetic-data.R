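#' Generate a toy protein-like chain
#'
#' Grows a self-avoiding random chain with fixed bond length 3.8 A (one
#' point per residue, a CA-level caricature of a folded domain). A
#' centripetal bias pulls each step toward the running centroid so larger
#' `compactness` yields more long-range contacts; clashes (non-consecutive
#' pairs closer than 3.2 A) trigger resampling with backtracking.
#'
#' @param L Number of residues (>= 5).
#' @param seed Integer seed.
#' @param compactness Strength of the centripetal bias in \[0, 1\]
#'   (default 0.55).
#' @param bondLength Consecutive-residue distance (default 3.8 A).
#' @param clash Minimum allowed non-consecutive distance (default 3.2 A).
#' @param maxRetries Placement attempts per residue before backtracking;
#'   an error is raised if the chain repeatedly fails to grow.
#' @return Numeric matrix (L, 3) of coordinates.
#' @export
generateToyStructure <- function(L, seed = 1L, compactness = 0.55,
                                 bondLength = 3.8, clash = 3.2,
                                 maxRetries = 200L) {
  stopifnot(L >= 5)
  set.seed(seed)
  for (attempt in 1:50) {
    coords <- matrix(NA_real_, L, 3)
    coords[1, ] <- c(0, 0, 0)
    coords[2, ] <- c(bondLength, 0, 0)
    i <- 3L
    fails <- 0L
    while (i <= L) {
      placed <- FALSE
      ctr <- colMeans(coords[seq_len(i - 1L), , drop = FALSE])
      for (r in seq_len(maxRetries)) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        # centripetal blend, annealed away when placement keeps clashing
        lam <- 0.6 * compactness * max(0, 1 - 2 * r / maxRetries)
        pull <- ctr - coords[i - 1L, ]
        np <- sqrt(sum(pull^2))
        if (np > 1e-9) u <- (1 - lam) * u + lam * pull / np
        u <- u / sqrt(sum(u^2))
        cand <- coords[i - 1L, ] + bondLength * u
        dmin <- min(sqrt(rowSums(sweep(coords[seq_len(i - 2L), , drop = FALSE],
                                       2, cand)^2)))
        if (dmin > clash) {
          coords[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (placed) {
        i <- i + 1L
      } else {
        # backtrack a few residues and regrow
        fails <- fails + 1L
        if (fails > 50L) break
        i <- max(3L, i - 3L)
        coords[i:L, ] <- NA_real_
      }
    }
    if (i > L) return(coords)
  }
  stop("failed to place a self-avoiding chain after maximum retries")
}

#' Contact map of a coordinate chain
#'
#' @param coords Numeric matrix (L, 3).
#' @param threshold Contact distance in Angstrom (default 8).
#' @param minSeparation Pairs with |i - j| below this are excluded
#'   (default 2, i.e. the diagonal band |i-j| <= 1 never counts).
#' @return Logical symmetric matrix (L, L).
#' @export
contactMapFromCoords <- function(coords, threshold = 8.0,
                                 minSeparation = 2L) {
  D <- as.matrix(stats::dist(coords))
  cm <- D < threshold
  sep <- abs(row(cm) - col(cm))
  cm[sep < minSeparation] <- FALSE
  cm
}

#' Sample a synthetic MSA with couplings planted at contacts
#'
#' Sequences are drawn by Gibbs sampling from a pairwise model. A sparse
#' set of coupling edges is selected from the contact map (separation >=
#' `minCouplingSeparation`, at most `maxDegree` coupled partners per
#' column, largest separations first — mimicking the sparse strong
#' couplings of real families). Each coupled edge (i, j) carries two
#' favoured letter pairs — the target pair (t_i, t_j) and one random
#' alternative pair — rewarded with coupling strength `coupling`. Coupled
#' columns carry equal conservation fields on their target and
#' alternative letters, so the two pair-modes genuinely alternate across
#' homologs (co-evolving sites are variable sites), while the coupling
#' term makes the two letters flip jointly rather than independently.
#' All other columns mutate i.i.d. away from the
#' target letter at rate `mutationRate`. By default each homolog row is
#' its own chain (random initialization, `burnin` sweeps); a single
#' thinned chain is available via `chains = "single"`. No gaps are
#' produced by default; `gapRate` exercises the gap channel.
#'
#' @param contactMap Logical (L, L) matrix (see [contactMapFromCoords()]).
#' @param targetSeq Optional target sequence (default: random).
#' @param K Number of homolog rows to sample (>= 2).
#' @param coupling Coupling strength J >= 0 (log-odds bonus per favoured
#'   pair; default 2).
#' @param mutationRate Per-column mutation probability away from the
#'   target letter for uncoupled columns (default 0.35).
#' @param minCouplingSeparation Smallest |i - j| of planted coupling edges
#'   (default 6).
#' @param maxDegree Maximum number of coupling edges per column
#'   (default 2).
#' @param fieldScale Factor applied to the conservation fields of coupled
#'   columns (default 1: same strength as uncoupled columns, but shared
#'   between the two favoured letters).
#' @param gapRate Probability of replacing a homolog letter by a gap
#'   (default 0).
#' @param burnin,thin Gibbs burn-in sweeps and thinning interval
#'   (defaults 100 and 5; `thin` applies to single-chain mode).
#' @param chains `"independent"` (default) or `"single"`.
#' @param seed Integer seed.
#' @return An [Msa-class]; the first homolog row is the target itself.
#'   The selected coupling edges are attached as attribute
#'   `"couplingEdges"` (two-column matrix).
#' @export
generateCoupledMsa <- function(contactMap, targetSeq = NULL, K = 256L,
                               coupling = 2.0, mutationRate = 0.35,
                               minCouplingSeparation = 6L, maxDegree = 2L,
                               fieldScale = 1, gapRate = 0,
                               burnin = 100L, thin = 5L,
                               chains = c("independent", "single"),
                               seed = 1L) {
  stopifnot(K >= 2, coupling >= 0, mutationRate > 0, mutationRate < 1)
  chains <- match.arg(chains)
  L <- nrow(contactMap)
  set.seed(seed)
  if (is.null(targetSeq)) {
    tIdx <- sample.int(20L, L, replace = TRUE)
  } else {
    tIdx <- match(strsplit(toupper(targetSeq), "")[[1]], aaAlphabet)
    if (any(is.na(tIdx))) stop("targetSeq must use the 20 standard letters")
  }
  cand <- which(upper.tri(contactMap) & contactMap, arr.ind = TRUE)
  cand <- cand[cand[, 2] - cand[, 1] >= minCouplingSeparation, ,
               drop = FALSE]
  # greedy degree-capped selection, largest separations first
  ord <- order(-(cand[, 2] - cand[, 1]), runif(nrow(cand)))
  deg <- integer(L)
  keep <- logical(nrow(cand))
  for (r in ord) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (deg[i] < maxDegree && deg[j] < maxDegree) {
      keep[r] <- TRUE
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
    }
  }
  eIdx <- cand[keep, , drop = FALSE]
  E <- nrow(eIdx)
  alt <- matrix(0L, max(E, 1L), 2L)
  for (e in seq_len(E)) {
    # an alternative compatible pair distinct from the target pair
    alt[e, 1] <- sample(setdiff(1:20, tIdx[eIdx[e, 1]]), 1L)
    alt[e, 2] <- sample(setdiff(1:20, tIdx[eIdx[e, 2]]), 1L)
  }
  h0 <- log(19 * (1 - mutationRate) / mutationRate)
  field <- matrix(0, L, 20L)
  field[cbind(seq_len(L), tIdx)] <- h0
  coupled <- unique(as.vector(eIdx))
  field[coupled, ] <- 0
  field[cbind(coupled, tIdx[coupled])] <- h0 * fieldScale
  for (e in seq_len(E)) {
    field[eIdx[e, 1], alt[e, 1]] <- h0 * fieldScale
    field[eIdx[e, 2], alt[e, 2]] <- h0 * fieldScale
  }
  S <- gibbsMsaCpp(tIdx - 1L,
                   if (E > 0) eIdx - 1L else matrix(0L, 0, 2),
                   if (E > 0) alt - 1L else matrix(0L, 0, 2),
                   coupling, field, K - 1L, as.integer(burnin),
                   as.integer(thin),
                   as.integer(sample.int(.Machine$integer.max, 1L)),
                   chains == "independent")
  rows <- apply(S + 1L, 1, function(s) paste(aaAlphabet[s], collapse = ""))
  if (gapRate > 0) {
    rows <- vapply(rows, function(r) {
      s <- strsplit(r, "")[[1]]
      g <- runif(L) < gapRate
      s[g] <- "-"
      paste(s, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  target <- paste(aaAlphabet[tIdx], collapse = "")
  out <- Msa(target, c(target, rows),
             c("target", paste0("sample_", seq_len(K - 1L))))
  attr(out, "couplingEdges") <- eIdx
  out
}

#' Generate a complete synthetic benchmark target
#'
#' Bundles a toy structure, its contact map and a coupled MSA.
#'
#' @param L Chain length (default 48).
#' @param K MSA depth (default 256).
#' @param seed Integer seed.
#' @param compactness Passed to [generateToyStructure()].
#' @param coupling,mutationRate Passed to [generateCoupledMsa()].
#' @return A [ToyTarget-class].
#' @export
generateToyTarget <- function(L = 48L, K = 256L, seed = 1L,
                              compactness = 0.55, coupling = 2.0,
                              mutationRate = 0.35) {
  coords <- generateToyStructure(L, seed = seed, compactness = compactness)
  cm <- contactMapFromCoords(coords)
  msa <- generateCoupledMsa(cm, K = K, coupling = coupling,
                            mutationRate = mutationRate, seed = seed + 10000L)
  new("ToyTarget", coords = coords, contactMap = cm, msa = msa)
}

#' Moment-matched MSA pair separable only by higher-order statistics
#'
#' Constructs two alignments A and B over three designated columns such
#' that all single-column compositions and all pairwise joint frequencies
#' (hence the covariance matrices) are exactly identical, while the
#' three-way joint distributions have disjoint support: the designated
#' columns of A enumerate the even-parity patterns over a two-letter
#' alphabet and those of B the odd-parity patterns, each exactly K/4
#' times. Any predictor that is a function of first- and second-order
#' column statistics alone therefore returns identical output for A and B,
#' although the two alignments are categorically different at third order.
#'
#' @param K Number of homolog rows; must be a positive multiple of 4
#'   (exact moment matching assigns K/4 rows per parity pattern), K >= 8.
#' @param L Alignment length (default 20; the three designated columns are
#'   placed away from each other, remaining columns are identical filler).
#' @param seed Integer seed (filler sequence and letter choice).
#' @return A list with elements `A` and `B` ([Msa-class] objects, the
#'   target row included), `columns` (the three designated column
#'   indices) and `letters` (the two letters used).
#' @export
generateParityCounterexample <- function(K = 16L, L = 20L, seed = 1L) {
  if (K < 8L || K %% 4L != 0L)
    stop("K must be a multiple of 4 and at least 8")
  if (L < 9L) stop("L must be at least 9")
  set.seed(seed)
  tIdx <- sample.int(20L, L, replace = TRUE)
  target <- paste(aaAlphabet[tIdx], collapse = "")
  cols <- round(c(0.15, 0.5, 0.85) * L)
  letters2 <- aaAlphabet[sample.int(20L, 2L)]
  even <- rbind(c(0, 0, 0), c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))
  odd <- 1 - even
  mkRows <- function(patterns) {
    reps <- patterns[rep(1:4, each = K / 4L), , drop = FALSE]
    vapply(seq_len(K), function(k) {
      s <- strsplit(target, "")[[1]]
      s[cols] <- letters2[reps[k, ] + 1L]
      paste(s, collapse = "")
    }, "")
  }
  list(A = Msa(target, mkRows(even), paste0("A_", seq_len(K))),
       B = Msa(target, mkRows(odd), paste0("B_", seq_len(K))),
       columns = cols, letters = letters2)
}

#' Weighted one-hot column covariance of an MSA
#'
#' The classical DCA input statistic: the weighted sample covariance of
#' the 21-state one-hot indicators of every column pair,
#' cov(i,j)\[a,b\] = E_w\[1(s_i = a) 1(s_j = b)\] - f_i(a) f_j(b), with
#' expectation under the normalized sequence weights.
#'
#' @param msa An [Msa-class].
#' @param weights A [WeightVector-class] (default: computed from `msa`).
#' @return Numeric array (L, L, 21, 21).
#' @export
msaCovariance <- function(msa, weights = sequenceWeights(msa)) {
  L <- msaLength(msa)
  K <- msaDepth(msa)
  wn <- weights@w / weights@mEff
  S <- .msaCodeMatrix(msa@homologs)  # codes: 1..21 standard+gap
  X <- array(0, dim = c(K, L, 21L))  # one-hot indicators
  for (a in 1:21) X[, , a] <- (S == a) * 1
  # weighted single-column frequencies: (L, 21)
  f1 <- apply(X, c(2, 3), function(v) sum(v * wn))
  Xw <- matrix(X, nrow = K)  # K x (L*21)
  M2 <- t(Xw * wn) %*% Xw    # (L*21) x (L*21) weighted second moments
  cv <- array(0, dim = c(L, L, 21L, 21L))
  for (a in 1:21) {
    for (b in 1:21) {
      ia <- (a - 1L) * L + seq_len(L)
      ib <- (b - 1L) * L + seq_len(L)
      cv[, , a, b] <- M2[ia, ib] - outer(f1[, a], f1[, b])
    }
  }
  cv
}

#' Mutual information between alignment columns
#'
#' Weighted mutual information of every column pair, a model-free
#' co-evolution baseline used to check that the synthetic benchmark is
#' learnable at all. The plug-in estimator is strongly biased upward for
#' high-entropy columns at realistic alignment depths, so by default the
#' first-order (Miller-Madow) bias term (r-1)(c-1)/(2K) is subtracted;
#' the average-product correction (APC), the standard normalization in
#' MI-based contact prediction, is also available.
#'
#' @inheritParams msaCovariance
#' @param correction `"mm"` (Miller-Madow bias subtraction, default),
#'   `"apc"` (bias subtraction plus average-product correction) or
#'   `"none"` (raw plug-in values).
#' @return Numeric matrix (L, L) of MI values (nats), zero diagonal.
#' @export
msaMutualInformation <- function(msa, weights = sequenceWeights(msa),
                                 correction = c("mm", "apc", "none")) {
  correction <- match.arg(correction)
  L <- msaLength(msa)
  K <- msaDepth(msa)
  S <- .msaCodeMatrix(msa@homologs)
  wn <- weights@w / weights@mEff
  mi <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      jt <- tapply(wn, list(S[, i], S[, j]), sum)
      jt[is.na(jt)] <- 0
      jt <- jt / sum(jt)
      pi <- rowSums(jt)
      pj <- colSums(jt)
      nz <- jt > 0
      v <- sum(jt[nz] * log(jt[nz] / outer(pi, pj)[nz]))
      if (correction != "none")
        v <- v - (sum(pi > 0) - 1) * (sum(pj > 0) - 1) / (2 * K)
      mi[i, j] <- mi[j, i] <- v
    }
  }
  if (correction == "apc") {
    colMean <- rowSums(mi) / (L - 1)
    allMean <- sum(mi) / (L * (L - 1))
    mi <- mi - outer(colMean, colMean) / allMean
    diag(mi) <- 0
  }
  mi
}
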