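test_that("toy chains have exact bonds and respect self-avoidance", {
  for (s in 1:3) {
    coords <- generateToyStructure(30, seed = s)
    bonds <- sqrt(rowSums(diff(coords)^2))
    expect_equal(bonds, rep(3.8, 29), tolerance = 1e-6)
    D <- as.matrix(dist(coords))
    nonconsec <- D[abs(row(D) - col(D)) >= 2]
    expect_gt(min(nonconsec), 3.0)
    # determinism
    expect_identical(coords, generateToyStructure(30, seed = s))
  }
})

test_that("higher compactness yields more long-range contacts on average", {
  count <- function(cc) {
    mean(vapply(1:10, function(s) {
      cm <- contactMapFromCoords(generateToyStructure(40, seed = s,
                                                      compactness = cc))
      sum(cm[abs(row(cm) - col(cm)) >= 24]) / 2
    }, 0))
  }
  lo <- count(0.2); mid <- count(0.55); hi <- count(0.9)
  expect_lt(lo, mid)
  expect_lt(mid, hi)
})

test_that("coupled MSAs are gapless, deterministic, and target-consistent", {
  cm <- contactMapFromCoords(generateToyStructure(24, seed = 5))
  msa <- generateCoupledMsa(cm, K = 20, seed = 9)
  expect_equal(msaDepth(msa), 20L)
  expect_false(any(grepl("-", msaHomologs(msa), fixed = TRUE)))
  expect_identical(msaHomologs(msa)[1], msaTarget(msa))
  msa2 <- generateCoupledMsa(cm, K = 20, seed = 9)
  expect_identical(msaHomologs(msa2), msaHomologs(msa))
  withGaps <- generateCoupledMsa(cm, K = 20, gapRate = 0.1, seed = 9)
  expect_true(any(grepl("-", msaHomologs(withGaps), fixed = TRUE)))
})

test_that("zero coupling gives statistically independent columns", {
  # Monte-Carlo null: per-column row shuffling destroys any dependence,
  # so the mean absolute pair covariance of the real alignment must sit
  # within 3 standard errors of the shuffled one.
  cm <- matrix(FALSE, 16, 16)
  pairStat <- function(rows) {
    S <- coevodist:::.msaCodeMatrix(rows)
    msa <- Msa(rows[1], rows)
    cv <- msaCovariance(msa, new("WeightVector",
                                 w = rep(1, length(rows)),
                                 mEff = length(rows)))
    sel <- upper.tri(matrix(0, ncol(S), ncol(S)))
    mean(apply(abs(cv), c(1, 2), max)[sel])
  }
  diffs <- vapply(1:6, function(s) {
    msa <- generateCoupledMsa(cm, K = 80, coupling = 0, seed = s)
    rows <- msaHomologs(msa)
    set.seed(s + 500)
    shuffled <- apply(do.call(rbind, strsplit(rows, "")), 2, sample)
    rowsNull <- apply(shuffled, 1, paste, collapse = "")
    pairStat(rows) - pairStat(rowsNull)
  }, 0)
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-3)
})

test_that("strong coupling puts contact MI above the non-contact tail", {
  tgt <- generateToyTarget(L = 48, K = 256, seed = 71)
  msa <- targetMsa(tgt)
  mi <- msaMutualInformation(msa)
  edges <- attr(msa, "couplingEdges")
  cm <- targetContacts(tgt)
  sep <- abs(row(cm) - col(cm))
  nonContact <- mi[upper.tri(cm) & !cm & sep >= 6]
  q95 <- quantile(nonContact, 0.95)
  expect_gt(mean(mi[edges] > q95), 0.5)
})

test_that("the synthetic benchmark is learnable by MI ranking", {
  prec <- vapply(1:8, function(s) {
    tgt <- generateToyTarget(L = 48, K = 256, seed = 400 + s)
    mi <- msaMutualInformation(targetMsa(tgt))
    contactPrecision(mi, targetContacts(tgt), 5, "long")$precision
  }, 0)
  expect_gt(median(prec), 0.5)
})

test_that("parity alignments match to second order and differ at third", {
  out <- generateParityCounterexample(K = 16, L = 20, seed = 3)
  A <- out$A; B <- out$B
  # identical single-column compositions
  SA <- coevodist:::.msaCodeMatrix(msaHomologs(A))
  SB <- coevodist:::.msaCodeMatrix(msaHomologs(B))
  for (i in seq_len(20))
    expect_identical(table(SA[, i]), table(SB[, i]))
  # covariance matrices identical to numerical precision
  cvA <- msaCovariance(A)
  cvB <- msaCovariance(B)
  expect_lt(max(abs(cvA - cvB)), 1e-12)
  # three-way joints on the designated columns have disjoint support
  tw <- function(S, cols) table(apply(S[, cols], 1, paste, collapse = "-"))
  jA <- tw(SA, out$columns); jB <- tw(SB, out$columns)
  allPat <- union(names(jA), names(jB))
  pA <- setNames(rep(0, length(allPat)), allPat); pA[names(jA)] <- jA / sum(jA)
  pB <- setNames(rep(0, length(allPat)), allPat); pB[names(jB)] <- jB / sum(jB)
  tv <- sum(abs(pA - pB)) / 2
  expect_gte(tv, 0.4)
  expect_error(generateParityCounterexample(K = 10), "multiple of 4")
})

test_that("covariance-only features cannot distinguish the parity pair", {
  out <- generateParityCounterexample(K = 16, L = 12, seed = 4)
  # raw-encoding aggregation (the no_E_R feature path) is a function of
  # first- and second-order column statistics only: identical for A and B
  wA <- sequenceWeights(out$A)
  wB <- sequenceWeights(out$B)
  expect_equal(seqWeights(wA), seqWeights(wB))
  hA <- pairFeatures(aggregateH(encodedValues(encodePairwise(out$A)), wA))
  hB <- pairFeatures(aggregateH(encodedValues(encodePairwise(out$B)), wB))
  expect_lt(max(abs(hA - hB)), 1e-12)
  # hence any covariance-only predictor returns identical outputs
  m <- buildVariant("no_E_R", tinyEnc(), tinyHead(), seed = 5)
  dA <- distogramArray(modelPredict(m, out$A))
  dB <- distogramArray(modelPredict(m, out$B))
  expect_lt(max(abs(dA - dB)), 1e-10)
})

test_that("msaCovariance matches a hand computation on a 4-row alignment", {
  msa <- Msa("AC", c("AC", "AD", "CC", "CD"))
  wv <- sequenceWeights(msa, identityThreshold = 0.99)
  cv <- msaCovariance(msa, wv)
  # all weights 1/count with no identical rows -> uniform 1/4
  iA <- which(aaGapAlphabet == "A"); iC <- which(aaGapAlphabet == "C")
  iD <- which(aaGapAlphabet == "D")
  # col1: A,A,C,C ; col2: C,D,C,D independent => covariance 0
  expect_equal(cv[1, 2, iA, iC], 0.5 * 0.5 - 0.5 * 0.5, tolerance = 1e-12)
  expect_equal(cv[1, 1, iA, iA], 0.5 - 0.25, tolerance = 1e-12)
  expect_equal(cv[1, 1, iA, iC], 0 - 0.25, tolerance = 1e-12)
  expect_equal(cv[2, 2, iC, iD], 0 - 0.25, tolerance = 1e-12)
  # identical rows: no variation anywhere
  cv0 <- msaCovariance(Msa("ACD", rep("ACD", 3)))
  expect_equal(max(abs(cv0)), 0, tolerance = 1e-12)
})
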