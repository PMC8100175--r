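test_that("the bin specification defines exactly 37 left-open intervals", {
  edges <- binSpec()
  expect_length(edges, 38L)
  expect_equal(edges[1], 0)
  expect_equal(edges[2], 2.5)
  expect_equal(edges[37], 20)
  expect_equal(edges[38], Inf)
  expect_equal(diff(edges[2:37]), rep(0.5, 35))
  expect_true(all(diff(edges) > 0))
})

test_that("distances map to bins with the right-closed convention", {
  expect_identical(distanceToBin(7.83), 12L)   # the (7.5, 8.0] interval
  expect_identical(distanceToBin(25.0), 37L)
  expect_identical(distanceToBin(2.5), 1L)
  expect_identical(distanceToBin(2.50001), 2L)
  expect_identical(distanceToBin(20.0), 36L)
  expect_identical(distanceToBin(c(1, 3.2, 19.9)), c(1L, 3L, 36L))
  expect_error(distanceToBin(0), "positive")
  expect_error(distanceToBin(-2), "positive")
})

test_that("contact probability sums the sub-threshold mass", {
  L <- 3L
  p <- array(0, dim = c(L, L, 37))
  p[, , 12] <- 1    # all mass in (7.5, 8.0]
  dg <- new("Distogram", p = p)
  expect_equal(contactProbability(dg), matrix(1, L, L))
  p2 <- array(1 / 37, dim = c(L, L, 37))
  expect_equal(contactProbability(new("Distogram", p = p2)),
               matrix(12 / 37, L, L), tolerance = 1e-12)
  p3 <- array(0, dim = c(L, L, 37)); p3[, , 37] <- 1
  expect_equal(contactProbability(new("Distogram", p = p3)), matrix(0, L, L))
  expect_error(contactProbability(dg, threshold = 8.3), "bin edge")
})

test_that("contact probability is monotone in the threshold", {
  set.seed(20)
  p <- array(runif(2 * 2 * 37), dim = c(2, 2, 37))
  p <- p / array(rep(apply(p, c(1, 2), sum), 37), dim(p))
  dg <- new("Distogram", p = p)
  probs <- vapply(seq(2.5, 20, by = 0.5), function(thr)
    contactProbability(dg, thr)[1, 2], 0)
  expect_true(all(diff(probs) >= -1e-12))
})

test_that("head construction is seeded and follows the configured scale", {
  h1 <- buildHead(tinyHead(), inChannels = 24L, seed = 3)
  h2 <- buildHead(tinyHead(), inChannels = 24L, seed = 3)
  expect_identical(h1$params, h2$params)
  def <- headConfig()
  expect_equal(def$nBlocks, 72L)
  expect_equal(def$channels, 96L)
  shallow <- headConfig(nBlocks = 36L)
  expect_equal(shallow$nBlocks, 36L)
  expect_error(headConfig(nBlocks = 0))
})

test_that("predicted distograms are normalized and symmetric", {
  C <- 3L
  X <- randomEmbedding(C, 6, 4, seed = 21)
  wv <- randomWeights(4, seed = 22)
  feats <- aggregateH(X, wv)
  head <- buildHead(tinyHead(), inChannels = aggregatedChannels(C), seed = 4)
  dg <- predictDistogram(head, feats)
  p <- distogramArray(dg)
  expect_equal(apply(p, c(1, 2), sum), matrix(1, 6, 6), tolerance = 1e-8)
  expect_equal(p, aperm(p, c(2, 1, 3)), tolerance = 1e-12)
  expect_true(all(p >= 0))
})

test_that("a zeroed output layer yields uniform distributions", {
  C <- 2L
  X <- randomEmbedding(C, 5, 3, seed = 23)
  wv <- randomWeights(3, seed = 24)
  head <- buildHead(tinyHead(), inChannels = aggregatedChannels(C), seed = 5)
  head$params[["head.out.W"]][] <- 0
  head$params[["head.out.b"]][] <- 0
  dg <- predictDistogram(head, aggregateH(X, wv))
  expect_equal(distogramArray(dg), array(1 / 37, c(5, 5, 37)),
               tolerance = 1e-12)
})

test_that("a dilation-1 head is locally translation consistent", {
  # embed a crop into a larger zero field: central logits must match the
  # stand-alone crop away from the padding boundary
  C <- 2L
  D <- aggregatedChannels(C)
  head <- buildHead(headConfig(nBlocks = 1L, channels = 4L,
                               dilationCycle = 1L), inChannels = D, seed = 6)
  set.seed(25)
  n <- 7L; pad <- 6L
  Hc <- array(rnorm(n * n * D), dim = c(n, n, D))
  big <- array(0, dim = c(n + 2 * pad, n + 2 * pad, D))
  big[pad + 1:n, pad + 1:n, ] <- Hc
  lc <- coevodist:::.headForward(head$params, head$config, head$bnState, Hc)$logits
  lb <- coevodist:::.headForward(head$params, head$config, head$bnState, big)$logits
  inner <- 3:5  # away from the crop's own zero-padding context
  expect_equal(lb[pad + inner, pad + inner, ], lc[inner, inner, ],
               tolerance = 1e-8)
})

test_that("distograms survive the plain-text container round trip", {
  set.seed(26)
  p <- array(runif(4 * 4 * 37), dim = c(4, 4, 37))
  p <- (p + aperm(p, c(2, 1, 3))) / 2
  p <- p / array(rep(apply(p, c(1, 2), sum), 37), dim(p))
  dg <- new("Distogram", p = p)
  path <- withr::local_tempfile(fileext = ".csv")
  saveDistogram(dg, path)
  back <- loadDistogram(path)
  expect_equal(distogramArray(back), p, tolerance = 1e-12)
})

test_that("RR contact export is sorted and round-trips", {
  set.seed(27)
  cmap <- matrix(runif(36), 6, 6)
  cmap <- (cmap + t(cmap)) / 2
  path <- withr::local_tempfile(fileext = ".rr")
  writeContactsRR(cmap, path)
  df <- readContactsRR(path)
  expect_true(all(diff(df$prob) <= 1e-12))
  expect_true(all(df$j - df$i >= 2))
  expect_equal(df$prob, cmap[cbind(df$i, df$j)], tolerance = 1e-6)
})
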