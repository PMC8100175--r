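test_that("MSA subsampling caps the depth reproducibly", {
  set.seed(30)
  rows <- vapply(1:50, function(k)
    paste(sample(aaAlphabet, 8, replace = TRUE), collapse = ""), "")
  msa <- Msa(rows[1], rows)
  expect_identical(sampleMsa(msa, 1000L, seed = 1), msa)  # no-op below cap
  sub <- sampleMsa(msa, 20L, seed = 1)
  expect_equal(msaDepth(sub), 20L)
  expect_true(all(msaHomologs(sub) %in% rows))
  # original order is preserved
  expect_identical(order(match(msaIds(sub), msaIds(msa))), 1:20L)
  expect_identical(sampleMsa(msa, 20L, seed = 1), sub)
  expect_false(identical(sampleMsa(msa, 20L, seed = 2), sub))
})

test_that("crop enumeration covers all pairs and is reproducible", {
  expect_length(cropPairs(100, 128, mode = "tiled"), 1L)
  expect_equal(cropPairs(100, 128, mode = "tiled")[[1]]$rows, 1:100)
  tiles <- cropPairs(256, 128, mode = "tiled")
  expect_length(tiles, 4L)
  covered <- matrix(FALSE, 256, 256)
  for (tl in tiles) covered[tl$rows, tl$cols] <- TRUE
  expect_true(all(covered))
  r1 <- cropPairs(300, 64, seed = 4, mode = "random", n = 3)
  r2 <- cropPairs(300, 64, seed = 4, mode = "random", n = 3)
  expect_identical(r1, r2)
  expect_length(r1[[1]]$rows, 64L)
})

test_that("label maps bin true distances and mask short separations", {
  coords <- generateToyStructure(10, seed = 3)
  lm <- labelsFromCoords(coords)
  D <- as.matrix(dist(coords))
  expect_identical(lm$bins[2, 7], distanceToBin(D[2, 7]))
  expect_false(any(lm$mask[abs(row(lm$bins) - col(lm$bins)) <= 1]))
  coords[4, ] <- NA
  lm2 <- labelsFromCoords(coords)
  expect_false(any(lm2$mask[4, ]))
  expect_false(any(lm2$mask[, 4]))
})

test_that("architecture variants wire the expected channel counts", {
  enc <- tinyEnc(C = 4L)
  hd <- tinyHead()
  m <- buildVariant("full", enc, hd, seed = 1)
  expect_equal(ncol(m@params[["head.proj.W"]]), aggregatedChannels(4L))
  mOP <- buildVariant("no_OP", enc, hd, seed = 1)
  expect_equal(ncol(mOP@params[["head.proj.W"]]), 8L)  # 2C only
  mR <- buildVariant("no_R", enc, hd, seed = 1)
  expect_equal(dim(mR@params[["head.lin.W"]]),
               c(37L, aggregatedChannels(4L)))
  mER <- buildVariant("no_E_R", enc, hd, seed = 1)
  expect_equal(dim(mER@params[["head.lin.W"]]),
               c(37L, aggregatedChannels(41L)))
  expect_false(any(grepl("^enc", names(mER@params))))
  expect_error(buildVariant("bogus", enc, hd), "arg")
  # reference scale: C = 64 gives the 4224-channel head input
  expect_equal(aggregatedChannels(encoderConfig()$channels), 4224L)
})

test_that("training reduces the loss and zero learning rate freezes it", {
  tgt <- generateToyTarget(L = 16L, K = 12L, seed = 41)
  m <- buildVariant("full", tinyEnc(), tinyHead(), seed = 2)
  tr <- trainModel(m, list(tgt), trainConfig(steps = 60L,
                                             learningRate = 5e-3, seed = 3))
  expect_lt(mean(tail(tr$lossTrace, 5)), mean(head(tr$lossTrace, 5)))
  frozen <- trainModel(m, list(tgt),
                       trainConfig(steps = 5L, learningRate = 0, seed = 3))
  expect_equal(diff(frozen$lossTrace), rep(0, 4), tolerance = 1e-12)
  expect_error(trainModel(m, list(), trainConfig(steps = 1L)), "empty")
})

test_that("training is reproducible under a fixed seed", {
  tgt <- generateToyTarget(L = 14L, K = 10L, seed = 42)
  m <- buildVariant("no_R", tinyEnc(), tinyHead(), seed = 5)
  cfg <- trainConfig(steps = 8L, learningRate = 3e-3, seed = 7)
  t1 <- trainModel(m, list(tgt), cfg)
  t2 <- trainModel(m, list(tgt), cfg)
  expect_identical(t1$lossTrace, t2$lossTrace)
  expect_identical(t1$model@params, t2$model@params)
})

test_that("tiled-crop loss equals the full-matrix loss when L fits one crop", {
  tgt <- generateToyTarget(L = 12L, K = 8L, seed = 43)
  m <- buildVariant("no_E_R", tinyEnc(), tinyHead(), seed = 6)
  msa <- targetMsa(tgt)
  labels <- labelsFromCoords(targetCoords(tgt))
  lossFull <- modelLoss(m, msa, labels)
  lossTiled <- modelLoss(m, msa, labels,
                         crops = cropPairs(12L, 128L, mode = "tiled"))
  expect_equal(lossTiled, lossFull, tolerance = 1e-12)
})

test_that("model prediction yields a valid distogram deterministically", {
  tgt <- generateToyTarget(L = 12L, K = 10L, seed = 44)
  m <- buildVariant("full", tinyEnc(), tinyHead(), seed = 8)
  d1 <- modelPredict(m, targetMsa(tgt))
  d2 <- modelPredict(m, targetMsa(tgt))
  expect_equal(distogramArray(d1), distogramArray(d2), tolerance = 1e-14)
  p <- distogramArray(d1)
  expect_equal(apply(p, c(1, 2), sum), matrix(1, 12, 12), tolerance = 1e-8)
  expect_equal(p, aperm(p, c(2, 1, 3)), tolerance = 1e-12)
})
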