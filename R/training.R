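#' Training configuration
#'
#' @param steps Number of optimization steps.
#' @param learningRate Adam learning rate (default 3e-3).
#' @param maxMsaSample Cap on homolog rows sampled per step (default 1000,
#'   as in the reference training setup; sampling doubles as data
#'   augmentation).
#' @param cropSize Distance-matrix crop size (default 128: pairwise
#'   distances between two groups of up to 128 consecutive residues).
#' @param seed Integer seed controlling sampling, cropping and shuffling.
#' @return A configuration list.
#' @export
trainConfig <- function(steps = 200L, learningRate = 3e-3,
                        maxMsaSample = 1000L, cropSize = 128L, seed = 1L) {
  stopifnot(steps >= 1, learningRate >= 0, maxMsaSample >= 1, cropSize >= 1)
  list(steps = as.integer(steps), learningRate = learningRate,
       maxMsaSample = as.integer(maxMsaSample),
       cropSize = as.integer(cropSize), seed = as.integer(seed))
}

#' Subsample an MSA
#'
#' Draws a uniform random subset (without replacement) of at most `maxN`
#' homolog rows, keeping the original order; a no-op when K <= maxN.
#' Sequence weights must be recomputed on the subset.
#'
#' @param msa An [Msa-class].
#' @param maxN Maximum number of rows to keep.
#' @param seed Integer seed.
#' @return An [Msa-class] with min(K, maxN) rows.
#' @export
sampleMsa <- function(msa, maxN = 1000L, seed = 1L) {
  stopifnot(maxN >= 1)
  K <- msaDepth(msa)
  if (K <= maxN) return(msa)
  set.seed(seed)
  keep <- sort(sample.int(K, maxN))
  Msa(msa@target, msa@homologs[keep], msa@ids[keep])
}

#' Crop index ranges for a pair matrix
#'
#' Splits (or samples from) the L x L pair matrix into crops of
#' `crop` x `crop` consecutive-residue blocks. `tiled` mode returns
#' ceiling(L/crop)^2 crops covering every pair at least once; `random`
#' mode draws `n` crops with uniform start offsets.
#'
#' @param L Target length.
#' @param crop Crop size (>= 1); crops have length min(L, crop).
#' @param seed Integer seed (random mode).
#' @param mode `"random"` or `"tiled"`.
#' @param n Number of crops in random mode (default 1).
#' @return A list of crops, each a list with integer vectors `rows` and
#'   `cols`.
#' @export
cropPairs <- function(L, crop, seed = 1L, mode = c("random", "tiled"),
                      n = 1L) {
  mode <- match.arg(mode)
  stopifnot(crop >= 1)
  cl <- min(L, crop)
  if (mode == "tiled") {
    starts <- unique(c(seq(1L, L - cl + 1L, by = cl),
                       L - cl + 1L))
    out <- list()
    for (r0 in starts) for (c0 in starts)
      out[[length(out) + 1L]] <- list(rows = r0:(r0 + cl - 1L),
                                      cols = c0:(c0 + cl - 1L))
    return(out)
  }
  set.seed(seed)
  lapply(seq_len(n), function(dummy) {
    r0 <- sample.int(L - cl + 1L, 1L)
    c0 <- sample.int(L - cl + 1L, 1L)
    list(rows = r0:(r0 + cl - 1L), cols = c0:(c0 + cl - 1L))
  })
}

#' True-bin label map from coordinates
#'
#' @param coords Numeric (L, 3) coordinate matrix (NA rows = missing).
#' @param minSeparation Pairs with |i-j| below this are masked out of the
#'   loss (default 2).
#' @return A list with `bins` (L, L integer matrix in 1..37) and `mask`
#'   (logical L, L; FALSE where coordinates are missing or separation is
#'   too small).
#' @export
labelsFromCoords <- function(coords, minSeparation = 2L) {
  L <- nrow(coords)
  ok <- stats::complete.cases(coords)
  D <- as.matrix(stats::dist(coords))
  bins <- matrix(1L, L, L)
  pos <- which(D > 0)
  bins[pos] <- distanceToBin(D[pos])
  mask <- outer(ok, ok) & abs(row(bins) - col(bins)) >= minSeparation
  list(bins = bins, mask = mask)
}

#' Build an architecture variant
#'
#' Assembles the model used in the contribution analysis: `"full"` is
#' encoder + aggregator (with outer products) + 2D residual head; `"no_R"`
#' drops the 2D head (per-pair linear 37-way classifier on h); `"no_E_R"`
#' additionally drops the encoder (the aggregator runs on the raw
#' 41-channel encodings, giving covariance-like pair statistics);
#' `"no_OP"` keeps encoder and head but removes the outer-product block,
#' so h(i,j) = concat(f(i), f(j)) with D = 2C.
#'
#' @param variant One of `"full"`, `"no_R"`, `"no_E_R"`, `"no_OP"`.
#' @param encCfg Encoder configuration ([encoderConfig()]).
#' @param headCfg Head configuration ([headConfig()]).
#' @param seed Integer seed for parameter initialization.
#' @return A [CoevModel-class].
#' @export
buildVariant <- function(variant = c("full", "no_R", "no_E_R", "no_OP"),
                         encCfg = encoderConfig(), headCfg = headConfig(),
                         seed = 1L) {
  variant <- match.arg(variant)
  params <- list()
  bnState <- list()
  hasEncoder <- variant %in% c("full", "no_R", "no_OP")
  includeOP <- variant %in% c("full", "no_R", "no_E_R")
  C <- if (hasEncoder) encCfg$channels else 41L
  D <- aggregatedChannels(C, includeOP)
  if (hasEncoder) {
    enc <- buildEncoder(encCfg, seed = seed)
    params <- c(params, enc$params)
    bnState <- c(bnState, enc$bnState)
  }
  if (variant %in% c("full", "no_OP")) {
    head <- buildHead(headCfg, inChannels = D, seed = seed + 1L)
    params <- c(params, head$params)
    bnState <- c(bnState, head$bnState)
  } else {
    set.seed(seed + 1L)
    params[["head.lin.W"]] <- .initConvW(37L, D, 1L)
    params[["head.lin.b"]] <- rep(0, 37L)
  }
  new("CoevModel", variant = variant, encCfg = encCfg, headCfg = headCfg,
      params = params, bnState = bnState)
}

.variantHasEncoder <- function(variant) variant %in% c("full", "no_R", "no_OP")
.variantIncludeOP <- function(variant) variant %in% c("full", "no_R", "no_E_R")
.variantHasHead <- function(variant) variant %in% c("full", "no_OP")

# Full forward pass of a variant on one (encoded) MSA.
# Returns logits over the crop plus the caches needed for backward.
.modelForward <- function(model, encArr, wv, rows, cols, train = FALSE) {
  variant <- model@variant
  caches <- list(rows = rows, cols = cols, wv = wv)
  bnState <- model@bnState
  if (.variantHasEncoder(variant)) {
    fw <- .encoderForward(model@params, model@encCfg, bnState, encArr,
                          train = train)
    X <- fw$Y
    bnState <- fw$bnState
    caches$enc <- fw$caches
    caches$encIn <- encArr
  } else {
    X <- encArr
  }
  caches$X <- X
  includeOP <- .variantIncludeOP(variant)
  H <- aggregateHForwardCpp(X, wv@w, wv@mEff, rows - 1L, cols - 1L,
                            includeOP, 0L)
  caches$H <- H
  if (.variantHasHead(variant)) {
    hw <- .headForward(model@params, model@headCfg, bnState, H,
                       train = train)
    logits <- hw$logits
    bnState <- hw$bnState
    caches$head <- hw$caches
  } else {
    logits <- conv2dForwardCpp(H, model@params[["head.lin.W"]],
                               model@params[["head.lin.b"]], 1L, 1L)
  }
  if (identical(rows, cols))
    logits <- (logits + aperm(logits, c(2, 1, 3))) / 2
  list(logits = logits, caches = caches, bnState = bnState)
}

.modelBackward <- function(model, caches, dLogits) {
  variant <- model@variant
  if (identical(caches$rows, caches$cols))
    dLogits <- (dLogits + aperm(dLogits, c(2, 1, 3))) / 2
  grads <- list()
  if (.variantHasHead(variant)) {
    hb <- .headBackward(model@params, model@headCfg, caches$head, dLogits)
    grads <- .addGrads(grads, hb$grads)
    dH <- hb$dX
  } else {
    cbk <- conv2dBackwardCpp(caches$H, model@params[["head.lin.W"]],
                             dLogits, 1L, 1L,
                             needDx = .variantHasEncoder(variant))
    grads[["head.lin.W"]] <- cbk$dW
    grads[["head.lin.b"]] <- as.numeric(cbk$db)
    dH <- cbk$dX
  }
  if (.variantHasEncoder(variant)) {
    wv <- caches$wv
    dX <- aggregateHBackwardCpp(caches$X, wv@w, wv@mEff,
                                caches$rows - 1L, caches$cols - 1L,
                                .variantIncludeOP(variant), dH)
    eg <- .encoderBackward(model@params, model@encCfg, caches$enc, dX)
    grads <- .addGrads(grads, eg)
  }
  grads
}

#' Train a model on a set of targets
#'
#' One optimization step processes one target: the MSA is (re-)subsampled
#' to at most `cfg$maxMsaSample` rows (a form of data augmentation),
#' sequence weights are recomputed on the subsample, a crop of at most
#' `cfg$cropSize` x `cfg$cropSize` pairs is drawn when L exceeds the crop
#' size, and the masked 37-way cross-entropy over the crop is minimized
#' with Adam. Fully seeded and single-threaded, hence reproducible.
#'
#' @param model A [CoevModel-class] from [buildVariant()].
#' @param dataset List of targets; each element needs `msa` (an
#'   [Msa-class]) and `labels` (from [labelsFromCoords()]). A
#'   [ToyTarget-class] may be supplied directly.
#' @param cfg From [trainConfig()].
#' @param verbose Print the loss every 25 steps.
#' @return A list with the trained `model` and the numeric `lossTrace`.
#' @export
trainModel <- function(model, dataset, cfg = trainConfig(),
                       verbose = FALSE) {
  if (length(dataset) == 0) stop("empty training dataset")
  dataset <- lapply(dataset, function(d) {
    if (is(d, "ToyTarget"))
      list(msa = targetMsa(d), labels = labelsFromCoords(targetCoords(d)))
    else d
  })
  opt <- .adamInit(model@params)
  lossTrace <- numeric(cfg$steps)
  set.seed(cfg$seed)
  order <- sample(rep(seq_along(dataset),
                      length.out = max(cfg$steps, length(dataset))))
  stepSeeds <- sample.int(.Machine$integer.max - 1L, cfg$steps)
  for (step in seq_len(cfg$steps)) {
    tgt <- dataset[[order[(step - 1L) %% length(order) + 1L]]]
    msa <- sampleMsa(tgt$msa, cfg$maxMsaSample, seed = stepSeeds[step])
    wv <- sequenceWeights(msa)
    encArr <- encodedValues(encodePairwise(msa))
    L <- msaLength(msa)
    crop <- cropPairs(L, cfg$cropSize, seed = stepSeeds[step],
                      mode = "random")[[1]]
    fw <- .modelForward(model, encArr, wv, crop$rows, crop$cols,
                        train = TRUE)
    bins <- tgt$labels$bins[crop$rows, crop$cols, drop = FALSE]
    mask <- tgt$labels$mask[crop$rows, crop$cols, drop = FALSE]
    ce <- .softmaxCE(fw$logits, bins, mask)
    if (!is.finite(ce$loss))
      stop(sprintf("training diverged at step %d (loss = %s)",
                   step, format(ce$loss)))
    lossTrace[step] <- ce$loss
    grads <- .modelBackward(model, fw$caches, ce$dlogits)
    if (cfg$learningRate > 0) {
      upd <- .adamStep(model@params, grads, opt, cfg$learningRate)
      model@params <- upd$params
      opt <- upd$opt
      model@bnState <- fw$bnState
    }
    if (verbose && step %% 25L == 0L)
      message(sprintf("step %4d  loss %.4f", step, ce$loss))
  }
  list(model = model, lossTrace = lossTrace)
}

#' Masked cross-entropy of a model on one target (no parameter update)
#'
#' @param model A [CoevModel-class].
#' @param msa An [Msa-class].
#' @param labels From [labelsFromCoords()].
#' @param crops Optional list of crops (default: the full matrix).
#' @return Mean masked cross-entropy (nats), averaged over crop pairs.
#' @export
modelLoss <- function(model, msa, labels, crops = NULL) {
  wv <- sequenceWeights(msa)
  encArr <- encodedValues(encodePairwise(msa))
  L <- msaLength(msa)
  if (is.null(crops)) crops <- list(list(rows = 1:L, cols = 1:L))
  tot <- 0
  n <- 0
  for (cr in crops) {
    fw <- .modelForward(model, encArr, wv, cr$rows, cr$cols, train = FALSE)
    mask <- labels$mask[cr$rows, cr$cols, drop = FALSE]
    ce <- .softmaxCE(fw$logits, labels$bins[cr$rows, cr$cols, drop = FALSE],
                     mask)
    tot <- tot + ce$loss * sum(mask)
    n <- n + sum(mask)
  }
  tot / n
}

#' Predict a distogram with a trained model
#'
#' Full evaluation-mode forward pass over all residue pairs: encode the
#' MSA, aggregate pair features and apply the model's distance estimator;
#' logits are symmetrized before the softmax.
#'
#' @param model A [CoevModel-class].
#' @param msa An [Msa-class].
#' @param maxMsaSample Optional row cap applied before prediction (default
#'   NULL: use the full alignment).
#' @param seed Seed for the optional subsampling.
#' @return A [Distogram-class].
#' @export
modelPredict <- function(model, msa, maxMsaSample = NULL, seed = 1L) {
  if (!is.null(maxMsaSample)) msa <- sampleMsa(msa, maxMsaSample, seed)
  wv <- sequenceWeights(msa)
  encArr <- encodedValues(encodePairwise(msa))
  L <- msaLength(msa)
  fw <- .modelForward(model, encArr, wv, 1:L, 1:L, train = FALSE)
  .logitsToDistogram(fw$logits)
}

#' Toy-scale model configurations for the synthetic benchmark
#'
#' The hyperparameters used throughout the package's synthetic-benchmark
#' experiments: an encoder with 1 residual block and 8 channels (receptive
#' field 7) and a head with 2 residual blocks, 16 channels and dilations
#' (1, 2). These are deliberate scale-downs of the reference architecture
#' (8/64 and 72/96) chosen so that a full ablation study runs on a single
#' CPU; see the package vignette.
#'
#' @return A list with elements `enc` and `head`.
#' @export
toyModelConfig <- function() {
  list(enc = encoderConfig(nBlocks = 1L, channels = 8L),
       head = headConfig(nBlocks = 2L, channels = 16L,
                         dilationCycle = c(1L, 2L)))
}

#' Ablation study on synthetic targets
#'
#' Trains the requested architecture variants on a shared set of synthetic
#' training targets and evaluates long-range top-L/5 contact precision on
#' a disjoint evaluation set, repeating over replicate seeds (which vary
#' parameter initialization, MSA subsampling and target order). This
#' reproduces, at toy scale, the contribution analysis of the full
#' architecture versus its ablations.
#'
#' @param trainTargets,evalTargets Lists of [ToyTarget-class] objects
#'   (disjoint sets; see [generateToyTarget()]).
#' @param variants Character vector of variant names (see
#'   [buildVariant()]).
#' @param seeds Integer vector of replicate seeds (>= 1).
#' @param steps,learningRate,maxMsaSample Training-loop settings (see
#'   [trainConfig()]).
#' @param predictMsaSample Row cap applied at prediction time.
#' @param fraction,rangeClass Evaluation metric settings (see
#'   [contactPrecision()]).
#' @return A data.frame with one row per (variant, seed, evaluation
#'   target): columns `variant`, `seed`, `target`, `precision`.
#' @export
ablationStudy <- function(trainTargets, evalTargets,
                          variants = c("full", "no_OP", "no_E_R"),
                          seeds = 1:5, steps = 400L,
                          learningRate = 5e-3, maxMsaSample = 32L,
                          predictMsaSample = 64L,
                          fraction = 5, rangeClass = "long") {
  res <- list()
  cfgs <- toyModelConfig()
  for (seed in seeds) {
    for (variant in variants) {
      model <- buildVariant(variant, cfgs$enc, cfgs$head, seed = seed)
      tr <- trainModel(model, trainTargets,
                       trainConfig(steps = steps,
                                   learningRate = learningRate,
                                   maxMsaSample = maxMsaSample,
                                   seed = seed))
      for (ti in seq_along(evalTargets)) {
        tgt <- evalTargets[[ti]]
        dg <- modelPredict(tr$model, targetMsa(tgt),
                           maxMsaSample = predictMsaSample, seed = seed)
        cp <- contactProbability(dg)
        prec <- contactPrecision(cp, targetContacts(tgt),
                                 fraction = fraction,
                                 rangeClass = rangeClass)
        res[[length(res) + 1L]] <- data.frame(variant = variant,
                                              seed = seed, target = ti,
                                              precision = prec$precision)
      }
    }
  }
  do.call(rbind, res)
}
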