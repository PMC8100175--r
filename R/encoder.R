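#' Encoder configuration
#'
#' The MSA encoder is a 1D convolutional residual network applied to each
#' pairwise target-homolog alignment independently. Defaults follow the
#' reference architecture: 8 residual blocks, each holding two batch-norm
#' layers, two kernel-3 convolutions with 64 filters and ELU
#' nonlinearities, preceded by a 41 -> C input projection (a kernel-1
#' convolution, counted separately from the residual blocks).
#'
#' @param nBlocks Number of residual blocks (default 8). 0 reduces the
#'   encoder to the input projection.
#' @param channels Embedding channels C (default 64).
#' @param kernelSize Odd convolution kernel size (default 3).
#' @return A configuration list.
#' @export
encoderConfig <- function(nBlocks = 8L, channels = 64L, kernelSize = 3L) {
  nBlocks <- as.integer(nBlocks)
  channels <- as.integer(channels)
  kernelSize <- as.integer(kernelSize)
  if (is.na(nBlocks) || nBlocks < 0L)
    stop("nBlocks must be a non-negative integer")
  if (is.na(channels) || channels < 1L)
    stop("channels must be a positive integer")
  if (is.na(kernelSize) || kernelSize < 1L || kernelSize %% 2L == 0L)
    stop("kernelSize must be an odd positive integer")
  list(nBlocks = nBlocks, channels = channels, kernelSize = kernelSize)
}

#' Receptive field of a 1D convolution stack
#'
#' For `nConvLayers` stacked convolutions of size `kernelSize` (dilation 1)
#' the span of input positions influencing one output position is
#' `1 + nConvLayers * (kernelSize - 1)`; the default encoder (8 blocks = 16
#' convolution layers of kernel 3) has receptive field 33.
#'
#' @param nConvLayers Number of convolution layers (>= 0).
#' @param kernelSize Kernel size (>= 1).
#' @return Integer receptive field size.
#' @examples
#' receptiveField(16, 3)  # 33
#' @export
receptiveField <- function(nConvLayers, kernelSize) {
  stopifnot(nConvLayers >= 0, kernelSize >= 1)
  as.integer(1 + nConvLayers * (kernelSize - 1))
}

# Parameter names for an encoder with the given config (flat registry).
.encParamNames <- function(cfg) {
  nm <- c("enc.proj.W", "enc.proj.b")
  for (bl in seq_len(cfg$nBlocks)) {
    p <- sprintf("enc.b%d.", bl)
    nm <- c(nm, paste0(p, c("bn1.gamma", "bn1.beta", "conv1.W", "conv1.b",
                            "bn2.gamma", "bn2.beta", "conv2.W", "conv2.b")))
  }
  nm
}

#' Build a seeded MSA encoder
#'
#' Constructs the residual encoder with reproducible (seeded) parameter
#' initialization. Blocks use the pre-activation layout
#' norm -> ELU -> conv -> norm -> ELU -> conv with an identity skip.
#'
#' @param config From [encoderConfig()].
#' @param seed Integer seed for parameter initialization.
#' @return A list with elements `config`, `params` (flat named list) and
#'   `bnState` (running statistics).
#' @export
buildEncoder <- function(config = encoderConfig(), seed = 1L) {
  set.seed(seed)
  C <- config$channels
  ks <- config$kernelSize
  params <- list()
  params[["enc.proj.W"]] <- .initConvW(C, 41L, 1L)
  params[["enc.proj.b"]] <- rep(0, C)
  bnState <- list()
  for (bl in seq_len(config$nBlocks)) {
    p <- sprintf("enc.b%d.", bl)
    for (half in 1:2) {
      bn <- .newBnParams(C)
      params[[paste0(p, "bn", half, ".gamma")]] <- bn$gamma
      params[[paste0(p, "bn", half, ".beta")]] <- bn$beta
      params[[paste0(p, "conv", half, ".W")]] <- .initConvW(C, C, ks)
      params[[paste0(p, "conv", half, ".b")]] <- rep(0, C)
      bnState[[paste0(p, "bn", half)]] <- .newBnState(C)
    }
  }
  list(config = config, params = params, bnState = bnState)
}

# Forward pass. X: (41, L, K) array. Returns embeddings (C, L, K), the
# updated bn state, and caches for the backward pass.
.encoderForward <- function(params, cfg, bnState, X, train = FALSE) {
  ks <- cfg$kernelSize
  caches <- list()
  Y <- conv1dForwardCpp(X, params[["enc.proj.W"]], params[["enc.proj.b"]],
                        1L, 1L)
  caches$projX <- X
  for (bl in seq_len(cfg$nBlocks)) {
    p <- sprintf("enc.b%d.", bl)
    cb <- list(inp = Y)
    z <- Y
    for (half in 1:2) {
      bn <- .bnForward(z, params[[paste0(p, "bn", half, ".gamma")]],
                       params[[paste0(p, "bn", half, ".beta")]],
                       bnState[[paste0(p, "bn", half)]], train, 1L)
      bnState[[paste0(p, "bn", half)]] <- bn$state
      cb[[paste0("bn", half)]] <- bn$cache
      el <- .eluForward(bn$y)
      cb[[paste0("elu", half)]] <- el$cache
      cb[[paste0("convIn", half)]] <- el$y
      z <- conv1dForwardCpp(el$y, params[[paste0(p, "conv", half, ".W")]],
                            params[[paste0(p, "conv", half, ".b")]], ks, 1L)
    }
    Y <- Y + z
    caches[[sprintf("b%d", bl)]] <- cb
  }
  list(Y = Y, bnState = bnState, caches = caches)
}

# Backward pass: gradient of loss w.r.t. encoder parameters (dY given).
.encoderBackward <- function(params, cfg, caches, dY) {
  ks <- cfg$kernelSize
  grads <- list()
  for (bl in rev(seq_len(cfg$nBlocks))) {
    p <- sprintf("enc.b%d.", bl)
    cb <- caches[[sprintf("b%d", bl)]]
    dz <- dY  # gradient into the conv branch output
    for (half in 2:1) {
      wname <- paste0(p, "conv", half, ".W")
      cbk <- conv1dBackwardCpp(cb[[paste0("convIn", half)]],
                               params[[wname]], dz, ks, 1L)
      grads[[wname]] <- cbk$dW
      grads[[paste0(p, "conv", half, ".b")]] <- as.numeric(cbk$db)
      dElu <- .eluBackward(cb[[paste0("elu", half)]], cbk$dX)
      bnb <- .bnBackward(cb[[paste0("bn", half)]], dElu)
      grads[[paste0(p, "bn", half, ".gamma")]] <- bnb$dgamma
      grads[[paste0(p, "bn", half, ".beta")]] <- bnb$dbeta
      dz <- bnb$dx
    }
    dY <- dY + dz  # skip connection
  }
  cbk <- conv1dBackwardCpp(caches$projX, params[["enc.proj.W"]], dY, 1L, 1L)
  grads[["enc.proj.W"]] <- cbk$dW
  grads[["enc.proj.b"]] <- as.numeric(cbk$db)
  grads
}

#' Embed an encoded MSA
#'
#' Applies the encoder to every pairwise alignment independently (no
#' mixing across homolog rows), producing one C-channel embedding per
#' residue per homolog. Rows may be processed in chunks without changing
#' the result; evaluation mode (frozen normalization statistics) is used.
#'
#' @param encoder From [buildEncoder()].
#' @param encMsa An [EncodedMsa-class].
#' @param chunk Optional number of homolog rows per forward chunk.
#' @return Numeric array (C, L, K) of per-homolog residue embeddings.
#' @export
encodeMsa <- function(encoder, encMsa, chunk = NULL) {
  X <- encodedValues(encMsa)
  if (dim(X)[1] != 41L) stop("encoded MSA must have 41 channels")
  K <- dim(X)[3]
  if (is.null(chunk) || chunk >= K) {
    return(.encoderForward(encoder$params, encoder$config, encoder$bnState,
                           X, train = FALSE)$Y)
  }
  out <- array(0, dim = c(encoder$config$channels, dim(X)[2], K))
  for (k0 in seq(1L, K, by = chunk)) {
    k1 <- min(K, k0 + chunk - 1L)
    out[, , k0:k1] <- .encoderForward(encoder$params, encoder$config,
                                      encoder$bnState,
                                      X[, , k0:k1, drop = FALSE],
                                      train = FALSE)$Y
  }
  out
}
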