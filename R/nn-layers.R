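# Internal neural-network primitives shared by the 1D encoder and the 2D
# distance head. Feature layouts: 1D maps are arrays (C, L, K) with the
# channel axis first; 2D maps are arrays (L, L, C) with the channel axis
# last (matching the compiled convolution kernels). Batch statistics are
# taken over all non-channel axes, i.e. (K x L) positions for 1D maps and
# L^2 positions for 2D maps: homolog rows are independent samples of the
# same alignment, so they share normalization statistics.

.bnMomentum <- 0.1
.bnEps <- 1e-5

.newBnParams <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C))
}

.newBnState <- function(C) {
  list(rmean = rep(0, C), rvar = rep(1, C))
}

# x: array with channel axis `chAxis` (1 for 1D maps, 3 for 2D maps).
.bnForward <- function(x, gamma, beta, state, train, chAxis) {
  d <- dim(x)
  C <- d[chAxis]
  xm <- if (chAxis == 1L) matrix(x, nrow = C) else t(matrix(x, ncol = C))
  if (train) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    state$rmean <- (1 - .bnMomentum) * state$rmean + .bnMomentum * mu
    state$rvar <- (1 - .bnMomentum) * state$rvar + .bnMomentum * v
  } else {
    mu <- state$rmean
    v <- state$rvar
    xc <- xm - mu
  }
  istd <- 1 / sqrt(v + .bnEps)
  xhat <- xc * istd
  ym <- xhat * gamma + beta
  y <- if (chAxis == 1L) array(ym, d) else array(t(ym), d)
  list(y = y, state = state,
       cache = list(xhat = xhat, istd = istd, gamma = gamma,
                    d = d, chAxis = chAxis, train = train))
}

.bnBackward <- function(cache, dy) {
  d <- cache$d
  C <- if (cache$chAxis == 1L) d[1] else d[3]
  dym <- if (cache$chAxis == 1L) matrix(dy, nrow = C) else t(matrix(dy, ncol = C))
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  n <- ncol(dym)
  dxhat <- dym * cache$gamma
  if (cache$train) {
    dxm <- cache$istd *
      (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dxm <- cache$istd * dxhat
  }
  dx <- if (cache$chAxis == 1L) array(dxm, d) else array(t(dxm), d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.eluForward <- function(x) {
  neg <- x < 0
  y <- x
  y[neg] <- exp(x[neg]) - 1
  list(y = y, cache = list(y = y, neg = neg))
}

.eluBackward <- function(cache, dy) {
  dx <- dy
  dx[cache$neg] <- dy[cache$neg] * (cache$y[cache$neg] + 1)
  dx
}

# He-style fan-in initialization for convolution weights.
.initConvW <- function(cout, cin, ktaps) {
  sd <- sqrt(2 / (cin * ktaps))
  matrix(rnorm(cout * cin * ktaps, sd = sd), nrow = cout)
}

# Masked 37-way softmax cross-entropy over pair logits.
# logits: (n1, n2, B); labels: (n1, n2) integer bins in 1..B; mask logical.
# Returns mean loss over masked pairs and the gradient w.r.t. logits.
.softmaxCE <- function(logits, labels, mask) {
  d <- dim(logits)
  B <- d[3]
  zm <- matrix(logits, ncol = B)
  zm <- zm - apply(zm, 1, max)
  ez <- exp(zm)
  p <- ez / rowSums(ez)
  idx <- as.vector(mask)
  lab <- as.vector(labels)
  n <- sum(idx)
  if (n == 0) stop("no valid pairs in loss mask")
  picked <- p[cbind(which(idx), lab[idx])]
  loss <- -mean(log(pmax(picked, 1e-12)))
  g <- p
  g[cbind(which(idx), lab[idx])] <- picked - 1
  g[!idx, ] <- 0
  g <- g / n
  list(loss = loss, dlogits = array(g, d))
}

# Adam optimizer over a flat named list of parameter arrays.
.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# Accumulate gradient lists (named, possibly overlapping names).
.addGrads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
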