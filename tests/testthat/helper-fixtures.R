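# Shared fixtures: everything is generated in code at test time.

# A tiny hand-written alignment with a gap and a wildcard.
tinyMsa <- function() {
  Msa("MKTAYIA", c("MKTAYIA", "MRT-YLA", "MKTXYIA"),
      ids = c("t", "h1", "h2"))
}

randomEmbedding <- function(C, L, K, seed = 1) {
  set.seed(seed)
  array(rnorm(C * L * K), dim = c(C, L, K))
}

randomWeights <- function(K, seed = 1) {
  set.seed(seed)
  w <- runif(K, 0.2, 1)
  new("WeightVector", w = w, mEff = sum(w))
}

# Naive reference implementations used as oracles.
oracleF <- function(X, wv) {
  d <- dim(X)
  f <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) f <- f + wv@w[k] * X[, , k]
  f / wv@mEff
}

oracleG <- function(X, wv) {
  d <- dim(X)
  g <- array(0, dim = c(d[1], d[1], d[2], d[2]))
  for (k in seq_len(d[3]))
    for (i in seq_len(d[2]))
      for (j in seq_len(d[2]))
        g[, , i, j] <- g[, , i, j] + wv@w[k] * outer(X[, i, k], X[, j, k])
  g / wv@mEff
}

oracleH <- function(X, wv) {
  C <- dim(X)[1]; L <- dim(X)[2]
  f <- oracleF(X, wv)
  g <- oracleG(X, wv)
  h <- array(0, dim = c(L, L, 2 * C + C^2))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      h[i, j, ] <- c(f[, i], f[, j], as.vector(g[, , i, j]))
    }
  }
  h
}

# Exhaustive sequence-weight oracle (pairwise identity count).
oracleWeights <- function(rows, thr = 0.8) {
  K <- length(rows)
  ch <- strsplit(rows, "")
  L <- length(ch[[1]])
  n <- rep(1L, K)
  for (a in seq_len(K - 1)) {
    for (b in (a + 1):K) {
      id <- sum(ch[[a]] == ch[[b]]) / L
      if (id >= thr) {
        n[a] <- n[a] + 1L
        n[b] <- n[b] + 1L
      }
    }
  }
  1 / n
}

# Exhaustive top-k contact precision oracle.
oraclePrecision <- function(pred, truth, fraction, rng) {
  L <- nrow(pred)
  cand <- data.frame()
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      s <- j - i
      if (s >= rng[1] && s <= rng[2] && !is.na(truth[i, j]))
        cand <- rbind(cand, data.frame(i = i, j = j, p = pred[i, j],
                                       t = truth[i, j]))
    }
  }
  cand <- cand[order(-cand$p, cand$i, cand$j), ]
  k <- min(max(1, round(L / fraction)), nrow(cand))
  mean(cand$t[seq_len(k)])
}

# A tiny trained-free model configuration for structural tests.
tinyEnc <- function(C = 4L, blocks = 1L) encoderConfig(nBlocks = blocks, channels = C)
tinyHead <- function(ch = 6L, blocks = 1L)
  headConfig(nBlocks = blocks, channels = ch, dilationCycle = 1L)

# Brute-force minimum RMSD over rigid motions (random-restart optimization
# over rotation angles), independent of the Kabsch algebra.
bruteForceRmsd <- function(a, b) {
  ac <- scale(a, scale = FALSE)
  bc <- scale(b, scale = FALSE)
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rx %*% Ry %*% Rz
  }
  obj <- function(ang) sqrt(mean(rowSums((bc %*% rotmat(ang) - ac)^2)))
  best <- Inf
  set.seed(123)
  for (s in 1:20) {
    res <- optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))
    best <- min(best, res$value)
  }
  best
}
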