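#' Convert a distogram into smooth pairwise distance potentials
#'
#' DFIRE-style reference-state conversion: for every residue pair the
#' potential at distance d is E(d) = -log((p(bin(d)) + eps) /
#' (p(lastBin) + eps)), i.e. the negative log-probability relative to the
#' no-information reference (the open (20, Inf) bin), smoothed by a cubic
#' spline over the bin centers and held flat beyond the last finite bin.
#' A uniform distribution therefore gives an identically-zero potential,
#' and pairs with all mass in the last bin carry no restraint.
#'
#' @param dist A [Distogram-class].
#' @param eps Pseudo-probability regularizer (default 1e-4).
#' @param minSeparation Pairs with |i-j| below this are skipped
#'   (default 2).
#' @return A list with `splines` (named list `"i_j"` of spline functions),
#'   `pairs` (two-column matrix of pair indices) and `knots` (bin-center
#'   distances).
#' @export
distogramToPotential <- function(dist, eps = 1e-4, minSeparation = 2L) {
  p <- distogramArray(dist)
  L <- dim(p)[1]
  ctr <- binCenters()
  pairs <- which(upper.tri(p[, , 1]), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= minSeparation, , drop = FALSE]
  splines <- vector("list", nrow(pairs))
  names(splines) <- sprintf("%d_%d", pairs[, 1], pairs[, 2])
  for (r in seq_len(nrow(pairs))) {
    pb <- p[pairs[r, 1], pairs[r, 2], ]
    e <- -log((pb + eps) / (pb[37] + eps))
    splines[[r]] <- splinefun(ctr, e, method = "natural")
  }
  list(splines = splines, pairs = pairs, knots = ctr, L = L)
}

# Total energy and gradient of a conformation under the pair potentials
# plus harmonic chain-bond restraints (target 3.8 A).
.foldEnergy <- function(xyz, pot, bondK = 10, bondLen = 3.8) {
  L <- pot$L
  X <- matrix(xyz, L, 3)
  E <- 0
  G <- matrix(0, L, 3)
  maxd <- 20.25  # beyond the last finite knot the potential is flat
  for (r in seq_len(nrow(pot$pairs))) {
    i <- pot$pairs[r, 1]; j <- pot$pairs[r, 2]
    dvec <- X[i, ] - X[j, ]
    d <- sqrt(sum(dvec^2))
    if (d >= maxd || d < 1e-6) next
    sf <- pot$splines[[r]]
    E <- E + sf(d)
    gmag <- sf(d, deriv = 1L)
    g <- gmag * dvec / d
    G[i, ] <- G[i, ] + g
    G[j, ] <- G[j, ] - g
  }
  for (i in seq_len(L - 1L)) {
    dvec <- X[i, ] - X[i + 1L, ]
    d <- sqrt(sum(dvec^2))
    E <- E + bondK * (d - bondLen)^2
    g <- 2 * bondK * (d - bondLen) * dvec / max(d, 1e-6)
    G[i, ] <- G[i, ] + g
    G[i + 1L, ] <- G[i + 1L, ] - g
  }
  list(E = E, G = as.vector(G))
}

#' Realize a CA-level structure from distance potentials
#'
#' Minimizes the summed pair potential plus harmonic chain-bond
#' restraints over residue coordinates with L-BFGS, from several
#' restarts. The first restarts start from a distance-geometry embedding
#' (classical scaling of the modal distances, the standard initialization
#' for distance-restraint realization), later ones from perturbed copies
#' and pure random walks. Distances are blind to chirality, so the mirror
#' image of every initialization is also refined and the lower-energy
#' enantiomer kept. The best restart is returned.
#'
#' @param pot From [distogramToPotential()].
#' @param dist Optional [Distogram-class] used for the distance-geometry
#'   initialization (modal bin centers); when omitted, all restarts use
#'   random-walk initializations.
#' @param L Number of residues (>= 3; defaults to the potential's L).
#' @param seed Integer seed for the restarts.
#' @param nRestarts Number of restarts (default 8).
#' @param nSteps Maximum optimizer iterations per restart (default 300).
#' @param bondK Bond restraint stiffness (energy/A^2, default 10).
#' @return A list with `coords` (L, 3 matrix), `energy`, `energies` (per
#'   restart and chirality) and `converged` (optimizer convergence flag
#'   of the best restart).
#' @export
realizeStructure <- function(pot, dist = NULL, L = pot$L, seed = 1L,
                             nRestarts = 8L, nSteps = 300L, bondK = 10) {
  stopifnot(L >= 3)
  set.seed(seed)
  mdsInit <- NULL
  if (!is.null(dist)) {
    p <- distogramArray(dist)
    ctr <- binCenters()
    dm <- matrix(ctr[37] + 2, L, L)
    diag(dm) <- 0
    for (r in seq_len(nrow(pot$pairs))) {
      i <- pot$pairs[r, 1]; j <- pot$pairs[r, 2]
      dm[i, j] <- dm[j, i] <- ctr[which.max(p[i, j, ])]
    }
    for (i in seq_len(L - 1L)) dm[i, i + 1L] <- dm[i + 1L, i] <- 3.8
    mdsInit <- stats::cmdscale(dm, k = 3)
  }
  best <- NULL
  energies <- numeric(0)
  for (rs in seq_len(nRestarts)) {
    if (!is.null(mdsInit) && rs <= max(1L, nRestarts %/% 2L)) {
      x0 <- mdsInit + matrix(rnorm(3 * L, sd = 0.5 * (rs - 1L)), L, 3)
    } else {
      # random-walk initialization with approximate bond geometry
      steps <- matrix(rnorm(3 * (L - 1L)), ncol = 3)
      steps <- 3.8 * steps / sqrt(rowSums(steps^2))
      x0 <- apply(rbind(c(0, 0, 0), steps), 2, cumsum)
    }
    for (mirror in c(FALSE, TRUE)) {
      xs <- x0
      if (mirror) xs[, 3] <- -xs[, 3]
      opt <- optim(as.vector(xs),
                   fn = function(v) .foldEnergy(v, pot, bondK)$E,
                   gr = function(v) .foldEnergy(v, pot, bondK)$G,
                   method = "L-BFGS-B",
                   control = list(maxit = nSteps))
      energies <- c(energies, opt$value)
      if (is.null(best) || opt$value < best$value) {
        best <- opt
      }
    }
  }
  list(coords = matrix(best$par, L, 3), energy = best$value,
       energies = energies, converged = best$convergence == 0L)
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Least-squares rigid superposition of two equal-length coordinate sets
#' using the Kabsch algorithm with a proper rotation (determinant +1), and
#' the resulting root-mean-square deviation.
#'
#' @param a,b Numeric (L, 3) coordinate matrices, L >= 3.
#' @return RMSD in Angstrom after optimal superposition of `b` onto `a`.
#' @export
kabschRmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b), nrow(a) >= 3, ncol(a) == 3, ncol(b) == 3)
  ac <- scale(a, scale = FALSE)
  bc <- scale(b, scale = FALSE)
  s <- svd(crossprod(bc, ac))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  br <- bc %*% R
  sqrt(mean(rowSums((br - ac)^2)))
}

#' Distance-matrix RMS error between two conformations
#'
#' @param a,b Numeric (L, 3) coordinate matrices.
#' @param minSeparation Pairs with |i-j| below this are ignored
#'   (default 2).
#' @return Root-mean-square difference of the pairwise distances.
#' @export
distanceMatrixRms <- function(a, b, minSeparation = 2L) {
  da <- as.matrix(stats::dist(a))
  db <- as.matrix(stats::dist(b))
  sel <- upper.tri(da) & (col(da) - row(da) >= minSeparation)
  sqrt(mean((da[sel] - db[sel])^2))
}

#' Build a sharp distogram from known coordinates
#'
#' Discretizes a narrow Gaussian centred on the true distance of every
#' pair over the 37 bins (plus a small uniform floor) — the idealized
#' prediction used for potential-recovery experiments. The Gaussian width
#' keeps the derived potential wells smooth enough for gradient-based
#' realization while the mode still identifies the true bin.
#'
#' @param coords Numeric (L, 3) coordinate matrix.
#' @param sd Gaussian width in Angstrom (default 0.5, one bin).
#' @param softening Probability mass spread uniformly over all bins
#'   (default 0.02).
#' @return A [Distogram-class].
#' @export
sharpDistogram <- function(coords, sd = 0.5, softening = 0.02) {
  L <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  ctr <- binCenters()
  p <- array(softening / 37, dim = c(L, L, 37L))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      d <- if (i == j) ctr[1] else min(D[i, j], ctr[37])
      w <- exp(-0.5 * ((ctr - d) / sd)^2)
      p[i, j, ] <- p[i, j, ] + (1 - softening) * w / sum(w)
    }
  }
  new("Distogram", p = p)
}

#' Write / read CA-only coordinates as minimal PDB
#'
#' @param coords Numeric (L, 3) coordinate matrix.
#' @param path Output path.
#' @param chain Chain identifier (default "A").
#' @return `writeCaPdb`: `path` invisibly; `readCaPdb`: an (L, 3) matrix.
#' @export
writeCaPdb <- function(coords, path, chain = "A") {
  L <- nrow(coords)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(L), chain, seq_len(L),
    coords[, 1], coords[, 2], coords[, 3])
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' @rdname writeCaPdb
#' @export
readCaPdb <- function(path) {
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  m <- cbind(as.numeric(substr(lines, 31, 38)),
             as.numeric(substr(lines, 39, 46)),
             as.numeric(substr(lines, 47, 54)))
  colnames(m) <- c("x", "y", "z")
  m
}
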