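// Compiled kernels: convolutions (forward/backward), the co-evolution
// aggregator, pairwise sequence-identity weights, and the Gibbs sampler
// behind the synthetic coupled-MSA generator.
//
// Layout conventions (column-major, matching R arrays):
//   1D feature maps: cube (channels, L, K)     -- one slice per homolog
//   2D feature maps: cube (L1, L2, channels)   -- one slice per channel
//   conv1d weights:  mat  (Cout, Cin*ks), column block t = tap offset t
//   conv2d weights:  mat  (Cout, Cin*ks*ks), column c*ks*ks + u*ks + v
//                    = input channel c, row tap u, col tap v

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col1d(const arma::mat& Xs, int ks, int dilation) {
  const int Cin = Xs.n_rows, L = Xs.n_cols;
  arma::mat M(Cin * ks, L, arma::fill::zeros);
  for (int t = 0; t < ks; ++t) {
    int off = (t - (ks - 1) / 2) * dilation;
    int lo = std::max(0, -off), hi = std::min(L, L - off);
    if (lo < hi)
      M.rows(t * Cin, (t + 1) * Cin - 1).cols(lo, hi - 1) =
        Xs.cols(lo + off, hi - 1 + off);
  }
  return M;
}

// [[Rcpp::export]]
arma::cube conv1dForwardCpp(const arma::cube& X, const arma::mat& W,
                            const arma::vec& b, int ks, int dilation) {
  const int L = X.n_cols, K = X.n_slices, Cout = W.n_rows;
  arma::cube Y(Cout, L, K);
  for (int k = 0; k < K; ++k) {
    arma::mat M = im2col1d(X.slice(k), ks, dilation);
    Y.slice(k) = W * M;
    Y.slice(k).each_col() += b;
  }
  return Y;
}

// [[Rcpp::export]]
List conv1dBackwardCpp(const arma::cube& X, const arma::mat& W,
                       const arma::cube& dY, int ks, int dilation) {
  const int Cin = X.n_rows, L = X.n_cols, K = X.n_slices;
  arma::mat dW(arma::size(W), arma::fill::zeros);
  arma::vec db(W.n_rows, arma::fill::zeros);
  arma::cube dX(arma::size(X), arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    arma::mat M = im2col1d(X.slice(k), ks, dilation);
    dW += dY.slice(k) * M.t();
    db += arma::sum(dY.slice(k), 1);
    arma::mat dM = W.t() * dY.slice(k);  // (Cin*ks) x L
    arma::mat& dXs = dX.slice(k);
    for (int t = 0; t < ks; ++t) {
      int off = (t - (ks - 1) / 2) * dilation;
      int lo = std::max(0, -off), hi = std::min(L, L - off);
      if (lo < hi)
        dXs.cols(lo + off, hi - 1 + off) +=
          dM.rows(t * Cin, (t + 1) * Cin - 1).cols(lo, hi - 1);
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

static arma::mat im2col2d(const arma::cube& X, int ks, int dilation) {
  const int L1 = X.n_rows, L2 = X.n_cols, Cin = X.n_slices;
  arma::mat M(Cin * ks * ks, L1 * L2, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    const arma::mat& Xs = X.slice(c);
    for (int u = 0; u < ks; ++u) {
      int offr = (u - (ks - 1) / 2) * dilation;
      int ilo = std::max(0, -offr), ihi = std::min(L1, (int)L1 - offr);
      for (int v = 0; v < ks; ++v) {
        int offc = (v - (ks - 1) / 2) * dilation;
        int jlo = std::max(0, -offc), jhi = std::min(L2, (int)L2 - offc);
        int r = c * ks * ks + u * ks + v;
        for (int j = jlo; j < jhi; ++j)
          for (int i = ilo; i < ihi; ++i)
            M(r, i + L1 * j) = Xs(i + offr, j + offc);
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
arma::cube conv2dForwardCpp(const arma::cube& X, const arma::mat& W,
                            const arma::vec& b, int ks, int dilation) {
  const int L1 = X.n_rows, L2 = X.n_cols, Cout = W.n_rows;
  arma::mat Ym;
  if (ks == 1) {
    // pointwise convolution: no patch extraction needed
    const arma::mat Xm(const_cast<double*>(X.memptr()), (size_t)L1 * L2,
                       X.n_slices, false, true);
    Ym = W * Xm.t();
  } else {
    arma::mat M = im2col2d(X, ks, dilation);
    Ym = W * M;
  }
  Ym.each_col() += b;
  arma::cube Y(L1, L2, Cout);
  for (int c = 0; c < Cout; ++c)
    Y.slice(c) = arma::reshape(Ym.row(c), L1, L2);
  return Y;
}

// [[Rcpp::export]]
List conv2dBackwardCpp(const arma::cube& X, const arma::mat& W,
                       const arma::cube& dY, int ks, int dilation,
                       bool needDx = true) {
  const int L1 = X.n_rows, L2 = X.n_cols, Cin = X.n_slices;
  const int Cout = W.n_rows;
  arma::mat dYm(Cout, L1 * L2);
  for (int c = 0; c < Cout; ++c)
    dYm.row(c) = arma::vectorise(dY.slice(c)).t();
  arma::vec db = arma::sum(dYm, 1);
  if (ks == 1) {
    const arma::mat Xm(const_cast<double*>(X.memptr()), (size_t)L1 * L2,
                       X.n_slices, false, true);
    arma::mat dW = dYm * Xm;
    arma::cube dX(L1, L2, Cin);
    if (needDx) {
      arma::mat dXm = dYm.t() * W;  // (L1*L2) x Cin
      for (int c = 0; c < Cin; ++c)
        dX.slice(c) = arma::reshape(dXm.col(c), L1, L2);
    } else {
      dX.zeros();
    }
    return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
  }
  arma::mat M = im2col2d(X, ks, dilation);
  arma::mat dW = dYm * M.t();
  arma::cube dX(arma::size(X), arma::fill::zeros);
  if (needDx) {
    arma::mat dM = W.t() * dYm;
    for (int c = 0; c < Cin; ++c) {
      arma::mat& dXs = dX.slice(c);
      for (int u = 0; u < ks; ++u) {
        int offr = (u - (ks - 1) / 2) * dilation;
        int ilo = std::max(0, -offr), ihi = std::min(L1, (int)L1 - offr);
        for (int v = 0; v < ks; ++v) {
          int offc = (v - (ks - 1) / 2) * dilation;
          int jlo = std::max(0, -offc), jhi = std::min(L2, (int)L2 - offc);
          int r = c * ks * ks + u * ks + v;
          for (int j = jlo; j < jhi; ++j)
            for (int i = ilo; i < ihi; ++i)
              dXs(i + offr, j + offc) += dM(r, i + L1 * j);
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Weighted-average pair features h(i,j) = concat(f(i), f(j), g(i,j)).
// X: cube (C, L, K); rows/cols: 0-based residue index vectors;
// returns cube (nr, nc, D) with D = 2C (+ C^2 when includeOP).
// g(i,j) flattened column-major: channel 2C + a + C*b = X_k[a,i]*X_k[b,j].
// Homologs are consumed in chunks so peak memory is independent of K.
// [[Rcpp::export]]
arma::cube aggregateHForwardCpp(const arma::cube& X, const arma::vec& w,
                                double meff, const arma::uvec& rows,
                                const arma::uvec& cols, bool includeOP,
                                int chunk) {
  const int C = X.n_rows, K = X.n_slices;
  const int nr = rows.n_elem, nc = cols.n_elem;
  const int D = includeOP ? 2 * C + C * C : 2 * C;
  arma::mat f(C, X.n_cols, arma::fill::zeros);
  for (int k = 0; k < K; ++k) f += w(k) * X.slice(k);
  f /= meff;
  arma::cube H(nr, nc, D, arma::fill::zeros);
  for (int a = 0; a < C; ++a) {
    arma::mat& Hf = H.slice(a);
    arma::mat& Hg = H.slice(C + a);
    for (int i = 0; i < nr; ++i) Hf.row(i).fill(f(a, rows(i)));
    for (int j = 0; j < nc; ++j) Hg.col(j).fill(f(a, cols(j)));
  }
  if (includeOP) {
    // G as a GEMM: M((a,i),(b,j)) = sum_k w_k X_k(a,rows_i) X_k(b,cols_j)
    // accumulated over homolog chunks so peak memory is independent of K.
    arma::mat M(C * nr, C * nc, arma::fill::zeros);
    if (chunk < 1) chunk = K;
    arma::mat Brt(C * nr, chunk), Bct(C * nc, chunk);
    for (int k0 = 0; k0 < K; k0 += chunk) {
      int k1 = std::min(K, k0 + chunk);
      int nk = k1 - k0;
      for (int k = k0; k < k1; ++k) {
        const arma::mat& A = X.slice(k);
        for (int i = 0; i < nr; ++i)
          Brt.col(k - k0).subvec(C * i, C * i + C - 1) = A.col(rows(i));
        for (int j = 0; j < nc; ++j)
          Bct.col(k - k0).subvec(C * j, C * j + C - 1) =
            (w(k) / meff) * A.col(cols(j));
      }
      M += Brt.cols(0, nk - 1) * Bct.cols(0, nk - 1).t();
    }
    for (int b = 0; b < C; ++b) {
      for (int a = 0; a < C; ++a) {
        arma::mat& Hs = H.slice(2 * C + a + C * b);
        for (int j = 0; j < nc; ++j) {
          const double* Mc = M.colptr(b + (size_t)C * j);
          double* Hc = Hs.colptr(j);
          for (int i = 0; i < nr; ++i) Hc[i] = Mc[a + (size_t)C * i];
        }
      }
    }
  }
  return H;
}

// Gradient of aggregateHForwardCpp w.r.t. X (weights treated as constants).
// [[Rcpp::export]]
arma::cube aggregateHBackwardCpp(const arma::cube& X, const arma::vec& w,
                                 double meff, const arma::uvec& rows,
                                 const arma::uvec& cols, bool includeOP,
                                 const arma::cube& dH) {
  const int C = X.n_rows, L = X.n_cols, K = X.n_slices;
  const int nr = rows.n_elem, nc = cols.n_elem;
  arma::mat df(C, L, arma::fill::zeros);
  for (int a = 0; a < C; ++a) {
    const arma::mat& Hf = dH.slice(a);
    const arma::mat& Hg = dH.slice(C + a);
    for (int i = 0; i < nr; ++i) df(a, rows(i)) += arma::accu(Hf.row(i));
    for (int j = 0; j < nc; ++j) df(a, cols(j)) += arma::accu(Hg.col(j));
  }
  arma::cube dX(C, L, K);
  for (int k = 0; k < K; ++k) dX.slice(k) = (w(k) / meff) * df;
  if (includeOP) {
    // D((a,i),(b,j)) = dH(i, j, 2C + a + C*b); then per homolog
    // dXr_k += (w_k/meff) * D  vec(Xc_k) and dXc_k += (w_k/meff) * D^T vec(Xr_k)
    arma::mat D(C * nr, C * nc);
    for (int b = 0; b < C; ++b) {
      for (int a = 0; a < C; ++a) {
        const arma::mat& Hs = dH.slice(2 * C + a + C * b);
        for (int j = 0; j < nc; ++j) {
          double* Dc = D.colptr(b + (size_t)C * j);
          const double* Hc = Hs.colptr(j);
          for (int i = 0; i < nr; ++i) Dc[a + (size_t)C * i] = Hc[i];
        }
      }
    }
    arma::mat Brt(C * nr, K), Bct(C * nc, K);
    for (int k = 0; k < K; ++k) {
      const arma::mat& A = X.slice(k);
      for (int i = 0; i < nr; ++i)
        Brt.col(k).subvec(C * i, C * i + C - 1) = A.col(rows(i));
      for (int j = 0; j < nc; ++j)
        Bct.col(k).subvec(C * j, C * j + C - 1) = A.col(cols(j));
    }
    arma::mat dBrt = D * Bct;        // (C*nr, K)
    arma::mat dBct = D.t() * Brt;    // (C*nc, K)
    for (int k = 0; k < K; ++k) {
      arma::mat& dXs = dX.slice(k);
      const double s = w(k) / meff;
      for (int i = 0; i < nr; ++i)
        dXs.col(rows(i)) += s * dBrt.col(k).subvec(C * i, C * i + C - 1);
      for (int j = 0; j < nc; ++j)
        dXs.col(cols(j)) += s * dBct.col(k).subvec(C * j, C * j + C - 1);
    }
  }
  return dX;
}

// PSICOV-style sequence weights: w_k = 1 / #{k' : identity(k,k') >= thr},
// the count including k itself; identity = fraction of identical characters
// over all L columns (gap treated as an ordinary character).
// S: integer matrix (K, L) of symbol codes.
// [[Rcpp::export]]
arma::vec seqWeightsCpp(const arma::imat& S, double thr) {
  const int K = S.n_rows, L = S.n_cols;
  arma::ivec n(K, arma::fill::ones);  // self
  for (int k = 0; k < K; ++k) {
    for (int k2 = k + 1; k2 < K; ++k2) {
      int same = 0;
      for (int j = 0; j < L; ++j)
        if (S(k, j) == S(k2, j)) ++same;
      if ((double)same / L >= thr) { ++n(k); ++n(k2); }
    }
  }
  arma::vec w(K);
  for (int k = 0; k < K; ++k) w(k) = 1.0 / n(k);
  return w;
}

// Gibbs sampler over sequences of length L with 20 states.
// Per-column per-letter fields `field` (L x 20) control conservation;
// couplings: bonus J when a contact edge (i,j) carries one of its two
// favoured letter pairs (the target pair or the edge's alternative pair).
// edges: (E,2) 0-based columns; alt: (E,2) alternative letters (a2, b2).
// independent = true runs one chain per output row (random init, burn-in
// sweeps each); false runs a single thinned chain after burn-in.
// Returns (K, L) sampled states 0..19.
// [[Rcpp::export]]
arma::imat gibbsMsaCpp(const arma::ivec& target, const arma::imat& edges,
                       const arma::imat& alt, double J,
                       const arma::mat& field, int K, int burnin, int thin,
                       int seed, bool independent) {
  const int L = target.n_elem, E = edges.n_rows;
  std::vector<std::vector<int>> colEdges(L);
  for (int e = 0; e < E; ++e) {
    colEdges[edges(e, 0)].push_back(e);
    colEdges[edges(e, 1)].push_back(e);
  }
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> rstate(0, 19);
  arma::imat out(K, L);
  arma::vec energy(20), prob(20);

  auto sweepOnce = [&](arma::ivec& s) {
    for (int i = 0; i < L; ++i) {
      energy = field.row(i).t();
      for (int e : colEdges[i]) {
        int a1, b1o, a2, b2o, other;
        if (edges(e, 0) == i) {
          other = edges(e, 1);
          a1 = target(i); b1o = target(other);
          a2 = alt(e, 0); b2o = alt(e, 1);
        } else {
          other = edges(e, 0);
          a1 = target(i); b1o = target(other);
          a2 = alt(e, 1); b2o = alt(e, 0);
        }
        if (s(other) == b1o) energy(a1) += J;
        if (s(other) == b2o) energy(a2) += J;
      }
      double mx = energy.max();
      prob = arma::exp(energy - mx);
      prob /= arma::accu(prob);
      double u = unif(rng), acc = 0.0;
      int pick = 19;
      for (int a = 0; a < 20; ++a) {
        acc += prob(a);
        if (u <= acc) { pick = a; break; }
      }
      s(i) = pick;
    }
  };

  if (independent) {
    for (int k = 0; k < K; ++k) {
      arma::ivec s(L);
      for (int i = 0; i < L; ++i) s(i) = rstate(rng);
      for (int sweep = 0; sweep < burnin; ++sweep) sweepOnce(s);
      out.row(k) = s.t();
    }
  } else {
    arma::ivec s = target;
    int nsweeps = burnin + (K - 1) * thin + 1;
    int taken = 0, next = burnin;
    for (int sweep = 0; sweep < nsweeps; ++sweep) {
      sweepOnce(s);
      if (sweep == next && taken < K) {
        out.row(taken) = s.t();
        ++taken;
        next += thin;
      }
    }
  }
  return out;
}
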