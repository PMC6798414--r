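// Exhaustive minimum-error-margin corner search over exemplar subsets.
//
// The simplex-constrained least-squares projection (Gram form) is solved
// exactly by support enumeration of the KKT system (J <= 6).  A support's
// equality-constrained solution is accepted as the optimum when it is
// primal feasible (w >= 0) and dual feasible (KKT multipliers of the
// excluded coordinates >= 0); for convex QPs this certificate is exact.
// KKT inverses are cached per (subset, support) and reused across all
// projected points, and a subset's margin accumulation stops early once it
// exceeds the best margin found so far.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct SubsetSolver {
  const mat& G;          // full Gram matrix (corners x corners basis)
  uvec S;                // corner indices of this subset
  mat GSS;               // k x k Gram of the subset
  std::vector<mat> inv_; // cached KKT inverses, indexed by support bitmask
  std::vector<char> ready_;

  SubsetSolver(const mat& Gfull, const uvec& subset)
      : G(Gfull), S(subset), GSS(Gfull.submat(subset, subset)),
        inv_(1u << subset.n_elem), ready_(1u << subset.n_elem, 0) {}

  const mat& kktInverse(uword bits) {
    if (!ready_[bits]) {
      uword k = GSS.n_rows, ks = 0;
      uvec idx(k);
      for (uword j = 0; j < k; ++j) if (bits & (1u << j)) idx[ks++] = j;
      idx.resize(ks);
      mat M(ks + 1, ks + 1, fill::zeros);
      M.submat(0, 0, ks - 1, ks - 1) = 2.0 * GSS.submat(idx, idx);
      M.col(ks).head(ks).ones();
      M.row(ks).head(ks).ones();
      mat Minv;
      if (!inv(Minv, M)) Minv = pinv(M);
      inv_[bits] = Minv;
      ready_[bits] = 1;
    }
    return inv_[bits];
  }

  // squared projection residual of the point with corner inner products cx
  // and squared norm xn2; optionally writes the k weights
  double res2(const vec& cx, double xn2, vec* wOut) {
    const uword k = GSS.n_rows;
    const uword full = (1u << k) - 1u;
    double bestRes = datum::inf;
    vec bestW;
    bool haveBest = false;
    // supports ordered by decreasing size, full support first
    for (uword size = k; size >= 1; --size) {
      for (uword bits = 1; bits <= full; ++bits) {
        if (static_cast<uword>(__builtin_popcount(bits)) != size) continue;
        uvec idx(size);
        uword c = 0;
        for (uword j = 0; j < k; ++j) if (bits & (1u << j)) idx[c++] = j;
        const mat& Minv = kktInverse(bits);
        vec rhs(size + 1);
        rhs.head(size) = 2.0 * cx.elem(idx);
        rhs[size] = 1.0;
        vec sol = Minv * rhs;
        vec w = sol.head(size);
        if (w.min() < -1e-9) continue;
        double lambda = sol[size];
        double r2 = xn2 - 2.0 * dot(cx.elem(idx), w) +
                    dot(w, GSS.submat(idx, idx) * w);
        if (r2 < 0) r2 = 0;
        // dual feasibility of the excluded coordinates certifies optimality
        vec wFull = zeroPad(w, idx, k);
        bool dualOk = true;
        for (uword j = 0; j < k && dualOk; ++j) {
          if (bits & (1u << j)) continue;
          double gj = 2.0 * dot(GSS.row(j), wFull) - 2.0 * cx[j] + lambda;
          if (gj < -1e-8) dualOk = false;
        }
        if (dualOk) {
          if (wOut) *wOut = wFull;
          return r2;
        }
        if (r2 < bestRes) {
          bestRes = r2;
          haveBest = true;
          if (wOut) bestW = wFull;
        }
      }
      if (size == 1) break;
    }
    // no certificate (numerically degenerate corners): min feasible residual
    if (!haveBest) bestRes = xn2;  // unreachable for valid inputs
    if (wOut) *wOut = haveBest ? bestW : zeros<vec>(k);
    return bestRes;
  }

  static vec zeroPad(const vec& w, const uvec& idx, uword k) {
    vec out = zeros<vec>(k);
    out.elem(idx) = w;
    return out;
  }
};

}  // namespace

// [[Rcpp::export(name = ".cppSelectCorners")]]
Rcpp::List cppSelectCorners(const arma::mat& G, int J) {
  const uword M = G.n_rows;
  const uword Ju = static_cast<uword>(J);
  vec xn2 = G.diag();
  uvec comb(Ju);
  for (uword j = 0; j < Ju; ++j) comb[j] = j;
  double best = datum::inf;
  uvec bestS = comb;
  // margin-descending evaluation order front-loads large residuals so the
  // running-sum prune triggers early; refreshed whenever the best improves
  uvec order = regspace<uvec>(0, M - 1);
  while (true) {
    SubsetSolver solver(G, comb);
    double total = 0.0;
    vec deltas(M, fill::zeros);
    bool pruned = false;
    for (uword oi = 0; oi < M; ++oi) {
      uword m = order[oi];
      vec cx = G.submat(comb, uvec{m});
      double r2 = solver.res2(cx, xn2[m], nullptr);
      deltas[m] = r2 > 0 ? std::sqrt(r2) : 0.0;
      total += deltas[m];
      if (total >= best) { pruned = true; break; }
    }
    if (!pruned && total < best - 1e-12) {
      best = total;
      bestS = comb;
      order = sort_index(deltas, "descend");
    }
    // next lexicographic combination
    sword i = Ju - 1;
    while (i >= 0 && comb[i] == M - Ju + i) --i;
    if (i < 0) break;
    ++comb[i];
    for (uword j = i + 1; j < Ju; ++j) comb[j] = comb[j - 1] + 1;
  }
  return Rcpp::List::create(
      Rcpp::Named("cornerIds") = Rcpp::IntegerVector(bestS.begin(), bestS.end()),
      Rcpp::Named("marginTotal") = best);
}

// [[Rcpp::export(name = ".cppSimplexProject")]]
Rcpp::List cppSimplexProject(const arma::mat& A, const arma::mat& X) {
  // A: J x T corners, X: N x T points; returns K (N x J) and delta (N)
  const uword J = A.n_rows, N = X.n_rows;
  mat G = A * A.t();
  mat CX = A * X.t();             // J x N
  vec xn2 = sum(square(X), 1);
  uvec all = regspace<uvec>(0, J - 1);
  SubsetSolver solver(G, all);
  mat K(N, J);
  vec delta(N);
  for (uword i = 0; i < N; ++i) {
    vec w;
    double r2 = solver.res2(CX.col(i), xn2[i], &w);
    w.transform([](double v) { return v < 0 ? 0.0 : v; });
    w /= accu(w);
    K.row(i) = w.t();
    delta[i] = r2 > 0 ? std::sqrt(r2) : 0.0;
  }
  return Rcpp::List::create(Rcpp::Named("K") = K,
                            Rcpp::Named("delta") = delta);
}
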