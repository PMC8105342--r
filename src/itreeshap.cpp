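#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact interventional Shapley values for a tree ensemble, in the margin
// (log-odds) space of the ensemble.
//
// For one explicand x, one background row r and one tree, the restricted game
// v(S) = tree(x_S, r_{-S}) is a sum over leaves of
//   w_L * 1{A_L subset of S} * 1{B_L disjoint from S}
// where A_L are the path features whose constraint is met by x but not r
// (they must be "switched on") and B_L those met by r but not x. The Shapley
// value of such a unanimity-style game is closed-form:
//   j in A: +w_L (|A|-1)! |B|! / (|A|+|B|)!
//   j in B: -w_L |A|! (|B|-1)! / (|A|+|B|)!
// and 0 for all other features. Averaging over background rows and summing
// over trees gives the interventional Shapley value of the ensemble; the
// ensemble's constant offset cancels. Feature constraints are pre-collapsed
// per leaf to one interval [lo, hi) per distinct feature, so |A| + |B| is at
// most the number of distinct features on the path.
//
// trees: list of lists with elements
//   leaf_value : numeric, one entry per leaf
//   cons_start : integer, length n_leaves + 1, 0-based offsets into the
//                constraint arrays (constraints of leaf l occupy
//                [cons_start[l], cons_start[l+1]))
//   cons_feat  : integer, 0-based feature column
//   cons_lo, cons_hi : numeric interval; satisfied iff lo <= v < hi
//                (comparison in float, matching the ensemble's own splits)
// [[Rcpp::export]]
NumericMatrix interventional_shap_cpp(List trees, NumericMatrix X,
                                      NumericMatrix bg) {
  int n = X.nrow(), d = X.ncol(), nb = bg.nrow(), nt = trees.size();
  if (bg.ncol() != d) stop("background column count must match X");
  if (nb < 1) stop("background must contain at least one row");

  // factorials up to the deepest possible path (collapsed constraints)
  std::vector<double> fact(171);
  fact[0] = 1.0;
  for (int i = 1; i <= 170; ++i) fact[i] = fact[i - 1] * (double)i;

  // unpack trees once
  int T = nt;
  std::vector<NumericVector> leaf_value(T);
  std::vector<IntegerVector> cons_start(T), cons_feat(T);
  std::vector<NumericVector> cons_lo(T), cons_hi(T);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    leaf_value[t] = tr["leaf_value"];
    cons_start[t] = tr["cons_start"];
    cons_feat[t] = tr["cons_feat"];
    cons_lo[t] = tr["cons_lo"];
    cons_hi[t] = tr["cons_hi"];
  }

  NumericMatrix phi(n, d);
  std::vector<int> A(256), B(256);

  for (int i = 0; i < n; ++i) {
    for (int r = 0; r < nb; ++r) {
      for (int t = 0; t < T; ++t) {
        const NumericVector &lv = leaf_value[t];
        const IntegerVector &cs = cons_start[t];
        const IntegerVector &cf = cons_feat[t];
        const NumericVector &lo = cons_lo[t];
        const NumericVector &hi = cons_hi[t];
        int nl = lv.size();
        for (int l = 0; l < nl; ++l) {
          int from = cs[l], to = cs[l + 1];
          int na = 0, nbf = 0;
          bool dead = false;
          for (int c = from; c < to; ++c) {
            int f = cf[c];
            float xv = (float)X(i, f), rv = (float)bg(r, f);
            float flo = (float)lo[c], fhi = (float)hi[c];
            bool sx = (xv >= flo) && (xv < fhi);
            bool sr = (rv >= flo) && (rv < fhi);
            if (sx && sr) continue;
            if (!sx && !sr) { dead = true; break; }
            if (sx) A[na++] = f; else B[nbf++] = f;
          }
          if (dead) continue;
          int m = na + nbf;
          if (m == 0) continue;  // leaf reached by every coalition: constant
          double w = lv[l];
          if (na > 0) {
            double cA = w * fact[na - 1] * fact[nbf] / fact[m];
            for (int k = 0; k < na; ++k) phi(i, A[k]) += cA;
          }
          if (nbf > 0) {
            double cB = w * fact[na] * fact[nbf - 1] / fact[m];
            for (int k = 0; k < nbf; ++k) phi(i, B[k]) -= cB;
          }
        }
      }
    }
  }
  double inv = 1.0 / (double)nb;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) phi(i, j) *= inv;
  return phi;
}

// Double-precision margin of the parsed ensemble (leaf sums, no constant),
// used for high-precision local-accuracy anchoring.
// [[Rcpp::export]]
NumericVector tree_margin_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    NumericVector lv = tr["leaf_value"];
    IntegerVector cs = tr["cons_start"];
    IntegerVector cf = tr["cons_feat"];
    NumericVector lo = tr["cons_lo"];
    NumericVector hi = tr["cons_hi"];
    int nl = lv.size();
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < nl; ++l) {
        bool ok = true;
        for (int c = cs[l]; c < cs[l + 1]; ++c) {
          float xv = (float)X(i, cf[c]);
          if (!((xv >= (float)lo[c]) && (xv < (float)hi[c]))) { ok = false; break; }
        }
        if (ok) { out[i] += lv[l]; break; }  // leaves partition the space
      }
    }
  }
  return out;
}
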