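#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Count unordered pairs (i, j) with |a_i - a_j| <= t, a sorted ascending.
static double count_diff_le(const std::vector<int>& a, int t) {
  double cnt = 0.0;
  std::size_t lo = 0;
  for (std::size_t hi = 0; hi < a.size(); ++hi) {
    while (a[hi] - a[lo] > t) ++lo;
    cnt += static_cast<double>(hi - lo);
  }
  return cnt;
}

static inline int sgn(double x) { return (x > 0) - (x < 0); }

// FF-vs-FFPE gene-pair ordering consistency for one paired sample.
//
// ff, ffpe: expression vectors over an identical gene list.
// r2: twice the ascending midranks of the FF sample (integers; midranks are
//     multiples of 1/2, so doubling makes rank differences exact integers).
// m_exclude: number of pairs with the smallest FF rank difference to drop,
//     ties at the cut broken by lexicographic gene-ID pair.
// A pair is consistent iff sign(expr_i - expr_j) is equal and nonzero in both
// samples; pairs tied in either sample count toward neither k nor n.
// [[Rcpp::export]]
List cpp_pair_consistency(NumericVector ff, NumericVector ffpe,
                          IntegerVector r2, double m_exclude,
                          CharacterVector genes) {
  const int n = ff.size();
  if (ffpe.size() != n || r2.size() != n || genes.size() != n)
    stop("ff, ffpe, ranks and gene ids must have equal length");
  if (n < 2) stop("need at least 2 genes");

  int t2 = -1;          // rank-difference value at the exclusion cut
  double below = 0.0;   // pairs strictly below the cut
  double need_tied = 0; // pairs at the cut still to exclude
  if (m_exclude > 0) {
    std::vector<int> sorted(r2.begin(), r2.end());
    std::sort(sorted.begin(), sorted.end());
    int lo = 0, hi = 2 * (n - 1);
    while (lo < hi) { // smallest t with count_le(t) >= m_exclude
      int mid = lo + (hi - lo) / 2;
      if (count_diff_le(sorted, mid) >= m_exclude) hi = mid; else lo = mid + 1;
    }
    t2 = lo;
    below = (t2 > 0) ? count_diff_le(sorted, t2 - 1) : 0.0;
    need_tied = m_exclude - below;
  }

  double n_eval = 0, k_cons = 0, n_tied = 0, n_excl = below;
  std::vector<int> cut_i, cut_j;

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = r2[i] - r2[j];
      if (d < 0) d = -d;
      if (m_exclude > 0 && d < t2) continue;
      if (m_exclude > 0 && d == t2) {
        cut_i.push_back(i);
        cut_j.push_back(j);
        continue;
      }
      int sf = sgn(ff[i] - ff[j]), sp = sgn(ffpe[i] - ffpe[j]);
      if (sf == 0 || sp == 0) { n_tied += 1; continue; }
      n_eval += 1;
      if (sf == sp) k_cons += 1;
    }
  }

  if (!cut_i.empty()) {
    // lexicographic order on the (sorted) gene-ID pair decides which
    // equal-rank-difference pairs fall inside the exclusion set
    const int np = cut_i.size();
    std::vector<int> ord(np);
    for (int p = 0; p < np; ++p) ord[p] = p;
    std::vector<std::string> key_a(np), key_b(np);
    for (int p = 0; p < np; ++p) {
      std::string a = as<std::string>(genes[cut_i[p]]);
      std::string b = as<std::string>(genes[cut_j[p]]);
      if (b < a) std::swap(a, b);
      key_a[p] = a; key_b[p] = b;
    }
    std::sort(ord.begin(), ord.end(), [&](int x, int y) {
      if (key_a[x] != key_a[y]) return key_a[x] < key_a[y];
      return key_b[x] < key_b[y];
    });
    for (int p = 0; p < np; ++p) {
      if (p < need_tied) { n_excl += 1; continue; }
      int i = cut_i[ord[p]], j = cut_j[ord[p]];
      int sf = sgn(ff[i] - ff[j]), sp = sgn(ffpe[i] - ffpe[j]);
      if (sf == 0 || sp == 0) { n_tied += 1; continue; }
      n_eval += 1;
      if (sf == sp) k_cons += 1;
    }
  }

  return List::create(_["n_evaluated"] = n_eval, _["k_consistent"] = k_cons,
                      _["n_tied"] = n_tied, _["n_excluded"] = n_excl);
}

// Gene pairs whose ordering direction holds in >= threshold fraction of the
// cohort (ties count toward neither direction; denominator is cohort size).
// X: genes x samples. Returns 1-based index pairs with per-direction counts.
// [[Rcpp::export]]
List cpp_stable_pairs(NumericMatrix X, double threshold) {
  const int n = X.nrow(), s = X.ncol();
  std::vector<int> ia, ja, ngt, nlt;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int gt = 0, lt = 0;
      for (int c = 0; c < s; ++c) {
        double d = X(i, c) - X(j, c);
        if (d > 0) ++gt; else if (d < 0) ++lt;
      }
      int mx = gt > lt ? gt : lt;
      if (static_cast<double>(mx) / s >= threshold) {
        ia.push_back(i + 1); ja.push_back(j + 1);
        ngt.push_back(gt); nlt.push_back(lt);
      }
    }
  }
  return List::create(_["i"] = wrap(ia), _["j"] = wrap(ja),
                      _["n_gt"] = wrap(ngt), _["n_lt"] = wrap(nlt));
}

// Reversal gene pairs between two phenotype classes: one direction holds
// strictly in > threshold fraction of class-0 samples and the opposite
// direction in > threshold fraction of class-1 samples.
// [[Rcpp::export]]
List cpp_reversal_pairs(NumericMatrix X0, NumericMatrix X1, double threshold) {
  if (X0.nrow() != X1.nrow()) stop("class matrices must share the gene list");
  const int n = X0.nrow(), s0 = X0.ncol(), s1 = X1.ncol();
  std::vector<int> ia, ja, n0gt, n0lt, n1gt, n1lt;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int gt0 = 0, lt0 = 0, gt1 = 0, lt1 = 0;
      for (int c = 0; c < s0; ++c) {
        double d = X0(i, c) - X0(j, c);
        if (d > 0) ++gt0; else if (d < 0) ++lt0;
      }
      for (int c = 0; c < s1; ++c) {
        double d = X1(i, c) - X1(j, c);
        if (d > 0) ++gt1; else if (d < 0) ++lt1;
      }
      double f0gt = static_cast<double>(gt0) / s0;
      double f0lt = static_cast<double>(lt0) / s0;
      double f1gt = static_cast<double>(gt1) / s1;
      double f1lt = static_cast<double>(lt1) / s1;
      bool fwd = f0gt > threshold && f1lt > threshold;
      bool rev = f0lt > threshold && f1gt > threshold;
      if (fwd || rev) {
        ia.push_back(i + 1); ja.push_back(j + 1);
        n0gt.push_back(gt0); n0lt.push_back(lt0);
        n1gt.push_back(gt1); n1lt.push_back(lt1);
      }
    }
  }
  return List::create(_["i"] = wrap(ia), _["j"] = wrap(ja),
                      _["n0_gt"] = wrap(n0gt), _["n0_lt"] = wrap(n0lt),
                      _["n1_gt"] = wrap(n1gt), _["n1_lt"] = wrap(n1lt));
}
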