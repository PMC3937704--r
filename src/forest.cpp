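// Regression random forest with per-tree out-of-bag permutation importance.
//
// Each tree is grown on one bootstrap sample (n draws with replacement) by
// CART variance-reduction splitting; mtry candidate predictors are drawn
// without replacement at every node; nodes with more than `min_node` cases
// and non-zero response variance are split. The ~1/3 of cases outside a
// tree's bootstrap sample (its OOB set) are that tree's test set: raw
// permutation importance of predictor v is the mean over trees of
// [OOB MSE with v's OOB values permuted  -  OOB MSE baseline], one fresh
// permutation per tree and per variable.
//
// Growing uses presorted index arrays: each feature is argsorted once per
// forest; per tree the bootstrap multiset is emitted in feature order, and
// every split stable-partitions all feature arrays, so no sorting happens
// inside nodes.
//
// The RNG is a seeded xorshift64* (splitmix64-scrambled), so results are
// bit-reproducible for a given (inputs, seed) independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
#include <cstdint>
using namespace Rcpp;

namespace {

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) {
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x2545F4914F6CDD1DULL;
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // deterministic integer in [0, n); modulo bias is irrelevant here
  int unifInt(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Forest {
  std::vector<int> var;      // split variable, -1 for leaf
  std::vector<double> split; // split threshold (x <= split goes left)
  std::vector<int> left, right;
  std::vector<double> pred;  // leaf prediction (node mean)
  std::vector<int> offset;   // node offset of each tree; length ntree + 1
};

struct NodeJob {
  int id;         // node index relative to tree base
  int start, end; // range in the per-feature sorted sample arrays
};

inline double predictRow(const Forest& f, int base, const double* X, int n,
                         int row, int permVar, int permRow) {
  int nd = base;
  while (f.var[nd] >= 0) {
    int v = f.var[nd];
    int src = (v == permVar) ? permRow : row;
    double x = X[static_cast<size_t>(v) * n + src];
    nd = base + ((x <= f.split[nd]) ? f.left[nd] : f.right[nd]);
  }
  return f.pred[nd];
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix Xr, NumericVector yr, int ntree, int mtry,
                int min_node, double seed, bool importance,
                bool keep_inbag, bool keep_perms) {
  const int n = Xr.nrow(), p = Xr.ncol();
  if (n < 2) stop("need at least 2 observations");
  if (ntree < 1) stop("ntree must be >= 1");
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  if (min_node < 1) min_node = 1;
  const double* X = Xr.begin();
  const double* y = yr.begin();
  const size_t np = static_cast<size_t>(n) * p;

  // forest-level argsort of every feature (ties by row index: stable)
  std::vector<int> fullSorted(np);
  for (int f = 0; f < p; ++f) {
    int* a = fullSorted.data() + static_cast<size_t>(f) * n;
    std::iota(a, a + n, 0);
    const double* xv = X + static_cast<size_t>(f) * n;
    std::stable_sort(a, a + n, [xv](int i, int j) { return xv[i] < xv[j]; });
  }

  Forest f;
  f.offset.reserve(ntree + 1);
  f.offset.push_back(0);

  std::vector<double> oobSum(n, 0.0);
  std::vector<int> oobCnt(n, 0);
  std::vector<double> impAcc(p, 0.0), impSq(p, 0.0);
  IntegerMatrix inbagOut;
  if (keep_inbag) inbagOut = IntegerMatrix(n, ntree);
  List permsOut(keep_perms ? ntree : 0);

  std::vector<int> inbag(n), feat(p), oobIdx, permIdx;
  std::vector<int> sorted(np);   // bootstrap multiset, sorted per feature
  std::vector<int> bufL(n), bufR(n);
  std::vector<double> treePred;
  std::vector<NodeJob> stack;
  std::vector<char> used(p);

  for (int t = 0; t < ntree; ++t) {
    XRng rng(static_cast<uint64_t>(seed) * 0x100000001b3ULL +
             static_cast<uint64_t>(t) * 0x9e3779b9ULL + 17ULL);

    // bootstrap sample (multiset of row indices)
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) inbag[rng.unifInt(n)]++;
    if (keep_inbag)
      for (int i = 0; i < n; ++i) inbagOut(i, t) = inbag[i];

    // emit the multiset in each feature's sort order (no per-node sorts)
    for (int fi = 0; fi < p; ++fi) {
      const int* a = fullSorted.data() + static_cast<size_t>(fi) * n;
      int* s = sorted.data() + static_cast<size_t>(fi) * n;
      int pos = 0;
      for (int i = 0; i < n; ++i) {
        const int r = a[i];
        for (int c = inbag[r]; c > 0; --c) s[pos++] = r;
      }
    }

    const int base = f.offset[t];
    std::fill(used.begin(), used.end(), 0);

    // root
    f.var.push_back(-1); f.split.push_back(0.0);
    f.left.push_back(-1); f.right.push_back(-1); f.pred.push_back(0.0);
    stack.clear();
    stack.push_back(NodeJob{0, 0, n});

    while (!stack.empty()) {
      NodeJob job = stack.back();
      stack.pop_back();
      const int ns = job.end - job.start;
      const int* memb = sorted.data() + job.start; // feature-0 view of node
      double sum = 0.0, sumsq = 0.0;
      for (int i = 0; i < ns; ++i) {
        const double v = y[memb[i]];
        sum += v;
        sumsq += v * v;
      }
      f.pred[base + job.id] = sum / ns;
      const double nodeSS = sumsq - sum * sum / ns;
      if (ns <= min_node || nodeSS <= 1e-12) continue; // leaf

      // draw mtry candidate features without replacement
      for (int j = 0; j < p; ++j) feat[j] = j;
      int bestVar = -1;
      double bestGain = sum * sum / ns, bestThr = 0.0;
      for (int m = 0; m < mtry; ++m) {
        const int pick = m + rng.unifInt(p - m);
        std::swap(feat[m], feat[pick]);
        const int v = feat[m];
        const double* xv = X + static_cast<size_t>(v) * n;
        const int* a = sorted.data() + static_cast<size_t>(v) * n + job.start;
        double cum = 0.0;
        for (int i = 0; i < ns - 1; ++i) {
          cum += y[a[i]];
          if (xv[a[i + 1]] > xv[a[i]]) {
            const int nl = i + 1, nr = ns - nl;
            const double rest = sum - cum;
            const double gain = cum * cum / nl + rest * rest / nr;
            if (gain > bestGain + 1e-12) {
              bestGain = gain;
              bestVar = v;
              bestThr = 0.5 * (xv[a[i]] + xv[a[i + 1]]);
            }
          }
        }
      }
      if (bestVar < 0) continue; // none of the candidates splits the node

      // stable-partition every feature's segment by the chosen split so
      // each side stays sorted in every feature
      const double* xs = X + static_cast<size_t>(bestVar) * n;
      const double thr = bestThr;
      int nl = 0;
      for (int fi = 0; fi < p; ++fi) {
        int* s = sorted.data() + static_cast<size_t>(fi) * n;
        int cl = 0, cr = 0;
        for (int i = job.start; i < job.end; ++i) {
          const int r = s[i];
          if (xs[r] <= thr) bufL[cl++] = r; else bufR[cr++] = r;
        }
        std::copy(bufL.begin(), bufL.begin() + cl, s + job.start);
        std::copy(bufR.begin(), bufR.begin() + cr, s + job.start + cl);
        nl = cl;
      }
      used[bestVar] = 1;
      const int lid = static_cast<int>(f.var.size()) - base;
      const int rid = lid + 1;
      for (int k = 0; k < 2; ++k) {
        f.var.push_back(-1); f.split.push_back(0.0);
        f.left.push_back(-1); f.right.push_back(-1); f.pred.push_back(0.0);
      }
      f.var[base + job.id] = bestVar;
      f.split[base + job.id] = thr;
      f.left[base + job.id] = lid;
      f.right[base + job.id] = rid;
      stack.push_back(NodeJob{lid, job.start, job.start + nl});
      stack.push_back(NodeJob{rid, job.start + nl, job.end});
    }
    f.offset.push_back(static_cast<int>(f.var.size()));

    // OOB predictions + permutation importance for this tree
    oobIdx.clear();
    for (int i = 0; i < n; ++i)
      if (inbag[i] == 0) oobIdx.push_back(i);
    const int no = static_cast<int>(oobIdx.size());
    if (no == 0) {
      if (keep_perms) permsOut[t] = List(0);
      continue;
    }
    treePred.resize(no);
    double mseBase = 0.0;
    for (int j = 0; j < no; ++j) {
      treePred[j] = predictRow(f, base, X, n, oobIdx[j], -1, -1);
      oobSum[oobIdx[j]] += treePred[j];
      oobCnt[oobIdx[j]]++;
      const double e = treePred[j] - y[oobIdx[j]];
      mseBase += e * e;
    }
    mseBase /= no;

    if (importance) {
      List treePerms(keep_perms ? p : 0);
      for (int v = 0; v < p; ++v) {
        if (!used[v]) {
          // permuting a variable absent from every split cannot change
          // predictions: contribution is exactly 0
          if (keep_perms) treePerms[v] = IntegerVector(0);
          continue;
        }
        permIdx = oobIdx;
        for (int j = no - 1; j > 0; --j) {
          const int k = rng.unifInt(j + 1);
          std::swap(permIdx[j], permIdx[k]);
        }
        double mseP = 0.0;
        for (int j = 0; j < no; ++j) {
          const double pr = predictRow(f, base, X, n, oobIdx[j], v,
                                       permIdx[j]);
          const double e = pr - y[oobIdx[j]];
          mseP += e * e;
        }
        mseP /= no;
        const double d = mseP - mseBase;
        impAcc[v] += d;
        impSq[v] += d * d;
        if (keep_perms) {
          IntegerVector pv(no);
          for (int j = 0; j < no; ++j) pv[j] = permIdx[j] + 1;
          treePerms[v] = pv;
        }
      }
      if (keep_perms) permsOut[t] = treePerms;
    }
  }

  NumericVector oobPred(n, NA_REAL);
  double oobMse = 0.0;
  int nOob = 0;
  for (int i = 0; i < n; ++i) {
    if (oobCnt[i] > 0) {
      oobPred[i] = oobSum[i] / oobCnt[i];
      const double e = oobPred[i] - y[i];
      oobMse += e * e;
      nOob++;
    }
  }
  oobMse = (nOob > 0) ? oobMse / nOob : NA_REAL;

  NumericVector impRaw(p, NA_REAL), impSd(p, NA_REAL);
  if (importance) {
    for (int v = 0; v < p; ++v) {
      impRaw[v] = impAcc[v] / ntree;
      const double varv = impSq[v] / ntree - impRaw[v] * impRaw[v];
      impSd[v] = varv > 0 ? std::sqrt(varv / ntree) : 0.0;
    }
  }

  List out = List::create(
      _["node_var"] = IntegerVector(f.var.begin(), f.var.end()),
      _["node_split"] = NumericVector(f.split.begin(), f.split.end()),
      _["node_left"] = IntegerVector(f.left.begin(), f.left.end()),
      _["node_right"] = IntegerVector(f.right.begin(), f.right.end()),
      _["node_pred"] = NumericVector(f.pred.begin(), f.pred.end()),
      _["tree_offset"] = IntegerVector(f.offset.begin(), f.offset.end()),
      _["oob_pred"] = oobPred,
      _["oob_mse"] = oobMse,
      _["importance_raw"] = impRaw,
      _["importance_sd"] = impSd);
  if (keep_inbag) out["inbag"] = inbagOut;
  if (keep_perms) out["perms"] = permsOut;
  return out;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix Xnew) {
  IntegerVector var = forest["node_var"];
  NumericVector split = forest["node_split"];
  IntegerVector left = forest["node_left"];
  IntegerVector right = forest["node_right"];
  NumericVector pred = forest["node_pred"];
  IntegerVector offset = forest["tree_offset"];
  const int ntree = offset.size() - 1;
  const int n = Xnew.nrow();
  NumericVector out(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = 0; t < ntree; ++t) {
      int nd = offset[t];
      while (var[nd] >= 0) {
        double x = Xnew(i, var[nd]);
        nd = offset[t] + ((x <= split[nd]) ? left[nd] : right[nd]);
      }
      acc += pred[nd];
    }
    out[i] = acc / ntree;
  }
  return out;
}
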