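// Random survival forest core: log-rank splitting, Nelson-Aalen leaves,
// ensemble-mortality prediction and permutation importance.
//
// All randomness flows through std::mt19937 seeded from R, with explicit
// Fisher-Yates shuffles / modulo draws so that results are reproducible for a
// given seed independent of the C++ standard library in use.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

// draw uniformly from {0, ..., n-1}; modulo bias is negligible for n << 2^32
inline int randBelow(std::mt19937& gen, int n) {
  return static_cast<int>(gen() % static_cast<unsigned int>(n));
}

// Harrell's concordance over comparable pairs: (i, j) with time_i < time_j
// and event_i = 1. Pairs tied on time are never comparable; tied risk scores
// earn 0.5 credit. Returns -1 when no comparable pair exists.
double harrellC(const std::vector<double>& time,
                const std::vector<int>& event,
                const std::vector<double>& risk) {
  const int n = static_cast<int>(time.size());
  double num = 0.0;
  long long den = 0;
  for (int i = 0; i < n; ++i) {
    if (!event[i]) continue;
    for (int j = 0; j < n; ++j) {
      if (time[i] < time[j]) {
        ++den;
        if (risk[i] > risk[j]) num += 1.0;
        else if (risk[i] == risk[j]) num += 0.5;
      }
    }
  }
  if (den == 0) return -1.0;
  return num / static_cast<double>(den);
}

// Two-group log-rank statistic (O-E)^2 / V with hypergeometric variance,
// summed over distinct event times. Returns 0 when V degenerates.
double logrankStat(const std::vector<double>& time,
                   const std::vector<int>& event,
                   const std::vector<int>& grp) {
  const int n = static_cast<int>(time.size());
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] < time[b]; });
  int atRisk = n, atRisk1 = 0;
  for (int i = 0; i < n; ++i) if (grp[i] == 1) ++atRisk1;
  double oe = 0.0, v = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    int d = 0, d1 = 0, nt = atRisk, nt1 = atRisk1;
    double t = time[ord[i]];
    while (j < n && time[ord[j]] == t) {
      int s = ord[j];
      if (event[s]) { ++d; if (grp[s] == 1) ++d1; }
      --atRisk;
      if (grp[s] == 1) --atRisk1;
      ++j;
    }
    if (d > 0 && nt > 0) {
      double p1 = static_cast<double>(nt1) / nt;
      oe += d1 - d * p1;
      if (nt > 1)
        v += d * p1 * (1.0 - p1) *
             (static_cast<double>(nt - d) / (nt - 1));
    }
    i = j;
  }
  if (v <= 0.0) return 0.0;
  return oe * oe / v;
}

struct Node {
  int var;      // -1 for leaf
  double thr;
  int left, right;
  int leafRow;  // row into the tree's CHF matrix, -1 for internal nodes
};

struct TreeBuilder {
  const NumericMatrix& X;     // samples x proteins
  const NumericVector& time;
  const IntegerVector& event;
  const std::vector<double>& grid;  // global distinct event times, sorted
  int mtry, minLeaf, minSplit;
  std::mt19937 gen;

  std::vector<Node> nodes;
  std::vector<std::vector<double>> leafCHF;
  std::vector<double> leafMort;

  TreeBuilder(const NumericMatrix& X_, const NumericVector& time_,
              const IntegerVector& event_, const std::vector<double>& grid_,
              int mtry_, int minLeaf_, int minSplit_, unsigned int seed)
      : X(X_), time(time_), event(event_), grid(grid_), mtry(mtry_),
        minLeaf(minLeaf_), minSplit(minSplit_), gen(seed) {}

  int makeLeaf(const std::vector<int>& idx) {
    // Nelson-Aalen over the node's (bootstrap) samples, evaluated on the
    // shared global event-time grid as a right-continuous step function.
    const int m = static_cast<int>(idx.size());
    std::vector<int> ord(idx);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return time[a] < time[b]; });
    std::vector<double> chf(grid.size(), 0.0);
    double H = 0.0;
    int atRisk = m, i = 0;
    size_t g = 0;
    while (i < m) {
      int j = i;
      double t = time[ord[i]];
      int d = 0;
      while (j < m && time[ord[j]] == t) {
        if (event[ord[j]]) ++d;
        ++j;
      }
      // grid points strictly before this time carry the hazard so far
      while (g < grid.size() && grid[g] < t) chf[g++] = H;
      if (d > 0) H += static_cast<double>(d) / atRisk;
      atRisk -= (j - i);
      i = j;
    }
    while (g < grid.size()) chf[g++] = H;
    double mort = 0.0;
    for (double h : chf) mort += h;
    leafCHF.push_back(std::move(chf));
    leafMort.push_back(mort);
    Node nd{-1, 0.0, -1, -1, static_cast<int>(leafCHF.size()) - 1};
    nodes.push_back(nd);
    return static_cast<int>(nodes.size()) - 1;
  }

  int build(std::vector<int>& idx) {
    const int m = static_cast<int>(idx.size());
    int nEvents = 0;
    for (int s : idx) if (event[s]) ++nEvents;
    if (m < minSplit || nEvents == 0) return makeLeaf(idx);

    // node-local event-time table
    std::vector<int> ord(idx);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return time[a] < time[b]; });
    std::vector<double> evTimes;  // distinct event times in node
    std::vector<int> dTot, nTot;  // events and at-risk at each
    {
      int atRisk = m, i = 0;
      while (i < m) {
        int j = i;
        double t = time[ord[i]];
        int d = 0;
        while (j < m && time[ord[j]] == t) {
          if (event[ord[j]]) ++d;
          ++j;
        }
        if (d > 0) {
          evTimes.push_back(t);
          dTot.push_back(d);
          nTot.push_back(atRisk);
        }
        atRisk -= (j - i);
        i = j;
      }
    }
    const int U = static_cast<int>(evTimes.size());
    // rank[i]: number of node event times <= time of sample idx[i]
    // erank[i]: index of the sample's own event time (events only), else -1
    std::vector<int> rank(m), erank(m, -1);
    for (int i = 0; i < m; ++i) {
      int s = idx[i];
      int r = static_cast<int>(std::upper_bound(evTimes.begin(), evTimes.end(),
                                                time[s]) - evTimes.begin());
      rank[i] = r;
      if (event[s]) {
        int e = static_cast<int>(std::lower_bound(evTimes.begin(), evTimes.end(),
                                                  time[s]) - evTimes.begin());
        if (e < U && evTimes[e] == time[s]) erank[i] = e;
      }
    }

    // sample mtry candidate proteins without replacement (Fisher-Yates),
    // then evaluate in ascending index order for deterministic tie-breaks
    const int p = X.ncol();
    std::vector<int> feat(p);
    for (int f = 0; f < p; ++f) feat[f] = f;
    const int k = std::min(mtry, p);
    for (int f = 0; f < k; ++f) {
      int swp = f + randBelow(gen, p - f);
      std::swap(feat[f], feat[swp]);
    }
    std::vector<int> cand(feat.begin(), feat.begin() + k);
    std::sort(cand.begin(), cand.end());

    double bestStat = 0.0, bestThr = 0.0;
    int bestVar = -1;

    std::vector<int> nodePos(m);
    for (int i = 0; i < m; ++i) nodePos[i] = i;
    std::vector<int> cnt(U), dL(U);

    for (int f : cand) {
      // order node positions by feature value
      std::sort(nodePos.begin(), nodePos.end(), [&](int a, int b) {
        double xa = X(idx[a], f), xb = X(idx[b], f);
        if (xa != xb) return xa < xb;
        return a < b;
      });
      if (X(idx[nodePos[0]], f) == X(idx[nodePos[m - 1]], f)) continue;
      std::fill(cnt.begin(), cnt.end(), 0);
      std::fill(dL.begin(), dL.end(), 0);
      int nLeft = 0;
      int i = 0;
      while (i < m) {
        double v = X(idx[nodePos[i]], f);
        int j = i;
        while (j < m && X(idx[nodePos[j]], f) == v) {
          int pos = nodePos[j];
          if (rank[pos] > 0) ++cnt[rank[pos] - 1];
          if (erank[pos] >= 0) ++dL[erank[pos]];
          ++nLeft;
          ++j;
        }
        if (j >= m) break;  // all remaining equal: no threshold here
        if (nLeft >= minLeaf && (m - nLeft) >= minLeaf) {
          // nL(t_u) = # left samples with rank > u = suffix sum of cnt
          double oe = 0.0, var = 0.0;
          int suffix = 0;
          for (int u = U - 1; u >= 0; --u) {
            suffix += cnt[u];
            // at-risk in left at event time u: left samples with time >= t_u,
            // i.e. rank >= u+1  -> suffix sums from u
            int nL = suffix;
            int nt = nTot[u], d = dTot[u];
            double p1 = static_cast<double>(nL) / nt;
            oe += dL[u] - d * p1;
            if (nt > 1)
              var += d * p1 * (1.0 - p1) *
                     (static_cast<double>(nt - d) / (nt - 1));
          }
          if (var > 0.0) {
            double stat = oe * oe / var;
            if (stat > bestStat) {
              bestStat = stat;
              bestVar = f;
              bestThr = (v + X(idx[nodePos[j]], f)) / 2.0;
            }
          }
        }
        i = j;
      }
    }

    if (bestVar < 0 || bestStat <= 0.0) return makeLeaf(idx);

    std::vector<int> leftIdx, rightIdx;
    leftIdx.reserve(m);
    rightIdx.reserve(m);
    for (int s : idx) {
      if (X(s, bestVar) <= bestThr) leftIdx.push_back(s);
      else rightIdx.push_back(s);
    }
    Node nd{bestVar, bestThr, -1, -1, -1};
    nodes.push_back(nd);
    int self = static_cast<int>(nodes.size()) - 1;
    int l = build(leftIdx);
    int r = build(rightIdx);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }
};

// route one sample (row of X) down a tree given flat node arrays
inline int routeLeaf(const IntegerVector& var, const NumericVector& thr,
                     const IntegerVector& left, const IntegerVector& right,
                     const NumericMatrix& X, int row) {
  int node = 0;
  while (var[node] >= 0) {
    node = (X(row, var[node]) <= thr[node]) ? left[node] : right[node];
  }
  return node;
}

// mortality per sample, averaged over trees; if inbag is supplied, only
// trees where the sample is out-of-bag contribute (NaN when none)
std::vector<double> forestMortality(const List& trees, const NumericMatrix& X,
                                    const IntegerMatrix* inbag) {
  const int n = X.nrow();
  const int T = trees.size();
  std::vector<double> acc(n, 0.0);
  std::vector<int> cntTrees(n, 0);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector var = tree["var"];
    NumericVector thr = tree["thr"];
    IntegerVector left = tree["left"];
    IntegerVector right = tree["right"];
    IntegerVector leafRow = tree["leafRow"];
    NumericVector mort = tree["leafMortality"];
    for (int i = 0; i < n; ++i) {
      if (inbag && (*inbag)(i, t) > 0) continue;
      int node = routeLeaf(var, thr, left, right, X, i);
      acc[i] += mort[leafRow[node]];
      ++cntTrees[i];
    }
  }
  for (int i = 0; i < n; ++i) {
    if (cntTrees[i] > 0) acc[i] /= cntTrees[i];
    else acc[i] = std::numeric_limits<double>::quiet_NaN();
  }
  return acc;
}

double concordanceDropNaN(const std::vector<double>& time,
                          const std::vector<int>& event,
                          const std::vector<double>& risk) {
  std::vector<double> t2, r2;
  std::vector<int> e2;
  for (size_t i = 0; i < risk.size(); ++i) {
    if (std::isnan(risk[i])) continue;
    t2.push_back(time[i]);
    e2.push_back(event[i]);
    r2.push_back(risk[i]);
  }
  return harrellC(t2, e2, r2);
}

}  // namespace

// [[Rcpp::export]]
double cppHarrellC(NumericVector time, IntegerVector event,
                   NumericVector risk) {
  std::vector<double> t(time.begin(), time.end());
  std::vector<int> e(event.begin(), event.end());
  std::vector<double> r(risk.begin(), risk.end());
  return harrellC(t, e, r);
}

// [[Rcpp::export]]
double cppLogrankStat(NumericVector time, IntegerVector event,
                      IntegerVector grp) {
  std::vector<double> t(time.begin(), time.end());
  std::vector<int> e(event.begin(), event.end());
  std::vector<int> g(grp.begin(), grp.end());
  return logrankStat(t, e, g);
}

// [[Rcpp::export]]
List cppFitRSF(NumericMatrix X, NumericVector time, IntegerVector event,
               int nTrees, int mtry, int minLeaf, int minSplit,
               unsigned int seed) {
  const int n = X.nrow();
  // global grid: distinct event times of the training data
  std::vector<double> grid;
  for (int i = 0; i < n; ++i) if (event[i]) grid.push_back(time[i]);
  std::sort(grid.begin(), grid.end());
  grid.erase(std::unique(grid.begin(), grid.end()), grid.end());

  List trees(nTrees);
  IntegerMatrix inbag(n, nTrees);
  for (int t = 0; t < nTrees; ++t) {
    TreeBuilder tb(X, time, event, grid, mtry, minLeaf, minSplit,
                   seed + static_cast<unsigned int>(t) * 2654435761u + 1u);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int s = randBelow(tb.gen, n);
      idx[i] = s;
      inbag(s, t) += 1;
    }
    tb.build(idx);
    const int nn = static_cast<int>(tb.nodes.size());
    IntegerVector var(nn), left(nn), right(nn), leafRow(nn);
    NumericVector thr(nn);
    for (int i = 0; i < nn; ++i) {
      var[i] = tb.nodes[i].var;
      thr[i] = tb.nodes[i].thr;
      left[i] = tb.nodes[i].left;
      right[i] = tb.nodes[i].right;
      leafRow[i] = tb.nodes[i].leafRow;
    }
    const int nl = static_cast<int>(tb.leafCHF.size());
    NumericMatrix chf(nl, static_cast<int>(grid.size()));
    NumericVector mort(nl);
    for (int l = 0; l < nl; ++l) {
      for (size_t g = 0; g < grid.size(); ++g) chf(l, g) = tb.leafCHF[l][g];
      mort[l] = tb.leafMort[l];
    }
    trees[t] = List::create(
        _["var"] = var, _["thr"] = thr, _["left"] = left, _["right"] = right,
        _["leafRow"] = leafRow, _["leafCHF"] = chf, _["leafMortality"] = mort);
  }
  return List::create(_["trees"] = trees,
                      _["grid"] = NumericVector(grid.begin(), grid.end()),
                      _["inbag"] = inbag);
}

// [[Rcpp::export]]
NumericVector cppPredictMortality(List trees, NumericMatrix X,
                                  Nullable<IntegerMatrix> inbag) {
  std::vector<double> out;
  if (inbag.isNotNull()) {
    IntegerMatrix ib(inbag);
    out = forestMortality(trees, X, &ib);
  } else {
    out = forestMortality(trees, X, nullptr);
  }
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
NumericMatrix cppPredictCHF(List trees, NumericMatrix X) {
  // ensemble cumulative hazard per sample over the shared grid
  const int n = X.nrow();
  const int T = trees.size();
  List tree0 = trees[0];
  NumericMatrix chf0 = tree0["leafCHF"];
  const int G = chf0.ncol();
  NumericMatrix out(n, G);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector var = tree["var"];
    NumericVector thr = tree["thr"];
    IntegerVector left = tree["left"];
    IntegerVector right = tree["right"];
    IntegerVector leafRow = tree["leafRow"];
    NumericMatrix chf = tree["leafCHF"];
    for (int i = 0; i < n; ++i) {
      int node = routeLeaf(var, thr, left, right, X, i);
      int lr = leafRow[node];
      for (int g = 0; g < G; ++g) out(i, g) += chf(lr, g);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < G; ++g) out(i, g) /= T;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cppPermImportance(List trees, NumericMatrix X,
                                NumericVector time, IntegerVector event,
                                int nRepeats, unsigned int seed,
                                Nullable<IntegerMatrix> inbag) {
  // importance(p, r) = C(original) - C(column p permuted), permutation r
  const int n = X.nrow();
  const int p = X.ncol();
  std::vector<double> tvec(time.begin(), time.end());
  std::vector<int> evec(event.begin(), event.end());

  IntegerMatrix ib;
  const IntegerMatrix* ibp = nullptr;
  if (inbag.isNotNull()) {
    ib = IntegerMatrix(inbag);
    ibp = &ib;
  }
  std::vector<double> base = forestMortality(trees, X, ibp);
  double c0 = concordanceDropNaN(tvec, evec, base);

  NumericMatrix imp(p, nRepeats);
  NumericMatrix Xp(clone(X));
  std::mt19937 gen(seed);
  std::vector<int> perm(n);
  std::vector<double> orig(n);
  for (int r = 0; r < nRepeats; ++r) {
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = randBelow(gen, i + 1);
      std::swap(perm[i], perm[j]);
    }
    for (int f = 0; f < p; ++f) {
      for (int i = 0; i < n; ++i) orig[i] = Xp(i, f);
      for (int i = 0; i < n; ++i) Xp(i, f) = orig[perm[i]];
      std::vector<double> risk = forestMortality(trees, Xp, ibp);
      double cp = concordanceDropNaN(tvec, evec, risk);
      imp(f, r) = c0 - cp;
      for (int i = 0; i < n; ++i) Xp(i, f) = orig[i];
    }
  }
  return imp;
}
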