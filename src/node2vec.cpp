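#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Self-contained splitmix64 RNG: bit-identical output on every platform,
// independent of R's RNG state (walk generation and SGNS training must be
// reproducible from a single integer seed).
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed + 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static inline bool is_neighbor(const IntegerVector& nbr, int lo, int hi, int x) {
  // binary search in nbr[lo, hi): neighbor lists are sorted per node
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (nbr[mid] == x) return true;
    if (nbr[mid] < x) lo = mid + 1; else hi = mid;
  }
  return false;
}

// Biased second-order random walks (node2vec). Graph in CSR form:
// offsets (n+1), neighbors (0-based, sorted per node), weights.
// Returns an (r * n) x l integer matrix, padded with -1 after walk end
// (isolated nodes yield length-1 walks).
// [[Rcpp::export(name = ".cpp_generate_walks")]]
IntegerMatrix cpp_generate_walks(IntegerVector offsets, IntegerVector neighbors,
                                 NumericVector weights, int n, int r, int l,
                                 double p, double q, double seed) {
  SplitMix rng((uint64_t)seed);
  IntegerMatrix walks(r * n, l);
  std::fill(walks.begin(), walks.end(), -1);
  std::vector<double> cum;
  int row = 0;
  for (int rep = 0; rep < r; ++rep) {
    for (int start = 0; start < n; ++start, ++row) {
      walks(row, 0) = start;
      int prev = -1, cur = start;
      for (int step = 1; step < l; ++step) {
        int lo = offsets[cur], hi = offsets[cur + 1];
        int deg = hi - lo;
        if (deg == 0) break;  // isolated or dead-end node
        cum.resize(deg);
        double tot = 0.0;
        for (int j = 0; j < deg; ++j) {
          int nxt = neighbors[lo + j];
          double w = weights[lo + j];
          if (prev >= 0) {
            if (nxt == prev) w /= p;
            else if (!is_neighbor(neighbors, offsets[prev], offsets[prev + 1], nxt)) w /= q;
            // nxt adjacent to prev: bias factor 1
          }
          tot += w;
          cum[j] = tot;
        }
        double u = rng.unif() * tot;
        int pick = 0;
        while (pick < deg - 1 && cum[pick] < u) ++pick;
        prev = cur;
        cur = neighbors[lo + pick];
        walks(row, step) = cur;
      }
    }
  }
  return walks;
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over a walk corpus.
// walks: (-1)-padded integer matrix of token ids in [0, V).
// Negative sampling from the unigram distribution raised to 3/4.
// Single-threaded; deterministic given `seed`.
// [[Rcpp::export(name = ".cpp_train_sgns")]]
NumericMatrix cpp_train_sgns(IntegerMatrix walks, int V, int d, int window,
                             int negatives, int epochs, double lr0, double seed) {
  SplitMix rng((uint64_t)seed);
  const int nw = walks.nrow(), l = walks.ncol();

  std::vector<double> counts(V, 0.0);
  long long T = 0;
  for (int i = 0; i < nw; ++i)
    for (int j = 0; j < l; ++j)
      if (walks(i, j) >= 0) { counts[walks(i, j)] += 1.0; ++T; }

  // cumulative table of counts^0.75 for negative sampling
  std::vector<double> negcum(V);
  double tot = 0.0;
  for (int v = 0; v < V; ++v) {
    tot += (counts[v] > 0 ? std::pow(counts[v], 0.75) : 0.0);
    negcum[v] = tot;
  }

  // init: in-vectors uniform(-0.5/d, 0.5/d), out-vectors zero (word2vec style)
  std::vector<double> syn0((size_t)V * d), syn1((size_t)V * d, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / d;

  std::vector<double> err(d);
  const double total_tokens = (double)T * epochs + 1.0;
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int wi = 0; wi < nw; ++wi) {
      for (int ci = 0; ci < l; ++ci) {
        int center = walks(wi, ci);
        if (center < 0) break;
        processed += 1.0;
        double lr = lr0 * std::max(1e-4, 1.0 - processed / total_tokens);
        int b = (int)(rng.unif() * window);  // reduced window, word2vec convention
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int cj = ci + off;
          if (cj < 0 || cj >= l) continue;
          int ctx = walks(wi, cj);
          if (ctx < 0) continue;
          double* vin = &syn0[(size_t)center * d];
          std::fill(err.begin(), err.end(), 0.0);
          for (int s = 0; s < negatives + 1; ++s) {
            int target; double label;
            if (s == 0) { target = ctx; label = 1.0; }
            else {
              // smallest index with negcum > u
              double u = rng.unif() * tot;
              int loN = 0, hiN = V - 1;
              while (loN < hiN) {
                int mid = (loN + hiN) / 2;
                if (negcum[mid] > u) hiN = mid; else loN = mid + 1;
              }
              target = loN;
              if (target == ctx) continue;
              label = 0.0;
            }
            double* vout = &syn1[(size_t)target * d];
            double f = 0.0;
            for (int k = 0; k < d; ++k) f += vin[k] * vout[k];
            double g = (label - sigmoid(f)) * lr;
            for (int k = 0; k < d; ++k) {
              err[k] += g * vout[k];
              vout[k] += g * vin[k];
            }
          }
          for (int k = 0; k < d; ++k) vin[k] += err[k];
        }
      }
    }
  }

  NumericMatrix out(V, d);
  for (int v = 0; v < V; ++v)
    for (int k = 0; k < d; ++k)
      out(v, k) = syn0[(size_t)v * d + k];
  return out;
}
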