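// Skip-gram with negative sampling over heterogeneous (typed) node corpora.
// Negatives for a (center, context) pair are drawn from the node type of the
// context node, from a per-type unigram^0.75 noise distribution. Single
// threaded and fully deterministic given the seed.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(unif() * n); }
};

// Per-type noise table: cumulative unigram^0.75 weights over the type's
// nodes; sampling is a binary search on a uniform draw.
struct NoiseTable {
  std::vector<int> nodes;     // 0-based node indices
  std::vector<double> cum;
  int draw(SplitMix64 &rng) const {
    if (nodes.empty()) return -1;
    double u = rng.unif() * cum.back();
    size_t lo = 0, hi = cum.size() - 1;
    while (lo < hi) {
      size_t mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return nodes[lo];
  }
};

std::vector<NoiseTable> make_noise_tables(const std::vector<double> &counts,
                                          const IntegerVector &type,
                                          int n_types) {
  std::vector<NoiseTable> tabs(n_types);
  for (int t = 0; t < n_types; ++t) {
    double acc = 0.0;
    for (size_t v = 0; v < counts.size(); ++v) {
      if (type[v] == t + 1 && counts[v] > 0) {
        acc += std::pow(counts[v], 0.75);
        tabs[t].nodes.push_back(static_cast<int>(v));
        tabs[t].cum.push_back(acc);
      }
    }
  }
  return tabs;
}

inline double sigmoidf(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, IntegerVector node_type, int n_nodes,
                         int dim, int window, int negatives, int epochs,
                         double alpha0, int min_count, double seed) {
  if (dim < 1 || window < 1) stop("dim and window must be >= 1");
  std::vector<double> counts(n_nodes, 0.0);
  long long total_tokens = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sent = sentences[s];
    for (int i = 0; i < sent.size(); ++i) {
      int v = sent[i] - 1;
      if (v < 0 || v >= n_nodes) stop("sentence token out of range");
      counts[v] += 1.0;
      ++total_tokens;
    }
  }
  int n_types = 0;
  for (int v = 0; v < n_nodes; ++v) n_types = std::max(n_types, node_type[v]);
  std::vector<NoiseTable> noise = make_noise_tables(counts, node_type, n_types);

  SplitMix64 rng(static_cast<uint64_t>(seed) * 0x9E3779B9ULL + 1ULL);
  std::vector<double> syn0(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> syn1(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (rng.unif() - 0.5) / dim;
  }

  const double min_alpha = alpha0 * 1e-4;
  long long processed = 0;
  const long long total = std::max<long long>(1, total_tokens * epochs);
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      int len = sent.size();
      for (int i = 0; i < len; ++i) {
        ++processed;
        int center = sent[i] - 1;
        if (counts[center] < min_count) continue;
        double alpha = alpha0 * (1.0 - static_cast<double>(processed) / total);
        if (alpha < min_alpha) alpha = min_alpha;
        int reduced = rng.below(window);  // word2vec dynamic window
        int span = window - reduced;
        for (int j = i - span; j <= i + span; ++j) {
          if (j < 0 || j >= len || j == i) continue;
          int context = sent[j] - 1;
          if (counts[context] < min_count) continue;
          double *vc = &syn0[static_cast<size_t>(center) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          int ctx_type = node_type[context] - 1;
          for (int neg = 0; neg <= negatives; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = context;
              label = 1.0;
            } else {
              target = -1;
              for (int tries = 0; tries < 100; ++tries) {
                int cand = noise[ctx_type].draw(rng);
                if (cand >= 0 && cand != context) { target = cand; break; }
              }
              if (target < 0) continue;  // type has no alternative node
              label = 0.0;
            }
            double *vt = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += vc[d] * vt[d];
            double g = (label - sigmoidf(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * vt[d];
              vt[d] += g * vc[d];
            }
          }
          for (int d = 0; d < dim; ++d) vc[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v) {
    for (int d = 0; d < dim; ++d) {
      out(v, d) = syn0[static_cast<size_t>(v) * dim + d];
    }
  }
  return out;
}

// Expose the type-aware noise sampler for instrumentation tests: draws `n`
// negatives for a context node and returns 1-based node indices.
// [[Rcpp::export(name = ".sgns_sample_negatives")]]
IntegerVector sgns_sample_negatives(NumericVector counts, IntegerVector node_type,
                                    int context, int n, double seed) {
  int n_nodes = counts.size();
  std::vector<double> cnt(counts.begin(), counts.end());
  int n_types = 0;
  for (int v = 0; v < n_nodes; ++v) n_types = std::max(n_types, node_type[v]);
  std::vector<NoiseTable> noise = make_noise_tables(cnt, node_type, n_types);
  SplitMix64 rng(static_cast<uint64_t>(seed) * 0x9E3779B9ULL + 1ULL);
  int ctx = context - 1;
  int ctx_type = node_type[ctx] - 1;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int target = -1;
    for (int tries = 0; tries < 100; ++tries) {
      int cand = noise[ctx_type].draw(rng);
      if (cand >= 0 && cand != ctx) { target = cand; break; }
    }
    out[i] = target + 1;
  }
  return out;
}
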