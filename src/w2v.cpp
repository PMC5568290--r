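// Skip-gram embedding training with hierarchical-softmax output and exact
// sentence log-likelihood scoring. Single-threaded with an internal
// xorshift64* RNG so that a seed fully determines the trained model.
//
// Conventions: syn0 is the |V| x d input-vector matrix, syn1 the
// (|V|-1) x d inner-node matrix of the Huffman tree. For a word w with
// root-to-leaf path (node_i, bit_i), P(w | v) = prod_i sigmoid((1-2*bit_i)
// * <syn1[node_i], v>). Training maximises sum over skip-gram pairs of
// log P(context | center), i.e. input = center vector, output path =
// context word.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline double log_sigmoid(double z) {
  // numerically stable log(1/(1+exp(-z)))
  if (z >= 0.0) return -std::log1p(std::exp(-z));
  return z - std::log1p(std::exp(z));
}

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  int next_int(int n) { return (int)(next() % (uint64_t)n); }
};

// [[Rcpp::export]]
List cpp_train_sg_hs(List sentences, NumericMatrix syn0_in,
                     NumericMatrix syn1_in, List codes, List points,
                     int epochs, int window, double alpha0, double alpha_min,
                     double seed, bool dynamic_window) {
  NumericMatrix syn0 = clone(syn0_in);
  NumericMatrix syn1 = clone(syn1_in);
  const int d = syn0.ncol();
  const int n_sent = sentences.size();

  // pre-extract sentence int vectors and path tables
  std::vector<IntegerVector> sents(n_sent);
  long long total_tokens = 0;
  for (int i = 0; i < n_sent; ++i) {
    sents[i] = sentences[i];
    total_tokens += sents[i].size();
  }
  const int V = syn0.nrow();
  std::vector<IntegerVector> code_v(V), point_v(V);
  for (int w = 0; w < V; ++w) {
    code_v[w] = codes[w];
    point_v[w] = points[w];
  }

  XorShift rng((uint64_t)seed);
  const double total_words =
      (double)total_tokens * (double)epochs + 1.0;
  double processed = 0.0;
  std::vector<double> neu1e(d);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int si = 0; si < n_sent; ++si) {
      const IntegerVector &sen = sents[si];
      const int len = sen.size();
      for (int t = 0; t < len; ++t) {
        double alpha = alpha0 * (1.0 - processed / total_words);
        if (alpha < alpha_min) alpha = alpha_min;
        processed += 1.0;
        const int center = sen[t];
        const int b = dynamic_window ? rng.next_int(window) : 0;
        const int span = window - b;
        for (int j = -span; j <= span; ++j) {
          if (j == 0) continue;
          const int ct = t + j;
          if (ct < 0 || ct >= len) continue;
          const int context = sen[ct];
          const IntegerVector &cd = code_v[context];
          const IntegerVector &pt = point_v[context];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int k = 0; k < cd.size(); ++k) {
            const int node = pt[k];  // 0-based row of syn1
            double x = 0.0;
            for (int c = 0; c < d; ++c) x += syn0(center, c) * syn1(node, c);
            const double f = 1.0 / (1.0 + std::exp(-x));
            const double g = (1.0 - (double)cd[k] - f) * alpha;
            for (int c = 0; c < d; ++c) {
              neu1e[c] += g * syn1(node, c);
              syn1(node, c) += g * syn0(center, c);
            }
          }
          for (int c = 0; c < d; ++c) syn0(center, c) += neu1e[c];
        }
      }
    }
  }
  return List::create(_["syn0"] = syn0, _["syn1"] = syn1,
                      _["trained_words"] = (double)total_tokens * epochs);
}

// Exact sentence log-likelihood: sum over ordered skip-gram pairs within
// the window of log P(context | center), each conditional the product of
// sigmoids along the context word's Huffman path. Returns c(ll, n_pairs).
// Tokens with id < 0 (out of vocabulary) are skipped.
// [[Rcpp::export]]
NumericVector cpp_sentence_loglik(IntegerVector sent, NumericMatrix syn0,
                                  NumericMatrix syn1, List codes, List points,
                                  int window) {
  const int d = syn0.ncol();
  const int V = syn0.nrow();
  std::vector<IntegerVector> code_v(V), point_v(V);
  std::vector<bool> seen(V, false);
  std::vector<int> ids;
  ids.reserve(sent.size());
  for (int i = 0; i < sent.size(); ++i)
    if (sent[i] >= 0) {
      ids.push_back(sent[i]);
      if (!seen[sent[i]]) {
        code_v[sent[i]] = codes[sent[i]];
        point_v[sent[i]] = points[sent[i]];
        seen[sent[i]] = true;
      }
    }
  const int len = (int)ids.size();
  double ll = 0.0;
  double n_pairs = 0.0;
  for (int t = 0; t < len; ++t) {
    const int center = ids[t];
    for (int j = -window; j <= window; ++j) {
      if (j == 0) continue;
      const int ct = t + j;
      if (ct < 0 || ct >= len) continue;
      const int context = ids[ct];
      const IntegerVector &cd = code_v[context];
      const IntegerVector &pt = point_v[context];
      for (int k = 0; k < cd.size(); ++k) {
        const int node = pt[k];
        double x = 0.0;
        for (int c = 0; c < d; ++c) x += syn0(center, c) * syn1(node, c);
        ll += log_sigmoid((1.0 - 2.0 * (double)cd[k]) * x);
      }
      n_pairs += 1.0;
    }
  }
  return NumericVector::create(ll, n_pairs);
}
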