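// Skip-gram with negative sampling over term token streams, with jointly
// trained document vectors (dbow style: the document vector predicts each of
// its tokens). Single-threaded with an internal xorshift RNG so a fixed seed
// reproduces the table exactly. The learning rate starts at alpha0 and is
// reduced by `decay` each epoch, floored at 1e-4.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// One (input row, output word) SGNS update with `negative` negative samples.
void train_pair(std::vector<double>& in, size_t in_off,
                std::vector<double>& out, int target, int dim, double alpha,
                int negative, const std::vector<double>& neg_cdf, XorShift& rng,
                std::vector<double>& grad) {
  std::fill(grad.begin(), grad.end(), 0.0);
  for (int k = 0; k <= negative; ++k) {
    int tgt; double label;
    if (k == 0) { tgt = target; label = 1.0; }
    else {
      double u = rng.unif();
      tgt = (int)(std::lower_bound(neg_cdf.begin(), neg_cdf.end(), u) -
                  neg_cdf.begin());
      if (tgt >= (int)neg_cdf.size()) tgt = (int)neg_cdf.size() - 1;
      if (tgt == target) continue;
      label = 0.0;
    }
    size_t out_off = (size_t)tgt * dim;
    double dot = 0.0;
    for (int d = 0; d < dim; ++d) dot += in[in_off + d] * out[out_off + d];
    double g = (label - sigmoid(dot)) * alpha;
    for (int d = 0; d < dim; ++d) {
      grad[d] += g * out[out_off + d];
      out[out_off + d] += g * in[in_off + d];
    }
  }
  for (int d = 0; d < dim; ++d) in[in_off + d] += grad[d];
}

}  // namespace

// docs: list of integer vectors, 0-based term indices per document.
// Returns list(term_vectors = V x dim, doc_vectors = D x dim).
// [[Rcpp::export(name = ".sgns_train")]]
List sgns_train(List docs, int n_terms, int dim, int window, int epochs,
                double alpha0, double decay, int negative, bool train_words,
                double seed) {
  int n_docs = docs.size();
  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);

  // unigram^0.75 negative-sampling distribution
  std::vector<double> freq(n_terms, 0.0);
  std::vector<std::vector<int> > seqs(n_docs);
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector v = docs[d];
    seqs[d].assign(v.begin(), v.end());
    for (int t : seqs[d]) freq[t] += 1.0;
  }
  std::vector<double> neg_cdf(n_terms, 0.0);
  double z = 0.0;
  for (int i = 0; i < n_terms; ++i) z += std::pow(freq[i], 0.75);
  double acc = 0.0;
  for (int i = 0; i < n_terms; ++i) {
    acc += std::pow(freq[i], 0.75) / z;
    neg_cdf[i] = acc;
  }

  std::vector<double> syn0((size_t)n_terms * dim);   // term input vectors
  std::vector<double> dvec((size_t)n_docs * dim);    // document vectors
  std::vector<double> syn1((size_t)n_terms * dim, 0.0);  // output vectors
  for (size_t i = 0; i < syn0.size(); ++i) syn0[i] = (rng.unif() - 0.5) / dim;
  for (size_t i = 0; i < dvec.size(); ++i) dvec[i] = (rng.unif() - 0.5) / dim;

  std::vector<double> grad(dim);
  for (int e = 0; e < epochs; ++e) {
    double alpha = alpha0 - e * decay;
    if (alpha < 1e-4) alpha = 1e-4;
    for (int d = 0; d < n_docs; ++d) {
      const std::vector<int>& seq = seqs[d];
      int n = (int)seq.size();
      for (int t = 0; t < n; ++t) {
        // document predicts the token (dbow)
        train_pair(dvec, (size_t)d * dim, syn1, seq[t], dim, alpha, negative,
                   neg_cdf, rng, grad);
        if (!train_words) continue;
        int b = rng.below(window);  // reduced-window sampling
        for (int c = t - window + b; c <= t + window - b; ++c) {
          if (c < 0 || c >= n || c == t) continue;
          train_pair(syn0, (size_t)seq[t] * dim, syn1, seq[c], dim, alpha,
                     negative, neg_cdf, rng, grad);
        }
      }
    }
  }

  NumericMatrix tm(n_terms, dim), dm(n_docs, dim);
  for (int i = 0; i < n_terms; ++i)
    for (int d = 0; d < dim; ++d) tm(i, d) = syn0[(size_t)i * dim + d];
  for (int i = 0; i < n_docs; ++i)
    for (int d = 0; d < dim; ++d) dm(i, d) = dvec[(size_t)i * dim + d];
  return List::create(_["term_vectors"] = tm, _["doc_vectors"] = dm);
}
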