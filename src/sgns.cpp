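// Skip-gram with negative sampling, word2vec style.
// Single-threaded and seeded with its own PRNG so training is bit-for-bit
// reproducible across runs and platforms.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

inline std::uint64_t next_state(std::uint64_t &s) {
  // xorshift64*
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

inline double runif01(std::uint64_t &s) {
  return (next_state(s) >> 11) * (1.0 / 9007199254740992.0);
}

inline std::uint64_t rint(std::uint64_t &s) { return next_state(s); }

}  // namespace

// tokens: 0-based word ids with -1 as utterance separators.
// counts: vocabulary counts aligned with ids (for the negative-sampling
// distribution, unigram^{3/4}).
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(IntegerVector tokens, int vocab_size,
                             NumericVector counts, int dim, int window,
                             int epochs, int negative, double alpha,
                             double sample, int seed) {
  const int n_stream = tokens.size();
  std::uint64_t rng = 0x9E3779B97F4A7C15ULL ^ (std::uint64_t)(seed + 1);
  for (int i = 0; i < 8; ++i) next_state(rng);  // warm up

  // unigram^0.75 table for negative sampling
  const int table_size = 1000000;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    for (int i = 0; i < vocab_size; ++i) total += std::pow(counts[i], 0.75);
    int i = 0;
    double cum = std::pow(counts[0], 0.75) / total;
    for (int t = 0; t < table_size; ++t) {
      table[t] = i;
      if ((t + 1.0) / table_size > cum && i < vocab_size - 1) {
        ++i;
        cum += std::pow(counts[i], 0.75) / total;
      }
    }
  }

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (runif01(rng) - 0.5) / dim;

  long long n_real = 0;
  double total_count = 0.0;
  for (int i = 0; i < n_stream; ++i)
    if (tokens[i] >= 0) ++n_real;
  for (int i = 0; i < vocab_size; ++i) total_count += counts[i];

  const double alpha_min = alpha * 1e-4;
  const long long train_total = (long long)epochs * (n_real > 0 ? n_real : 1);
  long long processed = 0;
  std::vector<double> grad(dim);
  std::vector<int> sent;
  sent.reserve(256);

  for (int ep = 0; ep < epochs; ++ep) {
    int pos = 0;
    while (pos < n_stream) {
      sent.clear();
      while (pos < n_stream && tokens[pos] >= 0) {
        int w = tokens[pos];
        ++pos;
        if (sample > 0) {
          double f = counts[w] / total_count;
          double keep = (std::sqrt(f / sample) + 1.0) * sample / f;
          if (keep < runif01(rng)) {
            ++processed;
            continue;
          }
        }
        sent.push_back(w);
      }
      if (pos < n_stream) ++pos;  // skip separator
      const int ns = (int)sent.size();
      for (int i = 0; i < ns; ++i) {
        ++processed;
        double lr = alpha * (1.0 - (double)processed / (train_total + 1));
        if (lr < alpha_min) lr = alpha_min;
        int b = (int)(rint(rng) % (std::uint64_t)window);
        for (int j = i - window + b; j <= i + window - b; ++j) {
          if (j == i || j < 0 || j >= ns) continue;
          const int context = sent[j];
          const int center = sent[i];
          double *v_in = &syn0[(size_t)context * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = center;
              label = 1.0;
            } else {
              target = table[rint(rng) % table_size];
              if (target == center) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v_in[k] * v_out[k];
            double pred;
            if (dot > 8.0) pred = 1.0;
            else if (dot < -8.0) pred = 0.0;
            else pred = 1.0 / (1.0 + std::exp(-dot));
            double g = (label - pred) * lr;
            for (int k = 0; k < dim; ++k) grad[k] += g * v_out[k];
            for (int k = 0; k < dim; ++k) v_out[k] += g * v_in[k];
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i)
    for (int k = 0; k < dim; ++k) out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
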