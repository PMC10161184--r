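// Deterministic single-threaded CBOW trainer with negative sampling.
//
// Follows the classic word2vec.c update rules: mean-of-context forward pass
// (cbow_mean = 1), dynamic window shrinking, frequency subsampling, a 0.75-power
// unigram table for negative sampling, linear learning-rate decay, and the
// 25214903917 * x + 11 linear congruential generator so a given seed always
// reproduces the same vectors on any platform.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const int EXP_TABLE_SIZE = 1000;
const double MAX_EXP = 6.0;
const int UNIGRAM_TABLE_SIZE = 1000000;

inline unsigned long long lcg(unsigned long long &state) {
  state = state * 25214903917ULL + 11ULL;
  return state;
}

// uniform in [0, 1) from the top bits, word2vec style
inline double lcg_unif(unsigned long long &state) {
  lcg(state);
  return ((state >> 16) & 0xFFFFFFFFULL) / 4294967296.0;
}

}  // namespace

// Train CBOW vectors on integer-coded sentences.
//
// sentences: list of integer vectors, 0-based token ids (out-of-vocabulary
//   tokens already removed); counts: per-id corpus counts; returns a V x dim
//   matrix of input vectors.
// [[Rcpp::export(name = ".cbow_train_cpp")]]
NumericMatrix cbow_train_cpp(List sentences, NumericVector counts, int dim,
                             int window, int epochs, int negative,
                             double sample, double alpha, double min_alpha,
                             double seed) {
  const int V = counts.size();
  if (V < 1) stop("empty vocabulary");
  const int n_sent = sentences.size();

  double total_count = 0.0;
  for (int i = 0; i < V; ++i) total_count += counts[i];
  if (total_count <= 0) stop("vocabulary has zero total count");

  // sigmoid lookup table
  std::vector<double> exp_table(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double x = (i / (double)EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP;
    double e = std::exp(x);
    exp_table[i] = e / (e + 1.0);
  }

  // unigram table for negative sampling, counts^0.75
  std::vector<int> unigram(UNIGRAM_TABLE_SIZE);
  {
    double norm = 0.0;
    for (int i = 0; i < V; ++i) norm += std::pow(counts[i], 0.75);
    int i = 0;
    double cum = std::pow(counts[0], 0.75) / norm;
    for (int a = 0; a < UNIGRAM_TABLE_SIZE; ++a) {
      unigram[a] = i;
      if ((a + 1.0) / UNIGRAM_TABLE_SIZE > cum && i < V - 1) {
        ++i;
        cum += std::pow(counts[i], 0.75) / norm;
      }
    }
  }

  unsigned long long rng = (unsigned long long)seed;
  if (rng == 0ULL) rng = 1ULL;

  // flatten sentences once so the training loop never touches R structures
  std::vector<int> words;
  std::vector<size_t> offsets(n_sent + 1, 0);
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector raw = sentences[s];
    for (int i = 0; i < raw.size(); ++i) {
      int w = raw[i];
      if (w < 0 || w >= V) stop("token id out of range");
      words.push_back(w);
    }
    offsets[s + 1] = words.size();
  }

  // precomputed subsampling keep-probabilities
  std::vector<double> keep_prob(V, 1.0);
  if (sample > 0) {
    for (int i = 0; i < V; ++i) {
      double f = counts[i] / total_count;
      if (f > 0) {
        double k = std::sqrt(sample / f) + sample / f;
        keep_prob[i] = k < 1.0 ? k : 1.0;
      }
    }
  }

  // syn0 ~ U(-0.5, 0.5)/dim, syn1neg = 0; single precision like word2vec.c
  std::vector<float> syn0((size_t)V * dim), syn1neg((size_t)V * dim, 0.0f);
  for (size_t a = 0; a < (size_t)V * dim; ++a) {
    lcg(rng);
    syn0[a] = (float)((((rng >> 16) & 0xFFFF) / 65536.0 - 0.5) / dim);
  }

  // planned word count for the learning-rate schedule
  double train_words = total_count * epochs;
  double words_done = 0.0;
  double lr = alpha;

  std::vector<int> sent_buf;
  std::vector<float> neu1(dim), neu1e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      sent_buf.clear();
      for (size_t i = offsets[s]; i < offsets[s + 1]; ++i) {
        int w = words[i];
        words_done += 1.0;
        if (keep_prob[w] < 1.0 && keep_prob[w] < lcg_unif(rng)) continue;
        sent_buf.push_back(w);
      }
      lr = alpha - (alpha - min_alpha) * (words_done / (train_words + 1.0));
      if (lr < min_alpha) lr = min_alpha;

      const int slen = (int)sent_buf.size();
      for (int pos = 0; pos < slen; ++pos) {
        const int center = sent_buf[pos];
        const int b = (int)(lcg(rng) % (unsigned long long)window);

        std::fill(neu1.begin(), neu1.end(), 0.0f);
        std::fill(neu1e.begin(), neu1e.end(), 0.0f);
        int cw = 0;
        for (int a = b; a < window * 2 + 1 - b; ++a) {
          if (a == window) continue;
          int c = pos - window + a;
          if (c < 0 || c >= slen) continue;
          const float *v = &syn0[(size_t)sent_buf[c] * dim];
          for (int k = 0; k < dim; ++k) neu1[k] += v[k];
          ++cw;
        }
        if (cw == 0) continue;
        const float inv_cw = 1.0f / cw;
        for (int k = 0; k < dim; ++k) neu1[k] *= inv_cw;

        for (int d = 0; d <= negative; ++d) {
          int target;
          double label;
          if (d == 0) {
            target = center;
            label = 1.0;
          } else {
            target = unigram[(lcg(rng) >> 16) % UNIGRAM_TABLE_SIZE];
            if (target == center) continue;
            label = 0.0;
          }
          float *out = &syn1neg[(size_t)target * dim];
          double f = 0.0;
          for (int k = 0; k < dim; ++k) f += neu1[k] * out[k];
          double g;
          if (f > MAX_EXP) {
            g = (label - 1.0) * lr;
          } else if (f < -MAX_EXP) {
            g = label * lr;
          } else {
            int idx = (int)((f + MAX_EXP) * (EXP_TABLE_SIZE / MAX_EXP / 2.0));
            g = (label - exp_table[idx]) * lr;
          }
          const float gf = (float)g;
          for (int k = 0; k < dim; ++k) neu1e[k] += gf * out[k];
          for (int k = 0; k < dim; ++k) out[k] += gf * neu1[k];
        }

        for (int a = b; a < window * 2 + 1 - b; ++a) {
          if (a == window) continue;
          int c = pos - window + a;
          if (c < 0 || c >= slen) continue;
          float *v = &syn0[(size_t)sent_buf[c] * dim];
          for (int k = 0; k < dim; ++k) v[k] += neu1e[k];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < dim; ++k) out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
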