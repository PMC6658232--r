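#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Skip-gram with negative sampling, sequential stochastic ascent.
//
// words:     concatenated corpus as 1-based vocabulary ids
// sent_off:  0-based sentence offsets, length n_sentences + 1
// Win, Wout: input / output embedding tables, d x W (columns are words);
//            updated in place
// neg_table: sampling table of 1-based word ids (unigram-based noise
//            distribution U(w))
// alpha0:    initial learning rates, c(old, new); plain training passes the
//            same rate twice
// word_class: per word id, 1 = old (V0 ∩ V1) or 2 = new (V1 \ V0); the rate
//            applied to a vector update is the rate of the word whose vector
//            is being moved
// Rates decay linearly to 0 over n = epochs * T center-word samples.
// Sentence order is reshuffled each epoch from the seeded generator, so the
// whole run is deterministic given the seed.
// [[Rcpp::export]]
void cpp_skipgram_train(IntegerVector words, IntegerVector sent_off,
                        NumericMatrix Win, NumericMatrix Wout, int window,
                        int k, int epochs, IntegerVector neg_table,
                        NumericVector alpha0, IntegerVector word_class,
                        int seed) {
  const int d = Win.nrow();
  const int n_sent = sent_off.size() - 1;
  const size_t tab = neg_table.size();
  double* in = REAL(Win);
  double* out = REAL(Wout);
  std::mt19937 rng((uint32_t)seed);

  const double n_total = (double)epochs * (double)words.size();
  double t = 0.0;
  std::vector<int> order(n_sent);
  for (int i = 0; i < n_sent; ++i) order[i] = i;
  std::vector<double> neu1e(d);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n_sent - 1; i > 0; --i) {  // Fisher-Yates
      int j = (int)(rng() % (uint32_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    for (int si = 0; si < n_sent; ++si) {
      const int lo = sent_off[order[si]], hi = sent_off[order[si] + 1];
      for (int c = lo; c < hi; ++c) {
        const int wi = words[c] - 1;
        const double decay = std::max(0.0, 1.0 - t / n_total);
        const double a_in = alpha0[word_class[wi] - 1] * decay;
        double* v = in + (size_t)wi * d;
        for (int j = -window; j <= window; ++j) {
          if (j == 0) continue;
          const int p = c + j;
          if (p < lo || p >= hi) continue;
          const int wo = words[p] - 1;
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int neg = 0; neg <= k; ++neg) {
            int target; double label;
            if (neg == 0) { target = wo; label = 1.0; }
            else {
              target = neg_table[rng() % tab] - 1;
              if (target == wo) continue;
              label = 0.0;
            }
            double* u = out + (size_t)target * d;
            double s = 0.0;
            for (int m = 0; m < d; ++m) s += v[m] * u[m];
            const double g = label - sigmoid(s);
            const double a_out = alpha0[word_class[target] - 1] * decay;
            for (int m = 0; m < d; ++m) {
              neu1e[m] += g * u[m];
              u[m] += a_out * g * v[m];
            }
          }
          for (int m = 0; m < d; ++m) v[m] += a_in * neu1e[m];
        }
        t += 1.0;
      }
    }
  }
}
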