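#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// log(sum(exp(x))) with max-subtraction
static inline double logsumexp(const double* x, int n) {
  double m = x[0];
  for (int i = 1; i < n; ++i) if (x[i] > m) m = x[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// Forward-backward for a linear chain with per-position emission log
// potentials (L x K) and position-independent transition log potentials
// (K x K, trans(a,b) scores a -> b). Returns log-partition, unary
// marginals (L x K) and pairwise marginals ((L-1) x K x K).
// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix emission, NumericMatrix trans) {
  const int L = emission.nrow(), K = emission.ncol();
  if (trans.nrow() != K || trans.ncol() != K)
    stop("transition matrix must be K x K");
  std::vector<double> alpha(L * K), beta(L * K), tmp(K);

  for (int k = 0; k < K; ++k) alpha[k] = emission(0, k);
  for (int l = 1; l < L; ++l)
    for (int k = 0; k < K; ++k) {
      for (int a = 0; a < K; ++a) tmp[a] = alpha[(l - 1) * K + a] + trans(a, k);
      alpha[l * K + k] = emission(l, k) + logsumexp(tmp.data(), K);
    }
  const double log_z = logsumexp(alpha.data() + (L - 1) * K, K);

  for (int k = 0; k < K; ++k) beta[(L - 1) * K + k] = 0.0;
  for (int l = L - 2; l >= 0; --l)
    for (int a = 0; a < K; ++a) {
      for (int b = 0; b < K; ++b)
        tmp[b] = trans(a, b) + emission(l + 1, b) + beta[(l + 1) * K + b];
      beta[l * K + a] = logsumexp(tmp.data(), K);
    }

  NumericMatrix unary(L, K);
  for (int l = 0; l < L; ++l)
    for (int k = 0; k < K; ++k)
      unary(l, k) = std::exp(alpha[l * K + k] + beta[l * K + k] - log_z);

  NumericVector pair(std::max(L - 1, 0) * K * K);
  for (int l = 0; l + 1 < L; ++l)
    for (int a = 0; a < K; ++a)
      for (int b = 0; b < K; ++b)
        pair[l + (L - 1) * (a + K * b)] =
          std::exp(alpha[l * K + a] + trans(a, b) + emission(l + 1, b) +
                   beta[(l + 1) * K + b] - log_z);
  if (L > 1) pair.attr("dim") = IntegerVector::create(L - 1, K, K);

  return List::create(_["log_z"] = log_z, _["unary"] = unary,
                      _["pairwise"] = pair);
}

// Viterbi decoding; ties broken toward the lower label index. Returns a
// 1-based label index path of length L.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(NumericMatrix emission, NumericMatrix trans) {
  const int L = emission.nrow(), K = emission.ncol();
  std::vector<double> delta(L * K);
  std::vector<int> back(L * K);
  for (int k = 0; k < K; ++k) delta[k] = emission(0, k);
  for (int l = 1; l < L; ++l)
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = delta[(l - 1) * K] + trans(0, k);
      for (int a = 1; a < K; ++a) {
        double s = delta[(l - 1) * K + a] + trans(a, k);
        if (s > best) { best = s; arg = a; }  // strict: keeps lowest index
      }
      delta[l * K + k] = emission(l, k) + best;
      back[l * K + k] = arg;
    }
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta[(L - 1) * K + k] > delta[(L - 1) * K + arg]) arg = k;
  IntegerVector path(L);
  path[L - 1] = arg + 1;
  for (int l = L - 1; l > 0; --l) {
    arg = back[l * K + arg];
    path[l - 1] = arg + 1;
  }
  return path;
}

// Emission log-potential table (L x K) from sparse per-position features.
// idx: 1-based feature ids, concatenated over positions; off: 0-based
// offsets of length L+1 into idx/val.
// [[Rcpp::export]]
NumericMatrix cpp_emission_scores(IntegerVector idx, NumericVector val,
                                  IntegerVector off, NumericMatrix Wf) {
  const int L = off.size() - 1, K = Wf.nrow();
  NumericMatrix em(L, K);
  const double* W = REAL(Wf);
  for (int l = 0; l < L; ++l)
    for (int j = off[l]; j < off[l + 1]; ++j) {
      const double* col = W + (size_t)(idx[j] - 1) * K;
      const double v = val[j];
      for (int k = 0; k < K; ++k) em(l, k) += col[k] * v;
    }
  return em;
}

// Negative log-likelihood and dense gradients for one labeled sentence.
// y is 1-based. Gradient = expected - observed feature counts (no L2).
// [[Rcpp::export]]
List cpp_sentence_nll_grad(IntegerVector idx, NumericVector val,
                           IntegerVector off, IntegerVector y,
                           NumericMatrix Wf, NumericMatrix Wg) {
  const int L = off.size() - 1, K = Wf.nrow(), F = Wf.ncol();
  NumericMatrix em = cpp_emission_scores(idx, val, off, Wf);
  List fb = cpp_forward_backward(em, Wg);
  const double log_z = fb["log_z"];
  NumericMatrix unary = fb["unary"];

  double gold = 0.0;
  for (int l = 0; l < L; ++l) {
    gold += em(l, y[l] - 1);
    if (l > 0) gold += Wg(y[l - 1] - 1, y[l] - 1);
  }

  NumericMatrix gf(K, F), gg(K, K);
  double* G = REAL(gf);
  for (int l = 0; l < L; ++l)
    for (int j = off[l]; j < off[l + 1]; ++j) {
      double* col = G + (size_t)(idx[j] - 1) * K;
      const double v = val[j];
      for (int k = 0; k < K; ++k) col[k] += unary(l, k) * v;
      col[y[l] - 1] -= v;
    }
  if (L > 1) {
    NumericVector pair = fb["pairwise"];
    for (int l = 0; l + 1 < L; ++l)
      for (int a = 0; a < K; ++a)
        for (int b = 0; b < K; ++b)
          gg(a, b) += pair[l + (L - 1) * (a + K * b)];
    for (int l = 1; l < L; ++l) gg(y[l - 1] - 1, y[l] - 1) -= 1.0;
  }
  return List::create(_["nll"] = log_z - gold, _["grad_f"] = gf,
                      _["grad_g"] = gg);
}

// One AdaGrad epoch over a featurized corpus. Each element of `sents` is
// list(idx, val, off, y) as above. Wf, Wg, Gf, Gg (accumulated squared
// gradients) are updated in place; `order` is the 1-based visiting order.
// L2 is applied as one dense gradient pass at the end of the epoch so that
// per-sentence updates stay sparse. Returns the summed data NLL observed
// during the pass.
// [[Rcpp::export]]
double cpp_crf_epoch(List sents, NumericMatrix Wf, NumericMatrix Wg,
                     NumericMatrix Gf, NumericMatrix Gg, double step,
                     double eps, double l2, IntegerVector order) {
  const int K = Wf.nrow(), F = Wf.ncol();
  double* W = REAL(Wf); double* G = REAL(Gf);
  double* Wt = REAL(Wg); double* Gt = REAL(Gg);
  std::vector<double> gradf((size_t)K * F, 0.0);
  std::vector<size_t> touched;
  std::vector<double> alpha, beta, tmp(K), em, unary, gg((size_t)K * K);
  double total_nll = 0.0;

  for (int s = 0; s < order.size(); ++s) {
    List sent = sents[order[s] - 1];
    IntegerVector idx = sent["idx"]; NumericVector val = sent["val"];
    IntegerVector off = sent["off"]; IntegerVector y = sent["y"];
    const int L = off.size() - 1;
    em.assign((size_t)L * K, 0.0);
    for (int l = 0; l < L; ++l)
      for (int j = off[l]; j < off[l + 1]; ++j) {
        const double* col = W + (size_t)(idx[j] - 1) * K;
        const double v = val[j];
        for (int k = 0; k < K; ++k) em[l * K + k] += col[k] * v;
      }

    // forward-backward in place
    alpha.assign((size_t)L * K, 0.0); beta.assign((size_t)L * K, 0.0);
    for (int k = 0; k < K; ++k) alpha[k] = em[k];
    for (int l = 1; l < L; ++l)
      for (int k = 0; k < K; ++k) {
        for (int a = 0; a < K; ++a)
          tmp[a] = alpha[(l - 1) * K + a] + Wt[a + (size_t)k * K];
        alpha[l * K + k] = em[l * K + k] + logsumexp(tmp.data(), K);
      }
    const double log_z = logsumexp(alpha.data() + (size_t)(L - 1) * K, K);
    for (int l = L - 2; l >= 0; --l)
      for (int a = 0; a < K; ++a) {
        for (int b = 0; b < K; ++b)
          tmp[b] = Wt[a + (size_t)b * K] + em[(l + 1) * K + b] +
                   beta[(l + 1) * K + b];
        beta[l * K + a] = logsumexp(tmp.data(), K);
      }

    double gold = 0.0;
    for (int l = 0; l < L; ++l) {
      gold += em[l * K + y[l] - 1];
      if (l > 0) gold += Wt[(y[l - 1] - 1) + (size_t)(y[l] - 1) * K];
    }
    total_nll += log_z - gold;

    unary.assign((size_t)L * K, 0.0);
    for (int l = 0; l < L; ++l)
      for (int k = 0; k < K; ++k)
        unary[l * K + k] = std::exp(alpha[l * K + k] + beta[l * K + k] - log_z);

    // emission gradient, accumulated sparsely
    touched.clear();
    for (int l = 0; l < L; ++l)
      for (int j = off[l]; j < off[l + 1]; ++j) {
        const size_t base = (size_t)(idx[j] - 1) * K;
        const double v = val[j];
        for (int k = 0; k < K; ++k) gradf[base + k] += unary[l * K + k] * v;
        gradf[base + y[l] - 1] -= v;
        touched.push_back(base);
      }
    for (size_t t = 0; t < touched.size(); ++t) {
      const size_t base = touched[t];
      for (int k = 0; k < K; ++k) {
        const double g = gradf[base + k];
        if (g != 0.0) {
          G[base + k] += g * g;
          W[base + k] -= step * g / std::sqrt(G[base + k] + eps);
          gradf[base + k] = 0.0;
        }
      }
    }

    // transition gradient (dense, K x K)
    std::fill(gg.begin(), gg.end(), 0.0);
    for (int l = 0; l + 1 < L; ++l)
      for (int a = 0; a < K; ++a) {
        const double aa = alpha[l * K + a];
        for (int b = 0; b < K; ++b)
          gg[a + (size_t)b * K] +=
            std::exp(aa + Wt[a + (size_t)b * K] + em[(l + 1) * K + b] +
                     beta[(l + 1) * K + b] - log_z);
      }
    for (int l = 1; l < L; ++l)
      gg[(y[l - 1] - 1) + (size_t)(y[l] - 1) * K] -= 1.0;
    if (L > 1)
      for (size_t c = 0; c < (size_t)K * K; ++c) {
        const double g = gg[c];
        if (g != 0.0) {
          Gt[c] += g * g;
          Wt[c] -= step * g / std::sqrt(Gt[c] + eps);
        }
      }
  }

  if (l2 > 0.0) {
    for (size_t c = 0; c < (size_t)K * F; ++c) {
      const double g = l2 * W[c];
      if (g != 0.0) {
        G[c] += g * g;
        W[c] -= step * g / std::sqrt(G[c] + eps);
      }
    }
    for (size_t c = 0; c < (size_t)K * K; ++c) {
      const double g = l2 * Wt[c];
      if (g != 0.0) {
        Gt[c] += g * g;
        Wt[c] -= step * g / std::sqrt(Gt[c] + eps);
      }
    }
  }
  return total_nll;
}
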