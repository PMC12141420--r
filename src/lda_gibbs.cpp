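// Collapsed Gibbs sampler for LDA, plus document-completion perplexity.
//
// Determinism contract: all randomness comes from counter-based
// per-document streams derived from (seed, canonical document index), and
// documents are swept in canonical order, so identical inputs and seed give
// bit-identical output regardless of platform RNG state.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// splitmix64: tiny, well-distributed counter RNG.
static inline uint64_t sm64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double u01(uint64_t &s) {
  return (double)(sm64(s) >> 11) * (1.0 / 9007199254740992.0); // [0,1)
}

static inline uint64_t docStreamSeed(uint64_t seed, uint64_t d) {
  uint64_t s = seed * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL;
  return s ^ ((d + 1) * 0x2545F4914F6CDD1DULL);
}

// The collapsed conditional p(z = k | z_-i, w): proportional to
// (n_dk + alpha) * (n_kv + beta) / (n_k. + V beta).
// Shared between the sampler and the exported probe below.
static inline void collapsedWeights(const int *ndk_d, const int *nkv_v,
                                    const int *nk, int K, int V,
                                    double alpha, double beta, double *out) {
  double vb = V * beta;
  for (int k = 0; k < K; ++k)
    out[k] = (ndk_d[k] + alpha) * (nkv_v[k] + beta) / (nk[k] + vb);
}

// [[Rcpp::export]]
NumericVector cpp_lda_conditional(IntegerMatrix ndk, IntegerMatrix nkv,
                                  IntegerVector nk, int d, int v,
                                  double alpha, double beta) {
  int K = ndk.ncol(), V = nkv.ncol();
  std::vector<int> ndkd(K), nkvv(K);
  for (int k = 0; k < K; ++k) {
    ndkd[k] = ndk(d - 1, k);
    nkvv[k] = nkv(k, v - 1);
  }
  NumericVector w(K);
  collapsedWeights(ndkd.data(), nkvv.data(), nk.begin(), K, V,
                   alpha, beta, w.begin());
  double s = 0;
  for (int k = 0; k < K; ++k) s += w[k];
  for (int k = 0; k < K; ++k) w[k] /= s;
  return w;
}

static double collapsedLogLik(const std::vector<int> &ndk,
                              const std::vector<int> &nkv,
                              const std::vector<int> &nk,
                              const std::vector<int> &nd,
                              int D, int V, int K,
                              double alpha, double beta) {
  double ll = K * (lgamma(V * beta) - V * lgamma(beta));
  for (int k = 0; k < K; ++k) {
    for (int v = 0; v < V; ++v) ll += lgamma(nkv[(size_t)k * V + v] + beta);
    ll -= lgamma(nk[k] + V * beta);
  }
  ll += D * (lgamma(K * alpha) - K * lgamma(alpha));
  for (int d = 0; d < D; ++d) {
    for (int k = 0; k < K; ++k) ll += lgamma(ndk[(size_t)d * K + k] + alpha);
    ll -= lgamma(nd[d] + K * alpha);
  }
  return ll;
}

// docIdx/wordIdx: 0-based, one entry per token, tokens grouped by document
// in canonical order (docIdx non-decreasing).
// [[Rcpp::export]]
List cpp_lda_fit(IntegerVector docIdx, IntegerVector wordIdx,
                 int D, int V, int K,
                 double alpha, double beta,
                 int nIter, int burnIn, double seed,
                 bool average, int sampleEvery) {
  size_t N = docIdx.size();
  std::vector<int> z(N);
  std::vector<int> ndk((size_t)D * K, 0), nkv((size_t)K * V, 0),
      nk(K, 0), nd(D, 0);
  std::vector<uint64_t> stream(D);
  uint64_t useed = (uint64_t)seed;
  for (int d = 0; d < D; ++d) stream[d] = docStreamSeed(useed, (uint64_t)d);

  // token ranges per document
  std::vector<size_t> start(D + 1, 0);
  for (size_t i = 0; i < N; ++i) nd[docIdx[i]]++;
  for (int d = 0; d < D; ++d) start[d + 1] = start[d] + nd[d];

  // init: uniform topic draw from the owning document's stream
  for (int d = 0; d < D; ++d) {
    for (size_t i = start[d]; i < start[d + 1]; ++i) {
      int k = (int)(u01(stream[d]) * K);
      if (k == K) k = K - 1;
      z[i] = k;
      ndk[(size_t)d * K + k]++;
      nkv[(size_t)k * V + wordIdx[i]]++;
      nk[k]++;
    }
  }

  NumericVector ll(nIter);
  std::vector<double> w(K);
  NumericMatrix phiAcc(K, V), thetaAcc(D, K);
  int nSamples = 0;

  for (int it = 0; it < nIter; ++it) {
    for (int d = 0; d < D; ++d) {
      int *ndk_d = &ndk[(size_t)d * K];
      uint64_t &st = stream[d];
      for (size_t i = start[d]; i < start[d + 1]; ++i) {
        int v = wordIdx[i], k = z[i];
        ndk_d[k]--; nkv[(size_t)k * V + v]--; nk[k]--;
        double tot = 0;
        double vb = V * beta;
        for (int kk = 0; kk < K; ++kk) {
          w[kk] = (ndk_d[kk] + alpha) * (nkv[(size_t)kk * V + v] + beta) /
                  (nk[kk] + vb);
          tot += w[kk];
        }
        double u = u01(st) * tot, c = 0;
        int knew = K - 1;
        for (int kk = 0; kk < K; ++kk) {
          c += w[kk];
          if (u < c) { knew = kk; break; }
        }
        z[i] = knew;
        ndk_d[knew]++; nkv[(size_t)knew * V + v]++; nk[knew]++;
      }
    }
    ll[it] = collapsedLogLik(ndk, nkv, nk, nd, D, V, K, alpha, beta);
    if (average && it + 1 > burnIn &&
        ((it + 1 - burnIn) % sampleEvery == 0)) {
      nSamples++;
      for (int k = 0; k < K; ++k)
        for (int v = 0; v < V; ++v)
          phiAcc(k, v) += (nkv[(size_t)k * V + v] + beta) / (nk[k] + V * beta);
      for (int d = 0; d < D; ++d)
        for (int k = 0; k < K; ++k)
          thetaAcc(d, k) +=
              (ndk[(size_t)d * K + k] + alpha) / (nd[d] + K * alpha);
    }
  }

  NumericMatrix phi(K, V), theta(D, K);
  if (average && nSamples > 0) {
    for (int k = 0; k < K; ++k)
      for (int v = 0; v < V; ++v) phi(k, v) = phiAcc(k, v) / nSamples;
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < K; ++k) theta(d, k) = thetaAcc(d, k) / nSamples;
    // renormalise rows against accumulated rounding
    for (int k = 0; k < K; ++k) {
      double s = 0;
      for (int v = 0; v < V; ++v) s += phi(k, v);
      for (int v = 0; v < V; ++v) phi(k, v) /= s;
    }
    for (int d = 0; d < D; ++d) {
      double s = 0;
      for (int k = 0; k < K; ++k) s += theta(d, k);
      for (int k = 0; k < K; ++k) theta(d, k) /= s;
    }
  } else {
    for (int k = 0; k < K; ++k)
      for (int v = 0; v < V; ++v)
        phi(k, v) = (nkv[(size_t)k * V + v] + beta) / (nk[k] + V * beta);
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < K; ++k)
        theta(d, k) = (ndk[(size_t)d * K + k] + alpha) / (nd[d] + K * alpha);
  }

  IntegerVector zOut(N);
  for (size_t i = 0; i < N; ++i) zOut[i] = z[i] + 1;
  IntegerMatrix ndkOut(D, K), nkvOut(K, V);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) ndkOut(d, k) = ndk[(size_t)d * K + k];
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) nkvOut(k, v) = nkv[(size_t)k * V + v];

  return List::create(_["phi"] = phi, _["theta"] = theta, _["z"] = zOut,
                      _["ndk"] = ndkOut, _["nkv"] = nkvOut,
                      _["loglik"] = ll);
}

// Document-completion perplexity: per held-out document, tokens are
// shuffled with the document's stream, the first half is folded in by short
// Gibbs runs against fixed phi to estimate theta_d, and the second half is
// scored under sum_k theta_dk phi_kv.
// [[Rcpp::export]]
List cpp_lda_perplexity(IntegerVector docIdx, IntegerVector wordIdx,
                        NumericMatrix phi, double alpha,
                        int foldIter, double seed) {
  int K = phi.nrow();
  size_t N = docIdx.size();
  int D = 0;
  for (size_t i = 0; i < N; ++i) D = std::max(D, docIdx[i] + 1);
  std::vector<int> nd(D, 0);
  for (size_t i = 0; i < N; ++i) nd[docIdx[i]]++;
  std::vector<size_t> start(D + 1, 0);
  for (int d = 0; d < D; ++d) start[d + 1] = start[d] + nd[d];

  uint64_t useed = (uint64_t)seed;
  double sumLog = 0;
  long nEval = 0;
  NumericMatrix thetaHat(D, K);
  std::vector<double> w(K);

  for (int d = 0; d < D; ++d) {
    size_t n = start[d + 1] - start[d];
    uint64_t st = docStreamSeed(useed, (uint64_t)d);
    std::vector<int> toks(n);
    for (size_t i = 0; i < n; ++i) toks[i] = wordIdx[start[d] + i];
    // Fisher-Yates with the document's stream
    for (size_t i = n; i > 1; --i) {
      size_t j = (size_t)(u01(st) * i);
      if (j >= i) j = i - 1;
      std::swap(toks[i - 1], toks[j]);
    }
    size_t nFold = (n + 1) / 2;
    std::vector<int> zf(nFold), ndkd(K, 0);
    for (size_t i = 0; i < nFold; ++i) {
      int k = (int)(u01(st) * K);
      if (k == K) k = K - 1;
      zf[i] = k; ndkd[k]++;
    }
    for (int it = 0; it < foldIter; ++it) {
      for (size_t i = 0; i < nFold; ++i) {
        int v = toks[i], k = zf[i];
        ndkd[k]--;
        double tot = 0;
        for (int kk = 0; kk < K; ++kk) {
          w[kk] = phi(kk, v) * (ndkd[kk] + alpha);
          tot += w[kk];
        }
        double u = u01(st) * tot, c = 0;
        int knew = K - 1;
        for (int kk = 0; kk < K; ++kk) {
          c += w[kk];
          if (u < c) { knew = kk; break; }
        }
        zf[i] = knew; ndkd[knew]++;
      }
    }
    double denom = (double)nFold + K * alpha;
    for (int k = 0; k < K; ++k) thetaHat(d, k) = (ndkd[k] + alpha) / denom;
    for (size_t i = nFold; i < n; ++i) {
      int v = toks[i];
      double p = 0;
      for (int k = 0; k < K; ++k) p += thetaHat(d, k) * phi(k, v);
      sumLog += log(p);
      nEval++;
    }
  }
  return List::create(_["sumLog"] = sumLog, _["nEval"] = (double)nEval,
                      _["theta"] = thetaHat);
}
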