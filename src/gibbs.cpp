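#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Deterministic, platform-independent generator (splitmix64) so that fitted
// models are bit-reproducible across machines for a given seed.
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  double next() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z = z ^ (z >> 31);
    return (double)(z >> 11) * (1.0 / 9007199254740992.0);
  }
};

static inline int sample_cdf(const std::vector<double>& p, double u) {
  // inverse-CDF draw from an unnormalised weight vector
  double tot = 0.0;
  for (double v : p) tot += v;
  double target = u * tot, acc = 0.0;
  int K = (int)p.size();
  for (int k = 0; k < K; ++k) {
    acc += p[k];
    if (target < acc) return k;
  }
  return K - 1;
}

// Collapsed Gibbs sampler shared by vanilla LDA and Red-LDA. Vanilla is the
// special case with every `copied` flag false. Count conventions:
//   n_dk  counts ALL tokens (copied tokens still occupy their note's topic
//         mixture);
//   n_kw / n_k count only non-copied tokens, so the topic-word distribution
//         is estimated without redundant text.
// Copied tokens whose word occurs in their record's source note draw their
// topic from the source note's current assignments of that word, smoothed
// by delta; copied words absent from the source fall back to the standard
// conditional over the redundancy-excluded counts.
// [[Rcpp::export]]
List cpp_gibbs_fit(const IntegerVector& tokens,      // flat, 0-based word ids
                   const IntegerVector& doc_ptr,     // length D+1 offsets
                   const LogicalVector& copied,      // flat, per token
                   const IntegerVector& record_of_doc, // 0-based record idx
                   const IntegerVector& source_doc,    // per record, 0-based doc
                   const IntegerVector& doc_order,     // sweep order, 0-based
                   int V, int K,
                   double alpha, double beta, double delta,
                   int n_iter, double seed) {
  const int D = doc_ptr.size() - 1;
  const int R = source_doc.size();
  const int N = tokens.size();

  std::vector<int> z(N, 0);
  std::vector<int> n_dk((size_t)D * K, 0);
  std::vector<int> n_kw((size_t)K * V, 0);
  std::vector<int> n_k(K, 0);

  // per record: positions of each word within the source document
  std::vector<std::unordered_map<int, std::vector<int> > > src_words(R);
  for (int r = 0; r < R; ++r) {
    int sd = source_doc[r];
    for (int i = doc_ptr[sd]; i < doc_ptr[sd + 1]; ++i) {
      src_words[r][tokens[i]].push_back(i);  // flat positions
    }
  }

  SplitMix64 rng((uint64_t)seed + 0x5DEECE66DULL);
  std::vector<double> p(K);

  // initialise in sweep order so vanilla and Red-LDA share draw sequences
  for (int oi = 0; oi < D; ++oi) {
    int d = doc_order[oi];
    for (int i = doc_ptr[d]; i < doc_ptr[d + 1]; ++i) {
      int k = (int)(rng.next() * K);
      if (k >= K) k = K - 1;
      z[i] = k;
      n_dk[(size_t)d * K + k]++;
      if (!copied[i]) {
        n_kw[(size_t)k * V + tokens[i]]++;
        n_k[k]++;
      }
    }
  }

  const double Vb = V * beta;
  uint64_t checksum = 0;  // rolling trajectory hash, wraps mod 2^64

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int oi = 0; oi < D; ++oi) {
      int d = doc_order[oi];
      int r = record_of_doc[d];
      for (int i = doc_ptr[d]; i < doc_ptr[d + 1]; ++i) {
        int w = tokens[i];
        int zi = z[i];
        n_dk[(size_t)d * K + zi]--;
        if (!copied[i]) {
          // standard conditional on (redundancy-excluded) counts
          n_kw[(size_t)zi * V + w]--;
          n_k[zi]--;
          for (int k = 0; k < K; ++k) {
            p[k] = (n_dk[(size_t)d * K + k] + alpha) *
                   (n_kw[(size_t)k * V + w] + beta) / (n_k[k] + Vb);
          }
          int k = sample_cdf(p, rng.next());
          z[i] = k;
          n_dk[(size_t)d * K + k]++;
          n_kw[(size_t)k * V + w]++;
          n_k[k]++;
        } else {
          std::unordered_map<int, std::vector<int> >::const_iterator it =
              src_words[r].find(w);
          if (it != src_words[r].end()) {
            // word present in source: topic from source assignments + delta
            for (int k = 0; k < K; ++k) p[k] = delta;
            for (size_t j = 0; j < it->second.size(); ++j) {
              p[z[it->second[j]]] += 1.0;
            }
          } else {
            // fallback: standard form over redundancy-excluded counts
            for (int k = 0; k < K; ++k) {
              p[k] = (n_dk[(size_t)d * K + k] + alpha) *
                     (n_kw[(size_t)k * V + w] + beta) / (n_k[k] + Vb);
            }
          }
          int k = sample_cdf(p, rng.next());
          z[i] = k;
          n_dk[(size_t)d * K + k]++;
        }
      }
    }
    for (int i = 0; i < N; ++i) {
      checksum = checksum * 1099511628211ULL + (uint64_t)z[i];
    }
  }

  IntegerMatrix ndk(D, K), nkw(K, V);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) ndk(d, k) = n_dk[(size_t)d * K + k];
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < V; ++w) nkw(k, w) = n_kw[(size_t)k * V + w];

  return List::create(_["z"] = IntegerVector(z.begin(), z.end()),
                      _["n_dk"] = ndk, _["n_kw"] = nkw,
                      _["n_k"] = IntegerVector(n_k.begin(), n_k.end()),
                      _["checksum"] = (double)(checksum >> 11));
}

// Fold-in inference for a held-out document: phi fixed, only the document's
// topic mixture is resampled; returns the smoothed theta after the final
// sweep.
// [[Rcpp::export]]
NumericVector cpp_fold_in(const IntegerVector& tokens,  // 0-based word ids
                          const NumericMatrix& phi,     // K x V
                          double alpha, int n_iter, double seed) {
  const int K = phi.nrow();
  const int N = tokens.size();
  std::vector<int> z(N, 0), n_dk(K, 0);
  SplitMix64 rng((uint64_t)seed + 0x5DEECE66DULL);
  std::vector<double> p(K);

  for (int i = 0; i < N; ++i) {
    int k = (int)(rng.next() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    n_dk[k]++;
  }
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < N; ++i) {
      int w = tokens[i];
      n_dk[z[i]]--;
      for (int k = 0; k < K; ++k) p[k] = (n_dk[k] + alpha) * phi(k, w);
      int k = sample_cdf(p, rng.next());
      z[i] = k;
      n_dk[k]++;
    }
  }
  NumericVector theta(K);
  for (int k = 0; k < K; ++k) theta[k] = (n_dk[k] + alpha) / (N + K * alpha);
  return theta;
}

// Best local-alignment score between two token sequences (linear memory).
// [[Rcpp::export]]
double cpp_smith_waterman(const IntegerVector& a, const IntegerVector& b,
                          double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double diag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up = prev[j] + gap;
      double left = cur[j - 1] + gap;
      double v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0.0) v = 0.0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}
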