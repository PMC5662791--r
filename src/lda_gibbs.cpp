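#include <Rcpp.h>
using namespace Rcpp;

// Draw a topic index from unnormalized weights p[0..K-1] summing to `total`.
static inline int draw_topic(const std::vector<double>& p, int K, double total) {
  double u = unif_rand() * total;
  double cum = 0.0;
  for (int k = 0; k < K; ++k) {
    cum += p[k];
    if (u <= cum) return k;
  }
  return K - 1;
}

// Collapsed Gibbs sampler for LDA.
//
// doc, word: 0-based parallel vectors, one entry per token, ordered by
// document index then token position (the fixed sweep order). Counts use the
// standard collapsed updates: p(z=k) ~ (n_dk + alpha) (n_kw + beta)/(n_k + V beta).
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List lda_gibbs_fit_cpp(IntegerVector doc, IntegerVector word,
                       int D, int V, int K,
                       double alpha, double beta, int n_iter) {
  const int N = doc.size();
  IntegerVector z(N);
  IntegerMatrix ndk(D, K), nkw(K, V);
  IntegerVector nk(K), nd(D);
  const double Vb = V * beta;

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk(doc[i], k)++;
    nkw(k, word[i])++;
    nk[k]++;
    nd[doc[i]]++;
  }

  std::vector<double> p(K);
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int k = z[i];
      ndk(d, k)--; nkw(k, w)--; nk[k]--;
      double total = 0.0;
      for (int t = 0; t < K; ++t) {
        p[t] = (ndk(d, t) + alpha) * (nkw(t, w) + beta) / (nk[t] + Vb);
        total += p[t];
      }
      k = draw_topic(p, K, total);
      z[i] = k;
      ndk(d, k)++; nkw(k, w)++; nk[k]++;
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["z"] = z, _["ndk"] = ndk, _["nkw"] = nkw,
                      _["nk"] = nk, _["nd"] = nd);
}

// Fold-in inference for one unseen document: training counts nkw/nk stay
// frozen; only the query's own topic counts n_qk move. Returns the posterior
// topic proportions (n_qk + alpha)/(N + K alpha) averaged over the final
// quarter of sweeps.
// [[Rcpp::export]]
NumericVector lda_fold_in_cpp(IntegerVector word, IntegerMatrix nkw,
                              IntegerVector nk, double alpha, double beta,
                              int n_iter) {
  const int K = nkw.nrow(), V = nkw.ncol(), N = word.size();
  NumericVector theta(K);
  const double Vb = V * beta;

  if (N == 0) {
    for (int k = 0; k < K; ++k) theta[k] = 1.0 / K;
    return theta;
  }

  IntegerVector z(N), nqk(K);
  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    nqk[k]++;
  }

  std::vector<double> p(K);
  int n_avg = n_iter / 4;
  if (n_avg < 1) n_avg = 1;
  const int avg_from = n_iter - n_avg;
  NumericVector acc(K);

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int w = word[i];
      int k = z[i];
      nqk[k]--;
      double total = 0.0;
      for (int t = 0; t < K; ++t) {
        p[t] = (nqk[t] + alpha) * (nkw(t, w) + beta) / (nk[t] + Vb);
        total += p[t];
      }
      k = draw_topic(p, K, total);
      z[i] = k;
      nqk[k]++;
    }
    if (it >= avg_from) {
      for (int k = 0; k < K; ++k)
        acc[k] += (nqk[k] + alpha) / (N + K * alpha);
    }
  }

  for (int k = 0; k < K; ++k) theta[k] = acc[k] / n_avg;
  return theta;
}
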