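#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// docs: list of 0-based integer vectors, one per document (drug); each entry
//       is a vocabulary (phenotype column) index. V: vocabulary size.
// Posterior means of theta (M x K) and phi (K x V) are averaged over
// post-burn-in states taken every `lag` sweeps, using the Rao-Blackwellised
// per-state estimates (n_dk + alpha)/(n_d + K alpha) and
// (n_kw + beta)/(n_k + V beta).
//
// All randomness goes through R's RNG so set.seed() makes runs bit-identical.

static int sample_categorical(const std::vector<double>& cum, double total) {
  double u = unif_rand() * total;
  int K = static_cast<int>(cum.size());
  for (int k = 0; k < K; ++k) {
    if (u < cum[k]) return k;
  }
  return K - 1;  // guard against rounding at the upper edge
}

// [[Rcpp::export]]
List cpp_lda_gibbs(List docs, int V, int K, double alpha, double beta,
                   int n_iter, int burn_in, int lag) {
  const int M = docs.size();
  std::vector<std::vector<int> > w(M);
  for (int d = 0; d < M; ++d) {
    IntegerVector dv = docs[d];
    w[d] = std::vector<int>(dv.begin(), dv.end());
  }

  std::vector<std::vector<int> > z(M);
  std::vector<int> ndk(static_cast<size_t>(M) * K, 0);
  std::vector<int> nkw(static_cast<size_t>(K) * V, 0);
  std::vector<int> nk(K, 0), nd(M, 0);

  RNGScope scope;

  for (int d = 0; d < M; ++d) {
    const int len = static_cast<int>(w[d].size());
    z[d].resize(len);
    nd[d] = len;
    for (int i = 0; i < len; ++i) {
      int k = static_cast<int>(unif_rand() * K);
      if (k >= K) k = K - 1;
      z[d][i] = k;
      ++ndk[static_cast<size_t>(d) * K + k];
      ++nkw[static_cast<size_t>(k) * V + w[d][i]];
      ++nk[k];
    }
  }

  NumericMatrix theta_sum(M, K), phi_sum(K, V);
  int n_samples = 0;
  std::vector<double> cum(K);
  const double Vbeta = V * beta;

  auto take_sample = [&]() {
    for (int d = 0; d < M; ++d) {
      const double denom = nd[d] + K * alpha;
      for (int k = 0; k < K; ++k)
        theta_sum(d, k) += (ndk[static_cast<size_t>(d) * K + k] + alpha) / denom;
    }
    for (int k = 0; k < K; ++k) {
      const double denom = nk[k] + Vbeta;
      for (int v = 0; v < V; ++v)
        phi_sum(k, v) += (nkw[static_cast<size_t>(k) * V + v] + beta) / denom;
    }
    ++n_samples;
  };

  for (int iter = 1; iter <= n_iter; ++iter) {
    for (int d = 0; d < M; ++d) {
      const size_t dK = static_cast<size_t>(d) * K;
      const int len = static_cast<int>(w[d].size());
      for (int i = 0; i < len; ++i) {
        const int v = w[d][i];
        const int old_k = z[d][i];
        --ndk[dK + old_k];
        --nkw[static_cast<size_t>(old_k) * V + v];
        --nk[old_k];

        double total = 0.0;
        for (int k = 0; k < K; ++k) {
          const double p = (ndk[dK + k] + alpha) *
            (nkw[static_cast<size_t>(k) * V + v] + beta) / (nk[k] + Vbeta);
          total += p;
          cum[k] = total;
        }
        const int new_k = sample_categorical(cum, total);
        z[d][i] = new_k;
        ++ndk[dK + new_k];
        ++nkw[static_cast<size_t>(new_k) * V + v];
        ++nk[new_k];
      }
    }
    if (iter > burn_in && (iter - burn_in) % lag == 0) take_sample();
  }
  if (n_samples == 0) take_sample();  // degenerate schedules keep final state

  NumericMatrix theta(M, K), phi(K, V);
  for (int d = 0; d < M; ++d)
    for (int k = 0; k < K; ++k) theta(d, k) = theta_sum(d, k) / n_samples;
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) phi(k, v) = phi_sum(k, v) / n_samples;

  return List::create(_["theta"] = theta, _["phi"] = phi,
                      _["n_samples"] = n_samples);
}

// Fold one (possibly perturbed) document into a fixed phi: Gibbs over that
// document's assignments only, phi held at the fitted values. Returns the
// averaged theta row for the document.
// [[Rcpp::export]]
NumericVector cpp_lda_foldin(IntegerVector doc, NumericMatrix phi,
                             double alpha, int n_iter, int burn_in, int lag) {
  const int K = phi.nrow();
  const int len = doc.size();
  std::vector<int> z(len), ndk(K, 0);
  std::vector<double> cum(K);

  RNGScope scope;

  for (int i = 0; i < len; ++i) {
    int k = static_cast<int>(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ++ndk[k];
  }

  NumericVector theta_sum(K);
  int n_samples = 0;
  const double denom = len + K * alpha;

  auto take_sample = [&]() {
    for (int k = 0; k < K; ++k) theta_sum[k] += (ndk[k] + alpha) / denom;
    ++n_samples;
  };

  for (int iter = 1; iter <= n_iter; ++iter) {
    for (int i = 0; i < len; ++i) {
      const int v = doc[i];
      --ndk[z[i]];
      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        total += (ndk[k] + alpha) * phi(k, v);
        cum[k] = total;
      }
      const int new_k = sample_categorical(cum, total);
      z[i] = new_k;
      ++ndk[new_k];
    }
    if (iter > burn_in && (iter - burn_in) % lag == 0) take_sample();
  }
  if (n_samples == 0) take_sample();

  NumericVector theta(K);
  for (int k = 0; k < K; ++k) theta[k] = theta_sum[k] / n_samples;
  return theta;
}

// p(ph|d) = sum_t p(t|d) p(ph|t), accumulated over topics in ascending index
// order with double precision, so the summation order is mathematically
// pinned down (unlike a BLAS gemm) and testable against a plain-loop oracle.
// [[Rcpp::export]]
NumericMatrix cpp_path_probabilities(NumericMatrix theta, NumericMatrix phi) {
  const int M = theta.nrow(), K = theta.ncol(), V = phi.ncol();
  if (phi.nrow() != K) stop("theta/phi topic dimensions disagree");
  NumericMatrix out(M, V);
  for (int d = 0; d < M; ++d) {
    for (int v = 0; v < V; ++v) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k) acc += theta(d, k) * phi(k, v);
      out(d, v) = acc;
    }
  }
  return out;
}
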