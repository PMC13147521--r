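#include <Rcpp.h>
using namespace Rcpp;

// Maximum a-posteriori state path for a track with per-SNP emission
// log-likelihoods (n x K matrix) and a uniform per-transition penalty.
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector viterbi_from_emissions(NumericMatrix emis, double switch_penalty) {
  const int n = emis.nrow(), K = emis.ncol();
  IntegerVector path(n);
  if (n == 0) return path;

  NumericVector delta(K);
  IntegerMatrix psi(n, K);
  for (int k = 0; k < K; ++k) delta[k] = emis(0, k);

  NumericVector nxt(K);
  for (int i = 1; i < n; ++i) {
    // best previous state overall (for switching in)
    int argbest = 0;
    for (int k = 1; k < K; ++k) if (delta[k] > delta[argbest]) argbest = k;
    double best = delta[argbest];
    for (int k = 0; k < K; ++k) {
      double stay = delta[k];
      double sw = best - switch_penalty;
      if (stay >= sw) {
        nxt[k] = stay + emis(i, k);
        psi(i, k) = k;
      } else {
        nxt[k] = sw + emis(i, k);
        psi(i, k) = argbest;
      }
    }
    for (int k = 0; k < K; ++k) delta[k] = nxt[k];
  }

  int last = 0;
  for (int k = 1; k < K; ++k) if (delta[k] > delta[last]) last = k;
  path[n - 1] = last + 1;
  for (int i = n - 1; i > 0; --i) {
    last = psi(i, last);
    path[i - 1] = last + 1;
  }
  return path;
}
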