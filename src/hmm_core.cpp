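#include <Rcpp.h>
using namespace Rcpp;

List fb_core_impl(NumericMatrix emis, NumericMatrix trans, NumericVector init);

// Scaled forward-backward for a homogeneous HMM with pattern-compressed
// emissions.
//   epat: K x P matrix of emission probabilities per state per site pattern
//   map: length-L 1-based pattern index per site
//   trans: K x K transition matrix (rows: from)
//   init: length-K initial distribution
// Returns posteriors (K x L), log-likelihood, the expected transition
// count matrix sum_t xi_t (K x K), and W (P x K): per-pattern sums of the
// state posteriors, for the branch-length M-step.
// [[Rcpp::export(name = ".fb_pat")]]
List fb_pat(NumericMatrix epat, IntegerVector map, NumericMatrix trans,
            NumericVector init) {
  const int K = epat.nrow();
  const R_xlen_t L = map.size();
  NumericMatrix emis(K, L);
  for (R_xlen_t t = 0; t < L; ++t) {
    const int p = map[t] - 1;
    for (int i = 0; i < K; ++i) emis(i, t) = epat(i, p);
  }
  List res = fb_core_impl(emis, trans, init);
  NumericMatrix post = res["posterior"];
  NumericMatrix W(epat.ncol(), K);
  for (R_xlen_t t = 0; t < L; ++t) {
    const int p = map[t] - 1;
    for (int i = 0; i < K; ++i) W(p, i) += post(i, t);
  }
  res["W"] = W;
  return res;
}

// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix emis, NumericMatrix trans, NumericVector init) {
  return fb_core_impl(emis, trans, init);
}

List fb_core_impl(NumericMatrix emis, NumericMatrix trans, NumericVector init) {
  const int K = emis.nrow();
  const R_xlen_t L = emis.ncol();
  if (trans.nrow() != K || trans.ncol() != K || init.size() != K)
    stop("dimension mismatch between emissions, transitions and initial distribution");
  for (int i = 0; i < K; ++i) {
    double s = 0.0;
    for (int j = 0; j < K; ++j) s += trans(i, j);
    if (std::abs(s - 1.0) > 1e-9) stop("transition row does not sum to 1");
  }
  NumericMatrix alpha(K, L), beta(K, L), post(K, L);
  NumericVector scale(L);
  double ll = 0.0;

  // forward
  double s0 = 0.0;
  for (int i = 0; i < K; ++i) { alpha(i, 0) = init[i] * emis(i, 0); s0 += alpha(i, 0); }
  if (s0 <= 0.0) stop("zero forward probability at site 1");
  for (int i = 0; i < K; ++i) alpha(i, 0) /= s0;
  scale[0] = s0; ll = std::log(s0);
  for (R_xlen_t t = 1; t < L; ++t) {
    double st = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(i, t - 1) * trans(i, j);
      a *= emis(j, t);
      alpha(j, t) = a; st += a;
    }
    if (st <= 0.0) stop("zero forward probability (numerical underflow)");
    for (int j = 0; j < K; ++j) alpha(j, t) /= st;
    scale[t] = st; ll += std::log(st);
  }

  // backward
  for (int i = 0; i < K; ++i) beta(i, L - 1) = 1.0;
  for (R_xlen_t t = L - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += trans(i, j) * emis(j, t + 1) * beta(j, t + 1);
      beta(i, t) = b / scale[t + 1];
    }
  }

  // posteriors
  for (R_xlen_t t = 0; t < L; ++t) {
    double s = 0.0;
    for (int i = 0; i < K; ++i) { post(i, t) = alpha(i, t) * beta(i, t); s += post(i, t); }
    for (int i = 0; i < K; ++i) post(i, t) /= s;
  }

  // expected transition counts
  NumericMatrix xi(K, K);
  for (R_xlen_t t = 0; t + 1 < L; ++t) {
    for (int i = 0; i < K; ++i) {
      const double ai = alpha(i, t);
      if (ai == 0.0) continue;
      for (int j = 0; j < K; ++j) {
        xi(i, j) += ai * trans(i, j) * emis(j, t + 1) * beta(j, t + 1) / scale[t + 1];
      }
    }
  }

  return List::create(_["posterior"] = post, _["loglik"] = ll, _["xi"] = xi);
}
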