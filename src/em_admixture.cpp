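#include <Rcpp.h>
using namespace Rcpp;

// EM for the diploid admixture likelihood on reference-allele dosages.
// G: n x L integer matrix of 0/1/2 dosages, NA = missing.
// Model: each of the two allele copies at (i,l) descends from ancestral
// population k with probability q_ik and is then the reference allele with
// probability p_kl, so the reference-allele probability is f_il = sum_k
// q_ik p_kl and loglik = sum g log f + (2-g) log(1-f) over called entries.
//
// Internally Q is held transposed (K x n) so the per-cell mixture sums run
// over contiguous memory for both Q and P (both K-major).

static double loglik_only(const int* G, int n, int L,
                          const std::vector<double>& Qt,
                          const double* P, int K) {
  double ll = 0.0;
  for (int l = 0; l < L; ++l) {
    const double* pl = P + (size_t)l * K;
    const int* gl = G + (size_t)l * n;
    for (int i = 0; i < n; ++i) {
      const int g = gl[i];
      if (g == NA_INTEGER) continue;
      const double* qi = Qt.data() + (size_t)i * K;
      double f = 0.0;
      for (int k = 0; k < K; ++k) f += qi[k] * pl[k];
      if (f < 1e-12) f = 1e-12;
      if (f > 1.0 - 1e-12) f = 1.0 - 1e-12;
      ll += g * std::log(f) + (2 - g) * std::log(1.0 - f);
    }
  }
  return ll;
}

// [[Rcpp::export]]
List em_admixture_cpp(IntegerMatrix G, NumericMatrix Q0, NumericMatrix P0,
                      double tol, int max_iter, double p_clamp) {
  const int n = G.nrow(), L = G.ncol(), K = Q0.ncol();
  const int* g_ptr = INTEGER(G);
  const double* p0 = REAL(P0);

  std::vector<double> Qt((size_t)n * K), Pv((size_t)K * L);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qt[(size_t)i * K + k] = Q0(i, k);
  std::copy(p0, p0 + (size_t)K * L, Pv.begin());

  std::vector<double> Qnum((size_t)n * K), Pnum((size_t)K * L),
      Pden((size_t)K * L);
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  bool converged = false;
  double ll_old = R_NegInf;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    std::fill(Qnum.begin(), Qnum.end(), 0.0);
    std::fill(Pnum.begin(), Pnum.end(), 0.0);
    std::fill(Pden.begin(), Pden.end(), 0.0);
    double ll = 0.0;

    for (int l = 0; l < L; ++l) {
      const double* pl = Pv.data() + (size_t)l * K;
      double* pn = Pnum.data() + (size_t)l * K;
      double* pd = Pden.data() + (size_t)l * K;
      const int* gl = g_ptr + (size_t)l * n;
      for (int i = 0; i < n; ++i) {
        const int g = gl[i];
        if (g == NA_INTEGER) continue;
        const double* qi = Qt.data() + (size_t)i * K;
        double* qn = Qnum.data() + (size_t)i * K;
        double f = 0.0;
        for (int k = 0; k < K; ++k) f += qi[k] * pl[k];
        if (f < 1e-12) f = 1e-12;
        if (f > 1.0 - 1e-12) f = 1.0 - 1e-12;
        ll += g * std::log(f) + (2 - g) * std::log(1.0 - f);
        const double wr = g / f;                 // reference-copy weight
        const double wa = (2 - g) / (1.0 - f);   // alternate-copy weight
        for (int k = 0; k < K; ++k) {
          const double qp = qi[k] * pl[k];
          const double ra = qp * wr;
          const double rb = (qi[k] - qp) * wa;
          qn[k] += ra + rb;
          pn[k] += ra;
          pd[k] += ra + rb;
        }
      }
    }
    trace.push_back(ll);

    // M-step
    for (int i = 0; i < n; ++i) {
      double* qi = Qt.data() + (size_t)i * K;
      const double* qn = Qnum.data() + (size_t)i * K;
      double rs = 0.0;
      for (int k = 0; k < K; ++k) rs += qn[k];
      if (rs > 0) for (int k = 0; k < K; ++k) qi[k] = qn[k] / rs;
    }
    for (size_t j = 0; j < Pv.size(); ++j) {
      if (Pden[j] > 1e-300) {
        double p = Pnum[j] / Pden[j];
        if (p < p_clamp) p = p_clamp;
        if (p > 1.0 - p_clamp) p = 1.0 - p_clamp;
        Pv[j] = p;
      }
    }

    if (it > 1 && ll - ll_old < tol) { converged = true; break; }
    ll_old = ll;
  }

  const double ll_final = loglik_only(g_ptr, n, L, Qt, Pv.data(), K);
  trace.push_back(ll_final);

  NumericMatrix Q(n, K), P(K, L);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = Qt[(size_t)i * K + k];
  std::copy(Pv.begin(), Pv.end(), REAL(P));

  return List::create(_["Q"] = Q, _["P"] = P,
                      _["loglik"] = ll_final,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["n_iter"] = std::min(it, max_iter),
                      _["converged"] = converged);
}
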