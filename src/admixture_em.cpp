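#include <Rcpp.h>
using namespace Rcpp;

// EM for the unsupervised admixture model on multi-allelic loci.
//
// Observations are the non-missing gene copies, flattened:
//   ind[j]  0-based individual index
//   col[j]  0-based global allele column (locus offset + within-locus allele)
//   loc[j]  0-based locus index
// Q is n_ind x K (row-stochastic), P is K x n_col where each locus owns a
// contiguous block of columns that is row-normalised per cluster.
//
// The E-step responsibilities r_jk = Q(i,k) P(k,a) / sum_k' ... drive closed
// form M-step updates of both Q and P; the log-likelihood recorded at each
// iteration is evaluated at the parameters entering that E-step, so the
// returned trace is non-decreasing by the usual EM argument.

// [[Rcpp::export]]
List admixture_em_cpp(IntegerVector ind, IntegerVector col, IntegerVector loc,
                      int n_ind, int n_col, int n_loc,
                      IntegerVector col_offset, IntegerVector n_alleles,
                      NumericMatrix Q0, NumericMatrix P0,
                      int max_iter, double tol, double freq_floor) {
  const int M = ind.size();
  const int K = Q0.ncol();

  NumericMatrix Q = clone(Q0);
  NumericMatrix P = clone(P0);
  NumericMatrix Qacc(n_ind, K);
  NumericMatrix Pacc(K, n_col);
  std::vector<double> w(K);

  // copies observed per individual (normaliser for Q updates)
  std::vector<double> n_obs(n_ind, 0.0);
  for (int j = 0; j < M; ++j) n_obs[ind[j]] += 1.0;

  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  double ll_prev = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    std::fill(Qacc.begin(), Qacc.end(), 0.0);
    std::fill(Pacc.begin(), Pacc.end(), 0.0);
    double ll = 0.0;

    for (int j = 0; j < M; ++j) {
      const int i = ind[j], a = col[j];
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        w[k] = Q(i, k) * P(k, a);
        s += w[k];
      }
      ll += std::log(s);
      const double inv = 1.0 / s;
      for (int k = 0; k < K; ++k) {
        const double r = w[k] * inv;
        Qacc(i, k) += r;
        Pacc(k, a) += r;
      }
    }
    trace.push_back(ll);

    // M-step: Q rows normalised by observed copy count
    for (int i = 0; i < n_ind; ++i) {
      const double inv = 1.0 / n_obs[i];
      for (int k = 0; k < K; ++k) Q(i, k) = Qacc(i, k) * inv;
    }
    // M-step: P normalised per (cluster, locus) block, floored to keep
    // log-likelihood finite when a cluster sees none of an allele
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < n_loc; ++l) {
        const int o = col_offset[l], na = n_alleles[l];
        double s = 0.0;
        for (int a = 0; a < na; ++a) s += Pacc(k, o + a);
        if (s <= 0.0) s = 1.0;  // degenerate cluster: uniform block below
        double s2 = 0.0;
        for (int a = 0; a < na; ++a) {
          double v = Pacc(k, o + a) / s;
          if (v < freq_floor) v = freq_floor;
          P(k, o + a) = v;
          s2 += v;
        }
        for (int a = 0; a < na; ++a) P(k, o + a) /= s2;
      }
    }

    if (iter > 0 && std::fabs(ll - ll_prev) <
          tol * (std::fabs(ll_prev) + 1e-12)) {
      converged = true;
      ll_prev = ll;
      break;
    }
    ll_prev = ll;
  }

  // log-likelihood at the final parameters
  double ll_final = 0.0;
  for (int j = 0; j < M; ++j) {
    const int i = ind[j], a = col[j];
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += Q(i, k) * P(k, a);
    ll_final += std::log(s);
  }
  trace.push_back(ll_final);

  return List::create(_["Q"] = Q, _["P"] = P,
                      _["loglik"] = ll_final,
                      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["n_iter"] = (int)trace.size() - 1,
                      _["converged"] = converged);
}
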