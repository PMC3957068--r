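// Linear-chain CRF numerics: penalized negative log-likelihood with
// analytic gradient via scaled forward-backward, and Viterbi decoding with
// additive per-label bias.
//
// Parameter layout (flat vector): state weights W[f*L + l] for feature f
// and label l, followed by transition weights T[a*L + b] for a -> b.
// Sequences are passed in CSR form: feat holds 0-based feature ids for all
// tokens, tok_ptr[t]..tok_ptr[t+1] delimits token t's features, and
// seq_ptr[s]..seq_ptr[s+1] delimits sequence s's tokens.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List crf_nll_grad(NumericVector params, IntegerVector feat,
                  IntegerVector tok_ptr, IntegerVector seq_ptr,
                  IntegerVector y, int F, int L, double l2) {
  const int nseq = seq_ptr.size() - 1;
  const double* W = params.begin();
  const double* T = params.begin() + (size_t)F * L;
  NumericVector grad((size_t)params.size());
  double* gW = grad.begin();
  double* gT = grad.begin() + (size_t)F * L;
  double nll = 0.0;

  std::vector<double> expT((size_t)L * L);
  for (int a = 0; a < L * L; ++a) expT[a] = std::exp(T[a]);
  std::vector<double> E, expE, alpha, beta, cvec, gamma;

  for (int s = 0; s < nseq; ++s) {
    const int t0 = seq_ptr[s];
    const int n = seq_ptr[s + 1] - t0;
    if (n <= 0) continue;

    E.assign((size_t)n * L, 0.0);
    for (int t = 0; t < n; ++t) {
      double* erow = &E[(size_t)t * L];
      for (int p = tok_ptr[t0 + t]; p < tok_ptr[t0 + t + 1]; ++p) {
        const double* wrow = W + (size_t)feat[p] * L;
        for (int l = 0; l < L; ++l) erow[l] += wrow[l];
      }
    }

    // gold path score
    double gold = 0.0;
    for (int t = 0; t < n; ++t) gold += E[(size_t)t * L + y[t0 + t]];
    for (int t = 0; t + 1 < n; ++t)
      gold += T[(size_t)y[t0 + t] * L + y[t0 + t + 1]];

    // per-position shift, exponentiate
    double shift_sum = 0.0;
    expE.assign((size_t)n * L, 0.0);
    for (int t = 0; t < n; ++t) {
      const double* erow = &E[(size_t)t * L];
      double m = erow[0];
      for (int l = 1; l < L; ++l) if (erow[l] > m) m = erow[l];
      shift_sum += m;
      for (int l = 0; l < L; ++l)
        expE[(size_t)t * L + l] = std::exp(erow[l] - m);
    }

    // scaled forward
    alpha.assign((size_t)n * L, 0.0);
    cvec.assign(n, 0.0);
    double csum = 0.0;
    for (int l = 0; l < L; ++l) { alpha[l] = expE[l]; csum += alpha[l]; }
    cvec[0] = csum;
    for (int l = 0; l < L; ++l) alpha[l] /= csum;
    for (int t = 1; t < n; ++t) {
      double* at = &alpha[(size_t)t * L];
      const double* ap = &alpha[(size_t)(t - 1) * L];
      for (int b = 0; b < L; ++b) {
        double acc = 0.0;
        for (int a = 0; a < L; ++a) acc += ap[a] * expT[(size_t)a * L + b];
        at[b] = acc * expE[(size_t)t * L + b];
      }
      csum = 0.0;
      for (int b = 0; b < L; ++b) csum += at[b];
      cvec[t] = csum;
      for (int b = 0; b < L; ++b) at[b] /= csum;
    }
    double logZ = shift_sum;
    for (int t = 0; t < n; ++t) logZ += std::log(cvec[t]);
    nll += logZ - gold;

    // scaled backward
    beta.assign((size_t)n * L, 0.0);
    for (int l = 0; l < L; ++l) beta[(size_t)(n - 1) * L + l] = 1.0 / cvec[n - 1];
    for (int t = n - 2; t >= 0; --t) {
      double* bt = &beta[(size_t)t * L];
      const double* bn = &beta[(size_t)(t + 1) * L];
      const double* en = &expE[(size_t)(t + 1) * L];
      for (int a = 0; a < L; ++a) {
        double acc = 0.0;
        const double* trow = &expT[(size_t)a * L];
        for (int b = 0; b < L; ++b) acc += trow[b] * en[b] * bn[b];
        bt[a] = acc / cvec[t];
      }
    }

    // state marginals -> gradient (expected minus empirical counts)
    gamma.assign(L, 0.0);
    for (int t = 0; t < n; ++t) {
      const double* at = &alpha[(size_t)t * L];
      const double* bt = &beta[(size_t)t * L];
      for (int l = 0; l < L; ++l) gamma[l] = at[l] * bt[l] * cvec[t];
      const int yt = y[t0 + t];
      for (int p = tok_ptr[t0 + t]; p < tok_ptr[t0 + t + 1]; ++p) {
        double* grow = gW + (size_t)feat[p] * L;
        for (int l = 0; l < L; ++l) grow[l] += gamma[l];
        grow[yt] -= 1.0;
      }
    }
    // pairwise marginals -> transition gradient
    for (int t = 0; t + 1 < n; ++t) {
      const double* at = &alpha[(size_t)t * L];
      const double* bn = &beta[(size_t)(t + 1) * L];
      const double* en = &expE[(size_t)(t + 1) * L];
      for (int a = 0; a < L; ++a) {
        const double* trow = &expT[(size_t)a * L];
        double* grow = gT + (size_t)a * L;
        const double aa = at[a];
        if (aa == 0.0) continue;
        for (int b = 0; b < L; ++b) grow[b] += aa * trow[b] * en[b] * bn[b];
      }
      gT[(size_t)y[t0 + t] * L + y[t0 + t + 1]] -= 1.0;
    }
  }

  if (l2 > 0.0) {
    double pen = 0.0;
    for (R_xlen_t i = 0; i < params.size(); ++i) {
      pen += params[i] * params[i];
      grad[i] += l2 * params[i];
    }
    nll += 0.5 * l2 * pen;
  }
  return List::create(_["nll"] = nll, _["grad"] = grad);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi(NumericVector params, IntegerVector feat,
                          IntegerVector tok_ptr, IntegerVector seq_ptr,
                          int F, int L, NumericVector bias) {
  const int nseq = seq_ptr.size() - 1;
  const double* W = params.begin();
  const double* T = params.begin() + (size_t)F * L;
  const int ntok = tok_ptr.size() - 1;
  IntegerVector out(ntok);

  std::vector<double> E, delta;
  std::vector<int> back;
  for (int s = 0; s < nseq; ++s) {
    const int t0 = seq_ptr[s];
    const int n = seq_ptr[s + 1] - t0;
    if (n <= 0) continue;
    E.assign((size_t)n * L, 0.0);
    for (int t = 0; t < n; ++t) {
      double* erow = &E[(size_t)t * L];
      for (int l = 0; l < L; ++l) erow[l] = bias[l];
      for (int p = tok_ptr[t0 + t]; p < tok_ptr[t0 + t + 1]; ++p) {
        const double* wrow = W + (size_t)feat[p] * L;
        for (int l = 0; l < L; ++l) erow[l] += wrow[l];
      }
    }
    delta.assign((size_t)n * L, 0.0);
    back.assign((size_t)n * L, 0);
    for (int l = 0; l < L; ++l) delta[l] = E[l];
    for (int t = 1; t < n; ++t) {
      const double* dp = &delta[(size_t)(t - 1) * L];
      double* dt = &delta[(size_t)t * L];
      int* bk = &back[(size_t)t * L];
      for (int b = 0; b < L; ++b) {
        double best = dp[0] + T[b];  // a = 0
        int arg = 0;
        for (int a = 1; a < L; ++a) {
          const double v = dp[a] + T[(size_t)a * L + b];
          if (v > best) { best = v; arg = a; }
        }
        dt[b] = best + E[(size_t)t * L + b];
        bk[b] = arg;
      }
    }
    const double* dl = &delta[(size_t)(n - 1) * L];
    int arg = 0;
    for (int l = 1; l < L; ++l) if (dl[l] > dl[arg]) arg = l;
    for (int t = n - 1; t >= 0; --t) {
      out[t0 + t] = arg;
      if (t > 0) arg = back[(size_t)t * L + arg];
    }
  }
  return out;
}
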