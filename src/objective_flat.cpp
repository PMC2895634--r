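#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x >= 0) {
    return 1.0 / (1.0 + std::exp(-x));
  } else {
    double e = std::exp(x);
    return e / (1.0 + e);
  }
}

// Flat-array objective/gradient used by the optimizer: all windows of all
// records are concatenated once per (data, width) so each evaluation is a
// single pass over contiguous arrays. theta_idx(j, win) is the linear
// index (base + 4 * j) into theta for position j of window `win`, or -1
// when the window contains a non-ACGU character (p = 0).


// [[Rcpp::export]]
List objective_grad_flat_cpp(IntegerMatrix theta_idx, NumericMatrix winS,
                             IntegerVector rec_nwin, NumericVector y,
                             NumericVector theta, NumericVector gamma,
                             double b_seq, double b_str, double slope,
                             double intercept, double lambda,
                             bool want_grad) {
  const int w = theta_idx.nrow();
  const int na = gamma.size();
  const int nrec = rec_nwin.size();
  const int* idx = theta_idx.begin();
  const double* ws = winS.begin();
  const double* th = theta.begin();
  const double* gm = gamma.begin();

  int max_nwin = 0;
  for (int t = 0; t < nrec; ++t)
    if (rec_nwin[t] > max_nwin) max_nwin = rec_nwin[t];
  std::vector<double> p(max_nwin), su(max_nwin), sv(max_nwin),
      logq(max_nwin);

  NumericVector g_theta(theta.size());
  NumericVector g_gamma(na);
  double g_bseq = 0.0, g_bstr = 0.0, g_slope = 0.0, g_intercept = 0.0;
  double obj = 0.0;
  NumericVector Nvec(nrec);

  int win0 = 0;
  for (int t = 0; t < nrec; ++t) {
    const int nwin = rec_nwin[t];
    double L = 0.0;
    for (int i = 0; i < nwin; ++i) {
      const int* col = idx + (size_t)(win0 + i) * w;
      if (col[0] < 0) { p[i] = 0.0; logq[i] = 0.0; continue; }
      double u = b_seq;
      for (int j = 0; j < w; ++j) u += th[col[j]];
      const double* wcol = ws + (size_t)(win0 + i) * na;
      double v = b_str;
      for (int a = 0; a < na; ++a) v += gm[a] * wcol[a];
      double s = sigmoid(u), tt = sigmoid(v);
      su[i] = s;
      sv[i] = tt;
      double pp = s * tt;
      if (pp > 1.0 - 1e-15) pp = 1.0 - 1e-15;
      p[i] = pp;
      logq[i] = std::log1p(-pp);
      L += logq[i];
    }
    double N = 1.0 - std::exp(L);
    Nvec[t] = N;
    double resid = slope * N + intercept - y[t];
    obj += resid * resid;
    if (want_grad) {
      double dN = 2.0 * resid * slope;
      g_slope += 2.0 * resid * N;
      g_intercept += 2.0 * resid;
      double P = std::exp(L);  // prod of q over this record
      for (int i = 0; i < nwin; ++i) {
        if (p[i] <= 0.0) continue;
        double q = 1.0 - p[i];
        double dp = dN * ((q > 1e-12) ? P / q : std::exp(L - logq[i]));
        double gu = dp * p[i] * (1.0 - su[i]);
        double gv = dp * p[i] * (1.0 - sv[i]);
        const int* col = idx + (size_t)(win0 + i) * w;
        for (int j = 0; j < w; ++j) g_theta[col[j]] += gu;
        g_bseq += gu;
        const double* wcol = ws + (size_t)(win0 + i) * na;
        for (int a = 0; a < na; ++a) g_gamma[a] += gv * wcol[a];
        g_bstr += gv;
      }
    }
    win0 += nwin;
  }

  double pen = 0.0;
  for (int k = 0; k < theta.size(); ++k) pen += th[k] * th[k];
  for (int a = 0; a < na; ++a) pen += gm[a] * gm[a];
  pen += b_seq * b_seq + b_str * b_str;
  obj += lambda * pen;
  if (want_grad) {
    for (int k = 0; k < theta.size(); ++k) g_theta[k] += 2.0 * lambda * th[k];
    for (int a = 0; a < na; ++a) g_gamma[a] += 2.0 * lambda * gm[a];
    g_bseq += 2.0 * lambda * b_seq;
    g_bstr += 2.0 * lambda * b_str;
  }

  return List::create(_["value"] = obj, _["g_theta"] = g_theta,
                      _["g_gamma"] = g_gamma, _["g_bseq"] = g_bseq,
                      _["g_bstr"] = g_bstr, _["g_slope"] = g_slope,
                      _["g_intercept"] = g_intercept, _["N"] = Nvec);
}

// Build the flat window encoding: theta linear indices per window and the
// per-record window counts. seqs are integer code vectors (-1 = other).
// [[Rcpp::export]]
List encode_windows_cpp(List seqs, int w) {
  const int nrec = seqs.size();
  IntegerVector rec_nwin(nrec);
  long total = 0;
  for (int t = 0; t < nrec; ++t) {
    IntegerVector s = seqs[t];
    int nwin = s.size() - w + 1;
    rec_nwin[t] = nwin;
    total += nwin;
  }
  IntegerMatrix theta_idx(w, total);
  int win = 0;
  for (int t = 0; t < nrec; ++t) {
    IntegerVector s = seqs[t];
    const int nwin = rec_nwin[t];
    for (int i = 0; i < nwin; ++i, ++win) {
      bool ok = true;
      for (int j = 0; j < w; ++j) {
        if (s[i + j] < 0) { ok = false; break; }
      }
      for (int j = 0; j < w; ++j) {
        theta_idx(j, win) = ok ? (s[i + j] + 4 * j) : -1;
      }
    }
  }
  return List::create(_["theta_idx"] = theta_idx, _["rec_nwin"] = rec_nwin);
}
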