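#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Noisy-OR motif scoring and the regularized least-squares objective with
// its analytic gradient. Window structure sums (profile mass per context
// letter summed over the window, already divided by w under the mean
// convention) are precomputed on the R side and passed per record.

static inline double sigmoid(double x) {
  if (x >= 0) {
    return 1.0 / (1.0 + std::exp(-x));
  } else {
    double e = std::exp(x);
    return e / (1.0 + e);
  }
}

// Per-window bound probabilities for one record.
// [[Rcpp::export]]
NumericVector window_probs_cpp(IntegerVector seq, NumericMatrix winS,
                               NumericMatrix theta, NumericVector gamma,
                               double b_seq, double b_str) {
  int w = theta.ncol();
  int n = seq.size();
  int nwin = n - w + 1;
  int na = gamma.size();
  NumericVector p(nwin);
  for (int i = 0; i < nwin; ++i) {
    bool valid = true;
    double u = b_seq;
    for (int j = 0; j < w; ++j) {
      int code = seq[i + j];
      if (code < 0) { valid = false; break; }
      u += theta(code, j);
    }
    if (!valid) { p[i] = 0.0; continue; }
    double v = b_str;
    for (int a = 0; a < na; ++a) v += gamma[a] * winS(a, i);
    p[i] = sigmoid(u) * sigmoid(v);
  }
  return p;
}

static double score_record(const IntegerVector& seq, const NumericMatrix& winS,
                           const NumericMatrix& theta,
                           const NumericVector& gamma, double b_seq,
                           double b_str) {
  NumericVector p = window_probs_cpp(seq, winS, theta, gamma, b_seq, b_str);
  double logq = 0.0;
  for (int i = 0; i < p.size(); ++i) {
    double q = 1.0 - p[i];
    if (q < 1e-300) q = 1e-300;
    logq += std::log(q);
  }
  return 1.0 - std::exp(logq);
}

// Noisy-OR score N for each record.
// [[Rcpp::export]]
NumericVector score_batch_cpp(List seqs, List winS_list, NumericMatrix theta,
                              NumericVector gamma, double b_seq,
                              double b_str) {
  int nrec = seqs.size();
  NumericVector out(nrec);
  for (int t = 0; t < nrec; ++t) {
    IntegerVector seq = seqs[t];
    NumericMatrix winS = winS_list[t];
    out[t] = score_record(seq, winS, theta, gamma, b_seq, b_str);
  }
  return out;
}

// Objective (sum of squared affinity residuals + L2 penalty on theta, gamma
// and the two biases) and its analytic gradient over all parameters.
// [[Rcpp::export]]
List objective_grad_cpp(List seqs, List winS_list, NumericVector y,
                        NumericMatrix theta, NumericVector gamma,
                        double b_seq, double b_str, double slope,
                        double intercept, double lambda,
                        bool want_grad) {
  int nrec = seqs.size();
  int w = theta.ncol();
  int na = gamma.size();
  NumericMatrix g_theta(4, w);
  NumericVector g_gamma(na);
  double g_bseq = 0.0, g_bstr = 0.0, g_slope = 0.0, g_intercept = 0.0;
  double obj = 0.0;
  NumericVector Nvec(nrec);

  for (int t = 0; t < nrec; ++t) {
    IntegerVector seq = seqs[t];
    NumericMatrix winS = winS_list[t];
    int n = seq.size();
    int nwin = n - w + 1;
    std::vector<double> p(nwin), su(nwin), sv(nwin), logq(nwin);
    std::vector<bool> valid(nwin);
    double L = 0.0;
    for (int i = 0; i < nwin; ++i) {
      bool ok = true;
      double u = b_seq;
      for (int j = 0; j < w; ++j) {
        int code = seq[i + j];
        if (code < 0) { ok = false; break; }
        u += theta(code, j);
      }
      valid[i] = ok;
      if (!ok) { p[i] = 0.0; logq[i] = 0.0; continue; }
      double v = b_str;
      for (int a = 0; a < na; ++a) v += gamma[a] * winS(a, i);
      double s = sigmoid(u), tt = sigmoid(v);
      su[i] = s;
      sv[i] = tt;
      p[i] = s * tt;
      double q = 1.0 - p[i];
      if (q < 1e-300) q = 1e-300;
      logq[i] = std::log(q);
      L += logq[i];
    }
    double N = 1.0 - std::exp(L);
    Nvec[t] = N;
    double resid = slope * N + intercept - y[t];
    obj += resid * resid;
    if (!want_grad) continue;
    double dN = 2.0 * resid * slope;  // dF/dN
    g_slope += 2.0 * resid * N;
    g_intercept += 2.0 * resid;
    for (int i = 0; i < nwin; ++i) {
      if (!valid[i] || p[i] <= 0.0) continue;
      // dN/dp_i = prod_{k != i} (1 - p_k)
      double dp = dN * std::exp(L - logq[i]);
      double gu = dp * p[i] * (1.0 - su[i]);
      double gv = dp * p[i] * (1.0 - sv[i]);
      for (int j = 0; j < w; ++j) g_theta(seq[i + j], j) += gu;
      g_bseq += gu;
      for (int a = 0; a < na; ++a) g_gamma[a] += gv * winS(a, i);
      g_bstr += gv;
    }
  }

  // penalty (slope/intercept excluded)
  double pen = 0.0;
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) pen += theta(b, j) * theta(b, j);
  for (int a = 0; a < na; ++a) pen += gamma[a] * gamma[a];
  pen += b_seq * b_seq + b_str * b_str;
  obj += lambda * pen;
  if (want_grad) {
    for (int j = 0; j < w; ++j)
      for (int b = 0; b < 4; ++b) g_theta(b, j) += 2.0 * lambda * theta(b, j);
    for (int a = 0; a < na; ++a) g_gamma[a] += 2.0 * lambda * gamma[a];
    g_bseq += 2.0 * lambda * b_seq;
    g_bstr += 2.0 * lambda * b_str;
  }

  return List::create(_["value"] = obj, _["g_theta"] = g_theta,
                      _["g_gamma"] = g_gamma, _["g_bseq"] = g_bseq,
                      _["g_bstr"] = g_bstr, _["g_slope"] = g_slope,
                      _["g_intercept"] = g_intercept, _["N"] = Nvec);
}
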