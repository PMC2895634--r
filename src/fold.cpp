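#include <Rcpp.h>
#include <random>
#include "classify.h"
#include <vector>
#include <utility>
using namespace Rcpp;

// Secondary-structure ensemble machinery: a nested (pseudoknot-free) folding
// model with per-pair pseudo-energies, an optional stacking bonus and a
// minimum hairpin size. Partition-function DP over intervals, stochastic
// traceback sampling, exhaustive enumeration (testing oracle) and per-base
// loop-context classification.
//
// Base codes: A=0, C=1, G=2, U=3; anything else is -1 upstream.
// partner[i] = 0-based pairing partner or -1 (unpaired).
// Context categories: 0=paired, 1=hairpin_loop, 2=external, 3=bulge,
// 4=internal_loop, 5=multiloop.

static inline double pair_weight(const NumericMatrix& pairE, double beta,
                                 int a, int b) {
  double e = pairE(a, b);
  if (!R_finite(e)) return 0.0;
  return std::exp(-beta * e);
}

// [[Rcpp::export]]
List fold_partition_cpp(IntegerVector seq, NumericMatrix pairE, double stackE,
                        int min_hairpin, double beta) {
  int n = seq.size();
  NumericMatrix Z(n, n), Zp(n, n);
  double wstack = std::exp(-beta * stackE);
  // zval(i,j) with i>j (empty interval) is 1
  auto zval = [&](int i, int j) -> double { return (i > j) ? 1.0 : Z(i, j); };
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // Zp: (i,j) paired
      double zp = 0.0;
      if (j - i - 1 >= min_hairpin && seq[i] >= 0 && seq[j] >= 0) {
        double wp = pair_weight(pairE, beta, seq[i], seq[j]);
        if (wp > 0.0) {
          double inner_p = Zp(i + 1, j - 1);
          double inner_all = Z(i + 1, j - 1);
          double rest = inner_all - inner_p;
          if (rest < 0.0) rest = 0.0;
          zp = wp * (wstack * inner_p + rest);
        }
      }
      Zp(i, j) = zp;
      // Z: i unpaired, or i paired with k
      double z = (len == 1) ? 1.0 : Z(i + 1, j);
      for (int k = i + min_hairpin + 1; k <= j; ++k) {
        if (Zp(i, k) > 0.0) z += Zp(i, k) * zval(k + 1, j);
      }
      Z(i, j) = z;
    }
  }
  double total = (n > 0) ? Z(0, n - 1) : 1.0;
  return List::create(_["Z"] = Z, _["Zp"] = Zp, _["total"] = total,
                      _["min_hairpin"] = min_hairpin);
}

namespace {

struct Sampler {
  const IntegerVector& seq;
  const NumericMatrix& Z;
  const NumericMatrix& Zp;
  const NumericMatrix& pairE;
  double stackE, beta, wstack;
  int minh;
  std::mt19937_64 rng;
  std::vector<int> partner;

  Sampler(const IntegerVector& s, const NumericMatrix& z,
          const NumericMatrix& zp, const NumericMatrix& pe, double se,
          int mh, double b, uint64_t seed)
      : seq(s), Z(z), Zp(zp), pairE(pe), stackE(se), beta(b),
        wstack(std::exp(-b * se)), minh(mh), rng(seed) {}

  inline double unif(std::mt19937_64& r) {
    return (r() >> 11) * (1.0 / 9007199254740992.0);
  }

  double zval(int i, int j) const { return (i > j) ? 1.0 : Z(i, j); }

  void pair_case(int i, int j) {
    partner[i] = j;
    partner[j] = i;
    int a = i + 1, b = j - 1;
    double wp = pair_weight(pairE, beta, seq[i], seq[j]);
    double w_st = wp * wstack * Zp(a, b);
    double r = unif(rng) * Zp(i, j);
    if (r < w_st) {
      pair_case(a, b);
    } else {
      interval_nofull(a, b);
    }
  }

  // structures on [i,j] excluding the case that (i,j) itself is paired
  void interval_nofull(int i, int j) {
    if (i > j) return;
    double total = Z(i, j) - Zp(i, j);
    double r = unif(rng) * total;
    double acc = (i == j) ? 1.0 : Z(i + 1, j);
    if (r < acc) {
      interval(i + 1, j);
      return;
    }
    int last = -1;
    for (int k = i + minh + 1; k <= j - 1; ++k) {
      if (Zp(i, k) > 0.0) {
        last = k;
        acc += Zp(i, k) * zval(k + 1, j);
        if (r < acc) break;
      }
    }
    if (last < 0) { interval(i + 1, j); return; }  // fp safety
    pair_case(i, last);
    interval(last + 1, j);
  }

  void interval(int i, int j) {
    if (i > j) return;
    double r = unif(rng) * Z(i, j);
    double acc = (i == j) ? 1.0 : Z(i + 1, j);
    if (r < acc) {
      interval(i + 1, j);
      return;
    }
    int last = -1;
    for (int k = i + minh + 1; k <= j; ++k) {
      if (Zp(i, k) > 0.0) {
        last = k;
        acc += Zp(i, k) * zval(k + 1, j);
        if (r < acc) break;
      }
    }
    if (last < 0) { interval(i + 1, j); return; }
    pair_case(i, last);
    interval(last + 1, j);
  }

  std::vector<int> draw() {
    int n = seq.size();
    partner.assign(n, -1);
    interval(0, n - 1);
    return partner;
  }
};

std::vector<int> classify_partner(const std::vector<int>& partner) {
  static ContextClassifier cc;
  std::vector<int> cat;
  cc.classify(partner, cat);
  return cat;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix sample_structures_cpp(IntegerVector seq, List tables,
                                    NumericMatrix pairE, double stackE,
                                    int min_hairpin, double beta,
                                    int n_samples, double seed) {
  NumericMatrix Z = tables["Z"], Zp = tables["Zp"];
  Sampler s(seq, Z, Zp, pairE, stackE, min_hairpin, beta,
            static_cast<uint64_t>(seed));
  int n = seq.size();
  IntegerMatrix out(n_samples, n);
  for (int t = 0; t < n_samples; ++t) {
    std::vector<int> p = s.draw();
    for (int i = 0; i < n; ++i) out(t, i) = p[i];
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector classify_contexts_cpp(IntegerVector partner) {
  int n = partner.size();
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = partner[i];
  std::vector<int> cat = classify_partner(p);
  return IntegerVector(cat.begin(), cat.end());
}

// Sample n_samples structures and accumulate per-base context-category
// counts; returns a 6 x n count matrix (rows = category codes 0..5).
// [[Rcpp::export]]
NumericMatrix annotation_counts_cpp(IntegerVector seq, List tables,
                                    NumericMatrix pairE, double stackE,
                                    int min_hairpin, double beta,
                                    int n_samples, double seed) {
  NumericMatrix Z = tables["Z"], Zp = tables["Zp"];
  Sampler s(seq, Z, Zp, pairE, stackE, min_hairpin, beta,
            static_cast<uint64_t>(seed));
  int n = seq.size();
  NumericMatrix counts(6, n);
  ContextClassifier cc;
  std::vector<int> cat;
  for (int t = 0; t < n_samples; ++t) {
    s.draw();
    cc.classify(s.partner, cat);
    for (int i = 0; i < n; ++i) counts(cat[i], i) += 1.0;
  }
  return counts;
}

namespace {

void enumerate_interval(int i, int j, const IntegerVector& seq,
                        const NumericMatrix& pairE, int minh,
                        std::vector<std::vector<std::pair<int, int> > >& out) {
  out.clear();
  if (i > j) {
    out.push_back(std::vector<std::pair<int, int> >());
    return;
  }
  // i unpaired
  std::vector<std::vector<std::pair<int, int> > > rest;
  enumerate_interval(i + 1, j, seq, pairE, minh, rest);
  for (size_t r = 0; r < rest.size(); ++r) out.push_back(rest[r]);
  // i paired with k
  for (int k = i + minh + 1; k <= j; ++k) {
    if (seq[i] < 0 || seq[k] < 0) continue;
    if (!R_finite(pairE(seq[i], seq[k]))) continue;
    std::vector<std::vector<std::pair<int, int> > > in, right;
    enumerate_interval(i + 1, k - 1, seq, pairE, minh, in);
    enumerate_interval(k + 1, j, seq, pairE, minh, right);
    for (size_t a = 0; a < in.size(); ++a) {
      for (size_t b = 0; b < right.size(); ++b) {
        std::vector<std::pair<int, int> > s;
        s.push_back(std::make_pair(i, k));
        s.insert(s.end(), in[a].begin(), in[a].end());
        s.insert(s.end(), right[b].begin(), right[b].end());
        out.push_back(s);
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List enumerate_structures_cpp(IntegerVector seq, NumericMatrix pairE,
                              double stackE, int min_hairpin, double beta) {
  int n = seq.size();
  std::vector<std::vector<std::pair<int, int> > > all;
  enumerate_interval(0, n - 1, seq, pairE, min_hairpin, all);
  int m = all.size();
  List partners(m);
  NumericVector weights(m);
  for (int s = 0; s < m; ++s) {
    IntegerVector partner(n, -1);
    double energy = 0.0;
    for (size_t p = 0; p < all[s].size(); ++p) {
      int i = all[s][p].first, j = all[s][p].second;
      partner[i] = j;
      partner[j] = i;
      energy += pairE(seq[i], seq[j]);
    }
    // stacking bonus: pair (i,j) with (i+1,j-1) also paired
    for (size_t p = 0; p < all[s].size(); ++p) {
      int i = all[s][p].first, j = all[s][p].second;
      if (i + 1 < j - 1 && partner[i + 1] == j - 1) energy += stackE;
    }
    partners[s] = partner;
    weights[s] = std::exp(-beta * energy);
  }
  return List::create(_["partners"] = partners, _["weights"] = weights);
}

// Batch annotation: per-sequence partition + sampling + classification in
// one call; returns a list of 6 x n category-count matrices.
// [[Rcpp::export]]
List annotate_batch_cpp(List seqs, NumericMatrix pairE, double stackE,
                        int min_hairpin, double beta, int n_samples,
                        NumericVector seeds) {
  int nrec = seqs.size();
  List out(nrec);
  for (int t = 0; t < nrec; ++t) {
    IntegerVector seq = seqs[t];
    List tabs = fold_partition_cpp(seq, pairE, stackE, min_hairpin, beta);
    out[t] = annotation_counts_cpp(seq, tabs, pairE, stackE, min_hairpin,
                                   beta, n_samples, seeds[t]);
  }
  return out;
}

// Mean per-base pairing probability from a sampled ensemble (acceptance
// check for the weakly structured pool group).
// [[Rcpp::export]]
double mean_paired_prob_cpp(IntegerVector seq, NumericMatrix pairE,
                            double stackE, int min_hairpin, double beta,
                            int n_samples, double seed) {
  List tabs = fold_partition_cpp(seq, pairE, stackE, min_hairpin, beta);
  NumericMatrix Z = tabs["Z"], Zp = tabs["Zp"];
  Sampler s(seq, Z, Zp, pairE, stackE, min_hairpin, beta,
            static_cast<uint64_t>(seed));
  long paired = 0;
  int n = seq.size();
  for (int t = 0; t < n_samples; ++t) {
    s.draw();
    for (int i = 0; i < n; ++i) {
      if (s.partner[i] >= 0) ++paired;
    }
  }
  return paired / (double)((long)n_samples * n);
}
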