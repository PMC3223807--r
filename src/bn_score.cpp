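#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Family sufficient statistics and scores for discrete Bayesian networks.
// `records` holds 1-based state indices, one row per observation.  Parent
// instantiations are linearised with the first parent varying fastest.

static void check_indices(const IntegerMatrix& records, int child,
                          const IntegerVector& parents,
                          const IntegerVector& arities) {
  const int n = records.ncol();
  if (arities.size() != n) stop("arities must match the record columns");
  if (child == NA_INTEGER || child < 1 || child > n)
    stop("child column index out of range");
  for (int p = 0; p < parents.size(); ++p)
    if (parents[p] == NA_INTEGER || parents[p] < 1 || parents[p] > n)
      stop("parent column index out of range");
}

static void family_counts(const IntegerMatrix& records, int child,
                          const IntegerVector& parents,
                          const IntegerVector& arities,
                          std::vector<double>& F, int& q, int& r) {
  const int M = records.nrow();
  const int np = parents.size();
  r = arities[child - 1];
  q = 1;
  std::vector<int> stride(np);
  for (int p = 0; p < np; ++p) {
    stride[p] = q;
    q *= arities[parents[p] - 1];
  }
  F.assign((size_t)q * r, 0.0);
  for (int m = 0; m < M; ++m) {
    int j = 0;
    for (int p = 0; p < np; ++p)
      j += (records(m, parents[p] - 1) - 1) * stride[p];
    F[(size_t)j + (size_t)q * (records(m, child - 1) - 1)] += 1.0;
  }
}

static double k2_from_counts(const std::vector<double>& F, int q, int r) {
  double s = 0.0;
  const double lgr = std::lgamma((double)r);
  for (int j = 0; j < q; ++j) {
    double Fj = 0.0;
    for (int k = 0; k < r; ++k) {
      const double f = F[(size_t)j + (size_t)q * k];
      Fj += f;
      s += std::lgamma(f + 1.0);
    }
    s += lgr - std::lgamma(Fj + r);
  }
  return s;
}

static double bic_from_counts(const std::vector<double>& F, int q, int r,
                              int M) {
  double ll = 0.0;
  for (int j = 0; j < q; ++j) {
    double Fj = 0.0;
    for (int k = 0; k < r; ++k) Fj += F[(size_t)j + (size_t)q * k];
    if (Fj > 0.0)
      for (int k = 0; k < r; ++k) {
        const double f = F[(size_t)j + (size_t)q * k];
        if (f > 0.0) ll += f * std::log(f / Fj);
      }
  }
  const double dim = (double)q * (r - 1.0);
  return ll - 0.5 * dim * std::log((double)M);
}

// [[Rcpp::export(name = ".familyCountsC")]]
NumericMatrix familyCountsC(IntegerMatrix records, int child,
                            IntegerVector parents, IntegerVector arities) {
  check_indices(records, child, parents, arities);
  std::vector<double> F;
  int q, r;
  family_counts(records, child, parents, arities, F, q, r);
  NumericMatrix out(q, r);
  for (int j = 0; j < q; ++j)
    for (int k = 0; k < r; ++k) out(j, k) = F[(size_t)j + (size_t)q * k];
  return out;
}

// [[Rcpp::export(name = ".familyScoreC")]]
double familyScoreC(IntegerMatrix records, int child, IntegerVector parents,
                    IntegerVector arities, std::string kind) {
  check_indices(records, child, parents, arities);
  std::vector<double> F;
  int q, r;
  family_counts(records, child, parents, arities, F, q, r);
  if (kind == "k2") return k2_from_counts(F, q, r);
  return bic_from_counts(F, q, r, records.nrow());
}

// Greedy K2-style parent selection for one child: repeatedly add the single
// candidate that most improves the family score, candidates scanned in the
// given order (first wins ties), stopping at max_parents or when no strict
// improvement remains.  Returns chosen parents as 1-based column indices, in
// the order they were added.
// [[Rcpp::export(name = ".greedyParentsC")]]
IntegerVector greedyParentsC(IntegerMatrix records, int child,
                             IntegerVector candidates, IntegerVector arities,
                             int maxParents, std::string kind) {
  check_indices(records, child, candidates, arities);
  std::vector<int> chosen;
  std::vector<bool> used(candidates.size(), false);
  std::vector<double> F;
  int q, r;
  const bool k2 = (kind == "k2");
  const int M = records.nrow();

  IntegerVector cur(0);
  family_counts(records, child, cur, arities, F, q, r);
  double best = k2 ? k2_from_counts(F, q, r) : bic_from_counts(F, q, r, M);

  while ((int)chosen.size() < maxParents) {
    double bestNew = best;
    int bestIdx = -1;
    for (int c = 0; c < candidates.size(); ++c) {
      if (used[c]) continue;
      IntegerVector trial((int)chosen.size() + 1);
      for (size_t i = 0; i < chosen.size(); ++i) trial[i] = chosen[i];
      trial[(int)chosen.size()] = candidates[c];
      family_counts(records, child, trial, arities, F, q, r);
      const double s =
          k2 ? k2_from_counts(F, q, r) : bic_from_counts(F, q, r, M);
      if (s > bestNew + 1e-12) {  // strict improvement; first candidate wins ties
        bestNew = s;
        bestIdx = c;
      }
    }
    if (bestIdx < 0) break;
    used[bestIdx] = true;
    chosen.push_back(candidates[bestIdx]);
    best = bestNew;
  }
  return IntegerVector(chosen.begin(), chosen.end());
}
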