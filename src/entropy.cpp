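#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chebyshev-distance template matching for approximate entropy.
// phi_m = mean_i log( C_i^m ), C_i^m = (#j with d(x_i, x_j) <= r) / (N-m+1),
// self-matches included (i == j counts).
static double phi(const NumericVector& x, int m, double r) {
  int n = x.size();
  int nt = n - m + 1;
  std::vector<int> count(nt, 0);
  for (int i = 0; i < nt; ++i) {
    count[i]++;  // self-match
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d > r) break;
      }
      if (d <= r) { count[i]++; count[j]++; }
    }
  }
  double s = 0.0;
  for (int i = 0; i < nt; ++i) s += std::log((double)count[i] / nt);
  return s / nt;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  return phi(x, m, r) - phi(x, m + 1, r);
}

// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // templates of length m and m+1 both indexed 0..nt-1
  long long A = 0, B = 0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d > r) break;
      }
      if (d <= r) {
        B++;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A++;
      }
    }
  }
  if (B == 0) return NA_REAL;   // undefined: no template matches
  if (A == 0) return R_PosInf;  // no matches extend to m + 1
  return -std::log((double)A / (double)B);
}

// One shared pairwise scan for both entropies (the pipeline hot path).
// Returns c(ApEn, SampEn); equals apen_cpp / sampen_cpp exactly.
// [[Rcpp::export]]
NumericVector apen_sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt_m = n - m + 1;   // ApEn templates of length m
  int nt_m1 = n - m;      // ApEn templates of length m+1 == SampEn templates
  std::vector<int> cm(nt_m, 1), cm1(nt_m1, 1);  // self-matches included
  long long A = 0, B = 0;
  for (int i = 0; i < nt_m1; ++i) {
    for (int j = i + 1; j < nt_m1; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d > r) break;
      }
      if (d <= r) {
        cm[i]++; cm[j]++;
        B++;
        if (std::fabs(x[i + m] - x[j + m]) <= r) {
          cm1[i]++; cm1[j]++;
          A++;
        }
      }
    }
  }
  // the one extra length-m template (start nt_m - 1) against all others
  int t = nt_m - 1;
  for (int j = 0; j < t; ++j) {
    double d = 0.0;
    for (int k = 0; k < m; ++k) {
      double diff = std::fabs(x[t + k] - x[j + k]);
      if (diff > d) d = diff;
      if (d > r) break;
    }
    if (d <= r) { cm[t]++; cm[j]++; }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nt_m; ++i) phi_m += std::log((double)cm[i] / nt_m);
  for (int i = 0; i < nt_m1; ++i) phi_m1 += std::log((double)cm1[i] / nt_m1);
  double apen = phi_m / nt_m - phi_m1 / nt_m1;
  double sampen;
  if (B == 0) sampen = NA_REAL;
  else if (A == 0) sampen = R_PosInf;
  else sampen = -std::log((double)A / (double)B);
  return NumericVector::create(apen, sampen);
}
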