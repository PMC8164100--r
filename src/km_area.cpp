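// Kaplan-Meier step-function areas and permutation inference for restricted
// mean state durations.  Hot path of the trial simulator: a permutation test
// at n_perm = 500 inside a 5000-replicate operating-characteristic run calls
// the area routine millions of times, so it lives in C++.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Area under the product-limit estimate of S on [0, tau].  Ties: events are
// processed before censorings at the same time.  If the last observation is a
// censoring at L < tau the curve is carried forward at S(L) up to tau.
static double km_area_core(const std::vector<double>& time,
                           const std::vector<int>& event,
                           double tau) {
  const size_t n = time.size();
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (time[a] != time[b]) return time[a] < time[b];
    return event[a] > event[b];  // events first at ties
  });

  double area = 0.0, surv = 1.0, prev_t = 0.0;
  double at_risk = static_cast<double>(n);
  size_t i = 0;
  while (i < n) {
    double t = time[ord[i]];
    // count events and censorings at this time
    int d = 0, c = 0;
    size_t j = i;
    while (j < n && time[ord[j]] == t) {
      if (event[ord[j]]) ++d; else ++c;
      ++j;
    }
    if (t >= tau) break;
    if (d > 0) {
      area += surv * (t - prev_t);
      surv *= 1.0 - d / at_risk;
      prev_t = t;
    }
    at_risk -= (d + c);
    i = j;
  }
  area += surv * (tau - prev_t);
  return area;
}

// [[Rcpp::export(name = ".km_area_cpp")]]
double km_area_cpp(NumericVector time, IntegerVector event, double tau) {
  std::vector<double> t(time.begin(), time.end());
  std::vector<int> e(event.begin(), event.end());
  double maxt = *std::max_element(t.begin(), t.end());
  return km_area_core(t, e, std::min(tau, maxt));
}

// Restricted mean duration in a response state for one group of patients:
// area under KM of PFS minus area under KM of the composite
// (state-entry or progression) time, both on [0, tau_eff].
static double state_mean_group(const std::vector<double>& t1,
                               const std::vector<int>& e1,
                               const std::vector<double>& t0,
                               const std::vector<int>& e0,
                               double tau_eff) {
  return km_area_core(t1, e1, tau_eff) - km_area_core(t0, e0, tau_eff);
}

static void split_by_arm(const NumericVector& t1, const IntegerVector& e1,
                         const NumericVector& t0, const IntegerVector& e0,
                         const std::vector<int>& arm,
                         std::vector<double>& t1a, std::vector<int>& e1a,
                         std::vector<double>& t0a, std::vector<int>& e0a,
                         std::vector<double>& t1b, std::vector<int>& e1b,
                         std::vector<double>& t0b, std::vector<int>& e0b) {
  t1a.clear(); e1a.clear(); t0a.clear(); e0a.clear();
  t1b.clear(); e1b.clear(); t0b.clear(); e0b.clear();
  const int n = t1.size();
  for (int i = 0; i < n; ++i) {
    if (arm[i] == 0) {
      t1a.push_back(t1[i]); e1a.push_back(e1[i]);
      t0a.push_back(t0[i]); e0a.push_back(e0[i]);
    } else {
      t1b.push_back(t1[i]); e1b.push_back(e1[i]);
      t0b.push_back(t0[i]); e0b.push_back(e0[i]);
    }
  }
}

// Between-arm difference (arm 0 minus arm 1) in restricted mean state
// duration at a fixed shared tau_eff.
// [[Rcpp::export(name = ".state_diff_cpp")]]
double state_diff_cpp(NumericVector t1, IntegerVector e1,
                      NumericVector t0, IntegerVector e0,
                      IntegerVector arm, double tau_eff) {
  std::vector<int> a(arm.begin(), arm.end());
  std::vector<double> t1a, t0a, t1b, t0b;
  std::vector<int> e1a, e0a, e1b, e0b;
  split_by_arm(t1, e1, t0, e0, a, t1a, e1a, t0a, e0a, t1b, e1b, t0b, e0b);
  return state_mean_group(t1a, e1a, t0a, e0a, tau_eff) -
         state_mean_group(t1b, e1b, t0b, e0b, tau_eff);
}

// Permutation distribution of the between-arm difference in restricted mean
// state duration under arm-label exchange.  Uses R's RNG (seed set from R).
// Returns the number of permuted |diff*| >= |observed diff| - 1e-12.
// [[Rcpp::export(name = ".perm_count_cpp")]]
int perm_count_cpp(NumericVector t1, IntegerVector e1,
                   NumericVector t0, IntegerVector e0,
                   IntegerVector arm, double tau_eff,
                   double obs_diff, int n_perm) {
  const int n = t1.size();
  std::vector<int> lab(arm.begin(), arm.end());
  std::vector<double> t1a, t0a, t1b, t0b;
  std::vector<int> e1a, e0a, e1b, e0b;
  const double thr = std::fabs(obs_diff) - 1e-12;
  int count = 0;
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle of arm labels
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(lab[i], lab[j]);
    }
    split_by_arm(t1, e1, t0, e0, lab, t1a, e1a, t0a, e0a, t1b, e1b, t0b, e0b);
    double d = state_mean_group(t1a, e1a, t0a, e0a, tau_eff) -
               state_mean_group(t1b, e1b, t0b, e0b, tau_eff);
    if (std::fabs(d) >= thr) ++count;
  }
  return count;
}

// Stratified bootstrap (within-arm resampling) of the ratio of restricted
// mean state durations, arm 0 over arm 1.  NaN when a resample's arm-1 mean
// is zero; the R caller drops those with a logged count.
// [[Rcpp::export(name = ".boot_ratio_cpp")]]
NumericVector boot_ratio_cpp(NumericVector t1, IntegerVector e1,
                             NumericVector t0, IntegerVector e0,
                             IntegerVector arm, double tau_eff, int n_boot) {
  std::vector<int> a(arm.begin(), arm.end());
  std::vector<int> idx_a, idx_b;
  const int n = t1.size();
  for (int i = 0; i < n; ++i) (a[i] == 0 ? idx_a : idx_b).push_back(i);
  const int na = idx_a.size(), nb = idx_b.size();
  std::vector<double> t1a(na), t0a(na), t1b(nb), t0b(nb);
  std::vector<int> e1a(na), e0a(na), e1b(nb), e0b(nb);
  NumericVector out(n_boot);
  RNGScope scope;
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < na; ++i) {
      int k = idx_a[static_cast<int>(unif_rand() * na) % na];
      t1a[i] = t1[k]; e1a[i] = e1[k]; t0a[i] = t0[k]; e0a[i] = e0[k];
    }
    for (int i = 0; i < nb; ++i) {
      int k = idx_b[static_cast<int>(unif_rand() * nb) % nb];
      t1b[i] = t1[k]; e1b[i] = e1[k]; t0b[i] = t0[k]; e0b[i] = e0[k];
    }
    double ma = state_mean_group(t1a, e1a, t0a, e0a, tau_eff);
    double mb = state_mean_group(t1b, e1b, t0b, e0b, tau_eff);
    out[b] = (mb > 0.0) ? ma / mb : NA_REAL;
  }
  return out;
}
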