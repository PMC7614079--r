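#include <Rcpp.h>
using namespace Rcpp;

// Per-sample threshold labeling of an extension trace against k ordered level
// means. A transition path (label 0) is the maximal run of samples between the
// last time the signal sat on the home side of its current level's mean and
// the first time it reaches another level's mean; everything else belongs to
// the current level's dwell (labels 1..k). Excursions beyond the home mean
// that return without reaching another mean stay part of the dwell.
// [[Rcpp::export]]
IntegerVector label_threshold_cpp(NumericVector z, NumericVector means) {
  const int n = z.size(), k = means.size();
  IntegerVector lab(n);
  if (n == 0 || k == 0) return lab;

  // initial level: nearest mean to the first sample (leading dwell is
  // edge-censored downstream, so this choice only affects discarded stats)
  int cur = 0;
  double best = R_PosInf;
  for (int j = 0; j < k; ++j) {
    double d = std::fabs(z[0] - means[j]);
    if (d < best) { best = d; cur = j; }
  }

  int dwell_start = 0;
  int last_below = (z[0] <= means[cur]) ? 0 : -1;
  int last_above = (z[0] >= means[cur]) ? 0 : -1;
  lab[0] = cur + 1;

  for (int i = 1; i < n; ++i) {
    const double zi = z[i];
    int dest = -1;
    if (cur < k - 1 && zi >= means[cur + 1]) {
      dest = cur + 1;
      while (dest < k - 1 && zi >= means[dest + 1]) ++dest;
    } else if (cur > 0 && zi <= means[cur - 1]) {
      dest = cur - 1;
      while (dest > 0 && zi <= means[dest - 1]) --dest;
    }
    if (dest >= 0) {
      // backtrack to the last sample on the home side of the current mean;
      // if the signal never touched home during this dwell (pass-through),
      // the whole provisional dwell is part of the transition path
      int anchor = (dest > cur) ? last_below : last_above;
      int tp_start = (anchor >= dwell_start) ? anchor + 1 : dwell_start;
      for (int t = tp_start; t < i; ++t) lab[t] = 0;
      cur = dest;
      dwell_start = i;
      last_below = (zi <= means[cur]) ? i : -1;
      last_above = (zi >= means[cur]) ? i : -1;
      lab[i] = cur + 1;
    } else {
      lab[i] = cur + 1;
      if (zi <= means[cur]) last_below = i;
      if (zi >= means[cur]) last_above = i;
    }
  }
  return lab;
}

// Per-fragment mean and variance of z over half-open index ranges
// [start_i, end_i] (1-based inclusive). Returns a 2-column matrix.
// [[Rcpp::export]]
NumericMatrix fragment_moments_cpp(NumericVector z, IntegerVector start,
                                   IntegerVector end) {
  const int m = start.size();
  NumericMatrix out(m, 2);
  for (int f = 0; f < m; ++f) {
    const int a = start[f] - 1, b = end[f] - 1;
    const int len = b - a + 1;
    double s = 0.0;
    for (int i = a; i <= b; ++i) s += z[i];
    const double mu = s / len;
    double ss = 0.0;
    for (int i = a; i <= b; ++i) {
      const double d = z[i] - mu;
      ss += d * d;
    }
    out(f, 0) = mu;
    out(f, 1) = (len > 1) ? ss / (len - 1) : 0.0;
  }
  return out;
}
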