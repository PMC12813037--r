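#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double median_of(std::vector<double> v) {
  size_t n = v.size();
  if (n == 0) return NA_REAL;
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double m = v[n / 2];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.end());
    m = 0.5 * (m + v[n / 2 - 1]);
  }
  return m;
}

// Artifact flagging against a running median of the last `window` accepted
// intervals. Flagged beats do not enter the reference buffer, so runs of
// consecutive artifacts remain detectable. Runs of <= max_run flagged beats
// are replaced by the reference (interpolated); longer runs are dropped.
// [[Rcpp::export]]
List clean_rr_cpp(NumericVector rr, double threshold, int window, int max_run) {
  int n = rr.size();
  LogicalVector flagged(n), dropped(n);
  NumericVector out(clone(rr));
  NumericVector ref_at(n);

  // initial reference: median of the leading beats
  int n_init = std::min<int>(n, 2 * window + 1);
  std::vector<double> init(rr.begin(), rr.begin() + n_init);
  double ref0 = median_of(init);

  std::vector<double> buf;  // last `window` accepted intervals
  buf.reserve(window + 1);

  for (int i = 0; i < n; ++i) {
    double ref = buf.empty() ? ref0 : median_of(buf);
    ref_at[i] = ref;
    double dev = std::abs(rr[i] - ref) / ref;
    if (dev > threshold) {
      flagged[i] = true;
    } else {
      buf.push_back(rr[i]);
      if ((int)buf.size() > window) buf.erase(buf.begin());
    }
  }

  // run-length rule on flagged beats
  int i = 0;
  while (i < n) {
    if (!flagged[i]) { ++i; continue; }
    int j = i;
    while (j < n && flagged[j]) ++j;
    int len = j - i;
    for (int k = i; k < j; ++k) {
      if (len > max_run) {
        dropped[k] = true;
        flagged[k] = false;  // excluded, not interpolated
      } else {
        out[k] = ref_at[k];
      }
    }
    i = j;
  }

  return List::create(_["rr_ms"] = out, _["interpolated"] = flagged,
                      _["dropped"] = dropped);
}

// Generate beat-by-beat RR intervals for a set of 5-min epochs with
// sinusoidal respiratory modulation: rr = base + A * sin(2*pi*f*tau), tau the
// elapsed time within the epoch at the interval's start; beat times cumulate.
// [[Rcpp::export]]
List simulate_rr_epochs_cpp(NumericVector t0_s, NumericVector amp_ms,
                            double base_ms, double f_hz, double duration_s) {
  int n_epochs = t0_s.size();
  std::vector<double> time_s, rr_ms;
  std::vector<int> epoch_idx;
  size_t guess = (size_t)(n_epochs * (duration_s * 1000.0 / base_ms + 2));
  time_s.reserve(guess); rr_ms.reserve(guess); epoch_idx.reserve(guess);

  for (int e = 0; e < n_epochs; ++e) {
    double A = amp_ms[e];
    double tau = 0.0;  // elapsed seconds within the epoch
    while (true) {
      double r = base_ms + A * std::sin(2.0 * M_PI * f_hz * tau);
      tau += r / 1000.0;
      if (tau > duration_s) break;
      time_s.push_back(t0_s[e] + tau);  // R-wave time = end of interval
      rr_ms.push_back(r);
      epoch_idx.push_back(e + 1);
    }
  }

  return List::create(_["beat_time_s"] = wrap(time_s), _["rr_ms"] = wrap(rr_ms),
                      _["epoch"] = wrap(epoch_idx));
}
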