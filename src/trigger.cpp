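#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Causal double-threshold state machine: the smoothed rectified envelope is
// compared against mu_b + k * sigma_b, where mu_b and sigma_b are baseline
// statistics of the raw rectified signal (`rect`), tracked over a circular
// buffer holding the most recent `base_n` clearly-relaxed samples (those
// below the OFF threshold), seeded from the initial `init_n` samples which
// are assumed relaxed. Using the rectified-sample SD (rather than the much
// smaller SD of the smoothed envelope) makes k_on = 3 a robust threshold.
// A state change must persist for `debounce_n` samples before it is
// committed, and is then backdated to the first sample of the run.
// [[Rcpp::export]]
IntegerVector wo_coarse_trigger(NumericVector env, NumericVector rect,
                                int init_n, int base_n,
                                double k_on, double k_off, int debounce_n) {
  int n = env.size();
  IntegerVector trig(n);
  std::vector<double> buf(base_n, 0.0);
  int cnt = 0, pos = 0;
  double sum = 0.0, sumsq = 0.0;
  auto push = [&](double v) {
    if (cnt < base_n) {
      buf[pos] = v; sum += v; sumsq += v * v; cnt++;
    } else {
      double old = buf[pos];
      sum += v - old; sumsq += v * v - old * old;
      buf[pos] = v;
    }
    pos = (pos + 1) % base_n;
  };
  int seed_n = init_n < n ? init_n : n;
  for (int t = 0; t < seed_n; ++t) push(rect[t]);

  int state = 0, run = 0;
  for (int t = 0; t < n; ++t) {
    double mu = cnt > 0 ? sum / cnt : 0.0;
    double var = cnt > 1 ? sumsq / cnt - mu * mu : 0.0;
    double sd = var > 0 ? std::sqrt(var) : 0.0;
    if (state == 0) {
      if (env[t] > mu + k_on * sd) {
        if (++run >= debounce_n) {
          state = 1;
          for (int j = t - run + 1; j <= t; ++j) trig[j] = 1;
          run = 0;
        }
      } else {
        run = 0;
        if (t >= seed_n && env[t] <= mu + k_off * sd) push(rect[t]);
      }
    } else {
      trig[t] = 1;
      if (env[t] < mu + k_off * sd) {
        if (++run >= debounce_n) {
          state = 0;
          for (int j = t - run + 1; j <= t; ++j) trig[j] = 0;
          run = 0;
        }
      } else {
        run = 0;
      }
    }
  }
  return trig;
}
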