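#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Annual projection of one age-structured female population, replicated over
// independent Monte Carlo iterations.
//
// Within one yearly step the order of events is:
//   1. density feedback multiplier from current total N,
//   2. offtake (post-census removal, before projection),
//   3. reproduction (Poisson recruits) and survival (binomial) -- or their
//      deterministic expectations when `stochastic` is false,
//   4. catastrophe (Bernoulli event thinning every age class).
//
// `fert_row` is the census-adjusted first row of the Leslie matrix; when
// `scale_fert_row` is true (pre-breeding census, first-row entries contain a
// survival factor) the feedback multiplier also scales the first row.
// `cat_prob` has length 1 (shared annual probability) or `iterations`
// (per-iteration probability, used by the catastrophe-magnitude scenario where
// each run draws its own frequency multiplier).
//
// Deterministic mode (`stochastic = false`) skips catastrophe draws entirely
// so that the projection equals the feedback-adjusted matrix-power sequence.

// [[Rcpp::export]]
List sim_engine(NumericVector surv, NumericVector fert_row, bool self_loop,
                NumericVector n0, int steps, int iterations,
                double K, double fb_c, double fb_theta,
                NumericVector cat_prob, double cat_severity,
                NumericVector offtake, double eq_threshold,
                bool stochastic, bool scale_fert_row,
                bool store_totals, int burnin) {
  const int k = surv.size();
  if (fert_row.size() != k || n0.size() != k || offtake.size() != k)
    stop("surv, fert_row, n0 and offtake must have equal length");
  if (steps < 1 || iterations < 1) stop("steps and iterations must be >= 1");

  NumericVector final_total(iterations);
  NumericVector min_after_burnin(iterations);
  LogicalVector quasi_extinct(iterations);
  int kept = store_totals ? (steps - burnin) : 0;
  if (kept < 0) kept = 0;
  NumericMatrix totals(kept, store_totals ? iterations : 0);

  std::vector<double> n(k), nn(k);
  RNGScope rng;

  for (int it = 0; it < iterations; ++it) {
    for (int x = 0; x < k; ++x) n[x] = n0[x];
    double cp = (cat_prob.size() == 1) ? cat_prob[0] : cat_prob[it];
    double minN = R_PosInf;
    double N = 0.0;
    for (int x = 0; x < k; ++x) N += n[x];

    for (int t = 0; t < steps; ++t) {
      if (N <= 0.0) {
        // absorbed: remaining record is zero
        if (store_totals && t >= burnin)
          for (int tt = t - burnin; tt < kept; ++tt) totals(tt, it) = 0.0;
        minN = 0.0;
        N = 0.0;
        break;
      }
      double s = 1.0;
      if (fb_c > 0.0 && K > 0.0)
        s = 1.0 / (1.0 + fb_c * std::pow(N / K, fb_theta));

      for (int x = 0; x < k; ++x) {
        if (offtake[x] > 0.0) {
          n[x] -= offtake[x];
          if (n[x] < 0.0) n[x] = 0.0;
        }
      }

      double repro_mean = 0.0;
      double fscale = scale_fert_row ? s : 1.0;
      for (int x = 0; x < k; ++x) repro_mean += fert_row[x] * fscale * n[x];

      if (stochastic) {
        nn[0] = (repro_mean > 0.0) ? R::rpois(repro_mean) : 0.0;
        for (int x = 0; x < k - 1; ++x) {
          double size = std::floor(n[x] + 0.5);
          if (size > 0.0) {
            double p = surv[x] * s;
            if (p > 1.0) p = 1.0;
            nn[x + 1] = R::rbinom(size, p);
          } else nn[x + 1] = 0.0;
        }
        if (self_loop) {
          double size = std::floor(n[k - 1] + 0.5);
          if (size > 0.0) {
            double p = surv[k - 1] * s;
            if (p > 1.0) p = 1.0;
            nn[k - 1] += R::rbinom(size, p);
          }
        }
        if (cp > 0.0 && unif_rand() < cp) {
          for (int x = 0; x < k; ++x) {
            double size = std::floor(nn[x] + 0.5);
            nn[x] = (size > 0.0) ? R::rbinom(size, 1.0 - cat_severity) : 0.0;
          }
        }
      } else {
        nn[0] = repro_mean;
        for (int x = 0; x < k - 1; ++x) {
          double p = surv[x] * s;
          if (p > 1.0) p = 1.0;
          nn[x + 1] = n[x] * p;
        }
        if (self_loop) {
          double p = surv[k - 1] * s;
          if (p > 1.0) p = 1.0;
          nn[k - 1] += n[k - 1] * p;
        }
      }

      N = 0.0;
      for (int x = 0; x < k; ++x) { n[x] = nn[x]; N += n[x]; }
      if (t >= burnin) {
        if (store_totals) totals(t - burnin, it) = N;
        if (N < minN) minN = N;
      }
    }
    final_total[it] = N;
    min_after_burnin[it] = (minN == R_PosInf) ? N : minN;
    quasi_extinct[it] = (N < eq_threshold);
  }

  List out = List::create(
    _["final_total"] = final_total,
    _["min_after_burnin"] = min_after_burnin,
    _["quasi_extinct"] = quasi_extinct);
  if (store_totals) out["totals"] = totals;
  return out;
}
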