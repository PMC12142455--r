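#include <Rcpp.h>
#include <set>
#include <cmath>
#include <climits>
using namespace Rcpp;

// Greedy nearest-neighbour propensity matching without replacement.
//
// Treated units are visited in the order supplied by the caller (descending
// propensity); each takes the unused control with the closest score. Ties
// at equal |score difference| break by smaller control id. A pair whose
// distance exceeds the caliper is discarded (the control stays available).
//
// treated_scores: scores of treated units in processing order.
// control_scores / control_ids: scores and integer ids of the controls.
// Returns, per treated unit, the matched control id (NA if discarded) and
// the score distance.
// [[Rcpp::export]]
List nn_match_cpp(NumericVector treated_scores,
                  NumericVector control_scores,
                  IntegerVector control_ids,
                  double caliper) {
  const int nt = treated_scores.size();
  const int ncon = control_scores.size();
  IntegerVector match_id(nt, NA_INTEGER);
  NumericVector match_dist(nt, NA_REAL);

  std::set<std::pair<double, int>> pool;  // (score, id), id breaks ties
  for (int c = 0; c < ncon; ++c)
    pool.insert({control_scores[c], control_ids[c]});

  for (int t = 0; t < nt; ++t) {
    if (pool.empty()) break;
    const double st = treated_scores[t];
    auto hi = pool.lower_bound({st, INT_MIN});
    double best_d = R_PosInf; std::pair<double, int> best{0.0, -1};
    if (hi != pool.end()) {
      best_d = std::fabs(hi->first - st);
      best = *hi;
    }
    if (hi != pool.begin()) {
      auto lo = std::prev(hi);
      const double d = std::fabs(lo->first - st);
      if (d < best_d || (d == best_d && (best.second < 0 || lo->second < best.second))) {
        best_d = d; best = *lo;
      }
    }
    // equal-distance neighbours with smaller ids may sit adjacent on either
    // side (identical scores); scan runs of equal scores for the min id
    if (best.second >= 0) {
      auto it = hi;
      while (it != pool.end() && std::fabs(it->first - st) == best_d) {
        if (it->second < best.second) best = *it;
        ++it;
      }
      it = hi;
      while (it != pool.begin()) {
        --it;
        if (std::fabs(it->first - st) != best_d) break;
        if (it->second < best.second) best = *it;
      }
    }
    if (best.second >= 0 && best_d <= caliper) {
      match_id[t] = best.second;
      match_dist[t] = best_d;
      pool.erase(best);
    }
  }
  return List::create(_["control_id"] = match_id, _["distance"] = match_dist);
}
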