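#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stochastic priority queue: a list of L demands with priorities x_i drawn
// uniformly on (floor, 1). Each step one demand is executed, chosen with
// probability x_i^alpha / sum_j x_j^alpha, its waiting time (current step -
// arrival step) recorded, and a fresh uniform priority put in its place.
// Executions during the burn-in are not emitted. Demands still queued at
// the end are returned as censored ages. Uses R's RNG so that set.seed()
// gives bit-identical runs.
// [[Rcpp::export]]
List simulate_queue_cpp(int L, double alpha, int steps, int burnin,
                        double floor_) {
  if (L < 1) stop("L must be >= 1");
  if (steps < 1) stop("steps must be >= 1");
  if (alpha < 0) stop("alpha must be >= 0");
  std::vector<double> x(L);
  std::vector<int> arrival(L, 0);
  for (int i = 0; i < L; ++i)
    x[i] = floor_ + (1.0 - floor_) * R::runif(0.0, 1.0);

  std::vector<int> taus;
  std::vector<double> pris;
  taus.reserve(steps > burnin ? steps - burnin : 0);
  pris.reserve(steps > burnin ? steps - burnin : 0);
  std::vector<double> w(L);
  int n_max_selected = 0;

  for (int t = 1; t <= steps; ++t) {
    double cur_max = x[0];
    for (int i = 1; i < L; ++i)
      if (x[i] > cur_max) cur_max = x[i];
    // weights are normalized by the current maximum before exponentiation:
    // selection probabilities are unchanged, but x^alpha cannot underflow
    // for every demand at once under large alpha
    double tot = 0.0;
    for (int i = 0; i < L; ++i) {
      w[i] = (alpha == 0.0) ? 1.0 : std::pow(x[i] / cur_max, alpha);
      tot += w[i];
    }
    double u = R::runif(0.0, tot);
    int sel = L - 1;
    double c = 0.0;
    for (int i = 0; i < L; ++i) {
      c += w[i];
      if (u <= c) { sel = i; break; }
    }
    if (x[sel] == cur_max) ++n_max_selected;
    if (t > burnin) {
      taus.push_back(t - arrival[sel]);
      pris.push_back(x[sel]);
    }
    x[sel] = floor_ + (1.0 - floor_) * R::runif(0.0, 1.0);
    arrival[sel] = t;
  }

  IntegerVector cens(L);
  NumericVector remaining(L);
  for (int i = 0; i < L; ++i) {
    cens[i] = steps - arrival[i];
    remaining[i] = x[i];
  }
  return List::create(_["taus"] = wrap(taus),
                      _["executed_priorities"] = wrap(pris),
                      _["censored_ages"] = cens,
                      _["remaining_priorities"] = remaining,
                      _["n_max_selected"] = n_max_selected);
}
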