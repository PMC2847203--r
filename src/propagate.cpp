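#include <Rcpp.h>
using namespace Rcpp;

// Daily-cycle Markov cohort arithmetic.  Transition matrices are supplied as
// an R x R x n_regime cube (row-stochastic slices); `regime` maps each day
// t = 1..T to a slice, so piecewise-constant age effects cost a handful of
// slices while polynomial age effects use one slice per day.

// occupancy vector after t days
// [[Rcpp::export]]
NumericVector cpp_propagate(NumericVector cube, IntegerVector regime,
                            NumericVector pi0, int t) {
  IntegerVector dims = cube.attr("dim");
  const int R = dims[0];
  NumericVector pi = clone(pi0), nxt(R);
  for (int day = 0; day < t; ++day) {
    const double *P = &cube[(regime[day] - 1) * R * R];
    for (int s = 0; s < R; ++s) nxt[s] = 0.0;
    for (int r = 0; r < R; ++r) {
      const double pr = pi[r];
      if (pr == 0.0) continue;
      for (int s = 0; s < R; ++s) nxt[s] += pr * P[r + s * R];
    }
    pi = clone(nxt);
  }
  return pi;
}

// discounted expected cost and utility-day accumulation over T days:
// sum_t disc[t] * (pi_t . costs) and sum_t disc[t] * (pi_t . utils)
// [[Rcpp::export]]
NumericVector cpp_ce_accumulate(NumericVector cube, IntegerVector regime,
                                NumericVector pi0, NumericVector disc,
                                NumericVector costs, NumericVector utils) {
  IntegerVector dims = cube.attr("dim");
  const int R = dims[0];
  const int T = regime.size();
  std::vector<double> pi(pi0.begin(), pi0.end()), nxt(R);
  double cost = 0.0, util = 0.0;
  for (int day = 0; day < T; ++day) {
    const double *P = &cube[(regime[day] - 1) * R * R];
    for (int s = 0; s < R; ++s) nxt[s] = 0.0;
    for (int r = 0; r < R; ++r) {
      const double pr = pi[r];
      if (pr == 0.0) continue;
      for (int s = 0; s < R; ++s) nxt[s] += pr * P[r + s * R];
    }
    double c = 0.0, u = 0.0;
    for (int s = 0; s < R; ++s) { c += nxt[s] * costs[s]; u += nxt[s] * utils[s]; }
    cost += disc[day] * c;
    util += disc[day] * u;
    pi.swap(nxt);
  }
  return NumericVector::create(cost, util);
}

// individual-level microsimulation of the same process: n trajectories from
// `start`, accumulating discounted cost and utility-days; a trajectory stops
// early once it enters an absorbing state with zero cost and utility.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_microsim(NumericVector cube, IntegerVector regime,
                           int start, NumericVector disc,
                           NumericVector costs, NumericVector utils,
                           LogicalVector absorbing, int n) {
  IntegerVector dims = cube.attr("dim");
  const int R = dims[0];
  const int T = regime.size();
  NumericMatrix out(n, 2);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    int state = start - 1;
    double cost = 0.0, util = 0.0;
    for (int day = 0; day < T; ++day) {
      const double *P = &cube[(regime[day] - 1) * R * R];
      double u = unif_rand(), acc = 0.0;
      int s = R - 1;
      for (int k = 0; k < R; ++k) {
        acc += P[state + k * R];
        if (u <= acc) { s = k; break; }
      }
      state = s;
      cost += disc[day] * costs[state];
      util += disc[day] * utils[state];
      if (absorbing[state] && costs[state] == 0.0 && utils[state] == 0.0) break;
    }
    out(i, 0) = cost;
    out(i, 1) = util;
  }
  return out;
}

// simulate up to `ndays` one-day transitions under a fixed matrix P, tallying
// the from->to counts (modified in place); stops once an absorbing state is
// entered (the transition into it is counted, the stay there is not observed).
// Returns the final state (1-based).
// [[Rcpp::export]]
int cpp_sim_segment(NumericMatrix P, int start, int ndays,
                    IntegerMatrix counts, LogicalVector absorbing) {
  const int R = P.nrow();
  int state = start - 1;
  RNGScope scope;
  for (int day = 0; day < ndays; ++day) {
    double u = unif_rand(), acc = 0.0;
    int s = R - 1;
    for (int k = 0; k < R; ++k) {
      acc += P(state, k);
      if (u <= acc) { s = k; break; }
    }
    counts(state, s) += 1;
    state = s;
    if (absorbing[state]) break;
  }
  return state + 1;
}
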