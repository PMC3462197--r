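#include <Rcpp.h>
using namespace Rcpp;

// Sequential commuter allocation.
//
// Each step places one commuter: an origin is drawn among origins with
// remaining out-capacity (uniformly, or proportionally to remaining
// out-capacity), then a destination is drawn with probability proportional
// to remaining_in[j] * decay(i, j) (or to the eligibility indicator alone
// for the uniform baseline). Both margins are decremented.
//
// `decay` is exp(-beta * d) with ineligible (e.g. self) cells set to 0;
// a zero decay entry makes a destination permanently ineligible for that
// origin. Eligibility otherwise requires remaining_in[j] > 0. Because
// remaining capacity only decreases, an origin whose weight row sums to
// zero ("starved") can never recover and is retired; its remaining
// commuters are reported as unplaced.
//
// Uses R's RNG (two unif_rand() draws per step, one if the origin is
// forced), so results are reproducible from set.seed() and can be mirrored
// draw-for-draw by a pure-R reference implementation.
//
// [[Rcpp::export]]
List allocate_commuters_cpp(IntegerVector out0, IntegerVector in0,
                            NumericMatrix decay, bool uniform_dest,
                            bool origin_by_mass) {
  const int n_core = decay.nrow();
  const int n_dest = decay.ncol();
  if (out0.size() != n_core) stop("out0 length must equal nrow(decay)");
  if (in0.size() != n_dest) stop("in0 length must equal ncol(decay)");

  std::vector<int> rem_out(out0.begin(), out0.end());
  std::vector<int> rem_in(in0.begin(), in0.end());
  IntegerMatrix flows(n_core, n_dest);

  std::vector<int> active;
  active.reserve(n_core);
  for (int i = 0; i < n_core; ++i)
    if (rem_out[i] > 0) active.push_back(i);

  double unplaced = 0.0;
  long long steps = 0;

  while (!active.empty()) {
    if ((++steps & 0xFFFF) == 0) Rcpp::checkUserInterrupt();

    // origin draw
    int pos;
    const int n_active = static_cast<int>(active.size());
    if (n_active == 1) {
      pos = 0;
    } else if (origin_by_mass) {
      double tot = 0.0;
      for (int p = 0; p < n_active; ++p) tot += rem_out[active[p]];
      const double target = unif_rand() * tot;
      double cum = 0.0;
      pos = n_active - 1;
      for (int p = 0; p < n_active; ++p) {
        cum += rem_out[active[p]];
        if (cum > target) { pos = p; break; }
      }
    } else {
      pos = static_cast<int>(unif_rand() * n_active);
      if (pos >= n_active) pos = n_active - 1;
    }
    const int i = active[pos];

    // destination weights for origin i
    double S = 0.0;
    for (int j = 0; j < n_dest; ++j) {
      if (rem_in[j] <= 0) continue;
      S += uniform_dest ? (decay(i, j) > 0.0 ? 1.0 : 0.0)
                        : decay(i, j) * rem_in[j];
    }

    if (S <= 0.0) {  // starved origin: retire it
      unplaced += rem_out[i];
      rem_out[i] = 0;
      active[pos] = active.back();
      active.pop_back();
      continue;
    }

    const double target = unif_rand() * S;
    double cum = 0.0;
    int j = -1, last_pos_j = -1;
    for (int jj = 0; jj < n_dest; ++jj) {
      if (rem_in[jj] <= 0) continue;
      const double w = uniform_dest ? (decay(i, jj) > 0.0 ? 1.0 : 0.0)
                                    : decay(i, jj) * rem_in[jj];
      if (w <= 0.0) continue;
      last_pos_j = jj;
      cum += w;
      if (cum > target) { j = jj; break; }
    }
    if (j < 0) j = last_pos_j;  // guard against float round-off at the top end

    flows(i, j) += 1;
    rem_out[i] -= 1;
    rem_in[j] -= 1;
    if (rem_out[i] == 0) {
      active[pos] = active.back();
      active.pop_back();
    }
  }

  return List::create(_["flows"] = flows,
                      _["unplaced"] = unplaced,
                      _["remaining_in"] = IntegerVector(rem_in.begin(), rem_in.end()));
}
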