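// Exact solver for the (alpha,beta)-k-feature-set selection problem.
//
// maximize   sum_f w_f x_f        (w_f = number of sample pairs feature f
//                                  explains: differing on between-class
//                                  pairs, agreeing on within-class pairs)
// subject to sum_f x_f = k, forced features fixed to 1, and for every
//            constrained pair p: sum_{f in set(p)} x_f >= req_p
//
// Complete branch-and-bound with most-constrained-pair branching: at each
// node the unmet pair with the fewest undecided member features is chosen
// and the branches enumerate which of its undecided members is the first
// (in weight order) to enter the solution — the standard complete search
// for covering problems. Once every pair constraint is met, the optimal
// completion is closed-form: the remaining k - chosen slots take the
// largest-weight undecided features (additional features never violate a
// >= constraint). Upper bound at any node: current objective plus the sum
// of the largest k - chosen undecided weights. Fully deterministic:
// features are examined in weight order with original index as tie-break,
// the first optimum encountered is kept.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct BB {
  int m = 0, k = 0, P = 0;
  std::vector<std::vector<int>> fp;   // feature -> constrained pair ids
  std::vector<std::vector<int>> pf;   // pair -> member feature ids
  std::vector<double> w;
  std::vector<int> order;             // feature ids by weight desc
  std::vector<int> cov, avail, req;
  std::vector<signed char> state;     // 0 undecided, 1 in, -1 out
  std::vector<signed char> scratch;   // membership bitmap workspace
  int n_unmet = 0, chosen = 0, P_active = 0;
  std::vector<int> n_active;          // per feature: active pairs covered
  long long total_cov = 0, slack_tot = 0, min_miss_static = 0;
  double obj = 0.0;
  long long nodes = 0, node_limit = 0;
  bool feasible_only = false, found = false, limit_hit = false, stop = false;
  double best_obj = -1.0;
  std::vector<signed char> best;

  void include(int f) {
    state[f] = 1; ++chosen; obj += w[f];
    total_cov += n_active[f];
    for (int p : fp[f]) {
      --avail[p];
      if (++cov[p] == req[p]) --n_unmet;
    }
  }
  void undo_include(int f) {
    state[f] = 0; --chosen; obj -= w[f];
    total_cov -= n_active[f];
    for (int p : fp[f]) {
      ++avail[p];
      if (cov[p]-- == req[p]) ++n_unmet;
    }
  }
  void exclude(int f) {
    state[f] = -1;
    for (int p : fp[f]) --avail[p];
  }
  void undo_exclude(int f) {
    state[f] = 0;
    for (int p : fp[f]) ++avail[p];
  }

  // sum of the `need` largest undecided weights; -1 if fewer available
  double top_undecided(int need, std::vector<int>* take = nullptr) const {
    double s = 0.0;
    int got = 0;
    for (int f : order) {
      if (got == need) break;
      if (state[f] == 0) {
        s += w[f];
        if (take) take->push_back(f);
        ++got;
      }
    }
    return got == need ? s : -1.0;
  }

  void record(double total, const std::vector<int>& extra) {
    if (!found || total > best_obj) {
      found = true;
      best_obj = total;
      best = state;
      for (int f : extra) best[f] = 1;
      if (feasible_only) stop = true;
    }
  }

  void dfs() {
    if (stop || limit_hit) return;
    if (++nodes > node_limit) { limit_hit = true; return; }

    int slots = k - chosen;
    // miss accounting: every selected feature misses P - |fp| pairs and a
    // pair p tolerates at most k - req_p missing selected features
    long long cur_miss = (long long)chosen * P_active - total_cov;
    if (cur_miss + (long long)slots * min_miss_static > slack_tot) return;
    if (n_unmet == 0) {
      std::vector<int> extra;
      double s = top_undecided(slots, &extra);
      if (s >= 0.0) record(obj + s, extra);
      return;
    }
    if (slots == 0) return;
    if (found && !feasible_only) {
      // early-exit bound: accumulate the largest undecided weights and
      // stop as soon as the bound provably exceeds the incumbent
      double gap = best_obj - obj;
      double s = 0.0;
      int got = 0;
      bool beats = false;
      for (int f : order) {
        if (state[f] != 0) continue;
        s += w[f];
        if (s > gap) { beats = true; break; }
        if (++got == slots) break;
      }
      if (!beats) return;   // even the best completion cannot improve
    }

    // most-constrained unmet pair; prune if one is already dead
    int pstar = -1, best_avail = INT_MAX;
    for (int p = 0; p < P; ++p) {
      if (cov[p] >= req[p]) continue;
      if (cov[p] + avail[p] < req[p]) return;
      if (chosen - cov[p] > k - req[p]) return;   // miss budget blown
      if (avail[p] < best_avail) { best_avail = avail[p]; pstar = p; }
    }

    // candidates: undecided members of pstar, heaviest first
    std::vector<int> cand;
    cand.reserve(pf[pstar].size());
    for (int f : pf[pstar]) scratch[f] = 1;
    for (int f : order)
      if (state[f] == 0 && scratch[f]) cand.push_back(f);
    for (int f : pf[pstar]) scratch[f] = 0;

    int n_excluded = 0;
    for (int f : cand) {
      include(f);
      dfs();
      undo_include(f);
      if (stop || limit_hit) break;
      exclude(f);          // later branches: f is not in the solution
      ++n_excluded;
    }
    for (int i = 0; i < n_excluded; ++i) undo_exclude(cand[i]);
  }
};

} // namespace

// [[Rcpp::export(name = ".fs_branch_and_bound")]]
List fs_branch_and_bound(int n_feat,
                         List feat_pairs,      // per feature: 0-based pair ids
                         IntegerVector pair_req,
                         NumericVector weights,
                         int k,
                         IntegerVector forced, // 0-based feature ids
                         IntegerVector banned, // 0-based, fixed out
                         bool feasible_only,
                         double node_limit,
                         IntegerVector incumbent) { // 0-based, or empty
  BB bb;
  bb.m = n_feat;
  bb.k = k;
  bb.P = pair_req.size();
  bb.feasible_only = feasible_only;
  bb.node_limit = (long long)node_limit;
  bb.w.assign(weights.begin(), weights.end());
  bb.req.assign(pair_req.begin(), pair_req.end());
  bb.cov.assign(bb.P, 0);
  bb.avail.assign(bb.P, 0);
  bb.state.assign(bb.m, 0);
  bb.scratch.assign(bb.m, 0);
  bb.fp.resize(bb.m);
  bb.pf.resize(bb.P);
  for (int f = 0; f < bb.m; ++f) {
    IntegerVector v = feat_pairs[f];
    bb.fp[f].assign(v.begin(), v.end());
    for (int p : bb.fp[f]) {
      ++bb.avail[p];
      bb.pf[p].push_back(f);
    }
  }
  // miss accounting over constrained pairs only (req > 0)
  bb.slack_tot = 0;
  bb.P_active = 0;
  for (int p = 0; p < bb.P; ++p)
    if (bb.req[p] > 0) {
      ++bb.P_active;
      bb.slack_tot += (long long)(k - bb.req[p]);
    }
  bb.n_active.assign(bb.m, 0);
  for (int f = 0; f < bb.m; ++f)
    for (int p : bb.fp[f])
      if (bb.req[p] > 0) ++bb.n_active[f];
  bb.min_miss_static = bb.P_active;
  for (int f = 0; f < bb.m; ++f)
    bb.min_miss_static = std::min(bb.min_miss_static,
                                  (long long)(bb.P_active - bb.n_active[f]));
  bb.order.resize(bb.m);
  for (int f = 0; f < bb.m; ++f) bb.order[f] = f;
  std::stable_sort(bb.order.begin(), bb.order.end(),
                   [&](int a, int b) { return bb.w[a] > bb.w[b]; });

  for (int f : banned) {
    bb.state[f] = -1;
    for (int p : bb.fp[f]) --bb.avail[p];
  }
  int n_free = bb.m - (int)banned.size();
  bool root_infeasible = (k < (int)forced.size() || k > n_free);
  // unmet count must be initialized before forced inclusions so that
  // include()'s crossing bookkeeping stays consistent
  for (int p = 0; p < bb.P; ++p)
    if (bb.req[p] > 0) ++bb.n_unmet;
  for (int f : forced) bb.include(f);

  // seed with a known feasible selection so bound pruning is active from
  // the root (its objective is recomputed here, never trusted)
  if (!feasible_only && incumbent.size() == k) {
    double tot = 0.0;
    std::vector<int> dummy;
    std::vector<int> covc(bb.P, 0);
    for (int f : incumbent) {
      tot += bb.w[f];
      for (int p : bb.fp[f]) ++covc[p];
    }
    bool ok = true;
    for (int p = 0; p < bb.P; ++p)
      if (covc[p] < bb.req[p]) ok = false;
    if (ok) {
      bb.found = true;
      bb.best_obj = tot;
      bb.best.assign(bb.m, 0);
      for (int f : incumbent) bb.best[f] = 1;
    }
  }

  if (!root_infeasible) bb.dfs();

  std::vector<int> sel;
  if (bb.found)
    for (int f = 0; f < bb.m; ++f)
      if (bb.best[f] == 1) sel.push_back(f);

  std::string status;
  if (bb.found)
    status = bb.limit_hit ? "node_limit_feasible"
                          : (feasible_only ? "feasible" : "optimal");
  else
    status = bb.limit_hit ? "node_limit" : "infeasible";

  return List::create(
    _["selected"] = IntegerVector(sel.begin(), sel.end()),
    _["objective"] = bb.found ? bb.best_obj : NA_REAL,
    _["status"] = status,
    _["nodes"] = (double)bb.nodes);
}
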