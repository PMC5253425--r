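// Simulated-annealing search over full-sib partitions under a monogamous
// mating assumption. The likelihood of a cluster marginalises one latent
// (sire, dam) pair per cluster: per locus,
//   P(cluster) = sum_{gs,gd} HW(gs) HW(gd) prod_o P(obs_o | gs, gd)
// where P(obs | gs, gd) folds Mendelian transmission and the uniform
// miscall model. Those per-offspring pair weights depend only on the
// observed code, so they arrive as a 9 x 4 table (columns: obs 0, 1, 2,
// missing) and per-locus pair priors as a 9 x L matrix.
//
// All randomness comes from R's RNG so results are reproducible under
// set.seed() in the calling wrapper.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct LikContext {
  const int *codes;      // n x L, column-major, values 0..3 (3 = missing)
  const double *wtab;    // 9 x 4, column-major
  const double *prior9;  // 9 x L, column-major
  int n, L;

  // log-likelihood of one cluster given its member indices
  double cluster_ll(const std::vector<int> &members) const {
    double ll = 0.0;
    double acc[9];
    for (int l = 0; l < L; ++l) {
      const double *pr = prior9 + 9 * l;
      for (int k = 0; k < 9; ++k) acc[k] = pr[k];
      for (size_t m = 0; m < members.size(); ++m) {
        int c = codes[members[m] + n * l];
        if (c == 3) continue;
        const double *w = wtab + 9 * c;
        for (int k = 0; k < 9; ++k) acc[k] *= w[k];
      }
      double s = 0.0;
      for (int k = 0; k < 9; ++k) s += acc[k];
      ll += std::log(s);
    }
    return ll;
  }
};

struct State {
  std::vector<int> assign;                // cluster id per offspring
  std::vector<std::vector<int>> members;  // members per cluster id
  std::vector<double> cll;                // cached cluster log-likelihoods
  std::vector<int> active;                // ids of non-empty clusters
  std::vector<int> pos_in_active;         // position of id in active, -1 if empty
  double total;

  void init_singletons(const LikContext &ctx) {
    int n = ctx.n;
    assign.resize(n);
    members.assign(n, {});
    cll.assign(n, 0.0);
    active.clear();
    pos_in_active.assign(n, -1);
    total = 0.0;
    for (int i = 0; i < n; ++i) {
      assign[i] = i;
      members[i] = {i};
      cll[i] = ctx.cluster_ll(members[i]);
      pos_in_active[i] = (int)active.size();
      active.push_back(i);
      total += cll[i];
    }
  }

  void deactivate(int id) {
    int p = pos_in_active[id];
    int last = active.back();
    active[p] = last;
    pos_in_active[last] = p;
    active.pop_back();
    pos_in_active[id] = -1;
  }

  void activate(int id) {
    pos_in_active[id] = (int)active.size();
    active.push_back(id);
  }

  int free_id() const {
    for (size_t id = 0; id < members.size(); ++id)
      if (members[id].empty()) return (int)id;
    return -1;  // cannot happen: at most n clusters for n offspring
  }

  void remove_member(int id, int o) {
    std::vector<int> &v = members[id];
    v.erase(std::find(v.begin(), v.end(), o));
  }
};

inline int rint(int n) {  // uniform integer in [0, n)
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// apply "move offspring o from cluster a to cluster b" (b may be empty)
void do_move(State &st, const LikContext &ctx, int o, int b,
             double ll_a_new, double ll_b_new) {
  int a = st.assign[o];
  st.total += (ll_a_new + ll_b_new) - (st.cll[a] + st.cll[b]);
  st.remove_member(a, o);
  if (st.members[a].empty()) {
    st.deactivate(a);
    st.cll[a] = 0.0;
  } else {
    st.cll[a] = ll_a_new;
  }
  if (st.members[b].empty()) st.activate(b);
  st.members[b].push_back(o);
  st.cll[b] = ll_b_new;
  st.assign[o] = b;
}

// one greedy pass: move each offspring to its best cluster (or a fresh
// singleton) if that improves the total; returns true if anything moved
bool greedy_pass(State &st, const LikContext &ctx) {
  bool moved = false;
  std::vector<int> tmp;
  for (int o = 0; o < ctx.n; ++o) {
    int a = st.assign[o];
    tmp = st.members[a];
    tmp.erase(std::find(tmp.begin(), tmp.end(), o));
    double ll_a_without = tmp.empty() ? 0.0 : ctx.cluster_ll(tmp);
    double base = st.cll[a];
    int best_b = -1;
    double best_gain = 1e-9, best_ll_b = 0.0;
    // fresh singleton
    if (st.members[a].size() > 1) {
      std::vector<int> solo = {o};
      double ll_solo = ctx.cluster_ll(solo);
      double gain = (ll_a_without + ll_solo) - base;
      if (gain > best_gain) {
        best_gain = gain; best_b = -2; best_ll_b = ll_solo;
      }
    }
    for (size_t t = 0; t < st.active.size(); ++t) {
      int b = st.active[t];
      if (b == a) continue;
      tmp = st.members[b];
      tmp.push_back(o);
      double ll_b_new = ctx.cluster_ll(tmp);
      double gain = (ll_a_without + ll_b_new) - (base + st.cll[b]);
      if (gain > best_gain) {
        best_gain = gain; best_b = b; best_ll_b = ll_b_new;
      }
    }
    if (best_b == -2) {
      int id = st.free_id();
      do_move(st, ctx, o, id, ll_a_without, best_ll_b);
      moved = true;
    } else if (best_b >= 0) {
      do_move(st, ctx, o, best_b, ll_a_without, best_ll_b);
      moved = true;
    }
  }
  return moved;
}

}  // namespace

// [[Rcpp::export(name = ".anneal_monogamy_cpp")]]
List anneal_monogamy_cpp(IntegerMatrix codes, NumericMatrix wtab,
                         NumericMatrix prior9, int restarts,
                         int moves_per_restart, double cooling,
                         int cool_interval, double init_temp,
                         int greedy_sweeps) {
  LikContext ctx{codes.begin(), wtab.begin(), prior9.begin(),
                 codes.nrow(), codes.ncol()};
  int n = ctx.n;
  if (n < 2) stop("need at least 2 offspring");

  State st;
  st.init_singletons(ctx);
  double start_ll = st.total;

  // pilot: estimate a starting temperature from downhill move costs so
  // that a typical uphill-cost proposal accepts with ~50% probability
  double T0 = init_temp;
  if (!(T0 > 0)) {
    std::vector<double> drops;
    for (int t = 0; t < 200; ++t) {
      int o = rint(n);
      int o2 = rint(n);
      if (st.assign[o2] == st.assign[o]) continue;
      int a = st.assign[o], b = st.assign[o2];
      std::vector<int> ta = st.members[a];
      ta.erase(std::find(ta.begin(), ta.end(), o));
      std::vector<int> tb = st.members[b];
      tb.push_back(o);
      double d = (ta.empty() ? 0.0 : ctx.cluster_ll(ta)) + ctx.cluster_ll(tb)
                 - st.cll[a] - st.cll[b];
      if (d < 0 && R_finite(d)) drops.push_back(-d);
    }
    if (drops.empty()) {
      T0 = 1.0;
    } else {
      std::nth_element(drops.begin(), drops.begin() + drops.size() / 2,
                       drops.end());
      T0 = drops[drops.size() / 2] / std::log(2.0);
    }
    if (!(T0 > 0)) T0 = 1.0;
  }

  std::vector<int> best_assign = st.assign;
  double best_ll = st.total;

  std::vector<int> tmp;
  for (int r = 0; r < restarts; ++r) {
    st.init_singletons(ctx);
    double T = T0;
    for (int t = 0; t < moves_per_restart; ++t) {
      if ((t + 1) % cool_interval == 0) T *= cooling;
      double u = unif_rand();
      if (u < 0.6) {
        // move one offspring to another cluster or a fresh singleton
        int o = rint(n);
        int a = st.assign[o];
        bool fresh = unif_rand() < 0.15;
        int b;
        if (fresh) {
          if (st.members[a].size() == 1) continue;
          b = st.free_id();
        } else {
          int o2 = rint(n);
          b = st.assign[o2];
          if (b == a) continue;
        }
        tmp = st.members[a];
        tmp.erase(std::find(tmp.begin(), tmp.end(), o));
        double ll_a_new = tmp.empty() ? 0.0 : ctx.cluster_ll(tmp);
        tmp = st.members[b];
        tmp.push_back(o);
        double ll_b_new = ctx.cluster_ll(tmp);
        double d = (ll_a_new + ll_b_new) - (st.cll[a] + st.cll[b]);
        if (d >= 0 || unif_rand() < std::exp(d / T)) {
          do_move(st, ctx, o, b, ll_a_new, ll_b_new);
        }
      } else if (u < 0.8) {
        // merge the clusters of two random offspring
        int o1 = rint(n), o2 = rint(n);
        int a = st.assign[o1], b = st.assign[o2];
        if (a == b) continue;
        tmp = st.members[a];
        tmp.insert(tmp.end(), st.members[b].begin(), st.members[b].end());
        double ll_new = ctx.cluster_ll(tmp);
        double d = ll_new - st.cll[a] - st.cll[b];
        if (d >= 0 || unif_rand() < std::exp(d / T)) {
          st.total += d;
          for (size_t m = 0; m < st.members[b].size(); ++m)
            st.assign[st.members[b][m]] = a;
          st.members[a] = tmp;
          st.members[b].clear();
          st.deactivate(b);
          st.cll[b] = 0.0;
          st.cll[a] = ll_new;
        }
      } else {
        // split a cluster by a random bipartition
        int o = rint(n);
        int a = st.assign[o];
        if (st.members[a].size() < 2) continue;
        std::vector<int> keep, out;
        for (size_t m = 0; m < st.members[a].size(); ++m) {
          if (unif_rand() < 0.5) keep.push_back(st.members[a][m]);
          else out.push_back(st.members[a][m]);
        }
        if (keep.empty() || out.empty()) continue;
        double ll_keep = ctx.cluster_ll(keep);
        double ll_out = ctx.cluster_ll(out);
        double d = ll_keep + ll_out - st.cll[a];
        if (d >= 0 || unif_rand() < std::exp(d / T)) {
          int b = st.free_id();
          st.total += d;
          st.members[a] = keep;
          st.cll[a] = ll_keep;
          st.members[b] = out;
          st.cll[b] = ll_out;
          for (size_t m = 0; m < out.size(); ++m) st.assign[out[m]] = b;
          st.activate(b);
        }
      }
    }
    // greedy polish
    for (int s = 0; s < greedy_sweeps; ++s) {
      if (!greedy_pass(st, ctx)) break;
    }
    if (st.total > best_ll) {
      best_ll = st.total;
      best_assign = st.assign;
    }
  }

  // renumber clusters densely in order of first appearance
  std::vector<int> relabel(n, -1);
  int next = 0;
  IntegerVector out_assign(n);
  for (int i = 0; i < n; ++i) {
    if (relabel[best_assign[i]] < 0) relabel[best_assign[i]] = next++;
    out_assign[i] = relabel[best_assign[i]] + 1;
  }
  return List::create(_["assign"] = out_assign,
                      _["log_lik"] = best_ll,
                      _["start_log_lik"] = start_ll,
                      _["n_clusters"] = next,
                      _["init_temp"] = T0);
}

// [[Rcpp::export(name = ".partition_loglik_mono_cpp")]]
double partition_loglik_mono_cpp(IntegerMatrix codes, NumericMatrix wtab,
                                 NumericMatrix prior9, IntegerVector assign) {
  LikContext ctx{codes.begin(), wtab.begin(), prior9.begin(),
                 codes.nrow(), codes.ncol()};
  int n = ctx.n;
  std::vector<std::vector<int>> members;
  for (int i = 0; i < n; ++i) {
    int a = assign[i] - 1;
    if (a < 0) stop("cluster labels must be positive integers");
    if ((int)members.size() <= a) members.resize(a + 1);
    members[a].push_back(i);
  }
  double ll = 0.0;
  for (size_t a = 0; a < members.size(); ++a) {
    if (!members[a].empty()) ll += ctx.cluster_ll(members[a]);
  }
  return ll;
}
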