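// SMC' coalescent simulator for a single chromosome under a
// piecewise-constant diploid demography. Times are in generations before
// sampling; rates are per bp per generation. Marginal genealogies follow the
// time-inhomogeneous coalescent; linkage follows the SMC' approximation
// (prune-and-regraft at recombination breakpoints, back-coalescence onto the
// pruned lineage allowed).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Demography {
  std::vector<double> t0;  // epoch start times, t0[0] == 0, increasing
  std::vector<double> N;   // diploid sizes

  int epoch_at(double t) const {
    int i = (int)(std::upper_bound(t0.begin(), t0.end(), t) - t0.begin()) - 1;
    return i < 0 ? 0 : i;
  }

  // First event time after `from` for a process with hazard
  // k_pairs / (2 N(t)); returns time, capped at `cap` (returns cap if the
  // event falls beyond it). `exhaust` carries the remaining unit-exponential
  // hazard in/out so a capped draw can be resumed.
  double next_event(double from, double k_pairs, double cap,
                    double &exhaust) const {
    double cur = from;
    int i = epoch_at(cur);
    while (true) {
      double haz = k_pairs / (2.0 * N[i]);
      double t_end = (i + 1 < (int)t0.size()) ? t0[i + 1] : R_PosInf;
      double seg_end = std::min(t_end, cap);
      double need = exhaust / haz;
      if (cur + need <= seg_end) {
        exhaust = 0.0;
        return cur + need;
      }
      exhaust -= haz * (seg_end - cur);
      cur = seg_end;
      if (cur >= cap) return cap;
      ++i;
    }
  }
};

struct Tree {
  int n;                       // leaves
  std::vector<int> parent, c1, c2;
  std::vector<double> time;
  int root;

  int n_nodes() const { return 2 * n - 1; }

  double total_length() const {
    double s = 0.0;
    for (int v = 0; v < n_nodes(); ++v)
      if (v != root) s += time[parent[v]] - time[v];
    return s;
  }

  void leaves_under(int v, std::vector<int> &out) const {
    if (v < n) { out.push_back(v); return; }
    leaves_under(c1[v], out);
    leaves_under(c2[v], out);
  }
};

// Standard (time-inhomogeneous) coalescent tree for n leaves.
Tree initial_tree(int n, const Demography &dem) {
  Tree tr;
  tr.n = n;
  tr.parent.assign(2 * n - 1, -1);
  tr.c1.assign(2 * n - 1, -1);
  tr.c2.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  int next = n;
  while ((int)active.size() > 1) {
    int k = (int)active.size();
    double ex = R::exp_rand();
    t = dem.next_event(t, k * (k - 1) / 2.0, R_PosInf, ex);
    int i = std::min(k - 1, (int)(R::unif_rand() * k));
    int j = std::min(k - 2, (int)(R::unif_rand() * (k - 1)));
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    tr.time[next] = t;
    tr.c1[next] = a; tr.c2[next] = b;
    tr.parent[a] = next; tr.parent[b] = next;
    int hi = std::max(i, j), lo = std::min(i, j);
    active[hi] = active.back();
    active.pop_back();
    active[lo] = next;
    ++next;
  }
  tr.root = active[0];
  return tr;
}

// One SMC' transition: recombination point uniform on branches, detached
// lineage re-coalesces against the original tree.
void smc_prime_step(Tree &tr, const Demography &dem) {
  int nn = tr.n_nodes();
  // pick recombination point proportional to branch length
  double LT = tr.total_length();
  double u = R::unif_rand() * LT;
  int b = -1;
  double t_r = 0.0;
  for (int v = 0; v < nn; ++v) {
    if (v == tr.root) continue;
    double len = tr.time[tr.parent[v]] - tr.time[v];
    if (u < len) { b = v; t_r = tr.time[v] + u; break; }
    u -= len;
  }
  if (b < 0) return;  // numerical slip; keep tree

  // node times above t_r partition the hazard into constant-k segments
  std::vector<double> knots;
  for (int v = tr.n; v < nn; ++v)
    if (tr.time[v] > t_r) knots.push_back(tr.time[v]);
  std::sort(knots.begin(), knots.end());

  // count branches crossing time t (for t < t_root); above the root a single
  // ancestral line remains
  double t_root = tr.time[tr.root];
  double cur = t_r;
  double ex = R::exp_rand();
  double t_new = -1.0;
  size_t ki = 0;
  while (true) {
    double seg_end = (ki < knots.size()) ? knots[ki] : R_PosInf;
    int k;
    if (cur >= t_root) {
      k = 1;
      seg_end = R_PosInf;
    } else {
      k = 0;
      for (int v = 0; v < nn; ++v) {
        if (v == tr.root) continue;
        if (tr.time[v] <= cur && tr.time[tr.parent[v]] > cur) ++k;
      }
    }
    double got = dem.next_event(cur, (double)k, seg_end, ex);
    if (got < seg_end || !R_finite(seg_end)) { t_new = got; break; }
    cur = seg_end;
    ++ki;
  }

  // choose the target lineage among branches crossing t_new
  int target = -1;  // -1 encodes the above-root line
  if (t_new < t_root) {
    std::vector<int> crossing;
    for (int v = 0; v < nn; ++v) {
      if (v == tr.root) continue;
      if (tr.time[v] <= t_new && tr.time[tr.parent[v]] > t_new)
        crossing.push_back(v);
    }
    int idx = std::min((int)crossing.size() - 1,
                       (int)(R::unif_rand() * crossing.size()));
    target = crossing[idx];
    if (target == b) return;  // back-coalescence: tree unchanged
  }

  // detach b: splice out its parent p, sibling c inherits p's branch
  int p = tr.parent[b];
  int c = (tr.c1[p] == b) ? tr.c2[p] : tr.c1[p];
  int pp = tr.parent[p];
  if (target == p) target = c;  // p's branch is now part of c's
  if (pp >= 0) {
    if (tr.c1[pp] == p) tr.c1[pp] = c; else tr.c2[pp] = c;
    tr.parent[c] = pp;
  } else {
    tr.parent[c] = -1;
    tr.root = c;
  }

  // regraft: reuse node index p at time t_new
  tr.time[p] = t_new;
  tr.c1[p] = b;
  tr.parent[b] = p;
  if (target < 0 || target == tr.root) {
    // coalesce with the (possibly new) root line above its time
    int old_root = tr.root;
    tr.c2[p] = old_root;
    tr.parent[old_root] = p;
    tr.parent[p] = -1;
    tr.root = p;
  } else {
    int gp = tr.parent[target];
    tr.c2[p] = target;
    tr.parent[target] = p;
    if (tr.c1[gp] == target) tr.c1[gp] = p; else tr.c2[gp] = p;
    tr.parent[p] = gp;
  }
}

}  // namespace

// [[Rcpp::export]]
List smc_replicate_cpp(NumericVector epoch_start, NumericVector epoch_size,
                       double L, double mu, double rec, int n,
                       bool genotypes) {
  if (n < 2) stop("need at least 2 sampled chromosomes");
  Demography dem;
  for (int i = 0; i < epoch_start.size(); ++i) {
    if (epoch_size[i] <= 0) stop("zero or negative epoch size");
    dem.t0.push_back(epoch_start[i]);
    dem.N.push_back(epoch_size[i]);
  }

  std::vector<double> mut_pos;
  std::vector<int> mut_count;
  std::vector<std::vector<int>> mut_leaves;

  Tree tr = initial_tree(n, dem);
  double x = 0.0;
  while (x < L) {
    double LT = tr.total_length();
    double d = (rec > 0.0 && LT > 0.0) ? R::exp_rand() / (rec * LT) : R_PosInf;
    double x1 = std::min((double)L, x + d);
    if (mu > 0.0 && LT > 0.0) {
      int nm = (int)R::rpois(mu * (x1 - x) * LT);
      for (int m = 0; m < nm; ++m) {
        // branch proportional to length
        double u = R::unif_rand() * LT;
        int bsel = -1;
        for (int v = 0; v < tr.n_nodes(); ++v) {
          if (v == tr.root) continue;
          double len = tr.time[tr.parent[v]] - tr.time[v];
          if (u < len) { bsel = v; break; }
          u -= len;
        }
        if (bsel < 0) continue;
        double pos = std::floor(x + R::unif_rand() * (x1 - x)) + 1.0;
        if (pos > L) pos = L;
        std::vector<int> lv;
        tr.leaves_under(bsel, lv);
        mut_pos.push_back(pos);
        mut_count.push_back((int)lv.size());
        if (genotypes) mut_leaves.push_back(lv);
      }
    }
    if (x1 >= L) break;
    smc_prime_step(tr, dem);
    x = x1;
  }

  // sort by position, deduplicate (rejection of repeat hits)
  int S = (int)mut_pos.size();
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return mut_pos[a] < mut_pos[b];
  });
  std::vector<int> keep;
  double last = -1.0;
  for (int i = 0; i < S; ++i) {
    if (mut_pos[ord[i]] != last) {
      keep.push_back(ord[i]);
      last = mut_pos[ord[i]];
    }
  }
  int K = (int)keep.size();
  IntegerVector out_pos(K), out_count(K);
  for (int i = 0; i < K; ++i) {
    out_pos[i] = (int)mut_pos[keep[i]];
    out_count[i] = mut_count[keep[i]];
  }
  List res = List::create(_["position"] = out_pos,
                          _["derived_count"] = out_count);
  if (genotypes) {
    IntegerMatrix gt(n, K);
    for (int i = 0; i < K; ++i)
      for (int lf : mut_leaves[keep[i]]) gt(lf, i) = 1;
    res["genotypes"] = gt;
  }
  return res;
}
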