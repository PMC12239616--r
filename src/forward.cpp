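// Forward Wright-Fisher simulator: diploid, multiplicative fitness across
// sites with dominance h, exonic mutations drawn from a discretized DFE,
// per-block mutation/recombination rate maps, optional sweep or
// frequency-dependent balancing scenario with restart-on-failure, and
// population rescaling by a factor Q (sizes and durations divided by Q;
// rates and selection coefficients multiplied by Q; scaled selection
// coefficients floored at -0.95 so genotype fitnesses stay positive).
//
// Haplotypes are immutable copy-on-write objects shared between
// generations; each carries its neutral and selected (fitness-affecting)
// mutations as separate sorted arrays of packed (position, id) keys, so
// per-generation fitness evaluation only touches the sparse selected
// arrays.
#include <Rcpp.h>
#include <vector>
#include <memory>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

typedef uint64_t Key;  // position << 32 | mutation id

inline Key make_key(int pos, int id) {
  return ((Key)(uint32_t)pos << 32) | (uint32_t)id;
}
inline int key_pos(Key k) { return (int)(k >> 32); }
inline int key_id(Key k) { return (int)(uint32_t)(k & 0xffffffffULL); }

struct Registry {
  std::vector<int> pos;
  std::vector<double> s;
  int add(int p, double sv) {
    pos.push_back(p);
    s.push_back(sv);
    return (int)pos.size() - 1;
  }
  void truncate(size_t k) {
    pos.resize(k);
    s.resize(k);
  }
};

struct HapData {
  std::vector<Key> neu;  // neutral mutations, sorted
  std::vector<Key> sel;  // fitness-affecting mutations, sorted
};
typedef std::shared_ptr<const HapData> HapPtr;

const HapData EMPTY_HAP;

// inverse-CDF sampler for Poisson with fixed small mean
struct PoisTable {
  std::vector<double> cum;
  void build(double lambda) {
    cum.clear();
    if (lambda <= 0) return;
    double p = std::exp(-lambda), acc = p;
    int k = 0;
    cum.push_back(acc);
    while (acc < 1.0 - 1e-13 && k < 200) {
      ++k;
      p *= lambda / k;
      acc += p;
      cum.push_back(acc);
    }
  }
  int draw() const {
    if (cum.empty()) return 0;
    double u = R::unif_rand();
    for (size_t k = 0; k < cum.size(); ++k)
      if (u <= cum[k]) return (int)k;
    return (int)cum.size();
  }
};

struct BlockSampler {
  std::vector<double> cum;
  std::vector<int> b0, b1;
  double total;
  void build(const NumericVector &rate, int block, int L) {
    int nb = (L + block - 1) / block;
    cum.resize(nb);
    b0.resize(nb);
    b1.resize(nb);
    double acc = 0.0;
    for (int i = 0; i < nb; ++i) {
      b0[i] = i * block + 1;
      b1[i] = std::min(L, (i + 1) * block);
      acc += rate[i] * (b1[i] - b0[i] + 1);
      cum[i] = acc;
    }
    total = acc;
  }
  int draw_pos() const {
    double u = R::unif_rand() * total;
    int i = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (i >= (int)cum.size()) i = (int)cum.size() - 1;
    int span = b1[i] - b0[i] + 1;
    int off = std::min(span - 1, (int)(R::unif_rand() * span));
    return b0[i] + off;
  }
};

// copy entries from alternating source arrays split at crossover positions
void splice_arrays(const std::vector<Key> &a, const std::vector<Key> &b,
                   const std::vector<int> &cx, bool start_a,
                   std::vector<Key> &out) {
  const std::vector<Key> *src = start_a ? &a : &b;
  const std::vector<Key> *oth = start_a ? &b : &a;
  size_t is = 0, io = 0;
  out.clear();
  for (int c : cx) {
    Key bound = make_key(c + 1, 0);  // first key with pos > c
    while (is < src->size() && (*src)[is] < bound) out.push_back((*src)[is++]);
    while (io < oth->size() && (*oth)[io] < bound) ++io;
    std::swap(src, oth);
    std::swap(is, io);
  }
  while (is < src->size()) out.push_back((*src)[is++]);
}

inline void insert_key(std::vector<Key> &v, Key k) {
  v.insert(std::upper_bound(v.begin(), v.end(), k), k);
}

inline bool has_key(const std::vector<Key> &v, Key k) {
  auto it = std::lower_bound(v.begin(), v.end(), k);
  return it != v.end() && *it == k;
}

}  // namespace

// [[Rcpp::export]]
List wf_forward_cpp(NumericVector epoch_start, NumericVector epoch_size,
                    int L, IntegerVector exon_start, IntegerVector exon_end,
                    NumericVector dfe_prop, NumericVector dfe_lo,
                    NumericVector dfe_hi, double dfe_refN, double h,
                    NumericVector mu_block, NumericVector rec_block,
                    int block, double Q, int mode, double sel_par,
                    double tau_gens, int sel_pos, double burnin_gens,
                    double post_gens, int n_sample_dip, int max_restarts,
                    int cleanup_interval, bool track_traj) {
  if (Q < 1) stop("rescaling factor Q must be >= 1");
  double psum = 0.0;
  for (double p : dfe_prop) {
    if (p < 0) stop("DFE proportions must be non-negative");
    psum += p;
  }
  if (std::abs(psum - 1.0) > 1e-9) stop("DFE proportions must sum to 1");

  std::vector<char> exonic(L + 1, 0);
  for (int i = 0; i < exon_start.size(); ++i)
    for (int p = exon_start[i]; p <= exon_end[i]; ++p) exonic[p] = 1;

  int T_burn = (int)std::llround(burnin_gens / Q);
  int T_post = (int)std::llround(post_gens / Q);
  int T = T_burn + T_post;
  double N_anc = epoch_size[epoch_size.size() - 1];
  auto size_at = [&](int gbs) -> int {
    double N;
    if (gbs >= T_post) {
      N = N_anc;
    } else {
      double t_un = gbs * Q;
      int i = (int)epoch_start.size() - 1;
      while (i > 0 && epoch_start[i] > t_un) --i;
      N = epoch_size[i];
    }
    int Ns = (int)std::llround(N / Q);
    return std::max(std::max(2, n_sample_dip), Ns);
  };

  BlockSampler mu_s, rec_s;
  mu_s.build(mu_block, block, L);
  rec_s.build(rec_block, block, L);
  PoisTable mut_tab, rec_tab;
  mut_tab.build(mu_s.total * Q);
  rec_tab.build(rec_s.total * Q);

  Registry reg;
  auto draw_dfe = [&]() -> double {
    double u = R::unif_rand();
    int cls = 0;
    double acc = 0.0;
    for (int c = 0; c < dfe_prop.size(); ++c) {
      acc += dfe_prop[c];
      if (u <= acc) { cls = c; break; }
      cls = c;
    }
    double twoNs = dfe_lo[cls] + R::unif_rand() * (dfe_hi[cls] - dfe_lo[cls]);
    double s = -twoNs / (2.0 * dfe_refN);
    return std::max(-0.95, s * Q);
  };

  int N0 = size_at(T_post);
  HapPtr empty = std::make_shared<const HapData>();
  std::vector<HapPtr> pop(2 * N0, empty), nxt;

  int sel_id = -1;
  bool sel_fixed = false;
  int fix_gen = -1;
  int restarts = 0;
  int t_intro = (mode == 0) ? -1 : T - (int)std::llround(tau_gens / Q);
  if (mode != 0 && (t_intro < T_burn || t_intro < 1 || t_intro >= T))
    stop("introduction time must fall inside the post-burn-in phase");
  double sel_s_scaled = (mode == 1) ? sel_par * Q : 0.0;
  Key sel_key = 0;

  std::vector<HapPtr> snapshot;
  size_t snapshot_reg = 0;
  std::vector<double> traj;
  std::vector<double> w, cw;

  auto inject_selected = [&]() {
    sel_id = reg.add(sel_pos, sel_s_scaled);
    sel_key = make_key(sel_pos, sel_id);
    int hsel = std::min((int)pop.size() - 1,
                        (int)(R::unif_rand() * pop.size()));
    HapData *hd = new HapData(*pop[hsel]);
    insert_key(hd->sel, sel_key);
    pop[hsel] = HapPtr(hd);
  };

  auto count_selected = [&]() -> int {
    int c = 0;
    for (const HapPtr &hp : pop)
      if (has_key(hp->sel, sel_key)) ++c;
    return c;
  };

  // remove a set of (fixed) mutations from every haplotype, preserving
  // structural sharing
  auto purge = [&](const std::vector<char> &drop_neu,
                   const std::vector<char> &drop_sel) {
    std::unordered_map<const HapData *, HapPtr> memo;
    for (HapPtr &hp : pop) {
      auto it = memo.find(hp.get());
      if (it != memo.end()) { hp = it->second; continue; }
      bool any = false;
      for (Key k : hp->neu)
        if (drop_neu[key_id(k)]) { any = true; break; }
      if (!any) {
        for (Key k : hp->sel)
          if (drop_sel[key_id(k)]) { any = true; break; }
      }
      HapPtr repl = hp;
      if (any) {
        HapData *hd = new HapData();
        hd->neu.reserve(hp->neu.size());
        hd->sel.reserve(hp->sel.size());
        for (Key k : hp->neu)
          if (!drop_neu[key_id(k)]) hd->neu.push_back(k);
        for (Key k : hp->sel)
          if (!drop_sel[key_id(k)]) hd->sel.push_back(k);
        repl = HapPtr(hd);
      }
      memo[hp.get()] = repl;
      hp = repl;
    }
  };

  int g = 0;
  for (;;) {
    while (g < T) {
      int N_next = size_at(T - (g + 1));
      int N_cur = (int)pop.size() / 2;

      if (sel_id >= 0 && !sel_fixed) {
        int sel_cnt = count_selected();
        double F = (double)sel_cnt / (2.0 * N_cur);
        if (track_traj) traj.push_back(F);
        bool fail = (sel_cnt == 0) || (mode == 2 && sel_cnt == 2 * N_cur);
        if (fail) {
          if (++restarts > max_restarts)
            stop("restart cap exceeded: scenario appears infeasible");
          pop = snapshot;
          reg.truncate(snapshot_reg);
          g = t_intro;
          inject_selected();
          continue;
        }
        if (mode == 1 && sel_cnt == 2 * N_cur) {
          sel_fixed = true;
          fix_gen = T - g;
          std::vector<char> dn(reg.pos.size(), 0), ds(reg.pos.size(), 0);
          ds[sel_id] = 1;
          purge(dn, ds);
        } else if (mode == 2) {
          reg.s[sel_id] = std::max(-0.95, (sel_par - F) * Q);
        }
      }

      // fitness from the selected arrays only
      w.assign(N_cur, 1.0);
      for (int i = 0; i < N_cur; ++i) {
        const std::vector<Key> &a = pop[2 * i]->sel;
        const std::vector<Key> &b = pop[2 * i + 1]->sel;
        if (a.empty() && b.empty()) continue;
        size_t ia = 0, ib = 0;
        double wi = 1.0;
        while (ia < a.size() || ib < b.size()) {
          Key k;
          bool hom = false;
          if (ia < a.size() && ib < b.size()) {
            if (a[ia] == b[ib]) { k = a[ia]; hom = true; ++ia; ++ib; }
            else if (a[ia] < b[ib]) { k = a[ia++]; }
            else { k = b[ib++]; }
          } else if (ia < a.size()) { k = a[ia++]; }
          else { k = b[ib++]; }
          double s = reg.s[key_id(k)];
          double f = hom ? 1.0 + s : 1.0 + h * s;
          wi *= (f > 0.0 ? f : 0.0);
          if (wi == 0.0) break;
        }
        w[i] = wi;
      }
      cw.assign(N_cur, 0.0);
      double acc = 0.0;
      for (int i = 0; i < N_cur; ++i) { acc += w[i]; cw[i] = acc; }
      if (acc <= 0.0) {
        for (int i = 0; i < N_cur; ++i) cw[i] = i + 1.0;
        acc = N_cur;
      }

      nxt.resize(2 * N_next);
      std::vector<int> cx;
      for (int i = 0; i < 2 * N_next; ++i) {
        double u = R::unif_rand() * acc;
        int par = (int)(std::lower_bound(cw.begin(), cw.end(), u) -
                        cw.begin());
        if (par >= N_cur) par = N_cur - 1;
        const HapPtr &h1 = pop[2 * par], &h2 = pop[2 * par + 1];
        int ncx = rec_tab.draw();
        int nmut = mut_tab.draw();
        if (ncx == 0 && nmut == 0) {
          nxt[i] = (R::unif_rand() < 0.5) ? h1 : h2;
          continue;
        }
        HapData *hd = new HapData();
        if (ncx == 0) {
          const HapPtr &src = (R::unif_rand() < 0.5) ? h1 : h2;
          hd->neu = src->neu;
          hd->sel = src->sel;
        } else {
          cx.clear();
          for (int c = 0; c < ncx; ++c) cx.push_back(rec_s.draw_pos());
          std::sort(cx.begin(), cx.end());
          bool start_a = R::unif_rand() < 0.5;
          splice_arrays(h1->neu, h2->neu, cx, start_a, hd->neu);
          splice_arrays(h1->sel, h2->sel, cx, start_a, hd->sel);
        }
        for (int m = 0; m < nmut; ++m) {
          int p = mu_s.draw_pos();
          double s = exonic[p] ? draw_dfe() : 0.0;
          int id = reg.add(p, s);
          insert_key(s != 0.0 ? hd->sel : hd->neu, make_key(p, id));
        }
        nxt[i] = HapPtr(hd);
      }
      pop.swap(nxt);
      ++g;

      if (mode != 0 && g == t_intro && sel_id < 0) {
        snapshot = pop;
        snapshot_reg = reg.pos.size();
        inject_selected();
      }

      if (cleanup_interval > 0 && g % cleanup_interval == 0 &&
          !reg.pos.empty()) {
        std::vector<int> cnt(reg.pos.size(), 0);
        for (const HapPtr &hp : pop) {
          for (Key k : hp->neu) ++cnt[key_id(k)];
          for (Key k : hp->sel) ++cnt[key_id(k)];
        }
        int twoN = (int)pop.size();
        std::vector<char> dn(reg.pos.size(), 0), ds(reg.pos.size(), 0);
        bool any = false;
        for (size_t id = 0; id < cnt.size(); ++id) {
          if (cnt[id] == twoN && (int)id != sel_id) {
            dn[id] = 1;
            ds[id] = 1;
            any = true;
          }
        }
        if (any) purge(dn, ds);
      }
    }
    // only replicates in which the beneficial mutation fixed are retained:
    // a sweep still segregating (or lost) at sampling restarts from the
    // introduction-time state
    if (!(mode == 1 && !sel_fixed && sel_id >= 0)) break;
    int c = count_selected();
    if (c == (int)pop.size()) {
      sel_fixed = true;
      fix_gen = 0;
      std::vector<char> dn(reg.pos.size(), 0), ds(reg.pos.size(), 0);
      ds[sel_id] = 1;
      purge(dn, ds);
      break;
    }
    if (++restarts > max_restarts)
      stop("restart cap exceeded: scenario appears infeasible");
    pop = snapshot;
    reg.truncate(snapshot_reg);
    g = t_intro;
    inject_selected();
  }

  int N_fin = (int)pop.size() / 2;
  double sel_freq = NA_REAL;
  if (mode == 1) sel_freq = 1.0;
  else if (mode == 2) sel_freq = (double)count_selected() / (2.0 * N_fin);

  // sample n_sample_dip diploids without replacement
  std::vector<int> ind(N_fin);
  for (int i = 0; i < N_fin; ++i) ind[i] = i;
  for (int i = 0; i < n_sample_dip; ++i) {
    int j = i + std::min(N_fin - 1 - i, (int)(R::unif_rand() * (N_fin - i)));
    std::swap(ind[i], ind[j]);
  }
  int ns = 2 * n_sample_dip;
  std::vector<const HapData *> shaps(ns);
  for (int i = 0; i < n_sample_dip; ++i) {
    shaps[2 * i] = pop[2 * ind[i]].get();
    shaps[2 * i + 1] = pop[2 * ind[i] + 1].get();
  }
  std::vector<Key> all;
  for (int i = 0; i < ns; ++i) {
    all.insert(all.end(), shaps[i]->neu.begin(), shaps[i]->neu.end());
    all.insert(all.end(), shaps[i]->sel.begin(), shaps[i]->sel.end());
  }
  std::sort(all.begin(), all.end());
  // keys sort by (pos, id): group ids, drop multi-id positions and
  // sample-monomorphic sites
  std::vector<Key> keep_key;
  std::vector<int> keep_cnt;
  for (size_t k = 0; k < all.size();) {
    size_t j = k;
    int pos = key_pos(all[k]);
    bool multi = false;
    Key cur = all[k];
    int c = 0;
    size_t jj = k;
    while (jj < all.size() && key_pos(all[jj]) == pos) {
      if (all[jj] != cur) multi = true;
      ++jj;
    }
    j = jj;
    if (!multi) {
      c = (int)(j - k);
      if (c > 0 && c < ns) {
        keep_key.push_back(cur);
        keep_cnt.push_back(c);
      }
    }
    k = j;
  }
  int S = (int)keep_key.size();
  IntegerVector out_pos(S), out_der(S);
  IntegerMatrix gt(ns, S);
  for (int s = 0; s < S; ++s) {
    out_pos[s] = key_pos(keep_key[s]);
    out_der[s] = keep_cnt[s];
    for (int i = 0; i < ns; ++i) {
      if (has_key(shaps[i]->neu, keep_key[s]) ||
          has_key(shaps[i]->sel, keep_key[s]))
        gt(i, s) = 1;
    }
  }

  List res = List::create(
      _["position"] = out_pos, _["derived_count"] = out_der,
      _["genotypes"] = gt, _["n_sample"] = ns,
      _["sel_fixed"] = sel_fixed, _["sel_freq"] = sel_freq,
      _["fix_gen_scaled"] = fix_gen, _["restarts"] = restarts,
      _["N_final_scaled"] = N_fin, _["T_scaled"] = T);
  if (track_traj) res["trajectory"] = NumericVector(traj.begin(), traj.end());
  return res;
}
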