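// Structured-coalescent simulator with recombination, migration, exponential
// growth and timed demographic events (size changes, population merges,
// migration-rate resets).  Hudson-style ancestral-recombination-graph walk:
// lineages carry intervals of ancestral sequence; coalescences emit edges of
// a marginal-tree forest; mutations are dropped on edges in proportion to
// span x branch length (infinite-sites, positions discretised to integer bp).
//
// Times are in generations, population sizes are diploid N, rates are per
// generation (recombination/mutation per bp per generation).  All randomness
// comes from R's RNG so set.seed() on the R side makes runs reproducible.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Segment {
  double left, right;  // half-open [left, right) in bp, 0-based
  int node;            // forest node carrying this material
  int ndesc;           // sample leaves subtended at this interval
};

struct Lineage {
  std::vector<Segment> segs;  // sorted, disjoint, non-empty
  int pop;
};

struct Edge { double left, right; int parent, child; };

struct PopState {
  double N_ref;   // diploid size at backward time t_ref
  double growth;  // forward exponential growth rate (backward shrink)
  double t_ref;
};

inline double pop_size_at(const PopState &p, double t) {
  if (p.growth == 0.0) return p.N_ref;
  return p.N_ref * std::exp(-p.growth * (t - p.t_ref));
}

// waiting time to coalescence for k lineages in pop p starting at time t0;
// hazard lambda(s) = k(k-1)/(4N(t0)) * exp(g s)
inline double coal_wait(const PopState &p, int k, double t0) {
  if (k < 2) return R_PosInf;
  double lam0 = (double)k * (k - 1) / (4.0 * pop_size_at(p, t0));
  double E = R::exp_rand();
  if (p.growth == 0.0) return E / lam0;
  double arg = 1.0 + p.growth * E / lam0;
  if (arg <= 0.0) return R_PosInf;  // only possible for negative growth
  return std::log(arg) / p.growth;
}

inline void push_edge(std::vector<Edge> &edges, double l, double r, int par, int ch) {
  if (!edges.empty()) {
    Edge &e = edges.back();
    if (e.parent == par && e.child == ch && e.right == l) { e.right = r; return; }
  }
  edges.push_back(Edge{l, r, par, ch});
}

inline void push_seg(std::vector<Segment> &out, double l, double r, int node, int nd) {
  if (!out.empty()) {
    Segment &s = out.back();
    if (s.node == node && s.ndesc == nd && s.right == l) { s.right = r; return; }
  }
  out.push_back(Segment{l, r, node, nd});
}

// merge lineage B into A at time t; returns true if A survives (non-empty)
bool coalesce_pair(Lineage &A, Lineage &B, double t, int n_samples,
                   std::vector<double> &node_time, std::vector<Edge> &edges) {
  const std::vector<Segment> &SA = A.segs, &SB = B.segs;
  std::vector<double> cuts;
  cuts.reserve(2 * (SA.size() + SB.size()));
  for (const Segment &s : SA) { cuts.push_back(s.left); cuts.push_back(s.right); }
  for (const Segment &s : SB) { cuts.push_back(s.left); cuts.push_back(s.right); }
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());

  std::vector<Segment> out;
  out.reserve(SA.size() + SB.size());
  int u = -1;  // new node, allocated on first overlapping interval
  size_t ia = 0, ib = 0;
  for (size_t c = 0; c + 1 < cuts.size(); ++c) {
    double x1 = cuts[c], x2 = cuts[c + 1];
    while (ia < SA.size() && SA[ia].right <= x1) ++ia;
    while (ib < SB.size() && SB[ib].right <= x1) ++ib;
    bool inA = ia < SA.size() && SA[ia].left <= x1;
    bool inB = ib < SB.size() && SB[ib].left <= x1;
    if (inA && inB) {
      if (u < 0) { u = (int)node_time.size(); node_time.push_back(t); }
      push_edge(edges, x1, x2, u, SA[ia].node);
      push_edge(edges, x1, x2, u, SB[ib].node);
      int nd = SA[ia].ndesc + SB[ib].ndesc;
      if (nd < n_samples) push_seg(out, x1, x2, u, nd);
      // nd == n_samples: local MRCA found, interval retired
    } else if (inA) {
      push_seg(out, x1, x2, SA[ia].node, SA[ia].ndesc);
    } else if (inB) {
      push_seg(out, x1, x2, SB[ib].node, SB[ib].ndesc);
    }
  }
  A.segs.swap(out);
  return !A.segs.empty();
}

}  // namespace

// [[Rcpp::export]]
List sim_coalescent_cpp(IntegerVector n_haps, double seq_len,
                        double recomb_rate, double mut_rate,
                        NumericVector pop_sizes, NumericVector pop_growth,
                        NumericMatrix mig, DataFrame events_df,
                        double max_time = 1e9) {
  const int npop = n_haps.size();
  int n_samples = 0;
  for (int i = 0; i < npop; ++i) n_samples += n_haps[i];
  if (n_samples < 2) stop("need at least 2 haplotypes");

  std::vector<PopState> pops(npop);
  for (int i = 0; i < npop; ++i) pops[i] = PopState{pop_sizes[i], pop_growth[i], 0.0};
  std::vector<std::vector<double> > M(npop, std::vector<double>(npop, 0.0));
  for (int i = 0; i < npop; ++i)
    for (int j = 0; j < npop; ++j) M[i][j] = mig(i, j);

  NumericVector ev_time = events_df["time"];
  IntegerVector ev_kind = events_df["kind"];  // 0 size, 1 merge i->j, 2 migration set
  IntegerVector ev_i = events_df["pop_i"], ev_j = events_df["pop_j"];
  NumericVector ev_size = events_df["size"], ev_growth = events_df["growth"];
  NumericVector ev_rate = events_df["rate"];
  const int nev = ev_time.size();

  std::vector<Lineage> lin;
  lin.reserve(2 * n_samples);
  std::vector<double> node_time;
  node_time.reserve(4 * n_samples);
  int leaf = 0;
  for (int p = 0; p < npop; ++p)
    for (int s = 0; s < n_haps[p]; ++s) {
      Lineage L;
      L.segs.push_back(Segment{0.0, seq_len, leaf, 1});
      L.pop = p;
      lin.push_back(L);
      node_time.push_back(0.0);
      ++leaf;
    }
  std::vector<Edge> edges;
  edges.reserve(8 * n_samples);

  double t = 0.0;
  int ev = 0;
  long n_recomb = 0;
  std::vector<int> kcount(npop);

  while (lin.size() >= 2) {
    if (t > max_time) stop("coalescent exceeded max_time; check the model");
    std::fill(kcount.begin(), kcount.end(), 0);
    for (const Lineage &L : lin) kcount[L.pop]++;

    // candidate waiting times (independent-hazard inversion, take the min)
    double w_best = R_PosInf;
    int etype = -1, epop = -1;
    for (int p = 0; p < npop; ++p) {
      double w = coal_wait(pops[p], kcount[p], t);
      if (w < w_best) { w_best = w; etype = 0; epop = p; }
    }
    double span_tot = 0.0;
    if (recomb_rate > 0.0)
      for (const Lineage &L : lin)
        span_tot += L.segs.back().right - L.segs.front().left;
    if (recomb_rate > 0.0 && span_tot > 0.0) {
      double w = R::exp_rand() / (recomb_rate * span_tot);
      if (w < w_best) { w_best = w; etype = 1; }
    }
    double mig_tot = 0.0;
    for (int p = 0; p < npop; ++p) {
      double row = 0.0;
      for (int q = 0; q < npop; ++q) row += M[p][q];
      mig_tot += kcount[p] * row;
    }
    if (mig_tot > 0.0) {
      double w = R::exp_rand() / mig_tot;
      if (w < w_best) { w_best = w; etype = 2; }
    }

    if (ev < nev && (!(R_FINITE(w_best)) || t + w_best >= ev_time[ev])) {
      // jump to the demographic event(s)
      t = ev_time[ev];
      while (ev < nev && ev_time[ev] <= t) {
        int i = ev_i[ev], j = ev_j[ev];
        switch (ev_kind[ev]) {
          case 0:
            pops[i] = PopState{ev_size[ev], ev_growth[ev], t};
            break;
          case 1:
            for (Lineage &L : lin) if (L.pop == i) L.pop = j;
            for (int q = 0; q < npop; ++q) { M[i][q] = 0.0; M[q][i] = 0.0; }
            break;
          case 2:
            M[i][j] = ev_rate[ev];
            M[j][i] = ev_rate[ev];
            break;
        }
        ++ev;
      }
      continue;
    }
    if (!R_FINITE(w_best))
      stop("no possible event left before coalescence completed; model leaves isolated populations");
    t += w_best;

    if (etype == 0) {
      // coalesce two uniformly chosen lineages of pop epop
      int k = kcount[epop];
      int a = (int)(R::unif_rand() * k), b = (int)(R::unif_rand() * (k - 1));
      if (a >= k) a = k - 1;
      if (b >= k - 1) b = k - 2;
      if (b >= a) ++b;
      int ia = -1, ib = -1, seen = 0;
      for (size_t x = 0; x < lin.size(); ++x)
        if (lin[x].pop == epop) {
          if (seen == a) ia = (int)x;
          if (seen == b) ib = (int)x;
          ++seen;
        }
      bool alive = coalesce_pair(lin[ia], lin[ib], t, n_samples, node_time, edges);
      // B was merged into A: remove ib, and ia too if A emptied (local MRCA
      // everywhere); swap-pop highest index first to keep indices valid
      if (!alive) {
        int hi = std::max(ia, ib), lo = std::min(ia, ib);
        lin[hi] = lin.back(); lin.pop_back();
        lin[lo] = lin.back(); lin.pop_back();
      } else {
        lin[ib] = lin.back(); lin.pop_back();
      }
    } else if (etype == 1) {
      double u = R::unif_rand() * span_tot, acc = 0.0;
      int idx = -1;
      for (size_t x = 0; x < lin.size(); ++x) {
        acc += lin[x].segs.back().right - lin[x].segs.front().left;
        if (u <= acc) { idx = (int)x; break; }
      }
      if (idx < 0) idx = (int)lin.size() - 1;
      Lineage &L = lin[idx];
      double lo = L.segs.front().left, hi = L.segs.back().right;
      double x = R::runif(lo, hi);
      if (x <= lo || x >= hi) continue;  // measure-zero guard
      Lineage R2; R2.pop = L.pop;
      std::vector<Segment> keep;
      for (const Segment &s : L.segs) {
        if (s.right <= x) keep.push_back(s);
        else if (s.left >= x) R2.segs.push_back(s);
        else {
          keep.push_back(Segment{s.left, x, s.node, s.ndesc});
          R2.segs.push_back(Segment{x, s.right, s.node, s.ndesc});
        }
      }
      if (keep.empty() || R2.segs.empty()) continue;  // breakpoint outside material
      L.segs.swap(keep);
      lin.push_back(R2);
      ++n_recomb;
    } else {
      // migration: choose source pop weighted by k_i * rowsum_i, then lineage, then dest
      double u = R::unif_rand() * mig_tot, acc = 0.0;
      int src = -1;
      for (int p = 0; p < npop; ++p) {
        double row = 0.0;
        for (int q = 0; q < npop; ++q) row += M[p][q];
        acc += kcount[p] * row;
        if (u <= acc) { src = p; break; }
      }
      if (src < 0) continue;
      int pick = (int)(R::unif_rand() * kcount[src]);
      if (pick >= kcount[src]) pick = kcount[src] - 1;
      int idx = -1, seen = 0;
      for (size_t x = 0; x < lin.size(); ++x)
        if (lin[x].pop == src) { if (seen == pick) { idx = (int)x; break; } ++seen; }
      double row = 0.0;
      for (int q = 0; q < npop; ++q) row += M[src][q];
      double v = R::unif_rand() * row, acc2 = 0.0;
      int dst = src;
      for (int q = 0; q < npop; ++q) { acc2 += M[src][q]; if (v <= acc2) { dst = q; break; } }
      lin[idx].pop = dst;
    }
  }

  // drop mutations on edges
  const size_t nE = edges.size();
  std::vector<double> cumw(nE);
  double W = 0.0;
  for (size_t e = 0; e < nE; ++e) {
    W += (edges[e].right - edges[e].left) *
         (node_time[edges[e].parent] - node_time[edges[e].child]);
    cumw[e] = W;
  }
  int nmut = (W > 0.0 && mut_rate > 0.0) ? (int)R::rpois(mut_rate * W) : 0;

  std::vector<std::vector<int> > kids(node_time.size());
  for (size_t e = 0; e < nE; ++e) kids[edges[e].parent].push_back((int)e);

  std::vector<std::pair<double, std::vector<char> > > sites;
  sites.reserve(nmut);
  std::vector<int> stack;
  for (int m = 0; m < nmut; ++m) {
    double u = R::unif_rand() * W;
    size_t e = std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin();
    if (e >= nE) e = nE - 1;
    double pos = R::runif(edges[e].left, edges[e].right);
    std::vector<char> carrier(n_samples, 0);
    stack.clear();
    stack.push_back(edges[e].child);
    while (!stack.empty()) {
      int nd = stack.back(); stack.pop_back();
      if (nd < n_samples) { carrier[nd] = 1; continue; }
      for (int ei : kids[nd])
        if (edges[ei].left <= pos && pos < edges[ei].right)
          stack.push_back(edges[ei].child);
    }
    sites.push_back(std::make_pair(pos, carrier));
  }
  std::sort(sites.begin(), sites.end(),
            [](const std::pair<double, std::vector<char> > &a,
               const std::pair<double, std::vector<char> > &b) {
              return a.first < b.first;
            });
  // discretise to integer bp in [1, seq_len]; drop collisions (rare)
  std::vector<int> keep_idx;
  std::vector<int> ipos;
  int last = -1;
  for (size_t s = 0; s < sites.size(); ++s) {
    int p = (int)std::floor(sites[s].first) + 1;
    if (p > (int)seq_len) p = (int)seq_len;
    if (p == last) continue;
    keep_idx.push_back((int)s);
    ipos.push_back(p);
    last = p;
  }
  const int S = (int)keep_idx.size();
  IntegerMatrix G(n_samples, S);
  for (int s = 0; s < S; ++s) {
    const std::vector<char> &carrier = sites[keep_idx[s]].second;
    for (int r = 0; r < n_samples; ++r) G(r, s) = carrier[r];
  }
  return List::create(_["positions"] = wrap(ipos), _["genotypes"] = G,
                      _["n_recomb"] = (double)n_recomb,
                      _["total_weight"] = W,
                      _["n_nodes"] = (double)node_time.size(),
                      _["n_edges"] = (double)nE,
                      _["node_times"] = wrap(node_time),
                      _["tmrca_max"] = node_time.empty() ? 0.0 :
                        *std::max_element(node_time.begin(), node_time.end()));
}
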