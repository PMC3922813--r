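#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Canonical link-type order (must match link_types() on the R side):
// 0 C1C1, 1 C1D1, 2 D1D1, 3 C2C2, 4 C2D2, 5 D2D2,
// 6 C1C2, 7 C1D2, 8 D1C2, 9 D1D2.
// Strategies 0 = C, 1 = D; groups 0, 1 internally.
static inline int type_index(int s1, int g1, int s2, int g2) {
  if (g1 == g2) return (g1 == 0 ? 0 : 3) + s1 + s2;
  int sa = (g1 == 0) ? s1 : s2;  // group-1 endpoint first
  int sb = (g1 == 0) ? s2 : s1;
  return 6 + 2 * sa + sb;
}

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

struct Net {
  int n1, n2, N;
  std::vector<int> group, strat;          // per node
  std::vector<int> ea, eb;                // per edge
  std::vector<std::vector<int>> adj;      // adjacency lists
  std::vector<int> nC, nD;                // neighbour strategy counts
  std::vector<long> tcount;               // per-type link counts
  long coop1, coop2;

  void init(IntegerVector grp, IntegerVector st, IntegerMatrix edges,
            int n1_, int n2_) {
    n1 = n1_; n2 = n2_; N = n1 + n2;
    group.assign(grp.begin(), grp.end());
    strat.assign(st.begin(), st.end());
    int L = edges.nrow();
    ea.resize(L); eb.resize(L);
    adj.assign(N, {});
    nC.assign(N, 0); nD.assign(N, 0);
    tcount.assign(10, 0);
    coop1 = coop2 = 0;
    for (int i = 0; i < N; ++i)
      if (strat[i] == 0) { if (group[i] == 0) ++coop1; else ++coop2; }
    for (int e = 0; e < L; ++e) {
      int a = edges(e, 0), b = edges(e, 1);
      ea[e] = a; eb[e] = b;
      adj[a].push_back(b); adj[b].push_back(a);
      if (strat[b] == 0) ++nC[a]; else ++nD[a];
      if (strat[a] == 0) ++nC[b]; else ++nD[b];
      ++tcount[type_index(strat[a], group[a], strat[b], group[b])];
    }
  }

  double payoff(int i, const double* M) const {
    // accumulated payoff over current neighbours; M row-major 2x2 [s_i][s_j]
    return nC[i] * M[2 * strat[i]] + nD[i] * M[2 * strat[i] + 1];
  }

  bool is_neighbor(int i, int j) const {
    const std::vector<int>& v = adj[i];
    return std::find(v.begin(), v.end(), j) != v.end();
  }

  void drop_adj(int i, int j) {
    std::vector<int>& v = adj[i];
    auto it = std::find(v.begin(), v.end(), j);
    std::iter_swap(it, v.end() - 1);
    v.pop_back();
  }

  void flip_strategy(int j) {
    int olds = strat[j], news = 1 - olds;
    for (int u : adj[j]) {
      if (olds == 0) { --nC[u]; ++nD[u]; } else { --nD[u]; ++nC[u]; }
      --tcount[type_index(olds, group[j], strat[u], group[u])];
      ++tcount[type_index(news, group[j], strat[u], group[u])];
    }
    strat[j] = news;
    long d = (news == 0) ? 1 : -1;
    if (group[j] == 0) coop1 += d; else coop2 += d;
  }
};

// One Fermi strategy-update event.  Returns true if a strategy changed.
// pair_by_link: draw the (focal, neighbour) pair as a uniform link with a
// uniform orientation (pair probability proportional to link mass, the
// sampling the mean-field layer assumes); otherwise draw a uniform focal
// node and then a uniform neighbour (weights pairs by 1/degree).
static bool strategy_event(Net& net, const double* M, double w,
                           bool focal_adopts, bool pair_by_link) {
  int i, j;
  if (pair_by_link) {
    int L = (int)net.ea.size();
    if (L == 0) return false;
    int e = runif_int(L);
    if (unif_rand() < 0.5) { i = net.ea[e]; j = net.eb[e]; }
    else { i = net.eb[e]; j = net.ea[e]; }
  } else {
    i = runif_int(net.N);
    if (net.adj[i].empty()) return false;       // isolated focal: no-op
    j = net.adj[i][runif_int((int)net.adj[i].size())];
  }
  if (net.strat[i] == net.strat[j]) return false;
  double pi = net.payoff(i, M), pj = net.payoff(j, M);
  // default: focal i's strategy tries to replace neighbour j's
  double diff = focal_adopts ? (pj - pi) : (pi - pj);
  double acc = 1.0 / (1.0 + std::exp(-w * diff));
  if (unif_rand() < acc) {
    net.flip_strategy(focal_adopts ? i : j);
    return true;
  }
  return false;
}

// One linking event.  Returns true if the network changed.
static bool link_event(Net& net, const double* k10, double p) {
  int L = (int)net.ea.size();
  if (L == 0) return false;
  int e = runif_int(L);
  int a = net.ea[e], b = net.eb[e];
  int t = type_index(net.strat[a], net.group[a], net.strat[b], net.group[b]);
  if (unif_rand() >= k10[t]) return false;      // link survives
  int keep = (unif_rand() < 0.5) ? a : b;
  int gt = (unif_rand() < p) ? net.group[keep] : 1 - net.group[keep];
  int lo = (gt == 0) ? 0 : net.n1;
  int ng = (gt == 0) ? net.n1 : net.n2;
  // delete first: the old partner becomes eligible again (reconnection allowed)
  net.drop_adj(a, b); net.drop_adj(b, a);
  int v = -1;
  for (int tries = 0; tries < 64; ++tries) {
    int cand = lo + runif_int(ng);
    if (cand != keep && !net.is_neighbor(keep, cand)) { v = cand; break; }
  }
  if (v < 0) {
    // dense corner case: enumerate eligible partners
    std::vector<int> elig;
    for (int cand = lo; cand < lo + ng; ++cand)
      if (cand != keep && !net.is_neighbor(keep, cand)) elig.push_back(cand);
    if (!elig.empty()) v = elig[runif_int((int)elig.size())];
  }
  if (v < 0) {
    // no eligible partner on the chosen side: consume as a no-op
    net.adj[a].push_back(b); net.adj[b].push_back(a);
    return false;
  }
  // bookkeeping for the removed edge
  if (net.strat[b] == 0) --net.nC[a]; else --net.nD[a];
  if (net.strat[a] == 0) --net.nC[b]; else --net.nD[b];
  --net.tcount[t];
  // add keep -- v
  net.ea[e] = keep; net.eb[e] = v;
  net.adj[keep].push_back(v); net.adj[v].push_back(keep);
  if (net.strat[v] == 0) ++net.nC[keep]; else ++net.nD[keep];
  if (net.strat[keep] == 0) ++net.nC[v]; else ++net.nD[v];
  ++net.tcount[type_index(net.strat[keep], net.group[keep],
                          net.strat[v], net.group[v])];
  return true;
}

// event_mode: 0 = mixed (strategy with probability W), 1 = strategy only,
// 2 = link only.
// [[Rcpp::export]]
List cpp_run_abm(IntegerVector group, IntegerVector strat,
                 IntegerMatrix edges, int n1, int n2,
                 NumericMatrix payoff, NumericVector k10,
                 double p, double W, double w,
                 double n_events, int sample_every,
                 int event_mode, bool focal_adopts, bool pair_by_link,
                 bool stop_on_absorb) {
  Net net;
  net.init(group, strat, edges, n1, n2);
  double M[4] = { payoff(0, 0), payoff(0, 1), payoff(1, 0), payoff(1, 1) };
  std::vector<double> kv(k10.begin(), k10.end());

  long horizon = (long)n_events;
  std::vector<double> rec_event, rec_x1, rec_x2;
  std::vector<long> rec_counts;
  auto record = [&](long ev) {
    rec_event.push_back((double)ev);
    rec_x1.push_back((double)net.coop1 / net.n1);
    rec_x2.push_back((double)net.coop2 / net.n2);
    for (int t = 0; t < 10; ++t) rec_counts.push_back(net.tcount[t]);
  };
  record(0);
  long ev = 0;
  bool absorbed = false;
  for (ev = 1; ev <= horizon; ++ev) {
    bool do_strategy;
    if (event_mode == 1) do_strategy = true;
    else if (event_mode == 2) do_strategy = false;
    else do_strategy = (unif_rand() < W);
    if (do_strategy) strategy_event(net, M, w, focal_adopts, pair_by_link);
    else link_event(net, kv.data(), p);
    if (sample_every > 0 && ev % sample_every == 0) record(ev);
    if (stop_on_absorb) {
      long coop = net.coop1 + net.coop2;
      if (coop == 0 || coop == net.N) { absorbed = true; break; }
    }
  }
  if (ev > horizon) ev = horizon;
  if (rec_event.back() != (double)ev) record(ev);

  int L = (int)net.ea.size();
  IntegerMatrix out_edges(L, 2);
  for (int e = 0; e < L; ++e) { out_edges(e, 0) = net.ea[e]; out_edges(e, 1) = net.eb[e]; }
  int nrec = (int)rec_event.size();
  NumericMatrix counts(nrec, 10);
  for (int r = 0; r < nrec; ++r)
    for (int t = 0; t < 10; ++t) counts(r, t) = (double)rec_counts[r * 10 + t];
  return List::create(
    _["strategy"] = IntegerVector(net.strat.begin(), net.strat.end()),
    _["edges"] = out_edges,
    _["event"] = NumericVector(rec_event.begin(), rec_event.end()),
    _["x1"] = NumericVector(rec_x1.begin(), rec_x1.end()),
    _["x2"] = NumericVector(rec_x2.begin(), rec_x2.end()),
    _["type_counts"] = counts,
    _["events_run"] = (double)ev,
    _["absorbed"] = absorbed);
}

// Sample the single-link embedded chain: returns visited state indices
// (0-based) after burnin.
// [[Rcpp::export]]
IntegerVector cpp_simulate_chain(NumericMatrix P, int init, int burnin, int n) {
  int m = P.nrow();
  std::vector<double> cum(m * m);
  for (int i = 0; i < m; ++i) {
    double s = 0;
    for (int j = 0; j < m; ++j) { s += P(i, j); cum[i * m + j] = s; }
  }
  int state = init;
  IntegerVector out(n);
  for (long t = 0; t < burnin + (long)n; ++t) {
    double u = unif_rand() * cum[state * m + m - 1];
    const double* row = &cum[state * m];
    state = (int)(std::upper_bound(row, row + m, u) - row);
    if (state >= m) state = m - 1;
    if (t >= burnin) out[t - burnin] = state;
  }
  return out;
}
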