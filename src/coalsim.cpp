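// Coalescent simulation over demographic DAGs (population splits + pulse
// admixture), Jukes-Cantor finite-site mutation, and the summary statistics
// used by the ABC machinery.  Time is measured in generations, backwards from
// the present; the pair-coalescence rate within a population of effective
// size N is k(k-1)/2 per 2N generations.  All randomness comes from R's RNG
// so set.seed() on the R side gives bit-reproducible output.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <map>
#include <string>
using namespace Rcpp;

namespace {

struct Genealogy {
  int nsamp;                 // sampled (leaf) lineages
  std::vector<int> parent;   // parent node index, -1 for root
  std::vector<double> time;  // node ages in generations
};

struct Event {
  double t;
  int type;   // 0 = split (a -> b), 1 = admix (a -> b w.p. r, else c)
  int a, b, c;
  double r;
};

// Structured coalescent with instantaneous events, backwards in time.
Genealogy simulate_genealogy(const std::vector<double>& popN,
                             std::vector<Event> events,
                             const std::vector<int>& samp_pop) {
  const int P = static_cast<int>(popN.size());
  const int n = static_cast<int>(samp_pop.size());
  std::stable_sort(events.begin(), events.end(),
                   [](const Event& x, const Event& y) { return x.t < y.t; });

  Genealogy g;
  g.nsamp = n;
  g.parent.assign(2 * n - 1, -1);
  g.time.assign(2 * n - 1, 0.0);

  std::vector<std::vector<int>> act(P + 1);
  for (int i = 0; i < n; ++i) act[samp_pop[i]].push_back(i);

  double t = 0.0;
  size_t ev = 0;
  int nactive = n, next_node = n;
  std::vector<double> rate(P + 1, 0.0);

  while (nactive > 1) {
    double total = 0.0;
    for (int p = 1; p <= P; ++p) {
      double k = static_cast<double>(act[p].size());
      rate[p] = (k > 1.0) ? k * (k - 1.0) / (4.0 * popN[p - 1]) : 0.0;
      total += rate[p];
    }
    double wait = (total > 0.0) ? exp_rand() / total : R_PosInf;
    if (ev < events.size() && t + wait >= events[ev].t) {
      t = events[ev].t;
      const Event& e = events[ev];
      if (e.type == 0) {  // split: everything in a moves to b
        for (int lin : act[e.a]) act[e.b].push_back(lin);
        act[e.a].clear();
      } else {            // admixture pulse
        for (int lin : act[e.a]) {
          if (unif_rand() < e.r) act[e.b].push_back(lin);
          else act[e.c].push_back(lin);
        }
        act[e.a].clear();
      }
      ++ev;
      continue;
    }
    if (!R_FINITE(wait))
      stop("coalescent cannot complete: lineages stranded in disconnected populations");
    t += wait;
    double u = unif_rand() * total;
    int p = 1;
    for (; p < P; ++p) { if (u < rate[p]) break; u -= rate[p]; }
    // merge two random lineages of population p
    std::vector<int>& pool = act[p];
    int i = static_cast<int>(unif_rand() * pool.size());
    int j = static_cast<int>(unif_rand() * (pool.size() - 1));
    if (j >= i) ++j;
    int anc = next_node++;
    g.parent[pool[i]] = anc;
    g.parent[pool[j]] = anc;
    g.time[anc] = t;
    if (i > j) std::swap(i, j);
    pool[j] = anc;              // replace one child by the ancestor,
    pool.erase(pool.begin() + i);  // drop the other
    --nactive;
  }
  return g;
}

struct Mut { int site; int node; double t; };

// Preorder (parents before children): node indices by decreasing age.
std::vector<int> age_order(const Genealogy& g) {
  std::vector<int> ord(g.parent.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = static_cast<int>(i);
  std::stable_sort(ord.begin(), ord.end(),
                   [&g](int a, int b) { return g.time[a] > g.time[b]; });
  return ord;
}

std::vector<Mut> draw_mutations(const Genealogy& g, int L, double mu) {
  std::vector<Mut> muts;
  for (size_t v = 0; v < g.parent.size(); ++v) {
    if (g.parent[v] < 0) continue;
    double blen = g.time[g.parent[v]] - g.time[v];
    int m = static_cast<int>(R::rpois(mu * L * blen));
    for (int k = 0; k < m; ++k) {
      Mut mt;
      mt.site = static_cast<int>(unif_rand() * L);
      if (mt.site == L) mt.site = L - 1;
      mt.node = static_cast<int>(v);
      mt.t = g.time[v] + unif_rand() * blen;
      muts.push_back(mt);
    }
  }
  return muts;
}

inline int jc_mutate(int base) {  // uniform change to one of the other 3
  int d = 1 + static_cast<int>(unif_rand() * 3.0);
  if (d == 4) d = 3;
  return (base + d) & 3;
}

// Leaf states at polymorphic sites, one contiguous byte string per sample
// (cache-friendly pairwise comparisons).
typedef std::vector<std::vector<unsigned char>> SiteSeqs;

SiteSeqs variable_site_seqs(const Genealogy& g, std::vector<Mut>& muts) {
  std::stable_sort(muts.begin(), muts.end(), [](const Mut& a, const Mut& b) {
    if (a.site != b.site) return a.site < b.site;
    return a.t > b.t;
  });
  std::vector<int> ord = age_order(g);
  int nn = static_cast<int>(g.parent.size());
  std::vector<int> state(nn);
  SiteSeqs seqs(g.nsamp);
  size_t i = 0;
  while (i < muts.size()) {
    size_t j = i;
    while (j < muts.size() && muts[j].site == muts[i].site) ++j;
    std::fill(state.begin(), state.end(), 0);
    for (int v : ord) {
      if (g.parent[v] >= 0) state[v] = state[g.parent[v]];
      for (size_t m = i; m < j; ++m)
        if (muts[m].node == v) state[v] = jc_mutate(state[v]);
    }
    int first = state[0];
    bool poly = false;
    for (int s = 1; s < g.nsamp; ++s)
      if (state[s] != first) { poly = true; break; }
    if (poly)
      for (int s = 0; s < g.nsamp; ++s)
        seqs[s].push_back(static_cast<unsigned char>(state[s]));
    i = j;
  }
  return seqs;
}

inline double seq_diff(const std::vector<unsigned char>& x,
                       const std::vector<unsigned char>& y) {
  int d = 0;
  const size_t n = x.size();
  for (size_t c = 0; c < n; ++c) d += (x[c] != y[c]);
  return static_cast<double>(d);
}

// Full alignment (all L sites, random root bases).
IntegerMatrix full_alignment(const Genealogy& g, int L, double mu) {
  std::vector<Mut> muts = draw_mutations(g, L, mu);
  std::stable_sort(muts.begin(), muts.end(), [](const Mut& a, const Mut& b) {
    if (a.node != b.node) return a.node < b.node;
    return a.t > b.t;
  });
  int nn = static_cast<int>(g.parent.size());
  std::vector<std::vector<unsigned char>> seq(nn);
  std::vector<int> ord = age_order(g);
  seq[ord[0]].resize(L);
  for (int s = 0; s < L; ++s) {
    int b = static_cast<int>(unif_rand() * 4.0);
    seq[ord[0]][s] = static_cast<unsigned char>(b == 4 ? 3 : b);
  }
  for (size_t oi = 1; oi < ord.size(); ++oi) {
    int v = ord[oi];
    seq[v] = seq[g.parent[v]];
    auto lo = std::lower_bound(muts.begin(), muts.end(), v,
        [](const Mut& m, int node) { return m.node < node; });
    for (auto it = lo; it != muts.end() && it->node == v; ++it)
      seq[v][it->site] = static_cast<unsigned char>(jc_mutate(seq[v][it->site]));
  }
  IntegerMatrix out(g.nsamp, L);
  for (int s = 0; s < g.nsamp; ++s)
    for (int c = 0; c < L; ++c) out(s, c) = seq[s][c];
  return out;
}

double tajima_d(double S, double k, int n) {
  if (S <= 0.0 || n < 2) return 0.0;
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i <= n - 1; ++i) { a1 += 1.0 / i; a2 += 1.0 / (double(i) * i); }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * double(n) + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  double denom = std::sqrt(e1 * S + e2 * S * (S - 1.0));
  if (denom <= 0.0) return 0.0;
  return (k - S / a1) / denom;
}

// Per-population and between-population statistics on the variable-site
// matrix of one locus, accumulated into `acc` (length 5*P + 2*C(P,2)):
// per pop: Nh, S, mean pairwise diff, var pairwise diff, Tajima's D;
// per pair (i<j): mean between-pop diff, Hudson's FST.
void accumulate_stats(const SiteSeqs& seqs, const std::vector<int>& samp_pop,
                      int P, std::vector<double>& acc) {
  int nS = static_cast<int>(seqs.empty() ? 0 : seqs[0].size());
  std::vector<std::vector<int>> idx(P + 1);
  for (size_t i = 0; i < samp_pop.size(); ++i) idx[samp_pop[i]].push_back(static_cast<int>(i));

  std::vector<double> kw(P + 1, 0.0);
  int pos = 0;
  for (int p = 1; p <= P; ++p) {
    const std::vector<int>& ii = idx[p];
    int np = static_cast<int>(ii.size());
    // distinct haplotypes
    std::map<std::string, int> uniq;
    for (int a : ii)
      uniq[std::string(seqs[a].begin(), seqs[a].end())]++;
    double Nh = static_cast<double>(uniq.size());
    // segregating sites within pop
    double S = 0.0;
    for (int c = 0; c < nS; ++c) {
      unsigned char f = seqs[ii[0]][c];
      for (int a = 1; a < np; ++a)
        if (seqs[ii[a]][c] != f) { S += 1.0; break; }
    }
    // pairwise differences
    double sum = 0.0, sum2 = 0.0;
    int npair = np * (np - 1) / 2;
    for (int a = 0; a < np; ++a)
      for (int b = a + 1; b < np; ++b) {
        double d = seq_diff(seqs[ii[a]], seqs[ii[b]]);
        sum += d; sum2 += d * d;
      }
    double kbar = (npair > 0) ? sum / npair : 0.0;
    double vark = (npair > 1) ? (sum2 - sum * sum / npair) / (npair - 1.0) : 0.0;
    kw[p] = kbar;
    acc[pos++] += Nh;
    acc[pos++] += S;
    acc[pos++] += kbar;
    acc[pos++] += vark;
    acc[pos++] += tajima_d(S, kbar, np);
  }
  for (int p = 1; p <= P; ++p)
    for (int q = p + 1; q <= P; ++q) {
      double sum = 0.0; long cnt = 0;
      for (int a : idx[p])
        for (int b : idx[q]) { sum += seq_diff(seqs[a], seqs[b]); ++cnt; }
      double kb = (cnt > 0) ? sum / cnt : 0.0;
      double fst = (kb > 0.0) ? 1.0 - 0.5 * (kw[p] + kw[q]) / kb : 0.0;
      acc[pos++] += kb;
      acc[pos++] += fst;
    }
}

std::vector<Event> build_events(const IntegerMatrix& ev_code,
                                const NumericVector& ev_t,
                                const NumericVector& ev_r) {
  std::vector<Event> events(ev_code.nrow());
  for (int e = 0; e < ev_code.nrow(); ++e) {
    events[e].type = ev_code(e, 0);
    events[e].a = ev_code(e, 1);
    events[e].b = ev_code(e, 2);
    events[e].c = ev_code(e, 3);
    events[e].t = ev_t[e];
    events[e].r = ev_r[e];
  }
  return events;
}

}  // namespace

//' @name coalsim-internal
//' @title Internal coalescent-engine entry points
//' @description Compiled workhorses behind [simulate_scenario()] and
//'   [run_abc()]. Not part of the user API.
//' @keywords internal
//' @noRd

// [[Rcpp::export(name = ".sim_dataset_cpp")]]
List sim_dataset_cpp(NumericVector popN, IntegerMatrix ev_code, NumericVector ev_t,
                     NumericVector ev_r, IntegerVector samp_pop,
                     IntegerVector lengths, NumericVector mu) {
  std::vector<double> N(popN.begin(), popN.end());
  std::vector<int> sp(samp_pop.begin(), samp_pop.end());
  std::vector<Event> events = build_events(ev_code, ev_t, ev_r);
  int nloci = lengths.size();
  List out(nloci);
  for (int l = 0; l < nloci; ++l) {
    Genealogy g = simulate_genealogy(N, events, sp);
    out[l] = full_alignment(g, lengths[l], mu[l]);
  }
  return out;
}

// [[Rcpp::export(name = ".sim_stats_cpp")]]
NumericVector sim_stats_cpp(NumericVector popN, IntegerMatrix ev_code, NumericVector ev_t,
                            NumericVector ev_r, IntegerVector samp_pop,
                            IntegerVector lengths, NumericVector mu, int n_stat_pops) {
  std::vector<double> N(popN.begin(), popN.end());
  std::vector<int> sp(samp_pop.begin(), samp_pop.end());
  std::vector<Event> events = build_events(ev_code, ev_t, ev_r);
  int P = n_stat_pops;
  int nstat = 5 * P + P * (P - 1);
  std::vector<double> acc(nstat, 0.0);
  int nloci = lengths.size();
  for (int l = 0; l < nloci; ++l) {
    Genealogy g = simulate_genealogy(N, events, sp);
    std::vector<Mut> muts = draw_mutations(g, lengths[l], mu[l]);
    SiteSeqs seqs = variable_site_seqs(g, muts);
    accumulate_stats(seqs, sp, P, acc);
  }
  NumericVector out(nstat);
  for (int s = 0; s < nstat; ++s) out[s] = acc[s] / nloci;
  return out;
}

// Batch simulation for ABC: `draws` is an n_sims x n_params matrix; population
// sizes, event times and admixture rates are looked up by column index
// (1-based; pop_n_idx per population, ev_t_idx / ev_r_idx per event, 0 in
// ev_r_idx meaning "not an admixture event").
// [[Rcpp::export(name = ".sim_stats_batch_cpp")]]
NumericMatrix sim_stats_batch_cpp(IntegerVector pop_n_idx, IntegerMatrix ev_code,
                                  IntegerVector ev_t_idx, IntegerVector ev_r_idx,
                                  NumericMatrix draws, IntegerVector samp_pop,
                                  IntegerVector lengths, NumericVector mu,
                                  int n_stat_pops) {
  int nsims = draws.nrow();
  int P = static_cast<int>(pop_n_idx.size());
  int nev = ev_code.nrow();
  int nstat = 5 * n_stat_pops + n_stat_pops * (n_stat_pops - 1);
  int nloci = lengths.size();
  std::vector<int> sp(samp_pop.begin(), samp_pop.end());
  NumericMatrix out(nsims, nstat);
  std::vector<double> N(P);
  std::vector<Event> events(nev);
  for (int e = 0; e < nev; ++e) {
    events[e].type = ev_code(e, 0);
    events[e].a = ev_code(e, 1);
    events[e].b = ev_code(e, 2);
    events[e].c = ev_code(e, 3);
  }
  std::vector<double> acc(nstat);
  for (int s = 0; s < nsims; ++s) {
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
    for (int p = 0; p < P; ++p) N[p] = draws(s, pop_n_idx[p] - 1);
    for (int e = 0; e < nev; ++e) {
      events[e].t = draws(s, ev_t_idx[e] - 1);
      events[e].r = (ev_r_idx[e] > 0) ? draws(s, ev_r_idx[e] - 1) : 0.0;
    }
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int l = 0; l < nloci; ++l) {
      Genealogy g = simulate_genealogy(N, events, sp);
      std::vector<Mut> muts = draw_mutations(g, lengths[l], mu[l]);
      SiteSeqs seqs = variable_site_seqs(g, muts);
      accumulate_stats(seqs, sp, n_stat_pops, acc);
    }
    for (int st = 0; st < nstat; ++st) out(s, st) = acc[st] / nloci;
  }
  return out;
}

// [[Rcpp::export(name = ".sim_tmrca_cpp")]]
NumericVector sim_tmrca_cpp(double N, int n, int reps) {
  std::vector<double> popN(1, N);
  std::vector<Event> no_events;
  std::vector<int> sp(n, 1);
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    Genealogy g = simulate_genealogy(popN, no_events, sp);
    out[r] = g.time[2 * n - 2];
  }
  return out;
}
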