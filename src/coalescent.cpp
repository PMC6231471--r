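#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Structured coalescent for up to three extant demes under an
// isolation-with-migration topology: the outgroup deme `f` splits from the
// ancestor of the two sister demes at T1 (generations, backward); the two
// sisters merge at T2 (T2 <= T1).  Demes 0..2 are extant, 3 is the sister
// ancestor, 4 the root.  Sizes are diploid Ne; coalescence rate for k
// lineages in a deme of size N is k(k-1)/2 / (2N) per generation.
// Backward size change: N_d(t) = Ne[d] * exp(-r[d] * min(t, t_end[d]))
// (r >= 0 models forward exponential growth; the size is frozen at the
// founding value beyond t_end).  Migration is continuous among extant demes
// only (t < T2), with backward per-lineage per-generation rates mig(d, j).

struct Lin {
  int deme;
  int c0, c1, c2;  // descendant leaves per sampling deme
  int node;        // tree node id (tree mode only)
};

static const double BIG_T = 1e300;

struct Engine {
  int n[3];
  int f;                 // outgroup deme index
  double T1, T2;
  double Ne[3], Ne_anc1, Ne_anc2;
  double r[3], t_end[3];
  double mig[3][3];
  double mig_row[3];

  // tree recording (optional)
  bool build_tree;
  std::vector<double> node_time;
  std::vector<int> node_left, node_right, node_parent;

  // sfs accumulation (optional)
  double *sfs;
  int d0, d1;  // strides: index = c0 + d0*(c1 + d1*c2)

  std::vector<Lin> lin;

  double deme_size(int d, double t) const {
    if (d == 3) return Ne_anc1;
    if (d == 4) return Ne_anc2;
    double te = t < t_end[d] ? t : t_end[d];
    return Ne[d] * std::exp(-r[d] * te);
  }

  // waiting time to next coalescence among k lineages in deme d starting at
  // time t, assuming the size law in force at t holds (segments are capped
  // at law-change boundaries by the caller)
  double coal_wait(int d, int k, double t) const {
    double C = 0.5 * (double)k * (double)(k - 1);
    double E = exp_rand();
    double N_t = deme_size(d, t);
    bool growing = (d < 3) && (t < t_end[d]) && (r[d] > 0.0);
    if (!growing) return 2.0 * N_t * E / C;
    double rd = r[d];
    return std::log(1.0 + E * 2.0 * N_t * rd / C) / rd;
  }

  void run() {
    int NL = n[0] + n[1] + n[2];
    lin.clear();
    lin.reserve(NL);
    int id = 0;
    for (int d = 0; d < 3; d++)
      for (int i = 0; i < n[d]; i++) {
        Lin L;
        L.deme = d;
        L.c0 = d == 0; L.c1 = d == 1; L.c2 = d == 2;
        L.node = id++;
        lin.push_back(L);
      }
    if (build_tree) {
      int NN = 2 * NL - 1;
      node_time.assign(NN, 0.0);
      node_left.assign(NN, -1);
      node_right.assign(NN, -1);
      node_parent.assign(NN, -1);
    }
    int next_node = NL;
    double t = 0.0;
    long guard = 0;

    while ((int)lin.size() > 1) {
      if (++guard > 100000000L) stop("coalescent did not complete");
      // per-deme lineage counts
      int k[5] = {0, 0, 0, 0, 0};
      for (size_t i = 0; i < lin.size(); i++) k[lin[i].deme]++;

      // current segment end: next law-change boundary
      double segend = BIG_T;
      if (t < T2) segend = std::min(segend, T2);
      else if (t < T1) segend = std::min(segend, T1);
      for (int d = 0; d < 3; d++)
        if (k[d] > 0 && t < t_end[d]) segend = std::min(segend, t_end[d]);

      // candidate coalescence per deme
      double dt = BIG_T;
      int ev_deme = -1;
      for (int d = 0; d < 5; d++) {
        if (k[d] >= 2) {
          double w = coal_wait(d, k[d], t);
          if (w < dt) { dt = w; ev_deme = d; }
        }
      }
      // candidate migration (extant demes, t < T2)
      bool ev_mig = false;
      double RM = 0.0;
      if (t < T2) {
        for (int d = 0; d < 3; d++) RM += k[d] * mig_row[d];
        if (RM > 0.0) {
          double w = exp_rand() / RM;
          if (w < dt) { dt = w; ev_mig = true; ev_deme = -1; }
        }
      }

      double step = std::min(dt, segend - t);
      if (sfs && step > 0.0) {
        for (size_t i = 0; i < lin.size(); i++)
          sfs[lin[i].c0 + d0 * (lin[i].c1 + d1 * lin[i].c2)] += step;
      }

      if (t + dt >= segend) {
        t = segend;
        if (t >= T1) {
          for (size_t i = 0; i < lin.size(); i++) lin[i].deme = 4;
        } else if (t >= T2) {
          for (size_t i = 0; i < lin.size(); i++)
            if (lin[i].deme != f && lin[i].deme < 3) lin[i].deme = 3;
        }
        // t_end boundaries need no action (size law switches implicitly)
        continue;
      }
      t += dt;

      if (ev_mig) {
        // pick lineage proportional to its deme's outgoing rate
        double u = unif_rand() * RM, acc = 0.0;
        int pick = -1;
        for (size_t i = 0; i < lin.size(); i++) {
          if (lin[i].deme < 3) {
            acc += mig_row[lin[i].deme];
            if (acc >= u) { pick = (int)i; break; }
          }
        }
        if (pick < 0) pick = (int)lin.size() - 1;
        int d = lin[pick].deme;
        double v = unif_rand() * mig_row[d], a2 = 0.0;
        int dest = d;
        for (int j = 0; j < 3; j++) {
          if (j == d) continue;
          a2 += mig[d][j];
          if (a2 >= v) { dest = j; break; }
        }
        lin[pick].deme = dest;
      } else {
        // coalescence in ev_deme: pick an unordered pair uniformly
        int kd = k[ev_deme];
        int a = (int)std::floor(unif_rand() * kd);
        int b = (int)std::floor(unif_rand() * (kd - 1));
        if (b >= a) b++;
        if (a > kd - 1) a = kd - 1;
        if (b > kd - 1) b = kd - 1;
        int ia = -1, ib = -1, seen = 0;
        for (size_t i = 0; i < lin.size(); i++) {
          if (lin[i].deme == ev_deme) {
            if (seen == a) ia = (int)i;
            if (seen == b) ib = (int)i;
            seen++;
          }
        }
        Lin merged;
        merged.deme = ev_deme;
        merged.c0 = lin[ia].c0 + lin[ib].c0;
        merged.c1 = lin[ia].c1 + lin[ib].c1;
        merged.c2 = lin[ia].c2 + lin[ib].c2;
        merged.node = next_node;
        if (build_tree) {
          node_time[next_node] = t;
          node_left[next_node] = lin[ia].node;
          node_right[next_node] = lin[ib].node;
          node_parent[lin[ia].node] = next_node;
          node_parent[lin[ib].node] = next_node;
        }
        next_node++;
        if (ia > ib) std::swap(ia, ib);
        lin.erase(lin.begin() + ib);
        lin.erase(lin.begin() + ia);
        lin.push_back(merged);
      }
    }
  }
};

static void fill_engine(Engine &eng, IntegerVector n, int f, double T1,
                        double T2, NumericVector Ne, double Ne_anc1,
                        double Ne_anc2, NumericVector r, NumericVector t_end,
                        NumericMatrix mig) {
  for (int d = 0; d < 3; d++) {
    eng.n[d] = n[d];
    eng.Ne[d] = Ne[d];
    eng.r[d] = r[d];
    eng.t_end[d] = t_end[d];
    eng.mig_row[d] = 0.0;
    for (int j = 0; j < 3; j++) {
      eng.mig[d][j] = (d == j) ? 0.0 : mig(d, j);
      if (d != j) eng.mig_row[d] += mig(d, j);
    }
  }
  eng.f = f;
  eng.T1 = R_finite(T1) ? T1 : BIG_T;
  eng.T2 = R_finite(T2) ? T2 : BIG_T;
  eng.Ne_anc1 = Ne_anc1;
  eng.Ne_anc2 = Ne_anc2;
}

// Accumulate expected branch lengths by joint descendant configuration over
// n_sims independent genealogies.  Returns the flattened array of
// dimensions (n0+1, n1+1, n2+1); cell (i,j,k) holds the total length of
// branches subtending i, j, k sampled leaves in demes 0, 1, 2.
// [[Rcpp::export]]
NumericVector cpp_branch_sfs(IntegerVector n, int f, double T1, double T2,
                             NumericVector Ne, double Ne_anc1, double Ne_anc2,
                             NumericVector r, NumericVector t_end,
                             NumericMatrix mig, int n_sims) {
  Engine eng;
  fill_engine(eng, n, f, T1, T2, Ne, Ne_anc1, Ne_anc2, r, t_end, mig);
  int D0 = n[0] + 1, D1 = n[1] + 1, D2 = n[2] + 1;
  NumericVector out(D0 * D1 * D2);
  eng.build_tree = false;
  eng.sfs = REAL(out);
  eng.d0 = D0;
  eng.d1 = D1;
  for (int s = 0; s < n_sims; s++) eng.run();
  out.attr("dim") = IntegerVector::create(D0, D1, D2);
  return out;
}

// Total branch lengths of n_gen independent genealogies (first pass of the
// exact length-weighted site sampler: under infinite sites in the
// low-mutation limit, a segregating site's genealogy is drawn proportional
// to total branch length).
// [[Rcpp::export]]
NumericVector cpp_sim_lengths(IntegerVector n, int f, double T1, double T2,
                              NumericVector Ne, double Ne_anc1,
                              double Ne_anc2, NumericVector r,
                              NumericVector t_end, NumericMatrix mig,
                              int n_gen) {
  Engine eng;
  fill_engine(eng, n, f, T1, T2, Ne, Ne_anc1, Ne_anc2, r, t_end, mig);
  eng.build_tree = true;
  eng.sfs = 0;
  int NL = n[0] + n[1] + n[2];
  int NN = 2 * NL - 1;
  NumericVector out(n_gen);
  for (int g = 0; g < n_gen; g++) {
    eng.run();
    double tot = 0.0;
    for (int v = 0; v < NN; v++)
      if (eng.node_parent[v] >= 0)
        tot += eng.node_time[eng.node_parent[v]] - eng.node_time[v];
    out[g] = tot;
  }
  return out;
}

// Second pass: replays the identical genealogy stream (call with the same
// R random seed as cpp_sim_lengths) and drops sites_per_gen[g] mutations
// on genealogy g, each on a branch chosen proportional to its length.
// Mutation placement uses a private xorshift generator so the R stream
// stays synchronized with the first pass.  Returns leaves x total-sites
// 0/1; leaves ordered deme 0, 1, 2.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_sites(IntegerVector n, int f, double T1, double T2,
                            NumericVector Ne, double Ne_anc1, double Ne_anc2,
                            NumericVector r, NumericVector t_end,
                            NumericMatrix mig,
                            IntegerVector sites_per_gen, int mut_seed) {
  Engine eng;
  fill_engine(eng, n, f, T1, T2, Ne, Ne_anc1, Ne_anc2, r, t_end, mig);
  eng.build_tree = true;
  eng.sfs = 0;
  int NL = n[0] + n[1] + n[2];
  int NN = 2 * NL - 1;
  int n_gen = sites_per_gen.size();
  int n_loci = 0;
  for (int g = 0; g < n_gen; g++) n_loci += sites_per_gen[g];
  IntegerMatrix out(NL, n_loci);
  std::vector<int> stack;
  unsigned long long s = (unsigned long long)mut_seed * 2685821657736338717ULL + 1ULL;
  int l = 0;
  for (int g = 0; g < n_gen; g++) {
    eng.run();
    if (sites_per_gen[g] == 0) continue;
    double tot = 0.0;
    for (int v = 0; v < NN; v++)
      if (eng.node_parent[v] >= 0)
        tot += eng.node_time[eng.node_parent[v]] - eng.node_time[v];
    for (int m = 0; m < sites_per_gen[g]; m++) {
      // xorshift64* uniform
      s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
      double u01 = (double)((s * 2685821657736338717ULL) >> 11) /
        9007199254740992.0;
      double u = u01 * tot, acc = 0.0;
      int pick = -1;
      for (int v = 0; v < NN; v++) {
        if (eng.node_parent[v] < 0) continue;
        acc += eng.node_time[eng.node_parent[v]] - eng.node_time[v];
        if (acc >= u) { pick = v; break; }
      }
      if (pick < 0) pick = 0;
      stack.clear();
      stack.push_back(pick);
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        if (v < NL) out(v, l) = 1;
        else {
          stack.push_back(eng.node_left[v]);
          stack.push_back(eng.node_right[v]);
        }
      }
      l++;
    }
  }
  return out;
}
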