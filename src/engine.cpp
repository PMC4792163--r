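#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-layer RNG streams: mt19937_64 with hand-rolled bounded-int and
// uniform-double draws, so trajectories are bit-reproducible for a given
// stream seed independent of the C++ standard library's distribution
// implementations.
struct Stream {
  std::mt19937_64 g;
  explicit Stream(uint64_t seed) : g(seed) {}
  // modulo draw; bias is < 2^-53 for the n used here (n <= N)
  int bounded(int n) { return (int)(g() % (uint64_t)n); }
  double unif() { return (g() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Csr {
  std::vector<int> off, nb;
  int n;
  void build(const List& adj) {
    n = adj.size();
    off.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) {
      IntegerVector v = adj[i];
      off[i + 1] = off[i] + v.size();
    }
    nb.resize(off[n]);
    for (int i = 0; i < n; ++i) {
      IntegerVector v = adj[i];
      for (int j = 0; j < v.size(); ++j) nb[off[i] + j] = v[j];  // 0-based
    }
  }
  int deg(int x) const { return off[x + 1] - off[x]; }
};

static inline double fermi(double u_self, double u_nb, double K) {
  // exp overflow saturates to Inf -> probability 0; never NaN
  return 1.0 / (1.0 + std::exp((u_self - u_nb) / K));
}

static inline double util(double p_own, double p_part, double alpha,
                          bool additive) {
  return additive ? p_own + alpha * p_part
                  : (1.0 - alpha) * p_own + alpha * p_part;
}

struct Engine {
  Csr G1, G2;
  std::vector<int> match1, match2;  // partner maps, 0-based
  double M1[2][2], M2[3][3];        // payoff tables in plain arrays
  double alpha, K;
  bool additive, frozen;
  std::vector<int> s1, s2;
  std::vector<double> P1, P2;    // live payoffs (fresh mode)
  std::vector<double> F1, F2;    // frozen payoffs (frozen mode)
  long skips;

  void set_matrices(const NumericMatrix& A1, const NumericMatrix& A2) {
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) M1[i][j] = A1(i, j);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) M2[i][j] = A2(i, j);
  }
  double pay(int layer, int si, int sj) const {
    return (layer == 1) ? M1[si][sj] : M2[si][sj];
  }

  double node_util(int layer, int x, const std::vector<double>& Pa,
                   const std::vector<double>& Pb) const {
    // Pa = own-layer payoffs, Pb = other-layer payoffs
    int partner = (layer == 1) ? match1[x] : match2[x];
    return util(Pa[x], Pb[partner], alpha, additive);
  }

  // accumulated payoffs of a whole layer from scratch
  void recompute(int layer, std::vector<double>& P) {
    const Csr& G = (layer == 1) ? G1 : G2;
    const std::vector<int>& s = (layer == 1) ? s1 : s2;
    P.assign(G.n, 0.0);
    for (int x = 0; x < G.n; ++x) {
      double acc = 0.0;
      for (int j = G.off[x]; j < G.off[x + 1]; ++j)
        acc += pay(layer, s[x], s[G.nb[j]]);
      P[x] = acc;
    }
  }

  // flip node x on `layer` to strategy snew, maintaining live payoffs
  void flip(int layer, int x, int snew) {
    Csr& G = (layer == 1) ? G1 : G2;
    std::vector<int>& s = (layer == 1) ? s1 : s2;
    std::vector<double>& P = (layer == 1) ? P1 : P2;
    int sold = s[x];
    double acc = 0.0;
    for (int j = G.off[x]; j < G.off[x + 1]; ++j) {
      int w = G.nb[j];
      P[w] += pay(layer, s[w], snew) - pay(layer, s[w], sold);
      acc += pay(layer, snew, s[w]);
    }
    P[x] = acc;
    s[x] = snew;
  }

  // one asynchronous imitation event on `layer`; returns +/- strategy deltas
  // via the counts array (length 3)
  void step(int layer, Stream& st, std::vector<long>& cnt) {
    Csr& G = (layer == 1) ? G1 : G2;
    std::vector<int>& s = (layer == 1) ? s1 : s2;
    int x = st.bounded(G.n);
    int d = G.deg(x);
    if (d == 0) { ++skips; return; }
    int y = G.nb[G.off[x] + st.bounded(d)];
    const std::vector<double>& Pa =
        frozen ? ((layer == 1) ? F1 : F2) : ((layer == 1) ? P1 : P2);
    const std::vector<double>& Pb =
        frozen ? ((layer == 1) ? F2 : F1) : ((layer == 1) ? P2 : P1);
    double ux = node_util(layer, x, Pa, Pb);
    double uy = node_util(layer, y, Pa, Pb);
    double p = fermi(ux, uy, K);
    double u = st.unif();  // always consumed: fixed draw count per event
    if (s[y] != s[x] && u < p) {
      --cnt[s[x]];
      ++cnt[s[y]];
      if (frozen) s[x] = s[y]; else flip(layer, x, s[y]);
    }
  }
};

// [[Rcpp::export]]
List run_coupled_sim(List adj1, List adj2, IntegerVector match1_r,
                     NumericMatrix M1, NumericMatrix M2, double alpha,
                     bool additive, double K, int mcs_total,
                     IntegerVector s1_init, IntegerVector s2_init,
                     double seed1, double seed2, bool frozen, bool shuffled) {
  Engine e;
  e.G1.build(adj1);
  e.G2.build(adj2);
  int N = e.G1.n;
  e.set_matrices(M1, M2);
  e.alpha = alpha; e.K = K; e.additive = additive; e.frozen = frozen;
  e.skips = 0;
  e.match1.resize(N); e.match2.resize(N);
  for (int i = 0; i < N; ++i) {
    e.match1[i] = match1_r[i] - 1;        // layer-2 partner of layer-1 node i
    e.match2[e.match1[i]] = i;
  }
  e.s1.assign(s1_init.begin(), s1_init.end());
  e.s2.assign(s2_init.begin(), s2_init.end());
  e.recompute(1, e.P1);
  e.recompute(2, e.P2);

  Stream st1((uint64_t)seed1), st2((uint64_t)seed2);
  std::vector<long> c1(3, 0), c2(3, 0);
  for (int i = 0; i < N; ++i) ++c1[e.s1[i]];
  for (int i = 0; i < N; ++i) ++c2[e.s2[i]];

  NumericMatrix traj(mcs_total + 1, 5);
  auto record = [&](int row) {
    traj(row, 0) = (double)c1[0] / N;
    traj(row, 1) = (double)c1[1] / N;
    traj(row, 2) = (double)c2[0] / N;
    traj(row, 3) = (double)c2[1] / N;
    traj(row, 4) = (double)c2[2] / N;
  };
  record(0);

  std::vector<int> order;
  if (shuffled) order.resize(2 * N);
  for (int t = 1; t <= mcs_total; ++t) {
    if (frozen) {
      e.recompute(1, e.F1);
      e.recompute(2, e.F2);
    }
    if (!shuffled) {
      for (int i = 0; i < N; ++i) {
        e.step(1, st1, c1);
        e.step(2, st2, c2);
      }
    } else {
      for (int i = 0; i < 2 * N; ++i) order[i] = (i < N) ? 1 : 2;
      for (int i = 2 * N - 1; i > 0; --i)
        std::swap(order[i], order[st1.bounded(i + 1)]);
      for (int i = 0; i < 2 * N; ++i)
        e.step(order[i], order[i] == 1 ? st1 : st2, order[i] == 1 ? c1 : c2);
    }
    if (t % 1024 == 0) Rcpp::checkUserInterrupt();
    record(t);
  }

  return List::create(_["traj"] = traj,
                      _["strategies1"] = IntegerVector(e.s1.begin(), e.s1.end()),
                      _["strategies2"] = IntegerVector(e.s2.begin(), e.s2.end()),
                      _["skips"] = (double)e.skips);
}

// Tally outcomes of independent single imitation events from a fixed state.
// Outcome code: focal * 3 + adopted strategy, or 3 * N for "no change".
// [[Rcpp::export]]
IntegerVector sample_step_outcomes(List adj1, List adj2,
                                   IntegerVector match1_r, NumericMatrix M1,
                                   NumericMatrix M2, double alpha,
                                   bool additive, double K,
                                   IntegerVector s1_init,
                                   IntegerVector s2_init, int layer,
                                   double n_draws, double seed) {
  Engine e;
  e.G1.build(adj1);
  e.G2.build(adj2);
  int N = e.G1.n;
  e.set_matrices(M1, M2);
  e.alpha = alpha; e.K = K; e.additive = additive; e.frozen = false;
  e.skips = 0;
  e.match1.resize(N); e.match2.resize(N);
  for (int i = 0; i < N; ++i) {
    e.match1[i] = match1_r[i] - 1;
    e.match2[e.match1[i]] = i;
  }
  e.s1.assign(s1_init.begin(), s1_init.end());
  e.s2.assign(s2_init.begin(), s2_init.end());
  e.recompute(1, e.P1);
  e.recompute(2, e.P2);

  Csr& G = (layer == 1) ? e.G1 : e.G2;
  std::vector<int>& s = (layer == 1) ? e.s1 : e.s2;
  Stream st((uint64_t)seed);
  IntegerVector counts(3 * G.n + 1);
  long total = (long)n_draws;
  for (long k = 0; k < total; ++k) {
    int x = st.bounded(G.n);
    int d = G.deg(x);
    if (d == 0) { ++counts[3 * G.n]; continue; }
    int y = G.nb[G.off[x] + st.bounded(d)];
    double ux = e.node_util(layer, x, (layer == 1) ? e.P1 : e.P2,
                            (layer == 1) ? e.P2 : e.P1);
    double uy = e.node_util(layer, y, (layer == 1) ? e.P1 : e.P2,
                            (layer == 1) ? e.P2 : e.P1);
    double p = fermi(ux, uy, K);
    double u = st.unif();
    if (s[y] != s[x] && u < p) ++counts[3 * x + s[y]];
    else ++counts[3 * G.n];
  }
  return counts;
}
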