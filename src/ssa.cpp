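// Gillespie direct-method engine for the TF-sharing transcription model.
//
// Channels are laid out in a fixed order (per-promoter bind, per-promoter
// unbind, competitor bind, competitor unbind, per-promoter transcribe,
// per-promoter degrade) so that the cumulative-propensity search is
// deterministic for a given random stream. Each replicate runs on its own
// counter-seeded xoshiro256++ stream, so replicate k is bit-reproducible in
// isolation regardless of how many replicates are requested.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]; never 0 so -log(u) is finite
  double unif() {
    return (static_cast<double>(next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
};

inline uint64_t stream_seed(uint64_t master, uint64_t k) {
  uint64_t x = master * 0x9E3779B97F4A7C15ULL + k + 1ULL;
  return Xoshiro::splitmix64(x);
}

struct Pars {
  int NP, NT, NC;
  double kon, koff, konc, koffc, r, rbasal, gamma;
  bool activator;
};

Pars read_pars(const List &model) {
  Pars p;
  p.NP = as<int>(model["n_promoters"]);
  p.NT = as<int>(model["n_tf"]);
  p.NC = as<int>(model["n_competitors"]);
  p.kon = as<double>(model["k_on"]);
  p.koff = as<double>(model["k_off"]);
  p.konc = as<double>(model["k_on_c"]);
  p.koffc = as<double>(model["k_off_c"]);
  p.r = as<double>(model["r"]);
  p.rbasal = as<double>(model["r_basal"]);
  p.gamma = as<double>(model["gamma"]);
  p.activator = as<std::string>(model["mode"]) == "activator";
  return p;
}

struct State {
  std::vector<int> s, m;
  int c;
};

// One Gillespie step. Returns the waiting time (R_PosInf if no channel can
// fire, in which case the state is left untouched); mutates the state.
double step(const Pars &p, State &st, Xoshiro &rng) {
  const int NP = p.NP;
  int n = 0;
  for (int i = 0; i < NP; ++i) n += st.s[i];
  const int F = p.NT - n - st.c;
  std::vector<double> a(4 * NP + 2);
  double A = 0.0;
  for (int i = 0; i < NP; ++i) A += (a[i] = p.kon * F * (1 - st.s[i]));
  for (int i = 0; i < NP; ++i) A += (a[NP + i] = p.koff * st.s[i]);
  A += (a[2 * NP] = p.konc * F * (p.NC - st.c));
  A += (a[2 * NP + 1] = p.koffc * st.c);
  for (int i = 0; i < NP; ++i) {
    double tr = p.activator ? p.r * st.s[i] + p.rbasal * (1 - st.s[i])
                            : p.r * (1 - st.s[i]);
    A += (a[2 * NP + 2 + i] = tr);
  }
  for (int i = 0; i < NP; ++i) A += (a[3 * NP + 2 + i] = p.gamma * st.m[i]);
  if (A <= 0.0) return R_PosInf;
  const double dt = -std::log(rng.unif()) / A;
  double target = rng.unif() * A, cum = 0.0;
  int ch = static_cast<int>(a.size()) - 1;
  for (size_t j = 0; j < a.size(); ++j) {
    cum += a[j];
    if (target <= cum) { ch = static_cast<int>(j); break; }
  }
  if (ch < NP) st.s[ch] = 1;
  else if (ch < 2 * NP) st.s[ch - NP] = 0;
  else if (ch == 2 * NP) st.c += 1;
  else if (ch == 2 * NP + 1) st.c -= 1;
  else if (ch < 3 * NP + 2) st.m[ch - 2 * NP - 2] += 1;
  else st.m[ch - 3 * NP - 2] -= 1;
  return dt;
}

State init_state(const Pars &p, const IntegerVector &init_s, int init_c,
                 const IntegerVector &init_m) {
  State st;
  st.s.assign(init_s.begin(), init_s.end());
  st.m.assign(init_m.begin(), init_m.end());
  st.c = init_c;
  (void)p;
  return st;
}

} // namespace

// Final states of n_cells independent replicates at t = burn_in.
// Returns an integer matrix with columns s_1..s_NP, c, m_1..m_NP.
// [[Rcpp::export(name = ".ssa_population_cpp")]]
IntegerMatrix ssa_population_cpp(List model, int n_cells, double burn_in,
                                 double seed, IntegerVector init_s, int init_c,
                                 IntegerVector init_m) {
  const Pars p = read_pars(model);
  IntegerMatrix out(n_cells, 2 * p.NP + 1);
  const uint64_t master = static_cast<uint64_t>(seed);
  for (int k = 0; k < n_cells; ++k) {
    Xoshiro rng(stream_seed(master, static_cast<uint64_t>(k)));
    State st = init_state(p, init_s, init_c, init_m);
    double t = 0.0;
    while (true) {
      State before = st;
      const double w = step(p, st, rng);
      if (!R_FINITE(w)) break;          // absorbing: state holds forever
      t += w;
      if (t >= burn_in) { st = before; break; }  // state in force at burn_in
    }
    for (int i = 0; i < p.NP; ++i) out(k, i) = st.s[i];
    out(k, p.NP) = st.c;
    for (int i = 0; i < p.NP; ++i) out(k, p.NP + 1 + i) = st.m[i];
    if ((k & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Single trajectory. recording: 0 = every event, 1 = fixed grid of spacing dt.
// Returns a numeric matrix with columns time, s_1..s_NP, c, m_1..m_NP.
// [[Rcpp::export(name = ".ssa_trajectory_cpp")]]
NumericMatrix ssa_trajectory_cpp(List model, double t_end, double seed,
                                 int recording, double dt,
                                 IntegerVector init_s, int init_c,
                                 IntegerVector init_m) {
  const Pars p = read_pars(model);
  Xoshiro rng(stream_seed(static_cast<uint64_t>(seed), 0));
  State st = init_state(p, init_s, init_c, init_m);
  const int ncol = 2 * p.NP + 2;
  std::vector<double> rows;
  auto record = [&](double t, const State &x) {
    rows.push_back(t);
    for (int i = 0; i < p.NP; ++i) rows.push_back(x.s[i]);
    rows.push_back(x.c);
    for (int i = 0; i < p.NP; ++i) rows.push_back(x.m[i]);
  };
  double t = 0.0;
  if (recording == 0) {
    record(t, st);
    while (true) {
      const double w = step(p, st, rng);
      if (!R_FINITE(w) || t + w > t_end) break;
      t += w;
      record(t, st);
      if (rows.size() % 4096 < static_cast<size_t>(ncol)) Rcpp::checkUserInterrupt();
    }
  } else {
    double next_rec = 0.0;
    while (next_rec <= t_end) {
      State before = st;
      const double w = step(p, st, rng);
      const double t_event = R_FINITE(w) ? t + w : R_PosInf;
      while (next_rec <= t_end && next_rec < t_event) {
        record(next_rec, before);
        next_rec += dt;
      }
      if (t_event > t_end) break;
      t = t_event;
      Rcpp::checkUserInterrupt();
    }
  }
  const int nrow = static_cast<int>(rows.size()) / ncol;
  NumericMatrix out(nrow, ncol);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < ncol; ++j) out(i, j) = rows[i * ncol + j];
  return out;
}
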