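// Exact stochastic simulation (Gillespie direct method) of the six-reaction
// two-state expression network, first-passage sampling with optional
// tau-leaping, and batch cohort evolution for the in-silico sorting
// experiment.  All randomness flows from a single 64-bit seed through a
// splitmix64 stream splitter, so replicate r of a batch is unchanged when
// the batch grows.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>

namespace {

struct NetPars {
  double kG, kG0, dG, kR, kR0, kP, dR, dP, K;
  int hillK;
};

NetPars as_pars(const Rcpp::NumericVector& p) {
  NetPars q;
  q.kG = p["kG"]; q.kG0 = p["kG0"]; q.dG = p["dG"];
  q.kR = p["kR"]; q.kR0 = p["kR0"]; q.kP = p["kP"];
  q.dR = p["dR"]; q.dP = p["dP"]; q.K = p["K"];
  q.hillK = static_cast<int>(p["hillK"]);
  return q;
}

inline std::uint64_t splitmix64(std::uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  std::uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(std::uint64_t seed) : gen(seed) {}
  double unif() {  // in (0, 1]
    return ((gen() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
  int poisson(double mu) {
    std::poisson_distribution<int> d(mu);
    return d(gen);
  }
};

struct State {
  int alpha;
  double m, n;
};

inline double occ(double n, const NetPars& p) {
  if (n <= 0.0) return 0.0;
  if (p.hillK == 1) return n / (n + p.K);
  const double r = std::pow(n / p.K, p.hillK);
  return r / (r + 1.0);
}

// channel order follows the reaction table: 1 inactivation, 2 activation,
// 3 transcription, 4 translation, 5 mRNA decay, 6 protein decay
inline void props(const State& s, const NetPars& p, double a[6]) {
  const double h = occ(s.n, p);
  a[0] = s.alpha == 1 ? p.dG : 0.0;
  a[1] = s.alpha == 0 ? p.kG * h + p.kG0 : 0.0;
  a[2] = s.alpha == 1 ? p.kR * h + p.kR0 : 0.0;
  a[3] = p.kP * s.m;
  a[4] = p.dR * s.m;
  a[5] = p.dP * s.n;
}

inline void apply(State& s, int j) {
  switch (j) {
    case 0: s.alpha = 0; break;
    case 1: s.alpha = 1; break;
    case 2: s.m += 1; break;
    case 3: s.n += 1; break;
    case 4: s.m -= 1; break;
    case 5: s.n -= 1; break;
  }
}

// one exact step; returns waiting time, or -1 if all propensities vanish
inline double step(State& s, const NetPars& p, Rng& rng, int* fired) {
  double a[6];
  props(s, p, a);
  const double a0 = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
  if (a0 <= 0.0) { *fired = -1; return -1.0; }
  const double dt = rng.expo(a0);
  double u = rng.unif() * a0;
  int j = 0;
  for (; j < 5; ++j) { if (u <= a[j]) break; u -= a[j]; }
  apply(s, j);
  *fired = j;
  return dt;
}

} // namespace

// Exact trajectory.  record = 0: final state only; 1: every jump; 2: states
// sampled on a fixed time grid of spacing sample_dt (plus gene-switch
// events, so reactive segments can still be delimited).
// [[Rcpp::export(name = ".ssa_simulate_cpp")]]
Rcpp::List ssa_simulate_cpp(Rcpp::NumericVector pars, Rcpp::IntegerVector init,
                            double tmax, double max_events, double seed,
                            int record = 1, double sample_dt = 0.0) {
  const NetPars p = as_pars(pars);
  std::uint64_t sd = static_cast<std::uint64_t>(seed);
  Rng rng(splitmix64(sd));
  State s{init[0], static_cast<double>(init[1]), static_cast<double>(init[2])};

  std::vector<double> ts;
  std::vector<int> al, mm, nn;
  auto push = [&](double t) {
    ts.push_back(t); al.push_back(s.alpha);
    mm.push_back(static_cast<int>(s.m)); nn.push_back(static_cast<int>(s.n));
  };
  push(0.0);

  double t = 0.0, nev = 0.0, next_sample = sample_dt;
  long interrupt_tick = 0;
  bool exhausted = false;
  while (t < tmax) {
    int j;
    State prev = s;
    const double dt = step(s, p, rng, &j);
    if (j < 0) break;  // absorbing state
    if (t + dt > tmax) { s = prev; t = tmax; break; }
    t += dt;
    nev += 1.0;
    if (record == 1) push(t);
    else if (record == 2) {
      while (next_sample <= t) {  // grid states use the pre-jump state
        State cur = s; s = prev;
        push(next_sample);
        s = cur;
        next_sample += sample_dt;
      }
      if (j == 0 || j == 1) push(t);  // keep gene-switch events exactly
    }
    if (nev >= max_events) { exhausted = true; break; }
    if ((++interrupt_tick & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (record != 1) push(t);

  return Rcpp::List::create(
    Rcpp::Named("time") = ts, Rcpp::Named("alpha") = al,
    Rcpp::Named("m") = mm, Rcpp::Named("n") = nn,
    Rcpp::Named("tEnd") = t, Rcpp::Named("events") = nev,
    Rcpp::Named("exhausted") = exhausted);
}

// First-passage sampling: run until the protein count first satisfies
// n > threshold (up = true) or n <= threshold (up = false).  Also records
// the dwell-excluded transition time T = hit time minus the last time the
// source metastable protein level was touched (n >= meta for a downward
// switch, n <= meta upward).  Optional tau-leaping treats the two gene
// channels (and any species below 20 copies) exactly and leaps the rest.
// [[Rcpp::export(name = ".ssa_fpt_cpp")]]
Rcpp::List ssa_fpt_cpp(Rcpp::NumericVector pars, Rcpp::IntegerVector init,
                       double threshold, bool up, double meta,
                       int replicates, double max_events, double seed,
                       bool leap = false, double eps = 0.03) {
  const NetPars p = as_pars(pars);
  Rcpp::NumericVector hit(replicates), trans(replicates), events(replicates);
  Rcpp::LogicalVector censored(replicates);

  for (int r = 0; r < replicates; ++r) {
    std::uint64_t sd = static_cast<std::uint64_t>(seed) * 2654435761ULL +
                       static_cast<std::uint64_t>(r) + 1ULL;
    Rng rng(splitmix64(sd));
    State s{init[0], static_cast<double>(init[1]),
            static_cast<double>(init[2])};
    double t = 0.0, nev = 0.0, last_meta = 0.0;
    long interrupt_tick = 0;
    bool done = false, cens = false;

    auto at_meta = [&]() { return up ? (s.n <= meta) : (s.n >= meta); };
    auto at_target = [&]() {
      return up ? (s.n > threshold) : (s.n <= threshold);
    };

    while (!done) {
      if (nev >= max_events) { cens = true; break; }
      double a[6];
      props(s, p, a);
      const double a0 = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
      if (a0 <= 0.0) { cens = !at_target(); break; }

      bool leapable = leap && s.m >= 20 && s.n >= 20;
      if (!leapable) {
        int j;
        const double dt = step(s, p, rng, &j);
        t += dt; nev += 1.0;
      } else {
        // Cao-style step size from mRNA/protein drift and diffusion
        const double mu_m = a[2] - a[4], var_m = a[2] + a[4];
        const double mu_n = a[3] - a[5], var_n = a[3] + a[5];
        const double gm = std::max(eps * s.m, 1.0);
        const double gn = std::max(eps * s.n, 1.0);
        double tau = std::min(
            std::min(gm / std::max(std::fabs(mu_m), 1e-300), gm * gm / var_m),
            std::min(gn / std::max(std::fabs(mu_n), 1e-300), gn * gn / var_n));
        const double acrit = a[0] + a[1];
        if (tau < 10.0 / a0) {  // leap not worthwhile: exact step
          int j;
          const double dt = step(s, p, rng, &j);
          t += dt; nev += 1.0;
        } else {
          double tcrit = acrit > 0.0 ? rng.expo(acrit) : HUGE_VAL;
          bool fire_crit = tcrit <= tau;
          if (fire_crit) tau = tcrit;
          const int k3 = rng.poisson(a[2] * tau);
          const int k4 = rng.poisson(a[3] * tau);
          const int k5 = rng.poisson(a[4] * tau);
          const int k6 = rng.poisson(a[5] * tau);
          if (s.m + k3 - k5 < 0.0 || s.n + k4 - k6 < 0.0) {
            // would go negative: fall back to an exact step
            int j;
            const double dt = step(s, p, rng, &j);
            t += dt; nev += 1.0;
            continue;
          }
          s.m += k3 - k5;
          s.n += k4 - k6;
          if (fire_crit) {
            double u = rng.unif() * acrit;
            s.alpha = (u <= a[0]) ? 0 : 1;
          }
          t += tau;
          nev += 1.0;
        }
      }
      if (at_meta()) last_meta = t;
      if (at_target()) done = true;
      if ((++interrupt_tick & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    hit[r] = cens ? NA_REAL : t;
    trans[r] = cens ? NA_REAL : t - last_meta;
    events[r] = nev;
    censored[r] = cens;
  }

  return Rcpp::List::create(
    Rcpp::Named("hit") = hit, Rcpp::Named("transition") = trans,
    Rcpp::Named("events") = events, Rcpp::Named("censored") = censored);
}

// Evolve a cohort of cells independently and report the protein count of
// every cell at each record time.  states: 3-column (alpha, m, n) matrix.
// [[Rcpp::export(name = ".ssa_cohort_cpp")]]
Rcpp::IntegerMatrix ssa_cohort_cpp(Rcpp::IntegerMatrix states,
                                   Rcpp::NumericVector record_times,
                                   Rcpp::NumericVector pars, double seed,
                                   double max_events_per_cell = 1e9) {
  const NetPars p = as_pars(pars);
  const int ncell = states.nrow(), ntime = record_times.size();
  Rcpp::IntegerMatrix out(ncell, ntime);

  for (int c = 0; c < ncell; ++c) {
    std::uint64_t sd = static_cast<std::uint64_t>(seed) * 2654435761ULL +
                       static_cast<std::uint64_t>(c) + 977ULL;
    Rng rng(splitmix64(sd));
    State s{states(c, 0), static_cast<double>(states(c, 1)),
            static_cast<double>(states(c, 2))};
    double t = 0.0, nev = 0.0;
    int k = 0;
    while (k < ntime) {
      double a[6];
      props(s, p, a);
      const double a0 = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
      double dt = (a0 > 0.0 && nev < max_events_per_cell)
                      ? rng.expo(a0) : HUGE_VAL;
      while (k < ntime && t + dt >= record_times[k]) {
        out(c, k) = static_cast<int>(s.n);
        ++k;
      }
      if (k >= ntime) break;
      t += dt;
      nev += 1.0;
      double u = rng.unif() * a0;
      int j = 0;
      for (; j < 5; ++j) { if (u <= a[j]) break; u -= a[j]; }
      apply(s, j);
    }
    if (c % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
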