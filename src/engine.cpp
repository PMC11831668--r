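// Modified Next Reaction Method inner loop.
//
// Each reaction channel j carries an internal clock T_j (consumed internal
// time) and a next internal firing time P_j; the channel minimising
// (P_j - T_j) / a_j fires next (Anderson's formulation of the next reaction
// method).  Randomness is organised as explicit, serialisable streams: one
// independent stream per slow channel and a single shared stream for all
// fast channels, which is what makes common-random-number replicate
// generation from snapshots possible.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Random streams: xorshift64* generators, seeded via splitmix64 from a
// master seed and a per-stream integer key.  State is a single nonzero
// uint64, shipped to R as two exactly-representable 32-bit halves.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64_next(uint64_t &s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t xorshift64star(uint64_t &x) {
  x ^= x >> 12;
  x ^= x << 25;
  x ^= x >> 27;
  return x * 0x2545F4914F6CDD1DULL;
}

// strictly inside (0, 1)
static inline double unif01(uint64_t &x) {
  return (static_cast<double>(xorshift64star(x) >> 11) + 0.5) *
         (1.0 / 9007199254740992.0);
}

static inline double rexp1(uint64_t &x) { return -std::log(unif01(x)); }

static inline uint64_t decode_state(double hi, double lo) {
  return (static_cast<uint64_t>(static_cast<uint32_t>(hi)) << 32) |
         static_cast<uint64_t>(static_cast<uint32_t>(lo));
}

static inline void encode_state(uint64_t s, double &hi, double &lo) {
  hi = static_cast<double>(static_cast<uint32_t>(s >> 32));
  lo = static_cast<double>(static_cast<uint32_t>(s & 0xFFFFFFFFULL));
}

// [[Rcpp::export]]
NumericMatrix cpp_make_streams(double master_seed, IntegerVector keys) {
  int n = keys.size();
  NumericMatrix out(2, n);
  for (int i = 0; i < n; ++i) {
    uint64_t s = static_cast<uint64_t>(master_seed) ^
                 (0x9E3779B97F4A7C15ULL * (static_cast<uint64_t>(keys[i]) + 1));
    uint64_t st = splitmix64_next(s);
    st ^= splitmix64_next(s);
    if (st == 0) st = 0x9E3779B97F4A7C15ULL;
    encode_state(st, out(0, i), out(1, i));
  }
  return out;
}

// n uniform draws from stream `which` (1-based); returns values + new state
// [[Rcpp::export]]
List cpp_draw_uniform(NumericMatrix streams, int which, int n) {
  if (which < 1 || which > streams.ncol()) stop("stream index out of range");
  uint64_t st = decode_state(streams(0, which - 1), streams(1, which - 1));
  NumericVector v(n);
  for (int i = 0; i < n; ++i) v[i] = unif01(st);
  NumericMatrix ns = clone(streams);
  encode_state(st, ns(0, which - 1), ns(1, which - 1));
  return List::create(_["values"] = v, _["streams"] = ns);
}

// ---------------------------------------------------------------------------
// Propensities.  kind codes: 0 zeroth, 1 unimolecular, 2 bimolecular between
// distinct species, 3 bimolecular between identical molecules (n(n-1)/2
// combinatorics).  `ceff` is the stochastic (copy-number) constant, already
// converted from concentration units by the caller.
// ---------------------------------------------------------------------------

static inline double propensity1(int kind, double ceff, const std::vector<double> &pop,
                                 int r1, int r2) {
  switch (kind) {
  case 0: return ceff;
  case 1: return ceff * pop[r1];
  case 2: return ceff * pop[r1] * pop[r2];
  case 3: return ceff * pop[r1] * (pop[r1] - 1.0) * 0.5;
  }
  return 0.0;
}

// ---------------------------------------------------------------------------
// Main propagation loop.
//
// Advances the engine until KMC time t_f (possibly +Inf) or until max_steps
// events have fired, whichever comes first.  When stopping at t_f the
// pending reaction is NOT fired: internal clocks are advanced by
// a_j * (t_f - t) and the pending P draws are retained, which makes
// pause/resume statistically (in fact bitwise) neutral.
//
// Species samples are recorded on a fixed grid next_sample, next_sample+dt,
// ... carrying the pre-step state across sample points (zero-order hold,
// exact for piecewise-constant paths).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(IntegerMatrix delta, IntegerVector kind, NumericVector ceff,
             IntegerVector r1, IntegerVector r2,
             NumericVector pop0, double t0,
             NumericVector T0, NumericVector P0,
             NumericMatrix streams0, IntegerVector stream_of,
             double t_f, double max_steps,
             double sample_interval, double next_sample,
             LogicalVector record_slow) {
  const int nchan = kind.size();
  const int nspec = delta.nrow();

  std::vector<double> pop(pop0.begin(), pop0.end());
  std::vector<double> T(T0.begin(), T0.end());
  std::vector<double> P(P0.begin(), P0.end());
  std::vector<double> a(nchan);
  std::vector<double> counts(nchan, 0.0);
  double t = t0;

  const int nstream = streams0.ncol();
  std::vector<uint64_t> st(nstream);
  for (int i = 0; i < nstream; ++i) st[i] = decode_state(streams0(0, i), streams0(1, i));

  // sparse population updates and the reaction dependency graph: firing j
  // can only change the propensity of channels whose reactants j touches
  std::vector<std::vector<std::pair<int, int> > > upd(nchan);
  std::vector<std::vector<int> > dep(nchan);
  for (int j = 0; j < nchan; ++j) {
    for (int i = 0; i < nspec; ++i)
      if (delta(i, j) != 0) upd[j].push_back(std::make_pair(i, delta(i, j)));
    for (int k = 0; k < nchan; ++k) {
      bool affected = (k == j);
      if (!affected && kind[k] != 0) {
        for (size_t u = 0; u < upd[j].size(); ++u) {
          int sp = upd[j][u].first;
          if (sp == r1[k] || (kind[k] == 2 && sp == r2[k])) { affected = true; break; }
        }
      }
      if (affected) dep[j].push_back(k);
    }
  }

  // absolute next-firing times; internal clocks T are flushed lazily, only
  // when a channel's propensity changes (t_flush marks the last flush time)
  std::vector<double> tnext(nchan), t_flush(nchan, t);
  for (int j = 0; j < nchan; ++j) {
    a[j] = propensity1(kind[j], ceff[j], pop, r1[j], r2[j]);
    tnext[j] = a[j] > 0.0 ? t + (P[j] - T[j]) / a[j] : R_PosInf;
  }

  const bool sampling = sample_interval > 0.0;
  std::vector<double> samp;  // row-major: time, species...
  if (sampling && R_finite(t_f)) {
    double approx = (t_f - next_sample) / sample_interval + 2.0;
    if (approx > 0 && approx < 2e8)
      samp.reserve(static_cast<size_t>(approx) * (nspec + 1));
  }
  std::vector<std::vector<double> > events(nchan);

  double steps = 0.0;
  bool exhausted = false;
  bool hit_tf = false;

  while (steps < max_steps) {
    int best = 0;
    double tn = tnext[0];
    for (int j = 1; j < nchan; ++j)
      if (tnext[j] < tn) { tn = tnext[j]; best = j; }
    if (!R_finite(tn)) { exhausted = true; break; }
    if (tn > t_f) { hit_tf = true; break; }

    if (sampling) {
      while (next_sample < tn) {
        samp.push_back(next_sample);
        for (int i = 0; i < nspec; ++i) samp.push_back(pop[i]);
        next_sample += sample_interval;
      }
    }

    for (size_t u = 0; u < upd[best].size(); ++u) {
      int i = upd[best][u].first;
      pop[i] += upd[best][u].second;
      if (pop[i] < 0)
        stop("negative population for species %d after firing channel %d",
             i + 1, best + 1);
    }
    t = tn;
    counts[best] += 1.0;
    if (record_slow[best]) events[best].push_back(tn);

    const std::vector<int> &dj = dep[best];
    for (size_t u = 0; u < dj.size(); ++u) {
      int k = dj[u];
      T[k] += a[k] * (t - t_flush[k]);  // flush with the old propensity
      t_flush[k] = t;
      if (k == best) P[k] += rexp1(st[stream_of[k] - 1]);
      a[k] = propensity1(kind[k], ceff[k], pop, r1[k], r2[k]);
      tnext[k] = a[k] > 0.0 ? t + (P[k] - T[k]) / a[k] : R_PosInf;
    }
    steps += 1.0;
  }

  // statistically-neutral pause at t_f (also used to lay down a flat tail
  // when every propensity vanished before t_f)
  if ((hit_tf || exhausted) && R_finite(t_f) && t < t_f) t = t_f;
  for (int j = 0; j < nchan; ++j) {
    T[j] += a[j] * (t - t_flush[j]);
    t_flush[j] = t;
  }
  if (sampling && R_finite(t_f) && t >= t_f) {
    while (next_sample <= t_f) {
      samp.push_back(next_sample);
      for (int i = 0; i < nspec; ++i) samp.push_back(pop[i]);
      next_sample += sample_interval;
    }
  }

  NumericMatrix streams1(2, nstream);
  for (int i = 0; i < nstream; ++i) encode_state(st[i], streams1(0, i), streams1(1, i));

  size_t nrow = sampling ? samp.size() / (nspec + 1) : 0;
  NumericMatrix samples(static_cast<int>(nrow), nspec + 1);
  for (size_t r = 0; r < nrow; ++r)
    for (int cidx = 0; cidx <= nspec; ++cidx)
      samples(static_cast<int>(r), cidx) = samp[r * (nspec + 1) + cidx];

  List ev(nchan);
  for (int j = 0; j < nchan; ++j) ev[j] = NumericVector(events[j].begin(), events[j].end());

  return List::create(
      _["pop"] = NumericVector(pop.begin(), pop.end()),
      _["t"] = t,
      _["T"] = NumericVector(T.begin(), T.end()),
      _["P"] = NumericVector(P.begin(), P.end()),
      _["a"] = NumericVector(a.begin(), a.end()),
      _["streams"] = streams1,
      _["steps"] = steps,
      _["counts"] = NumericVector(counts.begin(), counts.end()),
      _["samples"] = samples,
      _["events"] = ev,
      _["exhausted"] = exhausted,
      _["next_sample"] = next_sample);
}
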