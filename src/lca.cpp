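#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Step response of a critically damped second-order high-pass filter:
// starts at A, crosses zero once at t = tau, reverses sign, decays to 0.
inline double irr_step(double t, double A, double tau) {
  return A * (1.0 - t / tau) * std::exp(-t / tau);
}

// --- per-trial RNG substreams -------------------------------------------
// Each trial gets its own xoshiro256++ stream seeded from (master seed,
// trial index) via splitmix64. With fixed streams every trial's noise
// path is a fixed function of the trial index, so simulation-based
// objectives evaluated under a common master seed are smooth in the model
// parameters (true common random numbers).

struct TrialRng {
  uint64_t s[4];
  double cached;
  bool has_cached;

  explicit TrialRng(uint64_t seed) : cached(0.0), has_cached(false) {
    // splitmix64 expansion of the seed into the xoshiro state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() {  // uniform in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline double norm() {  // standard normal via Box-Muller, pair-cached
    if (has_cached) {
      has_cached = false;
      return cached;
    }
    const double u1 = unif(), u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 6.283185307179586476925286766559 * u2;
    cached = r * std::sin(a);
    has_cached = true;
    return r * std::cos(a);
  }

  // normal truncated at zero (rejection; near-certain acceptance for the
  // parameter ranges in use, the guard caps pathological cases)
  inline double tnorm0(double mu, double sd) {
    if (sd <= 0.0) return mu > 0.0 ? mu : 0.0;
    for (int k = 0; k < 1000; ++k) {
      double x = mu + sd * norm();
      if (x >= 0.0) return x;
    }
    return 0.0;
  }
};

//' Batch trial simulation for the extended leaky competing accumulator
//'
//' Two response codes (correct, error) accumulate external input with leak
//' (self-inhibition), lateral inhibition and Gaussian noise until one
//' crosses the threshold; activations are floored at zero. The relevant
//' (controlled) input onsets at a per-trial lead drawn from a truncated
//' normal; the irrelevant (automatic) input onsets at t = 0 with the sign
//' pattern +h(t) toward the stimulus-side code and -h(t) toward the other.
//' The drift is integrated with a Heun (trapezoidal) scheme, splitting
//' the step exactly at the relevant-input onset and handling floor-exit
//' events within the step; noise is added Euler-Maruyama fashion.
//'
//' Per-trial parameter vectors must all have length n. Columns of the
//' returned matrix: rt (decision + residual, ms), correct (0/1),
//' timed_out (0/1), decision_time (ms), lead (ms).
//'
//' @noRd
// [[Rcpp::export]]
NumericMatrix lca_simulate_cpp(int n,
                               NumericVector rel,
                               NumericVector irr_amp,
                               NumericVector irr_tau,
                               NumericVector prep_correct,
                               NumericVector prep_error,
                               IntegerVector congruent,
                               double lead_mean, double lead_sd,
                               double leak, double lateral,
                               double noise_sd, double threshold,
                               double resid_mean, double resid_sd,
                               double dt, double max_time,
                               double master_seed) {
  NumericMatrix out(n, 5);
  const double sqdt = std::sqrt(dt);
  const long nstep = (long)std::ceil(max_time / dt);
  const bool noisy = noise_sd > 0.0;
  const uint64_t mseed = (uint64_t)master_seed;

  for (int i = 0; i < n; ++i) {
    TrialRng rng(mseed ^ ((uint64_t)(i + 1) * 0xD1B54A32D192ED03ULL));
    const double lead = rng.tnorm0(lead_mean, lead_sd);
    const double A = irr_amp[i], tau = irr_tau[i];
    const double relc = rel[i], rele = 1.0 - rel[i];
    // stimulus side coincides with the correct response in congruent trials
    const double s1 = congruent[i] ? 1.0 : -1.0;
    double a1 = prep_correct[i], a2 = prep_error[i];
    int winner = 0;
    double tcross = NA_REAL;

    for (long step = 0; step < nstep; ++step) {
      const double t = step * dt;
      double b1 = a1, b2 = a2;
      // split the step exactly at the relevant-input onset so the drift
      // integration never averages across the discontinuity
      double tsub = t;
      double remaining = dt;
      if (lead > t && lead < t + dt) remaining = lead - t;
      while (remaining > 0.0) {
        const double on = (tsub >= lead) ? 1.0 : 0.0;
        const double hs = remaining;
        const double h0 = s1 * irr_step(tsub, A, tau);
        const double h1 = s1 * irr_step(tsub + hs, A, tau);
        // Heun (trapezoidal) drift update
        const double f1a = on * relc + h0 - leak * b1 - lateral * b2;
        const double f2a = on * rele - h0 - leak * b2 - lateral * b1;
        double p1 = b1 + hs * f1a;
        double p2 = b2 + hs * f2a;
        if (p1 < 0.0) p1 = 0.0;
        if (p2 < 0.0) p2 = 0.0;
        const double f1b = on * relc + h1 - leak * p1 - lateral * p2;
        const double f2b = on * rele - h1 - leak * p2 - lateral * p1;
        const double c1 = b1, c2 = b2;
        b1 = c1 + 0.5 * hs * (f1a + f1b);
        b2 = c2 + 0.5 * hs * (f2a + f2b);
        // floor-exit event: a code pinned at zero with inward drift at
        // the substep start but outward drift at its end leaves the
        // floor at the (linearly interpolated) drift zero-crossing
        if (c1 == 0.0 && f1a < 0.0 && f1b > 0.0)
          b1 = 0.5 * hs * (f1b * f1b) / (f1b - f1a);
        if (c2 == 0.0 && f2a < 0.0 && f2b > 0.0)
          b2 = 0.5 * hs * (f2b * f2b) / (f2b - f2a);
        if (b1 < 0.0) b1 = 0.0;
        if (b2 < 0.0) b2 = 0.0;
        tsub += hs;
        remaining = (t + dt) - tsub;
      }
      if (noisy) {
        b1 += noise_sd * sqdt * rng.norm();
        b2 += noise_sd * sqdt * rng.norm();
      }
      if (b1 < 0.0) b1 = 0.0;
      if (b2 < 0.0) b2 = 0.0;
      if (b1 >= threshold || b2 >= threshold) {
        // linear interpolation of the within-step crossing time
        double f1 = (b1 >= threshold) ? (threshold - a1) / (b1 - a1) : 2.0;
        double f2 = (b2 >= threshold) ? (threshold - a2) / (b2 - a2) : 2.0;
        winner = (f1 <= f2) ? 1 : 2;
        tcross = t + dt * std::min(f1, f2);
        break;
      }
      a1 = b1;
      a2 = b2;
    }

    if (winner == 0) {
      out(i, 0) = NA_REAL;
      out(i, 1) = NA_REAL;
      out(i, 2) = 1.0;
      out(i, 3) = NA_REAL;
    } else {
      const double resid = rng.tnorm0(resid_mean, resid_sd);
      out(i, 0) = tcross + resid;
      out(i, 1) = (winner == 1) ? 1.0 : 0.0;
      out(i, 2) = 0.0;
      out(i, 3) = tcross;
    }
    out(i, 4) = lead;
  }
  colnames(out) = CharacterVector::create("rt", "correct", "timed_out",
                                          "decision_time", "lead");
  return out;
}
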