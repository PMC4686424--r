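#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Counter-based per-trial substreams: each trial draws from its own
// xoshiro256++ generator seeded by (seed, stream, trial index) through
// splitmix64, so trial i is reproducible independent of trial order and of
// how many draws earlier trials consumed.  Execution and braking noise use
// separate substreams so the execution path of a stop trial is identical to
// the go trial with the same index (common random numbers).

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t rotl64(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct NormStream {
  uint64_t s[4];
  bool has_spare;
  double spare;
  NormStream(uint64_t seed, uint64_t trial, uint64_t stream) {
    uint64_t x = seed;
    x ^= 0x9E3779B97f4A7C15ULL * (trial + 0x632BE59BD9B4E019ULL);
    x ^= rotl64(0xBF58476D1CE4E5B9ULL, (int)(stream % 63)) + stream;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    has_spare = false;
    spare = 0.0;
  }
  inline uint64_t next() {
    const uint64_t result = rotl64(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl64(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1]
    return ((next() >> 11) + 1.0) * 0x1.0p-53;
  }
  inline double norm() {  // Box-Muller with cached spare
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1 = unif();
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double ang = 6.283185307179586476925287 * u2;
    spare = r * std::sin(ang);
    has_spare = true;
    return r * std::cos(ang);
  }
};

// ---------------------------------------------------------------------
// Continuous-time trial kernel.
//
// model codes: 0 = go (execution only), 1 = dependent process (DPM),
// 2 = independent race, 3 = interactive race.
//
// The Euler-Maruyama grid is anchored at the onset delay tr (step k ends
// at tr + (k+1) dt) with a truncated final step at the deadline, and
// boundary crossings are located by linear interpolation within the
// crossing step.  Onset, deadline and stop-signal times therefore enter
// the simulated outcome continuously, not rounded to the grid — which
// both removes most of the O(dt) discretization bias and makes summary
// statistics smooth functions of the parameters (important for the
// simplex/gradient stages of fitting).
//
// Execution: dphi_e = v_e dt + sigma dW from 0 at tr;
// theta_e(t) = phi_e(t) * cosh(xb (t - tr)).
// DPM braking: phi_b starts at theta_e(SSD) at t = SSD and drifts by
// -v_b with the same sigma and no gain; the trial is stopped when it
// reaches 0 before theta_e reaches a.
// Independent: theta_b starts at 0 at t = SSD, drift +v_b, races to a.
// Interactive: theta_b starts at 0 at t = SSD + sso, drift +v_b, and the
// response criterion becomes theta_e - theta_b >= a.
// If execution and braking cross in the same step, the earlier
// interpolated crossing time wins.
//
// Discrete monitoring misses within-step excursions across a boundary,
// which biases first-passage times upward by ~ beta sigma sqrt(h) in
// boundary units (beta = 0.5826, the Broadie-Glasserman continuity
// correction). Each crossing test therefore uses an effective boundary
// pulled toward the process by beta times the process's instantaneous
// diffusion scale (sigma gamma(t) for the gain-scaled execution state).
//
// auc accumulates the trapezoid integral of theta_e up to the outcome.

static const double BG_BETA = 0.5826;

struct TrialResult {
  double rt;   // NA when no response
  double auc;
};

// gain lookup for full steps: g[k] = cosh(xb (k+1) dt) — independent of
// tr because the grid is onset-anchored; the truncated final step falls
// back to a direct cosh
struct GainTable {
  std::vector<double> g;
  double xb, dt;
  GainTable(double xb_, double dt_, double deadline) : xb(xb_), dt(dt_) {
    int n = (int)std::ceil(deadline / dt_) + 2;
    g.resize(n > 0 ? n : 0, 1.0);
    if (xb_ > 0) {
      for (int k = 0; k < (int)g.size(); ++k) {
        g[k] = std::cosh(xb_ * (k + 1) * dt_);
      }
    }
  }
  inline double at(int k, double ts, bool full) const {
    if (xb <= 0) return 1.0;
    if (full && k < (int)g.size()) return g[k];
    return std::cosh(xb * ts);
  }
};

template <typename ZE, typename ZB>
static TrialResult run_trial(int model, double a, double tr, double v_e,
                             double v_b, double xb, double sigma,
                             double sso, double ssd, double dt,
                             double deadline, const GainTable &gt,
                             ZE &&ze, ZB &&zb) {
  TrialResult out;
  out.rt = NA_REAL;
  out.auc = 0.0;
  const double ss_abs = (model == 3) ? ssd + sso : ssd;
  const bool has_brake = model != 0;

  // DPM stop cue arriving before the execution process starts: the
  // braking process inherits state 0 and reaches its 0 boundary at once
  if (model == 1 && ssd <= tr) return out;

  double t_prev = tr;
  double phi = 0.0, theta_prev = 0.0;
  double brake = 0.0, brake_prev = 0.0;
  bool brake_on = false;
  int k = 0;
  while (t_prev < deadline - 1e-12) {
    const double h = std::min(dt, deadline - t_prev);
    const double t = t_prev + h;
    const double z = ze(k);
    const double zbv = has_brake ? zb(k) : 0.0;
    ++k;

    phi += v_e * h + sigma * std::sqrt(h) * z;
    const double ts = t - tr;
    const double gnow = gt.at(k - 1, ts, h == dt);
    const double theta = phi * gnow;

    // braking initialisation and update
    double tb_start = t;  // time from which `brake` is evolving this step
    if (has_brake && !brake_on && t > ss_abs) {
      brake_on = true;
      // the braking process exists from ss_abs, which may pre-date the
      // execution onset; its first increment aggregates [ss_abs, t]
      const double t0 = ss_abs;
      if (model == 1) {
        // state of theta_e at the stop-signal delay, interpolated
        double frac = (ssd - t_prev) / h;
        if (frac < 0) frac = 0;
        brake_prev = theta_prev + frac * (theta - theta_prev);
      } else {
        brake_prev = 0.0;
      }
      const double hb = t - t0;
      const double drift = (model == 1) ? -v_b : v_b;
      brake = brake_prev + drift * hb +
              sigma * std::sqrt(hb > 0 ? hb : 0) * zbv;
      tb_start = t0;
    } else if (brake_on) {
      brake_prev = brake;
      const double drift = (model == 1) ? -v_b : v_b;
      brake += drift * h + sigma * std::sqrt(h) * zbv;
      tb_start = t_prev;
    }

    // interpolated crossing times within this step (Inf = no crossing)
    const double exec_prev =
        (model == 3 && brake_on) ? theta_prev - brake_prev : theta_prev;
    const double exec_now =
        (model == 3 && brake_on) ? theta - brake : theta;
    const double escale =
        (model == 3 && brake_on) ? std::sqrt(gnow * gnow + 1.0) : gnow;
    const double a_eff = a - BG_BETA * sigma * escale * std::sqrt(h);
    double tc_e = R_PosInf, tc_b = R_PosInf;
    if (exec_now >= a_eff && exec_prev < a_eff) {
      tc_e = t_prev + h * (a_eff - exec_prev) / (exec_now - exec_prev);
    } else if (exec_now >= a_eff) {
      tc_e = t_prev;
    }
    if (brake_on && model != 3) {
      const double bshift = BG_BETA * sigma * std::sqrt(h);
      const double target = (model == 1) ? bshift : a - bshift;
      const bool hit = (model == 1) ? (brake <= target) : (brake >= target);
      if (hit) {
        const double b0 = brake_prev, b1 = brake;
        double span = b1 - b0;
        double frac = (span != 0) ? (target - b0) / span : 0.0;
        if (frac < 0) frac = 0;
        if (frac > 1) frac = 1;
        tc_b = tb_start + (t - tb_start) * frac;
      }
    }

    if (tc_e <= tc_b && tc_e < R_PosInf) {
      // response: integrate theta_e up to the crossing
      const double frac = (tc_e - t_prev) / h;
      const double theta_c = theta_prev + frac * (theta - theta_prev);
      out.auc += 0.5 * (theta_prev + theta_c) * (tc_e - t_prev);
      out.rt = tc_e;
      return out;
    }
    if (model != 3 && tc_b < R_PosInf) {
      // stopped: no response, integrate up to the braking outcome
      const double tc = std::max(tc_b, t_prev);
      const double frac = (tc - t_prev) / h;
      const double theta_c = theta_prev + frac * (theta - theta_prev);
      out.auc += 0.5 * (theta_prev + theta_c) * (tc - t_prev);
      return out;
    }
    out.auc += 0.5 * (theta_prev + theta) * h;
    theta_prev = theta;
    t_prev = t;
  }
  return out;
}

static int max_steps(double tr, double dt, double deadline) {
  double span = deadline - tr;
  if (span <= 0) return 0;
  return (int)std::ceil(span / dt - 1e-12);
}

// [[Rcpp::export]]
List cpp_simulate(int model, int n, double a, double tr, double v_e,
                  double v_b, double xb, double sigma, double sso,
                  double ssd, double dt, double deadline, double seed,
                  double stream_offset) {
  if (dt <= 0) stop("dt must be > 0");
  if (n < 0) stop("n must be >= 0");
  const uint64_t useed = (uint64_t)seed;
  const uint64_t off = (uint64_t)stream_offset;
  NumericVector rt(n, NA_REAL);
  NumericVector auc(n, 0.0);
  const GainTable gt(xb, dt, deadline);
  for (int i = 0; i < n; ++i) {
    NormStream ge(useed, off + (uint64_t)i, 0u);
    NormStream gb(useed, off + (uint64_t)i, 1u);
    TrialResult r = run_trial(
        model, a, tr, v_e, v_b, xb, sigma, sso, ssd, dt, deadline, gt,
        [&](int) { return ge.norm(); }, [&](int) { return gb.norm(); });
    rt[i] = r.rt;
    auc[i] = r.auc;
  }
  return List::create(_["rt"] = rt, _["auc"] = auc);
}

// Pre-generated standard-normal increments for a block of trials:
// column j holds the per-step (since onset) draws of trial j, so
// simulations that reuse the matrix across cost evaluations see common
// random numbers without regenerating them.

// [[Rcpp::export]]
NumericMatrix cpp_noise_matrix(int n, int nsteps, double seed,
                               double stream_offset, int substream) {
  NumericMatrix z(nsteps, n);
  const uint64_t useed = (uint64_t)seed;
  const uint64_t off = (uint64_t)stream_offset;
  for (int i = 0; i < n; ++i) {
    NormStream g(useed, off + (uint64_t)i, (uint64_t)substream);
    for (int k = 0; k < nsteps; ++k) z(k, i) = g.norm();
  }
  return z;
}

// Cached-noise variant.  With antithetic = 1, trials 2j and 2j+1 share
// noise column j with opposite signs (antithetic variates): the n
// simulated trials consume ceil(n/2) noise columns and the Monte-Carlo
// variance of the summary statistics drops well below 1/n.

// [[Rcpp::export]]
List cpp_simulate_cached(int model, double a, double tr, double v_e,
                         double v_b, double xb, double sigma, double sso,
                         double ssd, double dt, double deadline,
                         NumericMatrix ze, NumericMatrix zb,
                         int n_out, int antithetic) {
  if (dt <= 0) stop("dt must be > 0");
  const int n = n_out;
  const int need_cols = antithetic ? (n + 1) / 2 : n;
  const int need_steps = max_steps(0.0, dt, deadline);
  if (ze.nrow() < need_steps || ze.ncol() < need_cols) {
    stop("noise matrix too small");
  }
  const bool has_brake = model != 0;
  if (has_brake && (zb.ncol() < need_cols || zb.nrow() < need_steps)) {
    stop("braking noise matrix too small");
  }
  NumericVector rt(n, NA_REAL);
  NumericVector auc(n, 0.0);
  const GainTable gt(xb, dt, deadline);
  for (int i = 0; i < n; ++i) {
    const int icol = antithetic ? i / 2 : i;
    const double sgn = (antithetic && (i % 2 == 1)) ? -1.0 : 1.0;
    const double *col = &ze(0, icol);
    const double *bcol = has_brake ? &zb(0, icol) : (const double *)0;
    TrialResult r = run_trial(
        model, a, tr, v_e, v_b, xb, sigma, sso, ssd, dt, deadline, gt,
        [&](int k) { return sgn * col[k]; },
        [&](int k) { return sgn * bcol[k]; });
    rt[i] = r.rt;
    auc[i] = r.auc;
  }
  return List::create(_["rt"] = rt, _["auc"] = auc);
}

// Full execution-process path for one trial (braking not simulated).
// Rows at t = tr + dt, tr + 2 dt, ..., ending at the boundary crossing
// (if stop_at_boundary) or the deadline.

// [[Rcpp::export]]
DataFrame cpp_execution_path(double a, double tr, double v_e, double xb,
                             double sigma, double dt, double deadline,
                             double seed, double stream_offset,
                             bool stop_at_boundary) {
  if (dt <= 0) stop("dt must be > 0");
  NormStream ge((uint64_t)seed, (uint64_t)stream_offset, 0u);
  std::vector<double> tv, phiv, thv;
  double t_prev = tr, phi = 0.0, theta = 0.0;
  while (t_prev < deadline - 1e-12) {
    const double h = std::min(dt, deadline - t_prev);
    const double t = t_prev + h;
    phi += v_e * h + sigma * std::sqrt(h) * ge.norm();
    const double ts = t - tr;
    theta = (xb > 0) ? phi * std::cosh(xb * ts) : phi;
    tv.push_back(t);
    phiv.push_back(phi);
    thv.push_back(theta);
    if (stop_at_boundary && theta >= a) break;
    t_prev = t;
  }
  return DataFrame::create(_["time"] = tv, _["phi_e"] = phiv,
                           _["theta_e"] = thv);
}
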