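// Core engine: deterministic RNG, random interaction-matrix assembly,
// adaptive Dormand-Prince 5(4) integration of competitive Lotka-Volterra
// dynamics, paired with/without-antagonist runs and the tile sweep loop.
// Everything randomness-related lives here so that a community seed gives
// bit-identical draws whether invoked from R or from the sweep inner loop.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 mixing + mt19937_64 stream, Box-Muller normals.
// mt19937_64 and the constructions below are fully specified, so draws are
// platform-independent (std::*_distribution would not be).
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &s) {
  uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// order-independent stream derivation for (root, tile, replicate)
static inline uint64_t derive_seed(uint64_t root, uint64_t a, uint64_t b) {
  uint64_t s = root;
  uint64_t z = splitmix64(s);
  s = z ^ (a + 0x9e3779b97f4a7c15ULL);
  z = splitmix64(s);
  s = z ^ (b + 0xbf58476d1ce4e5b9ULL);
  z = splitmix64(s);
  // keep within 2^53 so the value survives an R double round trip
  return z & ((1ULL << 53) - 1ULL);
}

class Rng {
 public:
  explicit Rng(uint64_t seed) {
    uint64_t s = seed;
    gen_.seed(splitmix64(s));
    has_cached_ = false;
    cached_ = 0.0;
  }
  // uniform on [0, 1)
  double unif() { return (gen_() >> 11) * (1.0 / 9007199254740992.0); }
  double normal() {
    if (has_cached_) {
      has_cached_ = false;
      return cached_;
    }
    double u1;
    do { u1 = unif(); } while (u1 <= 0.0);
    const double u2 = unif();
    const double rad = std::sqrt(-2.0 * std::log(u1));
    const double ang = 6.283185307179586476925287 * u2;
    cached_ = rad * std::sin(ang);
    has_cached_ = true;
    return rad * std::cos(ang);
  }
  // |N(0, sigma^2)| with exact zeros resampled (r and impacts must be > 0)
  double half_normal(double sigma) {
    double v = std::fabs(normal()) * sigma;
    while (v == 0.0) v = std::fabs(normal()) * sigma;
    return v;
  }

 private:
  std::mt19937_64 gen_;
  bool has_cached_;
  double cached_;
};

// ---------------------------------------------------------------------------
// System assembly. alpha is row-major N x N; alpha[i][j] = effect of species
// j on species i's growth bracket. Draw order is fixed: focal off-diagonals
// (row-major), focal growth rates, antagonist impacts (row-major over the
// n x m block), antagonist growth rates. Because the focal draws come first,
// assemble(n, 0, ...) with the same seed reproduces the focal community of
// assemble(n, m, ...) exactly -- the pairing contract.
// ---------------------------------------------------------------------------

struct Sys {
  int n, m;
  std::vector<double> alpha;  // row-major (n+m) x (n+m)
  std::vector<double> r;
};

static void assemble(int n, int m, double sigma, double A, uint64_t seed,
                     Sys &out) {
  Rng rng(seed);
  const int N = n + m;
  out.n = n;
  out.m = m;
  out.alpha.assign((size_t)N * N, 0.0);
  out.r.assign(N, 0.0);
  const double b = A / n;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      out.alpha[(size_t)i * N + j] = (i == j) ? 1.0 : b * rng.unif();
  for (int i = 0; i < n; ++i) out.r[i] = rng.half_normal(1.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      out.alpha[(size_t)i * N + (n + j)] = rng.half_normal(sigma);
  for (int i = n; i < N; ++i) {
    for (int j = n; j < N; ++j) out.alpha[(size_t)i * N + j] = 1.0;
    out.r[i] = rng.half_normal(1.0);
  }
}

// ---------------------------------------------------------------------------
// Lotka-Volterra RHS and Dormand-Prince 5(4) integration with positivity
// clipping (negative components produced by floating-point error are set to
// zero on step acceptance; extinction is absorbing so this is exact).
// ---------------------------------------------------------------------------

static void lv_rhs(const std::vector<double> &alpha,
                   const std::vector<double> &r, const std::vector<double> &x,
                   std::vector<double> &dx) {
  const int N = (int)r.size();
  for (int i = 0; i < N; ++i) {
    const double *ai = &alpha[(size_t)i * N];
    double s = 0.0;
    for (int j = 0; j < N; ++j) s += ai[j] * x[j];
    dx[i] = r[i] * x[i] * (1.0 - s);
  }
}

struct IntStatus {
  bool ok;
  int steps;        // accepted + rejected attempts
  double deriv_inf; // infinity norm of RHS at t_end
};

static IntStatus dopri5(const std::vector<double> &alpha,
                        const std::vector<double> &r, std::vector<double> &x,
                        double t_end, double rtol, double atol,
                        int max_steps) {
  const int N = (int)r.size();
  // Dormand-Prince coefficients
  const double a21 = 1.0 / 5;
  const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
               a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
               a64 = 49.0 / 176, a65 = -5103.0 / 18656;
  const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
               b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  // b - b* (embedded 4th-order error coefficients)
  const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
               e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  std::vector<double> k1(N), k2(N), k3(N), k4(N), k5(N), k6(N), k7(N),
      ytmp(N), ynew(N);
  double t = 0.0, h = 1e-2;
  lv_rhs(alpha, r, x, k1);
  int steps = 0;
  IntStatus st;
  while (t < t_end) {
    if (steps >= max_steps || h < 1e-13) {
      st.ok = false;
      st.steps = steps;
      std::vector<double> dx(N);
      lv_rhs(alpha, r, x, dx);
      double dn = 0.0;
      for (int i = 0; i < N; ++i) dn = std::max(dn, std::fabs(dx[i]));
      st.deriv_inf = dn;
      return st;
    }
    bool last = false;
    if (t + h >= t_end) {
      h = t_end - t;
      last = true;
    }
    for (int i = 0; i < N; ++i) ytmp[i] = x[i] + h * a21 * k1[i];
    lv_rhs(alpha, r, ytmp, k2);
    for (int i = 0; i < N; ++i)
      ytmp[i] = x[i] + h * (a31 * k1[i] + a32 * k2[i]);
    lv_rhs(alpha, r, ytmp, k3);
    for (int i = 0; i < N; ++i)
      ytmp[i] = x[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    lv_rhs(alpha, r, ytmp, k4);
    for (int i = 0; i < N; ++i)
      ytmp[i] =
          x[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    lv_rhs(alpha, r, ytmp, k5);
    for (int i = 0; i < N; ++i)
      ytmp[i] = x[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    lv_rhs(alpha, r, ytmp, k6);
    for (int i = 0; i < N; ++i)
      ynew[i] = x[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    lv_rhs(alpha, r, ynew, k7);  // FSAL stage
    double err = 0.0;
    for (int i = 0; i < N; ++i) {
      const double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                            e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sk =
          atol + rtol * std::max(std::fabs(x[i]), std::fabs(ynew[i]));
      const double q = e / sk;
      err += q * q;
    }
    err = std::sqrt(err / N);
    if (err <= 1.0) {
      t += h;
      bool clipped = false;
      for (int i = 0; i < N; ++i) {
        if (ynew[i] < 0.0) {
          ynew[i] = 0.0;
          clipped = true;
        }
      }
      x = ynew;
      if (clipped)
        lv_rhs(alpha, r, x, k1);
      else
        k1 = k7;
      if (last && t >= t_end) break;
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
    ++steps;
  }
  st.ok = true;
  st.steps = steps;
  std::vector<double> dx(N);
  lv_rhs(alpha, r, x, dx);
  double dn = 0.0;
  for (int i = 0; i < N; ++i) dn = std::max(dn, std::fabs(dx[i]));
  st.deriv_inf = dn;
  return st;
}

// ---------------------------------------------------------------------------
// Metrics on focal compositions
// ---------------------------------------------------------------------------

// zero densities below floor, normalize first n entries; false if all extinct
static bool focal_composition(const std::vector<double> &x, int n,
                              double floor_, std::vector<double> &p) {
  p.assign(n, 0.0);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    double v = x[i] < floor_ ? 0.0 : x[i];
    p[i] = v;
    tot += v;
  }
  if (tot <= 0.0) return false;
  for (int i = 0; i < n; ++i) p[i] /= tot;
  return true;
}

static double bray_curtis_cpp(const std::vector<double> &p,
                              const std::vector<double> &q) {
  double c = 0.0;
  for (size_t i = 0; i < p.size(); ++i) c += std::min(p[i], q[i]);
  return 1.0 - c;
}

static void kendall_counts(const std::vector<double> &p,
                           const std::vector<double> &q, long &nc, long &nd) {
  nc = nd = 0;
  const int n = (int)p.size();
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dp = p[i] - p[j], dq = q[i] - q[j];
      if (dp == 0.0 || dq == 0.0) continue;  // ties count toward neither
      if (dp * dq > 0.0)
        ++nc;
      else
        ++nd;
    }
}

// ---------------------------------------------------------------------------
// Paired run kernel: one focal draw, simulated with and without antagonists.
// pairing_mode 0 = paired (same focal draw), 1 = independent baseline draw.
// Returns through out[]: bc, tau_std, tau_lit, degenerate, conv_with,
// conv_without.
// ---------------------------------------------------------------------------

static void paired_kernel(int n, int m, double sigma, double A, uint64_t seed,
                          double x0, double t_end, double rtol, double atol,
                          int max_steps, double conv_tol, double floor_,
                          int pairing_mode, double out[6]) {
  Sys with_sys, base_sys;
  assemble(n, m, sigma, A, seed, with_sys);
  const uint64_t base_seed =
      (pairing_mode == 0) ? seed : derive_seed(seed, 0x1dde9e4dULL, 1);
  assemble(n, 0, sigma, A, base_seed, base_sys);

  std::vector<double> xw(n + m, x0), xb(n, x0);
  IntStatus sw = dopri5(with_sys.alpha, with_sys.r, xw, t_end, rtol, atol,
                        max_steps);
  IntStatus sb =
      dopri5(base_sys.alpha, base_sys.r, xb, t_end, rtol, atol, max_steps);

  out[4] = (sw.ok && sw.deriv_inf < conv_tol) ? 1.0 : 0.0;
  out[5] = (sb.ok && sb.deriv_inf < conv_tol) ? 1.0 : 0.0;

  std::vector<double> p, q;
  const bool okw = sw.ok && focal_composition(xw, n, floor_, p);
  const bool okb = sb.ok && focal_composition(xb, n, floor_, q);
  if (!okw || !okb) {
    out[0] = out[1] = out[2] = NA_REAL;
    out[3] = 1.0;
    return;
  }
  out[0] = bray_curtis_cpp(q, p);
  long nc, nd;
  kendall_counts(q, p, nc, nd);
  const double npairs = n * (n - 1) / 2.0;
  out[1] = npairs > 0 ? (nc - nd) / npairs : NA_REAL;
  out[2] = (nc - nd) / (double)n;
  out[3] = 0.0;
}

// ---------------------------------------------------------------------------
// R-facing exports
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_sample_focal_block(int n, double A, double seed) {
  Rng rng((uint64_t)seed);
  NumericMatrix out(n, n);
  const double b = A / n;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      out(i, j) = (i == j) ? 1.0 : b * rng.unif();
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_half_normal_matrix(int nrow, int ncol, double sigma,
                                            double seed) {
  Rng rng((uint64_t)seed);
  NumericMatrix out(nrow, ncol);
  // row-major draw order to match assembly
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < ncol; ++j) out(i, j) = rng.half_normal(sigma);
  return out;
}

// [[Rcpp::export]]
List cpp_assemble(int n, int m, double sigma, double A, double seed) {
  Sys s;
  assemble(n, m, sigma, A, (uint64_t)seed, s);
  const int N = n + m;
  NumericMatrix alpha(N, N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) alpha(i, j) = s.alpha[(size_t)i * N + j];
  return List::create(_["alpha"] = alpha,
                      _["r"] = NumericVector(s.r.begin(), s.r.end()));
}

// [[Rcpp::export]]
List cpp_integrate(NumericMatrix alpha, NumericVector r, NumericVector x0,
                   double t_end, double rtol, double atol, int max_steps) {
  const int N = r.size();
  std::vector<double> al((size_t)N * N), rv(N), x(N);
  for (int i = 0; i < N; ++i) {
    rv[i] = r[i];
    x[i] = x0[i];
    for (int j = 0; j < N; ++j) al[(size_t)i * N + j] = alpha(i, j);
  }
  IntStatus st = dopri5(al, rv, x, t_end, rtol, atol, max_steps);
  return List::create(_["densities"] = NumericVector(x.begin(), x.end()),
                      _["ok"] = st.ok, _["steps"] = st.steps,
                      _["deriv_inf_norm"] = st.deriv_inf);
}

// [[Rcpp::export]]
NumericVector cpp_paired_run(int n, int m, double sigma, double A, double seed,
                             double x0, double t_end, double rtol, double atol,
                             int max_steps, double conv_tol, double floor_,
                             int pairing_mode) {
  double out[6];
  paired_kernel(n, m, sigma, A, (uint64_t)seed, x0, t_end, rtol, atol,
                max_steps, conv_tol, floor_, pairing_mode, out);
  NumericVector res(6);
  for (int i = 0; i < 6; ++i) res[i] = out[i];
  res.names() = CharacterVector::create("bray_curtis", "tau_std", "tau_lit",
                                        "degenerate", "converged_with",
                                        "converged_without");
  return res;
}

// [[Rcpp::export]]
double cpp_replicate_seed(double root_seed, int tile_index, int replicate) {
  return (double)derive_seed((uint64_t)root_seed, (uint64_t)tile_index,
                             (uint64_t)replicate);
}

// tiles: K x 4 matrix of (n, m, sigma, A) rows in canonical order.
// Returns K x 5: mean_bc, mean_tau_std, mean_tau_lit, used, degenerate.
// [[Rcpp::export]]
NumericMatrix cpp_run_sweep(NumericMatrix tiles, int replicates,
                            double root_seed, double x0, double t_end,
                            double rtol, double atol, int max_steps,
                            double conv_tol, double floor_,
                            int pairing_mode) {
  const int K = tiles.nrow();
  NumericMatrix res(K, 5);
  double out[6];
  for (int k = 0; k < K; ++k) {
    const int n = (int)tiles(k, 0);
    const int m = (int)tiles(k, 1);
    const double sigma = tiles(k, 2);
    const double A = tiles(k, 3);
    double sbc = 0.0, sts = 0.0, stl = 0.0;
    long used = 0, degen = 0;
    for (int rep = 0; rep < replicates; ++rep) {
      const uint64_t seed =
          derive_seed((uint64_t)root_seed, (uint64_t)(k + 1),
                      (uint64_t)(rep + 1));
      paired_kernel(n, m, sigma, A, seed, x0, t_end, rtol, atol, max_steps,
                    conv_tol, floor_, pairing_mode, out);
      if (out[3] > 0.5) {
        ++degen;
      } else {
        sbc += out[0];
        sts += out[1];
        stl += out[2];
        ++used;
      }
      if ((rep & 255) == 0) Rcpp::checkUserInterrupt();
    }
    res(k, 0) = used > 0 ? sbc / used : NA_REAL;
    res(k, 1) = used > 0 ? sts / used : NA_REAL;
    res(k, 2) = used > 0 ? stl / used : NA_REAL;
    res(k, 3) = (double)used;
    res(k, 4) = (double)degen;
  }
  return res;
}
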