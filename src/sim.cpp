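// Overdamped Langevin (Brownian) kernel and analytic landscape evaluation.
// Units: A, kcal/mol, ps. RNG is mt19937_64 + explicit Box-Muller so that
// trajectories are bit-reproducible for a given seed.
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

struct Landscape {
  std::vector<double> ac, ad, aw;          // axial Gaussian center/depth/width
  double lateral_k;                        // harmonic confinement toward axis
  double pairA, pairL;                     // screened repulsion A exp(-r/l)/r
  std::vector<double> cc, cd, cw, ct;      // coordination center/depth/width/same-z tol
};

static Landscape parse_landscape(const List& p) {
  Landscape L;
  L.ac = as<std::vector<double>>(p["axial_center"]);
  L.ad = as<std::vector<double>>(p["axial_depth"]);
  L.aw = as<std::vector<double>>(p["axial_width"]);
  L.lateral_k = as<double>(p["lateral_k"]);
  L.pairA = as<double>(p["pair_amplitude"]);
  L.pairL = as<double>(p["pair_screening"]);
  L.cc = as<std::vector<double>>(p["coord_center"]);
  L.cd = as<std::vector<double>>(p["coord_depth"]);
  L.cw = as<std::vector<double>>(p["coord_width"]);
  L.ct = as<std::vector<double>>(p["coord_tol"]);
  return L;
}

// energy + gradient accumulation; comp[4] = axial, lateral, pair, coordination
static double eval_landscape(const Landscape& L, const double* x, const double* y,
                             const double* z, int n, double* fx, double* fy,
                             double* fz, double* comp) {
  for (int i = 0; i < n; ++i) { fx[i] = fy[i] = fz[i] = 0.0; }
  for (int k = 0; k < 4; ++k) comp[k] = 0.0;
  // axial wells/barriers
  for (int i = 0; i < n; ++i) {
    for (size_t j = 0; j < L.ac.size(); ++j) {
      double dzj = z[i] - L.ac[j];
      double w2 = L.aw[j] * L.aw[j];
      double e = L.ad[j] * std::exp(-dzj * dzj / (2.0 * w2));
      comp[0] += e;
      fz[i] += e * dzj / w2;           // -dE/dz
    }
    double el = 0.5 * L.lateral_k * (x[i] * x[i] + y[i] * y[i]);
    comp[1] += el;
    fx[i] -= L.lateral_k * x[i];
    fy[i] -= L.lateral_k * y[i];
  }
  // pairwise screened repulsion, soft-core clamp below r = 1 A
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (L.pairA > 0.0) {
        if (r <= 1.0) {
          comp[2] += L.pairA * std::exp(-1.0 / L.pairL);
        } else {
          double e = L.pairA * std::exp(-r / L.pairL) / r;
          comp[2] += e;
          double dEdr = -e * (1.0 / L.pairL + 1.0 / r);
          double s = -dEdr / r;        // force magnitude / r
          fx[i] += s * dx; fy[i] += s * dy; fz[i] += s * dz;
          fx[j] -= s * dx; fy[j] -= s * dy; fz[j] -= s * dz;
        }
      }
      // coordination terms: act on the pair's mean z and z-separation
      for (size_t m = 0; m < L.cc.size(); ++m) {
        double zbar = 0.5 * (z[i] + z[j]);
        double dzz = z[i] - z[j];
        double w2 = L.cw[m] * L.cw[m], t2 = L.ct[m] * L.ct[m];
        double u = zbar - L.cc[m];
        double e = L.cd[m] * std::exp(-u * u / (2.0 * w2)) *
                   std::exp(-dzz * dzz / (2.0 * t2));
        comp[3] += e;
        double dEdzi = e * (-0.5 * u / w2 - dzz / t2);
        double dEdzj = e * (-0.5 * u / w2 + dzz / t2);
        fz[i] -= dEdzi;
        fz[j] -= dEdzj;
      }
    }
  }
  return comp[0] + comp[1] + comp[2] + comp[3];
}

// [[Rcpp::export(name = ".landscape_eval_cpp")]]
List landscape_eval_cpp(NumericMatrix pos, List params) {
  int n = pos.nrow();
  Landscape L = parse_landscape(params);
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  double comp[4];
  double e = eval_landscape(L, x.data(), y.data(), z.data(), n,
                            fx.data(), fy.data(), fz.data(), comp);
  NumericMatrix f(n, 3);
  for (int i = 0; i < n; ++i) { f(i, 0) = fx[i]; f(i, 1) = fy[i]; f(i, 2) = fz[i]; }
  return List::create(_["energy"] = e,
                      _["force"] = f,
                      _["components"] = NumericVector::create(
                          _["axial"] = comp[0], _["lateral"] = comp[1],
                          _["pair"] = comp[2], _["coordination"] = comp[3]));
}

struct Gauss {
  std::mt19937_64 rng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Gauss(uint64_t seed) : rng(seed) {}
  double next() {
    if (has_spare) { has_spare = false; return spare; }
    // Box-Muller on (0,1] uniforms; explicit so results are portable
    double u1 = 0.0, u2 = 0.0;
    do { u1 = (rng() >> 11) * (1.0 / 9007199254740992.0); } while (u1 <= 0.0);
    u2 = (rng() >> 11) * (1.0 / 9007199254740992.0);
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericMatrix pos0, List params, NumericVector D, double dt,
                  int nsteps, int stride, double kbt, bool noise, double seed,
                  NumericMatrix bias_k, NumericMatrix bias_center,
                  double z_min, double z_max) {
  int n = pos0.nrow();
  Landscape L = parse_landscape(params);
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2); }
  double comp[4];
  Gauss g(static_cast<uint64_t>(seed));
  int nrec = (stride > 0) ? nsteps / stride : 0;
  NumericVector rec(static_cast<R_xlen_t>(nrec) * n * 3);
  int irec = 0;
  for (int s = 1; s <= nsteps; ++s) {
    eval_landscape(L, x.data(), y.data(), z.data(), n,
                   fx.data(), fy.data(), fz.data(), comp);
    for (int i = 0; i < n; ++i) {
      double Fx = fx[i] - bias_k(i, 0) * (x[i] - bias_center(i, 0));
      double Fy = fy[i] - bias_k(i, 1) * (y[i] - bias_center(i, 1));
      double Fz = fz[i] - bias_k(i, 2) * (z[i] - bias_center(i, 2));
      if (!std::isfinite(Fx) || !std::isfinite(Fy) || !std::isfinite(Fz))
        stop("non-finite force on ion %d at step %d", i + 1, s);
      double mob = D[i] * dt / kbt;
      double sig = noise ? std::sqrt(2.0 * D[i] * dt) : 0.0;
      x[i] += mob * Fx + (noise ? sig * g.next() : 0.0);
      y[i] += mob * Fy + (noise ? sig * g.next() : 0.0);
      z[i] += mob * Fz + (noise ? sig * g.next() : 0.0);
      // reflecting walls on z (used for bounded equilibrium sampling)
      while (z[i] < z_min || z[i] > z_max) {
        if (z[i] < z_min) z[i] = 2.0 * z_min - z[i];
        if (z[i] > z_max) z[i] = 2.0 * z_max - z[i];
      }
    }
    if (stride > 0 && s % stride == 0 && irec < nrec) {
      for (int i = 0; i < n; ++i) {
        rec[irec + nrec * (0L + 3L * i)] = x[i];
        rec[irec + nrec * (1L + 3L * i)] = y[i];
        rec[irec + nrec * (2L + 3L * i)] = z[i];
      }
      ++irec;
    }
  }
  rec.attr("dim") = IntegerVector::create(nrec, 3, n);
  NumericMatrix fin(n, 3);
  for (int i = 0; i < n; ++i) { fin(i, 0) = x[i]; fin(i, 1) = y[i]; fin(i, 2) = z[i]; }
  return List::create(_["frames"] = rec, _["final"] = fin);
}
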