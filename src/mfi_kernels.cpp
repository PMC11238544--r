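#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Analytical potentials / biases
//
// A potential is described by a small tagged list coming from R; the same
// descriptors are used for the physical potential and for every static bias,
// so the total force on the Langevin particle is -grad of their sum.
// ---------------------------------------------------------------------------

struct PotSpec {
  int type; // 0 poly1d, 1 poly2d, 2 multiwell1d, 3 harmonic, 4 wall
  std::vector<double> coef;       // poly1d: c0..cn
  std::vector<double> pi, pj, pc; // poly2d triplets (pow s1, pow s2, coef)
  std::vector<double> A, c, w;    // multiwell1d gaussian depths/centers/widths
  double conf_k = 0, conf_c = 0;  // multiwell1d confining term k*((s-c)/s0)^p
  double conf_s = 1; int conf_p = 0;
  std::vector<double> center, kappa; // harmonic
  int axis = 0; double at = 0, kap = 0; int side = 1, expo = 2; // wall
};

static PotSpec parse_pot(const List& sp) {
  PotSpec p;
  std::string t = as<std::string>(sp["type"]);
  if (t == "poly1d") {
    p.type = 0; p.coef = as<std::vector<double>>(sp["coef"]);
  } else if (t == "poly2d") {
    p.type = 1;
    NumericMatrix m = sp["coef"];
    for (int k = 0; k < m.nrow(); ++k) {
      p.pi.push_back(m(k, 0)); p.pj.push_back(m(k, 1)); p.pc.push_back(m(k, 2));
    }
  } else if (t == "multiwell1d") {
    p.type = 2;
    p.A = as<std::vector<double>>(sp["depth"]);
    p.c = as<std::vector<double>>(sp["center"]);
    p.w = as<std::vector<double>>(sp["width"]);
    p.conf_k = as<double>(sp["conf_k"]); p.conf_c = as<double>(sp["conf_c"]);
    p.conf_s = as<double>(sp["conf_s"]); p.conf_p = as<int>(sp["conf_p"]);
  } else if (t == "harmonic") {
    p.type = 3;
    p.center = as<std::vector<double>>(sp["center"]);
    p.kappa = as<std::vector<double>>(sp["kappa"]);
  } else if (t == "wall") {
    p.type = 4;
    p.axis = as<int>(sp["axis"]) - 1; // R is 1-based
    p.at = as<double>(sp["at"]); p.kap = as<double>(sp["kappa"]);
    p.side = (as<std::string>(sp["side"]) == "upper") ? 1 : -1;
    p.expo = as<int>(sp["exponent"]);
  } else {
    stop("unknown potential type '%s'", t.c_str());
  }
  return p;
}

// value; grad accumulated into g[0..d-1]
static double pot_eval(const PotSpec& p, const double* s, int d, double* g) {
  switch (p.type) {
  case 0: { // poly1d, Horner
    double v = 0, dv = 0;
    for (int k = (int)p.coef.size() - 1; k >= 0; --k) {
      dv = dv * s[0] + v;
      v = v * s[0] + p.coef[k];
    }
    g[0] += dv;
    return v;
  }
  case 1: {
    double v = 0;
    for (size_t k = 0; k < p.pc.size(); ++k) {
      double a = p.pi[k], b = p.pj[k], c = p.pc[k];
      double x1a = std::pow(s[0], a), x2b = std::pow(s[1], b);
      v += c * x1a * x2b;
      if (a > 0) g[0] += c * a * std::pow(s[0], a - 1) * x2b;
      if (b > 0) g[1] += c * b * x1a * std::pow(s[1], b - 1);
    }
    return v;
  }
  case 2: {
    double v = 0;
    for (size_t k = 0; k < p.A.size(); ++k) {
      double dx = s[0] - p.c[k];
      double e = std::exp(-dx * dx / (2.0 * p.w[k] * p.w[k]));
      v += -p.A[k] * e;
      g[0] += p.A[k] * (dx / (p.w[k] * p.w[k])) * e;
    }
    if (p.conf_p > 0) {
      double u = (s[0] - p.conf_c) / p.conf_s;
      v += p.conf_k * std::pow(u, p.conf_p);
      g[0] += p.conf_k * p.conf_p * std::pow(u, p.conf_p - 1) / p.conf_s;
    }
    return v;
  }
  case 3: {
    double v = 0;
    for (int a = 0; a < d; ++a) {
      double dx = s[a] - p.center[a];
      v += 0.5 * p.kappa[a] * dx * dx;
      g[a] += p.kappa[a] * dx;
    }
    return v;
  }
  case 4: {
    double dx = s[p.axis] - p.at;
    if ((p.side > 0 && dx > 0) || (p.side < 0 && dx < 0)) {
      double v = p.kap * std::pow(std::abs(dx), p.expo);
      g[p.axis] += (dx > 0 ? 1 : -1) * p.kap * p.expo *
                   std::pow(std::abs(dx), p.expo - 1);
      return v;
    }
    return 0.0;
  }
  }
  return 0.0;
}

// [[Rcpp::export]]
List cpp_pot_eval(List spec, NumericMatrix pts) {
  PotSpec p = parse_pot(spec);
  int n = pts.nrow(), d = pts.ncol();
  NumericVector val(n);
  NumericMatrix grad(n, d);
  std::vector<double> s(d), g(d);
  for (int k = 0; k < n; ++k) {
    for (int a = 0; a < d; ++a) { s[a] = pts(k, a); g[a] = 0; }
    val[k] = pot_eval(p, s.data(), d, g.data());
    for (int a = 0; a < d; ++a) grad(k, a) = g[a];
  }
  return List::create(_["value"] = val, _["gradient"] = grad);
}

// minimum-image displacement on one axis
static inline double wrapd(double dx, bool per, double L) {
  if (per) dx -= L * std::nearbyint(dx / L);
  return dx;
}

// ---------------------------------------------------------------------------
// Underdamped (BAOAB) / overdamped (Euler-Maruyama) Langevin with optional
// on-the-fly metadynamics.  One RNG per run; one normal draw per axis per
// step in fixed order, so the stored-sample stride never changes the path.
// ---------------------------------------------------------------------------

struct RunRng {
  std::mt19937_64 eng;
  explicit RunRng(uint64_t seed) : eng(seed) {}
  double unif() {
    // 53-bit uniform in (0,1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() { // Box-Muller, cosine branch only: fixed draw count
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// [[Rcpp::export]]
List cpp_langevin(List potentials, Nullable<List> metad, double kT,
                  double friction, double mass, double dt, int nsteps,
                  NumericVector x0, double seed, int stride,
                  NumericVector lower, NumericVector upper,
                  LogicalVector periodic, NumericVector margin,
                  std::string scheme) {
  int d = x0.size();
  std::vector<PotSpec> pots;
  for (int i = 0; i < potentials.size(); ++i)
    pots.push_back(parse_pot(potentials[i]));

  bool do_metad = metad.isNotNull();
  double w0 = 0, biasf = NA_REAL, mkT = kT;
  int pace = 0;
  std::vector<double> sigM(d);
  if (do_metad) {
    List m(metad);
    w0 = as<double>(m["w0"]);
    pace = as<int>(m["pace"]);
    NumericVector sm = m["sigma"];
    for (int a = 0; a < d; ++a) sigM[a] = sm[a];
    if (m.containsElementNamed("bias_factor") && !Rf_isNull(m["bias_factor"]))
      biasf = as<double>(m["bias_factor"]);
    if (m.containsElementNamed("kT")) mkT = as<double>(m["kT"]);
  }

  std::vector<double> hc, ht, hh; // hill centers (d-interleaved), times, heights
  std::vector<double> L(d);
  for (int a = 0; a < d; ++a) L[a] = upper[a] - lower[a];

  std::vector<double> x(d), v(d, 0.0), g(d), f(d);
  for (int a = 0; a < d; ++a) x[a] = x0[a];

  RunRng rng((uint64_t)seed);
  bool baoab = (scheme == "baoab");
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(kT / mass * (1.0 - c1 * c1));

  // metadynamics bias value/gradient at point (sum over deposited hills)
  auto metad_bias = [&](const double* s, double* gb) -> double {
    double V = 0;
    for (int a = 0; a < d; ++a) gb[a] = 0;
    size_t m = hh.size();
    for (size_t j = 0; j < m; ++j) {
      double e = 0;
      double dxs[2];
      for (int a = 0; a < d; ++a) {
        double dx = wrapd(s[a] - hc[j * d + a], periodic[a], L[a]);
        dxs[a] = dx;
        e += dx * dx / (2.0 * sigM[a] * sigM[a]);
      }
      double k = hh[j] * std::exp(-e);
      V += k;
      for (int a = 0; a < d; ++a) gb[a] += -dxs[a] / (sigM[a] * sigM[a]) * k;
    }
    return V;
  };

  std::vector<double> gb(d);
  auto total_force = [&](const double* s, double* out) {
    for (int a = 0; a < d; ++a) g[a] = 0;
    for (auto& p : pots) pot_eval(p, s, d, g.data());
    if (do_metad && !hh.empty()) {
      metad_bias(s, gb.data());
      for (int a = 0; a < d; ++a) g[a] += gb[a];
    }
    for (int a = 0; a < d; ++a) out[a] = -g[a];
  };

  int nsamp = nsteps / stride + 1;
  NumericVector times(nsamp);
  NumericMatrix samples(nsamp, d);
  int ks = 0;
  times[ks] = 0.0;
  for (int a = 0; a < d; ++a) samples(ks, a) = x[a];
  ++ks;

  total_force(x.data(), f.data());
  for (int step = 1; step <= nsteps; ++step) {
    if (baoab) {
      for (int a = 0; a < d; ++a) v[a] += 0.5 * dt * f[a] / mass;
      for (int a = 0; a < d; ++a) x[a] += 0.5 * dt * v[a];
      for (int a = 0; a < d; ++a) v[a] = c1 * v[a] + c2 * rng.norm();
      for (int a = 0; a < d; ++a) x[a] += 0.5 * dt * v[a];
    } else { // overdamped Euler-Maruyama
      total_force(x.data(), f.data());
      double mob = 1.0 / (friction * mass);
      double amp = std::sqrt(2.0 * kT * mob * dt);
      for (int a = 0; a < d; ++a) x[a] += mob * dt * f[a] + amp * rng.norm();
    }
    for (int a = 0; a < d; ++a) {
      if (periodic[a]) {
        double u = (x[a] - lower[a]) / L[a];
        x[a] = lower[a] + (u - std::floor(u)) * L[a];
      } else if (x[a] < lower[a] - margin[a] || x[a] > upper[a] + margin[a]) {
        stop("trajectory escaped the declared CV domain on axis %d at step %d "
             "(s = %.4f): add walls or widen the domain", a + 1, step, x[a]);
      }
    }
    if (do_metad && step % pace == 0) {
      double h = w0;
      if (R_finite(biasf)) {
        double Vc = hh.empty() ? 0.0 : metad_bias(x.data(), gb.data());
        h = w0 * std::exp(-Vc / ((biasf - 1.0) * mkT));
      }
      ht.push_back(step * dt);
      hh.push_back(h);
      for (int a = 0; a < d; ++a) hc.push_back(x[a]);
    }
    if (step % stride == 0) {
      times[ks] = step * dt;
      for (int a = 0; a < d; ++a) samples(ks, a) = x[a];
      ++ks;
    }
    if (baoab) { // second half-kick with the force at the new position
      total_force(x.data(), f.data());
      for (int a = 0; a < d; ++a) v[a] += 0.5 * dt * f[a] / mass;
    }
  }

  int m = hh.size();
  NumericMatrix hcent(m, d);
  NumericVector htim(m), hhei(m);
  for (int j = 0; j < m; ++j) {
    htim[j] = ht[j]; hhei[j] = hh[j];
    for (int a = 0; a < d; ++a) hcent(j, a) = hc[j * d + a];
  }
  return List::create(_["times"] = times, _["samples"] = samples,
                      _["hill_times"] = htim, _["hill_centers"] = hcent,
                      _["hill_heights"] = hhei);
}

// ---------------------------------------------------------------------------
// Separable Gaussian kernel sums on a rectilinear grid.
//
// For kernel sums both the KDE of window samples (density / force numerator)
// and the metadynamics bias (value / gradient) have the same separable
// structure, so the exp() work is O(n * (nx + ny)) and the grid fill is a
// fused multiply-accumulate.
// ---------------------------------------------------------------------------

// KDE kernel sums: returns unscaled kernel sum and per-axis force numerators
// num_a = sum_k (wrap(s - s_k)_a / h_a^2) * K_k
// [[Rcpp::export]]
List cpp_kde(NumericMatrix samples, NumericVector xax, NumericVector yax,
             NumericVector h, LogicalVector periodic, NumericVector period) {
  int n = samples.nrow(), d = samples.ncol();
  int nx = xax.size(), ny = (d == 2) ? yax.size() : 1;
  NumericVector ksum(nx * ny), num1(nx * ny), num2(d == 2 ? nx * ny : 0);
  std::vector<double> ax(nx), bx(nx), ay(ny), by(ny);
  double h1 = h[0], h2 = (d == 2) ? h[1] : 1.0;
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < nx; ++i) {
      double dx = wrapd(xax[i] - samples(k, 0), periodic[0], period[0]);
      ax[i] = std::exp(-dx * dx / (2.0 * h1 * h1));
      bx[i] = dx / (h1 * h1) * ax[i];
    }
    if (d == 1) {
      for (int i = 0; i < nx; ++i) { ksum[i] += ax[i]; num1[i] += bx[i]; }
    } else {
      for (int j = 0; j < ny; ++j) {
        double dy = wrapd(yax[j] - samples(k, 1), periodic[1], period[1]);
        ay[j] = std::exp(-dy * dy / (2.0 * h2 * h2));
        by[j] = dy / (h2 * h2) * ay[j];
      }
      for (int j = 0; j < ny; ++j) {
        double a2 = ay[j], b2 = by[j];
        double* ks = &ksum[(size_t)j * nx];
        double* n1 = &num1[(size_t)j * nx];
        double* n2 = &num2[(size_t)j * nx];
        for (int i = 0; i < nx; ++i) {
          ks[i] += ax[i] * a2;
          n1[i] += bx[i] * a2;
          n2[i] += ax[i] * b2;
        }
      }
    }
  }
  return List::create(_["ksum"] = ksum, _["num1"] = num1, _["num2"] = num2);
}

// Metadynamics bias and true gradient dV/ds on the grid.
// [[Rcpp::export]]
List cpp_hills_grid(NumericMatrix centers, NumericMatrix sigmas,
                    NumericVector heights, NumericVector xax,
                    NumericVector yax, LogicalVector periodic,
                    NumericVector period) {
  int m = centers.nrow(), d = centers.ncol();
  int nx = xax.size(), ny = (d == 2) ? yax.size() : 1;
  NumericVector V(nx * ny), G1(nx * ny), G2(d == 2 ? nx * ny : 0);
  std::vector<double> ax(nx), bx(nx), ay(ny), by(ny);
  for (int k = 0; k < m; ++k) {
    double w = heights[k], s1 = sigmas(k, 0);
    double s2 = (d == 2) ? sigmas(k, 1) : 1.0;
    for (int i = 0; i < nx; ++i) {
      double dx = wrapd(xax[i] - centers(k, 0), periodic[0], period[0]);
      ax[i] = std::exp(-dx * dx / (2.0 * s1 * s1));
      bx[i] = -dx / (s1 * s1) * ax[i]; // d/ds of the x factor
    }
    if (d == 1) {
      for (int i = 0; i < nx; ++i) { V[i] += w * ax[i]; G1[i] += w * bx[i]; }
    } else {
      for (int j = 0; j < ny; ++j) {
        double dy = wrapd(yax[j] - centers(k, 1), periodic[1], period[1]);
        ay[j] = std::exp(-dy * dy / (2.0 * s2 * s2));
        by[j] = -dy / (s2 * s2) * ay[j];
      }
      for (int j = 0; j < ny; ++j) {
        double a2 = ay[j], b2 = by[j];
        double* vv = &V[(size_t)j * nx];
        double* g1 = &G1[(size_t)j * nx];
        double* g2 = &G2[(size_t)j * nx];
        for (int i = 0; i < nx; ++i) {
          vv[i] += w * ax[i] * a2;
          g1[i] += w * bx[i] * a2;
          g2[i] += w * ax[i] * b2;
        }
      }
    }
  }
  return List::create(_["V"] = V, _["G1"] = G1, _["G2"] = G2);
}

// nearest-node histogram of samples (counts per node)
// [[Rcpp::export]]
NumericVector cpp_histogram(NumericMatrix samples, NumericVector xax,
                            NumericVector yax, LogicalVector periodic,
                            NumericVector period) {
  int n = samples.nrow(), d = samples.ncol();
  int nx = xax.size(), ny = (d == 2) ? yax.size() : 1;
  double dx = (nx > 1) ? xax[1] - xax[0] : 1.0;
  double dy = (ny > 1) ? yax[1] - yax[0] : 1.0;
  NumericVector H(nx * ny);
  for (int k = 0; k < n; ++k) {
    int i = (int)std::lround((samples(k, 0) - xax[0]) / dx);
    if (periodic[0]) i = ((i % nx) + nx) % nx;
    else i = std::min(std::max(i, 0), nx - 1);
    int j = 0;
    if (d == 2) {
      j = (int)std::lround((samples(k, 1) - yax[0]) / dy);
      if (periodic[1]) j = ((j % ny) + ny) % ny;
      else j = std::min(std::max(j, 0), ny - 1);
    }
    H[(size_t)j * nx + i] += 1.0;
  }
  return H;
}
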