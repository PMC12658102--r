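// Finite-volume (Claverie-style) solver for the Lamm equation
//
//   dc/dt = (1/r) d/dr [ r D dc/dr - s w^2 r^2 c ]
//
// on a uniform radial grid with no-flux walls at the meniscus and the
// cell bottom.  Face fluxes use exponential (Scharfetter-Gummel) fitting,
// which reduces to central differencing at low Peclet number and to pure
// upwinding as D -> 0, and conserves sector mass (integral of c r dr)
// to round-off.  Time stepping is a theta scheme (theta = 0.5 gives
// Crank-Nicolson) with a tridiagonal solve per species and step.
//
// Reacting systems are handled in the rapid-equilibrium limit by operator
// splitting: after each transport step every cell is projected back onto
// the mass-action manifold, conserving local monomer equivalents.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bernoulli function x / (exp(x) - 1), numerically stable.
static inline double bern(double x) {
  if (std::fabs(x) < 1e-10) return 1.0 - 0.5 * x;
  if (x > 700.0) return 0.0;
  if (x < -700.0) return -x;
  return x / std::expm1(x);
}

// Free-monomer concentration m solving sum_k n_k m^{n_k} / K_k = tot.
// Monotone in m; safeguarded Newton with bisection fallback.
static double free_monomer(double tot, const std::vector<double>& n,
                           const std::vector<double>& K, double guess) {
  if (tot <= 0.0) return 0.0;
  double lo = 0.0, hi = tot;
  double m = (guess > 0.0 && guess < tot) ? guess : 0.5 * tot;
  for (int it = 0; it < 100; ++it) {
    double f = -tot, fp = 0.0;
    for (size_t k = 0; k < n.size(); ++k) {
      double p = std::pow(m, n[k]);
      f += n[k] * p / K[k];
      fp += (m > 0.0) ? n[k] * n[k] * p / (K[k] * m) : ((n[k] == 1.0) ? 1.0 / K[k] : 0.0);
    }
    if (std::fabs(f) <= 1e-12 * tot) break;
    if (f > 0.0) hi = m; else lo = m;
    double mn = (fp > 0.0) ? m - f / fp : 0.5 * (lo + hi);
    if (!(mn > lo && mn < hi)) mn = 0.5 * (lo + hi);
    if (std::fabs(mn - m) <= 1e-14 * (m + 1e-300)) { m = mn; break; }
    m = mn;
  }
  return m;
}

// Thomas algorithm for tridiagonal systems (in-place on scratch copies).
static void thomas(const std::vector<double>& a, std::vector<double>& b,
                   const std::vector<double>& c, std::vector<double>& d,
                   std::vector<double>& x) {
  const int n = (int)b.size();
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  x[n - 1] = d[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    x[i] = (d[i] - c[i] * x[i + 1]) / b[i];
}

// [[Rcpp::export(name = ".lamm_solve_cpp")]]
List lamm_solve_cpp(double rm, double rb, int ncells, double omega2,
                    NumericVector s_sec, NumericVector D_cm2s,
                    NumericVector c0, NumericVector times,
                    NumericVector n_units, NumericVector K_overall,
                    bool react, double cfl, double theta) {
  const int nspec = s_sec.size();
  const int nt = times.size();
  const double h = (rb - rm) / ncells;

  std::vector<double> rc(ncells);           // cell centers
  for (int i = 0; i < ncells; ++i) rc[i] = rm + (i + 0.5) * h;

  // constant-in-time operator A per species: dc_i/dt = lo c_{i-1} + di c_i + up c_{i+1}
  std::vector<std::vector<double> > lo(nspec), di(nspec), up(nspec);
  double vmax = 0.0;
  for (int k = 0; k < nspec; ++k) {
    lo[k].assign(ncells, 0.0); di[k].assign(ncells, 0.0); up[k].assign(ncells, 0.0);
    const double s = s_sec[k], D = D_cm2s[k];
    for (int f = 1; f < ncells; ++f) {      // interior faces
      const double rf = rm + f * h;
      const double v = s * omega2 * rf;       // sedimentation velocity at face
      if (v > vmax) vmax = v;
      double fl, fr;                        // F = fl*c_left - fr*c_right  (flux, >0 toward bottom)
      if (D > 0.0) {
        const double pe = v * h / D;
        fl = rf * (D / h) * bern(-pe);
        fr = rf * (D / h) * bern(pe);
      } else {
        fl = rf * v; fr = 0.0;              // pure upwind in the D = 0 limit
      }
      // cell f-1: dc/dt -= F/(r h);  cell f: dc/dt += F/(r h)
      di[k][f - 1] -= fl / (rc[f - 1] * h);
      up[k][f - 1] += fr / (rc[f - 1] * h);
      lo[k][f]     += fl / (rc[f] * h);
      di[k][f]     -= fr / (rc[f] * h);
    }
  }

  // concentrations, flattened [cell, species]
  std::vector<std::vector<double> > c(nspec);
  for (int k = 0; k < nspec; ++k) c[k].assign(ncells, c0[k]);

  std::vector<double> n_vec(n_units.begin(), n_units.end());
  std::vector<double> K_vec(K_overall.begin(), K_overall.end());
  std::vector<double> mprev(ncells, -1.0);  // warm starts for the local root solves

  const double t_end = times[nt - 1];
  double dt_base = (vmax > 0.0) ? cfl * h / vmax : t_end / 200.0;
  if (dt_base > t_end / 50.0) dt_base = t_end / 50.0;
  if (dt_base <= 0.0) stop("non-positive time step");

  NumericVector out(ncells * nt * nspec);
  out.attr("dim") = IntegerVector::create(ncells, nt, nspec);
  NumericVector mass_trace(nt + 1);
  double mass0 = 0.0;
  for (int k = 0; k < nspec; ++k)
    for (int i = 0; i < ncells; ++i) mass0 += n_vec[k] * c[k][i] * rc[i] * h;
  mass_trace[0] = mass0;

  std::vector<double> a(ncells), b(ncells), cc(ncells), d(ncells), x(ncells);
  double worst_neg = 0.0;
  double t = 0.0;
  for (int it = 0; it < nt; ++it) {
    const double t_target = times[it];
    while (t < t_target - 1e-9) {
      double dt = dt_base;
      if (t + dt > t_target) dt = t_target - t;
      for (int k = 0; k < nspec; ++k) {
        // rhs = (I + (1-theta) dt A) c ; solve (I - theta dt A) x = rhs
        const double ex = (1.0 - theta) * dt, im = theta * dt;
        for (int i = 0; i < ncells; ++i) {
          double r = c[k][i] * (1.0 + ex * di[k][i]);
          if (i > 0) r += ex * lo[k][i] * c[k][i - 1];
          if (i < ncells - 1) r += ex * up[k][i] * c[k][i + 1];
          d[i] = r;
          a[i] = -im * lo[k][i];
          b[i] = 1.0 - im * di[k][i];
          cc[i] = -im * up[k][i];
        }
        thomas(a, b, cc, d, x);
        for (int i = 0; i < ncells; ++i) {
          if (x[i] < 0.0) { if (x[i] < worst_neg) worst_neg = x[i]; x[i] = 0.0; }
          c[k][i] = x[i];
        }
      }
      if (react && nspec > 1) {
        for (int i = 0; i < ncells; ++i) {
          double tot = 0.0;
          for (int k = 0; k < nspec; ++k) tot += n_vec[k] * c[k][i];
          const double m = free_monomer(tot, n_vec, K_vec, mprev[i]);
          mprev[i] = m;
          for (int k = 0; k < nspec; ++k) c[k][i] = std::pow(m, n_vec[k]) / K_vec[k];
        }
      }
      t += dt;
    }
    double mass = 0.0;
    for (int k = 0; k < nspec; ++k) {
      for (int i = 0; i < ncells; ++i) {
        out[i + ncells * (it + nt * k)] = c[k][i];
        mass += n_vec[k] * c[k][i] * rc[i] * h;
      }
    }
    mass_trace[it + 1] = mass;
  }

  double scale = 0.0;
  for (int k = 0; k < nspec; ++k) if (c0[k] > scale) scale = c0[k];
  if (scale > 0.0 && -worst_neg > 1e-4 * scale)
    stop("Lamm solver produced negative concentrations beyond tolerance (min %g)", worst_neg);

  return List::create(_["r"] = NumericVector(rc.begin(), rc.end()),
                      _["conc"] = out,
                      _["mass_trace"] = mass_trace,
                      _["dt"] = dt_base);
}

// [[Rcpp::export(name = ".free_monomer_cpp")]]
double free_monomer_cpp(double tot, NumericVector n, NumericVector K) {
  std::vector<double> nv(n.begin(), n.end()), Kv(K.begin(), K.end());
  return free_monomer(tot, nv, Kv, -1.0);
}
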