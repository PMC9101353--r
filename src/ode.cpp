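#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scalar root machinery for the implicit rate equations.
//
// Bundle model: the dashpot/motor branch obeys
//   gamma * x + lambda0 * exp(-x^2/V^2) = rhs
// where x is the elongation rate of the secondary branch. The left-hand
// side is monotone in x iff gamma >= sqrt(2) e^{-1/2} lambda0 / V; below
// that the motor force-velocity curve can admit multiple rate roots and we
// continue from the previous rate.

namespace {

struct RateEq {
  double gamma, lambda0, V, rhs;
  double g(double x) const {
    double u = x / V;
    return gamma * x + lambda0 * std::exp(-u * u) - rhs;
  }
  double dg(double x) const {
    double u = x / V;
    return gamma - lambda0 * (2.0 * x / (V * V)) * std::exp(-u * u);
  }
};

// bisection refine on a sign-change bracket
double bisect(const RateEq& eq, double lo, double hi, double tol) {
  double flo = eq.g(lo);
  for (int i = 0; i < 200; ++i) {
    double mid = 0.5 * (lo + hi);
    double fm = eq.g(mid);
    if (std::abs(fm) < tol || (hi - lo) < 1e-15 * (1.0 + std::abs(mid))) return mid;
    if ((flo < 0) == (fm < 0)) { lo = mid; flo = fm; } else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// Solve the rate equation; warm-started safeguarded Newton with a
// bracket-scan fallback that also detects the multi-root regime.
double solve_rate(const RateEq& eq, double x0, bool* multi, bool* fail) {
  const double tol = 1e-11 * std::max(1.0, eq.lambda0);
  bool monotone = eq.gamma * eq.V >= std::sqrt(2.0) * std::exp(-0.5) * eq.lambda0;
  double span = 10.0 * eq.V * (1.0 + std::abs(eq.rhs) / eq.lambda0);
  // also cover the purely viscous solution scale
  double xv = (eq.rhs - eq.lambda0) / eq.gamma;
  double lo = std::min(-span, xv - span), hi = std::max(span, xv + span);

  if (monotone) {
    double x = x0;
    if (!std::isfinite(x)) x = xv;
    for (int i = 0; i < 60; ++i) {
      double fx = eq.g(x);
      if (std::abs(fx) < tol) return x;
      double d = eq.dg(x);
      if (d <= 0 || !std::isfinite(d)) break;
      double step = fx / d;
      x -= step;
      if (x < lo) x = lo;
      if (x > hi) x = hi;
    }
    // Newton failed to settle: fall through to bisection
    double flo = eq.g(lo), fhi = eq.g(hi);
    if ((flo < 0) != (fhi < 0)) return bisect(eq, lo, hi, tol);
    *fail = true;
    return x0;
  }

  // non-monotone regime: scan for all sign changes, pick root nearest x0
  const int n = 1600;
  double best = NA_REAL, bestd = R_PosInf;
  int nroots = 0;
  double xprev = lo, fprev = eq.g(lo);
  for (int i = 1; i <= n; ++i) {
    double x = lo + (hi - lo) * i / n;
    double fx = eq.g(x);
    if ((fprev < 0) != (fx < 0) || fx == 0.0) {
      double r = bisect(eq, xprev, x, tol);
      ++nroots;
      double d = std::abs(r - x0);
      if (d < bestd) { bestd = d; best = r; }
    }
    xprev = x; fprev = fx;
  }
  if (nroots == 0) { *fail = true; return x0; }
  if (nroots > 1) *multi = true;
  return best;
}

// Local segment dynamics, first-order implicit form:
//   chidot = f/Gamma - nu*chi - (1/(2 Gamma)) * (1 - exp(-chidot^2))
// Solve for y = chidot given chi.
struct ChiEq {
  double nu, f, Gamma, chi;
  double u() const { return f / Gamma - nu * chi; }
  double g(double y) const {
    return y + (1.0 - std::exp(-y * y)) / (2.0 * Gamma) - u();
  }
  double dg(double y) const {
    return 1.0 + (y / Gamma) * std::exp(-y * y);
  }
};

double chi_bisect(const ChiEq& eq, double lo, double hi, double tol) {
  double flo = eq.g(lo);
  for (int i = 0; i < 200; ++i) {
    double mid = 0.5 * (lo + hi);
    double fm = eq.g(mid);
    if (std::abs(fm) < tol || (hi - lo) < 1e-15 * (1.0 + std::abs(mid))) return mid;
    if ((flo < 0) == (fm < 0)) { lo = mid; flo = fm; } else hi = mid;
  }
  return 0.5 * (lo + hi);
}

double solve_chidot(const ChiEq& eq, double y0, bool* multi, bool* fail) {
  const double tol = 1e-13;
  // g is monotone iff Gamma > 1/sqrt(2e) (min of y e^{-y^2} is -1/sqrt(2e))
  bool monotone = eq.Gamma > 1.0 / std::sqrt(2.0 * std::exp(1.0));
  double span = 2.0 + std::abs(eq.u()) + 1.0 / eq.Gamma;
  double lo = -span, hi = span;
  if (monotone) {
    double y = std::isfinite(y0) ? y0 : eq.u();
    for (int i = 0; i < 60; ++i) {
      double fy = eq.g(y);
      if (std::abs(fy) < tol) return y;
      double d = eq.dg(y);
      if (d <= 0 || !std::isfinite(d)) break;
      y -= fy / d;
      if (y < lo) y = lo;
      if (y > hi) y = hi;
    }
    double flo = eq.g(lo), fhi = eq.g(hi);
    if ((flo < 0) != (fhi < 0)) return chi_bisect(eq, lo, hi, tol);
    *fail = true;
    return y0;
  }
  // nearest-root continuation: scan a narrow window around the previous
  // rate first (any root inside is nearer than any root outside), then
  // fall back to the full bracket
  if (std::isfinite(y0)) {
    double wlo = std::max(lo, y0 - 0.5), whi = std::min(hi, y0 + 0.5);
    const int nw = 80;
    double best = NA_REAL, bestd = R_PosInf;
    int nroots = 0;
    double xprev = wlo, fprev = eq.g(wlo);
    for (int i = 1; i <= nw; ++i) {
      double x = wlo + (whi - wlo) * i / nw;
      double fx = eq.g(x);
      if ((fprev < 0) != (fx < 0) || fx == 0.0) {
        double r = chi_bisect(eq, xprev, x, tol);
        ++nroots;
        double d = std::abs(r - y0);
        if (d < bestd) { bestd = d; best = r; }
      }
      xprev = x; fprev = fx;
    }
    // a window root at distance d is provably nearest when d does not
    // reach any unscanned part of the full bracket
    double safe = R_PosInf;
    if (wlo > lo) safe = std::min(safe, y0 - wlo);
    if (whi < hi) safe = std::min(safe, whi - y0);
    if (nroots > 0 && bestd <= safe) {
      if (nroots > 1) *multi = true;
      return best;
    }
  }
  const int n = 1200;
  double best = NA_REAL, bestd = R_PosInf;
  int nroots = 0;
  double xprev = lo, fprev = eq.g(lo);
  for (int i = 1; i <= n; ++i) {
    double x = lo + (hi - lo) * i / n;
    double fx = eq.g(x);
    if ((fprev < 0) != (fx < 0) || fx == 0.0) {
      double r = chi_bisect(eq, xprev, x, tol);
      ++nroots;
      double d = std::abs(r - y0);
      if (d < bestd) { bestd = d; best = r; }
    }
    xprev = x; fprev = fx;
  }
  if (nroots == 0) { *fail = true; return y0; }
  if (nroots > 1) *multi = true;
  return best;
}

} // namespace

// [[Rcpp::export(name = ".cpp_solve_rate")]]
List cpp_solve_rate(double rhs, double gamma, double lambda0, double V,
                    double prev_rate) {
  RateEq eq{gamma, lambda0, V, rhs};
  bool multi = false, fail = false;
  double r = solve_rate(eq, prev_rate, &multi, &fail);
  return List::create(_["rate"] = r, _["multi_root"] = multi,
                      _["failed"] = fail, _["residual"] = eq.g(r));
}

// Integrate the secondary-branch elongation delta2 along a (possibly
// non-uniform) fine time grid on which delta_l(t), K(t) and k(t) have been
// pre-evaluated. Heun (trapezoidal predictor-corrector) stepping with the
// implicit rate solved at every stage, warm-started from the previous rate.
// [[Rcpp::export(name = ".cpp_integrate_bundle")]]
List cpp_integrate_bundle(NumericVector t, NumericVector delta_l,
                          NumericVector Kt, NumericVector kt,
                          double gamma, double lambda0, double V,
                          double delta2_init, double prev_rate_init) {
  int m = t.size();
  NumericVector d2(m), rate(m);
  bool multi = false, fail = false;
  double d2cur = delta2_init, rprev = prev_rate_init;
  for (int i = 0; i < m; ++i) {
    double rhs = Kt[i] * (delta_l[i] - d2cur) + lambda0 - kt[i] * d2cur;
    RateEq eq{gamma, lambda0, V, rhs};
    double r1 = solve_rate(eq, rprev, &multi, &fail);
    d2[i] = d2cur; rate[i] = r1;
    if (fail) break;
    if (i + 1 < m) {
      double h = t[i + 1] - t[i];
      double pred = d2cur + h * r1;
      double rhs2 = Kt[i + 1] * (delta_l[i + 1] - pred) + lambda0 - kt[i + 1] * pred;
      RateEq eq2{gamma, lambda0, V, rhs2};
      double r2 = solve_rate(eq2, r1, &multi, &fail);
      if (fail) break;
      d2cur += 0.5 * h * (r1 + r2);
      rprev = r2;
    }
  }
  return List::create(_["delta2"] = d2, _["rate"] = rate,
                      _["multi_root"] = multi, _["failed"] = fail);
}

// Integrate the first-order implicit chi dynamics on a time grid with
// n_sub RK4 substeps per grid interval. chi carries units of time; chidot
// is dimensionless.
// [[Rcpp::export(name = ".cpp_integrate_chi")]]
List cpp_integrate_chi(NumericVector t, double nu, double f, double Gamma,
                       double chi0, double chidot_guess, int n_sub) {
  int m = t.size();
  NumericVector chi(m), chidot(m);
  bool multi = false, fail = false;
  double c = chi0, y = chidot_guess;
  auto G = [&](double cc, double yguess) {
    ChiEq eq{nu, f, Gamma, cc};
    return solve_chidot(eq, yguess, &multi, &fail);
  };
  for (int i = 0; i < m; ++i) {
    y = G(c, y);
    chi[i] = c; chidot[i] = y;
    if (fail) break;
    if (i + 1 < m) {
      double H = (t[i + 1] - t[i]) / n_sub;
      for (int s = 0; s < n_sub && !fail; ++s) {
        double k1 = G(c, y);
        double k2 = G(c + 0.5 * H * k1, k1);
        double k3 = G(c + 0.5 * H * k2, k2);
        double k4 = G(c + H * k3, k3);
        c += H * (k1 + 2 * k2 + 2 * k3 + k4) / 6.0;
        y = k4;
      }
    }
  }
  return List::create(_["chi"] = chi, _["chidot"] = chidot,
                      _["multi_root"] = multi, _["failed"] = fail);
}
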