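#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Wright-Fisher diffusion solver for expected (joint) site frequency
// spectra. Time is measured in units of 2*N_ref generations, population
// sizes as ratios nu = N/N_ref, migration as M = 2*N_ref*m. The density
// phi(x[,y]) is advanced by implicit Euler; in two dimensions the operator
// is split and each direction solved implicitly on its tridiagonal system
// (ADI). Drift is discretised in conservative form, migration advection is
// fully upwinded so the one-directional operators are M-matrices and the
// scheme preserves positivity. New mutations are injected each step at the
// first interior grid point of each axis.

namespace {

// Workspace for the one-directional implicit solves; allocated once per
// integration, reused across rows and time steps.
struct Ws {
  std::vector<double> lo, di, up, rhs, V, invh;
  void init(const std::vector<double>& xx) {
    int G = xx.size();
    lo.resize(G); di.resize(G); up.resize(G); rhs.resize(G);
    V.resize(G); invh.resize(G - 1);
    for (int j = 0; j < G; ++j) V[j] = xx[j] * (1.0 - xx[j]);
    for (int j = 0; j < G - 1; ++j) invh[j] = 1.0 / (xx[j + 1] - xx[j]);
  }
};

// Build the implicit system (I - dt*A) for one direction and solve in place.
// a_half[j] is the advection coefficient at midpoint j+1/2 (length G-1),
// nu the size ratio of this population.
inline void implicitStep1D(double* phi, const std::vector<double>& cwid,
                           double nu, const double* a_half, double dt,
                           int G, Ws& w) {
  double D = 1.0 / (2.0 * nu);
  for (int j = 0; j < G; ++j) {
    double Alo = 0.0, Adi = 0.0, Aup = 0.0;
    if (j > 0) {
      double am = a_half[j - 1], ih = w.invh[j - 1];
      Alo = (am > 0 ? am : 0.0) + D * w.V[j - 1] * ih;
      Adi = (am < 0 ? am : 0.0) - D * w.V[j] * ih;
    }
    if (j < G - 1) {
      double ap = a_half[j], ih = w.invh[j];
      Adi += -(ap > 0 ? ap : 0.0) - D * w.V[j] * ih;
      Aup = -(ap < 0 ? ap : 0.0) + D * w.V[j + 1] * ih;
    }
    double sc = dt / cwid[j];
    w.lo[j] = -sc * Alo;
    w.di[j] = 1.0 - sc * Adi;
    w.up[j] = -sc * Aup;
    w.rhs[j] = phi[j];
  }
  // Thomas solve
  for (int i = 1; i < G; ++i) {
    double f = w.lo[i] / w.di[i - 1];
    w.di[i] -= f * w.up[i - 1];
    w.rhs[i] -= f * w.rhs[i - 1];
  }
  w.rhs[G - 1] /= w.di[G - 1];
  for (int i = G - 2; i >= 0; --i)
    w.rhs[i] = (w.rhs[i] - w.up[i] * w.rhs[i + 1]) / w.di[i];
  for (int i = 0; i < G; ++i) phi[i] = w.rhs[i];
}

std::vector<double> cellWidths(const std::vector<double>& xx) {
  int G = xx.size();
  std::vector<double> c(G);
  c[0] = (xx[1] - xx[0]) / 2.0;
  c[G - 1] = (xx[G - 1] - xx[G - 2]) / 2.0;
  for (int j = 1; j < G - 1; ++j) c[j] = (xx[j + 1] - xx[j - 1]) / 2.0;
  return c;
}

} // namespace

// [[Rcpp::export(name = ".integrate_one_pop")]]
NumericVector integrate_one_pop(NumericVector phiIn, NumericVector xxIn,
                                double T, double nu0, double g,
                                double theta0, double dtTarget) {
  std::vector<double> phi(phiIn.begin(), phiIn.end());
  std::vector<double> xx(xxIn.begin(), xxIn.end());
  int G = xx.size();
  std::vector<double> cwid = cellWidths(xx);
  std::vector<double> a_half(G - 1, 0.0);
  Ws w; w.init(xx);
  if (T <= 0) return phiIn;
  int nsteps = (int)std::ceil(T / dtTarget);
  if (nsteps < 5) nsteps = 5;
  double dt = T / nsteps;
  for (int s = 0; s < nsteps; ++s) {
    double tau = (s + 1) * dt;
    double nu = nu0 * std::exp(g * tau);
    phi[1] += dt / xx[1] * theta0 / 2.0 * 2.0 / (xx[2] - xx[0]);
    implicitStep1D(phi.data(), cwid, nu, a_half.data(), dt, G, w);
  }
  return NumericVector(phi.begin(), phi.end());
}

// [[Rcpp::export(name = ".integrate_two_pop")]]
NumericMatrix integrate_two_pop(NumericMatrix phiIn, NumericVector xxIn,
                                double T, double nu10, double g1,
                                double nu20, double g2,
                                double m12, double m21,
                                double theta0, double dtTarget) {
  int G = xxIn.size();
  std::vector<double> xx(xxIn.begin(), xxIn.end());
  std::vector<double> cwid = cellWidths(xx);
  NumericMatrix phi = clone(phiIn);
  if (T <= 0) return phi;
  int nsteps = (int)std::ceil(T / dtTarget);
  if (nsteps < 5) nsteps = 5;
  if (nsteps > 400) nsteps = 400;  // long epochs approach equilibrium
  double dt = T / nsteps;

  std::vector<double> col(G), row(G), a_half(G - 1), xmid(G - 1);
  for (int j = 0; j < G - 1; ++j) xmid[j] = (xx[j] + xx[j + 1]) / 2.0;
  Ws w; w.init(xx);
  double* pd = REAL(phi);
  double inj = theta0 / 2.0 * 4.0 / ((xx[2] - xx[0]) * xx[1]) / xx[1];
  for (int s = 0; s < nsteps; ++s) {
    double tau = (s + 1) * dt;
    double nu1 = nu10 * std::exp(g1 * tau);
    double nu2 = nu20 * std::exp(g2 * tau);
    // inject new mutations (x-axis = population 1, y-axis = population 2)
    pd[1] += dt * inj;          // phi(1, 0)
    pd[G] += dt * inj;          // phi(0, 1)
    // x-direction sweep: for each fixed y_k, advection a(x) = m12*(y_k - x)
    for (int k = 0; k < G; ++k) {
      double* colp = pd + (size_t)k * G;  // column k is contiguous
      for (int j = 0; j < G - 1; ++j) a_half[j] = m12 * (xx[k] - xmid[j]);
      implicitStep1D(colp, cwid, nu1, a_half.data(), dt, G, w);
    }
    // y-direction sweep: for each fixed x_j, advection a(y) = m21*(x_j - y)
    for (int j = 0; j < G; ++j) {
      for (int k = 0; k < G; ++k) row[k] = pd[(size_t)k * G + j];
      for (int k = 0; k < G - 1; ++k) a_half[k] = m21 * (xx[j] - xmid[k]);
      implicitStep1D(row.data(), cwid, nu2, a_half.data(), dt, G, w);
      for (int k = 0; k < G; ++k) pd[(size_t)k * G + j] = row[k];
    }
  }
  return phi;
}

// [[Rcpp::export(name = ".sample_sfs2d")]]
NumericMatrix sample_sfs2d(NumericMatrix phi, NumericVector xxIn,
                           int n1, int n2) {
  int G = xxIn.size();
  std::vector<double> xx(xxIn.begin(), xxIn.end());
  std::vector<double> w = cellWidths(xx);
  // binomial sampling matrices
  auto binmat = [&](int n) {
    NumericMatrix B(n + 1, G);
    for (int j = 0; j < G; ++j) {
      double x = xx[j];
      for (int i = 0; i <= n; ++i) {
        double lb;
        if (x <= 0.0) lb = (i == 0) ? 0.0 : R_NegInf;
        else if (x >= 1.0) lb = (i == n) ? 0.0 : R_NegInf;
        else lb = Rf_lchoose(n, i) + i * std::log(x) + (n - i) * std::log1p(-x);
        B(i, j) = R_finite(lb) ? std::exp(lb) : 0.0;
      }
    }
    return B;
  };
  NumericMatrix B1 = binmat(n1), B2 = binmat(n2);
  NumericMatrix S(n1 + 1, n2 + 1);
  // S = B1 * diag(w) * phi * diag(w) * B2^T
  for (int i = 0; i <= n1; ++i) {
    std::vector<double> tmp(G, 0.0);
    for (int k = 0; k < G; ++k) {
      double acc = 0.0;
      for (int j = 0; j < G; ++j) acc += B1(i, j) * w[j] * phi(j, k);
      tmp[k] = acc * w[k];
    }
    for (int l = 0; l <= n2; ++l) {
      double acc = 0.0;
      for (int k = 0; k < G; ++k) acc += tmp[k] * B2(l, k);
      S(i, l) = acc;
    }
  }
  return S;
}

// [[Rcpp::export(name = ".sample_sfs1d")]]
NumericVector sample_sfs1d(NumericVector phi, NumericVector xxIn, int n) {
  int G = xxIn.size();
  std::vector<double> xx(xxIn.begin(), xxIn.end());
  std::vector<double> w = cellWidths(xx);
  NumericVector S(n + 1);
  for (int i = 0; i <= n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < G; ++j) {
      double x = xx[j], b;
      if (x <= 0.0) b = (i == 0) ? 1.0 : 0.0;
      else if (x >= 1.0) b = (i == n) ? 1.0 : 0.0;
      else {
        double lb = Rf_lchoose(n, i) + i * std::log(x) + (n - i) * std::log1p(-x);
        b = std::exp(lb);
      }
      acc += b * w[j] * phi[j];
    }
    S[i] = acc;
  }
  return S;
}
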