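// Steady incompressible RANS solver on a 2-D body-fitted structured grid.
// SIMPLE pressure-velocity coupling on a colocated arrangement with
// Rhie-Chow face interpolation; standard k-eps closure with wall functions.
// Planar and axisymmetric modes. All loops use fixed ordering so that a
// given input produces bit-identical output.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// standard k-eps constants
static const double CMU = 0.09, CE1 = 1.44, CE2 = 1.92, SIG_K = 1.0, SIG_E = 1.3;
static const double KAPPA = 0.41, EWALL = 9.8, YLAM = 11.25;
static const double EPS_FLOOR = 1e-12, K_TINY = 1e-14;

struct Grid {
  int ni, nj, mode; // mode: 0 planar, 1 axisymmetric (y = r >= 0, j=0 at axis)
  // node coordinates (ni+1)*(nj+1)
  std::vector<double> xn, yn;
  // cells
  std::vector<double> vol, cx, cy;
  // x-faces (between (i-1,j) and (i,j)), index i + j*(ni+1), i = 0..ni
  std::vector<double> xSx, xSy, xfcx, xfcy, xgeo, xlam;
  // y-faces (between (i,j-1) and (i,j)), index i + j*ni, j = 0..nj
  std::vector<double> ySx, ySy, yfcx, yfcy, ygeo, ylamw;

  int id(int i, int j) const { return i + j * ni; }
  int nid(int i, int j) const { return i + j * (ni + 1); }
  int xf(int i, int j) const { return i + j * (ni + 1); }
  int yf(int i, int j) const { return i + j * ni; }
};

static void build_grid(Grid &g, NumericMatrix xn, NumericMatrix yn, int mode) {
  g.ni = xn.nrow() - 1; g.nj = xn.ncol() - 1; g.mode = mode;
  int ni = g.ni, nj = g.nj, ncell = ni * nj;
  g.xn.assign(xn.begin(), xn.end());
  g.yn.assign(yn.begin(), yn.end());
  g.vol.resize(ncell); g.cx.resize(ncell); g.cy.resize(ncell);
  for (int j = 0; j < nj; ++j) for (int i = 0; i < ni; ++i) {
    int n00 = g.nid(i, j), n10 = g.nid(i + 1, j), n11 = g.nid(i + 1, j + 1), n01 = g.nid(i, j + 1);
    double x0 = g.xn[n00], y0 = g.yn[n00], x1 = g.xn[n10], y1 = g.yn[n10];
    double x2 = g.xn[n11], y2 = g.yn[n11], x3 = g.xn[n01], y3 = g.yn[n01];
    double area = 0.5 * ((x0 * y1 - x1 * y0) + (x1 * y2 - x2 * y1) +
                         (x2 * y3 - x3 * y2) + (x3 * y0 - x0 * y3));
    if (!(area > 0.0))
      stop("meshing error: inverted or degenerate cell at (i=%d, j=%d)", i + 1, j + 1);
    int c = g.id(i, j);
    g.cx[c] = 0.25 * (x0 + x1 + x2 + x3);
    g.cy[c] = 0.25 * (y0 + y1 + y2 + y3);
    g.vol[c] = (mode == 1) ? area * std::max(g.cy[c], 1e-300) : area;
  }
  // x-faces: edge from node (i,j) to (i,j+1), outward-positive toward +i
  int nxf = (ni + 1) * nj;
  g.xSx.resize(nxf); g.xSy.resize(nxf); g.xfcx.resize(nxf); g.xfcy.resize(nxf);
  g.xgeo.resize(nxf); g.xlam.resize(nxf);
  for (int j = 0; j < nj; ++j) for (int i = 0; i <= ni; ++i) {
    int na = g.nid(i, j), nb = g.nid(i, j + 1);
    double dx = g.xn[nb] - g.xn[na], dy = g.yn[nb] - g.yn[na];
    double Sx = dy, Sy = -dx;
    double fr = (mode == 1) ? 0.5 * (g.yn[na] + g.yn[nb]) : 1.0;
    int f = g.xf(i, j);
    g.xSx[f] = Sx * fr; g.xSy[f] = Sy * fr;
    g.xfcx[f] = 0.5 * (g.xn[na] + g.xn[nb]);
    g.xfcy[f] = 0.5 * (g.yn[na] + g.yn[nb]);
    double S2 = g.xSx[f] * g.xSx[f] + g.xSy[f] * g.xSy[f];
    if (i > 0 && i < ni) {
      int P = g.id(i - 1, j), N = g.id(i, j);
      double dxn = g.cx[N] - g.cx[P], dyn = g.cy[N] - g.cy[P];
      double sd = g.xSx[f] * dxn + g.xSy[f] * dyn;
      g.xgeo[f] = S2 / sd;
      double lam = ((g.xfcx[f] - g.cx[P]) * dxn + (g.xfcy[f] - g.cy[P]) * dyn) / (dxn * dxn + dyn * dyn);
      g.xlam[f] = std::min(0.99, std::max(0.01, lam));
    } else {
      int P = (i == 0) ? g.id(0, j) : g.id(ni - 1, j);
      double dxn = g.xfcx[f] - g.cx[P], dyn = g.xfcy[f] - g.cy[P];
      double sd = std::fabs(g.xSx[f] * dxn + g.xSy[f] * dyn);
      g.xgeo[f] = (sd > 0) ? S2 / sd : 0.0;
      g.xlam[f] = 1.0;
    }
  }
  // y-faces: edge from node (i,j) to (i+1,j), outward-positive toward +j
  int nyf = ni * (nj + 1);
  g.ySx.resize(nyf); g.ySy.resize(nyf); g.yfcx.resize(nyf); g.yfcy.resize(nyf);
  g.ygeo.resize(nyf); g.ylamw.resize(nyf);
  for (int j = 0; j <= nj; ++j) for (int i = 0; i < ni; ++i) {
    int na = g.nid(i, j), nb = g.nid(i + 1, j);
    double dx = g.xn[nb] - g.xn[na], dy = g.yn[nb] - g.yn[na];
    double Sx = -dy, Sy = dx;
    double fr = (mode == 1) ? 0.5 * (g.yn[na] + g.yn[nb]) : 1.0;
    int f = g.yf(i, j);
    g.ySx[f] = Sx * fr; g.ySy[f] = Sy * fr;
    g.yfcx[f] = 0.5 * (g.xn[na] + g.xn[nb]);
    g.yfcy[f] = 0.5 * (g.yn[na] + g.yn[nb]);
    double S2 = g.ySx[f] * g.ySx[f] + g.ySy[f] * g.ySy[f];
    if (j > 0 && j < nj) {
      int P = g.id(i, j - 1), N = g.id(i, j);
      double dxn = g.cx[N] - g.cx[P], dyn = g.cy[N] - g.cy[P];
      double sd = g.ySx[f] * dxn + g.ySy[f] * dyn;
      g.ygeo[f] = S2 / sd;
      double lam = ((g.yfcx[f] - g.cx[P]) * dxn + (g.yfcy[f] - g.cy[P]) * dyn) / (dxn * dxn + dyn * dyn);
      g.ylamw[f] = std::min(0.99, std::max(0.01, lam));
    } else {
      int P = (j == 0) ? g.id(i, 0) : g.id(i, nj - 1);
      double dxn = g.yfcx[f] - g.cx[P], dyn = g.yfcy[f] - g.cy[P];
      double sd = std::fabs(g.ySx[f] * dxn + g.ySy[f] * dyn);
      g.ygeo[f] = (sd > 0) ? S2 / sd : 0.0;
      g.ylamw[f] = 1.0;
    }
  }
}

struct Settings {
  double alpha_u, alpha_p, alpha_t, tol;
  int maxit, scheme, nsweep;  // scheme: 0 first-order upwind, 1 limited SOU
  bool turb;
};

struct Work {
  // per-cell implicit coefficients: aP phi = aE phiE + aW phiW + aN phiN + aS phiS + b
  std::vector<double> aP, aE, aW, aN, aS, b;
  void init(int n) { aP.assign(n, 0); aE.assign(n, 0); aW.assign(n, 0); aN.assign(n, 0); aS.assign(n, 0); b.assign(n, 0); }
};

struct State {
  std::vector<double> u, v, p, k, eps, mut;
  std::vector<double> mx, my;      // face mass fluxes, +i and +j positive
  std::vector<double> dU;          // vol/aP of the momentum equation
  std::vector<double> gpx, gpy;    // pressure gradient
  std::vector<double> tauw, ypw, uparw, ystarw; // per-cell wall data (0 if not wall-adjacent)
  std::vector<int> wallcell;       // 0/1
};

// minmod-limited second-order upwind face excess over first-order upwind
static inline double sou_excess(double phiC, double phiD, double phiUU) {
  double d1 = phiC - phiUU;
  if (d1 == 0.0) return 0.0;
  double r = (phiD - phiC) / d1;
  double psi = std::max(0.0, std::min(1.0, r));
  return 0.5 * psi * d1;
}

// Green-Gauss gradient of cell field phi with boundary face values supplied by
// btype: 0 zero-gradient, 1 Dirichlet (value array per inlet row / scalar for walls)
static void gradient(const Grid &g, const std::vector<double> &phi,
                     const std::vector<double> *inlet_val, // Dirichlet at i=0 if non-null
                     bool wall_dirichlet_zero,             // walls: phi_b = 0 (else zero-grad)
                     double outlet_val, bool outlet_dirichlet,
                     std::vector<double> &gx, std::vector<double> &gy) {
  int ni = g.ni, nj = g.nj, ncell = ni * nj;
  gx.assign(ncell, 0.0); gy.assign(ncell, 0.0);
  // interior x-faces
  for (int j = 0; j < nj; ++j) for (int i = 1; i < ni; ++i) {
    int f = g.xf(i, j), P = g.id(i - 1, j), N = g.id(i, j);
    double lam = g.xlam[f];
    double phif = (1 - lam) * phi[P] + lam * phi[N];
    gx[P] += (phif - phi[P]) * g.xSx[f]; gy[P] += (phif - phi[P]) * g.xSy[f];
    gx[N] -= (phif - phi[N]) * g.xSx[f]; gy[N] -= (phif - phi[N]) * g.xSy[f];
  }
  for (int j = 1; j < nj; ++j) for (int i = 0; i < ni; ++i) {
    int f = g.yf(i, j), P = g.id(i, j - 1), N = g.id(i, j);
    double lam = g.ylamw[f];
    double phif = (1 - lam) * phi[P] + lam * phi[N];
    gx[P] += (phif - phi[P]) * g.ySx[f]; gy[P] += (phif - phi[P]) * g.ySy[f];
    gx[N] -= (phif - phi[N]) * g.ySx[f]; gy[N] -= (phif - phi[N]) * g.ySy[f];
  }
  // boundaries (using the (phi_f - phi_P) form, zero-gradient faces contribute nothing)
  for (int j = 0; j < nj; ++j) {
    if (inlet_val) {
      int f = g.xf(0, j), P = g.id(0, j);
      double d = (*inlet_val)[j] - phi[P];
      gx[P] -= d * g.xSx[f]; gy[P] -= d * g.xSy[f]; // outward = -S at west boundary
    }
    if (outlet_dirichlet) {
      int f = g.xf(ni, j), P = g.id(ni - 1, j);
      double d = outlet_val - phi[P];
      gx[P] += d * g.xSx[f]; gy[P] += d * g.xSy[f];
    }
  }
  if (wall_dirichlet_zero) {
    for (int i = 0; i < ni; ++i) {
      if (g.mode == 0) { // planar: south wall
        int f = g.yf(i, 0), P = g.id(i, 0);
        double d = 0.0 - phi[P];
        gx[P] -= d * g.ySx[f]; gy[P] -= d * g.ySy[f];
      }
      int f = g.yf(i, nj), P = g.id(i, nj - 1);
      double d = 0.0 - phi[P];
      gx[P] += d * g.ySx[f]; gy[P] += d * g.ySy[f];
    }
  }
  for (int c = 0; c < ncell; ++c) { gx[c] /= g.vol[c]; gy[c] /= g.vol[c]; }
}

// wall-function shear coefficient: tau_w * A / u_par, i.e. the implicit
// diffusion-like coefficient tying the wall cell velocity to the (zero) wall value
static inline void wall_coeff(double rho, double mu, double kP, double upar, double yP,
                              double A, bool turb, double &cw, double &tauw, double &ystar) {
  if (!turb) { cw = mu * A / yP; tauw = cw * upar / std::max(A, 1e-300); ystar = 0.0; return; }
  double ust = std::pow(CMU, 0.25) * std::sqrt(std::max(kP, 0.0));
  ystar = rho * ust * yP / mu;
  if (ystar > YLAM) cw = rho * ust * KAPPA * A / std::log(EWALL * ystar);
  else cw = mu * A / yP;
  tauw = cw * upar / std::max(A, 1e-300);
}

// assemble convection (first-order upwind implicit + limited SOU deferred) and
// central diffusion for a generic transported scalar, into Work w.
// gamma: per-cell diffusivity; fluxes from st.mx/st.my.
static void conv_diff(const Grid &g, const State &st, const std::vector<double> &gamma,
                      const std::vector<double> &phi, int scheme, Work &w) {
  int ni = g.ni, nj = g.nj;
  for (int j = 0; j < nj; ++j) for (int i = 1; i < ni; ++i) {
    int f = g.xf(i, j), P = g.id(i - 1, j), N = g.id(i, j);
    double F = st.mx[f];
    double lam = g.xlam[f];
    double gf = (1 - lam) * gamma[P] + lam * gamma[N];
    double D = gf * g.xgeo[f];
    w.aE[P] += D + std::max(-F, 0.0); w.aP[P] += D + std::max(F, 0.0);
    w.aW[N] += D + std::max(F, 0.0);  w.aP[N] += D + std::max(-F, 0.0);
    if (scheme == 1) {
      if (F > 0.0 && i >= 2) {
        double ex = sou_excess(phi[P], phi[N], phi[g.id(i - 2, j)]);
        w.b[P] -= F * ex; w.b[N] += F * ex;
      } else if (F < 0.0 && i + 1 < ni) {
        double ex = sou_excess(phi[N], phi[P], phi[g.id(i + 1, j)]);
        w.b[P] -= F * ex; w.b[N] += F * ex;
      }
    }
  }
  for (int j = 1; j < nj; ++j) for (int i = 0; i < ni; ++i) {
    int f = g.yf(i, j), P = g.id(i, j - 1), N = g.id(i, j);
    double F = st.my[f];
    double lam = g.ylamw[f];
    double gf = (1 - lam) * gamma[P] + lam * gamma[N];
    double D = gf * g.ygeo[f];
    w.aN[P] += D + std::max(-F, 0.0); w.aP[P] += D + std::max(F, 0.0);
    w.aS[N] += D + std::max(F, 0.0);  w.aP[N] += D + std::max(-F, 0.0);
    if (scheme == 1) {
      if (F > 0.0 && j >= 2) {
        double ex = sou_excess(phi[P], phi[N], phi[g.id(i, j - 2)]);
        w.b[P] -= F * ex; w.b[N] += F * ex;
      } else if (F < 0.0 && j + 1 < nj) {
        double ex = sou_excess(phi[N], phi[P], phi[g.id(i, j + 1)]);
        w.b[P] -= F * ex; w.b[N] += F * ex;
      }
    }
  }
}

// inlet (Dirichlet) and outlet (convective outflow) boundary closure for a scalar
static void inout_bc(const Grid &g, const State &st, const std::vector<double> &gamma,
                     const std::vector<double> &bval, Work &w) {
  int ni = g.ni, nj = g.nj;
  for (int j = 0; j < nj; ++j) {
    int P = g.id(0, j), f = g.xf(0, j);
    double Fin = st.mx[f]; // > 0 into the domain
    w.b[P] += Fin * bval[j];
    double D = gamma[P] * g.xgeo[f];
    w.aP[P] += D; w.b[P] += D * bval[j];
    int Q = g.id(ni - 1, j), fo = g.xf(ni, j);
    w.aP[Q] += std::max(st.mx[fo], 0.0);
  }
}

static double l1_raw(const Grid &g, const Work &w, const std::vector<double> &phi,
                     double &scale) {
  int ni = g.ni, nj = g.nj;
  double r = 0;
  scale = 0;
  for (int j = 0; j < nj; ++j) for (int i = 0; i < ni; ++i) {
    int c = g.id(i, j);
    double ax = w.aP[c] * phi[c];
    if (i + 1 < ni) ax -= w.aE[c] * phi[g.id(i + 1, j)];
    if (i - 1 >= 0) ax -= w.aW[c] * phi[g.id(i - 1, j)];
    if (j + 1 < nj) ax -= w.aN[c] * phi[g.id(i, j + 1)];
    if (j - 1 >= 0) ax -= w.aS[c] * phi[g.id(i, j - 1)];
    r += std::fabs(ax - w.b[c]);
    scale += std::fabs(w.aP[c] * phi[c]);
  }
  for (int c = 0; c < ni * nj; ++c) scale += std::fabs(w.b[c]);
  return r;
}

static double l1_residual(const Grid &g, const Work &w, const std::vector<double> &phi) {
  double scale;
  double r = l1_raw(g, w, phi, scale);
  return (scale > 0) ? r / scale : r;
}

// alternating-direction TDMA line relaxation (one full sweep = i-lines then j-lines)
static void tdma_sweeps(const Grid &g, const Work &w, std::vector<double> &phi, int nsweep) {
  int ni = g.ni, nj = g.nj;
  std::vector<double> P(std::max(ni, nj)), Q(std::max(ni, nj));
  for (int s = 0; s < nsweep; ++s) {
    for (int j = 0; j < nj; ++j) { // lines along i
      for (int i = 0; i < ni; ++i) {
        int c = g.id(i, j);
        double rhs = w.b[c];
        if (j + 1 < nj) rhs += w.aN[c] * phi[g.id(i, j + 1)];
        if (j - 1 >= 0) rhs += w.aS[c] * phi[g.id(i, j - 1)];
        double low = (i > 0) ? -w.aW[c] : 0.0, up = (i + 1 < ni) ? -w.aE[c] : 0.0;
        double den = w.aP[c] + low * ((i > 0) ? P[i - 1] : 0.0);
        P[i] = -up / den;
        Q[i] = (rhs - low * ((i > 0) ? Q[i - 1] : 0.0)) / den;
      }
      for (int i = ni - 1; i >= 0; --i)
        phi[g.id(i, j)] = P[i] * ((i + 1 < ni) ? phi[g.id(i + 1, j)] : 0.0) + Q[i];
    }
    for (int i = 0; i < ni; ++i) { // lines along j
      for (int j = 0; j < nj; ++j) {
        int c = g.id(i, j);
        double rhs = w.b[c];
        if (i + 1 < ni) rhs += w.aE[c] * phi[g.id(i + 1, j)];
        if (i - 1 >= 0) rhs += w.aW[c] * phi[g.id(i - 1, j)];
        double low = (j > 0) ? -w.aS[c] : 0.0, up = (j + 1 < nj) ? -w.aN[c] : 0.0;
        double den = w.aP[c] + low * ((j > 0) ? P[j - 1] : 0.0);
        P[j] = -up / den;
        Q[j] = (rhs - low * ((j > 0) ? Q[j - 1] : 0.0)) / den;
      }
      for (int j = nj - 1; j >= 0; --j)
        phi[g.id(i, j)] = P[j] * ((j + 1 < nj) ? phi[g.id(i, j + 1)] : 0.0) + Q[j];
    }
  }
}

// Jacobi-preconditioned conjugate gradients for the (symmetric) pressure correction
static void cg_solve(const Grid &g, const Work &w, std::vector<double> &x,
                     double rtol, int maxit) {
  int ni = g.ni, nj = g.nj, n = ni * nj;
  std::vector<double> r(n), z(n), pv(n), Ap(n);
  auto apply = [&](const std::vector<double> &q, std::vector<double> &out) {
    for (int j = 0; j < nj; ++j) for (int i = 0; i < ni; ++i) {
      int c = g.id(i, j);
      double ax = w.aP[c] * q[c];
      if (i + 1 < ni) ax -= w.aE[c] * q[g.id(i + 1, j)];
      if (i - 1 >= 0) ax -= w.aW[c] * q[g.id(i - 1, j)];
      if (j + 1 < nj) ax -= w.aN[c] * q[g.id(i, j + 1)];
      if (j - 1 >= 0) ax -= w.aS[c] * q[g.id(i, j - 1)];
      out[c] = ax;
    }
  };
  apply(x, Ap);
  double r0 = 0;
  for (int c = 0; c < n; ++c) { r[c] = w.b[c] - Ap[c]; r0 += r[c] * r[c]; }
  r0 = std::sqrt(r0);
  if (r0 == 0) return;
  double rz = 0;
  for (int c = 0; c < n; ++c) { z[c] = r[c] / w.aP[c]; pv[c] = z[c]; rz += r[c] * z[c]; }
  for (int it = 0; it < maxit; ++it) {
    apply(pv, Ap);
    double pAp = 0;
    for (int c = 0; c < n; ++c) pAp += pv[c] * Ap[c];
    if (pAp <= 0) break;
    double alpha = rz / pAp, rn = 0;
    for (int c = 0; c < n; ++c) { x[c] += alpha * pv[c]; r[c] -= alpha * Ap[c]; rn += r[c] * r[c]; }
    if (std::sqrt(rn) < rtol * r0) break;
    double rz_new = 0;
    for (int c = 0; c < n; ++c) { z[c] = r[c] / w.aP[c]; rz_new += r[c] * z[c]; }
    double beta = rz_new / rz; rz = rz_new;
    for (int c = 0; c < n; ++c) pv[c] = z[c] + beta * pv[c];
  }
}

// locate wall-adjacent cells, compute wall shear data into st
static void update_wall_data(const Grid &g, State &st, double rho, double mu, bool turb) {
  int ni = g.ni, nj = g.nj, ncell = ni * nj;
  st.tauw.assign(ncell, 0.0); st.ypw.assign(ncell, 0.0);
  st.uparw.assign(ncell, 0.0); st.ystarw.assign(ncell, 0.0);
  st.wallcell.assign(ncell, 0);
  auto do_face = [&](int P, double Sx, double Sy, double fcx, double fcy, double sgn) {
    double A = std::sqrt(Sx * Sx + Sy * Sy);
    if (A <= 0) return;
    double nx = sgn * Sx / A, ny = sgn * Sy / A; // outward normal
    double yP = std::fabs((fcx - g.cx[P]) * nx + (fcy - g.cy[P]) * ny);
    double un = st.u[P] * nx + st.v[P] * ny;
    double tx = st.u[P] - un * nx, ty = st.v[P] - un * ny;
    double upar = std::sqrt(tx * tx + ty * ty);
    double cw, tw, yst;
    wall_coeff(rho, mu, st.k[P], upar, yP, A, turb, cw, tw, yst);
    // keep the closer wall if a cell touches two (only when nj is tiny)
    if (!st.wallcell[P] || yP < st.ypw[P]) {
      st.wallcell[P] = 1; st.tauw[P] = tw; st.ypw[P] = yP; st.uparw[P] = upar; st.ystarw[P] = yst;
    }
  };
  for (int i = 0; i < ni; ++i) {
    if (g.mode == 0) { int f = g.yf(i, 0); do_face(g.id(i, 0), g.ySx[f], g.ySy[f], g.yfcx[f], g.yfcy[f], -1.0); }
    int f = g.yf(i, nj); do_face(g.id(i, nj - 1), g.ySx[f], g.ySy[f], g.yfcx[f], g.yfcy[f], 1.0);
  }
}

// wall shear implicit coefficient added to the momentum aP
static void wall_momentum(const Grid &g, const State &st, double rho, double mu, bool turb,
                          Work &wu, Work &wv) {
  int ni = g.ni, nj = g.nj;
  auto add = [&](int P, double Sx, double Sy) {
    double A = std::sqrt(Sx * Sx + Sy * Sy);
    if (A <= 0) return;
    double cw, tw, yst;
    wall_coeff(rho, mu, st.k[P], st.uparw[P], st.ypw[P], A, turb, cw, tw, yst);
    wu.aP[P] += cw; wv.aP[P] += cw;
  };
  for (int i = 0; i < ni; ++i) {
    if (g.mode == 0) { int f = g.yf(i, 0); add(g.id(i, 0), g.ySx[f], g.ySy[f]); }
    int f = g.yf(i, nj); add(g.id(i, nj - 1), g.ySx[f], g.ySy[f]);
  }
}

static void assemble_momentum(const Grid &g, State &st, double rho, double mu,
                              const std::vector<double> &uin, const Settings &set,
                              Work &wu, Work &wv) {
  int ni = g.ni, nj = g.nj, ncell = ni * nj;
  std::vector<double> gamma(ncell), zero(nj, 0.0);
  for (int c = 0; c < ncell; ++c) gamma[c] = mu + st.mut[c];
  wu.init(ncell); wv.init(ncell);
  conv_diff(g, st, gamma, st.u, set.scheme, wu);
  // v shares convection/diffusion structure; assemble separately for its deferred terms
  conv_diff(g, st, gamma, st.v, set.scheme, wv);
  inout_bc(g, st, gamma, uin, wu);
  inout_bc(g, st, gamma, zero, wv);
  wall_momentum(g, st, rho, mu, set.turb, wu, wv);
  if (g.mode == 1) { // axisymmetric hoop-stress sink on the radial component
    for (int c = 0; c < ncell; ++c)
      wv.aP[c] += 2.0 * gamma[c] * g.vol[c] / std::max(g.cy[c] * g.cy[c], 1e-300);
  }
  for (int c = 0; c < ncell; ++c) {
    wu.b[c] -= st.gpx[c] * g.vol[c];
    wv.b[c] -= st.gpy[c] * g.vol[c];
  }
}

static void relax_implicit(Work &w, const std::vector<double> &phi_old, double alpha) {
  int n = (int)w.aP.size();
  for (int c = 0; c < n; ++c) {
    w.aP[c] /= alpha;
    w.b[c] += (1.0 - alpha) * w.aP[c] * phi_old[c];
  }
}

static void turb_sources(const Grid &g, State &st, double rho, double mu,
                         const std::vector<double> &uin, std::vector<double> &Pk) {
  int ni = g.ni, nj = g.nj, ncell = ni * nj;
  std::vector<double> gux, guy, gvx, gvy, zero(nj, 0.0);
  gradient(g, st.u, &uin, true, 0.0, false, gux, guy);
  gradient(g, st.v, &zero, true, 0.0, false, gvx, gvy);
  Pk.assign(ncell, 0.0);
  for (int c = 0; c < ncell; ++c) {
    double s2 = 2.0 * gux[c] * gux[c] + 2.0 * gvy[c] * gvy[c] +
                (guy[c] + gvx[c]) * (guy[c] + gvx[c]);
    if (g.mode == 1) {
      double vr = st.v[c] / std::max(g.cy[c], 1e-300);
      s2 += 2.0 * vr * vr;
    }
    Pk[c] = st.mut[c] * s2;
  }
  // wall-adjacent production from the wall shear (log-law gradient)
  for (int c = 0; c < ncell; ++c) if (st.wallcell[c]) {
    double ust = std::pow(CMU, 0.25) * std::sqrt(std::max(st.k[c], 0.0));
    if (st.ystarw[c] > YLAM && ust > 0)
      Pk[c] = st.tauw[c] * ust / (KAPPA * st.ypw[c]);
    else
      Pk[c] = st.tauw[c] * st.uparw[c] / std::max(st.ypw[c], 1e-300);
  }
}

static void assemble_k(const Grid &g, State &st, double rho, double mu,
                       const std::vector<double> &kin, const std::vector<double> &Pk,
                       const Settings &set, Work &w) {
  int ni = g.ni, nj = g.nj, ncell = ni * nj;
  std::vector<double> gamma(ncell);
  for (int c = 0; c < ncell; ++c) gamma[c] = mu + st.mut[c] / SIG_K;
  w.init(ncell);
  conv_diff(g, st, gamma, st.k, set.scheme, w);
  inout_bc(g, st, gamma, kin, w);
  for (int c = 0; c < ncell; ++c) {
    w.b[c] += Pk[c] * g.vol[c];
    w.aP[c] += rho * st.eps[c] / std::max(st.k[c], K_TINY) * g.vol[c];
  }
}

static void assemble_eps(const Grid &g, State &st, double rho, double mu,
                         const std::vector<double> &ein, const std::vector<double> &Pk,
                         const Settings &set, Work &w) {
  int ni = g.ni, nj = g.nj, ncell = ni * nj;
  std::vector<double> gamma(ncell);
  for (int c = 0; c < ncell; ++c) gamma[c] = mu + st.mut[c] / SIG_E;
  w.init(ncell);
  conv_diff(g, st, gamma, st.eps, set.scheme, w);
  inout_bc(g, st, gamma, ein, w);
  for (int c = 0; c < ncell; ++c) {
    double kk = std::max(st.k[c], K_TINY);
    w.b[c] += CE1 * st.eps[c] / kk * Pk[c] * g.vol[c];
    w.aP[c] += CE2 * rho * st.eps[c] / kk * g.vol[c];
  }
  // fixed dissipation in wall-adjacent cells (equilibrium log-layer value)
  for (int c = 0; c < ncell; ++c) if (st.wallcell[c]) {
    double ew = std::pow(CMU, 0.75) * std::pow(std::max(st.k[c], 0.0), 1.5) / (KAPPA * st.ypw[c]);
    w.aP[c] = 1.0; w.aE[c] = w.aW[c] = w.aN[c] = w.aS[c] = 0.0; w.b[c] = ew;
  }
}

// Rhie-Chow interior face fluxes + balanced outlet fluxes
static void face_fluxes(const Grid &g, State &st, double rho) {
  int ni = g.ni, nj = g.nj;
  for (int j = 0; j < nj; ++j) for (int i = 1; i < ni; ++i) {
    int f = g.xf(i, j), P = g.id(i - 1, j), N = g.id(i, j);
    double lam = g.xlam[f];
    double uf = (1 - lam) * st.u[P] + lam * st.u[N];
    double vf = (1 - lam) * st.v[P] + lam * st.v[N];
    double dUf = (1 - lam) * st.dU[P] + lam * st.dU[N];
    double gpf_d = ((1 - lam) * st.gpx[P] + lam * st.gpx[N]) * (g.cx[N] - g.cx[P]) +
                   ((1 - lam) * st.gpy[P] + lam * st.gpy[N]) * (g.cy[N] - g.cy[P]);
    st.mx[f] = rho * (uf * g.xSx[f] + vf * g.xSy[f]) +
               rho * dUf * g.xgeo[f] * ((st.p[P] - st.p[N]) + gpf_d);
  }
  for (int j = 1; j < nj; ++j) for (int i = 0; i < ni; ++i) {
    int f = g.yf(i, j), P = g.id(i, j - 1), N = g.id(i, j);
    double lam = g.ylamw[f];
    double uf = (1 - lam) * st.u[P] + lam * st.u[N];
    double vf = (1 - lam) * st.v[P] + lam * st.v[N];
    double dUf = (1 - lam) * st.dU[P] + lam * st.dU[N];
    double gpf_d = ((1 - lam) * st.gpx[P] + lam * st.gpx[N]) * (g.cx[N] - g.cx[P]) +
                   ((1 - lam) * st.gpy[P] + lam * st.gpy[N]) * (g.cy[N] - g.cy[P]);
    st.my[f] = rho * (uf * g.ySx[f] + vf * g.ySy[f]) +
               rho * dUf * g.ygeo[f] * ((st.p[P] - st.p[N]) + gpf_d);
  }
  for (int i = 0; i < ni; ++i) { st.my[g.yf(i, 0)] = 0.0; st.my[g.yf(i, nj)] = 0.0; }
  // outlet: upwinded, then scaled for global balance
  double fin = 0, fout = 0, aout = 0;
  for (int j = 0; j < nj; ++j) fin += st.mx[g.xf(0, j)];
  for (int j = 0; j < nj; ++j) {
    int f = g.xf(ni, j), P = g.id(ni - 1, j);
    st.mx[f] = rho * (st.u[P] * g.xSx[f] + st.v[P] * g.xSy[f]);
    fout += st.mx[f];
    aout += std::sqrt(g.xSx[f] * g.xSx[f] + g.xSy[f] * g.xSy[f]);
  }
  if (fout > 1e-30 * std::fabs(fin) && fout > 0) {
    double s = fin / fout;
    for (int j = 0; j < nj; ++j) st.mx[g.xf(ni, j)] *= s;
  } else {
    for (int j = 0; j < nj; ++j) {
      int f = g.xf(ni, j);
      double A = std::sqrt(g.xSx[f] * g.xSx[f] + g.xSy[f] * g.xSy[f]);
      st.mx[f] = fin * A / aout;
    }
  }
}

static Settings read_settings(List s) {
  Settings set;
  set.alpha_u = as<double>(s["relax_u"]);
  set.alpha_p = as<double>(s["relax_p"]);
  set.alpha_t = as<double>(s["relax_turb"]);
  set.maxit = as<int>(s["max_iterations"]);
  set.tol = as<double>(s["residual_tolerance"]);
  set.scheme = as<int>(s["scheme"]); // 0 or 1
  set.turb = as<bool>(s["turbulence"]);
  set.nsweep = s.containsElementNamed("inner_sweeps") ? as<int>(s["inner_sweeps"]) : 2;
  return set;
}

// [[Rcpp::export]]
List cpp_simple_solve(NumericMatrix xn, NumericMatrix yn, int mode,
                      NumericVector uin_, NumericVector kin_, NumericVector ein_,
                      double rho, double mu, List settings,
                      Nullable<List> init = R_NilValue) {
  Grid g; build_grid(g, xn, yn, mode);
  int ni = g.ni, nj = g.nj, ncell = ni * nj;
  Settings set = read_settings(settings);
  std::vector<double> uin(uin_.begin(), uin_.end());
  std::vector<double> kin(kin_.begin(), kin_.end());
  std::vector<double> ein(ein_.begin(), ein_.end());
  for (int j = 0; j < nj; ++j) ein[j] = std::max(ein[j], EPS_FLOOR);

  State st;
  st.u.assign(ncell, 0); st.v.assign(ncell, 0); st.p.assign(ncell, 0);
  st.k.assign(ncell, 0); st.eps.assign(ncell, EPS_FLOOR); st.mut.assign(ncell, 0);
  st.dU.assign(ncell, 0);
  st.mx.assign((ni + 1) * nj, 0); st.my.assign(ni * (nj + 1), 0);
  if (init.isNotNull()) {
    List in(init);
    NumericMatrix iu = in["u"], iv = in["v"], ip = in["p"], ik = in["k"], ie = in["eps"], im = in["mut"];
    for (int c = 0; c < ncell; ++c) {
      st.u[c] = iu[c]; st.v[c] = iv[c]; st.p[c] = ip[c];
      st.k[c] = std::max((double)ik[c], 0.0);
      st.eps[c] = std::max((double)ie[c], EPS_FLOOR);
      st.mut[c] = std::max((double)im[c], 0.0);
    }
  } else {
    for (int j = 0; j < nj; ++j) for (int i = 0; i < ni; ++i) {
      int c = g.id(i, j);
      st.u[c] = uin[j]; st.k[c] = std::max(kin[j], 0.0); st.eps[c] = ein[j];
    }
    if (set.turb)
      for (int c = 0; c < ncell; ++c)
        st.mut[c] = std::min(rho * CMU * st.k[c] * st.k[c] / st.eps[c], 1e5 * mu);
  }
  // fixed inlet fluxes
  double fin_tot = 0;
  for (int j = 0; j < nj; ++j) {
    st.mx[g.xf(0, j)] = rho * uin[j] * g.xSx[g.xf(0, j)];
    fin_tot += st.mx[g.xf(0, j)];
  }
  update_wall_data(g, st, rho, mu, set.turb);
  // initial interior/outlet fluxes from the velocity field (no pressure term yet)
  for (int c = 0; c < ncell; ++c) st.dU[c] = 0.0;
  st.gpx.assign(ncell, 0); st.gpy.assign(ncell, 0);
  face_fluxes(g, st, rho);

  Work wu, wv, wp, wk, we;
  std::vector<double> Pk, gppx, gppy, pp(ncell, 0.0);
  int nhist = 0;
  NumericMatrix hist(set.maxit, 5);
  bool converged = false, diverged = false;
  long n_clip_k = 0, n_clip_e = 0;
  double first_ru = -1;
  int it = 0;

  for (it = 1; it <= set.maxit; ++it) {
    // pressure gradient (outlet Dirichlet p = 0)
    gradient(g, st.p, nullptr, false, 0.0, true, st.gpx, st.gpy);
    update_wall_data(g, st, rho, mu, set.turb);
    assemble_momentum(g, st, rho, mu, uin, set, wu, wv);
    relax_implicit(wu, st.u, set.alpha_u);
    relax_implicit(wv, st.v, set.alpha_u);
    double scale_u, scale_v;
    double ru_raw = l1_raw(g, wu, st.u, scale_u);
    double rv_raw = l1_raw(g, wv, st.v, scale_v);
    // both momentum components share the u-equation scale so that a
    // machine-zero transverse component reads as converged, not 0/0
    double mscale = std::max(scale_u, 1e-300);
    double ru = ru_raw / mscale, rv = rv_raw / mscale;
    for (int c = 0; c < ncell; ++c) st.dU[c] = g.vol[c] / wu.aP[c];
    tdma_sweeps(g, wu, st.u, set.nsweep);
    tdma_sweeps(g, wv, st.v, set.nsweep);

    face_fluxes(g, st, rho);

    // pressure correction
    wp.init(ncell);
    double rp_abs = 0;
    for (int j = 0; j < nj; ++j) for (int i = 1; i < ni; ++i) {
      int f = g.xf(i, j), P = g.id(i - 1, j), N = g.id(i, j);
      double lam = g.xlam[f];
      double a = rho * ((1 - lam) * st.dU[P] + lam * st.dU[N]) * g.xgeo[f];
      wp.aE[P] += a; wp.aP[P] += a;
      wp.aW[N] += a; wp.aP[N] += a;
    }
    for (int j = 1; j < nj; ++j) for (int i = 0; i < ni; ++i) {
      int f = g.yf(i, j), P = g.id(i, j - 1), N = g.id(i, j);
      double lam = g.ylamw[f];
      double a = rho * ((1 - lam) * st.dU[P] + lam * st.dU[N]) * g.ygeo[f];
      wp.aN[P] += a; wp.aP[P] += a;
      wp.aS[N] += a; wp.aP[N] += a;
    }
    std::vector<double> aout_coef(nj, 0.0);
    for (int j = 0; j < nj; ++j) { // outlet p' = 0
      int P = g.id(ni - 1, j), f = g.xf(ni, j);
      double a = rho * st.dU[P] * g.xgeo[f];
      aout_coef[j] = a;
      wp.aP[P] += a;
    }
    for (int j = 0; j < nj; ++j) for (int i = 0; i < ni; ++i) {
      int c = g.id(i, j);
      double imb = st.mx[g.xf(i + 1, j)] - st.mx[g.xf(i, j)] +
                   st.my[g.yf(i, j + 1)] - st.my[g.yf(i, j)];
      wp.b[c] = -imb;
      rp_abs += std::fabs(imb);
    }
    double rp = rp_abs / std::max(std::fabs(fin_tot), 1e-300);
    std::fill(pp.begin(), pp.end(), 0.0);
    cg_solve(g, wp, pp, 1e-3, 10 * (ni + nj));

    // corrections
    for (int c = 0; c < ncell; ++c) st.p[c] += set.alpha_p * pp[c];
    gradient(g, pp, nullptr, false, 0.0, true, gppx, gppy);
    for (int c = 0; c < ncell; ++c) {
      st.u[c] -= st.dU[c] * gppx[c];
      st.v[c] -= st.dU[c] * gppy[c];
    }
    for (int j = 0; j < nj; ++j) for (int i = 1; i < ni; ++i) {
      int f = g.xf(i, j), P = g.id(i - 1, j), N = g.id(i, j);
      double lam = g.xlam[f];
      double a = rho * ((1 - lam) * st.dU[P] + lam * st.dU[N]) * g.xgeo[f];
      st.mx[f] += a * (pp[P] - pp[N]);
    }
    for (int j = 1; j < nj; ++j) for (int i = 0; i < ni; ++i) {
      int f = g.yf(i, j), P = g.id(i, j - 1), N = g.id(i, j);
      double lam = g.ylamw[f];
      double a = rho * ((1 - lam) * st.dU[P] + lam * st.dU[N]) * g.ygeo[f];
      st.my[f] += a * (pp[P] - pp[N]);
    }
    for (int j = 0; j < nj; ++j)
      st.mx[g.xf(ni, j)] += aout_coef[j] * pp[g.id(ni - 1, j)];

    // turbulence transport
    double rk = 0, re = 0;
    if (set.turb) {
      turb_sources(g, st, rho, mu, uin, Pk);
      assemble_k(g, st, rho, mu, kin, Pk, set, wk);
      relax_implicit(wk, st.k, set.alpha_t);
      rk = l1_residual(g, wk, st.k);
      tdma_sweeps(g, wk, st.k, set.nsweep);
      for (int c = 0; c < ncell; ++c) if (st.k[c] < 0) { st.k[c] = 0.0; ++n_clip_k; }
      assemble_eps(g, st, rho, mu, ein, Pk, set, we);
      // keep the wall-cell Dirichlet rows un-relaxed
      for (int c = 0; c < ncell; ++c) {
        if (!st.wallcell[c]) {
          we.aP[c] /= set.alpha_t;
          we.b[c] += (1.0 - set.alpha_t) * we.aP[c] * st.eps[c];
        }
      }
      re = l1_residual(g, we, st.eps);
      tdma_sweeps(g, we, st.eps, set.nsweep);
      for (int c = 0; c < ncell; ++c) if (st.eps[c] < EPS_FLOOR) { st.eps[c] = EPS_FLOOR; ++n_clip_e; }
      for (int c = 0; c < ncell; ++c) {
        double mn = rho * CMU * st.k[c] * st.k[c] / st.eps[c];
        mn = std::min(mn, 1e5 * mu);
        st.mut[c] += set.alpha_t * (mn - st.mut[c]);
      }
    }

    hist(it - 1, 0) = ru; hist(it - 1, 1) = rv; hist(it - 1, 2) = rp;
    hist(it - 1, 3) = rk; hist(it - 1, 4) = re;
    nhist = it;

    bool bad = false;
    for (int c = 0; c < ncell; ++c)
      if (!std::isfinite(st.u[c]) || !std::isfinite(st.v[c]) || !std::isfinite(st.p[c]) ||
          !std::isfinite(st.k[c]) || !std::isfinite(st.eps[c])) { bad = true; break; }
    if (bad) stop("numerical failure: non-finite field value at iteration %d", it);
    if (first_ru < 0) first_ru = std::max(ru, 1e-300);
    if (it > 100 && ru > 1e5 * first_ru) { diverged = true; break; }

    double rmax = std::max(std::max(ru, rv), rp);
    if (set.turb) rmax = std::max(rmax, std::max(rk, re));
    if (rmax < set.tol) { converged = true; break; }
  }
  if (it > set.maxit) it = set.maxit;

  auto mat = [&](std::vector<double> &vsrc) {
    NumericMatrix m(ni, nj);
    std::copy(vsrc.begin(), vsrc.end(), m.begin());
    return m;
  };
  NumericMatrix mxm(ni + 1, nj), mym(ni, nj + 1);
  std::copy(st.mx.begin(), st.mx.end(), mxm.begin());
  std::copy(st.my.begin(), st.my.end(), mym.begin());
  NumericMatrix h2(nhist, 5);
  for (int r = 0; r < nhist; ++r) for (int c2 = 0; c2 < 5; ++c2) h2(r, c2) = hist(r, c2);
  // global mass imbalance
  double fout = 0;
  for (int j = 0; j < nj; ++j) fout += st.mx[g.xf(ni, j)];
  return List::create(
    _["u"] = mat(st.u), _["v"] = mat(st.v), _["p"] = mat(st.p),
    _["k"] = mat(st.k), _["eps"] = mat(st.eps), _["mut"] = mat(st.mut),
    _["mx"] = mxm, _["my"] = mym,
    _["residuals"] = h2, _["converged"] = converged, _["diverged"] = diverged,
    _["iterations"] = nhist, _["n_clipped_k"] = (double)n_clip_k,
    _["n_clipped_eps"] = (double)n_clip_e,
    _["mass_imbalance"] = std::fabs(fout - fin_tot) / std::max(std::fabs(fin_tot), 1e-300));
}

// Standalone assembly of one transport equation from a given state, for
// inspection and verification. Fluxes are plain interpolated face velocities.
// [[Rcpp::export]]
List cpp_assemble(std::string eqn, NumericMatrix xn, NumericMatrix yn, int mode,
                  NumericMatrix u0, NumericMatrix v0, NumericMatrix p0,
                  NumericMatrix k0, NumericMatrix e0, NumericMatrix m0,
                  NumericVector uin_, NumericVector kin_, NumericVector ein_,
                  double rho, double mu, List settings) {
  Grid g; build_grid(g, xn, yn, mode);
  int ni = g.ni, nj = g.nj, ncell = ni * nj;
  Settings set = read_settings(settings);
  std::vector<double> uin(uin_.begin(), uin_.end());
  std::vector<double> kin(kin_.begin(), kin_.end());
  std::vector<double> ein(ein_.begin(), ein_.end());
  State st;
  st.u.assign(u0.begin(), u0.end()); st.v.assign(v0.begin(), v0.end());
  st.p.assign(p0.begin(), p0.end()); st.k.assign(k0.begin(), k0.end());
  st.eps.assign(e0.begin(), e0.end()); st.mut.assign(m0.begin(), m0.end());
  st.dU.assign(ncell, 0);
  st.mx.assign((ni + 1) * nj, 0); st.my.assign(ni * (nj + 1), 0);
  st.gpx.assign(ncell, 0); st.gpy.assign(ncell, 0);
  // plain face fluxes from the given velocity field
  for (int j = 0; j < nj; ++j) {
    st.mx[g.xf(0, j)] = rho * uin[j] * g.xSx[g.xf(0, j)];
    for (int i = 1; i < ni; ++i) {
      int f = g.xf(i, j), P = g.id(i - 1, j), N = g.id(i, j);
      double lam = g.xlam[f];
      st.mx[f] = rho * (((1 - lam) * st.u[P] + lam * st.u[N]) * g.xSx[f] +
                        ((1 - lam) * st.v[P] + lam * st.v[N]) * g.xSy[f]);
    }
    int f = g.xf(ni, j), P = g.id(ni - 1, j);
    st.mx[f] = rho * (st.u[P] * g.xSx[f] + st.v[P] * g.xSy[f]);
  }
  for (int j = 1; j < nj; ++j) for (int i = 0; i < ni; ++i) {
    int f = g.yf(i, j), P = g.id(i, j - 1), N = g.id(i, j);
    double lam = g.ylamw[f];
    st.my[f] = rho * (((1 - lam) * st.u[P] + lam * st.u[N]) * g.ySx[f] +
                      ((1 - lam) * st.v[P] + lam * st.v[N]) * g.ySy[f]);
  }
  update_wall_data(g, st, rho, mu, set.turb);
  gradient(g, st.p, nullptr, false, 0.0, true, st.gpx, st.gpy);
  Work wu, wv, w;
  if (eqn == "u" || eqn == "v") {
    assemble_momentum(g, st, rho, mu, uin, set, wu, wv);
    relax_implicit(wu, st.u, set.alpha_u);
    relax_implicit(wv, st.v, set.alpha_u);
    w = (eqn == "u") ? wu : wv;
  } else if (eqn == "k" || eqn == "eps") {
    std::vector<double> Pk;
    turb_sources(g, st, rho, mu, uin, Pk);
    if (eqn == "k") {
      assemble_k(g, st, rho, mu, kin, Pk, set, w);
      relax_implicit(w, st.k, set.alpha_t);
    } else {
      assemble_eps(g, st, rho, mu, ein, Pk, set, w);
      for (int c = 0; c < ncell; ++c) if (!st.wallcell[c]) {
        w.aP[c] /= set.alpha_t;
        w.b[c] += (1.0 - set.alpha_t) * w.aP[c] * st.eps[c];
      }
    }
  } else {
    stop("unknown equation '%s'", eqn.c_str());
  }
  for (int c = 0; c < ncell; ++c)
    if (w.aP[c] == 0.0)
      stop("assembly error: zero diagonal at cell %d", c + 1);
  auto vec = [&](std::vector<double> &s) { return NumericVector(s.begin(), s.end()); };
  return List::create(_["aP"] = vec(w.aP), _["aE"] = vec(w.aE), _["aW"] = vec(w.aW),
                      _["aN"] = vec(w.aN), _["aS"] = vec(w.aS), _["b"] = vec(w.b),
                      _["ni"] = ni, _["nj"] = nj);
}

// cell geometry helper used by the R-side mesh accessors (single source of truth
// for areas/centroids so R and C++ agree to the bit)
// [[Rcpp::export]]
List cpp_cell_geometry(NumericMatrix xn, NumericMatrix yn, int mode) {
  Grid g; build_grid(g, xn, yn, mode);
  int ni = g.ni, nj = g.nj;
  NumericMatrix vol(ni, nj), cx(ni, nj), cy(ni, nj);
  std::copy(g.vol.begin(), g.vol.end(), vol.begin());
  std::copy(g.cx.begin(), g.cx.end(), cx.begin());
  std::copy(g.cy.begin(), g.cy.end(), cy.begin());
  // inlet face areas (magnitude)
  NumericVector ain(nj);
  for (int j = 0; j < nj; ++j) {
    int f = g.xf(0, j);
    ain[j] = std::sqrt(g.xSx[f] * g.xSx[f] + g.xSy[f] * g.xSy[f]);
  }
  return List::create(_["volume"] = vol, _["cx"] = cx, _["cy"] = cy,
                      _["inlet_face_areas"] = ain);
}
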