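// Staggered-grid (MAC) fractional-step solver for 2D incompressible flow
// through a masked geometry, with an optional standard k-omega closure.
//
// Layout on a uniform grid of nx*ny cells with spacing h:
//   u : (nx+1) x ny  velocities on x-face centers
//   v : nx x (ny+1)  velocities on y-face centers
//   p, k, omega, nut : nx x ny cell centers
// x is streamwise (inlet at i = 0, outlet at i = nx), y cross-stream.
// A cell is fluid iff fluid(i,j) != 0; the domain border rows are solid.
//
// Scheme: explicit convection (first-order upwind, optionally blended with
// central), explicit diffusion, Chorin projection with a conjugate-gradient
// pressure Poisson solve (Neumann at walls/inlet, Dirichlet 0 at the outlet
// faces). Outlet velocity is zero-gradient with a uniform flux correction so
// the global mass balance is exact before projection.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

const double KW_ALPHA = 5.0 / 9.0;
const double KW_BETA = 0.075;
const double KW_BETA_STAR = 0.09;
const double KW_SIGMA = 0.5;
const double KW_SIGMA_STAR = 0.5;
const double OMEGA_FLOOR = 1e-8;

struct Solver {
  int nx, ny;
  double h, rho, mu, nu;
  std::vector<int> fl;            // nx*ny cell fluid flags
  std::vector<int> ut, vt;        // face types: 0 dead, 1 interior, 2 inlet, 3 outlet
  std::vector<double> u, v, us, vs, p, k, w, nut;
  // compressed Poisson system over fluid cells
  int nf = 0;
  std::vector<int> cid, cell_of;
  std::vector<double> Adiag;
  std::vector<int> nb;            // 4*nf neighbour ids, -1 if absent
  std::vector<double> cg_r, cg_d, cg_q, rhs;
  // configuration
  double ptol = 1e-6;
  int max_outer = 30, cg_max = 4000;
  int conv_scheme = 0;            // 0 upwind, 1 blend
  double blend = 0.75;
  int turb = 0;
  bool komega_inlet_bc = true;
  double nut_max = 0.0, tin = 0.05, inlet_width = 0.027;
  double cfl_limit = 0.8;
  double uref = 1.0;
  // diagnostics
  double max_div = 0.0;
  long kfloor = 0, cg_total = 0, cg_calls = 0;
  bool pfail = false;
  std::vector<double> res_hist;

  inline int ic(int i, int j) const { return i + nx * j; }
  inline int iu(int i, int j) const { return i + (nx + 1) * j; }
  inline int iv(int i, int j) const { return i + nx * j; }

  void setup(const IntegerMatrix& fluid) {
    nx = fluid.nrow();
    ny = fluid.ncol();
    fl.assign(nx * ny, 0);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) fl[ic(i, j)] = fluid(i, j) != 0;
    u.assign((nx + 1) * ny, 0.0);
    v.assign(nx * (ny + 1), 0.0);
    us = u; vs = v;
    p.assign(nx * ny, 0.0);
    k.assign(nx * ny, 0.0);
    w.assign(nx * ny, OMEGA_FLOOR);
    nut.assign(nx * ny, 0.0);
    ut.assign((nx + 1) * ny, 0);
    vt.assign(nx * (ny + 1), 0);
    for (int j = 0; j < ny; ++j) {
      if (fl[ic(0, j)]) ut[iu(0, j)] = 2;
      if (fl[ic(nx - 1, j)]) ut[iu(nx, j)] = 3;
      for (int i = 1; i < nx; ++i)
        if (fl[ic(i - 1, j)] && fl[ic(i, j)]) ut[iu(i, j)] = 1;
    }
    for (int j = 1; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (fl[ic(i, j - 1)] && fl[ic(i, j)]) vt[iv(i, j)] = 1;
    // Poisson structure
    cid.assign(nx * ny, -1);
    cell_of.clear();
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (fl[ic(i, j)]) { cid[ic(i, j)] = (int)cell_of.size(); cell_of.push_back(ic(i, j)); }
    nf = (int)cell_of.size();
    Adiag.assign(nf, 0.0);
    nb.assign(4 * nf, -1);
    for (int id = 0; id < nf; ++id) {
      int c = cell_of[id], i = c % nx, j = c / nx;
      double d = 0.0;
      if (i > 0 && fl[ic(i - 1, j)]) { nb[4 * id] = cid[ic(i - 1, j)]; d += 1.0; }
      if (i < nx - 1 && fl[ic(i + 1, j)]) { nb[4 * id + 1] = cid[ic(i + 1, j)]; d += 1.0; }
      if (i == nx - 1) d += 2.0;  // Dirichlet p = 0 on the outlet face
      if (j > 0 && fl[ic(i, j - 1)]) { nb[4 * id + 2] = cid[ic(i, j - 1)]; d += 1.0; }
      if (j < ny - 1 && fl[ic(i, j + 1)]) { nb[4 * id + 3] = cid[ic(i, j + 1)]; d += 1.0; }
      Adiag[id] = d > 0.0 ? d : 1.0;
    }
    cg_r.assign(nf, 0.0); cg_d.assign(nf, 0.0); cg_q.assign(nf, 0.0); rhs.assign(nf, 0.0);
  }

  void matvec(const std::vector<double>& x, std::vector<double>& y) const {
    for (int id = 0; id < nf; ++id) {
      double s = Adiag[id] * x[id];
      for (int q = 0; q < 4; ++q) {
        int m = nb[4 * id + q];
        if (m >= 0) s -= x[m];
      }
      y[id] = s;
    }
  }

  // inlet Dirichlet, outlet zero-gradient plus uniform flux correction
  void apply_bc(std::vector<double>& U, const std::vector<double>& uin) {
    double qin = 0.0, qout = 0.0;
    int nout = 0;
    for (int j = 0; j < ny; ++j) {
      if (ut[iu(0, j)] == 2) { U[iu(0, j)] = uin[j]; qin += uin[j]; }
      if (ut[iu(nx, j)] == 3) {
        U[iu(nx, j)] = U[iu(nx - 1, j)];
        qout += U[iu(nx, j)];
        ++nout;
      }
    }
    if (nout > 0) {
      double corr = (qin - qout) / nout;
      for (int j = 0; j < ny; ++j)
        if (ut[iu(nx, j)] == 3) U[iu(nx, j)] += corr;
    }
  }

  // one projection step of size dt with frozen eddy viscosity
  // returns false on Poisson failure
  bool step(double dt, const std::vector<double>& uin) {
    const double hh = h * h;
    // --- momentum: u faces ---
    for (int j = 1; j < ny - 1; ++j) {
      for (int i = 1; i < nx; ++i) {
        int f = iu(i, j);
        if (ut[f] != 1) { continue; }
        double uc = u[f];
        double uw = u[iu(i - 1, j)], ue = u[iu(i + 1, j)];
        int fn = iu(i, j + 1), fs = iu(i, j - 1);
        double un = ut[fn] ? u[fn] : -uc;
        double usn = ut[fs] ? u[fs] : -uc;
        double vb = 0.25 * (v[iv(i - 1, j)] + v[iv(i, j)] +
                            v[iv(i - 1, j + 1)] + v[iv(i, j + 1)]);
        double ddx_up = uc > 0 ? (uc - uw) / h : (ue - uc) / h;
        double ddy_up = vb > 0 ? (uc - usn) / h : (un - uc) / h;
        double ddx = ddx_up, ddy = ddy_up;
        if (conv_scheme == 1) {
          ddx = blend * (ue - uw) / (2 * h) + (1 - blend) * ddx_up;
          ddy = blend * (un - usn) / (2 * h) + (1 - blend) * ddy_up;
        }
        double nue = nu;
        if (turb) nue += 0.5 * (nut[ic(i - 1, j)] + nut[ic(i, j)]);
        double lap = (ue - 2 * uc + uw + un - 2 * uc + usn) / hh;
        us[f] = uc + dt * (-(uc * ddx + vb * ddy) + nue * lap);
      }
    }
    // --- momentum: v faces ---
    for (int j = 1; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int f = iv(i, j);
        if (vt[f] != 1) continue;
        double vc = v[f];
        double vs_ = v[iv(i, j - 1)], vn = v[iv(i, j + 1)];
        double vw, ve;
        if (i == 0) vw = -vc;                       // inlet: v = 0
        else vw = vt[iv(i - 1, j)] ? v[iv(i - 1, j)] : -vc;
        if (i == nx - 1) ve = vc;                   // outlet: zero gradient
        else ve = vt[iv(i + 1, j)] ? v[iv(i + 1, j)] : -vc;
        double ub = 0.25 * (u[iu(i, j - 1)] + u[iu(i + 1, j - 1)] +
                            u[iu(i, j)] + u[iu(i + 1, j)]);
        double ddx_up = ub > 0 ? (vc - vw) / h : (ve - vc) / h;
        double ddy_up = vc > 0 ? (vc - vs_) / h : (vn - vc) / h;
        double ddx = ddx_up, ddy = ddy_up;
        if (conv_scheme == 1) {
          ddx = blend * (ve - vw) / (2 * h) + (1 - blend) * ddx_up;
          ddy = blend * (vn - vs_) / (2 * h) + (1 - blend) * ddy_up;
        }
        double nue = nu;
        if (turb) nue += 0.5 * (nut[ic(i, j - 1)] + nut[ic(i, j)]);
        double lap = (ve - 2 * vc + vw + vn - 2 * vc + vs_) / hh;
        vs[f] = vc + dt * (-(ub * ddx + vc * ddy) + nue * lap);
      }
    }
    apply_bc(us, uin);
    // --- pressure Poisson: A p = b, A = -h^2 * Laplacian ---
    double scale = rho * hh / dt;
    for (int id = 0; id < nf; ++id) {
      int c = cell_of[id], i = c % nx, j = c / nx;
      double div = (us[iu(i + 1, j)] - us[iu(i, j)] +
                    vs[iv(i, j + 1)] - vs[iv(i, j)]) / h;
      rhs[id] = -scale * div;
    }
    // target: post-projection |div| <= ptol * uref / h in every fluid cell
    double rtol = ptol * (uref / h) * scale;
    bool ok = false;
    res_hist.clear();
    for (int outer = 0; outer < max_outer && !ok; ++outer) {
      ok = cg_solve(rtol);
      double mr = 0.0;
      for (int id = 0; id < nf; ++id) mr = std::max(mr, std::fabs(cg_r[id]));
      res_hist.push_back(mr / scale * h);  // scaled divergence residual
    }
    if (!ok) { pfail = true; return false; }
    // --- correction ---
    double g = dt / (rho * h);
    for (int j = 1; j < ny - 1; ++j) {
      for (int i = 1; i < nx; ++i) {
        int f = iu(i, j);
        if (ut[f] == 1)
          u[f] = us[f] - g * (p[ic(i, j)] - p[ic(i - 1, j)]);
      }
    }
    for (int j = 0; j < ny; ++j) {
      if (ut[iu(0, j)] == 2) u[iu(0, j)] = us[iu(0, j)];
      if (ut[iu(nx, j)] == 3)
        u[iu(nx, j)] = us[iu(nx, j)] - g * (0.0 - p[ic(nx - 1, j)]) * 2.0;
    }
    for (int j = 1; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int f = iv(i, j);
        if (vt[f] == 1)
          v[f] = vs[f] - g * (p[ic(i, j)] - p[ic(i, j - 1)]);
      }
    // --- divergence diagnostic ---
    for (int id = 0; id < nf; ++id) {
      int c = cell_of[id], i = c % nx, j = c / nx;
      double div = (u[iu(i + 1, j)] - u[iu(i, j)] +
                    v[iv(i, j + 1)] - v[iv(i, j)]) / h;
      double sc = std::fabs(div) * h / uref;
      if (sc > max_div) max_div = sc;
    }
    return true;
  }

  // conjugate gradients on A p = rhs, warm-started from current p,
  // stopping on the max-norm of the residual
  bool cg_solve(double rtol) {
    std::vector<double> x(nf);
    for (int id = 0; id < nf; ++id) x[id] = p[cell_of[id]];
    matvec(x, cg_q);
    double rr = 0.0, mr = 0.0;
    for (int id = 0; id < nf; ++id) {
      cg_r[id] = rhs[id] - cg_q[id];
      cg_d[id] = cg_r[id];
      rr += cg_r[id] * cg_r[id];
      mr = std::max(mr, std::fabs(cg_r[id]));
    }
    int it = 0;
    while (mr > rtol && it < cg_max) {
      matvec(cg_d, cg_q);
      double dq = 0.0;
      for (int id = 0; id < nf; ++id) dq += cg_d[id] * cg_q[id];
      if (dq <= 0.0) break;
      double a = rr / dq;
      double rr_new = 0.0;
      mr = 0.0;
      for (int id = 0; id < nf; ++id) {
        x[id] += a * cg_d[id];
        cg_r[id] -= a * cg_q[id];
        rr_new += cg_r[id] * cg_r[id];
        mr = std::max(mr, std::fabs(cg_r[id]));
      }
      double beta = rr_new / rr;
      rr = rr_new;
      for (int id = 0; id < nf; ++id) cg_d[id] = cg_r[id] + beta * cg_d[id];
      ++it;
    }
    cg_total += it;
    ++cg_calls;
    for (int id = 0; id < nf; ++id) p[cell_of[id]] = x[id];
    return mr <= rtol;
  }

  // standard (Wilcox) k-omega update: explicit convection/diffusion and
  // production, semi-implicit destruction; wall and inlet overrides
  void komega_step(double dt, const std::vector<double>& uin) {
    int n = nx * ny;
    std::vector<double> uc(n, 0.0), vc(n, 0.0), kn(n, 0.0), wn(n, OMEGA_FLOOR);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = ic(i, j);
        if (!fl[c]) continue;
        uc[c] = 0.5 * (u[iu(i, j)] + u[iu(i + 1, j)]);
        vc[c] = 0.5 * (v[iv(i, j)] + v[iv(i, j + 1)]);
      }
    auto grad = [&](const std::vector<double>& q, int i, int j, int dim,
                    bool noslip) -> double {
      // dim 0: d/dx, dim 1: d/dy. Solid neighbours mirror the value
      // (no-slip wall halfway); open domain edges use a zero-gradient
      // ghost so inlet/outlet boundaries carry no spurious shear.
      int c = ic(i, j);
      double qp, qm;
      int ip = dim == 0 ? i + 1 : i, jp = dim == 0 ? j : j + 1;
      int im = dim == 0 ? i - 1 : i, jm = dim == 0 ? j : j - 1;
      bool inp = ip >= 0 && ip < nx && jp >= 0 && jp < ny;
      bool inm = im >= 0 && im < nx && jm >= 0 && jm < ny;
      if (inp && fl[ic(ip, jp)]) qp = q[ic(ip, jp)];
      else if (inp) qp = noslip ? -q[c] : q[c];
      else qp = q[c];
      if (inm && fl[ic(im, jm)]) qm = q[ic(im, jm)];
      else if (inm) qm = noslip ? -q[c] : q[c];
      else qm = q[c];
      return (qp - qm) / (2.0 * h);
    };
    auto lap = [&](const std::vector<double>& q, int i, int j) -> double {
      // zero-flux at walls and open boundaries
      int c = ic(i, j);
      double s = 0.0;
      const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
      for (int q4 = 0; q4 < 4; ++q4) {
        int ii = i + di[q4], jj = j + dj[q4];
        double qn = (ii >= 0 && ii < nx && jj >= 0 && jj < ny && fl[ic(ii, jj)])
                        ? q[ic(ii, jj)] : q[c];
        s += qn - q[c];
      }
      return s / (h * h);
    };
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = ic(i, j);
        if (!fl[c]) continue;
        double ux = grad(uc, i, j, 0, true), uy = grad(uc, i, j, 1, true);
        double vx = grad(vc, i, j, 0, true), vy = grad(vc, i, j, 1, true);
        double s2 = 2.0 * ux * ux + 2.0 * vy * vy + (uy + vx) * (uy + vx);
        double prod = nut[c] * s2;
        // upwind convection with zero-gradient ghosts
        auto upw = [&](const std::vector<double>& q) -> double {
          double qe = (i + 1 < nx && fl[ic(i + 1, j)]) ? q[ic(i + 1, j)] : q[c];
          double qw = (i - 1 >= 0 && fl[ic(i - 1, j)]) ? q[ic(i - 1, j)] : q[c];
          double qn2 = (j + 1 < ny && fl[ic(i, j + 1)]) ? q[ic(i, j + 1)] : q[c];
          double qs = (j - 1 >= 0 && fl[ic(i, j - 1)]) ? q[ic(i, j - 1)] : q[c];
          double cx = uc[c] > 0 ? (q[c] - qw) / h : (qe - q[c]) / h;
          double cy = vc[c] > 0 ? (q[c] - qs) / h : (qn2 - q[c]) / h;
          return uc[c] * cx + vc[c] * cy;
        };
        double dk = -upw(k) + prod + (nu + KW_SIGMA_STAR * nut[c]) * lap(k, i, j);
        double dw = -upw(w) + KW_ALPHA * s2 +
                    (nu + KW_SIGMA * nut[c]) * lap(w, i, j);
        kn[c] = (k[c] + dt * dk) / (1.0 + dt * KW_BETA_STAR * w[c]);
        wn[c] = (w[c] + dt * dw) / (1.0 + dt * KW_BETA * w[c]);
        if (kn[c] < 0.0) { kn[c] = 0.0; ++kfloor; }
        if (wn[c] < OMEGA_FLOOR) wn[c] = OMEGA_FLOOR;
      }
    // wall override: near-wall asymptote at the first cell (distance h/2)
    double wwall = 6.0 * nu / (KW_BETA * (0.5 * h) * (0.5 * h));
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = ic(i, j);
        if (!fl[c]) continue;
        bool wall = (i > 0 && !fl[ic(i - 1, j)]) ||
                    (i < nx - 1 && !fl[ic(i + 1, j)]) ||
                    (j > 0 && !fl[ic(i, j - 1)]) ||
                    (j < ny - 1 && !fl[ic(i, j + 1)]);
        if (wall) wn[c] = wwall;
        // inlet: k from turbulence intensity of the instantaneous inlet speed
        if (i == 0 && komega_inlet_bc) {
          double ui = std::fabs(uin[j]);
          double ki = 1.5 * (tin * ui) * (tin * ui);
          kn[c] = ki;
          double li = 0.07 * inlet_width;
          wn[c] = std::max(std::sqrt(std::max(ki, 0.0)) /
                               (std::pow(KW_BETA_STAR, 0.25) * li),
                           OMEGA_FLOOR);
        }
      }
    k.swap(kn);
    w.swap(wn);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = ic(i, j);
        if (!fl[c]) { nut[c] = 0.0; continue; }
        nut[c] = std::min(k[c] / std::max(w[c], OMEGA_FLOOR), nut_max);
      }
  }

  double max_speed() const {
    double m = 0.0;
    for (size_t i = 0; i < u.size(); ++i) m = std::max(m, std::fabs(u[i]));
    for (size_t i = 0; i < v.size(); ++i) m = std::max(m, std::fabs(v[i]));
    return m;
  }
  double max_nut() const {
    double m = 0.0;
    if (turb) for (int c = 0; c < nx * ny; ++c) m = std::max(m, nut[c]);
    return m;
  }
};

NumericMatrix to_mat(const std::vector<double>& x, int nr, int nc) {
  NumericMatrix m(nr, nc);
  std::copy(x.begin(), x.end(), m.begin());
  return m;
}

void from_mat(const NumericMatrix& m, std::vector<double>& x) {
  x.assign(m.begin(), m.end());
}

}  // namespace

// [[Rcpp::export]]
List cpp_run(IntegerMatrix fluid, double h, double dt,
             NumericVector sched_t, NumericMatrix sched_u,
             double t0, double t_end, NumericVector snap_times,
             Nullable<List> init, List cfg, double rho, double mu,
             double uref, double flux_t0) {
  Solver S;
  S.setup(fluid);
  S.h = h; S.rho = rho; S.mu = mu; S.nu = mu / rho;
  S.ptol = as<double>(cfg["poisson_tol"]);
  S.max_outer = as<int>(cfg["max_outer"]);
  S.cg_max = as<int>(cfg["cg_max"]);
  S.conv_scheme = as<int>(cfg["convection"]);
  S.blend = as<double>(cfg["blend"]);
  S.turb = as<int>(cfg["turb"]);
  S.nut_max = as<double>(cfg["nut_max_ratio"]) * S.nu;
  S.tin = as<double>(cfg["inlet_intensity"]);
  S.inlet_width = as<double>(cfg["inlet_width_m"]);
  S.cfl_limit = as<double>(cfg["cfl_limit"]);
  bool adaptive = as<int>(cfg["adaptive"]) != 0;
  S.uref = std::max(uref, 1e-9);

  if (init.isNotNull()) {
    List in(init);
    if (in.containsElementNamed("u") && !Rf_isNull(in["u"]))
      from_mat(in["u"], S.u);
    if (in.containsElementNamed("v") && !Rf_isNull(in["v"]))
      from_mat(in["v"], S.v);
    if (in.containsElementNamed("p") && !Rf_isNull(in["p"]))
      from_mat(in["p"], S.p);
    if (in.containsElementNamed("k") && !Rf_isNull(in["k"]))
      from_mat(in["k"], S.k);
    if (in.containsElementNamed("omega") && !Rf_isNull(in["omega"]))
      from_mat(in["omega"], S.w);
    if (in.containsElementNamed("nut") && !Rf_isNull(in["nut"]))
      from_mat(in["nut"], S.nut);
  }

  int nt = sched_t.size();
  std::vector<double> uin(S.ny, 0.0);
  auto inlet_at = [&](double t) {
    if (nt == 1) {
      for (int j = 0; j < S.ny; ++j) uin[j] = sched_u(0, j);
      return;
    }
    double tc = std::min(std::max(t, sched_t[0]), sched_t[nt - 1]);
    int a = 0;
    while (a < nt - 2 && sched_t[a + 1] < tc) ++a;
    double f = (tc - sched_t[a]) / std::max(sched_t[a + 1] - sched_t[a], 1e-300);
    f = std::min(std::max(f, 0.0), 1.0);
    for (int j = 0; j < S.ny; ++j)
      uin[j] = (1 - f) * sched_u(a, j) + f * sched_u(a + 1, j);
  };

  int nmacro = (int)std::lround((t_end - t0) / dt);
  if (nmacro < 1) nmacro = 1;
  double t = t0;
  int snap_ptr = 0;
  List snaps;
  double flux_in = 0.0, flux_out = 0.0;
  long nsub_total = 0;
  // snapshot of the initial state if requested
  while (snap_ptr < snap_times.size() && snap_times[snap_ptr] <= t0 + 1e-12) {
    snaps.push_back(List::create(
        _["t"] = t0, _["u"] = to_mat(S.u, S.nx + 1, S.ny),
        _["v"] = to_mat(S.v, S.nx, S.ny + 1),
        _["p"] = to_mat(S.p, S.nx, S.ny),
        _["k"] = S.turb ? to_mat(S.k, S.nx, S.ny) : NumericMatrix(0, 0),
        _["omega"] = S.turb ? to_mat(S.w, S.nx, S.ny) : NumericMatrix(0, 0),
        _["nut"] = S.turb ? to_mat(S.nut, S.nx, S.ny) : NumericMatrix(0, 0)));
    ++snap_ptr;
  }

  for (int m = 0; m < nmacro && !S.pfail; ++m) {
    double t_next = t0 + (m + 1) * dt;
    int nsub = 1;
    if (adaptive) {
      inlet_at(t_next);
      double umax = S.max_speed();
      for (int j = 0; j < S.ny; ++j) umax = std::max(umax, std::fabs(uin[j]));
      double numax = S.nu + S.max_nut();
      // additive advective + diffusive restriction; the diffusive factor 6
      // covers the wall-ghost stencil (coefficient 3 in the wall-normal
      // direction) with margin
      nsub = std::max(1, (int)std::ceil(dt * umax / (S.cfl_limit * h) +
                                        dt * 6.0 * numax / (0.8 * h * h)));
      if (nsub > 5000) nsub = 5000;
    }
    double dts = (t_next - t) / nsub;
    for (int s = 0; s < nsub; ++s) {
      double tn = t + dts;
      inlet_at(tn);
      if (!S.step(dts, uin)) break;
      if (S.turb) S.komega_step(dts, uin);
      if (tn > flux_t0) {
        double qi = 0.0, qo = 0.0;
        for (int j = 0; j < S.ny; ++j) {
          if (S.ut[S.iu(0, j)] == 2) qi += S.u[S.iu(0, j)];
          if (S.ut[S.iu(S.nx, j)] == 3) qo += S.u[S.iu(S.nx, j)];
        }
        flux_in += qi * h * dts;
        flux_out += qo * h * dts;
      }
      t = tn;
      ++nsub_total;
    }
    if (S.pfail) break;
    while (snap_ptr < snap_times.size() && snap_times[snap_ptr] <= t + 1e-9) {
      snaps.push_back(List::create(
          _["t"] = t, _["u"] = to_mat(S.u, S.nx + 1, S.ny),
          _["v"] = to_mat(S.v, S.nx, S.ny + 1),
          _["p"] = to_mat(S.p, S.nx, S.ny),
          _["k"] = S.turb ? to_mat(S.k, S.nx, S.ny) : NumericMatrix(0, 0),
          _["omega"] = S.turb ? to_mat(S.w, S.nx, S.ny) : NumericMatrix(0, 0),
          _["nut"] = S.turb ? to_mat(S.nut, S.nx, S.ny) : NumericMatrix(0, 0)));
      ++snap_ptr;
    }
  }

  return List::create(
      _["snapshots"] = snaps,
      _["t"] = t,
      _["u"] = to_mat(S.u, S.nx + 1, S.ny),
      _["v"] = to_mat(S.v, S.nx, S.ny + 1),
      _["p"] = to_mat(S.p, S.nx, S.ny),
      _["k"] = S.turb ? to_mat(S.k, S.nx, S.ny) : NumericMatrix(0, 0),
      _["omega"] = S.turb ? to_mat(S.w, S.nx, S.ny) : NumericMatrix(0, 0),
      _["nut"] = S.turb ? to_mat(S.nut, S.nx, S.ny) : NumericMatrix(0, 0),
      _["max_div_scaled"] = S.max_div,
      _["kfloor_events"] = (double)S.kfloor,
      _["flux_in"] = flux_in,
      _["flux_out"] = flux_out,
      _["n_substeps"] = (double)nsub_total,
      _["mean_cg_iters"] = S.cg_calls ? (double)S.cg_total / S.cg_calls : 0.0,
      _["poisson_failed"] = S.pfail,
      _["residual_history"] = wrap(S.res_hist));
}

// [[Rcpp::export]]
List cpp_komega(IntegerMatrix fluid, double h, double dt, int n_steps,
                NumericMatrix u, NumericMatrix v,
                NumericMatrix k0, NumericMatrix w0,
                double rho, double mu, double nut_max_ratio,
                double inlet_intensity, double inlet_width_m,
                NumericVector uin, int inlet_bc) {
  Solver S;
  S.setup(fluid);
  S.h = h; S.rho = rho; S.mu = mu; S.nu = mu / rho;
  S.turb = 1;
  S.komega_inlet_bc = inlet_bc != 0;
  S.nut_max = nut_max_ratio * S.nu;
  S.tin = inlet_intensity;
  S.inlet_width = inlet_width_m;
  from_mat(u, S.u);
  from_mat(v, S.v);
  from_mat(k0, S.k);
  from_mat(w0, S.w);
  for (int c = 0; c < S.nx * S.ny; ++c)
    S.nut[c] = S.fl[c] ? std::min(S.k[c] / std::max(S.w[c], OMEGA_FLOOR),
                                  S.nut_max) : 0.0;
  std::vector<double> ui(S.ny, 0.0);
  for (int j = 0; j < std::min((int)uin.size(), S.ny); ++j) ui[j] = uin[j];
  for (int s = 0; s < n_steps; ++s) S.komega_step(dt, ui);
  return List::create(_["k"] = to_mat(S.k, S.nx, S.ny),
                      _["omega"] = to_mat(S.w, S.nx, S.ny),
                      _["nut"] = to_mat(S.nut, S.nx, S.ny),
                      _["kfloor_events"] = (double)S.kfloor);
}
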