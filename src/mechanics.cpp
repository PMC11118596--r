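#include <Rcpp.h>
#include "spv_core.h"

using namespace Rcpp;

// Tissue energy, analytic forces and per-cell hydrostatic pressure for the
// two-type quadratic area/perimeter energy
//   e = sum_i K_i/2 (a_i - a0_i)^2 + G_i/2 (p_i - p0_i)^2
// in box units (box side L = sqrt(N0), unit mean initial area).

namespace {

inline void check_inputs(int n, const IntegerVector& type, const NumericMatrix& par) {
  if (par.nrow() != PAR_NROW)
    stop("parameter matrix must have %d rows", (int)PAR_NROW);
  for (int i = 0; i < n; ++i)
    if (type[i] < 0 || type[i] >= par.ncol())
      stop("type label out of range for parameter matrix");
}

} // namespace

// [[Rcpp::export(name = ".cpp_energy")]]
List cpp_energy(NumericVector x, NumericVector y, double L,
                IntegerVector type, NumericMatrix par) {
  const int n = x.size();
  check_inputs(n, type, par);
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  std::vector<VCell> cells;
  compute_voronoi(px, py, L, cells);

  NumericVector per_cell(n), areas(n), perims(n);
  double ea = 0, ep = 0;
  for (int i = 0; i < n; ++i) {
    const int t = type[i];
    const double da = cells[i].area - par(PAR_A0, t);
    const double dp = cells[i].perim - par(PAR_P0, t);
    const double wa = 0.5 * par(PAR_K, t) * da * da;
    const double wp = 0.5 * par(PAR_GAMMA, t) * dp * dp;
    per_cell[i] = wa + wp;
    ea += wa; ep += wp;
    areas[i] = cells[i].area;
    perims[i] = cells[i].perim;
  }
  return List::create(_["total"] = ea + ep, _["area_part"] = ea,
                      _["perimeter_part"] = ep, _["per_cell"] = per_cell,
                      _["areas"] = areas, _["perimeters"] = perims);
}

namespace {

// Accumulate minus-gradient contributions of one cell's energy terms into fx,
// fy. Each Voronoi vertex is the circumcenter of (generator, ownerA, ownerB);
// its Jacobians w.r.t. the three generators follow from implicit
// differentiation of the equidistance conditions and are rank-1 here.
void cell_force_contrib(const VCell& c, int i, double coefA, double coefP,
                        std::vector<double>& gx, std::vector<double>& gy) {
  const size_t nv = c.vx.size();
  for (size_t k = 0; k < nv; ++k) {
    const size_t kp = (k == 0) ? nv - 1 : k - 1;
    const size_t kn = (k + 1 == nv) ? 0 : k + 1;

    // dA/dv_k and dP/dv_k of this cell's polygon
    const double dAx = 0.5 * (c.vy[kn] - c.vy[kp]);
    const double dAy = 0.5 * (c.vx[kp] - c.vx[kn]);
    double ux = c.vx[k] - c.vx[kp], uy = c.vy[k] - c.vy[kp];
    double lu = std::sqrt(ux * ux + uy * uy);
    double wxv = c.vx[k] - c.vx[kn], wyv = c.vy[k] - c.vy[kn];
    double lw = std::sqrt(wxv * wxv + wyv * wyv);
    double dPx = 0, dPy = 0;
    if (lu > 0) { dPx += ux / lu; dPy += uy / lu; }
    if (lw > 0) { dPx += wxv / lw; dPy += wyv / lw; }

    const double gEx = coefA * dAx + coefP * dPx;
    const double gEy = coefA * dAy + coefP * dPy;

    // generator triple (origin, qa, qb) in cell-relative coordinates
    const double qax = c.ex[kp], qay = c.ey[kp];
    const double qbx = c.ex[k],  qby = c.ey[k];
    const int ba = c.eb[kp], bb = c.eb[k];
    const double det = qax * qby - qay * qbx;
    if (std::fabs(det) < 1e-12) continue; // near-collinear triple: no stable vertex motion
    const double vxk = c.vx[k], vyk = c.vy[k];

    // dv in direction e of generator g is w_g * (r_g . e) with:
    const double wax = (qby - qay) / det, way = (qax - qbx) / det; // g = cell, r = v
    const double wbx = qby / det,          wby = -qbx / det;       // g = qa,  r = qa - v
    const double wcx = -qay / det,         wcy = qax / det;        // g = qb,  r = qb - v

    const double sa = wax * gEx + way * gEy;
    gx[i] += sa * vxk;           gy[i] += sa * vyk;
    const double sb = wbx * gEx + wby * gEy;
    gx[ba] += sb * (qax - vxk);  gy[ba] += sb * (qay - vyk);
    const double sc = wcx * gEx + wcy * gEy;
    gx[bb] += sc * (qbx - vxk);  gy[bb] += sc * (qby - vyk);
  }
}

} // namespace

void spv_forces(const std::vector<double>& px, const std::vector<double>& py,
                double L, const std::vector<int>& type, const NumericMatrix& par,
                const std::vector<VCell>& cells,
                std::vector<double>& fx, std::vector<double>& fy) {
  const int n = (int)px.size();
  fx.assign(n, 0.0);
  fy.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const int t = type[i];
    const double coefA = par(PAR_K, t) * (cells[i].area - par(PAR_A0, t));
    const double coefP = par(PAR_GAMMA, t) * (cells[i].perim - par(PAR_P0, t));
    cell_force_contrib(cells[i], i, coefA, coefP, fx, fy);
  }
  for (int i = 0; i < n; ++i) { fx[i] = -fx[i]; fy[i] = -fy[i]; }
}

// [[Rcpp::export(name = ".cpp_forces")]]
List cpp_forces(NumericVector x, NumericVector y, double L,
                IntegerVector type, NumericMatrix par) {
  const int n = x.size();
  check_inputs(n, type, par);
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  std::vector<VCell> cells;
  compute_voronoi(px, py, L, cells);
  std::vector<int> ty(type.begin(), type.end());
  std::vector<double> fx, fy;
  spv_forces(px, py, L, ty, par, cells, fx, fy);

  NumericMatrix F(n, 2);
  double e = 0;
  for (int i = 0; i < n; ++i) {
    F(i, 0) = fx[i];
    F(i, 1) = fy[i];
    const int t = type[i];
    const double da = cells[i].area - par(PAR_A0, t);
    const double dp = cells[i].perim - par(PAR_P0, t);
    e += 0.5 * par(PAR_K, t) * da * da + 0.5 * par(PAR_GAMMA, t) * dp * dp;
  }
  return List::create(_["forces"] = F, _["energy"] = e);
}

// [[Rcpp::export(name = ".cpp_pressure")]]
NumericVector cpp_pressure(NumericVector x, NumericVector y, double L,
                           IntegerVector type, NumericMatrix par) {
  const int n = x.size();
  check_inputs(n, type, par);
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  std::vector<VCell> cells;
  compute_voronoi(px, py, L, cells);
  NumericVector P(n);
  for (int i = 0; i < n; ++i) {
    const int t = type[i];
    const double a = cells[i].area, p = cells[i].perim;
    P[i] = -par(PAR_K, t) * (a - par(PAR_A0, t))
         - par(PAR_GAMMA, t) * p / (2.0 * a) * (p - par(PAR_P0, t));
  }
  return P;
}
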