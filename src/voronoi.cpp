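#include <Rcpp.h>
#include <algorithm>
#include "spv_core.h"

using namespace Rcpp;

namespace {

struct Cand {
  double x, y, d2;
  int base;
};

// Clip the convex polygon by the half-plane of points closer to the cell
// generator (origin) than to candidate q: keep {v : v.q <= |q|^2/2}.
// Returns true if the polygon changed. Edge owners travel with their edges;
// the freshly cut edge is owned by q.
bool clip_halfplane(std::vector<double>& vx, std::vector<double>& vy,
                    std::vector<int>& eb,
                    std::vector<double>& ex, std::vector<double>& ey,
                    double qx, double qy, int base) {
  const double half = 0.5 * (qx * qx + qy * qy);
  const size_t n = vx.size();
  static thread_local std::vector<double> s;
  s.resize(n);
  bool any_out = false, all_out = true;
  for (size_t k = 0; k < n; ++k) {
    s[k] = qx * vx[k] + qy * vy[k] - half;
    if (s[k] > 0) any_out = true; else all_out = false;
  }
  if (!any_out) return false;
  if (all_out) ::Rf_error("voronoi: cell polygon vanished (inconsistent geometry)");

  std::vector<double> nvx, nvy, nex, ney;
  std::vector<int> neb;
  nvx.reserve(n + 2); nvy.reserve(n + 2);
  nex.reserve(n + 2); ney.reserve(n + 2); neb.reserve(n + 2);

  for (size_t k = 0; k < n; ++k) {
    const size_t k1 = (k + 1 == n) ? 0 : k + 1;
    const double sa = s[k], sb = s[k1];
    if (sa <= 0) {
      nvx.push_back(vx[k]); nvy.push_back(vy[k]);
      if (sb <= 0) {
        neb.push_back(eb[k]); nex.push_back(ex[k]); ney.push_back(ey[k]);
      } else {
        // leave through edge k at X; the cut edge (owned by q) starts at X
        neb.push_back(eb[k]); nex.push_back(ex[k]); ney.push_back(ey[k]);
        const double t = sa / (sa - sb);
        nvx.push_back(vx[k] + t * (vx[k1] - vx[k]));
        nvy.push_back(vy[k] + t * (vy[k1] - vy[k]));
        neb.push_back(base); nex.push_back(qx); ney.push_back(qy);
      }
    } else if (sb <= 0) {
      // re-enter through edge k at Y; remainder of edge k keeps its owner
      const double t = sa / (sa - sb);
      nvx.push_back(vx[k] + t * (vx[k1] - vx[k]));
      nvy.push_back(vy[k] + t * (vy[k1] - vy[k]));
      neb.push_back(eb[k]); nex.push_back(ex[k]); ney.push_back(ey[k]);
    }
  }
  vx.swap(nvx); vy.swap(nvy);
  eb.swap(neb); ex.swap(nex); ey.swap(ney);
  return true;
}

inline double max_r2(const std::vector<double>& vx, const std::vector<double>& vy) {
  double m = 0;
  for (size_t k = 0; k < vx.size(); ++k) {
    const double r2 = vx[k] * vx[k] + vy[k] * vy[k];
    if (r2 > m) m = r2;
  }
  return m;
}

void finish_cell(VCell& c) {
  const size_t n = c.vx.size();
  double A = 0, P = 0;
  for (size_t k = 0; k < n; ++k) {
    const size_t k1 = (k + 1 == n) ? 0 : k + 1;
    A += c.vx[k] * c.vy[k1] - c.vx[k1] * c.vy[k];
    const double dx = c.vx[k1] - c.vx[k], dy = c.vy[k1] - c.vy[k];
    P += std::sqrt(dx * dx + dy * dy);
  }
  c.area = 0.5 * A;
  c.perim = P;
}

} // namespace

void compute_voronoi(const std::vector<double>& px,
                     const std::vector<double>& py,
                     double L,
                     std::vector<VCell>& cells) {
  const int n = (int)px.size();
  if (n < 3) ::Rf_error("voronoi: need at least 3 cells");
  cells.assign(n, VCell());

  // Uniform grid over the box for candidate search (~2 points per grid cell).
  const int m = std::max(1, (int)std::floor(std::sqrt(n / 2.0)));
  const bool use_grid = (m >= 5);
  const double h = L / m;
  std::vector<int> head, nxt;
  std::vector<int> gx(n), gy(n);
  if (use_grid) {
    head.assign(m * m, -1);
    nxt.assign(n, -1);
    for (int j = 0; j < n; ++j) {
      int a = (int)(px[j] / h); if (a >= m) a = m - 1;
      int b = (int)(py[j] / h); if (b >= m) b = m - 1;
      gx[j] = a; gy[j] = b;
      const int cell = b * m + a;
      nxt[j] = head[cell];
      head[cell] = j;
    }
  }

  const double W = 0.75 * L;
  std::vector<Cand> cand;

  for (int i = 0; i < n; ++i) {
    VCell& c = cells[i];
    // initial bounding square (always clipped away by the 8 periodic
    // self-images, which every search path supplies)
    c.vx = { -W,  W,  W, -W };
    c.vy = { -W, -W,  W,  W };
    c.eb = { -1, -1, -1, -1 };
    c.ex = { 0, 0, 0, 0 };
    c.ey = { 0, 0, 0, 0 };
    double mr2 = 2.0 * W * W;

    if (!use_grid) {
      cand.clear();
      for (int j = 0; j < n; ++j)
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b) {
            if (j == i && a == 0 && b == 0) continue;
            const double cx = px[j] + a * L - px[i];
            const double cy = py[j] + b * L - py[i];
            const double d2 = cx * cx + cy * cy;
            if (j != i && d2 < 1e-18)
              ::Rf_error("voronoi: coincident cell centers %d and %d", i + 1, j + 1);
            cand.push_back({cx, cy, d2, j});
          }
      std::sort(cand.begin(), cand.end(),
                [](const Cand& a, const Cand& b) { return a.d2 < b.d2; });
      for (const Cand& q : cand) {
        if (q.d2 >= 4.0 * mr2) break;
        if (clip_halfplane(c.vx, c.vy, c.eb, c.ex, c.ey, q.x, q.y, q.base))
          mr2 = max_r2(c.vx, c.vy);
      }
    } else {
      const int rmax = 3 * m + 3;
      for (int r = 0; r <= rmax; ++r) {
        cand.clear();
        for (int di = -r; di <= r; ++di)
          for (int dj = -r; dj <= r; ++dj) {
            if (std::max(std::abs(di), std::abs(dj)) != r) continue;
            const int ga = gx[i] + di, gb = gy[i] + dj;
            // image shift from unwrapped grid coordinate
            const int sa = (int)std::floor((double)ga / m);
            const int sb = (int)std::floor((double)gb / m);
            const int wa = ga - sa * m, wb = gb - sb * m;
            for (int j = head[wb * m + wa]; j != -1; j = nxt[j]) {
              if (j == i && sa == 0 && sb == 0) continue;
              const double cx = px[j] + sa * L - px[i];
              const double cy = py[j] + sb * L - py[i];
              const double d2 = cx * cx + cy * cy;
              if (j != i && d2 < 1e-18)
                ::Rf_error("voronoi: coincident cell centers %d and %d", i + 1, j + 1);
              cand.push_back({cx, cy, d2, j});
            }
          }
        std::sort(cand.begin(), cand.end(),
                  [](const Cand& a, const Cand& b) { return a.d2 < b.d2; });
        for (const Cand& q : cand) {
          if (q.d2 >= 4.0 * mr2) break;
          if (clip_halfplane(c.vx, c.vy, c.eb, c.ex, c.ey, q.x, q.y, q.base))
            mr2 = max_r2(c.vx, c.vy);
        }
        // no point in ring r+1 can be closer than r*h
        const double dmin = r * h;
        if (dmin * dmin >= 4.0 * mr2) break;
        if (r == rmax)
          ::Rf_error("voronoi: candidate search did not converge (cell %d)", i + 1);
      }
    }

    for (size_t k = 0; k < c.eb.size(); ++k)
      if (c.eb[k] < 0)
        ::Rf_error("voronoi: unbounded cell %d (internal error)", i + 1);
    finish_cell(c);
    if (!(c.area > 0))
      ::Rf_error("voronoi: non-positive cell area (cell %d)", i + 1);
  }
}

// [[Rcpp::export(name = ".cpp_voronoi")]]
List cpp_voronoi(NumericVector x, NumericVector y, double L,
                 double edge_tol = 1e-9) {
  const int n = x.size();
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  std::vector<VCell> cells;
  compute_voronoi(px, py, L, cells);

  NumericVector area(n), perim(n);
  List nbrs(n), verts(n);
  for (int i = 0; i < n; ++i) {
    const VCell& c = cells[i];
    area[i] = c.area;
    perim[i] = c.perim;
    const size_t nv = c.vx.size();
    NumericMatrix vm(nv, 2);
    std::vector<int> nb;
    nb.reserve(nv);
    for (size_t k = 0; k < nv; ++k) {
      vm(k, 0) = c.vx[k] + px[i];
      vm(k, 1) = c.vy[k] + py[i];
      const size_t k1 = (k + 1 == nv) ? 0 : k + 1;
      const double dx = c.vx[k1] - c.vx[k], dy = c.vy[k1] - c.vy[k];
      if (std::sqrt(dx * dx + dy * dy) > edge_tol)
        nb.push_back(c.eb[k] + 1); // 1-based, edge order, with multiplicity
    }
    nbrs[i] = wrap(nb);
    verts[i] = vm;
  }
  return List::create(_["areas"] = area, _["perimeters"] = perim,
                      _["neighbors"] = nbrs, _["vertices"] = verts);
}
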