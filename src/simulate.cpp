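#include <Rcpp.h>
#include <algorithm>
#include "spv_core.h"

using namespace Rcpp;

void spv_forces(const std::vector<double>& px, const std::vector<double>& py,
                double L, const std::vector<int>& type, const NumericMatrix& par,
                const std::vector<VCell>& cells,
                std::vector<double>& fx, std::vector<double>& fy);

// Coupled dynamics + stochastic birth-death loop.
//
// Each step: one Voronoi tessellation; analytic forces; forward-Euler update
// of positions (mobility * force + self-propulsion) and Euler-Maruyama update
// of polarization angles; then, if a growth coupling is active, birth/death
// events are sampled with the rates frozen at this step's geometry
// (thinning: P(birth) = rb*dt, P(death) = rd*dt per cell per step).
// Division replaces the parent by two children offset by +/- d along a
// uniformly random direction (d = div_offset * sqrt(parent area)); extrusion
// removes the cell center. coupling: 0 none, 1 area (with perimeter weight
// beta), 2 pressure (relative to homeostatic pressure ph per type).
//
// All randomness uses R's RNG, so runs are reproducible via set.seed().
// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(NumericVector x0, NumericVector y0, NumericVector theta0,
                  IntegerVector type0, IntegerVector id0, double L,
                  NumericMatrix par, double dt, int n_steps, int record_every,
                  int coupling, NumericVector ph, double div_offset,
                  double t0, int next_id0, bool record_cells = false,
                  bool quiet = false) {
  const double n0_ref = L * L; // box units: initial-cell-count normalization
  std::vector<double> px(x0.begin(), x0.end()), py(y0.begin(), y0.end());
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<int> ty(type0.begin(), type0.end());
  std::vector<int> id(id0.begin(), id0.end());
  int next_id = next_id0;
  if (par.nrow() != PAR_NROW) stop("parameter matrix must have %d rows", (int)PAR_NROW);

  RNGScope rng;

  // observables
  std::vector<double> ot, oe;
  std::vector<int> oN, oNm;
  std::vector<double> oar, oam, opr, opm, oPr, oPm, ogr, ogm;
  // event log
  std::vector<double> ev_t;
  std::vector<int> ev_kind, ev_cell, ev_child1, ev_child2;
  // optional per-cell records
  std::vector<double> ct, ca, cp;
  std::vector<int> ctyp;

  long rate_warn = 0, refuse_warn = 0;
  std::vector<VCell> cells;
  std::vector<double> fx, fy, rb, rd;

  auto record = [&](double t, const std::vector<VCell>& cl,
                    const std::vector<double>& rbv, const std::vector<double>& rdv,
                    bool have_rates) {
    const int n = (int)px.size();
    double e = 0;
    double sa[2] = {0, 0}, sp[2] = {0, 0}, sP[2] = {0, 0}, sg[2] = {0, 0};
    int cnt[2] = {0, 0};
    for (int i = 0; i < n; ++i) {
      const int t_ = ty[i];
      const double a = cl[i].area, p = cl[i].perim;
      const double da = a - par(PAR_A0, t_), dp = p - par(PAR_P0, t_);
      e += 0.5 * par(PAR_K, t_) * da * da + 0.5 * par(PAR_GAMMA, t_) * dp * dp;
      sa[t_] += a; sp[t_] += p;
      sP[t_] += -par(PAR_K, t_) * da - par(PAR_GAMMA, t_) * p / (2 * a) * dp;
      if (have_rates) sg[t_] += rbv[i] - rdv[i];
      cnt[t_]++;
    }
    ot.push_back(t); oN.push_back(n); oNm.push_back(cnt[1]); oe.push_back(e);
    oar.push_back(cnt[0] ? sa[0] / cnt[0] : NA_REAL);
    oam.push_back(cnt[1] ? sa[1] / cnt[1] : NA_REAL);
    opr.push_back(cnt[0] ? sp[0] / cnt[0] : NA_REAL);
    opm.push_back(cnt[1] ? sp[1] / cnt[1] : NA_REAL);
    oPr.push_back(cnt[0] ? sP[0] / cnt[0] : NA_REAL);
    oPm.push_back(cnt[1] ? sP[1] / cnt[1] : NA_REAL);
    ogr.push_back(cnt[0] && have_rates ? sg[0] / cnt[0] : NA_REAL);
    ogm.push_back(cnt[1] && have_rates ? sg[1] / cnt[1] : NA_REAL);
    if (record_cells)
      for (int i = 0; i < n; ++i) {
        ct.push_back(t); ca.push_back(cl[i].area); cp.push_back(cl[i].perim);
        ctyp.push_back(ty[i]);
      }
  };

  double t = t0;
  for (int step = 0; step <= n_steps; ++step) {
    const int n = (int)px.size();
    compute_voronoi(px, py, L, cells);

    // rates frozen at this step's geometry
    const bool have_rates = coupling > 0;
    if (have_rates) {
      rb.assign(n, 0.0); rd.assign(n, 0.0);
      for (int i = 0; i < n; ++i) {
        const int t_ = ty[i];
        double xdev;
        if (coupling == 1) {
          xdev = (cells[i].area - par(PAR_A0, t_))
               + par(PAR_BETA, t_) * (cells[i].perim - par(PAR_P0, t_));
        } else {
          const double a = cells[i].area, p = cells[i].perim;
          const double Pi = -par(PAR_K, t_) * (a - par(PAR_A0, t_))
                          - par(PAR_GAMMA, t_) * p / (2 * a) * (p - par(PAR_P0, t_));
          xdev = Pi - ph[t_];
        }
        const double lam = par(PAR_LAM, t_);
        rb[i] = par(PAR_RB0, t_) + lam * std::max(0.0, xdev);
        rd[i] = par(PAR_RD0, t_) - lam * std::min(0.0, xdev);
        if ((rb[i] + rd[i]) * dt > 0.1) rate_warn++;
      }
    }

    if (step % record_every == 0 || step == n_steps)
      record(t, cells, rb, rd, have_rates);
    if (step == n_steps) break;

    // forces + forward Euler / Euler-Maruyama
    spv_forces(px, py, L, ty, par, cells, fx, fy);
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(fx[i]) || !std::isfinite(fy[i]))
        stop("non-finite force on cell %d at t = %g", i + 1, t);
      const int t_ = ty[i];
      px[i] = wrap_coord(px[i] + dt * (par(PAR_MU, t_) * fx[i]
                                       + par(PAR_V0, t_) * std::cos(th[i])), L);
      py[i] = wrap_coord(py[i] + dt * (par(PAR_MU, t_) * fy[i]
                                       + par(PAR_V0, t_) * std::sin(th[i])), L);
      th[i] += std::sqrt(2.0 * par(PAR_DR, t_) * dt) * norm_rand();
    }
    t += dt;

    if (have_rates) {
      // sample events for every cell, then apply (births first, then deaths)
      std::vector<int> births, deaths;
      for (int i = 0; i < n; ++i) {
        const double u = unif_rand();
        if (u < rb[i] * dt) births.push_back(i);
        else if (u < (rb[i] + rd[i]) * dt) deaths.push_back(i);
      }
      for (int i : births) {
        const double d = div_offset * std::sqrt(cells[i].area);
        double cx1, cy1, cx2, cy2;
        bool ok = false;
        for (int tries = 0; tries < 32 && !ok; ++tries) {
          const double phi = 2.0 * M_PI * unif_rand(); // division-plane angle
          const double nxv = -std::sin(phi), nyv = std::cos(phi);
          cx1 = wrap_coord(px[i] + d * nxv, L); cy1 = wrap_coord(py[i] + d * nyv, L);
          cx2 = wrap_coord(px[i] - d * nxv, L); cy2 = wrap_coord(py[i] - d * nyv, L);
          ok = true;
          for (size_t j = 0; j < px.size(); ++j) {
            if ((int)j == i) continue;
            double dx = std::fabs(cx1 - px[j]); dx = std::min(dx, L - dx);
            double dy = std::fabs(cy1 - py[j]); dy = std::min(dy, L - dy);
            if (dx * dx + dy * dy < 1e-18) { ok = false; break; }
            dx = std::fabs(cx2 - px[j]); dx = std::min(dx, L - dx);
            dy = std::fabs(cy2 - py[j]); dy = std::min(dy, L - dy);
            if (dx * dx + dy * dy < 1e-18) { ok = false; break; }
          }
        }
        if (!ok) stop("division placement failed after 32 attempts");
        const int parent = id[i];
        ev_t.push_back(t); ev_kind.push_back(1); ev_cell.push_back(parent);
        ev_child1.push_back(next_id); ev_child2.push_back(next_id + 1);
        // parent slot becomes child 1, child 2 is appended
        px[i] = cx1; py[i] = cy1; id[i] = next_id++;
        th[i] = 2.0 * M_PI * unif_rand();
        px.push_back(cx2); py.push_back(cy2);
        th.push_back(2.0 * M_PI * unif_rand());
        ty.push_back(ty[i]); id.push_back(next_id++);
      }
      if (!deaths.empty()) {
        std::sort(deaths.begin(), deaths.end(), std::greater<int>());
        for (int i : deaths) {
          if ((int)px.size() <= 3) { refuse_warn++; continue; }
          ev_t.push_back(t); ev_kind.push_back(2); ev_cell.push_back(id[i]);
          ev_child1.push_back(NA_INTEGER); ev_child2.push_back(NA_INTEGER);
          px.erase(px.begin() + i); py.erase(py.begin() + i);
          th.erase(th.begin() + i); ty.erase(ty.begin() + i);
          id.erase(id.begin() + i);
        }
      }
    }
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  if (!quiet && rate_warn > 0)
    Rcpp::warning("total event rate * dt exceeded 0.1 for %ld cell-steps; "
                  "the frozen-rate approximation degrades (reduce dt)", rate_warn);
  if (!quiet && refuse_warn > 0)
    Rcpp::warning("%ld death events skipped to keep at least 3 cells", refuse_warn);

  NumericVector ofrac(ot.size());
  for (size_t k = 0; k < ot.size(); ++k) ofrac[k] = (double)oNm[k] / oN[k];
  CharacterVector ev_name(ev_kind.size());
  for (size_t q = 0; q < ev_kind.size(); ++q)
    ev_name[q] = ev_kind[q] == 1 ? "birth" : "death";

  DataFrame obs = DataFrame::create(
      _["time"] = ot, _["n"] = oN, _["n_mutant"] = oNm,
      _["f"] = ofrac,
      _["energy"] = oe,
      _["mean_area_resident"] = oar, _["mean_area_mutant"] = oam,
      _["mean_perim_resident"] = opr, _["mean_perim_mutant"] = opm,
      _["mean_pressure_resident"] = oPr, _["mean_pressure_mutant"] = oPm,
      _["mean_growth_resident"] = ogr, _["mean_growth_mutant"] = ogm);

  DataFrame events = DataFrame::create(
      _["time"] = ev_t, _["event"] = ev_name,
      _["cell_id"] = ev_cell, _["child1"] = ev_child1, _["child2"] = ev_child2);

  List out = List::create(
      _["x"] = wrap(px), _["y"] = wrap(py), _["theta"] = wrap(th),
      _["type"] = wrap(ty), _["id"] = wrap(id), _["time"] = t,
      _["next_id"] = next_id, _["observables"] = obs, _["events"] = events);
  if (record_cells)
    out["cell_records"] = DataFrame::create(
        _["time"] = ct, _["type"] = ctyp, _["area"] = ca, _["perimeter"] = cp);
  (void)n0_ref;
  return out;
}
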