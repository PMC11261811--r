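// Event-driven (discontinuous) molecular dynamics core.
//
// Beads move ballistically between discrete events: hard-core collisions,
// square-well captures/escapes, hard reflections at bond-window walls,
// Andersen-thermostat ghost collisions, and trajectory snapshots. All
// randomness comes from R's RNG so runs are reproducible under set.seed().
//
// Units: length Angstrom, mass amu, energy kcal/mol; the time unit is
// A * sqrt(amu / (kcal/mol)) ~ 48.9 fs.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

enum EvType { EV_PAIR = 0, EV_BOND = 1, EV_GHOST = 2, EV_RECHECK = 3,
              EV_FRAME = 4, EV_SYNC = 5, EV_CELL = 6 };

struct Event {
  double t;
  int a, b;
  int type;
  long ca, cb;
};

struct EventCmp {
  bool operator()(const Event& x, const Event& y) const { return x.t > y.t; }
};

static inline long long pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

class DMD {
public:
  int n;
  std::vector<double> px, py, pz, vx, vy, vz, tloc, mass;
  std::vector<int> type, chain;
  std::vector<long> cnt;
  int ntype;
  std::vector<double> sigma2, wellr, wellr2, eps;  // ntype x ntype
  std::vector<char> inter_only;
  double L, halfL;
  bool pbc;
  double kT, ghost_rate;
  std::unordered_map<long long, int> bond_of;  // pair key -> bond index
  std::vector<double> bond_rmin2, bond_rmax2;
  std::unordered_set<long long> excl;
  std::unordered_set<long long> inwell;
  int bond_span;          // max |i-j| over bonds/exclusions (quick reject)
  bool intra_topo;        // bonds/exclusions are all intra-chain
  double horizon;         // scheduling window; a global resync re-predicts
  // cell lists (used when the box holds >= 3 cells of the interaction
  // range): nonbonded events are discovered within a 27-cell stencil and
  // at cell-boundary crossings; bonded pairs via the adjacency list
  bool use_cells;
  int ncell;
  double csize;
  std::vector<std::vector<int> > cells;
  std::vector<int> cell_of;
  std::vector<std::vector<int> > topo_adj;
  double U;  // potential energy (sum of -eps over occupied wells)
  double tnow;
  std::priority_queue<Event, std::vector<Event>, EventCmp> q;

  // logs
  std::vector<double> ev_t;
  std::vector<int> ev_a, ev_b;
  std::vector<std::string> ev_kind;
  int max_log;
  std::vector<double> ghost_log;
  int max_ghost_log;

  long n_events;

  double tab(const std::vector<double>& m, int a, int b) const {
    return m[type[a] * ntype + type[b]];
  }

  inline double wrap(double d) const {
    if (!pbc) return d;
    while (d > halfL) d -= L;
    while (d < -halfL) d += L;
    return d;
  }

  void rel(int i, int j, double t, double& dx, double& dy, double& dz,
           double& dvx, double& dvy, double& dvz) const {
    double xi = px[i] + vx[i] * (t - tloc[i]);
    double yi = py[i] + vy[i] * (t - tloc[i]);
    double zi = pz[i] + vz[i] * (t - tloc[i]);
    double xj = px[j] + vx[j] * (t - tloc[j]);
    double yj = py[j] + vy[j] * (t - tloc[j]);
    double zj = pz[j] + vz[j] * (t - tloc[j]);
    dx = wrap(xj - xi); dy = wrap(yj - yi); dz = wrap(zj - zi);
    dvx = vx[j] - vx[i]; dvy = vy[j] - vy[i]; dvz = vz[j] - vz[i];
  }

  void advance(int i, double t) {
    px[i] += vx[i] * (t - tloc[i]);
    py[i] += vy[i] * (t - tloc[i]);
    pz[i] += vz[i] * (t - tloc[i]);
    if (pbc) {
      px[i] -= L * std::floor(px[i] / L);
      py[i] -= L * std::floor(py[i] / L);
      pz[i] -= L * std::floor(pz[i] / L);
    }
    tloc[i] = t;
  }

  // earliest positive root of |dr + dv t|^2 = R2, approaching branch
  static double t_approach(double d2, double b, double a, double R2) {
    if (b >= 0 || a <= 0) return INF;
    double disc = b * b - a * (d2 - R2);
    if (disc <= 0) return INF;
    double t = (-b - std::sqrt(disc)) / a;
    if (t < 0) t = 0;
    return t;
  }

  // outward crossing of R2 (from inside), always exists when d2 < R2
  static double t_leave(double d2, double b, double a, double R2) {
    if (a <= 0) return INF;
    double disc = b * b - a * (d2 - R2);
    if (disc < 0) disc = 0;
    double t = (-b + std::sqrt(disc)) / a;
    if (t < 0) t = 0;
    return t;
  }

  // time until the minimum-image vector changes image in any component
  double t_image(double dx, double dy, double dz,
                 double dvx, double dvy, double dvz) const {
    if (!pbc) return INF;
    double tmin = INF;
    double d[3] = {dx, dy, dz};
    double v[3] = {dvx, dvy, dvz};
    for (int k = 0; k < 3; k++) {
      if (v[k] > 1e-14) tmin = std::min(tmin, (halfL - d[k]) / v[k]);
      else if (v[k] < -1e-14) tmin = std::min(tmin, (-halfL - d[k]) / v[k]);
    }
    return std::max(tmin, 0.0);
  }

  // topology (bond / exclusion) pairs are only possible within
  // bond_span indices on the same chain, so most pairs skip the hashes
  bool maybe_topo(int i, int j) const {
    if (intra_topo && chain[i] != chain[j]) return false;
    return std::abs(i - j) <= bond_span;
  }

  // schedule the next event of pair (i, j); only events no later than
  // tmax are pushed - later ones are rediscovered at the global resync
  void predict_pair(int i, int j, double t, double tmax) {
    long long key = pkey(i, j, n);
    bool topo = maybe_topo(i, j);
    if (topo && excl.count(key)) return;
    double dx, dy, dz, dvx, dvy, dvz;
    double t0 = std::max(tloc[i], tloc[j]);
    if (t0 < t) t0 = t;
    rel(i, j, t0, dx, dy, dz, dvx, dvy, dvz);
    double d2 = dx * dx + dy * dy + dz * dz;
    double b = dx * dvx + dy * dvy + dz * dvz;
    double a = dvx * dvx + dvy * dvy + dvz * dvz;

    if (topo) {
      auto it = bond_of.find(key);
      if (it != bond_of.end()) {
        int bi = it->second;
        double tin = t_approach(d2, b, a, bond_rmin2[bi]);
        double tout = t_leave(d2, b, a, bond_rmax2[bi]);
        double te = std::min(tin, tout);
        if (t0 + te <= tmax) q.push({t0 + te, i, j, EV_BOND, cnt[i], cnt[j]});
        return;
      }
    }

    double s2 = tab(sigma2, i, j);
    double w2 = tab(wellr2, i, j);
    bool has_well = w2 > 0 &&
      (!inter_only[type[i] * ntype + type[j]] || chain[i] != chain[j]);
    if (has_well && inwell.count(key)) {
      double tc = t_approach(d2, b, a, s2);
      double tx = t_leave(d2, b, a, w2);
      double te = std::min(tc, tx);
      // occupied wells are short-ranged: always keep their next event
      if (te < INF) q.push({t0 + te, i, j, EV_PAIR, cnt[i], cnt[j]});
      return;
    }
    double R2 = has_well ? w2 : s2;
    double th = t_approach(d2, b, a, R2);
    double timg = t_image(dx, dy, dz, dvx, dvy, dvz);
    if (th < INF && th <= timg) {
      if (t0 + th <= tmax) q.push({t0 + th, i, j, EV_PAIR, cnt[i], cnt[j]});
    } else if (pbc && timg < th && t0 + timg + 1e-9 <= tmax) {
      q.push({t0 + timg + 1e-9, i, j, EV_RECHECK, cnt[i], cnt[j]});
    }
  }

  void predict_all_for(int i, double t) {
    double tmax = t + horizon;
    for (int j = 0; j < n; j++) {
      if (j != i) predict_pair(std::min(i, j), std::max(i, j), t, tmax);
    }
  }

  int cell_linear(int cx, int cy, int cz) const {
    cx = (cx % ncell + ncell) % ncell;
    cy = (cy % ncell + ncell) % ncell;
    cz = (cz % ncell + ncell) % ncell;
    return cx + ncell * (cy + ncell * cz);
  }

  int cell_at(double x, double y, double z) const {
    int cx = std::min((int)std::floor(x / csize), ncell - 1);
    int cy = std::min((int)std::floor(y / csize), ncell - 1);
    int cz = std::min((int)std::floor(z / csize), ncell - 1);
    if (cx < 0) cx = 0; if (cy < 0) cy = 0; if (cz < 0) cz = 0;
    return cx + ncell * (cy + ncell * cz);
  }

  void cell_remove(int i) {
    std::vector<int>& v = cells[cell_of[i]];
    for (size_t k = 0; k < v.size(); k++) {
      if (v[k] == i) { v[k] = v.back(); v.pop_back(); break; }
    }
  }

  // predict i against every bead in its 27-cell stencil plus its bonded
  // partners (which may lie outside the stencil only transiently)
  void predict_neighbors(int i, double t, bool only_greater = false) {
    double tmax = t + (only_greater ? 1.05 : 1.0) * horizon;
    if (!only_greater) {
      for (size_t k = 0; k < topo_adj[i].size(); k++) {
        int j = topo_adj[i][k];
        predict_pair(std::min(i, j), std::max(i, j), t, tmax);
      }
    }
    int c = cell_of[i];
    int cx = c % ncell, cy = (c / ncell) % ncell, cz = c / (ncell * ncell);
    for (int dx = -1; dx <= 1; dx++) {
      for (int dy = -1; dy <= 1; dy++) {
        for (int dz = -1; dz <= 1; dz++) {
          const std::vector<int>& v = cells[cell_linear(cx + dx, cy + dy, cz + dz)];
          for (size_t k = 0; k < v.size(); k++) {
            int j = v[k];
            if (j == i || (only_greater && j < i)) continue;
            if (maybe_topo(i, j)) {
              long long key = pkey(i, j, n);
              if (excl.count(key) || bond_of.count(key)) continue;
            }
            predict_pair(std::min(i, j), std::max(i, j), t, tmax);
          }
        }
      }
    }
  }

  // periodic stencil-limited re-prediction: recovers any pair event that
  // was beyond the scheduling horizon when last examined
  void resync_cells(double t) {
    for (int i = 0; i < n; i++) {
      for (size_t k = 0; k < topo_adj[i].size(); k++) {
        int j = topo_adj[i][k];
        if (j > i) predict_pair(i, j, t, t + 1.05 * horizon);
      }
      predict_neighbors(i, t, true);
    }
  }

  // next crossing of the bead's current cell boundary
  void push_cell_event(int i, double t) {
    double x = px[i] + vx[i] * (t - tloc[i]);
    double y = py[i] + vy[i] * (t - tloc[i]);
    double z = pz[i] + vz[i] * (t - tloc[i]);
    int c = cell_of[i];
    int cx = c % ncell, cy = (c / ncell) % ncell, cz = c / (ncell * ncell);
    double tmin = INF;
    double p3[3] = {x, y, z};
    double v3[3] = {vx[i], vy[i], vz[i]};
    int c3[3] = {cx, cy, cz};
    for (int k = 0; k < 3; k++) {
      if (v3[k] > 1e-14) {
        double edge = (c3[k] + 1) * csize;
        tmin = std::min(tmin, (edge - p3[k]) / v3[k]);
      } else if (v3[k] < -1e-14) {
        double edge = c3[k] * csize;
        tmin = std::min(tmin, (edge - p3[k]) / v3[k]);
      }
    }
    if (tmin < 0) tmin = 0;
    if (tmin < INF) q.push({t + tmin + 1e-12, i, -1, EV_CELL, cnt[i], 0});
  }

  void handle_cell(const Event& e) {
    int i = e.a;
    advance(i, e.t);
    int newc = cell_at(px[i] + vx[i] * 1e-9,
                       py[i] + vy[i] * 1e-9,
                       pz[i] + vz[i] * 1e-9);
    if (newc != cell_of[i]) {
      cell_remove(i);
      cell_of[i] = newc;
      cells[newc].push_back(i);
      predict_neighbors(i, e.t);
    }
    push_cell_event(i, e.t);
  }

  void repredict(int i, double t) {
    if (use_cells) {
      predict_neighbors(i, t);
      push_cell_event(i, t);
    } else {
      predict_all_for(i, t);
    }
  }

  void resync(double t) {
    double tmax = t + 1.05 * horizon;
    for (int i = 0; i < n; i++) {
      for (int j = i + 1; j < n; j++) predict_pair(i, j, t, tmax);
    }
  }

  void log_event(double t, int a, int b, const char* kind) {
    if ((int)ev_t.size() >= max_log) return;
    ev_t.push_back(t); ev_a.push_back(a); ev_b.push_back(b);
    ev_kind.push_back(kind);
  }

  // apply radial impulse so relative radial velocity becomes vr_new
  void radial_impulse(int i, int j, double nx, double ny, double nz,
                      double vr, double vr_new) {
    double mu = mass[i] * mass[j] / (mass[i] + mass[j]);
    double J = mu * (vr_new - vr);
    vx[i] -= J / mass[i] * nx; vy[i] -= J / mass[i] * ny;
    vz[i] -= J / mass[i] * nz;
    vx[j] += J / mass[j] * nx; vy[j] += J / mass[j] * ny;
    vz[j] += J / mass[j] * nz;
  }

  void handle_pair(const Event& e) {
    int i = e.a, j = e.b;
    advance(i, e.t); advance(j, e.t);
    double dx, dy, dz, dvx, dvy, dvz;
    rel(i, j, e.t, dx, dy, dz, dvx, dvy, dvz);
    double d2 = dx * dx + dy * dy + dz * dz;
    double d = std::sqrt(d2);
    if (d < 1e-12) stop("coincident beads at a pair event");
    double nx = dx / d, ny = dy / d, nz = dz / d;
    double vr = dvx * nx + dvy * ny + dvz * nz;
    long long key = pkey(i, j, n);
    double mu = mass[i] * mass[j] / (mass[i] + mass[j]);

    if (e.type == EV_BOND) {
      // hard reflection at either bond wall
      radial_impulse(i, j, nx, ny, nz, vr, -vr);
      log_event(e.t, i, j, "bond");
    } else {
      double s2 = tab(sigma2, i, j);
      double w2 = tab(wellr2, i, j);
      bool has_well = w2 > 0 &&
        (!inter_only[type[i] * ntype + type[j]] || chain[i] != chain[j]);
      double ep = has_well ? tab(eps, i, j) : 0.0;
      bool inside = has_well && inwell.count(key);
      bool at_core = !has_well ||
        (inside && std::fabs(d2 - s2) < std::fabs(d2 - w2));
      if (at_core) {
        radial_impulse(i, j, nx, ny, nz, vr, -vr);
        log_event(e.t, i, j, "core");
      } else if (!inside) {
        // capture: fall into the well, radial KE increases by eps
        double vr_new = -std::sqrt(vr * vr + 2.0 * ep / mu);
        radial_impulse(i, j, nx, ny, nz, vr, vr_new);
        inwell.insert(key);
        U -= ep;
        log_event(e.t, i, j, "capture");
      } else {
        // escape attempt at the outer well edge
        if (vr * vr >= 2.0 * ep / mu) {
          double vr_new = std::sqrt(vr * vr - 2.0 * ep / mu);
          radial_impulse(i, j, nx, ny, nz, vr, vr_new);
          inwell.erase(key);
          U += ep;
          log_event(e.t, i, j, "escape");
        } else {
          radial_impulse(i, j, nx, ny, nz, vr, -vr);
          log_event(e.t, i, j, "bounce");
        }
      }
    }
    cnt[i]++; cnt[j]++;
    repredict(i, e.t);
    repredict(j, e.t);
  }

  void handle_ghost(const Event& e) {
    int i = e.a;
    advance(i, e.t);
    double sd = std::sqrt(kT / mass[i]);
    vx[i] = norm_rand() * sd;
    vy[i] = norm_rand() * sd;
    vz[i] = norm_rand() * sd;
    // logged as standard-normal deviates (v / sd) so the thermostat can
    // be tested against N(0,1) across beads of different mass
    if ((int)ghost_log.size() + 3 <= max_ghost_log) {
      ghost_log.push_back(vx[i] / sd);
      ghost_log.push_back(vy[i] / sd);
      ghost_log.push_back(vz[i] / sd);
    }
    cnt[i]++;
    repredict(i, e.t);
    q.push({e.t + exp_rand() / ghost_rate, i, -1, EV_GHOST, 0, 0});
  }

  double kinetic() const {
    double ke = 0;
    for (int i = 0; i < n; i++) {
      ke += 0.5 * mass[i] *
        (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    }
    return ke;
  }
};

// [[Rcpp::export(name = ".dmd_run")]]
List dmd_run(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
             IntegerVector type, IntegerVector chain,
             NumericMatrix sigma_tbl, NumericMatrix wellr_tbl,
             NumericMatrix eps_tbl, LogicalMatrix inter_only_tbl,
             NumericMatrix bonds, NumericMatrix excl_pairs,
             double box, bool pbc, double kT, double ghost_rate,
             double t_end, double frame_interval,
             double max_events = 5e7, int max_log = 0,
             int max_ghost_log = 0, double horizon = 5.0) {
  DMD S;
  S.n = pos.nrow();
  S.ntype = sigma_tbl.nrow();
  S.L = box; S.halfL = box / 2.0; S.pbc = pbc;
  S.kT = kT; S.ghost_rate = ghost_rate;
  S.U = 0; S.tnow = 0; S.n_events = 0;
  S.max_log = max_log; S.max_ghost_log = max_ghost_log;
  S.horizon = horizon > 0 ? horizon : t_end;

  S.px.resize(S.n); S.py.resize(S.n); S.pz.resize(S.n);
  S.vx.resize(S.n); S.vy.resize(S.n); S.vz.resize(S.n);
  S.tloc.assign(S.n, 0.0);
  S.mass.resize(S.n); S.type.resize(S.n); S.chain.resize(S.n);
  S.cnt.assign(S.n, 0);
  for (int i = 0; i < S.n; i++) {
    S.px[i] = pos(i, 0); S.py[i] = pos(i, 1); S.pz[i] = pos(i, 2);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    S.mass[i] = mass[i]; S.type[i] = type[i]; S.chain[i] = chain[i];
  }
  int nt = S.ntype;
  S.sigma2.resize(nt * nt); S.wellr.resize(nt * nt);
  S.wellr2.resize(nt * nt); S.eps.resize(nt * nt);
  S.inter_only.resize(nt * nt);
  for (int a = 0; a < nt; a++) {
    for (int b = 0; b < nt; b++) {
      S.sigma2[a * nt + b] = sigma_tbl(a, b) * sigma_tbl(a, b);
      S.wellr[a * nt + b] = wellr_tbl(a, b);
      S.wellr2[a * nt + b] = wellr_tbl(a, b) * wellr_tbl(a, b);
      S.eps[a * nt + b] = eps_tbl(a, b);
      S.inter_only[a * nt + b] = inter_only_tbl(a, b);
    }
  }
  for (int k = 0; k < bonds.nrow(); k++) {
    int i = (int)bonds(k, 0), j = (int)bonds(k, 1);
    long long key = pkey(i, j, S.n);
    S.bond_of[key] = k;
    S.bond_rmin2.push_back(bonds(k, 2) * bonds(k, 2));
    S.bond_rmax2.push_back(bonds(k, 3) * bonds(k, 3));
  }
  S.bond_span = 0;
  S.intra_topo = true;
  for (int k = 0; k < bonds.nrow(); k++) {
    int i = (int)bonds(k, 0), j = (int)bonds(k, 1);
    S.bond_span = std::max(S.bond_span, std::abs(i - j));
    if (S.chain[i] != S.chain[j]) S.intra_topo = false;
  }
  for (int k = 0; k < excl_pairs.nrow(); k++) {
    int i = (int)excl_pairs(k, 0), j = (int)excl_pairs(k, 1);
    S.excl.insert(pkey(i, j, S.n));
    S.bond_span = std::max(S.bond_span, std::abs(i - j));
    if (S.chain[i] != S.chain[j]) S.intra_topo = false;
  }

  // initial validation + well occupancy + predictions
  for (int i = 0; i < S.n; i++) {
    for (int j = i + 1; j < S.n; j++) {
      long long key = pkey(i, j, S.n);
      if (S.excl.count(key)) continue;
      double dx, dy, dz, dvx, dvy, dvz;
      S.rel(i, j, 0.0, dx, dy, dz, dvx, dvy, dvz);
      double d2 = dx * dx + dy * dy + dz * dz;
      auto it = S.bond_of.find(key);
      if (it != S.bond_of.end()) {
        int bi = it->second;
        if (d2 < S.bond_rmin2[bi] * (1 - 1e-9) ||
            d2 > S.bond_rmax2[bi] * (1 + 1e-9)) {
          stop("initial bond %d-%d outside its window", i + 1, j + 1);
        }
      } else {
        double s2 = S.tab(S.sigma2, i, j);
        if (d2 < s2 * (1 - 1e-9)) {
          stop("initial hard-core overlap between beads %d and %d",
               i + 1, j + 1);
        }
        double w2 = S.tab(S.wellr2, i, j);
        bool has_well = w2 > 0 &&
          (!S.inter_only[S.type[i] * nt + S.type[j]] ||
           S.chain[i] != S.chain[j]);
        if (has_well && d2 < w2) {
          S.inwell.insert(key);
          S.U -= S.tab(S.eps, i, j);
        }
      }
    }
  }
  // interaction range -> cell-list mode if the box holds >= 3 cells
  double rint = 0;
  for (int a = 0; a < nt * nt; a++) {
    rint = std::max(rint, std::sqrt(S.sigma2[a]));
    rint = std::max(rint, S.wellr[a]);
  }
  S.topo_adj.assign(S.n, std::vector<int>());
  for (std::unordered_map<long long, int>::iterator it = S.bond_of.begin();
       it != S.bond_of.end(); ++it) {
    int i = (int)(it->first / S.n), j = (int)(it->first % S.n);
    S.topo_adj[i].push_back(j);
    S.topo_adj[j].push_back(i);
  }
  S.use_cells = pbc && rint > 0 && std::floor(box / rint) >= 3;
  if (S.use_cells) {
    S.ncell = (int)std::floor(box / rint);
    if (S.ncell > 40) S.ncell = 40;
    S.csize = box / S.ncell;
    S.cells.assign(S.ncell * S.ncell * S.ncell, std::vector<int>());
    S.cell_of.resize(S.n);
    for (int i = 0; i < S.n; i++) {
      S.cell_of[i] = S.cell_at(S.px[i], S.py[i], S.pz[i]);
      S.cells[S.cell_of[i]].push_back(i);
    }
    for (int i = 0; i < S.n; i++) {
      S.predict_neighbors(i, 0.0);
      S.push_cell_event(i, 0.0);
    }
    S.q.push({S.horizon, -1, -1, EV_SYNC, 0, 0});
  } else {
    S.resync(0.0);
    S.q.push({S.horizon, -1, -1, EV_SYNC, 0, 0});
  }
  if (ghost_rate > 0 && kT > 0) {
    for (int i = 0; i < S.n; i++) {
      S.q.push({exp_rand() / ghost_rate, i, -1, EV_GHOST, 0, 0});
    }
  }
  double next_frame = frame_interval > 0 ? frame_interval : t_end;
  S.q.push({std::min(next_frame, t_end), -1, -1, EV_FRAME, 0, 0});

  std::vector<NumericMatrix> frames;
  std::vector<double> frame_times, frame_ke, frame_u;
  double E0 = S.kinetic() + S.U;
  double max_drift = 0;

  bool done = false;
  while (!done) {
    if (S.q.empty()) stop("event queue ran dry before t_end");
    Event e = S.q.top(); S.q.pop();
    if (e.t < S.tnow - 1e-9) stop("event-time regression (internal error)");
    if (e.type == EV_PAIR || e.type == EV_BOND || e.type == EV_RECHECK) {
      if (S.cnt[e.a] != e.ca || S.cnt[e.b] != e.cb) continue;  // stale
    }
    if (e.type == EV_CELL && S.cnt[e.a] != e.ca) continue;  // stale
    S.tnow = std::max(S.tnow, e.t);
    switch (e.type) {
    case EV_FRAME: {
      double tf = e.t;
      for (int i = 0; i < S.n; i++) S.advance(i, tf);
      NumericMatrix fr(S.n, 3);
      for (int i = 0; i < S.n; i++) {
        fr(i, 0) = S.px[i]; fr(i, 1) = S.py[i]; fr(i, 2) = S.pz[i];
      }
      frames.push_back(fr);
      frame_times.push_back(tf);
      frame_ke.push_back(S.kinetic());
      frame_u.push_back(S.U);
      if (ghost_rate <= 0) {
        max_drift = std::max(max_drift,
                             std::fabs(S.kinetic() + S.U - E0));
      }
      if (tf >= t_end - 1e-12) { done = true; break; }
      double nf = tf + (frame_interval > 0 ? frame_interval : t_end);
      S.q.push({std::min(nf, t_end), -1, -1, EV_FRAME, 0, 0});
      break;
    }
    case EV_GHOST:
      S.handle_ghost(e);
      S.n_events++;
      break;
    case EV_RECHECK:
      S.predict_pair(e.a, e.b, e.t, e.t + S.horizon);
      break;
    case EV_CELL:
      S.handle_cell(e);
      break;
    case EV_SYNC:
      if (S.use_cells) S.resync_cells(e.t); else S.resync(e.t);
      S.q.push({e.t + S.horizon, -1, -1, EV_SYNC, 0, 0});
      break;
    default:
      S.handle_pair(e);
      S.n_events++;
    }
    if (S.n_events > (long)max_events) {
      stop("exceeded max_events (%g) before reaching t_end", max_events);
    }
  }

  NumericMatrix fin_pos(S.n, 3), fin_vel(S.n, 3);
  for (int i = 0; i < S.n; i++) {
    fin_pos(i, 0) = S.px[i]; fin_pos(i, 1) = S.py[i]; fin_pos(i, 2) = S.pz[i];
    fin_vel(i, 0) = S.vx[i]; fin_vel(i, 1) = S.vy[i]; fin_vel(i, 2) = S.vz[i];
  }
  return List::create(
    _["frames"] = wrap(frames),
    _["times"] = wrap(frame_times),
    _["kinetic"] = wrap(frame_ke),
    _["potential"] = wrap(frame_u),
    _["pos"] = fin_pos, _["vel"] = fin_vel,
    _["n_events"] = (double)S.n_events,
    _["energy_drift"] = max_drift,
    _["events"] = DataFrame::create(
      _["t"] = wrap(S.ev_t), _["a"] = wrap(S.ev_a), _["b"] = wrap(S.ev_b),
      _["kind"] = wrap(S.ev_kind)),
    _["ghost_draws"] = wrap(S.ghost_log));
}
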