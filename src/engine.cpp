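// Tick-level simulation core: hard-disc Brownian agents on a periodic 2-D
// box with circular low-diffusivity domains and stochastic monomer<->dimer
// conversion. All randomness comes from R's RNG so that a run is
// bit-reproducible given set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

const int SP_MONOMER = 0;
const int SP_DIMER   = 1;
const int SP_INERT   = 2;

// xoshiro256++ generator seeded from R's RNG: the whole run stays
// reproducible under set.seed() while per-draw cost stays a few ns
// (R's norm_rand uses quantile inversion, far too slow for the tick loop)
struct FastRng {
  uint64_t s[4];
  bool have_spare;
  double spare;

  void seed_from_R() {
    uint64_t z = (uint64_t)(unif_rand() * 4294967296.0);
    z = (z << 32) ^ (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) {  // splitmix64 expansion
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
    have_spare = false;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  inline double norm() {  // Marsaglia polar method
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

inline double wrap1(double v, double L) {
  double w = v - L * std::floor(v / L);
  if (w >= L) w -= L;   // guard against v/L rounding up
  return w;
}

// minimal-image difference component, in [-L/2, L/2]
inline double mdiff(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

struct Sim {
  double L;
  // agent storage (slots are never reused; dead slots stay with alive=false)
  std::vector<double> x, y, rad, ux, uy;
  std::vector<int> sp, id;
  std::vector<char> alive;
  std::vector<int> alive_ids;      // slot indices of live agents
  int next_id;

  // domains
  std::vector<double> dx_, dy_, dr_;

  // spatial grid; falls back to all-pairs when discs are large vs the box
  bool brute;
  int nc;
  double cell;
  std::vector<std::vector<int> > cells;
  std::vector<int> cellof;

  int cell_index(double px, double py) const {
    int ix = (int)(px / cell); if (ix >= nc) ix = nc - 1; if (ix < 0) ix = 0;
    int iy = (int)(py / cell); if (iy >= nc) iy = nc - 1; if (iy < 0) iy = 0;
    return iy * nc + ix;
  }

  void grid_insert(int i) {
    if (brute) return;
    int c = cell_index(x[i], y[i]);
    cells[c].push_back(i);
    if ((int)cellof.size() <= i) cellof.resize(i + 1, -1);
    cellof[i] = c;
  }
  void grid_remove(int i) {
    if (brute) return;
    int c = cellof[i];
    std::vector<int>& v = cells[c];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == i) { v[k] = v.back(); v.pop_back(); break; }
    cellof[i] = -1;
  }
  void grid_move(int i, double nx, double ny) {
    if (brute) { x[i] = nx; y[i] = ny; return; }
    int c0 = cellof[i], c1 = cell_index(nx, ny);
    x[i] = nx; y[i] = ny;
    if (c0 != c1) {
      std::vector<int>& v = cells[c0];
      for (size_t k = 0; k < v.size(); ++k)
        if (v[k] == i) { v[k] = v.back(); v.pop_back(); break; }
      cells[c1].push_back(i);
      cellof[i] = c1;
    }
  }

  // visit every live agent within the 3x3 cell neighbourhood of (px, py)
  template <typename F>
  void neighbours(double px, double py, F f) const {
    if (brute) {
      for (size_t k = 0; k < alive_ids.size(); ++k) f(alive_ids[k]);
      return;
    }
    int ix = (int)(px / cell); if (ix >= nc) ix = nc - 1;
    int iy = (int)(py / cell); if (iy >= nc) iy = nc - 1;
    for (int a = -1; a <= 1; ++a) {
      int cx = (ix + a + nc) % nc;
      for (int b = -1; b <= 1; ++b) {
        int cy = (iy + b + nc) % nc;
        const std::vector<int>& v = cells[cy * nc + cx];
        for (size_t k = 0; k < v.size(); ++k) f(v[k]);
      }
    }
  }

  // strict overlap test (tangency allowed) against all live agents
  // except slots e1, e2
  bool any_overlap(double px, double py, double pr, int e1, int e2) const {
    bool hit = false;
    neighbours(px, py, [&](int j) {
      if (hit || j == e1 || j == e2 || !alive[j]) return;
      double ddx = mdiff(x[j] - px, L), ddy = mdiff(y[j] - py, L);
      double s = pr + rad[j];
      if (ddx * ddx + ddy * ddy < s * s) hit = true;
    });
    return hit;
  }

  bool in_domain(double px, double py) const {
    for (size_t k = 0; k < dx_.size(); ++k) {
      double ddx = mdiff(dx_[k] - px, L), ddy = mdiff(dy_[k] - py, L);
      if (ddx * ddx + ddy * ddy <= dr_[k] * dr_[k]) return true;  // closed disc
    }
    return false;
  }

  int add_agent(double px, double py, double pr, int species) {
    int i = (int)x.size();
    x.push_back(px); y.push_back(py); rad.push_back(pr);
    ux.push_back(px); uy.push_back(py);
    sp.push_back(species); id.push_back(next_id++);
    alive.push_back(1);
    cellof.push_back(-1);
    alive_ids.push_back(i);
    grid_insert(i);
    return i;
  }

  void kill_agent(int i) {
    grid_remove(i);
    alive[i] = 0;
    for (size_t k = 0; k < alive_ids.size(); ++k)
      if (alive_ids[k] == i) {
        alive_ids[k] = alive_ids.back();
        alive_ids.pop_back();
        break;
      }
  }
};

}  // namespace

// Run the simulation for n_steps ticks.
//
// agents0: matrix with columns x, y, radius; species0: 0 monomer, 1 dimer,
// 2 inert. domains: matrix with columns cx, cy, r (0 rows = none).
// step_law: 0 half-normal, 1 Rayleigh. thin: record every `thin` ticks
// (step 0 and the final step are always recorded). snapshot_every /
// record_events enable diagnostic output for tests.
// [[Rcpp::export]]
List cpp_run(NumericMatrix agents0, IntegerVector species0,
             NumericMatrix domains, double box_length,
             double d_out, double d_in, double inert_speed_factor,
             int step_law, double k_b, double k_d,
             double capture_threshold_fraction, double r_monomer,
             int n_steps, int thin,
             int snapshot_every = 0, bool record_events = false,
             int dissoc_max_retries = 20) {
  if (box_length <= 0) stop("box_length must be positive");
  if (thin < 1) thin = 1;

  RNGScope scope;
  FastRng rng;
  rng.seed_from_R();
  Sim S;
  S.L = box_length;
  S.next_id = 1;

  for (int k = 0; k < domains.nrow(); ++k) {
    S.dx_.push_back(domains(k, 0));
    S.dy_.push_back(domains(k, 1));
    S.dr_.push_back(domains(k, 2));
  }

  // grid sizing: cells must cover both the largest radius sum and the
  // dimerisation capture distance within one 3x3 neighbourhood
  double rmax = r_monomer * std::sqrt(2.0);
  for (int i = 0; i < agents0.nrow(); ++i)
    if (agents0(i, 2) > rmax) rmax = agents0(i, 2);
  double need = std::max(2.0 * rmax,
                         2.0 * r_monomer * (1.0 + capture_threshold_fraction));
  S.nc = need > 0 ? (int)std::floor(box_length / need) : 0;
  S.brute = (S.nc < 4);
  if (!S.brute) {
    S.cell = box_length / S.nc;
    S.cells.resize((size_t)S.nc * S.nc);
  }

  for (int i = 0; i < agents0.nrow(); ++i)
    S.add_agent(wrap1(agents0(i, 0), S.L), wrap1(agents0(i, 1), S.L),
                agents0(i, 2), species0[i]);

  const double capture_dist = 2.0 * r_monomer * (1.0 + capture_threshold_fraction);
  const double cap2 = capture_dist * capture_dist;
  const double dimer_step_scale = 1.0 / std::pow(2.0, 0.25);

  // conservation reference: molecule count (dimer = 2 molecules)
  long mol0 = 0;
  for (size_t i = 0; i < S.sp.size(); ++i)
    mol0 += (S.sp[i] == SP_MONOMER) ? 1 : (S.sp[i] == SP_DIMER ? 2 : 0);

  // recorded series
  std::vector<int> rec_step;
  std::vector<int> rec_nm, rec_nd;
  std::vector<double> rec_fd, rec_fin;
  std::vector<double> snap;        // step,id,species,radius,x,y,ux,uy
  std::vector<double> events;      // step,type,id1,id2
  long n_dimerise = 0, n_dissociate = 0, n_deferred = 0, n_abandoned = 0;

  std::vector<int> order;

  auto record = [&](int step) {
    int nm = 0, nd = 0, min_ = 0, din = 0;
    for (size_t k = 0; k < S.alive_ids.size(); ++k) {
      int i = S.alive_ids[k];
      if (S.sp[i] == SP_MONOMER) {
        ++nm;
        if (S.in_domain(S.x[i], S.y[i])) ++min_;
      } else if (S.sp[i] == SP_DIMER) {
        ++nd;
        if (S.in_domain(S.x[i], S.y[i])) ++din;
      }
    }
    long mol = (long)nm + 2L * nd;
    if (mol != mol0)
      stop("internal consistency violation: molecule count changed");
    rec_step.push_back(step);
    rec_nm.push_back(nm);
    rec_nd.push_back(nd);
    rec_fd.push_back(mol > 0 ? 2.0 * nd / (double)mol : NA_REAL);
    rec_fin.push_back(mol > 0 ? (min_ + 2.0 * din) / (double)mol : NA_REAL);
  };

  auto snapshot = [&](int step) {
    for (size_t k = 0; k < S.alive_ids.size(); ++k) {
      int i = S.alive_ids[k];
      snap.push_back(step); snap.push_back(S.id[i]); snap.push_back(S.sp[i]);
      snap.push_back(S.rad[i]); snap.push_back(S.x[i]); snap.push_back(S.y[i]);
      snap.push_back(S.ux[i]); snap.push_back(S.uy[i]);
    }
  };

  record(0);
  if (snapshot_every > 0) snapshot(0);

  for (int step = 1; step <= n_steps; ++step) {
    // fresh uniform visiting order over agents alive at tick start
    order.assign(S.alive_ids.begin(), S.alive_ids.end());
    for (int k = (int)order.size() - 1; k > 0; --k) {
      int j = (int)(rng.unif() * (k + 1));
      if (j > k) j = k;
      std::swap(order[k], order[j]);
    }

    for (size_t oi = 0; oi < order.size(); ++oi) {
      int i = order[oi];
      if (!S.alive[i]) continue;  // consumed by an event earlier this tick

      // ---- Brownian step proposal ----
      double D = S.in_domain(S.x[i], S.y[i]) ? d_in : d_out;
      double scale = std::sqrt(D);
      if (S.sp[i] == SP_INERT) scale *= inert_speed_factor;
      else if (S.sp[i] == SP_DIMER) scale *= dimer_step_scale;

      if (scale > 0) {
        double r;
        if (step_law == 0) {
          r = scale * std::fabs(rng.norm());
        } else {
          double u = rng.unif();
          if (u <= 0) u = 1e-300;
          r = scale * std::sqrt(-2.0 * std::log(u));
        }
        double th = 2.0 * M_PI * rng.unif();
        double sx = r * std::cos(th), sy = r * std::sin(th);
        double nx = wrap1(S.x[i] + sx, S.L), ny = wrap1(S.y[i] + sy, S.L);
        if (!S.any_overlap(nx, ny, S.rad[i], i, -1)) {
          S.grid_move(i, nx, ny);
          S.ux[i] += sx; S.uy[i] += sy;
        }
      }

      // ---- dimerisation (monomers) ----
      // one k_b draw per focal monomer per tick; the draw precedes the
      // candidate scan (the two commute: the event needs both u < k_b and
      // a non-empty candidate set), which keeps the scan off the hot path
      if (S.sp[i] == SP_MONOMER && k_b > 0 && rng.unif() < k_b) {
        // nearest monomer within the capture threshold, ties broken uniformly
        int best = -1, nties = 0;
        double bestd2 = 0;
        S.neighbours(S.x[i], S.y[i], [&](int j) {
          if (j == i || !S.alive[j] || S.sp[j] != SP_MONOMER) return;
          double ddx = mdiff(S.x[j] - S.x[i], S.L);
          double ddy = mdiff(S.y[j] - S.y[i], S.L);
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 > cap2) return;
          if (best < 0 || d2 < bestd2) { best = j; bestd2 = d2; nties = 1; }
          else if (d2 == bestd2) {
            ++nties;
            if (rng.unif() < 1.0 / nties) best = j;
          }
        });
        if (best >= 0) {
          double hx = mdiff(S.x[best] - S.x[i], S.L);
          double hy = mdiff(S.y[best] - S.y[i], S.L);
          double cx = wrap1(S.x[i] + 0.5 * hx, S.L);
          double cy = wrap1(S.y[i] + 0.5 * hy, S.L);
          double rd = S.rad[i] * std::sqrt(2.0);  // area of two monomers
          if (!S.any_overlap(cx, cy, rd, i, best)) {
            int id1 = S.id[i], id2 = S.id[best];
            S.kill_agent(i);
            S.kill_agent(best);
            S.add_agent(cx, cy, rd, SP_DIMER);  // acts from the next tick
            ++n_dimerise;
            if (record_events) {
              events.push_back(step); events.push_back(1);
              events.push_back(id1); events.push_back(id2);
            }
          } else {
            ++n_abandoned;
            if (record_events) {
              events.push_back(step); events.push_back(4);
              events.push_back(S.id[i]); events.push_back(S.id[best]);
            }
          }
        }
      }
      // ---- dissociation (dimers) ----
      else if (S.sp[i] == SP_DIMER && k_d > 0) {
        if (rng.unif() < k_d) {
          double rm = S.rad[i] / std::sqrt(2.0);
          bool placed = false;
          for (int t = 0; t < dissoc_max_retries && !placed; ++t) {
            double phi = 2.0 * M_PI * rng.unif();
            double ax = rm * std::cos(phi), ay = rm * std::sin(phi);
            double p1x = wrap1(S.x[i] + ax, S.L), p1y = wrap1(S.y[i] + ay, S.L);
            double p2x = wrap1(S.x[i] - ax, S.L), p2y = wrap1(S.y[i] - ay, S.L);
            // the two children are tangent by construction; test others only
            if (!S.any_overlap(p1x, p1y, rm, i, -1) &&
                !S.any_overlap(p2x, p2y, rm, i, -1)) {
              int odid = S.id[i];
              S.kill_agent(i);
              S.add_agent(p1x, p1y, rm, SP_MONOMER);
              S.add_agent(p2x, p2y, rm, SP_MONOMER);
              placed = true;
              ++n_dissociate;
              if (record_events) {
                events.push_back(step); events.push_back(2);
                events.push_back(odid); events.push_back(NA_REAL);
              }
            }
          }
          if (!placed) {
            ++n_deferred;  // dimer persists; event deferred to a later tick
            if (record_events) {
              events.push_back(step); events.push_back(3);
              events.push_back(S.id[i]); events.push_back(NA_REAL);
            }
          }
        }
      }
    }

    if (step % thin == 0 || step == n_steps) record(step);
    if (snapshot_every > 0 && (step % snapshot_every == 0 || step == n_steps))
      snapshot(step);
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  // series
  int nr = (int)rec_step.size();
  NumericMatrix series(nr, 5);
  for (int k = 0; k < nr; ++k) {
    series(k, 0) = rec_step[k];
    series(k, 1) = rec_nm[k];
    series(k, 2) = rec_nd[k];
    series(k, 3) = rec_fd[k];
    series(k, 4) = rec_fin[k];
  }
  colnames(series) = CharacterVector::create("step", "n_monomers", "n_dimers",
                                             "fraction_dimeric", "fraction_inside");

  // final agents
  int na = (int)S.alive_ids.size();
  NumericMatrix fin(na, 7);
  for (int k = 0; k < na; ++k) {
    int i = S.alive_ids[k];
    fin(k, 0) = S.id[i]; fin(k, 1) = S.sp[i]; fin(k, 2) = S.rad[i];
    fin(k, 3) = S.x[i];  fin(k, 4) = S.y[i];
    fin(k, 5) = S.ux[i]; fin(k, 6) = S.uy[i];
  }
  colnames(fin) = CharacterVector::create("id", "species", "radius",
                                          "x", "y", "ux", "uy");

  NumericMatrix snapm(snap.size() / 8, 8);
  for (size_t k = 0; k < snap.size() / 8; ++k)
    for (int c = 0; c < 8; ++c) snapm(k, c) = snap[8 * k + c];
  if (snapm.nrow() > 0)
    colnames(snapm) = CharacterVector::create("step", "id", "species", "radius",
                                              "x", "y", "ux", "uy");

  NumericMatrix evm(events.size() / 4, 4);
  for (size_t k = 0; k < events.size() / 4; ++k)
    for (int c = 0; c < 4; ++c) evm(k, c) = events[4 * k + c];
  if (evm.nrow() > 0)
    colnames(evm) = CharacterVector::create("step", "type", "id1", "id2");

  return List::create(
    _["series"] = series,
    _["agents"] = fin,
    _["counts"] = IntegerVector::create(
      _["dimerise"] = (int)n_dimerise, _["dissociate"] = (int)n_dissociate,
      _["dissociation_deferred"] = (int)n_deferred,
      _["dimerisation_abandoned"] = (int)n_abandoned),
    _["snapshots"] = snapm,
    _["events"] = evm);
}

// Grid-backed overlap query for a candidate disc against a static
// configuration (used to verify grid vs all-pairs agreement).
// [[Rcpp::export]]
bool cpp_overlaps(NumericVector candidate, double radius,
                  NumericMatrix agents, double box_length,
                  double r_monomer = 0.0) {
  Sim S;
  S.L = box_length;
  S.next_id = 1;
  double rmax = std::max(radius, r_monomer * std::sqrt(2.0));
  for (int i = 0; i < agents.nrow(); ++i)
    if (agents(i, 2) > rmax) rmax = agents(i, 2);
  double need = 2.0 * rmax;
  S.nc = need > 0 ? (int)std::floor(box_length / need) : 0;
  S.brute = (S.nc < 4);
  if (!S.brute) {
    S.cell = box_length / S.nc;
    S.cells.resize((size_t)S.nc * S.nc);
  }
  for (int i = 0; i < agents.nrow(); ++i)
    S.add_agent(wrap1(agents(i, 0), S.L), wrap1(agents(i, 1), S.L),
                agents(i, 2), SP_MONOMER);
  return S.any_overlap(wrap1(candidate[0], S.L), wrap1(candidate[1], S.L),
                       radius, -1, -1);
}
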