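// Core of the 3D cellular-automaton spheroid model.
//
// The lattice is an L x L x L grid; each site is empty (0) or holds one cell
// of clone 1 or clone 2.  Cells divide, move and die as independent Poisson
// processes and the system is advanced by Gillespie's stochastic simulation
// algorithm.  Movement and division target the 26-site 3D Moore neighbourhood
// of length 1; blocked events consume the SSA step (time advances, the state
// is unchanged).  All randomness comes from R's RNG so set.seed() on the R
// side makes trajectories bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NOFF = 26;
static int OFF[NOFF][3];
static bool off_ready = false;

static void init_offsets() {
  if (off_ready) return;
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        OFF[k][0] = dx; OFF[k][1] = dy; OFF[k][2] = dz; ++k;
      }
  off_ready = true;
}

// Event bookkeeping: selections vs. realised outcomes per process.
struct Tally {
  long div_sel = 0, div_ok = 0;
  long move_sel = 0, move_ok = 0;
  long death_sel = 0;
};

class CAState {
public:
  int L;
  std::vector<signed char> occ;   // 0 empty, 1 clone A, 2 clone B
  std::vector<int> cells[2];      // site indices per clone
  std::vector<int> pos;           // index of a site's cell in its clone list
  bool boundary_contact;

  CAState(const IntegerVector& arr, int L_) : L(L_), boundary_contact(false) {
    init_offsets();
    const R_xlen_t n = (R_xlen_t)L * L * L;
    if (arr.size() != n) stop("occupancy array does not match lattice edge");
    occ.resize(n);
    pos.assign(n, -1);
    for (R_xlen_t i = 0; i < n; ++i) {
      int v = arr[i];
      if (v < 0 || v > 2) stop("occupancy values must be 0 (empty), 1 or 2");
      occ[i] = (signed char)v;
      if (v > 0) {
        pos[i] = (int)cells[v - 1].size();
        cells[v - 1].push_back((int)i);
        if (on_frame((int)i)) boundary_contact = true;
      }
    }
  }

  inline bool on_frame(int s) const {
    int x = s % L, y = (s / L) % L, z = s / (L * L);
    return x == 0 || y == 0 || z == 0 || x == L - 1 || y == L - 1 || z == L - 1;
  }

  inline int count(int c) const { return (int)cells[c].size(); }
  inline int total_cells() const { return count(0) + count(1); }

  // neighbour site of s in direction d at distance k; -1 if out of grid
  inline int step(int s, int d, int k) const {
    int x = s % L + OFF[d][0] * k;
    int y = (s / L) % L + OFF[d][1] * k;
    int z = s / (L * L) + OFF[d][2] * k;
    if (x < 0 || y < 0 || z < 0 || x >= L || y >= L || z >= L) return -1;
    return x + L * (y + L * z);
  }

  void place(int s, int clone) {           // clone is 0-based here
    occ[s] = (signed char)(clone + 1);
    pos[s] = (int)cells[clone].size();
    cells[clone].push_back(s);
    if (on_frame(s)) boundary_contact = true;
  }

  void remove(int s) {
    int clone = occ[s] - 1;
    int p = pos[s];
    std::vector<int>& v = cells[clone];
    int last = v.back();
    v[p] = last;
    pos[last] = p;
    v.pop_back();
    occ[s] = 0;
    pos[s] = -1;
  }

  void relocate(int s, int t) {            // move the cell at s to empty t
    int clone = occ[s] - 1;
    int p = pos[s];
    cells[clone][p] = t;
    pos[t] = p;
    occ[t] = occ[s];
    occ[s] = 0;
    pos[s] = -1;
    if (on_frame(t)) boundary_contact = true;
  }

  // uniform choice among empty Moore neighbours; false if fully blocked
  bool try_move(int s) {
    int empt[NOFF]; int ne = 0;
    for (int d = 0; d < NOFF; ++d) {
      int t = step(s, d, 1);
      if (t >= 0 && occ[t] == 0) empt[ne++] = t;
    }
    if (ne == 0) return false;
    int t = empt[(int)(unif_rand() * ne) % ne];
    relocate(s, t);
    return true;
  }

  // Division: daughter goes to an empty Moore neighbour if one exists.
  // Otherwise, with aggression a > 1, the nearest empty site within
  // Chebyshev distance a along one of the 26 lattice rays is located; a ray
  // achieving the minimal distance is chosen uniformly at random and the
  // contiguous run of cells on it is pushed outward by one step, freeing the
  // neighbour site for the daughter.  Clone labels are preserved in order.
  bool try_divide(int s, int aggression) {
    int clone = occ[s] - 1;
    int empt[NOFF]; int ne = 0;
    for (int d = 0; d < NOFF; ++d) {
      int t = step(s, d, 1);
      if (t >= 0 && occ[t] == 0) empt[ne++] = t;
    }
    if (ne > 0) {
      int t = empt[(int)(unif_rand() * ne) % ne];
      place(t, clone);
      return true;
    }
    if (aggression <= 1) return false;
    int best_k = aggression + 1;
    int dirs[NOFF]; int nd = 0;
    for (int d = 0; d < NOFF; ++d) {
      for (int k = 2; k <= aggression; ++k) {
        int t = step(s, d, k);
        if (t < 0) break;                    // frame is a wall: ray blocked
        if (occ[t] == 0) {
          if (k < best_k) { best_k = k; nd = 0; }
          if (k == best_k) dirs[nd++] = d;
          break;
        }
      }
    }
    if (nd == 0) return false;
    int d = dirs[(int)(unif_rand() * nd) % nd];
    // shift the run outward: site at distance j-1 moves to distance j
    for (int j = best_k; j >= 2; --j) {
      int from = step(s, d, j - 1);
      int to = step(s, d, j);
      relocate(from, to);
    }
    place(step(s, d, 1), clone);
    return true;
  }

  // local clone proportions within Chebyshev radius nb of site s (self
  // excluded); returns false when no other cell is in range
  bool local_proportions(int s, int nb, double r[2]) const {
    int x0 = s % L, y0 = (s / L) % L, z0 = s / (L * L);
    long cnt[2] = {0, 0};
    for (int dz = -nb; dz <= nb; ++dz) {
      int z = z0 + dz; if (z < 0 || z >= L) continue;
      for (int dy = -nb; dy <= nb; ++dy) {
        int y = y0 + dy; if (y < 0 || y >= L) continue;
        for (int dx = -nb; dx <= nb; ++dx) {
          int x = x0 + dx; if (x < 0 || x >= L) continue;
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int v = occ[x + L * (y + L * z)];
          if (v > 0) cnt[v - 1]++;
        }
      }
    }
    long tot = cnt[0] + cnt[1];
    if (tot == 0) { r[0] = r[1] = 0.0; return false; }
    r[0] = (double)cnt[0] / tot;
    r[1] = (double)cnt[1] / tot;
    return true;
  }
};

// effective motility of clone i given proportions r and interaction matrix
static inline double eff_motility(int i, const double* m, const double r[2],
                                  const NumericMatrix& I) {
  double M = m[i];
  for (int j = 0; j < 2; ++j)
    if (j != i) M += r[j] * I(i, j);
  return M > 0.0 ? M : 0.0;
}

struct EventLog {
  std::vector<int> clone, process, success;
  std::vector<double> dt;
  int limit;
  explicit EventLog(int lim) : limit(lim) {}
  void add(int c, int p, double t, bool ok) {
    if ((int)clone.size() >= limit) return;
    clone.push_back(c + 1); process.push_back(p);
    dt.push_back(t); success.push_back(ok ? 1 : 0);
  }
};

// Advance the state by SSA until `until`; returns number of events executed.
// Processes: 1 division, 2 movement, 3 death.
static long ssa_advance(CAState& st, double& time, double until,
                        const double* prolif, const double* motil,
                        const int* aggression, double death_frac,
                        const NumericMatrix& inter, int neighborhood,
                        Tally& tl, EventLog* log, long max_events) {
  long nev = 0;
  const bool global = neighborhood <= 0;
  std::vector<double> cum;    // per-cell cumulative rates (local mode)
  while (time < until) {
    if (max_events >= 0 && nev >= max_events) break;
    int n0 = st.count(0), n1 = st.count(1);
    long ntot = n0 + n1;
    if (ntot == 0) { time = until; break; }
    if (ntot >= (long)st.L * st.L * st.L)
      stop("lattice overflow: no empty site left (edge %d, %ld cells); "
           "use a larger lattice or a shorter end time", st.L, ntot);

    double total = 0.0;
    double Mg[2] = {0.0, 0.0};
    if (global) {
      double r[2] = {(double)n0 / ntot, (double)n1 / ntot};
      for (int c = 0; c < 2; ++c) Mg[c] = eff_motility(c, motil, r, inter);
      total = n0 * (prolif[0] * (1.0 + death_frac) + Mg[0]) +
              n1 * (prolif[1] * (1.0 + death_frac) + Mg[1]);
    } else {
      cum.resize(ntot);
      double acc = 0.0;
      long i = 0;
      for (int c = 0; c < 2; ++c) {
        for (int ci = 0; ci < st.count(c); ++ci, ++i) {
          double r[2];
          st.local_proportions(st.cells[c][ci], neighborhood, r);
          double M = eff_motility(c, motil, r, inter);
          acc += prolif[c] * (1.0 + death_frac) + M;
          cum[i] = acc;
        }
      }
      total = acc;
    }
    if (total <= 0.0) { time = until; break; }

    double dt = exp_rand() / total;
    if (time + dt > until) { time = until; break; }
    time += dt;

    int clone = -1, site = -1, process = 0;
    if (global) {
      double u = unif_rand() * total;
      double acc = 0.0;
      int n[2] = {n0, n1};
      for (int c = 0; c < 2 && process == 0; ++c) {
        double rates[3] = {prolif[c], Mg[c], death_frac * prolif[c]};
        for (int p = 0; p < 3; ++p) {
          acc += n[c] * rates[p];
          if (u <= acc) {
            clone = c; process = p + 1;
            site = st.cells[c][(int)(unif_rand() * n[c]) % n[c]];
            break;
          }
        }
      }
      if (process == 0) {  // numerical edge: fall back to last class
        clone = n1 > 0 ? 1 : 0; process = 3;
        site = st.cells[clone][(int)(unif_rand() * st.count(clone)) % st.count(clone)];
      }
    } else {
      double u = unif_rand() * total;
      long lo = 0, hi = ntot - 1;
      while (lo < hi) { long mid = (lo + hi) / 2; if (cum[mid] < u) lo = mid + 1; else hi = mid; }
      clone = lo < n0 ? 0 : 1;
      int ci = clone == 0 ? (int)lo : (int)(lo - n0);
      site = st.cells[clone][ci];
      double r[2];
      st.local_proportions(site, neighborhood, r);
      double M = eff_motility(clone, motil, r, inter);
      double base = lo > 0 ? cum[lo - 1] : 0.0;
      double v = u - base;
      if (v <= prolif[clone]) process = 1;
      else if (v <= prolif[clone] + M) process = 2;
      else process = 3;
    }

    bool ok = true;
    switch (process) {
      case 1: tl.div_sel++;  ok = st.try_divide(site, aggression[clone]);
              if (ok) tl.div_ok++;  break;
      case 2: tl.move_sel++; ok = st.try_move(site);
              if (ok) tl.move_ok++; break;
      case 3: tl.death_sel++; st.remove(site); break;
    }
    if (log) log->add(clone, process, dt, ok);
    ++nev;
    if (nev % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  return nev;
}

static IntegerVector state_to_array(const CAState& st) {
  R_xlen_t n = (R_xlen_t)st.L * st.L * st.L;
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = st.occ[i];
  out.attr("dim") = IntegerVector::create(st.L, st.L, st.L);
  return out;
}

// z-collapse: per clone, an L x L 0/1 matrix with a 1 wherever any z holds a
// cell of that clone
static List collapse_masks(const CAState& st) {
  int L = st.L;
  IntegerMatrix mA(L, L), mB(L, L);
  for (int c = 0; c < 2; ++c) {
    IntegerMatrix& m = c == 0 ? mA : mB;
    for (size_t i = 0; i < st.cells[c].size(); ++i) {
      int s = st.cells[c][i];
      m(s % L, (s / L) % L) = 1;
    }
  }
  return List::create(Named("A") = mA, Named("B") = mB);
}

static List tally_to_list(const Tally& tl) {
  return List::create(
    Named("divisions_selected") = (double)tl.div_sel,
    Named("divisions_realized") = (double)tl.div_ok,
    Named("moves_selected") = (double)tl.move_sel,
    Named("moves_realized") = (double)tl.move_ok,
    Named("deaths") = (double)tl.death_sel);
}

// [[Rcpp::export]]
List cpp_advance(IntegerVector occ, int L, NumericVector prolif,
                 NumericVector motil, IntegerVector aggression,
                 double death_frac, NumericMatrix inter, int neighborhood,
                 double time, double until, int max_events, int record_limit) {
  CAState st(occ, L);
  Tally tl;
  EventLog log(record_limit > 0 ? record_limit : 0);
  double t = time;
  double p[2] = {prolif[0], prolif[1]};
  double m[2] = {motil[0], motil[1]};
  int ag[2] = {aggression[0], aggression[1]};
  long nev = ssa_advance(st, t, until, p, m, ag, death_frac, inter,
                         neighborhood, tl, record_limit > 0 ? &log : nullptr,
                         max_events);
  List out = List::create(
    Named("occupancy") = state_to_array(st),
    Named("time") = t,
    Named("counts") = NumericVector::create(st.count(0), st.count(1)),
    Named("n_events") = (double)nev,
    Named("tally") = tally_to_list(tl),
    Named("boundary_contact") = st.boundary_contact);
  if (record_limit > 0)
    out["log"] = DataFrame::create(
      Named("clone") = wrap(log.clone), Named("process") = wrap(log.process),
      Named("dt") = wrap(log.dt), Named("success") = wrap(log.success));
  return out;
}

// [[Rcpp::export]]
List cpp_run(IntegerVector occ, int L, NumericVector prolif,
             NumericVector motil, IntegerVector aggression, double death_frac,
             NumericMatrix inter, int neighborhood, double t0,
             NumericVector snapshot_times, bool keep_final_state) {
  CAState st(occ, L);
  Tally tl;
  double t = t0;
  double p[2] = {prolif[0], prolif[1]};
  double m[2] = {motil[0], motil[1]};
  int ag[2] = {aggression[0], aggression[1]};
  int ns = snapshot_times.size();
  List snaps(ns);
  for (int i = 0; i < ns; ++i) {
    double target = snapshot_times[i];
    if (target > t)
      ssa_advance(st, t, target, p, m, ag, death_frac, inter, neighborhood,
                  tl, nullptr, -1);
    snaps[i] = List::create(
      Named("time") = target,
      Named("masks") = collapse_masks(st),
      Named("counts") = NumericVector::create(st.count(0), st.count(1)));
  }
  List out = List::create(
    Named("snapshots") = snaps,
    Named("tally") = tally_to_list(tl),
    Named("boundary_contact") = st.boundary_contact);
  if (keep_final_state) out["occupancy"] = state_to_array(st);
  return out;
}

// [[Rcpp::export]]
List cpp_execute_move(IntegerVector occ, int L, int site) {
  CAState st(occ, L);
  if (st.occ[site] == 0) stop("site is empty");
  bool ok = st.try_move(site);
  return List::create(Named("occupancy") = state_to_array(st),
                      Named("success") = ok);
}

// [[Rcpp::export]]
List cpp_execute_division(IntegerVector occ, int L, int site, int aggression) {
  CAState st(occ, L);
  if (st.occ[site] == 0) stop("site is empty");
  bool ok = st.try_divide(site, aggression);
  return List::create(Named("occupancy") = state_to_array(st),
                      Named("success") = ok);
}

// [[Rcpp::export]]
List cpp_execute_death(IntegerVector occ, int L, int site) {
  CAState st(occ, L);
  if (st.occ[site] == 0) stop("site is empty");
  st.remove(site);
  return List::create(Named("occupancy") = state_to_array(st),
                      Named("success") = true);
}

// [[Rcpp::export]]
List cpp_local_proportions(IntegerVector occ, int L, int site, int neighborhood) {
  CAState st(occ, L);
  double r[2];
  bool any = st.local_proportions(site, neighborhood, r);
  return List::create(Named("proportions") = NumericVector::create(r[0], r[1]),
                      Named("any_neighbours") = any);
}
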