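// Growth kernels for physical networks on periodic cubic lattices.
//
// All randomness goes through R's RNG (unif_rand / norm_rand) so that
// set.seed() at the R level gives bit-for-bit reproducible runs.
//
// Site indexing is 0-based here; R wrappers convert to 1-based.
// Sites are laid out in R array order: site = sum_k c_k * L^k.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Lattice {
  int d, L;
  long long n;
  std::vector<long long> stride;
  Lattice(int d_, int L_) : d(d_), L(L_), stride(d_) {
    n = 1;
    for (int k = 0; k < d; ++k) { stride[k] = n; n *= L; }
  }
};

inline int runif_int(int m) {
  // uniform on {0, ..., m-1}
  int r = (int)(unif_rand() * m);
  return r >= m ? m - 1 : r;
}

// Shared walk state over one lattice: ownership, walk-position index and
// an exact empty-site list supporting O(1) uniform sampling.
struct Arena {
  Lattice lat;
  std::vector<int> owner;   // 0 = empty, else node id >= 1
  std::vector<int> pos;     // index within current walk's trajectory, -1 otherwise
  std::vector<int> empties; // list of empty sites
  std::vector<int> where;   // where[site] = index in empties, -1 if occupied

  Arena(int d, int L) : lat(d, L) {
    owner.assign(lat.n, 0);
    pos.assign(lat.n, -1);
    empties.resize(lat.n);
    where.resize(lat.n);
    for (long long s = 0; s < lat.n; ++s) { empties[s] = (int)s; where[s] = (int)s; }
  }

  // Rebuild empties/where from an externally supplied owner vector.
  void load_owner(const IntegerVector &ow) {
    empties.clear();
    for (long long s = 0; s < lat.n; ++s) {
      owner[s] = ow[s];
      if (ow[s] == 0) { where[s] = (int)empties.size(); empties.push_back((int)s); }
      else where[s] = -1;
    }
  }

  long long n_empty() const { return (long long)empties.size(); }

  int sample_empty() {
    int idx = runif_int((int)empties.size());
    return empties[idx];
  }

  void claim(int site, int id) {
    owner[site] = id;
    int idx = where[site];
    int last = empties.back();
    empties[idx] = last; where[last] = idx;
    empties.pop_back();
    where[site] = -1;
  }

  void release(int site) {
    owner[site] = 0;
    where[site] = (int)empties.size();
    empties.push_back(site);
  }
};

// One growing walk. Trajectory sites plus their coordinates (needed to
// restore the head after a loop erasure without divisions).
struct Walk {
  std::vector<int> traj;
  std::vector<int> coords; // flattened, d per entry
  long long steps = 0;     // proposals made
  long long erased = 0;    // sites removed by loop erasure
  bool hit = false;
  int hit_a = -1, hit_b = -1, partner = 0;
  bool closed = false;     // straight walk that met itself (no bond)
  bool budget_exceeded = false;
};

inline int neighbor_site(const Lattice &lat, int site, const int *c, int axis, int dir) {
  int ca = c[axis];
  if (dir > 0) {
    return (ca == lat.L - 1) ? site - (int)((long long)(lat.L - 1) * lat.stride[axis])
                             : site + (int)lat.stride[axis];
  }
  return (ca == 0) ? site + (int)((long long)(lat.L - 1) * lat.stride[axis])
                   : site - (int)lat.stride[axis];
}

void start_walk(Arena &A, Walk &w, int start, int id) {
  const int d = A.lat.d;
  A.claim(start, id);
  A.pos[start] = 0;
  w.traj.push_back(start);
  w.coords.resize(d);
  int s = start;
  for (int k = 0; k < d; ++k) { w.coords[k] = s % A.lat.L; s /= A.lat.L; }
}

// Kinetic loop-erased random walk. Propose a uniform neighbor of the head:
// empty -> extend; own trajectory -> erase the loop (releasing occupancy);
// other node -> stop with a bond (only when allow_hit).
void run_lerw(Arena &A, Walk &w, int id, long long target, bool allow_hit, long long budget) {
  const int d = A.lat.d;
  if (target > 0 && (long long)w.traj.size() >= target) return;
  while (true) {
    if (w.steps >= budget) { w.budget_exceeded = true; return; }
    int head = w.traj.back();
    const int *c = &w.coords[(w.traj.size() - 1) * d];
    int pick = runif_int(2 * d);
    int axis = pick >> 1, dir = (pick & 1) ? 1 : -1;
    int hc[32];
    for (int k = 0; k < d; ++k) hc[k] = c[k];
    int nxt = neighbor_site(A.lat, head, hc, axis, dir);
    ++w.steps;
    int ow = A.owner[nxt];
    if (ow == 0) {
      A.claim(nxt, id);
      A.pos[nxt] = (int)w.traj.size();
      w.traj.push_back(nxt);
      w.coords.resize(w.traj.size() * d);
      int *nc = &w.coords[(w.traj.size() - 1) * d];
      for (int k = 0; k < d; ++k) nc[k] = hc[k];
      nc[axis] += dir;
      if (nc[axis] == A.lat.L) nc[axis] = 0;
      if (nc[axis] < 0) nc[axis] = A.lat.L - 1;
      if (target > 0 && (long long)w.traj.size() >= target) return;
    } else if (ow == id) {
      // loop erasure back to the earlier visit of nxt
      int j = A.pos[nxt];
      for (size_t q = j + 1; q < w.traj.size(); ++q) {
        A.release(w.traj[q]);
        A.pos[w.traj[q]] = -1;
        ++w.erased;
      }
      w.traj.resize(j + 1);
      w.coords.resize((size_t)(j + 1) * d);
    } else {
      if (allow_hit) {
        w.hit = true; w.hit_a = head; w.hit_b = nxt; w.partner = ow;
        return;
      }
      // hits disabled (free seed growth): treat as blocked proposal
    }
  }
}

// Straight-ray walk, digitized by face-adjacent voxel traversal
// (Amanatides-Woo). mode 0: uniform random direction; mode 1: random
// lattice axis. Stops on meeting another node (bond) or itself (closed).
void run_straight(Arena &A, Walk &w, int id, long long target, bool allow_hit, long long budget) {
  const int d = A.lat.d;
  std::vector<double> u(d), tMax(d), tDelta(d);
  bool axis_mode = w.partner == -2; // flag smuggled in by caller
  w.partner = 0;
  if (axis_mode) {
    int pick = runif_int(2 * d);
    for (int k = 0; k < d; ++k) u[k] = 0.0;
    u[pick >> 1] = (pick & 1) ? 1.0 : -1.0;
  } else {
    double nrm = 0.0;
    do {
      nrm = 0.0;
      for (int k = 0; k < d; ++k) { u[k] = norm_rand(); nrm += u[k] * u[k]; }
    } while (nrm < 1e-12);
    nrm = std::sqrt(nrm);
    for (int k = 0; k < d; ++k) u[k] /= nrm;
  }
  for (int k = 0; k < d; ++k) {
    if (std::fabs(u[k]) < 1e-15) { tDelta[k] = R_PosInf; tMax[k] = R_PosInf; }
    else { tDelta[k] = 1.0 / std::fabs(u[k]); tMax[k] = 0.5 * tDelta[k]; }
  }
  while (true) {
    if (w.steps >= budget) { w.budget_exceeded = true; return; }
    int axis = 0;
    for (int k = 1; k < d; ++k) if (tMax[k] < tMax[axis]) axis = k;
    int dir = (u[axis] >= 0) ? 1 : -1;
    int head = w.traj.back();
    const int *c = &w.coords[(w.traj.size() - 1) * d];
    int hc[32];
    for (int k = 0; k < d; ++k) hc[k] = c[k];
    int nxt = neighbor_site(A.lat, head, hc, axis, dir);
    ++w.steps;
    tMax[axis] += tDelta[axis];
    int ow = A.owner[nxt];
    if (ow == 0) {
      A.claim(nxt, id);
      A.pos[nxt] = (int)w.traj.size();
      w.traj.push_back(nxt);
      w.coords.resize(w.traj.size() * d);
      int *nc = &w.coords[(w.traj.size() - 1) * d];
      for (int k = 0; k < d; ++k) nc[k] = hc[k];
      nc[axis] += dir;
      if (nc[axis] == A.lat.L) nc[axis] = 0;
      if (nc[axis] < 0) nc[axis] = A.lat.L - 1;
      if (target > 0 && (long long)w.traj.size() >= target) return;
    } else if (ow == id) {
      w.closed = true; // ray met itself after wrapping: node closes, no bond
      return;
    } else {
      if (allow_hit) {
        w.hit = true; w.hit_a = head; w.hit_b = nxt; w.partner = ow;
        return;
      }
      w.closed = true;
      return;
    }
  }
}

void dispatch_walk(Arena &A, Walk &w, int id, int process, long long target,
                   bool allow_hit, long long budget) {
  if (process == 0) run_lerw(A, w, id, target, allow_hit, budget);
  else {
    if (process == 2) w.partner = -2; // axis mode flag
    run_straight(A, w, id, target, allow_hit, budget);
  }
}

} // namespace

// Grow a single trajectory on an existing occupancy (unit-level op).
// owner: length L^d integer vector, 0 = empty. Returns the updated owner
// alongside the trajectory and hit information. process: 0 lerw,
// 1 straight_random_dir, 2 straight_axis.
// [[Rcpp::export]]
List cpp_grow_single(int d, int L, IntegerVector owner, int start0, int node_id,
                     int process, double target, bool allow_hit, double budget) {
  Arena A(d, L);
  A.load_owner(owner);
  if (A.owner[start0] != 0) stop("start site is occupied");
  Walk w;
  start_walk(A, w, start0, node_id);
  dispatch_walk(A, w, node_id, process, (long long)target, allow_hit, (long long)budget);
  IntegerVector traj(w.traj.begin(), w.traj.end());
  IntegerVector new_owner(A.owner.begin(), A.owner.end());
  return List::create(
    _["trajectory"] = traj,
    _["owner"] = new_owner,
    _["hit"] = w.hit,
    _["hit_a"] = w.hit_a, _["hit_b"] = w.hit_b, _["partner"] = w.partner,
    _["closed"] = w.closed,
    _["steps"] = (double)w.steps, _["erased"] = (double)w.erased,
    _["budget_exceeded"] = w.budget_exceeded);
}

// Full growth run. n_max < 0 means grow to saturation.
// Returns flat trajectory storage (sites + offsets), per-node stats,
// bonds, cumulative volume V_t and an event log.
// [[Rcpp::export]]
List cpp_grow_network(int d, int L, int process, double n_max, double v0,
                      double seed_budget, double node_budget_factor) {
  Arena A(d, L);
  long long nmax = (n_max < 0) ? -1 : (long long)n_max;

  std::vector<int> all_sites;   // concatenated trajectories
  std::vector<double> offsets;  // start index (0-based) of each node's trajectory
  std::vector<double> volumes, Vt;
  std::vector<double> ev_seed, ev_steps, ev_erased, ev_len_before;
  std::vector<int> ev_partner, ev_hit_a, ev_hit_b;
  std::vector<int> bond_a, bond_b, bond_i, bond_j;
  bool saturated = false, seed_failed = false;
  double Vtot = 0;
  long long node_budget = (long long)(node_budget_factor * (double)A.lat.n) + 1000000LL;

  long long t = 0;
  while (true) {
    if (nmax >= 0 && t >= nmax) break;
    if (A.n_empty() == 0) { saturated = true; break; }
    int start = A.sample_empty();
    int id = (int)t + 1;
    Walk w;
    start_walk(A, w, start, id);
    if (t == 0) {
      // free-growing seed node: hits are impossible anyway, but disable
      // them so straight-mode self-closure is the only stop
      long long tgt = (long long)v0;
      dispatch_walk(A, w, id, process, tgt, false, (long long)seed_budget);
      if ((long long)w.traj.size() < tgt && !w.closed) seed_failed = true;
    } else {
      dispatch_walk(A, w, id, process, -1, true, node_budget);
    }
    // clear walk position marks
    for (int s : w.traj) A.pos[s] = -1;
    offsets.push_back((double)all_sites.size());
    all_sites.insert(all_sites.end(), w.traj.begin(), w.traj.end());
    double v = (double)w.traj.size();
    volumes.push_back(v);
    Vtot += v;
    Vt.push_back(Vtot);
    ev_seed.push_back((double)start);
    ev_steps.push_back((double)w.steps);
    ev_erased.push_back((double)w.erased);
    ev_len_before.push_back(v + (double)w.erased);
    ev_partner.push_back(w.hit ? w.partner : 0);
    ev_hit_a.push_back(w.hit ? w.hit_a : -1);
    ev_hit_b.push_back(w.hit ? w.hit_b : -1);
    if (w.hit) {
      bond_a.push_back(w.hit_a); bond_b.push_back(w.hit_b);
      bond_i.push_back(id); bond_j.push_back(w.partner);
    }
    ++t;
    if (t % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  if (A.n_empty() == 0) saturated = true;

  IntegerVector owner(A.owner.begin(), A.owner.end());
  return List::create(
    _["N"] = (double)t,
    _["owner"] = owner,
    _["sites"] = IntegerVector(all_sites.begin(), all_sites.end()),
    _["offsets"] = NumericVector(offsets.begin(), offsets.end()),
    _["volumes"] = NumericVector(volumes.begin(), volumes.end()),
    _["V_t"] = NumericVector(Vt.begin(), Vt.end()),
    _["bond_a"] = IntegerVector(bond_a.begin(), bond_a.end()),
    _["bond_b"] = IntegerVector(bond_b.begin(), bond_b.end()),
    _["bond_i"] = IntegerVector(bond_i.begin(), bond_i.end()),
    _["bond_j"] = IntegerVector(bond_j.begin(), bond_j.end()),
    _["seed_site"] = NumericVector(ev_seed.begin(), ev_seed.end()),
    _["steps"] = NumericVector(ev_steps.begin(), ev_steps.end()),
    _["erased"] = NumericVector(ev_erased.begin(), ev_erased.end()),
    _["len_before_erasure"] = NumericVector(ev_len_before.begin(), ev_len_before.end()),
    _["partner"] = IntegerVector(ev_partner.begin(), ev_partner.end()),
    _["hit_a"] = IntegerVector(ev_hit_a.begin(), ev_hit_a.end()),
    _["hit_b"] = IntegerVector(ev_hit_b.begin(), ev_hit_b.end()),
    _["saturated"] = saturated,
    _["seed_failed"] = seed_failed);
}

// Free LERW on the infinite lattice Z^d (no substrate, no obstacles),
// used for fractal-dimension estimation. Coordinates are packed into a
// 64-bit key (16 bits per axis, offset 32768), limiting extents to
// +/- 32767 per axis, ample for trajectory lengths up to ~1e5.
// [[Rcpp::export]]
List cpp_free_lerw(int d, double target_len, double budget) {
  if (d < 1 || d > 4) stop("free-space LERW supports 1 <= d <= 4");
  long long target = (long long)target_len;
  std::unordered_map<uint64_t, int> posmap;
  posmap.reserve((size_t)(2 * target));
  std::vector<int> coords; // flattened trajectory coords
  coords.reserve((size_t)(target * d));
  std::vector<uint64_t> keys;
  keys.reserve((size_t)target);

  auto pack = [d](const int *c) {
    uint64_t k = 0;
    for (int a = 0; a < d; ++a) k |= ((uint64_t)(uint16_t)(c[a] + 32768)) << (16 * a);
    return k;
  };

  std::vector<int> c0(d, 0);
  keys.push_back(pack(c0.data()));
  posmap[keys[0]] = 0;
  coords.insert(coords.end(), c0.begin(), c0.end());
  long long steps = 0;
  bool exceeded = false;
  size_t len = 1;

  while ((long long)len < target) {
    if (steps >= (long long)budget) { exceeded = true; break; }
    int pick = runif_int(2 * d);
    int axis = pick >> 1, dir = (pick & 1) ? 1 : -1;
    ++steps;
    int nc[4];
    const int *head = &coords[(len - 1) * d];
    for (int a = 0; a < d; ++a) nc[a] = head[a];
    nc[axis] += dir;
    if (nc[axis] > 32767 || nc[axis] < -32767) stop("trajectory extent exceeds packing range");
    uint64_t key = pack(nc);
    auto it = posmap.find(key);
    if (it == posmap.end()) {
      posmap[key] = (int)len;
      keys.push_back(key);
      for (int a = 0; a < d; ++a) coords.push_back(nc[a]);
      ++len;
    } else {
      int j = it->second;
      for (size_t q = j + 1; q < len; ++q) posmap.erase(keys[q]);
      len = (size_t)j + 1;
      keys.resize(len);
      coords.resize(len * d);
    }
    if (steps % 10000000 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix m((int)len, d);
  for (size_t i = 0; i < len; ++i)
    for (int a = 0; a < d; ++a) m((int)i, a) = coords[i * d + a];
  return List::create(_["coords"] = m, _["steps"] = (double)steps,
                      _["budget_exceeded"] = exceeded);
}
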