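// Bond-fluctuation-model kernel for the Dynamic Loop chromatin simulator.
//
// Monomers occupy 2x2x2 cubes of lattice sites keyed by the minimal ("reference")
// corner.  Excluded volume is tracked on a 256^3 occupancy lattice addressed
// modulo 256 (chains are free in space; only relative coordinates matter, and a
// single-chain span anywhere near 254 lattice units is unreachable for the chain
// lengths this package targets -- the kernel still reports the largest span seen
// so callers can assert this).  Loop partner searches use a cell list with cells
// of linear size 4.
//
// All randomness comes from R's RNG stream (RNGScope via Rcpp attributes), so
// set.seed() on the R side makes every run replayable.

#include <RcppArmadillo.h>
#include <vector>
#include <cstdint>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

constexpr int LMASK = 255;          // occupancy lattice is 256^3
constexpr int CMASK = 63;           // cell grid is 64^3, cell size 4

inline int site_index(int x, int y, int z) {
  return ((x & LMASK) << 16) | ((y & LMASK) << 8) | (z & LMASK);
}
inline int cell_index(int x, int y, int z) {
  return (((x >> 2) & CMASK) << 12) | (((y >> 2) & CMASK) << 6) | ((z >> 2) & CMASK);
}

// ---- allowed bond vectors ---------------------------------------------------

// Base classes (2,0,0),(2,1,0),(2,1,1),(2,2,1),(3,0,0),(3,1,0) closed under
// axis permutation and sign inversion: 108 vectors, squared lengths 4,5,6,9,10.
struct BondTable {
  bool ok[7][7][7];
  BondTable() {
    for (int a = 0; a < 7; ++a)
      for (int b = 0; b < 7; ++b)
        for (int c = 0; c < 7; ++c)
          ok[a][b][c] = false;
    const int cls[6][3] = {{2,0,0},{2,1,0},{2,1,1},{2,2,1},{3,0,0},{3,1,0}};
    int perm[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
    for (int k = 0; k < 6; ++k)
      for (int pi = 0; pi < 6; ++pi)
        for (int s = 0; s < 8; ++s) {
          int v[3];
          for (int d = 0; d < 3; ++d) {
            v[d] = cls[k][perm[pi][d]];
            if (s & (1 << d)) v[d] = -v[d];
          }
          ok[v[0] + 3][v[1] + 3][v[2] + 3] = true;
        }
  }
  inline bool allowed(int dx, int dy, int dz) const {
    if (dx < -3 || dx > 3 || dy < -3 || dy > 3 || dz < -3 || dz > 3) return false;
    return ok[dx + 3][dy + 3][dz + 3];
  }
};

const BondTable BT;

// ---- 48-element cubic symmetry group ---------------------------------------

// Signed permutations acting on cube reference corners: when an axis is
// negated the cube [x, x+1] maps to [-x-1, -x], so the new reference corner
// picks up a -1 on that axis.
inline void apply_rot(int rot, const int* v, int* out) {
  static const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  const int* pr = perms[rot >> 3];
  int s = rot & 7;
  for (int d = 0; d < 3; ++d) {
    int val = v[pr[d]];
    out[d] = (s & (1 << d)) ? (-val - 1) : val;
  }
}

// Fast internal generator (xoshiro256++), seeded from R's RNG stream at
// kernel entry so that set.seed() on the R side fully determines every run.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() { return (double)(next() >> 11) * 0x1.0p-53; }
  inline int rint(int n) {
    int k = (int)(runif() * n);
    return k >= n ? n - 1 : k;
  }
};

inline uint64_t seed_from_R() {
  double a = unif_rand(), b = unif_rand();
  return (uint64_t)(a * 4294967296.0) << 32 | (uint64_t)(b * 4294967296.0);
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_bond_allowed(IntegerMatrix deltas) {
  int n = deltas.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = BT.allowed(deltas(i, 0), deltas(i, 1), deltas(i, 2));
  return out;
}

// ---- dynamics ---------------------------------------------------------------

// Runs `sweeps` Monte Carlo sweeps of the Dynamic Loop model.  One sweep = N
// local trial moves, each followed by one loop-formation event (skipped when
// p == 0); loop lifetimes are decremented once per sweep.
//
// pos0:   N x 3 integer matrix of reference corners (valid conformation)
// loops0: k x 3 matrix (i, j, remaining_lifetime), 1-based indices
// Returns final state, stored conformations, and per-record-point series.
// [[Rcpp::export]]
List cpp_run_bfm(IntegerMatrix pos0, IntegerMatrix loops0, int sweeps,
                 double p, double lambda, double coloc_threshold,
                 int store_every, int record_every) {
  const int N = pos0.nrow();
  if (N < 1) stop("empty chain");
  if (record_every < 1) record_every = 1;
  const double thr2 = coloc_threshold * coloc_threshold;
  Xoshiro rng(seed_from_R());

  std::vector<int> X(N), Y(N), Z(N);
  for (int i = 0; i < N; ++i) { X[i] = pos0(i,0); Y[i] = pos0(i,1); Z[i] = pos0(i,2); }

  // an invalid starting bond could never repair itself (single-site moves
  // keep the incident bonds inside the allowed set), so reject it up front
  for (int i = 0; i + 1 < N; ++i)
    if (!BT.allowed(X[i+1]-X[i], Y[i+1]-Y[i], Z[i+1]-Z[i]))
      stop("initial conformation has a disallowed bond at monomer %d", i + 1);

  // occupancy lattice (0/1 per site)
  std::vector<uint8_t> occ(1 << 24, 0);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c) {
          int s = site_index(X[i] + a, Y[i] + b, Z[i] + c);
          if (occ[s]) stop("initial conformation violates excluded volume");
          occ[s] = 1;
        }

  // cell list over reference corners
  std::vector<int> head(1 << 18, -1), nxt(N, -1), prv(N, -1), cellof(N);
  for (int i = 0; i < N; ++i) {
    int c = cell_index(X[i], Y[i], Z[i]);
    cellof[i] = c;
    nxt[i] = head[c];
    if (head[c] >= 0) prv[head[c]] = i;
    prv[i] = -1;
    head[c] = i;
  }

  // active loops + adjacency
  std::vector<int> li, lj;
  std::vector<double> llife;
  std::vector<std::vector<int>> adj(N);
  for (int k = 0; k < loops0.nrow(); ++k) {
    int i = loops0(k,0) - 1, j = loops0(k,1) - 1;
    li.push_back(i); lj.push_back(j); llife.push_back(loops0(k,2));
    adj[i].push_back(j); adj[j].push_back(i);
  }

  auto remove_loop = [&](size_t k) {
    int i = li[k], j = lj[k];
    auto drop = [](std::vector<int>& v, int val) {
      for (size_t t = 0; t < v.size(); ++t)
        if (v[t] == val) { v[t] = v.back(); v.pop_back(); return; }
    };
    drop(adj[i], j); drop(adj[j], i);
    li[k] = li.back(); li.pop_back();
    lj[k] = lj.back(); lj.pop_back();
    llife[k] = llife.back(); llife.pop_back();
  };

  const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

  int n_rec = sweeps / record_every;
  NumericVector rec_rg2(n_rec), rec_acc(n_rec);
  IntegerVector rec_nloop(n_rec), rec_sweep(n_rec);
  List stored;
  IntegerVector stored_at;
  if (store_every > 0) {
    stored = List(sweeps / store_every);
    stored_at = IntegerVector(sweeps / store_every);
  }
  int n_store = 0;
  int span_max = 0;
  long long created = 0, expired = 0;

  std::vector<int> cand;
  cand.reserve(64);

  for (int sw = 1; sw <= sweeps; ++sw) {
    int acc = 0;
    for (int step = 0; step < N; ++step) {
      // ---- trial move ----
      int m = rng.rint(N);
      const int* d = dirs[rng.rint(6)];
      int nx = X[m] + d[0], ny = Y[m] + d[1], nz = Z[m] + d[2];
      bool okmove = true;
      if (m > 0 && !BT.allowed(nx - X[m-1], ny - Y[m-1], nz - Z[m-1])) okmove = false;
      if (okmove && m < N - 1 &&
          !BT.allowed(X[m+1] - nx, Y[m+1] - ny, Z[m+1] - nz)) okmove = false;
      if (okmove) {
        // leading face of the displaced cube: 4 fresh sites must be empty
        int axis = (d[0] ? 0 : (d[1] ? 1 : 2));
        int sgn = d[axis];
        int fx[4], fy[4], fz[4];
        int t = 0;
        for (int u = 0; u < 2; ++u)
          for (int v = 0; v < 2; ++v) {
            int px, py, pz;
            if (axis == 0) { px = (sgn > 0) ? nx + 1 : nx; py = ny + u; pz = nz + v; }
            else if (axis == 1) { py = (sgn > 0) ? ny + 1 : ny; px = nx + u; pz = nz + v; }
            else { pz = (sgn > 0) ? nz + 1 : nz; px = nx + u; py = ny + v; }
            fx[t] = px; fy[t] = py; fz[t] = pz; ++t;
          }
        for (int q = 0; q < 4 && okmove; ++q)
          if (occ[site_index(fx[q], fy[q], fz[q])]) okmove = false;
        if (okmove && !adj[m].empty()) {
          for (int qj : adj[m]) {
            double ddx = nx - X[qj], ddy = ny - Y[qj], ddz = nz - Z[qj];
            if (ddx*ddx + ddy*ddy + ddz*ddz >= thr2) { okmove = false; break; }
          }
        }
        if (okmove) {
          // trailing face of the old cube frees 4 sites
          for (int u = 0; u < 2; ++u)
            for (int v = 0; v < 2; ++v) {
              int px, py, pz;
              if (axis == 0) { px = (sgn > 0) ? X[m] : X[m] + 1; py = Y[m] + u; pz = Z[m] + v; }
              else if (axis == 1) { py = (sgn > 0) ? Y[m] : Y[m] + 1; px = X[m] + u; pz = Z[m] + v; }
              else { pz = (sgn > 0) ? Z[m] : Z[m] + 1; px = X[m] + u; py = Y[m] + v; }
              occ[site_index(px, py, pz)] = 0;
            }
          for (int q = 0; q < 4; ++q) occ[site_index(fx[q], fy[q], fz[q])] = 1;
          X[m] = nx; Y[m] = ny; Z[m] = nz;
          int c = cell_index(nx, ny, nz);
          if (c != cellof[m]) {
            if (prv[m] >= 0) nxt[prv[m]] = nxt[m]; else head[cellof[m]] = nxt[m];
            if (nxt[m] >= 0) prv[nxt[m]] = prv[m];
            cellof[m] = c;
            nxt[m] = head[c]; prv[m] = -1;
            if (head[c] >= 0) prv[head[c]] = m;
            head[c] = m;
          }
          ++acc;
        }
      }
      // ---- loop-formation event ----
      // One monomer is picked at random; if it has co-localized, not-yet-
      // looped partners, one partner is picked uniformly and the loop forms
      // with probability p.  The p-coin is independent of the candidate set,
      // so it is flipped first and the (expensive) candidate search is only
      // done when it succeeds -- the same joint distribution.
      if (p > 0 && rng.runif() < p) {
        int mm = rng.rint(N);
        cand.clear();
        int cx = X[mm] >> 2, cy = Y[mm] >> 2, cz = Z[mm] >> 2;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              int ci = (((cx + a) & CMASK) << 12) | (((cy + b) & CMASK) << 6) | ((cz + c) & CMASK);
              for (int j = head[ci]; j >= 0; j = nxt[j]) {
                if (std::abs(j - mm) < 2) continue;
                double ddx = X[j] - X[mm], ddy = Y[j] - Y[mm], ddz = Z[j] - Z[mm];
                if (ddx*ddx + ddy*ddy + ddz*ddz >= thr2) continue;
                bool already = false;
                for (int qj : adj[mm]) if (qj == j) { already = true; break; }
                if (!already) cand.push_back(j);
              }
            }
        if (!cand.empty()) {
          int j = cand[rng.rint((int)cand.size())];
          double life = R::rpois(lambda);
          li.push_back(mm); lj.push_back(j); llife.push_back(life);
          adj[mm].push_back(j); adj[j].push_back(mm);
          ++created;
        }
      }
    }
    // ---- lifetime decay at sweep end ----
    for (size_t k = 0; k < llife.size(); ) {
      llife[k] -= 1.0;
      if (llife[k] <= 0) { remove_loop(k); ++expired; }
      else ++k;
    }
    // ---- recording ----
    if (sw % record_every == 0) {
      double sx = 0, sy = 0, sz = 0, sxx = 0, syy = 0, szz = 0;
      int mnx = X[0], mxx = X[0], mny = Y[0], mxy = Y[0], mnz = Z[0], mxz = Z[0];
      for (int i = 0; i < N; ++i) {
        sx += X[i]; sy += Y[i]; sz += Z[i];
        sxx += (double)X[i]*X[i]; syy += (double)Y[i]*Y[i]; szz += (double)Z[i]*Z[i];
        if (X[i] < mnx) mnx = X[i]; if (X[i] > mxx) mxx = X[i];
        if (Y[i] < mny) mny = Y[i]; if (Y[i] > mxy) mxy = Y[i];
        if (Z[i] < mnz) mnz = Z[i]; if (Z[i] > mxz) mxz = Z[i];
      }
      int span = std::max(mxx - mnx, std::max(mxy - mny, mxz - mnz));
      if (span > span_max) span_max = span;
      int r = sw / record_every - 1;
      rec_rg2[r] = (sxx - sx*sx/N + syy - sy*sy/N + szz - sz*sz/N) / N;
      rec_nloop[r] = (int)li.size();
      rec_acc[r] = (double)acc / N;
      rec_sweep[r] = sw;
    }
    if (store_every > 0 && sw % store_every == 0) {
      IntegerMatrix cp(N, 3);
      for (int i = 0; i < N; ++i) { cp(i,0) = X[i]; cp(i,1) = Y[i]; cp(i,2) = Z[i]; }
      stored[n_store] = cp;
      stored_at[n_store] = sw;
      ++n_store;
    }
  }

  IntegerMatrix posF(N, 3);
  for (int i = 0; i < N; ++i) { posF(i,0) = X[i]; posF(i,1) = Y[i]; posF(i,2) = Z[i]; }
  int nl = (int)li.size();
  NumericMatrix loopsF(nl, 3);
  for (int k = 0; k < nl; ++k) { loopsF(k,0) = li[k] + 1; loopsF(k,1) = lj[k] + 1; loopsF(k,2) = llife[k]; }

  return List::create(
    _["positions"] = posF, _["loops"] = loopsF,
    _["stored"] = stored, _["stored_at"] = stored_at,
    _["sweep"] = rec_sweep, _["rg2"] = rec_rg2, _["loop_count"] = rec_nloop,
    _["acceptance"] = rec_acc, _["span_max"] = span_max,
    _["loops_created"] = (double)created, _["loops_expired"] = (double)expired);
}

// ---- single trial move (reference path for tests / the trial_move op) -------

// [[Rcpp::export]]
List cpp_trial_move(IntegerMatrix pos, int monomer, IntegerVector dir,
                    IntegerMatrix loops, double coloc_threshold) {
  // 1-based monomer index; dir one of the six unit vectors.
  int N = pos.nrow(), m = monomer - 1;
  int nx = pos(m,0) + dir[0], ny = pos(m,1) + dir[1], nz = pos(m,2) + dir[2];
  bool ok = true;
  if (m > 0 && !BT.allowed(nx - pos(m-1,0), ny - pos(m-1,1), nz - pos(m-1,2))) ok = false;
  if (ok && m < N - 1 && !BT.allowed(pos(m+1,0) - nx, pos(m+1,1) - ny, pos(m+1,2) - nz)) ok = false;
  if (ok) {
    for (int i = 0; i < N && ok; ++i) {
      if (i == m) continue;
      if (std::abs(pos(i,0) - nx) <= 1 && std::abs(pos(i,1) - ny) <= 1 &&
          std::abs(pos(i,2) - nz) <= 1) ok = false;
    }
  }
  if (ok) {
    double thr2 = coloc_threshold * coloc_threshold;
    for (int k = 0; k < loops.nrow() && ok; ++k) {
      int i = loops(k,0) - 1, j = loops(k,1) - 1, q = -1;
      if (i == m) q = j; else if (j == m) q = i;
      if (q >= 0) {
        double dx = nx - pos(q,0), dy = ny - pos(q,1), dz = nz - pos(q,2);
        if (dx*dx + dy*dy + dz*dz >= thr2) ok = false;
      }
    }
  }
  IntegerMatrix out = clone(pos);
  if (ok) { out(m,0) = nx; out(m,1) = ny; out(m,2) = nz; }
  return List::create(_["accepted"] = ok, _["positions"] = out);
}

// ---- superposition sampling -------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_sites_disjoint(IntegerMatrix a, IntegerMatrix b, IntegerMatrix shifts) {
  // For each shift row: are the occupied site sets of a and b + shift disjoint?
  int ns = shifts.nrow();
  LogicalVector out(ns);
  std::vector<uint32_t> stamp(1 << 24, 0);
  uint32_t sv = 0;
  for (int s = 0; s < ns; ++s) {
    ++sv;
    for (int i = 0; i < a.nrow(); ++i)
      for (int u = 0; u < 2; ++u)
        for (int v = 0; v < 2; ++v)
          for (int w = 0; w < 2; ++w)
            stamp[site_index(a(i,0)+u, a(i,1)+v, a(i,2)+w)] = sv;
    bool clash = false;
    for (int i = 0; i < b.nrow() && !clash; ++i)
      for (int u = 0; u < 2 && !clash; ++u)
        for (int v = 0; v < 2 && !clash; ++v)
          for (int w = 0; w < 2 && !clash; ++w)
            if (stamp[site_index(b(i,0)+shifts(s,0)+u, b(i,1)+shifts(s,1)+v,
                                 b(i,2)+shifts(s,2)+w)] == sv) clash = true;
    out[s] = !clash;
  }
  return out;
}

// Dautenhahn-Hall superposition trials at one target center-of-mass distance.
// Each trial: sample one conformation from each ensemble (with replacement),
// rotate each by a random element of the 48-element cubic symmetry group,
// translate b by the integer vector bringing the center-of-mass separation
// closest to target_r along the x axis, and accept iff the occupied site sets
// are disjoint.  Shape statistics are accumulated over accepted trials.
// [[Rcpp::export]]
List cpp_superpose(List confs_a, List confs_b, double target_r, int n_trials,
                   int dens_half, bool collect_shapes) {
  int nA = confs_a.size(), nB = confs_b.size();
  if (nA < 1 || nB < 1) stop("empty ensemble");
  if (n_trials < 1) stop("n_trials must be positive");

  // pre-extract integer matrices
  std::vector<IntegerMatrix> A(nA), B(nB);
  for (int i = 0; i < nA; ++i) A[i] = as<IntegerMatrix>(confs_a[i]);
  for (int i = 0; i < nB; ++i) B[i] = as<IntegerMatrix>(confs_b[i]);

  std::vector<uint32_t> stamp(1 << 24, 0);
  uint32_t sv = 0;
  Xoshiro rng(seed_from_R());

  long long n_acc = 0;
  double sum_r = 0, sum_r_all = 0;
  double sum_rg2 = 0;                       // pooled over both chains of accepted pairs
  double sum_A = 0, sum_A2 = 0;             // pooled asphericity
  long long n_shape = 0;
  double sum_ang = 0, sum_ang2 = 0;
  long long n_ang = 0, n_degen = 0;
  int nbins = 2 * dens_half + 1;
  NumericVector dens_a(nbins), dens_b(nbins);

  std::vector<int> ra(3), rb(3);
  int maxN = 0;
  for (int i = 0; i < nA; ++i) maxN = std::max(maxN, (int)A[i].nrow());
  for (int i = 0; i < nB; ++i) maxN = std::max(maxN, (int)B[i].nrow());
  std::vector<int> ax(maxN), ay(maxN), az(maxN), bx(maxN), by(maxN), bz(maxN);

  arma::mat33 Ta, Tb;
  arma::vec3 eva, evb;
  arma::mat33 Va, Vb;

  for (int t = 0; t < n_trials; ++t) {
    const IntegerMatrix& ca = A[rng.rint(nA)];
    const IntegerMatrix& cb = B[rng.rint(nB)];
    int Na = ca.nrow(), Nb = cb.nrow();
    int rot_a = rng.rint(48), rot_b = rng.rint(48);
    double cax = 0, cay = 0, caz = 0, cbx = 0, cby = 0, cbz = 0;
    for (int i = 0; i < Na; ++i) {
      int v[3] = {ca(i,0), ca(i,1), ca(i,2)}, o[3];
      apply_rot(rot_a, v, o);
      ax[i] = o[0]; ay[i] = o[1]; az[i] = o[2];
      cax += o[0]; cay += o[1]; caz += o[2];
    }
    for (int i = 0; i < Nb; ++i) {
      int v[3] = {cb(i,0), cb(i,1), cb(i,2)}, o[3];
      apply_rot(rot_b, v, o);
      bx[i] = o[0]; by[i] = o[1]; bz[i] = o[2];
      cbx += o[0]; cby += o[1]; cbz += o[2];
    }
    cax /= Na; cay /= Na; caz /= Na;
    cbx /= Nb; cby /= Nb; cbz /= Nb;
    // recenter a near the origin (keeps occupancy addressing well inside 256)
    int sa0 = (int)std::lround(cax), sa1 = (int)std::lround(cay), sa2 = (int)std::lround(caz);
    for (int i = 0; i < Na; ++i) { ax[i] -= sa0; ay[i] -= sa1; az[i] -= sa2; }
    cax -= sa0; cay -= sa1; caz -= sa2;
    // shift b so that com_b - com_a is closest to (target_r, 0, 0)
    int t0 = (int)std::lround(cax + target_r - cbx);
    int t1 = (int)std::lround(cay - cby);
    int t2 = (int)std::lround(caz - cbz);
    for (int i = 0; i < Nb; ++i) { bx[i] += t0; by[i] += t1; bz[i] += t2; }
    double dx = cbx + t0 - cax, dy = cby + t1 - cay, dz = cbz + t2 - caz;
    double rr = std::sqrt(dx*dx + dy*dy + dz*dz);
    sum_r_all += rr;

    // cheap bounding-box rejection of a clash
    bool maybe = true;
    {
      int amn[3] = {ax[0], ay[0], az[0]}, amx[3] = {ax[0], ay[0], az[0]};
      int bmn[3] = {bx[0], by[0], bz[0]}, bmx[3] = {bx[0], by[0], bz[0]};
      for (int i = 1; i < Na; ++i) {
        if (ax[i] < amn[0]) amn[0] = ax[i]; if (ax[i] > amx[0]) amx[0] = ax[i];
        if (ay[i] < amn[1]) amn[1] = ay[i]; if (ay[i] > amx[1]) amx[1] = ay[i];
        if (az[i] < amn[2]) amn[2] = az[i]; if (az[i] > amx[2]) amx[2] = az[i];
      }
      for (int i = 1; i < Nb; ++i) {
        if (bx[i] < bmn[0]) bmn[0] = bx[i]; if (bx[i] > bmx[0]) bmx[0] = bx[i];
        if (by[i] < bmn[1]) bmn[1] = by[i]; if (by[i] > bmx[1]) bmx[1] = by[i];
        if (bz[i] < bmn[2]) bmn[2] = bz[i]; if (bz[i] > bmx[2]) bmx[2] = bz[i];
      }
      maybe = !(bmn[0] > amx[0] + 1 || amn[0] > bmx[0] + 1 ||
                bmn[1] > amx[1] + 1 || amn[1] > bmx[1] + 1 ||
                bmn[2] > amx[2] + 1 || amn[2] > bmx[2] + 1);
    }
    bool accepted = true;
    if (maybe) {
      ++sv;
      for (int i = 0; i < Na; ++i)
        for (int u = 0; u < 2; ++u)
          for (int v = 0; v < 2; ++v)
            for (int w = 0; w < 2; ++w)
              stamp[site_index(ax[i]+u, ay[i]+v, az[i]+w)] = sv;
      for (int i = 0; i < Nb && accepted; ++i)
        for (int u = 0; u < 2 && accepted; ++u)
          for (int v = 0; v < 2 && accepted; ++v)
            for (int w = 0; w < 2 && accepted; ++w)
              if (stamp[site_index(bx[i]+u, by[i]+v, bz[i]+w)] == sv) accepted = false;
    }
    if (!accepted) continue;
    ++n_acc;
    sum_r += rr;
    if (!collect_shapes) continue;

    // gyration tensors of the two chains (monomer centers = corner + 0.5;
    // the constant offset drops out of central moments)
    auto gyr = [](const std::vector<int>& x, const std::vector<int>& y,
                  const std::vector<int>& z, int n, double mx, double my, double mz,
                  arma::mat33& T) {
      double xx=0, yy=0, zz=0, xy=0, xz=0, yz=0;
      for (int i = 0; i < n; ++i) {
        double ux = x[i]-mx, uy = y[i]-my, uz = z[i]-mz;
        xx += ux*ux; yy += uy*uy; zz += uz*uz;
        xy += ux*uy; xz += ux*uz; yz += uy*uz;
      }
      T(0,0)=xx/n; T(1,1)=yy/n; T(2,2)=zz/n;
      T(0,1)=T(1,0)=xy/n; T(0,2)=T(2,0)=xz/n; T(1,2)=T(2,1)=yz/n;
    };
    gyr(ax, ay, az, Na, cax, cay, caz, Ta);
    gyr(bx, by, bz, Nb, cbx + t0, cby + t1, cbz + t2, Tb);
    arma::eig_sym(eva, Va, Ta);
    arma::eig_sym(evb, Vb, Tb);
    double tra = eva(0)+eva(1)+eva(2), trb = evb(0)+evb(1)+evb(2);
    sum_rg2 += tra + trb;
    auto asph = [](const arma::vec3& ev, double tr) {
      double d1 = ev(2)-ev(1), d2 = ev(1)-ev(0), d3 = ev(0)-ev(2);
      return (d1*d1 + d2*d2 + d3*d3) / (2.0 * tr * tr);
    };
    if (tra > 0 && trb > 0) {
      double Aa = asph(eva, tra), Ab = asph(evb, trb);
      sum_A += Aa + Ab; sum_A2 += Aa*Aa + Ab*Ab;
      n_shape += 2;
    }
    bool dega = (eva(2) - eva(1)) < 1e-9 * std::max(tra, 1.0);
    bool degb = (evb(2) - evb(1)) < 1e-9 * std::max(trb, 1.0);
    if (dega || degb) {
      ++n_degen;
    } else {
      double dot = Va(0,2)*Vb(0,2) + Va(1,2)*Vb(1,2) + Va(2,2)*Vb(2,2);
      double ang = std::acos(std::min(1.0, std::fabs(dot))) * 180.0 / M_PI;
      sum_ang += ang; sum_ang2 += ang*ang; ++n_ang;
    }
    if (rr > 1e-9) {
      double ux = dx/rr, uy = dy/rr, uz = dz/rr;
      double midx = cax + dx/2, midy = cay + dy/2, midz = caz + dz/2;
      for (int i = 0; i < Na; ++i) {
        double s = (ax[i]-midx)*ux + (ay[i]-midy)*uy + (az[i]-midz)*uz;
        int bin = (int)std::floor(s) + dens_half;
        if (bin >= 0 && bin < nbins) dens_a[bin] += 1;
      }
      for (int i = 0; i < Nb; ++i) {
        double s = (bx[i]-midx)*ux + (by[i]-midy)*uy + (bz[i]-midz)*uz;
        int bin = (int)std::floor(s) + dens_half;
        if (bin >= 0 && bin < nbins) dens_b[bin] += 1;
      }
    }
  }

  return List::create(
    _["n_total"] = (double)n_trials, _["n_accepted"] = (double)n_acc,
    _["mean_r_accepted"] = n_acc > 0 ? sum_r / n_acc : NA_REAL,
    _["mean_r_all"] = sum_r_all / n_trials,
    _["sum_rg2"] = sum_rg2, _["n_chains"] = (double)(2 * n_acc),
    _["sum_asph"] = sum_A, _["sum_asph2"] = sum_A2, _["n_asph"] = (double)n_shape,
    _["sum_angle"] = sum_ang, _["sum_angle2"] = sum_ang2, _["n_angle"] = (double)n_ang,
    _["n_degenerate"] = (double)n_degen,
    _["dens_a"] = dens_a, _["dens_b"] = dens_b);
}
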