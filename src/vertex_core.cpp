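// Compiled core of the vertex model: polygon geometry, the dimensionless
// tissue energy, incremental energy deltas, the Metropolis vertex-move loop
// with T1 neighbour exchanges and per-iteration parameter ramps, and a
// Bowyer-Watson Delaunay triangulator backing the Voronoi tissue builder.
//
// All public entry points use R's RNG (via Rcpp), so runs are reproducible
// with set.seed() from the R side.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <array>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// basic geometry

static inline double sq(double x) { return x * x; }

// signed area (positive = counter-clockwise) and perimeter of a ring,
// with vertex `sub` (index into the global vertex array, or -1) read from
// (sx, sy) instead of the stored coordinates.
static void ring_metrics(const std::vector<int>& ring,
                         const std::vector<double>& vx,
                         const std::vector<double>& vy,
                         int sub, double sx, double sy,
                         double* area, double* perim) {
  const int k = (int)ring.size();
  double a = 0.0, p = 0.0;
  double x0, y0, x1, y1;
  int id = ring[k - 1];
  x0 = (id == sub) ? sx : vx[id];
  y0 = (id == sub) ? sy : vy[id];
  for (int i = 0; i < k; ++i) {
    id = ring[i];
    x1 = (id == sub) ? sx : vx[id];
    y1 = (id == sub) ? sy : vy[id];
    a += x0 * y1 - x1 * y0;
    p += std::sqrt(sq(x1 - x0) + sq(y1 - y0));
    x0 = x1; y0 = y1;
  }
  *area = 0.5 * a;
  *perim = p;
}

static inline double cross3(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// proper (interior) intersection of segments p1-p2 and p3-p4
static bool seg_cross(double x1, double y1, double x2, double y2,
                      double x3, double y3, double x4, double y4) {
  double d1 = cross3(x3, y3, x4, y4, x1, y1);
  double d2 = cross3(x3, y3, x4, y4, x2, y2);
  double d3 = cross3(x1, y1, x2, y2, x3, y3);
  double d4 = cross3(x1, y1, x2, y2, x4, y4);
  return (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)));
}

// is the ring a simple polygon? O(k^2) pairwise segment test.
static bool ring_simple(const std::vector<int>& ring,
                        const std::vector<double>& vx,
                        const std::vector<double>& vy,
                        int sub, double sx, double sy) {
  const int k = (int)ring.size();
  if (k < 3) return false;
  std::vector<double> x(k), y(k);
  for (int i = 0; i < k; ++i) {
    int id = ring[i];
    x[i] = (id == sub) ? sx : vx[id];
    y[i] = (id == sub) ? sy : vy[id];
  }
  for (int i = 0; i < k; ++i) {
    int i2 = (i + 1) % k;
    for (int j = i + 1; j < k; ++j) {
      int j2 = (j + 1) % k;
      if (j == i || j2 == i || j == i2) continue;  // adjacent share a vertex
      if (seg_cross(x[i], y[i], x[i2], y[i2], x[j], y[j], x[j2], y[j2]))
        return false;
    }
  }
  return true;
}

// ---------------------------------------------------------------------------
// mesh container

struct Mesh {
  std::vector<double> vx, vy;
  std::vector<std::vector<int>> faces;  // 0-based vertex rings, CCW
  std::vector<double> A0, Gamma;
  std::vector<int> tracked;             // face indices (0-based)

  // derived connectivity
  std::vector<int> ea, eb;              // edge endpoints, ea < eb
  std::vector<int> ef1, ef2;            // incident faces (-1 if none)
  std::vector<double> etens;            // effective line tension per edge
  std::vector<std::vector<int>> vfaces; // vertex -> incident faces
  std::vector<std::vector<int>> vedges; // vertex -> incident edges

  double lambda, bfactor, a0_min;

  long long ekey(int a, int b) const {
    if (a > b) std::swap(a, b);
    return (long long)a * (long long)vx.size() + b;
  }

  void rebuild_derived() {
    const int nv = (int)vx.size();
    ea.clear(); eb.clear(); ef1.clear(); ef2.clear(); etens.clear();
    vfaces.assign(nv, {});
    vedges.assign(nv, {});
    std::map<long long, int> emap;
    for (int f = 0; f < (int)faces.size(); ++f) {
      const std::vector<int>& r = faces[f];
      const int k = (int)r.size();
      for (int i = 0; i < k; ++i) {
        vfaces[r[i]].push_back(f);
        int a = r[i], b = r[(i + 1) % k];
        long long key = ekey(a, b);
        std::map<long long, int>::iterator it = emap.find(key);
        if (it == emap.end()) {
          int id = (int)ea.size();
          emap[key] = id;
          ea.push_back(std::min(a, b));
          eb.push_back(std::max(a, b));
          ef1.push_back(f);
          ef2.push_back(-1);
        } else {
          ef2[it->second] = f;
        }
      }
    }
    for (int e = 0; e < (int)ea.size(); ++e) {
      etens.push_back(lambda * (ef2[e] == -1 ? bfactor : 1.0));
      vedges[ea[e]].push_back(e);
      vedges[eb[e]].push_back(e);
    }
  }

  double elen(int e) const {
    return std::sqrt(sq(vx[ea[e]] - vx[eb[e]]) + sq(vy[ea[e]] - vy[eb[e]]));
  }

  // elastic term with the degenerate-resting-area floor: below a0_min the
  // relative form 1/2 (A/A0 - 1)^2 switches to the dimensional 1/2 (A - A0)^2
  double elastic(double A, double a0) const {
    if (a0 >= a0_min) return 0.5 * sq(A / a0 - 1.0);
    return 0.5 * sq(A - a0);
  }

  double face_energy(int f, int sub, double sx, double sy) const {
    double A, P;
    ring_metrics(faces[f], vx, vy, sub, sx, sy, &A, &P);
    return elastic(std::fabs(A), A0[f]) + 0.5 * Gamma[f] * sq(P);
  }

  double total_energy() const {
    double E = 0.0;
    for (int f = 0; f < (int)faces.size(); ++f)
      E += face_energy(f, -1, 0, 0);
    for (int e = 0; e < (int)ea.size(); ++e)
      E += etens[e] * elen(e);
    return E;
  }

  // energy change from moving vertex v to (nx, ny); only incident terms
  double local_delta(int v, double nx, double ny) const {
    double d = 0.0;
    for (size_t i = 0; i < vfaces[v].size(); ++i) {
      int f = vfaces[v][i];
      d += face_energy(f, v, nx, ny) - face_energy(f, -1, 0, 0);
    }
    for (size_t i = 0; i < vedges[v].size(); ++i) {
      int e = vedges[v][i];
      int o = (ea[e] == v) ? eb[e] : ea[e];
      double l0 = std::sqrt(sq(vx[v] - vx[o]) + sq(vy[v] - vy[o]));
      double l1 = std::sqrt(sq(nx - vx[o]) + sq(ny - vy[o]));
      d += etens[e] * (l1 - l0);
    }
    return d;
  }

  // geometric admissibility of moving v to (nx, ny)
  bool move_valid(int v, double nx, double ny) const {
    for (size_t i = 0; i < vfaces[v].size(); ++i) {
      int f = vfaces[v][i];
      double A, P;
      ring_metrics(faces[f], vx, vy, v, nx, ny, &A, &P);
      if (A <= 1e-12) return false;
      if (!ring_simple(faces[f], vx, vy, v, nx, ny)) return false;
    }
    return true;
  }
};

static Mesh mesh_from_list(List m, List params) {
  Mesh M;
  NumericMatrix V = m["vertices"];
  const int nv = V.nrow();
  M.vx.resize(nv); M.vy.resize(nv);
  for (int i = 0; i < nv; ++i) { M.vx[i] = V(i, 0); M.vy[i] = V(i, 1); }
  List fl = m["faces"];
  for (int f = 0; f < fl.size(); ++f) {
    IntegerVector r = fl[f];
    std::vector<int> ring(r.size());
    for (int i = 0; i < r.size(); ++i) ring[i] = r[i] - 1;
    M.faces.push_back(ring);
  }
  M.A0 = as<std::vector<double>>(m["resting_area"]);
  M.Gamma = as<std::vector<double>>(m["contractility"]);
  LogicalVector tr = m["tracked"];
  for (int f = 0; f < tr.size(); ++f) if (tr[f]) M.tracked.push_back(f);
  M.lambda = as<double>(params["line_tension_tilde"]);
  M.bfactor = as<double>(params["boundary_tension_factor"]);
  M.a0_min = as<double>(params["a0_min"]);
  M.rebuild_derived();
  return M;
}

static List mesh_to_list(const Mesh& M, List original) {
  const int nv = (int)M.vx.size();
  NumericMatrix V(nv, 2);
  for (int i = 0; i < nv; ++i) { V(i, 0) = M.vx[i]; V(i, 1) = M.vy[i]; }
  List fl(M.faces.size());
  for (size_t f = 0; f < M.faces.size(); ++f) {
    IntegerVector r((int)M.faces[f].size());
    for (int i = 0; i < r.size(); ++i) r[i] = M.faces[f][i] + 1;
    fl[f] = r;
  }
  List out = clone(original);
  out["vertices"] = V;
  out["faces"] = fl;
  out["resting_area"] = wrap(M.A0);
  out["contractility"] = wrap(M.Gamma);
  return out;
}

// [[Rcpp::export]]
double cpp_tissue_energy(List mesh, List params) {
  Mesh M = mesh_from_list(mesh, params);
  return M.total_energy();
}

// [[Rcpp::export]]
double cpp_local_energy_delta(List mesh, List params, int vertex,
                              double nx, double ny) {
  Mesh M = mesh_from_list(mesh, params);
  return M.local_delta(vertex - 1, nx, ny);
}

// [[Rcpp::export]]
bool cpp_move_valid(List mesh, List params, int vertex, double nx, double ny) {
  Mesh M = mesh_from_list(mesh, params);
  return M.move_valid(vertex - 1, nx, ny);
}

// [[Rcpp::export]]
bool cpp_ring_simple(NumericMatrix coords) {
  std::vector<double> x(coords.nrow()), y(coords.nrow());
  std::vector<int> ring(coords.nrow());
  for (int i = 0; i < coords.nrow(); ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); ring[i] = i;
  }
  return ring_simple(ring, x, y, -1, 0, 0);
}

// Metropolis acceptance rule shared by vertex moves and T1 rewirings:
// downhill always, uphill with probability p_accept.
static inline bool mc_accept(double dE, double p_accept) {
  return dE < 0.0 || unif_rand() < p_accept;
}

// [[Rcpp::export]]
LogicalVector cpp_accept_rule(NumericVector delta_e, double p_accept) {
  LogicalVector out(delta_e.size());
  for (int i = 0; i < delta_e.size(); ++i)
    out[i] = mc_accept(delta_e[i], p_accept);
  return out;
}

// ---------------------------------------------------------------------------
// T1 transitions

// Attempt the T1 rewiring of edge e = (i, j); returns the energy change on
// success (via *dE) and whether the flip was applied. Acceptance follows the
// same Metropolis rule as vertex moves.
static bool attempt_t1(Mesh& M, int e, double new_len, double p_accept,
                       bool* geometric_fail) {
  *geometric_fail = true;
  int i = M.ea[e], j = M.eb[e];
  int A = M.ef1[e], B = M.ef2[e];
  if (B == -1) return false;                 // boundary edge: no T1
  if (M.vfaces[i].size() != 3 || M.vfaces[j].size() != 3) return false;
  if ((int)M.faces[A].size() <= 3 || (int)M.faces[B].size() <= 3) return false;
  int C = -1, D = -1;
  for (size_t k = 0; k < M.vfaces[i].size(); ++k) {
    int f = M.vfaces[i][k];
    if (f != A && f != B) C = f;
  }
  for (size_t k = 0; k < M.vfaces[j].size(); ++k) {
    int f = M.vfaces[j][k];
    if (f != A && f != B) D = f;
  }
  if (C == -1 || D == -1 || C == D) return false;

  // rotated endpoint positions: midpoint +/- new_len/2 along the orthogonal
  double mx = 0.5 * (M.vx[i] + M.vx[j]), my = 0.5 * (M.vy[i] + M.vy[j]);
  double dx = M.vx[j] - M.vx[i], dy = M.vy[j] - M.vy[i];
  double L = std::sqrt(sq(dx) + sq(dy));
  if (L < 1e-14) return false;
  double ux = -dy / L, uy = dx / L;
  double px = 0.5 * new_len * ux, py = 0.5 * new_len * uy;

  // saved state for revert
  std::vector<int> sA = M.faces[A], sB = M.faces[B], sC = M.faces[C],
                   sD = M.faces[D];
  double six = M.vx[i], siy = M.vy[i], sjx = M.vx[j], sjy = M.vy[j];
  double E_before = M.total_energy();

  double bestE = std::numeric_limits<double>::infinity();
  std::vector<int> bA, bB, bC, bD;
  double bix = 0, biy = 0, bjx = 0, bjy = 0;

  for (int side = 0; side < 2; ++side) {
    double ix = (side == 0) ? mx + px : mx - px;
    double iy = (side == 0) ? my + py : my - py;
    double jx = (side == 0) ? mx - px : mx + px;
    double jy = (side == 0) ? my - py : my + py;
    for (int ci = 0; ci < 2; ++ci) {
      for (int di = 0; di < 2; ++di) {
        // candidate rings: A loses j, B loses i, C gains j next to i,
        // D gains i next to j
        std::vector<int> cA, cB, cC, cD;
        for (size_t k = 0; k < sA.size(); ++k)
          if (sA[k] != j) cA.push_back(sA[k]);
        for (size_t k = 0; k < sB.size(); ++k)
          if (sB[k] != i) cB.push_back(sB[k]);
        for (size_t k = 0; k < sC.size(); ++k) {
          if (sC[k] == i && ci == 0) cC.push_back(j);
          cC.push_back(sC[k]);
          if (sC[k] == i && ci == 1) cC.push_back(j);
        }
        for (size_t k = 0; k < sD.size(); ++k) {
          if (sD[k] == j && di == 0) cD.push_back(i);
          cD.push_back(sD[k]);
          if (sD[k] == j && di == 1) cD.push_back(i);
        }
        M.faces[A] = cA; M.faces[B] = cB; M.faces[C] = cC; M.faces[D] = cD;
        M.vx[i] = ix; M.vy[i] = iy; M.vx[j] = jx; M.vy[j] = jy;
        bool ok = true;
        int ff[4] = {A, B, C, D};
        for (int q = 0; q < 4 && ok; ++q) {
          double Aq, Pq;
          if ((int)M.faces[ff[q]].size() < 3) { ok = false; break; }
          ring_metrics(M.faces[ff[q]], M.vx, M.vy, -1, 0, 0, &Aq, &Pq);
          if (Aq <= 1e-12) ok = false;
          else if (!ring_simple(M.faces[ff[q]], M.vx, M.vy, -1, 0, 0)) ok = false;
        }
        if (ok) {
          M.rebuild_derived();
          double E_after = M.total_energy();
          if (E_after < bestE) {
            bestE = E_after;
            bA = cA; bB = cB; bC = cC; bD = cD;
            bix = ix; biy = iy; bjx = jx; bjy = jy;
          }
        }
        // revert for the next candidate
        M.faces[A] = sA; M.faces[B] = sB; M.faces[C] = sC; M.faces[D] = sD;
        M.vx[i] = six; M.vy[i] = siy; M.vx[j] = sjx; M.vy[j] = sjy;
      }
    }
  }
  M.rebuild_derived();
  if (!std::isfinite(bestE)) return false;  // no geometrically valid rewiring
  *geometric_fail = false;

  double dE = bestE - E_before;
  if (!mc_accept(dE, p_accept)) return false;

  M.faces[A] = bA; M.faces[B] = bB; M.faces[C] = bC; M.faces[D] = bD;
  M.vx[i] = bix; M.vy[i] = biy; M.vx[j] = bjx; M.vy[j] = bjy;
  M.rebuild_derived();
  return true;
}

// [[Rcpp::export]]
List cpp_t1_sweep(List mesh, List params, double d_min, double new_len,
                  double p_accept) {
  Mesh M = mesh_from_list(mesh, params);
  double E0 = M.total_energy();
  int done = 0, skipped = 0;
  // collect candidate vertex pairs first; topology changes during the sweep
  std::vector<std::pair<int, int>> cand;
  for (int e = 0; e < (int)M.ea.size(); ++e)
    if (M.ef2[e] != -1 && M.elen(e) < d_min)
      cand.push_back(std::make_pair(M.ea[e], M.eb[e]));
  for (size_t c = 0; c < cand.size(); ++c) {
    // re-locate the edge (ids are stable; edge indices are not)
    int found = -1;
    for (int e = 0; e < (int)M.ea.size(); ++e)
      if (M.ea[e] == cand[c].first && M.eb[e] == cand[c].second) { found = e; break; }
    if (found == -1 || M.ef2[found] == -1 || M.elen(found) >= d_min) continue;
    bool gf;
    if (attempt_t1(M, found, new_len, p_accept, &gf)) ++done;
    else if (gf) ++skipped;
  }
  double E1 = M.total_energy();
  return List::create(_["mesh"] = mesh_to_list(M, mesh),
                      _["n_rewired"] = done,
                      _["n_skipped"] = skipped,
                      _["energy_delta"] = E1 - E0);
}

// ---------------------------------------------------------------------------
// Metropolis run loop

// schedule: list(condition = 0 control / 1 contractility / 2 resting_area,
//                rate, ramp_start_iter (0-based), targets = 1-based face ids)
// [[Rcpp::export]]
List cpp_run(List mesh, List params, List schedule,
             int n_iterations, int iterations_per_sts, int sts_offset,
             bool enable_t1, bool record) {
  Mesh M = mesh_from_list(mesh, params);
  const double p_accept = as<double>(params["p_accept"]);
  const double delta_max = as<double>(params["delta_max"]);
  const double d_min = as<double>(params["d_min"]);
  const double t1_new_length = as<double>(params["t1_new_length"]);
  const int t1_check = as<int>(params["t1_check_interval"]);
  const bool literal = as<std::string>(params["proposal_mode"]) == "literal";

  const int cond = as<int>(schedule["condition"]);
  const double rate = as<double>(schedule["rate"]);
  const double ramp_start = as<double>(schedule["ramp_start_iter"]);
  IntegerVector tg = schedule["targets"];
  std::vector<int> targets(tg.size());
  for (int i = 0; i < tg.size(); ++i) targets[i] = tg[i] - 1;

  const int nv = (int)M.vx.size();
  long accepted = 0, rejected = 0, rejected_geom = 0;
  long t1_done = 0, t1_skipped = 0;
  double delta_sum = 0.0, max_disp = 0.0;
  const double E_init = M.total_energy();

  // per-sts observable records for tracked faces
  std::vector<double> rec_sts, rec_face, rec_P, rec_A, rec_C;
  std::map<long long, double> prev_len;  // edge length one sts ago

  int n_rec_sts = record ? (n_iterations / std::max(iterations_per_sts, 1) + 1) : 0;
  (void)n_rec_sts;

  // record helper
  struct Rec {
    std::vector<double>*s, *f, *p, *a, *c;
    void operator()(const Mesh& M, double sts) {
      for (size_t t = 0; t < M.tracked.size(); ++t) {
        int fc = M.tracked[t];
        double A, P;
        ring_metrics(M.faces[fc], M.vx, M.vy, -1, 0, 0, &A, &P);
        A = std::fabs(A);
        s->push_back(sts); f->push_back(fc + 1);
        p->push_back(P); a->push_back(A);
        c->push_back(4.0 * M_PI * A / sq(P));
      }
    }
  } rec = {&rec_sts, &rec_face, &rec_P, &rec_A, &rec_C};

  struct Snap {
    std::map<long long, double>* m;
    void operator()(const Mesh& M) {
      m->clear();
      for (int e = 0; e < (int)M.ea.size(); ++e)
        (*m)[(long long)M.ea[e] * (long long)M.vx.size() + M.eb[e]] = M.elen(e);
    }
  } snap = {&prev_len};

  if (record) rec(M, sts_offset);
  snap(M);

  for (int it = 0; it < n_iterations; ++it) {
    const long long global_it = (long long)sts_offset * iterations_per_sts + it;
    // one trial vertex move
    int v = (int)std::floor(unif_rand() * nv);
    if (v == nv) v = nv - 1;
    double dx, dy;
    if (literal) {
      double d = unif_rand() * delta_max;
      dx = d; dy = d;
    } else {
      dx = (2.0 * unif_rand() - 1.0) * delta_max;
      dy = (2.0 * unif_rand() - 1.0) * delta_max;
    }
    double nx = M.vx[v] + dx, ny = M.vy[v] + dy;
    if (!M.move_valid(v, nx, ny)) {
      ++rejected_geom;
    } else {
      double dE = M.local_delta(v, nx, ny);
      if (mc_accept(dE, p_accept)) {
        M.vx[v] = nx; M.vy[v] = ny;
        ++accepted;
        delta_sum += dE;
        double md = std::max(std::fabs(dx), std::fabs(dy));
        if (md > max_disp) max_disp = md;
      } else {
        ++rejected;
      }
    }
    // parameter ramps, once per global iteration
    if (cond != 0 && rate > 0.0 && (double)global_it >= ramp_start) {
      if (cond == 1) {
        for (size_t t = 0; t < targets.size(); ++t)
          M.Gamma[targets[t]] *= (1.0 + rate);
      } else {
        for (size_t t = 0; t < targets.size(); ++t)
          M.A0[targets[t]] *= (1.0 - rate);
      }
    }
    // periodic T1 sweep: short edges that shrank since the last sts
    if (enable_t1 && t1_check > 0 && (it + 1) % t1_check == 0) {
      std::vector<std::pair<int, int>> cand;
      for (int e = 0; e < (int)M.ea.size(); ++e) {
        if (M.ef2[e] == -1) continue;
        double l = M.elen(e);
        if (l >= d_min) continue;
        std::map<long long, double>::iterator pl =
          prev_len.find((long long)M.ea[e] * (long long)nv + M.eb[e]);
        if (pl == prev_len.end() || l >= pl->second) continue;
        cand.push_back(std::make_pair(M.ea[e], M.eb[e]));
      }
      for (size_t c = 0; c < cand.size(); ++c) {
        int found = -1;
        for (int e = 0; e < (int)M.ea.size(); ++e)
          if (M.ea[e] == cand[c].first && M.eb[e] == cand[c].second) {
            found = e; break;
          }
        if (found == -1 || M.ef2[found] == -1 || M.elen(found) >= d_min)
          continue;
        double Eb = M.total_energy();
        bool gf;
        if (attempt_t1(M, found, t1_new_length, p_accept, &gf)) {
          ++t1_done;
          delta_sum += M.total_energy() - Eb;
        } else if (gf) {
          ++t1_skipped;
        }
      }
    }
    // sts boundary bookkeeping
    if (iterations_per_sts > 0 && (it + 1) % iterations_per_sts == 0) {
      if (record) rec(M, sts_offset + (it + 1) / iterations_per_sts);
      snap(M);
      Rcpp::checkUserInterrupt();
    }
  }

  DataFrame obs = DataFrame::create(
    _["sts"] = wrap(rec_sts), _["cell"] = wrap(rec_face),
    _["perimeter"] = wrap(rec_P), _["area"] = wrap(rec_A),
    _["circularity"] = wrap(rec_C));

  return List::create(
    _["mesh"] = mesh_to_list(M, mesh),
    _["observables"] = obs,
    _["accepted"] = (double)accepted,
    _["rejected"] = (double)rejected,
    _["rejected_geometry"] = (double)rejected_geom,
    _["t1_count"] = (double)t1_done,
    _["t1_skipped"] = (double)t1_skipped,
    _["delta_sum"] = delta_sum,
    _["max_displacement"] = max_disp,
    _["energy_initial"] = E_init,
    _["energy_final"] = M.total_energy());
}

// ---------------------------------------------------------------------------
// Bowyer-Watson Delaunay triangulation (backs the Voronoi tissue builder)

struct Tri {
  int a, b, c;
  double cx, cy, r2;
  bool dead;
};

static bool circumcircle(double ax, double ay, double bx, double by,
                         double cx, double cy, double* ox, double* oy,
                         double* r2) {
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) return false;
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  *ox = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  *oy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  *r2 = sq(ax - *ox) + sq(ay - *oy);
  return true;
}

// [[Rcpp::export]]
List cpp_delaunay(NumericVector x, NumericVector y) {
  const int n = x.size();
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) { px[i] = x[i]; py[i] = y[i]; }
  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double w = std::max(xmax - xmin, ymax - ymin) + 1.0;
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  px[n] = cx - 30.0 * w; py[n] = cy - 10.0 * w;
  px[n + 1] = cx + 30.0 * w; py[n + 1] = cy - 10.0 * w;
  px[n + 2] = cx; py[n + 2] = cy + 30.0 * w;

  std::vector<Tri> tris;
  Tri t0; t0.a = n; t0.b = n + 1; t0.c = n + 2; t0.dead = false;
  circumcircle(px[t0.a], py[t0.a], px[t0.b], py[t0.b], px[t0.c], py[t0.c],
               &t0.cx, &t0.cy, &t0.r2);
  tris.push_back(t0);

  std::map<long long, int> edge_count;
  std::vector<long long> poly_edges;
  for (int i = 0; i < n; ++i) {
    edge_count.clear();
    poly_edges.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (tris[t].dead) continue;
      double dx = px[i] - tris[t].cx, dy = py[i] - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2 * (1.0 + 1e-12)) {
        tris[t].dead = true;
        int vv[3] = {tris[t].a, tris[t].b, tris[t].c};
        for (int e = 0; e < 3; ++e) {
          int a = vv[e], b = vv[(e + 1) % 3];
          if (a > b) std::swap(a, b);
          long long key = (long long)a * (long long)(n + 3) + b;
          edge_count[key] += 1;
        }
      }
    }
    for (std::map<long long, int>::iterator it = edge_count.begin();
         it != edge_count.end(); ++it)
      if (it->second == 1) poly_edges.push_back(it->first);
    for (size_t e = 0; e < poly_edges.size(); ++e) {
      int a = (int)(poly_edges[e] / (n + 3));
      int b = (int)(poly_edges[e] % (n + 3));
      Tri nt; nt.a = a; nt.b = b; nt.c = i; nt.dead = false;
      if (!circumcircle(px[a], py[a], px[b], py[b], px[i], py[i],
                        &nt.cx, &nt.cy, &nt.r2))
        continue;  // degenerate (collinear) – skip
      tris.push_back(nt);
    }
    // periodic compaction keeps the scan linear in live triangles
    if (tris.size() > 8u * (size_t)(i + 4)) {
      std::vector<Tri> keep;
      keep.reserve(tris.size());
      for (size_t t = 0; t < tris.size(); ++t)
        if (!tris[t].dead) keep.push_back(tris[t]);
      tris.swap(keep);
    }
  }

  std::vector<int> ta, tb, tc;
  std::vector<double> ccx, ccy;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (tris[t].dead) continue;
    if (tris[t].a >= n || tris[t].b >= n || tris[t].c >= n) continue;
    ta.push_back(tris[t].a + 1);
    tb.push_back(tris[t].b + 1);
    tc.push_back(tris[t].c + 1);
    ccx.push_back(tris[t].cx);
    ccy.push_back(tris[t].cy);
  }
  const int m = (int)ta.size();
  IntegerMatrix T(m, 3);
  NumericMatrix CC(m, 2);
  for (int t = 0; t < m; ++t) {
    T(t, 0) = ta[t]; T(t, 1) = tb[t]; T(t, 2) = tc[t];
    CC(t, 0) = ccx[t]; CC(t, 1) = ccy[t];
  }
  return List::create(_["triangles"] = T, _["circumcenters"] = CC);
}
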