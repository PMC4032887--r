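#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>
#include <unordered_map>

using namespace Rcpp;

// Multi-seed Fast Marching solver for |grad T| * I = 1 on an anisotropic
// voxel lattice. Upwind Godunov discretization: per axis only the smaller
// accepted neighbor enters the quadratic. Voxels with I == 0 are hard
// barriers (never accepted). Optionally halts once a voxel whose Euclidean
// distance to the nearest boundary voxel exceeds dmax would be accepted.
//
// Front labels: every boundary voxel carries a label; accepted voxels
// inherit the label of their minimal-T accepted 6-neighbor. A voxel whose
// accepted 6-neighborhood (at acceptance time) spans >= 2 labels is
// recorded as a collision voxel, in acceptance (= nondecreasing T) order.

static const double INF = std::numeric_limits<double>::infinity();

struct HeapItem {
  double t;
  int idx;
  bool operator>(const HeapItem& o) const { return t > o.t; }
};

// solve sum_a max(T - t_a, 0)^2 / s_a^2 = 1 / I^2 for T
static double solve_upwind(double t[3], const double s[3], double inten) {
  // collect finite upwind values with weights, sorted ascending
  struct Cand { double t, w; };
  Cand c[3];
  int n = 0;
  for (int a = 0; a < 3; ++a) {
    if (R_finite(t[a])) { c[n].t = t[a]; c[n].w = 1.0 / (s[a] * s[a]); ++n; }
  }
  if (n == 0) return INF;
  // insertion sort by t
  for (int i = 1; i < n; ++i) {
    Cand key = c[i];
    int j = i - 1;
    while (j >= 0 && c[j].t > key.t) { c[j + 1] = c[j]; --j; }
    c[j + 1] = key;
  }
  double rhs = 1.0 / (inten * inten);
  double best = INF;
  for (int k = 1; k <= n; ++k) {
    // solve with the first k candidates: sum w_i (T - t_i)^2 = rhs
    double A = 0, B = 0, C = -rhs;
    for (int i = 0; i < k; ++i) {
      A += c[i].w;
      B += -2.0 * c[i].w * c[i].t;
      C += c[i].w * c[i].t * c[i].t;
    }
    double disc = B * B - 4 * A * C;
    if (disc < 0) continue;
    double T = (-B + std::sqrt(disc)) / (2 * A);
    if (T < c[k - 1].t) continue;          // not upwind w.r.t. used values
    if (k < n && T > c[k].t) continue;     // should have used more values
    best = T;
    break;
  }
  if (!R_finite(best)) {
    // fallback: one-sided update from the smallest candidate
    best = c[0].t + std::sqrt(rhs / c[0].w);
  }
  return best;
}

// [[Rcpp::export(name = ".fm_run_cpp")]]
List fm_run_cpp(NumericVector voxels, IntegerVector dims, NumericVector spacing,
                IntegerMatrix boundary, IntegerVector blabels, double dmax) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double s[3] = {sx, sy, sz};
  const int ntot = nx * ny * nz;
  std::vector<double> T(ntot, INF);
  std::vector<int> lab(ntot, 0);
  std::vector<unsigned char> state(ntot, 0); // 0 far, 1 trial, 2 accepted

  const bool limited = R_finite(dmax);

  // spatial hash of boundary points for nearest-boundary distance queries
  std::unordered_map<long long, std::vector<int> > buckets;
  double cell = limited ? dmax : 1.0;
  if (cell <= 0) cell = 1.0;
  const int nb = boundary.nrow();
  if (nb == 0) stop("boundary must be nonempty");
  std::vector<double> bx(nb), by(nb), bz(nb);
  for (int i = 0; i < nb; ++i) {
    bx[i] = (boundary(i, 0) - 1) * sx;
    by[i] = (boundary(i, 1) - 1) * sy;
    bz[i] = (boundary(i, 2) - 1) * sz;
    if (limited) {
      long long cx = (long long)std::floor(bx[i] / cell);
      long long cy = (long long)std::floor(by[i] / cell);
      long long cz = (long long)std::floor(bz[i] / cell);
      long long key = (cx * 73856093LL) ^ (cy * 19349663LL) ^ (cz * 83492791LL);
      buckets[key].push_back(i);
    }
  }
  auto bdist = [&](int i, int j, int k) -> double {
    double px = i * sx, py = j * sy, pz = k * sz;
    double best = INF;
    if (!limited) return 0.0;
    long long cx = (long long)std::floor(px / cell);
    long long cy = (long long)std::floor(py / cell);
    long long cz = (long long)std::floor(pz / cell);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          long long key = ((cx + dx) * 73856093LL) ^ ((cy + dy) * 19349663LL) ^
                          ((cz + dz) * 83492791LL);
          auto it = buckets.find(key);
          if (it == buckets.end()) continue;
          for (int b : it->second) {
            double d2 = (px - bx[b]) * (px - bx[b]) +
                        (py - by[b]) * (py - by[b]) +
                        (pz - bz[b]) * (pz - bz[b]);
            if (d2 < best) best = d2;
          }
        }
    return std::sqrt(best);
  };

  std::priority_queue<HeapItem, std::vector<HeapItem>, std::greater<HeapItem> > heap;

  auto lin = [&](int i, int j, int k) { return i + nx * (j + ny * k); };

  for (int b = 0; b < nb; ++b) {
    int i = boundary(b, 0) - 1, j = boundary(b, 1) - 1, k = boundary(b, 2) - 1;
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
      stop("boundary voxel outside stack");
    int v = lin(i, j, k);
    if (voxels[v] <= 0) stop("boundary voxel has zero intensity");
    T[v] = 0.0;
    lab[v] = blabels[b];
    state[v] = 2;
  }

  const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};

  auto update_trial = [&](int i, int j, int k) {
    int v = lin(i, j, k);
    if (state[v] == 2) return;
    double inten = voxels[v];
    if (inten <= 0) return; // hard barrier
    double tax[3];
    for (int a = 0; a < 3; ++a) {
      double tmin = INF;
      for (int dir = 0; dir < 2; ++dir) {
        int ii = i + (a == 0 ? (dir ? 1 : -1) : 0);
        int jj = j + (a == 1 ? (dir ? 1 : -1) : 0);
        int kk = k + (a == 2 ? (dir ? 1 : -1) : 0);
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        int w = lin(ii, jj, kk);
        if (state[w] == 2 && T[w] < tmin) tmin = T[w];
      }
      tax[a] = tmin;
    }
    double tnew = solve_upwind(tax, s, inten);
    if (tnew < T[v]) {
      T[v] = tnew;
      state[v] = 1;
      heap.push({tnew, v});
    }
  };

  // seed the heap
  for (int b = 0; b < nb; ++b) {
    int i = boundary(b, 0) - 1, j = boundary(b, 1) - 1, k = boundary(b, 2) - 1;
    for (int d = 0; d < 6; ++d) {
      int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      update_trial(ii, jj, kk);
    }
  }

  std::vector<int> coll_idx;
  std::vector<double> coll_T;
  std::vector<int> coll_labA, coll_labB;

  bool halted = false;
  int far_idx = -1;
  double far_dist = -1.0;

  while (!heap.empty()) {
    HeapItem top = heap.top();
    heap.pop();
    int v = top.idx;
    if (state[v] == 2) continue;       // stale entry
    if (top.t > T[v]) continue;        // superseded
    int k = v / (nx * ny);
    int j = (v - k * nx * ny) / nx;
    int i = v - k * nx * ny - j * nx;

    if (limited) {
      double d = bdist(i, j, k);
      if (d > dmax) { halted = true; break; }
      if (d > far_dist) { far_dist = d; far_idx = v; }
    }

    state[v] = 2;

    // label inheritance + collision detection over accepted 6-neighbors
    int bestlab = 0, otherlab = 0;
    double bestT = INF;
    for (int d = 0; d < 6; ++d) {
      int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      int w = lin(ii, jj, kk);
      if (state[w] != 2 || w == v) continue;
      if (T[w] < bestT) { bestT = T[w]; bestlab = lab[w]; }
    }
    lab[v] = bestlab;
    for (int d = 0; d < 6; ++d) {
      int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      int w = lin(ii, jj, kk);
      if (state[w] == 2 && lab[w] != 0 && lab[w] != bestlab) {
        otherlab = lab[w];
        break;
      }
    }
    if (otherlab != 0) {
      coll_idx.push_back(v + 1);
      coll_T.push_back(T[v]);
      coll_labA.push_back(bestlab);
      coll_labB.push_back(otherlab);
    }

    for (int d = 0; d < 6; ++d) {
      int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      update_trial(ii, jj, kk);
    }
  }

  bool exhausted = limited && !halted;

  NumericVector Tout(T.begin(), T.end());
  Tout.attr("dim") = dims;
  IntegerVector Lout(lab.begin(), lab.end());
  Lout.attr("dim") = dims;
  IntegerVector Sout(ntot);
  for (int v = 0; v < ntot; ++v) Sout[v] = state[v];
  Sout.attr("dim") = dims;

  return List::create(
      _["T"] = Tout, _["label"] = Lout, _["state"] = Sout,
      _["farthest"] = far_idx + 1, _["farthest_dist"] = far_dist,
      _["halted"] = halted, _["exhausted"] = exhausted,
      _["collision_idx"] = IntegerVector(coll_idx.begin(), coll_idx.end()),
      _["collision_T"] = NumericVector(coll_T.begin(), coll_T.end()),
      _["collision_labA"] = IntegerVector(coll_labA.begin(), coll_labA.end()),
      _["collision_labB"] = IntegerVector(coll_labB.begin(), coll_labB.end()));
}
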