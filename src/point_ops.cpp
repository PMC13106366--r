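// Low-level spatial kernels: uniform-grid fixed-radius neighbor search and
// the exact algorithms built on it (density clustering, PCA normals,
// constrained region growing). Contracts are exactness; the grid is only an
// index structure.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Grid {
  double cell;
  double ox, oy, oz;
  std::unordered_map<long long, std::vector<int>> cells;
  const double* x;
  const double* y;
  const double* z;
  int n;

  static long long key(int i, int j, int k) {
    // 21 bits per axis, offset to keep indices positive
    const long long B = 1 << 20;
    return (((long long)(i + B)) << 42) | (((long long)(j + B)) << 21) |
           ((long long)(k + B));
  }

  Grid(const NumericMatrix& pts, double cell_) : cell(cell_) {
    n = pts.nrow();
    x = &pts(0, 0);
    y = &pts(0, 1);
    z = &pts(0, 2);
    ox = oy = oz = R_PosInf;
    for (int i = 0; i < n; ++i) {
      ox = std::min(ox, x[i]);
      oy = std::min(oy, y[i]);
      oz = std::min(oz, z[i]);
    }
    cells.reserve(n);
    for (int i = 0; i < n; ++i) cells[cell_of(i)].push_back(i);
  }

  long long cell_of(int i) const {
    return key((int)std::floor((x[i] - ox) / cell),
               (int)std::floor((y[i] - oy) / cell),
               (int)std::floor((z[i] - oz) / cell));
  }

  // exact neighbors of point i within radius r (r <= cell), excluding self
  template <class F>
  void visit_neighbors(int i, double r, F f) const {
    double r2 = r * r;
    int ci = (int)std::floor((x[i] - ox) / cell);
    int cj = (int)std::floor((y[i] - oy) / cell);
    int ck = (int)std::floor((z[i] - oz) / cell);
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk) {
          auto it = cells.find(key(ci + di, cj + dj, ck + dk));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
            if (dx * dx + dy * dy + dz * dz <= r2) f(j);
          }
        }
  }
};

}  // namespace

// Density-based clustering with a fixed deterministic rule:
// core point  : |N_eps(p)| >= min_pts (neighborhood includes p itself);
// clusters    : connected components of the core-core eps graph, numbered
//               in order of their smallest point index;
// border point: non-core point with >= 1 core neighbor, assigned to the
//               lowest cluster id among its core neighbors;
// otherwise   : noise (label 0).
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix pts, double eps, int min_pts) {
  int n = pts.nrow();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  Grid g(pts, eps);

  std::vector<char> core(n, 0);
  for (int i = 0; i < n; ++i) {
    int cnt = 1;  // the point itself
    g.visit_neighbors(i, eps, [&](int) { ++cnt; });
    core[i] = cnt >= min_pts;
  }

  std::vector<int> comp(n, 0);
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || comp[i] != 0) continue;
    ++next_id;
    std::queue<int> q;
    q.push(i);
    comp[i] = next_id;
    while (!q.empty()) {
      int p = q.front();
      q.pop();
      g.visit_neighbors(p, eps, [&](int j) {
        if (core[j] && comp[j] == 0) {
          comp[j] = next_id;
          q.push(j);
        }
      });
    }
  }

  for (int i = 0; i < n; ++i) {
    if (core[i]) {
      labels[i] = comp[i];
    } else {
      int best = 0;
      g.visit_neighbors(i, eps, [&](int j) {
        if (core[j] && (best == 0 || comp[j] < best)) best = comp[j];
      });
      labels[i] = best;
    }
  }
  return labels;
}

// Per-point unit normal and curvature from the covariance of the k nearest
// neighbors. nn_idx is 1-based (RANN convention) and includes the point
// itself in its row. curvature = lambda0 / (lambda0+lambda1+lambda2),
// lambda0 the smallest eigenvalue. Normals are oriented to n_z >= 0
// (ties: n_y >= 0, then n_x >= 0) so reruns are deterministic.
// [[Rcpp::export]]
NumericMatrix cpp_normals_curvature(NumericMatrix pts, IntegerMatrix nn_idx) {
  int n = pts.nrow(), k = nn_idx.ncol();
  NumericMatrix out(n, 4);
  arma::mat33 C;
  arma::vec3 mu, eval3;
  arma::mat33 evec;
  for (int i = 0; i < n; ++i) {
    mu.zeros();
    for (int j = 0; j < k; ++j) {
      int q = nn_idx(i, j) - 1;
      mu[0] += pts(q, 0);
      mu[1] += pts(q, 1);
      mu[2] += pts(q, 2);
    }
    mu /= k;
    C.zeros();
    for (int j = 0; j < k; ++j) {
      int q = nn_idx(i, j) - 1;
      double d0 = pts(q, 0) - mu[0], d1 = pts(q, 1) - mu[1],
             d2 = pts(q, 2) - mu[2];
      C(0, 0) += d0 * d0;
      C(0, 1) += d0 * d1;
      C(0, 2) += d0 * d2;
      C(1, 1) += d1 * d1;
      C(1, 2) += d1 * d2;
      C(2, 2) += d2 * d2;
    }
    C(1, 0) = C(0, 1);
    C(2, 0) = C(0, 2);
    C(2, 1) = C(1, 2);
    arma::eig_sym(eval3, evec, arma::mat(C));
    double nx = evec(0, 0), ny = evec(1, 0), nz = evec(2, 0);
    if (nz < 0 || (nz == 0 && (ny < 0 || (ny == 0 && nx < 0)))) {
      nx = -nx;
      ny = -ny;
      nz = -nz;
    }
    double tot = eval3[0] + eval3[1] + eval3[2];
    out(i, 0) = nx;
    out(i, 1) = ny;
    out(i, 2) = nz;
    out(i, 3) = tot > 0 ? std::max(eval3[0], 0.0) / tot : 0.0;
  }
  return out;
}

// Multi-seed region growing in plant-synchronous rounds.
//   labels0 : initial labels (0 unassigned, k >= 1 seed of plant k)
//   centers : K x 2 matrix of constraint-cylinder axes (x, y)
//   radius2 : squared base radius r_k^2 per plant
//   z_min   : lower bound of every constraint region
// A candidate q joins plant k from a frontier point p when
// |p-q| < delta, |n_p . n_q| >= tau_n and q lies in C_yk. Points claimed by
// two or more plants in the same round become contested: they are frozen
// (never labeled, never grown from) and their claimant sets are returned.
// [[Rcpp::export]]
List cpp_grow_instances(NumericMatrix pts, NumericMatrix normals,
                        IntegerVector labels0, NumericMatrix centers,
                        NumericVector radius2, double z_min, double delta,
                        double tau_n) {
  int n = pts.nrow();
  int K = centers.nrow();
  Grid g(pts, delta);
  std::vector<int> labels(labels0.begin(), labels0.end());
  std::vector<char> contested(n, 0);
  std::vector<std::vector<int>> frontier(K + 1), claim_sets(n);
  for (int i = 0; i < n; ++i)
    if (labels[i] > 0) frontier[labels[i]].push_back(i);

  std::vector<int> claimed_by(n, 0);   // 0 none, -1 multi, else plant id
  std::vector<int> touched;

  bool any = true;
  while (any) {
    any = false;
    touched.clear();
    for (int k = 1; k <= K; ++k) {
      double cx = centers(k - 1, 0), cy = centers(k - 1, 1),
             r2 = radius2[k - 1];
      for (int p : frontier[k]) {
        g.visit_neighbors(p, delta, [&](int q) {
          if (labels[q] != 0 || contested[q]) return;
          double dx = pts(q, 0) - cx, dy = pts(q, 1) - cy;
          if (dx * dx + dy * dy > r2 || pts(q, 2) < z_min) return;
          double dot = normals(p, 0) * normals(q, 0) +
                       normals(p, 1) * normals(q, 1) +
                       normals(p, 2) * normals(q, 2);
          if (std::fabs(dot) < tau_n) return;
          if (claimed_by[q] == 0) {
            claimed_by[q] = k;
            touched.push_back(q);
            claim_sets[q].push_back(k);
          } else if (claimed_by[q] != k && claimed_by[q] != -1) {
            claim_sets[q].push_back(k);
            claimed_by[q] = -1;
          } else if (claimed_by[q] == -1 && claim_sets[q].back() != k) {
            claim_sets[q].push_back(k);
          }
        });
      }
    }
    for (int k = 1; k <= K; ++k) frontier[k].clear();
    for (int q : touched) {
      if (claimed_by[q] == -1) {
        contested[q] = 1;
      } else {
        labels[q] = claimed_by[q];
        frontier[claimed_by[q]].push_back(q);
        claim_sets[q].clear();
        any = true;
      }
      claimed_by[q] = 0;
    }
    // contested points freeze permanently; growth continues while any
    // plant labeled a new point this round
    if (!any) {
      bool frontiers_empty = true;
      for (int k = 1; k <= K; ++k)
        if (!frontier[k].empty()) frontiers_empty = false;
      if (frontiers_empty) break;
    }
  }

  std::vector<int> cont_idx;
  for (int i = 0; i < n; ++i)
    if (contested[i]) cont_idx.push_back(i + 1);
  List claims(cont_idx.size());
  for (size_t i = 0; i < cont_idx.size(); ++i) {
    std::vector<int> s = claim_sets[cont_idx[i] - 1];
    std::sort(s.begin(), s.end());
    s.erase(std::unique(s.begin(), s.end()), s.end());
    claims[i] = wrap(s);
  }
  return List::create(_["labels"] = wrap(labels),
                      _["contested"] = wrap(cont_idx),
                      _["claims"] = claims);
}

// Connected components over points under joint proximity and normal
// agreement: edge (p,q) iff |p-q| <= radius and |n_p . n_q| >= tau.
// Components numbered in order of their smallest member index.
// [[Rcpp::export]]
IntegerVector cpp_normal_components(NumericMatrix pts, NumericMatrix normals,
                                    double radius, double tau) {
  int n = pts.nrow();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  Grid g(pts, radius);
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    if (labels[i] != 0) continue;
    ++next_id;
    std::queue<int> q;
    q.push(i);
    labels[i] = next_id;
    while (!q.empty()) {
      int p = q.front();
      q.pop();
      g.visit_neighbors(p, radius, [&](int j) {
        if (labels[j] != 0) return;
        double dot = normals(p, 0) * normals(j, 0) +
                     normals(p, 1) * normals(j, 1) +
                     normals(p, 2) * normals(j, 2);
        if (std::fabs(dot) >= tau) {
          labels[j] = next_id;
          q.push(j);
        }
      });
    }
  }
  return labels;
}

// Exact fixed-radius neighbor lists (1-based, self excluded), used by the
// overlap-attribution correction where per-point candidate sets are needed.
// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix pts, NumericMatrix queries,
                          double radius) {
  int nq = queries.nrow();
  int n = pts.nrow();
  List out(nq);
  if (n == 0) return out;
  Grid g(pts, radius);
  double r2 = radius * radius;
  for (int i = 0; i < nq; ++i) {
    std::vector<int> nb;
    double qx = queries(i, 0), qy = queries(i, 1), qz = queries(i, 2);
    int ci = (int)std::floor((qx - g.ox) / g.cell);
    int cj = (int)std::floor((qy - g.oy) / g.cell);
    int ck = (int)std::floor((qz - g.oz) / g.cell);
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk) {
          auto it = g.cells.find(Grid::key(ci + di, cj + dj, ck + dk));
          if (it == g.cells.end()) continue;
          for (int j : it->second) {
            double dx = qx - g.x[j], dy = qy - g.y[j], dz = qz - g.z[j];
            if (dx * dx + dy * dy + dz * dz <= r2) nb.push_back(j + 1);
          }
        }
    std::sort(nb.begin(), nb.end());
    out[i] = wrap(nb);
  }
  return out;
}
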