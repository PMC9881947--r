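// Constrained Delaunay triangulation of multi-domain raster images, plus
// connected-component labeling. Coordinates are pixel units, y-up
// (pixel (r,c) owns the unit square [c,c+1] x [H-r-1, H-r]).
//
// Pipeline (driven from R): incremental Delaunay insertion with Lawson
// legalization -> segment recovery by edge flipping -> Laplacian smoothing of
// free vertices with re-legalization -> flood classification of triangles
// into regions bounded by constrained edges.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <deque>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// connected-component labeling (4- or 8-connectivity), iterative BFS
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& img, int connectivity) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 4) ? 4 : 8;
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (img(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * H);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (img(qr, qc) != 0 && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * H);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// triangulation engine
// ---------------------------------------------------------------------------

namespace {

struct Tri {
  int v[3];  // CCW vertex ids
  int n[3];  // n[i]: neighbor sharing the edge opposite v[i], -1 if none
};

inline long long ekey(int a, int b) {
  if (a > b) std::swap(a, b);
  return (long long)a * 2000000LL + b;
}

struct Mesher {
  std::vector<double> X, Y;
  std::vector<char> fixedv;
  std::vector<Tri> T;
  std::vector<char> alive;
  std::vector<int> vtri;  // one alive triangle incident to each vertex
  std::unordered_set<long long> cedge;
  int last_tri = 0;
  static constexpr double EPS = 1e-9;

  double orient(int a, int b, double px, double py) const {
    return (X[b] - X[a]) * (py - Y[a]) - (Y[b] - Y[a]) * (px - X[a]);
  }
  double orient3(int a, int b, int c) const { return orient(a, b, X[c], Y[c]); }

  // > 0 when d lies inside the circumcircle of CCW triangle (a,b,c)
  double incircle(int a, int b, int c, int d) const {
    double ax = X[a] - X[d], ay = Y[a] - Y[d];
    double bx = X[b] - X[d], by = Y[b] - Y[d];
    double cx = X[c] - X[d], cy = Y[c] - Y[d];
    double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
    return ax * (by * c2 - b2 * cy) - ay * (bx * c2 - b2 * cx) + a2 * (bx * cy - by * cx);
  }

  void replace_neighbor(int t, int oldn, int newn) {
    if (t < 0) return;
    for (int i = 0; i < 3; ++i)
      if (T[t].n[i] == oldn) {
        T[t].n[i] = newn;
        return;
      }
  }

  int locate(double px, double py) {
    int t = last_tri;
    if (t >= (int)T.size() || !alive[t]) {
      t = -1;
      for (int i = (int)T.size() - 1; i >= 0; --i)
        if (alive[i]) {
          t = i;
          break;
        }
    }
    int guard = 4 * (int)T.size() + 64;
    while (guard-- > 0) {
      const Tri& tr = T[t];
      int move = -1;
      double worst = -EPS;
      for (int i = 0; i < 3; ++i) {
        int u = tr.v[(i + 1) % 3], w = tr.v[(i + 2) % 3];
        double o = orient(u, w, px, py);
        if (o < worst) {
          worst = o;
          move = i;
        }
      }
      if (move < 0) {
        last_tri = t;
        return t;
      }
      int nb = tr.n[move];
      if (nb < 0) {
        last_tri = t;
        return t;  // clamp to hull (should not happen inside super box)
      }
      t = nb;
    }
    // fallback: exhaustive scan
    for (int i = 0; i < (int)T.size(); ++i) {
      if (!alive[i]) continue;
      const Tri& tr = T[i];
      bool in = true;
      for (int k = 0; k < 3 && in; ++k)
        if (orient(tr.v[(k + 1) % 3], tr.v[(k + 2) % 3], px, py) < -1e-6) in = false;
      if (in) {
        last_tri = i;
        return i;
      }
    }
    return -1;
  }

  int new_tri(int a, int b, int c) {
    Tri t;
    t.v[0] = a;
    t.v[1] = b;
    t.v[2] = c;
    t.n[0] = t.n[1] = t.n[2] = -1;
    T.push_back(t);
    alive.push_back(1);
    return (int)T.size() - 1;
  }

  struct EdgeRef {
    int t, i;
  };

  int index_of(int t, int v) const {
    for (int k = 0; k < 3; ++k)
      if (T[t].v[k] == v) return k;
    return -1;
  }

  // flip edge opposite v[i] of triangle t with its neighbor; returns false if
  // the quad is not strictly convex.
  bool flip(int t, int i) {
    int o = T[t].n[i];
    if (o < 0) return false;
    int a = T[t].v[i], b = T[t].v[(i + 1) % 3], c = T[t].v[(i + 2) % 3];
    if (cedge.count(ekey(b, c))) return false;
    int j = -1;
    for (int k = 0; k < 3; ++k)
      if (T[o].v[k] != b && T[o].v[k] != c) j = k;
    if (j < 0) return false;
    int q = T[o].v[j];
    // convexity: new triangles (a,b,q) and (a,q,c) must be CCW
    if (orient3(a, b, q) <= EPS || orient3(a, q, c) <= EPS) return false;
    // o is CCW and contains directed edge (c,b): o = (q, c', b') with
    // w[j+1] == c, w[j+2] == b
    int nb_t_ab = T[t].n[(i + 2) % 3];  // across (a,b)
    int nb_t_ca = T[t].n[(i + 1) % 3];  // across (c,a)
    int nb_o_bq = T[o].n[(j + 1) % 3];  // across (b,q)
    int nb_o_qc = T[o].n[(j + 2) % 3];  // across (q,c)
    T[t].v[0] = a;
    T[t].v[1] = b;
    T[t].v[2] = q;
    T[t].n[0] = nb_o_bq;
    T[t].n[1] = o;
    T[t].n[2] = nb_t_ab;
    T[o].v[0] = a;
    T[o].v[1] = q;
    T[o].v[2] = c;
    T[o].n[0] = nb_o_qc;
    T[o].n[1] = nb_t_ca;
    T[o].n[2] = t;
    replace_neighbor(nb_o_bq, o, t);
    replace_neighbor(nb_t_ca, t, o);
    vtri[a] = t;
    vtri[b] = t;
    vtri[q] = t;
    vtri[c] = o;
    return true;
  }

  void legalize_all_from(std::vector<EdgeRef>& stack) {
    int guard = 50 * (int)T.size() + 1000;
    while (!stack.empty() && guard-- > 0) {
      EdgeRef e = stack.back();
      stack.pop_back();
      int t = e.t, i = e.i;
      if (t < 0 || t >= (int)T.size() || !alive[t]) continue;
      int o = T[t].n[i];
      if (o < 0) continue;
      int b = T[t].v[(i + 1) % 3], c = T[t].v[(i + 2) % 3];
      if (cedge.count(ekey(b, c))) continue;
      int j = -1;
      for (int k = 0; k < 3; ++k)
        if (T[o].v[k] != b && T[o].v[k] != c) j = k;
      if (j < 0) continue;
      int q = T[o].v[j];
      if (incircle(T[t].v[0], T[t].v[1], T[t].v[2], q) <= EPS) continue;
      if (flip(t, i)) {
        for (int k = 0; k < 3; ++k) {
          stack.push_back({t, k});
          stack.push_back({o, k});
        }
      }
    }
  }

  void insert_point(int p) {
    double px = X[p], py = Y[p];
    int t = locate(px, py);
    if (t < 0) stop("point location failed");
    // barycentric-style edge orientations
    double o[3];
    for (int i = 0; i < 3; ++i)
      o[i] = orient(T[t].v[(i + 1) % 3], T[t].v[(i + 2) % 3], px, py);
    int onedge = -1;
    double area2 = orient3(T[t].v[0], T[t].v[1], T[t].v[2]);
    double tol = 1e-10 + 1e-9 * area2;
    int nz = 0;
    for (int i = 0; i < 3; ++i)
      if (o[i] <= tol) {
        onedge = i;
        ++nz;
      }
    std::vector<EdgeRef> stack;
    if (nz >= 2) return;  // duplicate of an existing vertex: skip
    if (nz == 1) {
      split_edge(t, onedge, p, stack);
    } else {
      split_interior(t, p, stack);
    }
    legalize_all_from(stack);
  }

  void split_interior(int t, int p, std::vector<EdgeRef>& stack) {
    int a = T[t].v[0], b = T[t].v[1], c = T[t].v[2];
    int A = T[t].n[0], B = T[t].n[1], C = T[t].n[2];
    int t1 = t;  // (a,b,p)
    T[t1].v[0] = a;
    T[t1].v[1] = b;
    T[t1].v[2] = p;
    int t2 = new_tri(b, c, p);
    int t3 = new_tri(c, a, p);
    T[t1].n[0] = t2;
    T[t1].n[1] = t3;
    T[t1].n[2] = C;
    T[t2].n[0] = t3;
    T[t2].n[1] = t1;
    T[t2].n[2] = A;
    T[t3].n[0] = t1;
    T[t3].n[1] = t2;
    T[t3].n[2] = B;
    replace_neighbor(A, t, t2);
    replace_neighbor(B, t, t3);
    vtri[p] = t1;
    vtri[a] = t1;
    vtri[b] = t1;
    vtri[c] = t2;
    stack.push_back({t1, 2});
    stack.push_back({t2, 2});
    stack.push_back({t3, 2});
  }

  void split_edge(int t, int i, int p, std::vector<EdgeRef>& stack) {
    int vi = T[t].v[i], v1 = T[t].v[(i + 1) % 3], v2 = T[t].v[(i + 2) % 3];
    int o = T[t].n[i];
    int nb1 = T[t].n[(i + 1) % 3];  // across (v2, vi)
    int nb2 = T[t].n[(i + 2) % 3];  // across (vi, v1)
    bool was_con = cedge.count(ekey(v1, v2)) > 0;
    if (was_con) {
      cedge.erase(ekey(v1, v2));
      cedge.insert(ekey(v1, p));
      cedge.insert(ekey(p, v2));
    }
    int t1 = t;  // (vi, v1, p)
    T[t1].v[0] = vi;
    T[t1].v[1] = v1;
    T[t1].v[2] = p;
    int t2 = new_tri(vi, p, v2);
    T[t1].n[1] = t2;  // across (p, vi)
    T[t1].n[2] = nb2;
    T[t2].n[1] = nb1;  // across (v2, vi)
    T[t2].n[2] = t1;
    replace_neighbor(nb1, t, t2);
    vtri[vi] = t1;
    vtri[v1] = t1;
    vtri[v2] = t2;
    vtri[p] = t1;
    if (o < 0) {
      T[t1].n[0] = -1;
      T[t2].n[0] = -1;
      stack.push_back({t1, 2});
      stack.push_back({t2, 1});
      return;
    }
    int j = -1;
    for (int k = 0; k < 3; ++k)
      if (T[o].v[k] != v1 && T[o].v[k] != v2) j = k;
    int q = T[o].v[j];
    int nbo1 = T[o].n[(j + 1) % 3];  // across (v1, q)  [w: (q, v2, v1)]
    int nbo2 = T[o].n[(j + 2) % 3];  // across (q, v2)
    int o1 = o;  // (q, v2, p)
    T[o1].v[0] = q;
    T[o1].v[1] = v2;
    T[o1].v[2] = p;
    int o2 = new_tri(q, p, v1);
    T[t1].n[0] = o2;  // across (v1, p)
    T[t2].n[0] = o1;  // across (p, v2)
    T[o1].n[0] = t2;  // across (v2, p)
    T[o1].n[1] = o2;  // across (p, q)
    T[o1].n[2] = nbo2;
    T[o2].n[0] = t1;  // across (p, v1)
    T[o2].n[1] = nbo1;
    T[o2].n[2] = o1;
    replace_neighbor(nbo1, o, o2);
    vtri[q] = o1;
    stack.push_back({t1, 2});
    stack.push_back({t2, 1});
    stack.push_back({o1, 2});
    stack.push_back({o2, 1});
  }

  // enumerate star of vertex v; returns false when the star is open (hull)
  bool star(int v, std::vector<int>& tris_out) const {
    tris_out.clear();
    int t0 = vtri[v];
    if (t0 < 0 || !alive[t0]) return false;
    int cur = t0;
    int guard = 256;
    while (guard-- > 0) {
      int i = index_of(cur, v);
      if (i < 0) return false;
      tris_out.push_back(cur);
      int nxt = cur >= 0 ? T[cur].n[(i + 2) % 3] : -1;  // across (v, v[i+1])
      if (nxt < 0) return false;
      if (nxt == t0) return true;
      cur = nxt;
    }
    return false;
  }

  bool edge_exists(int a, int b) const {
    std::vector<int> st;
    if (!star_any(a, st)) return false;
    for (int t : st)
      for (int k = 0; k < 3; ++k)
        if (T[t].v[k] == b) return true;
    return false;
  }

  // star enumeration that also works for hull vertices (walk both ways)
  bool star_any(int v, std::vector<int>& out) const {
    out.clear();
    int t0 = vtri[v];
    if (t0 < 0 || t0 >= (int)T.size() || !alive[t0] || index_of(t0, v) < 0) {
      // fallback: scan
      for (int t = 0; t < (int)T.size(); ++t)
        if (alive[t] && index_of(t, v) >= 0) {
          t0 = t;
          break;
        }
      if (t0 < 0 || !alive[t0] || index_of(t0, v) < 0) return false;
    }
    int cur = t0, guard = 512;
    while (guard-- > 0) {
      out.push_back(cur);
      int i = index_of(cur, v);
      int nxt = T[cur].n[(i + 2) % 3];
      if (nxt == t0) return true;
      if (nxt < 0) break;
      cur = nxt;
    }
    cur = t0;
    guard = 512;
    while (guard-- > 0) {
      int i = index_of(cur, v);
      int nxt = T[cur].n[(i + 1) % 3];  // rotate the other way
      if (nxt < 0 || nxt == t0) return true;
      out.push_back(nxt);
      cur = nxt;
    }
    return true;
  }

  bool seg_cross(int a, int b, int u, int w) const {
    double o1 = orient3(a, b, u), o2 = orient3(a, b, w);
    double o3 = orient3(u, w, a), o4 = orient3(u, w, b);
    return (o1 > EPS) != (o2 > EPS) && (o1 < -EPS) != (o2 < -EPS) &&
           (o3 > EPS) != (o4 > EPS) && (o3 < -EPS) != (o4 < -EPS) &&
           std::abs(o1) > EPS && std::abs(o2) > EPS && std::abs(o3) > EPS &&
           std::abs(o4) > EPS;
  }

  bool insert_constraint(int a, int b) {
    int guard = 500;
    while (guard-- > 0) {
      if (edge_exists(a, b)) {
        cedge.insert(ekey(a, b));
        return true;
      }
      // find a crossing edge reachable from a, flip the first flippable one
      std::vector<int> st;
      if (!star_any(a, st)) return false;
      int ct = -1, ci = -1;
      for (int t : st) {
        int i = index_of(t, a);
        int u = T[t].v[(i + 1) % 3], w = T[t].v[(i + 2) % 3];
        if (seg_cross(a, b, u, w)) {
          ct = t;
          ci = i;
          break;
        }
      }
      if (ct < 0) return false;  // degenerate (collinear vertex on segment)
      bool flipped = false;
      int march = 256;
      while (march-- > 0) {
        int u = T[ct].v[(ci + 1) % 3], w = T[ct].v[(ci + 2) % 3];
        if (cedge.count(ekey(u, w))) return false;  // constraints intersect
        if (flip(ct, ci)) {
          flipped = true;
          break;
        }
        // advance into the neighbor across the crossing edge
        int o = T[ct].n[ci];
        if (o < 0) return false;
        int j = -1;
        for (int k = 0; k < 3; ++k)
          if (T[o].v[k] != u && T[o].v[k] != w) j = k;
        int z = T[o].v[j];
        if (z == b) return false;  // reached b without flippable edge
        // segment exits o across (u,z) or (z,w)
        if (seg_cross(a, b, u, z)) {
          ci = index_of(o, w);
          ct = o;
        } else if (seg_cross(a, b, z, w)) {
          ci = index_of(o, u);
          ct = o;
        } else {
          return false;  // collinear degeneracy
        }
      }
      if (!flipped) return false;
    }
    return false;
  }

  // Delaunay refinement: insert circumcenters of low-quality triangles
  // (quality = 4*sqrt(3)*A / sum of squared edges) lying inside the image
  // rectangle. r_min stops refinement at the target resolution.
  int refine(double q_min, double r_min, double W, double H, int max_pts) {
    int inserted = 0;
    for (int round = 0; round < 3; ++round) {
      std::vector<std::pair<double, double>> centers;
      for (int t = 0; t < (int)T.size(); ++t) {
        if (!alive[t]) continue;
        int a = T[t].v[0], b = T[t].v[1], c = T[t].v[2];
        if (a < 4 || b < 4 || c < 4) continue;
        double cx = (X[a] + X[b] + X[c]) / 3.0, cy = (Y[a] + Y[b] + Y[c]) / 3.0;
        if (cx < 0 || cx > W || cy < 0 || cy > H) continue;
        double area2 = orient3(a, b, c);
        double l2 = 0;
        double ex[3] = {X[b] - X[a], X[c] - X[b], X[a] - X[c]};
        double ey[3] = {Y[b] - Y[a], Y[c] - Y[b], Y[a] - Y[c]};
        for (int k = 0; k < 3; ++k) l2 += ex[k] * ex[k] + ey[k] * ey[k];
        double q = 2.0 * 1.7320508075688772 * area2 / l2;
        if (q >= q_min) continue;
        // circumcenter
        double d = 2.0 * area2;
        if (d <= 1e-12) continue;
        double a2 = X[a] * X[a] + Y[a] * Y[a];
        double b2 = X[b] * X[b] + Y[b] * Y[b];
        double c2 = X[c] * X[c] + Y[c] * Y[c];
        double ux = (a2 * (Y[b] - Y[c]) + b2 * (Y[c] - Y[a]) + c2 * (Y[a] - Y[b])) / d;
        double uy = (a2 * (X[c] - X[b]) + b2 * (X[a] - X[c]) + c2 * (X[b] - X[a])) / d;
        double rr = (ux - X[a]) * (ux - X[a]) + (uy - Y[a]) * (uy - Y[a]);
        if (rr < r_min * r_min) continue;
        if (ux < 0.3 || ux > W - 0.3 || uy < 0.3 || uy > H - 0.3) continue;
        centers.push_back({ux, uy});
      }
      if (centers.empty()) break;
      for (auto& c : centers) {
        if (inserted >= max_pts) return inserted;
        X.push_back(c.first);
        Y.push_back(c.second);
        fixedv.push_back(0);
        vtri.push_back(-1);
        insert_point((int)X.size() - 1);
        ++inserted;
      }
    }
    return inserted;
  }

  void smooth(int iters, int n_super) {
    std::vector<int> st;
    std::vector<EdgeRef> stack;
    for (int pass = 0; pass < iters; ++pass) {
      for (int v = n_super; v < (int)X.size(); ++v) {
        if (fixedv[v]) continue;
        if (!star(v, st)) continue;
        // neighbor centroid
        double sx = 0, sy = 0;
        int cnt = 0;
        std::unordered_set<int> seen;
        for (int t : st)
          for (int k = 0; k < 3; ++k) {
            int u = T[t].v[k];
            if (u != v && !seen.count(u)) {
              seen.insert(u);
              sx += X[u];
              sy += Y[u];
              ++cnt;
            }
          }
        if (cnt < 3) continue;
        double ox = X[v], oy = Y[v];
        double tx = sx / cnt, ty = sy / cnt;
        for (int attempt = 0; attempt < 3; ++attempt) {
          X[v] = ox + (tx - ox) / (1 << attempt);
          Y[v] = oy + (ty - oy) / (1 << attempt);
          bool ok = true;
          for (int t : st)
            if (orient3(T[t].v[0], T[t].v[1], T[t].v[2]) <= 1e-9) {
              ok = false;
              break;
            }
          if (ok) break;
          X[v] = ox;
          Y[v] = oy;
        }
      }
      stack.clear();
      for (int t = 0; t < (int)T.size(); ++t)
        if (alive[t])
          for (int k = 0; k < 3; ++k) stack.push_back({t, k});
      legalize_all_from(stack);
    }
  }
};

}  // namespace

// fixed_pts: k x 2 constraint vertices (px, y-up); segments: s x 2 (1-based
// into fixed_pts); interior: m x 2 free vertices; region_grid: H x W integer
// region ids (row 1 = top of image); returns mesh in pixel y-up coordinates.
// [[Rcpp::export]]
List cpp_triangulate(const NumericMatrix& fixed_pts, const IntegerMatrix& segments,
                     const NumericMatrix& interior, const IntegerMatrix& region_grid,
                     int smooth_iters, double refine_q, double refine_rmin) {
  const int H = region_grid.nrow(), W = region_grid.ncol();
  const int nf = fixed_pts.nrow(), ni = interior.nrow();
  Mesher M;
  const double m = std::max(W, H) * 0.25 + 2.0;
  // super box
  M.X = {-m, W + m, W + m, -m};
  M.Y = {-m, -m, H + m, H + m};
  M.fixedv = {1, 1, 1, 1};
  M.vtri = {0, 0, 1, 1};
  M.new_tri(0, 1, 2);
  M.new_tri(0, 2, 3);
  M.T[0].n[0] = -1;
  M.T[0].n[1] = 1;
  M.T[0].n[2] = -1;
  M.T[1].n[0] = -1;
  M.T[1].n[1] = -1;
  M.T[1].n[2] = 0;
  for (int i = 0; i < nf; ++i) {
    M.X.push_back(fixed_pts(i, 0));
    M.Y.push_back(fixed_pts(i, 1));
    M.fixedv.push_back(1);
    M.vtri.push_back(-1);
  }
  for (int i = 0; i < ni; ++i) {
    M.X.push_back(interior(i, 0));
    M.Y.push_back(interior(i, 1));
    M.fixedv.push_back(0);
    M.vtri.push_back(-1);
  }
  const int n_super = 4;
  for (int i = n_super; i < (int)M.X.size(); ++i) M.insert_point(i);

  // constraint recovery
  int failed = 0;
  for (int s = 0; s < segments.nrow(); ++s) {
    int a = segments(s, 0) - 1 + n_super;
    int b = segments(s, 1) - 1 + n_super;
    if (a == b) continue;
    if (!M.insert_constraint(a, b)) ++failed;
  }

  if (failed == 0 && smooth_iters > 0) {
    M.smooth(2, n_super);
    if (refine_q > 0) {
      int cap = (int)M.X.size();  // at most double the vertex count
      M.refine(refine_q, refine_rmin, W, H, cap);
    }
    M.smooth(smooth_iters, n_super);
  }

  // flood components across non-constrained edges
  const int nT = (int)M.T.size();
  std::vector<int> comp(nT, -1);
  int ncomp = 0;
  std::vector<int> stack;
  for (int t0 = 0; t0 < nT; ++t0) {
    if (!M.alive[t0] || comp[t0] >= 0) continue;
    comp[t0] = ncomp;
    stack.clear();
    stack.push_back(t0);
    while (!stack.empty()) {
      int t = stack.back();
      stack.pop_back();
      for (int i = 0; i < 3; ++i) {
        int o = M.T[t].n[i];
        if (o < 0 || comp[o] >= 0) continue;
        int u = M.T[t].v[(i + 1) % 3], w = M.T[t].v[(i + 2) % 3];
        if (M.cedge.count(ekey(u, w))) continue;
        comp[o] = ncomp;
        stack.push_back(o);
      }
    }
    ++ncomp;
  }

  // keep alive triangles with no super vertex; majority region id by area
  std::vector<int> keep;
  keep.reserve(nT);
  std::vector<std::unordered_map<int, double>> votes(ncomp);
  for (int t = 0; t < nT; ++t) {
    if (!M.alive[t]) continue;
    bool super = false;
    for (int k = 0; k < 3; ++k)
      if (M.T[t].v[k] < n_super) super = true;
    if (super) continue;
    keep.push_back(t);
    double cx = 0, cy = 0;
    for (int k = 0; k < 3; ++k) {
      cx += M.X[M.T[t].v[k]];
      cy += M.Y[M.T[t].v[k]];
    }
    cx /= 3.0;
    cy /= 3.0;
    int col = std::min(W - 1, std::max(0, (int)std::floor(cx)));
    int row = std::min(H - 1, std::max(0, (int)std::floor(H - cy)));
    double a2 = M.orient3(M.T[t].v[0], M.T[t].v[1], M.T[t].v[2]);
    votes[comp[t]][region_grid(row, col)] += std::abs(a2);
  }
  std::vector<int> comp_region(ncomp, 0);
  for (int c = 0; c < ncomp; ++c) {
    double best = -1;
    for (auto& kv : votes[c])
      if (kv.second > best) {
        best = kv.second;
        comp_region[c] = kv.first;
      }
  }

  const int nV = (int)M.X.size() - n_super;
  NumericMatrix pts(nV, 2);
  LogicalVector isfix(nV);
  for (int i = 0; i < nV; ++i) {
    pts(i, 0) = M.X[i + n_super];
    pts(i, 1) = M.Y[i + n_super];
    isfix[i] = M.fixedv[i + n_super] != 0;
  }
  IntegerMatrix tri((int)keep.size(), 3);
  IntegerVector region((int)keep.size());
  for (int r = 0; r < (int)keep.size(); ++r) {
    int t = keep[r];
    for (int k = 0; k < 3; ++k) tri(r, k) = M.T[t].v[k] - n_super + 1;
    region[r] = comp_region[comp[t]];
  }
  // constrained edges among real vertices
  std::vector<std::pair<int, int>> ce;
  for (long long key : M.cedge) {
    int a = (int)(key / 2000000LL), b = (int)(key % 2000000LL);
    if (a >= n_super && b >= n_super)
      ce.push_back({a - n_super + 1, b - n_super + 1});
  }
  IntegerMatrix cem((int)ce.size(), 2);
  for (int i = 0; i < (int)ce.size(); ++i) {
    cem(i, 0) = ce[i].first;
    cem(i, 1) = ce[i].second;
  }
  return List::create(_["points"] = pts, _["fixed"] = isfix, _["triangles"] = tri,
                      _["region"] = region, _["constrained"] = cem,
                      _["n_failed_segments"] = failed);
}
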