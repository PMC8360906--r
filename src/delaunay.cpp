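#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bowyer-Watson incremental Delaunay triangulation in double precision.
// Adequate for generic point sets (uniform random seeds, Lloyd iterates);
// exact predicates are not needed at the densities used here.

namespace {

struct Tri {
  int a, b, c;
  bool alive;
  double ccx, ccy, r2; // circumcenter and squared circumradius
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// circumcircle of (a,b,c); returns false if degenerate
inline bool circumcircle(double ax, double ay, double bx, double by,
                         double cx, double cy, double &ccx, double &ccy,
                         double &r2) {
  double d = 2.0 * orient2d(ax, ay, bx, by, cx, cy);
  if (std::fabs(d) < 1e-14) return false;
  double a2 = ax * ax + ay * ay;
  double b2 = bx * bx + by * by;
  double c2 = cx * cx + cy * cy;
  ccx = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  ccy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - ccx, dy = ay - ccy;
  r2 = dx * dx + dy * dy;
  return true;
}

struct EdgeKey {
  int u, v; // unordered, u < v
  bool operator==(const EdgeKey &o) const { return u == o.u && v == o.v; }
};
struct EdgeHash {
  size_t operator()(const EdgeKey &e) const {
    return std::hash<long long>()((long long)e.u * 1000003LL + e.v);
  }
};

} // namespace

// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> px(n + 3), py(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0);
    py[i] = pts(i, 1);
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) dmax = 1.0;
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  // super-triangle (CCW), comfortably enclosing every circumcircle
  px[n] = cx - 30.0 * dmax; py[n] = cy - 20.0 * dmax;
  px[n + 1] = cx + 30.0 * dmax; py[n + 1] = cy - 20.0 * dmax;
  px[n + 2] = cx; py[n + 2] = cy + 30.0 * dmax;

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  {
    Tri t;
    t.a = n; t.b = n + 1; t.c = n + 2; t.alive = true;
    circumcircle(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c],
                 t.ccx, t.ccy, t.r2);
    tris.push_back(t);
  }

  std::vector<int> bad;
  std::unordered_map<EdgeKey, std::pair<int, int>, EdgeHash> edges; // key -> (count, directed u->v flag packed)
  std::vector<std::pair<int, int>> boundary;

  for (int p = 0; p < n; ++p) {
    double x = px[p], y = py[p];
    bad.clear();
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double dx = x - tris[t].ccx, dy = y - tris[t].ccy;
      if (dx * dx + dy * dy < tris[t].r2 * (1.0 + 1e-12)) bad.push_back(t);
    }
    // cavity boundary: directed edges (CCW in their triangle) seen once
    edges.clear();
    for (int bi : bad) {
      int vs[3] = {tris[bi].a, tris[bi].b, tris[bi].c};
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e + 1) % 3];
        EdgeKey k{std::min(u, v), std::max(u, v)};
        auto it = edges.find(k);
        if (it == edges.end())
          edges[k] = std::make_pair(1, u); // remember directed origin
        else
          it->second.first++;
      }
    }
    boundary.clear();
    for (auto &kv : edges) {
      if (kv.second.first == 1) {
        int u = kv.second.second;
        int v = (kv.first.u == u) ? kv.first.v : kv.first.u;
        boundary.push_back(std::make_pair(u, v));
      }
    }
    for (int bi : bad) tris[bi].alive = false;
    for (auto &e : boundary) {
      Tri t;
      t.a = e.first; t.b = e.second; t.c = p; t.alive = true;
      if (orient2d(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c]) < 0)
        std::swap(t.b, t.c);
      if (!circumcircle(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c],
                        t.ccx, t.ccy, t.r2))
        continue; // degenerate sliver on the cavity rim; drop
      tris.push_back(t);
    }
  }

  int m = 0;
  for (auto &t : tris)
    if (t.alive && t.a < n && t.b < n && t.c < n) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (auto &t : tris) {
    if (!(t.alive && t.a < n && t.b < n && t.c < n)) continue;
    out(r, 0) = t.a + 1;
    out(r, 1) = t.b + 1;
    out(r, 2) = t.c + 1;
    ++r;
  }
  return out;
}
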