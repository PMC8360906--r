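#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Vertex-model mechanics on a periodic rectangular box.
//
// Cells are vertex-index cycles (CSR layout: cell_vert 0-based, cell_ptr
// offsets). Vertex coordinates live in [0,Lx)x[0,Ly); each polygon is
// unwrapped with the minimum-image convention edge by edge, which is valid
// while every cell edge is shorter than half the box.
//
// Per-cell energy: U = (A-1)^2 + (g/2) (L + lambda/(2 g))^2, g = gamma*mult.
//
// A soft quadratic barrier KB*A^2 is added for A < 0 only: it is inactive on
// every physically valid configuration and merely steers line searches away
// from cell inversion during strongly compressed relaxation steps.
static const double KB = 1e4;

namespace {

inline double minim(double d, double L) { return d - L * std::round(d / L); }

struct CellGeom {
  double A, L;
};

// unwrap cell vertices into ux/uy (caller-provided buffers), return geometry
inline CellGeom cell_geom(const double *x, const int *cv, int s, int e,
                          double Lx, double Ly, double *ux, double *uy) {
  int nv = e - s;
  ux[0] = x[2 * cv[s]];
  uy[0] = x[2 * cv[s] + 1];
  for (int t = 1; t < nv; ++t) {
    int i = cv[s + t], j = cv[s + t - 1];
    ux[t] = ux[t - 1] + minim(x[2 * i] - x[2 * j], Lx);
    uy[t] = uy[t - 1] + minim(x[2 * i + 1] - x[2 * j + 1], Ly);
  }
  double A = 0.0, L = 0.0;
  for (int t = 0; t < nv; ++t) {
    int u = (t + 1) % nv;
    A += ux[t] * uy[u] - ux[u] * uy[t];
    double dx = ux[u] - ux[t], dy = uy[u] - uy[t];
    L += std::sqrt(dx * dx + dy * dy);
  }
  CellGeom g;
  g.A = 0.5 * A;
  g.L = L;
  return g;
}

} // namespace

// [[Rcpp::export(name = ".tissue_geom_cpp")]]
List tissue_geom_cpp(NumericVector x, IntegerVector cell_vert,
                     IntegerVector cell_ptr, NumericVector box) {
  int nc = cell_ptr.size() - 1;
  NumericVector area(nc), perim(nc);
  std::vector<double> ux(64), uy(64);
  for (int c = 0; c < nc; ++c) {
    int s = cell_ptr[c], e = cell_ptr[c + 1];
    if ((int)ux.size() < e - s) { ux.resize(e - s); uy.resize(e - s); }
    CellGeom g = cell_geom(REAL(x), INTEGER(cell_vert), s, e, box[0], box[1],
                           ux.data(), uy.data());
    area[c] = g.A;
    perim[c] = g.L;
  }
  return List::create(_["area"] = area, _["perimeter"] = perim);
}

// [[Rcpp::export(name = ".tissue_energy_cpp")]]
double tissue_energy_cpp(NumericVector x, IntegerVector cell_vert,
                         IntegerVector cell_ptr, NumericVector box,
                         double lambda, double gamma, NumericVector gmult) {
  int nc = cell_ptr.size() - 1;
  double U = 0.0;
  std::vector<double> ux(64), uy(64);
  for (int c = 0; c < nc; ++c) {
    int s = cell_ptr[c], e = cell_ptr[c + 1];
    if ((int)ux.size() < e - s) { ux.resize(e - s); uy.resize(e - s); }
    CellGeom g = cell_geom(REAL(x), INTEGER(cell_vert), s, e, box[0], box[1],
                           ux.data(), uy.data());
    double gg = gamma * gmult[c];
    double dL = g.L + lambda / (2.0 * gg);
    U += (g.A - 1.0) * (g.A - 1.0) + 0.5 * gg * dL * dL;
    if (g.A < 0) U += KB * g.A * g.A;
  }
  return U;
}

// [[Rcpp::export(name = ".tissue_grad_cpp")]]
NumericVector tissue_grad_cpp(NumericVector x, IntegerVector cell_vert,
                              IntegerVector cell_ptr, NumericVector box,
                              double lambda, double gamma,
                              NumericVector gmult) {
  int nc = cell_ptr.size() - 1;
  NumericVector grad(x.size());
  std::vector<double> ux(64), uy(64);
  const int *cv = INTEGER(cell_vert);
  for (int c = 0; c < nc; ++c) {
    int s = cell_ptr[c], e = cell_ptr[c + 1];
    int nv = e - s;
    if ((int)ux.size() < nv) { ux.resize(nv); uy.resize(nv); }
    CellGeom g = cell_geom(REAL(x), cv, s, e, box[0], box[1], ux.data(),
                           uy.data());
    double gg = gamma * gmult[c];
    double cA = 2.0 * (g.A - 1.0);
    if (g.A < 0) cA += 2.0 * KB * g.A;
    double cL = gg * (g.L + lambda / (2.0 * gg));
    for (int t = 0; t < nv; ++t) {
      int prev = (t + nv - 1) % nv, next = (t + 1) % nv;
      int gi = cv[s + t];
      double dAx = 0.5 * (uy[next] - uy[prev]);
      double dAy = 0.5 * (ux[prev] - ux[next]);
      double ex = ux[t] - ux[prev], ey = uy[t] - uy[prev];
      double lp = std::sqrt(ex * ex + ey * ey);
      double fx = ux[t] - ux[next], fy = uy[t] - uy[next];
      double ln = std::sqrt(fx * fx + fy * fy);
      double dLx = 0.0, dLy = 0.0;
      if (lp > 1e-12) { dLx += ex / lp; dLy += ey / lp; }
      if (ln > 1e-12) { dLx += fx / ln; dLy += fy / ln; }
      grad[2 * gi] += cA * dAx + cL * dLx;
      grad[2 * gi + 1] += cA * dAy + cL * dLy;
    }
  }
  return grad;
}
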