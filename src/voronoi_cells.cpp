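#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Clipped Voronoi cells from a Delaunay neighbour structure.
//
// The Voronoi cell of seed i restricted to a convex window equals the
// intersection of the window with the bisector half-planes between i and
// its Delaunay neighbours only (non-neighbour bisectors are redundant).
// Each cell is therefore computed by Sutherland-Hodgman clipping of the
// viewport rectangle against those half-planes, which keeps the cells an
// exact partition of the rectangle up to floating-point rounding.

struct Poly {
  std::vector<double> x, y;
  size_t size() const { return x.size(); }
};

// clip polygon by half-plane a*x + b*y <= c
static void clip_halfplane(const Poly &in, double a, double b, double c,
                           Poly &out) {
  out.x.clear();
  out.y.clear();
  const size_t n = in.size();
  if (n == 0) return;
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    double fx = in.x[i], fy = in.y[i];
    double sx = in.x[j], sy = in.y[j];
    double df = a * fx + b * fy - c;
    double ds = a * sx + b * sy - c;
    bool fin = df <= 0.0, sin_ = ds <= 0.0;
    if (fin) {
      out.x.push_back(fx);
      out.y.push_back(fy);
    }
    if (fin != sin_) {
      double t = df / (df - ds);
      out.x.push_back(fx + t * (sx - fx));
      out.y.push_back(fy + t * (sy - fy));
    }
  }
}

static double poly_area(const Poly &p) {
  double s = 0.0;
  size_t n = p.size();
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    s += p.x[i] * p.y[j] - p.x[j] * p.y[i];
  }
  return 0.5 * s;
}

// area centroid by the signed-area decomposition formula
static void poly_centroid(const Poly &p, double area, double &cx, double &cy) {
  double sx = 0.0, sy = 0.0;
  size_t n = p.size();
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    double cross = p.x[i] * p.y[j] - p.x[j] * p.y[i];
    sx += (p.x[i] + p.x[j]) * cross;
    sy += (p.y[i] + p.y[j]) * cross;
  }
  cx = sx / (6.0 * area);
  cy = sy / (6.0 * area);
}

// [[Rcpp::export]]
List clip_voronoi_cells(NumericVector sx, NumericVector sy, List neighbours,
                        double xmin, double xmax, double ymin, double ymax,
                        bool keep_polygons) {
  const int n = sx.size();
  NumericVector area(n), cx(n), cy(n);
  List polys(keep_polygons ? n : 0);
  Poly cur, nxt;
  for (int i = 0; i < n; ++i) {
    cur.x = {xmin, xmax, xmax, xmin};
    cur.y = {ymin, ymin, ymax, ymax};
    IntegerVector nb = neighbours[i];
    for (int k = 0; k < nb.size(); ++k) {
      int j = nb[k] - 1;  // 1-based from R
      double a = 2.0 * (sx[j] - sx[i]);
      double b = 2.0 * (sy[j] - sy[i]);
      double c = sx[j] * sx[j] + sy[j] * sy[j] - sx[i] * sx[i] -
                 sy[i] * sy[i];
      clip_halfplane(cur, a, b, c, nxt);
      std::swap(cur, nxt);
      if (cur.size() == 0) break;
    }
    double A = poly_area(cur);
    area[i] = A;
    if (A > 0.0) {
      poly_centroid(cur, A, cx[i], cy[i]);
    } else {
      cx[i] = sx[i];
      cy[i] = sy[i];
    }
    if (keep_polygons) {
      NumericMatrix m(cur.size(), 2);
      for (size_t v = 0; v < cur.size(); ++v) {
        m(v, 0) = cur.x[v];
        m(v, 1) = cur.y[v];
      }
      polys[i] = m;
    }
  }
  return List::create(_["area"] = area, _["centroid_x"] = cx,
                      _["centroid_y"] = cy, _["polygons"] = polys);
}

// Brute-force nearest-seed labelling of probe points (test oracle support;
// ties broken by lowest seed index).
// [[Rcpp::export]]
IntegerVector nearest_seed(NumericVector px, NumericVector py,
                           NumericVector sx, NumericVector sy) {
  const int np = px.size(), ns = sx.size();
  IntegerVector lab(np);
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < ns; ++j) {
      double dx = px[i] - sx[j], dy = py[i] - sy[j];
      double d = dx * dx + dy * dy;
      if (d < best) {
        best = d;
        bj = j;
      }
    }
    lab[i] = bj + 1;
  }
  return lab;
}
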