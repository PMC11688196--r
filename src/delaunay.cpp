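#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bowyer-Watson incremental Delaunay triangulation.
// Returns an m x 3 matrix of 1-based vertex indices into pts.
// Cocircular degeneracies are broken by the strict in-circle test with a
// relative epsilon; collinear triangles never survive because their
// circumradius is treated as infinite.

struct Tri {
  int a, b, c;     // vertex indices (0-based; >= n means super-triangle vertex)
  double cx, cy;   // circumcenter
  double r2;       // squared circumradius
  bool alive;
};

static inline bool circumcircle(const std::vector<double>& px,
                                const std::vector<double>& py,
                                int a, int b, int c,
                                double& cx, double& cy, double& r2) {
  double ax = px[a], ay = py[a], bx = px[b], by = py[b], ccx = px[c], ccy = py[c];
  double d = 2.0 * (ax * (by - ccy) + bx * (ccy - ay) + ccx * (ay - by));
  if (std::fabs(d) < 1e-12) return false; // collinear
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = ccx * ccx + ccy * ccy;
  cx = (a2 * (by - ccy) + b2 * (ccy - ay) + c2 * (ay - by)) / d;
  cy = (a2 * (ccx - bx) + b2 * (ax - ccx) + c2 * (bx - ax)) / d;
  double dx = ax - cx, dy = ay - cy;
  r2 = dx * dx + dy * dy;
  return true;
}

// [[Rcpp::export]]
IntegerMatrix delaunay_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");

  std::vector<double> px(n + 3), py(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1);
    if (px[i] < xmin) xmin = px[i];
    if (px[i] > xmax) xmax = px[i];
    if (py[i] < ymin) ymin = py[i];
    if (py[i] > ymax) ymax = py[i];
  }
  double dx = xmax - xmin, dy = ymax - ymin;
  double dmax = std::max(dx, dy);
  if (dmax <= 0) dmax = 1.0;
  double midx = (xmin + xmax) / 2.0, midy = (ymin + ymax) / 2.0;
  // super-triangle well outside the data
  px[n]     = midx - 1000.0 * dmax; py[n]     = midy - 50.0 * dmax;
  px[n + 1] = midx + 1000.0 * dmax; py[n + 1] = midy - 50.0 * dmax;
  px[n + 2] = midx;                 py[n + 2] = midy + 1000.0 * dmax;

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  {
    Tri t; t.a = n; t.b = n + 1; t.c = n + 2; t.alive = true;
    circumcircle(px, py, t.a, t.b, t.c, t.cx, t.cy, t.r2);
    tris.push_back(t);
  }

  std::vector<int> bad;
  std::vector<std::pair<int,int> > edges;

  for (int i = 0; i < n; ++i) {
    double x = px[i], y = py[i];
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double ddx = x - tris[t].cx, ddy = y - tris[t].cy;
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 < tris[t].r2 * (1.0 + 1e-12) + 1e-12) bad.push_back((int)t);
    }
    // boundary edges of the cavity: edges of bad triangles appearing once
    edges.clear();
    for (size_t k = 0; k < bad.size(); ++k) {
      const Tri& t = tris[bad[k]];
      edges.push_back(std::make_pair(t.a, t.b));
      edges.push_back(std::make_pair(t.b, t.c));
      edges.push_back(std::make_pair(t.c, t.a));
    }
    std::vector<bool> dup(edges.size(), false);
    for (size_t e1 = 0; e1 < edges.size(); ++e1) {
      if (dup[e1]) continue;
      for (size_t e2 = e1 + 1; e2 < edges.size(); ++e2) {
        if (dup[e2]) continue;
        if ((edges[e1].first == edges[e2].second && edges[e1].second == edges[e2].first) ||
            (edges[e1].first == edges[e2].first && edges[e1].second == edges[e2].second)) {
          dup[e1] = true; dup[e2] = true;
        }
      }
    }
    for (size_t k = 0; k < bad.size(); ++k) tris[bad[k]].alive = false;
    for (size_t e = 0; e < edges.size(); ++e) {
      if (dup[e]) continue;
      Tri t; t.a = edges[e].first; t.b = edges[e].second; t.c = i; t.alive = true;
      if (!circumcircle(px, py, t.a, t.b, t.c, t.cx, t.cy, t.r2)) {
        t.cx = 0; t.cy = 0; t.r2 = R_PosInf; // degenerate: swallow on next insert
      }
      tris.push_back(t);
    }
    // periodic compaction keeps the scan linear in live triangles
    if (tris.size() > 8u * (size_t)(i + 4)) {
      std::vector<Tri> keep;
      keep.reserve(tris.size());
      for (size_t t = 0; t < tris.size(); ++t)
        if (tris[t].alive) keep.push_back(tris[t]);
      tris.swap(keep);
    }
  }

  int m = 0;
  for (size_t t = 0; t < tris.size(); ++t)
    if (tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive) continue;
    if (tris[t].a >= n || tris[t].b >= n || tris[t].c >= n) continue;
    out(r, 0) = tris[t].a + 1; out(r, 1) = tris[t].b + 1; out(r, 2) = tris[t].c + 1;
    ++r;
  }
  return out;
}
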