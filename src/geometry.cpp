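#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// 2D computational-geometry kernel for alpha-shape analysis of localization
// point clouds: Bowyer-Watson Delaunay triangulation, convex triangle
// clipping for overlap areas, fixed-radius neighbour counts, and
// point-in-polygon tests.

static inline long double orient2d(long double ax, long double ay,
                                   long double bx, long double by,
                                   long double cx, long double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// positive when d lies inside the circumcircle of CCW triangle abc
static inline long double incircle(long double ax, long double ay,
                                   long double bx, long double by,
                                   long double cx, long double cy,
                                   long double dx, long double dy) {
  long double adx = ax - dx, ady = ay - dy;
  long double bdx = bx - dx, bdy = by - dy;
  long double cdx = cx - dx, cdy = cy - dy;
  long double ad = adx * adx + ady * ady;
  long double bd = bdx * bdx + bdy * bdy;
  long double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx);
}

struct Tri { int a, b, c; bool alive; };

// Delaunay triangulation, O(n^2) incremental insertion with a super-triangle.
// A deterministic sub-nanometre symbolic jitter breaks cocircular ties
// (square lattices, grid-snapped localizations) without affecting areas at
// the precision the data carry.
// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) return IntegerMatrix(0, 3);

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, (double)x[i]); xmax = std::max(xmax, (double)x[i]);
    ymin = std::min(ymin, (double)y[i]); ymax = std::max(ymax, (double)y[i]);
  }
  double diag = std::hypot(xmax - xmin, ymax - ymin);
  if (diag <= 0) return IntegerMatrix(0, 3);

  std::vector<long double> px(n + 3), py(n + 3);
  // deterministic LCG jitter, amplitude 1e-9 of the extent
  unsigned long long s = 88172645463325252ULL;
  double amp = 1e-9 * diag;
  for (int i = 0; i < n; ++i) {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    double j1 = (double)(s % 1000003ULL) / 1000003.0 - 0.5;
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    double j2 = (double)(s % 1000003ULL) / 1000003.0 - 0.5;
    px[i] = (long double)x[i] + amp * j1;
    py[i] = (long double)y[i] + amp * j2;
  }
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  double R = 50.0 * diag;
  px[n]     = cx - 2.0 * R; py[n]     = cy - R;
  px[n + 1] = cx + 2.0 * R; py[n + 1] = cy - R;
  px[n + 2] = cx;           py[n + 2] = cy + 2.0 * R;

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2, true});

  std::vector<int> bad;
  std::vector<std::pair<int,int> > edges;

  for (int p = 0; p < n; ++p) {
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      if (incircle(px[tris[t].a], py[tris[t].a],
                   px[tris[t].b], py[tris[t].b],
                   px[tris[t].c], py[tris[t].c],
                   px[p], py[p]) > 0.0L)
        bad.push_back((int)t);
    }
    if (bad.empty()) continue;  // duplicate point: already represented
    edges.clear();
    for (size_t k = 0; k < bad.size(); ++k) {
      Tri &t = tris[bad[k]];
      int e[3][2] = {{t.a, t.b}, {t.b, t.c}, {t.c, t.a}};
      for (int j = 0; j < 3; ++j)
        edges.push_back(std::make_pair(e[j][0], e[j][1]));
      t.alive = false;
    }
    // boundary edges of the cavity appear exactly once (in either direction)
    for (size_t i = 0; i < edges.size(); ++i) {
      bool dup = false;
      for (size_t j = 0; j < edges.size(); ++j) {
        if (i == j) continue;
        if ((edges[i].first == edges[j].first && edges[i].second == edges[j].second) ||
            (edges[i].first == edges[j].second && edges[i].second == edges[j].first)) {
          dup = true; break;
        }
      }
      if (dup) continue;
      int a = edges[i].first, b = edges[i].second;
      long double o = orient2d(px[a], py[a], px[b], py[b], px[p], py[p]);
      if (o == 0.0L) continue;  // collinear with cavity edge: degenerate
      Tri nt;
      if (o > 0) { nt.a = a; nt.b = b; nt.c = p; }
      else       { nt.a = b; nt.b = a; nt.c = p; }
      nt.alive = true;
      tris.push_back(nt);
    }
  }

  int m = 0;
  for (size_t t = 0; t < tris.size(); ++t)
    if (tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive || tris[t].a >= n || tris[t].b >= n || tris[t].c >= n)
      continue;
    out(r, 0) = tris[t].a + 1;
    out(r, 1) = tris[t].b + 1;
    out(r, 2) = tris[t].c + 1;
    ++r;
  }
  return out;
}

static double polyArea(const std::vector<double> &X, const std::vector<double> &Y) {
  double a = 0.0; size_t n = X.size();
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    a += X[i] * Y[j] - X[j] * Y[i];
  }
  return 0.5 * a;
}

// Sutherland-Hodgman: clip convex subject polygon by the half-plane left of
// directed edge (x1,y1)->(x2,y2)
static void clipHalfPlane(std::vector<double> &X, std::vector<double> &Y,
                          double x1, double y1, double x2, double y2) {
  std::vector<double> OX, OY;
  size_t n = X.size();
  if (n == 0) return;
  double ex = x2 - x1, ey = y2 - y1;
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    double si = ex * (Y[i] - y1) - ey * (X[i] - x1);
    double sj = ex * (Y[j] - y1) - ey * (X[j] - x1);
    if (si >= 0) { OX.push_back(X[i]); OY.push_back(Y[i]); }
    if ((si > 0 && sj < 0) || (si < 0 && sj > 0)) {
      double t = si / (si - sj);
      OX.push_back(X[i] + t * (X[j] - X[i]));
      OY.push_back(Y[i] + t * (Y[j] - Y[i]));
    }
  }
  X.swap(OX); Y.swap(OY);
}

// intersection area of two triangle sets whose member triangles have
// pairwise-disjoint interiors (Delaunay subsets), by convex clipping
// [[Rcpp::export(name = ".triset_intersection_area_cpp")]]
double triset_intersection_area_cpp(NumericMatrix pa, IntegerMatrix ta,
                                    NumericMatrix pb, IntegerMatrix tb) {
  int na = ta.nrow(), nb = tb.nrow();
  double total = 0.0;
  std::vector<double> bxlo(nb), bxhi(nb), bylo(nb), byhi(nb);
  for (int j = 0; j < nb; ++j) {
    double xlo = R_PosInf, xhi = R_NegInf, ylo = R_PosInf, yhi = R_NegInf;
    for (int k = 0; k < 3; ++k) {
      double xx = pb(tb(j, k) - 1, 0), yy = pb(tb(j, k) - 1, 1);
      xlo = std::min(xlo, xx); xhi = std::max(xhi, xx);
      ylo = std::min(ylo, yy); yhi = std::max(yhi, yy);
    }
    bxlo[j] = xlo; bxhi[j] = xhi; bylo[j] = ylo; byhi[j] = yhi;
  }
  for (int i = 0; i < na; ++i) {
    double ax[3], ay[3];
    for (int k = 0; k < 3; ++k) {
      ax[k] = pa(ta(i, k) - 1, 0);
      ay[k] = pa(ta(i, k) - 1, 1);
    }
    // ensure CCW
    if (orient2d(ax[0], ay[0], ax[1], ay[1], ax[2], ay[2]) < 0) {
      std::swap(ax[1], ax[2]); std::swap(ay[1], ay[2]);
    }
    double axlo = std::min(ax[0], std::min(ax[1], ax[2]));
    double axhi = std::max(ax[0], std::max(ax[1], ax[2]));
    double aylo = std::min(ay[0], std::min(ay[1], ay[2]));
    double ayhi = std::max(ay[0], std::max(ay[1], ay[2]));
    for (int j = 0; j < nb; ++j) {
      if (bxhi[j] < axlo || bxlo[j] > axhi || byhi[j] < aylo || bylo[j] > ayhi)
        continue;
      double bx[3], by[3];
      for (int k = 0; k < 3; ++k) {
        bx[k] = pb(tb(j, k) - 1, 0);
        by[k] = pb(tb(j, k) - 1, 1);
      }
      if (orient2d(bx[0], by[0], bx[1], by[1], bx[2], by[2]) < 0) {
        std::swap(bx[1], bx[2]); std::swap(by[1], by[2]);
      }
      std::vector<double> X(ax, ax + 3), Y(ay, ay + 3);
      for (int e = 0; e < 3; ++e) {
        int f = (e + 1) % 3;
        clipHalfPlane(X, Y, bx[e], by[e], bx[f], by[f]);
        if (X.empty()) break;
      }
      if (X.size() >= 3) total += std::fabs(polyArea(X, Y));
    }
  }
  return total;
}

// number of other points within radius r of each point (self excluded);
// x-sorted sweep keeps this fast for dense synapse clouds
// [[Rcpp::export(name = ".count_within_radius_cpp")]]
IntegerVector count_within_radius_cpp(NumericVector x, NumericVector y, double r) {
  int n = x.size();
  IntegerVector out(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double r2 = r * r;
  for (int ii = 0; ii < n; ++ii) {
    int i = ord[ii];
    for (int jj = ii + 1; jj < n; ++jj) {
      int j = ord[jj];
      double dx = x[j] - x[i];
      if (dx > r) break;
      double dy = y[j] - y[i];
      if (dx * dx + dy * dy <= r2) { out[i]++; out[j]++; }
    }
  }
  return out;
}

// ray-casting point-in-polygon; points on the boundary count as inside
// (within floating tolerance)
// [[Rcpp::export(name = ".points_in_polygon_cpp")]]
LogicalVector points_in_polygon_cpp(NumericVector px, NumericVector py,
                                    NumericVector vx, NumericVector vy) {
  int n = px.size(), m = vx.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool inside = false;
    double X = px[i], Y = py[i];
    for (int j = 0, k = m - 1; j < m; k = j++) {
      double xj = vx[j], yj = vy[j], xk = vx[k], yk = vy[k];
      // boundary check
      double cross = (xk - xj) * (Y - yj) - (yk - yj) * (X - xj);
      double dot = (X - xj) * (X - xk) + (Y - yj) * (Y - yk);
      if (std::fabs(cross) < 1e-9 * (std::fabs(xk - xj) + std::fabs(yk - yj) + 1.0)
          && dot <= 1e-9) { inside = true; break; }
      if (((yj > Y) != (yk > Y)) &&
          (X < (xk - xj) * (Y - yj) / (yk - yj) + xj))
        inside = !inside;
    }
    out[i] = inside;
  }
  return out;
}
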