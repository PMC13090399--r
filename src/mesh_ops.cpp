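#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// ---- point-triangle closest point (Ericson, Real-Time Collision Detection) ----

static inline void closest_pt_triangle(const double* p, const double* a,
                                       const double* b, const double* c,
                                       double* out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
}

static inline double dist2(const double* p, const double* q) {
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// ---- uniform grid over triangle AABBs ----

struct TriGrid {
  int nx, ny, nz;
  double ox, oy, oz, cs;        // origin and cubic cell size
  std::vector<std::vector<int>> cells;

  inline int clampi(int v, int lo, int hi) const {
    return v < lo ? lo : (v > hi ? hi : v);
  }
  inline int cell_of(double x, double y, double z, int* cx, int* cy, int* cz) const {
    *cx = clampi((int)std::floor((x - ox) / cs), 0, nx - 1);
    *cy = clampi((int)std::floor((y - oy) / cs), 0, ny - 1);
    *cz = clampi((int)std::floor((z - oz) / cs), 0, nz - 1);
    return (*cz * ny + *cy) * nx + *cx;
  }
};

static void build_grid(const NumericMatrix& V, const IntegerMatrix& F, TriGrid& g) {
  int m = F.nrow();
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = std::numeric_limits<double>::infinity();
    hi[d] = -std::numeric_limits<double>::infinity();
  }
  int n = V.nrow();
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = V(i, d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  double ex = hi[0]-lo[0], ey = hi[1]-lo[1], ez = hi[2]-lo[2];
  double emax = std::max(ex, std::max(ey, ez));
  if (emax <= 0) emax = 1.0;
  // aim for roughly one triangle per occupied cell along the surface
  double cs = emax / std::max(1.0, std::cbrt((double)m) * 2.0);
  if (cs <= 0) cs = emax;
  g.cs = cs;
  g.ox = lo[0] - 0.5 * cs; g.oy = lo[1] - 0.5 * cs; g.oz = lo[2] - 0.5 * cs;
  g.nx = std::max(1, (int)std::ceil((ex + cs) / cs));
  g.ny = std::max(1, (int)std::ceil((ey + cs) / cs));
  g.nz = std::max(1, (int)std::ceil((ez + cs) / cs));
  g.cells.assign((size_t)g.nx * g.ny * g.nz, std::vector<int>());
  for (int t = 0; t < m; ++t) {
    double tlo[3], thi[3];
    for (int d = 0; d < 3; ++d) {
      double v0 = V(F(t,0), d), v1 = V(F(t,1), d), v2 = V(F(t,2), d);
      tlo[d] = std::min(v0, std::min(v1, v2));
      thi[d] = std::max(v0, std::max(v1, v2));
    }
    int cx0, cy0, cz0, cx1, cy1, cz1;
    g.cell_of(tlo[0], tlo[1], tlo[2], &cx0, &cy0, &cz0);
    g.cell_of(thi[0], thi[1], thi[2], &cx1, &cy1, &cz1);
    for (int cz = cz0; cz <= cz1; ++cz)
      for (int cy = cy0; cy <= cy1; ++cy)
        for (int cx = cx0; cx <= cx1; ++cx)
          g.cells[((size_t)cz * g.ny + cy) * g.nx + cx].push_back(t);
  }
}

// Exact closest point on a triangulated surface for each query row.
// F uses 0-based vertex indices. Returns foot points, distances and the
// (1-based) index of the nearest face. Grid-accelerated but identical to a
// brute-force scan over all triangles.
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  int m = F.nrow(), q = Q.nrow();
  if (m == 0) stop("mesh has no faces");
  TriGrid g;
  build_grid(V, F, g);

  NumericMatrix P(q, 3);
  NumericVector D(q);
  IntegerVector FI(q);
  std::vector<int> stamp(m, -1);

  for (int qi = 0; qi < q; ++qi) {
    double p[3] = { Q(qi,0), Q(qi,1), Q(qi,2) };
    double best = std::numeric_limits<double>::infinity();
    double bestPt[3] = {0,0,0};
    int bestTri = -1;
    double r = g.cs;
    int plox = 1, phix = 0, ploy = 1, phiy = 0, ploz = 1, phiz = 0; // empty previous box
    while (true) {
      int lox, loy, loz, hix, hiy, hiz;
      g.cell_of(p[0]-r, p[1]-r, p[2]-r, &lox, &loy, &loz);
      g.cell_of(p[0]+r, p[1]+r, p[2]+r, &hix, &hiy, &hiz);
      for (int cz = loz; cz <= hiz; ++cz)
        for (int cy = loy; cy <= hiy; ++cy)
          for (int cx = lox; cx <= hix; ++cx) {
            if (cx >= plox && cx <= phix && cy >= ploy && cy <= phiy &&
                cz >= ploz && cz <= phiz) continue; // already scanned
            const std::vector<int>& lst = g.cells[((size_t)cz * g.ny + cy) * g.nx + cx];
            for (size_t u = 0; u < lst.size(); ++u) {
              int t = lst[u];
              if (stamp[t] == qi) continue;
              stamp[t] = qi;
              double a[3] = { V(F(t,0),0), V(F(t,0),1), V(F(t,0),2) };
              double b[3] = { V(F(t,1),0), V(F(t,1),1), V(F(t,1),2) };
              double c[3] = { V(F(t,2),0), V(F(t,2),1), V(F(t,2),2) };
              double foot[3];
              closest_pt_triangle(p, a, b, c, foot);
              double d2 = dist2(p, foot);
              if (d2 < best) {
                best = d2;
                bestPt[0] = foot[0]; bestPt[1] = foot[1]; bestPt[2] = foot[2];
                bestTri = t;
              }
            }
          }
      bool fullCover = (lox == 0 && loy == 0 && loz == 0 &&
                        hix == g.nx - 1 && hiy == g.ny - 1 && hiz == g.nz - 1);
      if (bestTri >= 0 && std::sqrt(best) <= r) break;
      if (fullCover) break; // every triangle scanned: best is the global optimum
      plox = lox; phix = hix; ploy = loy; phiy = hiy; ploz = loz; phiz = hiz;
      r *= 2.0;
    }
    P(qi,0) = bestPt[0]; P(qi,1) = bestPt[1]; P(qi,2) = bestPt[2];
    D[qi] = std::sqrt(best);
    FI[qi] = bestTri + 1;
  }
  return List::create(_["point"] = P, _["distance"] = D, _["face"] = FI);
}

// Gaussian smoothing of a sparse displacement field over mesh vertices.
// refV: all reference vertices (n x 3); srcPts: points carrying raw
// displacements (s x 3); disp: raw displacements (s x 3); sigma: bandwidth.
// Weights exp(-d^2 / (2 sigma^2)) truncated at 3 sigma, normalized per
// vertex; vertices with no source within 3 sigma receive zero displacement.
// [[Rcpp::export]]
NumericMatrix cpp_smooth_field(NumericMatrix refV, NumericMatrix srcPts,
                               NumericMatrix disp, double sigma) {
  int n = refV.nrow(), s = srcPts.nrow();
  if (disp.nrow() != s) stop("disp/srcPts row mismatch");
  if (sigma <= 0) stop("sigma must be > 0");
  NumericMatrix out(n, 3);
  double cut2 = 9.0 * sigma * sigma;
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int i = 0; i < n; ++i) {
    double px = refV(i,0), py = refV(i,1), pz = refV(i,2);
    double wsum = 0.0, ax = 0.0, ay = 0.0, az = 0.0;
    for (int j = 0; j < s; ++j) {
      double dx = px - srcPts(j,0), dy = py - srcPts(j,1), dz = pz - srcPts(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > cut2) continue;
      double w = std::exp(-d2 * inv2s2);
      wsum += w;
      ax += w * disp(j,0); ay += w * disp(j,1); az += w * disp(j,2);
    }
    if (wsum > 0) { out(i,0) = ax / wsum; out(i,1) = ay / wsum; out(i,2) = az / wsum; }
  }
  return out;
}

// Nearest vertex (brute force): index (1-based) and distance per query.
// [[Rcpp::export]]
List cpp_nearest_vertex(NumericMatrix V, NumericMatrix Q) {
  int n = V.nrow(), q = Q.nrow();
  if (n == 0) stop("no vertices");
  IntegerVector idx(q);
  NumericVector d(q);
  for (int i = 0; i < q; ++i) {
    double p[3] = { Q(i,0), Q(i,1), Q(i,2) };
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    for (int j = 0; j < n; ++j) {
      double v[3] = { V(j,0), V(j,1), V(j,2) };
      double d2 = dist2(p, v);
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    d[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = d);
}
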