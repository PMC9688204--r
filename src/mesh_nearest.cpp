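// Nearest-point queries from sample points to a triangle mesh, with a
// uniform-grid spatial index. Used by the nominal-actual deviation
// analysis, where 1e5 samples against ~4e4 triangles make pure-R
// distance loops impractical.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
};

// closest point on triangle (a,b,c) to p (Ericson, Real-Time Collision
// Detection, 5.1.5)
static Vec3 closest_on_triangle(const Vec3& p, const Vec3& a, const Vec3& b,
                                const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = ab.dot(ap), d2 = ac.dot(ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = ab.dot(bp), d4 = ac.dot(bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = ab.dot(cp), d6 = ac.dot(cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// [[Rcpp::export]]
List mesh_nearest_cpp(NumericMatrix points, NumericMatrix V, IntegerMatrix F) {
  const int np = points.nrow();
  const int nf = F.nrow();
  if (nf == 0) stop("reference mesh has no faces");

  std::vector<Vec3> A(nf), B(nf), C(nf), N(nf);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  double mean_edge = 0.0;
  for (int i = 0; i < nf; ++i) {
    int ia = F(i, 0) - 1, ib = F(i, 1) - 1, ic = F(i, 2) - 1;
    A[i] = Vec3(V(ia, 0), V(ia, 1), V(ia, 2));
    B[i] = Vec3(V(ib, 0), V(ib, 1), V(ib, 2));
    C[i] = Vec3(V(ic, 0), V(ic, 1), V(ic, 2));
    N[i] = (B[i] - A[i]).cross(C[i] - A[i]);
    double xs[3] = {A[i].x, B[i].x, C[i].x};
    double ys[3] = {A[i].y, B[i].y, C[i].y};
    double zs[3] = {A[i].z, B[i].z, C[i].z};
    lo[0] = std::min(lo[0], *std::min_element(xs, xs + 3));
    lo[1] = std::min(lo[1], *std::min_element(ys, ys + 3));
    lo[2] = std::min(lo[2], *std::min_element(zs, zs + 3));
    hi[0] = std::max(hi[0], *std::max_element(xs, xs + 3));
    hi[1] = std::max(hi[1], *std::max_element(ys, ys + 3));
    hi[2] = std::max(hi[2], *std::max_element(zs, zs + 3));
    double e1 = std::sqrt((B[i] - A[i]).dot(B[i] - A[i]));
    double e2 = std::sqrt((C[i] - B[i]).dot(C[i] - B[i]));
    mean_edge += (e1 + e2) * 0.5;
  }
  mean_edge /= nf;
  double cell = std::max(mean_edge * 2.0, 1e-9);
  int nx = std::max(1, std::min(128, (int)std::ceil((hi[0] - lo[0]) / cell)));
  int ny = std::max(1, std::min(128, (int)std::ceil((hi[1] - lo[1]) / cell)));
  int nz = std::max(1, std::min(128, (int)std::ceil((hi[2] - lo[2]) / cell)));
  double cx = (hi[0] - lo[0]) / nx + 1e-12;
  double cy = (hi[1] - lo[1]) / ny + 1e-12;
  double cz = (hi[2] - lo[2]) / nz + 1e-12;

  // bin triangles by bounding box
  std::vector<std::vector<int> > grid((size_t)nx * ny * nz);
  auto cell_of = [&](double x, double y, double z, int& ix, int& iy, int& iz) {
    ix = std::min(nx - 1, std::max(0, (int)((x - lo[0]) / cx)));
    iy = std::min(ny - 1, std::max(0, (int)((y - lo[1]) / cy)));
    iz = std::min(nz - 1, std::max(0, (int)((z - lo[2]) / cz)));
  };
  for (int i = 0; i < nf; ++i) {
    int ix0, iy0, iz0, ix1, iy1, iz1;
    double x0 = std::min(A[i].x, std::min(B[i].x, C[i].x));
    double y0 = std::min(A[i].y, std::min(B[i].y, C[i].y));
    double z0 = std::min(A[i].z, std::min(B[i].z, C[i].z));
    double x1 = std::max(A[i].x, std::max(B[i].x, C[i].x));
    double y1 = std::max(A[i].y, std::max(B[i].y, C[i].y));
    double z1 = std::max(A[i].z, std::max(B[i].z, C[i].z));
    cell_of(x0, y0, z0, ix0, iy0, iz0);
    cell_of(x1, y1, z1, ix1, iy1, iz1);
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int iz = iz0; iz <= iz1; ++iz)
          grid[(size_t)(ix * ny + iy) * nz + iz].push_back(i);
  }

  NumericVector dist(np), side(np);
  IntegerVector tri(np);
  NumericMatrix nearest(np, 3);
  double cmin = std::min(cx, std::min(cy, cz));

  for (int q = 0; q < np; ++q) {
    Vec3 p(points(q, 0), points(q, 1), points(q, 2));
    int ix, iy, iz;
    cell_of(p.x, p.y, p.z, ix, iy, iz);
    double best = std::numeric_limits<double>::infinity();
    int best_tri = -1;
    Vec3 best_pt;
    int max_ring = std::max(nx, std::max(ny, nz));
    for (int ring = 0; ring <= max_ring; ++ring) {
      // once a candidate is found, expand one extra ring layer to be safe
      if (best_tri >= 0 && ring * cmin > std::sqrt(best) + cmin) break;
      int x0 = std::max(0, ix - ring), x1 = std::min(nx - 1, ix + ring);
      int y0 = std::max(0, iy - ring), y1 = std::min(ny - 1, iy + ring);
      int z0 = std::max(0, iz - ring), z1 = std::min(nz - 1, iz + ring);
      for (int gx = x0; gx <= x1; ++gx)
        for (int gy = y0; gy <= y1; ++gy)
          for (int gz = z0; gz <= z1; ++gz) {
            // only the shell of the current ring
            if (ring > 0 && gx != x0 && gx != x1 && gy != y0 && gy != y1 &&
                gz != z0 && gz != z1)
              continue;
            const std::vector<int>& bucket = grid[(size_t)(gx * ny + gy) * nz + gz];
            for (size_t k = 0; k < bucket.size(); ++k) {
              int t = bucket[k];
              Vec3 cp = closest_on_triangle(p, A[t], B[t], C[t]);
              double dd = (cp - p).dot(cp - p);
              if (dd < best) {
                best = dd;
                best_tri = t;
                best_pt = cp;
              }
            }
          }
      if (best_tri >= 0 && (ring + 1) * cmin > std::sqrt(best) + cmin &&
          ring >= 1)
        break;
    }
    dist[q] = std::sqrt(best);
    tri[q] = best_tri + 1;
    double s = N[best_tri].dot(p - best_pt);
    side[q] = (s > 0) - (s < 0);
    nearest(q, 0) = best_pt.x;
    nearest(q, 1) = best_pt.y;
    nearest(q, 2) = best_pt.z;
  }
  return List::create(_["distance"] = dist, _["triangle"] = tri,
                      _["side"] = side, _["nearest"] = nearest);
}
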