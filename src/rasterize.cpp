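#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pixel convention (package-wide): 0-based, pixel centers at integer
// coordinates, u along width. Pixel (ix, iy) has center (ix, iy) and maps to
// R matrix element [iy + 1, ix + 1].

static inline double edge_fn(double ax, double ay, double bx, double by,
                             double px, double py) {
  return (bx - ax) * (py - ay) - (by - ay) * (px - ax);
}

// [[Rcpp::export(name = ".cpp_raster_hard")]]
IntegerMatrix cpp_raster_hard(NumericMatrix uv, IntegerMatrix faces,
                              int width, int height) {
  IntegerMatrix out(height, width);
  const int nf = faces.nrow();
  for (int f = 0; f < nf; ++f) {
    const int i0 = faces(f, 0), i1 = faces(f, 1), i2 = faces(f, 2);
    const double ax = uv(i0, 0), ay = uv(i0, 1);
    const double bx = uv(i1, 0), by = uv(i1, 1);
    const double cx = uv(i2, 0), cy = uv(i2, 1);
    const double area = edge_fn(ax, ay, bx, by, cx, cy);
    if (std::fabs(area) < 1e-14) continue;
    const double s = area > 0 ? 1.0 : -1.0;
    int x0 = (int)std::ceil(std::min(ax, std::min(bx, cx)));
    int x1 = (int)std::floor(std::max(ax, std::max(bx, cx)));
    int y0 = (int)std::ceil(std::min(ay, std::min(by, cy)));
    int y1 = (int)std::floor(std::max(ay, std::max(by, cy)));
    x0 = std::max(x0, 0); y0 = std::max(y0, 0);
    x1 = std::min(x1, width - 1); y1 = std::min(y1, height - 1);
    for (int iy = y0; iy <= y1; ++iy) {
      for (int ix = x0; ix <= x1; ++ix) {
        const double px = ix, py = iy;
        const double w0 = s * edge_fn(ax, ay, bx, by, px, py);
        const double w1 = s * edge_fn(bx, by, cx, cy, px, py);
        const double w2 = s * edge_fn(cx, cy, ax, ay, px, py);
        if (w0 >= 0 && w1 >= 0 && w2 >= 0) out(iy, ix) = 1;
      }
    }
  }
  return out;
}

struct SegDist {
  double d;        // unsigned distance
  double t;        // clamped parameter along segment
  bool at_vertex;  // true if nearest feature is an endpoint
  int which_vertex; // 0 = a, 1 = b (valid when at_vertex)
};

static inline SegDist seg_dist(double ax, double ay, double bx, double by,
                               double px, double py) {
  SegDist r;
  const double ex = bx - ax, ey = by - ay;
  const double len2 = ex * ex + ey * ey;
  double t = len2 > 0 ? ((px - ax) * ex + (py - ay) * ey) / len2 : 0.0;
  if (t <= 0.0) {
    r.t = 0.0; r.at_vertex = true; r.which_vertex = 0;
    r.d = std::sqrt((px - ax) * (px - ax) + (py - ay) * (py - ay));
  } else if (t >= 1.0) {
    r.t = 1.0; r.at_vertex = true; r.which_vertex = 1;
    r.d = std::sqrt((px - bx) * (px - bx) + (py - by) * (py - by));
  } else {
    r.t = t; r.at_vertex = false; r.which_vertex = -1;
    const double qx = ax + t * ex, qy = ay + t * ey;
    r.d = std::sqrt((px - qx) * (px - qx) + (py - qy) * (py - qy));
  }
  return r;
}

// Signed 2D distance from pixel p to triangle (positive inside).
static inline double tri_signed_dist(const double *tx, const double *ty,
                                     double px, double py) {
  const double area = edge_fn(tx[0], ty[0], tx[1], ty[1], tx[2], ty[2]);
  const double s = area >= 0 ? 1.0 : -1.0;
  bool inside = true;
  for (int e = 0; e < 3; ++e) {
    const int j = (e + 1) % 3;
    if (s * edge_fn(tx[e], ty[e], tx[j], ty[j], px, py) < 0) { inside = false; break; }
  }
  double dmin = R_PosInf;
  for (int e = 0; e < 3; ++e) {
    const int j = (e + 1) % 3;
    SegDist sd = seg_dist(tx[e], ty[e], tx[j], ty[j], px, py);
    if (sd.d < dmin) dmin = sd.d;
  }
  return inside ? dmin : -dmin;
}

static inline double sigmoid(double x) {
  if (x >= 0) { const double z = std::exp(-x); return 1.0 / (1.0 + z); }
  const double z = std::exp(x); return z / (1.0 + z);
}

// Soft silhouette: occupancy(p) = 1 - prod_f (1 - sigmoid(k * d_f(p))).
// Faces farther than cutoff px from a pixel are skipped (their sigmoid is
// numerically 0); accumulation is done in log space for stability.
// [[Rcpp::export(name = ".cpp_raster_soft")]]
NumericMatrix cpp_raster_soft(NumericMatrix uv, IntegerMatrix faces,
                              int width, int height, double sharpness,
                              double cutoff) {
  NumericMatrix logq(height, width); // sum of log(1 - s_f)
  const int nf = faces.nrow();
  double tx[3], ty[3];
  for (int f = 0; f < nf; ++f) {
    for (int v = 0; v < 3; ++v) {
      tx[v] = uv(faces(f, v), 0);
      ty[v] = uv(faces(f, v), 1);
    }
    int x0 = (int)std::ceil(std::min(tx[0], std::min(tx[1], tx[2])) - cutoff);
    int x1 = (int)std::floor(std::max(tx[0], std::max(tx[1], tx[2])) + cutoff);
    int y0 = (int)std::ceil(std::min(ty[0], std::min(ty[1], ty[2])) - cutoff);
    int y1 = (int)std::floor(std::max(ty[0], std::max(ty[1], ty[2])) + cutoff);
    x0 = std::max(x0, 0); y0 = std::max(y0, 0);
    x1 = std::min(x1, width - 1); y1 = std::min(y1, height - 1);
    for (int iy = y0; iy <= y1; ++iy) {
      for (int ix = x0; ix <= x1; ++ix) {
        const double d = tri_signed_dist(tx, ty, (double)ix, (double)iy);
        double sf = sigmoid(sharpness * d);
        if (sf > 1.0 - 1e-12) sf = 1.0 - 1e-12;
        logq(iy, ix) += std::log1p(-sf);
      }
    }
  }
  NumericMatrix out(height, width);
  for (int i = 0; i < height * width; ++i) out[i] = 1.0 - std::exp(logq[i]);
  return out;
}

// Gradient of signed distance w.r.t. the three triangle vertices, for the
// nearest boundary feature. g is a 3x2 output (per-vertex du, dv).
static void tri_signed_dist_grad(const double *tx, const double *ty,
                                 double px, double py, double *g /*6*/) {
  for (int i = 0; i < 6; ++i) g[i] = 0.0;
  bool inside = true;
  const double area = edge_fn(tx[0], ty[0], tx[1], ty[1], tx[2], ty[2]);
  const double s = area >= 0 ? 1.0 : -1.0;
  for (int e = 0; e < 3 && inside; ++e) {
    const int j = (e + 1) % 3;
    if (s * edge_fn(tx[e], ty[e], tx[j], ty[j], px, py) < 0) inside = false;
  }
  double dmin = R_PosInf; int emin = 0; SegDist best;
  for (int e = 0; e < 3; ++e) {
    const int j = (e + 1) % 3;
    SegDist sd = seg_dist(tx[e], ty[e], tx[j], ty[j], px, py);
    if (sd.d < dmin) { dmin = sd.d; emin = e; best = sd; }
  }
  const double sign = inside ? 1.0 : -1.0;
  const int ia = emin, ib = (emin + 1) % 3;
  const double ax = tx[ia], ay = ty[ia], bx = tx[ib], by = ty[ib];
  if (best.at_vertex) {
    // d_unsigned = |p - v|; grad w.r.t. v = (v - p) / |p - v|
    const int iv = best.which_vertex == 0 ? ia : ib;
    const double vx = tx[iv], vy = ty[iv];
    if (dmin > 1e-12) {
      g[iv * 2 + 0] = sign * (vx - px) / dmin;
      g[iv * 2 + 1] = sign * (vy - py) / dmin;
    }
  } else {
    // perpendicular foot: d_unsigned = |cross(e, p-a)| / |e|
    const double ex = bx - ax, ey = by - ay;
    const double elen = std::sqrt(ex * ex + ey * ey);
    if (elen < 1e-12) return;
    const double c = ex * (py - ay) - ey * (px - ax);
    const double cs = c >= 0 ? 1.0 : -1.0; // sign of the cross product
    // d_signed = sign * |c| / |e| = sign * cs * c / |e|
    const double k = sign * cs;
    // dc/da = (by - py, px - bx); dc/db = (py - ay, ax - px)
    g[ia * 2 + 0] = k * ((by - py) / elen + c * ex / (elen * elen * elen));
    g[ia * 2 + 1] = k * ((px - bx) / elen + c * ey / (elen * elen * elen));
    g[ib * 2 + 0] = k * ((py - ay) / elen - c * ex / (elen * elen * elen));
    g[ib * 2 + 1] = k * ((ax - px) / elen - c * ey / (elen * elen * elen));
  }
}

// Vector-Jacobian product of the soft rasterizer: given dL/dmask, return
// dL/duv (n x 2). Recomputes the per-pixel aggregation in log space.
// [[Rcpp::export(name = ".cpp_raster_soft_vjp")]]
NumericMatrix cpp_raster_soft_vjp(NumericMatrix uv, IntegerMatrix faces,
                                  int width, int height, double sharpness,
                                  double cutoff, NumericMatrix grad_mask) {
  const int nf = faces.nrow();
  NumericMatrix logq(height, width);
  double tx[3], ty[3], g[6];
  // pass 1: total log-product per pixel
  for (int f = 0; f < nf; ++f) {
    for (int v = 0; v < 3; ++v) {
      tx[v] = uv(faces(f, v), 0);
      ty[v] = uv(faces(f, v), 1);
    }
    int x0 = (int)std::ceil(std::min(tx[0], std::min(tx[1], tx[2])) - cutoff);
    int x1 = (int)std::floor(std::max(tx[0], std::max(tx[1], tx[2])) + cutoff);
    int y0 = (int)std::ceil(std::min(ty[0], std::min(ty[1], ty[2])) - cutoff);
    int y1 = (int)std::floor(std::max(ty[0], std::max(ty[1], ty[2])) + cutoff);
    x0 = std::max(x0, 0); y0 = std::max(y0, 0);
    x1 = std::min(x1, width - 1); y1 = std::min(y1, height - 1);
    for (int iy = y0; iy <= y1; ++iy)
      for (int ix = x0; ix <= x1; ++ix) {
        const double d = tri_signed_dist(tx, ty, (double)ix, (double)iy);
        double sf = sigmoid(sharpness * d);
        if (sf > 1.0 - 1e-12) sf = 1.0 - 1e-12;
        logq(iy, ix) += std::log1p(-sf);
      }
  }
  // pass 2: dL/ds_f = -dL/dmask * prod_{f' != f}(1 - s_f'), chain to uv
  NumericMatrix duv(uv.nrow(), 2);
  for (int f = 0; f < nf; ++f) {
    for (int v = 0; v < 3; ++v) {
      tx[v] = uv(faces(f, v), 0);
      ty[v] = uv(faces(f, v), 1);
    }
    int x0 = (int)std::ceil(std::min(tx[0], std::min(tx[1], tx[2])) - cutoff);
    int x1 = (int)std::floor(std::max(tx[0], std::max(tx[1], tx[2])) + cutoff);
    int y0 = (int)std::ceil(std::min(ty[0], std::min(ty[1], ty[2])) - cutoff);
    int y1 = (int)std::floor(std::max(ty[0], std::max(ty[1], ty[2])) + cutoff);
    x0 = std::max(x0, 0); y0 = std::max(y0, 0);
    x1 = std::min(x1, width - 1); y1 = std::min(y1, height - 1);
    for (int iy = y0; iy <= y1; ++iy)
      for (int ix = x0; ix <= x1; ++ix) {
        const double gm = grad_mask(iy, ix);
        if (gm == 0.0) continue;
        const double d = tri_signed_dist(tx, ty, (double)ix, (double)iy);
        double sf = sigmoid(sharpness * d);
        if (sf > 1.0 - 1e-12) sf = 1.0 - 1e-12;
        // mask = 1 - exp(logq); dmask/ds_f = exp(logq - log(1 - s_f))
        const double others = std::exp(logq(iy, ix) - std::log1p(-sf));
        const double ds_dd = sharpness * sf * (1.0 - sf);
        const double w = gm * others * ds_dd;
        if (w == 0.0) continue;
        tri_signed_dist_grad(tx, ty, (double)ix, (double)iy, g);
        for (int v = 0; v < 3; ++v) {
          duv(faces(f, v), 0) += w * g[v * 2 + 0];
          duv(faces(f, v), 1) += w * g[v * 2 + 1];
        }
      }
  }
  return duv;
}
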