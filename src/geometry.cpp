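#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Minimum distance from each voxel centre to a closed polyline.
// Voxel centre (0-based index i) sits at origin + i * h (isotropic spacing).
// cutoff > 0 restricts work to voxels within `cutoff` of a segment's bounding
// box; untouched voxels are returned as +Inf.
// [[Rcpp::export]]
NumericVector cpp_dist_field(IntegerVector dim, double h, NumericVector origin,
                             NumericMatrix verts, double cutoff) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox, R_PosInf);
  const int n = verts.nrow();
  for (int s = 0; s < n; ++s) {
    const int t = (s + 1) % n;
    const double ax = verts(s, 0), ay = verts(s, 1), az = verts(s, 2);
    const double bx = verts(t, 0), by = verts(t, 1), bz = verts(t, 2);
    const double ex = bx - ax, ey = by - ay, ez = bz - az;
    const double ee = ex * ex + ey * ey + ez * ez;
    // bounding box in voxel indices
    int i0 = 0, i1 = nx - 1, j0 = 0, j1 = ny - 1, k0 = 0, k1 = nz - 1;
    if (cutoff > 0) {
      i0 = std::max(0, (int)std::floor((std::min(ax, bx) - cutoff - origin[0]) / h));
      i1 = std::min(nx - 1, (int)std::ceil((std::max(ax, bx) + cutoff - origin[0]) / h));
      j0 = std::max(0, (int)std::floor((std::min(ay, by) - cutoff - origin[1]) / h));
      j1 = std::min(ny - 1, (int)std::ceil((std::max(ay, by) + cutoff - origin[1]) / h));
      k0 = std::max(0, (int)std::floor((std::min(az, bz) - cutoff - origin[2]) / h));
      k1 = std::min(nz - 1, (int)std::ceil((std::max(az, bz) + cutoff - origin[2]) / h));
    }
    for (int k = k0; k <= k1; ++k) {
      const double pz = origin[2] + k * h;
      for (int j = j0; j <= j1; ++j) {
        const double py = origin[1] + j * h;
        for (int i = i0; i <= i1; ++i) {
          const double px = origin[0] + i * h;
          double u = 0.0;
          if (ee > 0) {
            u = clampd(((px - ax) * ex + (py - ay) * ey + (pz - az) * ez) / ee,
                       0.0, 1.0);
          }
          const double dx = px - (ax + u * ex);
          const double dy = py - (ay + u * ey);
          const double dz = pz - (az + u * ez);
          const double d2 = dx * dx + dy * dy + dz * dz;
          const R_xlen_t idx = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          if (d2 < out[idx] * out[idx] || out[idx] == R_PosInf) {
            const double d = std::sqrt(d2);
            if (d < out[idx]) out[idx] = d;
          }
        }
      }
    }
  }
  return out;
}

static inline void crossp(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dotp(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline bool unitize(double *v) {
  double n = std::sqrt(dotp(v, v));
  if (n < 1e-12) return false;
  v[0] /= n; v[1] /= n; v[2] /= n;
  return true;
}

// Writhe of a closed polygon by the exact per-segment-pair solid-angle
// expression (the quadrilateral formula of Klenin & Langowski, method 1a).
// Adjacent segment pairs (sharing a vertex) contribute exactly zero and are
// skipped.
// [[Rcpp::export]]
double cpp_writhe(NumericMatrix verts) {
  const int n = verts.nrow();
  double wr = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue; // adjacent through closure
      double p1[3], p2[3], p3[3], p4[3];
      for (int d = 0; d < 3; ++d) {
        p1[d] = verts(i, d);
        p2[d] = verts((i + 1) % n, d);
        p3[d] = verts(j, d);
        p4[d] = verts((j + 1) % n, d);
      }
      double r12[3], r13[3], r14[3], r23[3], r24[3], r34[3];
      for (int d = 0; d < 3; ++d) {
        r12[d] = p2[d] - p1[d];
        r13[d] = p3[d] - p1[d];
        r14[d] = p4[d] - p1[d];
        r23[d] = p3[d] - p2[d];
        r24[d] = p4[d] - p2[d];
        r34[d] = p4[d] - p3[d];
      }
      // coplanar segment pair: the Gauss integrand vanishes identically
      // (and the asin formula sits on its branch cut), so contribute 0
      double cr0[3];
      crossp(r34, r12, cr0);
      const double sg0 = dotp(cr0, r13);
      const double scale = std::sqrt(dotp(r34, r34) * dotp(r12, r12) *
                                     dotp(r13, r13));
      if (std::fabs(sg0) < 1e-10 * scale) continue;
      double n1[3], n2[3], n3[3], n4[3];
      crossp(r13, r14, n1);
      crossp(r14, r24, n2);
      crossp(r24, r23, n3);
      crossp(r23, r13, n4);
      if (!unitize(n1) || !unitize(n2) || !unitize(n3) || !unitize(n4))
        continue; // coplanar degenerate pair: zero solid angle
      double omega = std::asin(clampd(dotp(n1, n2), -1.0, 1.0)) +
                     std::asin(clampd(dotp(n2, n3), -1.0, 1.0)) +
                     std::asin(clampd(dotp(n3, n4), -1.0, 1.0)) +
                     std::asin(clampd(dotp(n4, n1), -1.0, 1.0));
      wr += (sg0 > 0 ? 1.0 : -1.0) * omega / (2.0 * M_PI);
    }
  }
  return wr;
}

// Separable Gaussian blur of a 3D grid; sigma in voxel units. Truncated
// kernel is renormalised at the boundaries so flat fields stay flat.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim,
                                double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (sigma <= 0) return clone(vol);
  const int rad = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> kern(2 * rad + 1);
  for (int i = -rad; i <= rad; ++i)
    kern[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));

  NumericVector a = clone(vol);
  NumericVector b(a.size());
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const int ns[3] = {nx, ny, nz};
  const R_xlen_t st[3] = {sx, sy, sz};

  for (int axis = 0; axis < 3; ++axis) {
    const int nAxis = ns[axis];
    const R_xlen_t stride = st[axis];
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int idxAlong = axis == 0 ? i : (axis == 1 ? j : k);
          const R_xlen_t base = i * sx + (R_xlen_t)j * sy + (R_xlen_t)k * sz;
          double acc = 0.0, wsum = 0.0;
          const int lo = std::max(0, idxAlong - rad);
          const int hi = std::min(nAxis - 1, idxAlong + rad);
          for (int m = lo; m <= hi; ++m) {
            const double w = kern[m - idxAlong + rad];
            acc += w * a[base + (R_xlen_t)(m - idxAlong) * stride];
            wsum += w;
          }
          b[base] = acc / wsum;
        }
      }
    }
    std::swap(a, b);
  }
  return a;
}

// Label connected components of a logical mask, 26-connectivity.
// Labels are 1..K in discovery order; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(nvox, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    if (!mask[v] || lab[v] != 0) continue;
    ++next;
    stack.push_back(v);
    lab[v] = next;
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int ci = cur % nx;
      const int cj = (cur / nx) % ny;
      const int ck = cur / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int ni = ci + di, nj = cj + dj, nk = ck + dk;
            if (ni < 0 || ni >= nx || nj < 0 || nj >= ny || nk < 0 || nk >= nz)
              continue;
            const R_xlen_t nv =
                (R_xlen_t)ni + (R_xlen_t)nx * (nj + (R_xlen_t)ny * nk);
            if (mask[nv] && lab[nv] == 0) {
              lab[nv] = next;
              stack.push_back(nv);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Trilinear interpolation at points given in continuous 0-based voxel index
// coordinates. Points outside the grid return NA.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = NA_REAL;
      continue;
    }
    int i = std::min((int)std::floor(x), nx - 2);
    int j = std::min((int)std::floor(y), ny - 2);
    int k = std::min((int)std::floor(z), nz - 2);
    if (nx == 1) i = 0;
    if (ny == 1) j = 0;
    if (nz == 1) k = 0;
    const double fx = x - i, fy = y - j, fz = z - k;
    double acc = 0.0;
    for (int dk = 0; dk <= 1; ++dk) {
      const double wz = dk ? fz : 1 - fz;
      const int kk = std::min(k + dk, nz - 1);
      for (int dj = 0; dj <= 1; ++dj) {
        const double wy = dj ? fy : 1 - fy;
        const int jj = std::min(j + dj, ny - 1);
        for (int di = 0; di <= 1; ++di) {
          const double wx = di ? fx : 1 - fx;
          const int ii = std::min(i + di, nx - 1);
          acc += wx * wy * wz *
                 vol[(R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
        }
      }
    }
    out[p] = acc;
  }
  return out;
}

// Excluded-volume penalty over non-adjacent vertex pairs (cyclic index
// distance >= 2) closer than dmin: sum of squared shortfalls, plus its
// gradient with respect to every vertex.
// [[Rcpp::export]]
List cpp_overlap(NumericMatrix verts, double dmin) {
  const int n = verts.nrow();
  double pen = 0.0;
  NumericMatrix grad(n, 3);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue; // cyclically adjacent
      double dx = verts(i, 0) - verts(j, 0);
      double dy = verts(i, 1) - verts(j, 1);
      double dz = verts(i, 2) - verts(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d >= dmin) continue;
      double short_ = dmin - d;
      pen += short_ * short_;
      double f = -2.0 * short_ / std::max(d, 1e-6); // d/dv_i of (dmin-d)^2
      grad(i, 0) += f * dx; grad(i, 1) += f * dy; grad(i, 2) += f * dz;
      grad(j, 0) -= f * dx; grad(j, 1) -= f * dy; grad(j, 2) -= f * dz;
    }
  }
  return List::create(Named("penalty") = pen, Named("gradient") = grad);
}
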