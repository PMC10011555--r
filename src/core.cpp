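// Compiled kernels for fiber3d: separable convolution, per-voxel 3x3
// symmetric eigenanalysis, B-spline plane rotation, lateral resampling.
#include <RcppArmadillo.h>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Reflect index into [0, n-1] (symmetric with edge repeat: dcba|abcd|dcba).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Correlation of a 3D volume with a 1D kernel along one axis (0=x, 1=y, 2=z).
// Kernel is applied as out[i] = sum_t w[t + h] * in[i + t], t in [-h, h],
// with reflective boundary handling. Array layout is R column-major (x fastest).
// [[Rcpp::export]]
NumericVector cpp_conv_axis(const NumericVector& vol, const IntegerVector& dim,
                            const NumericVector& kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kernel.size();
  const int h = (klen - 1) / 2;
  if (klen % 2 != 1) stop("kernel length must be odd");
  NumericVector out(vol.size());
  const double* in = vol.begin();
  double* o = out.begin();
  const double* w = kernel.begin();

  if (axis == 0) {
    std::vector<double> buf(nx + 2 * h);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        const double* line = in + (size_t)nx * (y + (size_t)ny * z);
        double* oline = o + (size_t)nx * (y + (size_t)ny * z);
        for (int x = 0; x < nx; ++x) buf[h + x] = line[x];
        for (int t = 0; t < h; ++t) {
          buf[t] = line[reflect_idx(t - h, nx)];
          buf[nx + h + t] = line[reflect_idx(nx + t, nx)];
        }
        for (int x = 0; x < nx; ++x) oline[x] = 0.0;
        const double* b = buf.data();
        for (int t = 0; t < klen; ++t) {
          const double wt = w[t];
          const double* bt = b + t;
          for (int x = 0; x < nx; ++x) oline[x] += wt * bt[x];
        }
      }
    }
  } else if (axis == 1) {
    std::vector<int> src(ny * klen);
    for (int y = 0; y < ny; ++y)
      for (int t = 0; t < klen; ++t)
        src[y * klen + t] = reflect_idx(y + t - h, ny);
    for (int z = 0; z < nz; ++z) {
      const size_t zoff = (size_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) {
        double* oline = o + zoff + (size_t)nx * y;
        const int* s = &src[y * klen];
        for (int x = 0; x < nx; ++x) oline[x] = 0.0;
        for (int t = 0; t < klen; ++t) {
          const double wt = w[t];
          const double* iline = in + zoff + (size_t)nx * s[t];
          for (int x = 0; x < nx; ++x) oline[x] += wt * iline[x];
        }
      }
    }
  } else if (axis == 2) {
    std::vector<int> src(nz * klen);
    for (int z = 0; z < nz; ++z)
      for (int t = 0; t < klen; ++t)
        src[z * klen + t] = reflect_idx(z + t - h, nz);
    const size_t plane = (size_t)nx * ny;
    for (int z = 0; z < nz; ++z) {
      double* oplane = o + plane * z;
      const int* s = &src[z * klen];
      for (size_t i = 0; i < plane; ++i) oplane[i] = 0.0;
      for (int t = 0; t < klen; ++t) {
        const double wt = w[t];
        const double* iplane = in + plane * s[t];
        for (size_t i = 0; i < plane; ++i) oplane[i] += wt * iplane[i];
      }
    }
  } else {
    stop("axis must be 0, 1 or 2");
  }
  out.attr("dim") = dim;
  return out;
}

// Fixed hemisphere convention for axial (sign-free) orientation vectors:
// z >= 0; if z == 0 then y >= 0; if z == y == 0 then x >= 0.
static inline void hemisphere(double& x, double& y, double& z) {
  if (z < 0.0 || (z == 0.0 && (y < 0.0 || (y == 0.0 && x < 0.0)))) {
    x = -x; y = -y; z = -z;
  }
}

// Analytic eigenvalues of a symmetric 3x3 matrix (Cardano), returned in
// algebraically descending order e[0] >= e[1] >= e[2].
static inline void eig3_values(double a, double b, double c,
                               double d, double e, double f,
                               double* ev) {
  // matrix [[a, b, c], [b, d, e], [c, e, f]]
  const double p1 = b * b + c * c + e * e;
  if (p1 == 0.0) {
    ev[0] = a; ev[1] = d; ev[2] = f;
    if (ev[0] < ev[1]) std::swap(ev[0], ev[1]);
    if (ev[1] < ev[2]) std::swap(ev[1], ev[2]);
    if (ev[0] < ev[1]) std::swap(ev[0], ev[1]);
    return;
  }
  const double q = (a + d + f) / 3.0;
  const double aa = a - q, dd = d - q, ff = f - q;
  const double p2 = aa * aa + dd * dd + ff * ff + 2.0 * p1;
  const double p = std::sqrt(p2 / 6.0);
  // r = det(B) / 2 with B = (A - qI) / p
  const double ip = 1.0 / p;
  const double b00 = aa * ip, b01 = b * ip, b02 = c * ip;
  const double b11 = dd * ip, b12 = e * ip, b22 = ff * ip;
  double r = 0.5 * (b00 * (b11 * b22 - b12 * b12)
                    - b01 * (b01 * b22 - b12 * b02)
                    + b02 * (b01 * b12 - b11 * b02));
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  const double phi = std::acos(r) / 3.0;
  ev[0] = q + 2.0 * p * std::cos(phi);
  ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  ev[1] = 3.0 * q - ev[0] - ev[2];
}

// Eigenvector of [[a,b,c],[b,d,e],[c,e,f]] for eigenvalue lam via cross
// products of rows of (A - lam I); returns squared norm of the best cross
// product (0 signals failure / degeneracy).
static inline double eig3_vector(double a, double b, double c,
                                 double d, double e, double f,
                                 double lam, double* v) {
  const double r0x = a - lam, r0y = b, r0z = c;
  const double r1x = b, r1y = d - lam, r1z = e;
  const double r2x = c, r2y = e, r2z = f - lam;
  double cx[3], cy[3], cz[3], n2[3];
  cx[0] = r0y * r1z - r0z * r1y; cy[0] = r0z * r1x - r0x * r1z; cz[0] = r0x * r1y - r0y * r1x;
  cx[1] = r0y * r2z - r0z * r2y; cy[1] = r0z * r2x - r0x * r2z; cz[1] = r0x * r2y - r0y * r2x;
  cx[2] = r1y * r2z - r1z * r2y; cy[2] = r1z * r2x - r1x * r2z; cz[2] = r1x * r2y - r1y * r2x;
  int best = 0;
  for (int i = 0; i < 3; ++i) {
    n2[i] = cx[i] * cx[i] + cy[i] * cy[i] + cz[i] * cz[i];
    if (n2[i] > n2[best]) best = i;
  }
  if (n2[best] <= 0.0) return 0.0;
  const double inv = 1.0 / std::sqrt(n2[best]);
  v[0] = cx[best] * inv; v[1] = cy[best] * inv; v[2] = cz[best] * inv;
  return n2[best];
}

// Per-voxel eigenanalysis of a symmetric Hessian field. Returns eigenvalues
// sorted by increasing magnitude (|l1| <= |l2| <= |l3|) and the unit
// eigenvector of the dominant (smallest-magnitude) eigenvalue, mapped to the
// z >= 0 hemisphere. Falls back to LAPACK for degenerate voxels.
// [[Rcpp::export]]
List cpp_eig3_v1(const NumericVector& hxx, const NumericVector& hxy,
                 const NumericVector& hxz, const NumericVector& hyy,
                 const NumericVector& hyz, const NumericVector& hzz) {
  const R_xlen_t n = hxx.size();
  NumericVector l1(n), l2(n), l3(n), vx(n), vy(n), vz(n);
  arma::mat33 A;
  arma::vec3 eval;
  arma::mat33 evec;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double a = hxx[i], b = hxy[i], c = hxz[i];
    const double d = hyy[i], e = hyz[i], f = hzz[i];
    double ev[3];
    eig3_values(a, b, c, d, e, f, ev);
    // sort by |lambda|
    double s[3] = {ev[0], ev[1], ev[2]};
    if (std::fabs(s[0]) > std::fabs(s[1])) std::swap(s[0], s[1]);
    if (std::fabs(s[1]) > std::fabs(s[2])) std::swap(s[1], s[2]);
    if (std::fabs(s[0]) > std::fabs(s[1])) std::swap(s[0], s[1]);
    const double scale = std::max({std::fabs(s[0]), std::fabs(s[1]), std::fabs(s[2])});
    double v[3] = {0.0, 0.0, 1.0};
    if (scale > 0.0) {
      const double n2 = eig3_vector(a, b, c, d, e, f, s[0], v);
      // cross products are quadratic in the matrix entries; require a
      // comfortably non-degenerate null space, else use LAPACK
      if (n2 < 1e-12 * scale * scale * scale * scale) {
        A(0, 0) = a; A(0, 1) = b; A(0, 2) = c;
        A(1, 0) = b; A(1, 1) = d; A(1, 2) = e;
        A(2, 0) = c; A(2, 1) = e; A(2, 2) = f;
        arma::eig_sym(eval, evec, A);
        int k = 0;
        for (int j = 1; j < 3; ++j)
          if (std::fabs(eval(j)) < std::fabs(eval(k))) k = j;
        s[0] = eval(k);
        v[0] = evec(0, k); v[1] = evec(1, k); v[2] = evec(2, k);
        // keep magnitude ordering of the remaining two
        double rest[2];
        int m = 0;
        for (int j = 0; j < 3; ++j) if (j != k) rest[m++] = eval(j);
        if (std::fabs(rest[0]) > std::fabs(rest[1])) std::swap(rest[0], rest[1]);
        s[1] = rest[0]; s[2] = rest[1];
      }
    }
    hemisphere(v[0], v[1], v[2]);
    l1[i] = s[0]; l2[i] = s[1]; l3[i] = s[2];
    vx[i] = v[0]; vy[i] = v[1]; vz[i] = v[2];
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3,
                      _["vx"] = vx, _["vy"] = vy, _["vz"] = vz);
}

// Full per-voxel decomposition (all eigenvalues and eigenvectors) via LAPACK,
// sorted by |lambda|, eigenvectors hemisphere-normalized.
// [[Rcpp::export]]
List cpp_eig3_full(const NumericVector& hxx, const NumericVector& hxy,
                   const NumericVector& hxz, const NumericVector& hyy,
                   const NumericVector& hyz, const NumericVector& hzz) {
  const R_xlen_t n = hxx.size();
  NumericMatrix lam(n, 3);
  NumericMatrix v1(n, 3), v2(n, 3), v3(n, 3);
  arma::mat33 A;
  arma::vec3 eval;
  arma::mat33 evec;
  for (R_xlen_t i = 0; i < n; ++i) {
    A(0, 0) = hxx[i]; A(0, 1) = hxy[i]; A(0, 2) = hxz[i];
    A(1, 0) = hxy[i]; A(1, 1) = hyy[i]; A(1, 2) = hyz[i];
    A(2, 0) = hxz[i]; A(2, 1) = hyz[i]; A(2, 2) = hzz[i];
    arma::eig_sym(eval, evec, A);
    int ord[3] = {0, 1, 2};
    std::sort(ord, ord + 3, [&](int p, int q) {
      return std::fabs(eval(p)) < std::fabs(eval(q));
    });
    NumericMatrix* vs[3] = {&v1, &v2, &v3};
    for (int j = 0; j < 3; ++j) {
      lam(i, j) = eval(ord[j]);
      double x = evec(0, ord[j]), y = evec(1, ord[j]), z = evec(2, ord[j]);
      hemisphere(x, y, z);
      (*vs[j])(i, 0) = x; (*vs[j])(i, 1) = y; (*vs[j])(i, 2) = z;
    }
  }
  return List::create(_["lambda"] = lam, _["v1"] = v1, _["v2"] = v2,
                      _["v3"] = v3);
}

// ---------------------------------------------------------------------------
// Cubic B-spline prefilter (recursive, mirror boundary) and interpolation.

static const double SPLINE_POLE = -0.2679491924311227; // sqrt(3) - 2

// Whole-sample mirror (no edge repeat: s[-1] = s[1]), the boundary
// extension the recursive prefilter assumes; the interpolator must match it
// or interpolation at the data points is no longer exact near edges.
static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i = i % period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i;
}

static void bspline_prefilter_line(double* c, int n, int stride) {
  if (n < 2) return;
  const double z1 = SPLINE_POLE;
  const double gain = (1.0 - z1) * (1.0 - 1.0 / z1);
  for (int i = 0; i < n; ++i) c[i * stride] *= gain;
  // causal initialization (mirror boundary, truncated series)
  int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z1)));
  if (horizon > n) horizon = n;
  double sum = c[0];
  double zn = z1;
  for (int i = 1; i < horizon; ++i) {
    sum += zn * c[i * stride];
    zn *= z1;
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i * stride] += z1 * c[(i - 1) * stride];
  // anticausal initialization
  c[(n - 1) * stride] = (z1 / (z1 * z1 - 1.0)) *
    (c[(n - 1) * stride] + z1 * c[(n - 2) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[i * stride] = z1 * (c[(i + 1) * stride] - c[i * stride]);
}

static inline void bspline_weights(double t, double* w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// Interpolate a prefiltered 2D plane (nu x nv, u fastest) at (u, v).
static inline double bspline_sample2d(const double* c, int nu, int nv,
                                      double u, double v) {
  const int iu = (int)std::floor(u), iv = (int)std::floor(v);
  double wu[4], wv[4];
  bspline_weights(u - iu, wu);
  bspline_weights(v - iv, wv);
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) {
    const int vj = mirror_idx(iv - 1 + j, nv);
    double row = 0.0;
    for (int i = 0; i < 4; ++i) {
      const int ui = mirror_idx(iu - 1 + i, nu);
      row += wu[i] * c[ui + (size_t)nu * vj];
    }
    acc += wv[j] * row;
  }
  return acc;
}

// Rotate a 3D volume about one coordinate axis through the volume center.
// axis: 0 = x (plane y-z), 2 = z (plane x-y). Positive angles rotate content
// right-handedly about the +axis (z: +x toward +y; x: +y toward +z).
// Cubic B-spline interpolation with prefiltering; returns the resampled
// volume and a validity mask (source position inside the original grid).
// [[Rcpp::export]]
List cpp_rotate_axis(const NumericVector& vol, const IntegerVector& dim,
                     int axis, double angle_deg) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  LogicalVector valid(vol.size());
  const double th = angle_deg * M_PI / 180.0;
  const double ca = std::cos(th), sa = std::sin(th);

  int nu, nv, nslice;
  if (axis == 2) { nu = nx; nv = ny; nslice = nz; }
  else if (axis == 0) { nu = ny; nv = nz; nslice = nx; }
  else stop("axis must be 0 (x) or 2 (z)");
  const double cu = 0.5 * (nu - 1), cv = 0.5 * (nv - 1);

  std::vector<double> plane((size_t)nu * nv);
  for (int s = 0; s < nslice; ++s) {
    // gather slice
    for (int v = 0; v < nv; ++v)
      for (int u = 0; u < nu; ++u) {
        size_t idx;
        if (axis == 2) idx = (size_t)u + (size_t)nx * (v + (size_t)ny * s);
        else idx = (size_t)s + (size_t)nx * (u + (size_t)ny * v);
        plane[u + (size_t)nu * v] = vol[idx];
      }
    // prefilter along u then v
    for (int v = 0; v < nv; ++v) bspline_prefilter_line(&plane[(size_t)nu * v], nu, 1);
    for (int u = 0; u < nu; ++u) bspline_prefilter_line(&plane[u], nv, nu);
    // inverse-map sampling
    for (int v = 0; v < nv; ++v)
      for (int u = 0; u < nu; ++u) {
        const double du = u - cu, dv = v - cv;
        const double su = cu + ca * du + sa * dv;
        const double sv = cv - sa * du + ca * dv;
        const bool ok = su >= 0.0 && su <= nu - 1.0 && sv >= 0.0 && sv <= nv - 1.0;
        const double val = ok ? bspline_sample2d(plane.data(), nu, nv, su, sv) : 0.0;
        size_t idx;
        if (axis == 2) idx = (size_t)u + (size_t)nx * (v + (size_t)ny * s);
        else idx = (size_t)s + (size_t)nx * (u + (size_t)ny * v);
        out[idx] = val;
        valid[idx] = ok;
      }
  }
  out.attr("dim") = dim;
  valid.attr("dim") = dim;
  return List::create(_["volume"] = out, _["valid"] = valid);
}

// Bilinear in-plane (x, y) resampling to a new lateral grid; z untouched.
// Pixel-center coordinate mapping: src = (dst + 0.5) * n_src / n_dst - 0.5.
// [[Rcpp::export]]
NumericVector cpp_resample_lateral(const NumericVector& vol,
                                   const IntegerVector& dim,
                                   int new_nx, int new_ny) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)new_nx * new_ny * nz);
  const double fx = (double)nx / new_nx, fy = (double)ny / new_ny;
  for (int z = 0; z < nz; ++z) {
    const size_t zin = (size_t)nx * ny * z;
    const size_t zout = (size_t)new_nx * new_ny * z;
    for (int y = 0; y < new_ny; ++y) {
      double sy = (y + 0.5) * fy - 0.5;
      if (sy < 0) sy = 0;
      if (sy > ny - 1) sy = ny - 1;
      const int iy = std::min((int)std::floor(sy), ny - 2 < 0 ? 0 : ny - 2);
      const double ty = sy - iy;
      for (int x = 0; x < new_nx; ++x) {
        double sx = (x + 0.5) * fx - 0.5;
        if (sx < 0) sx = 0;
        if (sx > nx - 1) sx = nx - 1;
        const int ix = std::min((int)std::floor(sx), nx - 2 < 0 ? 0 : nx - 2);
        const double tx = sx - ix;
        const double v00 = vol[zin + ix + (size_t)nx * iy];
        const double v10 = vol[zin + std::min(ix + 1, nx - 1) + (size_t)nx * iy];
        const double v01 = vol[zin + ix + (size_t)nx * std::min(iy + 1, ny - 1)];
        const double v11 = vol[zin + std::min(ix + 1, nx - 1) +
                               (size_t)nx * std::min(iy + 1, ny - 1)];
        out[zout + x + (size_t)new_nx * y] =
          (1 - ty) * ((1 - tx) * v00 + tx * v10) + ty * ((1 - tx) * v01 + tx * v11);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(new_nx, new_ny, nz);
  return out;
}
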