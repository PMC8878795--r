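#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "rng.h"
using namespace Rcpp;

// Exact ray-grid intersection lengths (Siddon / Amanatides-Woo traversal).
// Segment p0 -> p1, isotropic voxels of size `vox`, `org` = low corner of
// voxel (0,0,0).  Emits (linear 0-based index, length mm); lengths telescope
// so their sum equals the in-grid chord length to machine precision.
template <class F>
static void traceSegment(const double *p0, const double *p1, int nx, int ny,
                         int nz, const double *org, double vox, F &&emit) {
  double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L <= 0) return;
  int dims[3] = {nx, ny, nz};
  double tmin = 0.0, tmax = 1.0;
  for (int k = 0; k < 3; ++k) {
    double lo = org[k], hi = org[k] + dims[k] * vox;
    if (std::fabs(d[k]) < 1e-14) {
      if (p0[k] < lo || p0[k] > hi) return;
    } else {
      double ta = (lo - p0[k]) / d[k], tb = (hi - p0[k]) / d[k];
      if (ta > tb) std::swap(ta, tb);
      if (ta > tmin) tmin = ta;
      if (tb < tmax) tmax = tb;
      if (tmin >= tmax) return;
    }
  }
  // starting voxel (nudge inside)
  double tstart = tmin + 1e-12 * (tmax - tmin);
  int idx[3];
  for (int k = 0; k < 3; ++k) {
    idx[k] = (int)std::floor((p0[k] + tstart * d[k] - org[k]) / vox);
    if (idx[k] < 0) idx[k] = 0;
    if (idx[k] >= dims[k]) idx[k] = dims[k] - 1;
  }
  double tNext[3], tDelta[3];
  int step[3];
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(d[k]) < 1e-14) {
      step[k] = 0;
      tNext[k] = 1e300;
      tDelta[k] = 1e300;
    } else if (d[k] > 0) {
      step[k] = 1;
      tNext[k] = (org[k] + (idx[k] + 1) * vox - p0[k]) / d[k];
      tDelta[k] = vox / d[k];
    } else {
      step[k] = -1;
      tNext[k] = (org[k] + idx[k] * vox - p0[k]) / d[k];
      tDelta[k] = -vox / d[k];
    }
  }
  double tcur = tmin;
  int guard = nx + ny + nz + 6;
  while (tcur < tmax && guard-- > 0) {
    int kmin = 0;
    if (tNext[1] < tNext[kmin]) kmin = 1;
    if (tNext[2] < tNext[kmin]) kmin = 2;
    double tstop = tNext[kmin] < tmax ? tNext[kmin] : tmax;
    double len = (tstop - tcur) * L;
    if (len > 0)
      emit((size_t)idx[2] * nx * ny + (size_t)idx[1] * nx + idx[0], len);
    tcur = tstop;
    if (tstop >= tmax) break;
    idx[kmin] += step[kmin];
    if (idx[kmin] < 0 || idx[kmin] >= dims[kmin]) break;
    tNext[kmin] += tDelta[kmin];
  }
}

// [[Rcpp::export]]
List cpp_siddon_path(NumericVector p0, NumericVector p1, IntegerVector dim,
                     NumericVector origin, double vox) {
  std::vector<double> len;
  std::vector<int> idx;
  traceSegment(REAL(p0), REAL(p1), dim[0], dim[1], dim[2], REAL(origin), vox,
               [&](size_t j, double l) {
                 idx.push_back((int)j + 1);  // 1-based for R
                 len.push_back(l);
               });
  return List::create(_["index"] = wrap(idx), _["length"] = wrap(len));
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericMatrix ep, NumericVector x,
                                  IntegerVector dim, NumericVector origin,
                                  double vox) {
  int n = ep.nrow();
  NumericVector y(n);
  const double *xp = REAL(x);
  for (int i = 0; i < n; ++i) {
    double p0[3] = {ep(i, 0), ep(i, 1), ep(i, 2)};
    double p1[3] = {ep(i, 3), ep(i, 4), ep(i, 5)};
    double acc = 0;
    traceSegment(p0, p1, dim[0], dim[1], dim[2], REAL(origin), vox,
                 [&](size_t j, double l) { acc += l * xp[j]; });
    y[i] = acc;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_back_project(NumericMatrix ep, NumericVector y,
                               IntegerVector dim, NumericVector origin,
                               double vox) {
  int n = ep.nrow();
  NumericVector x((R_xlen_t)dim[0] * dim[1] * dim[2]);
  double *xp = REAL(x);
  for (int i = 0; i < n; ++i) {
    double yi = y[i];
    if (yi == 0) continue;
    double p0[3] = {ep(i, 0), ep(i, 1), ep(i, 2)};
    double p1[3] = {ep(i, 3), ep(i, 4), ep(i, 5)};
    traceSegment(p0, p1, dim[0], dim[1], dim[2], REAL(origin), vox,
                 [&](size_t j, double l) { xp[j] += l * yi; });
  }
  return x;
}

// [[Rcpp::export]]
NumericVector cpp_ray_integral(NumericMatrix ep, NumericVector mu,
                               IntegerVector dim, NumericVector origin,
                               double vox) {
  int n = ep.nrow();
  NumericVector out(n);
  const double *mp = REAL(mu);
  for (int i = 0; i < n; ++i) {
    double p0[3] = {ep(i, 0), ep(i, 1), ep(i, 2)};
    double p1[3] = {ep(i, 3), ep(i, 4), ep(i, 5)};
    double acc = 0;
    traceSegment(p0, p1, dim[0], dim[1], dim[2], REAL(origin), vox,
                 [&](size_t j, double l) { acc += l * mp[j]; });
    out[i] = acc;
  }
  return out;
}

// Sensitivity image by uniform sampling of detector crystal pairs:
// backprojection of the attenuation factor over `nsamp` random LORs.
// [[Rcpp::export]]
NumericVector cpp_sensitivity_image(NumericMatrix centers, IntegerVector sector,
                                    int nsamp, int min_secdiff, int nsec,
                                    NumericVector mu, IntegerVector mudim,
                                    NumericVector muorigin, double muvox,
                                    IntegerVector dim, NumericVector origin,
                                    double vox, double seed) {
  int nc = centers.nrow();
  NumericVector s((R_xlen_t)dim[0] * dim[1] * dim[2]);
  double *sp = REAL(s);
  bool hasMu = mu.size() > 0;
  RNG rng;
  rng.seed((uint64_t)seed, 11);
  for (int i = 0; i < nsamp; ++i) {
    int a, b, sd;
    do {
      a = (int)(rng.unif() * nc);
      b = (int)(rng.unif() * nc);
      if (a >= nc) a = nc - 1;
      if (b >= nc) b = nc - 1;
      int ds = std::abs(sector[a] - sector[b]);
      sd = std::min(ds, nsec - ds);
    } while (a == b || sd < min_secdiff);
    double p0[3] = {centers(a, 0), centers(a, 1), centers(a, 2)};
    double p1[3] = {centers(b, 0), centers(b, 1), centers(b, 2)};
    double att = 1.0;
    if (hasMu) {
      double acc = 0;
      traceSegment(p0, p1, mudim[0], mudim[1], mudim[2], REAL(muorigin), muvox,
                   [&](size_t j, double l) { acc += l * mu[j]; });
      att = std::exp(-acc);
    }
    traceSegment(p0, p1, dim[0], dim[1], dim[2], REAL(origin), vox,
                 [&](size_t j, double l) { sp[j] += l * att; });
  }
  return s;
}

// ---- dead time --------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_dead_time(NumericVector t, IntegerVector scope, double tau_ns,
                            bool paralyzable) {
  R_xlen_t n = t.size();
  LogicalVector keep(n);
  int nscope = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (scope[i] + 1 > nscope) nscope = scope[i] + 1;
  std::vector<double> last(nscope, -1e300);
  for (R_xlen_t i = 0; i < n; ++i) {
    int s = scope[i];
    if (paralyzable) {
      keep[i] = (t[i] - last[s]) > tau_ns;
      last[s] = t[i];  // every arrival extends the dead period
    } else {
      if (t[i] >= last[s]) {
        keep[i] = true;
        last[s] = t[i] + tau_ns;
      } else {
        keep[i] = false;
      }
    }
  }
  return keep;
}

// ---- separable Gaussian blur (shared with the MLEM driver) ------------------

void blur3_inplace(double *x, int nx, int ny, int nz, double sigma_vox,
                   std::vector<double> &buf) {
  if (sigma_vox <= 0) return;
  int h = (int)std::ceil(4.0 * sigma_vox);
  std::vector<double> ker(2 * h + 1);
  double ks = 0;
  for (int k = -h; k <= h; ++k) {
    ker[k + h] = std::exp(-0.5 * k * k / (sigma_vox * sigma_vox));
    ks += ker[k + h];
  }
  for (auto &v : ker) v /= ks;
  size_t ntot = (size_t)nx * ny * nz;
  if (buf.size() < ntot) buf.resize(ntot);
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - i - 1;
    }
    return i;
  };
  // x-direction
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int q = -h; q <= h; ++q) acc += ker[q + h] * x[base + reflect(i + q, nx)];
        buf[base + i] = acc;
      }
    }
  // y-direction
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) {
        double acc = 0;
        for (int q = -h; q <= h; ++q)
          acc += ker[q + h] * buf[base + (size_t)reflect(j + q, ny) * nx];
        x[base + (size_t)j * nx] = acc;
      }
    }
  // z-direction
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)j * nx + i;
      for (int k = 0; k < nz; ++k) {
        double acc = 0;
        for (int q = -h; q <= h; ++q)
          acc += ker[q + h] * x[base + (size_t)reflect(k + q, nz) * nx * ny];
        buf[base + (size_t)k * nx * ny] = acc;
      }
      for (int k = 0; k < nz; ++k) x[base + (size_t)k * nx * ny] = buf[base + (size_t)k * nx * ny];
    }
}

// [[Rcpp::export]]
NumericVector cpp_blur3(NumericVector x, IntegerVector dim, double fwhm_mm,
                        double vox) {
  NumericVector out = clone(x);
  std::vector<double> buf;
  blur3_inplace(REAL(out), dim[0], dim[1], dim[2],
                fwhm_mm / 2.3548200450309493 / vox, buf);
  return out;
}
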