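#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

void blur3_inplace(double *x, int nx, int ny, int nz, double sigma_vox,
                   std::vector<double> &buf);

// Siddon traversal (duplicated signature from projector.cpp via template
// would need a header; a compact local copy keeps this translation unit
// self-contained).
template <class F>
static void traceSeg(const double *p0, const double *p1, int nx, int ny,
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

// MLEM / penalized-MLEM driver with an image-space Gaussian PSF applied on
// both sides of the geometric projector.  The system matrix row for LOR i is
// q_i * G_i * R  with q_i = N_i * A_i.  The quadratic-penalty variant uses a
// De Pierro separable surrogate over the 6-neighborhood (weights 1), so each
// update solves a per-voxel quadratic; beta = 0 takes the exact EM branch.
// [[Rcpp::export]]
List cpp_mlem(NumericMatrix ep, NumericVector y, NumericVector q,
              IntegerVector dim, NumericVector origin, double vox,
              NumericVector sens, double psf_fwhm_mm, int niter, double beta,
              IntegerVector snapshot_iters, double x0) {
  int nlor = ep.nrow();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  double sigma = psf_fwhm_mm / 2.3548200450309493 / vox;
  std::vector<double> buf;

  // cache the geometric projector in CSR form (float lengths)
  std::vector<size_t> rowptr(nlor + 1, 0);
  std::vector<int> col;
  std::vector<float> len;
  {
    size_t est = (size_t)nlor * (size_t)(nx + ny + nz) / 2;
    col.reserve(std::min(est, (size_t)3e8));
    len.reserve(std::min(est, (size_t)3e8));
    for (int i = 0; i < nlor; ++i) {
      double p0[3] = {ep(i, 0), ep(i, 1), ep(i, 2)};
      double p1[3] = {ep(i, 3), ep(i, 4), ep(i, 5)};
      traceSeg(p0, p1, nx, ny, nz, REAL(origin), vox, [&](size_t j, double l) {
        col.push_back((int)j);
        len.push_back((float)l);
      });
      rowptr[i + 1] = col.size();
    }
  }

  // sensitivity image: external (sampled over all LORs) or internal
  std::vector<double> s(nvox, 0.0);
  if (sens.size() == (R_xlen_t)nvox) {
    for (size_t j = 0; j < nvox; ++j) s[j] = sens[j];
  } else {
    for (int i = 0; i < nlor; ++i) {
      double qi = q[i];
      for (size_t p = rowptr[i]; p < rowptr[i + 1]; ++p)
        s[col[p]] += qi * len[p];
    }
    blur3_inplace(s.data(), nx, ny, nz, sigma, buf);
  }

  std::vector<double> x(nvox, x0), xb(nvox), bp(nvox);
  NumericVector loglik(niter);
  List snaps;
  std::vector<int> snapIters(snapshot_iters.begin(), snapshot_iters.end());

  for (int it = 0; it < niter; ++it) {
    // forward: yhat_i = q_i * <G_i, R x>
    for (size_t j = 0; j < nvox; ++j) xb[j] = x[j];
    blur3_inplace(xb.data(), nx, ny, nz, sigma, buf);
    std::fill(bp.begin(), bp.end(), 0.0);
    double ll = 0;
    for (int i = 0; i < nlor; ++i) {
      double acc = 0;
      for (size_t p = rowptr[i]; p < rowptr[i + 1]; ++p)
        acc += (double)len[p] * xb[col[p]];
      double yh = q[i] * acc;
      if (yh > 0) {
        if (y[i] > 0) ll += y[i] * std::log(yh);
        ll -= yh;
        double r = y[i] / yh * q[i];
        if (r != 0)
          for (size_t p = rowptr[i]; p < rowptr[i + 1]; ++p)
            bp[col[p]] += (double)len[p] * r;
      }
    }
    loglik[it] = ll;
    blur3_inplace(bp.data(), nx, ny, nz, sigma, buf);

    if (beta <= 0) {
      for (size_t j = 0; j < nvox; ++j)
        x[j] = s[j] > 0 ? x[j] * bp[j] / s[j] : 0.0;
    } else {
      // De Pierro surrogate: beta*W*x^2 + (s - beta*M)*x - c = 0
      std::vector<double> xold(x);
      for (int kz = 0; kz < nz; ++kz)
        for (int jy = 0; jy < ny; ++jy)
          for (int ix = 0; ix < nx; ++ix) {
            size_t j = (size_t)kz * nx * ny + (size_t)jy * nx + ix;
            if (s[j] <= 0) { x[j] = 0; continue; }
            double c = xold[j] * bp[j];
            double M = 0;
            int W = 0;
            const int off[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                                   {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
            for (int q6 = 0; q6 < 6; ++q6) {
              int ii = ix + off[q6][0], jj = jy + off[q6][1], kk = kz + off[q6][2];
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              size_t nb = (size_t)kk * nx * ny + (size_t)jj * nx + ii;
              M += 0.5 * (xold[j] + xold[nb]);
              ++W;
            }
            double A = beta * W;
            double B = s[j] - beta * M;
            // stable root of A x^2 + B x - c = 0 (exact EM limit as A -> 0)
            x[j] = c <= 0 ? 0.0
                          : 2.0 * c / (B + std::sqrt(B * B + 4.0 * A * c));
          }
    }
    for (int si : snapIters)
      if (si == it + 1) {
        NumericVector xi(nvox);
        for (size_t j = 0; j < nvox; ++j) xi[j] = x[j];
        snaps.push_back(xi, std::string("iter") + std::to_string(si));
      }
  }

  NumericVector xout(nvox), sout(nvox);
  for (size_t j = 0; j < nvox; ++j) {
    xout[j] = x[j];
    sout[j] = s[j];
  }
  return List::create(_["x"] = xout, _["loglik"] = loglik,
                      _["snapshots"] = snaps, _["sens"] = sout);
}
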