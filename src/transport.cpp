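#include <Rcpp.h>
#include <algorithm>
#include "rng.h"
#include "scanner.h"
using namespace Rcpp;

static const double C_MM_PER_NS = 299.792458;
static const double E511 = 511.0;

// ---- photon physics helpers -------------------------------------------------

// Klein-Nishina total cross-section shape (per electron, Thomson units dropped)
static double knTotal(double alpha) {
  double a = alpha;
  double l = std::log(1.0 + 2.0 * a);
  return (1.0 + a) / (a * a) * (2.0 * (1.0 + a) / (1.0 + 2.0 * a) - l / a) +
         l / (2.0 * a) - (1.0 + 3.0 * a) / ((1.0 + 2.0 * a) * (1.0 + 2.0 * a));
}
static const double KN511 = knTotal(1.0);
static inline double knRatio(double E) { return knTotal(E / E511) / KN511; }

// Sample cos(theta) from the Klein-Nishina differential cross-section by
// rejection with a uniform envelope (g <= 2 for all angles and energies).
static inline double sampleKNcos(RNG &rng, double alpha) {
  for (;;) {
    double mu = 2.0 * rng.unif() - 1.0;
    double P = 1.0 / (1.0 + alpha * (1.0 - mu));
    double g = P * P * (P + 1.0 / P - (1.0 - mu * mu));
    if (2.0 * rng.unif() <= g) return mu;
  }
}

static inline void rotateDirection(double *d, double cosT, double phi) {
  double sinT = std::sqrt(std::max(0.0, 1.0 - cosT * cosT));
  // orthonormal basis perpendicular to d
  double ax[3] = {0, 0, 0};
  if (std::fabs(d[0]) <= std::fabs(d[1]) && std::fabs(d[0]) <= std::fabs(d[2])) ax[0] = 1;
  else if (std::fabs(d[1]) <= std::fabs(d[2])) ax[1] = 1;
  else ax[2] = 1;
  double e1[3] = {d[1] * ax[2] - d[2] * ax[1], d[2] * ax[0] - d[0] * ax[2],
                  d[0] * ax[1] - d[1] * ax[0]};
  double n = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int k = 0; k < 3; ++k) e1[k] /= n;
  double e2[3] = {d[1] * e1[2] - d[2] * e1[1], d[2] * e1[0] - d[0] * e1[2],
                  d[0] * e1[1] - d[1] * e1[0]};
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int k = 0; k < 3; ++k)
    d[k] = cosT * d[k] + sinT * (cp * e1[k] + sp * e2[k]);
  n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  for (int k = 0; k < 3; ++k) d[k] /= n;
}

static inline void isotropicDir(RNG &rng, double *d) {
  double z = 2.0 * rng.unif() - 1.0;
  double phi = 2.0 * M_PI * rng.unif();
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  d[0] = r * std::cos(phi);
  d[1] = r * std::sin(phi);
  d[2] = z;
}

// ---- physics configuration --------------------------------------------------

struct Physics {
  double eres;        // fractional FWHM at 511 keV
  double noncolDeg;   // acollinearity FWHM, degrees
  double prangeFwhm;  // positron range FWHM, mm (per-axis Gaussian)
  double muPe511;     // LYSO photoelectric mu at 511 keV, mm^-1
  double muC511;      // LYSO Compton mu at 511 keV, mm^-1
  double threshold;   // singles low-energy threshold, keV (post blur)
  int simpleMode;     // 1: first-interaction full-absorption detector
  double ecut;        // photon termination energy, keV
  int maxChain;
  inline double muPe(double E) const {
    double r = E511 / E;
    return muPe511 * r * r * r;
  }
  inline double muC(double E) const { return muC511 * knRatio(E); }
  inline double muTot(double E) const { return muPe(E) + muC(E); }
  inline double esigma(double E) const {
    // resolution scales as 1/sqrt(E), anchored at eres @ 511 keV
    return eres * std::sqrt(E511 * E) / 2.3548200450309493;
  }
};

static Physics physFromVec(const double *p) {
  Physics ph;
  ph.eres = p[0];
  ph.noncolDeg = p[1];
  ph.prangeFwhm = p[2];
  ph.muPe511 = p[3];
  ph.muC511 = p[4];
  ph.threshold = p[5];
  ph.simpleMode = (int)p[6];
  ph.ecut = p[7];
  ph.maxChain = (int)p[8];
  return ph;
}

// ---- attenuation grid -------------------------------------------------------

struct MuGrid {
  const double *v = nullptr;
  int nx = 0, ny = 0, nz = 0;
  double ox = 0, oy = 0, oz = 0, vox = 1;
  double mumax = 0;
  bool empty() const { return v == nullptr || mumax <= 0; }
  inline double at(double x, double y, double z) const {
    int i = (int)std::floor((x - ox) / vox);
    int j = (int)std::floor((y - oy) / vox);
    int k = (int)std::floor((z - oz) / vox);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
    return v[(size_t)k * nx * ny + (size_t)j * nx + i];
  }
  bool boxIntersect(const double p[3], const double d[3], double &t0, double &t1) const {
    t0 = 0.0;
    t1 = 1e300;
    double lo[3] = {ox, oy, oz};
    double hi[3] = {ox + nx * vox, oy + ny * vox, oz + nz * vox};
    for (int k = 0; k < 3; ++k) {
      if (std::fabs(d[k]) < 1e-12) {
        if (p[k] < lo[k] || p[k] > hi[k]) return false;
      } else {
        double ta = (lo[k] - p[k]) / d[k], tb = (hi[k] - p[k]) / d[k];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 >= t1) return false;
      }
    }
    return t1 > 0.0;
  }
};

// Woodcock tracking through the voxelized attenuation map.
// Returns false if the photon was absorbed (terminated below ecut).
// pos/dir/E/flight are updated in place; nscat counts Compton interactions.
static bool phantomStage(const MuGrid &g, const Physics &ph, RNG &rng,
                         double *pos, double *dir, double &E, double &flight,
                         int &nscat) {
  if (g.empty()) return true;
  for (;;) {
    double t0, t1;
    if (!g.boxIntersect(pos, dir, t0, t1)) return true;  // escaped
    double kr = knRatio(E);
    double mumaj = g.mumax * kr;
    double t = t0;
    bool interacted = false;
    for (;;) {
      t += rng.expdev() / mumaj;
      if (t >= t1) break;
      double px = pos[0] + t * dir[0], py = pos[1] + t * dir[1],
             pz = pos[2] + t * dir[2];
      double mul = g.at(px, py, pz) * kr;
      if (rng.unif() * mumaj <= mul) {
        // Compton scatter (photoelectric negligible in soft materials here)
        pos[0] = px; pos[1] = py; pos[2] = pz;
        flight += t;
        ++nscat;
        double alpha = E / E511;
        double cosT = sampleKNcos(rng, alpha);
        E = E / (1.0 + alpha * (1.0 - cosT));
        rotateDirection(dir, cosT, 2.0 * M_PI * rng.unif());
        if (E < ph.ecut) return false;  // absorbed
        interacted = true;
        break;
      }
    }
    if (!interacted) return true;  // crossed the grid without interaction
  }
}

// ---- detector stage ---------------------------------------------------------

struct Deposit {
  int crystal;
  double e;
  double flight;  // flight path at (first) interaction in this crystal, mm
};

// Track a photon through the crystal ring; per-crystal energy deposits are
// accumulated (detector-side Compton chains allowed unless simpleMode).
static int detectorStage(const Scanner &sc, const Physics &ph, RNG &rng,
                         const double *pos0, const double *dir0, double E0,
                         double flight0, Deposit *dep, int maxDep) {
  double pos[3] = {pos0[0], pos0[1], pos0[2]};
  double dir[3] = {dir0[0], dir0[1], dir0[2]};
  double E = E0, flight = flight0;
  int nd = 0;
  Scanner::Interval iv[64];
  for (int chain = 0; chain < ph.maxChain; ++chain) {
    int niv = sc.intervals(pos, dir, iv);
    if (niv == 0) break;
    double mumaj = ph.muTot(E);
    bool interacted = false;
    double tHit = 0;
    int secHit = -1;
    for (int q = 0; q < niv && !interacted; ++q) {
      double t = iv[q].t0;
      for (;;) {
        t += rng.expdev() / mumaj;
        if (t >= iv[q].t1) break;
        double px = pos[0] + t * dir[0], py = pos[1] + t * dir[1],
               pz = pos[2] + t * dir[2];
        double u, v;
        sc.toLocal(iv[q].sec, px, py, u, v);
        if (sc.inLyso(u, v, pz)) {  // mu_local = mumaj inside, 0 in gaps
          interacted = true;
          tHit = t;
          secHit = iv[q].sec;
          break;
        }
      }
    }
    if (!interacted) break;  // escaped the ring
    double px = pos[0] + tHit * dir[0], py = pos[1] + tHit * dir[1],
           pz = pos[2] + tHit * dir[2];
    double u, v;
    sc.toLocal(secHit, px, py, u, v);
    int crys = sc.assign(secHit, u, v, pz);
    if (crys < 0) break;  // should not happen (gap rejected above)
    flight += tHit;
    pos[0] = px; pos[1] = py; pos[2] = pz;

    double edep;
    bool stop = false;
    if (ph.simpleMode) {
      edep = E;
      stop = true;
    } else {
      double ppe = ph.muPe(E) / ph.muTot(E);
      if (rng.unif() < ppe) {
        edep = E;  // photoelectric absorption
        stop = true;
      } else {
        double alpha = E / E511;
        double cosT = sampleKNcos(rng, alpha);
        double Enew = E / (1.0 + alpha * (1.0 - cosT));
        edep = E - Enew;
        E = Enew;
        rotateDirection(dir, cosT, 2.0 * M_PI * rng.unif());
        if (E < ph.ecut) {  // deposit the remainder locally
          edep += E;
          stop = true;
        }
      }
    }
    // merge into an existing deposit for the same crystal
    int slot = -1;
    for (int k = 0; k < nd; ++k)
      if (dep[k].crystal == crys) { slot = k; break; }
    if (slot < 0) {
      if (nd < maxDep) {
        dep[nd].crystal = crys;
        dep[nd].e = edep;
        dep[nd].flight = flight;
        ++nd;
      }
    } else {
      dep[slot].e += edep;
    }
    if (stop) break;
  }
  return nd;
}

// ---- shape primitives -------------------------------------------------------
// columns of the primitive matrix:
// kind (1 cyl-z, 2 sphere, 3 box, 5 point), cx, cy, cz, d1, d2, d3, rate_bq
struct Prim {
  int kind;
  double c[3], d1, d2, d3, rate;
  bool contains(const double *p) const {
    double dx = p[0] - c[0], dy = p[1] - c[1], dz = p[2] - c[2];
    switch (kind) {
      case 1:  // cylinder along z: d1 radius, d2 height
        return (dx * dx + dy * dy <= d1 * d1) && std::fabs(dz) <= 0.5 * d2;
      case 2:
        return dx * dx + dy * dy + dz * dz <= d1 * d1;
      case 3:
        return std::fabs(dx) <= 0.5 * d1 && std::fabs(dy) <= 0.5 * d2 &&
               std::fabs(dz) <= 0.5 * d3;
      case 5:
        return false;  // zero-measure
      default:
        return false;
    }
  }
  void sample(RNG &rng, double *p) const {
    switch (kind) {
      case 1: {
        double r = d1 * std::sqrt(rng.unif());
        double a = 2.0 * M_PI * rng.unif();
        p[0] = c[0] + r * std::cos(a);
        p[1] = c[1] + r * std::sin(a);
        p[2] = c[2] + (rng.unif() - 0.5) * d2;
        break;
      }
      case 2: {
        double dd[3];
        isotropicDir(rng, dd);
        double r = d1 * std::cbrt(rng.unif());
        for (int k = 0; k < 3; ++k) p[k] = c[k] + r * dd[k];
        break;
      }
      case 3:
        p[0] = c[0] + (rng.unif() - 0.5) * d1;
        p[1] = c[1] + (rng.unif() - 0.5) * d2;
        p[2] = c[2] + (rng.unif() - 0.5) * d3;
        break;
      default:
        for (int k = 0; k < 3; ++k) p[k] = c[k];
    }
  }
};

// ---- main simulation driver -------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix prims, double duration, NumericVector geomp,
                  NumericVector phys, double seed, NumericVector muvec,
                  IntegerVector mudim, NumericVector muorigin, double muvox) {
  Scanner sc = scannerFromParams(REAL(geomp));
  Physics ph = physFromVec(REAL(phys));
  MuGrid grid;
  if (muvec.size() > 0) {
    grid.v = REAL(muvec);
    grid.nx = mudim[0];
    grid.ny = mudim[1];
    grid.nz = mudim[2];
    grid.ox = muorigin[0];
    grid.oy = muorigin[1];
    grid.oz = muorigin[2];
    grid.vox = muvox;
    double m = 0;
    for (R_xlen_t i = 0; i < muvec.size(); ++i)
      if (muvec[i] > m) m = muvec[i];
    grid.mumax = m;
  }

  int np = prims.nrow();
  std::vector<Prim> P(np);
  double totRate = 0;
  std::vector<double> cum(np);
  for (int i = 0; i < np; ++i) {
    P[i].kind = (int)prims(i, 0);
    P[i].c[0] = prims(i, 1);
    P[i].c[1] = prims(i, 2);
    P[i].c[2] = prims(i, 3);
    P[i].d1 = prims(i, 4);
    P[i].d2 = prims(i, 5);
    P[i].d3 = prims(i, 6);
    P[i].rate = prims(i, 7);
    totRate += P[i].rate;
    cum[i] = totRate;
  }

  RNG master;
  master.seed((uint64_t)seed, 0);
  long nCand = totRate > 0 ? master.poisson(totRate * duration) : 0;

  std::vector<double> s_t, s_e;
  std::vector<int> s_id, s_ev;
  std::vector<signed char> s_sc, s_ph;
  size_t reserve0 = (size_t)std::min((double)nCand, 4e7);
  s_t.reserve(reserve0);
  s_e.reserve(reserve0);
  s_id.reserve(reserve0);
  s_ev.reserve(reserve0);

  long nAccepted = 0;
  Deposit dep[64];

  for (long i = 0; i < nCand; ++i) {
    RNG rng;
    rng.seed((uint64_t)seed + 0x51ED270C5ULL, (uint64_t)(i + 1));
    // choose a primitive by activity share
    double r = rng.unif() * totRate;
    int pi = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
    if (pi >= np) pi = np - 1;
    double pt[3];
    P[pi].sample(rng, pt);
    // later primitives override earlier ones: thinning
    bool overridden = false;
    for (int j = pi + 1; j < np; ++j)
      if (P[j].contains(pt)) { overridden = true; break; }
    if (overridden) continue;
    long ev = nAccepted++;
    double tdec_ns = rng.unif() * duration * 1e9;

    // annihilation point: positron range as per-axis Gaussian
    double apos[3] = {pt[0], pt[1], pt[2]};
    if (ph.prangeFwhm > 0) {
      double sg = ph.prangeFwhm / 2.3548200450309493;
      for (int k = 0; k < 3; ++k) apos[k] += sg * rng.normal();
    }
    double d1[3], d2[3];
    isotropicDir(rng, d1);
    for (int k = 0; k < 3; ++k) d2[k] = -d1[k];
    if (ph.noncolDeg > 0) {
      double sg = ph.noncolDeg * M_PI / 180.0 / 2.3548200450309493;
      double dev = std::fabs(sg * rng.normal());
      rotateDirection(d2, std::cos(dev), 2.0 * M_PI * rng.unif());
    }

    for (int phn = 0; phn < 2; ++phn) {
      double pos[3] = {apos[0], apos[1], apos[2]};
      double dir[3] = {phn == 0 ? d1[0] : d2[0], phn == 0 ? d1[1] : d2[1],
                       phn == 0 ? d1[2] : d2[2]};
      double E = E511, flight = 0;
      int nscat = 0;
      if (!phantomStage(grid, ph, rng, pos, dir, E, flight, nscat)) continue;
      int nd = detectorStage(sc, ph, rng, pos, dir, E, flight, dep, 64);
      for (int k = 0; k < nd; ++k) {
        double eb = dep[k].e + ph.esigma(dep[k].e) * rng.normal();
        if (eb < ph.threshold) continue;
        s_t.push_back(tdec_ns + dep[k].flight / C_MM_PER_NS);
        s_e.push_back(eb);
        s_id.push_back(dep[k].crystal);
        s_ev.push_back((int)ev);
        s_sc.push_back((signed char)(nscat > 0 ? 1 : 0));
        s_ph.push_back((signed char)phn);
      }
    }
  }

  // time-order the singles stream
  size_t n = s_t.size();
  std::vector<size_t> idx(n);
  for (size_t i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](size_t a, size_t b) { return s_t[a] < s_t[b]; });

  NumericVector ot(n), oe(n);
  IntegerVector oid(n), oev(n), osc(n), oph(n);
  for (size_t i = 0; i < n; ++i) {
    size_t j = idx[i];
    ot[i] = s_t[j];
    oe[i] = s_e[j];
    oid[i] = s_id[j];
    oev[i] = s_ev[j];
    osc[i] = s_sc[j];
    oph[i] = s_ph[j];
  }
  return List::create(_["t_ns"] = ot, _["flat_id"] = oid, _["energy"] = oe,
                      _["event_id"] = oev, _["scattered"] = osc,
                      _["photon"] = oph, _["n_decays"] = (double)nAccepted,
                      _["n_candidates"] = (double)nCand,
                      _["total_rate"] = totRate);
}

// ---- exported helpers for unit tests ---------------------------------------

// [[Rcpp::export]]
NumericVector cpp_sample_kn(int n, double energy_kev, double seed) {
  RNG rng;
  rng.seed((uint64_t)seed, 7);
  double alpha = energy_kev / E511;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sampleKNcos(rng, alpha);
  return out;
}

// [[Rcpp::export]]
double cpp_kn_total_ratio(double energy_kev) { return knRatio(energy_kev); }

// [[Rcpp::export]]
List cpp_emit_pairs(int n, double noncol_deg, double prange_fwhm, double seed) {
  RNG rng;
  rng.seed((uint64_t)seed, 3);
  NumericMatrix D1(n, 3), D2(n, 3), DS(n, 3);
  double sgr = noncol_deg * M_PI / 180.0 / 2.3548200450309493;
  double sgp = prange_fwhm / 2.3548200450309493;
  for (int i = 0; i < n; ++i) {
    double d1[3], d2[3];
    isotropicDir(rng, d1);
    for (int k = 0; k < 3; ++k) d2[k] = -d1[k];
    if (noncol_deg > 0) {
      double dev = std::fabs(sgr * rng.normal());
      rotateDirection(d2, std::cos(dev), 2.0 * M_PI * rng.unif());
    }
    for (int k = 0; k < 3; ++k) {
      D1(i, k) = d1[k];
      D2(i, k) = d2[k];
      DS(i, k) = prange_fwhm > 0 ? sgp * rng.normal() : 0.0;
    }
  }
  return List::create(_["d1"] = D1, _["d2"] = D2, _["displacement"] = DS);
}

// [[Rcpp::export]]
List cpp_aimed_photons(NumericVector geomp, NumericVector phys,
                       NumericVector origin, NumericVector dir, double energy,
                       int n, double seed) {
  Scanner sc = scannerFromParams(REAL(geomp));
  Physics ph = physFromVec(REAL(phys));
  double d[3] = {dir[0], dir[1], dir[2]};
  double nn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  for (int k = 0; k < 3; ++k) d[k] /= nn;
  double p[3] = {origin[0], origin[1], origin[2]};
  IntegerVector nsing(n);
  NumericVector emax(n);
  Deposit dep[64];
  for (int i = 0; i < n; ++i) {
    RNG rng;
    rng.seed((uint64_t)seed + 0xA1B2ULL, (uint64_t)(i + 1));
    int nd = detectorStage(sc, ph, rng, p, d, energy, 0.0, dep, 64);
    int ns = 0;
    double em = 0;
    for (int k = 0; k < nd; ++k) {
      double eb = dep[k].e + ph.esigma(dep[k].e) * rng.normal();
      if (eb >= ph.threshold) {
        ++ns;
        if (eb > em) em = eb;
      }
    }
    nsing[i] = ns;
    emax[i] = em;
  }
  return List::create(_["n_singles"] = nsing, _["e_max"] = emax);
}

// [[Rcpp::export]]
List cpp_phantom_escape(NumericVector muvec, IntegerVector mudim,
                        NumericVector muorigin, double muvox,
                        NumericVector origin, NumericVector dir, double energy,
                        int n, double seed, double ecut) {
  MuGrid grid;
  grid.v = REAL(muvec);
  grid.nx = mudim[0];
  grid.ny = mudim[1];
  grid.nz = mudim[2];
  grid.ox = muorigin[0];
  grid.oy = muorigin[1];
  grid.oz = muorigin[2];
  grid.vox = muvox;
  double m = 0;
  for (R_xlen_t i = 0; i < muvec.size(); ++i)
    if (muvec[i] > m) m = muvec[i];
  grid.mumax = m;
  Physics ph;
  ph.ecut = ecut;
  int unscattered = 0, escaped = 0;
  double nn = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
  for (int i = 0; i < n; ++i) {
    RNG rng;
    rng.seed((uint64_t)seed + 0xC3D4ULL, (uint64_t)(i + 1));
    double pos[3] = {origin[0], origin[1], origin[2]};
    double d[3] = {dir[0] / nn, dir[1] / nn, dir[2] / nn};
    double E = energy, fl = 0;
    int nsc = 0;
    if (phantomStage(grid, ph, rng, pos, d, E, fl, nsc)) {
      ++escaped;
      if (nsc == 0) ++unscattered;
    }
  }
  return List::create(_["escaped"] = escaped, _["unscattered"] = unscattered);
}

// [[Rcpp::export]]
NumericMatrix cpp_crystal_centers(NumericVector geomp) {
  Scanner sc = scannerFromParams(REAL(geomp));
  int n = sc.nCrystals();
  NumericMatrix out(n, 3);
  double xyz[3];
  for (int i = 0; i < n; ++i) {
    sc.center(i, xyz);
    out(i, 0) = xyz[0];
    out(i, 1) = xyz[1];
    out(i, 2) = xyz[2];
  }
  return out;
}
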